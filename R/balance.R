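#' Per-pixel carbon balance
#'
#' Combines the stock and flux terms: CB = CS + NEP * dt, with NEP converted
#' from g C m^-2 yr^-1 to Mg/hm^2 yr^-1 (factor 0.01) so both terms share
#' the stock unit.  Values may be negative (net-source pixels on low-stock
#' land).
#'
#' @param cs_density carbon-storage density grid, Mg/hm^2.
#' @param nep_grid NEP grid, g C m^-2 yr^-1.
#' @param delta_t accumulation interval in years (default 1).
#' @return carbon-balance `tercab_grid`, Mg/hm^2.
#' @export
carbon_balance <- function(cs_density, nep_grid, delta_t = 1) {
  stopifnot(delta_t > 0)
  assert_coregistered(cs_density, nep_grid)
  grid_like(as.vector(cs_density$values + 0.01 * nep_grid$values * delta_t),
            cs_density)
}

#' Interannual carbon-balance summaries
#'
#' Per-year regional totals (Tg) and means (Mg/hm^2), per-class per-year
#' means on that year's land cover, and piecewise rates of change (OLS
#' slopes of the yearly series over user-chosen windows, in units per
#' year).
#'
#' @param cb_stack carbon-balance `tercab_stack`, Mg/hm^2.
#' @param lulc_stack class-coded `tercab_stack` on the same years/geometry.
#' @param pixel_area_hm2 pixel area in hm^2.
#' @param windows optional list of `c(start_year, end_year)` windows for
#'   piecewise slopes.
#' @return list: `yearly` (data frame year, total_Tg, mean_Mg_hm2),
#'   `per_class` (class x year matrix of means), `window_rates` (data frame
#'   start, end, mean_rate, total_rate).
#' @export
interannual_summary <- function(cb_stack, lulc_stack, pixel_area_hm2 = 1,
                                windows = NULL) {
  stopifnot(inherits(cb_stack, "tercab_stack"), inherits(lulc_stack, "tercab_stack"))
  if (!identical(cb_stack$years, lulc_stack$years))
    stop("cb and lulc stacks cover different years", call. = FALSE)
  assert_coregistered(cb_stack$grids[[1]], lulc_stack$grids[[1]])
  years <- cb_stack$years
  classes <- lulc_classes()
  yearly <- data.frame(year = years, total_Tg = NA_real_, mean_Mg_hm2 = NA_real_)
  per_class <- matrix(NA_real_, length(classes), length(years),
                      dimnames = list(names(classes), years))
  for (k in seq_along(years)) {
    cb <- as.vector(cb_stack$grids[[k]]$values)
    cl <- as.vector(lulc_stack$grids[[k]]$values)
    ok <- !is.na(cb)
    yearly$total_Tg[k] <- sum(cb[ok]) * pixel_area_hm2 * 1e-6
    yearly$mean_Mg_hm2[k] <- mean(cb[ok])
    mns <- tapply(cb[ok & !is.na(cl)], factor(cl[ok & !is.na(cl)], levels = classes), mean)
    per_class[, k] <- as.numeric(mns)
  }
  window_rates <- NULL
  if (!is.null(windows)) {
    window_rates <- do.call(rbind, lapply(windows, function(w) {
      if (w[1] < min(years) || w[2] > max(years) || w[1] >= w[2])
        stop("window ", w[1], "-", w[2], " outside year range", call. = FALSE)
      sel <- years >= w[1] & years <= w[2]
      data.frame(start = w[1], end = w[2],
                 mean_rate = theta_slope(yearly$mean_Mg_hm2[sel]),
                 total_rate = theta_slope(yearly$total_Tg[sel]))
    }))
  }
  list(yearly = yearly, per_class = per_class, window_rates = window_rates)
}
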