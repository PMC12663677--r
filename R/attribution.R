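#' Fit the climate regression for one pixel
#'
#' Least-squares fit of the observed carbon-balance series on temperature
#' and precipitation, CB_CC = a*T + b*P + c.  The residual series
#' CB_HA = CB_obs - CB_CC is the human-activity component.  Solved in
#' closed form from the centred normal equations; a rank-deficient design
#' (constant T and P, or T collinear with P) leaves the pixel flagged.
#'
#' @param cb observed carbon-balance series, Mg/hm^2.
#' @param T_c temperature series, degrees C.
#' @param P_m precipitation series, metres.
#' @return list with `a`, `b`, `c`, `cb_cc` (fitted series), `cb_ha`
#'   (residual series), `ok` (FALSE when rank-deficient).
#' @export
fit_climate_model <- function(cb, T_c, P_m) {
  n <- length(cb)
  if (length(T_c) != n || length(P_m) != n) stop("series lengths differ", call. = FALSE)
  if (n < 4L) stop("need at least 4 years to fit a + b + c", call. = FALSE)
  dt <- T_c - mean(T_c); dp <- P_m - mean(P_m); dc <- cb - mean(cb)
  stt <- sum(dt^2); spp <- sum(dp^2); stp <- sum(dt * dp)
  det <- stt * spp - stp^2
  scale <- stt * spp
  if (scale == 0 || det <= 1e-12 * scale) {
    return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                cb_cc = rep(NA_real_, n), cb_ha = rep(NA_real_, n), ok = FALSE))
  }
  sct <- sum(dc * dt); scp <- sum(dc * dp)
  a <- (spp * sct - stp * scp) / det
  b <- (stt * scp - stp * sct) / det
  c0 <- mean(cb) - a * mean(T_c) - b * mean(P_m)
  cc <- a * T_c + b * P_m + c0
  list(a = a, b = b, c = c0, cb_cc = cc, cb_ha = cb - cc, ok = TRUE)
}

#' Driver scenarios and their labels
#' @return character vector naming scenario codes 1..4.
#' @export
driver_labels <- function() c("CC&HA", "CC", "HA", "no-change")

#' Classify drivers of a carbon-balance trend
#'
#' Applies the slope-sign criterion table: with an improving balance
#' (slope_obs > 0), both component slopes positive means climate and human
#' drivers share the change in proportion to their slopes
#' (100 * slope_cc / slope_obs and 100 * slope_ha / slope_obs); a negative
#' human slope attributes 100 percent to climate, a negative climate slope
#' 100 percent to human activity.  The mirrored rules apply under a
#' degrading balance (slope_obs < 0).  Mixed-scenario ratios are clipped to
#' [0, 100] (slopes can nearly cancel).  |slope_obs| below `tol` is the
#' undefined "no-change" scenario.
#'
#' @param slope_obs,slope_cc,slope_ha slopes of the observed, climate and
#'   residual series (vectors recycled together).
#' @param tol no-change tolerance on |slope_obs| (default 1e-12).
#' @return list of vectors: `scenario` (1 = CC&HA, 2 = CC, 3 = HA,
#'   4 = no-change), `contrib_cc`, `contrib_ha` (percent),
#'   `direction` (+1 improved, -1 degraded, 0 none), `clipped` (logical).
#' @export
classify_driver <- function(slope_obs, slope_cc, slope_ha, tol = 1e-12) {
  k <- max(length(slope_obs), length(slope_cc), length(slope_ha))
  so <- rep_len(slope_obs, k); sc <- rep_len(slope_cc, k); sh <- rep_len(slope_ha, k)
  scenario <- rep(NA_integer_, k)
  cc <- ha <- rep(NA_real_, k)
  ok <- !is.na(so) & !is.na(sc) & !is.na(sh)
  none <- ok & abs(so) < tol
  scenario[none] <- 4L
  # component slopes that are numerical dust relative to the observed slope
  # (e.g. the residual of an exact climate fit) are snapped to zero so they
  # fall into the single-driver rows instead of a degenerate ratio
  snap <- tol + 1e-9 * abs(so)
  sc[ok & abs(sc) < snap] <- 0
  sh[ok & abs(sh) < snap] <- 0
  up <- ok & !none & so > 0
  dn <- ok & !none & so < 0
  mixed <- (up & sc > 0 & sh > 0) | (dn & sc < 0 & sh < 0)
  cc_only <- (up & sc > 0 & sh <= 0) | (dn & sc < 0 & sh >= 0)
  ha_only <- (up | dn) & !mixed & !cc_only
  scenario[mixed] <- 1L; scenario[cc_only] <- 2L; scenario[ha_only] <- 3L
  raw_cc <- 100 * sc[mixed] / so[mixed]
  raw_ha <- 100 * sh[mixed] / so[mixed]
  cc[mixed] <- pmin(pmax(raw_cc, 0), 100)
  ha[mixed] <- pmin(pmax(raw_ha, 0), 100)
  clipped <- rep(FALSE, k)
  clipped[mixed] <- raw_cc < 0 | raw_cc > 100 | raw_ha < 0 | raw_ha > 100
  cc[cc_only] <- 100; ha[cc_only] <- 0
  cc[ha_only] <- 0;  ha[ha_only] <- 100
  direction <- rep(NA_real_, k)
  direction[up] <- 1; direction[dn] <- -1; direction[none] <- 0
  list(scenario = scenario, contrib_cc = cc, contrib_ha = ha,
       direction = direction, clipped = clipped)
}

#' Bin a contribution rate into five 20-percent levels
#'
#' Bins are left-closed: [0,20), [20,40), [40,60), [60,80), [80,100].
#'
#' @param contrib contribution rate(s) in percent, within [0, 100].
#' @return integer level 1..5 (`NA` propagates).
#' @export
contribution_levels <- function(contrib) {
  ok <- !is.na(contrib)
  if (any(contrib[ok] < 0 | contrib[ok] > 100))
    stop("contribution rate outside [0, 100]", call. = FALSE)
  lv <- rep(NA_integer_, length(contrib))
  lv[ok] <- pmin(contrib[ok] %/% 20 + 1L, 5L)
  as.integer(lv)
}

#' Per-pixel residual-trend attribution over a scene
#'
#' For every complete pixel: fit the climate regression, compute the
#' slopes of the observed, fitted and residual series, classify the driver
#' scenario, and derive contribution rates and 20-percent levels.
#'
#' @param cb_stack observed carbon-balance stack.
#' @param t_stack,p_stack temperature and precipitation stacks (same years,
#'   same geometry).
#' @param tol no-change tolerance passed to [classify_driver()].
#' @return list of grids: `a`, `b`, `c`, `slope_obs`, `slope_cc`,
#'   `slope_ha`, `scenario`, `contrib_cc`, `contrib_ha`, `direction`,
#'   `level_cc`, `level_ha`.
#' @export
attribution_stack <- function(cb_stack, t_stack, p_stack, tol = 1e-12) {
  stopifnot(identical(cb_stack$years, t_stack$years),
            identical(cb_stack$years, p_stack$years))
  assert_coregistered(cb_stack$grids[[1]], t_stack$grids[[1]], p_stack$grids[[1]])
  CB <- stack_matrix(cb_stack); TT <- stack_matrix(t_stack); PP <- stack_matrix(p_stack)
  n <- nrow(CB); npx <- ncol(CB)
  ok <- colSums(!is.finite(CB)) == 0 & colSums(!is.finite(TT)) == 0 &
        colSums(!is.finite(PP)) == 0
  a <- b <- c0 <- s_obs <- s_cc <- s_ha <- rep(NA_real_, npx)
  if (any(ok)) {
    cb <- CB[, ok, drop = FALSE]; tt <- TT[, ok, drop = FALSE]; pp <- PP[, ok, drop = FALSE]
    ct <- sweep(tt, 2, colMeans(tt)); cp <- sweep(pp, 2, colMeans(pp))
    cc <- sweep(cb, 2, colMeans(cb))
    stt <- colSums(ct^2); spp <- colSums(cp^2); stp <- colSums(ct * cp)
    det <- stt * spp - stp^2
    good <- det > 1e-12 * pmax(stt * spp, .Machine$double.xmin)
    sct <- colSums(cc * ct); scp <- colSums(cc * cp)
    av <- (spp * sct - stp * scp) / det
    bv <- (stt * scp - stp * sct) / det
    av[!good] <- NA; bv[!good] <- NA
    cv <- colMeans(cb) - av * colMeans(tt) - bv * colMeans(pp)
    # slopes against the year index; slope is linear so slope_ha = obs - cc
    i <- seq_len(n); si <- sum(i); si2 <- sum(i^2); den <- n * si2 - si^2
    sl <- function(M) (n * as.vector(crossprod(i, M)) - si * colSums(M)) / den
    so <- sl(cb)
    fitted <- tt * rep(av, each = n) + pp * rep(bv, each = n) +
      matrix(cv, n, sum(ok), byrow = TRUE)
    scc <- sl(fitted)
    a[ok] <- av; b[ok] <- bv; c0[ok] <- cv
    s_obs[ok] <- so; s_cc[ok] <- scc; s_ha[ok] <- so - scc
  }
  drv <- classify_driver(s_obs, s_cc, s_ha, tol = tol)
  tmpl <- cb_stack$grids[[1]]
  list(a = grid_like(a, tmpl), b = grid_like(b, tmpl), c = grid_like(c0, tmpl),
       slope_obs = grid_like(s_obs, tmpl),
       slope_cc = grid_like(s_cc, tmpl),
       slope_ha = grid_like(s_ha, tmpl),
       scenario = grid_like(as.numeric(drv$scenario), tmpl),
       contrib_cc = grid_like(drv$contrib_cc, tmpl),
       contrib_ha = grid_like(drv$contrib_ha, tmpl),
       direction = grid_like(drv$direction, tmpl),
       level_cc = grid_like(as.numeric(contribution_levels(drv$contrib_cc)), tmpl),
       level_ha = grid_like(as.numeric(contribution_levels(drv$contrib_ha)), tmpl))
}

#' Regional attribution summaries
#'
#' Improved/degraded area shares by the sign of the observed slope; within
#' each direction, mean climate and human contribution rates and area
#' shares of the five 20-percent contribution levels; plus the overall mean
#' contribution split across all attributed pixels.
#'
#' @param attr result of [attribution_stack()].
#' @param pixel_area_km2 pixel area in km^2.
#' @return list: `direction_share_pct` (improved/degraded), `by_direction`
#'   (data frame of mean contributions), `levels` (data frame of level area
#'   shares per driver and direction), `overall_contrib_pct` (named vector
#'   cc/ha).
#' @export
attribution_summary <- function(attr, pixel_area_km2 = 1) {
  dirv <- as.vector(attr$direction$values)
  cc <- as.vector(attr$contrib_cc$values)
  ha <- as.vector(attr$contrib_ha$values)
  ok <- !is.na(dirv) & dirv != 0
  n_imp <- sum(dirv[ok] > 0); n_deg <- sum(dirv[ok] < 0)
  share <- c(improved = 100 * n_imp / max(n_imp + n_deg, 1),
             degraded = 100 * n_deg / max(n_imp + n_deg, 1))
  by_dir <- do.call(rbind, lapply(c(improved = 1, degraded = -1), function(d) {
    sel <- ok & dirv == d & !is.na(cc)
    data.frame(n_pixels = sum(sel),
               area_km2 = sum(sel) * pixel_area_km2,
               mean_contrib_cc = if (any(sel)) mean(cc[sel]) else NA_real_,
               mean_contrib_ha = if (any(sel)) mean(ha[sel]) else NA_real_)
  }))
  by_dir <- cbind(direction = rownames(by_dir), by_dir)
  rownames(by_dir) <- NULL
  lvl <- expand.grid(direction = c("improved", "degraded"),
                     driver = c("cc", "ha"), level = 1:5,
                     stringsAsFactors = FALSE)
  lvl$share_pct <- mapply(function(d, drvr, l) {
    dv <- if (d == "improved") 1 else -1
    v <- if (drvr == "cc") cc else ha
    sel <- ok & dirv == dv & !is.na(v)
    if (!any(sel)) return(NA_real_)
    100 * mean(contribution_levels(v[sel]) == l)
  }, lvl$direction, lvl$driver, lvl$level)
  sel <- ok & !is.na(cc)
  overall <- c(cc = mean(cc[sel]), ha = mean(ha[sel]))
  list(direction_share_pct = share, by_direction = by_dir,
       levels = lvl, overall_contrib_pct = overall)
}
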