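#' Linear rate of change of a yearly series
#'
#' Ordinary least-squares slope against the year index i = 1..n, written in
#' the closed summation form
#' \deqn{\theta = \frac{n\sum i\,y_i - \sum i \sum y_i}{n\sum i^2 - (\sum i)^2}.}
#' Units are input units per year regardless of calendar labelling.
#'
#' @param y yearly values, length >= 3, no missing values.
#' @return the slope.
#' @export
theta_slope <- function(y) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 years for a trend", call. = FALSE)
  if (anyNA(y)) stop("series contains missing values", call. = FALSE)
  i <- seq_len(n)
  (n * sum(i * y) - sum(i) * sum(y)) / (n * sum(i^2) - sum(i)^2)
}

#' F test for a yearly linear trend
#'
#' Simple-regression F statistic with (1, n-2) degrees of freedom: the
#' regression mean square over the residual mean square, with the upper-tail
#' probability as p.  Equivalent to the two-sided t test on the slope
#' (F = t^2).  Degenerate cases: a perfect nonconstant linear fit has zero
#' residual variance and gets p = 0; a constant series has zero total
#' variance and gets slope 0, p = 1.
#'
#' @param y yearly values, length >= 3, no missing values.
#' @return list with `slope`, `F`, `p`.
#' @export
slope_f_test <- function(y) {
  n <- length(y)
  if (n < 3L) stop("need at least 3 years for a trend", call. = FALSE)
  if (anyNA(y)) stop("series contains missing values", call. = FALSE)
  i <- seq_len(n)
  b <- theta_slope(y)
  sxx <- sum((i - mean(i))^2)
  ssr <- b^2 * sxx
  sst <- sum((y - mean(y))^2)
  sse <- sst - ssr
  if (sst <= .Machine$double.eps * n) return(list(slope = 0, F = 0, p = 1))
  if (sse <= sst * 1e-12) return(list(slope = b, F = Inf, p = 0))
  f <- ssr / (sse / (n - 2))
  list(slope = b, F = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Five-way trend significance classes
#'
#' Codes: 1 = ESD (slope < 0, p < 0.01), 2 = SD (slope < 0,
#' 0.01 <= p < 0.05), 3 = NSC (p >= 0.05, or slope exactly 0), 4 = SI
#' (slope > 0, 0.01 <= p < 0.05), 5 = ESI (slope > 0, p < 0.01).
#'
#' @param slope,p vectors of slopes and p-values (recycled together).
#' @return integer vector of class codes 1..5 (`NA` propagates).
#' @export
classify_trend <- function(slope, p) {
  out <- rep(NA_integer_, length(slope))
  ok <- !is.na(slope) & !is.na(p)
  out[ok] <- 3L
  out[ok & slope < 0 & p < 0.05] <- 2L
  out[ok & slope < 0 & p < 0.01] <- 1L
  out[ok & slope > 0 & p < 0.05] <- 4L
  out[ok & slope > 0 & p < 0.01] <- 5L
  out
}

#' Trend-class labels
#' @return character vector naming codes 1..5.
#' @export
trend_class_labels <- function() c("ESD", "SD", "NSC", "SI", "ESI")

#' Per-pixel trend analysis of an annual stack
#'
#' Vectorised slope + F test + classification over every pixel with a
#' complete series; pixels with any missing year are excluded entirely.
#'
#' @param stack a `tercab_stack` with >= 3 years.
#' @return list of grids: `slope`, `F`, `p`, `class` (codes 1..5).
#' @export
trend_stack <- function(stack) {
  Y <- stack_matrix(stack)
  n <- nrow(Y)
  if (n < 3L) stop("need at least 3 years for a trend", call. = FALSE)
  tmpl <- stack$grids[[1]]
  ok <- colSums(!is.finite(Y)) == 0L
  i <- seq_len(n)
  sxx <- sum((i - mean(i))^2)
  slope <- p <- f <- rep(NA_real_, ncol(Y))
  if (any(ok)) {
    Yk <- Y[, ok, drop = FALSE]
    si <- sum(i); si2 <- sum(i^2)
    sy <- colSums(Yk)
    sxy <- as.vector(crossprod(i, Yk))
    b <- (n * sxy - si * sy) / (n * si2 - si^2)
    sst <- colSums(Yk^2) - sy^2 / n
    ssr <- b^2 * sxx
    sse <- pmax(sst - ssr, 0)
    fst <- ssr / (sse / (n - 2))
    pv <- stats::pf(fst, 1, n - 2, lower.tail = FALSE)
    # degenerate pixels: constant series (p = 1) and exact fits (p = 0)
    const <- sst <= .Machine$double.eps * n
    exact <- !const & sse <= sst * 1e-12
    b[const] <- 0; fst[const] <- 0; pv[const] <- 1
    fst[exact] <- Inf; pv[exact] <- 0
    slope[ok] <- b; f[ok] <- fst; p[ok] <- pv
  }
  list(slope = grid_like(slope, tmpl),
       F = grid_like(f, tmpl),
       p = grid_like(p, tmpl),
       class = grid_like(as.numeric(classify_trend(slope, p)), tmpl))
}

#' Areas and proportions of the five trend classes
#'
#' @param class_grid grid of class codes 1..5 (or a numeric vector of
#'   codes).
#' @param pixel_area_km2 pixel area in km^2.
#' @return object of class `tercab_trendsum`: data frame `table`
#'   (abbreviation, area_km2, proportion_pct), `significant_area_km2`
#'   (ESI + SI + SD + ESD) and `total_area_km2`.
#' @export
trend_summary <- function(class_grid, pixel_area_km2 = 1) {
  codes <- if (inherits(class_grid, "tercab_grid")) as.vector(class_grid$values)
           else as.vector(class_grid)
  codes <- codes[!is.na(codes)]
  cnt <- table(factor(codes, levels = 1:5))
  area <- as.numeric(cnt) * pixel_area_km2
  tot <- sum(area)
  tab <- data.frame(abbreviation = trend_class_labels(),
                    area_km2 = area,
                    proportion_pct = if (tot > 0) 100 * area / tot else 0 * area)
  structure(list(table = tab,
                 significant_area_km2 = sum(area[c(1, 2, 4, 5)]),
                 total_area_km2 = tot),
            class = "tercab_trendsum")
}

#' Summarise a printed five-class area table
#'
#' Applies the same accounting as [trend_summary()] to areas that were
#' tabulated elsewhere (e.g. a published classification table).
#'
#' @param table data frame with columns `abbreviation` and `area_km2`
#'   covering ESI, SI, NSC, SD, ESD.
#' @return a `tercab_trendsum`.
#' @export
trend_summary_from_table <- function(table) {
  stopifnot(all(c("abbreviation", "area_km2") %in% names(table)))
  lv <- trend_class_labels()
  if (!all(table$abbreviation %in% lv))
    stop("unknown trend-class abbreviation", call. = FALSE)
  area <- stats::setNames(rep(0, 5), lv)
  area[table$abbreviation] <- table$area_km2
  tot <- sum(area)
  tab <- data.frame(abbreviation = lv, area_km2 = unname(area),
                    proportion_pct = 100 * unname(area) / tot)
  structure(list(table = tab,
                 significant_area_km2 = sum(area[c("ESI", "SI", "SD", "ESD")]),
                 total_area_km2 = tot),
            class = "tercab_trendsum")
}

#' @export
print.tercab_trendsum <- function(x, ...) {
  cat("<tercab_trendsum> total", format(x$total_area_km2), "km^2, significant",
      format(x$significant_area_km2), "km^2\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
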