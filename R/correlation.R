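#' Pearson product-moment correlation
#'
#' Direct evaluation of the product-moment formula
#' \eqn{R_{xy} = \sum (x_i-\bar x)(y_i-\bar y) / \sqrt{\sum (x_i-\bar x)^2
#' \sum (y_i-\bar y)^2}}.  Zero variance in either series leaves the
#' coefficient undefined (`NA`).
#'
#' @param x,y numeric series of equal length >= 3.
#' @return the correlation, or `NA` when degenerate.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

#' First-order partial correlation
#'
#' Correlation between x and y after controlling for z, from the three
#' pairwise Pearson coefficients:
#' \deqn{R_{xy,z} = \frac{R_{xy} - R_{xz} R_{yz}}
#'   {\sqrt{(1 - R_{xz}^2)(1 - R_{yz}^2)}}.}
#' Identical to the Pearson correlation of the residuals of x and y after
#' regressing each on z.  When z is perfectly collinear with x or y the
#' coefficient is undefined (`NA`).
#'
#' @param x,y,z numeric series of equal length >= 3.
#' @return the partial correlation, or `NA` when degenerate.
#' @export
partial_correlation <- function(x, y, z) {
  rxy <- pearson_r(x, y); rxz <- pearson_r(x, z); ryz <- pearson_r(y, z)
  if (anyNA(c(rxy, rxz, ryz))) return(NA_real_)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) return(NA_real_)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' t test for a partial correlation
#'
#' \eqn{t = R \sqrt{(n - m - 1)/(1 - R^2)}} on n - m - 1 degrees of
#' freedom, where n is the number of years and m the number of independent
#' variables in the climate model (default 2: temperature and
#' precipitation).  p is two-sided; |R| = 1 is reported as p = 0.
#'
#' @param R partial correlation coefficient.
#' @param n number of years.
#' @param m number of independent variables controlled in the model.
#' @return list with `t` and `p`.
#' @export
partial_t_test <- function(R, n, m = 2) {
  df <- n - m - 1
  if (df < 1) stop("n - m - 1 must be >= 1", call. = FALSE)
  if (is.na(R)) return(list(t = NA_real_, p = NA_real_))
  if (abs(R) >= 1) return(list(t = sign(R) * Inf, p = 0))
  t <- R * sqrt(df / (1 - R^2))
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Six-way correlation significance classes
#'
#' Codes 1..6: 1 = ESNC (R < 0, p < 0.01), 2 = SNC (R < 0,
#' 0.01 <= p < 0.05), 3 = INC (R < 0, p >= 0.05), 4 = IPC (R > 0,
#' p >= 0.05), 5 = SPC (R > 0, 0.01 <= p < 0.05), 6 = ESPC (R > 0,
#' p < 0.01).  R exactly 0 is coded IPC-side neutral (4).
#'
#' @param R,p vectors of partial correlations and p-values.
#' @return integer codes 1..6 (`NA` propagates).
#' @export
classify_correlation <- function(R, p) {
  out <- rep(NA_integer_, length(R))
  ok <- !is.na(R) & !is.na(p)
  out[ok & R < 0] <- 3L
  out[ok & R < 0 & p < 0.05] <- 2L
  out[ok & R < 0 & p < 0.01] <- 1L
  out[ok & R >= 0] <- 4L
  out[ok & R > 0 & p < 0.05] <- 5L
  out[ok & R > 0 & p < 0.01] <- 6L
  out
}

#' Correlation-class labels
#' @return character vector naming codes 1..6.
#' @export
correlation_class_labels <- function() {
  c("ESNC", "SNC", "INC", "IPC", "SPC", "ESPC")
}

#' Per-pixel partial-correlation maps against two climate drivers
#'
#' For every pixel with complete series, computes the partial correlation
#' of the response with temperature controlling precipitation, and with
#' precipitation controlling temperature, plus t tests and six-way classes.
#'
#' @param cb_stack response `tercab_stack` (e.g. carbon balance).
#' @param t_stack,p_stack temperature and precipitation stacks on the same
#'   years and geometry.
#' @param m number of independent variables for the t-test df (default 2).
#' @return list with elements `temperature` and `precipitation`, each a
#'   list of grids `r` (partial correlation), `p`, `class`.
#' @export
correlation_stack <- function(cb_stack, t_stack, p_stack, m = 2) {
  stopifnot(identical(cb_stack$years, t_stack$years),
            identical(cb_stack$years, p_stack$years))
  assert_coregistered(cb_stack$grids[[1]], t_stack$grids[[1]], p_stack$grids[[1]])
  CB <- stack_matrix(cb_stack); TT <- stack_matrix(t_stack); PP <- stack_matrix(p_stack)
  n <- nrow(CB)
  ok <- colSums(!is.finite(CB)) == 0 & colSums(!is.finite(TT)) == 0 &
        colSums(!is.finite(PP)) == 0
  colcor <- function(A, B) {
    A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
    num <- colSums(A * B)
    den <- sqrt(colSums(A^2) * colSums(B^2))
    r <- num / den
    r[den == 0] <- NA_real_
    r
  }
  res_one <- function(rxy, rxz, ryz) {
    bad <- is.na(rxy) | is.na(rxz) | is.na(ryz) |
      abs(rxz) >= 1 - 1e-12 | abs(ryz) >= 1 - 1e-12
    r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    r[bad] <- NA_real_
    df <- n - m - 1
    t <- r * sqrt(df / pmax(1 - r^2, 0))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    p[!is.na(r) & abs(r) >= 1] <- 0
    list(r = r, p = p)
  }
  tmpl <- cb_stack$grids[[1]]
  out <- list()
  if (any(ok)) {
    cb <- CB[, ok, drop = FALSE]; tt <- TT[, ok, drop = FALSE]; pp <- PP[, ok, drop = FALSE]
    r_ct <- colcor(cb, tt); r_cp <- colcor(cb, pp); r_tp <- colcor(tt, pp)
    par_t <- res_one(r_ct, r_cp, r_tp)   # CB~T | P
    par_p <- res_one(r_cp, r_ct, r_tp)   # CB~P | T
  }
  pack <- function(res) {
    r <- p <- rep(NA_real_, ncol(CB))
    if (any(ok)) { r[ok] <- res$r; p[ok] <- res$p }
    list(r = grid_like(r, tmpl), p = grid_like(p, tmpl),
         class = grid_like(as.numeric(classify_correlation(r, p)), tmpl))
  }
  list(temperature = pack(par_t), precipitation = pack(par_p))
}

#' Areas and proportions of the six correlation classes
#'
#' @param class_grid grid (or vector) of class codes 1..6.
#' @param pixel_area_km2 pixel area in km^2.
#' @return data frame with abbreviation, area_km2, proportion_pct; the six
#'   classes partition the valid mask so proportions sum to 100.
#' @export
correlation_summary <- function(class_grid, pixel_area_km2 = 1) {
  codes <- if (inherits(class_grid, "tercab_grid")) as.vector(class_grid$values)
           else as.vector(class_grid)
  codes <- codes[!is.na(codes)]
  cnt <- table(factor(codes, levels = 1:6))
  area <- as.numeric(cnt) * pixel_area_km2
  data.frame(abbreviation = correlation_class_labels(),
             area_km2 = area,
             proportion_pct = if (sum(area) > 0) 100 * area / sum(area) else 0 * area)
}
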