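#' Discretize a continuous factor into strata
#'
#' Continuous drivers must be stratified before the variance-decomposition
#' q statistic applies.  Quantile bins give near-equal occupancy; equal
#' intervals split the value range.  Categorical factors (class codes)
#' should be passed through unchanged via `categorical = TRUE`.  When the
#' data support fewer than `k` distinct bins, k is reduced with a warning.
#'
#' @param x numeric vector or `tercab_grid` of factor values.
#' @param k requested number of strata (>= 2).
#' @param method `"quantile"` or `"equal"`.
#' @param categorical if TRUE, values are used as stratum labels directly.
#' @return integer stratum labels (vector, or grid when the input was a
#'   grid); `NA` propagates.
#' @export
discretize <- function(x, k = 5, method = c("quantile", "equal"),
                       categorical = FALSE) {
  method <- match.arg(method)
  is_grid <- inherits(x, "tercab_grid")
  v <- if (is_grid) as.vector(x$values) else as.vector(x)
  if (categorical) {
    lab <- as.integer(factor(v))
  } else {
    stopifnot(k >= 2)
    ok <- !is.na(v)
    if (sum(ok) < 2L) stop("not enough values to discretize", call. = FALSE)
    brk <- if (method == "quantile") {
      unique(stats::quantile(v[ok], probs = seq(0, 1, length.out = k + 1),
                             names = FALSE, type = 7))
    } else {
      seq(min(v[ok]), max(v[ok]), length.out = k + 1)
    }
    brk <- unique(brk)
    if (length(brk) - 1L < k)
      warning("only ", length(brk) - 1L, " distinct strata supported; k reduced",
              call. = FALSE)
    if (length(brk) < 2L) brk <- c(brk, brk + 1)
    lab <- as.integer(cut(v, breaks = brk, include.lowest = TRUE, labels = FALSE))
  }
  if (is_grid) grid_like(as.numeric(lab), x) else lab
}

#' Geographical-detector q statistic
#'
#' Variance decomposition of a response over a stratification:
#' \deqn{q = 1 - \frac{\sum_h N_h \sigma_h^2}{N \sigma^2}}
#' with population (N-weighted) variances, so q is the share of the total
#' variance explained by the strata: 0 when strata are uninformative, 1
#' when the response is constant within every stratum.
#'
#' @param y response values.
#' @param strata stratum label per value (any vector coercible to factor).
#'   Pairs with `NA` in either are dropped.
#' @return the q statistic, or `NA` (with a warning) when the overall
#'   variance is zero.
#' @export
q_statistic <- function(y, strata) {
  if (inherits(y, "tercab_grid")) y <- as.vector(y$values)
  if (inherits(strata, "tercab_grid")) strata <- as.vector(strata$values)
  if (length(y) != length(strata)) stop("y and strata lengths differ", call. = FALSE)
  keep <- !is.na(y) & !is.na(strata)
  y <- y[keep]; strata <- strata[keep]
  n <- length(y)
  if (n < 2L) stop("need at least 2 valid observations", call. = FALSE)
  vtot <- mean((y - mean(y))^2)
  if (vtot == 0) {
    warning("zero overall variance: q undefined", call. = FALSE)
    return(NA_real_)
  }
  f <- factor(strata)
  nh <- tabulate(f)
  mh <- tapply(y, f, mean)
  wss <- sum(tapply(y, f, function(v) sum((v - mean(v))^2)))
  1 - wss / (n * vtot)
}

#' Interaction detection between two stratified factors
#'
#' Computes q for each factor and for their overlay (the Cartesian pair
#' stratification) and assigns the canonical interaction type:
#' nonlinear weaken (q12 < min), single-factor nonlinear weaken
#' (min <= q12 <= max), two-factor enhancement (max < q12 < q1 + q2),
#' independent (q12 = q1 + q2), nonlinear enhancement (q12 > q1 + q2).
#' Empty overlay strata are dropped by construction of the cross factor.
#'
#' @param y response values.
#' @param strata1,strata2 stratum labels of the two factors.
#' @param eps equality tolerance for the independence boundary.
#' @return list with `q1`, `q2`, `q12`, `interaction_type`.
#' @export
interaction_q <- function(y, strata1, strata2, eps = 1e-12) {
  if (inherits(y, "tercab_grid")) y <- as.vector(y$values)
  if (inherits(strata1, "tercab_grid")) strata1 <- as.vector(strata1$values)
  if (inherits(strata2, "tercab_grid")) strata2 <- as.vector(strata2$values)
  keep <- !is.na(y) & !is.na(strata1) & !is.na(strata2)
  y <- y[keep]; s1 <- strata1[keep]; s2 <- strata2[keep]
  q1 <- q_statistic(y, s1)
  q2 <- q_statistic(y, s2)
  q12 <- q_statistic(y, interaction(factor(s1), factor(s2), drop = TRUE))
  lo <- min(q1, q2); hi <- max(q1, q2)
  type <- if (q12 < lo - eps) "nonlinear weaken"
          else if (q12 <= hi + eps) "single-factor nonlinear weaken"
          else if (abs(q12 - (q1 + q2)) <= eps) "independent"
          else if (q12 < q1 + q2) "two-factor enhancement"
          else "nonlinear enhancement"
  list(q1 = q1, q2 = q2, q12 = q12, interaction_type = type)
}

#' Factor-detector report over years
#'
#' Runs the factor detector for every (year, factor) pair, averages q over
#' years, ranks factors by the multiyear mean, and computes the full
#' pairwise interaction matrix per year.
#'
#' @param y_by_year named list (by year) of response grids or vectors.
#' @param factors named list of factor specifications; each element is
#'   either a grid/vector of pre-stratified labels, or a list
#'   `list(values = , categorical = , k = , method = )`.
#' @param k,method defaults for continuous factors (see [discretize()]).
#' @return list: `q_table` (factor, year, q), `summary` (factor, mean_q,
#'   rank), `interactions` (named list by year of list-matrices with q12
#'   and type).
#' @export
factor_report <- function(y_by_year, factors, k = 5, method = "quantile") {
  strat <- lapply(factors, function(f) {
    if (is.list(f) && !inherits(f, "tercab_grid")) {
      discretize(f$values,
                 k = if (!is.null(f$k)) f$k else k,
                 method = if (!is.null(f$method)) f$method else method,
                 categorical = isTRUE(f$categorical))
    } else f
  })
  strat <- lapply(strat, function(s) if (inherits(s, "tercab_grid")) as.vector(s$values) else as.vector(s))
  yrs <- names(y_by_year)
  rows <- list()
  inter <- list()
  for (yr in yrs) {
    y <- y_by_year[[yr]]
    if (inherits(y, "tercab_grid")) y <- as.vector(y$values)
    qv <- vapply(strat, function(s) q_statistic(y, s), numeric(1))
    rows[[yr]] <- data.frame(factor = names(strat), year = yr, q = unname(qv),
                             stringsAsFactors = FALSE)
    nf <- length(strat)
    qm <- matrix(NA_real_, nf, nf, dimnames = list(names(strat), names(strat)))
    tm <- matrix(NA_character_, nf, nf, dimnames = dimnames(qm))
    if (nf > 1) for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      res <- interaction_q(y, strat[[i]], strat[[j]])
      qm[i, j] <- qm[j, i] <- res$q12
      tm[i, j] <- tm[j, i] <- res$interaction_type
    }
    diag(qm) <- qv
    inter[[yr]] <- list(q12 = qm, type = tm)
  }
  q_table <- do.call(rbind, rows)
  mean_q <- tapply(q_table$q, q_table$factor, mean)
  summ <- data.frame(factor = names(mean_q), mean_q = as.numeric(mean_q))
  summ <- summ[order(-summ$mean_q), ]
  summ$rank <- seq_len(nrow(summ))
  rownames(summ) <- NULL
  list(q_table = q_table, summary = summ, interactions = inter)
}
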