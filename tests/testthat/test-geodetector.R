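test_that("discretize: quantile occupancy, pass-through, k reduction", {
  lab <- discretize(1:100, k = 5, method = "quantile")
  expect_equal(as.numeric(table(lab)), rep(20, 5))
  # skewed values: quantile bins balanced within +-1 of N/4
  set.seed(61)
  x <- rexp(200)
  cnt <- table(discretize(x, k = 4))
  expect_true(all(abs(cnt - 50) <= 1))
  # categorical pass-through keeps one label per code
  g <- mk_grid(c(1, 2, 2, 7), 2, 2)
  lab2 <- discretize(g, categorical = TRUE)
  expect_equal(length(unique(as.vector(lab2$values))), 3)
  # not enough distinct values -> fewer strata with a warning
  expect_warning(discretize(rep(c(1, 2), 50), k = 5), "reduced")
  # equal-interval method spans the range
  expect_equal(sort(unique(discretize(seq(0, 10, 0.1), k = 5, method = "equal"))),
               1:5)
})

test_that("q statistic: limits, hand value, and brute-force oracle", {
  expect_equal(q_statistic(c(1, 5, 2, 8), rep("A", 4)), 0)
  expect_equal(q_statistic(c(1, 1, 2, 2), c("A", "A", "B", "B")), 1)
  expect_equal(q_statistic(c(1, 2, 3, 4), c("A", "A", "B", "B")), 0.8)
  expect_warning(qna <- q_statistic(rep(3, 5), c(1, 1, 2, 2, 2)), "undefined")
  expect_true(is.na(qna))

  # brute-force group-by decomposition on random instances, and
  # invariance under stratum relabeling
  set.seed(62)
  for (r in 1:50) {
    n <- sample(10:60, 1)
    y <- rnorm(n)
    s <- sample(letters[1:sample(2:6, 1)], n, TRUE)
    pvar <- function(v) mean((v - mean(v))^2)
    brute <- 1 - sum(vapply(split(y, s), function(v) length(v) * pvar(v),
                            numeric(1))) / (n * pvar(y))
    q <- q_statistic(y, s)
    expect_equal(q, brute, tolerance = 1e-12)
    expect_true(q >= -1e-12 && q <= 1 + 1e-12)
    relab <- stats::setNames(sample(100:200, length(unique(s))), unique(s))
    expect_equal(q_statistic(y, relab[s]), q, tolerance = 1e-12)
  }
})

test_that("refining a stratification never decreases q", {
  set.seed(63)
  for (r in 1:20) {
    y <- rnorm(80)
    coarse <- sample(1:3, 80, TRUE)
    fine <- paste(coarse, sample(1:2, 80, TRUE))  # refines coarse
    expect_gte(q_statistic(y, fine), q_statistic(y, coarse) - 1e-12)
  }
})

test_that("interaction detector applies the comparison rules", {
  set.seed(64)
  y <- rnorm(120)
  s1 <- sample(1:4, 120, TRUE); s2 <- sample(1:3, 120, TRUE)
  res <- interaction_q(y, s1, s2)
  # overlay refines both factors, so q12 >= max(q1, q2)
  expect_gte(res$q12, max(res$q1, res$q2) - 1e-12)
  # idempotent overlay: strata2 == strata1 gives q12 = q1, single-factor class
  same <- interaction_q(y, s1, s1)
  expect_equal(same$q12, same$q1, tolerance = 1e-12)
  expect_equal(same$interaction_type, "single-factor nonlinear weaken")
  # rule application on synthetic q triples via a controlled response:
  # classify directly through the comparison logic
  mk <- function(q1, q2, q12) {
    # exercise the decision rules without a data detour
    lo <- min(q1, q2); hi <- max(q1, q2)
    if (q12 < lo) "nonlinear weaken"
    else if (q12 <= hi) "single-factor nonlinear weaken"
    else if (abs(q12 - (q1 + q2)) <= 1e-12) "independent"
    else if (q12 < q1 + q2) "two-factor enhancement"
    else "nonlinear enhancement"
  }
  expect_equal(mk(0.2, 0.3, 0.6), "nonlinear enhancement")
  expect_equal(mk(0.2, 0.3, 0.4), "two-factor enhancement")
})

test_that("factor report ranks constructed drivers correctly", {
  set.seed(65)
  scene <- tiny_scene(seed = 9, shape = c(14, 14))
  y <- grid_like(colMeans(stack_matrix(scene$npp)), scene$npp$grids[[1]])
  yv <- as.vector(y$values)
  factors <- list(
    self = discretize(yv + rnorm(length(yv), 0, 1e-6), k = 12),
    elevation = discretize(scene$covariates$elevation, k = 5),
    noise = discretize(rnorm(length(yv)), k = 5)
  )
  rep_ <- factor_report(list(y2022 = y), factors)
  s <- rep_$summary
  expect_equal(s$factor[1], "self")
  expect_gt(s$mean_q[s$factor == "self"], 0.9)
  expect_lt(s$mean_q[s$factor == "noise"], 0.2)
  # permuting a factor's pixels destroys its explanatory power
  set.seed(66)
  elev_lab <- as.vector(factors$elevation$values)
  q_orig <- q_statistic(yv, elev_lab)
  q_perm <- q_statistic(yv, sample(elev_lab))
  expect_lt(q_perm, q_orig)
  expect_lt(q_perm, 0.15)
  # interaction matrix is symmetric with factor q on the diagonal
  im <- rep_$interactions[[1]]$q12
  expect_equal(im, t(im))
  expect_equal(unname(diag(im)),
               unname(rep_$q_table$q[match(rownames(im), rep_$q_table$factor)]))
})
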