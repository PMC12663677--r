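test_that("climate regression recovers exact and noisy coefficients", {
  set.seed(51)
  T_c <- 24 + 0.03 * (1:23) + rnorm(23, 0, 0.3)
  P_m <- 1.8 + rnorm(23, 0, 0.1)
  cb <- 0.2 * T_c + 3 * P_m + 100
  fit <- fit_climate_model(cb, T_c, P_m)
  expect_equal(c(fit$a, fit$b, fit$c), c(0.2, 3, 100), tolerance = 1e-9)
  expect_equal(fit$cb_ha, rep(0, 23), tolerance = 1e-9)

  # normal-equations oracle via lm on random series
  for (r in 1:200) {
    cb <- rnorm(23); tt <- rnorm(23); pp <- rnorm(23)
    fit <- fit_climate_model(cb, tt, pp)
    ref <- unname(stats::coef(stats::lm(cb ~ tt + pp)))
    expect_equal(c(fit$c, fit$a, fit$b), ref, tolerance = 1e-8)
    # residuals orthogonal to regressors and constant
    expect_equal(sum(fit$cb_ha), 0, tolerance = 1e-8)
    expect_equal(sum(fit$cb_ha * tt), 0, tolerance = 1e-8)
    expect_equal(sum(fit$cb_ha * pp), 0, tolerance = 1e-8)
  }

  # rank deficiency flags the pixel
  bad <- fit_climate_model(rnorm(23), rep(24, 23), rep(1.8, 23))
  expect_false(bad$ok)
  expect_true(is.na(bad$a))
})

test_that("driver classification applies the six-row criterion table", {
  lab <- driver_labels()
  # improved, both drivers positive: contributions are slope ratios
  r <- classify_driver(1.0, 0.3, 0.7)
  expect_equal(lab[r$scenario], "CC&HA")
  expect_equal(c(r$contrib_cc, r$contrib_ha), c(30, 70))
  # improved, human slope negative: climate takes 100
  r <- classify_driver(0.5, 0.8, -0.3)
  expect_equal(lab[r$scenario], "CC")
  expect_equal(c(r$contrib_cc, r$contrib_ha), c(100, 0))
  # degraded, climate positive: human takes 100
  r <- classify_driver(-0.5, 0.2, -0.7)
  expect_equal(lab[r$scenario], "HA")
  expect_equal(c(r$contrib_cc, r$contrib_ha), c(0, 100))
  # degraded, both negative: ratio rule again
  r <- classify_driver(-1.0, -0.4, -0.6)
  expect_equal(lab[r$scenario], "CC&HA")
  expect_equal(c(r$contrib_cc, r$contrib_ha), c(40, 60))
  # near-zero observed slope: no-change scenario, undefined contributions
  r <- classify_driver(1e-14, 1e-14, 0)
  expect_equal(lab[r$scenario], "no-change")
  expect_true(is.na(r$contrib_cc))
  # mixed ratios exceeding [0,100] are clipped and flagged
  r <- classify_driver(0.1, 1.2, -1.1)  # cc-only row (ha < 0)
  expect_equal(c(r$contrib_cc, r$contrib_ha), c(100, 0))
  r <- classify_driver(c(0.1), c(0.05), c(0.05))
  expect_false(r$clipped)
  # same-sign contributions always sum to 100
  set.seed(52)
  so <- runif(100, 0.1, 2) * sample(c(-1, 1), 100, TRUE)
  sc <- so * runif(100); sh <- so - sc
  r <- classify_driver(so, sc, sh)
  mixed <- r$scenario == 1
  expect_equal(r$contrib_cc[mixed] + r$contrib_ha[mixed], rep(100, sum(mixed)),
               tolerance = 1e-9)
})

test_that("contribution levels are left-closed 20-percent bins", {
  expect_equal(contribution_levels(c(0, 19.99, 20, 59, 80, 100)),
               c(1L, 1L, 2L, 3L, 5L, 5L))
  expect_error(contribution_levels(101), "outside")
  expect_true(is.na(contribution_levels(NA)))
})

test_that("slope decomposition is additive and attribution recovers truth", {
  scene <- generate_scene(scene_config(shape = c(10, 10), seed = 77))
  cb <- inject_climate_signal(scene, a = 0.2, b = 3, c = 100)
  at <- attribution_stack(cb, scene$temperature, scene$precipitation)
  # slope_cc + slope_ha = slope_obs (linearity)
  expect_equal(as.vector(at$slope_cc$values + at$slope_ha$values),
               as.vector(at$slope_obs$values), tolerance = 1e-10)
  # pure climate signal: coefficients recovered, CC contribution 100 everywhere
  expect_equal(as.vector(at$a$values), rep(0.2, 100), tolerance = 1e-8)
  expect_equal(as.vector(at$b$values), rep(3, 100), tolerance = 1e-8)
  defined <- !is.na(at$contrib_cc$values)
  expect_true(all(at$contrib_cc$values[defined] == 100))
  # probes match the scalar route
  CB <- stack_matrix(cb); TT <- stack_matrix(scene$temperature)
  PP <- stack_matrix(scene$precipitation)
  for (j in c(4, 55)) {
    fit <- fit_climate_model(CB[, j], TT[, j], PP[, j])
    expect_equal(at$a$values[j], fit$a, tolerance = 1e-10)
    expect_equal(at$slope_cc$values[j], theta_slope(fit$cb_cc), tolerance = 1e-10)
  }
})

test_that("an injected human disturbance raises HA contribution on its footprint", {
  scene <- generate_scene(scene_config(shape = c(16, 16), seed = 101))
  cb <- inject_climate_signal(scene, a = 0.5, b = 2, c = 80)
  # superimpose a strong monotone non-climatic decline inside a known patch
  foot <- patch_footprint(scene, list(rows = c(3, 8), cols = c(4, 9)))
  ny <- length(cb$years)
  for (k in seq_len(ny)) {
    v <- as.vector(cb$grids[[k]]$values)
    v[foot] <- v[foot] - 2 * (k - 1)
    cb$grids[[k]] <- grid_like(v, cb$grids[[k]])
  }
  at <- attribution_stack(cb, scene$temperature, scene$precipitation)
  ha <- as.vector(at$contrib_ha$values)
  expect_gt(mean(ha[foot], na.rm = TRUE), mean(ha[!foot], na.rm = TRUE))
  s <- attribution_summary(at, 0.01)
  expect_equal(unname(sum(s$direction_share_pct)), 100, tolerance = 1e-9)
})
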