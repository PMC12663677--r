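test_that("soil respiration follows the closed form and its limits", {
  expect_equal(soil_respiration(17, 0, 5), 0)                 # P = 0 annihilates
  expect_equal(soil_respiration(0, 1e9, 1e9), 1.55, tolerance = 1e-6)
  # frozen reference point, computed by hand from the formula
  expect_equal(soil_respiration(25, 2, 5),
               1.55 * exp(0.031 * 25) * (2 / 2.68) * (5 / 7.23),
               tolerance = 1e-15)
  expect_equal(round(soil_respiration(25, 2, 5), 4), 1.7363)
  expect_error(soil_respiration(20, -1, 5), "precipitation")
  expect_error(soil_respiration(20, 1, -5), "SOC")
})

test_that("Rs is strictly increasing in each argument (numerical partials)", {
  set.seed(8)
  T0 <- runif(50, 10, 30); P0 <- runif(50, 0.2, 3); S0 <- runif(50, 0.5, 12)
  h <- 1e-6
  expect_true(all(soil_respiration(T0 + h, P0, S0) > soil_respiration(T0, P0, S0)))
  expect_true(all(soil_respiration(T0, P0 + h, S0) > soil_respiration(T0, P0, S0)))
  expect_true(all(soil_respiration(T0, P0, S0 + h) > soil_respiration(T0, P0, S0)))
})

test_that("heterotrophic respiration power law and chained evaluation", {
  expect_equal(heterotrophic_respiration(0), 0)
  expect_equal(heterotrophic_respiration(1), 0.6163)
  expect_equal(round(heterotrophic_respiration(soil_respiration(25, 2, 5)), 4),
               0.9540)
  expect_error(heterotrophic_respiration(-0.1), "Rs")
  # grid path matches an independent scalar evaluation at random points
  set.seed(9)
  pts <- data.frame(T = runif(100, 5, 30), P = runif(100, 0.1, 3),
                    S = runif(100, 0.5, 15))
  grid_rs <- soil_respiration(pts$T, pts$P, pts$S)
  scalar <- vapply(seq_len(100), function(i) {
    0.6163 * (1.55 * exp(0.031 * pts$T[i]) * pts$P[i] / (pts$P[i] + 0.68) *
                pts$S[i] / (pts$S[i] + 2.23))^0.7918
  }, numeric(1))
  expect_equal(heterotrophic_respiration(grid_rs), scalar, tolerance = 1e-12)
})

test_that("NEP = NPP - Rh on grids, with NEP + Rh = NPP identically", {
  set.seed(10)
  nr <- 5; nc <- 6
  npp <- mk_grid(runif(nr * nc, 800, 1800), nr, nc)
  tg <- mk_grid(runif(nr * nc, 18, 28), nr, nc)
  pg <- mk_grid(runif(nr * nc, 0.8, 2.5), nr, nc)
  sg <- mk_grid(runif(nr * nc, 2, 10), nr, nc)
  res <- nep(npp, tg, pg, sg)
  expect_equal(res$nep$values + res$rh$values, npp$values, tolerance = 1e-12)
  expect_true(all(res$rs$values > 0))

  # spec worked example
  one <- nep(mk_grid(1500, 1, 1), mk_grid(25, 1, 1), mk_grid(2, 1, 1), mk_grid(5, 1, 1))
  expect_equal(round(one$nep$values[1, 1], 1), 546.0)
  # mm input is converted
  one_mm <- nep(mk_grid(1500, 1, 1), mk_grid(25, 1, 1), mk_grid(2000, 1, 1),
                mk_grid(5, 1, 1), precip_unit = "mm")
  expect_equal(one_mm$nep$values, one$nep$values)

  # higher SOC -> more respiration -> lower NEP, all else equal
  two <- nep(mk_grid(c(1500, 1500), 1, 2), mk_grid(c(25, 25), 1, 2),
             mk_grid(c(2, 2), 1, 2), mk_grid(c(5, 10), 1, 2))
  expect_lt(two$nep$values[1, 2], two$nep$values[1, 1])

  # NPP = 0 everywhere gives non-positive NEP
  zero <- nep(mk_grid(rep(0, 4), 2, 2), mk_grid(rep(20, 4), 2, 2),
              mk_grid(rep(1.5, 4), 2, 2), mk_grid(rep(4, 4), 2, 2))
  expect_true(all(zero$nep$values <= 0))
})

test_that("sink/source classification follows the sign of NEP", {
  g <- mk_grid(c(10, -5, 0, NA), 2, 2)
  cl <- classify_sink_source(g)
  expect_equal(as.vector(cl$values), c(1, -1, 0, NA))
})
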