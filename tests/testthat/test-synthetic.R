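test_that("scene generation is deterministic from the root seed", {
  a <- tiny_scene(seed = 3)
  b <- tiny_scene(seed = 3)
  expect_identical(stack_matrix(a$lulc), stack_matrix(b$lulc))
  expect_identical(stack_matrix(a$temperature), stack_matrix(b$temperature))
  expect_identical(stack_matrix(a$npp), stack_matrix(b$npp))
  expect_identical(a$soc$values, b$soc$values)
  c_ <- tiny_scene(seed = 4)
  expect_false(identical(stack_matrix(a$npp), stack_matrix(c_$npp)))
})

test_that("degenerate configurations behave as stated", {
  # identity transitions, no patches: land cover never changes and the
  # downstream transfer matrix is diagonal
  sc <- generate_scene(scene_config(shape = c(8, 8), seed = 2,
                                    transition_matrix = diag(7)))
  L <- stack_matrix(sc$lulc)
  expect_true(all(apply(L, 2, function(v) length(unique(v)) == 1)))
  tm <- transfer_matrix(sc$lulc$grids[[1]], sc$lulc$grids[[23]], 1)
  expect_equal(transfer_change(tm)$total_change, 0)

  # zero trend and zero noise: every climate grid identical across years
  sc0 <- generate_scene(scene_config(shape = c(6, 6), seed = 2,
                                     climate_trend = c(dT = 0, dP = 0),
                                     climate_noise_sd = c(T = 0, P = 0)))
  TT <- stack_matrix(sc0$temperature); PP <- stack_matrix(sc0$precipitation)
  expect_equal(max(apply(TT, 2, function(v) diff(range(v)))), 0)
  expect_equal(max(apply(PP, 2, function(v) diff(range(v)))), 0)

  # invalid transition matrix rejected
  bad <- diag(7); bad[1, 1] <- 0.5
  expect_error(scene_config(transition_matrix = bad), "summing to 1")
  expect_error(scene_config(class_proportions = rep(0.2, 7)), "sum to 1")
})

test_that("human patches convert exactly their footprint from their year on", {
  patch <- list(year = 2010, rows = c(3, 12), cols = c(5, 14), target_class = 7L)
  sc <- generate_scene(scene_config(shape = c(20, 20), seed = 6,
                                    transition_matrix = diag(7),
                                    human_patches = list(patch)))
  expect_equal(sc$truth$patches[[1]]$n_pixels, 100)
  foot <- patch_footprint(sc, sc$truth$patches[[1]])
  yrs <- sc$config$years
  before <- as.vector(sc$lulc$grids[[which(yrs == 2009)]]$values)
  after <- as.vector(sc$lulc$grids[[which(yrs == 2010)]]$values)
  final <- as.vector(sc$lulc$grids[[length(yrs)]]$values)
  expect_true(all(after[foot] == 7))
  expect_true(all(final[foot] == 7))
  changed <- which(before != after)
  expect_true(all(changed %in% which(foot & before != 7)))
  expect_equal(sort(changed), which(foot & before != 7))
})

test_that("empirical climate trends approach the configured trends as noise -> 0", {
  sc <- generate_scene(scene_config(shape = c(8, 8), seed = 12,
                                    climate_trend = c(dT = 0.05, dP = 0.004),
                                    climate_noise_sd = c(T = 1e-4, P = 1e-5)))
  TT <- stack_matrix(sc$temperature)
  slopes <- apply(TT, 2, theta_slope)
  expect_equal(unname(slopes), rep(0.05, 64), tolerance = 1e-2)
  PPs <- apply(stack_matrix(sc$precipitation), 2, theta_slope)
  expect_equal(unname(PPs), rep(0.004, 64), tolerance = 1e-2)
})

test_that("inject_climate_signal evaluates a*T + b*P + c exactly", {
  sc <- tiny_scene(seed = 8, shape = c(6, 6))
  const <- inject_climate_signal(sc, 0, 0, 5)
  expect_true(all(stack_matrix(const) == 5))
  ident <- inject_climate_signal(sc, 1, 0, 0)
  expect_equal(stack_matrix(ident), stack_matrix(sc$temperature))
  mix <- inject_climate_signal(sc, 0.2, 3, 100)
  TT <- stack_matrix(sc$temperature); PP <- stack_matrix(sc$precipitation)
  M <- stack_matrix(mix)
  for (j in c(1, 17, 36)) {
    expect_equal(M[, j], 0.2 * TT[, j] + 3 * PP[, j] + 100, tolerance = 1e-12)
  }
})

test_that("scene serialisation writes all stacks plus the truth record", {
  sc <- tiny_scene(seed = 10, shape = c(5, 5))
  dir <- withr::local_tempdir()
  files <- write_scene(sc, dir)
  expect_true(file.exists(file.path(dir, "lulc_2000.asc")))
  expect_true(file.exists(file.path(dir, "npp_2022.asc")))
  expect_true(file.exists(file.path(dir, "soc.asc")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  rt <- read_asc(file.path(dir, "temperature_2011.asc"), quiet = TRUE)
  k <- which(sc$config$years == 2011)
  expect_equal(rt$values, sc$temperature$grids[[k]]$values)
})
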