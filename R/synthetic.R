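#' Configuration for a synthetic multi-year scene
#'
#' Describes a tropical-island-like stated world for the 23-year analysis
#' window: initial land-cover composition dominated by forest and cropland,
#' slow annual Markov transitions, a warm wet climate with a mild warming
#' and wetting trend, NPP responding linearly to climate, a static
#' log-normal topsoil carbon field, and optional deterministic
#' human-disturbance patches with known footprints.
#'
#' Defaults are fixed once to values a field scientist would call
#' realistic for a tropical monsoon island: mean temperature 24.5 degC
#' (range 23.8-26.2 in the study region), precipitation 1.75 m/yr
#' (1.0-2.5 m), a 0.03 degC/yr warming trend (about 0.3 degC per decade),
#' interannual noise of 0.3 degC and 0.15 m, NPP around 1500 g C m^-2
#' yr^-1, and land cover about two-thirds forest and one-third cropland.
#'
#' @param shape c(rows, cols) of the scene grid.
#' @param years vector of years (default 2000:2022, i.e. n = 23).
#' @param pixel_area_hm2 pixel area in hm^2.
#' @param class_proportions 7 initial class fractions summing to 1, in
#'   dictionary order (see [lulc_classes()]).
#' @param transition_matrix 7x7 annual Markov matrix; rows sum to 1.
#' @param climate_base c(T = degC, P = m).
#' @param climate_trend c(dT = degC/yr, dP = m/yr).
#' @param climate_noise_sd c(T = degC, P = m), both >= 0.
#' @param npp_coefficients c(c0, c1, c2, sd): NPP = c0 + c1*T + c2*P +
#'   noise, clipped at 0.
#' @param soc_mean,soc_sd mean and spatial sd of the static SOC field
#'   (kg C m^-2); log-normal.
#' @param human_patches list of `list(year =, rows = c(r1, r2), cols =
#'   c(c1, c2), target_class =)` deterministic conversions applied from
#'   `year` onward.
#' @param seed root RNG seed; per-variable child streams are derived from
#'   it so adding one variable does not perturb the others.
#' @return a `tercab_scene_config` list.
#' @export
scene_config <- function(shape = c(40, 40),
                         years = 2000:2022,
                         pixel_area_hm2 = 1,
                         class_proportions = c(cropland = 0.29, forest = 0.65,
                                               shrubland = 0.001, grassland = 0.003,
                                               water = 0.016, barren = 0.001,
                                               impervious = 0.039),
                         transition_matrix = default_transitions(),
                         climate_base = c(T = 24.5, P = 1.75),
                         climate_trend = c(dT = 0.03, dP = 0.002),
                         climate_noise_sd = c(T = 0.3, P = 0.15),
                         npp_coefficients = c(c0 = 200, c1 = 40, c2 = 200, sd = 80),
                         soc_mean = 5, soc_sd = 1.5,
                         human_patches = list(),
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  if (!all(dim(transition_matrix) == c(7, 7)) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stop("transition matrix must be 7x7 with non-negative rows summing to 1",
         call. = FALSE)
  if (any(climate_noise_sd < 0) || npp_coefficients[["sd"]] < 0)
    stop("noise sd must be >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape), years = as.integer(years),
                 pixel_area_hm2 = pixel_area_hm2,
                 class_proportions = class_proportions,
                 transition_matrix = transition_matrix,
                 climate_base = climate_base, climate_trend = climate_trend,
                 climate_noise_sd = climate_noise_sd,
                 npp_coefficients = npp_coefficients,
                 soc_mean = soc_mean, soc_sd = soc_sd,
                 human_patches = human_patches,
                 seed = as.integer(seed),
                 precip_unit = "m"),
            class = "tercab_scene_config")
}

#' Default annual land-cover transition matrix
#'
#' Near-diagonal transitions whose magnitudes mimic two decades of slow
#' cropland/forest exchange with modest urbanisation: about 0.5 percent of
#' any vegetated class turns over per year.
#'
#' @return 7x7 row-stochastic matrix in dictionary class order.
#' @export
default_transitions <- function() {
  cls <- names(lulc_classes())
  m <- diag(7) * 0
  dimnames(m) <- list(cls, cls)
  m["cropland", ] <- c(0.9930, 0.0045, 0, 0, 0.0005, 0, 0.0020)
  m["forest", ]   <- c(0.0040, 0.9955, 0, 0, 0, 0, 0.0005)
  m["shrubland", ] <- c(0.0010, 0.0040, 0.9950, 0, 0, 0, 0)
  m["grassland", ] <- c(0.0040, 0.0020, 0, 0.9920, 0.0005, 0, 0.0015)
  m["water", ]    <- c(0.0010, 0.0005, 0, 0, 0.9980, 0, 0.0005)
  m["barren", ]   <- c(0.0030, 0.0010, 0, 0.0005, 0.0005, 0.9940, 0.0010)
  m["impervious", ] <- c(0.0002, 0, 0, 0, 0.0003, 0, 0.9995)
  m
}

child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2551)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

smooth_field <- function(nr, nc, coefs) {
  # low-order 2-D polynomial on [0,1]^2; cheap smooth spatial structure
  r <- matrix(rep(seq(0, 1, length.out = nr), nc), nr, nc)
  c_ <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  coefs[1] + coefs[2] * r + coefs[3] * c_ + coefs[4] * r * c_ +
    coefs[5] * (r - 0.5)^2 + coefs[6] * (c_ - 0.5)^2
}

#' Generate a synthetic scene with known ground truth
#'
#' Land cover evolves by per-pixel Markov sampling from the annual
#' transition matrix, overridden deterministically by any configured
#' human-disturbance patches (the truth record keeps their footprints).
#' Temperature is a smooth elevation-lapsed field plus linear trend plus
#' white noise; precipitation is a smooth field plus trend plus noise,
#' floored at 0; NPP responds linearly to both and is clipped at 0; SOC is
#' a static log-normal field.  Static covariates (elevation, slope,
#' aspect, vegetation type, soil type, soil erosion, population, GDP) are
#' generated for the detector stage.  Everything is reproducible from the
#' root seed.
#'
#' @param config a [scene_config()].
#' @return a `tercab_scene` list: `config`, stacks `lulc`, `temperature`,
#'   `precipitation`, `npp` (each a `tercab_stack`), static grids `soc`,
#'   `covariates` (named list), and `truth` (trends and patch footprints).
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "tercab_scene_config"))
  nr <- config$shape[1]; nc <- config$shape[2]; npx <- nr * nc
  yrs <- config$years; ny <- length(yrs)
  tmpl <- grid_create(matrix(0, nr, nc), cellsize = 100, crs = "local-metric")
  as_grid <- function(v) grid_like(as.numeric(v), tmpl)

  # --- static fields -------------------------------------------------------
  set.seed(child_seed(config$seed, "elevation"))
  elev <- smooth_field(nr, nc, c(60, 150, 120, 200, 900, 700)) +
    matrix(stats::rnorm(npx, 0, 8), nr, nc)
  elev <- pmax(elev, 0)
  grad_r <- rbind(diff(elev), 0); grad_c <- cbind(t(diff(t(elev))), 0)
  slope_deg <- atan(sqrt(grad_r^2 + grad_c^2) / tmpl$cellsize) * 180 / pi
  aspect <- (atan2(grad_c, grad_r) * 180 / pi) %% 360

  set.seed(child_seed(config$seed, "soc"))
  mu <- log(config$soc_mean^2 / sqrt(config$soc_mean^2 + config$soc_sd^2))
  sg <- sqrt(log(1 + (config$soc_sd / config$soc_mean)^2))
  soc <- matrix(stats::rlnorm(npx, mu, sg), nr, nc)

  # --- land cover ----------------------------------------------------------
  set.seed(child_seed(config$seed, "lulc"))
  cls <- unname(lulc_classes())
  lulc0 <- matrix(sample(cls, npx, replace = TRUE, prob = config$class_proportions),
                  nr, nc)
  P <- config$transition_matrix
  cumP <- t(apply(P, 1, cumsum))
  cumP[, 7] <- 1  # guard against rounding drift in the last bin
  lulc_list <- vector("list", ny)
  cur <- lulc0
  patch_mask <- function(p) {
    m <- matrix(FALSE, nr, nc)
    m[p$rows[1]:p$rows[2], p$cols[1]:p$cols[2]] <- TRUE
    m
  }
  apply_patches <- function(m, yr) {
    for (p in config$human_patches)
      if (yr >= p$year) m[patch_mask(p)] <- p$target_class
    m
  }
  cur <- apply_patches(cur, yrs[1])
  lulc_list[[1]] <- as_grid(cur)
  identityP <- all(P == diag(7))
  for (k in seq_len(ny - 1L)) {
    if (!identityP) {
      u <- stats::runif(npx)
      nxt <- cur
      for (ci in cls) {
        sel <- cur == ci
        if (any(sel))
          nxt[sel] <- cls[findInterval(u[sel], cumP[ci, ], left.open = TRUE) + 1L]
      }
      cur <- nxt
    }
    cur <- apply_patches(cur, yrs[k + 1L])
    lulc_list[[k + 1L]] <- as_grid(cur)
  }

  # --- climate -------------------------------------------------------------
  lapse <- -0.006  # degC per m elevation
  t_base <- config$climate_base[["T"]] + lapse * (elev - mean(elev))
  set.seed(child_seed(config$seed, "temperature"))
  t_list <- lapply(seq_len(ny), function(k) {
    as_grid(t_base + config$climate_trend[["dT"]] * (k - 1) +
              matrix(stats::rnorm(npx, 0, config$climate_noise_sd[["T"]]), nr, nc))
  })
  set.seed(child_seed(config$seed, "precipitation"))
  p_base <- config$climate_base[["P"]] +
    smooth_field(nr, nc, c(0, 0.25, -0.15, 0.1, 0.3, 0.2)) - 0.15
  p_list <- lapply(seq_len(ny), function(k) {
    as_grid(pmax(p_base + config$climate_trend[["dP"]] * (k - 1) +
                   matrix(stats::rnorm(npx, 0, config$climate_noise_sd[["P"]]), nr, nc), 0))
  })

  # --- NPP -----------------------------------------------------------------
  set.seed(child_seed(config$seed, "npp"))
  co <- config$npp_coefficients
  npp_list <- lapply(seq_len(ny), function(k) {
    v <- co[["c0"]] + co[["c1"]] * t_list[[k]]$values +
      co[["c2"]] * p_list[[k]]$values +
      matrix(stats::rnorm(npx, 0, co[["sd"]]), nr, nc)
    as_grid(pmax(v, 0))
  })

  # --- socio-economic covariates ------------------------------------------
  set.seed(child_seed(config$seed, "social"))
  pop <- exp(smooth_field(nr, nc, c(3, -2, 2, 1, -3, 2)) +
               matrix(stats::rnorm(npx, 0, 0.4), nr, nc))
  gdp <- pop * exp(matrix(stats::rnorm(npx, 0, 0.3), nr, nc))
  set.seed(child_seed(config$seed, "soil"))
  soil_type <- 1 + (findInterval(as.vector(soc), stats::quantile(soc, c(0.3, 0.7))) +
                      sample(0:1, npx, TRUE, prob = c(0.85, 0.15)))
  soil_erosion <- 1 + findInterval(as.vector(slope_deg), c(2, 8, 20))
  veg_type <- ifelse(lulc0 == 2, 1 + (elev > stats::median(elev)),
                     ifelse(lulc0 == 1, 3, 4))

  truth <- list(
    climate_trend = config$climate_trend,
    npp_coefficients = config$npp_coefficients,
    patches = lapply(config$human_patches, function(p) {
      list(year = p$year, rows = p$rows, cols = p$cols,
           target_class = p$target_class,
           n_pixels = (p$rows[2] - p$rows[1] + 1L) * (p$cols[2] - p$cols[1] + 1L))
    })
  )
  structure(list(
    config = config,
    lulc = annual_stack(yrs, lulc_list),
    temperature = annual_stack(yrs, t_list),
    precipitation = annual_stack(yrs, p_list),
    npp = annual_stack(yrs, npp_list),
    soc = as_grid(soc),
    covariates = list(
      elevation = as_grid(elev), slope = as_grid(slope_deg),
      aspect = as_grid(aspect), vegetation_type = as_grid(veg_type),
      soil_type = as_grid(matrix(soil_type, nr, nc)),
      soil_erosion = as_grid(matrix(soil_erosion, nr, nc)),
      population = as_grid(pop), gdp = as_grid(gdp)
    ),
    truth = truth
  ), class = "tercab_scene")
}

#' @export
print.tercab_scene <- function(x, ...) {
  cat(sprintf("<tercab_scene> %d x %d pixels, years %d..%d, seed %d\n",
              x$config$shape[1], x$config$shape[2],
              min(x$config$years), max(x$config$years), x$config$seed))
  invisible(x)
}

#' Build a noise-free climate-driven carbon-balance stack
#'
#' Evaluates CB = a*T + b*P + c per pixel-year from the scene's climate
#' stacks with no residual term, so downstream attribution must recover
#' (a, b, c) exactly and assign the whole trend to climate.
#'
#' @param scene a `tercab_scene`.
#' @param a Mg hm^-2 per degC.
#' @param b Mg hm^-2 per m precipitation.
#' @param c intercept, Mg hm^-2.
#' @return a `tercab_stack` of CB grids.
#' @export
inject_climate_signal <- function(scene, a, b, c) {
  stopifnot(inherits(scene, "tercab_scene"))
  grids <- lapply(seq_along(scene$config$years), function(k) {
    grid_like(as.vector(a * scene$temperature$grids[[k]]$values +
                          b * scene$precipitation$grids[[k]]$values + c),
              scene$temperature$grids[[k]])
  })
  annual_stack(scene$config$years, grids)
}

#' Per-pixel yearly mask of a patch footprint
#' @param scene a `tercab_scene`.
#' @param patch one element of `scene$truth$patches`.
#' @return logical vector over pixels (column-major) marking the footprint.
#' @export
patch_footprint <- function(scene, patch) {
  nr <- scene$config$shape[1]; nc <- scene$config$shape[2]
  m <- matrix(FALSE, nr, nc)
  m[patch$rows[1]:patch$rows[2], patch$cols[1]:patch$cols[2]] <- TRUE
  as.vector(m)
}
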