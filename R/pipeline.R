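#' Write the rasters of a scene to an output directory
#'
#' Serialises every stack and static grid as ESRI ASCII rasters plus a
#' `truth.json` ground-truth record.
#'
#' @param scene a `tercab_scene`.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_scene <- function(scene, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wr_stack <- function(stack, stem) {
    vapply(seq_along(stack$years), function(k) {
      f <- file.path(outdir, sprintf("%s_%d.asc", stem, stack$years[k]))
      write_asc(stack$grids[[k]], f)
      f
    }, character(1))
  }
  files <- c(files, wr_stack(scene$lulc, "lulc"),
             wr_stack(scene$temperature, "temperature"),
             wr_stack(scene$precipitation, "precipitation"),
             wr_stack(scene$npp, "npp"))
  f <- file.path(outdir, "soc.asc"); write_asc(scene$soc, f); files <- c(files, f)
  for (nm in names(scene$covariates)) {
    f <- file.path(outdir, paste0(nm, ".asc"))
    write_asc(scene$covariates[[nm]], f); files <- c(files, f)
  }
  tf <- file.path(outdir, "truth.json")
  jsonlite::write_json(scene$truth, tf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, tf))
}

#' Default pipeline configuration
#'
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate","storage","nep","balance","trend","corr","attribute",
#'   "geodetect","transfer")`.
#' @param scene list of [scene_config()] overrides (e.g. `shape`, `seed`,
#'   `human_patches`).
#' @param pixel_area_hm2,pixel_area_km2 pixel areas used for summaries.
#' @return a config list suitable for [run_pipeline()].
#' @export
pipeline_config <- function(stages = c("simulate", "storage", "nep", "balance",
                                       "trend", "corr", "attribute",
                                       "geodetect", "transfer"),
                            scene = list(),
                            pixel_area_hm2 = 1,
                            pixel_area_km2 = 0.01) {
  list(stages = stages, scene = scene,
       pixel_area_hm2 = pixel_area_hm2, pixel_area_km2 = pixel_area_km2)
}

#' Run the carbon-balance pipeline end to end
#'
#' Chains the analysis on a synthetic scene: scene generation, carbon
#' storage bookkeeping, the NEP model, the carbon balance, per-pixel trend
#' classification, partial-correlation screening, residual-trend
#' attribution, the geographical detector and the land-use transfer
#' matrix.  Writes per-stage rasters (`.asc`), summary CSVs and a JSON run
#' log recording the seed and parameters.  Identical config + seed gives
#' identical outputs.
#'
#' @param config list from [pipeline_config()], or a path to a JSON file
#'   with the same structure.
#' @param outdir output directory.
#' @param seed root seed; overrides `config$scene$seed` when given.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("tercab_"),
                         seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stages <- config$stages
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc_args <- config$scene
  if (!is.null(seed)) sc_args$seed <- as.integer(seed)
  scfg <- do.call(scene_config, sc_args)
  scene <- generate_scene(scfg)
  if ("simulate" %in% stages) write_scene(scene, file.path(outdir, "scene"))

  res <- list(scene = scene)
  yrs <- scfg$years
  dens_tab <- carbon_density_table()
  a_hm2 <- config$pixel_area_hm2
  a_km2 <- config$pixel_area_km2

  cs_stack <- annual_stack(yrs, lapply(scene$lulc$grids, density_map, table = dens_tab))
  if ("storage" %in% stages) {
    st <- total_storage(scene$lulc$grids[[length(yrs)]], dens_tab, a_hm2)
    utils::write.csv(st$per_class, file.path(outdir, "storage_per_class.csv"),
                     row.names = FALSE)
    write_asc(st$density_map, file.path(outdir, "cs_density_final.asc"))
    res$storage <- st
  }

  nep_stack <- annual_stack(yrs, lapply(seq_along(yrs), function(k) {
    nep(scene$npp$grids[[k]], scene$temperature$grids[[k]],
        scene$precipitation$grids[[k]], scene$soc)$nep
  }))
  if ("nep" %in% stages) {
    for (k in seq_along(yrs))
      write_asc(nep_stack$grids[[k]], file.path(outdir, sprintf("nep_%d.asc", yrs[k])))
    res$nep <- nep_stack
  }

  cb_stack <- annual_stack(yrs, lapply(seq_along(yrs), function(k) {
    carbon_balance(cs_stack$grids[[k]], nep_stack$grids[[k]])
  }))
  if ("balance" %in% stages) {
    summ <- interannual_summary(cb_stack, scene$lulc, a_hm2)
    per_class <- as.data.frame(t(summ$per_class))
    utils::write.csv(cbind(summ$yearly, per_class),
                     file.path(outdir, "interannual.csv"), row.names = FALSE)
    for (k in seq_along(yrs))
      write_asc(cb_stack$grids[[k]], file.path(outdir, sprintf("cb_%d.asc", yrs[k])))
    res$balance <- summ
  }

  if ("trend" %in% stages) {
    tr <- trend_stack(cb_stack)
    write_asc(tr$slope, file.path(outdir, "slope.asc"))
    write_asc(tr$p, file.path(outdir, "pvalue.asc"))
    write_asc(tr$class, file.path(outdir, "class.asc"))
    ts <- trend_summary(tr$class, a_km2)
    utils::write.csv(ts$table, file.path(outdir, "trend_summary.csv"), row.names = FALSE)
    jsonlite::write_json(as.list(stats::setNames(trend_class_labels(), 1:5)),
                         file.path(outdir, "class_legend.json"), auto_unbox = TRUE)
    res$trend <- tr
  }

  if ("corr" %in% stages) {
    cr <- correlation_stack(cb_stack, scene$temperature, scene$precipitation)
    for (v in names(cr)) {
      write_asc(cr[[v]]$r, file.path(outdir, sprintf("pcor_%s.asc", v)))
      write_asc(cr[[v]]$class, file.path(outdir, sprintf("pcor_%s_class.asc", v)))
      utils::write.csv(correlation_summary(cr[[v]]$class, a_km2),
                       file.path(outdir, sprintf("pcor_%s_summary.csv", v)),
                       row.names = FALSE)
    }
    jsonlite::write_json(as.list(stats::setNames(correlation_class_labels(), 1:6)),
                         file.path(outdir, "pcor_legend.json"), auto_unbox = TRUE)
    res$corr <- cr
  }

  if ("attribute" %in% stages) {
    at <- attribution_stack(cb_stack, scene$temperature, scene$precipitation)
    write_asc(at$slope_cc, file.path(outdir, "cbcc_slope.asc"))
    write_asc(at$slope_ha, file.path(outdir, "cbha_slope.asc"))
    write_asc(at$scenario, file.path(outdir, "scenario.asc"))
    write_asc(at$contrib_cc, file.path(outdir, "contrib_cc.asc"))
    write_asc(at$contrib_ha, file.path(outdir, "contrib_ha.asc"))
    asum <- attribution_summary(at, a_km2)
    utils::write.csv(asum$by_direction, file.path(outdir, "attribution_summary.csv"),
                     row.names = FALSE)
    res$attribution <- at
    res$attribution_summary <- asum
  }

  if ("geodetect" %in% stages) {
    cb_mean <- grid_like(colMeans(stack_matrix(cb_stack)), cb_stack$grids[[1]])
    factors <- list(
      temperature = discretize(grid_like(colMeans(stack_matrix(scene$temperature)),
                                         cb_mean), k = 5),
      precipitation = discretize(grid_like(colMeans(stack_matrix(scene$precipitation)),
                                           cb_mean), k = 5),
      elevation = discretize(scene$covariates$elevation, k = 5),
      slope = discretize(scene$covariates$slope, k = 5),
      land_use = discretize(scene$lulc$grids[[length(yrs)]], categorical = TRUE),
      soil_type = discretize(scene$covariates$soil_type, categorical = TRUE),
      population = discretize(scene$covariates$population, k = 5),
      gdp = discretize(scene$covariates$gdp, k = 5)
    )
    rep_ <- factor_report(stats::setNames(list(cb_mean), "multiyear"), factors)
    utils::write.csv(rep_$q_table, file.path(outdir, "q_table.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(rep_$interactions[[1]]$q12),
                     file.path(outdir, "interaction_matrix.csv"))
    res$geodetector <- rep_
  }

  if ("transfer" %in% stages) {
    tm <- transfer_matrix(scene$lulc$grids[[1]], scene$lulc$grids[[length(yrs)]],
                          a_km2)
    write_transfer_matrix(tm, file.path(outdir, "transfer_matrix.csv"))
    res$transfer <- tm
  }

  log <- list(seed = scfg$seed, years = range(yrs), shape = scfg$shape,
              stages = stages, pixel_area_hm2 = a_hm2, pixel_area_km2 = a_km2,
              package_version = as.character(utils::packageVersion("tercab")),
              r_version = as.character(getRversion()))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches `tercab <stage> --outdir DIR --seed N [--shape R,C]` where
#' stage is `simulate` or `report` (all stages).  Intended for use from a
#' small Rscript wrapper; exposed as a function so it is testable.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the pipeline result.
#' @export
tercab_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: tercab <stage> [--outdir DIR] [--seed N]")
  stage <- args[[1]]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i)) args[[i + 1L]] else default
  }
  outdir <- opt("--outdir", "tercab_out")
  seed <- as.integer(opt("--seed", "1"))
  shape <- as.integer(strsplit(opt("--shape", "40,40"), ",")[[1]])
  stages <- if (stage == "report") {
    c("simulate", "storage", "nep", "balance", "trend", "corr",
      "attribute", "geodetect", "transfer")
  } else stage
  cfg <- pipeline_config(stages = stages, scene = list(shape = shape))
  run_pipeline(cfg, outdir = outdir, seed = seed)
}
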