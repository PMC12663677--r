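#' Create a georeferenced grid
#'
#' A `tercab_grid` is a light-weight single-band raster: a numeric matrix in
#' row-major map order (row 1 = northernmost row), an affine georeference
#' given by the lower-left corner and a square cell size, and an optional
#' coordinate reference string.  Nodata cells are stored as `NA` internally
#' and serialised with an explicit sentinel.
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length in CRS units (> 0).
#' @param crs coordinate reference identifier (free text, e.g. an EPSG code
#'   or proj string); `NA` means unspecified local coordinates.
#' @param nodata sentinel written to disk for `NA` cells.
#' @return an object of class `tercab_grid`.
#' @export
grid_create <- function(values, xll = 0, yll = 0, cellsize = 1,
                        crs = NA_character_, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L, cellsize > 0)
  structure(
    list(values = values, xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), crs = crs,
         nodata = as.numeric(nodata)),
    class = "tercab_grid"
  )
}

#' @export
print.tercab_grid <- function(x, ...) {
  cat(sprintf("<tercab_grid> %d x %d cells, cellsize %g, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  crs: %s | nodata cells: %d\n",
              ifelse(is.na(x$crs), "<local>", x$crs), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.tercab_grid <- function(x) dim(x$values)

#' Grid values as a matrix
#' @param grid a `tercab_grid`.
#' @return numeric matrix with `NA` for nodata.
#' @export
grid_values <- function(grid) {
  stopifnot(inherits(grid, "tercab_grid"))
  grid$values
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

#' Check that grids share shape and georeference
#'
#' All per-pixel operations require co-registered inputs; this stops with an
#' informative error when shapes or transforms disagree.
#'
#' @param ... grids (or lists of grids) to compare.
#' @return invisibly `TRUE`.
#' @export
assert_coregistered <- function(...) {
  gs <- list(...)
  gs <- unlist(lapply(gs, function(g) if (inherits(g, "tercab_grid")) list(g) else g),
               recursive = FALSE)
  if (length(gs) < 2L) return(invisible(TRUE))
  ref <- gs[[1L]]
  for (k in seq_along(gs)[-1L]) {
    if (!same_geometry(ref, gs[[k]]))
      stop("grids are not co-registered: grid ", k, " has shape ",
           paste(dim(gs[[k]]$values), collapse = "x"),
           " / origin (", gs[[k]]$xll, ",", gs[[k]]$yll, ") vs reference ",
           paste(dim(ref$values), collapse = "x"),
           " / origin (", ref$xll, ",", ref$yll, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a grid from an ESRI ASCII raster file
#'
#' Reads the plain-text ESRI ASCII grid interchange format (`.asc`): a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by the cell values, north row first.  If a
#' sidecar `.prj` file with the same stem exists its first line is taken as
#' the CRS; otherwise a warning is issued and local unit-square coordinates
#' are assumed.
#'
#' @param path path to the `.asc` file.
#' @param quiet suppress the missing-CRS warning.
#' @return a [grid_create()] object; sentinel cells are `NA`.
#' @export
read_asc <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (k in 1:6) {
    ln <- strsplit(trimws(readLines(con, n = 1L)), "[[:space:]]+")[[1L]]
    hdr[[tolower(ln[1L])]] <- as.numeric(ln[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  vals <- scan(con, what = double(), n = hdr$ncols * hdr$nrows, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("truncated ASCII grid: ", path, call. = FALSE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  prj <- sub("\\.asc$", ".prj", path)
  crs <- NA_character_
  if (file.exists(prj)) {
    crs <- readLines(prj, n = 1L)
  } else if (!quiet) {
    warning("no CRS sidecar for ", basename(path),
            "; assuming local unit coordinates", call. = FALSE)
  }
  grid_create(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, crs = crs, nodata = hdr$nodata_value)
}

#' Write a grid to an ESRI ASCII raster file
#'
#' @param grid a `tercab_grid`.
#' @param path output path (conventionally `.asc`).  A `.prj` sidecar is
#'   written when the grid carries a CRS.
#' @param digits significant digits used for the values (default keeps full
#'   double precision round-trips).
#' @return the path, invisibly.
#' @export
write_asc <- function(grid, path, digits = 17) {
  stopifnot(inherits(grid, "tercab_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cellsize),
    sprintf("NODATA_value %.10g", grid$nodata)
  ), con)
  fmt <- paste0("%.", digits, "g")
  writeLines(apply(m, 1L, function(r) paste(sprintf(fmt, r), collapse = " ")), con)
  if (!is.na(grid$crs)) writeLines(grid$crs, sub("\\.asc$", ".prj", path))
  invisible(path)
}

#' Align grids to a target geometry by nearest neighbour
#'
#' Every output grid gets the target's shape and transform; each target cell
#' takes the value of the source cell whose centre is nearest (snap-to-cell
#' lookup, no interpolation), so class-coded grids never acquire codes absent
#' from the source.  Target cells falling outside the source extent become
#' nodata; if no target cell overlaps the source at all, this is an error.
#'
#' @param grids a `tercab_grid` or list of them.
#' @param target grid defining the output geometry.
#' @param method resampling method; only `"nearest"` is supported.
#' @return a list of aligned grids (a single grid input returns a list of 1).
#' @export
align_stack <- function(grids, target, method = "nearest") {
  method <- match.arg(method, "nearest")
  if (inherits(grids, "tercab_grid")) grids <- list(grids)
  stopifnot(inherits(target, "tercab_grid"))
  nr <- nrow(target$values); nc <- ncol(target$values)
  # target cell-centre coordinates
  xc <- target$xll + (seq_len(nc) - 0.5) * target$cellsize
  yc <- target$yll + (nr - seq_len(nr) + 0.5) * target$cellsize
  lapply(grids, function(g) {
    if (same_geometry(g, target)) {
      out <- g
      out$crs <- target$crs
      return(out)
    }
    src <- g$values
    col_idx <- floor((xc - g$xll) / g$cellsize) + 1L
    row_idx <- floor((g$yll + nrow(src) * g$cellsize - yc) / g$cellsize) + 1L
    ok_c <- col_idx >= 1L & col_idx <= ncol(src)
    ok_r <- row_idx >= 1L & row_idx <= nrow(src)
    if (!any(ok_c) || !any(ok_r))
      stop("extents do not overlap: source grid cannot be aligned to target",
           call. = FALSE)
    out <- matrix(NA_real_, nr, nc)
    ri <- row_idx[ok_r]; ci <- col_idx[ok_c]
    out[ok_r, ok_c] <- src[ri, ci, drop = FALSE]
    grid_create(out, xll = target$xll, yll = target$yll,
                cellsize = target$cellsize, crs = target$crs,
                nodata = g$nodata)
  })
}

#' Bundle per-year grids into an annual stack
#'
#' @param years strictly increasing integer years.
#' @param grids list of co-registered grids, one per year.
#' @return an object of class `tercab_stack`.
#' @export
annual_stack <- function(years, grids) {
  years <- as.integer(years)
  if (length(years) != length(grids))
    stop("years and grids must have equal length", call. = FALSE)
  if (length(years) > 1L && any(diff(years) <= 0L))
    stop("years must be strictly increasing", call. = FALSE)
  stopifnot(all(vapply(grids, inherits, logical(1), "tercab_grid")))
  if (length(grids) > 1L) do.call(assert_coregistered, grids)
  structure(list(years = years, grids = grids), class = "tercab_stack")
}

#' @export
print.tercab_stack <- function(x, ...) {
  cat(sprintf("<tercab_stack> %d years (%d..%d), %d x %d cells\n",
              length(x$years), min(x$years), max(x$years),
              nrow(x$grids[[1]]$values), ncol(x$grids[[1]]$values)))
  invisible(x)
}

#' Flatten a stack to a years-by-pixels matrix
#'
#' Rows are years in order; columns are pixels in column-major matrix order.
#' Used by all per-pixel time-series statistics.
#'
#' @param stack a `tercab_stack`.
#' @return numeric matrix, `length(years)` rows.
#' @export
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "tercab_stack"))
  t(vapply(stack$grids, function(g) as.vector(g$values),
           numeric(length(stack$grids[[1]]$values))))
}

#' Rebuild a grid from a pixel vector using a template geometry
#' @param values vector of length `prod(dim(template))`, column-major.
#' @param template grid supplying shape and transform.
#' @return a `tercab_grid`.
#' @export
grid_like <- function(values, template) {
  stopifnot(inherits(template, "tercab_grid"))
  grid_create(matrix(values, nrow(template$values), ncol(template$values)),
              xll = template$xll, yll = template$yll,
              cellsize = template$cellsize, crs = template$crs,
              nodata = template$nodata)
}

#' Pixels with complete data across one or more stacks
#'
#' A pixel is kept only when every stack has a finite value in every year —
#' the single common mask used by all multi-year statistics, so sample size
#' never drifts between years.
#'
#' @param ... `tercab_stack` objects on a common geometry.
#' @return logical vector over pixels (column-major).
#' @export
complete_mask <- function(...) {
  stacks <- list(...)
  ok <- NULL
  for (s in stacks) {
    m <- stack_matrix(s)
    good <- colSums(!is.finite(m)) == 0L
    ok <- if (is.null(ok)) good else ok & good
  }
  ok
}
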