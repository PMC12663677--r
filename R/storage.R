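#' Land-cover class dictionary
#'
#' The seven-class land-cover legend used throughout the package (cropland,
#' forest, shrubland, grassland, water, barren, impervious), coded 1..7.
#'
#' @return named integer vector mapping class name to code.
#' @export
lulc_classes <- function() {
  c(cropland = 1L, forest = 2L, shrubland = 3L, grassland = 4L,
    water = 5L, barren = 6L, impervious = 7L)
}

#' Per-class four-pool carbon density table
#'
#' Loads a carbon-density table with one row per land-cover class and the
#' four pools in Mg/hm^2: aboveground biomass (`Ca`), belowground biomass
#' (`Cb`), soil organic carbon (`Cs`) and dead organic matter (`Cd`).  The
#' default is the Hainan tropical-island parameterisation shipped with the
#' package.
#'
#' @param path CSV with columns `class,name,Ca,Cb,Cs,Cd` (name optional);
#'   `NULL` loads the packaged default.
#' @return data frame with an additional `density` column (the pool sum).
#' @export
carbon_density_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "carbon_density_hainan.csv",
                        package = "tercab", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "Ca", "Cb", "Cs", "Cd")
  if (!all(need %in% names(tab)))
    stop("density table must have columns class,Ca,Cb,Cs,Cd", call. = FALSE)
  if (any(tab[c("Ca", "Cb", "Cs", "Cd")] < 0))
    stop("carbon densities must be non-negative", call. = FALSE)
  if (anyDuplicated(tab$class)) stop("duplicated class codes", call. = FALSE)
  tab$density <- tab$Ca + tab$Cb + tab$Cs + tab$Cd
  tab
}

#' Map land-cover classes to total carbon density
#'
#' Per pixel the carbon density is the sum of the four pools of its class
#' (Mg/hm^2).  Nodata propagates; a class code without a table row is an
#' error naming the offending code.
#'
#' @param lulc class-coded `tercab_grid`.
#' @param table a [carbon_density_table()].
#' @return density `tercab_grid`, Mg/hm^2.
#' @export
density_map <- function(lulc, table = carbon_density_table()) {
  stopifnot(inherits(lulc, "tercab_grid"))
  codes <- lulc$values
  seen <- sort(unique(codes[!is.na(codes)]))
  unknown <- setdiff(seen, table$class)
  if (length(unknown))
    stop("land-cover code(s) not in density table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  lut <- stats::setNames(table$density, table$class)
  out <- matrix(unname(lut[as.character(codes)]), nrow(codes), ncol(codes))
  grid_like(as.vector(out), lulc)
}

#' Total carbon storage by class
#'
#' Bookkeeping estimate of regional carbon storage: each class contributes
#' its area times its four-pool density sum.  Totals are reported in Tg
#' (1 Tg = 1e6 Mg) and per class; the pixelwise sum of the density map times
#' pixel area is the same number by construction.
#'
#' @param lulc class-coded `tercab_grid`.
#' @param table a [carbon_density_table()].
#' @param pixel_area_hm2 area of one pixel in hm^2 (> 0).
#' @return list with `density_map` (grid), `per_class` (data frame: class,
#'   name, area_hm2, storage_Mg, storage_Tg), `total_storage_Mg`,
#'   `total_storage_Tg`.
#' @export
total_storage <- function(lulc, table = carbon_density_table(),
                          pixel_area_hm2 = 1) {
  stopifnot(pixel_area_hm2 > 0)
  codes <- lulc$values[!is.na(lulc$values)]
  if (!length(codes)) stop("grid has no valid pixels", call. = FALSE)
  dmap <- density_map(lulc, table)
  cnt <- table(factor(codes, levels = table$class))
  per <- data.frame(
    class = table$class,
    name = if ("name" %in% names(table)) table$name else as.character(table$class),
    area_hm2 = as.numeric(cnt) * pixel_area_hm2,
    stringsAsFactors = FALSE
  )
  per$storage_Mg <- per$area_hm2 * table$density
  per$storage_Tg <- per$storage_Mg * 1e-6
  list(density_map = dmap,
       per_class = per,
       total_storage_Mg = sum(per$storage_Mg),
       total_storage_Tg = sum(per$storage_Tg))
}

#' Land-use transfer matrix between two years
#'
#' Cross-tabulates co-registered class grids: cell (i, j) is the area that
#' is class i in the start year and class j in the end year.  Pixels nodata
#' in either year are excluded (their count is reported) so that the grand
#' total is conserved on the common mask.
#'
#' @param lulc_start,lulc_end class-coded grids on one geometry.
#' @param pixel_area_km2 area of one pixel in km^2.
#' @param classes class codes defining row/column order (default the 7-class
#'   dictionary).
#' @return object of class `tercab_transfer`: `matrix` (areas km^2),
#'   `row_totals`, `col_totals`, `grand_total`, `excluded_pixels`.
#' @export
transfer_matrix <- function(lulc_start, lulc_end, pixel_area_km2 = 1,
                            classes = lulc_classes()) {
  assert_coregistered(lulc_start, lulc_end)
  a <- as.vector(lulc_start$values)
  b <- as.vector(lulc_end$values)
  keep <- !is.na(a) & !is.na(b)
  tab <- table(factor(a[keep], levels = classes),
               factor(b[keep], levels = classes))
  m <- unclass(tab) * pixel_area_km2
  dimnames(m) <- list(from = names(classes), to = names(classes))
  structure(
    list(matrix = m,
         row_totals = rowSums(m),
         col_totals = colSums(m),
         grand_total = sum(m),
         excluded_pixels = sum(!keep)),
    class = "tercab_transfer"
  )
}

#' Read a printed transfer matrix from CSV
#'
#' Reads a class-by-class area matrix with optional printed `total` row and
#' column.  Printed totals, when present, are kept as-is (they may differ
#' from recomputed cell sums in the last printed digit); otherwise totals
#' are computed from the cells.
#'
#' @param path CSV whose first column is the start-year class name and whose
#'   remaining columns are end-year classes (plus optional `total`).
#' @return a `tercab_transfer` object.
#' @export
read_transfer_matrix <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  has_tot_row <- tolower(rn[length(rn)]) == "total"
  has_tot_col <- tolower(colnames(body)[ncol(body)]) == "total"
  cls_rows <- if (has_tot_row) seq_len(length(rn) - 1L) else seq_along(rn)
  cls_cols <- if (has_tot_col) seq_len(ncol(body) - 1L) else seq_len(ncol(body))
  m <- body[cls_rows, cls_cols, drop = FALSE]
  rownames(m) <- rn[cls_rows]
  row_tot <- if (has_tot_col) stats::setNames(body[cls_rows, ncol(body)], rn[cls_rows])
             else rowSums(m)
  col_tot <- if (has_tot_row) stats::setNames(body[length(rn), cls_cols], colnames(m))
             else colSums(m)
  grand <- if (has_tot_row && has_tot_col) body[length(rn), ncol(body)] else sum(m)
  structure(
    list(matrix = m, row_totals = row_tot, col_totals = col_tot,
         grand_total = unname(grand), excluded_pixels = NA_integer_),
    class = "tercab_transfer"
  )
}

#' Change summaries of a transfer matrix
#'
#' Loss of class i is its row total minus the diagonal (area leaving i);
#' gain of class j is its column total minus the diagonal (area entering j);
#' total change is the sum of all off-diagonal cells.
#'
#' @param tm a `tercab_transfer`.
#' @return list with `loss`, `gain` (named vectors, km^2), `unchanged`
#'   (diagonal), and `total_change`.
#' @export
transfer_change <- function(tm) {
  stopifnot(inherits(tm, "tercab_transfer"))
  d <- diag(tm$matrix)
  list(loss = tm$row_totals - d,
       gain = tm$col_totals - d,
       unchanged = d,
       # via grand_total so the convention matches loss/gain (row totals
       # minus diagonal); identical to the off-diagonal cell sum except for
       # last-digit rounding in printed tables
       total_change = tm$grand_total - sum(d))
}

#' @export
print.tercab_transfer <- function(x, ...) {
  cat("<tercab_transfer> grand total", format(x$grand_total), "km^2\n")
  print(round(x$matrix, 2))
  invisible(x)
}

#' Write a transfer matrix (with totals) to CSV
#' @param tm a `tercab_transfer`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_transfer_matrix <- function(tm, path) {
  m <- rbind(cbind(tm$matrix, total = tm$row_totals),
             total = c(tm$col_totals, tm$grand_total))
  df <- data.frame(from = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
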