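#' Construct an elevation raster
#'
#' Cells are addressed `(row, col)` with row 1 at the north edge; the
#' origin `(xll, yll)` is the lower-left corner of the grid, matching the
#' Arc/Info ASCII Grid convention. Planar rasters have `cell_size` in
#' metres; geographic rasters in decimal degrees, with east--west cell
#' spacing shrinking towards the poles (handled by great-circle
#' distances).
#'
#' @param elevation numeric matrix of elevations in metres (`NA` = nodata).
#' @param cell_size positive cell size (metres or degrees).
#' @param xll,yll coordinates of the lower-left corner.
#' @param nodata_value sentinel written to file for `NA` cells.
#' @param crs_kind `"planar_metres"` or `"geographic_degrees"`.
#' @return Object of class `"dem_raster"`.
#' @export
dem_raster <- function(elevation, cell_size, xll = 0, yll = 0,
                       nodata_value = -9999,
                       crs_kind = c("planar_metres", "geographic_degrees")) {
  crs_kind <- match.arg(crs_kind)
  if (!is.matrix(elevation) || !is.numeric(elevation))
    stop("elevation must be a numeric matrix", call. = FALSE)
  stop_if_not_scalar_finite(cell_size, "cell_size")
  if (cell_size <= 0) stop("cell_size must be positive", call. = FALSE)
  if (any(!is.finite(elevation) & !is.na(elevation)))
    stop("elevations must be finite or NA", call. = FALSE)
  structure(
    list(elevation = elevation, n_rows = nrow(elevation),
         n_cols = ncol(elevation), cell_size = cell_size,
         xll = xll, yll = yll, nodata_value = nodata_value,
         crs_kind = crs_kind),
    class = "dem_raster"
  )
}

#' @export
print.dem_raster <- function(x, ...) {
  cat(sprintf("dem_raster: %d x %d cells, cell size %g (%s)\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs_kind))
  rng <- range(x$elevation, na.rm = TRUE)
  cat(sprintf("  elevation %g..%g m, %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$elevation))))
  invisible(x)
}

# Cell-centre coordinates. Row 1 is the north edge, so its centre sits at
# yll + (n_rows - 0.5) * cell_size.
cell_xy <- function(dem, row, col) {
  cbind(x = dem$xll + (col - 0.5) * dem$cell_size,
        y = dem$yll + (dem$n_rows - row + 0.5) * dem$cell_size)
}

cell_index <- function(row, col, n_cols) (row - 1L) * n_cols + col

index_rowcol <- function(idx, n_cols) {
  cbind(row = (idx - 1L) %/% n_cols + 1L, col = (idx - 1L) %% n_cols + 1L)
}

#' Read an Arc/Info ASCII Grid file
#'
#' Parses the standard header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`; case-insensitive) followed by
#' row-major elevation values, top row first.
#'
#' @param path path to a `.asc` file.
#' @param crs_kind coordinate interpretation of the grid; cell sizes below
#'   1 usually indicate decimal degrees.
#' @return A [dem_raster()].
#' @export
read_ascii_grid <- function(path, crs_kind = c("planar_metres",
                                               "geographic_degrees")) {
  crs_kind <- match.arg(crs_kind)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed header at line ", i, call. = FALSE)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("header missing: ", paste(setdiff(need, names(hdr)), collapse = ", "),
         call. = FALSE)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = " "),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " cells, found ", length(vals), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  dem_raster(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, nodata, crs_kind)
}

#' Write a raster to the Arc/Info ASCII Grid dialect
#' @param dem a [dem_raster()] (elevations, or any per-cell field such as
#'   a travel-time surface repacked with [as_dem_raster()]).
#' @param path output file path.
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(dem, path, digits = 6) {
  m <- dem$elevation
  m[is.na(m)] <- dem$nodata_value
  hdr <- c(sprintf("ncols %d", dem$n_cols),
           sprintf("nrows %d", dem$n_rows),
           sprintf("xllcorner %.10g", dem$xll),
           sprintf("yllcorner %.10g", dem$yll),
           sprintf("cellsize %.10g", dem$cell_size),
           sprintf("NODATA_value %.10g", dem$nodata_value))
  body <- apply(m, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Repack a per-cell field on an existing grid as a raster
#' @param values numeric matrix conformable with `template$elevation`.
#' @param template a [dem_raster()] supplying grid geometry.
#' @return A [dem_raster()] carrying `values`.
#' @export
as_dem_raster <- function(values, template) {
  dem_raster(values, template$cell_size, template$xll, template$yll,
             template$nodata_value, template$crs_kind)
}

#' Generate a synthetic terrain with a closed-form travel-time oracle
#'
#' Three terrain families used throughout testing: `plane` (constant
#' gradient, so travel along the gradient has an exact analytic time),
#' `cone` (apex at the grid centre with constant radial grade) and
#' `ridge` (a Gaussian wall along a column, for barrier/detour cases).
#' Optional seeded Gaussian micro-noise roughens the surface.
#'
#' @param kind `"plane"`, `"cone"` or `"ridge"`.
#' @param n_rows,n_cols grid size.
#' @param cell_size cell size (metres for planar grids).
#' @param base_elev elevation at the grid origin (plane) or background
#'   level (ridge), metres.
#' @param slope_x,slope_y plane gradient, metres of elevation per metre
#'   easting / northing.
#' @param apex_elev,grade cone apex elevation (m) and radial descent
#'   (m per m).
#' @param ridge_height,ridge_col,ridge_width ridge wall height (m),
#'   centre column, and Gaussian width in cells.
#' @param noise_sd standard deviation of seeded cell noise, metres.
#' @param seed integer seed for the noise; same seed, same terrain.
#' @param crs_kind,xll,yll grid georeferencing (see [dem_raster()]).
#' @return A [dem_raster()].
#' @export
synth_dem <- function(kind = c("plane", "cone", "ridge"),
                      n_rows = 20, n_cols = 20, cell_size = 1000,
                      base_elev = 3860, slope_x = 0, slope_y = 0,
                      apex_elev = 4500, grade = 0.05,
                      ridge_height = 500, ridge_col = NULL, ridge_width = 2,
                      noise_sd = 0, seed = NULL,
                      crs_kind = "planar_metres", xll = 0, yll = 0) {
  kind <- match.arg(kind)
  rows <- matrix(seq_len(n_rows), n_rows, n_cols)
  cols <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  x <- (cols - 0.5) * cell_size
  y <- (n_rows - rows + 0.5) * cell_size
  elev <- switch(kind,
    plane = base_elev + slope_x * x + slope_y * y,
    cone = {
      cx <- (n_cols / 2) * cell_size
      cy <- (n_rows / 2) * cell_size
      apex_elev - grade * sqrt((x - cx)^2 + (y - cy)^2)
    },
    ridge = {
      if (is.null(ridge_col)) ridge_col <- ceiling(n_cols / 2)
      base_elev + ridge_height *
        exp(-((cols - ridge_col) / ridge_width)^2)
    })
  if (noise_sd > 0)
    elev <- elev + with_seed(seed, matrix(stats::rnorm(n_rows * n_cols,
                                                       sd = noise_sd),
                                          n_rows, n_cols))
  dem_raster(elev, cell_size, xll, yll, crs_kind = crs_kind)
}
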