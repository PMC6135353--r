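#' Georeferenced raster grid
#'
#' A minimal planar raster container: a numeric matrix with a cell size in
#' metres, the (x, y) map coordinates of the upper-left corner, and a nodata
#' sentinel used on disk. Row 1 is the northmost row; cell `(r, c)` has its
#' centre at `(x + (c - 0.5) * cell_size, y - (r - 0.5) * cell_size)`.
#' Missing cells are held as `NA` in memory and written as the sentinel.
#'
#' @param values Numeric matrix (rows x cols).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin Length-2 numeric, map coordinates of the upper-left corner.
#' @param nodata Sentinel written to disk for `NA` cells.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1000,
                        origin = c(0, nrow(values) * cell_size),
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0,
            length(origin) == 2L)
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d x %d cells, %.0f m cell size\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  origin (UL): %.1f, %.1f; nodata: %g\n",
              x$origin[1], x$origin[2], x$nodata))
  if (length(v)) {
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
as.matrix.raster_grid <- function(x, ...) x$values

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Map coordinates of cell centres
#'
#' @param grid A `raster_grid`.
#' @param rows,cols 1-based row/column indices (vectorised, recycled).
#' @return A two-column matrix of (x, y) centre coordinates.
#' @export
cell_centres <- function(grid, rows, cols) {
  stopifnot(is_raster_grid(grid))
  cbind(x = grid$origin[1] + (cols - 0.5) * grid$cell_size,
        y = grid$origin[2] - (rows - 0.5) * grid$cell_size)
}

#' Check that rasters share shape, cell size and origin
#'
#' All multi-raster pipeline stages require aligned inputs; misalignment is
#' a loud error, never a silent resample.
#'
#' @param grids A list of at least two `raster_grid` objects.
#' @param tol Metric tolerance for cell size and origin comparisons.
#' @return Invisibly `TRUE`; otherwise an error naming the first mismatch.
#' @export
check_aligned <- function(grids, tol = 1e-6) {
  stopifnot(is.list(grids), length(grids) >= 2L)
  ref <- grids[[1L]]
  stopifnot(is_raster_grid(ref))
  for (i in seq_along(grids)[-1L]) {
    g <- grids[[i]]
    stopifnot(is_raster_grid(g))
    if (!identical(dim(g$values), dim(ref$values))) {
      stop(sprintf("raster %d misaligned: shape %dx%d vs %dx%d", i,
                   nrow(g$values), ncol(g$values),
                   nrow(ref$values), ncol(ref$values)), call. = FALSE)
    }
    if (abs(g$cell_size - ref$cell_size) > tol) {
      stop(sprintf("raster %d misaligned: cell_size %g vs %g", i,
                   g$cell_size, ref$cell_size), call. = FALSE)
    }
    if (any(abs(g$origin - ref$origin) > tol)) {
      stop(sprintf("raster %d misaligned: origin (%g, %g) vs (%g, %g)", i,
                   g$origin[1], g$origin[2], ref$origin[1], ref$origin[2]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a raster from disk
#'
#' Supports the ESRI ASCII grid format (`.asc`), a lossless plain-text
#' interchange format: a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of values,
#' north row first.
#'
#' @param path File path.
#' @param format Only `"esri_ascii"` is supported.
#' @return A `raster_grid`.
#' @export
read_raster <- function(path, format = "esri_ascii") {
  format <- match.arg(format, c("esri_ascii", "geotiff"))
  if (format == "geotiff") {
    stop("GeoTIFF is not supported by this build; use ESRI ASCII grid",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("malformed ESRI ASCII grid: ", path, call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L) stop("malformed header line: ", lines[i], call. = FALSE)
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("ESRI ASCII header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  }
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc) {
    stop(sprintf("expected %d values, found %d in %s", nr * nc, length(body),
                 path), call. = FALSE)
  }
  vals <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  vals[vals == hdr$nodata_value] <- NA_real_
  raster_grid(vals, cell_size = hdr$cellsize,
              origin = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize),
              nodata = hdr$nodata_value)
}

#' Write a raster to disk
#'
#' @param grid A `raster_grid`.
#' @param path Output path.
#' @param format Only `"esri_ascii"` is supported.
#' @param digits Significant digits; the default round-trips doubles exactly.
#' @return Invisibly `path`.
#' @export
write_raster <- function(grid, path, format = "esri_ascii", digits = 17) {
  stopifnot(is_raster_grid(grid))
  format <- match.arg(format, c("esri_ascii", "geotiff"))
  if (format == "geotiff") {
    stop("GeoTIFF is not supported by this build; use ESRI ASCII grid",
         call. = FALSE)
  }
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %s", formatC(grid$origin[1], format = "g", digits = 17)),
    sprintf("yllcorner %s", formatC(grid$origin[2] - nr * grid$cell_size,
                                    format = "g", digits = 17)),
    sprintf("cellsize %s", formatC(grid$cell_size, format = "g", digits = 17)),
    sprintf("NODATA_value %s", formatC(grid$nodata, format = "g", digits = 17))
  )
  v[is.na(v)] <- grid$nodata
  rows <- apply(v, 1L, function(r) {
    paste(formatC(r, format = "g", digits = digits), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}
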