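#' Threshold a connectivity surface into binary habitat
#'
#' The threshold is a percentile (linear-interpolation quantile) of the
#' reference surface — by default over its positive values only, since
#' kernel and path-density surfaces are dominated by structural zeros that
#' would otherwise collapse low percentiles to 0. Cells strictly greater
#' than the threshold become 1.
#'
#' @param surface A `raster_grid` to classify.
#' @param reference An aligned `raster_grid` whose value distribution sets
#'   the threshold (typically the first epoch's surface, so one threshold
#'   is shared across epochs).
#' @param percentile Percentile in (0, 100); default 10.
#' @param positive_only If `TRUE` (default) the percentile is taken over
#'   positive reference values; if `FALSE`, over all non-nodata values.
#' @return A `binary_habitat` list: `raster` of 0/1, `threshold_value`,
#'   `percentile`, `reference_epoch`.
#' @export
threshold_to_binary <- function(surface, reference = surface,
                                percentile = 10, positive_only = TRUE) {
  stopifnot(percentile > 0, percentile < 100)
  check_aligned(list(surface, reference))
  refv <- reference$values[!is.na(reference$values)]
  if (positive_only) refv <- refv[refv > 0]
  if (!length(refv)) {
    stop("reference surface has no positive values; threshold undefined",
         call. = FALSE)
  }
  thr <- quantile(refv, percentile / 100, type = 7, names = FALSE)
  b <- ifelse(surface$values > thr, 1, 0)
  b[is.na(surface$values)] <- NA_real_
  structure(
    list(raster = raster_grid(b, cell_size = surface$cell_size,
                              origin = surface$origin,
                              nodata = surface$nodata),
         threshold_value = thr, percentile = percentile),
    class = "binary_habitat"
  )
}

#' Label patches of connected habitat
#'
#' Connected components of the 1-cells under 8-neighbour adjacency (cells
#' sharing an edge or a corner join the same patch — the FRAGSTATS
#' default). For each patch the area, the centroid of the cell centres in
#' map coordinates, and the radius of gyration — the mean Euclidean
#' distance from each cell centre to the patch centroid (FRAGSTATS GYRATE)
#' — are computed.
#'
#' @param binary A `binary_habitat` (or a `raster_grid` of 0/1).
#' @param connectivity 8 (default) or 4.
#' @return A `patch_set` list: `labels` raster (0 = background), `patches`
#'   data frame (`id`, `n_cells`, `area_m2`, `centroid_x`, `centroid_y`,
#'   `gyrate_m`).
#' @export
label_patches <- function(binary, connectivity = 8) {
  grid <- if (inherits(binary, "binary_habitat")) binary$raster else binary
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hab <- which(!is.na(v) & v == 1)
  labels <- matrix(0, nr, nc)
  labels[is.na(v)] <- NA_real_
  if (!length(hab)) {
    return(structure(list(labels = raster_grid(labels, grid$cell_size,
                                               grid$origin, grid$nodata),
                          patches = data.frame(id = integer(),
                                               n_cells = integer(),
                                               area_m2 = numeric(),
                                               centroid_x = numeric(),
                                               centroid_y = numeric(),
                                               gyrate_m = numeric()),
                          cell_size = grid$cell_size),
                     class = "patch_set"))
  }
  # adjacency among habitat cells only
  hr <- row(v)[hab]; hc <- col(v)[hab]
  rm_id <- (hr - 1L) * nc + hc
  in_hab <- logical(nr * nc); in_hab[rm_id] <- TRUE
  idx_of <- integer(nr * nc); idx_of[rm_id] <- seq_along(hab)
  nbr <- if (connectivity == 8) {
    list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  } else list(c(0, 1), c(1, 0))
  efrom <- integer(0); eto <- integer(0)
  for (d in nbr) {
    r2 <- hr + d[1]; c2 <- hc + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    id2 <- (r2[ok] - 1L) * nc + c2[ok]
    hit <- in_hab[id2]
    efrom <- c(efrom, idx_of[rm_id[ok]][hit])
    eto <- c(eto, idx_of[id2][hit])
  }
  g <- igraph::make_graph(as.vector(rbind(efrom, eto)), n = length(hab),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[hab] <- comp
  cs <- grid$cell_size
  xy <- cell_centres(grid, hr, hc)
  patches <- do.call(rbind, lapply(split(seq_along(hab), comp), function(ii) {
    cx <- mean(xy[ii, 1]); cy <- mean(xy[ii, 2])
    gy <- mean(sqrt((xy[ii, 1] - cx)^2 + (xy[ii, 2] - cy)^2))
    data.frame(id = comp[ii[1]], n_cells = length(ii),
               area_m2 = length(ii) * cs^2,
               centroid_x = cx, centroid_y = cy, gyrate_m = gy)
  }))
  rownames(patches) <- NULL
  structure(list(labels = raster_grid(labels, cs, grid$origin, grid$nodata),
                 patches = patches, cell_size = cs),
            class = "patch_set")
}

#' Landscape pattern metrics of a patch set
#'
#' PLAND (habitat percentage of the landscape), LPI (largest patch as a
#' percentage of the landscape), number of patches, and correlation length
#' — the area-weighted mean radius of gyration, the average within-patch
#' traversal distance.
#'
#' @param patches A `patch_set`.
#' @param landscape_cells Total number of landscape (non-nodata) cells.
#' @return A `metrics_report` data frame row: `pland`, `lpi`, `n_patches`,
#'   `correlation_length_m`.
#' @export
compute_metrics <- function(patches, landscape_cells) {
  stopifnot(landscape_cells > 0)
  p <- patches$patches
  if (!nrow(p)) {
    out <- data.frame(pland = 0, lpi = 0, n_patches = 0L,
                      correlation_length_m = 0)
  } else {
    out <- data.frame(
      pland = 100 * sum(p$n_cells) / landscape_cells,
      lpi = 100 * max(p$n_cells) / landscape_cells,
      n_patches = nrow(p),
      correlation_length_m = sum(p$n_cells / sum(p$n_cells) * p$gyrate_m)
    )
  }
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Relative change between two metric values, in percent
#'
#' @param before,after Metric values; `before` must be non-zero.
#' @return `100 * (after - before) / before`.
#' @export
relative_change <- function(before, after) {
  if (any(before == 0)) stop("relative change undefined for before = 0",
                             call. = FALSE)
  100 * (after - before) / before
}
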