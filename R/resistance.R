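#' Convert habitat suitability to landscape resistance
#'
#' Inverts and rescales suitability linearly so the best observed habitat
#' has resistance exactly 1 and the worst exactly 100:
#' `r = 1 + 99 * (s_max - s) / (s_max - s_min)`.
#'
#' @param s Suitability values in `[s_min, s_max]` (vectorised).
#' @param s_min,s_max Scale endpoints, `s_min < s_max`.
#' @return Resistance values in \[1, 100\].
#' @export
suitability_to_resistance <- function(s, s_min, s_max) {
  stopifnot(s_min < s_max)
  if (any(s < s_min - 1e-12 | s > s_max + 1e-12, na.rm = TRUE)) {
    stop("suitability outside [s_min, s_max]", call. = FALSE)
  }
  1 + 99 * (s_max - s) / (s_max - s_min)
}

#' @rdname suitability_to_resistance
#' @param r Resistance values in \[1, 100\].
#' @export
resistance_to_suitability <- function(r, s_min, s_max) {
  stopifnot(s_min < s_max)
  s_max - (r - 1) * (s_max - s_min) / 99
}

new_resistance <- function(raster, epoch_label) {
  v <- raster$values
  if (any(v < 1 - 1e-9 | v > 100 + 1e-9, na.rm = TRUE)) {
    stop("resistance values must lie in [1, 100]", call. = FALSE)
  }
  structure(list(raster = raster, epoch_label = epoch_label),
            class = "resistance_grid")
}

#' @export
print.resistance_grid <- function(x, ...) {
  v <- x$raster$values
  cat(sprintf("resistance_grid '%s': %d x %d cells, range [%.2f, %.2f]\n",
              x$epoch_label, nrow(v), ncol(v),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

# Bilinear resampling of a raster to a coarser integer-multiple cell size.
# Each target cell centre is interpolated from the four surrounding source
# cell centres (clamped at the borders); NA neighbours are dropped and the
# remaining weights renormalised.
bilinear_resample <- function(grid, target_cell_size) {
  f <- target_cell_size / grid$cell_size
  if (abs(f - round(f)) > 1e-9 || f < 1) {
    stop("target cell size must be an integer multiple of the source",
         call. = FALSE)
  }
  f <- round(f)
  if (f == 1L) return(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  nr2 <- floor(nr / f); nc2 <- floor(nc / f)
  if (nr2 < 1 || nc2 < 1) stop("grid too small for that resampling factor",
                               call. = FALSE)
  # 0-based fractional position of each target cell centre in source
  # cell-centre coordinates
  pos <- function(j) (j - 0.5) * f - 0.5
  out <- matrix(NA_real_, nr2, nc2)
  ri <- pos(seq_len(nr2)); ci <- pos(seq_len(nc2))
  r0 <- pmin(pmax(floor(ri), 0), nr - 1); r1 <- pmin(r0 + 1, nr - 1)
  c0 <- pmin(pmax(floor(ci), 0), nc - 1); c1 <- pmin(c0 + 1, nc - 1)
  wr <- ri - floor(ri); wc <- ci - floor(ci)
  for (i in seq_len(nr2)) {
    for (j in seq_len(nc2)) {
      vs <- c(grid$values[r0[i] + 1, c0[j] + 1],
              grid$values[r0[i] + 1, c1[j] + 1],
              grid$values[r1[i] + 1, c0[j] + 1],
              grid$values[r1[i] + 1, c1[j] + 1])
      ws <- c((1 - wr[i]) * (1 - wc[j]), (1 - wr[i]) * wc[j],
              wr[i] * (1 - wc[j]), wr[i] * wc[j])
      ok <- !is.na(vs)
      out[i, j] <- if (any(ok)) sum(vs[ok] * ws[ok]) / sum(ws[ok]) else NA_real_
    }
  }
  raster_grid(out, cell_size = target_cell_size, origin = grid$origin,
              nodata = grid$nodata)
}

#' Build a resistance raster from land cover and a suitability table
#'
#' Looks up each cell's class mean suitability, converts it with
#' [suitability_to_resistance()] using the observed minimum and maximum
#' class means as the scale endpoints (so both endpoints are attained),
#' then optionally resamples to a coarser cell size with bilinear
#' interpolation.
#'
#' @param landcover A `landcover_grid`.
#' @param table A `suitability_table` covering every class present.
#' @param target_cell_size Output cell size in metres; must be an integer
#'   multiple of the land-cover cell size. Default keeps the source size.
#' @return A `resistance_grid`.
#' @export
build_resistance <- function(landcover, table,
                             target_cell_size = landcover$raster$cell_size) {
  present <- unique(landcover$raster$values[!is.na(landcover$raster$values)])
  missing_cl <- setdiff(present, table$class_code)
  if (length(missing_cl)) {
    stop("classes missing from suitability table: ",
         paste(missing_cl, collapse = ", "), call. = FALSE)
  }
  s_min <- min(table$mean_suitability)
  s_max <- max(table$mean_suitability)
  res_by_class <- suitability_to_resistance(table$mean_suitability,
                                            s_min, s_max)
  idx <- match(landcover$raster$values, table$class_code)
  vals <- matrix(res_by_class[idx], nrow(landcover$raster$values))
  r <- raster_grid(vals, cell_size = landcover$raster$cell_size,
                   origin = landcover$raster$origin,
                   nodata = landcover$raster$nodata)
  r <- bilinear_resample(r, target_cell_size)
  # bilinear interpolation of values in [1,100] stays in [1,100]; clamp
  # only against floating-point dust
  r$values[] <- pmin(100, pmax(1, r$values))
  new_resistance(r, landcover$epoch_label)
}

#' Project resistance forward under a deforestation-risk surface
#'
#' In the default `"literal"` mode the projected resistance is
#' `min(100, r_now + risk * r_transition)`: the per-cell deforestation
#' probability times the resistance the cell would have as
#' plantations/regrowth, added to the current resistance and clipped at the
#' scale maximum. The `"expectation"` mode instead forms the probabilistic
#' mixture `r_now + risk * (r_transition - r_now)`, which cannot exceed the
#' transition resistance. Cells with zero risk are unchanged in both modes.
#'
#' @param r_now A `resistance_grid`.
#' @param risk Aligned `raster_grid` of probabilities in \[0, 1\].
#' @param r_transition Resistance of the transition class, in \[1, 100\].
#' @param mode `"literal"` or `"expectation"`.
#' @param epoch_label Label for the projected epoch.
#' @return A `resistance_grid`.
#' @export
project_future_resistance <- function(r_now, risk, r_transition,
                                      mode = c("literal", "expectation"),
                                      epoch_label = paste0(r_now$epoch_label,
                                                           "+")) {
  mode <- match.arg(mode)
  check_aligned(list(r_now$raster, risk))
  stopifnot(r_transition >= 1, r_transition <= 100)
  p <- risk$values
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("risk values must lie in [0, 1]", call. = FALSE)
  }
  v <- r_now$raster$values
  out <- v
  out[] <- switch(mode,
                  literal = pmin(100, v + p * r_transition),
                  expectation = v + p * (r_transition - v))
  g <- raster_grid(out, cell_size = r_now$raster$cell_size,
                   origin = r_now$raster$origin, nodata = r_now$raster$nodata)
  new_resistance(g, epoch_label)
}

source_point_set <- function(df, threshold, seed, epoch_label) {
  structure(df, threshold = threshold, seed = seed,
            epoch_label = epoch_label,
            class = c("source_points", "data.frame"))
}

uniform_grid <- function(dims, seed) {
  with_seed(seed, matrix(runif(prod(dims)), dims[1], dims[2]))
}

#' Seed disperser source points from a resistance surface
#'
#' Draws one uniform random number per cell, weights it by the reciprocal
#' of resistance (`w = u / r`), and selects exactly `n_target` cells with
#' the largest weights; the stored threshold is the `n_target`-th largest
#' weight (ties broken by row-major cell order). Habitat quality thereby
#' controls the seeding density while the random grid keeps placement
#' stochastic and reproducible.
#'
#' @param r A `resistance_grid`.
#' @param n_target Number of source points to select.
#' @param seed Seed for the uniform grid.
#' @return A `source_points` data frame (`row`, `col`, `weight`) with
#'   attributes `threshold`, `seed`, `epoch_label`.
#' @export
seed_source_points <- function(r, n_target, seed = 1) {
  v <- r$raster$values
  ok <- which(!is.na(v))
  if (n_target > length(ok)) {
    stop("n_target exceeds the number of non-nodata cells", call. = FALSE)
  }
  u <- uniform_grid(dim(v), seed)
  w <- u / v
  # row-major index for deterministic tie-breaking
  rm_idx <- (row(v) - 1L) * ncol(v) + col(v)
  ord <- order(-w[ok], rm_idx[ok])
  sel <- ok[ord[seq_len(n_target)]]
  thr <- w[ok][ord[n_target]]
  df <- data.frame(row = row(v)[sel], col = col(v)[sel], weight = w[sel])
  df <- df[order(df$row, df$col), ]
  rownames(df) <- NULL
  source_point_set(df, threshold = thr, seed = seed,
                   epoch_label = r$epoch_label)
}

#' Reapply a stored seeding threshold to another epoch's resistance
#'
#' Regenerates the same uniform grid (same seed), reweights it by the new
#' epoch's resistance, and keeps every cell whose weight still reaches the
#' stored threshold. Because `w = u / r` is non-increasing in resistance,
#' epochs with higher resistance yield fewer points.
#'
#' @param r A `resistance_grid` for the new epoch.
#' @param threshold Threshold from the reference epoch's
#'   [seed_source_points()] call.
#' @param seed The same seed used for the reference epoch.
#' @return A `source_points` data frame.
#' @export
reapply_threshold <- function(r, threshold, seed = 1) {
  v <- r$raster$values
  u <- uniform_grid(dim(v), seed)
  w <- u / v
  sel <- which(!is.na(w) & w >= threshold)
  df <- data.frame(row = row(v)[sel], col = col(v)[sel], weight = w[sel])
  df <- df[order(df$row, df$col), ]
  rownames(df) <- NULL
  source_point_set(df, threshold = threshold, seed = seed,
                   epoch_label = r$epoch_label)
}
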