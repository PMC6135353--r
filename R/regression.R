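#' Assemble the per-point predictor table for diversity regression
#'
#' One row per source point with non-missing local diversity; predictors
#' are sampled at the point's cell (nearest-cell, no interpolation): the
#' focal mean landscape resistance within `focal_radius`, the (smoothed)
#' least-cost-path density, and the cumulative resistant kernel value.
#'
#' @param points A `source_points` data frame.
#' @param resistance A `resistance_grid`.
#' @param kernel A `kernel_surface` (or aligned `raster_grid`).
#' @param lcp A `path_density` (or aligned `raster_grid`), normally the
#'   focal-mean smoothed surface.
#' @param diversity A `local_diversity` data frame, rows in point order.
#' @param focal_radius Radius in metres for the resistance focal mean.
#' @return A `predictor_table` data frame: `point`, `row`, `col`,
#'   `focal_resistance`, `lcp_density`, `kernel_density`, `local_alleles`,
#'   `local_ho`.
#' @export
assemble_predictor_table <- function(points, resistance, kernel, lcp,
                                     diversity, focal_radius = 10000) {
  kgrid <- if (inherits(kernel, "kernel_surface")) kernel$raster else kernel
  lgrid <- if (inherits(lcp, "path_density")) lcp$raster else lcp
  check_aligned(list(resistance$raster, kgrid, lgrid))
  stopifnot(nrow(diversity) == nrow(points))
  fm <- focal_mean(resistance$raster, focal_radius)
  idx <- cbind(points$row, points$col)
  out <- data.frame(point = seq_len(nrow(points)),
                    row = points$row, col = points$col,
                    focal_resistance = fm$values[idx],
                    lcp_density = lgrid$values[idx],
                    kernel_density = kgrid$values[idx],
                    local_alleles = diversity$local_alleles,
                    local_ho = diversity$local_ho)
  out <- out[!is.na(out$local_alleles) & !is.na(out$local_ho), ]
  if (!nrow(out)) stop("no points with non-missing local diversity",
                       call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("predictor_table", "data.frame")
  out
}

#' Compare single-predictor and global diversity models
#'
#' Ordinary least squares of a local-diversity response on each predictor
#' alone and on all three together. The kernel predictor enters as
#' `1 / (kernel + eps)` (reciprocal transform linearising the saturating
#' diversity-connectivity relationship), with `eps` the smallest positive
#' kernel value as a zero guard. Deviance explained for Gaussian least
#' squares equals R-squared. LOWESS curves (span 2/3) of the response
#' against each raw predictor are attached for plotting.
#'
#' @param table A `predictor_table`.
#' @param response `"alleles"` or `"ho"`.
#' @param kernel_transform `"reciprocal"` (default) or `"identity"`.
#' @return A `diversity_models` list: `comparison` data frame (`model`,
#'   `deviance_explained`), `fits` (the `lm` objects), `lowess` curves,
#'   `response`, `epsilon`.
#' @export
fit_diversity_models <- function(table, response = c("alleles", "ho"),
                                 kernel_transform = c("reciprocal",
                                                      "identity")) {
  response <- match.arg(response)
  kernel_transform <- match.arg(kernel_transform)
  if (nrow(table) < 10L) stop("need at least 10 rows", call. = FALSE)
  y <- if (response == "alleles") table$local_alleles else table$local_ho
  pos <- table$kernel_density[table$kernel_density > 0]
  eps <- if (length(pos)) min(pos) else 1
  kern <- switch(kernel_transform,
                 reciprocal = 1 / (table$kernel_density + eps),
                 identity = table$kernel_density)
  d <- data.frame(y = y, resistance = table$focal_resistance,
                  lcp = table$lcp_density, kernel = kern)
  for (nm in c("resistance", "lcp", "kernel")) {
    if (stats::var(d[[nm]]) == 0) {
      stop("predictor '", nm, "' is constant; fit undefined", call. = FALSE)
    }
  }
  forms <- list(resistance = y ~ resistance, lcp = y ~ lcp,
                kernel = y ~ kernel,
                global = y ~ resistance + lcp + kernel)
  fits <- lapply(forms, function(f) stats::lm(f, data = d))
  if (anyNA(coef(fits$global))) {
    stop("singular design: collinear predictors in the global model",
         call. = FALSE)
  }
  comparison <- data.frame(
    model = names(fits),
    deviance_explained = vapply(fits, function(f) summary(f)$r.squared, 0)
  )
  rownames(comparison) <- NULL
  lows <- list(
    resistance = lowess(table$focal_resistance, y, f = 2 / 3),
    lcp = lowess(table$lcp_density, y, f = 2 / 3),
    kernel = lowess(table$kernel_density, y, f = 2 / 3)
  )
  structure(list(comparison = comparison, fits = fits, lowess = lows,
                 response = response, epsilon = eps),
            class = "diversity_models")
}

#' @export
print.diversity_models <- function(x, ...) {
  cat(sprintf("diversity_models (response: %s)\n", x$response))
  print(x$comparison, row.names = FALSE)
  invisible(x)
}
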