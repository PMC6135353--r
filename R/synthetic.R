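#' Land-cover class table
#'
#' Defines the categorical legend shared by all land-cover rasters: integer
#' class codes, names, which classes are forest, and the single class that
#' deforested cells transition into (the plantations/regrowth analogue).
#'
#' @param codes Integer class codes (unique).
#' @param names Character class names.
#' @param is_forest Logical, one per class.
#' @param transition_code Code of the class deforested cells become; must be
#'   a non-forest class in `codes`.
#' @return A `class_table` data frame with attribute `transition_code`.
#' @export
class_table <- function(codes, names, is_forest, transition_code) {
  codes <- as.integer(codes)
  stopifnot(length(codes) == length(names),
            length(codes) == length(is_forest),
            !anyDuplicated(codes))
  if (!any(is_forest) || all(is_forest)) {
    stop("class table needs at least one forest and one non-forest class",
         call. = FALSE)
  }
  transition_code <- as.integer(transition_code)
  if (!transition_code %in% codes || is_forest[match(transition_code, codes)]) {
    stop("`transition_code` must name a non-forest class", call. = FALSE)
  }
  out <- data.frame(class_code = codes, class_name = names,
                    is_forest = as.logical(is_forest),
                    stringsAsFactors = FALSE)
  attr(out, "transition_code") <- transition_code
  class(out) <- c("class_table", "data.frame")
  out
}

#' Default Borneo-like land-cover legend
#'
#' Eight classes typical of an insular SE-Asian forest landscape, with the
#' panel-consensus habitat-suitability of each class (1 worst, 5 best) for a
#' forest-dependent felid carried as the `true_suitability` attribute.
#' Deforested cells transition to plantations/regrowth.
#'
#' @return A `class_table` with a `true_suitability` attribute (named by code).
#' @export
default_classes <- function() {
  ct <- class_table(
    codes = 1:8,
    names = c("water", "peat_swamp_forest", "lowland_forest",
              "montane_forest", "plantation_regrowth", "lowland_mosaic",
              "lowland_open", "urban"),
    is_forest = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    transition_code = 5L
  )
  suit <- c(`1` = 1.111, `2` = 3.286, `3` = 4.500, `4` = 4.250,
            `5` = 2.000, `6` = 2.125, `7` = 1.429, `8` = 1.000)
  attr(ct, "true_suitability") <- suit
  ct
}

transition_code <- function(classes) attr(classes, "transition_code")

forest_mask <- function(grid) {
  stopifnot(inherits(grid, "landcover_grid"))
  fc <- grid$classes$class_code[grid$classes$is_forest]
  m <- matrix(grid$raster$values %in% fc, nrow(grid$raster$values))
  m[is.na(grid$raster$values)] <- NA
  m
}

#' Fraction of non-nodata cells that are forest
#' @param grid A `landcover_grid`.
#' @return A single number in \[0, 1\].
#' @export
forest_fraction <- function(grid) {
  m <- forest_mask(grid)
  mean(m, na.rm = TRUE)
}

new_landcover <- function(raster, classes, epoch_label) {
  vals <- raster$values[!is.na(raster$values)]
  if (!all(vals %in% classes$class_code)) {
    stop("land-cover raster contains codes absent from the class table",
         call. = FALSE)
  }
  structure(list(raster = raster, classes = classes,
                 epoch_label = epoch_label),
            class = "landcover_grid")
}

#' @export
print.landcover_grid <- function(x, ...) {
  cat(sprintf("landcover_grid '%s': %d x %d cells, forest fraction %.3f\n",
              x$epoch_label, nrow(x$raster$values), ncol(x$raster$values),
              forest_fraction(x)))
  invisible(x)
}

# Separable Gaussian smoothing with edge renormalisation (zero-pad then
# divide by the smoothed indicator, so edges average over in-bounds mass).
smooth_field <- function(m, sigma) {
  w <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-w, w), sd = sigma)
  k <- k / sum(k)
  smooth_cols <- function(x) {
    xp <- rbind(matrix(0, w, ncol(x)), x, matrix(0, w, ncol(x)))
    r <- stats::filter(xp, k, sides = 2)
    matrix(r[(w + 1):(w + nrow(x)), ], nrow = nrow(x))
  }
  num <- t(smooth_cols(t(smooth_cols(m))))
  den <- t(smooth_cols(t(smooth_cols(matrix(1, nrow(m), ncol(m))))))
  num / den
}

#' Generate a synthetic categorical land-cover raster
#'
#' Thresholds Gaussian-smoothed white noise at the class-fraction quantiles,
#' giving contiguous patches whose spatial grain grows with `patchiness`
#' (the smoothing sigma, in cells) and whose per-class cell fractions track
#' the requested proportions.
#'
#' @param shape Length-2 integer (rows, cols).
#' @param cell_size Cell size in metres.
#' @param class_fractions Named numeric vector, names are class codes from
#'   `classes`; must sum to 1 within 1e-9. Classes are laid out along the
#'   smoothed-noise gradient in the order given.
#' @param classes A `class_table`.
#' @param patchiness Positive smoothing sigma in cells.
#' @param seed Integer seed; identical arguments and seed give identical
#'   rasters.
#' @param epoch_label Label stored on the result.
#' @return A `landcover_grid`.
#' @export
generate_landcover <- function(shape, cell_size, class_fractions,
                               classes = default_classes(), patchiness = 4,
                               seed = 1, epoch_label = "t0") {
  stopifnot(length(shape) == 2L, all(shape >= 1), patchiness > 0)
  fr <- as.numeric(class_fractions)
  codes <- suppressWarnings(as.integer(names(class_fractions)))
  if (anyNA(codes)) stop("class_fractions must be named by class code",
                         call. = FALSE)
  if (!all(codes %in% classes$class_code)) {
    stop("unknown class code in class_fractions: ",
         paste(setdiff(codes, classes$class_code), collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("class fractions must sum to 1 (got ", sum(fr), ")", call. = FALSE)
  }
  vals <- with_seed(seed, {
    noise <- matrix(rnorm(shape[1] * shape[2]), shape[1], shape[2])
    field <- smooth_field(noise, patchiness)
    # class breakpoints at the empirical quantiles of the smoothed field
    cum <- cumsum(fr)
    brk <- quantile(field, probs = cum[-length(cum)], type = 7, names = FALSE)
    idx <- findInterval(field, brk, left.open = TRUE) + 1L
    matrix(codes[idx], shape[1], shape[2])
  })
  new_landcover(raster_grid(vals, cell_size = cell_size), classes, epoch_label)
}

# Chebyshev distance (in cells) from each forest cell to the nearest
# non-forest cell, by iterative min-plus dilation over the 8-neighbourhood.
edge_distance <- function(forest) {
  nr <- nrow(forest); nc <- ncol(forest)
  d <- matrix(Inf, nr, nc)
  d[!forest] <- 0
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    nb <- pmin(shift(d, 1, 0), shift(d, -1, 0), shift(d, 0, 1),
               shift(d, 0, -1), shift(d, 1, 1), shift(d, 1, -1),
               shift(d, -1, 1), shift(d, -1, -1)) + 1
    new <- pmin(d, nb)
    if (all(new == d | (is.infinite(new) & is.infinite(d)))) break
    d <- new
  }
  d
}

#' Generate an edge-concentrated deforestation-risk surface
#'
#' Produces the per-cell probability that a currently forested cell is
#' deforested over the next interval. Within `interior_cutoff` cells of a
#' forest edge the risk is a base rate inflated by an exponentially
#' decaying edge boost (e-folding scale of two cells); deeper interior
#' forest carries `interior_rate` — exactly 0 by default, the regime a
#' fitted deforestation model produces in intact core forest. With
#' `edge_weight = 0` the surface is a uniform `base_rate` on all forest.
#' This is a fixture generator for the risk surface the pipeline consumes;
#' it is not a fitted deforestation model.
#'
#' @param grid A `landcover_grid`.
#' @param edge_weight Non-negative multiplier for the edge boost; 0 gives a
#'   uniform `base_rate` on forest.
#' @param base_rate Edge-zone base deforestation probability in \[0, 1\].
#' @param seed Integer seed (accepted for interface symmetry; the surface is
#'   a deterministic function of the land cover).
#' @param interior_rate Risk in forest deeper than `interior_cutoff` cells
#'   from an edge (diffuse attrition); default 0.
#' @param interior_cutoff Edge-zone depth in cells.
#' @return A `raster_grid` of probabilities, zero on non-forest cells.
#' @export
generate_deforestation_risk <- function(grid, edge_weight = 8,
                                        base_rate = 0.05, seed = 1,
                                        interior_rate = 0,
                                        interior_cutoff = 3) {
  stopifnot(base_rate >= 0, base_rate <= 1, edge_weight >= 0,
            interior_rate >= 0, interior_rate <= 1, interior_cutoff >= 1)
  fm <- forest_mask(grid)
  f <- fm; f[is.na(f)] <- FALSE
  risk <- matrix(0, nrow(f), ncol(f))
  if (edge_weight == 0 || all(f | is.na(fm))) {
    # no edge gradient (or no edges at all): uniform base rate
    risk[f] <- base_rate
  } else {
    d <- edge_distance(f)
    boost <- exp(-(d[f] - 1) / 2)
    v <- pmin(1, base_rate * (1 + edge_weight * boost))
    v[d[f] > interior_cutoff] <- interior_rate
    risk[f] <- v
  }
  risk[is.na(fm)] <- NA
  raster_grid(risk, cell_size = grid$raster$cell_size,
              origin = grid$raster$origin, nodata = grid$raster$nodata)
}

#' Apply one epoch of stochastic forest loss
#'
#' Each forest cell independently transitions to the class table's
#' transition class with probability given by the aligned risk raster;
#' non-forest cells are never modified.
#'
#' @param grid A `landcover_grid`.
#' @param risk A `raster_grid` of probabilities aligned with `grid`.
#' @param seed Integer seed.
#' @param epoch_label Label for the degraded epoch.
#' @return A new `landcover_grid`.
#' @export
degrade_landcover <- function(grid, risk, seed = 1,
                              epoch_label = paste0(grid$epoch_label, "+")) {
  check_aligned(list(grid$raster, risk))
  rv <- risk$values
  if (any(rv < 0 | rv > 1, na.rm = TRUE)) {
    stop("risk values must lie in [0, 1]", call. = FALSE)
  }
  fm <- forest_mask(grid)
  vals <- with_seed(seed, {
    v <- grid$raster$values
    f <- which(fm)
    flip <- runif(length(f)) < rv[f]
    v[f[flip]] <- transition_code(grid$classes)
    v
  })
  new_landcover(raster_grid(vals, cell_size = grid$raster$cell_size,
                            origin = grid$raster$origin,
                            nodata = grid$raster$nodata),
                grid$classes, epoch_label)
}

#' Generate a synthetic expert habitat-suitability panel
#'
#' Emulates an elicitation in which each expert reports an integer 1-5
#' suitability per land-cover class and a population-density estimate
#' (individuals per 100 km^2). Reported suitability is
#' `round(truth + expert bias + noise)` clipped to \[1, 5\], with expert bias
#' drawn once per expert from `N(0, (rating_sd/2)^2)` and per-response noise
#' from `N(0, rating_sd^2)`. Each (expert, class) response is independently
#' missing with probability `missing_prob`. Density is
#' `density_slope * reported suitability + N(0, density_sd^2)`, floored at 0.
#'
#' @param true_suitability Named numeric vector (class code -> truth in
#'   \[1, 5\]).
#' @param n_experts Number of experts (>= 2).
#' @param rating_sd Rating noise standard deviation (>= 0).
#' @param missing_prob Per-response missingness probability in \[0, 1).
#' @param density_slope Individuals per 100 km^2 per suitability unit.
#' @param density_sd Density noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return An `expert_ratings` data frame with columns `expert_id`,
#'   `class_code`, `suitability`, `density_per_100km2` (`NA` = missing).
#' @export
generate_expert_ratings <- function(true_suitability, n_experts = 13,
                                    rating_sd = 0.5, missing_prob = 0.25,
                                    density_slope = 0.35, density_sd = 0.15,
                                    seed = 1) {
  if (n_experts < 2) stop("need at least 2 experts", call. = FALSE)
  stopifnot(rating_sd >= 0, density_sd >= 0,
            missing_prob >= 0, missing_prob < 1)
  codes <- suppressWarnings(as.integer(names(true_suitability)))
  if (anyNA(codes)) stop("true_suitability must be named by class code",
                         call. = FALSE)
  stopifnot(all(true_suitability >= 1), all(true_suitability <= 5))
  nc <- length(codes)
  with_seed(seed, {
    bias <- rnorm(n_experts, 0, rating_sd / 2)
    df <- expand.grid(expert_id = seq_len(n_experts), class_code = codes,
                      KEEP.OUT.ATTRS = FALSE)
    truth <- as.numeric(true_suitability)[match(df$class_code, codes)]
    raw <- truth + bias[df$expert_id] + rnorm(nrow(df), 0, rating_sd)
    df$suitability <- pmin(5L, pmax(1L, as.integer(round(raw))))
    df$density_per_100km2 <- pmax(0, density_slope * df$suitability +
                                    rnorm(nrow(df), 0, density_sd))
    miss <- runif(nrow(df)) < missing_prob
    df$suitability[miss] <- NA_integer_
    df$density_per_100km2[miss] <- NA_real_
    class(df) <- c("expert_ratings", "data.frame")
    df
  })
}

#' Write / read the expert rating CSV interchange format
#'
#' Columns `expert_id, class_code, suitability, density_per_100km2`; empty
#' fields denote missing responses.
#'
#' @param ratings An `expert_ratings` data frame.
#' @param path CSV path.
#' @return `write_ratings_csv` invisibly returns `path`; `read_ratings_csv`
#'   returns an `expert_ratings` data frame.
#' @export
write_ratings_csv <- function(ratings, path) {
  write.csv(as.data.frame(ratings), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "class_code", "suitability", "density_per_100km2")
  if (!all(need %in% names(df))) {
    stop("rating CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$suitability <- as.integer(df$suitability)
  class(df) <- c("expert_ratings", "data.frame")
  df
}

#' Build the packaged three-epoch synthetic scenario
#'
#' Generates a land-cover mosaic at epoch t0, applies two successive rounds
#' of edge-concentrated forest loss to obtain t1 and t2, keeps the t1->t2
#' risk surface (the projection input), and simulates an expert panel over
#' the legend's suitability truths. Loss is concentrated at forest edges
#' (8-fold edge boost decaying into a 6-cell edge zone) with a small
#' diffuse interior component in the first interval only, and accelerates
#' between intervals (edge-zone base rates 0.02 then 0.06), mirroring an
#' intensifying edge-driven deforestation regime; the panel defaults
#' (13 experts, noise sd 0.5, 25% missingness) produce the high-agreement
#' regime the analysis assumes.
#'
#' @param shape Raster shape (rows, cols).
#' @param cell_size Cell size in metres.
#' @param seed Master scenario seed; every stage derives its own substream.
#' @param classes A `class_table` carrying `true_suitability`.
#' @param class_fractions Epoch-t0 cell fractions (named by class code).
#' @param patchiness Smoothing sigma in cells for the t0 mosaic.
#' @param base_rates Interior deforestation probabilities for the two
#'   intervals (t0->t1, t1->t2).
#' @param edge_weight Edge boost passed to [generate_deforestation_risk()].
#' @param n_experts,rating_sd,missing_prob Panel parameters.
#' @return A `conn_scenario` list: `grids` (three `landcover_grid`), `risk`
#'   (t1->t2 risk raster), `panel`, `classes`, `seed`.
#' @export
build_scenario <- function(shape = c(120, 120), cell_size = 1000, seed = 1,
                           classes = default_classes(),
                           class_fractions = c(`3` = 0.40, `4` = 0.12,
                                               `2` = 0.08, `5` = 0.10,
                                               `6` = 0.12, `7` = 0.10,
                                               `1` = 0.05, `8` = 0.03),
                           patchiness = 12, base_rates = c(0.02, 0.06),
                           edge_weight = 8, n_experts = 13,
                           rating_sd = 0.5, missing_prob = 0.25) {
  t0 <- generate_landcover(shape, cell_size, class_fractions, classes,
                           patchiness, seed = derive_seed(seed, "landcover"),
                           epoch_label = "t0")
  risk01 <- generate_deforestation_risk(t0, edge_weight, base_rates[1],
                                        seed = derive_seed(seed, "risk01"),
                                        interior_rate = 0.01)
  t1 <- degrade_landcover(t0, risk01, seed = derive_seed(seed, "degrade01"),
                          epoch_label = "t1")
  risk12 <- generate_deforestation_risk(t1, edge_weight, base_rates[2],
                                        seed = derive_seed(seed, "risk12"),
                                        interior_cutoff = 2)
  t2 <- degrade_landcover(t1, risk12, seed = derive_seed(seed, "degrade12"),
                          epoch_label = "t2")
  panel <- generate_expert_ratings(attr(classes, "true_suitability"),
                                   n_experts = n_experts,
                                   rating_sd = rating_sd,
                                   missing_prob = missing_prob,
                                   seed = derive_seed(seed, "panel"))
  structure(list(grids = list(t0 = t0, t1 = t1, t2 = t2), risk = risk12,
                 panel = panel, classes = classes, seed = seed),
            class = "conn_scenario")
}
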