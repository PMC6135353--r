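#' Lattice graph of a resistance surface
#'
#' Builds the weighted movement graph used by all cost-distance operations.
#' Cells are vertices (row-major ids); adjacent non-nodata cells are joined
#' by an undirected edge whose weight is the mean of the two cells'
#' resistances times the centre-to-centre distance: `cell_size * (r_a +
#' r_b) / 2`, multiplied by `sqrt(2)` for diagonal moves. Edges are
#' constructed in a fixed per-cell order (E, S, SE, SW) so equal-cost path
#' choices are deterministic.
#'
#' @param r A `resistance_grid`.
#' @param connectivity 8 (default) or 4 neighbours.
#' @return An igraph graph with a `weight` edge attribute; vertex
#'   `(row, col)` has id `(row - 1) * ncols + col`.
#' @export
grid_graph <- function(r, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  v <- r$raster$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- r$raster$cell_size
  id <- function(row, col) (row - 1L) * nc + col
  edges <- list(); weights <- list(); e <- 0L
  add <- function(r1, c1, r2, c2, diag) {
    a <- v[cbind(r1, c1)]; b <- v[cbind(r2, c2)]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NULL)
    w <- cs * (a[ok] + b[ok]) / 2
    if (diag) w <- w * sqrt(2)
    e <<- e + 1L
    edges[[e]] <<- rbind(id(r1[ok], c1[ok]), id(r2[ok], c2[ok]))
    weights[[e]] <<- w
  }
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  east <- cols < nc; south <- rows < nr
  add(rows[east], cols[east], rows[east], cols[east] + 1L, FALSE)
  add(rows[south], cols[south], rows[south] + 1L, cols[south], FALSE)
  if (connectivity == 8) {
    se <- south & east
    add(rows[se], cols[se], rows[se] + 1L, cols[se] + 1L, TRUE)
    sw <- south & cols > 1L
    add(rows[sw], cols[sw], rows[sw] + 1L, cols[sw] - 1L, TRUE)
  }
  g <- igraph::make_graph(as.vector(do.call(cbind, edges)), n = nr * nc,
                          directed = FALSE)
  igraph::E(g)$weight <- unlist(weights)
  attr(g, "grid_dim") <- c(nr, nc)
  g
}

cell_ids <- function(points, nc) (points$row - 1L) * nc + points$col

#' Accumulated-cost field from one source cell
#'
#' Least-cost (Dijkstra) distance from the source to every cell of the
#' lattice, in cost units (resistance times metres along the route). Cells
#' whose accumulated cost exceeds `max_cost` are marked infinite.
#'
#' @param r A `resistance_grid`.
#' @param source Length-2 integer `(row, col)`.
#' @param max_cost Cost ceiling (default unlimited).
#' @param connectivity 8 or 4 neighbours.
#' @param graph Optional pre-built [grid_graph()] to reuse.
#' @return A `cost_distance_field` list: `raster` (costs, `Inf` where
#'   unreached), `source`, `max_cost`, `predecessor` (matrix of row-major
#'   back-pointer ids, `NA` at the source and unreached cells).
#' @export
cost_distance <- function(r, source, max_cost = Inf, connectivity = 8,
                          graph = NULL) {
  v <- r$raster$values
  nr <- nrow(v); nc <- ncol(v)
  stopifnot(length(source) == 2L, source[1] >= 1, source[1] <= nr,
            source[2] >= 1, source[2] <= nc)
  if (is.na(v[source[1], source[2]])) {
    stop("source cell is nodata", call. = FALSE)
  }
  g <- if (is.null(graph)) grid_graph(r, connectivity) else graph
  sid <- (source[1] - 1L) * nc + source[2]
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = sid, to = igraph::V(g),
                           weights = igraph::E(g)$weight,
                           predecessors = TRUE, output = "vpath")
  )
  d <- suppressWarnings(
    as.vector(igraph::distances(g, v = sid, weights = igraph::E(g)$weight))
  )
  d[d > max_cost] <- Inf
  pred <- as.integer(sp$predecessors)
  pred[!is.finite(d)] <- NA_integer_
  pred[sid] <- NA_integer_
  costs <- matrix(d, nr, nc, byrow = TRUE)
  costs[is.na(v)] <- NA_real_
  structure(
    list(raster = raster_grid(costs, cell_size = r$raster$cell_size,
                              origin = r$raster$origin,
                              nodata = r$raster$nodata),
         source = source, max_cost = max_cost,
         predecessor = matrix(pred, nr, nc, byrow = TRUE)),
    class = "cost_distance_field"
  )
}

#' Pairwise least-cost distances among source points
#'
#' @param r A `resistance_grid`.
#' @param sources A `source_points` data frame.
#' @param connectivity 8 or 4 neighbours.
#' @return A symmetric matrix of cost distances (cost units).
#' @export
cost_distance_matrix <- function(r, sources, connectivity = 8) {
  g <- grid_graph(r, connectivity)
  ids <- cell_ids(sources, ncol(r$raster$values))
  suppressWarnings(
    igraph::distances(g, v = ids, to = ids, weights = igraph::E(g)$weight)
  )
}

#' Cumulative resistant kernel surface
#'
#' Each source carries an initial expected disperser density of 1 at its
#' cell; the expected density at any other cell decays linearly with the
#' accumulated least-cost distance, reaching zero at the dispersal
#' bandwidth: `k = max(0, 1 - c / bandwidth)`. The cumulative surface sums
#' kernels over all sources.
#'
#' @param r A `resistance_grid`.
#' @param sources A `source_points` data frame.
#' @param bandwidth Dispersal threshold in cost units (e.g. 125000).
#' @param connectivity 8 or 4 neighbours.
#' @return A `kernel_surface` list: `raster`, `bandwidth`, `epoch_label`.
#' @export
cumulative_resistant_kernel <- function(r, sources, bandwidth,
                                        connectivity = 8) {
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (nrow(sources) < 1L) stop("no source points", call. = FALSE)
  v <- r$raster$values
  nc <- ncol(v)
  g <- grid_graph(r, connectivity)
  ids <- cell_ids(sources, nc)
  d <- suppressWarnings(
    igraph::distances(g, v = ids, weights = igraph::E(g)$weight)
  )
  k <- 1 - d / bandwidth
  k[] <- pmax(0, k)
  surf <- matrix(colSums(k), nrow(v), nc, byrow = TRUE)
  surf[is.na(v)] <- NA_real_
  structure(
    list(raster = raster_grid(surf, cell_size = r$raster$cell_size,
                              origin = r$raster$origin,
                              nodata = r$raster$nodata),
         bandwidth = bandwidth, epoch_label = r$epoch_label),
    class = "kernel_surface"
  )
}

#' Factorial least-cost-path density surface
#'
#' Extracts one least-cost path for every unordered pair of source points
#' and counts, per cell, how many paths cross it (path endpoints included).
#' Pairs whose least-cost distance exceeds `max_cost` (if given) contribute
#' nothing. Equal-cost alternatives are resolved deterministically by the
#' engine's fixed edge order.
#'
#' @param r A `resistance_grid`.
#' @param sources A `source_points` data frame with at least 2 points.
#' @param max_cost Optional cost ceiling for a pair to count.
#' @param connectivity 8 or 4 neighbours.
#' @return A `path_density` list: `raster` (integer counts), `n_paths`,
#'   `smoothed = FALSE`, `epoch_label`.
#' @export
factorial_least_cost_paths <- function(r, sources, max_cost = NULL,
                                       connectivity = 8) {
  n <- nrow(sources)
  if (n < 2L) stop("need at least 2 source points", call. = FALSE)
  v <- r$raster$values
  nc <- ncol(v)
  g <- grid_graph(r, connectivity)
  ids <- cell_ids(sources, nc)
  counts <- integer(nrow(v) * nc)
  n_paths <- 0L
  for (i in seq_len(n - 1L)) {
    to <- ids[(i + 1L):n]
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = ids[i], to = to,
                             weights = igraph::E(g)$weight, output = "vpath")
    )$vpath
    keep <- vapply(sp, length, 1L) > 0L
    if (!is.null(max_cost)) {
      d <- suppressWarnings(
        igraph::distances(g, v = ids[i], to = to,
                          weights = igraph::E(g)$weight)
      )
      keep <- keep & as.vector(d) <= max_cost
    }
    if (any(keep)) {
      cells <- unlist(lapply(sp[keep], as.integer))
      tab <- tabulate(cells, nbins = length(counts))
      counts <- counts + tab
      n_paths <- n_paths + sum(keep)
    }
  }
  surf <- matrix(as.numeric(counts), nrow(v), nc, byrow = TRUE)
  surf[is.na(v)] <- NA_real_
  structure(
    list(raster = raster_grid(surf, cell_size = r$raster$cell_size,
                              origin = r$raster$origin,
                              nodata = r$raster$nodata),
         n_paths = n_paths, smoothed = FALSE, epoch_label = r$epoch_label),
    class = "path_density"
  )
}

#' Circular focal mean of a raster
#'
#' Replaces each cell with the mean over all cells whose centre lies within
#' the given Euclidean radius (inclusive). Edge cells average over the
#' in-bounds part of the window; nodata cells are excluded from every
#' window and stay nodata in the output.
#'
#' @param surface A `raster_grid`.
#' @param radius Window radius in metres (>= cell size).
#' @return A smoothed `raster_grid`.
#' @export
focal_mean <- function(surface, radius) {
  stopifnot(is_raster_grid(surface))
  cs <- surface$cell_size
  if (radius < cs) stop("radius must be at least one cell size", call. = FALSE)
  v <- surface$values
  nr <- nrow(v); nc <- ncol(v)
  rad_cells <- floor(radius / cs)
  offs <- expand.grid(dr = -rad_cells:rad_cells, dc = -rad_cells:rad_cells)
  offs <- offs[(offs$dr * cs)^2 + (offs$dc * cs)^2 <= radius^2 + 1e-9, ]
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  ok <- !is.na(v)
  vz <- v; vz[!ok] <- 0
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    if (abs(dr) >= nr || abs(dc) >= nc) next
    r1 <- max(1, 1 + dr):min(nr, nr + dr)
    c1 <- max(1, 1 + dc):min(nc, nc + dc)
    acc[r1, c1] <- acc[r1, c1] + vz[r1 - dr, c1 - dc]
    cnt[r1, c1] <- cnt[r1, c1] + ok[r1 - dr, c1 - dc]
  }
  out <- acc / cnt
  out[!ok] <- NA_real_
  raster_grid(out, cell_size = cs, origin = surface$origin,
              nodata = surface$nodata)
}
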