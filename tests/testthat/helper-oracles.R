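# Independent oracles and fixture builders shared across tests.

# A resistance grid from a plain matrix of values in [1, 100].
res_grid <- function(values, cell_size = 1000, epoch = "fix") {
  connscape:::new_resistance(
    raster_grid(values, cell_size = cell_size), epoch)
}

# Source points at given (row, col) pairs.
pts <- function(rows, cols) {
  df <- data.frame(row = as.integer(rows), col = as.integer(cols),
                   weight = 1)
  structure(df, threshold = 0, seed = 0, epoch_label = "fix",
            class = c("source_points", "data.frame"))
}

# Min-plus (Floyd-Warshall) closure over the same lattice weighting rule,
# built by direct neighbour scans -- independent of the package's graph
# machinery. Returns the full cell-by-cell cost matrix (row-major order).
fw_all_costs <- function(values, cell_size = 1000, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values); n <- nr * nc
  d <- matrix(Inf, n, n); diag(d) <- 0
  id <- function(r, c) (r - 1L) * nc + c
  nbrs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) nbrs <- c(nbrs, list(c(1, 1), c(1, -1)))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    for (dd in nbrs) {
      r2 <- r + dd[1]; c2 <- c + dd[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(values[r, c]) || is.na(values[r2, c2])) next
      w <- cell_size * (values[r, c] + values[r2, c2]) / 2
      if (all(dd != 0)) w <- w * sqrt(2)
      a <- id(r, c); b <- id(r2, c2)
      d[a, b] <- min(d[a, b], w); d[b, a] <- min(d[b, a], w)
    }
  }
  for (k in seq_len(n)) {
    dk <- d[, k]
    cand <- outer(dk, d[k, ], "+")
    upd <- cand < d
    d[upd] <- cand[upd]
  }
  d
}

# Exhaustive DFS over all simple paths between two cells (tiny grids only).
dfs_min_cost <- function(values, from, to, cell_size = 1000) {
  nr <- nrow(values); nc <- ncol(values)
  best <- Inf
  nbrs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  visited <- matrix(FALSE, nr, nc)
  recurse <- function(r, c, acc) {
    if (acc >= best) return(invisible())
    if (r == to[1] && c == to[2]) { best <<- acc; return(invisible()) }
    visited[r, c] <<- TRUE
    for (i in seq_len(nrow(nbrs))) {
      r2 <- r + nbrs[i, 1]; c2 <- c + nbrs[i, 2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (visited[r2, c2]) next
      w <- cell_size * (values[r, c] + values[r2, c2]) / 2
      if (all(nbrs[i, ] != 0)) w <- w * sqrt(2)
      recurse(r2, c2, acc + w)
    }
    visited[r, c] <<- FALSE
  }
  recurse(from[1], from[2], 0)
  best
}

# Two-way ANOVA sums of squares from the definition, complete balanced
# matrix only (experts in rows, classes in columns).
icc_oracle <- function(mat) {
  k <- nrow(mat); n <- ncol(mat)
  gm <- mean(mat)
  class_means <- colMeans(mat); expert_means <- rowMeans(mat)
  ss_rows <- k * sum((class_means - gm)^2)      # between classes
  ss_cols <- n * sum((expert_means - gm)^2)     # between experts
  ss_tot <- sum((mat - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  list(icc_single = (msr - mse) / (msr + (k - 1) * mse),
       icc_average = (msr - mse) / msr)
}

# Closed-form OLS via the normal equations.
ols_oracle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  solve(t(X) %*% X, t(X) %*% y)
}
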