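test_that("cost distance equals metric distance on unit resistance", {
  r <- res_grid(matrix(1, 7, 7))
  cd <- cost_distance(r, c(4, 1))
  expect_equal(cd$raster$values[4, 4], 3000)
  expect_equal(cd$raster$values[5, 2], 1414.214, tolerance = 1e-4)
  expect_equal(cd$raster$values[4, 1], 0)
})

test_that("strip costs sum averaged edge weights", {
  r <- res_grid(matrix(c(1, 5, 9), 1, 3))
  cd <- cost_distance(r, c(1, 1))
  expect_equal(cd$raster$values[1, 3], 10000)
  expect_equal(cd$raster$values[1, 2], 3000)
})

test_that("max_cost truncates the field to infinity beyond the frontier", {
  r <- res_grid(matrix(1, 1, 10))
  cd <- cost_distance(r, c(1, 1), max_cost = 4500)
  expect_true(all(is.finite(cd$raster$values[1, 1:5])))
  expect_true(all(is.infinite(cd$raster$values[1, 6:10])))
})

test_that("Dijkstra matches the min-plus closure oracle on random grids", {
  set.seed(42)
  for (case in 1:25) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    v <- matrix(runif(nr * nc, 1, 100), nr, nc)
    want <- fw_all_costs(v)
    r <- res_grid(v)
    src <- c(sample(nr, 1), sample(nc, 1))
    cd <- cost_distance(r, src)
    got <- as.vector(t(cd$raster$values))
    expect_equal(got, want[(src[1] - 1) * nc + src[2], ], tolerance = 1e-9)
  }
})

test_that("Dijkstra matches exhaustive path enumeration on tiny grids", {
  set.seed(7)
  for (case in 1:5) {
    v <- matrix(runif(9, 1, 50), 3, 3)
    r <- res_grid(v)
    cd <- cost_distance(r, c(1, 1))
    expect_equal(cd$raster$values[3, 3], dfs_min_cost(v, c(1, 1), c(3, 3)),
                 tolerance = 1e-9)
    expect_equal(cd$raster$values[2, 3], dfs_min_cost(v, c(1, 1), c(2, 3)),
                 tolerance = 1e-9)
  }
})

test_that("cost distances are symmetric and scale with resistance", {
  set.seed(9)
  v <- matrix(runif(64, 1, 20), 8, 8)
  r <- res_grid(v)
  src <- pts(c(1, 4, 8), c(2, 5, 7))
  d <- cost_distance_matrix(r, src)
  expect_equal(d, t(d))
  gamma <- 3
  d2 <- cost_distance_matrix(res_grid(v * gamma), src)
  expect_equal(d2, gamma * d, tolerance = 1e-9)
})

test_that("kernel decays linearly and adds across sources", {
  r <- res_grid(matrix(1, 1, 11))
  k <- cumulative_resistant_kernel(r, pts(1, 1), 125000)
  expect_equal(k$raster$values[1, 4], 1 - 3000 / 125000)
  # support ends at the bandwidth
  k2 <- cumulative_resistant_kernel(r, pts(1, 1), 5000)
  expect_equal(k2$raster$values[1, 6], 0)   # cost 5000 >= bandwidth
  expect_equal(k2$raster$values[1, 5], 0.2) # cost 4000 -> 1 - 0.8
  # two sources on one cell double the origin density
  k3 <- cumulative_resistant_kernel(r, pts(c(1, 1), c(1, 1)), 125000)
  expect_equal(k3$raster$values[1, 1], 2)
})

test_that("kernel at scaled bandwidth is invariant to resistance scaling", {
  set.seed(13)
  v <- matrix(runif(100, 1, 30), 10, 10)
  src <- pts(c(2, 7), c(3, 8))
  k1 <- cumulative_resistant_kernel(res_grid(v), src, 50000)
  k2 <- cumulative_resistant_kernel(res_grid(v * 2), src, 100000)
  expect_equal(k1$raster$values, k2$raster$values, tolerance = 1e-9)
})

test_that("raising resistance anywhere never raises kernel density", {
  set.seed(31)
  v <- matrix(runif(100, 1, 30), 10, 10)
  src <- pts(c(2, 9), c(2, 9))
  base <- cumulative_resistant_kernel(res_grid(v), src, 60000)
  for (i in 1:5) {
    v2 <- v
    cell <- sample(100, 1)
    v2[cell] <- min(100, v2[cell] + runif(1, 10, 60))
    pert <- cumulative_resistant_kernel(res_grid(v2), src, 60000)
    expect_true(all(pert$raster$values <= base$raster$values + 1e-12))
  }
})

test_that("factorial paths on a uniform strip trace the expected density", {
  r <- res_grid(matrix(1, 1, 11))
  # two endpoints: one path covering the whole strip
  f2 <- factorial_least_cost_paths(r, pts(c(1, 1), c(1, 11)))
  expect_equal(f2$n_paths, 1L)
  expect_true(all(f2$raster$values == 1))
  # three collinear sources at cells 1, 6, 11 (0, 5, 10 zero-based)
  f3 <- factorial_least_cost_paths(r, pts(c(1, 1, 1), c(1, 6, 11)))
  expect_equal(f3$n_paths, 3L)
  expect_equal(f3$raster$values[1, 4], 2)   # paths 1-6 and 1-11
  expect_equal(f3$raster$values[1, 8], 2)   # paths 6-11 and 1-11
  expect_equal(f3$raster$values[1, 6], 3)   # endpoint of two, interior of one
})

test_that("every unordered pair yields exactly one path", {
  set.seed(3)
  v <- matrix(runif(144, 1, 10), 12, 12)
  src <- pts(c(1, 3, 6, 10, 12), c(2, 11, 5, 9, 1))
  f <- factorial_least_cost_paths(res_grid(v), src)
  expect_equal(f$n_paths, 10L)
  # total cell-visits at least one cell per path
  expect_gte(sum(f$raster$values), 10)
  # max_cost filtering drops distant pairs
  d <- cost_distance_matrix(res_grid(v), src)
  cap <- stats::median(d[upper.tri(d)])
  fc <- factorial_least_cost_paths(res_grid(v), src, max_cost = cap)
  expect_equal(fc$n_paths, sum(d[upper.tri(d)] <= cap))
})

test_that("focal mean averages the inclusive circular window", {
  const <- raster_grid(matrix(7, 9, 9))
  expect_equal(focal_mean(const, 2000)$values, const$values)
  # a single 1 in zeros: 13-cell window at radius two cells
  v <- matrix(0, 11, 11); v[6, 6] <- 1
  sm <- focal_mean(raster_grid(v, cell_size = 1000), 2000)
  expect_equal(sm$values[6, 6], 1 / 13)
  expect_equal(sm$values[6, 8], 1 / 13)  # centre within distance 2
  expect_equal(sm$values[6, 9], 0)
  # interior mass conservation: window sum over the interior
  set.seed(5)
  v2 <- matrix(runif(15 * 15), 15, 15)
  sm2 <- focal_mean(raster_grid(v2, cell_size = 1000), 2000)
  inner <- 3:13
  expect_equal(mean(sm2$values[inner, inner]), mean(v2[inner, inner]),
               tolerance = 0.05)
})

test_that("4-neighbour mode forbids diagonal moves", {
  r <- res_grid(matrix(1, 3, 3))
  cd <- cost_distance(r, c(1, 1), connectivity = 4)
  expect_equal(cd$raster$values[2, 2], 2000)  # no diagonal shortcut
  cd8 <- cost_distance(r, c(1, 1), connectivity = 8)
  expect_equal(cd8$raster$values[2, 2], 1414.214, tolerance = 1e-3)
})
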