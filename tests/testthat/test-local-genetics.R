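test_that("shared-allele distance matches hand counts", {
  # identical genotypes; disjoint genotypes; the half-shared case
  g <- rbind(c(0L, 1L), c(0L, 1L), c(2L, 3L), c(1L, 1L))
  d <- genetic_distances(g)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
  expect_equal(d[1, 4], 0.5)  # shared copies: one allele of two
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # multi-locus averaging
  g2 <- rbind(c(0L, 0L, 5L, 6L), c(0L, 1L, 5L, 5L))
  # locus 1 shares 1 of 2; locus 2 shares 1 of 2 -> D = 1 - 2/4
  expect_equal(genetic_distances(g2)[1, 2], 0.5)
})

ibd_fixture <- function(n = 12, seed = 5) {
  # perfect isolation by distance: individuals on a line, genetic distance
  # increasing in spatial separation
  cost <- abs(outer(seq_len(n), seq_len(n), "-")) * 1000
  gen <- cost / max(cost)
  diag(gen) <- 0
  list(gen = gen, cost = cost)
}

test_that("correlogram bins cover all pairs in the requested classes", {
  fx <- ibd_fixture()
  cg <- mantel_correlogram(fx$gen, fx$cost, n_classes = 4, n_perm = 99,
                           seed = 1)
  expect_equal(nrow(cg), 4L)
  expect_equal(sum(cg$n_pairs), 12 * 11 / 2)
  expect_true(all(diff(cg$lower) > 0))
})

test_that("perfect isolation-by-distance is detected in the first class", {
  fx <- ibd_fixture()
  cg <- mantel_correlogram(fx$gen, fx$cost, n_classes = 4, n_perm = 199,
                           seed = 2)
  expect_gt(cg$mantel_r[1], 0)
  expect_lte(cg$p_value[1], 0.02)
  # far pairs are more dissimilar than average: negative tail class
  expect_lt(cg$mantel_r[4], 0)
  rng <- autocorrelation_range(cg)
  expect_gt(rng, 0)
})

test_that("autocorrelation range stops at the first insignificant class", {
  cg <- data.frame(class = 1:4, lower = c(0, 1, 2, 3),
                   upper = c(1, 2, 3, 4) * 1000,
                   mantel_r = c(0.4, 0.2, -0.1, -0.3),
                   p_value = c(0.001, 0.01, 0.6, 0.9), n_pairs = 10)
  expect_equal(autocorrelation_range(cg), 2000)
  cg$p_value[1] <- 0.5
  expect_equal(autocorrelation_range(cg), 0)
})

test_that("permutation p-values are invariant to individual relabeling", {
  fx <- ibd_fixture()
  perm <- c(4, 1, 12, 7, 3, 9, 2, 11, 6, 10, 5, 8)
  cg1 <- mantel_correlogram(fx$gen, fx$cost, n_classes = 3, n_perm = 99,
                            seed = 9)
  cg2 <- mantel_correlogram(fx$gen[perm, perm], fx$cost[perm, perm],
                            n_classes = 3, n_perm = 99, seed = 9)
  expect_equal(cg1$mantel_r, cg2$mantel_r, tolerance = 1e-12)
  # the permutation null is the same in distribution; realised p-values
  # agree to Monte Carlo error
  expect_true(all(abs(cg1$p_value - cg2$p_value) <= 0.05))
})

test_that("a constant genetic matrix is signalled", {
  n <- 8
  gen <- matrix(0.5, n, n); diag(gen) <- 0
  gen[1, 2] <- gen[2, 1] <- 0.5
  cost <- abs(outer(1:n, 1:n, "-")) * 100
  expect_error(mantel_correlogram(matrix(0, n, n), cost), "constant")
})

test_that("correlogram r agrees with an independent Mantel statistic", {
  skip_if_not_installed("vegan")
  fx <- ibd_fixture()
  cg <- mantel_correlogram(fx$gen, fx$cost, n_classes = 3, n_perm = 99,
                           seed = 3)
  # rebuild class 1 indicator and compare against vegan's Mantel r
  up <- upper.tri(fx$cost)
  rk <- rank(fx$cost[up], ties.method = "first")
  cls <- pmin(3, ceiling(rk / length(rk) * 3))
  ind <- matrix(0, 12, 12)
  ind[up][cls == 1] <- 1
  ind <- ind + t(ind)
  vr <- vegan::mantel(as.dist(fx$gen), as.dist(ind), permutations = 0)
  expect_equal(cg$mantel_r[1], -vr$statistic, tolerance = 1e-10)
})

test_that("local diversity matches the hand-computed neighbourhood", {
  geno <- rbind(c(0L, 1L), c(0L, 0L), c(1L, 2L))
  cost <- matrix(0, 3, 3)
  ld <- local_diversity(geno, cost, radius = 10, min_n = 2)
  expect_equal(ld$local_alleles[1], 3)
  expect_equal(ld$local_ho[1], 2 / 3)
  expect_equal(ld$local_he[1], 1 - (3 / 6)^2 - (2 / 6)^2 - (1 / 6)^2)
})

test_that("saturated windows collapse to the global summary", {
  set.seed(20)
  geno <- matrix(sample(0:9, 30 * 20, replace = TRUE), 15)
  cost <- matrix(runif(225, 0, 5000), 15, 15)
  cost <- (cost + t(cost)) / 2; diag(cost) <- 0
  ld <- local_diversity(geno, cost, radius = 1e9, min_n = 2)
  st <- connscape:::new_population(1:15, rep(TRUE, 15), geno, 0L, 15L, 10L)
  gs <- global_genetic_summary(st)
  expect_true(all(ld$local_he == gs$he))
  expect_true(all(ld$local_ho == gs$ho))
  expect_true(all(ld$local_n == 15L))
})

test_that("below-minimum neighbourhoods are reported missing", {
  geno <- matrix(sample(0:9, 8 * 4, replace = TRUE), 4)
  cost <- matrix(1e9, 4, 4); diag(cost) <- 0
  ld <- local_diversity(geno, cost, radius = 100, min_n = 2)
  expect_true(all(is.na(ld$local_he)))
  expect_true(all(ld$local_n == 1L))
})

test_that("local allele counts grow with the window radius", {
  set.seed(8)
  geno <- matrix(sample(0:9, 40 * 12, replace = TRUE), 20)
  cost <- abs(outer(1:20, 1:20, "-")) * 500
  prev <- rep(0, 20)
  for (rad in c(1000, 3000, 6000, 1e4)) {
    ld <- local_diversity(geno, cost, radius = rad, min_n = 2)
    expect_true(all(ld$local_alleles >= prev - 1e-12, na.rm = TRUE))
    prev <- ifelse(is.na(ld$local_alleles), prev, ld$local_alleles)
  }
})

test_that("replicate correlograms combine by mean r and median p", {
  fx <- ibd_fixture()
  cg1 <- mantel_correlogram(fx$gen, fx$cost, n_classes = 3, n_perm = 99,
                            seed = 1)
  cg2 <- cg1
  cg2$mantel_r <- cg2$mantel_r / 2
  cg2$p_value <- cg2$p_value * 2
  comb <- combine_correlograms(list(cg1, cg2))
  expect_equal(comb$mantel_r, 0.75 * cg1$mantel_r)
  expect_equal(comb$p_value, 1.5 * cg1$p_value)
})
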