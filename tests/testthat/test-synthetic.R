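test_that("land-cover generator hits requested fractions and is seeded", {
  fr <- c(`3` = 0.6, `6` = 0.3, `8` = 0.1)
  lc <- generate_landcover(c(200, 200), 1000, fr, patchiness = 4, seed = 42)
  got <- table(lc$raster$values) / (200 * 200)
  expect_equal(names(got), names(fr))
  expect_true(all(abs(as.numeric(got) - fr) <= 0.05))
  lc2 <- generate_landcover(c(200, 200), 1000, fr, patchiness = 4, seed = 42)
  expect_identical(lc$raster$values, lc2$raster$values)
  lc3 <- generate_landcover(c(200, 200), 1000, fr, patchiness = 4, seed = 43)
  expect_false(identical(lc$raster$values, lc3$raster$values))
})

test_that("degenerate single-class request fills the raster with that class", {
  lc <- generate_landcover(c(30, 30), 1000, c(`3` = 1), seed = 7)
  expect_true(all(lc$raster$values == 3))
})

test_that("generator validates fractions and class codes", {
  expect_error(generate_landcover(c(10, 10), 1000, c(`3` = 0.5, `6` = 0.4)),
               "sum to 1")
  expect_error(generate_landcover(c(10, 10), 1000, c(`99` = 1)),
               "unknown class")
})

test_that("degradation flips only forest, conserving the landscape", {
  lc <- generate_landcover(c(50, 50), 1000, c(`3` = 0.5, `6` = 0.5),
                           seed = 11)
  zero <- raster_grid(matrix(0, 50, 50))
  same <- degrade_landcover(lc, zero, seed = 2)
  expect_identical(same$raster$values, lc$raster$values)
  one <- raster_grid(matrix(1, 50, 50))
  gone <- degrade_landcover(lc, one, seed = 2)
  expect_equal(forest_fraction(gone), 0)
  # non-forest untouched, counts conserved
  nf <- lc$raster$values == 6
  expect_identical(gone$raster$values[nf], lc$raster$values[nf])
  expect_equal(length(gone$raster$values), length(lc$raster$values))
})

test_that("flip count under uniform risk matches the binomial law", {
  lc <- generate_landcover(c(120, 120), 1000, c(`3` = 0.7, `6` = 0.3),
                           patchiness = 3, seed = 5)
  n_forest <- sum(lc$raster$values == 3)
  expect_gt(n_forest, 9000)
  half <- raster_grid(matrix(0.5, 120, 120))
  after <- degrade_landcover(lc, half, seed = 99)
  flipped <- n_forest - sum(after$raster$values == 3)
  expect_lt(abs(flipped - n_forest * 0.5), 3 * sqrt(n_forest * 0.25))
})

test_that("risk surface is edge-concentrated, zero off forest", {
  lc <- generate_landcover(c(80, 80), 1000, c(`3` = 0.5, `6` = 0.5),
                           patchiness = 5, seed = 3)
  rk <- generate_deforestation_risk(lc, edge_weight = 1, base_rate = 0.1)
  expect_true(all(rk$values >= 0 & rk$values <= 1))
  expect_true(all(rk$values[lc$raster$values == 6] == 0))
  fm <- lc$raster$values == 3
  # edge cells: forest with a non-forest 8-neighbour
  d <- connscape:::edge_distance(fm)
  edge <- fm & d == 1
  interior <- fm & d > 1
  expect_gt(mean(rk$values[edge]), mean(rk$values[interior]))
})

test_that("risk degenerates to the uniform base rate without edge weighting", {
  lc <- generate_landcover(c(40, 40), 1000, c(`3` = 0.5, `6` = 0.5), seed = 3)
  rk <- generate_deforestation_risk(lc, edge_weight = 0, base_rate = 0.2)
  expect_true(all(rk$values[lc$raster$values == 3] == 0.2))
  allf <- generate_landcover(c(40, 40), 1000, c(`3` = 1), seed = 3)
  rk2 <- generate_deforestation_risk(allf, edge_weight = 5, base_rate = 0.2)
  expect_true(all(rk2$values == 0.2))
})

test_that("noiseless expert panel reports the exact truths", {
  truth <- c(`1` = 1, `3` = 5, `6` = 2)
  panel <- generate_expert_ratings(truth, n_experts = 5, rating_sd = 0,
                                   missing_prob = 0, seed = 4)
  for (cc in names(truth)) {
    expect_true(all(panel$suitability[panel$class_code == as.integer(cc)] ==
                      truth[[cc]]))
  }
})

test_that("per-class response counts follow the missingness binomial", {
  truth <- stats::setNames(rep(3, 13), 1:13)
  truth <- pmin(5, pmax(1, truth))
  ct <- class_table(1:13, paste0("c", 1:13),
                    c(rep(TRUE, 6), rep(FALSE, 7)), 13L)
  panel <- generate_expert_ratings(truth, n_experts = 13, rating_sd = 0.5,
                                   missing_prob = 0.3, seed = 21)
  per_class <- tapply(!is.na(panel$suitability), panel$class_code, sum)
  expected <- 13 * 0.7
  sdev <- sqrt(13 * 0.3 * 0.7)
  expect_true(all(abs(per_class - expected) <= 3 * sdev))
})

test_that("a low-noise panel yields high averaged-rater agreement", {
  truth <- attr(default_classes(), "true_suitability")
  panel <- generate_expert_ratings(truth, n_experts = 13, rating_sd = 0.2,
                                   missing_prob = 0, seed = 8)
  icc <- icc_two_way_mixed(ratings_matrix(panel))
  expect_gt(icc$icc_average, 0.9)
})

test_that("the packaged scenario loses forest monotonically, accelerating", {
  scen <- build_scenario(shape = c(80, 80), seed = 3)
  f <- vapply(scen$grids, forest_fraction, 0)
  expect_true(f[1] >= f[2] && f[2] >= f[3])
  expect_gt(f[2] - f[3], f[1] - f[2])  # accelerating loss
  expect_true(all(scen$risk$values >= 0 & scen$risk$values <= 1))
  # determinism of the whole scenario
  scen2 <- build_scenario(shape = c(80, 80), seed = 3)
  expect_identical(scen$grids$t2$raster$values,
                   scen2$grids$t2$raster$values)
  expect_identical(scen$panel, scen2$panel)
})

test_that("ratings CSV round-trips with empty cells as missing", {
  truth <- c(`1` = 2, `2` = 4)
  ct <- class_table(1:2, c("a", "b"), c(TRUE, FALSE), 2L)
  panel <- generate_expert_ratings(truth, n_experts = 4, rating_sd = 0.3,
                                   missing_prob = 0.4, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(panel, p)
  back <- read_ratings_csv(p)
  expect_equal(back$suitability, panel$suitability)
  expect_equal(back$density_per_100km2, panel$density_per_100km2,
               tolerance = 1e-12)
})
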