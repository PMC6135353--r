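#' Pairwise genetic distances (1 - proportion of shared alleles)
#'
#' For individuals i and j, the shared-allele count per locus is the
#' multiset intersection of their two allele copies (0, 1 or 2), summed
#' over loci: `Dps(i, j) = 1 - shared / (2 * n_loci)`. Identical genotypes
#' have distance 0; genotypes sharing no allele anywhere have distance 1.
#'
#' @param geno Integer matrix, one row per individual, `2 * n_loci`
#'   columns, locus-major pairs.
#' @return A `dist`-free plain symmetric matrix in \[0, 1\], zero diagonal.
#' @export
genetic_distances <- function(geno) {
  n <- nrow(geno)
  if (n < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (ncol(geno) %% 2L != 0L) stop("genotype matrix must have 2 columns per locus",
                                   call. = FALSE)
  L <- ncol(geno) / 2L
  shared <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a <- geno[, 2L * l - 1L]; b <- geno[, 2L * l]
    het <- a != b
    # multiset intersection of {a_i, b_i} and {a_j, b_j}
    eq_aa <- outer(a, a, "==") ; eq_ab <- outer(a, b, "==")
    eq_ba <- outer(b, a, "==") ; eq_bb <- outer(b, b, "==")
    s <- matrix(0, n, n)
    # row individual heterozygous: each of its two distinct alleles
    # contributes min(1, count in column individual)
    s_het <- (eq_aa | eq_ab) + (eq_ba | eq_bb)
    # row individual homozygous for a: shared = count of a in column pair
    s_hom <- eq_aa + eq_ab
    s[het, ] <- s_het[het, ]
    s[!het, ] <- s_hom[!het, ]
    shared <- shared + s
  }
  d <- 1 - shared / (2 * L)
  diag(d) <- 0
  d[] <- pmin(1, pmax(0, d))
  d
}

upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

#' Mantel correlogram of genetic distance against cost distance
#'
#' Pairwise cost distances are split into `n_classes` equal-frequency
#' classes. For each class the Mantel statistic is the correlation, over
#' all pairs, between genetic *similarity* (negated genetic distance) and
#' the class-membership indicator, so positive values mean pairs in that
#' class are genetically closer than average. One-sided significance comes
#' from joint row/column permutations of the genetic matrix.
#'
#' @param gen Symmetric genetic-distance matrix.
#' @param cost Symmetric cost-distance matrix, same order.
#' @param n_classes Number of distance classes.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Seed for the permutation stream.
#' @return A `mantel_correlogram` data frame: `class`, `lower`, `upper`,
#'   `mantel_r`, `p_value`, `n_pairs`.
#' @export
mantel_correlogram <- function(gen, cost, n_classes = 8, n_perm = 199,
                               seed = 1) {
  n <- nrow(gen)
  stopifnot(nrow(cost) == n, ncol(gen) == n, ncol(cost) == n, n_perm >= 99)
  up <- upper.tri(gen)
  gvec <- gen[up]; cvec <- cost[up]
  if (stats::sd(gvec) == 0) {
    stop("genetic distance matrix is constant; correlogram undefined",
         call. = FALSE)
  }
  npairs <- length(gvec)
  # equal-frequency classes via ranks (deterministic tie handling)
  rk <- rank(cvec, ties.method = "first")
  cls <- pmin(n_classes, ceiling(rk / npairs * n_classes))
  p_k <- tabulate(cls, n_classes) / npairs
  sd_g <- stats::sd(gvec) * sqrt((npairs - 1) / npairs)
  sd_i <- sqrt(p_k * (1 - p_k))
  class_r <- function(g) {
    s_k <- as.vector(rowsum(g, cls, reorder = TRUE))
    # cor(g, indicator_k) via class sums; negated so "near pairs similar"
    # is positive
    -((s_k / npairs) - mean(g) * p_k) / (sd_g * sd_i)
  }
  r_obs <- class_r(gvec)
  exceed <- integer(n_classes)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      gp <- gen[perm, perm][up]
      exceed <- exceed + (class_r(gp) >= r_obs - 1e-12)
    }
  })
  out <- data.frame(
    class = seq_len(n_classes),
    lower = as.vector(tapply(cvec, cls, min)),
    upper = as.vector(tapply(cvec, cls, max)),
    mantel_r = r_obs,
    p_value = (1 + exceed) / (n_perm + 1),
    n_pairs = tabulate(cls, n_classes)
  )
  class(out) <- c("mantel_correlogram", "data.frame")
  out
}

#' Average correlograms across simulation replicates
#'
#' Mantel r is averaged per class; significance is combined as the median
#' of the per-replicate permutation p-values.
#'
#' @param cgs A list of `mantel_correlogram` objects with identical
#'   classes.
#' @return A combined `mantel_correlogram`.
#' @export
combine_correlograms <- function(cgs) {
  stopifnot(length(cgs) >= 1L)
  out <- cgs[[1L]]
  rs <- sapply(cgs, function(x) x$mantel_r)
  ps <- sapply(cgs, function(x) x$p_value)
  out$mantel_r <- rowMeans(rs)
  out$p_value <- apply(as.matrix(ps), 1L, stats::median)
  out
}

#' Range of significant positive spatial genetic autocorrelation
#'
#' The upper cost bound of the last class in the *initial* run of classes
#' with positive Mantel r and p below `alpha`; 0 if the first class is not
#' significant. The sGD neighbourhood radius is half this range.
#'
#' @param cg A `mantel_correlogram`.
#' @param alpha Significance level.
#' @return Range in cost units.
#' @export
autocorrelation_range <- function(cg, alpha = 0.05) {
  sig <- cg$mantel_r > 0 & cg$p_value < alpha
  if (!length(sig) || !sig[1L]) return(0)
  last <- which(!sig)[1L]
  last <- if (is.na(last)) nrow(cg) else last - 1L
  cg$upper[last]
}

#' Local genetic diversity within cost-distance neighbourhoods
#'
#' For each individual, the neighbourhood is every individual within the
#' cost radius (inclusive, self included). Within each neighbourhood of at
#' least `min_n` members, the mean number of alleles per locus, observed
#' heterozygosity and expected heterozygosity are computed; smaller
#' neighbourhoods are reported missing.
#'
#' @param geno Genotype matrix (rows = individuals).
#' @param cost Symmetric cost matrix among the same individuals.
#' @param radius Neighbourhood radius in cost units (> 0).
#' @param min_n Minimum neighbourhood size (>= 2); default 10.
#' @return A `local_diversity` data frame: `point`, `local_n`,
#'   `local_alleles`, `local_ho`, `local_he` (`NA` where `local_n < min_n`).
#' @export
local_diversity <- function(geno, cost, radius, min_n = 10) {
  stopifnot(radius > 0, min_n >= 2)
  n <- nrow(geno)
  stopifnot(nrow(cost) == n)
  L <- ncol(geno) / 2L
  odd <- seq(1L, 2L * L, by = 2L)
  out <- data.frame(point = seq_len(n), local_n = NA_integer_,
                    local_alleles = NA_real_, local_ho = NA_real_,
                    local_he = NA_real_)
  for (i in seq_len(n)) {
    nb <- which(cost[i, ] <= radius)
    out$local_n[i] <- length(nb)
    if (length(nb) < min_n) next
    sub <- geno[nb, , drop = FALSE]
    he_l <- ho_l <- a_l <- numeric(L)
    for (l in seq_len(L)) {
      a1 <- sub[, 2L * l - 1L]; a2 <- sub[, 2L * l]
      p <- tabulate(match(c(a1, a2), unique(c(a1, a2)))) / (2 * length(nb))
      he_l[l] <- 1 - sum(p^2)
      ho_l[l] <- mean(a1 != a2)
      a_l[l] <- length(unique(c(a1, a2)))
    }
    out$local_alleles[i] <- mean(a_l)
    out$local_ho[i] <- mean(ho_l)
    out$local_he[i] <- mean(he_l)
  }
  class(out) <- c("local_diversity", "data.frame")
  out
}
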