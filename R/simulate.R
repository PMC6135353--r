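#' Simulation parameters for the individual-based genetic model
#'
#' Defaults follow standard landscape-genetics simulation practice for a
#' wide-ranging forest carnivore: 30 neutral loci with 10 alleles each,
#' infinite-allele mutation at 5e-4 per transmitted allele copy per
#' generation, inverse-square mating and dispersal weighting truncated at
#' the maximum cost-weighted dispersal distance, Poisson(2) offspring per
#' mating, and 200 non-overlapping generations.
#'
#' @param n_loci Number of diploid loci.
#' @param n_init_alleles Alleles per locus at initialisation (ids
#'   `0 .. n_init_alleles - 1`; mutants get fresh ids from there up).
#' @param mutation_rate Per-allele-copy mutation probability per
#'   generation.
#' @param offspring_mean Poisson mean litter size per mating.
#' @param max_cost_distance Hard truncation of mating/dispersal in cost
#'   units.
#' @param generations Number of non-overlapping generations.
#' @param n_reps Monte Carlo replicates.
#' @param movement_exponent Exponent of the inverse-power movement kernel.
#' @param cell_size Metres; floors the cost in the movement weight so the
#'   same-cell weight is finite.
#' @param regulation `"saturating"` (default): after each mateable female's
#'   first mating, additional mating events are drawn with replacement among
#'   mateable females until the offspring pool reaches the number of sites,
#'   regulating the population at the fixed-site carrying capacity while
#'   keeping Poisson litters and cost-weighted mate choice. `"poisson"`
#'   gives exactly one mating per female — an exactly-replacement fecundity
#'   under which populations random-walk to extinction; useful for
#'   demographic experiments, not for equilibrium genetics.
#' @param seed Master seed; replicate r runs under a derived substream.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_loci = 30, n_init_alleles = 10,
                       mutation_rate = 0.0005, offspring_mean = 2,
                       max_cost_distance = 125000, generations = 200,
                       n_reps = 10, movement_exponent = 2, cell_size = 1000,
                       regulation = c("saturating", "poisson"), seed = 1) {
  regulation <- match.arg(regulation)
  stopifnot(n_loci >= 1, n_init_alleles >= 2,
            mutation_rate >= 0, mutation_rate <= 1,
            offspring_mean > 0, max_cost_distance > 0, generations >= 1,
            n_reps >= 1, movement_exponent > 0, cell_size > 0)
  structure(list(n_loci = as.integer(n_loci),
                 n_init_alleles = as.integer(n_init_alleles),
                 mutation_rate = mutation_rate,
                 offspring_mean = offspring_mean,
                 max_cost_distance = max_cost_distance,
                 generations = as.integer(generations),
                 n_reps = as.integer(n_reps),
                 movement_exponent = movement_exponent,
                 cell_size = cell_size, regulation = regulation,
                 seed = seed),
            class = "sim_params")
}

#' Inverse-power movement weight with hard truncation
#'
#' `w = 1 / max(cost, cell_size)^p` for `cost <= max_cost_distance`, else
#' 0. The one-cell floor keeps the same-cell weight finite; weights are
#' normalised among candidates at the point of use, so only ratios matter.
#'
#' @param cost Cost distance(s), >= 0 (vectorised).
#' @param params A `sim_params`.
#' @return Numeric weights.
#' @export
movement_weight <- function(cost, params) {
  w <- 1 / pmax(cost, params$cell_size)^params$movement_exponent
  w[!is.finite(cost) | cost > params$max_cost_distance] <- 0
  w
}

new_population <- function(loc, female, geno, generation, n_sites,
                           next_allele, extinct = FALSE) {
  structure(list(loc = loc, female = female, geno = geno,
                 generation = generation, n_sites = n_sites,
                 next_allele = next_allele, extinct = extinct),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d individuals at %d sites, generation %d%s\n",
              length(x$loc), x$n_sites, x$generation,
              if (x$extinct) " (EXTINCT)" else ""))
  invisible(x)
}

#' Initialise a population, one individual per source location
#'
#' Sexes are i.i.d. Bernoulli(0.5); each of the `2 * n_loci` allele copies
#' is drawn uniformly from the initial allele pool, so the expected initial
#' expected-heterozygosity is `1 - 1/n_init_alleles` per locus.
#'
#' @param n_sites Number of source locations (>= 2); or pass a
#'   `source_points` data frame.
#' @param params A `sim_params`.
#' @param seed Seed (defaults to the params seed).
#' @return A `population_state` with every site occupied.
#' @export
init_population <- function(n_sites, params, seed = params$seed) {
  if (is.data.frame(n_sites)) n_sites <- nrow(n_sites)
  if (n_sites < 2L) stop("need at least 2 source locations", call. = FALSE)
  with_seed(seed, {
    geno <- matrix(sample.int(params$n_init_alleles,
                              n_sites * 2L * params$n_loci,
                              replace = TRUE) - 1L,
                   nrow = n_sites)
    new_population(loc = seq_len(n_sites),
                   female = runif(n_sites) < 0.5,
                   geno = geno, generation = 0L, n_sites = n_sites,
                   next_allele = params$n_init_alleles)
  })
}

# Gather one transmitted allele per locus from each parent row of `geno`.
# parent_idx: offspring -> parent row. Returns n_off x n_loci matrix.
gamete <- function(geno, parent_idx, n_loci) {
  n_off <- length(parent_idx)
  pick <- matrix(sample.int(2L, n_off * n_loci, replace = TRUE),
                 n_off, n_loci)
  cols <- 2L * matrix(rep(seq_len(n_loci), each = n_off), n_off) - 2L + pick
  matrix(geno[cbind(rep(parent_idx, n_loci), as.vector(cols))], n_off)
}

#' Advance the population one non-overlapping generation
#'
#' One generation comprises: (1) each female chooses a mate among males
#' within the maximum cost distance with probability proportional to the
#' movement weight (males may mate repeatedly); (2) each mating yields a
#' Poisson draw of offspring with Mendelian inheritance; (3) every
#' transmitted allele copy mutates with the per-copy mutation rate to a
#' globally novel allele (infinite-allele model); (4) all adults die;
#' (5) offspring, in random order, settle on vacant sites reachable within
#' the maximum cost distance from their natal site, with probability
#' proportional to the movement weight — offspring with no reachable vacant
#' site die; (6) realised mating and dispersal cost distances are recorded
#' as attributes `mating_costs` and `dispersal_costs`.
#'
#' @param state A `population_state`.
#' @param cost Symmetric site-by-site cost matrix covering all locations.
#' @param params A `sim_params`.
#' @return The next `population_state` (flagged `extinct` if empty). RNG
#'   state is consumed from the current stream; callers seed per replicate.
#' @export
step_generation <- function(state, cost, params) {
  n_sites <- state$n_sites
  stopifnot(nrow(cost) == n_sites, ncol(cost) == n_sites)
  if (state$extinct || length(state$loc) == 0L) {
    return(new_population(integer(0), logical(0),
                          state$geno[0, , drop = FALSE],
                          state$generation + 1L, n_sites,
                          state$next_allele, extinct = TRUE))
  }
  fem <- which(state$female); mal <- which(!state$female)
  mom_idx <- integer(0); dad_idx <- integer(0); mate_cost <- numeric(0)
  n_off_per <- integer(0)
  if (length(fem) && length(mal)) {
    # inverse-square mate weights, one row per female
    wmat <- matrix(movement_weight(cost[state$loc[fem], state$loc[mal],
                                        drop = FALSE], params),
                   nrow = length(fem))
    mateable <- which(rowSums(wmat) > 0)
    draw_mating <- function(fi) {
      i <- fem[fi]
      j <- mal[sample.int(length(mal), 1L, prob = wmat[fi, ])]
      k <- rpois(1L, params$offspring_mean)
      mate_cost <<- c(mate_cost, cost[state$loc[i], state$loc[j]])
      n_off_per <<- c(n_off_per, k)
      if (k > 0L) {
        mom_idx <<- c(mom_idx, rep.int(i, k))
        dad_idx <<- c(dad_idx, rep.int(j, k))
      }
    }
    for (fi in mateable) draw_mating(fi)
    if (params$regulation == "saturating" && length(mateable)) {
      max_events <- 10L * n_sites
      while (length(mom_idx) < n_sites &&
             length(n_off_per) < max_events) {
        draw_mating(mateable[sample.int(length(mateable), 1L)])
      }
    }
  }
  n_off <- length(mom_idx)
  next_allele <- state$next_allele
  if (n_off == 0L) {
    out <- new_population(integer(0), logical(0),
                          state$geno[0, , drop = FALSE],
                          state$generation + 1L, n_sites, next_allele,
                          extinct = TRUE)
    attr(out, "mating_costs") <- mate_cost
    attr(out, "dispersal_costs") <- numeric(0)
    attr(out, "offspring_counts") <- n_off_per
    return(out)
  }
  L <- params$n_loci
  gm <- gamete(state$geno, mom_idx, L)
  gp <- gamete(state$geno, dad_idx, L)
  geno_off <- matrix(0L, n_off, 2L * L)
  geno_off[, seq(1L, 2L * L, by = 2L)] <- gm
  geno_off[, seq(2L, 2L * L, by = 2L)] <- gp
  if (params$mutation_rate > 0) {
    mut <- which(runif(length(geno_off)) < params$mutation_rate)
    if (length(mut)) {
      geno_off[mut] <- next_allele + seq_along(mut) - 1L
      next_allele <- next_allele + length(mut)
    }
  }
  female_off <- runif(n_off) < 0.5
  natal <- state$loc[mom_idx]
  # settlement: random order, first-come competition for vacant sites
  ord <- sample.int(n_off)
  vacant <- rep(TRUE, n_sites)
  site <- rep(NA_integer_, n_off)
  disp_cost <- rep(NA_real_, n_off)
  for (o in ord) {
    w <- movement_weight(cost[natal[o], ], params)
    w[!vacant] <- 0
    tw <- sum(w)
    if (tw <= 0) next
    s <- sample.int(n_sites, 1L, prob = w)
    site[o] <- s
    disp_cost[o] <- cost[natal[o], s]
    vacant[s] <- FALSE
  }
  keep <- !is.na(site)
  # settled offspring per adult (mother + father credit), for empirical
  # effective-size estimation
  realized <- numeric(length(state$loc))
  if (any(keep)) {
    tb <- tabulate(c(mom_idx[keep], dad_idx[keep]), nbins = length(state$loc))
    realized <- realized + tb
  }
  out <- new_population(loc = site[keep], female = female_off[keep],
                        geno = geno_off[keep, , drop = FALSE],
                        generation = state$generation + 1L,
                        n_sites = n_sites, next_allele = next_allele,
                        extinct = !any(keep))
  attr(out, "mating_costs") <- mate_cost
  attr(out, "dispersal_costs") <- disp_cost[keep]
  attr(out, "offspring_counts") <- n_off_per
  attr(out, "realized_offspring") <- realized
  out
}

#' Global genetic summary of a population
#'
#' Expected heterozygosity is the mean over loci of `1 - sum(p_k^2)` with
#' `p_k` the current allele frequencies; observed heterozygosity is the
#' fraction of heterozygous locus-individual pairs; the inbreeding
#' coefficient is `F = 1 - Ho/He` (undefined and returned as `NA` with a
#' warning when He is 0); the allele count sums distinct alleles over loci.
#'
#' @param state A `population_state` with at least one individual.
#' @return A one-row data frame: `n`, `he`, `ho`, `f`, `total_alleles`.
#' @export
global_genetic_summary <- function(state) {
  n <- length(state$loc)
  if (n < 1L) stop("empty population has no genetic summary", call. = FALSE)
  L <- ncol(state$geno) / 2L
  he_l <- ho_l <- numeric(L); n_all <- integer(L)
  for (l in seq_len(L)) {
    a1 <- state$geno[, 2L * l - 1L]; a2 <- state$geno[, 2L * l]
    p <- tabulate(match(c(a1, a2), unique(c(a1, a2)))) / (2 * n)
    he_l[l] <- 1 - sum(p^2)
    ho_l[l] <- mean(a1 != a2)
    n_all[l] <- length(unique(c(a1, a2)))
  }
  he <- mean(he_l); ho <- mean(ho_l)
  data.frame(n = n, he = he, ho = ho,
             f = inbreeding_coefficient(he, ho),
             total_alleles = sum(n_all))
}

#' Inbreeding coefficient from expected and observed heterozygosity
#'
#' @param he,ho Expected and observed heterozygosity.
#' @return `1 - ho/he`; `NA` with a warning when `he` is 0.
#' @export
inbreeding_coefficient <- function(he, ho) {
  out <- ifelse(he > 0, 1 - ho / he, NA_real_)
  if (any(he == 0)) {
    warning("He = 0: inbreeding coefficient undefined", call. = FALSE)
  }
  out
}

#' Run replicated simulations over a pairwise cost matrix
#'
#' Runs `params$n_reps` independent replicates of `params$generations`
#' generations, each from a fresh initial population, under derived
#' per-replicate seed substreams. Per-generation trajectories record
#' population size, He, Ho, F, allele count and the mean realised mating
#' and dispersal cost distances.
#'
#' @param cost Symmetric site-by-site cost matrix.
#' @param params A `sim_params`.
#' @param record_every Record the trajectory every this many generations
#'   (the final generation is always recorded).
#' @return A `sim_runs` list: `trajectories` (list of per-rep data frames),
#'   `final_states` (list of `population_state`), `params`.
#' @export
simulate_from_costs <- function(cost, params, record_every = 10) {
  n_sites <- nrow(cost)
  traj <- vector("list", params$n_reps)
  finals <- vector("list", params$n_reps)
  for (r in seq_len(params$n_reps)) {
    rep_seed <- derive_seed(params$seed, paste0("rep", r))
    res <- with_seed(rep_seed, {
      state <- init_population(n_sites, params, seed = rep_seed + 1L)
      rows <- list()
      for (gen in seq_len(params$generations)) {
        state <- step_generation(state, cost, params)
        if (state$extinct) break
        if (gen %% record_every == 0L || gen == params$generations) {
          gs <- global_genetic_summary(state)
          mc <- attr(state, "mating_costs")
          dc <- attr(state, "dispersal_costs")
          gs$generation <- gen
          gs$mean_mating_cost <- if (length(mc)) mean(mc) else NA_real_
          gs$mean_dispersal_cost <- if (length(dc)) mean(dc) else NA_real_
          rows[[length(rows) + 1L]] <- gs
        }
      }
      list(traj = do.call(rbind, rows), state = state)
    })
    traj[[r]] <- res$traj
    finals[[r]] <- res$state
  }
  structure(list(trajectories = traj, final_states = finals,
                 params = params),
            class = "sim_runs")
}

#' Run the genetic simulation over a resistance surface
#'
#' Builds the pairwise least-cost matrix among the source points once, then
#' delegates to [simulate_from_costs()].
#'
#' @param sources A `source_points` data frame.
#' @param resistance A `resistance_grid`.
#' @param params A `sim_params`.
#' @param record_every Trajectory recording stride.
#' @return A `sim_runs` object with the cost matrix attached as `cost`.
#' @export
run_simulation <- function(sources, resistance, params, record_every = 10) {
  cost <- cost_distance_matrix(resistance, sources)
  out <- simulate_from_costs(cost, params, record_every)
  out$cost <- cost
  out$sources <- sources
  out
}

#' Across-replicate summary at the final recorded generation
#'
#' @param runs A `sim_runs` object.
#' @return A two-row data frame (`mean`, `sd`) over replicates of the
#'   final-generation population and genetic summaries; extinct replicates
#'   contribute `n = 0` and `NA` genetics.
#' @export
summarise_runs <- function(runs) {
  last <- lapply(seq_along(runs$trajectories), function(r) {
    tr <- runs$trajectories[[r]]
    extinct <- isTRUE(runs$final_states[[r]]$extinct)
    if (extinct || is.null(tr) || !nrow(tr)) {
      data.frame(n = 0, he = NA_real_, ho = NA_real_, f = NA_real_,
                 total_alleles = NA_real_, generation = NA_integer_,
                 mean_mating_cost = NA_real_, mean_dispersal_cost = NA_real_)
    } else tr[nrow(tr), ]
  })
  last <- do.call(rbind, last)
  num <- c("n", "he", "ho", "f", "total_alleles", "mean_mating_cost",
           "mean_dispersal_cost")
  out <- rbind(
    data.frame(stat = "mean", t(colMeans(last[num], na.rm = TRUE))),
    data.frame(stat = "sd", t(apply(last[num], 2, sd, na.rm = TRUE)))
  )
  rownames(out) <- NULL
  out
}

#' Allometric maximum-dispersal bound for mammals
#'
#' The widely used allometry `d_max = 40 * sqrt(home range)` relating a
#' mammal's maximum dispersal distance (km) to its home-range area (km^2);
#' for a felid with a 16 km^2 home range this gives the 160 km lower bound
#' used to justify dispersal thresholds of 125-250 km.
#'
#' @param home_range_km2 Home-range area in square kilometres.
#' @return Maximum dispersal distance in kilometres.
#' @export
allometric_dispersal_bound <- function(home_range_km2) {
  stopifnot(home_range_km2 > 0)
  40 * sqrt(home_range_km2)
}
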