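#' Configuration for the uniformity simulator
#'
#' @param model A [mutation_model()]; in `"explicit"` mode `mu` is
#'   interpreted as the per-copy mutation rate (the half-fixation argument
#'   makes the two numerically interchangeable for uniformity curves).
#' @param ne Number of independent selfing lines.
#' @param t_max Last generation simulated.
#' @param n_reps Monte-Carlo replicates.
#' @param mode `"effective"` (each line-locus fixes an eventually-fixed new
#'   allele with probability `mu` per generation) or `"explicit"` (full
#'   diploid per-copy simulation with selfed reproduction).
#' @param criterion `"fixed_only"` (a line deviates only once a new allele
#'   reaches homozygosity; the analytic model's convention, and the
#'   default) or `"observed_genotype"` (any non-ancestral genotype counts,
#'   heterozygotes included). Only meaningful in explicit mode.
#' @param infinite_alleles In explicit mode, make every mutation a novel
#'   allele instead of a stepwise +/-1 repeat change. Removes the (tiny)
#'   chance that a second mutation restores the ancestral size.
#' @param seed Integer seed; identical configurations reproduce identical
#'   output.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(model = mutation_model(), ne = 50, t_max = 202,
                       n_reps = 1000, mode = c("effective", "explicit"),
                       criterion = c("fixed_only", "observed_genotype"),
                       infinite_alleles = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  stopifnot(inherits(model, "mutation_model"), ne >= 1, t_max >= 1,
            n_reps >= 1)
  structure(list(model = model, ne = as.integer(ne),
                 t_max = as.integer(t_max), n_reps = as.integer(n_reps),
                 mode = mode, criterion = criterion,
                 infinite_alleles = isTRUE(infinite_alleles),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Monte-Carlo estimate of the genotype-uniformity curve
#'
#' Simulates `Ne` obligately selfing lines forward in time and estimates,
#' for every generation up to `t_max`, the probability `P_i(t)` that no
#' line has deviated from the ancestral multilocus genotype.
#'
#' In `"effective"` mode each line-locus acquires an eventually-fixed new
#' allele with probability `mu` per generation; the first deviation
#' generation is therefore the first success of `Ne * l` independent
#' Bernoulli(`mu`) streams, drawn directly from its exact geometric
#' distribution. In `"explicit"` mode each line is simulated as a diploid
#' selfer at the per-copy level (compiled code): gametes are random unions
#' from the same parent, each transmitted copy mutates with probability
#' `mu` under a stepwise model, and deviation is judged by `criterion`.
#'
#' @param config A [sim_config()].
#' @return A `"uniformity_curve"` data frame with columns `generation`,
#'   `estimate` (P_i-hat), `se` (binomial Monte-Carlo standard error) and
#'   `analytic` (the closed-form curve for the same parameters), with the
#'   configuration attached as an attribute.
#' @examples
#' cfg <- sim_config(ne = 50, t_max = 50, n_reps = 200, seed = 42)
#' head(simulate_uniformity(cfg))
#' @export
simulate_uniformity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mu <- config$model$mu
  l <- config$model$n_loci
  set.seed(config$seed)
  if (config$mode == "effective") {
    p_dev <- 1 - exp(config$ne * l * log1p(-mu))  # per-generation hazard
    first <- if (p_dev == 0) rep(config$t_max + 1L, config$n_reps)
             else pmin(stats::rgeom(config$n_reps, p_dev) + 1L,
                       config$t_max + 1L)
  } else {
    first <- explicit_first_deviation(config$n_reps, config$ne, l, mu,
                                      config$t_max,
                                      config$criterion == "fixed_only",
                                      config$infinite_alleles)
  }
  gen <- seq_len(config$t_max)
  surv <- 1 - stats::ecdf(first)(gen)   # P(first deviation > t)
  out <- data.frame(generation = gen,
                    estimate = surv,
                    se = sqrt(surv * (1 - surv) / config$n_reps),
                    analytic = uniformity_probability(config$model,
                                                      config$ne, gen))
  attr(out, "config") <- config
  class(out) <- c("uniformity_curve", "data.frame")
  out
}

#' Fixation probability of a new mutation under obligate selfing
#'
#' Follows a single locus that starts heterozygous (one new allele, one
#' ancestral) through generations of selfed propagation until the new
#' allele is either fixed or lost. Selfing an Aa parent yields AA, Aa, aa
#' offspring with probabilities 1/4, 1/2, 1/4, so the new allele is fixed
#' with probability exactly 1/2 -- the half-fixation argument behind the
#' fixation-effective mutation rate of [mutation_model()].
#'
#' @param n_reps Number of replicate lineages (`>= 1`).
#' @param seed Integer seed.
#' @return List with `estimate` (fixation fraction), `se` (binomial
#'   standard error) and `n_reps`.
#' @examples
#' fixation_probability_of_new_mutation(10000, seed = 1)$estimate
#' @export
fixation_probability_of_new_mutation <- function(n_reps = 1e5, seed = 1L) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  active <- rep(TRUE, n_reps)
  fixed <- logical(n_reps)
  while (any(active)) {
    u <- stats::runif(sum(active))
    idx <- which(active)
    fixed[idx[u < 0.25]] <- TRUE        # aa: new allele homozygous
    active[idx[u < 0.5]] <- FALSE       # resolved either way
  }
  est <- mean(fixed)
  list(estimate = est, se = sqrt(est * (1 - est) / n_reps), n_reps = n_reps)
}

#' Forward simulation of a microsatellite population under mixed mating
#'
#' Wright-Fisher population of constant size `n` with selfing rate `s`:
#' each offspring selfs with probability `s` (both gametes from one
#' parent), otherwise it is formed by random outcrossing between two
#' parents drawn with replacement. Each transmitted allele copy mutates
#' with probability `mu` by a stepwise +/-1 repeat change. Founder events
#' are instantaneous: the initial genotypes may be any number of rows and
#' the population jumps to size `n` in the first generation.
#'
#' @param n Population size (individuals).
#' @param n_loci Number of loci; ignored when `init` is a matrix.
#' @param mu Per-copy per-generation mutation rate; either a scalar or a
#'   vector with one rate per locus (e.g. dinucleotide loci mutating
#'   faster than longer motifs).
#' @param s Selfing rate in `[0, 1]`.
#' @param t Generations to simulate.
#' @param init Either `NULL` (monomorphic start, all alleles at repeat
#'   size `init_size`), an integer number of equifrequent starting alleles
#'   per locus, or a genotype matrix (rows = founders, columns =
#'   `2 * n_loci` allele sizes, loci in consecutive column pairs).
#' @param init_size Ancestral repeat size used for monomorphic or
#'   integer `init` (alleles then span `init_size`, `init_size + 1`, ...).
#' @param seed Optional integer seed (`NULL` = use current RNG state).
#' @return Integer matrix `n x (2 * n_loci)` of allele sizes, loci in
#'   consecutive column pairs.
#' @examples
#' pop <- simulate_ssr_population(50, 6, mu = 0, s = 1, t = 30,
#'                                init = 3, seed = 7)
#' @export
simulate_ssr_population <- function(n, n_loci = 6, mu = 4.96e-5, s = 1,
                                    t = 100, init = NULL, init_size = 20L,
                                    seed = NULL) {
  if (n < 1) stop("population size must be >= 1")
  if (s < 0 || s > 1) stop("'s' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(init)) {
    if (ncol(init) %% 2 != 0) stop("'init' must have 2 columns per locus")
    n_loci <- ncol(init) / 2
    pop <- init
  } else if (is.null(init)) {
    pop <- matrix(as.integer(init_size), nrow = n, ncol = 2 * n_loci)
  } else {
    k <- as.integer(init)
    pop <- matrix(sample.int(k, n * 2 * n_loci, replace = TRUE) +
                    as.integer(init_size) - 1L,
                  nrow = n, ncol = 2 * n_loci)
  }
  storage.mode(pop) <- "integer"
  col_a <- seq(1, 2 * n_loci, by = 2)
  col_b <- col_a + 1L
  for (gen in seq_len(t)) {
    n_cur <- nrow(pop)
    p1 <- sample.int(n_cur, n, replace = TRUE)
    p2 <- ifelse(stats::runif(n) < s, p1, sample.int(n_cur, n, replace = TRUE))
    gam <- function(parents) {
      pick_b <- matrix(stats::runif(n * n_loci) < 0.5, n, n_loci)
      g <- pop[parents, col_a, drop = FALSE]
      g[pick_b] <- pop[parents, col_b, drop = FALSE][pick_b]
      g
    }
    g1 <- gam(p1); g2 <- gam(p2)
    if (any(mu > 0)) {
      mu_mat <- matrix(rep(mu, length.out = n_loci), n, n_loci, byrow = TRUE)
      for (g in c("g1", "g2")) {
        m <- get(g)
        hit <- stats::runif(length(m)) < mu_mat
        if (any(hit))
          m[hit] <- m[hit] + sample(c(-1L, 1L), sum(hit), replace = TRUE)
        assign(g, m)
      }
    }
    nxt <- matrix(0L, n, 2 * n_loci)
    nxt[, col_a] <- g1
    nxt[, col_b] <- g2
    pop <- nxt
  }
  pop
}
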