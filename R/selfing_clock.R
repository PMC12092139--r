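#' Mutation model for the genotype-uniformity clock
#'
#' Bundles the per-locus, per-generation *fixation-effective* haploid
#' mutation rate `mu` with the number of SSR loci scored. In an obligately
#' selfing line a new allele arises at a diploid locus with probability
#' `2*mu_copy` per generation, but only half of the new alleles are ever
#' fixed during subsequent selfed propagation, so the rate of
#' eventually-fixed new alleles per locus is `2*mu_copy * 1/2 = mu_copy`.
#' `mu` here is that fixation-effective rate.
#'
#' The default `mu = 4.96e-5` is the lowest dinucleotide-repeat mutation
#' rate estimated from *Arabidopsis thaliana* mutation-accumulation lines,
#' a deliberately conservative choice; the default of six loci is the
#' number of dinucleotide-repeat markers in the study panel.
#'
#' @param mu Per-locus per-generation fixation-effective mutation rate,
#'   a probability in `[0, 1)`.
#' @param n_loci Number of SSR loci `l` (positive integer).
#' @return An object of class `"mutation_model"`.
#' @examples
#' mutation_model()
#' mutation_model(mu = 1e-4, n_loci = 18)
#' @export
mutation_model <- function(mu = 4.96e-5, n_loci = 6L) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0 || mu >= 1)
    stop("'mu' must be a single probability in [0, 1)")
  n_loci <- as.integer(n_loci)
  if (length(n_loci) != 1L || is.na(n_loci) || n_loci < 1L)
    stop("'n_loci' must be a positive integer")
  structure(list(mu = mu, n_loci = n_loci), class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Genotype-uniformity clock mutation model\n",
      "  fixation-effective mu: ", format(x$mu), " per locus per generation\n",
      "  loci (l): ", x$n_loci, "\n", sep = "")
  invisible(x)
}

#' Probability that a selfing line fixes no new SSR allele in t generations
#'
#' `P_t = (1 - mu)^(l * t)`: the probability that, over `t` generations of
#' obligate selfing, no eventually-fixed new allele arises at any of the
#' `l` loci of a single line. Evaluated in log space so very large `l * t`
#' do not underflow prematurely.
#'
#' @param model A [mutation_model()].
#' @param t Generations (non-negative; vectorised).
#' @return `P_t`, in `(0, 1]` (0 only in the limit).
#' @examples
#' prob_no_new_fixed_allele(mutation_model(), t = 21)
#' @export
prob_no_new_fixed_allele <- function(model, t) {
  stopifnot(inherits(model, "mutation_model"))
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be non-negative")
  exp(model$n_loci * t * log1p(-model$mu))
}

#' Probability that all Ne selfing lines retain the ancestral genotype
#'
#' `P_i = P_t ^ Ne`: with `Ne` independent selfing lines, the probability
#' that only the single ancestral multilocus genotype is observed across
#' the whole population after `t` generations.
#'
#' @param p_t Per-line no-new-fixed-allele probability `P_t`, in `[0, 1]`.
#' @param ne Effective population size: number of independent selfing
#'   lines (`>= 1`).
#' @return `P_i = p_t^ne`.
#' @examples
#' p_t <- prob_no_new_fixed_allele(mutation_model(), t = 21)
#' prob_population_uniform(p_t, ne = 500)
#' @export
prob_population_uniform <- function(p_t, ne) {
  if (any(!is.finite(p_t)) || any(p_t < 0) || any(p_t > 1))
    stop("'p_t' must lie in [0, 1]")
  if (any(ne < 1)) stop("'ne' must be >= 1")
  ifelse(p_t == 0, 0, exp(ne * log(p_t)))
}

#' Population uniformity probability P_i(t)
#'
#' Convenience composition of [prob_no_new_fixed_allele()] and
#' [prob_population_uniform()], computed wholly in log space.
#'
#' @inheritParams prob_no_new_fixed_allele
#' @inheritParams prob_population_uniform
#' @return `P_i(t) = ((1 - mu)^(l t))^Ne`.
#' @export
uniformity_probability <- function(model, ne, t) {
  stopifnot(inherits(model, "mutation_model"))
  if (any(ne < 1)) stop("'ne' must be >= 1")
  if (any(t < 0)) stop("'t' must be non-negative")
  exp(ne * model$n_loci * t * log1p(-model$mu))
}

#' Generations until genotype uniformity becomes improbable
#'
#' The smallest integer `t*` at which `P_i(t) = ((1-mu)^(l t))^Ne` falls
#' strictly below `alpha`. Uniform multilocus genotypes observed in the
#' field therefore bound the age of the population: at `t >= t*` the
#' observed uniformity would be improbable at level `alpha`. Computed from
#' the closed form `log(alpha) / (l * Ne * log(1 - mu))` with the boundary
#' handled strictly: if `P_i(t)` equals `alpha` exactly, `t` does not yet
#' qualify.
#'
#' @inheritParams uniformity_probability
#' @param alpha Probability threshold (default 0.05).
#' @return Integer `t*`; `Inf` with a warning when `mu = 0` (uniformity is
#'   then never improbable).
#' @examples
#' m <- mutation_model()             # mu = 4.96e-5, l = 6
#' generations_to_threshold(m, ne = 500)  # 21
#' generations_to_threshold(m, ne = 100)  # 101
#' generations_to_threshold(m, ne = 50)   # 202
#' @export
generations_to_threshold <- function(model, ne, alpha = 0.05) {
  stopifnot(inherits(model, "mutation_model"))
  if (length(ne) != 1L || ne < 1) stop("'ne' must be a single value >= 1")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly between 0 and 1")
  if (model$mu == 0) {
    warning("mu = 0: uniformity persists indefinitely; returning Inf")
    return(Inf)
  }
  rate <- model$n_loci * ne * log1p(-model$mu)   # negative
  tstar <- floor(log(alpha) / rate) + 1          # strict inequality
  # guard the closed form against floating-point edge effects
  log_pi <- function(t) ne * model$n_loci * t * log1p(-model$mu)
  while (log_pi(tstar) >= log(alpha)) tstar <- tstar + 1
  while (tstar > 1 && log_pi(tstar - 1) < log(alpha)) tstar <- tstar - 1
  as.integer(tstar)
}

#' Generation-time range
#'
#' Calendar time per generation, as a (min, max) range in years. The
#' study organisms are estimated at roughly 5-10 years per generation.
#'
#' @param min_years,max_years Per-generation calendar time bounds,
#'   `0 < min_years <= max_years`.
#' @return An object of class `"generation_time_range"`.
#' @export
generation_time_range <- function(min_years = 5, max_years = 10) {
  if (!(min_years > 0 && min_years <= max_years))
    stop("need 0 < min_years <= max_years")
  structure(list(min_years = min_years, max_years = max_years),
            class = "generation_time_range")
}

#' Convert a generation count to a calendar window
#'
#' @param t Generations (non-negative; vectorised).
#' @param g A [generation_time_range()].
#' @return A data frame with columns `t`, `years_min`, `years_max`.
#' @examples
#' calendar_window(202, generation_time_range(5, 10))  # 1010-2020 years
#' @export
calendar_window <- function(t, g = generation_time_range()) {
  stopifnot(inherits(g, "generation_time_range"))
  if (any(t < 0)) stop("'t' must be non-negative")
  data.frame(t = t, years_min = t * g$min_years, years_max = t * g$max_years)
}

#' Uniformity-clock summary across population-size scenarios
#'
#' For each effective population size, the first generation at which the
#' genotype-uniformity probability drops below `alpha`, with the implied
#' calendar window.
#'
#' @inheritParams generations_to_threshold
#' @param ne Vector of effective population sizes.
#' @param g A [generation_time_range()].
#' @return Data frame with columns `ne`, `t_star`, `years_min`, `years_max`.
#' @examples
#' clock_table(mutation_model(), ne = c(50, 100, 500))
#' @export
clock_table <- function(model = mutation_model(), ne = c(50, 100, 500),
                        alpha = 0.05, g = generation_time_range()) {
  t_star <- vapply(ne, function(n) as.numeric(generations_to_threshold(model, n, alpha)),
                   numeric(1))
  data.frame(ne = ne, t_star = t_star,
             years_min = t_star * g$min_years,
             years_max = t_star * g$max_years)
}
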