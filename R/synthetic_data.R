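#' Default synthetic sister-pair scenario
#'
#' Parameters of the synthetic study system: a mixed-mating chasmogamous
#' species and an obligately selfing (cleistogamous) sister recently
#' founded from it. The defaults mirror the sampling design the package
#' targets: an 18-locus SSR panel of which 6 loci are dinucleotide
#' repeats mutating at 4.96e-5 per copy per generation (the longer-motif
#' loci mutate at 1e-5); a chasmogamous
#' population of 250 with a high selfing/geitonogamy rate; a
#' cleistogamous lineage of effective size 50 founded from a single
#' individual 15 generations ago (inside the analytic uniformity
#' window); a SNP panel of 125 locus groups x 3 SNPs diverging for 35
#' generations; and RNA-seq-like variant tables with a low-heterozygosity,
#' deleterious-enriched selfing profile against a diverse outcrossing
#' profile.
#'
#' @param seed Integer seed; every generator is a pure function of its
#'   configuration, so identical configs give identical data.
#' @param ... Named overrides for any top-level component (`ssr`, `snps`,
#'   `variants`, `pgls`), each a list merged over the defaults.
#' @return A `"scenario_config"` list.
#' @export
scenario_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ssr = list(n_loci = 18L, n_dinuc = 6L, mu = 4.96e-5, mu_other = 1e-5,
               chasm_n = 250L, chasm_s = 0.95, chasm_sample = 54L,
               standing_alleles = 3L, burnin = 200L,
               cleist_ne = 50L, founder_gens = 15L, cleist_sample = 31L),
    snps = list(n_locus_groups = 125L, snps_per_locus = 3L,
                divergence_gens = 35L, ne_chasm = 250L, ne_cleist = 50L,
                chasm_sample = 30L, cleist_sample = 30L,
                chasm_selfing = 0.95, missing_rate = 0.05),
    variants = list(n_transcripts = 400L, samples_per_species = 8L,
                    selfing = list(density_per_kb = 0.1,
                                   nonsyn_fraction = 0.45,
                                   deleterious_fraction = 0.25),
                    outcrossing = list(density_per_kb = 1.0,
                                       nonsyn_fraction = 0.35,
                                       deleterious_fraction = 0.10)),
    pgls = list(n_species = 16L, selfing_fraction = 0.5,
                baseline = 2, effect = -1, sigma = 0.5))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  structure(cfg, class = "scenario_config")
}

pop_to_ssr_df <- function(pop, species, pops, sample_prefix) {
  n_loci <- ncol(pop) / 2
  df <- as.data.frame(pop)
  names(df) <- as.vector(rbind(paste0("loc", seq_len(n_loci), "_a"),
                               paste0("loc", seq_len(n_loci), "_b")))
  cbind(data.frame(sample = paste0(sample_prefix, seq_len(nrow(pop))),
                   population = pops, species = species), df)
}

#' Synthetic sister-pair SSR genotype table
#'
#' Forward-simulates (via [simulate_ssr_population()]) a mixed-mating
#' chasmogamous population from standing variation, founds a
#' cleistogamous lineage from a single individual of it, and runs both
#' forward to the present. Sampled individuals are split across two
#' population labels per species, so a genotype-uniform selfer shows the
#' same multilocus genotype in different "populations".
#'
#' @param cfg A [scenario_config()].
#' @return An [ssr_table()] with species `"chasm"` and `"cleist"`; the
#'   first `n_dinuc` loci carry motif length 2.
#' @export
make_sister_pair_ssr <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$ssr
  set.seed(cfg$seed)
  # dinucleotide loci mutate at the panel rate, longer motifs more slowly
  mu_vec <- c(rep(p$mu, p$n_dinuc), rep(p$mu_other, p$n_loci - p$n_dinuc))
  anc <- simulate_ssr_population(p$chasm_n, p$n_loci, mu_vec, p$chasm_s,
                                 t = p$burnin, init = p$standing_alleles)
  founder <- anc[sample.int(nrow(anc), 1L), , drop = FALSE]
  cleist <- simulate_ssr_population(p$cleist_ne, mu = mu_vec, s = 1,
                                    t = p$founder_gens, init = founder)
  chasm <- simulate_ssr_population(p$chasm_n, mu = mu_vec, s = p$chasm_s,
                                   t = p$founder_gens, init = anc)
  samp <- function(pop, k) pop[sample.int(nrow(pop), k), , drop = FALSE]
  two_pops <- function(prefix, k) paste0(prefix, rep(1:2, length.out = k))
  df <- rbind(
    pop_to_ssr_df(samp(chasm, p$chasm_sample), "chasm",
                  two_pops("chasmP", p$chasm_sample), "ch"),
    pop_to_ssr_df(samp(cleist, p$cleist_sample), "cleist",
                  two_pops("cleistP", p$cleist_sample), "cl"))
  motif <- stats::setNames(c(rep(2L, p$n_dinuc),
                             rep(3L, p$n_loci - p$n_dinuc)),
                           paste0("loc", seq_len(p$n_loci)))
  ssr_table(df, motif_len = motif)
}

#' Synthetic sister-pair SNP matrix
#'
#' Two-population drift simulation: ancestral allele frequencies drift
#' independently in the chasmogamous and cleistogamous lineages for the
#' configured number of generations (binomial Wright-Fisher steps; the
#' selfer drifts over `Ne` haploid-equivalent copies because obligate
#' selfing makes lines effectively haploid). Genotypes are drawn with the
#' mating-system-implied inbreeding (F = s/(2-s) for the mixed mater,
#' F = 1 for the selfer), SNPs carry locus-group structure for thinning
#' tests, and genotypes are masked at the configured missingness rate.
#' Expected fixed differences increase with divergence time.
#'
#' @param cfg A [scenario_config()].
#' @return A [snp_matrix()] with species `"chasm"` and `"cleist"`.
#' @export
make_sister_pair_snps <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$snps
  set.seed(cfg$seed + 1L)
  n_snp <- p$n_locus_groups * p$snps_per_locus
  p0 <- stats::runif(n_snp, 0.1, 0.9)
  drift <- function(freq, copies, gens) {
    for (g in seq_len(gens)) freq <- stats::rbinom(n_snp, copies, freq) / copies
    freq
  }
  pc <- drift(p0, 2L * p$ne_chasm, p$divergence_gens)
  pk <- drift(p0, p$ne_cleist, p$divergence_gens)
  f_chasm <- p$chasm_selfing / (2 - p$chasm_selfing)
  draw_geno <- function(freq, n, f) {
    probs <- rbind(`0` = (1 - freq)^2 + f * freq * (1 - freq),
                   `1` = 2 * freq * (1 - freq) * (1 - f),
                   `2` = freq^2 + f * freq * (1 - freq))
    t(vapply(seq_along(freq), function(j)
      sample(0:2, n, replace = TRUE, prob = probs[, j]), integer(n)))
  }
  g_ch <- t(draw_geno(pc, p$chasm_sample, f_chasm))
  g_cl <- t(draw_geno(pk, p$cleist_sample, 1))
  geno <- rbind(g_ch, g_cl)
  if (p$missing_rate > 0)
    geno[stats::runif(length(geno)) < p$missing_rate] <- NA_integer_
  samples <- data.frame(
    sample = c(paste0("ch", seq_len(p$chasm_sample)),
               paste0("cl", seq_len(p$cleist_sample))),
    species = rep(c("chasm", "cleist"), c(p$chasm_sample, p$cleist_sample)),
    population = rep(c("chasmP1", "cleistP1"),
                     c(p$chasm_sample, p$cleist_sample)))
  snps <- data.frame(
    snp_id = paste0("snp", seq_len(n_snp)),
    locus_id = paste0("loc", rep(seq_len(p$n_locus_groups),
                                 each = p$snps_per_locus)),
    pos_in_locus = rep(seq_len(p$snps_per_locus), p$n_locus_groups))
  snp_matrix(geno, samples, snps)
}

#' Synthetic per-sample heterozygous-SNV variant tables
#'
#' Transcript lengths are drawn once per call (log-normal around 1.4 kb,
#' shared by every sample); per transcript, each sample's heterozygous
#' SNV count is Poisson at the species profile's per-kb density. Effect
#' classes are Bernoulli draws at the profile's nonsynonymous fraction,
#' and nonsynonymous SNVs are deleterious with conditional probability
#' `deleterious_fraction / nonsyn_fraction`, so the realised fraction of
#' deleterious SNVs among all SNVs matches the configured one in
#' expectation. Scores are drawn from class-conditional uniforms.
#'
#' @param cfg A [scenario_config()].
#' @return A [variant_table()] with species `"selfing"` and
#'   `"outcrossing"`.
#' @export
make_variant_tables <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$variants
  set.seed(cfg$seed + 2L)
  len <- pmax(300L, round(stats::rlnorm(p$n_transcripts, log(1400), 0.4)))
  tr_ids <- sprintf("tr%04d", seq_len(p$n_transcripts))
  one_sample <- function(sample_id, species, prof) {
    lam <- len / 1000 * prof$density_per_kb
    counts <- stats::rpois(p$n_transcripts, lam)
    rows <- list()
    q_del <- if (prof$nonsyn_fraction > 0)
      prof$deleterious_fraction / prof$nonsyn_fraction else 0
    stopifnot(q_del <= 1)
    for (i in which(counts > 0)) {
      k <- counts[i]
      nonsyn <- stats::runif(k) < prof$nonsyn_fraction
      del <- nonsyn & (stats::runif(k) < q_del)
      score <- rep(NA_real_, k)
      score[del] <- stats::runif(sum(del), -8, -2.5)
      score[nonsyn & !del] <- stats::runif(sum(nonsyn & !del), -2.5, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, species = species, transcript_id = tr_ids[i],
        transcript_len_bp = len[i],
        snv_id = paste0(sample_id, "_", tr_ids[i], "_", seq_len(k)),
        effect = ifelse(nonsyn, "nonsynonymous", "synonymous"),
        score = score)
    }
    empty <- which(counts == 0)
    if (length(empty) > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, species = species, transcript_id = tr_ids[empty],
        transcript_len_bp = len[empty], snv_id = NA_character_,
        effect = NA_character_, score = NA_real_)
    do.call(rbind, rows)
  }
  out <- list()
  for (sp in c("selfing", "outcrossing")) {
    prof <- p[[sp]]
    for (i in seq_len(p$samples_per_species))
      out[[length(out) + 1L]] <- one_sample(paste0(sp, i), sp, prof)
  }
  variant_table(do.call(rbind, out))
}

#' Synthetic tree and trait table for the phylogenetic regression
#'
#' Random tree (\code{ape::rtree}) with a designated set of selfing
#' tips; the trait is Brownian noise on the tree plus the configured
#' selfing effect, so regressions should recover the effect's sign and
#' magnitude.
#'
#' @param cfg A [scenario_config()].
#' @return List with `tree` (`phylo`), `traits` (data frame `species`,
#'   `selfing`, `metric`), and `effect` (the true coefficient).
#' @export
make_pgls_dataset <- function(cfg = scenario_config()) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$pgls
  set.seed(cfg$seed + 3L)
  tree <- ape::rtree(p$n_species)
  selfers <- sample(tree$tip.label, round(p$selfing_fraction * p$n_species))
  C <- brownian_covariance(tree)
  noise <- p$sigma * drop(t(chol(C)) %*% stats::rnorm(p$n_species))
  selfing <- as.integer(tree$tip.label %in% selfers)
  traits <- data.frame(species = tree$tip.label, selfing = selfing,
                       metric = p$baseline + p$effect * selfing + noise)
  list(tree = tree, traits = traits, effect = p$effect)
}
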