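test_that("generators are pure functions of their configuration", {
  cfg <- scenario_config(seed = 17)
  expect_identical(make_sister_pair_ssr(cfg), make_sister_pair_ssr(cfg))
  expect_identical(make_sister_pair_snps(cfg)$geno,
                   make_sister_pair_snps(cfg)$geno)
  expect_identical(make_variant_tables(cfg), make_variant_tables(cfg))
  p1 <- make_pgls_dataset(cfg); p2 <- make_pgls_dataset(cfg)
  expect_identical(p1$traits, p2$traits)
  cfg2 <- scenario_config(seed = 18)
  expect_false(identical(make_sister_pair_ssr(cfg),
                         make_sister_pair_ssr(cfg2)))
})

test_that("the recently founded selfer is genotype-uniform", {
  # the line-based clock bounds how often uniformity should be seen:
  # P_i(founding time) with the panel's aggregate mutation rate; the
  # Wright-Fisher lineage, whose lines coalesce, should do no worse
  n_seed <- 8
  uniform <- vapply(seq_len(n_seed), function(s) {
    tab <- make_sister_pair_ssr(scenario_config(seed = s))
    cl <- as.data.frame(tab)[tab$species == "cleist", -(1:3)]
    nrow(unique(cl)) == 1
  }, logical(1))
  cfg <- scenario_config()
  log_pt <- cfg$ssr$founder_gens *
    (cfg$ssr$n_dinuc * log1p(-cfg$ssr$mu) +
     (cfg$ssr$n_loci - cfg$ssr$n_dinuc) * log1p(-cfg$ssr$mu_other))
  p_bound <- exp(cfg$ssr$cleist_ne * log_pt)
  expect_gte(mean(uniform), p_bound - 3 * sqrt(p_bound * (1 - p_bound) / n_seed))
})

test_that("an outcrossing control is heterozygous at polymorphic loci", {
  pop <- simulate_ssr_population(200, n_loci = 6, mu = 0, s = 0, t = 5,
                                 init = 3, seed = 2)
  het <- mean(pop[, seq(1, 12, 2)] != pop[, seq(2, 12, 2)])
  expect_gt(het, 0.2)
})

test_that("fixed differences grow with divergence time", {
  none <- make_sister_pair_snps(scenario_config(seed = 21,
            snps = list(divergence_gens = 0L, missing_rate = 0)))
  expect_equal(count_fixed_differences(none, "chasm", "cleist"), 0)
  short <- make_sister_pair_snps(scenario_config(seed = 21,
            snps = list(divergence_gens = 10L, missing_rate = 0)))
  long <- make_sister_pair_snps(scenario_config(seed = 21,
            snps = list(divergence_gens = 400L, missing_rate = 0)))
  expect_gte(count_fixed_differences(long, "chasm", "cleist"),
             count_fixed_differences(short, "chasm", "cleist"))
  expect_gt(count_fixed_differences(long, "chasm", "cleist"), 50)
})

test_that("variant tables respect configured densities and fractions", {
  empty <- make_variant_tables(scenario_config(seed = 1,
    variants = list(selfing = list(density_per_kb = 0),
                    outcrossing = list(density_per_kb = 0))))
  expect_true(all(is.na(empty$snv_id)))
  big <- make_variant_tables(scenario_config(seed = 2,
    variants = list(n_transcripts = 700L, samples_per_species = 1L,
                    outcrossing = list(density_per_kb = 1.0,
                                       nonsyn_fraction = 0.6,
                                       deleterious_fraction = 0.3))))
  out <- big[!is.na(big$snv_id) & big$species == "outcrossing", ]
  total_kb <- sum(unique(big[big$species == "outcrossing",
                             c("transcript_id", "transcript_len_bp")])$transcript_len_bp) / 1000
  expect_lt(abs(nrow(out) - total_kb), 3 * sqrt(total_kb))  # Poisson count
  del <- classify_deleterious(out$score)
  del[is.na(del)] <- FALSE
  p_hat <- mean(del)
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(out)))
  p_ns <- mean(out$effect == "nonsynonymous")
  expect_lt(abs(p_ns - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(out)))
})

test_that("the trait generator centres on zero without a selfing effect", {
  ests <- vapply(1:30, function(s) {
    pd <- make_pgls_dataset(scenario_config(seed = 100 + s,
                                            pgls = list(effect = 0)))
    fit_all_metrics(pd$traits, pd$tree)$selfing_estimate
  }, numeric(1))
  expect_lt(abs(mean(ests)), 3 * sd(ests) / sqrt(30))
})

test_that("generated tables round-trip through the readers", {
  cfg <- scenario_config(seed = 77,
                         variants = list(n_transcripts = 40L,
                                         samples_per_species = 2L))
  tab <- make_sister_pair_ssr(cfg)
  f <- tempfile(fileext = ".csv")
  write_ssr_csv(tab, f)
  back <- read_ssr_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
  m <- make_sister_pair_snps(cfg)
  f2 <- tempfile(fileext = ".tsv")
  write_snp_tsv(m, f2)
  back2 <- read_snp_tsv(f2)
  expect_equal(back2$geno, m$geno)
  v <- make_variant_tables(cfg)
  f3 <- tempfile(fileext = ".tsv")
  write_variant_tsv(v, f3)
  back3 <- read_variant_tsv(f3)
  expect_equal(syndrome_metrics_by_sample(back3),
               syndrome_metrics_by_sample(v))
})
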