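test_that("heterozygosity rule removes at the 0.6 boundary", {
  m <- toy_snps(list(hi = c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0),   # Ho = 0.7
                     at = c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0),   # Ho = 0.6
                     lo = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)))  # Ho = 0.5
  out <- filter_snps(m, min_minor_samples = 0)
  expect_equal(out$matrix$snps$snp_id, "lo")
  expect_equal(out$report$removed[out$report$rule == "high_heterozygosity"], 2)
})

test_that("minor-allele rule keeps exactly-three carriers", {
  m <- toy_snps(list(three = c(1, 1, 2, 0, 0, 0, 0, 0, 0, 0),  # 3 carriers
                     two = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0),    # 2 carriers
                     mono = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0)))  # invariant
  out <- filter_snps(m)
  expect_equal(out$matrix$snps$snp_id, "three")
  expect_equal(out$report$removed[out$report$rule == "minor_allele_samples"], 2)
})

test_that("missingness and one-per-locus rules report exact counts", {
  m <- read_snp_tsv(system.file("extdata", "toy_snps.tsv",
                                package = "selfingclock"))
  out <- filter_snps(m, min_prop_r = 0.7, one_per_locus = TRUE)
  rep <- out$report
  get <- function(rule) rep$removed[rep$rule == rule]
  expect_equal(get("high_heterozygosity"), 1)   # Ho = 0.6 exactly
  expect_equal(get("minor_allele_samples"), 1)
  expect_equal(get("missingness"), 1)
  expect_equal(get("one_per_locus"), 2)
  expect_equal(get("surviving"), 2)
  expect_setequal(out$matrix$snps$snp_id, c("snp_maf3", "snp_le1"))
  expect_equal(sum(rep$removed), attr(rep, "input"))
})

test_that("filtering is idempotent", {
  cfg <- scenario_config(seed = 5)
  m <- make_sister_pair_snps(cfg)
  once <- filter_snps(m, min_prop_r = 0.7, one_per_locus = TRUE)
  twice <- filter_snps(once$matrix, min_prop_r = 0.7, one_per_locus = TRUE)
  expect_identical(once$matrix$geno, twice$matrix$geno)
  expect_true(all(twice$report$removed[twice$report$rule != "surviving"] == 0))
})

test_that("polarisation uses the chasmogamous majority allele", {
  m <- toy_snps(list(both0 = c(0, 0, 0, 0, 0, 0),
                     fixed = c(0, 0, 0, 2, 2, 2),
                     tied = c(1, 0, 2, 1, 1, 1)),
                species = rep(c("X", "Y"), each = 3))
  ph <- polarize_and_histogram(m, "X", "Y")
  per <- ph$per_snp
  expect_equal(per$derived_derived_group[per$snp_id == "both0"], 0)
  expect_equal(per$derived_ancestral_group[per$snp_id == "both0"], 0)
  expect_equal(per$derived_derived_group[per$snp_id == "fixed"], 1)
  expect_equal(ph$n_ties, 1)   # 50/50 in X resolves to reference
  expect_true(per$tie[per$snp_id == "tied"])
})

test_that("derived-allele spectra match a hand-counted fixture", {
  # X (ancestral group): 4 samples, Y: 2 samples; alt copies in X decide
  gt <- list(s1 = c(0, 0, 0, 0, 0, 0),   # anc = ref; derived 0 / 0
             s2 = c(2, 2, 2, 0, 2, 2),   # anc = alt; derived X=1/4, Y=0
             s3 = c(1, 1, 0, 0, 2, 0),   # fa = 0.25 -> anc = ref; X .25, Y .5
             s4 = c(NA, NA, NA, NA, 1, 1))  # fa in X uses s1-s4 rows
  m <- toy_snps(gt, species = c("X", "X", "X", "X", "Y", "Y"))
  ph <- polarize_and_histogram(m, "X", "Y")
  per <- ph$per_snp
  expect_equal(per$derived_ancestral_group[per$snp_id == "s2"], 1 / 4)
  expect_equal(per$derived_derived_group[per$snp_id == "s2"], 0)
  expect_equal(per$derived_ancestral_group[per$snp_id == "s3"], 0.25)
  expect_equal(per$derived_derived_group[per$snp_id == "s3"], 0.5)
  expect_equal(sum(ph$histogram$ancestral_group), nrow(per))
})

test_that("SNPs missing from the whole ancestral group are excluded", {
  m <- toy_snps(list(a = c(NA, NA, NA, 0, 0, 0),
                     b = c(0, 0, 0, 2, 2, 2)),
                species = rep(c("X", "Y"), each = 3))
  ph <- polarize_and_histogram(m, "X", "Y")
  expect_equal(ph$n_excluded, 1)
  expect_equal(nrow(ph$per_snp), 1)
})

test_that("fixed differences count opposite monomorphism, symmetrically", {
  same <- toy_snps(list(a = c(0, 0, 0, 0), b = c(2, 2, 2, 2)))
  expect_equal(count_fixed_differences(same, "X", "Y"), 0)
  all_opp <- toy_snps(list(a = c(0, 0, 2, 2), b = c(2, 2, 0, 0)))
  expect_equal(count_fixed_differences(all_opp, "X", "Y"), 2)
  mixed <- toy_snps(list(f1 = c(0, 0, 2, 2), f2 = c(2, 2, 0, 0),
                         f3 = c(0, 0, 2, 2),
                         shared1 = c(1, 0, 1, 0), shared2 = c(0, 1, 2, 1)))
  expect_equal(count_fixed_differences(mixed, "X", "Y"), 3)
  expect_equal(count_fixed_differences(mixed, "Y", "X"), 3)
  # heterozygotes break monomorphism; missing genotypes do not
  het <- toy_snps(list(a = c(0, 1, 2, 2), b = c(0, NA, 2, 2)))
  expect_equal(count_fixed_differences(het, "X", "Y"), 1)
})

test_that("per-site pi equals average pairwise differences", {
  mono <- toy_snps(list(a = c(0, 0, 0, 0)))
  expect_equal(nucleotide_diversity(mono)$mean, 0)
  # p = 0.5 over n = 4 copies -> (4/3) * 0.5
  m <- toy_snps(list(a = c(1, 1)))
  expect_equal(unname(nucleotide_diversity(m)$per_snp), 4 / 3 * 0.5)
  # brute-force oracle over enumerated copy pairs
  set.seed(23)
  for (i in 1:20) {
    g <- sample(0:2, 5, replace = TRUE)
    m <- toy_snps(list(a = g))
    copies <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    expect_equal(unname(nucleotide_diversity(m)$per_snp), brute_pi(copies),
                 tolerance = 1e-12)
  }
  # a fixed difference carries no within-group diversity
  fx <- toy_snps(list(a = c(0, 0, 2, 2)))
  expect_equal(nucleotide_diversity(fx, "X")$mean, 0)
  expect_equal(nucleotide_diversity(fx, "Y")$mean, 0)
})

test_that("Evanno Delta-K matches hand calculations and invariances", {
  runs <- function(means, sds) do.call(rbind, lapply(seq_along(means),
    function(k) data.frame(K = k, loglik = means[k] + c(-1, 1) * sds[k] / sqrt(2))))
  lin <- evanno_delta_k(runs(c(-30, -20, -10, 0), rep(1, 4)))
  expect_equal(lin$delta_k[2:3], c(0, 0))
  hand <- evanno_delta_k(runs(c(-100, -50, -40, -38), rep(1, 4)))
  expect_equal(hand$delta_k[2:3], c(40, 8))
  shifted <- evanno_delta_k(runs(c(-100, -50, -40, -38) + 1000, rep(1, 4)))
  expect_equal(shifted$delta_k, hand$delta_k)
  zero_sd <- rbind(data.frame(K = 1, loglik = c(-5, -4)),
                   data.frame(K = 2, loglik = c(-3, -3)),
                   data.frame(K = 3, loglik = c(-2, -1)))
  expect_true(is.na(evanno_delta_k(zero_sd)$delta_k[2]))
  expect_error(evanno_delta_k(data.frame(K = c(1, 2), loglik = c(1, 2))),
               "consecutive")
})
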