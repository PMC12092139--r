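test_that("allele frequencies count copies and respect missing data", {
  tab <- toy_ssr(list(L1 = list(c(1, 1), c(1, 1))))
  expect_equal(allele_frequencies(tab)$p1$L1, c("1" = 1))
  tab <- toy_ssr(list(L1 = list(c(1, 1), c(1, 2))))
  expect_equal(allele_frequencies(tab)$p1$L1, c("1" = 0.75, "2" = 0.25))
  # a missing genotype leaves the denominator
  tab <- toy_ssr(list(L1 = list(c(1, 1), c(1, 2), c(NA, NA))))
  expect_equal(allele_frequencies(tab)$p1$L1, c("1" = 0.75, "2" = 0.25))
  expect_true(all(vapply(allele_frequencies(tab)$p1, sum, numeric(1)) == 1))
})

test_that("locus diversity gives textbook A, Ho, He", {
  mono <- toy_ssr(list(L1 = list(c(1, 1), c(1, 1))))
  d <- locus_diversity(mono)
  expect_equal(d[, c("A", "Ho", "He")], data.frame(A = 1L, Ho = 0, He = 0),
               ignore_attr = TRUE)
  hets <- toy_ssr(list(L1 = list(c(1, 2), c(1, 2))))
  d <- locus_diversity(hets)
  expect_equal(c(d$Ho, d$He), c(1, 0.5))
  mix <- toy_ssr(list(L1 = list(c(1, 1), c(1, 2), c(2, 2), c(1, 2))))
  d <- locus_diversity(mix)
  expect_equal(c(d$Ho, d$He), c(0.5, 0.5))
  # unbiased correction: 2N/(2N-1) with 2N = 8
  expect_equal(locus_diversity(mix, unbiased = TRUE)$He, 0.5 * 8 / 7)
})

test_that("rarefaction allelic richness matches brute-force enumeration", {
  mono <- toy_ssr(list(L1 = list(c(5, 5), c(5, 5))))
  expect_equal(allelic_richness(mono, g = 1)$Rs, 1)
  # copies {A, A, B, C}, g = 2 -> 11/6
  tab <- toy_ssr(list(L1 = list(c(1, 1), c(2, 3))))
  expect_equal(allelic_richness(tab, g = 2)$Rs, 11 / 6)
  # g = N returns the observed allele count
  expect_equal(allelic_richness(tab, g = 4)$Rs, 3)
  # randomized brute-force oracle, N <= 8 copies
  set.seed(13)
  for (i in 1:20) {
    n_ind <- sample(2:4, 1)
    geno <- lapply(seq_len(n_ind), function(j) sample(1:4, 2, replace = TRUE))
    tab <- toy_ssr(list(L1 = geno))
    copies <- unlist(geno)
    for (g in 1:(2 * n_ind)) {
      expect_equal(allelic_richness(tab, g = g)$Rs,
                   brute_rarefaction(copies, g), tolerance = 1e-12)
    }
  }
  expect_error(allelic_richness(tab, g = 2 * n_ind + 1), "exceeds")
})

test_that("F_IS spans homozygous excess to Hardy-Weinberg", {
  all_hom <- toy_ssr(list(L1 = list(c(1, 1), c(2, 2))))
  expect_equal(inbreeding_coefficient(all_hom)$Fis, 1)
  # Ho = He = 0.5 -> F_IS = 0
  mix <- toy_ssr(list(L1 = list(c(1, 1), c(1, 2), c(2, 2), c(1, 2))))
  expect_equal(inbreeding_coefficient(mix)$Fis, 0)
  # monomorphic loci drop out of the mean
  two <- toy_ssr(list(L1 = list(c(1, 1), c(2, 2)), L2 = list(c(3, 3), c(3, 3))))
  expect_equal(attr(inbreeding_coefficient(two), "means")$Fis, 1)
  expect_true(is.na(inbreeding_coefficient(two)$Fis[2]))
})

test_that("private alleles are those seen in exactly one population", {
  tab <- toy_ssr(list(L1 = list(c(1, 2), c(1, 2))), population = c("a", "b"))
  expect_equal(unname(private_alleles(tab)), c(0L, 0L))
  tab <- toy_ssr(list(L1 = list(c(1, 2), c(2, 3))), population = c("a", "b"))
  expect_equal(private_alleles(tab), c(a = 1L, b = 1L))
  # allele shared by two of three pops is private nowhere
  tab <- toy_ssr(list(L1 = list(c(1, 1), c(1, 2), c(3, 3))),
                 population = c("a", "b", "c"))
  expect_equal(private_alleles(tab), c(a = 0L, b = 1L, c = 1L))
})

test_that("Nei's D_A hits its hand-computed landmarks", {
  fx <- list(L1 = c("1" = 1))
  expect_equal(nei_da(fx, fx), 0)
  expect_equal(nei_da(list(L1 = c("1" = 1)), list(L1 = c("2" = 1))), 1)
  expect_equal(nei_da(list(L1 = c("1" = 1, "2" = 0)),
                      list(L1 = c("1" = 0.25, "2" = 0.75))), 0.5)
  # all-missing locus in one group is excluded with a warning
  expect_warning(
    d <- nei_da(list(L1 = c("1" = 1), L2 = c("9" = 1)),
                list(L1 = c("2" = 1), L2 = NULL)), "excluded")
  expect_equal(d, 1)
})

test_that("D_A matrices are symmetric, zero-diagonal and bounded", {
  cfg <- scenario_config(seed = 3)
  tab <- make_sister_pair_ssr(cfg)
  d <- da_matrix(tab, by = "population")
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("3-taxon NJ solves the three-point equations exactly", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  pl <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pl, d, tolerance = 1e-12)
})

test_that("NJ recovers the 4-taxon additive tree AB|CD", {
  lbl <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(lbl, lbl))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[lbl, lbl], d, tolerance = 1e-12)
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_equal(internal, 1, tolerance = 1e-12)
})

test_that("NJ reconstructs random additive trees exactly", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(true)
    est <- nj_tree(d)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("locus bootstrap is deterministic and finds full support", {
  # two loci that both separate species -> the split has 100% support
  tab <- toy_ssr(list(L1 = list(c(1, 1), c(1, 1), c(5, 5), c(5, 5)),
                      L2 = list(c(2, 2), c(2, 2), c(8, 8), c(8, 8))),
                 population = c("a1", "a2", "b1", "b2"))
  bs1 <- bootstrap_support(tab, n_reps = 30, seed = 7)
  bs2 <- bootstrap_support(tab, n_reps = 30, seed = 7)
  expect_identical(bs1$support, bs2$support)
  expect_true(any(bs1$support == 100))
  # identical multilocus genotypes sit at zero distance in every replicate
  d <- da_matrix(tab, by = "population")
  expect_equal(d["a1", "a2"], 0)
  expect_error(bootstrap_support(toy_ssr(list(L1 = list(c(1, 1), c(2, 2)))),
                                 n_reps = 5), "at least 2 loci")
})

test_that("He respects its allele-count bound and Rs grows with g", {
  set.seed(55)
  for (i in 1:10) {
    geno <- lapply(1:5, function(j) sample(1:3, 2, replace = TRUE))
    tab <- toy_ssr(list(L1 = geno))
    d <- locus_diversity(tab)
    expect_lte(d$He, 1 - 1 / d$A + 1e-12)
    rs <- vapply(1:10, function(g) allelic_richness(tab, g = g)$Rs, numeric(1))
    expect_true(all(diff(rs) >= -1e-12))
    expect_equal(rs[10], d$A)
  }
})
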