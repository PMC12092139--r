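#' Biallelic SNP genotype matrix
#'
#' Genotypes are coded 0 (homozygous reference), 1 (heterozygous),
#' 2 (homozygous alternate) or `NA` (missing). Every SNP carries a locus
#' group (the physical locus it was called from) and its order within
#' that locus, which drives one-SNP-per-locus thinning.
#'
#' @param geno Integer matrix, samples x SNPs, values in `{0, 1, 2, NA}`.
#' @param samples Data frame with columns `sample`, `species`,
#'   `population` (one row per matrix row).
#' @param snps Data frame with columns `snp_id`, `locus_id`,
#'   `pos_in_locus` (one row per matrix column).
#' @return An object of class `"snp_matrix"`.
#' @export
snp_matrix <- function(geno, samples, snps) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA")
  stopifnot(all(c("sample", "species", "population") %in% names(samples)),
            all(c("snp_id", "locus_id", "pos_in_locus") %in% names(snps)),
            nrow(samples) == nrow(geno), nrow(snps) == ncol(geno))
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  if (anyDuplicated(snps$snp_id)) stop("duplicate snp ids")
  dimnames(geno) <- list(samples$sample, snps$snp_id)
  structure(list(geno = geno, samples = samples, snps = snps),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("snp_matrix: ", nrow(x$geno), " samples x ", ncol(x$geno), " SNPs (",
      length(unique(x$snps$locus_id)), " locus groups)\n", sep = "")
  invisible(x)
}

#' @rdname snp_matrix
#' @param x Object to test.
#' @export
is_snp_matrix <- function(x) inherits(x, "snp_matrix")

n_snps <- function(m) ncol(m$geno)

sample_rows <- function(m, group) {
  rows <- which(m$samples$species == group | m$samples$population == group)
  if (length(rows) == 0) stop("no samples in group '", group, "'")
  rows
}

keep_snps <- function(m, keep) {
  snp_matrix(m$geno[, keep, drop = FALSE], m$samples,
             m$snps[keep, , drop = FALSE])
}

# per-SNP observed heterozygosity over genotyped samples; all-missing
# SNPs are unusable and treated as maximally heterozygous so the first
# rule removes them
snp_ho <- function(geno) {
  ho <- colMeans(geno == 1L, na.rm = TRUE)
  ho[is.nan(ho)] <- 1
  ho
}

# number of samples carrying the minor allele (a sample counts once
# whether heterozygous or homozygous for it)
minor_allele_samples <- function(geno) {
  vapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    g <- g[!is.na(g)]
    alt_copies <- sum(g)
    ref_copies <- 2 * length(g) - alt_copies
    if (alt_copies == ref_copies) return(min(sum(g >= 1), sum(g <= 1)))
    if (alt_copies < ref_copies) sum(g >= 1) else sum(g <= 1)
  }, numeric(1))
}

#' Filter a SNP matrix by the study's marker-quality rules
#'
#' Applies, in this order: (1) remove SNPs with observed heterozygosity
#' `>= max_ho` (excess heterozygosity flags collapsed paralogues);
#' (2) remove SNPs whose minor allele is carried by fewer than
#' `min_minor_samples` samples in the whole dataset (invariant SNPs have a
#' minor-allele count of 0 and are removed here too); (3) remove SNPs
#' genotyped in less than a proportion `min_prop_r` of samples; (4) with
#' `one_per_locus`, keep only the first SNP (smallest `pos_in_locus`) per
#' locus group, avoiding linked SNPs. The boundary conventions are
#' removal at `H_O >= max_ho` and retention at exactly
#' `min_minor_samples` carriers.
#'
#' @param m A [snp_matrix()].
#' @param max_ho Heterozygosity removal threshold (default 0.6).
#' @param min_minor_samples Minimum samples carrying the minor allele
#'   (default 3).
#' @param min_prop_r Minimum proportion of samples genotyped (the `R`
#'   threshold, e.g. 0.1 or 0.7); `NULL` skips the rule.
#' @param one_per_locus Thin to one SNP per locus group.
#' @return List with `matrix` (filtered [snp_matrix()]) and `report`, a
#'   data frame of per-rule removal counts whose removals plus survivors
#'   reconcile exactly with the input SNP count.
#' @export
filter_snps <- function(m, max_ho = 0.6, min_minor_samples = 3,
                        min_prop_r = NULL, one_per_locus = FALSE) {
  stopifnot(is_snp_matrix(m))
  if (n_snps(m) == 0) stop("empty SNP matrix")
  if (max_ho < 0 || max_ho > 1) stop("'max_ho' must lie in [0, 1]")
  n_in <- n_snps(m)
  report <- data.frame(rule = character(0), removed = integer(0))
  note <- function(rule, removed)
    rbind(report, data.frame(rule = rule, removed = removed))

  keep <- snp_ho(m$geno) < max_ho
  report <- note("high_heterozygosity", sum(!keep))
  m <- keep_snps(m, keep)

  keep <- minor_allele_samples(m$geno) >= min_minor_samples
  report <- note("minor_allele_samples", sum(!keep))
  m <- keep_snps(m, keep)

  if (!is.null(min_prop_r)) {
    if (min_prop_r < 0 || min_prop_r > 1) stop("'min_prop_r' must lie in [0, 1]")
    keep <- colMeans(!is.na(m$geno)) >= min_prop_r
    report <- note("missingness", sum(!keep))
    m <- keep_snps(m, keep)
  }
  if (isTRUE(one_per_locus)) {
    ord <- order(m$snps$locus_id, m$snps$pos_in_locus)
    first_idx <- ord[!duplicated(m$snps$locus_id[ord])]
    keep <- seq_len(n_snps(m)) %in% first_idx
    report <- note("one_per_locus", sum(!keep))
    m <- keep_snps(m, keep)
  }
  report <- rbind(report,
                  data.frame(rule = "surviving", removed = n_snps(m)))
  stopifnot(sum(report$removed) == n_in)
  attr(report, "input") <- n_in
  list(matrix = m, report = report)
}

#' Polarise SNPs on the chasmogamous majority allele and build spectra
#'
#' For each SNP the ancestral allele is the allele predominant (majority
#' of copies) in `ancestral_group`; 50/50 ties resolve to the reference
#' allele and are counted. The derived-allele frequency is then tabulated
#' for both groups. SNPs with no genotyped sample in the ancestral group
#' are excluded and counted.
#'
#' @param m A [snp_matrix()].
#' @param ancestral_group Species/population label of the chasmogamous
#'   (outcrossing-capable) group defining the ancestral state.
#' @param derived_group Label of the (e.g. cleistogamous) sister group.
#' @param breaks Histogram bin boundaries on `[0, 1]`.
#' @return List with `per_snp` (data frame of derived-allele frequencies
#'   per group), `histogram` (bin counts per group), `n_excluded`,
#'   `n_ties`.
#' @export
polarize_and_histogram <- function(m, ancestral_group, derived_group,
                                   breaks = seq(0, 1, by = 0.1)) {
  stopifnot(is_snp_matrix(m))
  ra <- sample_rows(m, ancestral_group)
  rd <- sample_rows(m, derived_group)
  alt_freq <- function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    sum(g) / (2 * length(g))
  }
  fa <- apply(m$geno[ra, , drop = FALSE], 2, alt_freq)
  fd <- apply(m$geno[rd, , drop = FALSE], 2, alt_freq)
  excluded <- is.na(fa)
  tie <- !excluded & fa == 0.5
  # ancestral = majority allele in the ancestral group; tie -> reference
  anc_is_alt <- !excluded & fa > 0.5
  derived_a <- ifelse(anc_is_alt, 1 - fa, fa)
  derived_d <- ifelse(anc_is_alt, 1 - fd, fd)
  per_snp <- data.frame(snp_id = m$snps$snp_id,
                        derived_ancestral_group = derived_a,
                        derived_derived_group = derived_d,
                        tie = tie)[!excluded, ]
  histo <- function(x) {
    x <- x[!is.na(x)]
    graphics::hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE,
                   right = TRUE)$counts
  }
  list(per_snp = per_snp,
       histogram = data.frame(
         bin_lo = utils::head(breaks, -1), bin_hi = breaks[-1],
         ancestral_group = histo(per_snp$derived_ancestral_group),
         derived_group = histo(per_snp$derived_derived_group)),
       n_excluded = sum(excluded), n_ties = sum(tie))
}

#' Count SNPs fixed for opposite alleles between two groups
#'
#' A SNP counts when one group is monomorphic for one allele and the
#' other group monomorphic for the other (missing genotypes excluded;
#' both groups must have at least one genotyped sample). Symmetric in its
#' group arguments.
#'
#' @param m A [snp_matrix()].
#' @param group_a,group_b Species/population labels (disjoint samples).
#' @return Integer count.
#' @export
count_fixed_differences <- function(m, group_a, group_b) {
  stopifnot(is_snp_matrix(m))
  ra <- sample_rows(m, group_a)
  rb <- sample_rows(m, group_b)
  if (length(intersect(ra, rb)) > 0) stop("groups must be disjoint")
  fixed_state <- function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_integer_)
    if (all(g == 0L)) return(0L)
    if (all(g == 2L)) return(2L)
    NA_integer_
  }
  sa <- apply(m$geno[ra, , drop = FALSE], 2, fixed_state)
  sb <- apply(m$geno[rb, , drop = FALSE], 2, fixed_state)
  sum(!is.na(sa) & !is.na(sb) & sa != sb)
}

#' Per-SNP nucleotide diversity
#'
#' Unbiased per-site `pi = n/(n-1) * 2 p (1-p)` with `n` the number of
#' non-missing allele copies -- the average number of pairwise differences
#' among the sampled copies. SNPs with fewer than 2 genotyped copies are
#' `NA` and excluded from the mean.
#'
#' @param m A [snp_matrix()].
#' @param group Optional species/population label (default: all samples).
#' @return List with `per_snp` (named vector) and `mean`.
#' @export
nucleotide_diversity <- function(m, group = NULL) {
  stopifnot(is_snp_matrix(m))
  rows <- if (is.null(group)) seq_len(nrow(m$geno)) else sample_rows(m, group)
  pi_site <- apply(m$geno[rows, , drop = FALSE], 2, function(g) {
    g <- g[!is.na(g)]
    n <- 2 * length(g)
    if (n < 2) return(NA_real_)
    p <- sum(g) / n
    n / (n - 1) * 2 * p * (1 - p)
  })
  list(per_snp = pi_site, mean = mean(pi_site, na.rm = TRUE))
}

#' Evanno Delta-K statistic from clustering run log-likelihoods
#'
#' `DeltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' the absolute second difference of the mean log-likelihood across K,
#' scaled by the between-run standard deviation at K. Requires at least
#' three consecutive K values with at least two runs each; a zero
#' standard deviation makes DeltaK undefined (`NA`) at that K.
#'
#' @param runs Data frame with columns `K` (integer) and `loglik`
#'   (one row per independent run).
#' @return Data frame `K`, `mean_loglik`, `sd_loglik`, `delta_k`
#'   (`NA` at the end points).
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "loglik") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) < 3 || !all(diff(ks) == 1))
    stop("need at least 3 consecutive K values")
  by_k <- split(runs$loglik, runs$K)
  if (any(lengths(by_k) < 2)) stop("need at least 2 runs per K")
  mu <- vapply(by_k, mean, numeric(1))
  sdv <- vapply(by_k, stats::sd, numeric(1))
  dk <- rep(NA_real_, length(ks))
  for (i in seq(2, length(ks) - 1)) {
    second <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1])
    dk[i] <- if (sdv[i] == 0) NA_real_ else second / sdv[i]
  }
  data.frame(K = ks, mean_loglik = unname(mu), sd_loglik = unname(sdv),
             delta_k = dk)
}
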