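# shared fixture builders (all fixtures are built in code)

# tiny SSR table: genotypes given as a list of locus -> list of c(a, b)
# per sample; NA pair = missing
toy_ssr <- function(genotypes, population = NULL, species = NULL) {
  n <- length(genotypes[[1]])
  df <- data.frame(sample = paste0("i", seq_len(n)),
                   population = population %||% rep("p1", n),
                   species = species %||% rep("sp1", n))
  for (lc in names(genotypes)) {
    ab <- do.call(rbind, genotypes[[lc]])
    df[[paste0(lc, "_a")]] <- ab[, 1]
    df[[paste0(lc, "_b")]] <- ab[, 2]
  }
  ssr_table(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# SNP matrix from a named list of genotype vectors (one per SNP)
toy_snps <- function(gt, locus_id = NULL, pos = NULL, species = NULL) {
  n <- length(gt[[1]])
  geno <- do.call(cbind, gt)
  species <- species %||% rep(c("X", "Y"), c(ceiling(n / 2), floor(n / 2)))
  samples <- data.frame(sample = paste0("s", seq_len(n)),
                        species = species, population = species)
  snps <- data.frame(snp_id = names(gt),
                     locus_id = locus_id %||% paste0("L", seq_along(gt)),
                     pos_in_locus = pos %||% rep(1L, length(gt)))
  snp_matrix(geno, samples, snps)
}

# brute-force rarefaction: mean distinct alleles over all size-g subsets
brute_rarefaction <- function(copies, g) {
  sets <- utils::combn(seq_along(copies), g)
  mean(apply(sets, 2, function(ix) length(unique(copies[ix]))))
}

# brute-force per-site pi: average pairwise differences among copies
brute_pi <- function(copies) {
  pairs <- utils::combn(length(copies), 2)
  mean(copies[pairs[1, ]] != copies[pairs[2, ]])
}

# minimal variant table row builder
vt_row <- function(sample, transcript, len, snv = NA, effect = NA,
                   score = NA, species = "sp") {
  data.frame(sample = sample, species = species, transcript_id = transcript,
             transcript_len_bp = len, snv_id = snv, effect = effect,
             score = score)
}
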