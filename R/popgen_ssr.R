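#' Diploid SSR genotype table
#'
#' Container for multilocus microsatellite genotypes: a data frame with
#' identifier columns `sample`, `population`, `species` followed by two
#' integer allele-size columns per locus, named `<locus>_a`, `<locus>_b`.
#' Missing alleles are `NA` internally (written as 0 in the CSV dialect,
#' see [read_ssr_csv()]). Allele pairs are unordered.
#'
#' @param df Data frame in the layout above.
#' @param motif_len Optional named integer vector of repeat-motif lengths
#'   per locus (e.g. 2 for dinucleotide repeats), used to pick the
#'   dinucleotide subset feeding the uniformity clock.
#' @return An `"ssr_table"` data frame with attributes `loci` and
#'   `motif_len`.
#' @export
ssr_table <- function(df, motif_len = NULL) {
  need <- c("sample", "population", "species")
  if (!all(need %in% names(df)))
    stop("missing identifier column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  geno_cols <- setdiff(names(df), need)
  if (length(geno_cols) == 0 || length(geno_cols) %% 2 != 0)
    stop("genotype columns must come in <locus>_a/<locus>_b pairs")
  loci <- unique(sub("_[ab]$", "", geno_cols))
  exp_cols <- as.vector(rbind(paste0(loci, "_a"), paste0(loci, "_b")))
  if (!identical(sort(geno_cols), sort(exp_cols)))
    stop("genotype columns must be named <locus>_a and <locus>_b")
  if (anyDuplicated(df$sample)) stop("duplicate sample ids")
  df <- df[, c(need, exp_cols)]
  for (cl in exp_cols) {
    v <- df[[cl]]
    v[!is.na(v) & v == 0] <- NA   # 0 is the missing code
    df[[cl]] <- as.integer(v)
  }
  # a genotype is missing as a pair: one NA allele implies both unknown
  for (lc in loci) {
    a <- df[[paste0(lc, "_a")]]; b <- df[[paste0(lc, "_b")]]
    miss <- is.na(a) | is.na(b)
    df[[paste0(lc, "_a")]][miss] <- NA
    df[[paste0(lc, "_b")]][miss] <- NA
  }
  if (!is.null(motif_len)) {
    if (is.null(names(motif_len)) || !all(loci %in% names(motif_len)))
      stop("'motif_len' must be named by locus")
    motif_len <- motif_len[loci]
  }
  structure(df, loci = loci, motif_len = motif_len,
            class = c("ssr_table", "data.frame"))
}

#' @rdname ssr_table
#' @param x Object to test.
#' @export
is_ssr_table <- function(x) inherits(x, "ssr_table")

ssr_loci <- function(tab) attr(tab, "loci")

# two-column allele matrix for one locus
locus_alleles <- function(tab, locus) {
  cbind(tab[[paste0(locus, "_a")]], tab[[paste0(locus, "_b")]])
}

#' Keep only samples genotyped at every locus
#'
#' Complete-case filter mirroring marker studies that retain only samples
#' amplifying the full panel.
#'
#' @param tab An [ssr_table()].
#' @return The filtered `ssr_table`.
#' @export
complete_cases_ssr <- function(tab) {
  stopifnot(is_ssr_table(tab))
  keep <- !Reduce(`|`, lapply(ssr_loci(tab),
                              function(lc) is.na(locus_alleles(tab, lc)[, 1])))
  ssr_table(as.data.frame(tab)[keep, , drop = FALSE],
            motif_len = attr(tab, "motif_len"))
}

#' Per-locus allele frequencies within groups
#'
#' Frequencies are computed over non-missing allele copies; an all-missing
#' locus within a group yields `NULL` for that locus (excluded downstream
#' with a warning where relevant).
#'
#' @param tab An [ssr_table()].
#' @param by Grouping column: `"population"`, `"species"`, or `"sample"`
#'   (one group per individual, for genotype-level distances).
#' @return Named list (group) of named lists (locus) of frequency vectors
#'   summing to 1.
#' @export
allele_frequencies <- function(tab, by = "population") {
  stopifnot(is_ssr_table(tab), by %in% c("population", "species", "sample"))
  groups <- split(seq_len(nrow(tab)), tab[[by]])
  lapply(groups, function(rows) {
    out <- lapply(ssr_loci(tab), function(lc) {
      al <- as.vector(locus_alleles(tab, lc)[rows, , drop = FALSE])
      al <- al[!is.na(al)]
      if (length(al) == 0) return(NULL)
      tb <- table(al)
      stats::setNames(as.numeric(tb) / sum(tb), names(tb))
    })
    stats::setNames(out, ssr_loci(tab))
  })
}

#' Per-locus diversity summaries (A, H_O, H_E)
#'
#' `A` is the observed allele count, `H_O` the fraction of heterozygous
#' individuals, and `H_E = 1 - sum(p^2)` the expected heterozygosity
#' (gene diversity). The small-sample correction `2N/(2N-1)` is available
#' via `unbiased = TRUE`.
#'
#' @param tab An [ssr_table()].
#' @param by Grouping column (`"population"` or `"species"`).
#' @param unbiased Apply Nei's unbiased correction to `H_E`.
#' @return Data frame with one row per group x locus (`group`, `locus`,
#'   `n`, `A`, `Ho`, `He`) plus attribute `"means"`, the per-group means.
#' @export
locus_diversity <- function(tab, by = "population", unbiased = FALSE) {
  stopifnot(is_ssr_table(tab))
  groups <- split(seq_len(nrow(tab)), tab[[by]])
  if (any(lengths(groups) == 0)) stop("empty group")
  rows <- list()
  for (g in names(groups)) {
    for (lc in ssr_loci(tab)) {
      al <- locus_alleles(tab, lc)[groups[[g]], , drop = FALSE]
      al <- al[!is.na(al[, 1]), , drop = FALSE]
      if (nrow(al) == 0) next
      p <- table(as.vector(al)) / (2 * nrow(al))
      he <- 1 - sum(p^2)
      if (unbiased) he <- he * 2 * nrow(al) / (2 * nrow(al) - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, locus = lc, n = nrow(al),
        A = length(p), Ho = mean(al[, 1] != al[, 2]), He = he)
    }
  }
  out <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(out, out$group), function(d)
    data.frame(group = d$group[1], A = mean(d$A), Ho = mean(d$Ho),
               He = mean(d$He))))
  rownames(means) <- NULL
  attr(out, "means") <- means
  out
}

# rarefaction term for one allele: 1 - C(N - Ni, g)/C(N, g), computed on
# log scale for stability
rarefy_term <- function(N, Ni, g) {
  if (N - Ni < g) return(1)
  1 - exp(lchoose(N - Ni, g) - lchoose(N, g))
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies,
#' `R_S = sum_i [1 - C(N - N_i, g)/C(N, g)]`, standardising allele counts
#' to a common sample size across groups.
#'
#' @param tab An [ssr_table()].
#' @param by Grouping column.
#' @param g Standardised number of gene copies; default is the largest
#'   value admissible for every group x locus (the smallest non-missing
#'   copy count, capped at twice the smallest group size).
#' @return Data frame `group`, `locus`, `g`, `Rs` plus `"means"` attribute.
#' @export
allelic_richness <- function(tab, by = "population", g = NULL) {
  stopifnot(is_ssr_table(tab))
  groups <- split(seq_len(nrow(tab)), tab[[by]])
  copy_counts <- unlist(lapply(groups, function(rows)
    vapply(ssr_loci(tab), function(lc) {
      al <- locus_alleles(tab, lc)[rows, 1]
      2 * sum(!is.na(al))
    }, numeric(1))))
  if (is.null(g)) g <- min(2 * min(lengths(groups)), copy_counts[copy_counts > 0])
  if (g < 1) stop("'g' must be >= 1")
  if (g > min(copy_counts[copy_counts > 0]))
    stop("'g' exceeds the smallest non-missing gene-copy count (",
         min(copy_counts[copy_counts > 0]), ")")
  rows <- list()
  for (grp in names(groups)) {
    for (lc in ssr_loci(tab)) {
      al <- as.vector(locus_alleles(tab, lc)[groups[[grp]], , drop = FALSE])
      al <- al[!is.na(al)]
      if (length(al) == 0) next
      counts <- table(al)
      rs <- sum(vapply(counts, function(ni)
        rarefy_term(length(al), as.numeric(ni), g), numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(group = grp, locus = lc,
                                              g = g, Rs = rs)
    }
  }
  out <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(out, out$group), function(d)
    data.frame(group = d$group[1], g = g, Rs = mean(d$Rs))))
  rownames(means) <- NULL
  attr(out, "means") <- means
  out
}

#' Inbreeding coefficient F_IS
#'
#' `F_IS = (H_E - H_O) / H_E` per locus; monomorphic loci (`H_E = 0`) are
#' excluded from the mean and reported as `NA`.
#'
#' @param tab An [ssr_table()].
#' @param by Grouping column.
#' @return Data frame `group`, `locus`, `Fis` plus `"means"` attribute
#'   (mean over polymorphic loci; `NA` when no locus is polymorphic).
#' @export
inbreeding_coefficient <- function(tab, by = "population") {
  div <- locus_diversity(tab, by = by)
  div$Fis <- ifelse(div$He > 0, (div$He - div$Ho) / div$He, NA_real_)
  means <- do.call(rbind, lapply(split(div, div$group), function(d)
    data.frame(group = d$group[1],
               Fis = if (all(is.na(d$Fis))) NA_real_
                     else mean(d$Fis, na.rm = TRUE))))
  rownames(means) <- NULL
  out <- div[, c("group", "locus", "Fis")]
  attr(out, "means") <- means
  out
}

#' Private alleles per population
#'
#' Counts, for every population, alleles observed in that population and
#' in no other.
#'
#' @param tab An [ssr_table()].
#' @param by Grouping column (needs at least 2 groups).
#' @return Named integer vector of private-allele counts.
#' @export
private_alleles <- function(tab, by = "population") {
  freqs <- allele_frequencies(tab, by = by)
  if (length(freqs) < 2) stop("need at least 2 groups")
  out <- stats::setNames(integer(length(freqs)), names(freqs))
  for (lc in ssr_loci(tab)) {
    present <- lapply(freqs, function(f) names(f[[lc]]))
    all_alleles <- unique(unlist(present))
    for (al in all_alleles) {
      holders <- names(present)[vapply(present, function(p) al %in% p,
                                       logical(1))]
      if (length(holders) == 1) out[holders] <- out[holders] + 1L
    }
  }
  out
}

#' Nei's D_A genetic distance between two frequency sets
#'
#' `D_A = 1 - (1/L) * sum_loci sum_alleles sqrt(x_i * y_i)`. Loci absent
#' (all-missing) in either group are excluded with a warning and `L`
#' adjusted.
#'
#' @param freqs_x,freqs_y Named lists of per-locus allele-frequency
#'   vectors, as one element of [allele_frequencies()].
#' @return `D_A` in `[0, 1]`.
#' @export
nei_da <- function(freqs_x, freqs_y) {
  loci <- intersect(names(freqs_x), names(freqs_y))
  ok <- vapply(loci, function(lc)
    !is.null(freqs_x[[lc]]) && !is.null(freqs_y[[lc]]), logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " locus/loci missing in one group excluded from D_A")
    loci <- loci[ok]
  }
  if (length(loci) == 0) stop("no shared scored loci")
  shared <- vapply(loci, function(lc) {
    x <- freqs_x[[lc]]; y <- freqs_y[[lc]]
    alleles <- union(names(x), names(y))
    xs <- stats::setNames(rep(0, length(alleles)), alleles); xs[names(x)] <- x
    ys <- stats::setNames(rep(0, length(alleles)), alleles); ys[names(y)] <- y
    sum(sqrt(xs * ys))
  }, numeric(1))
  min(max(1 - mean(shared), 0), 1)
}

#' Pairwise D_A distance matrix
#'
#' @param tab An [ssr_table()].
#' @param by `"population"`, `"species"`, or `"sample"` (genotype-level
#'   distances, each individual its own frequency vector).
#' @return Symmetric `dist`-convertible matrix with zero diagonal.
#' @export
da_matrix <- function(tab, by = "population") {
  freqs <- allele_frequencies(tab, by = by)
  n <- length(freqs)
  d <- matrix(0, n, n, dimnames = list(names(freqs), names(freqs)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <- nei_da(freqs[[i]], freqs[[j]])
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via \pkg{ape}). Negative branch lengths --
#' an artefact of the least-squares step on non-additive matrices -- are
#' clamped to zero with the deficit transferred to the sibling edge at the
#' same node, preserving path lengths through the parent.
#'
#' @param d Symmetric numeric matrix (zero diagonal) with row/col names,
#'   at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(as.matrix(d))) || any(is.na(d)))
    stop("distance matrix must be symmetric with no NA")
  if (nrow(as.matrix(d)) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib) > 0)
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  tr
}

#' Locus-bootstrap support for a D_A neighbour-joining tree
#'
#' Resamples loci with replacement, rebuilds the D_A matrix and NJ tree,
#' and reports for each internal edge of the reference tree the percentage
#' of replicates containing the same bipartition.
#'
#' @param tab An [ssr_table()] with at least 2 loci.
#' @param n_reps Bootstrap replicates.
#' @param seed Integer seed.
#' @param by Grouping for the frequency vectors (see [da_matrix()]).
#' @return List with `tree` (reference NJ tree) and `support` (percent
#'   support per internal node, as returned by [ape::prop.clades()],
#'   scaled to 0-100).
#' @export
bootstrap_support <- function(tab, n_reps = 100, seed = 1L,
                              by = "population") {
  stopifnot(is_ssr_table(tab))
  loci <- ssr_loci(tab)
  if (length(loci) < 2) stop("locus bootstrap needs at least 2 loci")
  subset_loci <- function(idx) {
    cols <- c("sample", "population", "species",
              as.vector(rbind(paste0(loci[idx], "_a"),
                              paste0(loci[idx], "_b"))))
    df <- as.data.frame(tab)[, cols]
    # disambiguate repeated loci drawn by the bootstrap
    names(df)[-(1:3)] <- as.vector(rbind(paste0("L", seq_along(idx), "_a"),
                                         paste0("L", seq_along(idx), "_b")))
    ssr_table(df)
  }
  ref <- nj_tree(da_matrix(tab, by = by))
  set.seed(seed)
  reps <- lapply(seq_len(n_reps), function(i) {
    idx <- sample(seq_along(loci), replace = TRUE)
    nj_tree(da_matrix(subset_loci(idx), by = by))
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = ref, support = 100 * counts / n_reps)
}
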