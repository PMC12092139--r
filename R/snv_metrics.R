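#' Per-sample heterozygous-SNV variant table
#'
#' Long-format table of heterozygous SNVs called against a reference
#' transcript set: one row per SNV, with columns `sample`, `species`,
#' `transcript_id`, `transcript_len_bp`, `snv_id`, `effect`
#' (`"synonymous"` or `"nonsynonymous"`), and `score` (a signed
#' protein-impact score such as PROVEAN, required for nonsynonymous
#' SNVs; `NA` marks an unscored variant, which is reported as
#' unclassified). Transcripts without any SNV appear as a single row with
#' `snv_id = NA` so they still contribute transcript length to the
#' per-kilobase denominators.
#'
#' @param df Data frame in the layout above.
#' @return A validated `"variant_table"` data frame.
#' @export
variant_table <- function(df) {
  need <- c("sample", "species", "transcript_id", "transcript_len_bp",
            "snv_id", "effect", "score")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  if (any(df$transcript_len_bp <= 0)) stop("transcript lengths must be > 0")
  has_snv <- !is.na(df$snv_id)
  if (!all(df$effect[has_snv] %in% c("synonymous", "nonsynonymous")))
    stop("effect must be 'synonymous' or 'nonsynonymous'")
  structure(df[, need], class = c("variant_table", "data.frame"))
}

#' Classify a protein-impact score as deleterious
#'
#' Strict absolute-value rule: deleterious iff `|score| > threshold`.
#' The absolute value is used because at heterozygous sites the derived
#' and ancestral alleles cannot be told apart, so large positive scores
#' are treated like large negative ones. `strict = FALSE` switches the
#' boundary to `|score| >= threshold`.
#'
#' @param score Signed numeric score(s); `NA` returns `NA` (unclassified).
#' @param threshold Cutoff (default 2.5).
#' @param strict Use `>` (default) rather than `>=` at the boundary.
#' @return Logical vector.
#' @examples
#' classify_deleterious(c(-3, 3, -2.5, -1))  # TRUE TRUE FALSE FALSE
#' @export
classify_deleterious <- function(score, threshold = 2.5, strict = TRUE) {
  if (strict) abs(score) > threshold else abs(score) >= threshold
}

#' Genomic selfing-syndrome metrics for one sample
#'
#' From a sample's heterozygous SNVs over its analysed transcripts:
#' * `snv_per_kb`: SNVs per kilobase of total transcript length;
#' * `nonsyn_fraction`: nonsynonymous SNVs / all SNVs;
#' * `deleterious_fraction`: deleterious SNVs / all *classified* SNVs
#'   (nonsynonymous SNVs with a missing score are unclassified and
#'   removed from this denominator, with their count reported);
#' * `deleterious_per_kb`;
#' * `fraction_transcripts_with_nonsyn_snv`.
#'
#' @param v A [variant_table()] restricted to one sample (or any subset
#'   whose rows share a length denominator).
#' @param threshold Deleteriousness cutoff passed to
#'   [classify_deleterious()].
#' @param strict Boundary convention, see [classify_deleterious()].
#' @return One-row data frame of the metrics plus `n_snv`, `total_kb`
#'   and `n_unclassified`.
#' @export
syndrome_metrics <- function(v, threshold = 2.5, strict = TRUE) {
  stopifnot(inherits(v, "variant_table"))
  if (nrow(v) == 0) stop("empty variant table")
  tr <- unique(v[, c("transcript_id", "transcript_len_bp")])
  if (anyDuplicated(tr$transcript_id))
    stop("inconsistent lengths for a transcript")
  total_kb <- sum(tr$transcript_len_bp) / 1000
  snvs <- v[!is.na(v$snv_id), , drop = FALSE]
  n_snv <- nrow(snvs)
  nonsyn <- snvs$effect == "nonsynonymous"
  del <- nonsyn & !is.na(snvs$score) &
    classify_deleterious(snvs$score, threshold, strict)
  unclassified <- nonsyn & is.na(snvs$score)
  n_classified <- n_snv - sum(unclassified)
  with_nonsyn <- unique(snvs$transcript_id[nonsyn])
  data.frame(
    snv_per_kb = n_snv / total_kb,
    nonsyn_fraction = if (n_snv == 0) 0 else mean(nonsyn),
    deleterious_fraction = if (n_classified == 0) 0
                           else sum(del) / n_classified,
    deleterious_per_kb = sum(del) / total_kb,
    fraction_transcripts_with_nonsyn_snv =
      length(with_nonsyn) / nrow(tr),
    n_snv = n_snv, total_kb = total_kb,
    n_unclassified = sum(unclassified))
}

#' Selfing-syndrome metrics for every sample in a variant table
#'
#' @inheritParams syndrome_metrics
#' @return Data frame with one row per sample (`sample`, `species`,
#'   metrics columns).
#' @export
syndrome_metrics_by_sample <- function(v, threshold = 2.5, strict = TRUE) {
  stopifnot(inherits(v, "variant_table"))
  parts <- split(seq_len(nrow(v)), v$sample)
  out <- do.call(rbind, lapply(names(parts), function(s) {
    sub <- variant_table(as.data.frame(v)[parts[[s]], ])
    cbind(data.frame(sample = s, species = sub$species[1]),
          syndrome_metrics(sub, threshold, strict))
  }))
  rownames(out) <- NULL
  out
}

metric_columns <- c("snv_per_kb", "nonsyn_fraction", "deleterious_fraction",
                    "deleterious_per_kb",
                    "fraction_transcripts_with_nonsyn_snv")

#' Compare syndrome metrics between a sister-species pair
#'
#' Two-sample t-test per metric between the per-sample metric vectors of
#' two species. The default is the equal-variance Student form; Welch's
#' unequal-variance form is available. Degenerate inputs with zero
#' variance in both groups and equal means are reported as `t = 0`,
#' `p = 1`.
#'
#' @param metrics Output of [syndrome_metrics_by_sample()].
#' @param species_a,species_b Species labels (each needs >= 2 samples).
#' @param test `"student"` (default) or `"welch"`.
#' @param metrics_cols Metric columns to test.
#' @return Data frame `metric`, `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_species_pair <- function(metrics, species_a, species_b,
                                 test = c("student", "welch"),
                                 metrics_cols = metric_columns) {
  test <- match.arg(test)
  a <- metrics[metrics$species == species_a, , drop = FALSE]
  b <- metrics[metrics$species == species_b, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 samples per species")
  rows <- lapply(metrics_cols, function(mc) {
    x <- a[[mc]]; y <- b[[mc]]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y))
        return(data.frame(metric = mc, mean_a = mean(x), mean_b = mean(y),
                          t = 0, df = length(x) + length(y) - 2, p = 1))
      # all variation is between groups: infinitely strong evidence
      return(data.frame(metric = mc, mean_a = mean(x), mean_b = mean(y),
                        t = sign(mean(x) - mean(y)) * Inf,
                        df = length(x) + length(y) - 2, p = 0))
    }
    tt <- stats::t.test(x, y, var.equal = (test == "student"))
    data.frame(metric = mc, mean_a = mean(x), mean_b = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Species-mean trait table from per-sample metrics
#'
#' Arithmetic mean of each metric across a species' samples -- the rows
#' fed to the phylogenetic regression.
#'
#' @param metrics Output of [syndrome_metrics_by_sample()].
#' @param selfing Optional named logical/0-1 vector (by species) marking
#'   obligate selfers; appended as a `selfing` column when given.
#' @param metrics_cols Metric columns to average.
#' @return Data frame with one row per species.
#' @export
species_means <- function(metrics, selfing = NULL,
                          metrics_cols = metric_columns) {
  parts <- split(metrics, metrics$species)
  out <- do.call(rbind, lapply(names(parts), function(sp) {
    cbind(data.frame(species = sp),
          as.data.frame(lapply(parts[[sp]][metrics_cols], mean)))
  }))
  rownames(out) <- NULL
  if (!is.null(selfing)) {
    if (!all(out$species %in% names(selfing)))
      stop("'selfing' must be named by species")
    out$selfing <- as.integer(selfing[out$species])
  }
  out
}
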