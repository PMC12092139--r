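#' Read and write the SSR genotype CSV dialect
#'
#' Header `sample,population,species,<locus>_a,<locus>_b,...`; missing
#' alleles are written as 0 (empty cells are also accepted on read).
#' Writers are deterministic: fixed column order, integer allele sizes.
#'
#' @param path File path.
#' @param motif_len Optional named motif-length vector, see [ssr_table()].
#' @param complete_cases Drop samples not genotyped at every locus.
#' @return [read_ssr_csv()] returns an [ssr_table()];
#'   [write_ssr_csv()] returns `path` invisibly.
#' @export
read_ssr_csv <- function(path, motif_len = NULL, complete_cases = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- ssr_table(df, motif_len = motif_len)
  if (complete_cases) tab <- complete_cases_ssr(tab)
  tab
}

#' @rdname read_ssr_csv
#' @param tab An [ssr_table()].
#' @export
write_ssr_csv <- function(tab, path) {
  stopifnot(is_ssr_table(tab))
  df <- as.data.frame(tab)
  geno_cols <- setdiff(names(df), c("sample", "population", "species"))
  for (cl in geno_cols) df[[cl]][is.na(df[[cl]])] <- 0L
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the SNP TSV dialect
#'
#' Long-format TSV `sample, species, population, snp_id, locus_id,
#' pos_in_locus, gt` with `gt` in `{0, 1, 2, NA}` and 1-based
#' `pos_in_locus` (VCF convention).
#'
#' @param path File path.
#' @return [read_snp_tsv()] returns a [snp_matrix()];
#'   [write_snp_tsv()] returns `path` invisibly.
#' @export
read_snp_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "species", "population", "snp_id", "locus_id",
            "pos_in_locus", "gt")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  samples <- unique(df[, c("sample", "species", "population")])
  snps <- unique(df[, c("snp_id", "locus_id", "pos_in_locus")])
  geno <- matrix(NA_integer_, nrow(samples), nrow(snps))
  geno[cbind(match(df$sample, samples$sample),
             match(df$snp_id, snps$snp_id))] <- as.integer(df$gt)
  snp_matrix(geno, samples, snps)
}

#' @rdname read_snp_tsv
#' @param m A [snp_matrix()].
#' @export
write_snp_tsv <- function(m, path) {
  stopifnot(is_snp_matrix(m))
  long <- expand.grid(si = seq_len(nrow(m$geno)), vi = seq_len(ncol(m$geno)))
  df <- data.frame(sample = m$samples$sample[long$si],
                   species = m$samples$species[long$si],
                   population = m$samples$population[long$si],
                   snp_id = m$snps$snp_id[long$vi],
                   locus_id = m$snps$locus_id[long$vi],
                   pos_in_locus = m$snps$pos_in_locus[long$vi],
                   gt = m$geno[cbind(long$si, long$vi)])
  df <- df[order(match(df$snp_id, m$snps$snp_id),
                 match(df$sample, m$samples$sample)), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a minimal VCF into a SNP matrix
#'
#' Parses the GT field only (via \pkg{vcfR}); phased (`|`) and unphased
#' (`/`) separators are equivalent. Multiallelic records are rejected
#' with a count. The locus group is taken from an INFO key (default
#' `LOC=`) when present, else from the CHROM field; position within
#' locus follows POS order within each group.
#'
#' @param path VCF file path (uncompressed or gzipped).
#' @param sample_meta Optional data frame `sample, species, population`;
#'   defaults to species = population = sample name.
#' @param locus_info_key INFO key holding the locus group.
#' @return A [snp_matrix()].
#' @export
read_snp_vcf <- function(path, sample_meta = NULL, locus_info_key = "LOC") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) rejected")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2 || !all(al %in% c("0", "1")))
      stop("malformed genotype string: '", g, "'")
    sum(al == "1")
  }
  geno <- t(apply(gt_chr, c(1, 2), code))   # samples x snps
  info <- fix$INFO
  loc <- rep(NA_character_, nrow(fix))
  if (!is.null(info)) {
    hit <- regmatches(info, regexpr(paste0(locus_info_key, "=[^;]+"), info))
    has <- grepl(paste0(locus_info_key, "="), info)
    loc[has] <- sub(paste0(locus_info_key, "="), "", hit)
  }
  loc[is.na(loc)] <- fix$CHROM[is.na(loc)]
  pos <- as.integer(fix$POS)
  pos_in_locus <- stats::ave(pos, loc, FUN = function(x) rank(x, ties.method = "first"))
  snps <- data.frame(snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, "_", fix$POS), fix$ID),
                     locus_id = loc, pos_in_locus = pos_in_locus)
  ids <- colnames(gt_chr)
  if (is.null(sample_meta))
    sample_meta <- data.frame(sample = ids, species = ids, population = ids)
  sample_meta <- sample_meta[match(ids, sample_meta$sample), ]
  snp_matrix(geno, sample_meta, snps)
}

#' Write a SNP matrix as a minimal VCF
#'
#' GT-only biallelic records with the locus group in `INFO` (`LOC=`).
#'
#' @param m A [snp_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(m, path) {
  stopifnot(is_snp_matrix(m))
  gt <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=LOC,Number=1,Type=String,Description=\"Locus group\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", m$samples$sample), collapse = "\t"))
  for (j in seq_len(ncol(m$geno))) {
    g <- m$geno[, j]
    gstr <- ifelse(is.na(g), "./.", gt[g + 1L])
    lines <- c(lines, paste(c(
      m$snps$locus_id[j], m$snps$pos_in_locus[j], m$snps$snp_id[j],
      "A", "T", ".", "PASS", paste0("LOC=", m$snps$locus_id[j]), "GT",
      gstr), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write the variant TSV dialect
#'
#' Columns `sample, species, transcript_id, transcript_len_bp, snv_id,
#' effect, score`; empty `snv_id` marks an SNV-less transcript row.
#'
#' @param path File path.
#' @return [read_variant_tsv()] returns a [variant_table()];
#'   [write_variant_tsv()] returns `path` invisibly.
#' @export
read_variant_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  variant_table(df)
}

#' @rdname read_variant_tsv
#' @param v A [variant_table()].
#' @export
write_variant_tsv <- function(v, path) {
  stopifnot(inherits(v, "variant_table"))
  utils::write.table(as.data.frame(v), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Write a report list as JSON
#'
#' @param x A list or data frame (e.g. a `FilterReport`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
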