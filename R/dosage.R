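#' RNA:DNA focus ratio per nucleus
#'
#' `rna_foci / dna_foci` — the per-nucleus proxy for transcripts per gene
#' copy obtained from combined nascent RNA FISH and DNA FISH counts.
#'
#' @param rna_foci,dna_foci non-negative focus counts (vectorised).
#' @return numeric ratio; `NA` (nucleus excluded) where `dna_foci == 0`.
#' @examples
#' rna_dna_ratio(10, 40)  # 0.25
#' @export
rna_dna_ratio <- function(rna_foci, dna_foci) {
  if (any(rna_foci < 0 | dna_foci < 0, na.rm = TRUE)) {
    stop("focus counts must be non-negative", call. = FALSE)
  }
  ifelse(dna_foci > 0, rna_foci / dna_foci, NA_real_)
}

#' Estimated proportion of gene copies on ecDNA
#'
#' `(dna_foci - cen7_foci) / dna_foci`: the centromere-7 focus count proxies
#' the chromosomal copy number, so the excess of gene DNA foci over CEN7
#' foci estimates the ecDNA-resident fraction. Negative values (CEN7 foci
#' exceeding gene foci, possible with miscounts) are retained, not clamped,
#' so anomalies stay visible; use the `anomalous` attribute to flag them.
#'
#' @param dna_foci,cen7_foci non-negative focus counts (vectorised).
#' @return numeric proportion with logical attribute `anomalous` marking
#'   negative values; `NA` where `dna_foci == 0`.
#' @examples
#' ecdna_proportion(50, 3)  # 0.94
#' @export
ecdna_proportion <- function(dna_foci, cen7_foci) {
  if (any(dna_foci < 0 | cen7_foci < 0, na.rm = TRUE)) {
    stop("focus counts must be non-negative", call. = FALSE)
  }
  out <- ifelse(dna_foci > 0, (dna_foci - cen7_foci) / dna_foci, NA_real_)
  attr(out, "anomalous") <- !is.na(out) & out < 0
  out
}

#' Correlation of RNA:DNA ratio with ecDNA proportion across nuclei
#'
#' Spearman rank correlation between the per-nucleus RNA:DNA focus ratio and
#' the estimated ecDNA proportion. Under equal per-copy transcription on
#' ecDNA and chromosome the expected correlation is zero; a positive
#' correlation indicates a per-copy efficiency difference between the two
#' compartments.
#'
#' @param nuclei data frame with columns `rna_foci`, `dna_foci`, `cen7_foci`
#'   (e.g. the `nuclei` table from [simulate_dosage_tables()]).
#' @param min_nuclei minimum number of valid nuclei (default 5).
#' @return list with `rho`, `p_value`, `n` (valid nuclei used) and
#'   `n_excluded`; `rho` is `NA` with an explanatory `note` when either
#'   variable is constant.
#' @export
ratio_proportion_correlation <- function(nuclei, min_nuclei = 5) {
  required <- c("rna_foci", "dna_foci", "cen7_foci")
  missing <- setdiff(required, names(nuclei))
  if (length(missing) > 0) {
    stop("nuclei table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ratio <- rna_dna_ratio(nuclei$rna_foci, nuclei$dna_foci)
  prop <- as.numeric(ecdna_proportion(nuclei$dna_foci, nuclei$cen7_foci))
  ok <- !is.na(ratio) & !is.na(prop)
  if (sum(ok) < min_nuclei) {
    stop(sprintf("need at least %d valid nuclei, have %d", min_nuclei,
                 sum(ok)), call. = FALSE)
  }
  if (length(unique(ratio[ok])) < 2 || length(unique(prop[ok])) < 2) {
    return(list(rho = NA_real_, p_value = NA_real_, n = sum(ok),
                n_excluded = sum(!ok), note = "constant column"))
  }
  ct <- suppressWarnings(
    stats::cor.test(ratio[ok], prop[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       n_excluded = sum(!ok))
}

#' Compare copy-number-normalised expression between exon groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of the per-exon
#' `rna_count / wgs_count` values between chromosomal-only exons and exons
#' carried on ecDNA. Equality of the two groups is the signature of equal
#' per-copy transcription; a shifted ecDNA group would indicate an
#' efficiency difference.
#'
#' @param exons data frame with columns `group` (values `"chromosomal"` /
#'   `"ecDNA"`), `wgs_count`, `rna_count`; a `normalized` column is used when
#'   present, otherwise computed (exons with `wgs_count == 0` are dropped).
#' @return list with `statistic` (U), `p_value`, `n_chromosomal`, `n_ecdna`,
#'   and the per-group `medians`.
#' @export
compare_exon_groups <- function(exons) {
  required <- c("group", "wgs_count", "rna_count")
  missing <- setdiff(required, names(exons))
  if (length(missing) > 0) {
    stop("exon table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(exons$normalized)) {
    exons$normalized <- ifelse(exons$wgs_count > 0,
                               exons$rna_count / exons$wgs_count, NA_real_)
  }
  exons <- exons[!is.na(exons$normalized), , drop = FALSE]
  g_chr <- exons$normalized[exons$group == "chromosomal"]
  g_ec <- exons$normalized[exons$group == "ecDNA"]
  if (length(g_chr) < 2 || length(g_ec) < 2) {
    stop("need at least 2 exons per group", call. = FALSE)
  }
  if (length(unique(c(g_chr, g_ec))) == 1) {
    # both groups constant and equal: U sits at its midpoint, no evidence
    return(list(statistic = length(g_chr) * length(g_ec) / 2, p_value = 1,
                n_chromosomal = length(g_chr), n_ecdna = length(g_ec),
                medians = c(chromosomal = g_chr[1], ecDNA = g_ec[1])))
  }
  wt <- suppressWarnings(stats::wilcox.test(g_ec, g_chr, exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_chromosomal = length(g_chr), n_ecdna = length(g_ec),
       medians = c(chromosomal = stats::median(g_chr),
                   ecDNA = stats::median(g_ec)))
}

#' Select heterozygous SNPs by control allele frequency
#'
#' Keeps SNPs whose germline (control blood WGS) allele frequency lies in
#' `[lo, hi]` (inclusive bounds; default 40-60%), the heterozygosity filter
#' applied before computing amplicon allele-frequency ratios.
#'
#' @param snps data frame with a column `af_control` in \[0, 1\].
#' @param lo,hi inclusive bounds (defaults 0.40, 0.60).
#' @return the filtered data frame.
#' @export
select_heterozygous_snps <- function(snps, lo = 0.40, hi = 0.60) {
  if (is.null(snps$af_control)) {
    stop("snp table is missing column 'af_control'", call. = FALSE)
  }
  out <- snps[!is.na(snps$af_control) &
                snps$af_control >= lo & snps$af_control <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Allele-frequency ratio analysis of amplicon SNPs
#'
#' For heterozygous SNPs with adequate RNA coverage (`rna_depth >=
#' min_rna_depth`, default 20 reads), computes the per-SNP ratio of the
#' amplified allele's frequency in tumour RNA-seq to its frequency in tumour
#' WGS, and the per-gene median of those ratios. A median near 1 means the
#' amplified (predominantly ecDNA-borne) allele is transcribed in proportion
#' to its copy number; a median above 1 indicates extra per-copy output from
#' the amplicon.
#'
#' @param snps data frame with columns `snp_id`, `gene`, `af_control`,
#'   `af_wgs_tumour`, `af_rna_tumour`, `rna_depth`.
#' @param min_rna_depth minimum RNA-seq read depth (inclusive, default 20).
#' @param het_lo,het_hi control-AF bounds passed to
#'   [select_heterozygous_snps()].
#' @return list with `snps` (qualifying SNPs plus an `af_ratio` column),
#'   `gene_medians` (data frame `gene`, `median_af_ratio`, `n_snps`) and
#'   `n_dropped` (list of counts per filtering step; genes with zero
#'   qualifying SNPs are simply absent from `gene_medians`).
#' @export
af_ratio_analysis <- function(snps, min_rna_depth = 20, het_lo = 0.40,
                              het_hi = 0.60) {
  required <- c("gene", "af_control", "af_wgs_tumour", "af_rna_tumour",
                "rna_depth")
  missing <- setdiff(required, names(snps))
  if (length(missing) > 0) {
    stop("snp table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(snps)
  het <- select_heterozygous_snps(snps, het_lo, het_hi)
  n1 <- nrow(het)
  keep <- het[!is.na(het$rna_depth) & het$rna_depth >= min_rna_depth &
                !is.na(het$af_wgs_tumour) & het$af_wgs_tumour > 0 &
                !is.na(het$af_rna_tumour), , drop = FALSE]
  keep$af_ratio <- keep$af_rna_tumour / keep$af_wgs_tumour
  med <- if (nrow(keep) > 0) {
    agg <- stats::aggregate(af_ratio ~ gene, data = keep, FUN = stats::median)
    cnt <- stats::aggregate(af_ratio ~ gene, data = keep, FUN = length)
    data.frame(gene = agg$gene, median_af_ratio = agg$af_ratio,
               n_snps = cnt$af_ratio)
  } else {
    data.frame(gene = character(0), median_af_ratio = numeric(0),
               n_snps = integer(0))
  }
  rownames(keep) <- NULL
  list(snps = keep, gene_medians = med,
       n_dropped = list(not_heterozygous = n0 - n1,
                        low_depth_or_missing = n1 - nrow(keep)))
}

#' Exon-group assignment for the EGFR amplicon
#'
#' The exon grouping of the EGFR-201 transcript implied by an exon 2-7
#' deletion on the ecDNA amplicon: exons 2-7 exist only on the chromosome,
#' exons 1 and 8-28 also on ecDNA. Group labels are inputs to the analysis
#' (normally derived from amplicon-reconstruction output); this fixture
#' covers the common EGFRvIII-type configuration.
#'
#' @return data frame with columns `exon_id` (1-28) and `group`.
#' @export
egfr_exon_groups <- function() {
  exon_id <- 1:28
  data.frame(exon_id = exon_id,
             group = ifelse(exon_id %in% 2:7, "chromosomal", "ecDNA"))
}
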