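#' Configuration for the copy-number-driven transcription simulator
#'
#' Encodes the generative model behind the dosage analyses: each nucleus
#' carries `chr7_copies` chromosomal EGFR copies and a random number of
#' ecDNA copies; every copy independently produces a nascent-transcription
#' focus with the compartment-specific probability, and sequencing depth
#' scales with copy number. Setting `p_transcribe_ec == p_transcribe_chr`
#' gives the copy-number-only null (per-copy transcription identical on
#' ecDNA and chromosome); a larger `p_transcribe_ec` encodes a per-copy
#' efficiency boost on ecDNA.
#'
#' Defaults emulate a high-copy EGFR-amplified line: 3 chromosome 7 copies,
#' ecDNA counts with mean 45 and strong over-dispersion (negative binomial,
#' size 2) reflecting the marked cell-to-cell copy-number heterogeneity of
#' ecDNA, and a per-copy nascent-focus probability of 0.5 (roughly half of
#' active gene copies display a nascent transcription focus at any instant,
#' consistent with bursty transcription).
#'
#' @param seed integer master seed.
#' @param n_nuclei number of nuclei.
#' @param chr7_copies chromosome 7 (hence chromosomal EGFR) copies per
#'   nucleus.
#' @param ec_mean,ec_size mean and negative-binomial size of the per-nucleus
#'   ecDNA copy-number distribution; `ec_mean = 0` gives no ecDNA.
#' @param p_transcribe_chr,p_transcribe_ec per-copy probability of a nascent
#'   RNA focus for chromosomal and ecDNA copies.
#' @param rna_depth_scale,wgs_depth_scale expected reads per transcribing /
#'   per present copy in the count tables.
#' @param n_exons,chromosomal_exons exon structure: exon ids `1..n_exons`
#'   with `chromosomal_exons` present only on the chromosome (the ecDNA
#'   deletion), all others on both compartments. Defaults follow the
#'   EGFR-201 exon 2-7 deletion (chromosomal = exons 2-7, ecDNA = 1, 8-28).
#' @param n_snps number of heterozygous amplicon SNPs to simulate.
#' @param snp_control_af_range range of the germline (control) allele
#'   frequency, default \[0.4, 0.6\].
#' @return list of class `dosage_sim_config`.
#' @export
dosage_sim_config <- function(seed = NULL, n_nuclei = 40, chr7_copies = 3,
                              ec_mean = 45, ec_size = 2,
                              p_transcribe_chr = 0.5,
                              p_transcribe_ec = 0.5,
                              rna_depth_scale = 100, wgs_depth_scale = 100,
                              n_exons = 28, chromosomal_exons = 2:7,
                              n_snps = 40,
                              snp_control_af_range = c(0.4, 0.6)) {
  assert_scalar_number(n_nuclei, "n_nuclei", 1)
  assert_scalar_number(chr7_copies, "chr7_copies", 1)
  assert_scalar_number(ec_mean, "ec_mean", 0)
  assert_scalar_number(ec_size, "ec_size", 0, strict_lower = TRUE)
  assert_scalar_number(p_transcribe_chr, "p_transcribe_chr", 0, 1)
  assert_scalar_number(p_transcribe_ec, "p_transcribe_ec", 0, 1)
  assert_scalar_number(rna_depth_scale, "rna_depth_scale", 0,
                       strict_lower = TRUE)
  assert_scalar_number(wgs_depth_scale, "wgs_depth_scale", 0,
                       strict_lower = TRUE)
  assert_scalar_number(n_exons, "n_exons", 2)
  assert_scalar_number(n_snps, "n_snps", 0)
  stopifnot(length(snp_control_af_range) == 2,
            snp_control_af_range[1] <= snp_control_af_range[2],
            all(snp_control_af_range >= 0 & snp_control_af_range <= 1))
  if (length(chromosomal_exons) == 0 ||
      any(!(chromosomal_exons %in% seq_len(n_exons)))) {
    stop("'chromosomal_exons' must be a non-empty subset of 1..n_exons",
         call. = FALSE)
  }
  structure(list(seed = seed, n_nuclei = as.integer(n_nuclei),
                 chr7_copies = as.integer(chr7_copies), ec_mean = ec_mean,
                 ec_size = ec_size, p_transcribe_chr = p_transcribe_chr,
                 p_transcribe_ec = p_transcribe_ec,
                 rna_depth_scale = rna_depth_scale,
                 wgs_depth_scale = wgs_depth_scale,
                 n_exons = as.integer(n_exons),
                 chromosomal_exons = as.integer(chromosomal_exons),
                 n_snps = as.integer(n_snps),
                 snp_control_af_range = snp_control_af_range),
            class = "dosage_sim_config")
}

#' Simulate per-nucleus, per-exon and per-SNP dosage tables
#'
#' Generates the three inputs of the dosage analyses under the configured
#' generative model:
#'
#' * **nuclei** — per nucleus: `dna_foci = chr7_copies + ec_copies`,
#'   `cen7_foci = chr7_copies`, `rna_foci` binomial per copy with the
#'   compartment-specific transcription probability.
#' * **exons** — per exon: WGS reads Poisson in the cohort-total copy number
#'   of the compartments carrying the exon, RNA reads Poisson in the
#'   cohort-total *transcribing* copy rate; `group` labels chromosomal-only
#'   vs ecDNA exons.
#' * **snps** — per heterozygous amplicon SNP: germline allele frequency
#'   uniform in `snp_control_af_range`; the amplified haplotype carries one
#'   chromosomal copy plus every ecDNA copy, so the tumour WGS allele
#'   frequency of the amplified allele is `(ec + 1) / (ec + chr)` (cohort
#'   totals) and the RNA allele frequency is the transcription-rate-weighted
#'   analogue; observed frequencies are binomial draws at Poisson depths.
#'
#' @param config a [dosage_sim_config()].
#' @return list of three data frames `nuclei`, `exons`, `snps` (see Details)
#'   plus `truth` (the latent per-nucleus copy numbers and expected allele
#'   frequencies).
#' @export
simulate_dosage_tables <- function(config = dosage_sim_config()) {
  stopifnot(inherits(config, "dosage_sim_config"))
  with_local_seed(config$seed, {
    n <- config$n_nuclei
    chr <- config$chr7_copies
    ec <- if (config$ec_mean == 0) rep(0L, n) else
      stats::rnbinom(n, size = config$ec_size, mu = config$ec_mean)
    rna_chr <- stats::rbinom(n, chr, config$p_transcribe_chr)
    rna_ec <- stats::rbinom(n, ec, config$p_transcribe_ec)
    nuclei <- data.frame(
      nucleus_id = sprintf("nucleus_%03d", seq_len(n)),
      rna_foci = rna_chr + rna_ec,
      dna_foci = chr + ec,
      cen7_foci = rep(chr, n)
    )

    # cohort-total copy numbers drive the bulk-sequencing tables
    total_chr <- n * chr
    total_ec <- sum(ec)
    exon_ids <- seq_len(config$n_exons)
    is_chromosomal <- exon_ids %in% config$chromosomal_exons
    cn <- ifelse(is_chromosomal, total_chr, total_chr + total_ec)
    tx <- ifelse(is_chromosomal,
                 total_chr * config$p_transcribe_chr,
                 total_chr * config$p_transcribe_chr +
                   total_ec * config$p_transcribe_ec)
    wgs_count <- stats::rpois(config$n_exons,
                              config$wgs_depth_scale * cn / (chr + mean(ec)))
    rna_count <- stats::rpois(config$n_exons,
                              config$rna_depth_scale * tx / (chr + mean(ec)))
    exons <- data.frame(
      exon_id = exon_ids,
      group = ifelse(is_chromosomal, "chromosomal", "ecDNA"),
      wgs_count = wgs_count,
      rna_count = rna_count
    )
    exons$normalized <- ifelse(exons$wgs_count > 0,
                               exons$rna_count / exons$wgs_count, NA_real_)

    # SNPs: amplified haplotype = one chromosomal copy + all ecDNA copies
    n_snps <- config$n_snps
    af_true_wgs <- (total_ec + n) / (total_ec + total_chr)
    tx_amp <- total_ec * config$p_transcribe_ec +
      n * config$p_transcribe_chr
    tx_tot <- total_ec * config$p_transcribe_ec +
      total_chr * config$p_transcribe_chr
    af_true_rna <- if (tx_tot > 0) tx_amp / tx_tot else NA_real_
    af_control <- stats::runif(n_snps, config$snp_control_af_range[1],
                               config$snp_control_af_range[2])
    wgs_depth <- stats::rpois(n_snps, config$wgs_depth_scale *
                                (chr + mean(ec)))
    rna_depth <- stats::rpois(n_snps, config$rna_depth_scale *
                                (chr * config$p_transcribe_chr +
                                   mean(ec) * config$p_transcribe_ec))
    af_wgs_obs <- ifelse(wgs_depth > 0,
                         stats::rbinom(n_snps, wgs_depth, af_true_wgs) /
                           pmax(wgs_depth, 1), NA_real_)
    af_rna_obs <- ifelse(rna_depth > 0 & !is.na(af_true_rna),
                         stats::rbinom(n_snps, rna_depth,
                                       ifelse(is.na(af_true_rna), 0,
                                              af_true_rna)) /
                           pmax(rna_depth, 1), NA_real_)
    snps <- data.frame(
      snp_id = sprintf("snp_%03d", seq_len(n_snps)),
      gene = rep("EGFR", n_snps),
      af_control = af_control,
      af_wgs_tumour = af_wgs_obs,
      af_rna_tumour = af_rna_obs,
      rna_depth = rna_depth
    )

    list(nuclei = nuclei, exons = exons, snps = snps,
         truth = list(ec_copies = ec, chr7_copies = chr,
                      af_true_wgs = af_true_wgs, af_true_rna = af_true_rna))
  })
}
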