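#' Simulation parameters for the synthetic-data generator
#'
#' Defines the study conditions the toy genome emulates: a tiling array with
#' 50 bp probes separated by 36 bp gaps (86 bp start-to-start pitch), three
#' correlated biological replicates with a target pairwise Pearson
#' correlation of 0.75 (the middle of the 0.71--0.78 band reported for real
#' replicate hybridizations), binding sites planted preferentially around
#' 300 bp upstream of TSSs, and site lengths of 1--1.8 kb (bound intervals on
#' the array platform average roughly 1.45 kb).
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of each chromosome (bp).
#' @param n_genes number of gene models to place.
#' @param gc genome GC fraction.
#' @param probe_len tiling-array probe length (bp).
#' @param probe_gap gap between consecutive probes (bp); start-to-start
#'   pitch is \code{probe_len + probe_gap}.
#' @param n_reps number of array replicates.
#' @param rep_corr target pairwise Pearson correlation between replicate
#'   noise components, in [0, 1).
#' @param noise_sd per-probe noise standard deviation (log2 units).
#' @param enrichment_mean fold enrichment of planted sites over background.
#' @param read_depth background per-base Poisson mean of the read-coverage
#'   track.
#' @param frag_len sequencing fragment length (bp); coverage enrichment
#'   extends \code{frag_len / 2} beyond each site flank.
#' @param n_sites number of binding sites to plant.
#' @param offset_mean,offset_sd mean and sd (bp) of the signed site-midpoint
#'   offset from the target TSS (negative = upstream).
#' @param ebox_range inclusive range of E-box (CANNTG) counts per site.
#' @param site_len_range inclusive range of planted site lengths (bp).
#' @param gene_len_range inclusive range of gene span lengths (bp).
#' @param tss_spacing minimum slot spacing between TSSs on a chromosome (bp);
#'   guarantees the -2 kb..+6 kb profile window is unambiguous.
#' @param shared_fraction fraction of planted sites present on both
#'   platforms in a full pipeline run (the remainder is split evenly).
#' @param seed master integer seed; every generator derives a named
#'   substream from it.
#' @return an object of class \code{sim_params} (a validated list).
#' @export
sim_params <- function(n_chroms = 2L, chrom_len = 1e6, n_genes = 50L,
                       gc = 0.36, probe_len = 50L, probe_gap = 36L,
                       n_reps = 3L, rep_corr = 0.75, noise_sd = 1,
                       enrichment_mean = 8, read_depth = 5, frag_len = 150L,
                       n_sites = 20L, offset_mean = -300, offset_sd = 50,
                       ebox_range = c(1L, 13L),
                       site_len_range = c(1000L, 1800L),
                       gene_len_range = c(1000L, 3000L),
                       tss_spacing = 10000L, shared_fraction = 0.6,
                       seed = 7L) {
  p <- list(n_chroms = as.integer(n_chroms), chrom_len = as.integer(chrom_len),
            n_genes = as.integer(n_genes), gc = gc,
            probe_len = as.integer(probe_len), probe_gap = as.integer(probe_gap),
            n_reps = as.integer(n_reps), rep_corr = rep_corr,
            noise_sd = noise_sd, enrichment_mean = enrichment_mean,
            read_depth = read_depth, frag_len = as.integer(frag_len),
            n_sites = as.integer(n_sites), offset_mean = offset_mean,
            offset_sd = offset_sd, ebox_range = as.integer(ebox_range),
            site_len_range = as.integer(site_len_range),
            gene_len_range = as.integer(gene_len_range),
            tss_spacing = as.integer(tss_spacing),
            shared_fraction = shared_fraction, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  if (p$n_chroms < 1L || p$chrom_len < 1L)
    stop("configuration error: chromosome count and length must be positive",
         call. = FALSE)
  if (p$gc < 0 || p$gc > 1) stop("gc must be in [0, 1]", call. = FALSE)
  if (p$probe_len <= 0L) stop("probe_len must be positive", call. = FALSE)
  if (p$probe_gap < 0L) stop("probe_gap must be non-negative", call. = FALSE)
  if (p$rep_corr < 0 || p$rep_corr >= 1)
    stop("rep_corr must be in [0, 1)", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (p$read_depth <= 0) stop("read_depth must be positive", call. = FALSE)
  if (p$n_reps < 1L) stop("need at least one replicate", call. = FALSE)
  if (length(p$ebox_range) != 2L || p$ebox_range[1] > p$ebox_range[2] ||
      p$ebox_range[1] < 0L)
    stop("ebox_range must be a non-negative increasing pair", call. = FALSE)
  if (p$shared_fraction < 0 || p$shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Peak-calling parameters for the tiling-array caller
#'
#' Defaults follow the published CARPET notator settings used for the array
#' analysis: percentile 0.95, -log10 p cutoff 13, at least 5 probes per
#' peak, at most 100 bp between member probes, at least 200 bp between
#' peaks, a 500 bp test window, and a 2 kb promoter definition.
#'
#' @param percentile candidate-probe quantile of the summarized intensities.
#' @param neg_log_p_cutoff retain peaks with -log10 p at or above this.
#' @param min_probes minimum candidate probes per run.
#' @param max_probe_gap maximum bp between the end of one candidate probe
#'   and the start of the next within a run.
#' @param min_peak_distance peaks closer than this (bp) are merged.
#' @param window_len test window length (bp); pads peaks shorter than this.
#' @param promoter_bp promoter extent upstream of the TSS (bp).
#' @param summarization replicate summarization method.
#' @return an object of class \code{carpet_params}.
#' @export
carpet_params <- function(percentile = 0.95, neg_log_p_cutoff = 13,
                          min_probes = 5L, max_probe_gap = 100L,
                          min_peak_distance = 200L, window_len = 500L,
                          promoter_bp = 2000L,
                          summarization = c("biweight", "mean")) {
  summarization <- match.arg(summarization)
  p <- list(percentile = percentile, neg_log_p_cutoff = neg_log_p_cutoff,
            min_probes = as.integer(min_probes),
            max_probe_gap = as.integer(max_probe_gap),
            min_peak_distance = as.integer(min_peak_distance),
            window_len = as.integer(window_len),
            promoter_bp = as.integer(promoter_bp),
            summarization = summarization)
  if (p$percentile <= 0 || p$percentile >= 1)
    stop("percentile must be in (0, 1)", call. = FALSE)
  if (p$min_probes < 1L) stop("min_probes must be >= 1", call. = FALSE)
  if (any(c(p$max_probe_gap, p$min_peak_distance, p$window_len,
            p$promoter_bp) < 0L))
    stop("bp parameters must be non-negative", call. = FALSE)
  structure(p, class = "carpet_params")
}
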