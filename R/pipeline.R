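#' Default run configuration
#'
#' Bundles the simulation, array-caller, coverage-caller, sweep, motif and
#' enrichment settings for a full pipeline run.  The configuration
#' round-trips losslessly through YAML via \code{\link{write_config}} /
#' \code{\link{read_config}}.
#'
#' @param seed master seed; every stage derives a named substream.
#' @return a nested list of class \code{run_config}.
#' @export
default_config <- function(seed = 7L) {
  structure(list(
    seed = as.integer(seed),
    sim = unclass(sim_params(seed = seed)),
    carpet = unclass(carpet_params()),
    seq_caller = list(window_bp = 300L, step_bp = 100L, prefilter_p = 0.01,
                      analysis_p = 1e-6),
    sweep = list(cutoffs = 10^-(2:10)),
    motifs = list(width = 6L, top_n = 40L, n_motifs = 10L),
    enrich = list(n_random_lists = 3L, muscle_list_size = 40L)
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a \code{run_config}.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass_recursive(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg <- coerce_config(cfg)
  structure(cfg, class = "run_config")
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_recursive) else x
}

coerce_config <- function(cfg) {
  ref <- unclass_recursive(default_config())
  for (sect in names(ref)) {
    if (is.list(ref[[sect]])) {
      for (k in names(ref[[sect]])) {
        if (!is.null(cfg[[sect]][[k]])) {
          mode_ref <- storage.mode(ref[[sect]][[k]])
          storage.mode(cfg[[sect]][[k]]) <- mode_ref
        }
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

config_sim_params <- function(config) {
  do.call(sim_params, config$sim)
}

config_carpet_params <- function(config) {
  do.call(carpet_params, config$carpet)
}

#' Run the full cross-platform concordance pipeline
#'
#' simulate -> call (both platforms) -> annotate -> sweep -> motifs ->
#' enrich, writing BED/TSV artifacts and a machine-readable JSON summary.
#' Of the planted sites, a \code{shared_fraction} is present on both
#' platforms and the remainder is split evenly between platform-specific
#' sets, emulating partially concordant experiments.  The designated
#' "muscle" gene list contains every true target gene plus random
#' padding, standing in for an independently derived expression list.
#' Identical config and seed give an identical summary.
#'
#' @param config a \code{run_config} (see \code{\link{default_config}}).
#' @param outdir output directory; NULL to skip writing files.
#' @param verbose print one progress line per stage.
#' @return the summary list (invisibly written to
#'   \code{outdir/summary.json}).
#' @export
run_all <- function(config = default_config(), outdir = NULL,
                    verbose = FALSE) {
  say <- function(...) if (verbose) message("[chipconcord] ", ...)
  params <- config_sim_params(config)
  cparams <- config_carpet_params(config)

  say("simulate: genome ", params$n_chroms, " x ", params$chrom_len, " bp, ",
      params$n_genes, " genes, ", params$n_sites, " sites")
  genome0 <- make_genome(params)
  genes <- make_gene_models(genome0, params)
  pl <- plant_binding_sites(genome0, genes, params)
  genome <- pl$genome
  truth <- pl$truth

  split <- split_truth(truth, params$shared_fraction, config$seed)
  chip_truth <- split$chip
  seq_truth <- split$seq

  say("call-chip: ", nrow(chip_truth), " platform sites")
  tiling <- simulate_tiling_track(genome, chip_truth, params)
  norm <- quantile_normalize(tiling)
  summ <- summarize_replicates(norm, cparams$summarization)
  chip_peaks <- call_tiling_peaks(summ, cparams)
  rep_cor <- replicate_correlation(norm)

  say("call-seq: ", nrow(seq_truth), " platform sites")
  coverage <- simulate_read_coverage(genome, seq_truth, params)
  seq_default <- call_seq_peaks(coverage,
                                window_bp = config$seq_caller$window_bp,
                                step_bp = config$seq_caller$step_bp,
                                prefilter_p = config$seq_caller$prefilter_p)
  seq_peaks <- filter_peaks_by_pvalue(seq_default,
                                      config$seq_caller$analysis_p)

  say("annotate")
  chip_map <- assign_peaks_to_genes(chip_peaks, genes, cparams)
  seq_map <- assign_peaks_to_genes(seq_peaks, genes, cparams)
  profile <- tss_density_profile(chip_map, genes)
  loc <- table(factor(chip_map$location,
                      levels = c("promoter", "intragenic", "distal",
                                 "unassigned")))
  chroms <- chromosome_distribution(chip_map, genes)

  say("compare & sweep")
  pk_overlap <- overlap_peak_sets(chip_peaks, seq_peaks)
  chip_genes <- sort(unique(chip_map$gene_id[!is.na(chip_map$gene_id)]))
  seq_genes <- sort(unique(seq_map$gene_id[!is.na(seq_map$gene_id)]))
  gene_overlap <- overlap_gene_lists(chip_genes, seq_genes)
  sweep <- tryCatch(
    stringency_sweep(seq_default, chip_peaks, genes,
                     cutoffs = config$sweep$cutoffs, params = cparams),
    error = function(e) NULL)
  inflection <- if (!is.null(sweep) && nrow(sweep) >= 4L)
    find_inflection(sweep) else NULL

  say("motifs")
  motifs <- NULL
  ebox_chip <- ebox_seq <- NULL
  if (nrow(chip_peaks) > 0L) {
    seqs <- peak_sequences(genome, chip_peaks, config$motifs$top_n)
    motifs <- discover_motifs(seqs, width = config$motifs$width,
                              top_n = config$motifs$top_n,
                              n_motifs = config$motifs$n_motifs,
                              bg_sequences = genome)
    ebox_chip <- motif_coverage_fraction(genome, chip_peaks)
  }
  if (nrow(seq_peaks) > 0L)
    ebox_seq <- motif_coverage_fraction(genome, seq_peaks)

  say("enrich")
  universe <- genes$gene_id
  muscle <- muscle_gene_list(truth, genes, config$enrich$muscle_list_size,
                             config$seed)
  enrich_tab <- NULL
  if (length(chip_genes) > 0L) {
    rnd <- random_gene_lists(universe,
                             size = min(length(muscle), length(universe)),
                             n_lists = config$enrich$n_random_lists,
                             seed = config$seed)
    lists <- c(list(muscle = muscle), rnd)
    enrich_tab <- do.call(rbind, lapply(names(lists), function(nm) {
      fe <- fold_enrichment(chip_genes, lists[[nm]], universe)
      data.frame(list = nm, n = fe$n_b, overlap = fe$overlap,
                 fold = fe$fold, p = fe$p, stringsAsFactors = FALSE)
    }))
  }

  recovery <- list(chip = evaluate_calls(chip_peaks, chip_truth)[1:4],
                   seq = evaluate_calls(seq_peaks, seq_truth)[1:4])

  summary <- list(
    config = unclass_recursive(config),
    seed = config$seed,
    n_truth_sites = nrow(truth),
    platforms = list(
      chip = peak_stats(chip_peaks),
      seq = peak_stats(seq_peaks),
      seq_default = peak_stats(seq_default)),
    recovery = recovery,
    replicate_correlation = list(
      min = min(rep_cor[upper.tri(rep_cor)]),
      max = max(rep_cor[upper.tri(rep_cor)])),
    location_classes = as.list(loc / max(1L, sum(loc))),
    profile_argmax_bin = if (any(profile$density > 0))
      profile$bin_start[which.max(profile$density)] else NA_integer_,
    peak_overlap = pk_overlap[c("n_a", "n_b", "n_a_hit", "fraction_a_hit")],
    gene_overlap = list(n_chip = length(chip_genes),
                        n_seq = length(seq_genes),
                        shared = length(gene_overlap$shared),
                        pct_of_chip = gene_overlap$pct_of_a),
    sweep_inflection = if (!is.null(inflection))
      inflection[c("neglog10", "flagged")] else NULL,
    top_motifs = if (!is.null(motifs)) lapply(motifs, function(m)
      list(consensus = m$consensus, map_score = m$map_score,
           n_sites = m$n_sites, is_ebox = m$is_ebox)) else NULL,
    ebox_coverage = list(
      chip = if (!is.null(ebox_chip)) ebox_chip[c("n_in_peaks", "n_genome",
                                                  "pct")] else NULL,
      seq = if (!is.null(ebox_seq)) ebox_seq[c("n_in_peaks", "n_genome",
                                               "pct")] else NULL),
    enrichment = if (!is.null(enrich_tab))
      split(enrich_tab[-1], enrich_tab$list) else NULL,
    chromosome_distribution = chroms)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_peaks(chip_peaks, file.path(outdir, "chip_peaks.bed"),
                file.path(outdir, "chip_peaks.tsv"))
    write_peaks(seq_peaks, file.path(outdir, "seq_peaks.bed"),
                file.path(outdir, "seq_peaks.tsv"))
    write_truth(truth, file.path(outdir, "truth.bed"),
                file.path(outdir, "truth.tsv"))
    utils::write.table(profile, file.path(outdir, "tss_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(sweep))
      utils::write.table(as.data.frame(sweep),
                         file.path(outdir, "sweep.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrich_tab))
      utils::write.table(enrich_tab, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  invisible(summary)
}

peak_stats <- function(peaks) {
  list(n = nrow(peaks),
       mean_length = if (nrow(peaks) > 0L) mean(peaks$end - peaks$start)
                     else NA_real_)
}

# Deterministic platform split: shared sites appear on both platforms, the
# remainder alternates chip/seq.
split_truth <- function(truth, shared_fraction, seed) {
  n <- nrow(truth)
  if (n == 0L) return(list(chip = truth, seq = truth))
  n_shared <- round(shared_fraction * n)
  withr::with_seed(derive_seed(seed, "split"), {
    idx <- sample.int(n)
  })
  shared <- idx[seq_len(n_shared)]
  rest <- idx[-seq_len(n_shared)]
  chip_only <- rest[seq_along(rest) %% 2L == 1L]
  seq_only <- rest[seq_along(rest) %% 2L == 0L]
  list(chip = truth[sort(c(shared, chip_only)), , drop = FALSE],
       seq = truth[sort(c(shared, seq_only)), , drop = FALSE])
}

# "Muscle" truth list: every planted target gene plus random padding.
muscle_gene_list <- function(truth, genes, size, seed) {
  core <- unique(truth$target_gene)
  pool <- setdiff(genes$gene_id, core)
  extra <- max(0L, min(size - length(core), length(pool)))
  withr::with_seed(derive_seed(seed, "muscle"), {
    pad <- if (extra > 0L) sample(pool, extra) else character(0)
  })
  sort(c(core, pad))
}

#' Ingest an external peak table
#'
#' Reads BED (0-based half-open) or a TSV with declared coordinate columns
#' in either 0-based half-open or 1-based inclusive dialect, returning the
#' package's peak data frame so counts and mean interval lengths are
#' directly computable.
#'
#' @param path input file.
#' @param dialect \code{"bed"} or \code{"tsv"}.
#' @param chrom_col,start_col,end_col,score_col,p_col column names (TSV
#'   dialect); score and p columns are optional.
#' @param one_based TRUE when TSV coordinates are 1-based inclusive.
#' @param platform provenance label attached to the peaks.
#' @return a peak data frame.
#' @export
ingest_peak_table <- function(path, dialect = c("bed", "tsv"),
                              chrom_col = "chrom", start_col = "start",
                              end_col = "end", score_col = NULL,
                              p_col = NULL, one_based = FALSE,
                              platform = "external") {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    peaks <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
    peaks$score <- if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
    peaks$neg_log10_p <- NA_real_
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c(chrom_col, start_col, end_col)
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols) > 0L)
      stop("missing column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
    start <- as.integer(tab[[start_col]])
    end <- as.integer(tab[[end_col]])
    if (one_based) start <- start - 1L
    peaks <- data.frame(chrom = as.character(tab[[chrom_col]]),
                        start = start, end = end, stringsAsFactors = FALSE)
    peaks$score <- if (!is.null(score_col)) as.numeric(tab[[score_col]])
                   else NA_real_
    peaks$neg_log10_p <- if (!is.null(p_col))
      -log10(as.numeric(tab[[p_col]])) else NA_real_
  }
  bad <- which(!is.finite(peaks$start) | !is.finite(peaks$end) |
                 peaks$end <= peaks$start)
  if (length(bad) > 0L)
    stop("malformed interval(s) at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  peaks$n_probes <- NA_integer_
  if (all(is.na(peaks$score))) peaks$score <- 0
  finish_peaks(peaks, platform)
}
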