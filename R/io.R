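# Fixture readers and writers.  FASTA and GFF3 go through Biostrings and
# rtracklayer; bedGraph and the truth/peak tables are written directly with
# full ("%.17g") float precision so that write -> read round-trips are exact
# at the byte level for the doubles involved.

#' Write all synthetic fixtures for a simulated study
#'
#' Emits genome FASTA (60-column), gene models GFF3 (1-based inclusive),
#' one bedGraph per array replicate, a run-length-encoded coverage
#' bedGraph, a truth BED6 and a full-precision truth TSV.  All interval
#' files are 0-based half-open except the GFF3.
#'
#' @param study list from \code{\link{simulate_study}} (or the same named
#'   elements assembled by hand).
#' @param outdir output directory, created if missing.
#' @param seed optional seed echoed in track headers.
#' @return named character vector of the files written.
#' @export
write_fixtures <- function(study, outdir, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             genes = file.path(outdir, "genes.gff3"),
             truth_bed = file.path(outdir, "truth.bed"),
             truth_tsv = file.path(outdir, "truth.tsv"),
             coverage = file.path(outdir, "coverage.bedGraph"))
  write_genome_fasta(study$genome, paths["genome"])
  write_gene_models_gff3(study$genes, paths["genes"])
  write_truth(study$truth, paths["truth_bed"], paths["truth_tsv"])
  write_coverage_bedgraph(study$coverage, paths["coverage"], seed = seed)
  reps <- character(0)
  if (!is.null(study$tiling)) {
    nr <- ncol(study$tiling$intensity)
    reps <- file.path(outdir, sprintf("probes_rep%d.bedGraph", seq_len(nr)))
    write_probe_track(study$tiling, reps, seed = seed)
    names(reps) <- sprintf("probes_rep%d", seq_len(nr))
  }
  c(paths, reps)
}

#' @rdname write_fixtures
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write gene models as GFF3
#'
#' The writer requires the TSS at the span edge (start on +, end - 1 on -),
#' which holds for transcript-span gene models; this is what makes the
#' GFF3 round-trip lossless.
#'
#' @param genes annotation data frame (see \code{\link{make_gene_models}}).
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  edge <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  if (nrow(genes) > 0L && any(edge != genes$tss))
    stop("GFF3 writer requires the TSS at the span edge", call. = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = intervals_to_iranges(genes$start, genes$end),
    strand = genes$strand)
  gr$type <- rep("gene", nrow(genes))
  gr$ID <- genes$gene_id
  gr$Name <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 file with gene features.
#' @return annotation data frame with a reconstructed \code{tss} column.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  out <- data.frame(gene_id = as.character(gr$ID),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    strand = strand,
                    tss = ifelse(strand == "+", start0, end0 - 1L),
                    start = start0, end = end0, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

bedgraph_header <- function(name, seed) {
  h <- sprintf("track type=bedGraph name=\"%s\"", name)
  if (!is.null(seed)) h <- c(sprintf("# seed=%d", as.integer(seed)), h)
  h
}

write_bedgraph_lines <- function(chrom, start, end, value, path, name,
                                 seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(bedgraph_header(name, seed), con)
  writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, start, end, value), con)
  invisible(path)
}

read_bedgraph_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             start = as.integer(vapply(parts, `[`, "", 2L)),
             end = as.integer(vapply(parts, `[`, "", 3L)),
             value = as.numeric(vapply(parts, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Write a replicate probe track as one bedGraph per replicate
#' @param track a \code{\link{probe_track}}.
#' @param paths character vector, one path per replicate.
#' @param seed optional seed echoed in headers.
#' @export
write_probe_track <- function(track, paths, seed = NULL) {
  stopifnot(length(paths) == ncol(track$intensity))
  for (r in seq_along(paths)) {
    write_bedgraph_lines(track$probes$chrom, track$probes$start,
                         track$probes$start + track$probe_len,
                         track$intensity[, r], paths[r],
                         name = sprintf("probes_rep%d", r), seed = seed)
  }
  invisible(paths)
}

#' Read replicate probe bedGraphs back into a probe track
#' @param paths one bedGraph per replicate, identical probe coordinates.
#' @return a \code{\link{probe_track}}.
#' @export
read_probe_track <- function(paths) {
  tabs <- lapply(paths, read_bedgraph_lines)
  ref <- tabs[[1]]
  for (t in tabs[-1]) {
    if (!identical(t$chrom, ref$chrom) || !identical(t$start, ref$start))
      stop("replicate bedGraphs have mismatched probe coordinates",
           call. = FALSE)
  }
  probe_len <- unique(ref$end - ref$start)
  if (length(probe_len) != 1L)
    stop("probe bedGraph has non-uniform probe lengths", call. = FALSE)
  intensity <- do.call(cbind, lapply(tabs, `[[`, "value"))
  colnames(intensity) <- paste0("rep", seq_along(paths))
  probe_track(data.frame(chrom = ref$chrom, start = ref$start,
                         stringsAsFactors = FALSE),
              intensity, probe_len)
}

#' Write a coverage track as run-length-encoded bedGraph
#' @param coverage a coverage track (see \code{\link{simulate_read_coverage}}).
#' @param path output file.
#' @param seed optional seed echoed in the header.
#' @export
write_coverage_bedgraph <- function(coverage, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(bedgraph_header("coverage", seed), con)
  for (cn in names(coverage$counts)) {
    r <- rle(coverage$counts[[cn]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", cn, start, end, r$values), con)
  }
  invisible(path)
}

#' Read a coverage bedGraph back into a coverage track
#' @param path bedGraph file with integer counts.
#' @return a coverage track.
#' @export
read_coverage_bedgraph <- function(path) {
  tab <- read_bedgraph_lines(path)
  counts <- lapply(split(tab, tab$chrom), function(d) {
    d <- d[order(d$start), ]
    if (d$start[1] != 0L || any(d$start[-1] != d$end[-nrow(d)]))
      stop("coverage bedGraph has gaps; expected full-chromosome cover",
           call. = FALSE)
    as.integer(rep(d$value, d$end - d$start))
  })
  structure(list(counts = counts), class = "coverage_track")
}

#' Write and read planted truth sites
#'
#' The BED6 (name = target gene, score = E-box count, strand ".") is the
#' interchange form; the TSV carries every truth column at full precision
#' and is the exact round-trip carrier.
#'
#' @param truth truth data frame.
#' @param bed_path,tsv_path output files (either may be NULL to skip).
#' @export
write_truth <- function(truth, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", truth$chrom, truth$start,
                     truth$end, truth$target_gene, truth$n_eboxes)
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(truth, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(truth)
}

#' @rdname write_truth
#' @param path truth TSV written by \code{write_truth}.
#' @export
read_truth_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(chrom = "character", start = "integer",
                                   end = "integer",
                                   offset_from_tss = "integer",
                                   n_eboxes = "integer",
                                   target_gene = "character",
                                   enrichment = "numeric"))
}

#' Write a peak set as BED6 plus a full TSV
#'
#' BED name is the peak rank and the BED score is
#' \code{min(1000, round(100 * score))}.
#'
#' @param peaks peak data frame (see \code{\link{call_tiling_peaks}}).
#' @param bed_path,tsv_path output files (either may be NULL to skip).
#' @export
write_peaks <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    lines <- sprintf("%s\t%d\t%d\t%d\t%d\t.", peaks$chrom, peaks$start,
                     peaks$end, peaks$rank,
                     pmin(1000L, as.integer(round(100 * peaks$score))))
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(peaks, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(peaks)
}
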