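#' Assign peaks to the nearest TSS and classify their location
#'
#' Each peak is represented by its integer midpoint
#' (\code{floor((start + end) / 2)}) and assigned to the gene minimizing
#' the absolute strand-aware TSS offset (negative = upstream: on + strand
#' genes the offset is \code{midpoint - tss}, on - strand genes
#' \code{tss - midpoint}).  Equidistant ties go to the lexicographically
#' smaller gene id.  Location classes partition the assigned peaks:
#' \code{promoter} if the offset lies in \code{[-promoter_bp, 0)},
#' \code{intragenic} if the midpoint falls inside the assigned gene span,
#' \code{distal} otherwise.  Peaks farther than 50 kb from every TSS are
#' left unassigned (NA gene, class \code{unassigned}).
#'
#' @param peaks peak data frame.
#' @param annotation gene models data frame.
#' @param params a \code{\link{carpet_params}} (promoter definition).
#' @param max_tss_distance peaks beyond this distance from every TSS stay
#'   unassigned.
#' @return the peak data frame with added columns \code{midpoint},
#'   \code{gene_id}, \code{tss_offset}, \code{location}.
#' @export
assign_peaks_to_genes <- function(peaks, annotation,
                                  params = carpet_params(),
                                  max_tss_distance = 50000L) {
  out <- peaks
  n <- nrow(peaks)
  out$midpoint <- (peaks$start + peaks$end) %/% 2L
  out$gene_id <- rep(NA_character_, n)
  out$tss_offset <- rep(NA_integer_, n)
  out$location <- rep("unassigned", n)
  if (nrow(peaks) == 0L) return(out)
  if (nrow(annotation) == 0L) {
    warning("empty annotation: all peaks unassigned")
    return(out)
  }
  for (i in seq_len(nrow(out))) {
    g <- annotation[annotation$chrom == out$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    offs <- ifelse(g$strand == "+", out$midpoint[i] - g$tss,
                   g$tss - out$midpoint[i])
    best <- which(abs(offs) == min(abs(offs)))
    if (length(best) > 1L) best <- best[order(g$gene_id[best])][1]
    if (abs(offs[best]) > max_tss_distance) next
    out$gene_id[i] <- g$gene_id[best]
    out$tss_offset[i] <- as.integer(offs[best])
    out$location[i] <-
      if (offs[best] >= -params$promoter_bp && offs[best] < 0L) "promoter"
      else if (out$midpoint[i] >= g$start[best] &&
               out$midpoint[i] < g$end[best]) "intragenic"
      else "distal"
  }
  out
}

#' TSS-relative peak density profile
#'
#' Peak midpoints with assigned offsets inside -2000..+6000 bp are counted
#' in 200 bp bins and divided by the number of genes, so summing the
#' profile times the gene count returns the number of in-window peaks.
#' The conventional 1e-4 scaling is presentation-only and not applied.
#'
#' @param peaks assigned peaks from \code{\link{assign_peaks_to_genes}}.
#' @param annotation gene models data frame (defines the gene count).
#' @param window \code{c(upstream, downstream)} window edges in bp.
#' @param bin_bp bin width in bp.
#' @return data frame with \code{bin_start}, \code{bin_end} (bp relative to
#'   the TSS) and \code{density}.
#' @export
tss_density_profile <- function(peaks, annotation,
                                window = c(-2000L, 6000L), bin_bp = 200L) {
  edges <- seq.int(window[1], window[2], by = bin_bp)
  nb <- length(edges) - 1L
  counts <- integer(nb)
  offs <- peaks$tss_offset
  offs <- offs[!is.na(offs) & offs >= window[1] & offs < window[2]]
  if (length(offs) > 0L) {
    idx <- findInterval(offs, edges, rightmost.closed = FALSE)
    tab <- tabulate(idx, nbins = nb)
    counts <- tab
  }
  n_genes <- max(1L, nrow(annotation))
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             density = counts / n_genes)
}

#' Overlap two peak sets
#'
#' A peak "hits" if it overlaps at least 1 bp of any peak in the other
#' set; counts are reported symmetrically.
#'
#' @param a,b peak data frames.
#' @return list with \code{n_a}, \code{n_b}, \code{n_a_hit},
#'   \code{n_b_hit}, \code{fraction_a_hit}, \code{fraction_b_hit}.
#' @export
overlap_peak_sets <- function(a, b) {
  a_hit <- interval_hits(a, b)
  b_hit <- interval_hits(b, a)
  list(n_a = nrow(a), n_b = nrow(b),
       n_a_hit = sum(a_hit), n_b_hit = sum(b_hit),
       fraction_a_hit = if (nrow(a) > 0L) mean(a_hit) else NA_real_,
       fraction_b_hit = if (nrow(b) > 0L) mean(b_hit) else NA_real_)
}

#' Overlap two gene lists
#'
#' Ids are case-normalized before intersection; duplicates are removed
#' with a warning.
#'
#' @param a,b character vectors of gene ids.
#' @return list with \code{shared} (sorted ids), \code{pct_of_a},
#'   \code{pct_of_b} (percentages, not rounded).
#' @export
overlap_gene_lists <- function(a, b) {
  norm <- function(x, lab) {
    x <- tolower(x)
    if (anyDuplicated(x)) {
      warning("duplicate ids in ", lab, " deduplicated")
      x <- unique(x)
    }
    x
  }
  a <- norm(a, "list a"); b <- norm(b, "list b")
  shared <- sort(intersect(a, b))
  list(shared = shared,
       pct_of_a = if (length(a) > 0L) 100 * length(shared) / length(a)
                  else NA_real_,
       pct_of_b = if (length(b) > 0L) 100 * length(shared) / length(b)
                  else NA_real_)
}

#' Per-chromosome fraction of genes with at least one assigned peak
#'
#' @param assigned peaks from \code{\link{assign_peaks_to_genes}}.
#' @param annotation gene models data frame.
#' @return data frame with \code{chrom}, \code{n_genes}, \code{n_hit},
#'   \code{fraction} (NA for chromosomes with no genes).
#' @export
chromosome_distribution <- function(assigned, annotation) {
  chroms <- sort(unique(annotation$chrom))
  hit_genes <- unique(assigned$gene_id[!is.na(assigned$gene_id)])
  rows <- lapply(chroms, function(cn) {
    g <- annotation$gene_id[annotation$chrom == cn]
    data.frame(chrom = cn, n_genes = length(g),
               n_hit = sum(g %in% hit_genes),
               fraction = if (length(g) > 0L) mean(g %in% hit_genes)
                          else NA_real_)
  })
  do.call(rbind, rows)
}
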