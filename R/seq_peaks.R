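#' Call peaks on a read-coverage track with a Poisson window test
#'
#' Sliding windows of \code{window_bp} at \code{step_bp} are tested with a
#' one-sided Poisson tail p-value of the window's total count against
#' \code{bg_lambda * window_bp} (the background rate defaults to the
#' genome-wide mean).  Windows passing a lenient pre-filter
#' (p <= \code{prefilter_p}) are merged when overlapping or adjacent; the
#' peak p-value is the minimum member-window p Bonferroni-adjusted by the
#' member-window count (conservative and monotone under window
#' refinement), and the score is the mean fold coverage over background.
#'
#' @param track a coverage track (see \code{\link{simulate_read_coverage}}).
#' @param window_bp window length in bp.
#' @param step_bp step between window starts in bp.
#' @param bg_lambda background per-base rate; default genome-wide mean.
#' @param prefilter_p lenient window p-value used to seed peaks; this is
#'   also the caller's "default threshold" anchoring stringency sweeps.
#' @return a peak data frame as in \code{\link{call_tiling_peaks}} plus a
#'   \code{p} column, with platform "seq".
#' @export
call_seq_peaks <- function(track, window_bp = 300L, step_bp = 100L,
                           bg_lambda = NULL, prefilter_p = 0.01) {
  stopifnot(inherits(track, "coverage_track"))
  if (length(track$counts) == 0L || all(lengths(track$counts) == 0L))
    stop("empty coverage track", call. = FALSE)
  window_bp <- as.integer(window_bp); step_bp <- as.integer(step_bp)
  if (!(window_bp >= step_bp && step_bp >= 1L))
    stop("need window_bp >= step_bp >= 1", call. = FALSE)
  if (is.null(bg_lambda))
    bg_lambda <- mean(unlist(track$counts, use.names = FALSE))
  if (bg_lambda <= 0) stop("zero background rate", call. = FALSE)

  pieces <- lapply(names(track$counts), function(cn) {
    x <- track$counts[[cn]]
    len <- length(x)
    if (len < window_bp) return(NULL)
    starts <- seq.int(0L, len - window_bp, by = step_bp)
    cs <- c(0, cumsum(as.numeric(x)))
    tot <- cs[starts + window_bp + 1L] - cs[starts + 1L]
    logp <- stats::ppois(tot - 1, bg_lambda * window_bp,
                         lower.tail = FALSE, log.p = TRUE)
    sig <- which(logp <= log(prefilter_p))
    if (length(sig) == 0L) return(NULL)
    gap_break <- starts[sig[-1]] > starts[sig[-length(sig)]] + window_bp
    grp <- cumsum(c(1L, as.integer(gap_break)))
    out <- lapply(split(sig, grp), function(members) {
      s <- starts[members[1]]
      e <- min(starts[members[length(members)]] + window_bp, len)
      k <- length(members)
      lp <- min(logp[members]) + log(k)     # Bonferroni over member windows
      lp <- min(lp, 0)
      cnt <- cs[e + 1L] - cs[s + 1L]
      data.frame(chrom = cn, start = s, end = e,
                 score = (cnt / (e - s)) / bg_lambda,
                 neg_log10_p = -lp / log(10), p = exp(lp),
                 n_probes = NA_integer_, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  peaks <- do.call(rbind, pieces)
  if (is.null(peaks)) {
    peaks <- empty_peaks()
    peaks$p <- numeric(0)
  }
  finish_peaks(peaks, "seq")
}

#' Filter a peak set by p-value and recompute ranks
#'
#' @param peaks peak data frame carrying a \code{p} column (or
#'   \code{neg_log10_p}, used as fallback).
#' @param cutoff p-value cutoff in (0, 1].
#' @return the filtered, re-ranked peak data frame.
#' @export
filter_peaks_by_pvalue <- function(peaks, cutoff) {
  if (!(is.numeric(cutoff) && length(cutoff) == 1L &&
        cutoff > 0 && cutoff <= 1))
    stop("cutoff must be a p-value in (0, 1]", call. = FALSE)
  p <- if ("p" %in% names(peaks)) peaks$p else 10^-peaks$neg_log10_p
  keep <- peaks[p <= cutoff, , drop = FALSE]
  platform <- if (nrow(keep) > 0L) keep$platform[1] else
    if (nrow(peaks) > 0L) peaks$platform[1] else "seq"
  keep$rank <- NULL; keep$platform <- NULL
  finish_peaks(keep, platform)
}

new_sweep_curve <- function(df) {
  stopifnot(all(c("cutoff", "normalized_peaks") %in% names(df)))
  if (is.unsorted(rev(df$cutoff), strictly = TRUE))
    stop("cutoffs must be strictly decreasing (increasing stringency)",
         call. = FALSE)
  structure(df, class = c("sweep_curve", "data.frame"))
}

#' Sweep peak-call stringency and track concordance with a reference
#'
#' At each cutoff the peak set is filtered, annotated to genes, and
#' compared with the reference peak set (1 bp-or-more interval overlap) and
#' the reference gene list; overlaps are normalized as a percentage of the
#' overlap at the first (default, most lenient) cutoff.
#'
#' @param seq_peaks peak data frame with p-values (the swept set).
#' @param ref_peaks reference peak data frame.
#' @param annotation gene models used for peak-to-gene assignment.
#' @param cutoffs p-value cutoffs ordered lenient to stringent; the first
#'   is the normalization anchor.
#' @param params a \code{\link{carpet_params}} (promoter definition for the
#'   annotation step).
#' @return a \code{sweep_curve} data frame with columns \code{cutoff},
#'   \code{n_peaks}, \code{n_genes}, \code{overlap_peaks},
#'   \code{overlap_genes}, \code{normalized_peaks}, \code{normalized_genes}.
#' @export
stringency_sweep <- function(seq_peaks, ref_peaks, annotation,
                             cutoffs = 10^-(2:10),
                             params = carpet_params()) {
  ref_genes <- assigned_gene_ids(ref_peaks, annotation, params)
  rows <- lapply(cutoffs, function(cf) {
    at <- filter_peaks_by_pvalue(seq_peaks, cf)
    genes <- assigned_gene_ids(at, annotation, params)
    data.frame(cutoff = cf, n_peaks = nrow(at), n_genes = length(genes),
               overlap_peaks = sum(interval_hits(ref_peaks, at)),
               overlap_genes = length(intersect(ref_genes, genes)))
  })
  out <- do.call(rbind, rows)
  if (out$overlap_peaks[1] == 0L || out$overlap_genes[1] == 0L)
    stop("zero overlap at the default cutoff: normalization undefined",
         call. = FALSE)
  out$normalized_peaks <- 100 * out$overlap_peaks / out$overlap_peaks[1]
  out$normalized_genes <- 100 * out$overlap_genes / out$overlap_genes[1]
  new_sweep_curve(out)
}

assigned_gene_ids <- function(peaks, annotation, params) {
  if (nrow(peaks) == 0L) return(character(0))
  map <- assign_peaks_to_genes(peaks, annotation, params)
  sort(unique(map$gene_id[!is.na(map$gene_id)]))
}

#' Locate the stringency at which a concordance curve becomes linear
#'
#' Works on x = -log10(cutoff) versus y = normalized overlap.  The discrete
#' second difference of the triple starting at x_j is
#' \code{y[j+2] - 2 y[j+1] + y[j]}; the chosen stringency is the smallest
#' interior x* such that every triple starting at or after x* has second
#' difference of magnitude at most \code{tol} (default 5\% of the range of
#' y, making the criterion invariant to affine rescaling of y).  If no x*
#' qualifies the last cutoff is returned with \code{flagged = TRUE}.
#'
#' @param curve a \code{sweep_curve} with at least 4 cutoffs.
#' @param tol absolute second-difference tolerance; NULL for range-relative
#'   default.
#' @param which use the \code{"peaks"} or \code{"genes"} normalized column.
#' @return list with \code{cutoff}, \code{neglog10}, \code{flagged}.
#' @export
find_inflection <- function(curve, tol = NULL, which = c("peaks", "genes")) {
  which <- match.arg(which)
  y <- curve[[paste0("normalized_", which)]]
  inflection_point(-log10(curve$cutoff), y, tol)
}

#' @rdname find_inflection
#' @param x increasing stringencies (-log10 cutoff).
#' @param y concordance values at each x.
#' @export
inflection_point <- function(x, y, tol = NULL) {
  n <- length(x)
  if (n < 4L) stop("need at least 4 cutoffs", call. = FALSE)
  stopifnot(length(y) == n, !is.unsorted(x, strictly = TRUE))
  if (is.null(tol)) tol <- 0.05 * diff(range(y))
  d2 <- abs(y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)])  # triple starting at j
  ok_from <- rev(cumprod(rev(as.integer(d2 <= tol)))) == 1L
  candidates <- which(ok_from)
  candidates <- candidates[candidates >= 2L]   # interior points only
  if (length(candidates) == 0L) {
    return(list(cutoff = 10^-x[n], neglog10 = x[n], flagged = TRUE))
  }
  j <- candidates[1]
  list(cutoff = 10^-x[j], neglog10 = x[j], flagged = FALSE)
}
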