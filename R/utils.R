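# Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a master seed
#'
#' All stochastic stages draw from their own named substream so that, e.g.,
#' changing motif settings does not perturb the simulation draws.  The
#' derived seed stays below 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed master integer seed.
#' @param tag short stage name (e.g. "genome", "sites").
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Intervals are 0-based half-open [start, end) throughout the package;
# GRanges/IRanges (1-based inclusive) are used only at computation and I/O
# boundaries via these two converters.
intervals_to_iranges <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = intervals_to_iranges(peaks$start, peaks$end)
  )
}

# 1 bp-or-more overlap hits of set a against set b (both 0-based half-open
# data frames with chrom/start/end).  Returns a logical flag per row of a.
interval_hits <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  ga <- peaks_to_granges(a)
  gb <- peaks_to_granges(b)
  GenomicRanges::countOverlaps(ga, gb, minoverlap = 1L) > 0L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_dna <- function(s, what = "sequence") {
  if (grepl("[^ACGT]", s)) {
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  }
  invisible(TRUE)
}
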