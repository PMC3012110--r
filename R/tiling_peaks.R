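#' Quantile-normalize replicate probe intensities
#'
#' After normalization each replicate's sorted values equal the
#' across-replicate mean order statistics while per-replicate ranks are
#' preserved (delegated to \code{limma::normalizeQuantiles}).  A
#' single-replicate track is returned unchanged with a warning.
#'
#' @param track a \code{\link{probe_track}}.
#' @return the normalized \code{probe_track}.
#' @export
quantile_normalize <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  if (ncol(track$intensity) < 2L) {
    warning("single replicate: quantile normalization is the identity")
    return(track)
  }
  norm <- limma::normalizeQuantiles(track$intensity, ties = TRUE)
  colnames(norm) <- colnames(track$intensity)
  probe_track(track$probes, norm, track$probe_len)
}

#' Summarize replicates into one value per probe
#'
#' \code{mean} is the arithmetic mean across replicates; \code{biweight} is
#' a one-step Tukey biweight location estimate started from the median with
#' tuning constant c = 5 and an un-scaled MAD (median absolute deviation
#' from the median) plus a small epsilon, so outlying replicates are
#' down-weighted even when the MAD is zero.  With all replicate values
#' identical both methods return that value.
#'
#' @param track a \code{\link{probe_track}}.
#' @param method \code{"biweight"} or \code{"mean"}.
#' @return a \code{summary_track}: list with \code{probes}, \code{value}
#'   (one numeric per probe) and \code{probe_len}.
#' @export
summarize_replicates <- function(track, method = c("biweight", "mean")) {
  stopifnot(inherits(track, "probe_track"))
  method <- match.arg(method)
  x <- track$intensity
  value <- if (method == "mean") rowMeans(x)
           else apply(x, 1L, tukey_biweight)
  structure(list(probes = track$probes, value = as.numeric(value),
                 probe_len = track$probe_len),
            class = "summary_track")
}

#' One-step Tukey biweight location estimate
#'
#' @param x numeric vector.
#' @param c tuning constant (default 5).
#' @param epsilon floor added to the MAD scale.
#' @return the biweight location estimate.
#' @export
tukey_biweight <- function(x, c = 5, epsilon = 1e-4) {
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  u <- (x - m) / (c * s + epsilon)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(mean(x))   # unreachable (median has weight 1)
  sum(w * x) / sum(w)
}

#' Pairwise Pearson correlation between replicates
#'
#' @param track a \code{\link{probe_track}} with at least 2 replicates and
#'   3 probes.
#' @return symmetric correlation matrix with unit diagonal; zero-variance
#'   replicates produce NA entries and a warning.
#' @export
replicate_correlation <- function(track) {
  stopifnot(inherits(track, "probe_track"))
  if (ncol(track$intensity) < 2L || nrow(track$intensity) < 3L)
    stop("need at least 2 replicates and 3 probes", call. = FALSE)
  sds <- apply(track$intensity, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance replicate: correlation undefined (NA)")
  suppressWarnings(stats::cor(track$intensity))
}

#' Call peaks on a summarized tiling-array track
#'
#' The caller follows the tiling-array (CARPET-parameter) recipe:
#' \enumerate{
#'   \item candidate probes are those with summarized value at or above the
#'     \code{percentile} quantile of all probe values;
#'   \item candidates are grouped into runs where the gap between the end
#'     of one candidate probe and the start of the next is at most
#'     \code{max_probe_gap} bp;
#'   \item runs with at least \code{min_probes} probes span first-probe
#'     start to last-probe end;
#'   \item peaks on the same chromosome closer than
#'     \code{min_peak_distance} bp are merged;
#'   \item each peak gets a one-sided z-test of its member-probe mean
#'     against a robust genome-wide background (median location, MAD
#'     scale, standard error scaled by sqrt(n)); probes are taken from a
#'     window of at least \code{window_len} bp centered on the peak, so
#'     the window only pads peaks shorter than it;
#'   \item peaks with \code{-log10 p >= neg_log_p_cutoff} are retained.
#' }
#' The peak score is the mean summarized intensity of the probes inside
#' the peak interval, reported separately from the p-value; ranks are
#' 1-based by descending score with coordinate tie-break.
#'
#' @param summary a \code{summary_track} from
#'   \code{\link{summarize_replicates}}.
#' @param params a \code{\link{carpet_params}} object.
#' @return a peak data frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{score}, \code{neg_log10_p},
#'   \code{n_probes}, \code{rank}, \code{platform} ("chip").
#' @export
call_tiling_peaks <- function(summary, params = carpet_params()) {
  stopifnot(inherits(summary, "summary_track"),
            inherits(params, "carpet_params"))
  vals <- summary$value
  if (length(vals) < 10L)
    stop("too few probes to estimate the background", call. = FALSE)
  thr <- stats::quantile(vals, params$percentile, names = FALSE)
  bg_med <- stats::median(vals)
  bg_sd <- stats::mad(vals)

  plen <- summary$probe_len
  pieces <- lapply(unique(summary$probes$chrom), function(cn) {
    on_chrom <- summary$probes$chrom == cn
    starts <- summary$probes$start[on_chrom]
    v <- vals[on_chrom]
    cand <- which(v >= thr)
    if (length(cand) == 0L) return(NULL)
    gaps <- starts[cand[-1]] - (starts[cand[-length(cand)]] + plen)
    run_id <- cumsum(c(1L, as.integer(gaps > params$max_probe_gap)))
    runs <- split(cand, run_id)
    runs <- runs[vapply(runs, length, 1L) >= params$min_probes]
    if (length(runs) == 0L) return(NULL)
    iv <- data.frame(
      start = vapply(runs, function(r) starts[r[1]], 1L),
      end = vapply(runs, function(r) starts[r[length(r)]] + plen, 1L))
    iv <- iv[order(iv$start), , drop = FALSE]
    iv <- merge_close_intervals(iv, params$min_peak_distance)

    out <- lapply(seq_len(nrow(iv)), function(i) {
      s <- iv$start[i]; e <- iv$end[i]
      member <- which(starts + plen > s & starts < e)
      win <- max(e - s, params$window_len)
      mid <- (s + e) %/% 2L
      ws <- mid - win %/% 2L; we <- ws + win
      tested <- which(starts + plen > ws & starts < we)
      n <- length(tested)
      m <- mean(v[tested])
      if (bg_sd > 0) {
        z <- (m - bg_med) / (bg_sd / sqrt(n))
        nlp <- -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
      } else {
        nlp <- if (m > bg_med) Inf else 0
      }
      data.frame(chrom = cn, start = s, end = e,
                 score = mean(v[member]), neg_log10_p = nlp,
                 n_probes = length(member), stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  peaks <- do.call(rbind, pieces)
  if (is.null(peaks)) peaks <- empty_peaks()
  peaks <- peaks[peaks$neg_log10_p >= params$neg_log_p_cutoff, , drop = FALSE]
  finish_peaks(peaks, "chip")
}

empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             score = numeric(0), neg_log10_p = numeric(0),
             n_probes = integer(0), stringsAsFactors = FALSE)
}

# Merge intervals on one chromosome whose gap is < min_dist (sorted input).
merge_close_intervals <- function(iv, min_dist) {
  if (nrow(iv) <= 1L) return(iv)
  out_s <- iv$start[1]; out_e <- iv$end[1]
  res <- list()
  for (i in 2:nrow(iv)) {
    if (iv$start[i] - out_e[length(out_e)] < min_dist) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[i])
    } else {
      out_s <- c(out_s, iv$start[i]); out_e <- c(out_e, iv$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

# Rank by descending score (ties: leftmost coordinate), attach platform.
finish_peaks <- function(peaks, platform) {
  if (nrow(peaks) == 0L) {
    peaks$rank <- integer(0)
    peaks$platform <- character(0)
    rownames(peaks) <- NULL
    return(peaks)
  }
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks$rank[ord] <- seq_len(nrow(peaks))
  peaks$platform <- platform
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Score called peaks against the planted truth
#'
#' A truth site counts as recovered if any peak overlaps it by at least
#' 1 bp; a peak is a false call if it overlaps no truth site.  With an
#' empty peak set the FDR is reported as 0.
#'
#' @param peaks peak data frame.
#' @param truth truth-site data frame.
#' @return list with \code{sensitivity}, \code{fdr}, \code{n_peaks},
#'   \code{n_truth}, and logical vectors \code{site_hit} and
#'   \code{peak_true}.
#' @export
evaluate_calls <- function(peaks, truth) {
  site_hit <- interval_hits(truth, peaks)
  peak_true <- interval_hits(peaks, truth)
  list(sensitivity = if (nrow(truth) > 0L) mean(site_hit) else NA_real_,
       fdr = if (nrow(peaks) > 0L) mean(!peak_true) else 0,
       n_peaks = nrow(peaks), n_truth = nrow(truth),
       site_hit = site_hit, peak_true = peak_true)
}
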