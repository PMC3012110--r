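# Degenerate-pattern scanning and MDscan-style motif discovery.
#
# Sequence coordinates returned by the scanner are 0-based, matching the
# package-wide half-open interval convention.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_check <- function(pattern) {
  letters <- strsplit(pattern, "")[[1]]
  if (length(letters) < 2L)
    stop("pattern width must be at least 2", call. = FALSE)
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad) > 0L)
    stop("invalid IUPAC letter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  letters
}

iupac_revcomp <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[iupac_check(pattern)]), collapse = "")
}

#' Scan a sequence for a degenerate IUPAC pattern
#'
#' Returns every (overlap-permissive) 0-based start position where the
#' window matches the pattern.  A single-strand scan suffices when the
#' pattern class is its own reverse complement (as for the E-box CANNTG);
#' otherwise both strands are scanned and positions deduplicated.  Strand
#' handling can be forced with \code{both_strands}.
#'
#' @param seq DNA string over A/C/G/T.
#' @param pattern IUPAC pattern (default the E-box, \code{"CANNTG"}).
#' @param both_strands NULL to decide from pattern palindromy, or a
#'   logical.
#' @return sorted integer vector of 0-based match starts.
#' @export
#' @examples
#' scan_pattern("CACCTGCAGGTG", "CANNTG")
scan_pattern <- function(seq, pattern = "CANNTG", both_strands = NULL) {
  iupac_check(pattern)
  check_dna(seq)
  if (is.null(both_strands)) both_strands <- iupac_revcomp(pattern) != pattern
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  subject <- Biostrings::DNAString(seq)
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(pattern), subject, fixed = FALSE)) - 1L
  if (both_strands) {
    rc <- iupac_revcomp(pattern)
    hits2 <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(rc), subject, fixed = FALSE)) - 1L
    hits <- union(hits, hits2)
  }
  sort(as.integer(hits))
}

#' Fraction of genome-wide pattern matches covered by peaks
#'
#' Counts every pattern match in the genome and the subset whose start
#' position lies inside a peak interval.
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks peak data frame (0-based half-open intervals).
#' @param pattern IUPAC pattern.
#' @return a \code{coverage_fraction} result (see
#'   \code{\link{coverage_fraction}}); \code{fraction} is NA when the
#'   genome has no matches.
#' @export
motif_coverage_fraction <- function(genome, peaks, pattern = "CANNTG") {
  n_genome <- 0L
  n_in_peaks <- 0L
  for (cn in names(genome)) {
    starts <- scan_pattern(genome[[cn]], pattern)
    n_genome <- n_genome + length(starts)
    pk <- peaks[peaks$chrom == cn, , drop = FALSE]
    if (nrow(pk) > 0L && length(starts) > 0L) {
      inside <- IRanges::countOverlaps(
        IRanges::IRanges(start = starts + 1L, width = 1L),
        intervals_to_iranges(pk$start, pk$end)) > 0L
      n_in_peaks <- n_in_peaks + sum(inside)
    }
  }
  coverage_fraction(n_in_peaks, n_genome)
}

#' Coverage fraction from match counts
#'
#' The arithmetic core of \code{\link{motif_coverage_fraction}}, exposed so
#' tabulated match counts (e.g. from a published census) can be converted
#' to the same result object.
#'
#' @param n_in_peaks matches inside peaks.
#' @param n_genome matches genome-wide.
#' @return list with \code{n_in_peaks}, \code{n_genome}, \code{fraction}
#'   and \code{pct} (percentage rounded to one decimal).
#' @export
coverage_fraction <- function(n_in_peaks, n_genome) {
  fraction <- if (n_genome > 0) n_in_peaks / n_genome else NA_real_
  list(n_in_peaks = n_in_peaks, n_genome = n_genome, fraction = fraction,
       pct = if (is.na(fraction)) NA_real_ else round(100 * fraction, 1))
}

# ---- MDscan-style discovery ------------------------------------------------

encode_seq <- function(s) {
  m <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  unname(m[strsplit(s, "")[[1]]])
}

# All width-w windows of a set of sequences as an integer matrix plus their
# origin (sequence index, 0-based offset).
window_matrix <- function(seqs, w) {
  pieces <- lapply(seq_along(seqs), function(i) {
    v <- encode_seq(seqs[[i]])
    n <- length(v) - w + 1L
    if (n < 1L) return(NULL)
    mat <- sapply(seq_len(w), function(j) v[j:(j + n - 1L)])
    if (n == 1L) mat <- matrix(mat, nrow = 1L)
    list(mat = mat, seq = rep(i, n), off = seq_len(n) - 1L)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  list(mat = do.call(rbind, lapply(pieces, `[[`, "mat")),
       seq = unlist(lapply(pieces, `[[`, "seq")),
       off = unlist(lapply(pieces, `[[`, "off")))
}

# Fit a k-th order Markov background to sequences; falls back to 0th order
# below 10 kb of input.  Returns log probabilities with +1 pseudocounts.
markov_background <- function(seqs, order = 3L, min_bp = 10000L) {
  total <- sum(nchar(seqs))
  if (total < min_bp) order <- 0L
  enc <- lapply(seqs, encode_seq)
  base_counts <- tabulate(unlist(enc), nbins = 4L) + 1
  log_base <- log(base_counts / sum(base_counts))
  if (order == 0L)
    return(list(order = 0L, log_base = log_base))
  ctx_counts <- matrix(1, nrow = 4L^order, ncol = 4L)
  for (v in enc) {
    n <- length(v)
    if (n <= order) next
    ctx <- rep(0L, n - order)
    for (j in seq_len(order))
      ctx <- ctx * 4L + (v[j:(n - order + j - 1L)] - 1L)
    nxt <- v[(order + 1L):n]
    tab <- table(factor(ctx + 1L, levels = seq_len(4L^order)),
                 factor(nxt, levels = 1:4))
    ctx_counts <- ctx_counts + unclass(tab)
  }
  list(order = order, log_base = log_base,
       log_cond = log(ctx_counts / rowSums(ctx_counts)))
}

# log P(word) under the background; word is an encoded integer vector.
markov_logp <- function(bg, word) {
  w <- length(word)
  lp <- sum(bg$log_base[word[seq_len(min(bg$order, w))]])
  if (bg$order == 0L) return(sum(bg$log_base[word]))
  if (w <= bg$order) return(lp)
  for (pos in (bg$order + 1L):w) {
    ctx <- 0L
    for (j in (pos - bg$order):(pos - 1L)) ctx <- ctx * 4L + (word[j] - 1L)
    lp <- lp + bg$log_cond[ctx + 1L, word[pos]]
  }
  lp
}

# Semi-MAP objective: conservation term log(n)/w * sum f log f (with 0.5
# pseudocounts, so among equally conserved site sets the larger one wins)
# minus the mean background log-likelihood of the member sites.
map_score <- function(counts, site_logp) {
  n <- sum(counts[1, ])
  f <- (counts + 0.5) / (n + 2)
  ent <- sum(f * log(f))
  log(n) / nrow(counts) * ent - mean(site_logp)
}

# MAP score of every prefix of an ordered site set (rows of winmat), via
# cumulative count matrices; returns a numeric vector indexed by prefix
# size (entries 1 = -Inf, prefixes start at 2).
prefix_map_scores <- function(winmat, rows, site_logp, w) {
  n <- length(rows)
  m <- winmat[rows, , drop = FALSE]
  cum_logp <- cumsum(site_logp[rows])
  scores <- rep(-Inf, n)
  counts <- matrix(0L, nrow = w, ncol = 4L)
  for (x in seq_len(n)) {
    counts[cbind(seq_len(w), m[x, ])] <-
      counts[cbind(seq_len(w), m[x, ])] + 1L
    if (x < 2L) next
    f <- (counts + 0.5) / (x + 2)
    scores[x] <- log(x) / w * sum(f * log(f)) - cum_logp[x] / x
  }
  scores
}

# log-odds of each candidate row under the member-set PWM vs base
# background frequencies
pwm_log_odds <- function(winmat, rows, member, log_base) {
  w <- ncol(winmat)
  counts <- count_matrix(winmat, member, w)
  lf <- log((counts + 0.5) / (length(member) + 2))
  m <- winmat[rows, , drop = FALSE]
  out <- numeric(length(rows))
  for (j in seq_len(w)) out <- out + lf[j, m[, j]] - log_base[m[, j]]
  out
}

count_matrix <- function(winmat, rows, w) {
  m <- winmat[rows, , drop = FALSE]
  counts <- sapply(1:4, function(b) colSums(m == b))
  if (w == 1L) counts <- matrix(counts, nrow = 1L)
  colnames(counts) <- c("A", "C", "G", "T")
  counts   # width x 4
}

#' Discover over-represented motifs in ranked peak sequences
#'
#' A greedy MDscan-style search.  Width-w words occurring in the top
#' \code{top_n} ranked sequences are ranked by exact occurrence count
#' across the whole corpus and the \code{n_seeds} most frequent are
#' evaluated.  For each seed, every window within \code{max_mismatch}
#' mismatches (default 2) across all sequences forms the candidate pool;
#' membership within the pool is then refined greedily: candidates are
#' ranked by log-odds under the current position weight matrix and the
#' prefix maximizing a MAP-style objective is kept, iterating until
#' stable (at most 5 rounds).  The objective is the column-conservation
#' log-likelihood (0.5 pseudocounts) scaled by \code{log(n)/w}, minus the
#' mean log-probability of member sites under a 3rd-order Markov
#' background fit to the input (0th-order below 10 kb of sequence).
#' Motifs whose consensi share \code{width - 1} or more aligned
#' compatible positions (over shifts of up to 1) are collapsed, keeping
#' the higher score.
#'
#' The background is the base composition of the input unless
#' \code{bg_sequences} (e.g. the genome) is supplied, in which case a
#' 3rd-order model is fit to it; fitting a high-order model to the peak
#' sequences themselves would absorb the very over-representation being
#' sought.
#'
#' @param sequences character vector of peak sequences, ranked by
#'   descending peak score.
#' @param width motif width (6 or 8 are the conventional choices).
#' @param top_n number of top-ranked sequences whose words seed the search.
#' @param n_motifs number of motifs to return.
#' @param max_mismatch mismatch allowance for site collection.
#' @param n_seeds number of seed words evaluated.
#' @param min_sites minimum member-site count for a reported motif.
#' @param bg_sequences optional background sequences for the 3rd-order
#'   Markov model.
#' @return list of motif objects (class \code{motif_matrix}), each with
#'   \code{counts} (width x 4), \code{map_score}, \code{seed_word},
#'   \code{n_sites}, \code{consensus}, \code{is_ebox}; sorted by
#'   descending score.
#' @export
discover_motifs <- function(sequences, width = 6L, top_n = 40L,
                            n_motifs = 10L, max_mismatch = 2L,
                            n_seeds = 50L, min_sites = 5L,
                            bg_sequences = NULL) {
  width <- as.integer(width)
  top_n <- min(as.integer(top_n), length(sequences))
  if (top_n < 1L) stop("no sequences provided", call. = FALSE)
  if (width > min(nchar(sequences)))
    stop("width exceeds the shortest sequence", call. = FALSE)
  lapply(sequences, check_dna)

  wm <- window_matrix(sequences, width)
  bg <- if (is.null(bg_sequences)) markov_background(sequences, order = 0L)
        else markov_background(bg_sequences, order = 3L)
  site_logp_all <- apply(wm$mat, 1L, function(row) markov_logp(bg, row))

  # seed words: width-mers present in the top-ranked sequences, ranked by
  # Poisson over-representation of their corpus-wide exact count against
  # the count expected under the background model (raw counts would be
  # dominated by words rich in the commonest bases)
  top_rows <- wm$seq <= top_n
  words_all <- apply(wm$mat, 1L, paste, collapse = "")
  cand <- unique(words_all[top_rows])
  idx <- match(cand, words_all)
  cnt <- as.integer(table(factor(words_all, levels = cand)))
  expected <- nrow(wm$mat) * exp(site_logp_all[idx])
  surprise <- -stats::ppois(cnt - 1L, expected, lower.tail = FALSE,
                            log.p = TRUE)
  seeds <- cand[order(-surprise, cand)][seq_len(min(n_seeds, length(cand)))]

  log_base <- {
    bc <- tabulate(as.vector(wm$mat), nbins = 4L) + 1
    log(bc / sum(bc))
  }
  motifs <- lapply(seeds, function(sw) {
    seed_vec <- as.integer(strsplit(sw, "")[[1]])
    mm <- rowSums(wm$mat != matrix(seed_vec, nrow = nrow(wm$mat),
                                   ncol = width, byrow = TRUE))
    pool <- which(mm <= max_mismatch)
    if (length(pool) < min_sites) return(NULL)
    member <- pool[mm[pool] == 0L]
    if (length(member) < 2L) member <- pool
    for (iter in 1:5) {
      lo <- pwm_log_odds(wm$mat, pool, member, log_base)
      ord <- pool[order(-lo, pool)]
      pm <- prefix_map_scores(wm$mat, ord, site_logp_all, width)
      pm[seq_len(min(min_sites - 1L, length(pm)))] <- -Inf
      new_member <- sort(ord[seq_len(which.max(pm))])
      if (identical(new_member, sort(member))) break
      member <- new_member
    }
    rows <- sort(member)
    counts <- count_matrix(wm$mat, rows, width)
    structure(list(counts = counts,
                   map_score = map_score(counts, site_logp_all[rows]),
                   seed_word = decode_word(seed_vec),
                   n_sites = length(rows),
                   consensus = consensus_from_counts(counts, 0.9)),
              class = "motif_matrix")
  })
  motifs <- motifs[!vapply(motifs, is.null, TRUE)]
  motifs <- motifs[order(-vapply(motifs, `[[`, 1, "map_score"))]

  kept <- list()
  for (m in motifs) {
    dup <- any(vapply(kept, function(k)
      consensus_similarity(k$consensus, m$consensus) >= width - 1L, TRUE))
    if (!dup) kept[[length(kept) + 1L]] <- m
    if (length(kept) >= n_motifs) break
  }
  for (i in seq_along(kept)) kept[[i]]$is_ebox <- is_ebox(kept[[i]]$consensus)
  kept
}

decode_word <- function(v) paste(c("A", "C", "G", "T")[v], collapse = "")

# mismatch counts of every window against an IUPAC consensus
consensus_mismatches <- function(winmat, cons) {
  sets <- IUPAC_SETS[strsplit(cons, "")[[1]]]
  ok <- sapply(seq_along(sets), function(j) {
    allowed <- match(sets[[j]], c("A", "C", "G", "T"))
    winmat[, j] %in% allowed
  })
  if (nrow(winmat) == 1L) ok <- matrix(ok, nrow = 1L)
  rowSums(!ok)
}

consensus_from_counts <- function(counts, threshold) {
  stopifnot(threshold > 0.5, threshold <= 1)
  bases <- c("A", "C", "G", "T")
  apply_col <- function(row) {
    f <- row / sum(row)
    ord <- order(-f, bases)          # frequency desc, base order tie-break
    cum <- cumsum(f[ord])
    k <- which(cum >= threshold - 1e-12)[1]
    set <- sort(bases[ord[seq_len(k)]])
    code <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s)
      identical(sort(s), set), TRUE)]
    code
  }
  paste(apply(counts, 1L, apply_col), collapse = "")
}

#' IUPAC consensus of a motif matrix, and the E-box test
#'
#' Per column, the consensus is the smallest IUPAC code covering the bases
#' whose combined frequency reaches \code{threshold} (bases are added in
#' decreasing frequency order with alphabetical tie-break).
#'
#' @param motif a \code{motif_matrix} from \code{\link{discover_motifs}},
#'   or a width x 4 count matrix.
#' @param threshold coverage threshold in (0.5, 1].
#' @return the IUPAC consensus string.
#' @export
consensus <- function(motif, threshold = 0.9) {
  counts <- if (inherits(motif, "motif_matrix")) motif$counts else motif
  consensus_from_counts(counts, threshold)
}

#' @rdname consensus
#' @param cons an IUPAC consensus string.
#' @return \code{is_ebox}: TRUE iff the consensus is a width-6 E-box
#'   (CANNTG with arbitrary codes at positions 3-4 and exactly C, A, T, G
#'   at positions 1, 2, 5, 6).
#' @export
is_ebox <- function(cons) {
  if (nchar(cons) != 6L) return(FALSE)
  l <- strsplit(cons, "")[[1]]
  l[1] == "C" && l[2] == "A" && l[5] == "T" && l[6] == "G"
}

# aligned compatible positions between two IUPAC consensi over shifts -1..1
consensus_similarity <- function(a, b) {
  la <- strsplit(a, "")[[1]]; lb <- strsplit(b, "")[[1]]
  compat <- function(x, y)
    length(intersect(IUPAC_SETS[[x]], IUPAC_SETS[[y]])) > 0L
  best <- 0L
  for (shift in -1:1) {
    n <- 0L
    for (i in seq_along(la)) {
      j <- i + shift
      if (j >= 1L && j <= length(lb) && compat(la[i], lb[j])) n <- n + 1L
    }
    best <- max(best, n)
  }
  best
}

#' Extract ranked peak sequences from a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param peaks peak data frame with ranks.
#' @param top_n number of top-ranked peaks to extract.
#' @return character vector of sequences ordered by ascending rank.
#' @export
peak_sequences <- function(genome, peaks, top_n = 40L) {
  peaks <- peaks[order(peaks$rank), , drop = FALSE]
  peaks <- peaks[seq_len(min(top_n, nrow(peaks))), , drop = FALSE]
  vapply(seq_len(nrow(peaks)), function(i)
    substr(genome[[peaks$chrom[i]]], peaks$start[i] + 1L, peaks$end[i]),
    character(1))
}
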