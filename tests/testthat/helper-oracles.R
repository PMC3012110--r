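# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately slow, literal translations of the definitions and
# share no code with the package internals.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# exhaustive window scan for an IUPAC pattern, 0-based starts
oracle_scan <- function(seq, pattern) {
  pl <- strsplit(pattern, "")[[1]]
  sl <- strsplit(seq, "")[[1]]
  w <- length(pl)
  hits <- integer(0)
  if (length(sl) < w) return(hits)
  for (i in seq_len(length(sl) - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(sl[i + j - 1L] %in% ORACLE_IUPAC[[pl[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# hypergeometric upper tail P[overlap >= k] by exhaustive enumeration of
# all size-|B| subsets of a universe of size N containing a fixed A
oracle_hyper_tail <- function(N, size_a, size_b, k) {
  sets <- utils::combn(N, size_b)
  overlaps <- colSums(sets <= size_a)   # A = elements 1..size_a
  mean(overlaps >= k)
}

# literal candidate-run grouping + merging on one chromosome
# (no p-value filtering); returns peak intervals
oracle_group_merge <- function(starts, values, probe_len, percentile,
                               min_probes, max_gap, min_dist) {
  thr <- stats::quantile(values, percentile, names = FALSE)
  cand <- which(values >= thr)
  runs <- list()
  cur <- integer(0)
  for (i in cand) {
    if (length(cur) == 0L) { cur <- i; next }
    gap <- starts[i] - (starts[cur[length(cur)]] + probe_len)
    if (gap <= max_gap) cur <- c(cur, i)
    else { runs[[length(runs) + 1L]] <- cur; cur <- i }
  }
  if (length(cur) > 0L) runs[[length(runs) + 1L]] <- cur
  runs <- Filter(function(r) length(r) >= min_probes, runs)
  if (length(runs) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  iv <- data.frame(
    start = sapply(runs, function(r) starts[r[1]]),
    end = sapply(runs, function(r) starts[r[length(r)]] + probe_len))
  iv <- iv[order(iv$start), , drop = FALSE]
  repeat {
    merged <- FALSE
    if (nrow(iv) >= 2L) {
      for (i in seq_len(nrow(iv) - 1L)) {
        if (iv$start[i + 1L] - iv$end[i] < min_dist) {
          iv$end[i] <- max(iv$end[i], iv$end[i + 1L])
          iv <- iv[-(i + 1L), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  rownames(iv) <- NULL
  iv
}

# O(n*m) pairwise interval overlap counter
oracle_overlap_hits <- function(a, b) {
  sapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmax(b$start, a$start[i]) < pmin(b$end, a$end[i]))
  })
}

empty_truth_df <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             offset_from_tss = integer(0), n_eboxes = integer(0),
             target_gene = character(0), enrichment = numeric(0),
             stringsAsFactors = FALSE)
}

random_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# small corpus with a fixed word planted k times per sequence
planted_corpus <- function(seed, n = 40, len = 500, k = 3,
                           word = "CAGGTG") {
  withr::with_seed(seed, {
    sapply(seq_len(n), function(i) {
      s <- random_dna(len)
      if (k > 0) {
        pos <- sample(seq(1, len - nchar(word), by = 10), k)
        for (p in pos) substr(s, p, p + nchar(word) - 1L) <- word
      }
      s
    })
  })
}
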