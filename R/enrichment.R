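#' Fold enrichment of one gene list in another
#'
#' With universe size N, the expected overlap of lists A and B under
#' random sampling is |A|.|B|/N; fold enrichment is the observed overlap
#' divided by that expectation (1.0 = random), and the p-value is the
#' upper hypergeometric tail P[X >= k].  The statistic is symmetric in A
#' and B.
#'
#' @param a,b character vectors of gene ids, subsets of the universe.
#' @param universe character vector of all gene ids.
#' @return list with \code{n_a}, \code{n_b}, \code{universe_size},
#'   \code{overlap}, \code{expected}, \code{fold}, \code{p}.
#' @export
fold_enrichment <- function(a, b, universe) {
  universe <- unique(universe)
  a <- unique(a); b <- unique(b)
  bad <- c(setdiff(a, universe), setdiff(b, universe))
  if (length(bad) > 0L)
    stop("ids outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  if (length(a) < 1L || length(b) < 1L)
    stop("both lists must be non-empty", call. = FALSE)
  N <- length(universe)
  k <- length(intersect(a, b))
  expected <- length(a) * length(b) / N
  p <- stats::phyper(k - 1, length(a), N - length(a), length(b),
                     lower.tail = FALSE)
  list(n_a = length(a), n_b = length(b), universe_size = N, overlap = k,
       expected = expected, fold = k / expected, p = p)
}

#' Seeded random control gene lists
#'
#' Each list is an independent draw without replacement from the universe;
#' the whole set of lists is deterministic under the seed.
#'
#' @param universe character vector of gene ids.
#' @param size genes per list.
#' @param n_lists number of lists.
#' @param seed integer seed.
#' @return list of character vectors named random1, random2, ...
#' @export
random_gene_lists <- function(universe, size, n_lists = 3L, seed = 1L) {
  universe <- unique(universe)
  if (size > length(universe))
    stop("list size exceeds the universe", call. = FALSE)
  withr::with_seed(derive_seed(seed, "randomlists"), {
    out <- lapply(seq_len(n_lists), function(i)
      sample(universe, size, replace = FALSE))
  })
  names(out) <- paste0("random", seq_len(n_lists))
  out
}

#' Classify qPCR amplicons by fold enrichment over control serum
#'
#' An amplicon validates when its IP/control ratio strictly exceeds the
#' threshold (the conventional rule is "greater than 2-fold over
#' pre-immune serum", so a ratio of exactly 2 does not validate).
#'
#' @param ratios positive numeric vector of per-amplicon IP/control fold
#'   enrichments.
#' @param threshold validation fold threshold.
#' @param tiers optional factor/character vector of tier labels, one per
#'   amplicon (e.g. top/middle/bottom rank bands).
#' @return list with \code{validated} (logical per amplicon),
#'   \code{n_validated}, \code{n_total}, \code{summary} ("37/40"-style
#'   string), and, when tiers are given, \code{by_tier} (data frame with
#'   per-tier counts and the same summary string).
#' @export
qpcr_validate <- function(ratios, threshold = 2.0, tiers = NULL) {
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be positive", call. = FALSE)
  flag <- ratios > threshold
  out <- list(validated = flag, n_validated = sum(flag),
              n_total = length(flag),
              summary = sprintf("%d/%d", sum(flag), length(flag)))
  if (!is.null(tiers)) {
    stopifnot(length(tiers) == length(ratios))
    tiers <- factor(tiers, levels = unique(tiers))
    by <- data.frame(tier = levels(tiers),
                     n_validated = as.integer(tapply(flag, tiers, sum)),
                     n_total = as.integer(table(tiers)))
    by$summary <- sprintf("%d/%d", by$n_validated, by$n_total)
    out$by_tier <- by
  }
  out
}
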