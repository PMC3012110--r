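#' Generate a toy genome
#'
#' Chromosome sequences are i.i.d. bases at the configured GC fraction
#' (P(G) = P(C) = gc/2).  Chromosomes are named chrI, chrII, ... and the
#' result is a named character vector over A/C/G/T.  Deterministic under
#' the master seed (substream "genome").
#'
#' @param params a \code{\link{sim_params}} object.
#' @return named character vector of chromosome sequences.
#' @export
#' @examples
#' g <- make_genome(sim_params(n_chroms = 1, chrom_len = 1000, seed = 1))
#' nchar(g)
make_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  base_p <- c(A = (1 - params$gc) / 2, C = params$gc / 2,
              G = params$gc / 2, T = (1 - params$gc) / 2)
  withr::with_seed(derive_seed(params$seed, "genome"), {
    chroms <- vapply(seq_len(params$n_chroms), function(i) {
      paste(sample(names(base_p), params$chrom_len, replace = TRUE,
                   prob = base_p), collapse = "")
    }, character(1))
  })
  names(chroms) <- paste0("chr", as.character(utils::as.roman(
    seq_len(params$n_chroms))))
  chroms
}

#' Place gene models on a genome
#'
#' TSSs are laid on a per-chromosome slot grid of pitch
#' \code{params$tss_spacing} with up to 1 kb of uniform jitter, so the
#' minimum pairwise TSS distance on a chromosome is at least
#' \code{tss_spacing - 1000} bp (>= 9 kb at defaults), keeping the
#' -2 kb..+6 kb profile window around each TSS unambiguous.  Strands are
#' drawn at random with both guaranteed present when two or more genes are
#' placed; the TSS sits at the span edge (start on +, end - 1 on -).
#'
#' @param genome named character vector from \code{\link{make_genome}}.
#' @param params a \code{\link{sim_params}} object.
#' @return a data frame (the annotation set) with columns \code{gene_id},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{start}, \code{end}
#'   (0-based half-open span).
#' @export
make_gene_models <- function(genome, params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_genes
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), tss = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)

  margin <- max(4000L, max(params$gene_len_range) + 1000L)
  jitter_max <- 999L
  slots <- do.call(rbind, lapply(names(genome), function(cn) {
    len <- nchar(genome[[cn]])
    hi <- len - margin - jitter_max
    if (hi < margin) return(NULL)
    pos <- seq.int(margin, hi, by = params$tss_spacing)
    data.frame(chrom = cn, slot = pos, idx = seq_along(pos),
               stringsAsFactors = FALSE)
  }))
  if (is.null(slots) || nrow(slots) < n)
    stop("configuration error: ", n, " genes do not fit on this genome ",
         "at tss_spacing = ", params$tss_spacing, call. = FALSE)
  # round-robin across chromosomes so every chromosome carries genes
  slots <- slots[order(slots$idx, slots$chrom), ]
  slots <- slots[seq_len(n), ]

  withr::with_seed(derive_seed(params$seed, "genes"), {
    tss <- slots$slot + sample.int(jitter_max + 1L, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    if (n >= 2L && length(unique(strand)) == 1L)
      strand[n] <- setdiff(c("+", "-"), strand[1])
    glen <- sample(seq.int(params$gene_len_range[1], params$gene_len_range[2]),
                   n, replace = TRUE)
  })
  start <- ifelse(strand == "+", tss, tss - glen + 1L)
  end <- ifelse(strand == "+", tss + glen, tss + 1L)
  out <- data.frame(gene_id = sprintf("gene%03d", seq_len(n)),
                    chrom = slots$chrom, strand = strand,
                    tss = as.integer(tss), start = as.integer(start),
                    end = as.integer(end), stringsAsFactors = FALSE)
  lens <- nchar(genome)[out$chrom]
  stopifnot(all(out$start >= 0L), all(out$end <= lens),
            all(out$tss >= out$start), all(out$tss < out$end))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
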