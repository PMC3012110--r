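#' Plant transcription-factor binding sites near TSSs
#'
#' Overwrites the genome sequence at each site with a construct containing a
#' known number of E-boxes (CANNTG), records the ground truth, and keeps all
#' sites pairwise disjoint.  Site midpoints sit at a signed, strand-aware
#' offset from the target gene's TSS drawn from \code{offset_dist}
#' (upstream is negative; on - strand genes upstream means larger genomic
#' coordinates).  The construct's background is scrubbed of incidental
#' E-boxes so that scanning the planted interval recovers exactly the
#' planted count.
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotation gene models from \code{\link{make_gene_models}}.
#' @param params a \code{\link{sim_params}} object.
#' @param n_sites number of sites (default \code{params$n_sites}).
#' @param offset_dist function(n) returning n signed bp offsets; default
#'   \code{round(rnorm(n, params$offset_mean, params$offset_sd))}.
#' @param ebox_range inclusive range of E-box counts per site.
#' @return list with elements \code{genome} (modified sequences) and
#'   \code{truth}, a data frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{offset_from_tss},
#'   \code{n_eboxes}, \code{target_gene}, \code{enrichment}.
#' @export
plant_binding_sites <- function(genome, annotation, params,
                                n_sites = params$n_sites,
                                offset_dist = NULL,
                                ebox_range = params$ebox_range) {
  stopifnot(inherits(params, "sim_params"))
  if (n_sites == 0L) {
    return(list(genome = genome, truth = empty_truth()))
  }
  if (n_sites > nrow(annotation))
    stop("more sites requested than genes available", call. = FALSE)
  if (is.null(offset_dist)) {
    offset_dist <- function(n)
      round(stats::rnorm(n, params$offset_mean, params$offset_sd))
  }

  withr::with_seed(derive_seed(params$seed, "sites"), {
    targets <- annotation[sample.int(nrow(annotation), n_sites), ]
    placed <- empty_truth()
    for (i in seq_len(n_sites)) {
      g <- targets[i, ]
      clen <- nchar(genome[[g$chrom]])
      ok <- FALSE
      for (attempt in 1:100) {
        slen <- sample(seq.int(params$site_len_range[1],
                               params$site_len_range[2]), 1L)
        off <- offset_dist(1L)
        mid <- if (g$strand == "+") g$tss + off else g$tss - off
        start <- as.integer(mid - slen %/% 2L)
        end <- start + slen
        if (start < 0L || end > clen) next
        same <- placed[placed$chrom == g$chrom, , drop = FALSE]
        if (nrow(same) > 0L &&
            any(pmax(same$start, start) < pmin(same$end, end))) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("failed to place site ", i, " without collision after ",
             "100 retries", call. = FALSE)
      k <- sample(seq.int(ebox_range[1], ebox_range[2]), 1L)
      site_seq <- make_site_sequence(slen, k, params$gc)
      substr(genome[[g$chrom]], start + 1L, end) <- site_seq
      placed <- rbind(placed, data.frame(
        chrom = g$chrom, start = start, end = end,
        offset_from_tss = as.integer(off), n_eboxes = as.integer(k),
        target_gene = g$gene_id, enrichment = params$enrichment_mean,
        stringsAsFactors = FALSE))
    }
  })
  placed <- placed[order(placed$chrom, placed$start), ]
  rownames(placed) <- NULL
  list(genome = genome, truth = placed)
}

empty_truth <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             offset_from_tss = integer(0), n_eboxes = integer(0),
             target_gene = character(0), enrichment = numeric(0),
             stringsAsFactors = FALSE)
}

# Build a site sequence of length len containing exactly k CANNTG matches:
# draw background at the genome GC, mutate away incidental E-boxes, then
# write k boxes on a disjoint grid and verify the final count.  The two
# central bases are a self-complementary pair with probability pal_p,
# mirroring the symmetric (homodimer-bound) E-box variants that dominate
# bHLH binding sites.
make_site_sequence <- function(len, k, gc, pal_p = 0.7) {
  stopifnot(len >= 8L * k + 8L)
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (attempt in 1:100) {
    s <- paste(sample(names(base_p), len, replace = TRUE, prob = base_p),
               collapse = "")
    for (scrub in 1:50) {
      hits <- scan_pattern(s, "CANNTG")
      if (length(hits) == 0L) break
      # destroying the leading C kills the match at that start
      for (h in hits) substr(s, h + 1L, h + 1L) <- "G"
    }
    if (length(scan_pattern(s, "CANNTG")) > 0L) next
    if (k > 0L) {
      grid <- seq.int(1L, len - 6L, by = 8L)
      starts <- sort(sample(grid, k))
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      for (st in starts) {
        n1 <- sample(c("A", "C", "G", "T"), 1L)
        n2 <- if (stats::runif(1) < pal_p) comp[[n1]]
              else sample(c("A", "C", "G", "T"), 1L)
        substr(s, st, st + 5L) <- paste0("CA", n1, n2, "TG")
      }
    }
    if (length(scan_pattern(s, "CANNTG")) == k) return(s)
  }
  stop("could not construct a site sequence with exactly ", k, " E-boxes",
       call. = FALSE)
}

#' Simulate a replicate tiling-array probe track
#'
#' Probes tile each chromosome at pitch \code{probe_len + probe_gap}
#' starting at position 0.  Each replicate's intensity is a shared latent
#' signal (0 background; \code{log2(enrichment)} at probes inside truth
#' sites, scaled by overlap fraction) plus correlated Gaussian noise
#' \code{noise_sd * (sqrt(rep_corr) * shared + sqrt(1 - rep_corr) * own)},
#' which yields an expected pairwise Pearson correlation of exactly
#' \code{rep_corr} between replicate noise components.
#'
#' @param genome named character vector of chromosome sequences.
#' @param truth truth-site data frame (may be empty).
#' @param params a \code{\link{sim_params}} object.
#' @return a \code{probe_track}: list with \code{probes} (data frame
#'   chrom/start), \code{intensity} (probes x replicates matrix) and
#'   \code{probe_len}.
#' @export
simulate_tiling_track <- function(genome, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  pitch <- params$probe_len + params$probe_gap
  probes <- do.call(rbind, lapply(names(genome), function(cn) {
    len <- nchar(genome[[cn]])
    starts <- seq.int(0L, len - params$probe_len, by = pitch)
    data.frame(chrom = cn, start = as.integer(starts),
               stringsAsFactors = FALSE)
  }))
  np <- nrow(probes)
  signal <- numeric(np)
  if (nrow(truth) > 0L) {
    gp <- peaks_to_granges(data.frame(chrom = probes$chrom,
                                      start = probes$start,
                                      end = probes$start + params$probe_len))
    gt <- peaks_to_granges(truth)
    ov <- GenomicRanges::findOverlaps(gp, gt)
    if (length(ov) > 0L) {
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(gp)[S4Vectors::queryHits(ov)],
        GenomicRanges::ranges(gt)[S4Vectors::subjectHits(ov)]))
      amp <- log2(truth$enrichment[S4Vectors::subjectHits(ov)])
      contrib <- amp * w / params$probe_len
      agg <- tapply(contrib, S4Vectors::queryHits(ov), sum)
      signal[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  withr::with_seed(derive_seed(params$seed, "tiling"), {
    shared <- stats::rnorm(np)
    own <- matrix(stats::rnorm(np * params$n_reps), nrow = np)
  })
  noise <- params$noise_sd *
    (sqrt(params$rep_corr) * shared +
       sqrt(1 - params$rep_corr) * own)
  intensity <- signal + noise
  colnames(intensity) <- paste0("rep", seq_len(params$n_reps))
  probe_track(probes, intensity, params$probe_len)
}

#' Construct a probe track object
#'
#' @param probes data frame with \code{chrom} and 0-based \code{start}.
#' @param intensity numeric matrix, probes x replicates (log2 IP/control).
#' @param probe_len probe length in bp.
#' @return an object of class \code{probe_track}.
#' @export
probe_track <- function(probes, intensity, probe_len) {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(probes) == nrow(intensity), ncol(intensity) >= 1L,
            probe_len > 0L)
  ord <- order(probes$chrom, probes$start)
  probes <- probes[ord, , drop = FALSE]
  intensity <- intensity[ord, , drop = FALSE]
  for (cn in unique(probes$chrom)) {
    st <- probes$start[probes$chrom == cn]
    if (is.unsorted(st, strictly = TRUE))
      stop("probe starts must be strictly increasing within a chromosome",
           call. = FALSE)
  }
  rownames(probes) <- NULL
  structure(list(probes = probes, intensity = intensity,
                 probe_len = as.integer(probe_len)),
            class = "probe_track")
}

#' Simulate a read-coverage track
#'
#' Per-base counts are Poisson with background mean \code{read_depth};
#' inside each truth site, extended by \code{frag_len / 2} on both flanks,
#' the mean is multiplied by the site's enrichment.
#'
#' @inheritParams simulate_tiling_track
#' @return a \code{coverage_track}: list with \code{counts}, a named list of
#'   per-chromosome integer vectors (index i = base i - 1).
#' @export
simulate_read_coverage <- function(genome, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  ext <- params$frag_len %/% 2L
  withr::with_seed(derive_seed(params$seed, "coverage"), {
    counts <- lapply(names(genome), function(cn) {
      len <- nchar(genome[[cn]])
      lam <- rep(params$read_depth, len)
      tt <- truth[truth$chrom == cn, , drop = FALSE]
      if (nrow(tt) > 0L) {
        for (i in seq_len(nrow(tt))) {
          a <- max(0L, tt$start[i] - ext)
          b <- min(len, tt$end[i] + ext)
          lam[(a + 1L):b] <- params$read_depth * tt$enrichment[i]
        }
      }
      as.integer(stats::rpois(len, lam))
    })
  })
  names(counts) <- names(genome)
  structure(list(counts = counts), class = "coverage_track")
}

#' Simulate the full synthetic study
#'
#' Convenience wrapper running genome, gene-model, site-planting and both
#' track simulations under one \code{\link{sim_params}} object.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return list with \code{genome}, \code{genes}, \code{truth},
#'   \code{tiling} (probe track) and \code{coverage} (coverage track).
#' @export
simulate_study <- function(params = sim_params()) {
  genome <- make_genome(params)
  genes <- make_gene_models(genome, params)
  pl <- plant_binding_sites(genome, genes, params)
  list(genome = pl$genome, genes = genes, truth = pl$truth,
       tiling = simulate_tiling_track(pl$genome, pl$truth, params),
       coverage = simulate_read_coverage(pl$genome, pl$truth, params))
}

#' Simulate a concordance curve with a lenient-to-strict regime break
#'
#' Generates a stringency-sweep fixture whose normalized overlap decays
#' non-linearly (quadratic excess) up to the break stringency and linearly
#' beyond it, with additive Gaussian noise -- the qualitative shape of a
#' two-platform concordance curve whose informative-to-truncation
#' transition sits at the break.
#'
#' @param break_neglog10 stringency (-log10 p) at which the curve becomes
#'   linear.
#' @param cutoffs p-value cutoffs, lenient to stringent.
#' @param noise_sd sd of additive noise on the normalized percentages.
#' @param curvature quadratic excess coefficient in the lenient regime.
#' @param slope linear decay per -log10 p unit in the strict regime.
#' @param seed integer seed.
#' @return a \code{sweep_curve} object (see \code{\link{stringency_sweep}}).
#' @export
simulate_sweep_curve <- function(break_neglog10 = 5.5,
                                 cutoffs = 10^-(1:10), noise_sd = 1,
                                 curvature = 15, slope = 4, seed = 1L) {
  x <- -log10(cutoffs)
  stopifnot(!is.unsorted(x, strictly = TRUE))
  base <- 60 - slope * (x - break_neglog10)
  excess <- ifelse(x < break_neglog10,
                   curvature * (break_neglog10 - x)^2, 0)
  withr::with_seed(derive_seed(seed, "sweepfix"), {
    y <- base + excess + stats::rnorm(length(x), 0, noise_sd)
  })
  y <- rev(cummax(rev(y)))        # keep the subset property of a real sweep
  y <- 100 * y / y[1]
  new_sweep_curve(data.frame(cutoff = cutoffs, n_peaks = NA_integer_,
                             n_genes = NA_integer_,
                             overlap_peaks = NA_integer_,
                             overlap_genes = NA_integer_,
                             normalized_peaks = y, normalized_genes = y,
                             stringsAsFactors = FALSE))
}
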