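test_that("genome generation is deterministic and honours GC", {
  p <- sim_params(n_chroms = 1L, chrom_len = 1000L, n_genes = 0L, seed = 1L)
  expect_identical(make_genome(p), make_genome(p))

  at_only <- make_genome(sim_params(n_chroms = 1L, chrom_len = 2000L,
                                    gc = 0, n_genes = 0L, seed = 2L))
  expect_false(grepl("[GC]", at_only[[1]]))

  # observed GC within 3 binomial sd of the target
  n <- 1e5L
  g <- make_genome(sim_params(n_chroms = 1L, chrom_len = n, gc = 0.5,
                              n_genes = 0L, seed = 3L))
  gc_obs <- lengths(regmatches(g, gregexpr("[GC]", g))) / n
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / n))

  expect_error(sim_params(chrom_len = 0), "configuration error")
})

test_that("gene models satisfy spacing, bounds and strand invariants", {
  p <- sim_params(seed = 11L)
  g <- make_genome(p)
  genes <- make_gene_models(g, p)
  expect_equal(nrow(genes), 50L)
  expect_equal(anyDuplicated(genes$gene_id), 0L)
  expect_true(all(genes$start >= 0))
  expect_true(all(genes$end <= nchar(g)[genes$chrom]))
  expect_true(all(genes$tss >= genes$start & genes$tss < genes$end))
  expect_setequal(unique(genes$strand), c("+", "-"))
  # exhaustive pairwise TSS distance scan, per chromosome
  for (cn in unique(genes$chrom)) {
    tss <- genes$tss[genes$chrom == cn]
    d <- abs(outer(tss, tss, "-"))
    expect_gte(min(d[upper.tri(d)]), 8000L)
  }

  empty <- make_gene_models(g, sim_params(n_genes = 0L))
  expect_equal(nrow(empty), 0L)
  expect_error(
    make_gene_models(g, sim_params(n_genes = 10000L)),
    "do not fit")
})

test_that("planted sites carry exact E-box counts and do not overlap", {
  p <- sim_params(seed = 5L)
  g <- make_genome(p)
  genes <- make_gene_models(g, p)
  pl <- plant_binding_sites(g, genes, p)
  expect_equal(nrow(pl$truth), 20L)
  for (i in seq_len(nrow(pl$truth))) {
    t <- pl$truth[i, ]
    s <- substr(pl$genome[[t$chrom]], t$start + 1L, t$end)
    expect_length(scan_pattern(s, "CANNTG"), t$n_eboxes)
  }
  # brute-force pairwise overlap check
  tr <- pl$truth
  for (i in seq_len(nrow(tr) - 1L)) {
    for (j in (i + 1L):nrow(tr)) {
      if (tr$chrom[i] != tr$chrom[j]) next
      expect_true(tr$end[i] <= tr$start[j] || tr$end[j] <= tr$start[i])
    }
  }
})

test_that("point-mass offsets put every site midpoint at TSS-300", {
  p <- sim_params(n_sites = 10L, seed = 9L)
  g <- make_genome(p)
  genes <- make_gene_models(g, p)
  pl <- plant_binding_sites(g, genes, p, offset_dist = function(n) rep(-300, n))
  tr <- pl$truth
  expect_true(all(tr$offset_from_tss == -300L))
  gg <- genes[match(tr$target_gene, genes$gene_id), ]
  mid <- (tr$start + tr$end) %/% 2L
  expect_equal(mid, ifelse(gg$strand == "+", gg$tss - 300L, gg$tss + 300L),
               tolerance = 1e-9)
})

test_that("tiling probes follow the 86 bp pitch and the noise model", {
  p <- sim_params(n_chroms = 1L, chrom_len = 100000L, n_genes = 0L,
                  seed = 21L)
  g <- make_genome(p)
  tr <- simulate_tiling_track(g, empty_truth_df(), p)
  starts <- tr$probes$start
  expect_equal(starts[1:4], c(0L, 86L, 172L, 258L))
  expect_true(all(diff(starts) == 86L))
  # no sites: per-replicate mean within 3 sd of 0 under the noise model
  np <- nrow(tr$probes)
  for (r in seq_len(ncol(tr$intensity))) {
    expect_lt(abs(mean(tr$intensity[, r])), 3 * p$noise_sd / sqrt(np))
  }
})

test_that("replicate correlation calibration hits the target band", {
  # ~10^4 probes, no signal: empirical r within 0.05 of the 0.75 target
  p <- sim_params(n_chroms = 1L, chrom_len = 900000L, n_genes = 0L,
                  rep_corr = 0.75, seed = 31L)
  g <- make_genome(p)
  tr <- simulate_tiling_track(g, empty_truth_df(), p)
  expect_gt(nrow(tr$probes), 1e4)
  r <- replicate_correlation(tr)
  off <- r[upper.tri(r)]
  expect_true(all(off >= 0.70 & off <= 0.80))
})

test_that("read coverage follows the Poisson model and is deterministic", {
  p <- sim_params(n_chroms = 1L, chrom_len = 200000L, n_genes = 0L,
                  read_depth = 5, seed = 41L)
  g <- make_genome(p)
  cv <- simulate_read_coverage(g, empty_truth_df(), p)
  m <- mean(cv$counts[[1]])
  expect_lt(abs(m - 5), 3 * sqrt(5 / 200000))
  expect_identical(cv, simulate_read_coverage(g, empty_truth_df(), p))

  # single 1.5 kb site at 10x: site/background mean ratio near 10
  truth <- data.frame(chrom = names(g)[1], start = 50000L, end = 51500L,
                      offset_from_tss = NA_integer_, n_eboxes = 0L,
                      target_gene = "x", enrichment = 10)
  p2 <- sim_params(n_chroms = 1L, chrom_len = 200000L, n_genes = 0L,
                   read_depth = 5, frag_len = 0L, seed = 43L)
  cv2 <- simulate_read_coverage(g, truth, p2)
  site_mean <- mean(cv2$counts[[1]][50001:51500])
  bg_mean <- mean(cv2$counts[[1]][-(50001:51500)])
  expect_gt(site_mean / bg_mean, 8)
  expect_lt(site_mean / bg_mean, 12)
})

test_that("fixtures round-trip through FASTA, GFF3, bedGraph and TSV", {
  p <- sim_params(n_chroms = 2L, chrom_len = 60000L, n_genes = 6L,
                  n_sites = 3L, seed = 13L)
  st <- simulate_study(p)
  d <- withr::local_tempdir()
  paths <- write_fixtures(st, d, seed = 13L)

  expect_identical(read_genome_fasta(paths[["genome"]]), st$genome)
  expect_identical(read_gene_models_gff3(paths[["genes"]]), st$genes)
  rt <- read_probe_track(unname(paths[grep("probes", names(paths))]))
  expect_identical(rt$probes, st$tiling$probes)
  expect_equal(unname(rt$intensity), unname(st$tiling$intensity))
  expect_identical(read_coverage_bedgraph(paths[["coverage"]])$counts,
                   st$coverage$counts)
  expect_identical(read_truth_tsv(paths[["truth_tsv"]]), st$truth)

  # BED line format: 0-based half-open, tab separated
  bed <- readLines(paths[["truth_bed"]])
  f <- strsplit(bed[1], "\t")[[1]]
  expect_identical(as.integer(f[2:3]), c(st$truth$start[1], st$truth$end[1]))
})
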