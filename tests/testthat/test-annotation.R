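toy_genes <- function() {
  data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chrI", "chrI", "chrII"),
    strand = c("+", "-", "+"),
    tss = c(10000L, 49999L, 10000L),
    start = c(10000L, 45000L, 10000L),
    end = c(12000L, 50000L, 13000L),
    stringsAsFactors = FALSE)
}

peak_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

test_that("peak-to-gene assignment applies the strand-aware offset rules", {
  genes <- toy_genes()
  # + strand: peak [9600, 9800) -> midpoint 9700 -> offset -300, promoter
  a <- assign_peaks_to_genes(peak_df("chrI", 9600, 9800), genes)
  expect_equal(a$gene_id, "geneA")
  expect_equal(a$tss_offset, -300L)
  expect_equal(a$location, "promoter")

  # - strand: TSS 49999, peak [50200, 50400) -> midpoint 50300 ->
  # offset -301 (upstream on the minus strand), promoter
  b <- assign_peaks_to_genes(peak_df("chrI", 50200, 50400), genes)
  expect_equal(b$gene_id, "geneB")
  expect_equal(b$tss_offset, -(50300L - 49999L))
  expect_equal(b$location, "promoter")

  # midpoint inside the assigned gene span -> intragenic
  c1 <- assign_peaks_to_genes(peak_df("chrI", 10500, 11500), genes)
  expect_equal(c1$location, "intragenic")

  # 5 kb past the TSS, outside the span -> distal
  d <- assign_peaks_to_genes(peak_df("chrII", 14800, 15200), genes)
  expect_equal(d$gene_id, "geneC")
  expect_equal(d$tss_offset, 5000L)
  expect_equal(d$location, "distal")

  # farther than 50 kb from every TSS -> unassigned
  far <- assign_peaks_to_genes(peak_df("chrII", 900000, 900200), genes)
  expect_true(is.na(far$gene_id))
  expect_equal(far$location, "unassigned")

  expect_warning(assign_peaks_to_genes(peak_df("chrI", 0, 100), genes[0, ]),
                 "empty annotation")
})

test_that("equidistant peaks go to the lexicographically smaller gene", {
  genes <- data.frame(gene_id = c("geneZ", "geneB"),
                      chrom = "chrI", strand = "+",
                      tss = c(1000L, 3000L), start = c(1000L, 3000L),
                      end = c(1500L, 3500L), stringsAsFactors = FALSE)
  a <- assign_peaks_to_genes(peak_df("chrI", 1900, 2100), genes)
  expect_equal(a$gene_id, "geneB")
})

test_that("TSS density profile counts in-window midpoints per gene", {
  genes <- toy_genes()
  pk <- peak_df("chrI", c(9600, 9650, 11000), c(9800, 9850, 11400))
  a <- assign_peaks_to_genes(pk, genes)
  prof <- tss_density_profile(a, genes)
  expect_equal(nrow(prof), 40L)
  expect_true(all(prof$density >= 0))
  # argmax bin is [-400, -200) where both promoter peaks fall
  expect_equal(prof$bin_start[which.max(prof$density)], -400L)
  # counting identity: sum(density) * n_genes = in-window peaks
  expect_equal(sum(prof$density) * nrow(genes), 3)

  none <- tss_density_profile(assign_peaks_to_genes(pk[0, ], genes), genes)
  expect_true(all(none$density == 0))
})

test_that("density profile is translation-equivariant", {
  genes <- toy_genes()
  pk <- peak_df("chrI", c(9600, 10500), c(9800, 11500))
  base <- tss_density_profile(assign_peaks_to_genes(pk, genes), genes)
  shift <- 1234L
  genes2 <- genes
  genes2$tss <- genes2$tss + shift
  genes2$start <- genes2$start + shift
  genes2$end <- genes2$end + shift
  pk2 <- peak_df(pk$chrom, pk$start + shift, pk$end + shift)
  shifted <- tss_density_profile(assign_peaks_to_genes(pk2, genes2), genes2)
  expect_equal(base, shifted)
})

test_that("peak-set overlap counts agree with the pairwise oracle", {
  a <- peak_df("chrI", c(0, 1000), c(100, 1500))
  expect_equal(overlap_peak_sets(a, a)$fraction_a_hit, 1)
  b <- peak_df("chrI", c(5000, 7000), c(5100, 7100))
  expect_equal(overlap_peak_sets(a, b)$fraction_a_hit, 0)
  # 1 bp overlap counts as a hit
  c1 <- peak_df("chrI", 99, 150)
  expect_equal(overlap_peak_sets(a, c1)$n_a_hit, 1L)

  withr::with_seed(7, {
    for (case in 1:10) {
      n <- sample(5:40, 1); m <- sample(5:40, 1)
      x <- peak_df(sample(c("chrI", "chrII"), n, TRUE),
                   s <- sample(0:5000, n), s + sample(50:500, n, TRUE))
      y <- peak_df(sample(c("chrI", "chrII"), m, TRUE),
                   t <- sample(0:5000, m), t + sample(50:500, m, TRUE))
      got <- overlap_peak_sets(x, y)
      expect_equal(got$n_a_hit, sum(oracle_overlap_hits(x, y)))
      expect_equal(got$n_b_hit, sum(oracle_overlap_hits(y, x)))
    }
  })
})

test_that("gene-list overlap handles case, duplicates and subsets", {
  r <- overlap_gene_lists(c("a", "B", "c"), c("b", "C", "d"))
  expect_equal(sort(r$shared), c("b", "c"))
  expect_equal(r$pct_of_a, 100 * 2 / 3)
  expect_equal(overlap_gene_lists(c("x"), c("y"))$pct_of_a, 0)
  sub <- overlap_gene_lists(c("a", "b"), c("a", "b", "c"))
  expect_equal(sub$pct_of_a, 100)
  expect_warning(overlap_gene_lists(c("a", "a", "b"), "b"), "duplicate")
})

test_that("chromosome distribution reflects per-chromosome hit rates", {
  genes <- toy_genes()
  all_hit <- assign_peaks_to_genes(
    peak_df(genes$chrom, genes$tss - 100L, genes$tss + 100L), genes)
  d <- chromosome_distribution(all_hit, genes)
  expect_equal(d$fraction, c(1, 1))
  none <- chromosome_distribution(all_hit[0, ], genes)
  expect_equal(none$fraction, c(0, 0))
})

test_that("biased planting makes the favoured chromosome's rate highest", {
  p <- sim_params(n_chroms = 3L, chrom_len = 400000L, n_genes = 36L,
                  n_sites = 0L, seed = 17L)
  g <- make_genome(p)
  genes <- make_gene_models(g, p)
  # plant on 2x as many chrI genes as on the others
  pick <- withr::with_seed(18, c(
    sample(genes$gene_id[genes$chrom == "chrI"], 8),
    sample(genes$gene_id[genes$chrom == "chrII"], 4),
    sample(genes$gene_id[genes$chrom == "chrIII"], 4)))
  gg <- genes[match(pick, genes$gene_id), ]
  pk <- peak_df(gg$chrom, gg$tss - 200L, gg$tss + 200L)
  d <- chromosome_distribution(assign_peaks_to_genes(pk, genes), genes)
  expect_equal(which.max(d$fraction), which(d$chrom == "chrI"))
  expect_true(all(d$fraction[d$chrom == "chrI"] >
                    d$fraction[d$chrom != "chrI"]))
})

test_that("location classes partition assigned peaks", {
  st <- simulate_study(sim_params(seed = 7L))
  s <- summarize_replicates(quantile_normalize(st$tiling), "biweight")
  pk <- call_tiling_peaks(s)
  a <- assign_peaks_to_genes(pk, st$genes)
  assigned <- a[!is.na(a$gene_id), ]
  expect_true(all(assigned$location %in%
                    c("promoter", "intragenic", "distal")))
  frac <- table(assigned$location) / nrow(assigned)
  expect_equal(sum(frac), 1)
})
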