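# chipconcord

Cross-platform concordance analysis of genome-wide transcription-factor
binding maps.

When the same factor is ChIPed and assayed on two different platforms — a
tiling microarray (ChIP-chip) and high-throughput sequencing (ChIP-seq) —
the two peak maps never agree perfectly, and the interesting questions are
quantitative: how many peaks and candidate target genes overlap, at what
calling stringency the comparison stabilizes, whether both maps
concentrate just upstream of transcription start sites, whether the bound
intervals are enriched for the factor's sequence motif, and whether the
implied target genes are enriched for an independently derived expression
list.  `chipconcord` implements that whole analysis for a bHLH-class
factor whose canonical site is the E-box `CANNTG`, and ships a
synthetic-data module that generates toy genomes with planted,
fully-known binding sites so every step can be validated against ground
truth.

The core pieces:

* **Tiling-array caller** (`call_tiling_peaks`): quantile normalization
  and Tukey-biweight probe summarization of replicate tracks, then
  percentile thresholding (0.95), probe-run grouping (≥ 5 probes, ≤ 100 bp
  gaps), merging (< 200 bp), and a robust one-sided z-test per peak with a
  −log10 p ≥ 13 cutoff.
* **Coverage caller** (`call_seq_peaks`): sliding-window Poisson tail
  p-values against the genome-wide rate, merged significant windows,
  Bonferroni-adjusted peak p-values; conventional analysis cutoff
  p ≤ 1e-6.
* **Concordance** (`overlap_peak_sets`, `overlap_gene_lists`,
  `stringency_sweep`, `find_inflection`): overlap counts, and a sweep of
  the p-value cutoff with a formalized inflection criterion (bounded
  second differences of the normalized concordance curve).
* **Annotation** (`assign_peaks_to_genes`, `tss_density_profile`):
  nearest-TSS assignment with strand-aware signed offsets,
  promoter/intragenic/distal classes, 200 bp binned density over
  −2 kb..+6 kb.
* **Motifs** (`scan_pattern`, `motif_coverage_fraction`,
  `discover_motifs`): overlap-permissive IUPAC scanning, genome-wide
  E-box coverage fractions, and a greedy MDscan-style discovery with a
  MAP-type objective.
* **Enrichment** (`fold_enrichment`, `random_gene_lists`,
  `qpcr_validate`): hypergeometric fold enrichment against a gene
  universe (fold = k · N / (|A|·|B|), 1.0 = random), seeded random
  control lists, and the strict >2-fold qPCR validation rule.

## Worked example

Simulate the default study (two 1 Mb chromosomes, 50 genes, 20 planted
sites centred ~300 bp upstream of their target TSSs, enrichment 8, noise
sd 1, three replicates at target correlation 0.75), call peaks on both
platforms, and compare:

```r
library(chipconcord)

st <- simulate_study(sim_params(seed = 7))

norm <- quantile_normalize(st$tiling)
round(range(replicate_correlation(norm)[upper.tri(diag(3))]), 3)
#> [1] 0.775 0.779

chip <- call_tiling_peaks(summarize_replicates(norm, "biweight"))
seqp <- filter_peaks_by_pvalue(call_seq_peaks(st$coverage), 1e-6)
c(nrow(chip), nrow(seqp))
#> [1] 20 20

evaluate_calls(chip, st$truth)[c("sensitivity", "fdr")]
#> $sensitivity
#> [1] 1
#> $fdr
#> [1] 0

map <- assign_peaks_to_genes(chip, st$genes)
table(map$location)
#> promoter
#>       20

prof <- tss_density_profile(map, st$genes)
prof$bin_start[which.max(prof$density)]
#> [1] -400

overlap_peak_sets(chip, seqp)$fraction_a_hit
#> [1] 1

motif_coverage_fraction(st$genome, chip)[c("n_in_peaks", "n_genome", "pct")]
#> $n_in_peaks
#> [1] 92
#> $n_genome
#> [1] 6693
#> $pct
#> [1] 1.4
```

All 20 planted sites are recovered by both callers with no false calls;
every peak classifies as promoter-proximal, the TSS profile peaks in the
[−400, −200) bin where the sites were planted, the two platforms'
peak sets overlap completely, and the called peaks cover 1.4% of the
genome's ~6,700 E-boxes — binding-site detection, not motif frequency,
drives the selection.  The planted target-gene list is recovered with a
fold enrichment of 2.5 over random expectation (hypergeometric
p ≈ 2e-14).

A full run — simulation, both callers, annotation, sweep, motifs,
enrichment, JSON summary — is one call (or `chipconcord run` from the
shell via the script in `exec/`):

```r
summary <- run_all(default_config(seed = 7), outdir = "out")
```

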