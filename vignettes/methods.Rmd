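---
title: "Methods: cross-platform concordance analysis of ChIP binding maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform concordance analysis of ChIP binding maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipconcord)
```

## The problem

Genome-wide maps of a transcription factor's binding sites can be measured
by hybridizing ChIP-enriched DNA to a tiling microarray (ChIP-chip) or by
sequencing it (ChIP-seq).  The two platforms have different noise
structures, dynamic ranges and analysis pipelines, so an important
question for any factor is how concordant the two resulting peak and
target-gene lists are, and at what calling stringency the comparison is
meaningful.  `chipconcord` implements that comparison end-to-end for a
basic helix-loop-helix (bHLH) style factor whose canonical binding site is
the E-box `CANNTG`: peak calling on both platforms, TSS-relative
annotation, stringency sweeps, motif statistics and gene-list enrichment —
all exercised against synthetic genomes with planted, fully known truth.

## The synthetic study

The generator (`sim_params()`, `simulate_study()`) emulates the
experimental geometry the analysis assumes rather than the biology of any
real genome:

* **Genome**: i.i.d. bases at a configurable GC fraction (default 0.36, a
  nematode-like composition); default two chromosomes of 1 Mb.
* **Gene models**: TSSs on a jittered 10 kb grid so every TSS is at least
  9 kb from its neighbours and the −2 kb..+6 kb profile window is
  unambiguous; spans 1–3 kb; both strands.
* **Binding sites**: default 20 sites, each targeted at a gene with a
  signed, strand-aware TSS offset drawn from N(−300, 50) bp — the
  upstream-proximal placement typical of promoter-bound factors.  Site
  lengths are 1–1.8 kb, matching the ~1.45 kb bound intervals typical of
  tiling-array peak calls.  Each site's sequence is rewritten to contain an
  exactly known number of E-boxes (1–13); the flanking construct is
  scrubbed so scanning the interval recovers exactly that count.  The two
  central bases of each planted box form a self-complementary pair with
  probability 0.7, concentrating the 16 possible `CANNTG` variants on the
  symmetric (homodimer-type) boxes; without that concentration no single
  variant occurs often enough to be discoverable by exact-word seeding.
* **Tiling track**: 50 bp probes every 86 bp (36 bp gaps).  Replicate
  intensity = shared signal + `noise_sd * (sqrt(r)*shared_noise +
  sqrt(1-r)*own_noise)`, which gives an expected pairwise Pearson
  correlation of exactly `rep_corr` (default 0.75, the middle of the
  0.71–0.78 band typical of good biological replicates).  Signal is
  `log2(enrichment)` scaled by the probe's overlap fraction with a site.
* **Coverage track**: per-base Poisson counts, background mean
  `read_depth` (default 5), multiplied by the site enrichment inside
  sites extended by `frag_len/2`.

Every stage draws from a named substream derived from one master seed
(`derive_seed()`), so changing, say, motif settings never perturbs the
simulation draws, and identical configurations give byte-identical
outputs.

What the generator does *not* emulate — real nucleotide composition and
repeats, mappability, probe cross-hybridization, fragment-length biases,
copy-number structure — bounds what passing tests demonstrate: they show
the analysis machinery is correct under its own model, not that it is
robust to every artifact of real data.

## Tiling-array peak calling

`call_tiling_peaks()` reconstructs a percentile-threshold caller in the
style of tiling-array packages, with the conventional defaults: candidate
percentile 0.95, −log10 p cutoff 13, at least 5 probes per peak, at most
100 bp between member probes, peaks closer than 200 bp merged, a 500 bp
test window, and a 2 kb promoter definition.  Replicates are first
quantile-normalized (via `limma`) and summarized per probe with either the
mean or a one-step Tukey biweight (c = 5, un-scaled MAD plus a 1e-4
epsilon so an outlying replicate is down-weighted even when the MAD is
zero).

The caller's statistical test is not prescribed by the parameter list, so
the package fixes one: a one-sided z-test of the windowed probe mean
against a robust genome-wide background (median location, MAD scale,
standard error scaled by sqrt(n)).  It is simple, reaches −log10 p ≥ 13
for genuine signal, and is fully testable.  The reported peak *score* is
the mean summarized intensity of member probes, kept separate from the
p-value: published tiling-array peak scores (range ~3–37) cannot be the
−log10 p values given a cutoff of 13, so both quantities are emitted
rather than guessing which one a legacy tool reported.

Other conventions fixed here: probe gaps are measured end-to-start;
threshold ties are included (≥); rank ties break to the leftmost
coordinate; the 500 bp window only pads peaks shorter than itself.

## Read-coverage peak calling and the stringency sweep

`call_seq_peaks()` tests sliding windows (default 300 bp every 100 bp)
with a one-sided Poisson tail p-value against the genome-wide mean rate,
merges windows passing a lenient p ≤ 0.01 pre-filter, and assigns each
peak the Bonferroni-adjusted minimum member-window p — monotone under
window refinement and conservative.  The pre-filter output is the
caller's "default" set and anchors sweep normalization; downstream
analysis conventionally filters at p ≤ 1e-6.

`stringency_sweep()` re-filters the peak set at increasingly stringent
cutoffs and tracks peak and gene-list overlap with a reference set,
normalized to the default-cutoff overlap.  `find_inflection()` formalizes
the qualitative "non-linear to near-linear transition" of such curves:
with x = −log10(cutoff), it returns the smallest interior x such that
every forward second difference of the normalized curve from x onwards
has magnitude at most 5% of the curve's range (a range-relative
tolerance, so the criterion is invariant to affine rescaling; the
tolerance is exposed as an argument since "near linear" admits no unique
formalization).  If no point qualifies the last cutoff is returned,
flagged.

## Annotation and profiles

Peaks are represented by their integer midpoints and assigned to the gene
with the nearest TSS (strand-aware signed offsets; upstream negative; on
minus-strand genes upstream means larger coordinates).  Location classes
partition assigned peaks — promoter (offset in [−2000, 0)), intragenic
(midpoint inside the assigned span), distal (everything else) — and peaks
more than 50 kb from every TSS stay unassigned so toy genomes remain
honest.  Whether a published promoter/intragenic split used midpoints or
any-overlap is generally unstated; the midpoint convention is used and
documented.  The TSS density profile bins assigned midpoints in 200 bp
bins over −2 kb..+6 kb and divides by the gene count; the conventional
1e-4 presentation scaling is left to plots.

## Motif statistics

`scan_pattern()` is overlap-permissive IUPAC matching (via `Biostrings`),
returning 0-based starts; a single-strand scan suffices for patterns that
are their own reverse complement as a class (`CANNTG`), otherwise both
strands are scanned and deduplicated.  `motif_coverage_fraction()` counts
the fraction of genome-wide matches whose start lies inside a peak.

`discover_motifs()` is a greedy, MDscan-style search.  Seeds are
width-length words from the top-ranked sequences, ranked by Poisson
over-representation of their corpus-wide count against the
composition-expected count (raw counts would be dominated by words rich
in the commonest bases).  Each seed's candidate pool is every window
within 2 mismatches; membership is refined by ranking the pool under the
current position weight matrix and keeping the prefix that maximizes a
MAP-style objective, iterating until stable.  The objective is the
column-conservation log-likelihood (0.5 pseudocounts) scaled by
`log(n)/width`, minus the mean background log-probability of member
sites.  The background is the base composition of the input unless an
explicit background sequence set (e.g. the genome) is supplied, in which
case a 3rd-order Markov model is fit to it; fitting a high-order model to
the 20 kb of peak sequences themselves would absorb the very
over-representation being sought, inverting the ranking.  Reported motifs
need at least 5 member sites (2-copy exact-duplicate words are otherwise
unbeatable), and near-duplicate consensi (≥ width−1 compatible aligned
positions over ±1 shifts) are collapsed keeping the higher score.  The
search is validated by planted-motif recovery, not by numeric agreement
with any particular legacy implementation.

## Enrichment statistics

`fold_enrichment()` formalizes "fold enrichment relative to theoretical
randomization" as observed overlap divided by |A|·|B|/N, which equals 1.0
in expectation for random lists, with an upper hypergeometric tail
p-value; the universe defaults to all annotated genes.
`random_gene_lists()` draws seeded, without-replacement control lists.
`qpcr_validate()` applies the strict "greater than 2-fold over control
serum" rule — a ratio of exactly 2 does not validate.

## Problem sizes and determinism

The default study (2 × 1 Mb, 50 genes, 20 sites, enrichment 8, noise sd
1) runs the full pipeline in well under a minute on one CPU; the test
suite exercises smaller genomes (200–900 kb) for multi-seed calibration
checks and brute-force oracle comparisons (≤ 100 probes, universes ≤ 25
genes, strings ≤ 30 bp) chosen so exhaustive enumeration stays instant.
Degenerate inputs are defined, not special-cased: flat tracks yield no
peaks (the background scale is zero and non-positive z-scores get p =
0.5), zero-variance replicates give flagged NA correlations, empty
annotations leave peaks unassigned with a warning, and a zero-overlap
sweep anchor is an error rather than a silent division by zero.

## Known limitations

* The tiling caller's z-test treats probes as independent; correlated
  probe noise would inflate −log10 p, which is acceptable here because
  the cutoff acts as a ranking threshold, not a calibrated error rate.
* The coverage caller models no control track or fragment-shift
  estimation; it is a background-rate scan, not a MACS replacement.
* Motif discovery evaluates a bounded seed set (default 50) and fixes
  width per call; very degenerate motifs outside the planted family may
  rank above weakly planted ones on GC-skewed corpora, as repeat-like
  motifs do in real peak sets.
* The synthetic "muscle" list is the planted target list plus padding;
  enrichment contrasts on it demonstrate calibration of the statistic,
  not biology.
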