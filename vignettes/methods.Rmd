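---
title: "Models and methods behind translatomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind translatomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical models, the parameter choices and
the numerical conventions used by `translatomics`, and says explicitly what
the synthetic-data tests do and do not demonstrate about real data.

## The experimental design the package assumes

A two-channel microarray experiment in which each array hybridizes one
Cy-labelled RNA sample against a genomic-DNA common reference. Samples come
from biological replicate cultures (default five), each sampled at two
temperatures (30 and 42 °C), and each split into three RNA pools: total
RNA, monosome-associated RNA and polysome-associated RNA recovered from
sucrose gradients. The probe tables consumed by `read_probe_table()` are a
simplified two-column dialect of feature-extraction output (processed
sample and reference signals with a probe→gene mapping and control flags);
the package does not parse vendor formats or re-map probes to the genome.

## GEM construction

`build_gem()` applies four steps in a fixed order: per-probe log2 ratios,
per-array median centering, between-array scale normalization in batches,
then control filtering and probe-to-gene averaging. Averaging after
normalization (rather than before) keeps every probe's information in the
normalization statistics.

**Negative intensities.** Background-subtracted processed signals can be
negative, and `log2` is undefined at or below zero. When exactly one
channel of a probe is non-positive, that channel's value is replaced by the
lowest positive value of the same channel's distribution *on that array*
before the ratio is taken; when both channels are non-positive the probe's
log ratio is set to 0. Two conventions had to be fixed here. First, the
replacement is applied to the offending *channel value*, not to the
resulting ratio — replacing the ratio would discard the information still
present in the good channel. Second, the replacement value is chosen
per-channel and per-array because arrays have independent intensity
scales. Zero intensities are treated like negatives, since they are equally
unusable under a logarithm. An array whose channel contains no positive
value at all has no defensible replacement and is an error.

**Scale normalization.** "Scale" normalization equalizes the spread of the
arrays: each centered column is divided by its median absolute deviation
(MAD) and multiplied by the geometric mean of its batch's column MADs, so
every array in a batch ends with the same MAD while the batch's overall
spread is preserved. The MAD is used without the 1.4826 normal-consistency
factor — only ratios of MADs enter the computation, so the factor cancels.
Normalization runs in two independent batches (total-RNA arrays;
monosome/polysome arrays) because ribosome-associated RNA has a different
intensity distribution from total RNA, and forcing a common scale across
the two kinds of sample would distort both. A column with MAD 0 is
degenerate data and raises an error naming the array.

## Rank products and pfp

Differential calls use the rank-product statistic on paired per-replicate
log2 fold changes (the 42 °C value minus the 30 °C value within the same
culture; pairing by culture is what the replicate structure supports). For
direction "up", genes are ranked 1..n within each replicate by descending
fold change and the statistic is the geometric mean of a gene's ranks.
Ties get average ranks.

The null is permutation of gene labels within every replicate column —
equivalently, each permutation independently shuffles each column of the
rank matrix. With B permutations pooled, a gene with observed statistic
RP(g) at position ρ(g) of the RP ordering gets E(g) = #{permuted RP ≤
RP(g)}/B and pfp(g) = E(g)/ρ(g). Three post-processing conventions:

- ρ uses maximum ranks under ties (the conservative choice; ties in RP are
  common in small problems).
- pfp is made non-decreasing along the RP ordering by a cumulative-maximum
  pass, the standard monotonicity enforcement for FDR-type quantities.
- pfp is capped at 1 for reporting.

Up and down directions are computed from the *same* permutation draws,
which makes the sign symmetry exact: negating every fold change swaps the
up and down results bit-for-bit. The Monte-Carlo estimator is validated in
the test suite against exhaustive enumeration of all within-column
permutations on small problems (4–5 genes, 2 replicates), agreeing to
within ±0.02 at B = 50 000.

The default B is 1000 with a mandatory seed; the significance threshold is
pfp ≤ 0.1 throughout.

## TE, classification, Venn and monosome partitioning

TE is computed per replicate and temperature as the log2 difference
between a numerator fraction (default polysome) and a denominator fraction
(default total); per-replicate ΔTE feeds rank products. Computing TE per
replicate and then contrasting (rather than contrasting means) is required
by the rank-product statistic and respects the culture pairing.

Classification intersects the TE and transcription call sets into
mutually exclusive groups (potentiated; TE-up with transcription
unchanged or down; transcription-only up/down; TE-down); a gene called
both TE-up and TE-down is a contradiction and an error. The four-way Venn
partition counts all 15 membership patterns over polysome-up, TE-up,
transcription-up and transcription-down.

The monosome/polysome partitioning contrast is formalized as a difference
of differences, `[mono(42) − poly(42)] − [mono(30) − poly(30)]` per
replicate — the natural per-replicate paired version of "change in
monosome abundance relative to polysome abundance". Its report
characterizes the significant genes (both directions pooled) by the
fraction of ORFs under 1000 nt and by their mean total-RNA abundance per
temperature versus the genome mean, each with a one-tailed Wilcoxon test
(alternative: shorter / lower). "Average abundance" is taken from the
total-RNA fraction of the GEM, averaged over replicates within each
temperature.

## Sequence-composition battery

All composition statistics are *pooled* over the gene set (total residue
or codon counts, not per-gene means): "frequency per 100 residues" and
RSCU are rates of the set as a whole. The null is 1000 random gene sets of
the same size drawn uniformly without replacement from protein-coding,
non-pseudogene genes; a statistic more than 2 SD from the null mean is
flagged (two-sided — both directions are informative). Alongside the
resampling flags, per-gene distributions are compared with one-tailed
tests: Wilcoxon for protein length, Welch t for the G+C windows.

Conventions:

- RSCU excludes start and stop codons from counting (their identity is
  constrained by initiation and termination, not by synonymous choice) and
  drops the single-codon families ATG and TGG, leaving 59 codons. Stop and
  start usage are tabulated separately as percentages of genes.
- Coordinates around the start codon place +1 at the first base of the
  start codon and −1 at the last upstream base; there is no position 0.
  The positional G+C profile averages, at each position, the G+C fraction
  of a window of half-width 12 nt (a 25-nt window; the smoothing width is
  exposed as a parameter since nothing in the design fixes it) over the
  genes that cover the position; windows are clipped at sequence ends, and
  a window bound landing on the nonexistent position 0 snaps inward.
- Genes with upstream regions truncated at a contig edge are dropped from
  the upstream G+C statistic with a warning.
- A degenerate null (SD = 0, possible for a rare codon at tiny set sizes)
  yields z = NA and no flag, with a warning, rather than an infinite z.

With 83 statistics per battery run and a 2 SD two-sided rule, a random
gene set is expected to trigger roughly 5% spurious flags; the test suite
asserts ≤ 15% averaged over repeated random sets.

## The synthetic-data generator

The generator exists to give every stage a ground truth. Its defaults are
the study conditions the pipeline targets: 2000 genes, five biological
replicates, three fractions at two temperatures, three probes per gene
(scaled down from real high-density arrays, which carry an order of
magnitude more probes per gene), 5% control probes, 1% negative channel
entries, and spiked groups — 74 TE-up genes (15 also transcriptionally up,
40 transcription-unchanged, 19 transcription-down), 3 TE-down, 30/150
transcription-only up/down, and 20 monosome-shift genes — with effect
sizes of +1.5 log2 units for ΔTE and the monosome shift and +2/−1.5 for
transcription. Baseline abundances are N(8, 1) in log2 units, with
per-gene polysome- and monosome-loading offsets of SD 0.5.

**Noise structure.** Biological noise (SD 0.3 log2 units) is drawn once
per gene, replicate and temperature and shared by the three fractions of
that culture: a biological replicate is one culture whose RNA is split
into the total, monosome and polysome pools, so culture-level variation
moves the fractions together and largely cancels from within-replicate
efficiency ratios. Technical noise (SD 0.1) is independent per probe and
array, and per-probe affinity effects (SD 0.25) are shared across arrays,
cancelling from the two-channel ratio.

**Negative intensities** are created by negating entries drawn from the
low-intensity tail of each channel (the bottom 5×rate quantile). This is
where background subtraction produces negatives in real data, and it is
the regime in which the min-positive replacement rule is a good
approximation; negating uniformly at random would instead corrupt bright
probes with multi-log2-unit errors that no analysis could undo.

**The genome.** Genes are drawn codon-by-codon: an amino-acid sequence
from a frequency vector, then a codon within each synonymous family with
probability proportional to w^(G+C count of the codon), with w solved
numerically (by `uniroot` on the expected G+C as a function of log w) so
the expected coding G+C hits the target exactly — 72% for background
genes, 62% for the TE set, values chosen to match a high-G+C
actinobacterial genome and the contrast observed in translationally
enhanced gene sets. An unreachable target given the amino-acid frequencies
is an error. TE-set genes additionally use a 40%-shorter length law
(log-normal, median ≈ 250 codons for background), amino-acid targets
enriched 1.6× for E/Q/M/V/K/I and depleted 0.7× for A/H/L/P/W/Y, shifted
start-codon shares (more ATG and TTG, less GTG) and stop-codon shares
(more TAA), and a planted G+C-rich block at coding positions +52..+75 —
centred near +63 — built from 100% G+C codons. Monosome-shift genes share
the short length law and sit 1.5 log2 units below the baseline abundance
mean, so the partitioning report's length and abundance associations have
a planted truth. Genes sit on random strands separated by 100-bp
intergenic spacers whose flanks carry the 50-bp upstream windows at the
gene's G+C level; 5% of background genes are flagged as pseudogenes.

**What the synthetic data does not emulate.** Probe-level spatial
artifacts, dye effects beyond a constant reference channel, operon
structure and transcription-unit boundaries, leaderless transcripts,
correlated gene expression, genuine background-subtraction physics, and
any sequence determinant of expression (composition and expression truth
are planted independently, so composition recovery and spike recovery are
separate checks). Passing tests therefore demonstrate the correctness and
calibration of the *procedures* under the stated noise model, not
performance guarantees on real arrays.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at the study's scale where
that is cheap (2000 genes × 30 arrays; B = 1000; 1000 random sets) and at
reduced scale where exactness is the point (oracle comparisons at 4–5
genes with B = 50 000 against exhaustive enumeration; 200-gene experiments
for fast end-to-end checks; 300–400 genes for composition calibrations).
Null calibration uses 50 spike-free experiments; sensitivity and FDR are
reported as means over three spiked experiments, since a single run
estimates a ~10% FDR from only ~80 calls. Exact identities (column
medians after centering, within-batch MAD equality, RSCU family means)
are asserted at 1e-12/1e-9; Monte-Carlo agreement at ±0.02; calibration
rates with generous margins (≤ 2% null calls, ≤ 15% spurious flags)
around their theoretical expectations.

## Known limitations

- The pipeline is fraction-level polysome profiling: no ribosome-footprint
  positional information, no isoform resolution.
- Only the "scale" between-array normalization of the original design is
  provided; no loess or quantile options, no missing-value imputation.
- Multi-part CDS concatenation is implemented but untested against real
  multi-exon annotation (absent in bacteria).
- pfp is a permutation estimate; with very few genes it is noisy, and at
  thousands of genes its accuracy is limited by B (1/B granularity in E).
- The probe→gene mapping is consumed as an input; probes mapping outside
  coding regions should be left unmapped, and are dropped with a count.
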