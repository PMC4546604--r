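---
title: "Methods: motif grammar, enrichment nulls and the activity signature"
author: "peakgrammar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif grammar, enrichment nulls and the activity signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakgrammar)
```

This vignette documents the models and procedures implemented in
`peakgrammar`, the tunable parameters and their defaults, the design of the
synthetic-data generators, and the numerical and design choices made where
the analysis was genuinely open. It states no empirical result beyond what
the package's tests and `scripts/acceptance.R` themselves compute.

## Coordinate and data model

All genomic intervals are 0-based, half-open `[start, end)` internally; BED
input is taken as-is and the peakzilla-style 1-based dialect is shifted on
read (`read_peaks(dialect = "peakzilla")`). A *peak* is a summit-anchored
interval with a caller score and a sample label, carried as one tibble row.
Keeping a single internal convention and converting at the I/O boundary
prevents off-by-one drift between modules; the two summit-table dialects
exist because peak callers disagree about summit indexing.

## Consensus scanning and the double-motif grammar

`scan_consensus()` matches a short consensus (default `CATTCC`, the TEAD
binding motif) against every offset of a sequence on both strands, allowing
up to `max_mismatch` substitutions (default 1, the allowance under which
most YAP1-bound regions contain at least one TEAD site). `N` bases never
match. A site matching both strands yields two records — strand identity is
needed downstream for pair orientation — but region-level presence is a
boolean, so palindromic double-counting cannot inflate presence fractions.

A *double motif* is an ordered pair of same-strand matches whose spacer
(gap between the end of the first occurrence and the start of the second,
always measured in plus-strand coordinates) lies in `[0, max_spacer]`.
Minus-strand pairs qualify on the same footing as plus-strand pairs: the
biologically relevant configuration is two sites in the same orientation,
wherever the motif text appears. All qualifying pairs are enumerated, not
only adjacent ones, because a region with three sites contains two
overlapping grammars and should count toward both spacers. `max_spacer`
defaults to 30 bp, comfortably covering the short-range spacings over which
cooperative dimeric binding is plausible.

Motif statistics are computed on 151-bp summit-centred windows by default —
the average genomic fragment length, and the window on which known-motif
occurrence statistics are defined. Whether published presence percentages
used this window or full peak-caller bounds is not documented; both are
supported (`motif_enrichment(window = NA)` scans full peak bounds), and the
summit window is the default because summit-proximal sequence is where
ChIP signal localises the binding event.

## Enrichment against chromosome-shuffled controls

The null region set relocates each peak uniformly at random within its own
chromosome, preserving width (`shuffle_regions()`). Placement is
independent per region; overlaps among shuffled regions are permitted and
the original location is not excluded — the simplest null consistent with
"shuffle within the same chromosome", and the differences are negligible at
realistic peak densities.

Enrichment is tested with the exact hypergeometric upper tail,
parameterised as: population = observed plus control regions, successes =
all hit regions, draw = the observed set. This matches "enrichment over
random control regions" with a single exact test. The tail is evaluated
through `stats::phyper`, which computes in log space; `log10_p` output is
provided because region-level enrichments routinely produce P-values far
below `1e-308`. One shuffled control set is used by default (`n_shuffles =
1`); pooling more reduces control variance where wanted.

For the spacer spectrum, each spacer `s` is tested two ways: against the
control spectrum at `s`, and against the pooled (region, spacer) hits over
all other spacers within the observed set. The second comparison asks
whether `s` stands out *within* the observed double-motif population; the
pooled-pairs construction is a design choice, as the printed comparison
("vs. other spacer lengths") does not define its population.

No multiple-testing correction is applied to spacer or gene-set P-values
by default (raw hypergeometric P is reported); `geneset_enrichment(adjust
= TRUE)` adds Benjamini–Hochberg.

## Coverage, correlation and meta-profiles

Reads are extended to 150 bp from their 5′ end in the read direction
(minus-strand reads extend leftward, covering `(p − 150, p]`), and each
read contributes `1e6 / library_size` per covered base, i.e.
reads-per-million density. Between-sample reproducibility is the Pearson
correlation of per-region mean densities; the module leaves the choice of
region set (one sample's peaks, or a union) to the caller, since published
correlations do not state which was used. Meta-profiles average density at
offsets `−flank..flank` around summits (default flank 1,000 bp).

## Threshold rules

The differential-expression rule requires, across the four knockdown
vs. control comparisons: all adjusted p ≤ 1e−5, a consistent direction,
and fold changes of at least 2 in one comparison and at least 1.2 in the
other three. Fold changes are linear magnitudes with down-regulation
expressed as control/knockdown. Boundary semantics are literal: `p ≤`
threshold and `fold ≥` threshold ("at least"), but reference density
strictly `< 100` ("below") in the differential-binding rule. The
negative-binomial model that produces adjusted p-values is out of scope;
the rules operate on its outputs.

## The activity signature classifier

Samples are labelled by *ranksum*: the sum of a sample's rank in
expression and its rank in copy number (average ranks on ties). In
`extremes` mode the top and bottom `top_fraction` (default 10%) become
`high`/`low`; in `all` mode a median split labels everyone, with ties at
the median going to `low`. Boundary ties are broken by sample identifier
with a warning, keeping the labelling deterministic.

The classifier is Gaussian naive Bayes — the continuous-input variant of
the predictor family used for this task — with per-gene, per-class mean
and unbiased variance, variances floored at `1e-9` times the global
expression variance so constant genes cannot create singular densities.
Expression is `log2(x + 1)`-transformed by default (`log2_transform =
FALSE` is available), which is where a Gaussian model is plausible for
FPKM-like data. Posteriors are computed in log space and normalised across
the two classes.

Evaluation repeats 1000 random 2/3–1/3 train/test splits. Splits are
stratified by class — a design choice beyond "randomly divided" — because
stratification guarantees both classes in every training and test subset,
without which iterations would fail sporadically. AUC uses the
Mann–Whitney pair formulation (ties count one half), which is invariant
under monotone transforms of the scores. Feature selection ranks genes by
absolute standardised mean difference (pooled SD); the original selection
method is undocumented, and this measure is the standard deterministic
choice. When `select_k` is set inside `iterated_holdout()`, selection uses
the training fold only, avoiding selection bias in the test AUC.

One caveat worth knowing: with a *fixed* dataset and labels, the mean AUC
over holdout splits concentrates on a dataset-dependent value, not on the
population value — chance gene–label associations persist across splits.
Null calibration should therefore average over independent null datasets
(as `scripts/acceptance.R` does), not rely on a single permutation.

## Synthetic data: what it emulates and what it does not

`gen_genome_with_peaks()` generates i.i.d.-base chromosomes (uniform
composition by default, GC configurable), places non-overlapping 151-bp
summit windows, and plants consensus motifs: with probability
`double_rate` a same-orientation pair with spacer drawn from
`spacer_dist`, otherwise with total probability `single_rate` a single
motif — so the marginal planted rates are exact Bernoulli rates. Motif
bases are written after the background and never mutated; the ledger
records planted type, strand, offsets and spacer per peak, letting tests
check planted rates exactly and total (planted + incidental) rates
statistically.

The default configuration encodes the study conditions the package is
calibrated against: 2,500 peaks of 151 bp, `single_rate = 0.86`,
`double_rate = 0.18` with all spacer mass at 3 bp, and a control-window
hit rate of 0.37, giving the characteristic ~2.3-fold single-motif
enrichment geometry (0.86/0.37). Two calibration choices deserve
explanation:

* **Exact-match scanning on synthetic data.** On the real genome, a 1-bp
  mismatch allowance yields a ~37% control hit rate because genomic base
  composition and correlation structure differ from i.i.d. uniform. On a
  uniform synthetic genome the same allowance would hit ~74% of control
  windows purely incidentally, destroying the fold geometry. The synthetic
  calibration therefore plants exact motifs and scans at 0 mismatches,
  reproducing the observed/control geometry rather than the mismatch
  parameter itself.
* **Background motif density.** Outside peak windows, motifs are scattered
  at density `d` solved from
  `1 − (1 − p_inc) · exp(−d · n_off) = background_hit_rate`, where
  `p_inc` is the analytic incidental hit probability of a window and
  `n_off = width − k + 1`. Background motifs intruding into peak windows
  are rejected so planted peak rates stay exact.

What the generators do **not** emulate: GC and repeat structure of real
genomes, degenerate motif variants, chromatin-driven peak placement, read
sequencing errors, or correlated gene–gene expression. Passing tests
demonstrate that the pipeline's statistics recover planted truth under the
stated geometry — not that real-genome values would be reproduced bit for
bit from raw data.

`gen_reads()` mixes uniform background reads with summit-centred fragments
(midpoints Gaussian around the summit, SD 50 bp, strand-balanced), with
the mixture weight solved from the target fold enrichment.
`gen_expression()` draws per-gene baselines on the log2 scale and shifts
signature genes between classes by `effect_size` noise-SD units; values
return to the linear scale as `2^x − 1` so the classifier's transform
recovers exactly Gaussian class-conditionals.

## Numerical choices and degenerate inputs

* Hypergeometric tails: `phyper` exact computation; `log10_p` for deep
  tails; inconsistent count parameterisations error.
* Fold with zero control hits is `NA` (flagged undefined) unless the
  observed count is also zero, in which case it is 1.
* Sequences shorter than the consensus scan to an empty match set (not an
  error); characters outside `{A, C, G, T, N}` error.
* Summit windows clip at chromosome bounds and carry a `clipped` flag.
* Nearest-TSS ties: smallest absolute distance, then lexicographically
  smallest gene id. Peaks with no same-chromosome TSS are flagged
  `unassigned` rather than dropped.
* Zero-variance inputs to Pearson correlation error (undefined PCC).
* The naive Bayes variance floor is `1e-9 ×` global variance; posteriors
  for the two classes sum to 1 to within 1e−12.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scale the analyses are designed
for while staying desk-sized: oracle sweeps use 10,000 random 200-bp
sequences (scanning), the full parameter lattice for populations up to 12
(hypergeometric), and 1,000-row tables (filter rules); parameter-recovery
runs use 2,500 peaks of 151 bp across ten seeds on 5-Mb chromosome pairs,
with the full 20-Mb default genome used for the fold-recovery run; the
classifier runs 200-iteration holdouts on 200 × 150 matrices. Where a
statistic is checked across ten independent seeds against per-seed 95%
intervals, the suite requires at most two misses and the pooled estimate
inside its pooled interval — the multiple-testing structure a ten-fold
repetition of a 95% check needs.

## Known limitations

* The consensus scanner is exact-and-mismatch only: no IUPAC degeneracy,
  no position-weight scoring.
* Nearest-TSS assignment is a heuristic; enhancers can skip the nearest
  gene.
* The peak-region overlap rule is ≥1 bp intersection of reported intervals
  (`min_overlap` exposed); summit-window-based overlap definitions can be
  emulated via `summit_window()` first.
* The SAM reader is a minimal single-end adapter (no CIGAR-aware span, no
  mapping-quality filter); position tables are the primary input.
* Shuffled nulls preserve width and chromosome only — not GC, mappability
  or distance-to-gene structure.
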