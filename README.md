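# peakgrammar

Tools for dissecting the *regulatory grammar* of transcription-factor
binding sites from ChIP-seq peak sets, built around the analysis of
YAP1/TEAD binding at distal enhancers. YAP1 carries no DNA-binding domain
of its own: it reaches chromatin through TEAD transcription factors, whose
hexameric consensus CATTCC (reverse complement GGAATG) dominates YAP1 peak
regions — both as single sites and as homotypic *double motifs*, two
same-orientation occurrences separated by a short spacer, with the 3-bp
spacer configuration specifically enriched. `peakgrammar` implements the
full analysis chain as composable, pipe-friendly R functions, plus
synthetic-data generators with planted ground truth so every stage is
testable without any external download.

Intended users: computational biologists analysing transcription-factor
ChIP-seq peak sets who want motif-grammar statistics, enhancer target-gene
assignment and downstream activity signatures in one coherent, tested
toolkit.

## What it computes

**Motif grammar.** For a consensus motif `m` of length `k` and a mismatch
allowance `δ`, `scan_consensus()` reports every offset where the sequence
matches `m` (strand `+`) or its reverse complement (strand `−`) with at
most `δ` substitutions. `find_motif_pairs()` enumerates same-orientation
pairs with spacer `s = offset₂ − (offset₁ + k) ∈ [0, s_max]`, and
`spacer_spectrum()` counts, per spacer, the regions containing at least one
such pair. Motif statistics are computed on 151-bp summit-centred windows
(the average ChIP fragment length) by default.

**Enrichment.** Observed region sets are compared against
chromosome-shuffled controls (`shuffle_regions()`: same chromosome, same
width, uniform placement) with the one-sided hypergeometric upper tail

P(X ≥ x) with population N = n_obs + n_ctrl, successes X = x_obs + x_ctrl,
draw n = n_obs,

computed exactly in log space (`hypergeom_upper_tail()`), so P-values far
below double underflow remain meaningful. The same test drives gene-set
enrichment over a gene universe (`geneset_enrichment()`) and the per-spacer
comparisons against control regions and against the pooled other spacer
lengths (`spacer_enrichment()`).

**Peaks to genes.** `nearest_tss_assign()` links every peak summit to the
closest gene TSS (signed distance, negative = upstream; proximal within 2
kb), `classify_features()` assigns each summit a genomic class with
priority promoter > 5′UTR > exon > intron > intergenic, and
`overlap_fraction()`/`metaprofile()`/`sample_correlation()` give the
overlap, coverage and reproducibility statistics (reads extended to 150 bp
and piled into reads-per-million density by `extend_and_pile()`).

**Filters.** `de_filter()` implements the knockdown differential-expression
rule (adjusted p ≤ 1e−5 in all four pairwise comparisons, consistent
direction, ≥2-fold in one comparison and ≥1.2-fold in the other three);
`diffbind_filter()` the differential-binding rule (p ≤ 1e−5, fold ≥ 2,
reference density < 100 reads/kb); `intersect_targets()` crosses DE genes
with peak assignments.

**Activity signature.** `ranksum_label()` labels tumour samples
high/low by the sum of expression and copy-number ranks (top and bottom 10%
by default); `nb_fit()`/`nb_predict()` implement a Gaussian naive Bayes
classifier over log2(x+1) expression; `iterated_holdout()` evaluates it by
1000 stratified random 2/3–1/3 splits, reporting the per-iteration
Mann–Whitney AUC (`auc_score()`); `select_features()` reduces the signature
to the top-k genes by standardised mean difference.

## Worked example

```r
library(peakgrammar)

# a synthetic genome with 300 planted-motif peaks (defaults: 86% single
# motifs, 18% double motifs at spacer 3, 37% background window hit rate)
g <- gen_genome_with_peaks(
  chrom_sizes = tibble::tibble(chrom = "chr_sim", size = 2e6),
  n_peaks = 300, seed = 7
)

motif_enrichment(g$peaks, g$genome, max_mismatch = 0, seed = 8)
#>   n_obs x_obs n_ctrl x_ctrl  fold p_value log10_p
#> 1   300   246    300     92 2.674       0 -37.791
```

246/300 (82%) of peak windows contain the consensus versus 92/300 (31%) of
shuffled controls — a 2.7-fold enrichment whose exact hypergeometric
P-value (10⁻³⁷·⁸) underflows the linear scale, hence the log10 column.

```r
seqs <- peak_window_sequences(g$peaks, g$genome)
sp   <- spacer_spectrum(seqs, max_mismatch = 0, max_spacer = 8)
sp[sp$n_regions_with_pair > 2, ]
#>   spacer n_regions_with_pair
#> 1      3                  45
autoplot(sp)   # bar chart of the spectrum
```

45/300 (15%) of regions carry a same-orientation double motif at spacer 3;
no other spacer exceeds 2 regions — the planted 3-bp grammar is recovered.

```r
sim <- gen_expression(n_genes = 200, n_samples = 150, signature_size = 10,
                      effect_size = 1, seed = 9)
cv <- iterated_holdout(sim$expr, sim$labels, sim$signature_genes,
                       n_iterations = 100, seed = 10)
cv
#> <nb_cv> 100 random holdout iterations (train fraction 0.667, 10 genes,
#>   150 labelled samples)
#>   mean AUC = 0.984
glance(cv)
#> # A tibble: 1 × 6
#>   mean_auc sd_auc n_iterations train_fraction n_genes n_samples
#> 1    0.984 0.0143          100          0.667      10       150
```

A 10-gene signature with a 1-SD per-gene class shift is detected almost
perfectly (mean AUC 0.984 over 100 random holdout splits).

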