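---
title: "Models and methods behind scATACkit"
author: "scATACkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scATACkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scATACkit implements the canonical droplet scATAC-seq processing chain
from mapped fragment coordinates to per-cluster differential
accessibility. This vignette explains each model, the parameters that
matter, the numerical choices, and what the bundled synthetic benchmark
does and does not demonstrate.

## Input model

The atomic record is a *fragment*: a 0-based, half-open genomic
interval `[start, end)` carrying a 16 bp cell barcode and a duplicate
count. The two Tn5 transposition events of a fragment sit at `start`
and `end − 1`; every stage that counts "cut sites" or "fragment ends"
counts these two positions. Alignment and read-level filtering are
upstream of this package: fragments arrive as a 5-column TSV.

## Barcode correction

Observed barcodes are compared to a whitelist. Candidates are whitelist
barcodes within Hamming distance 2 (an `N` mismatches every base; reads
with more than two `N`s are discarded as uninformative). Each candidate
`c` is scored by

* a prior proportional to `abundance(c) + 1`, where abundance is the
  exact-match count of `c` in the observed data — the pseudocount keeps
  unobserved whitelist entries reachable; and
* a likelihood treating each mismatch as a sequencing error with
  probability `10^(-Q/10)` (spread uniformly over the three wrong
  bases) and each match as a correct read with probability
  `1 − 10^(-Q/10)`.

Posteriors are normalised over candidates; the read is corrected to the
top candidate only when its posterior strictly exceeds 0.9 (a tie at
exactly 0.9 is *not* corrected). Fragment files carry no per-base
qualities, so the stream-level wrapper assumes a constant Phred 30; the
exact likelihood of the upstream basecaller is unknowable from the
fragment file, and this concrete substitution model is the package's
choice.

## Deduplication and QC

Read pairs with identical (chromosome, start, end, barcode) collapse to
one fragment with `dupCount` equal to the multiplicity; the operation
is idempotent and conserves record counts. Two QC views are computed on
*unique* fragments: the fragment-length histogram (bimodal in real
chromatin: nucleosome-free and mono-nucleosome fragments) and the TSS
enrichment profile. For the TSS curve, cut sites within ±2,000 bp of
each TSS are aggregated (offsets flipped for minus-strand genes), and
the curve is normalised as `(count + 1) / (flank mean + 1)` where the
flank mean is taken over the outermost 100 bp on each side — the +1
pseudocount keeps the curve defined on sparse data and pins the flank
level at 1 by construction. The enrichment score is the curve value at
offset 0. The normalisation is this package's choice; the per-base TSS
convention is BED-like (plus strand: interval start; minus strand:
`end − 1`).

## Peak calling

Per-base cut-site counts are smoothed with a centred 401 bp moving
window (edges clipped), then modelled with a three-component mixture:

* zero-inflation: geometric on {0, 1, 2, …}, `P(k) = p (1 − p)^k` — so
  zeros receive mass from all three components and EM apportions them;
* noise: negative binomial with mean `μ_n`, dispersion `φ_n`
  (variance `μ + μ²/φ`, i.e. `φ` is the `size` of `dnbinom`);
* signal: negative binomial `(μ_s, φ_s)` with `μ_s > μ_n` enforced for
  identifiability.

EM initialisation is deterministic given the seed: zeros seed the zero
component and a 1-D k-means (k = 2, quantile-initialised) on
`log1p(nonzero)` seeds the two NB components, with method-of-moments
dispersions. The dispersion M-step maximises the weighted NB
log-likelihood over `log φ` and never accepts a worse value than the
current one, making the procedure a generalised EM whose observed
log-likelihood trace is non-decreasing (asserted in the tests). The
stopping rule is a log-likelihood gain below `tol = 1e-6`; the
iteration cap defaults to 5,000 because the zero and noise components
overlap heavily and full convergence of their apportioning is slow
(each iteration is cheap: the data are value-aggregated). The fit uses
a uniform subsample of at most 10⁶ bases; classification uses all
bases.

A base is a peak base when the posterior odds signal:noise at its
smoothed count reach 1/5. The odds are monotone in the count above the
noise mean but can be inflated in the far left tail when the signal
component is more dispersed than the noise component; the classifier
therefore thresholds at the smallest count of the *final* passing run,
which coincides with the literal smallest passing count whenever the
odds are monotone. Runs of passing bases become intervals; intervals
separated by less than 500 bp merge. The odds contrast is signal vs
noise only (not noise + zero): the zero component models closed
chromatin, and a base with enough smoothed counts to matter is being
classified between the two open/noise regimes.

## Cell calling and the count matrix

Per barcode we count total fragments and fragments intersecting any
peak (half-open interval intersection). Cross-droplet contamination is
modelled as a fixed count: `round(rate × mean in-peak count over
barcodes with ≥ 1 fragment)` with rate 0.02, subtracted and clamped at
zero. The estimator (rate × mean) is this package's concrete reading of
a "depth-dependent fixed count". A two-NB mixture is fitted to the
adjusted counts by the same EM machinery (initial split at the 90th
percentile — most droplet barcodes are ambient); a barcode is a cell
when the posterior odds signal:noise reach 1,000. The peak × cell
matrix counts fragment ends (both ends counted separately, including
when both land in one peak) and keeps cell barcodes only.

## Clustering

The matrix is IDF-weighted: entry `(p, b)` is multiplied by
`log(1 + N/df_p)` with `df_p` the number of barcodes where peak `p` is
open; all-zero peaks are dropped. Raw counts (not binarised) are
weighted — the IDF transform is named, not specified, upstream, and
this algebraic form is the package's choice. A truncated SVD (IRLBA for
large matrices, dense SVD when small) gives barcode coordinates
`V diag(d)` in 15 components by default (dimensionality is
configurable; nothing upstream fixes it). Component signs are fixed by
making the largest-magnitude peak loading positive, so the embedding is
reproducible. Each barcode vector is then scaled to unit L2 norm — the
depth normalisation applied before any clustering.

Two clusterings are provided:

* **k-medoids** over k = 3–6: alternating assignment/medoid-update with
  Euclidean distances, at most 100 iterations, objective non-increasing.
  Five deterministic restarts are run per k and the lowest-objective fit
  kept, because the plain alternation can stall in poor local optima.
  The k with the largest mean silhouette width is reported.
* **Graph clustering**: a k-nearest-neighbour graph (k = 15) with
  shared-nearest-neighbour Jaccard edge weights (pruned at 1/15),
  partitioned by multilevel modularity optimisation. Plain modularity
  shatters large homogeneous populations (the resolution limit), so a
  small resolution grid (0.1, 0.25, 0.5, 1) is searched and the
  partition with the best mean silhouette in the embedding is kept —
  the same internal criterion as the k-medoids sweep, and computed
  without reference to any ground truth.

The 2-D map for plots is classical multidimensional scaling of the
embedding distances: deterministic, adequate for visual checks, and
never used for inference (stochastic neighbour embeddings add
hyperparameters without adding testable structure here).

## Annotation and term enrichment

Each peak is assigned to the gene whose TSS is closest, measuring
distance from the nearest peak base (0 if the TSS is inside the peak);
ties break to the lexicographically smallest gene name. Term
enrichment of the peak-related gene set uses the hypergeometric upper
tail `P(X ≥ m)` computed in log space, with `N` the gene universe, `n`
the peak-related genes, `M` the term's genes and `m` their overlap.
The universe defaults to all genes in the supplied term map (the
natural choice when term maps are taken as given); it is configurable.
Benjamini–Hochberg adjustment runs across terms and significance is
FDR < 0.05 (strict). GO-style and KEGG-style analyses differ only in
the term map supplied.

## Motif analysis

PWM counts get a 0.8 pseudocount before normalisation; scores are
natural-log odds against the background, with impossible cells clamped
at −30 nats. The scan threshold for a target p-value (default 1e−7) is
exact: scores are discretised at 1e−3 nats and the null score
distribution of a background-distributed window is built by
position-wise convolution; the threshold is the smallest score whose
upper tail is ≤ the target. When even the most probable window exceeds
the target (e.g. any 8-mer under a uniform background has probability
4⁻⁸ ≈ 1.5e−5 > 1e−7), the threshold is unattainable and the scan
returns no hits by contract. The discretisation resolution was
validated against exhaustive 4^L enumeration for short motifs.

Peaks are ranked by GC fraction and split into 5 equal-frequency
buckets; each bucket gets its own background composition and threshold,
and hits are unified across buckets — this prevents GC-rich peaks from
accumulating spurious GC-rich motif hits. Both strands are scanned with
the same discretised matrices, so scanning and thresholding are exactly
consistent.

Per-cell motif activity is the proportion of the cell's in-peak counts
that fall in motif-bearing peaks (cells with zero counts excluded); the
proportion already divides by per-cell depth, so no second depth
normalisation is applied. The distribution of proportions over cells is
converted to robust z-scores, `z = (x − median) / (1.4826 × MAD)`, with
all z defined as 0 when the MAD is zero.

## Differential accessibility

Cut-site size factors are each cell's total in-peak count divided by
the median total (median factor 1 by construction; zero-total cells are
excluded). The test operates on size-factor-normalised counts
`z = y/s`: per feature, the two group means of `z` are compared with a
two-sided Wald statistic on the log-mean difference, with variances
from the NB mean–variance model `Var = μ + α μ²` using a pooled
method-of-moments dispersion `α` (floored at 1e−8, the Poisson limit).
Working on `y/s` makes every statistic exactly invariant to scaling one
cell's counts and size factor together, which a weighted-sum estimator
would not be. The dispersion convention here is the edgeR-style `α`
(the mixture models use `φ = 1/α` as the NB size, as is natural for
`dnbinom`). Fold changes use a 0.1 pseudocount on normalised means so
they stay finite for empty groups; all-zero features are retained with
p = 1 and FC = 1. BH adjustment runs across features. Cluster-vs-rest
runs the test per cluster against all other cells; reporting filters
are (p < 0.05, |log2 FC| > log2 1.2) two-sided or (p < 0.05, FC > 2)
enriched-only, both strict. The named upstream test is a fast
asymptotic NB-family test; this Wald formulation is the package's
documented concrete choice, and its acceptance surface is agreement
with planted truth, not with any specific library's p-values.

## The synthetic benchmark

`syntheticConfig()` defaults define the standard benchmark used by the
tests and the acceptance script: 2 chromosomes × 1 Mb of i.i.d. random
sequence; 300 non-overlapping 1.5 kb peaks (≥ 1.5 kb apart so merged
calls never bridge two planted peaks); 3 cell types × 200 cells with
each peak assigned to one type at a per-bp cut rate 10× background in
its type; ~200 fragments per cell (Poisson); 2,000 ambient barcodes at
~20 background fragments; fragment lengths from a 75 ± 12 / 250 ± 25 bp
normal mixture (60/40) — nucleosome-free and mono-nucleosome modes;
barcode errors at 0.005/base against a whitelist of random 16-mers with
pairwise Hamming distance ≥ 3 (so ≤ 1-error reads have a unique nearest
barcode); 20% of fragments emitted twice to exercise deduplication; one
planted motif (length-12 consensus-heavy PWM) embedded in 25% of peaks,
preferentially those of its target cell type; 10% of peaks carry a
3-fold case-vs-control effect, with case/control assigned *within* each
type (the `"balanced"` option) so the contrast is orthogonal to cell
type. Gene models place one TSS at each peak centre plus background
genes, which produces the expected TSS enrichment.

What the generator does **not** emulate: realistic genome composition
(repeats, mappability, GC gradients), doublets, per-sample batch
structure, nucleosome phasing beyond the length mixture, index
hopping, or biological co-accessibility between peaks. Passing the
benchmark demonstrates that each algorithm recovers what it models
under its own assumptions at realistic magnitudes — not performance on
real tissue.

## Problem sizes and determinism

The test suite and acceptance script run the full pipeline on the
standard dataset (~190k fragment records, 2 Mb genome, ~1–2 min
end-to-end), the mixture-recovery study on 10⁶ draws, the
barcode-correction study on 10⁴ reads, and the calibration/power
studies on 2,000/500 features × 300–400 cells; these sizes give stable
estimates while keeping a full run interactive. One master seed derives
per-stage seeds by fixed offsets, so stages are independently
reproducible and identical seeds yield byte-identical outputs (verified
via the manifest's MD5 digests). Pipeline stages are resumable: each
stage's outputs are plain files, and `runPipeline(config, resumeFrom =
...)` reloads earlier stages from disk with digest-identical downstream
results.

## Known limitations

* The barcode likelihood assumes independent substitutions and constant
  quality when qualities are absent; indels are not modelled.
* The contamination estimator is a single global fixed count; it does
  not model barcode-specific contamination depth.
* The NB Wald test relies on large-group asymptotics; with very small
  clusters (tens of cells) its calibration degrades, and the singleton
  clusters are skipped outright.
* Exact motif-threshold DP cost grows with motif length × score range;
  at 1e−3 nat resolution this is comfortable for JASPAR-scale motifs
  (≤ ~25 bp) but not for very long PWMs.
* The pipeline assumes one sample; demultiplexing, doublet detection
  and batch correction are out of scope.
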