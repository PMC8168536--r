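# scATACkit

A desk-scale, fully testable reimplementation of the standard single-cell
ATAC-seq processing chain, starting from mapped fragment coordinates:

1. **Barcode correction** — observed 16 bp droplet barcodes are checked
   against a whitelist; barcodes within Hamming distance ≤ 2 of whitelist
   entries are scored with an abundance prior × per-base quality
   likelihood and corrected when the posterior exceeds 90%.
2. **Deduplication and QC** — read pairs with identical 5′ mapping
   positions and barcode collapse into fragments; QC views are the
   fragment-length histogram (nucleosome periodicity) and the
   TSS-enrichment profile.
3. **Peak calling** — per-base transposition events (each fragment
   contributes its two Tn5 insertion sites) are smoothed with a 401 bp
   window and modelled with a ZINBA-like three-component mixture: a
   geometric component for the zero-inflated background, a
   negative-binomial (NB) noise component and an NB signal component,

   P(k) = w₀ Geom(k; p) + w₁ NB(k; μ_n, φ_n) + w₂ NB(k; μ_s, φ_s),

   fitted by EM. Bases whose posterior odds signal:noise reach 1/5 are
   peak bases; intervals within 500 bp are merged into a
   position-sorted BED.
4. **Cell calling** — per-barcode in-peak fragment counts, minus a
   depth-dependent fixed contamination count (rate 0.02), are modelled
   with a two-NB mixture; barcodes with posterior odds ≥ 1,000 for the
   signal component are cells. The peak × cell matrix counts fragment
   ends per peak.
5. **Clustering** — latent semantic analysis: IDF weighting
   log(1 + N/df), truncated SVD (IRLBA), unit-L2 depth normalisation,
   then k-medoids (k = 3–6, silhouette-selected) and
   shared-nearest-neighbour graph clustering, with a 2-D map for plots.
6. **Annotation and enrichment** — peaks are assigned to the gene with
   the closest TSS; term enrichment of peak-related genes uses the
   hypergeometric upper tail

   P = 1 − Σ_{i=0}^{m−1} C(M,i) C(N−M, n−i) / C(N,n)

   with Benjamini–Hochberg FDR < 0.05.
7. **Motif analysis** — JASPAR PWMs are scanned over peak sequences at
   an exact p-value threshold of 1e−7 (dynamic-programming score
   distribution, GC-bucketed backgrounds, both strands); per-cell motif
   activity is the in-motif-peak proportion of reads converted to a
   robust z-score, z = (x − median)/(1.4826 · MAD).
8. **Differential accessibility** — cut-site size factors
   (total / median total), an NB Wald test with method-of-moments
   dispersion per feature, cluster-vs-rest and case-vs-control
   contrasts, filtered at (p < 0.05, |FC| > 1.2) or (p < 0.05, FC > 2).

Because real droplet experiments are too large to re-analyse at desk
scale, the package ships a first-class synthetic-data generator
(`simulateDataset()`) that plants cell types, peaks, motif occurrences
and case-vs-control effects with known ground truth, and every stage is
validated against that truth.

It is written Bioconductor-style: peaks are `GRanges`, the count matrix
is a `SummarizedExperiment` with a sparse assay, genomes are
`DNAStringSet`s, and the mixture fits are S4 classes with validity
checks.

## Worked example

```r
library(scATACkit)

cfg <- syntheticConfig(seed = 1, nCellTypes = 3, cellsPerType = 30,
                       nAmbientBarcodes = 200, nPeaks = 60,
                       chromLength = 300000L, whitelistSize = 400L,
                       fragmentsPerCellMean = 150)
ds  <- simulateDataset(cfg, dir = "demo_data", groupLabels = "balanced")
pc  <- pipelineConfig(inputDir = "demo_data", outDir = "demo_out", seed = 5)
run <- runPipeline(pc)
report <- pipelineReport(run, ds$truth)

run$zinba
#> ZinbaMixture (zero-inflated geometric + 2 NB)
#>   weights: zero 0.039, noise 0.840, signal 0.121
#>   pGeom 0.019 | noise mu 17.610 phi 26.153 | signal mu 52.607 phi 50.119
#>   logLik -2185515.10 after 181 EM iterations

report$clusters
#>  cluster cells     ratio
#>        0    30 0.3333333
#>        1    30 0.3333333
#>        2    30 0.3333333

report$scorecard
#>         metric value
#>     clusterARI     1
#>  cellPrecision     1
#>     cellRecall     1
```

The fitted mixture separates the background (noise mean ≈ 18 smoothed
events) from open chromatin (signal mean ≈ 53); 85 peaks and 90 cells
are called (the 90 planted cells, no ambient barcode), the three planted
cell types are recovered exactly (adjusted Rand index 1.0), and each
cluster shows ~60 differentially accessible peaks against the rest at
(p < 0.05, |FC| > 1.2) — the planted type-specific peaks.

A command-line wrapper with `simulate` and `run` subcommands is
installed under `inst/scripts/scatac.R`:

```sh
Rscript inst/scripts/scatac.R simulate --seed 1 --out demo_data
Rscript inst/scripts/scatac.R run --in demo_data --out demo_out --seed 5
```

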