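## shared fixtures, generated once per test run

.fixtures <- new.env()

## small dataset: quick, used by most unit tests
smallFixture <- function() {
    if (is.null(.fixtures$small)) {
        cfg <- syntheticConfig(seed = 11L, nChroms = 2L,
                               chromLength = 250000L, nCellTypes = 3L,
                               cellsPerType = 25L, nAmbientBarcodes = 150L,
                               nPeaks = 40L, whitelistSize = 300L,
                               fragmentsPerCellMean = 150)
        ds <- simulateDataset(cfg, groupLabels = "balanced")
        dedup <- deduplicateFragments(
            correctFragmentBarcodes(ds$fragments, ds$whitelist))
        .fixtures$small <- list(cfg = cfg, ds = ds, dedup = dedup)
    }
    .fixtures$small
}

## standard benchmark dataset: 2 Mb genome, 300 peaks, 3 x 200 cells
standardFixture <- function() {
    if (is.null(.fixtures$standard)) {
        dir <- file.path(tempdir(), "scatac-standard")
        cfg <- syntheticConfig(seed = 101L)
        ds <- simulateDataset(cfg, dir = dir, groupLabels = "balanced")
        .fixtures$standard <- list(cfg = cfg, ds = ds, dir = dir)
    }
    .fixtures$standard
}

## one full pipeline run on the standard dataset, shared across tests
standardRun <- function() {
    if (is.null(.fixtures$run)) {
        fx <- standardFixture()
        outDir <- file.path(tempdir(), "scatac-standard-out")
        pc <- pipelineConfig(inputDir = fx$dir, outDir = outDir,
                             seed = 202L)
        .fixtures$run <- list(run = runPipeline(pc), config = pc)
    }
    .fixtures$run
}

## Jaccard overlap between two GRanges peak sets
peakJaccard <- function(a, b) {
    suppressWarnings({
        inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b)))
        uni <- sum(GenomicRanges::width(GenomicRanges::union(a, b)))
    })
    inter / uni
}

## random PWM for motif tests
randomPwm <- function(len, seed, id = "test") {
    set.seed(seed)
    mat <- matrix(sample(1:30, 4L * len, replace = TRUE), 4, len,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    list(id = id, name = id, matrix = mat)
}

## random DNA string with given base probabilities
randomSeq <- function(n, seed, prob = rep(0.25, 4)) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
          collapse = "")
}
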