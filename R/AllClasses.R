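#' @import methods
#' @importFrom stats median mad quantile rnbinom rpois rbinom runif rnorm
#'   dnbinom dgeom kmeans optimize p.adjust pnorm setNames cmdscale dist
#'   var sd
#' @importFrom utils head tail read.table write.table
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Configuration for the synthetic scATAC-seq data generator
#'
#' Holds every knob of the synthetic dataset: genome geometry, cell-type
#' layout, fragment yield, barcode noise, fragment-length mixture, planted
#' motifs and planted case-vs-control differential effects.  The defaults
#' describe the standard benchmark dataset used throughout the package:
#' a 2 Mb genome with 300 planted peaks, 3 cell types of 200 cells each,
#' in-peak transposition rates 10-fold above background, and a bimodal
#' fragment-length distribution (nucleosome-free ~75 bp, mono-nucleosome
#' ~250 bp).
#'
#' @slot seed integer master seed; every random draw derives from it.
#' @slot nChroms number of chromosomes.
#' @slot chromLength chromosome length in bp (all chromosomes equal).
#' @slot nCellTypes number of planted cell types.
#' @slot cellsPerType cells per type.
#' @slot nAmbientBarcodes number of ambient (non-cell) barcodes.
#' @slot nPeaks number of planted accessible peaks.
#' @slot peakWidth peak width in bp.
#' @slot fragmentsPerCellMean Poisson mean of per-cell fragment count.
#' @slot ambientFragmentsMean Poisson mean of per-ambient-barcode fragments.
#' @slot barcodeErrorRate per-base substitution probability in emitted
#'   barcodes.
#' @slot fragLenModes data.frame with columns `mean`, `sd`, `weight`;
#'   weights sum to 1.
#' @slot plantedMotifs data.frame with columns `pwm` (id) and `fraction`
#'   (fraction of peaks carrying the consensus).
#' @slot diffFraction fraction of peaks given a case-vs-control effect.
#' @slot diffFold multiplicative accessibility effect in case cells.
#' @slot signalFold per-bp transposition rate in an accessible peak relative
#'   to background.
#' @slot whitelistSize number of whitelist barcodes.
#' @slot dupRate probability a fragment is emitted twice (pre-dedup).
#' @exportClass SyntheticConfig
setClass("SyntheticConfig", representation(
    seed = "integer", nChroms = "integer", chromLength = "integer",
    nCellTypes = "integer", cellsPerType = "integer",
    nAmbientBarcodes = "integer", nPeaks = "integer", peakWidth = "integer",
    fragmentsPerCellMean = "numeric", ambientFragmentsMean = "numeric",
    barcodeErrorRate = "numeric", fragLenModes = "data.frame",
    plantedMotifs = "data.frame", diffFraction = "numeric",
    diffFold = "numeric", signalFold = "numeric", whitelistSize = "integer",
    dupRate = "numeric"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    counts <- c(object@nChroms, object@chromLength, object@nCellTypes,
                object@cellsPerType, object@nAmbientBarcodes, object@nPeaks,
                object@peakWidth, object@whitelistSize)
    if (any(counts < 0L)) msg <- c(msg, "all counts must be >= 0")
    probs <- c(object@barcodeErrorRate, object@diffFraction, object@dupRate)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (nrow(object@fragLenModes) > 0 &&
        abs(sum(object@fragLenModes$weight) - 1) > 1e-8)
        msg <- c(msg, "fragment-length mode weights must sum to 1")
    if (object@diffFold <= 0) msg <- c(msg, "diffFold must be > 0")
    if (object@signalFold <= 0) msg <- c(msg, "signalFold must be > 0")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' Records everything the generator planted so downstream stages can be
#' scored against it: the barcode-to-cell-type map (with `"ambient"` for
#' non-cell barcodes), the true peak intervals, per-type per-peak
#' accessibility rates, planted motif sites, and the indices of peaks
#' carrying a case-vs-control effect.
#'
#' @slot barcodeType named character vector, barcode -> cell-type label or
#'   `"ambient"`.
#' @slot truePeaks [GenomicRanges::GRanges] of planted peaks.
#' @slot typeAccessibility numeric matrix, types x peaks, relative per-bp
#'   transposition rates.
#' @slot plantedMotifSites data.frame (pwm, chrom, start, end, strand).
#' @slot diffPeaks integer indices into `truePeaks` with the group effect.
#' @slot genes data.frame of synthetic gene models (name, chrom, tss,
#'   strand).
#' @exportClass SyntheticTruth
setClass("SyntheticTruth", representation(
    barcodeType = "character", truePeaks = "GRanges",
    typeAccessibility = "matrix", plantedMotifSites = "data.frame",
    diffPeaks = "integer", genes = "data.frame"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (length(object@barcodeType) && is.null(names(object@barcodeType)))
        msg <- c(msg, "barcodeType must be named by barcode")
    if (any(object@diffPeaks < 1L) ||
        any(object@diffPeaks > length(object@truePeaks)))
        msg <- c(msg, "diffPeaks must index truePeaks")
    if (length(msg)) msg else TRUE
})

#' Three-component zero-inflated count mixture for peak calling
#'
#' Parameters of the per-base count model: a geometric component absorbing
#' the zero-inflated background, a negative-binomial noise component and a
#' negative-binomial signal component.  Negative binomials are
#' parameterised by mean \eqn{\mu} and dispersion \eqn{\phi} with variance
#' \eqn{\mu + \mu^2/\phi} (i.e. \eqn{\phi} is the `size` of
#' [stats::dnbinom()]).
#'
#' @slot weights numeric length 3 (zero, noise, signal), summing to 1.
#' @slot pGeom geometric parameter of the zero-inflation component.
#' @slot muNoise,phiNoise noise NB mean and dispersion.
#' @slot muSignal,phiSignal signal NB mean and dispersion.
#' @slot logLik final fit log-likelihood.
#' @slot nIter EM iterations used.
#' @slot degenerate TRUE when the input was all-zero and no mixture could
#'   be fit (no peaks callable).
#' @exportClass ZinbaMixture
setClass("ZinbaMixture", representation(
    weights = "numeric", pGeom = "numeric",
    muNoise = "numeric", phiNoise = "numeric",
    muSignal = "numeric", phiSignal = "numeric",
    logLik = "numeric", logLikTrace = "numeric", nIter = "integer",
    degenerate = "logical"))

setValidity("ZinbaMixture", function(object) {
    msg <- character()
    if (length(object@weights) != 3L || any(object@weights < 0) ||
        abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must be 3 non-negative values summing to 1")
    if (object@pGeom <= 0 || object@pGeom > 1)
        msg <- c(msg, "pGeom must be in (0, 1]")
    if (!object@degenerate) {
        if (object@muNoise < 0 || object@muSignal < 0)
            msg <- c(msg, "means must be >= 0")
        if (object@phiNoise <= 0 || object@phiSignal <= 0)
            msg <- c(msg, "dispersions must be > 0")
        if (object@muSignal <= object@muNoise)
            msg <- c(msg, "muSignal must exceed muNoise")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ZinbaMixture", function(object) {
    cat("ZinbaMixture (zero-inflated geometric + 2 NB)\n")
    if (object@degenerate) {
        cat("  degenerate fit: all observations zero\n")
        return(invisible(NULL))
    }
    cat(sprintf("  weights: zero %.3f, noise %.3f, signal %.3f\n",
                object@weights[1], object@weights[2], object@weights[3]))
    cat(sprintf("  pGeom %.3f | noise mu %.3f phi %.3f | signal mu %.3f phi %.3f\n",
                object@pGeom, object@muNoise, object@phiNoise,
                object@muSignal, object@phiSignal))
    cat(sprintf("  logLik %.2f after %d EM iterations\n",
                object@logLik, object@nIter))
    invisible(NULL)
})

#' Two-component negative-binomial mixture for cell calling
#'
#' Separates per-barcode in-peak fragment counts into an ambient (noise)
#' and a cell (signal) component.  A barcode is called a cell when the
#' posterior odds of the signal component against the noise component
#' reach `oddsThreshold` (default 1,000).
#'
#' @slot weights numeric length 2 (noise, signal) summing to 1.
#' @slot muNoise,phiNoise,muSignal,phiSignal component parameters (NB with
#'   variance \eqn{\mu + \mu^2/\phi}).
#' @slot fixedCount contamination count subtracted before fitting.
#' @slot oddsThreshold posterior odds required to call a cell.
#' @slot logLik,nIter fit diagnostics.
#' @slot degenerate TRUE when EM collapsed to one component.
#' @exportClass TwoNbModel
setClass("TwoNbModel", representation(
    weights = "numeric",
    muNoise = "numeric", phiNoise = "numeric",
    muSignal = "numeric", phiSignal = "numeric",
    fixedCount = "numeric", oddsThreshold = "numeric",
    logLik = "numeric", nIter = "integer", degenerate = "logical"))

setValidity("TwoNbModel", function(object) {
    msg <- character()
    if (length(object@weights) != 2L || any(object@weights < 0) ||
        abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must be 2 non-negative values summing to 1")
    if (!object@degenerate && object@muSignal <= object@muNoise)
        msg <- c(msg, "muSignal must exceed muNoise")
    if (length(msg)) msg else TRUE
})

setMethod("show", "TwoNbModel", function(object) {
    cat("TwoNbModel (cell calling)\n")
    cat(sprintf("  weights: noise %.3f, signal %.3f | fixed count %g | odds %g\n",
                object@weights[1], object@weights[2], object@fixedCount,
                object@oddsThreshold))
    cat(sprintf("  noise mu %.2f phi %.3f | signal mu %.2f phi %.3f%s\n",
                object@muNoise, object@phiNoise, object@muSignal,
                object@phiSignal,
                if (object@degenerate) " [degenerate]" else ""))
    invisible(NULL)
})

#' Latent semantic analysis embedding of barcodes
#'
#' Truncated-SVD coordinates of barcodes in the IDF-weighted peak space.
#' Coordinates are right singular vectors scaled by singular values;
#' [l2Normalize()] rescales every barcode to the unit sphere (the depth
#' normalisation used before clustering).
#'
#' @slot coords numeric matrix, barcodes x components.
#' @slot singularValues decreasing singular values.
#' @slot normalized TRUE after L2 depth normalisation.
#' @exportClass LsaEmbedding
setClass("LsaEmbedding", representation(
    coords = "matrix", singularValues = "numeric", normalized = "logical"))

setValidity("LsaEmbedding", function(object) {
    msg <- character()
    if (ncol(object@coords) != length(object@singularValues))
        msg <- c(msg, "one singular value per component required")
    if (is.unsorted(rev(object@singularValues)))
        msg <- c(msg, "singular values must be decreasing")
    if (object@normalized && nrow(object@coords) > 0) {
        n2 <- sqrt(rowSums(object@coords^2))
        if (any(abs(n2 - 1) > 1e-9))
            msg <- c(msg, "normalized embedding rows must have unit norm")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "LsaEmbedding", function(object) {
    cat(sprintf("LsaEmbedding: %d barcodes x %d components%s\n",
                nrow(object@coords), ncol(object@coords),
                if (object@normalized) " (L2-normalized)" else ""))
    invisible(NULL)
})

#' @describeIn LsaEmbedding-class barcode coordinate matrix.
#' @param embedding an `LsaEmbedding`.
#' @export
embeddingCoords <- function(embedding) {
    stopifnot(is(embedding, "LsaEmbedding"))
    embedding@coords
}

#' @describeIn LsaEmbedding-class singular values of the decomposition.
#' @export
singularValues <- function(embedding) {
    stopifnot(is(embedding, "LsaEmbedding"))
    embedding@singularValues
}
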