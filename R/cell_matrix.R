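#' Per-barcode fragment tallies against a peak set
#'
#' Counts, per barcode, the total deduplicated fragments and how many of
#' them intersect any peak (half-open interval intersection).
#'
#' @param frags fragment data.frame.
#' @param peaks [GenomicRanges::GRanges] of peaks.
#' @return data.frame with `barcode`, `totalFragments`,
#'   `fragmentsInPeaks` and `adjustedCount` (initialised to
#'   `fragmentsInPeaks`; see [subtractContamination()]).
#' @export
barcodeStats <- function(frags, peaks) {
    if (nrow(frags) == 0L)
        return(data.frame(barcode = character(0),
                          totalFragments = integer(0),
                          fragmentsInPeaks = integer(0),
                          adjustedCount = integer(0)))
    barcodes <- sort(unique(frags$barcode))
    total <- table(factor(frags$barcode, levels = barcodes))
    inPeak <- integer(length(barcodes))
    if (length(peaks) > 0L) {
        fr <- fragmentsToGRanges(frags)
        ov <- GenomicRanges::findOverlaps(fr, peaks)
        hitFrag <- unique(S4Vectors::queryHits(ov))
        inPeak <- as.integer(table(factor(frags$barcode[hitFrag],
                                          levels = barcodes)))
    }
    data.frame(barcode = barcodes,
               totalFragments = as.integer(total),
               fragmentsInPeaks = inPeak,
               adjustedCount = inPeak)
}

#' Subtract the whitelist-contamination fixed count
#'
#' Models cross-droplet contamination as a depth-dependent fixed count:
#' `rate` times the mean in-peak count over barcodes with at least one
#' fragment, rounded, is subtracted from every barcode's in-peak count
#' (clamped at zero).
#'
#' @param stats data.frame from [barcodeStats()].
#' @param rate assumed contamination rate (default 0.02).
#' @return the stats data.frame with `adjustedCount` replaced; the
#'   subtracted count is attached as attribute `fixedCount`.
#' @export
subtractContamination <- function(stats, rate = 0.02) {
    withFrag <- stats$totalFragments >= 1L
    fixed <- if (any(withFrag))
        round(rate * mean(stats$fragmentsInPeaks[withFrag])) else 0
    stats$adjustedCount <- pmax(0L, stats$fragmentsInPeaks -
                                    as.integer(fixed))
    attr(stats, "fixedCount") <- as.integer(fixed)
    stats
}

## two-component NB mixture EM on non-negative integer counts,
## value-aggregated; initialisation splits at the 90th percentile
fitTwoNb <- function(values, seed = 1L, tol = 1e-6, maxIter = 500L) {
    values <- as.integer(values)
    n <- length(values)
    tab <- table(values)
    k <- as.integer(names(tab))
    nk <- as.numeric(tab)
    set.seed(seed)
    cut <- quantile(values, 0.9)
    hi <- values > cut
    if (!any(hi) || all(hi)) {
        ## single-component data: all-or-nothing call
        m <- mean(values)
        v <- var(values)
        phi <- if (is.na(v) || v <= m) 100 else max(0.1, m^2 / (v - m))
        return(list(w = c(1, 0), muN = m, phiN = phi,
                    muS = m * (1 + 1e-6), phiS = phi,
                    logLik = NA_real_, nIter = 0L, degenerate = TRUE))
    }
    momPhi <- function(x) {
        m <- mean(x); v <- var(x)
        if (is.na(v) || v <= m) 100 else min(1e4, max(0.05, m^2 / (v - m)))
    }
    muN <- max(mean(values[!hi]), 1e-6)
    muS <- max(mean(values[hi]), muN * 1.01)
    phiN <- momPhi(values[!hi]); phiS <- momPhi(values[hi])
    w <- c(mean(!hi), mean(hi))
    prev <- -Inf; iter <- 0L; ll <- NA_real_
    while (iter < maxIter) {
        iter <- iter + 1L
        ld <- cbind(dnbinom(k, size = phiN, mu = muN, log = TRUE),
                    dnbinom(k, size = phiS, mu = muS, log = TRUE))
        lw <- sweep(ld, 2, log(pmax(w, 1e-300)), "+")
        m <- apply(lw, 1, max)
        lse <- m + log(rowSums(exp(lw - m)))
        ll <- sum(nk * lse)
        r <- exp(lw - lse)
        rw <- r * nk
        cw <- colSums(rw)
        w <- pmax(cw / n, 1e-12); w <- w / sum(w)
        muN <- max(sum(rw[, 1] * k) / max(cw[1], 1e-12), 1e-6)
        muS <- max(sum(rw[, 2] * k) / max(cw[2], 1e-12), 1e-6)
        phiN <- nbDispersionUpdate(k, rw[, 1], muN, phiN)
        phiS <- nbDispersionUpdate(k, rw[, 2], muS, phiS)
        if (is.finite(prev) && ll - prev < tol) break
        prev <- ll
    }
    if (muS < muN) {
        tmp <- c(muN, phiN, w[1])
        muN <- muS; phiN <- phiS; w[1] <- w[2]
        muS <- tmp[1]; phiS <- tmp[2]; w[2] <- tmp[3]
    }
    degen <- abs(muS - muN) / max(muS, 1e-6) < 1e-3
    if (muS <= muN) muS <- muN * (1 + 1e-6)
    list(w = w, muN = muN, phiN = phiN, muS = muS, phiS = phiS,
         logLik = ll, nIter = iter, degenerate = degen)
}

#' Separate cell from non-cell barcodes
#'
#' Fits a two-component negative-binomial mixture to the
#' contamination-adjusted in-peak counts and calls a barcode a cell when
#' the posterior odds of the signal (cell) component against the noise
#' (ambient) component reach `oddsThreshold`.
#'
#' @param stats data.frame from [subtractContamination()].
#' @param seed EM initialisation seed.
#' @param oddsThreshold posterior odds required (default 1,000).
#' @return list with `model` ([TwoNbModel-class]) and `cells` (character
#'   vector of cell barcodes).
#' @export
callCells <- function(stats, seed = 1L, oddsThreshold = 1000) {
    fixed <- attr(stats, "fixedCount")
    if (is.null(fixed)) fixed <- 0L
    if (nrow(stats) == 0L) {
        model <- new("TwoNbModel", weights = c(1, 0), muNoise = 0,
                     phiNoise = 1, muSignal = 1e-6, phiSignal = 1,
                     fixedCount = as.numeric(fixed),
                     oddsThreshold = oddsThreshold, logLik = NA_real_,
                     nIter = 0L, degenerate = TRUE)
        return(list(model = model, cells = character(0)))
    }
    fit <- fitTwoNb(stats$adjustedCount, seed = seed)
    model <- new("TwoNbModel", weights = as.numeric(fit$w),
                 muNoise = fit$muN, phiNoise = fit$phiN,
                 muSignal = fit$muS, phiSignal = fit$phiS,
                 fixedCount = as.numeric(fixed),
                 oddsThreshold = oddsThreshold,
                 logLik = as.numeric(fit$logLik),
                 nIter = as.integer(fit$nIter), degenerate = fit$degenerate)
    cells <- cellOdds(model, stats$adjustedCount) >= oddsThreshold
    if (model@degenerate) {
        warning("cell-calling mixture collapsed to one component; ",
                "all-or-nothing call")
    }
    list(model = model, cells = stats$barcode[cells])
}

#' Posterior odds cell:ambient under a fitted two-NB model
#'
#' @param model a [TwoNbModel-class].
#' @param counts adjusted in-peak counts.
#' @return numeric odds.
#' @export
cellOdds <- function(model, counts) {
    if (model@degenerate) return(rep(0, length(counts)))
    ls <- log(model@weights[2]) +
        dnbinom(counts, size = model@phiSignal, mu = model@muSignal,
                log = TRUE)
    ln <- log(model@weights[1]) +
        dnbinom(counts, size = model@phiNoise, mu = model@muNoise,
                log = TRUE)
    exp(ls - ln)
}

#' Build the peak-by-barcode count matrix
#'
#' Entry (p, b) counts the fragment ends (start and `end - 1` separately)
#' of barcode b that fall inside peak p; barcodes not in `cells` are
#' dropped.
#'
#' @param frags fragment data.frame.
#' @param peaks [GenomicRanges::GRanges] of peaks.
#' @param cells character vector of cell barcodes to keep.
#' @return a [SummarizedExperiment::RangedSummarizedExperiment] with a
#'   sparse `counts` assay, `rowRanges` the peaks and one column per cell
#'   barcode.
#' @export
buildMatrix <- function(frags, peaks, cells) {
    cells <- sort(unique(cells))
    frags <- frags[frags$barcode %in% cells, , drop = FALSE]
    counts <- Matrix::sparseMatrix(
        i = integer(0), j = integer(0), x = numeric(0),
        dims = c(length(peaks), length(cells)))
    if (nrow(frags) > 0L && length(peaks) > 0L) {
        ends <- data.frame(chrom = rep(frags$chrom, 2L),
                           pos = c(frags$start, frags$end - 1L),
                           barcode = rep(frags$barcode, 2L))
        evGr <- GenomicRanges::GRanges(ends$chrom,
                                       IRanges::IRanges(ends$pos + 1L,
                                                        width = 1L))
        ov <- GenomicRanges::findOverlaps(evGr, peaks)
        if (length(ov) > 0L) {
            pi <- S4Vectors::subjectHits(ov)
            bi <- match(ends$barcode[S4Vectors::queryHits(ov)], cells)
            counts <- Matrix::sparseMatrix(
                i = pi, j = bi, x = rep(1, length(pi)),
                dims = c(length(peaks), length(cells)))
        }
    }
    colnames(counts) <- cells
    rownames(counts) <- paste0("peak", seq_along(peaks))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowRanges = peaks,
        colData = S4Vectors::DataFrame(barcode = cells, row.names = cells))
}
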