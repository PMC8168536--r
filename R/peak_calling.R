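#' Count transposition events per base
#'
#' Each fragment contributes one event at its start and one at `end - 1`
#' (the two Tn5 insertion positions); duplicate counts are ignored since
#' deduplicated fragments are unique molecules.  Fragments outside the
#' chromosome bounds are rejected with a message.
#'
#' @param frags fragment data.frame.
#' @param chromLengths named integer vector, chromosome -> length (bp).
#' @return named list, chromosome -> integer vector of per-base event
#'   counts (index 1 is base 0).
#' @export
countEvents <- function(frags, chromLengths) {
    track <- lapply(chromLengths, function(n) integer(n))
    if (nrow(frags) == 0L) return(track)
    known <- frags$chrom %in% names(chromLengths)
    inb <- known & frags$start >= 0L &
        frags$end <= chromLengths[frags$chrom]
    if (any(!inb))
        message("rejected ", sum(!inb), " out-of-bounds fragment(s)")
    frags <- frags[inb, , drop = FALSE]
    for (cn in unique(frags$chrom)) {
        sel <- frags$chrom == cn
        pos <- c(frags$start[sel], frags$end[sel] - 1L) + 1L
        track[[cn]] <- tabulate(pos, nbins = chromLengths[[cn]])
    }
    track
}

#' Smooth an event track with a centred moving window
#'
#' The smoothed value at base i is the total event count within
#' `(window - 1)/2` bp on either side, clipped at chromosome edges.
#'
#' @param track integer vector of per-base event counts, or a named list
#'   of them (one per chromosome).
#' @param window odd window width in bp (default 401).
#' @return smoothed track of the same shape.
#' @export
smoothEvents <- function(track, window = 401L) {
    if (window %% 2L != 1L) stop("smoothing window must be odd")
    half <- (window - 1L) %/% 2L
    smoothOne <- function(x) {
        n <- length(x)
        if (n == 0L) return(integer(0))
        cs <- c(0, cumsum(as.numeric(x)))
        hi <- pmin(seq_len(n) + half, n)
        lo <- pmax(seq_len(n) - half - 1L, 0L)
        as.integer(cs[hi + 1L] - cs[lo + 1L])
    }
    if (is.list(track)) lapply(track, smoothOne) else smoothOne(track)
}

## log densities of the three components at integer counts k
zinbaLogDens <- function(k, p, muN, phiN, muS, phiS) {
    cbind(dgeom(k, prob = p, log = TRUE),
          dnbinom(k, size = phiN, mu = muN, log = TRUE),
          dnbinom(k, size = phiS, mu = muS, log = TRUE))
}

## weighted NB dispersion update: maximize the weighted log-likelihood in
## log(phi), never returning a worse value than the current one (GEM step)
nbDispersionUpdate <- function(k, w, mu, phiCur) {
    obj <- function(logPhi)
        sum(w * dnbinom(k, size = exp(logPhi), mu = mu, log = TRUE))
    opt <- optimize(obj, interval = c(log(1e-3), log(1e6)), maximum = TRUE)
    if (opt$objective >= obj(log(phiCur))) exp(opt$maximum) else phiCur
}

#' Fit the three-component zero-inflated count mixture
#'
#' EM fit of the per-base smoothed count model: a geometric component for
#' the zero-inflated background, a negative-binomial noise component and a
#' negative-binomial signal component.  Zeros receive mass from all three
#' components and EM apportions them.  The fit is a generalised EM (the
#' dispersion update never decreases the expected complete-data
#' log-likelihood), so the observed log-likelihood trace is
#' non-decreasing.
#'
#' @param values non-negative integer observations (e.g. smoothed counts
#'   at a uniform subsample of bases).
#' @param seed seed for the k-means initialisation.
#' @param tol EM stops when the log-likelihood gain drops below `tol`.
#' @param maxIter maximum EM iterations; the default is generous because
#'   the zero and noise components overlap heavily and full convergence
#'   can take several thousand cheap iterations.
#' @return a [ZinbaMixture-class]; degenerate (weights (1,0,0)) when all
#'   observations are zero.
#' @export
fitZinba <- function(values, seed = 1L, tol = 1e-6, maxIter = 5000L) {
    values <- as.integer(values)
    if (any(values < 0L)) stop("counts must be non-negative")
    n <- length(values)
    if (n == 0L || all(values == 0L)) {
        return(new("ZinbaMixture", weights = c(1, 0, 0), pGeom = 1,
                   muNoise = 0, phiNoise = 1, muSignal = 1, phiSignal = 1,
                   logLik = 0, logLikTrace = numeric(0), nIter = 0L,
                   degenerate = TRUE))
    }
    tab <- table(values)
    k <- as.integer(names(tab))
    nk <- as.numeric(tab)

    ## initialization: zeros seed the zero component, 1-D k-means on
    ## log1p(nonzero) seeds the two NB components
    set.seed(seed)
    nz <- values[values > 0L]
    lnz <- log1p(nz)
    centers <- unique(quantile(lnz, c(0.25, 0.75)))
    if (length(centers) < 2L) {
        cl <- rep(1L, length(nz))
        muInit <- c(mean(nz), mean(nz) * 3)
        phiInit <- c(1, 1)
    } else {
        km <- kmeans(lnz, centers = matrix(centers, ncol = 1))
        ord <- order(km$centers)
        cl <- match(km$cluster, ord)
        muInit <- vapply(1:2, function(g) mean(nz[cl == g]), numeric(1))
        phiInit <- vapply(1:2, function(g) {
            m <- mean(nz[cl == g]); v <- var(nz[cl == g])
            if (is.na(v) || v <= m) 100 else min(1e4, max(0.1, m^2 / (v - m)))
        }, numeric(1))
    }
    n0 <- sum(values == 0L)
    wZero <- max(0.05, 0.5 * n0 / n)
    rest <- 1 - wZero
    wNoise <- rest * sum(cl == 1L) / length(nz)
    wSignal <- rest - wNoise
    w <- pmax(c(wZero, wNoise, wSignal), 1e-4)
    w <- w / sum(w)
    p <- 0.9
    muN <- max(muInit[1], 1e-6); phiN <- phiInit[1]
    muS <- max(muInit[2], muN * 1.01); phiS <- phiInit[2]

    trace <- numeric(0)
    prev <- -Inf
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        ld <- zinbaLogDens(k, p, muN, phiN, muS, phiS)
        lw <- sweep(ld, 2, log(w), "+")
        m <- apply(lw, 1, max)
        lse <- m + log(rowSums(exp(lw - m)))
        ll <- sum(nk * lse)
        trace <- c(trace, ll)
        r <- exp(lw - lse)            # responsibilities per unique value
        rw <- r * nk                  # weighted responsibilities
        cw <- colSums(rw)
        w <- pmax(cw / n, 1e-12)
        w <- w / sum(w)
        ## geometric: MLE p = 1 / (1 + weighted mean)
        mZero <- sum(rw[, 1] * k) / max(cw[1], 1e-12)
        p <- min(1, max(1e-6, 1 / (1 + mZero)))
        muN <- max(sum(rw[, 2] * k) / max(cw[2], 1e-12), 1e-6)
        muS <- max(sum(rw[, 3] * k) / max(cw[3], 1e-12), 1e-6)
        phiN <- nbDispersionUpdate(k, rw[, 2], muN, phiN)
        phiS <- nbDispersionUpdate(k, rw[, 3], muS, phiS)
        if (is.finite(prev) && ll - prev < tol) break
        prev <- ll
    }
    ## identifiability: signal is the larger-mean NB component
    if (muS < muN) {
        tmp <- c(muN, phiN, w[2]); muN <- muS; phiN <- phiS; w[2] <- w[3]
        muS <- tmp[1]; phiS <- tmp[2]; w[3] <- tmp[3]
    }
    if (muS <= muN) muS <- muN * (1 + 1e-6)
    new("ZinbaMixture", weights = as.numeric(w), pGeom = p,
        muNoise = muN, phiNoise = phiN, muSignal = muS, phiSignal = phiS,
        logLik = trace[length(trace)], logLikTrace = trace,
        nIter = iter, degenerate = FALSE)
}

#' Signal:noise posterior odds at given counts
#'
#' Evaluates, under a fitted [ZinbaMixture-class], the posterior odds of
#' the signal component against the noise component at each count.
#'
#' @param model a fitted [ZinbaMixture-class].
#' @param counts integer counts.
#' @return numeric odds (may be `Inf`).
#' @export
zinbaOdds <- function(model, counts) {
    ld <- zinbaLogDens(counts, model@pGeom, model@muNoise, model@phiNoise,
                       model@muSignal, model@phiSignal)
    exp((log(model@weights[3]) + ld[, 3]) -
        (log(model@weights[2]) + ld[, 2]))
}

#' Call peaks from a smoothed event track
#'
#' A base is a peak base when the posterior odds of the signal component
#' against the noise component at its smoothed count reach `odds`
#' (default 1/5).  The odds are monotone in the count above the noise
#' mean, so peak bases form an up-set of the count distribution and the
#' call reduces to thresholding at the smallest count of the final
#' passing run; maximal runs of passing bases become intervals and
#' intervals closer than `mergeDist` are merged.
#'
#' @param smoothed named list (chromosome -> smoothed counts) from
#'   [smoothEvents()].
#' @param model fitted [ZinbaMixture-class].
#' @param odds posterior odds threshold (default 1/5).
#' @param mergeDist merge intervals separated by less than this many bp
#'   (default 500).
#' @return [GenomicRanges::GRanges] of peaks, sorted; the count threshold
#'   is stored in `metadata()$thresholdCount`.
#' @export
callPeaks <- function(smoothed, model, odds = 1 / 5, mergeDist = 500L) {
    if (model@degenerate) {
        warning("degenerate count model: no peaks callable")
        gr <- GenomicRanges::GRanges()
        S4Vectors::metadata(gr)$thresholdCount <- NA_integer_
        return(gr)
    }
    if (!is.list(smoothed)) smoothed <- list(chr = smoothed)
    maxCount <- max(1L, max(unlist(lapply(smoothed, function(x)
        if (length(x)) max(x) else 0L))))
    oddsAt <- zinbaOdds(model, 0:maxCount)
    pass <- oddsAt >= odds
    if (!any(pass)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::metadata(gr)$thresholdCount <- NA_integer_
        return(gr)
    }
    ## the odds are monotone in the count above the noise mean but can be
    ## inflated in the far left tail when the signal component is more
    ## dispersed; the peak threshold is the start of the final up-run
    threshold <- if (all(pass)) 0L else max(which(!pass))  # 0-based + 1 - 1
    runs <- lapply(names(smoothed), function(cn) {
        x <- smoothed[[cn]]
        sig <- x >= threshold
        if (!any(sig)) return(NULL)
        r <- rle(sig)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values
        data.frame(chrom = cn, start = starts[keep], end = ends[keep])
    })
    runs <- do.call(rbind, runs)
    if (is.null(runs) || nrow(runs) == 0L) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::metadata(gr)$thresholdCount <- as.integer(threshold)
        return(gr)
    }
    gr <- GenomicRanges::GRanges(runs$chrom,
                                 IRanges::IRanges(runs$start, runs$end))
    gr <- GenomicRanges::reduce(GenomicRanges::sort(gr),
                                min.gapwidth = mergeDist)
    S4Vectors::metadata(gr)$thresholdCount <- as.integer(threshold)
    gr
}

#' Peak calling from fragments in one call
#'
#' Convenience wrapper: counts events, smooths, fits the count mixture on
#' a uniform subsample of bases, and calls peaks on all bases.
#'
#' @param frags fragment data.frame.
#' @param chromLengths named integer vector of chromosome lengths.
#' @param window smoothing window (bp, odd).
#' @param odds posterior odds threshold.
#' @param mergeDist merge distance (bp).
#' @param seed seed for the EM initialisation and base subsample.
#' @param maxFitBases fit the mixture on at most this many bases.
#' @return list with `peaks` (GRanges), `model` ([ZinbaMixture-class]) and
#'   `smoothed` tracks.
#' @export
callPeaksFromFragments <- function(frags, chromLengths, window = 401L,
                                   odds = 1 / 5, mergeDist = 500L,
                                   seed = 1L, maxFitBases = 1000000L) {
    track <- countEvents(frags, chromLengths)
    smoothed <- smoothEvents(track, window)
    allVals <- unlist(smoothed, use.names = FALSE)
    set.seed(deriveSeed(seed, "zinba"))
    if (length(allVals) > maxFitBases)
        allVals <- allVals[sort(sample.int(length(allVals), maxFitBases))]
    model <- fitZinba(allVals, seed = deriveSeed(seed, "zinba"))
    peaks <- callPeaks(smoothed, model, odds = odds, mergeDist = mergeDist)
    list(peaks = peaks, model = model, smoothed = smoothed)
}
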