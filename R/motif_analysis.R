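## log-odds score matrix (nats) of a PWM against a background, with a
## pseudocount added to each count before normalisation; -Inf cells
## (possible only at pseudocount 0) are clamped at -30 nats
pwmLogOdds <- function(pwm, background, pseudocount = 0.8) {
    mat <- pwm$matrix + pseudocount
    probs <- sweep(mat, 2, colSums(mat), "/")
    lo <- log(probs) - log(background)
    lo[!is.finite(lo)] <- -30
    pmax(lo, -30)
}

#' Exact log-odds score threshold for a target p-value
#'
#' Computes the exact null distribution of a PWM's log-odds score for a
#' random background sequence by position-wise convolution over scores
#' discretised at `resolution` (nats), and returns the smallest score
#' whose upper-tail probability is at most `pvalue`.  When even the
#' maximum score is more probable than `pvalue`, the threshold is
#' unattainable (`Inf`) and scanning yields no hits by contract.
#'
#' @param pwm PWM as from [readJaspar()] (list with `matrix`, 4 x L).
#' @param background base frequencies (A, C, G, T), summing to 1.
#' @param pvalue target upper-tail probability (default 1e-7).
#' @param resolution score discretisation in nats (default 1e-3).
#' @param pseudocount added to PWM counts before normalisation
#'   (default 0.8).
#' @return list with `threshold` (nats, possibly `Inf`), `intThreshold`,
#'   `resolution`, `intScores` (discretised 4 x L score matrix),
#'   `scores` (score grid, nats) and `tail` (upper-tail probability at
#'   each grid score).
#' @export
scoreThreshold <- function(pwm, background, pvalue = 1e-7,
                           resolution = 1e-3, pseudocount = 0.8) {
    if (pvalue <= 0 || pvalue >= 1)
        stop("pvalue must lie strictly between 0 and 1")
    if (abs(sum(background) - 1) > 1e-6)
        stop("background frequencies must sum to 1")
    lo <- pwmLogOdds(pwm, background, pseudocount)
    intScores <- round(lo / resolution)
    L <- ncol(intScores)
    lows <- apply(intScores, 2, min)
    highs <- apply(intScores, 2, max)
    minTot <- sum(lows)
    p <- 1    # point mass at score 0; index k maps to minTot + k - 1 at the end
    for (j in seq_len(L)) {
        acc <- numeric(length(p) + highs[j] - lows[j])
        for (b in 1:4) {
            sh <- intScores[b, j] - lows[j]
            acc[(1 + sh):(length(p) + sh)] <-
                acc[(1 + sh):(length(p) + sh)] + p * background[b]
        }
        p <- acc
    }
    scoresInt <- minTot + seq_along(p) - 1L
    tail <- rev(cumsum(rev(p)))
    idx <- which(tail <= pvalue)
    if (length(idx) > 0L) {
        intThreshold <- scoresInt[min(idx)]
        threshold <- intThreshold * resolution
    } else {
        intThreshold <- Inf
        threshold <- Inf
    }
    list(threshold = threshold, intThreshold = intThreshold,
         resolution = resolution, intScores = intScores,
         scores = scoresInt * resolution, tail = tail)
}

## base codes 1..4 for A/C/G/T, NA otherwise
seqToCodes <- function(s) {
    match(strsplit(toupper(s), "")[[1]], BASES)
}

## reverse complement of a PWM score/count matrix
reverseComplementMatrix <- function(mat) {
    out <- mat[c("T", "G", "C", "A"), rev(seq_len(ncol(mat))), drop = FALSE]
    rownames(out) <- BASES
    out
}

#' Scan peak sequences for PWM matches above a threshold
#'
#' Scores every window of every peak on both strands with the discretised
#' log-odds matrix used for the threshold computation, and reports
#' windows whose score meets the threshold.  Peaks shorter than the
#' motif are skipped.
#'
#' @param peakSeqs character vector (or [Biostrings::DNAStringSet]) of
#'   peak sequences.
#' @param pwm PWM (list with `matrix`).
#' @param thresholdObj per-peak threshold objects from
#'   [scoreThreshold()]: either one object used for all peaks, or a list
#'   indexed by the peak's bucket via `bucketOf`.
#' @param bucketOf optional integer vector mapping each peak to its
#'   bucket (when `thresholdObj` is a per-bucket list).
#' @return data.frame of hits: `pwm`, `peak`, `offset` (0-based within
#'   the peak), `strand`, `score` (nats).
#' @export
scanPeaks <- function(peakSeqs, pwm, thresholdObj, bucketOf = NULL) {
    peakSeqs <- as.character(peakSeqs)
    perBucket <- !is.null(bucketOf)
    hits <- list(); hi <- 0L
    L <- ncol(pwm$matrix)
    for (i in seq_along(peakSeqs)) {
        th <- if (perBucket) thresholdObj[[bucketOf[i]]] else thresholdObj
        if (!is.finite(th$intThreshold)) next
        codes <- seqToCodes(peakSeqs[i])
        n <- length(codes)
        if (n < L) next
        fwd <- th$intScores
        rev <- reverseComplementMatrix(th$intScores)
        nWin <- n - L + 1L
        scF <- numeric(nWin); scR <- numeric(nWin)
        ok <- rep(TRUE, nWin)
        for (j in seq_len(L)) {
            cj <- codes[j:(n - L + j)]
            bad <- is.na(cj)
            ok <- ok & !bad
            cj[bad] <- 1L
            scF <- scF + fwd[cbind(cj, j)]
            scR <- scR + rev[cbind(cj, j)]
        }
        fHit <- which(ok & scF >= th$intThreshold)
        rHit <- which(ok & scR >= th$intThreshold)
        if (length(fHit)) {
            hi <- hi + 1L
            hits[[hi]] <- data.frame(pwm = pwm$id, peak = i,
                                     offset = fHit - 1L, strand = "+",
                                     score = scF[fHit] * th$resolution)
        }
        if (length(rHit)) {
            hi <- hi + 1L
            hits[[hi]] <- data.frame(pwm = pwm$id, peak = i,
                                     offset = rHit - 1L, strand = "-",
                                     score = scR[rHit] * th$resolution)
        }
    }
    if (hi == 0L)
        return(data.frame(pwm = character(0), peak = integer(0),
                          offset = integer(0), strand = character(0),
                          score = numeric(0)))
    out <- do.call(rbind, hits)
    out[order(out$peak, out$offset, out$strand), , drop = FALSE]
}

#' Extract peak sequences from a genome
#'
#' @param genome [Biostrings::DNAStringSet], one entry per chromosome.
#' @param peaks [GenomicRanges::GRanges].
#' @return character vector of peak sequences.
#' @export
peakSequences <- function(genome, peaks) {
    bed <- grangesToBed(peaks)
    vapply(seq_len(nrow(bed)), function(i)
        as.character(Biostrings::subseq(genome[[bed$chrom[i]]],
                                        start = bed$start[i] + 1L,
                                        end = bed$end[i])), character(1))
}

#' GC-content buckets and per-bucket background frequencies
#'
#' Ranks peaks by GC fraction and splits them into `nBuckets`
#' equal-frequency buckets (sizes differing by at most one); each
#' bucket's background is the base composition of its member peaks.  With
#' fewer peaks than buckets a single bucket is used.
#'
#' @param peakSeqs character vector of peak sequences.
#' @param nBuckets number of buckets (default 5).
#' @return list with `bucketOf` (peak -> bucket) and `backgrounds` (list
#'   of A/C/G/T frequency vectors).
#' @export
gcBuckets <- function(peakSeqs, nBuckets = 5L) {
    peakSeqs <- as.character(peakSeqs)
    n <- length(peakSeqs)
    if (n == 0L) stop("no peaks")
    if (n < nBuckets) nBuckets <- 1L
    counts <- vapply(peakSeqs, function(s) {
        codes <- seqToCodes(s)
        tabulate(codes, nbins = 4L)
    }, numeric(4))
    gc <- (counts[2, ] + counts[3, ]) / pmax(colSums(counts), 1)
    rk <- rank(gc, ties.method = "first")
    bucketOf <- ceiling(rk * nBuckets / n)
    backgrounds <- lapply(seq_len(nBuckets), function(b) {
        tot <- rowSums(counts[, bucketOf == b, drop = FALSE])
        f <- tot / sum(tot)
        names(f) <- BASES
        f
    })
    list(bucketOf = as.integer(bucketOf), backgrounds = backgrounds)
}

#' Scan all PWMs over peaks with GC-matched backgrounds
#'
#' Buckets peaks by GC content, derives one exact score threshold per
#' bucket per PWM, scans each peak against its bucket's threshold and
#' unifies the hits across buckets into one list.
#'
#' @param peakSeqs character vector of peak sequences.
#' @param pwms named list of PWMs.
#' @param pvalue scan p-value threshold (default 1e-7).
#' @param nBuckets GC buckets (default 5).
#' @param pseudocount PWM pseudocount (default 0.8).
#' @return data.frame of hits across all PWMs (see [scanPeaks()]).
#' @export
scanAllMotifs <- function(peakSeqs, pwms, pvalue = 1e-7, nBuckets = 5L,
                          pseudocount = 0.8) {
    gb <- gcBuckets(peakSeqs, nBuckets)
    out <- lapply(pwms, function(pwm) {
        ths <- lapply(gb$backgrounds, function(bg)
            scoreThreshold(pwm, bg, pvalue = pvalue,
                           pseudocount = pseudocount))
        scanPeaks(peakSeqs, pwm, ths, bucketOf = gb$bucketOf)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-barcode motif accessibility proportions
#'
#' For each PWM, the fraction of a barcode's in-peak fragment-end counts
#' that fall in motif-bearing peaks.  Barcodes with zero total counts are
#' excluded.
#'
#' @param se peak-by-barcode [SummarizedExperiment::SummarizedExperiment]
#'   (assay `counts`).
#' @param hits motif hit data.frame from [scanAllMotifs()].
#' @return named list, PWM id -> named numeric vector of proportions.
#' @export
motifProportions <- function(se, hits) {
    m <- SummarizedExperiment::assay(se, "counts")
    totals <- Matrix::colSums(m)
    keep <- totals > 0
    pwms <- unique(hits$pwm)
    out <- lapply(pwms, function(id) {
        pk <- unique(hits$peak[hits$pwm == id])
        num <- Matrix::colSums(m[pk, , drop = FALSE])
        (num / totals)[keep]
    })
    names(out) <- pwms
    out
}

#' Modified z-scores from the median and scaled MAD
#'
#' Robust z-scores: `z = (x - median) / (1.4826 * MAD)` with `MAD =
#' median(|x - median|)`.  When the MAD is zero every z-score is defined
#' as 0.
#'
#' @param values numeric vector (at least 2 values).
#' @return numeric vector of modified z-scores (names preserved).
#' @export
madZscore <- function(values) {
    if (length(values) < 2L) stop("need at least 2 values")
    med <- median(values)
    madv <- median(abs(values - med))
    if (madv == 0) return(setNames(rep(0, length(values)), names(values)))
    (values - med) / (1.4826 * madv)
}

#' Per-barcode motif enrichment z-scores
#'
#' Combines [motifProportions()] and [madZscore()]: for every PWM the
#' distribution of per-barcode proportions is converted to robust
#' z-scores over barcodes.
#'
#' @param se peak-by-barcode matrix.
#' @param hits motif hits.
#' @return named list, PWM id -> named numeric z-score vector.
#' @export
motifZscores <- function(se, hits) {
    props <- motifProportions(se, hits)
    lapply(props, madZscore)
}
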