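#' Whitelist barcodes within a Hamming-distance bound
#'
#' Finds every whitelist barcode within `maxDist` substitutions of the
#' observed sequence.  `N` bases count as a mismatch against every base.
#'
#' @param sequence observed barcode (16 characters of A/C/G/T/N).
#' @param whitelist character vector of whitelist 16-mers.
#' @param maxDist maximum Hamming distance (default 2).
#' @return data.frame with columns `barcode` and `distance`, ordered by
#'   increasing distance; zero rows when nothing is within reach.
#' @export
hammingCandidates <- function(sequence, whitelist, maxDist = 2L) {
    len <- nchar(whitelist[1])
    if (nchar(sequence) != len)
        stop("barcode read length (", nchar(sequence),
             ") does not match whitelist length (", len, ")")
    readChars <- strsplit(sequence, "")[[1]]
    wlChars <- matrix(unlist(strsplit(whitelist, "")), ncol = len,
                      byrow = TRUE)
    d <- rowSums(sweep(wlChars, 2, readChars, FUN = "!="))
    keep <- which(d <= maxDist)
    keep <- keep[order(d[keep])]
    data.frame(barcode = whitelist[keep], distance = as.integer(d[keep]))
}

## substitution-model likelihood of an observed read given a true barcode:
## mismatch bases were sequencing errors (prob 10^(-Q/10), uniform over the
## three wrong bases), match bases were read correctly
readLikelihood <- function(readChars, candChars, qualities) {
    e <- 10^(-qualities / 10)
    mism <- readChars != candChars
    prod(ifelse(mism, e / 3, 1 - e))
}

#' Posterior barcode correction against a whitelist
#'
#' Scores each Hamming-distance candidate with an abundance prior
#' (observed exact-match count + 1 pseudocount) times a per-base quality
#' likelihood, normalises over candidates, and corrects to the top
#' candidate when its posterior exceeds `minPosterior` (strictly).  An
#' exact whitelist match is returned unchanged with posterior 1.  Reads
#' with more than two `N` bases are discarded (no candidates).
#'
#' @param sequence observed barcode string.
#' @param qualities per-base Phred scores (scalar recycled, or a vector of
#'   the barcode length).
#' @param whitelist character vector of whitelist barcodes.
#' @param abundance named numeric, whitelist barcode -> exact-match count;
#'   missing entries count as 0.
#' @param maxDist maximum Hamming distance for candidates.
#' @param minPosterior posterior required to correct (default 0.9; a
#'   posterior of exactly 0.9 is not corrected).
#' @return list with `corrected` (barcode or `NA`), `posterior` and
#'   `candidates` (data.frame: barcode, distance, posterior).
#' @export
posteriorCorrect <- function(sequence, qualities = 30, whitelist,
                             abundance = NULL, maxDist = 2L,
                             minPosterior = 0.9) {
    len <- nchar(whitelist[1])
    qualities <- rep_len(qualities, len)
    emptyCand <- data.frame(barcode = character(0), distance = integer(0),
                            posterior = numeric(0))
    nN <- lengths(regmatches(sequence, gregexpr("N", sequence)))
    if (nN > 2L)
        return(list(corrected = NA_character_, posterior = 0,
                    candidates = emptyCand))
    if (sequence %in% whitelist) {
        return(list(corrected = sequence, posterior = 1,
                    candidates = data.frame(barcode = sequence,
                                            distance = 0L, posterior = 1)))
    }
    cand <- hammingCandidates(sequence, whitelist, maxDist)
    if (nrow(cand) == 0L)
        return(list(corrected = NA_character_, posterior = 0,
                    candidates = emptyCand))
    readChars <- strsplit(sequence, "")[[1]]
    lik <- vapply(cand$barcode, function(b)
        readLikelihood(readChars, strsplit(b, "")[[1]], qualities),
        numeric(1))
    prior <- if (is.null(abundance)) rep(1, nrow(cand)) else {
        a <- abundance[cand$barcode]
        a[is.na(a)] <- 0
        a + 1
    }
    post <- prior * lik
    post <- post / sum(post)
    cand$posterior <- as.numeric(post)
    best <- which.max(post)
    corrected <- if (post[best] > minPosterior)
        cand$barcode[best] else NA_character_
    list(corrected = corrected,
         posterior = as.numeric(post[best]),
         candidates = cand)
}

## chunked one-hot matrix product: Hamming distances reads x whitelist
hammingDistanceMatrix <- function(reads, whitelist, len = 16L) {
    wlHot <- barcodeOneHot(whitelist, len)
    out <- matrix(0L, nrow = length(reads), ncol = length(whitelist))
    chunk <- 2000L
    for (s in seq(1L, length(reads), by = chunk)) {
        idx <- s:min(s + chunk - 1L, length(reads))
        rHot <- barcodeOneHot(reads[idx], len)
        out[idx, ] <- len - as.integer(rHot %*% t(wlHot))
    }
    out
}

#' Correct a vector of observed barcodes against a whitelist
#'
#' Vectorised correction for fragment streams: exact whitelist matches are
#' kept and define the abundance prior; every other distinct sequence is
#' corrected with [posteriorCorrect()] under a constant Phred quality
#' (fragment files carry no per-base qualities).
#'
#' @param barcodes character vector of observed barcode sequences.
#' @param whitelist character vector of whitelist barcodes.
#' @param quality constant Phred score assumed for every base (default 30).
#' @param maxDist,minPosterior see [posteriorCorrect()].
#' @return character vector aligned with `barcodes`: the corrected
#'   whitelist barcode, or `NA` where no confident correction exists.
#' @export
correctBarcodes <- function(barcodes, whitelist, quality = 30,
                            maxDist = 2L, minPosterior = 0.9) {
    if (length(barcodes) == 0L) return(character(0))
    len <- nchar(whitelist[1])
    out <- rep(NA_character_, length(barcodes))
    exact <- barcodes %in% whitelist
    out[exact] <- barcodes[exact]
    abundance <- table(factor(barcodes[exact], levels = whitelist))
    abundance <- setNames(as.numeric(abundance), whitelist)

    todo <- unique(barcodes[!exact])
    todo <- todo[nchar(todo) == len &
                 lengths(regmatches(todo, gregexpr("N", todo))) <= 2L]
    if (length(todo) > 0L) {
        dmat <- hammingDistanceMatrix(todo, whitelist, len)
        e <- 10^(-quality / 10)
        fixed <- vapply(seq_along(todo), function(i) {
            ci <- which(dmat[i, ] <= maxDist)
            if (length(ci) == 0L) return(NA_character_)
            d <- dmat[i, ci]
            lik <- (e / 3)^d * (1 - e)^(len - d)
            post <- (abundance[whitelist[ci]] + 1) * lik
            post <- post / sum(post)
            best <- which.max(post)
            if (post[best] > minPosterior) whitelist[ci[best]]
            else NA_character_
        }, character(1))
        map <- setNames(fixed, todo)
        sel <- !exact & barcodes %in% todo
        out[sel] <- map[barcodes[sel]]
    }
    out
}

#' Correct the barcode column of a fragment stream
#'
#' Applies [correctBarcodes()] to a fragment data.frame and drops records
#' whose barcode could not be confidently assigned.
#'
#' @param frags fragment data.frame (see [readFragments()]).
#' @param whitelist character vector of whitelist barcodes.
#' @param ... passed to [correctBarcodes()].
#' @return the fragment data.frame with corrected barcodes, uncorrectable
#'   records removed.
#' @export
correctFragmentBarcodes <- function(frags, whitelist, ...) {
    corrected <- correctBarcodes(frags$barcode, whitelist, ...)
    keep <- !is.na(corrected)
    frags <- frags[keep, , drop = FALSE]
    frags$barcode <- corrected[keep]
    rownames(frags) <- NULL
    frags
}
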