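#' Deduplicate a read-pair stream into fragments
#'
#' Read pairs whose two 5' mapping positions and barcode are identical are
#' collapsed into one fragment whose `dupCount` records the multiplicity.
#' Records with `end <= start` are rejected (with a message naming the
#' count).  Output is position-sorted.
#'
#' @param pairs data.frame with columns `chrom`, `start`, `end`,
#'   `barcode` (a `dupCount` column, if present, is summed).
#' @return position-sorted fragment data.frame with `dupCount` >= 1.
#' @export
deduplicateFragments <- function(pairs) {
    if (nrow(pairs) == 0L)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), barcode = character(0),
                          dupCount = integer(0)))
    bad <- pairs$end <= pairs$start
    if (any(bad)) {
        message("rejected ", sum(bad), " record(s) with end <= start")
        pairs <- pairs[!bad, , drop = FALSE]
    }
    w <- if ("dupCount" %in% names(pairs)) pairs$dupCount else
        rep(1L, nrow(pairs))
    key <- paste(pairs$chrom, pairs$start, pairs$end, pairs$barcode,
                 sep = "\r")
    agg <- rowsum(as.integer(w), key)
    first <- !duplicated(key)
    out <- pairs[first, c("chrom", "start", "end", "barcode"), drop = FALSE]
    out$dupCount <- as.integer(agg[key[first], 1])
    out <- out[order(out$chrom, out$start, out$end, out$barcode), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fragment-length histogram
#'
#' Counts unique fragments per length (`end - start`); duplicate counts
#' are not multiplied in.  The periodic structure of this histogram
#' (nucleosome-free and mono-nucleosome modes) is the standard first QC
#' view of an ATAC library.
#'
#' @param frags fragment data.frame.
#' @return named integer vector, length -> number of fragments.
#' @export
lengthHistogram <- function(frags) {
    if (nrow(frags) == 0L) return(setNames(integer(0), character(0)))
    tab <- table(frags$end - frags$start)
    setNames(as.integer(tab), names(tab))
}

#' TSS enrichment profile and score
#'
#' Aggregates transposition events (each fragment contributes its start
#' and `end - 1`) into offsets relative to every TSS within `window` bp,
#' flipping offsets for minus-strand genes so "downstream" always means
#' downstream of transcription.  The curve is normalised so its outermost
#' 100 bp flanks average 1: each offset's count + 1 is divided by the mean
#' flank count + 1.  The enrichment score is the curve value at offset 0.
#'
#' @param frags fragment data.frame.
#' @param genes gene models: data.frame with `chrom`, `tss` (0-based bp)
#'   and `strand`.
#' @param window half-width of the profile in bp (default 2000).
#' @return list with `offsets`, `counts`, `curve` (normalised) and
#'   `score`.
#' @export
tssEnrichment <- function(frags, genes, window = 2000L) {
    if (nrow(genes) == 0L) stop("gene list is empty")
    offsets <- (-window):window
    counts <- integer(length(offsets))
    if (nrow(frags) > 0L) {
        events <- data.frame(
            chrom = rep(frags$chrom, 2L),
            pos = c(frags$start, frags$end - 1L))
        evGr <- GenomicRanges::GRanges(events$chrom,
                                       IRanges::IRanges(events$pos + 1L,
                                                        width = 1L))
        tssGr <- GenomicRanges::GRanges(
            genes$chrom,
            IRanges::IRanges(pmax(1L, genes$tss + 1L - window),
                             genes$tss + 1L + window))
        ov <- GenomicRanges::findOverlaps(evGr, tssGr)
        if (length(ov) > 0L) {
            off <- events$pos[S4Vectors::queryHits(ov)] -
                genes$tss[S4Vectors::subjectHits(ov)]
            flip <- genes$strand[S4Vectors::subjectHits(ov)] == "-"
            off[flip] <- -off[flip]
            off <- off[abs(off) <= window]
            counts <- counts + tabulate(off + window + 1L,
                                        nbins = length(offsets))
        }
    }
    flankIdx <- c(seq_len(100L), length(offsets) - 99:0)
    flankMean <- mean(counts[flankIdx])
    curve <- (counts + 1) / (flankMean + 1)
    list(offsets = offsets, counts = counts, curve = curve,
         score = curve[window + 1L])
}

#' Full QC profile of a deduplicated fragment set
#'
#' Convenience wrapper producing the two QC views at once: the
#' fragment-length histogram and the TSS enrichment profile.
#'
#' @param frags fragment data.frame.
#' @param genes gene models (see [tssEnrichment()]).
#' @param window TSS window (bp).
#' @return list with `lengthHistogram`, `tss` and `nFragments`.
#' @export
qcProfile <- function(frags, genes, window = 2000L) {
    list(lengthHistogram = lengthHistogram(frags),
         tss = tssEnrichment(frags, genes, window),
         nFragments = nrow(frags))
}
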