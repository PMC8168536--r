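#' Assign each peak to the gene with the closest TSS
#'
#' Distance from a peak to a TSS is the minimum over peak bases of the
#' absolute offset (0 when the TSS lies inside the peak).  Ties are
#' broken toward the lexicographically smallest gene name.  Peaks on a
#' chromosome with no gene are left unassigned (`NA`) with a message.
#'
#' @param peaks [GenomicRanges::GRanges] of peaks.
#' @param genes gene models: data.frame with `name`, `chrom`, `tss`
#'   (0-based bp) and `strand`.
#' @return data.frame with one row per peak: `peak`, `gene`, `distance`.
#' @export
nearestTss <- function(peaks, genes) {
    if (nrow(genes) == 0L) stop("gene list is empty")
    bed <- grangesToBed(peaks)
    out <- data.frame(peak = seq_along(peaks),
                      gene = rep(NA_character_, length(peaks)),
                      distance = rep(NA_integer_, length(peaks)))
    genes <- genes[order(genes$name), , drop = FALSE]
    for (cn in unique(bed$chrom)) {
        pIdx <- which(bed$chrom == cn)
        g <- genes[genes$chrom == cn, , drop = FALSE]
        if (nrow(g) == 0L) next
        for (i in pIdx) {
            dd <- ifelse(g$tss < bed$start[i], bed$start[i] - g$tss,
                  ifelse(g$tss >= bed$end[i], g$tss - (bed$end[i] - 1L),
                         0L))
            j <- which.min(dd)   # genes sorted by name: ties -> smallest
            out$gene[i] <- g$name[j]
            out$distance[i] <- as.integer(dd[j])
        }
    }
    if (anyNA(out$gene))
        message(sum(is.na(out$gene)),
                " peak(s) on chromosomes without genes left unassigned")
    out
}

#' Upper-tail hypergeometric probability
#'
#' The probability of observing at least `m` annotated genes among `n`
#' draws from a universe of `N` genes of which `M` carry the annotation:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} /
#' \binom{N}{n},} evaluated as the upper tail in log space for numerical
#' stability.
#'
#' @param N universe size.
#' @param n number of drawn (peak-related) genes.
#' @param M genes annotated to the term.
#' @param m drawn genes annotated to the term.
#' @return the upper-tail probability `P(X >= m)`.
#' @export
hypergeomP <- function(N, n, M, m) {
    if (any(c(N, n, M, m) < 0) || m > min(n, M) || n > N || M > N)
        stop("inconsistent hypergeometric arguments")
    if (m == 0) return(1)
    i <- m:min(n, M)
    i <- i[n - i <= N - M]
    if (length(i) == 0) return(0)
    lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
    min(1, exp(logSumExp(lt)))
}

#' Term enrichment of peak-related genes
#'
#' For every term, assembles the 2x2 layout (`N` = universe size, `n` =
#' peak-related genes in the universe, `M` = genes annotated to the term,
#' `m` = peak-related genes annotated to the term), computes the
#' upper-tail hypergeometric p-value, applies Benjamini-Hochberg
#' adjustment across terms, and flags terms with FDR strictly below
#' `fdrCut`.  The same call serves GO-style and KEGG-style maps — only
#' the term-to-gene table changes.
#'
#' @param peakGenes character vector of peak-related gene names.
#' @param termMap data.frame with columns `term` and `gene`.
#' @param universe gene universe; defaults to all genes in `termMap`.
#' @param fdrCut significance threshold on the adjusted p-value
#'   (default 0.05).
#' @return data.frame with `term`, `N`, `n`, `M`, `m`, `p`, `fdr`,
#'   `significant`, ordered by p-value.
#' @export
enrichTerms <- function(peakGenes, termMap, universe = NULL,
                        fdrCut = 0.05) {
    if (is.null(universe)) universe <- unique(termMap$gene)
    universe <- unique(universe)
    if (length(universe) == 0L) stop("empty gene universe")
    termMap <- termMap[termMap$gene %in% universe, , drop = FALSE]
    peakGenes <- intersect(unique(peakGenes), universe)
    N <- length(universe)
    n <- length(peakGenes)
    terms <- unique(termMap$term)
    rows <- lapply(terms, function(tm) {
        tg <- unique(termMap$gene[termMap$term == tm])
        M <- length(tg)
        m <- length(intersect(tg, peakGenes))
        data.frame(term = tm, N = N, n = n, M = M, m = m,
                   p = hypergeomP(N, n, M, m))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        return(data.frame(term = character(0), N = integer(0),
                          n = integer(0), M = integer(0), m = integer(0),
                          p = numeric(0), fdr = numeric(0),
                          significant = logical(0)))
    out$fdr <- p.adjust(out$p, method = "BH")
    out$significant <- out$fdr < fdrCut
    out[order(out$p), , drop = FALSE]
}
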