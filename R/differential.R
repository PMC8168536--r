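#' Relative library sizes from cut-site totals
#'
#' Each cell's size factor is its total in-peak cut-site count divided by
#' the median total over cells, so the median factor is 1.  Cells with a
#' zero total cannot be normalised and are excluded with a message.
#'
#' @param se peak-by-barcode [SummarizedExperiment::SummarizedExperiment]
#'   (assay `counts`), or a matrix.
#' @return named numeric vector of size factors (zero-total cells
#'   absent).
#' @export
cutSiteSizeFactors <- function(se) {
    m <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "counts") else se
    totals <- Matrix::colSums(m)
    zero <- totals == 0
    if (any(zero))
        message("excluding ", sum(zero), " cell(s) with zero total count")
    totals <- totals[!zero]
    totals / median(totals)
}

#' Negative-binomial Wald test for differential accessibility
#'
#' Counts are first put on a common depth scale by dividing each cell by
#' its size factor.  Per feature, the two group means of the normalised
#' counts are compared with a two-sided Wald test on the log-mean
#' difference; the variance model is negative-binomial
#' (`Var = mu + alpha * mu^2`) with a per-feature dispersion `alpha`
#' estimated by the method of moments on the pooled within-group
#' residuals and floored at 1e-8.  Because every statistic is a function
#' of the normalised counts alone, scaling one cell's counts and its size
#' factor together leaves all results unchanged.  P-values are
#' Benjamini-Hochberg adjusted across features.  The fold change is
#' computed on normalised means with a pseudocount of 0.1 so it stays
#' finite for empty groups; features with no counts at all are retained
#' with `p = 1`, `FC = 1`.
#'
#' @param se peak-by-barcode matrix (or SummarizedExperiment).
#' @param groups named character vector barcode -> `"A"`/`"B"` (any two
#'   labels; the first sorted label plays A).
#' @param factors size factors from [cutSiteSizeFactors()]; computed when
#'   missing.
#' @param pseudocount added to normalised means in the fold change.
#' @return data.frame: `feature`, `meanA`, `meanB`, `log2FC`, `p`, `fdr`.
#' @export
nbTest <- function(se, groups, factors = NULL, pseudocount = 0.1) {
    m <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "counts") else se
    if (is.null(colnames(m))) colnames(m) <- names(groups)
    if (is.null(factors)) factors <- cutSiteSizeFactors(m)
    common <- intersect(colnames(m), intersect(names(groups),
                                               names(factors)))
    m <- m[, common, drop = FALSE]
    g <- groups[common]
    s <- factors[common]
    labs <- sort(unique(g))
    if (length(labs) != 2L) stop("exactly two groups required")
    aSel <- g == labs[1]
    bSel <- g == labs[2]
    if (!any(aSel) || !any(bSel)) stop("both groups must be nonempty")

    ## normalised counts: every statistic below is a function of these
    zmat <- sweep(as.matrix(m), 2, s, "/")
    nA <- sum(aSel); nB <- sum(bSel)
    muA <- rowMeans(zmat[, aSel, drop = FALSE])
    muB <- rowMeans(zmat[, bSel, drop = FALSE])
    varA <- if (nA > 1)
        rowSums((zmat[, aSel, drop = FALSE] - muA)^2) / (nA - 1)
        else rep(0, nrow(zmat))
    varB <- if (nB > 1)
        rowSums((zmat[, bSel, drop = FALSE] - muB)^2) / (nB - 1)
        else rep(0, nrow(zmat))

    ## pooled method-of-moments NB dispersion: Var = mu + alpha mu^2
    num <- (nA - 1) * (varA - muA) + (nB - 1) * (varB - muB)
    den <- (nA - 1) * muA^2 + (nB - 1) * muB^2
    alpha <- pmax(num / pmax(den, 1e-12), 1e-8)

    ## Wald test on log(muA) - log(muB); delta-method variances under the
    ## NB mean-variance model
    varMuA <- (muA + alpha * muA^2) / nA
    varMuB <- (muB + alpha * muB^2) / nB
    d <- log(muA) - log(muB)
    se2 <- varMuA / pmax(muA, 1e-12)^2 + varMuB / pmax(muB, 1e-12)^2
    z <- d / sqrt(pmax(se2, 1e-300))
    p <- 2 * pnorm(-abs(z))

    fc <- (muA + pseudocount) / (muB + pseudocount)
    empty <- muA + muB == 0
    p[empty] <- 1
    fc[empty] <- 1
    p[!is.finite(p)] <- 1
    feat <- rownames(m)
    if (is.null(feat)) feat <- as.character(seq_len(nrow(m)))
    data.frame(feature = feat, meanA = muA, meanB = muB,
               log2FC = log2(fc), p = p,
               fdr = p.adjust(p, method = "BH"), row.names = NULL)
}

#' One-vs-rest differential tests per cluster
#'
#' Runs [nbTest()] for every cluster against all other cells.  Singleton
#' clusters are skipped with a warning.
#'
#' @param se peak-by-barcode matrix.
#' @param labels named vector barcode -> cluster id.
#' @param factors size factors (computed when missing).
#' @return named list, cluster id -> [nbTest()] result.
#' @export
clusterVsRest <- function(se, labels, factors = NULL) {
    m <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "counts") else se
    if (is.null(factors)) factors <- cutSiteSizeFactors(m)
    ids <- sort(unique(labels))
    if (length(ids) < 2L) stop("need at least two clusters")
    out <- list()
    for (cl in ids) {
        inCl <- names(labels)[labels == cl]
        if (length(inCl) < 2L) {
            warning("skipping singleton cluster ", cl)
            next
        }
        g <- setNames(ifelse(labels == cl, "A_cluster", "B_rest"),
                      names(labels))
        out[[as.character(cl)]] <- nbTest(m, g, factors)
    }
    out
}

#' Apply the p-value / fold-change filter
#'
#' Two filtering modes mirror the two reporting styles for differential
#' features: `two_sided` keeps features with `p < pCut` and
#' `|log2FC| > log2(fcCut)`; `enriched` keeps `p < pCut` and
#' `FC > fcCut` (enriched only).  Both comparisons are strict.
#'
#' @param results data.frame from [nbTest()].
#' @param pCut p-value cutoff (default 0.05).
#' @param fcCut fold-change cutoff (default 1.2 two-sided; 2 is the
#'   conventional enriched-only cut).
#' @param mode `"two_sided"` or `"enriched"`.
#' @return list with `features` (the surviving rows) and `count`.
#' @export
applyThresholds <- function(results, pCut = 0.05, fcCut = 1.2,
                            mode = c("two_sided", "enriched")) {
    mode <- match.arg(mode)
    if (nrow(results) == 0L)
        return(list(features = results, count = 0L))
    keep <- if (mode == "two_sided")
        results$p < pCut & abs(results$log2FC) > log2(fcCut)
    else
        results$p < pCut & results$log2FC > log2(fcCut)
    list(features = results[keep, , drop = FALSE],
         count = sum(keep))
}
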