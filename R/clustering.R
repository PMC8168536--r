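#' Inverse-document-frequency weighting of a peak-by-barcode matrix
#'
#' Multiplies each peak's counts by `log(1 + nBarcodes / df)`, where `df`
#' is the number of barcodes with a non-zero count at that peak, and
#' drops peaks observed in no barcode.
#'
#' @param se [SummarizedExperiment::SummarizedExperiment] with a `counts`
#'   assay (peaks x barcodes), or a (sparse) matrix.
#' @return sparse weighted matrix (peaks with zero df removed).
#' @export
idfNormalize <- function(se) {
    m <- if (is(se, "SummarizedExperiment"))
        SummarizedExperiment::assay(se, "counts") else se
    if (prod(dim(m)) == 0) stop("matrix is empty")
    df <- Matrix::rowSums(m > 0)
    keep <- df > 0
    m <- m[keep, , drop = FALSE]
    idf <- log(1 + ncol(m) / df[keep])
    Matrix::Diagonal(x = idf) %*% m
}

#' Latent semantic analysis embedding
#'
#' Truncated SVD (IRLBA for large inputs, dense SVD when the matrix is
#' small relative to the requested rank) of the IDF-weighted matrix.
#' Barcode coordinates are right singular vectors scaled by singular
#' values.  The sign of each component is fixed so that the
#' largest-magnitude peak loading is positive, making the embedding
#' reproducible.
#'
#' @param weighted weighted peak-by-barcode matrix from [idfNormalize()].
#' @param nComponents embedding dimensionality (default 15).
#' @param seed seed for the IRLBA starting vector.
#' @return an [LsaEmbedding-class].
#' @export
lsaEmbed <- function(weighted, nComponents = 15L, seed = 1L) {
    nComponents <- as.integer(nComponents)
    if (nComponents >= min(dim(weighted)))
        stop("nComponents must be smaller than both matrix dimensions")
    set.seed(seed)
    if (min(dim(weighted)) <= max(50L, 3L * nComponents)) {
        sv <- svd(as.matrix(weighted), nu = nComponents, nv = nComponents)
        d <- sv$d[seq_len(nComponents)]
        u <- sv$u; v <- sv$v
    } else {
        sv <- irlba::irlba(weighted, nv = nComponents, nu = nComponents)
        d <- sv$d; u <- sv$u; v <- sv$v
    }
    ## deterministic sign: largest-|loading| peak positive per component
    for (j in seq_len(ncol(u))) {
        i <- which.max(abs(u[, j]))
        if (u[i, j] < 0) {
            u[, j] <- -u[, j]
            v[, j] <- -v[, j]
        }
    }
    coords <- sweep(v, 2, d, "*")
    rownames(coords) <- colnames(weighted)
    new("LsaEmbedding", coords = coords, singularValues = as.numeric(d),
        normalized = FALSE)
}

#' L2 depth normalisation of an embedding
#'
#' Scales every barcode's coordinate vector to unit Euclidean norm — the
#' depth normalisation applied before clustering.  Zero vectors cannot be
#' normalised and are dropped with a message.
#'
#' @param embedding an [LsaEmbedding-class].
#' @return the normalised [LsaEmbedding-class].
#' @export
l2Normalize <- function(embedding) {
    coords <- embedding@coords
    nrm <- sqrt(rowSums(coords^2))
    zero <- nrm == 0
    if (any(zero)) {
        message("dropping ", sum(zero), " barcode(s) with zero embedding")
        coords <- coords[!zero, , drop = FALSE]
        nrm <- nrm[!zero]
    }
    new("LsaEmbedding", coords = coords / nrm,
        singularValues = embedding@singularValues, normalized = TRUE)
}

#' k-medoids clustering of an embedding
#'
#' Deterministic (given seed) alternating k-medoids: assign each point to
#' the nearest medoid by Euclidean distance, then recompute each medoid
#' as the member minimising total within-cluster distance, until labels
#' stabilise (at most 100 iterations).  The total within-cluster distance
#' never increases across iterations.  Because the alternation can stall
#' in a poor local optimum, `nStart` independent initialisations (seeds
#' derived from `seed`) are run and the fit with the smallest final
#' objective is kept.
#'
#' @param embedding an [LsaEmbedding-class] (normalised).
#' @param k number of clusters (the classic sweep is 3-6).
#' @param seed seed for the initial medoid draws.
#' @param nStart number of restarts (default 5).
#' @return list with `labels` (named integer, 0-based cluster ids),
#'   `medoids` (row indices) and `objective` (total distance trace of
#'   the winning restart).
#' @export
kmedoidsCluster <- function(embedding, k, seed = 1L, nStart = 5L) {
    x <- embedding@coords
    n <- nrow(x)
    if (n < k) stop("fewer points than clusters")
    d <- as.matrix(dist(x))
    runOnce <- function(s) {
        set.seed(s)
        medoids <- sort(sample.int(n, k))
        objective <- numeric(0)
        labels <- rep(NA_integer_, n)
        for (iter in seq_len(100L)) {
            assign <- max.col(-d[, medoids, drop = FALSE],
                              ties.method = "first")
            objective <- c(objective,
                           sum(d[cbind(seq_len(n), medoids[assign])]))
            if (identical(assign, labels)) break
            labels <- assign
            medoids <- vapply(seq_len(k), function(g) {
                members <- which(assign == g)
                if (length(members) == 0L) return(medoids[g])
                members[which.min(colSums(d[members, members,
                                            drop = FALSE]))]
            }, integer(1))
        }
        list(labels = labels, medoids = medoids, objective = objective)
    }
    best <- NULL
    for (r in seq_len(max(1L, nStart))) {
        fit <- runOnce(seed + (r - 1L) * 7643L)
        if (is.null(best) ||
            tail(fit$objective, 1) < tail(best$objective, 1))
            best <- fit
    }
    labels <- best$labels
    names(labels) <- rownames(x)
    list(labels = labels - 1L, medoids = best$medoids,
         objective = best$objective)
}

## mean silhouette width of a labeling over a distance matrix
meanSilhouette <- function(labels, d) {
    sil <- cluster::silhouette(labels, dmatrix = d)
    if (is.null(dim(sil))) return(NA_real_)
    mean(sil[, "sil_width"])
}

#' k-medoids sweep with silhouette-based model selection
#'
#' Runs [kmedoidsCluster()] for every k in `kRange` and keeps the
#' labeling with the largest mean silhouette width.
#'
#' @param embedding an [LsaEmbedding-class].
#' @param kRange candidate cluster numbers (default 3:6).
#' @param seed seed (one sub-seed per k).
#' @return list with `labels`, `k`, `silhouettes` (named by k).
#' @export
kmedoidsSweep <- function(embedding, kRange = 3:6, seed = 1L) {
    d <- as.matrix(dist(embedding@coords))
    fits <- lapply(kRange, function(k)
        kmedoidsCluster(embedding, k, seed = seed + k))
    sils <- vapply(fits, function(f)
        meanSilhouette(f$labels + 1L, d), numeric(1))
    names(sils) <- kRange
    best <- which.max(sils)
    list(labels = fits[[best]]$labels, k = kRange[best],
         silhouettes = sils)
}

#' Shared-nearest-neighbour graph clustering
#'
#' Builds a k-nearest-neighbour graph on the embedding, weights edges by
#' the Jaccard overlap of neighbourhoods (shared nearest neighbours), and
#' partitions it by multilevel modularity optimisation (Louvain).  Plain
#' modularity tends to shatter large homogeneous populations, so the
#' search runs over a small grid of resolution parameters and the
#' partition with the best mean silhouette width in the embedding is
#' kept — the same internal criterion used for the k-medoids sweep.
#'
#' @param embedding an [LsaEmbedding-class].
#' @param nNeighbors neighbourhood size (default 15).
#' @param seed seed controlling the community search.
#' @param resolutions resolution grid for the modularity objective.
#' @return named integer vector of 0-based cluster ids.
#' @export
graphCluster <- function(embedding, nNeighbors = 15L, seed = 1L,
                         resolutions = c(0.1, 0.25, 0.5, 1)) {
    x <- embedding@coords
    n <- nrow(x)
    if (n <= nNeighbors) stop("need more points than neighbours")
    d <- as.matrix(dist(x))
    nbr <- t(apply(d, 1, function(row)
        order(row)[2:(nNeighbors + 1L)]))   # skip self
    ## SNN weights: Jaccard of neighbour sets over connected pairs
    edges <- NULL
    inc <- Matrix::sparseMatrix(
        i = rep(seq_len(n), each = nNeighbors),
        j = as.vector(t(nbr)), x = 1, dims = c(n, n))
    shared <- inc %*% Matrix::t(inc)
    cand <- Matrix::which(shared > 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    sh <- shared[cand]
    jac <- as.numeric(sh) / (2 * nNeighbors - as.numeric(sh))
    keep <- jac > 1 / 15
    g <- igraph::graph_from_data_frame(
        data.frame(from = cand[keep, 1], to = cand[keep, 2],
                   weight = jac[keep]),
        directed = FALSE,
        vertices = data.frame(name = seq_len(n)))
    best <- NULL
    bestSil <- -Inf
    for (r in resolutions) {
        set.seed(seed)
        comm <- igraph::cluster_louvain(g, resolution = r)
        lab <- igraph::membership(comm)[as.character(seq_len(n))]
        k <- length(unique(lab))
        sil <- if (k < 2L || k >= n) -Inf else meanSilhouette(lab, d)
        if (is.null(best) || sil > bestSil) {
            best <- lab
            bestSil <- sil
        }
    }
    labels <- as.integer(factor(best)) - 1L
    names(labels) <- rownames(x)
    labels
}

#' Two-dimensional map of an embedding for plotting
#'
#' Classical multidimensional scaling of the pairwise Euclidean distances
#' in the LSA space, giving a deterministic 2-D layout.  The map is for
#' visualisation only and is never used for inference.
#'
#' @param embedding an [LsaEmbedding-class].
#' @param seed kept for interface stability; the layout is fully
#'   deterministic.
#' @return n x 2 coordinate matrix.
#' @export
embed2d <- function(embedding, seed = 1L) {
    x <- embedding@coords
    if (nrow(x) == 0L) return(matrix(numeric(0), ncol = 2))
    if (nrow(x) == 1L) return(matrix(0, nrow = 1, ncol = 2,
                                     dimnames = list(rownames(x), NULL)))
    set.seed(seed)
    co <- cmdscale(dist(x), k = 2)
    if (ncol(co) < 2) co <- cbind(co, 0)
    rownames(co) <- rownames(x)
    co
}
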