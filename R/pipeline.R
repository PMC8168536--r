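#' Pipeline configuration
#'
#' Collects input paths, all stage parameters and the master seed into a
#' single serialisable list.  Defaults are the pipeline's fixed working
#' constants: 401 bp smoothing window, 500 bp peak merge distance,
#' peak-base posterior odds 1/5, cell-calling odds 1,000, contamination
#' rate 0.02, motif scan p-value 1e-7 with 5 GC buckets, 15 LSA
#' components, k-medoids sweep over 3-6 clusters, and the p < 0.05 /
#' |FC| > 1.2 (two-sided) and FC > 2 (enriched) reporting filters.
#'
#' @param inputDir directory containing the standard input files
#'   (`fragments.tsv`, `whitelist.txt`, `genome.fa`, `genes.bed`,
#'   `terms.tsv`, `pwms.jaspar`, optional `groups.tsv`); individual paths
#'   may be overridden.
#' @param outDir output directory.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param fragments,whitelist,genome,genes,terms,pwms,groups explicit
#'   input paths (override `inputDir`).
#' @param window,mergeDist,peakOdds peak-calling parameters.
#' @param contamination,cellOddsThreshold cell-calling parameters.
#' @param scanPvalue,nBuckets motif-scan parameters.
#' @param nComponents,kRange,nNeighbors clustering parameters.
#' @param pCut,fcCut,fcCutEnriched differential reporting filters.
#' @return a named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(inputDir = NULL, outDir, seed = 1L,
                           fragments = NULL, whitelist = NULL,
                           genome = NULL, genes = NULL, terms = NULL,
                           pwms = NULL, groups = NULL,
                           window = 401L, mergeDist = 500L,
                           peakOdds = 1 / 5, contamination = 0.02,
                           cellOddsThreshold = 1000,
                           scanPvalue = 1e-7, nBuckets = 5L,
                           nComponents = 15L, kRange = 3:6,
                           nNeighbors = 15L, pCut = 0.05, fcCut = 1.2,
                           fcCutEnriched = 2) {
    pick <- function(x, name) {
        if (!is.null(x)) return(x)
        if (is.null(inputDir)) return(NULL)
        file.path(inputDir, name)
    }
    cfg <- list(
        fragments = pick(fragments, "fragments.tsv"),
        whitelist = pick(whitelist, "whitelist.txt"),
        genome = pick(genome, "genome.fa"),
        genes = pick(genes, "genes.bed"),
        terms = pick(terms, "terms.tsv"),
        pwms = pick(pwms, "pwms.jaspar"),
        groups = pick(groups, "groups.tsv"),
        outDir = outDir, seed = as.integer(seed),
        window = as.integer(window), mergeDist = as.integer(mergeDist),
        peakOdds = peakOdds, contamination = contamination,
        cellOddsThreshold = cellOddsThreshold, scanPvalue = scanPvalue,
        nBuckets = as.integer(nBuckets),
        nComponents = as.integer(nComponents), kRange = as.integer(kRange),
        nNeighbors = as.integer(nNeighbors), pCut = pCut, fcCut = fcCut,
        fcCutEnriched = fcCutEnriched)
    if (!is.null(cfg$groups) && !file.exists(cfg$groups)) cfg$groups <- NULL
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Save / load a pipeline configuration
#'
#' @param config a `PipelineConfig`.
#' @param path JSON file path.
#' @return `loadPipelineConfig` returns the restored `PipelineConfig`.
#' @export
savePipelineConfig <- function(config, path) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' @rdname savePipelineConfig
#' @export
loadPipelineConfig <- function(path) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg$seed <- as.integer(cfg$seed)
    cfg$kRange <- as.integer(cfg$kRange)
    class(cfg) <- "PipelineConfig"
    cfg
}

PIPELINE_STAGES <- c("correct", "qc", "peaks", "cells", "cluster",
                     "annotate", "motifs", "differential")

## record one completed stage in the manifest
stageRecord <- function(params, outputs, t0, status = "ok") {
    list(params = params,
         outputs = as.list(outputs),
         md5 = as.list(tools::md5sum(unlist(outputs))),
         seconds = round(as.numeric(Sys.time()) - t0, 3),
         status = status)
}

#' Run the full pipeline
#'
#' Executes barcode correction, deduplication + QC, peak calling, cell
#' calling + matrix construction, clustering, annotation + enrichment,
#' motif analysis and differential accessibility, writing each stage's
#' outputs under `config$outDir` and recording parameters, output file
#' digests and runtimes in a manifest.  A failing stage is recorded in
#' the manifest with its error message and downstream stages are not
#' run.  Identical inputs and seed yield identical output digests.
#'
#' With `resumeFrom`, stages before the named one are not recomputed:
#' their results are reloaded from the output files of a previous run in
#' the same `outDir`, so a resumed run reproduces the from-scratch
#' digests of all downstream stages.
#'
#' @param config a [pipelineConfig()] list.
#' @param resumeFrom optional stage name (`"correct"`, `"qc"`,
#'   `"peaks"`, `"cells"`, `"cluster"`, `"annotate"`, `"motifs"`,
#'   `"differential"`) to resume from.
#' @return list with `manifest`, the in-memory stage results (`peaks`,
#'   `cells`, `matrix`, `labels`, ...), and `ok` (logical).
#' @export
runPipeline <- function(config, resumeFrom = NULL) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(resumeFrom))
        resumeFrom <- match.arg(resumeFrom, PIPELINE_STAGES)
    recompute <- function(stage) is.null(resumeFrom) ||
        match(stage, PIPELINE_STAGES) >= match(resumeFrom, PIPELINE_STAGES)
    manifest <- list()
    result <- list(manifest = NULL, ok = FALSE)
    fail <- function(stage, e) {
        manifest[[stage]] <<- list(status = "failed",
                                   error = conditionMessage(e))
        result$manifest <<- manifest
        writeManifest(manifest, config)
        result
    }
    out <- function(...) file.path(config$outDir, ...)

    ## stage 1: barcode correction
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        if (recompute("correct")) {
            frags <- readFragments(config$fragments)
            wl <- readLines(config$whitelist)
            corrected <- correctFragmentBarcodes(frags, wl)
            writeFragments(corrected, out("fragments.corrected.tsv"))
            corrected
        } else readFragments(out("fragments.corrected.tsv"))
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("correct", res))
    manifest$correct <- stageRecord(
        list(), out("fragments.corrected.tsv"), t0,
        if (recompute("correct")) "ok" else "resumed")
    corrected <- res

    ## stage 2: deduplication + QC
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        genes <- bedToGeneModels(read.table(config$genes, sep = "\t"))
        if (recompute("qc")) {
            dedup <- deduplicateFragments(corrected)
            qc <- qcProfile(dedup, genes)
            writeFragments(dedup, out("fragments.dedup.tsv"))
            jsonlite::write_json(list(
                nFragments = qc$nFragments,
                tssScore = qc$tss$score,
                lengthHistogram = as.list(qc$lengthHistogram)),
                out("qc.json"), auto_unbox = TRUE, digits = NA)
            list(dedup = dedup, genes = genes, qc = qc)
        } else list(dedup = readFragments(out("fragments.dedup.tsv")),
                    genes = genes, qc = NULL)
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("qc", res))
    manifest$qc <- stageRecord(
        list(), c(out("fragments.dedup.tsv"), out("qc.json")), t0,
        if (recompute("qc")) "ok" else "resumed")
    dedup <- res$dedup; genes <- res$genes; qc <- res$qc

    ## stage 3: peak calling
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        genome <- Biostrings::readDNAStringSet(config$genome)
        names(genome) <- sub("\\s.*", "", names(genome))
        chromLengths <- setNames(Biostrings::width(genome), names(genome))
        if (recompute("peaks")) {
            if (nrow(dedup) == 0L)
                stop("no fragments available for peak calling")
            pk <- callPeaksFromFragments(dedup, chromLengths,
                                         window = config$window,
                                         odds = config$peakOdds,
                                         mergeDist = config$mergeDist,
                                         seed = config$seed)
            if (length(pk$peaks) == 0L)
                stop("peak calling produced no peaks (degenerate or ",
                     "empty signal)")
            write.table(grangesToBed(pk$peaks), out("peaks.bed"),
                        sep = "\t", quote = FALSE, row.names = FALSE,
                        col.names = FALSE)
            list(peaks = pk$peaks, model = pk$model, genome = genome)
        } else {
            bed <- read.table(out("peaks.bed"), sep = "\t",
                              col.names = c("chrom", "start", "end"))
            list(peaks = bedToGRanges(bed), model = NULL, genome = genome)
        }
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("peaks", res))
    manifest$peaks <- stageRecord(
        list(window = config$window, odds = config$peakOdds,
             mergeDist = config$mergeDist), out("peaks.bed"), t0,
        if (recompute("peaks")) "ok" else "resumed")
    peaks <- res$peaks; zinba <- res$model; genome <- res$genome

    ## stage 4: cell calling + matrix
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        if (recompute("cells")) {
            stats <- barcodeStats(dedup, peaks)
            stats <- subtractContamination(stats,
                                           rate = config$contamination)
            cc <- callCells(stats, seed = deriveSeed(config$seed, "cells"),
                            oddsThreshold = config$cellOddsThreshold)
            se <- buildMatrix(dedup, peaks, cc$cells)
            writeLines(cc$cells, out("cells.txt"))
            Matrix::writeMM(SummarizedExperiment::assay(se, "counts"),
                            out("matrix.mtx"))
            writeLines(colnames(se), out("barcodes.tsv"))
            write.table(grangesToBed(SummarizedExperiment::rowRanges(se)),
                        out("matrix.peaks.bed"), sep = "\t", quote = FALSE,
                        row.names = FALSE, col.names = FALSE)
            list(stats = stats, model = cc$model, cells = cc$cells,
                 se = se)
        } else {
            cells <- readLines(out("cells.txt"))
            counts <- methods::as(Matrix::readMM(out("matrix.mtx")),
                                  "CsparseMatrix")
            colnames(counts) <- readLines(out("barcodes.tsv"))
            rownames(counts) <- paste0("peak", seq_len(nrow(counts)))
            se <- SummarizedExperiment::SummarizedExperiment(
                assays = list(counts = counts), rowRanges = peaks,
                colData = S4Vectors::DataFrame(barcode = colnames(counts),
                                               row.names =
                                                   colnames(counts)))
            list(stats = NULL, model = NULL, cells = cells, se = se)
        }
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("cells", res))
    manifest$cells <- stageRecord(
        list(contamination = config$contamination,
             odds = config$cellOddsThreshold),
        c(out("cells.txt"), out("matrix.mtx"), out("barcodes.tsv"),
          out("matrix.peaks.bed")), t0,
        if (recompute("cells")) "ok" else "resumed")
    se <- res$se; cellModel <- res$model; stats <- res$stats

    ## stage 5: clustering
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        if (recompute("cluster")) {
            weighted <- idfNormalize(se)
            emb <- lsaEmbed(weighted, nComponents = config$nComponents,
                            seed = deriveSeed(config$seed, "lsa"))
            emb <- l2Normalize(emb)
            km <- kmedoidsSweep(emb, kRange = config$kRange,
                                seed = deriveSeed(config$seed, "kmedoids"))
            glab <- graphCluster(emb, nNeighbors = config$nNeighbors,
                                 seed = deriveSeed(config$seed, "graph"))
            co2 <- embed2d(emb, seed = deriveSeed(config$seed, "tsne"))
            labTab <- data.frame(barcode = rownames(emb@coords),
                                 kmedoids = unname(km$labels),
                                 graph = unname(glab[rownames(emb@coords)]))
            write.table(labTab, out("clusters.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            write.table(data.frame(barcode = rownames(co2), co2),
                        out("embedding2d.tsv"), sep = "\t", quote = FALSE,
                        row.names = FALSE)
            list(emb = emb, km = km, glab = glab)
        } else {
            labTab <- read.table(out("clusters.tsv"), header = TRUE,
                                 sep = "\t",
                                 colClasses = c("character", "integer",
                                                "integer"))
            km <- list(labels = setNames(labTab$kmedoids, labTab$barcode),
                       k = length(unique(labTab$kmedoids)),
                       silhouettes = NULL)
            list(emb = NULL, km = km,
                 glab = setNames(labTab$graph, labTab$barcode))
        }
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("cluster", res))
    manifest$cluster <- stageRecord(
        list(nComponents = config$nComponents, k = res$km$k),
        c(out("clusters.tsv"), out("embedding2d.tsv")), t0,
        if (recompute("cluster")) "ok" else "resumed")
    emb <- res$emb; km <- res$km; glab <- res$glab

    ## stage 6: annotation + enrichment
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        if (recompute("annotate")) {
            ann <- nearestTss(peaks, genes)
            termMap <- read.table(config$terms, sep = "\t",
                                  col.names = c("term", "gene"),
                                  colClasses = "character")
            enr <- enrichTerms(ann$gene[!is.na(ann$gene)], termMap)
            write.table(ann, out("peak_annotation.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            write.table(enr, out("enrichment.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            list(ann = ann, enr = enr)
        } else {
            list(ann = read.table(out("peak_annotation.tsv"),
                                  header = TRUE, sep = "\t"),
                 enr = read.table(out("enrichment.tsv"), header = TRUE,
                                  sep = "\t"))
        }
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("annotate", res))
    manifest$annotate <- stageRecord(
        list(), c(out("peak_annotation.tsv"), out("enrichment.tsv")), t0,
        if (recompute("annotate")) "ok" else "resumed")
    ann <- res$ann; enr <- res$enr

    ## stage 7: motif analysis
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        if (recompute("motifs")) {
            pwms <- readJaspar(config$pwms)
            seqs <- peakSequences(genome, peaks)
            hits <- scanAllMotifs(seqs, pwms, pvalue = config$scanPvalue,
                                  nBuckets = config$nBuckets)
            zs <- motifZscores(se, hits)
            write.table(hits, out("motif_hits.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            zdf <- do.call(rbind, lapply(names(zs), function(id)
                data.frame(pwm = id, barcode = names(zs[[id]]),
                           z = unname(zs[[id]]))))
            if (is.null(zdf))
                zdf <- data.frame(pwm = character(0),
                                  barcode = character(0), z = numeric(0))
            write.table(zdf, out("motif_zscores.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
            list(hits = hits, zs = zs)
        } else {
            hits <- read.table(out("motif_hits.tsv"), header = TRUE,
                               sep = "\t",
                               colClasses = c("character", "integer",
                                              "integer", "character",
                                              "numeric"))
            zdf <- read.table(out("motif_zscores.tsv"), header = TRUE,
                              sep = "\t",
                              colClasses = c("character", "character",
                                             "numeric"))
            zs <- lapply(split(zdf, zdf$pwm), function(d)
                setNames(d$z, d$barcode))
            list(hits = hits, zs = zs)
        }
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("motifs", res))
    manifest$motifs <- stageRecord(
        list(pvalue = config$scanPvalue, nBuckets = config$nBuckets),
        c(out("motif_hits.tsv"), out("motif_zscores.tsv")), t0,
        if (recompute("motifs")) "ok" else "resumed")
    hits <- res$hits; zscores <- res$zs

    ## stage 8: differential accessibility
    t0 <- as.numeric(Sys.time())
    res <- tryCatch({
        factors <- cutSiteSizeFactors(se)
        labels <- km$labels
        diffs <- clusterVsRest(se, labels, factors)
        counts <- lapply(diffs, function(d)
            applyThresholds(d, pCut = config$pCut,
                            fcCut = config$fcCut)$count)
        diffTab <- do.call(rbind, lapply(names(diffs), function(cl)
            cbind(cluster = cl, diffs[[cl]])))
        write.table(diffTab, out("differential_cluster.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        caseRes <- NULL
        if (!is.null(config$groups)) {
            gr <- read.table(config$groups, sep = "\t",
                             col.names = c("barcode", "group"),
                             colClasses = "character")
            g <- setNames(gr$group, gr$barcode)
            g <- g[names(g) %in% colnames(se)]
            if (length(unique(g)) == 2L) {
                caseRes <- nbTest(se, g, factors)
                write.table(caseRes, out("differential_groups.tsv"),
                            sep = "\t", quote = FALSE, row.names = FALSE)
            }
        }
        list(diffs = diffs, counts = counts, caseRes = caseRes,
             factors = factors)
    }, error = function(e) e)
    if (inherits(res, "error")) return(fail("differential", res))
    diffOut <- out("differential_cluster.tsv")
    if (!is.null(res$caseRes))
        diffOut <- c(diffOut, out("differential_groups.tsv"))
    manifest$differential <- stageRecord(
        list(pCut = config$pCut, fcCut = config$fcCut), diffOut, t0)

    writeManifest(manifest, config)
    list(manifest = manifest, ok = TRUE,
         qc = qc, peaks = peaks, zinba = zinba, cellModel = cellModel,
         stats = stats, cells = colnames(se), matrix = se,
         embedding = emb, kmedoids = km, graphLabels = glab,
         annotation = ann, enrichment = enr, motifHits = hits,
         motifZ = zscores, diff = res$diffs, diffCounts = res$counts,
         diffGroups = res$caseRes)
}

writeManifest <- function(manifest, config) {
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
}

#' Summarise a pipeline run
#'
#' Builds the human-readable summary tables: per-cluster cell counts and
#' ratios, differential feature counts at the configured filters, the top
#' enriched terms, and — when the planted truth is supplied — a scorecard
#' with clustering ARI and cell-calling precision/recall.
#'
#' @param run result of [runPipeline()].
#' @param truth optional [SyntheticTruth-class].
#' @return list of data.frames (`clusters`, `differential`,
#'   `enrichment`, and `scorecard` when truth is given).
#' @export
pipelineReport <- function(run, truth = NULL) {
    if (!isTRUE(run$ok)) stop("pipeline run did not complete; see manifest")
    labels <- run$kmedoids$labels
    tab <- table(labels)
    clusters <- data.frame(cluster = names(tab),
                           cells = as.integer(tab),
                           ratio = as.numeric(tab) / sum(tab))
    differential <- data.frame(cluster = names(run$diffCounts),
                               significant = unlist(run$diffCounts))
    out <- list(clusters = clusters, differential = differential,
                enrichment = head(run$enrichment, 10L))
    if (!is.null(truth)) {
        trueType <- truth@barcodeType[names(labels)]
        ari <- adjustedRand(labels, trueType)
        realCells <- names(truth@barcodeType)[truth@barcodeType != "ambient"]
        called <- run$cells
        prec <- if (length(called)) mean(called %in% realCells) else NA_real_
        rec <- if (length(realCells))
            mean(realCells %in% called) else NA_real_
        out$scorecard <- data.frame(metric = c("clusterARI",
                                               "cellPrecision",
                                               "cellRecall"),
                                    value = c(ari, prec, rec))
    }
    out
}
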