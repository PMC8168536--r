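#' Build a synthetic-data configuration
#'
#' Returns a validated [SyntheticConfig-class] describing a synthetic
#' scATAC-seq experiment.  The defaults are the package's standard
#' benchmark: a 2 Mb genome (2 chromosomes), 300 planted peaks of 1.5 kb,
#' 3 cell types with 200 cells each, per-bp transposition rates in a
#' type's accessible peaks 10-fold above background, ~200 fragments per
#' cell, 2,000 ambient barcodes at ~20 fragments each, a bimodal
#' fragment-length mixture (nucleosome-free 75 bp, mono-nucleosome
#' 250 bp), per-base barcode error rate 0.005, one planted motif, and 10%
#' of peaks carrying a 3-fold case-vs-control effect.
#'
#' @param seed master seed (integer).
#' @param nChroms,chromLength,nCellTypes,cellsPerType,nAmbientBarcodes
#'   genome and population geometry.
#' @param nPeaks,peakWidth planted peak layout.
#' @param fragmentsPerCellMean,ambientFragmentsMean Poisson fragment
#'   yields.
#' @param barcodeErrorRate per-base substitution probability.
#' @param fragLenModes data.frame (`mean`, `sd`, `weight`).
#' @param plantedMotifs data.frame (`pwm`, `fraction`).
#' @param diffFraction,diffFold case-vs-control effect layout.
#' @param signalFold in-peak/background per-bp rate ratio.
#' @param whitelistSize whitelist barcodes (must cover cells + ambient).
#' @param dupRate probability that a fragment is emitted twice.
#' @return a [SyntheticConfig-class] object.
#' @export
syntheticConfig <- function(seed = 1L, nChroms = 2L, chromLength = 1000000L,
                            nCellTypes = 3L, cellsPerType = 200L,
                            nAmbientBarcodes = 2000L, nPeaks = 300L,
                            peakWidth = 1500L, fragmentsPerCellMean = 200,
                            ambientFragmentsMean = 20,
                            barcodeErrorRate = 0.005,
                            fragLenModes = data.frame(
                                mean = c(75, 250), sd = c(12, 25),
                                weight = c(0.6, 0.4)),
                            plantedMotifs = data.frame(
                                pwm = "MA0001", fraction = 0.25),
                            diffFraction = 0.1, diffFold = 3,
                            signalFold = 10, whitelistSize = 3000L,
                            dupRate = 0.2) {
    new("SyntheticConfig", seed = as.integer(seed),
        nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
        nCellTypes = as.integer(nCellTypes),
        cellsPerType = as.integer(cellsPerType),
        nAmbientBarcodes = as.integer(nAmbientBarcodes),
        nPeaks = as.integer(nPeaks), peakWidth = as.integer(peakWidth),
        fragmentsPerCellMean = fragmentsPerCellMean,
        ambientFragmentsMean = ambientFragmentsMean,
        barcodeErrorRate = barcodeErrorRate, fragLenModes = fragLenModes,
        plantedMotifs = plantedMotifs, diffFraction = diffFraction,
        diffFold = diffFold, signalFold = signalFold,
        whitelistSize = as.integer(whitelistSize), dupRate = dupRate)
}

## random 16-mers with pairwise Hamming distance >= 3, so that <=1
## substitution errors always have a unique nearest whitelist barcode
makeWhitelist <- function(n, seed, barcodeLength = 16L, minDist = 3L) {
    set.seed(deriveSeed(seed, "whitelist"))
    accepted <- character(0)
    acceptedMat <- NULL
    while (length(accepted) < n) {
        batch <- max(64L, n - length(accepted))
        cand <- vapply(seq_len(batch), function(i)
            paste(sample(BASES, barcodeLength, replace = TRUE),
                  collapse = ""), character(1))
        cand <- unique(cand)
        candMat <- barcodeOneHot(cand, barcodeLength)
        for (i in seq_along(cand)) {
            if (length(accepted) >= n) break
            v <- candMat[i, , drop = FALSE]
            if (!is.null(acceptedMat)) {
                d <- barcodeLength - as.vector(acceptedMat %*% t(v))
                if (any(d < minDist)) next
            }
            accepted <- c(accepted, cand[i])
            acceptedMat <- rbind(acceptedMat, v)
        }
    }
    accepted
}

## one-hot (4 per position) encoding used for fast Hamming via matmul
barcodeOneHot <- function(barcodes, len = 16L) {
    chars <- matrix(unlist(strsplit(barcodes, "")), ncol = len, byrow = TRUE)
    out <- matrix(0, nrow = length(barcodes), ncol = 4L * len)
    for (b in seq_along(BASES)) {
        hit <- chars == BASES[b]
        idx <- (seq_len(len) - 1L) * 4L + b
        out[, idx] <- hit + 0
    }
    out
}

## deterministic consensus + strongly informative count matrix per pwm id
makeSyntheticPwms <- function(ids, seed, length = 12L) {
    set.seed(deriveSeed(seed, "genome") + 7L)
    pwms <- list()
    for (id in ids) {
        consensus <- sample(1:4, length, replace = TRUE)
        mat <- matrix(5, nrow = 4, ncol = length, dimnames = list(BASES, NULL))
        mat[cbind(consensus, seq_len(length))] <- 85
        pwms[[id]] <- list(id = id, name = paste0("synthetic_", id),
                           matrix = mat,
                           consensus = paste(BASES[consensus], collapse = ""))
    }
    pwms
}

#' Generate a synthetic genome with planted peaks and motif sites
#'
#' Draws an i.i.d. random genome, places non-overlapping peaks with a
#' minimum separation of one peak width (so neighbouring called peaks are
#' never merged by the 500 bp rule), assigns each peak a cell type in
#' round-robin order, embeds planted motif consensus sequences inside
#' peaks — preferring the peaks of the motif's target cell type — and lays
#' down synthetic gene models with one TSS at each peak centre plus
#' background genes.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `truth`
#'   ([SyntheticTruth-class]) and `pwms` (list, JASPAR-style matrices with
#'   a `consensus` element).
#' @export
generateGenome <- function(config) {
    validObject(config)
    set.seed(deriveSeed(config@seed, "genome"))
    chromNames <- paste0("chr", seq_len(config@nChroms))
    seqs <- lapply(chromNames, function(cn)
        paste(sample(BASES, config@chromLength, replace = TRUE),
              collapse = ""))
    names(seqs) <- chromNames

    ## peak placement: per chromosome, peaks separated by >= minGap
    minGap <- max(1500L, config@peakWidth)
    nPeaks <- config@nPeaks
    peakDf <- NULL
    if (nPeaks > 0L) {
        perChrom <- diff(round(seq(0, nPeaks, length.out = config@nChroms + 1)))
        margin <- 3000L
        peakList <- list()
        for (ci in seq_len(config@nChroms)) {
            m <- perChrom[ci]
            if (m == 0L) next
            span <- config@chromLength - 2L * margin
            need <- m * (config@peakWidth + minGap)
            if (need > span)
                stop("cannot place ", m, " peaks of width ",
                     config@peakWidth, " with separation ", minGap,
                     " on a chromosome of length ", config@chromLength)
            slack <- span - need
            gaps <- sort(sample.int(slack + 1L, m, replace = TRUE) - 1L)
            starts <- margin + gaps +
                (seq_len(m) - 1L) * (config@peakWidth + minGap)
            peakList[[ci]] <- data.frame(chrom = chromNames[ci],
                                         start = starts,
                                         end = starts + config@peakWidth)
        }
        peakDf <- do.call(rbind, peakList)
    } else {
        peakDf <- data.frame(chrom = character(0), start = integer(0),
                             end = integer(0))
    }
    truePeaks <- bedToGRanges(peakDf)
    peakType <- if (nPeaks > 0L && config@nCellTypes > 0L)
        rep_len(seq_len(config@nCellTypes), nPeaks) else integer(0)

    ## per-type per-peak relative per-bp rates (background = 1)
    typeAcc <- matrix(1, nrow = config@nCellTypes, ncol = nPeaks)
    if (nPeaks > 0L)
        for (t in seq_len(config@nCellTypes))
            typeAcc[t, peakType == t] <- config@signalFold

    ## plant motif consensus sequences inside peaks
    pwmIds <- unique(as.character(config@plantedMotifs$pwm))
    pwms <- makeSyntheticPwms(c(pwmIds, "MA0099"), config@seed)
    sites <- data.frame(pwm = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0))
    if (nPeaks > 0L && nrow(config@plantedMotifs) > 0L) {
        for (j in seq_len(nrow(config@plantedMotifs))) {
            id <- as.character(config@plantedMotifs$pwm[j])
            frac <- config@plantedMotifs$fraction[j]
            nSites <- round(frac * nPeaks)
            if (nSites == 0L) next
            if (nSites > nPeaks)
                stop("planted motif fraction exceeds available peaks")
            targetType <- ((j - 1L) %% max(1L, config@nCellTypes)) + 1L
            pref <- which(peakType == targetType)
            rest <- setdiff(seq_len(nPeaks), pref)
            ordering <- c(sample(pref), sample(rest))
            chosen <- ordering[seq_len(nSites)]
            cons <- pwms[[id]]$consensus
            L <- nchar(cons)
            for (p in chosen) {
                off <- sample.int(config@peakWidth - L + 1L, 1L) - 1L
                st <- peakDf$start[p] + off     # 0-based
                strand <- sample(c("+", "-"), 1L)
                ins <- if (strand == "+") cons else revComp(cons)
                cn <- peakDf$chrom[p]
                substr(seqs[[cn]], st + 1L, st + L) <- ins
                sites <- rbind(sites, data.frame(
                    pwm = id, chrom = cn, start = st, end = st + L,
                    strand = strand))
            }
        }
    }

    ## gene models: one TSS per peak centre + background genes
    genes <- data.frame(name = character(0), chrom = character(0),
                        tss = integer(0), strand = character(0))
    if (nPeaks > 0L) {
        genes <- data.frame(
            name = sprintf("PG%04d", seq_len(nPeaks)),
            chrom = peakDf$chrom,
            tss = as.integer(floor((peakDf$start + peakDf$end) / 2)),
            strand = sample(c("+", "-"), nPeaks, replace = TRUE))
    }
    nBgGenes <- 100L
    if (config@chromLength > 2000L) {
        bg <- data.frame(
            name = sprintf("BG%04d", seq_len(nBgGenes)),
            chrom = sample(chromNames, nBgGenes, replace = TRUE),
            tss = sample.int(config@chromLength - 1000L, nBgGenes) + 500L,
            strand = sample(c("+", "-"), nBgGenes, replace = TRUE))
        genes <- rbind(genes, bg)
    }

    ## case-vs-control effect peaks
    nDiff <- round(config@diffFraction * nPeaks)
    diffPeaks <- if (nDiff > 0L) sort(sample.int(nPeaks, nDiff)) else integer(0)

    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- chromNames
    truth <- new("SyntheticTruth",
                 barcodeType = setNames(character(0), character(0)),
                 truePeaks = truePeaks, typeAccessibility = typeAcc,
                 plantedMotifSites = sites, diffPeaks = as.integer(diffPeaks),
                 genes = genes)
    list(genome = genome, truth = truth, pwms = pwms)
}

## draw fragment lengths from the configured normal mixture
drawFragmentLengths <- function(n, config) {
    if (n == 0L) return(integer(0))
    modes <- config@fragLenModes
    comp <- sample.int(nrow(modes), n, replace = TRUE, prob = modes$weight)
    len <- round(rnorm(n, mean = modes$mean[comp], sd = modes$sd[comp]))
    maxLen <- max(30L, min(500L, config@peakWidth - 10L))
    as.integer(pmin(pmax(len, 20L), maxLen))
}

## per-base substitution noise on barcode sequences
mutateBarcodes <- function(barcodes, rate) {
    if (length(barcodes) == 0L || rate <= 0) return(barcodes)
    len <- nchar(barcodes[1])
    n <- length(barcodes)
    hit <- which(matrix(runif(n * len) < rate, n, len), arr.ind = TRUE)
    if (nrow(hit) == 0L) return(barcodes)
    for (k in seq_len(nrow(hit))) {
        i <- hit[k, 1]; j <- hit[k, 2]
        cur <- substr(barcodes[i], j, j)
        sub <- sample(setdiff(BASES, cur), 1L)
        substr(barcodes[i], j, j) <- sub
    }
    barcodes
}

#' Simulate a fragment record stream with planted ground truth
#'
#' Emits one record per observed read pair, pre-deduplication: per cell the
#' fragment count is Poisson, each fragment falls entirely inside one of
#' the cell type's accessible peaks with probability proportional to the
#' peak's excess rate (or uniformly in the background), fragment lengths
#' follow the configured bimodal mixture, case cells multiply the rates of
#' the planted differential peaks by `diffFold`, ambient barcodes emit
#' uniform background fragments, barcodes carry per-base substitution
#' errors, and a fraction of fragments is emitted twice so deduplication
#' is exercised.
#'
#' @param truth a [SyntheticTruth-class] from [generateGenome()]; this
#'   function fills in its `barcodeType` slot.
#' @param config the matching [SyntheticConfig-class].
#' @param groupLabels optional named character vector mapping cell
#'   barcodes (or cell-type labels) to `"case"`/`"control"`; defaults to
#'   all control.  When a label is given per cell type, all cells of the
#'   type inherit it.  The string `"balanced"` assigns alternate cells of
#'   every type to case and control, keeping the contrast orthogonal to
#'   cell type.
#' @return list with `fragments` (pre-dedup record data.frame),
#'   `whitelist` (character), `truth` (completed [SyntheticTruth-class])
#'   and `groups` (named vector, barcode -> case/control).
#' @export
simulateFragments <- function(truth, config, groupLabels = NULL) {
    validObject(config)
    nCells <- config@nCellTypes * config@cellsPerType
    nNeeded <- nCells + config@nAmbientBarcodes
    if (config@whitelistSize < nNeeded)
        stop("whitelistSize must cover cell and ambient barcodes (need ",
             nNeeded, ")")
    whitelist <- makeWhitelist(config@whitelistSize, config@seed)
    cellBarcodes <- whitelist[seq_len(nCells)]
    ambientBarcodes <- if (config@nAmbientBarcodes > 0L)
        whitelist[nCells + seq_len(config@nAmbientBarcodes)] else character(0)
    if (length(intersect(cellBarcodes, ambientBarcodes)) > 0L)
        stop("cell and ambient barcode pools collide")

    types <- if (nCells > 0L)
        rep(seq_len(config@nCellTypes), each = config@cellsPerType)
        else integer(0)
    barcodeType <- setNames(
        c(paste0("type", types), rep("ambient", length(ambientBarcodes))),
        c(cellBarcodes, ambientBarcodes))
    truth@barcodeType <- barcodeType

    ## resolve case/control per cell barcode
    groups <- setNames(rep("control", nCells), cellBarcodes)
    if (identical(groupLabels, "balanced")) {
        groups[seq_len(nCells) %% 2L == 1L] <- "case"
        groupLabels <- NULL
    }
    if (!is.null(groupLabels)) {
        byType <- names(groupLabels) %in% paste0("type",
                                                 seq_len(config@nCellTypes))
        if (any(byType)) {
            for (tl in names(groupLabels)[byType])
                groups[paste0("type", types) == tl] <- groupLabels[[tl]]
        }
        direct <- intersect(names(groupLabels), cellBarcodes)
        groups[direct] <- groupLabels[direct]
    }

    set.seed(deriveSeed(config@seed, "fragments"))
    chromNames <- paste0("chr", seq_len(config@nChroms))
    peaks <- grangesToBed(truth@truePeaks)
    nPeaks <- nrow(peaks)
    genomeBp <- as.numeric(config@nChroms) * config@chromLength

    emit <- list()
    ei <- 0L

    sampleBackground <- function(n) {
        if (n == 0L) return(NULL)
        len <- drawFragmentLengths(n, config)
        chrom <- sample(chromNames, n, replace = TRUE)
        start <- vapply(len, function(l)
            sample.int(config@chromLength - l, 1L) - 1L, integer(1))
        data.frame(chrom = chrom, start = start, end = start + len)
    }

    ## cells
    if (nCells > 0L) {
        nFrags <- rpois(nCells, config@fragmentsPerCellMean)
        for (i in seq_len(nCells)) {
            nf <- nFrags[i]
            if (nf == 0L) next
            t <- types[i]
            rates <- if (nPeaks > 0L) truth@typeAccessibility[t, ] else numeric(0)
            if (groups[i] == "case" && length(truth@diffPeaks) > 0L)
                rates[truth@diffPeaks] <- rates[truth@diffPeaks] * config@diffFold
            ## excess in-peak intensity vs uniform background over genome
            excess <- pmax(rates - 1, 0) * config@peakWidth
            pPeak <- if (nPeaks > 0L) sum(excess) / (genomeBp + sum(excess)) else 0
            inPeak <- runif(nf) < pPeak
            nIn <- sum(inPeak)
            recs <- NULL
            if (nIn > 0L) {
                pk <- sample.int(nPeaks, nIn, replace = TRUE, prob = excess)
                len <- drawFragmentLengths(nIn, config)
                len <- pmin(len, config@peakWidth - 1L)
                off <- floor(runif(nIn) * (config@peakWidth - len)) # both ends inside
                start <- peaks$start[pk] + as.integer(off)
                recs <- data.frame(chrom = peaks$chrom[pk], start = start,
                                   end = start + len)
            }
            bg <- sampleBackground(nf - nIn)
            recs <- rbind(recs, bg)
            recs$barcode <- cellBarcodes[i]
            ei <- ei + 1L
            emit[[ei]] <- recs
        }
    }

    ## ambient barcodes: uniform background only
    if (length(ambientBarcodes) > 0L) {
        nFrags <- rpois(length(ambientBarcodes), config@ambientFragmentsMean)
        for (i in seq_along(ambientBarcodes)) {
            nf <- nFrags[i]
            if (nf == 0L) next
            recs <- sampleBackground(nf)
            recs$barcode <- ambientBarcodes[i]
            ei <- ei + 1L
            emit[[ei]] <- recs
        }
    }

    frags <- if (ei > 0L) do.call(rbind, emit) else
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), barcode = character(0))

    if (nrow(frags) > 0L) {
        ## barcode read errors, then PCR-style duplication of observed records
        frags$barcode <- mutateBarcodes(frags$barcode, config@barcodeErrorRate)
        dup <- runif(nrow(frags)) < config@dupRate
        frags <- rbind(frags, frags[dup, , drop = FALSE])
        frags$dupCount <- 1L
        frags <- frags[order(frags$chrom, frags$start, frags$end,
                             frags$barcode), , drop = FALSE]
        rownames(frags) <- NULL
    } else {
        frags$dupCount <- integer(0)
    }

    list(fragments = frags, whitelist = whitelist, truth = truth,
         groups = groups)
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the genome FASTA, barcode whitelist, position-sorted fragments
#' TSV, gene-model BED6, a synthetic term-to-gene map, the PWMs in JASPAR
#' text format, and the ground truth as JSON.
#'
#' @param dataset list as returned by [simulateDataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
               whitelist = file.path(dir, "whitelist.txt"),
               fragments = file.path(dir, "fragments.tsv"),
               genes = file.path(dir, "genes.bed"),
               terms = file.path(dir, "terms.tsv"),
               pwms = file.path(dir, "pwms.jaspar"),
               truth = file.path(dir, "truth.json"),
               groups = file.path(dir, "groups.tsv"))
    Biostrings::writeXStringSet(dataset$genome, paths["genome"])
    writeLines(dataset$whitelist, paths["whitelist"])
    writeFragments(dataset$fragments, paths["fragments"])
    genes <- dataset$truth@genes
    bed <- geneModelsToBed(genes)
    write.table(bed, paths["genes"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(dataset$termMap, paths["terms"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    writeJaspar(dataset$pwms, paths["pwms"])
    truth <- dataset$truth
    jsonlite::write_json(list(
        barcodeType = as.list(truth@barcodeType),
        truePeaks = grangesToBed(truth@truePeaks),
        typeAccessibility = truth@typeAccessibility,
        plantedMotifSites = truth@plantedMotifSites,
        diffPeaks = truth@diffPeaks,
        genes = truth@genes), paths["truth"], auto_unbox = TRUE, digits = NA)
    write.table(data.frame(barcode = names(dataset$groups),
                           group = unname(dataset$groups)),
                paths["groups"], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(paths)
}

## gene models (name, chrom, tss, strand) -> BED6 with a 500 bp body
geneModelsToBed <- function(genes) {
    start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 499L)
    end <- ifelse(genes$strand == "+", genes$tss + 500L, genes$tss + 1L)
    data.frame(chrom = genes$chrom, start = pmax(0L, as.integer(start)),
               end = as.integer(end), name = genes$name, score = 0L,
               strand = genes$strand)
}

## BED6 -> gene models, TSS per BED strand convention
bedToGeneModels <- function(bed) {
    data.frame(name = bed[[4]], chrom = bed[[1]],
               tss = ifelse(bed[[6]] == "+", bed[[2]], bed[[3]] - 1L),
               strand = bed[[6]])
}

#' Generate a full synthetic dataset in one call
#'
#' Runs [generateGenome()] and [simulateFragments()], builds a synthetic
#' term-to-gene map (every gene assigned 1-3 of 20 terms), and optionally
#' writes everything to `dir`.
#'
#' @param config a [SyntheticConfig-class].
#' @param dir optional output directory passed to [writeDataset()].
#' @param groupLabels optional case/control labels (see
#'   [simulateFragments()]).
#' @return list with `genome`, `truth`, `pwms`, `fragments`, `whitelist`,
#'   `groups`, `termMap` and (if written) `paths`.
#' @export
simulateDataset <- function(config, dir = NULL, groupLabels = NULL) {
    gen <- generateGenome(config)
    sim <- simulateFragments(gen$truth, config, groupLabels)
    genes <- sim$truth@genes
    set.seed(deriveSeed(config@seed, "genome") + 13L)
    termIds <- sprintf("T%03d", 1:20)
    termMap <- NULL
    if (nrow(genes) > 0L) {
        nTermsPer <- sample(1:3, nrow(genes), replace = TRUE)
        termMap <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
            data.frame(term = sample(termIds, nTermsPer[i]),
                       gene = genes$name[i])))
    } else {
        termMap <- data.frame(term = character(0), gene = character(0))
    }
    out <- list(genome = gen$genome, truth = sim$truth, pwms = gen$pwms,
                fragments = sim$fragments, whitelist = sim$whitelist,
                groups = sim$groups, termMap = termMap)
    if (!is.null(dir))
        out$paths <- writeDataset(out, dir)
    out
}
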