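BASES <- c("A", "C", "G", "T")

## per-stage seeds derived from one master seed; offsets keep stages
## independently reproducible while staying under .Machine$integer.max
deriveSeed <- function(seed, stage) {
    offsets <- c(genome = 11L, fragments = 23L, whitelist = 37L,
                 zinba = 41L, cells = 53L, lsa = 61L, kmedoids = 67L,
                 graph = 71L, tsne = 73L, diff = 79L)
    off <- offsets[[stage]]
    as.integer((as.numeric(seed) * 101 + off) %% 2147483647)
}

#' Read a fragment file
#'
#' Fragment files are 5-column tab-separated text with no header:
#' chromosome, start (0-based), end (half-open), 16-mer cell barcode and
#' duplicate count.  Pre-deduplication streams use duplicate count 1 on
#' every record (one row per observed read pair).
#'
#' @param path path to a fragments TSV (optionally gzip-compressed).
#' @return data.frame with columns `chrom`, `start`, `end`, `barcode`,
#'   `dupCount`.
#' @export
readFragments <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     colClasses = c("character", "integer", "integer",
                                    "character", "integer"),
                     col.names = c("chrom", "start", "end", "barcode",
                                   "dupCount"))
    df
}

#' Write a fragment file
#'
#' Records are sorted by (chrom, start, end, barcode) before writing, so
#' output is always position-sorted.
#'
#' @param frags fragment data.frame (see [readFragments()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFragments <- function(frags, path) {
    frags$start <- as.integer(frags$start)
    frags$end <- as.integer(frags$end)
    frags <- frags[order(frags$chrom, frags$start, frags$end,
                         frags$barcode), , drop = FALSE]
    write.table(frags, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

fragmentsToGRanges <- function(frags) {
    GenomicRanges::GRanges(
        seqnames = frags$chrom,
        ranges = IRanges::IRanges(start = frags$start + 1L,
                                  end = frags$end))
}

## GRanges (1-based closed) -> 0-based half-open data.frame
grangesToBed <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
}

bedToGRanges <- function(df) {
    GenomicRanges::GRanges(
        seqnames = df$chrom,
        ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read position weight matrices in JASPAR text format
#'
#' Parses the JASPAR 2020 flat format: a `>ID NAME` header followed by four
#' rows `A [ n n ... ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path path to a JASPAR-format text file.
#' @return named list of PWMs; each a list with `id`, `name` and `matrix`
#'   (4 x L numeric, rows A/C/G/T).
#' @export
readJaspar <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    heads <- grep("^>", lines)
    out <- list()
    for (h in seq_along(heads)) {
        i <- heads[h]
        hdr <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]]
        id <- hdr[1]
        name <- if (length(hdr) > 1) hdr[2] else id
        rows <- lapply(lines[i + 1:4], function(l) {
            l <- gsub("^[ACGT]\\s*\\[", "", l)
            l <- gsub("\\]\\s*$", "", l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1]])
        })
        mat <- do.call(rbind, rows)
        rownames(mat) <- BASES
        out[[id]] <- list(id = id, name = name, matrix = mat)
    }
    out
}

#' Write PWMs in JASPAR text format
#'
#' @param pwms named list of PWMs as returned by [readJaspar()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeJaspar <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (p in pwms) {
        writeLines(sprintf(">%s %s", p$id, p$name), con)
        for (b in BASES) {
            writeLines(sprintf("%s [ %s ]", b,
                               paste(format(p$matrix[b, ], trim = TRUE),
                                     collapse = " ")), con)
        }
    }
    invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' Standard permutation-model-adjusted agreement between two partitions of
#' the same items; 1 means identical up to relabeling, 0 is chance level.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
    stopifnot(length(a) == length(b))
    if (length(a) == 0) return(NA_real_)
    tab <- table(a, b)
    nij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    n2 <- choose(length(a), 2)
    expected <- ai * bj / n2
    maxidx <- (ai + bj) / 2
    if (maxidx == expected) return(1)
    (nij - expected) / (maxidx - expected)
}

logSumExp <- function(x) {
    x <- x[is.finite(x) | x == -Inf]
    m <- max(x)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(exp(x - m)))
}

## reverse complement for plain character vectors of ACGT barcode-like text
revComp <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                  character(1)))
}
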