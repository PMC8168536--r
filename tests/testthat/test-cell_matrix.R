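test_that("per-barcode peak-overlap tallies match a quadratic oracle", {
    peaks <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(151, 501),
                                                     c(300, 700)))
    ## half-open boundary: [100,150) does not intersect [150,300)
    frags <- data.frame(chrom = "chr1",
                        start = c(100L, 100L, 290L),
                        end = c(200L, 150L, 310L),
                        barcode = c("A", "A", "B"), dupCount = 1L)
    st <- barcodeStats(frags, peaks)
    expect_identical(st$fragmentsInPeaks[st$barcode == "A"], 1L)
    expect_identical(st$fragmentsInPeaks[st$barcode == "B"], 1L)
    expect_identical(st$totalFragments[st$barcode == "A"], 2L)

    set.seed(61)
    n <- 400
    start <- sample.int(5000, n, TRUE)
    rf <- data.frame(chrom = "chr1", start = start,
                     end = start + sample.int(200, n, TRUE),
                     barcode = sample(LETTERS[1:5], n, TRUE),
                     dupCount = 1L)
    ps <- sort(sample.int(5000, 10))
    rp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ps, ps + 150))
    st <- barcodeStats(rf, rp)
    ## brute force interval intersection per fragment
    pb <- as.data.frame(rp)
    inPeak <- vapply(seq_len(n), function(i)
        any(rf$start[i] + 1 <= pb$end & rf$end[i] >= pb$start),
        logical(1))
    oracle <- table(factor(rf$barcode[inPeak], levels = st$barcode))
    expect_identical(st$fragmentsInPeaks, as.integer(oracle))
})

test_that("contamination subtraction is a clamped fixed-count rule", {
    st <- data.frame(barcode = letters[1:3],
                     totalFragments = c(100L, 100L, 100L),
                     fragmentsInPeaks = c(100L, 100L, 100L),
                     adjustedCount = c(100L, 100L, 100L))
    out <- subtractContamination(st, rate = 0.02)
    expect_identical(attr(out, "fixedCount"), 2L)
    expect_identical(out$adjustedCount, rep(98L, 3))
    ## rate 0 is the identity
    out0 <- subtractContamination(st, rate = 0)
    expect_identical(out0$adjustedCount, st$fragmentsInPeaks)
    ## clamped at zero
    st$fragmentsInPeaks <- c(1L, 0L, 300L)
    out2 <- subtractContamination(st, rate = 0.05)
    expect_true(all(out2$adjustedCount >= 0L))
})

test_that("cell calling separates planted components and is anti-monotone", {
    set.seed(7)
    adj <- c(rnbinom(4000, size = 2, mu = 50),
             rnbinom(500, size = 2, mu = 5000))
    st <- data.frame(barcode = paste0("b", seq_along(adj)),
                     totalFragments = adj + 1L,
                     fragmentsInPeaks = adj, adjustedCount = adj)
    cc <- callCells(st, seed = 7, oddsThreshold = 1000)
    truthCell <- rep(c(FALSE, TRUE), c(4000, 500))
    called <- st$barcode %in% cc$cells
    expect_gte(mean(called == truthCell), 0.98)
    expect_gt(cc$model@muSignal, cc$model@muNoise)

    ## increasing the odds threshold never enlarges the cell set
    ccHi <- callCells(st, seed = 7, oddsThreshold = 1e6)
    expect_true(all(ccHi$cells %in% cc$cells))

    ## empty stats -> empty cell set
    ccE <- callCells(st[0, ], seed = 1)
    expect_length(ccE$cells, 0L)

    ## single-component data -> degeneracy flag, all-or-nothing
    one <- st[1:200, ]
    one$adjustedCount <- rep(10L, 200)
    expect_warning(ccD <- callCells(one, seed = 1), "collapsed")
    expect_true(ccD$model@degenerate)
})

test_that("count matrix counts fragment ends inside peaks", {
    peaks <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(51, 501), c(300, 600)))
    frags <- data.frame(chrom = "chr1",
                        start = c(100L, 250L, 450L),
                        end = c(250L, 400L, 550L),
                        barcode = c("A", "A", "B"), dupCount = 1L)
    se <- buildMatrix(frags, peaks, cells = c("A", "B"))
    m <- SummarizedExperiment::assay(se, "counts")
    ## [100,250): both ends (100, 249) inside peak 1 -> 2
    ## [250,400): one end (250) inside peak 1, end 399 outside -> 1
    expect_identical(as.numeric(m["peak1", "A"]), 3)
    ## [450,550): start outside, end 549 inside peak 2 -> 1
    expect_identical(as.numeric(m["peak2", "B"]), 1)
    ## non-cell barcodes dropped
    se2 <- buildMatrix(frags, peaks, cells = "A")
    expect_identical(colnames(se2), "A")

    ## column sums equal an independent per-barcode end tally
    fx <- smallFixture()
    truePeaks <- fx$ds$truth@truePeaks
    cells <- names(fx$ds$truth@barcodeType)
    seF <- buildMatrix(fx$dedup, truePeaks, cells)
    ends <- data.frame(chrom = rep(fx$dedup$chrom, 2),
                       pos = c(fx$dedup$start, fx$dedup$end - 1L),
                       barcode = rep(fx$dedup$barcode, 2))
    pb <- as.data.frame(truePeaks)
    tallies <- vapply(colnames(seF), function(b) {
        e <- ends[ends$barcode == b, ]
        sum(vapply(seq_len(nrow(e)), function(i)
            any(e$chrom[i] == pb$seqnames &
                e$pos[i] + 1 >= pb$start & e$pos[i] + 1 <= pb$end),
            logical(1)))
    }, numeric(1))
    expect_equal(unname(Matrix::colSums(
        SummarizedExperiment::assay(seF, "counts"))), unname(tallies))
})
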