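test_that("generator is deterministic and respects empty configurations", {
    cfg <- syntheticConfig(seed = 3L, nChroms = 1L, chromLength = 60000L,
                           nPeaks = 10L, nCellTypes = 2L, cellsPerType = 5L,
                           nAmbientBarcodes = 10L, whitelistSize = 50L,
                           peakWidth = 800L)
    g1 <- generateGenome(cfg)
    g2 <- generateGenome(cfg)
    expect_identical(as.character(g1$genome), as.character(g2$genome))
    expect_identical(as.data.frame(g1$truth@truePeaks),
                     as.data.frame(g2$truth@truePeaks))

    empty <- syntheticConfig(seed = 3L, nChroms = 1L, chromLength = 60000L,
                             nPeaks = 0L, nCellTypes = 2L, cellsPerType = 5L,
                             nAmbientBarcodes = 10L, whitelistSize = 50L)
    ge <- generateGenome(empty)
    expect_length(ge$truth@truePeaks, 0L)
    expect_identical(nrow(ge$truth@plantedMotifSites), 0L)

    ## no cells and no ambient barcodes -> empty fragment stream
    none <- syntheticConfig(seed = 3L, nChroms = 1L, chromLength = 60000L,
                            nPeaks = 5L, nCellTypes = 1L, cellsPerType = 0L,
                            nAmbientBarcodes = 0L, whitelistSize = 20L,
                            peakWidth = 800L)
    sim <- simulateFragments(generateGenome(none)$truth, none)
    expect_identical(nrow(sim$fragments), 0L)
})

test_that("planted motif consensus sites are embedded where recorded", {
    cfg <- syntheticConfig(seed = 5L, nChroms = 2L, chromLength = 300000L,
                           nPeaks = 100L, nCellTypes = 2L,
                           cellsPerType = 5L, nAmbientBarcodes = 10L,
                           whitelistSize = 50L, peakWidth = 900L,
                           plantedMotifs = data.frame(pwm = "MA0001",
                                                      fraction = 0.5))
    g <- generateGenome(cfg)
    sites <- g$truth@plantedMotifSites
    expect_identical(nrow(sites), 50L)
    cons <- g$pwms[["MA0001"]]$consensus
    for (i in seq_len(nrow(sites))) {
        s <- as.character(Biostrings::subseq(g$genome[[sites$chrom[i]]],
                                             sites$start[i] + 1L,
                                             sites$end[i]))
        expected <- if (sites$strand[i] == "+") cons else
            as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(cons)))
        expect_identical(s, expected)
    }
    ## each planted site lies inside a true peak
    siteGr <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$start + 1L,
                                                      sites$end))
    ov <- GenomicRanges::countOverlaps(siteGr, g$truth@truePeaks,
                                       type = "within")
    expect_true(all(ov == 1L))
})

test_that("fragment yield follows the configured Poisson model", {
    cfg <- syntheticConfig(seed = 9L, nChroms = 1L, chromLength = 200000L,
                           nPeaks = 20L, nCellTypes = 1L,
                           cellsPerType = 1000L, nAmbientBarcodes = 0L,
                           whitelistSize = 1100L,
                           fragmentsPerCellMean = 200,
                           barcodeErrorRate = 0, dupRate = 0,
                           peakWidth = 800L)
    sim <- simulateFragments(generateGenome(cfg)$truth, cfg)
    total <- nrow(sim$fragments)
    expect_lt(abs(total - 200000), 3 * sqrt(200000))
    ## error-free emission: every barcode on the whitelist
    expect_true(all(sim$fragments$barcode %in% sim$whitelist))

    ## per-cell counts consistent with Poisson (chi-square GoF, alpha 0.01)
    counts <- as.numeric(table(factor(sim$fragments$barcode,
                                      levels = names(sim$truth@barcodeType))))
    lambda <- 200
    edges <- unique(qpois(seq(0.1, 0.9, by = 0.1), lambda))
    obs <- as.numeric(table(cut(counts, c(-Inf, edges, Inf))))
    pr <- diff(c(0, ppois(edges, lambda), 1))
    chi <- suppressWarnings(chisq.test(obs, p = pr))
    expect_gt(chi$p.value, 0.01)
})

test_that("fragment lengths reproduce the configured bimodal mixture", {
    fx <- smallFixture()
    h <- lengthHistogram(fx$dedup)
    lens <- as.integer(names(h))
    counts <- as.integer(h)
    ## mode locations within +-10 bp of the configured means
    short <- lens[lens < 150]
    long <- lens[lens >= 150]
    m1 <- short[which.max(counts[lens < 150])]
    m2 <- long[which.max(counts[lens >= 150])]
    expect_lt(abs(m1 - 75), 10)
    expect_lt(abs(m2 - 250), 10)
})

test_that("whitelist has minimum pairwise Hamming distance 3", {
    wl <- scATACkit:::makeWhitelist(120L, seed = 4L)
    hot <- scATACkit:::barcodeOneHot(wl, 16L)
    d <- 16L - hot %*% t(hot)
    diag(d) <- 16L
    expect_gte(min(d), 3L)
})

test_that("written datasets round-trip and fragments come out sorted", {
    cfg <- syntheticConfig(seed = 13L, nChroms = 1L, chromLength = 100000L,
                           nPeaks = 10L, nCellTypes = 1L,
                           cellsPerType = 10L, nAmbientBarcodes = 20L,
                           whitelistSize = 50L, peakWidth = 800L,
                           fragmentsPerCellMean = 50)
    dir <- withr::local_tempdir()
    ds <- simulateDataset(cfg, dir = dir)
    back <- readFragments(file.path(dir, "fragments.tsv"))
    reSorted <- ds$fragments[order(ds$fragments$chrom, ds$fragments$start,
                                   ds$fragments$end, ds$fragments$barcode), ]
    rownames(reSorted) <- NULL
    expect_equal(back, reSorted)
    expect_false(is.unsorted(back$start[back$chrom == "chr1"]))
    pw <- readJaspar(file.path(dir, "pwms.jaspar"))
    expect_identical(pw[["MA0001"]]$matrix, ds$pwms[["MA0001"]]$matrix)
})
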