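test_that("event counting follows the two-ends convention", {
    cl <- c(chr1 = 1000L)
    frags <- data.frame(chrom = "chr1", start = 100L, end = 250L,
                        barcode = "AAAA", dupCount = 3L)
    tr <- countEvents(frags, cl)
    expect_identical(tr$chr1[101], 1L)  # base 100 (0-based)
    expect_identical(tr$chr1[250], 1L)  # base 249
    expect_identical(sum(tr$chr1), 2L)  # dupCount ignored

    ## shared start: counts add
    frags2 <- rbind(frags, frags)
    frags2$dupCount <- 1L
    tr2 <- countEvents(frags2, cl)
    expect_identical(tr2$chr1[101], 2L)

    ## conservation: n fragments -> 2n events
    set.seed(51)
    start <- sample.int(800, 500, TRUE)
    fr <- data.frame(chrom = "chr1", start = start,
                     end = start + sample.int(150, 500, TRUE),
                     barcode = "AAAA", dupCount = 1L)
    fr <- fr[fr$end <= 1000, ]
    expect_identical(sum(countEvents(fr, cl)$chr1), 2L * nrow(fr))

    ## out-of-bounds records rejected with a message
    oob <- data.frame(chrom = "chr1", start = 990L, end = 1100L,
                      barcode = "AAAA", dupCount = 1L)
    expect_message(tr3 <- countEvents(oob, cl), "out-of-bounds")
    expect_identical(sum(tr3$chr1), 0L)
})

test_that("window smoothing matches the brute-force window sum", {
    x <- integer(1000)
    x[500] <- 1L
    sm <- smoothEvents(x, 401L)
    expect_identical(sm[300:700], rep(1L, 401))
    expect_identical(sm[299], 0L)
    expect_identical(sm[701], 0L)
    expect_identical(smoothEvents(integer(50), 401L), integer(50))
    expect_error(smoothEvents(x, 400L), "odd")

    set.seed(52)
    y <- rpois(10000, 0.3)
    sm <- smoothEvents(y, 401L)
    brute <- vapply(seq_along(y), function(i)
        sum(y[max(1, i - 200):min(length(y), i + 200)]), numeric(1))
    expect_identical(sm, as.integer(brute))
})

test_that("EM fit is degenerate on all-zero input and monotone otherwise", {
    fit <- fitZinba(integer(5000))
    expect_true(fit@degenerate)
    expect_identical(fit@weights[1], 1)

    set.seed(53)
    comp <- sample.int(3, 50000, TRUE, prob = c(0.6, 0.3, 0.1))
    x <- integer(50000)
    x[comp == 1] <- rgeom(sum(comp == 1), 0.9)
    x[comp == 2] <- rnbinom(sum(comp == 2), size = 1, mu = 3)
    x[comp == 3] <- rnbinom(sum(comp == 3), size = 2, mu = 40)
    fit <- fitZinba(x, seed = 1)
    expect_false(fit@degenerate)
    expect_true(all(diff(fit@logLikTrace) > -1e-6))
    expect_gt(fit@muSignal, fit@muNoise)
    expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
    ## rough component recovery on this easy mixture
    expect_lt(abs(fit@muSignal - 40) / 40, 0.15)
})

test_that("peak calls equal density-threshold classification and merge correctly", {
    ## fitted model with well-separated components
    model <- new("ZinbaMixture", weights = c(0.3, 0.6, 0.1), pGeom = 0.9,
                 muNoise = 3, phiNoise = 5, muSignal = 60, phiSignal = 5,
                 logLik = 0, logLikTrace = numeric(0), nIter = 1L,
                 degenerate = FALSE)
    ## oracle threshold by direct evaluation of the two densities
    odds <- (model@weights[3] *
             dnbinom(0:200, size = model@phiSignal, mu = model@muSignal)) /
            (model@weights[2] *
             dnbinom(0:200, size = model@phiNoise, mu = model@muNoise))
    cstar <- max(which(odds < 1 / 5))  # 0-based count + 1 - 1
    track <- list(chr1 = as.integer(c(rep(0, 100), rep(cstar + 5L, 50),
                                      rep(0, 200), rep(cstar + 5L, 30),
                                      rep(0, 1000), rep(cstar - 1L, 40),
                                      rep(0, 100))))
    pk <- callPeaks(track, model, odds = 1 / 5, mergeDist = 500L)
    expect_identical(S4Vectors::metadata(pk)$thresholdCount,
                     as.integer(cstar))
    ## the two passing runs (gap 200 < 500) merge; the sub-threshold run
    ## is not called
    expect_length(pk, 1L)
    expect_identical(GenomicRanges::start(pk), 101L)
    expect_identical(GenomicRanges::end(pk), 380L)

    ## simple thresholding reproduces the call on random tracks
    set.seed(54)
    rnd <- list(chr1 = as.integer(rpois(5000, 2) +
                                  70L * rbinom(5000, 1, 0.02)))
    pk2 <- callPeaks(rnd, model, odds = 1 / 5, mergeDist = 1L)
    manual <- rnd$chr1 >= cstar
    expect_identical(sum(GenomicRanges::width(pk2)),
                     sum(rle(manual)$lengths[rle(manual)$values]))

    ## raising the odds never adds called bases
    pk3 <- callPeaks(rnd, model, odds = 1, mergeDist = 1L)
    suppressWarnings(
        expect_identical(
            sum(GenomicRanges::width(GenomicRanges::setdiff(pk3, pk2))),
            0L))

    ## no base passing -> empty call
    low <- list(chr1 = integer(100))
    expect_length(callPeaks(low, model, odds = 1e6), 0L)

    ## degenerate model -> empty with warning
    dg <- fitZinba(integer(10))
    expect_warning(pkd <- callPeaks(track, dg), "degenerate")
    expect_length(pkd, 0L)
})
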