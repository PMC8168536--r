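test_that("score-threshold DP equals exhaustive enumeration for short motifs", {
    bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
    for (L in 4:6) {
        pwm <- randomPwm(L, seed = 90 + L)
        th <- scoreThreshold(pwm, bg, pvalue = 1e-3)
        ints <- th$intScores
        grid <- as.matrix(expand.grid(rep(list(1:4), L)))
        sc <- vapply(seq_len(nrow(grid)), function(r)
            sum(ints[cbind(grid[r, ], seq_len(L))]), numeric(1))
        pr <- vapply(seq_len(nrow(grid)), function(r)
            prod(bg[grid[r, ]]), numeric(1))
        tails <- vapply(th$scores / th$resolution, function(s)
            sum(pr[sc >= s - 0.5]), numeric(1))
        expect_lt(max(abs(tails - th$tail)), 1e-12)
        bf <- suppressWarnings(min(th$scores[tails <= 1e-3]))
        expect_equal(th$threshold, bf, tolerance = 1e-12)
    }
})

test_that("degenerate PWMs make the scan threshold unattainable", {
    ## strict consensus, length 8: most probable window has background
    ## probability 4^-8 > 1e-7, so no threshold can exist at 1e-7
    cons <- matrix(0, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    cons[cbind(rep(2, 8), 1:8)] <- 1
    pwm <- list(id = "cons", name = "cons", matrix = cons)
    th7 <- scoreThreshold(pwm, rep(0.25, 4), pvalue = 1e-7, pseudocount = 0)
    expect_false(is.finite(th7$threshold))
    expect_identical(nrow(scanPeaks("CCCCCCCCCCCC", pwm, th7)), 0L)
    ## at p >= 4^-8 the max score is exactly attainable
    th4 <- scoreThreshold(pwm, rep(0.25, 4), pvalue = 1e-4, pseudocount = 0)
    expect_true(is.finite(th4$threshold))
    expect_equal(min(th4$tail[th4$tail > 0]), 4^-8, tolerance = 1e-12)

    ## flat PWM: every score 0, tail at 0 is 1, no hits by contract
    flat <- list(id = "flat", name = "flat",
                 matrix = matrix(1, 4, 6,
                                 dimnames = list(c("A", "C", "G", "T"),
                                                 NULL)))
    expect_false(is.finite(scoreThreshold(flat, rep(0.25, 4))$threshold))
    expect_error(scoreThreshold(flat, rep(0.25, 4), pvalue = 0), "pvalue")
})

test_that("scanning reports planted sites, both strands, and matches rescoring", {
    pwms <- scATACkit:::makeSyntheticPwms("M1", seed = 1)
    pwm <- pwms[["M1"]]
    th <- scoreThreshold(pwm, rep(0.25, 4), pvalue = 1e-7)
    cons <- pwm$consensus
    rcCons <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cons)))
    seqs <- c(paste0(strrep("A", 25), cons, strrep("A", 25)),
              paste0(strrep("A", 10), rcCons, strrep("A", 40)))
    hits <- scanPeaks(seqs, pwm, th)
    expect_identical(nrow(hits), 2L)
    expect_identical(hits$strand[hits$peak == 1], "+")
    expect_identical(hits$offset[hits$peak == 1], 25L)
    expect_identical(hits$strand[hits$peak == 2], "-")
    expect_identical(hits$offset[hits$peak == 2], 10L)

    ## zero hits expected on a 10 kb null sequence at p = 1e-7
    null <- randomSeq(10000, seed = 92, prob = c(0.3, 0.2, 0.2, 0.3))
    expect_identical(nrow(scanPeaks(null, pwm, th)), 0L)

    ## naive per-window rescoring oracle on random peaks at a loose
    ## threshold
    thLoose <- scoreThreshold(pwm, rep(0.25, 4), pvalue = 1e-3)
    peeks <- vapply(1:40, function(i) randomSeq(80, seed = 900 + i),
                    character(1))
    hitsL <- scanPeaks(peeks, pwm, thLoose)
    ints <- thLoose$intScores
    rcInts <- scATACkit:::reverseComplementMatrix(ints)
    L <- ncol(ints)
    oracle <- 0L
    for (i in seq_along(peeks)) {
        codes <- scATACkit:::seqToCodes(peeks[i])
        for (o in 0:(length(codes) - L)) {
            w <- codes[o + seq_len(L)]
            if (sum(ints[cbind(w, seq_len(L))]) >= thLoose$intThreshold)
                oracle <- oracle + 1L
            if (sum(rcInts[cbind(w, seq_len(L))]) >= thLoose$intThreshold)
                oracle <- oracle + 1L
        }
    }
    expect_identical(nrow(hitsL), oracle)

    ## strand symmetry: scanning the reverse-complemented sequences with
    ## the reverse-complemented PWM yields the mirror-image hit list
    ## (same strand labels, mirrored offsets, identical scores)
    rcPwm <- pwm
    rcPwm$matrix <- scATACkit:::reverseComplementMatrix(pwm$matrix)
    rcSeqs <- vapply(seqs, function(s)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
        character(1))
    thRc <- scoreThreshold(rcPwm, rep(0.25, 4), pvalue = 1e-7)
    hitsRc <- scanPeaks(rcSeqs, rcPwm, thRc)
    expect_identical(nrow(hitsRc), nrow(hits))
    for (k in seq_len(nrow(hits))) {
        mirror <- hitsRc[hitsRc$peak == hits$peak[k] &
                         hitsRc$offset == nchar(seqs[hits$peak[k]]) -
                             hits$offset[k] - ncol(pwm$matrix), ]
        expect_identical(nrow(mirror), 1L)
        expect_identical(mirror$strand, hits$strand[k])
        expect_equal(mirror$score, hits$score[k], tolerance = 1e-12)
    }
})

test_that("GC buckets are equal-frequency with per-bucket backgrounds", {
    seqs <- c(vapply(1:11, function(i) randomSeq(60, seed = 700 + i,
                                                 prob = c(0.4, 0.1, 0.1, 0.4)),
                     character(1)),
              vapply(1:11, function(i) randomSeq(60, seed = 800 + i,
                                                 prob = c(0.1, 0.4, 0.4, 0.1)),
                     character(1)))
    gb <- gcBuckets(seqs, nBuckets = 5)
    sizes <- table(gb$bucketOf)
    expect_lte(diff(range(sizes)), 1)
    ## AT-rich sequences land in the low-GC buckets
    expect_true(all(gb$bucketOf[1:11] <= 3))
    ## backgrounds sum to one and track bucket composition
    for (b in gb$backgrounds) expect_equal(sum(b), 1, tolerance = 1e-12)
    expect_gt(gb$backgrounds[[1]][["A"]], gb$backgrounds[[5]][["A"]])

    ## identical sequences: one effective composition everywhere
    same <- rep(randomSeq(50, seed = 1), 10)
    gbS <- gcBuckets(same, nBuckets = 5)
    for (b in gbS$backgrounds)
        expect_equal(b, gbS$backgrounds[[1]], tolerance = 1e-12)

    ## fewer peaks than buckets: single-bucket fallback
    gb1 <- gcBuckets(same[1:3], nBuckets = 5)
    expect_identical(length(gb1$backgrounds), 1L)

    ## a 50% GC corpus pools to near-uniform frequencies
    unif <- vapply(1:30, function(i) randomSeq(200, seed = 600 + i),
                   character(1))
    gbU <- gcBuckets(unif, nBuckets = 1)
    expect_lt(max(abs(gbU$backgrounds[[1]] - 0.25)), 0.02)
})

test_that("motif proportions and MAD z-scores follow their definitions", {
    counts <- Matrix::sparseMatrix(i = c(1, 2, 3, 1, 2),
                                   j = c(1, 1, 1, 2, 2),
                                   x = c(4, 4, 2, 3, 1), dims = c(3, 2))
    colnames(counts) <- c("b1", "b2")
    rownames(counts) <- paste0("peak", 1:3)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts))
    hits <- data.frame(pwm = "M1", peak = 1L, offset = 0L, strand = "+",
                       score = 1)
    pr <- motifProportions(se, hits)
    expect_equal(pr$M1[["b1"]], 0.4, tolerance = 1e-12)
    expect_equal(pr$M1[["b2"]], 0.75, tolerance = 1e-12)
    ## motif hitting every peak: proportion 1 everywhere
    hitsAll <- data.frame(pwm = "M1", peak = 1:3, offset = 0L,
                          strand = "+", score = 1)
    expect_true(all(motifProportions(se, hitsAll)$M1 == 1))

    ## worked example: [1,2,3,4,100] -> z(100) = 97 / 1.4826
    z <- madZscore(c(1, 2, 3, 4, 100))
    expect_equal(z[5], 97 / 1.4826, tolerance = 1e-9)
    expect_identical(madZscore(c(5, 5, 5, 5))[1], 0)
    zc <- madZscore(c(2, 2, 9))
    expect_identical(zc[1], 0)  # at the median
    expect_error(madZscore(1), "at least 2")
})
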