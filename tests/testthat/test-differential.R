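test_that("size factors are totals over the median total", {
    m <- matrix(c(10, 0, 20, 0, 40, 0), nrow = 2)
    colnames(m) <- c("a", "b", "c")
    f <- cutSiteSizeFactors(m)
    expect_equal(unname(f), c(0.5, 1, 2), tolerance = 1e-12)
    expect_equal(median(f), 1, tolerance = 1e-9)
    ## all equal -> all 1
    m2 <- matrix(5, 3, 4, dimnames = list(NULL, letters[1:4]))
    expect_true(all(cutSiteSizeFactors(m2) == 1))
    ## zero-total cells excluded with a message
    m3 <- cbind(m, d = c(0, 0))
    expect_message(f3 <- cutSiteSizeFactors(m3), "zero total")
    expect_identical(names(f3), c("a", "b", "c"))
})

test_that("identical groups produce unit fold changes", {
    set.seed(111)
    m <- matrix(rnbinom(100 * 40, size = 2, mu = 8), 100, 40)
    m <- cbind(m, m)   # group B is a copy of group A
    colnames(m) <- paste0("c", 1:80)
    g <- setNames(rep(c("A", "B"), each = 40), colnames(m))
    res <- nbTest(m, g, setNames(rep(1, 80), colnames(m)))
    expect_true(all(abs(res$log2FC) < 1e-12))
    ## all-zero features retained as uninformative
    m[1, ] <- 0
    res0 <- nbTest(m, g, setNames(rep(1, 80), colnames(m)))
    expect_identical(res0$p[1], 1)
    expect_identical(res0$log2FC[1], 0)
})

test_that("null simulation is calibrated and spiked features are found", {
    ## type-I error at nominal 0.05 under the null
    set.seed(11)
    n <- 150
    m <- matrix(rnbinom(2000 * 2 * n, size = 2, mu = 5), nrow = 2000)
    colnames(m) <- paste0("c", seq_len(2 * n))
    g <- setNames(rep(c("A", "B"), each = n), colnames(m))
    s <- setNames(rep(1, 2 * n), colnames(m))
    res <- nbTest(m, g, s)
    expect_gte(mean(res$p < 0.05), 0.03)
    expect_lte(mean(res$p < 0.05), 0.07)

    ## power on 3x spiked features (mean 10 vs 30)
    set.seed(11)
    n2 <- 200
    null <- matrix(rnbinom(400 * 2 * n2, size = 2, mu = 10), nrow = 400)
    spikeA <- matrix(rnbinom(100 * n2, size = 2, mu = 30), nrow = 100)
    spikeB <- matrix(rnbinom(100 * n2, size = 2, mu = 10), nrow = 100)
    m2 <- rbind(null, cbind(spikeA, spikeB))
    colnames(m2) <- paste0("c", seq_len(2 * n2))
    g2 <- setNames(rep(c("A", "B"), each = n2), colnames(m2))
    res2 <- nbTest(m2, g2, setNames(rep(1, 2 * n2), colnames(m2)))
    spiked <- res2[401:500, ]
    expect_gte(mean(spiked$p < 0.05 & spiked$log2FC > 1), 0.9)

    ## BH adjustment is monotone in p
    expect_true(all(diff(res2$fdr[order(res2$p)]) >= -1e-12))
    expect_true(all(res2$fdr >= res2$p - 1e-12))
})

test_that("statistics are invariant to joint count/factor scaling", {
    set.seed(112)
    m <- matrix(rnbinom(200 * 60, size = 2, mu = 6), 200, 60)
    colnames(m) <- paste0("c", 1:60)
    g <- setNames(rep(c("A", "B"), each = 30), colnames(m))
    f <- setNames(runif(60, 0.5, 2), colnames(m))
    base <- nbTest(m, g, f)
    m2 <- m
    m2[, 7] <- m2[, 7] * 3
    f2 <- f
    f2[7] <- f2[7] * 3
    scaled <- nbTest(m2, g, f2)
    expect_equal(scaled$p, base$p, tolerance = 1e-12)
    expect_equal(scaled$log2FC, base$log2FC, tolerance = 1e-12)
})

test_that("cluster-vs-rest covers every feature once per cluster", {
    fx <- smallFixture()
    truePeaks <- fx$ds$truth@truePeaks
    cells <- names(fx$ds$truth@barcodeType)[
        fx$ds$truth@barcodeType != "ambient"]
    se <- buildMatrix(fx$dedup, truePeaks, cells)
    labels <- setNames(fx$ds$truth@barcodeType[colnames(se)], colnames(se))
    diffs <- clusterVsRest(se, labels)
    expect_identical(sort(names(diffs)), sort(unique(labels)))
    for (d in diffs) expect_identical(nrow(d), length(truePeaks))
    ## the planted type-specific peaks come out enriched in their type
    d1 <- diffs[["type1"]]
    specific <- which(fx$ds$truth@typeAccessibility[1, ] >
                      fx$ds$truth@typeAccessibility[2, ])
    top <- applyThresholds(d1, pCut = 0.05, fcCut = 2,
                           mode = "enriched")$features$feature
    expect_gt(mean(paste0("peak", specific) %in% top), 0.9)
    expect_error(clusterVsRest(se, setNames(rep("x", ncol(se)),
                                            colnames(se))),
                 "two clusters")
})

test_that("threshold filter applies strict cuts in both modes", {
    res <- data.frame(feature = c("f1", "f2", "f3", "f4"),
                      meanA = 1, meanB = 1,
                      log2FC = c(2, -2, 0.1, 1.5),
                      p = c(0.01, 0.01, 0.001, 0.05),
                      fdr = c(0.02, 0.02, 0.004, 0.08))
    two <- applyThresholds(res, pCut = 0.05, fcCut = 1.2, mode = "two_sided")
    expect_setequal(two$features$feature, c("f1", "f2"))
    enr <- applyThresholds(res, pCut = 0.05, fcCut = 2, mode = "enriched")
    expect_identical(enr$features$feature, "f1")
    ## p exactly at the cut is excluded (f4); empty input gives count 0
    expect_false("f4" %in% two$features$feature)
    expect_identical(applyThresholds(res[0, ])$count, 0L)
})
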