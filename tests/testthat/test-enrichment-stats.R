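test_that("zScore implements the binomial standardisation", {
    expect_equal(zScore(5, 100, 0.05), 0)
    expect_equal(zScore(10, 100, 0.05), 5 / sqrt(4.75), tolerance = 1e-9)
    expect_equal(zScore(0, 50, 0.1), -5 / sqrt(4.5), tolerance = 1e-9)
    expect_equal(zScore(0, 0, 0.5), 0)  # no information
    expect_error(zScore(1, 10, 0), "strictly inside")
    expect_error(zScore(1, 10, 1), "strictly inside")
    # vectorised oracle: naive recomputation to 1e-12
    set.seed(41)
    n <- sample(0:50, 30, replace = TRUE)
    M <- vapply(n, function(x) if (x == 0) 0L else sample(0:x, 1),
                integer(1))
    p <- runif(30, 0.01, 0.99)
    naive <- mapply(function(M, n, p)
        if (n == 0) 0 else (M - n * p) / sqrt(n * p * (1 - p)), M, n, p)
    expect_equal(zScore(M, n, p), naive, tolerance = 1e-12)
})

test_that("adjustedZScores uses N-aware counts and guards n = 0", {
    masked <- pairCountSpectrum(chrom_from_string("NNNNNNNNNN"),
                                k = 2, dmax = 6)
    p <- pairProbability(presetModel("uniform", 2), dmax = 6, horizon = 2)
    expect_true(all(adjustedZScores(masked, p) == 0))
    # one planted pair with n = 1 and tiny p
    sp <- new("DistanceSpectrum", k = 7L, dmax = 13L,
              m = c(rep(0L, 6), 1L), n = c(rep(0, 6), 1),
              chrom = "toy", start = 0, end = 20)
    pp <- new("PairProbability", k = 7L, dmax = 13L,
              p = rep(1e-4, 7), horizon = 2L, degenerate = FALSE)
    T <- adjustedZScores(sp, pp)
    expect_equal(T[7], (1 - 1e-4) / sqrt(1e-4 * (1 - 1e-4)),
                 tolerance = 1e-9)
    expect_true(abs(T[7] - 99.99) < 0.02)
    expect_true(all(T[1:6] == 0))
})

test_that("classScore sums inclusively and classes partition the range", {
    expect_equal(classScore(rep(0, 100), 1, 1, 100), 0)
    expect_equal(classScore(rep(1, 4000 - 7 + 1), 7, 7, 500), 494)
    expect_error(classScore(rep(1, 10), 3, 1, 5), "outside")
    cls <- defaultLengthClasses(7, 4000)
    expect_equal(cls$d1, c(7, 7, 501, 1001, 1501, 2001, 2501, 3001, 3501))
    expect_equal(cls$d2, c(4000, 500, 1000, 1500, 2000, 2500, 3000, 3500,
                           4000))
    set.seed(43)
    T <- rnorm(4000 - 7 + 1)
    S <- vapply(seq_len(nrow(cls)), function(j)
        classScore(T, 7, cls$d1[j], cls$d2[j]), numeric(1))
    expect_equal(sum(S[-1L]), S[1L], tolerance = 1e-9)
})

test_that("parseLengthClasses validates bounds", {
    cls <- parseLengthClasses("7:500,501:1000", 7, 4000)
    expect_equal(cls$d1, c(7L, 501L))
    expect_error(parseLengthClasses("3:500", 7, 4000), "bounds")
    expect_error(parseLengthClasses("", 7, 4000), "empty")
})

test_that("empiricalCriticalValue is the nearest-rank upper quantile", {
    expect_equal(empiricalCriticalValue(1:20, 0.05), 19)
    expect_equal(empiricalCriticalValue(rep(3.5, 8), 0.2), 3.5)
    expect_equal(empiricalCriticalValue(42, 0.05), 42)
    expect_equal(empiricalCriticalValue(c(5, 1, 9), 0), 9)
    expect_error(empiricalCriticalValue(numeric(0)), "empty")
    # rank formula against direct definition on random sets
    set.seed(47)
    for (i in 1:20) {
        x <- rnorm(sample(1:50, 1))
        a <- runif(1, 0.01, 0.5)
        expect_equal(empiricalCriticalValue(x, a),
                     sort(x)[max(1, ceiling((1 - a) * length(x)))])
    }
})

test_that("enrichment calls are strict and respect the fully-masked guard", {
    gr <- GenomicRanges::GRanges(rep(c("c1", "c2"), each = 2),
                                 IRanges::IRanges(c(1, 101, 1, 101),
                                                  width = 100))
    gr$index <- c(0L, 1L, 0L, 1L)
    gr$nTotal <- c(10, 10, 10, 0)
    S <- matrix(c(2, 5, 7, 9), 4, 1, dimnames = list(NULL, "I_t"))
    scan <- new("IRScanResult",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(S = S), rowRanges = gr,
            colData = S4Vectors::DataFrame(label = "I_t", d1 = 1L,
                                           d2 = 10L, row.names = "I_t")))
    cvt <- new("CriticalValueTable",
        cv = matrix(c(2, 7), 2, 1, dimnames = list(c("c1", "c2"), "I_t")),
        alpha = 0.05, windowCounts = c(c1 = 2L, c2 = 2L), replicates = 1L)
    called <- callEnrichment(scan, cvt)
    fl <- SummarizedExperiment::assay(called, "enriched")[, 1L]
    # S = cv exactly -> not enriched (strict); masked window never enriched
    expect_identical(unname(fl), c(FALSE, TRUE, FALSE, FALSE))
    bad <- new("CriticalValueTable",
        cv = matrix(2, 1, 1, dimnames = list("c1", "I_t")),
        alpha = 0.05, windowCounts = c(c1 = 2L), replicates = 1L)
    expect_error(callEnrichment(scan, bad), "no critical values")
})

test_that("summary table reports percentages, Global % and weighted Mean cv", {
    gr <- GenomicRanges::GRanges(rep(c("c1", "c2"), c(10, 30)),
                                 IRanges::IRanges(seq(1, by = 100,
                                                      length.out = 40),
                                                  width = 100))
    gr$index <- 0:39
    gr$nTotal <- rep(10, 40)
    set.seed(49)
    S <- matrix(-abs(rnorm(40)), 40, 1, dimnames = list(NULL, "I_t"))
    S[c(1:3, 11:13), 1] <- 100  # 3 of 10 on c1, 3 of 30 on c2
    scan <- new("IRScanResult",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(S = S), rowRanges = gr,
            colData = S4Vectors::DataFrame(label = "I_t", d1 = 1L,
                                           d2 = 10L, row.names = "I_t")))
    cvt <- new("CriticalValueTable",
        cv = matrix(c(2, 4), 2, 1, dimnames = list(c("c1", "c2"), "I_t")),
        alpha = 0.05, windowCounts = c(c1 = 10L, c2 = 30L),
        replicates = 1L)
    summ <- summarizeEnrichment(callEnrichment(scan, cvt), cvt)
    expect_equal(summ$I_t[summ$Chr == "c1"], 30)
    expect_equal(summ$I_t[summ$Chr == "c2"], 10)
    expect_equal(summ$I_t[summ$Chr == "Global %"], 100 * 6 / 40)
    # weighted mean of cv: (10*2 + 30*4) / 40 = 3.5
    expect_equal(summ$I_t[summ$Chr == "Mean cv"], 3.5)
    expect_equal(summ$Wins[summ$Chr %in% c("c1", "c2")], c(10L, 30L))
})

test_that("critical-value table construction groups by scope", {
    gr <- GenomicRanges::GRanges(rep(c("c1", "c2"), each = 20),
                                 IRanges::IRanges(seq(1, by = 100,
                                                      length.out = 40),
                                                  width = 100))
    gr$index <- rep(0:19, 2)
    gr$nTotal <- rep(1, 40)
    S <- matrix(c(1:20, 101:120), 40, 1, dimnames = list(NULL, "I_t"))
    scan <- new("IRScanResult",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(S = S), rowRanges = gr,
            colData = S4Vectors::DataFrame(label = "I_t", d1 = 1L,
                                           d2 = 10L, row.names = "I_t")))
    per <- criticalValueTable(scan, alpha = 0.05, scope = "chromosome")
    expect_equal(criticalValues(per)["c1", "I_t"], 19)
    expect_equal(criticalValues(per)["c2", "I_t"], 119)
    glob <- criticalValueTable(scan, alpha = 0.05, scope = "global")
    expect_equal(criticalValues(glob)["global", "I_t"], sort(S[, 1])[38])
    # pooling two replicates doubles the window counts
    two <- criticalValueTable(list(scan, scan), alpha = 0.05,
                              scope = "chromosome")
    expect_equal(unname(two@windowCounts[c("c1", "c2")]), c(40L, 40L))
    # JSON round trip
    path <- tempfile(fileext = ".json")
    writeCriticalValues(per, path)
    back <- readCriticalValues(path)
    expect_equal(criticalValues(back), criticalValues(per))
    expect_equal(back@alpha, 0.05)
})
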