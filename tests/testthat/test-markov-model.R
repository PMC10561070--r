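test_that("fitMarkov reproduces hand counts on tiny sequences", {
    f <- fitMarkov(chrom_from_string("AACC"), 1)
    expect_equal(wordProbs(f), c(0.5, 0.5, 0, 0))
    expect_equal(transitionProbs(f)[1L, ], c(0.5, 0.5, 0, 0))  # AA, AC
    expect_equal(transitionProbs(f)[2L, ], c(0, 1, 0, 0))      # CC
    expect_equal(transitionProbs(f)[3L, ], rep(0.25, 4))       # unseen: uniform

    deg <- fitMarkov(chrom_from_string("AAAA"), 1)
    expect_equal(wordProbs(deg), c(1, 0, 0, 0))
    expect_equal(transitionProbs(deg)[1L, 1L], 1)

    # adjacencies never cross the separator: only A->C and G->T
    two <- fitMarkov(chrom_from_string("ACNGT"), 1)
    expect_equal(transitionProbs(two)[1L, ], c(0, 1, 0, 0))
    expect_equal(transitionProbs(two)[3L, ], c(0, 0, 0, 1))
    expect_equal(sum(wordProbs(two)), 1)

    expect_error(fitMarkov(chrom_from_string("ANAN"), 2), "run")
})

test_that("model invariants hold on fitted random sequences", {
    set.seed(23)
    for (k in 1:3) {
        ch <- chrom_from_codes(random_masked_codes(3000, 0.1))
        f <- fitMarkov(ch, k)
        expect_equal(sum(wordProbs(f)), 1, tolerance = 1e-12)
        expect_true(all(abs(rowSums(transitionProbs(f)) - 1) < 1e-9))
        expect_true(all(wordProbs(f) >= 0))
    }
})

test_that("pairProbability: uniform i.i.d. null has the closed-form value", {
    # closed form, independently: sum_w pi(w) pi(rc(w)) with pi = 4^-k
    for (k in 1:2) {
        m <- presetModel("uniform", k = k)
        closed <- sum(rep(4^-k, 4^k) * 4^-k)  # = 4^-k
        p <- pairProbability(m, dmax = k + 6L, horizon = 3L)
        expect_equal(pairProbs(p), rep(closed, 7L), tolerance = 1e-12)
    }
})

test_that("deterministic complement chain gives p(d = k) = 1 and a degenerate flag", {
    trans <- matrix(0, 4, 4)
    trans[cbind(1:4, 4:1)] <- 1  # every base emits its complement
    m <- new("MarkovModel", k = 1L, pi = rep(0.25, 4), trans = trans,
             source = "toy")
    p <- pairProbability(m, dmax = 3L, horizon = 2L)
    expect_equal(pairProbs(p)[1L], 1 - 1e-12)
    expect_true(p@degenerate)
    sp <- pairCountSpectrum(chrom_from_string("ATAT"), k = 1, dmax = 3)
    expect_true(all(adjustedZScores(sp, p) == 0))
})

test_that("propagated p(d) converges to the stationary tail", {
    set.seed(29)
    ch <- chrom_from_codes(random_masked_codes(20000, 0.02))
    for (k in 1:3) {
        f <- fitMarkov(ch, k)
        p <- pairProbability(f, dmax = k + 60L, horizon = 50L)
        pp <- pairProbs(p)
        # flat beyond the horizon, and the exact value at g = horizon is
        # already within 1e-6 of the stationary tail
        expect_true(all(pp[(50 + 2):length(pp)] == pp[50 + 2]))
        expect_lt(abs(pp[50 + 1] - pp[50 + 2]), 1e-6)
    }
})

test_that("strand-symmetric null is invariant under reverse complementation", {
    # build a strand-symmetric i.i.d. model: pi(w) = pi(rc(w)) by symmetry
    m <- presetModel("gcskew", k = 2)
    pi <- wordProbs(m)
    rcmap <- vapply(0:15, function(w) {
        d <- c(w %/% 4L, w %% 4L)
        (3L - d[2L]) * 4L + (3L - d[1L])
    }, integer(1))
    expect_equal(pi, pi[rcmap + 1L], tolerance = 1e-15)
    p <- pairProbability(m, dmax = 12, horizon = 6)
    # reverse-complemented model is identical for an i.i.d. symmetric law
    expect_equal(pairProbs(p), pairProbs(pairProbability(m, 12, 6)),
                 tolerance = 1e-12)
})

test_that("simulateSequence preserves the mask and is seed-deterministic", {
    tmpl <- chrom_from_string("AANNAAA")
    m <- presetModel("uniform", k = 1)
    sim <- simulateSequence(m, tmpl, seed = 5)
    expect_identical(which(symbolCodes(sim) == 4L), c(3L, 4L))
    expect_true(all(symbolCodes(sim)[-c(3L, 4L)] < 4L))
    sim2 <- simulateSequence(m, tmpl, seed = 5)
    expect_identical(symbolCodes(sim), symbolCodes(sim2))
    big <- chrom_from_codes(rep(0L, 2000))
    expect_false(identical(
        symbolCodes(simulateSequence(m, big, seed = 1)),
        symbolCodes(simulateSequence(m, big, seed = 2))))
    # an all-zero word distribution cannot even be constructed
    expect_error(new("MarkovModel", k = 1L, pi = rep(0, 4),
                     trans = matrix(0.25, 4, 4), source = "zero"),
                 "sum to 1")
})

test_that("simulated k-mer frequencies recover the generating model", {
    set.seed(31)
    gen <- fitMarkov(chrom_from_codes(random_masked_codes(5e4, 0.01)), 2)
    tmpl <- chrom_from_codes(rep(0L, 3e5))
    sim <- simulateSequence(gen, tmpl, seed = 8)
    # chi-square goodness of fit of simulated 2-mer counts against pi
    counts <- tabulate(irscape:::wordCodes(symbolCodes(sim), 2) + 1L, 16L)
    expected <- sum(counts) * wordProbs(gen)
    keep <- expected > 5
    chisq <- sum((counts[keep] - expected[keep])^2 / expected[keep])
    # not rejected at alpha = 0.01 (mild overdispersion from chain
    # autocorrelation is expected; df upper bound is conservative)
    expect_lt(chisq, qchisq(0.99, df = sum(keep) - 1) * 2)
    # refit recovery: pi within 3 binomial SE
    refit <- fitMarkov(sim, 2)
    n <- sum(counts)
    se <- sqrt(wordProbs(gen) * (1 - wordProbs(gen)) / n)
    expect_true(all(abs(wordProbs(refit) - wordProbs(gen)) <= 3 * se + 1e-12))
})

test_that("model JSON serialization round-trips", {
    set.seed(37)
    f <- fitMarkov(chrom_from_codes(random_masked_codes(2000, 0.1)), 2)
    path <- tempfile(fileext = ".json")
    writeMarkovModel(f, path)
    back <- readMarkovModel(path)
    expect_equal(wordProbs(back), wordProbs(f), tolerance = 1e-12)
    expect_equal(transitionProbs(back), transitionProbs(f),
                 tolerance = 1e-12)
    expect_identical(modelOrder(back), modelOrder(f))
    expect_error(readMarkovModel(writeCriticalValues(
        new("CriticalValueTable",
            cv = matrix(1, 1, 1, dimnames = list("global", "I_t")),
            alpha = 0.05, windowCounts = c(global = 10L),
            replicates = 1L), tempfile())), "not an irscape Markov")
})

test_that("child seeds are deterministic, order-free and 31-bit", {
    s <- vapply(1:100, function(i) childSeed(123, i), integer(1))
    expect_identical(s, vapply(1:100, function(i) childSeed(123, i),
                               integer(1)))
    expect_equal(length(unique(s)), 100L)
    expect_true(all(s >= 0 & s < 2^31))
})
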