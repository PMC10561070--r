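# shared fixtures and independent oracles

# string -> integer codes (A=0 C=1 G=2 T=3, N=4)
s2c <- function(s) {
    m <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L)
    unname(m[strsplit(s, "")[[1L]]])
}

chrom_from_string <- function(s, name = "toy") {
    codes <- s2c(s)
    new("MaskedChromosome", name = name, codes = codes,
        runs = segmentRuns(codes))
}

chrom_from_codes <- function(codes, name = "toy") {
    new("MaskedChromosome", name = name, codes = as.integer(codes),
        runs = segmentRuns(as.integer(codes)))
}

# brute-force double-loop spectrum oracle: for every start pair (i, i+d)
# check that the whole span sits in unambiguous sequence and that the
# second word is the base-complemented reversal of the first
brute_spectrum <- function(codes, k, dmax) {
    L <- length(codes)
    m <- integer(dmax - k + 1L)
    if (L < 2L * k) return(m)
    for (i in seq_len(L - 2L * k + 1L)) {
        w1 <- codes[i:(i + k - 1L)]
        if (any(w1 > 3L)) next
        rcw <- rev(3L - w1)
        for (d in k:dmax) {
            j <- i + d
            if (j + k - 1L > L) break
            if (any(codes[(i + k):(j + k - 1L)] > 3L)) break
            if (all(codes[j:(j + k - 1L)] == rcw))
                m[d - k + 1L] <- m[d - k + 1L] + 1L
        }
    }
    m
}

# random masked code sequence
random_masked_codes <- function(L, p_n = 0.1) {
    codes <- sample(0:3, L, replace = TRUE)
    codes[runif(L) < p_n] <- 4L
    as.integer(codes)
}

# memoised default-world calibration shared by several acceptance checks
.fixture_env <- new.env(parent = emptyenv())
default_calibration <- function() {
    if (is.null(.fixture_env$cal)) {
        spec <- syntheticSpec(seed = 1L)
        genome <- generateGenome(spec)
        .fixture_env$genome <- genome
        .fixture_env$cal <- controlCalibration(genome$chroms, k = 3L,
            dmax = 1000L, windowSize = 1e5, alpha = 0.05, seed = 1L)
    }
    .fixture_env$cal
}
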