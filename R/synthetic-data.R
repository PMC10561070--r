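#' Construct a plant directive
#'
#' Describes the inverted repeats planted into one window: \code{count}
#' stem/loop/stem' units, stems of \code{stemLength} sampled from the
#' background word distribution, loop lengths drawn from \code{loop}
#' (scalar: fixed; length 2: uniform integer range; longer: sampled with
#' replacement — a periodic set).
#'
#' @param window 0-based window ordinal.
#' @param count number of units to plant (default 400; sized so a planted
#'   window separates clearly from the null S distribution at k = 7).
#' @param stemLength stem length (default 7).
#' @param loop loop-length rule (default c(10, 100), uniform).
#' @param chrom 1-based chromosome ordinal (default 1).
#' @return a \linkS4class{PlantDirective}.
#' @export
plantDirective <- function(window, count = 400L, stemLength = 7L,
                           loop = c(10L, 100L), chrom = 1L) {
    new("PlantDirective", window = as.integer(window),
        chrom = as.integer(chrom), count = as.integer(count),
        stemLength = as.integer(stemLength), loop = as.integer(loop))
}

#' Random hard-mask layout for a synthetic chromosome
#'
#' Emulates a RepeatMasker/Tandem-Repeats-Finder hard-masked chromosome:
#' N caps of \code{capLength} at both ends, then alternating unmasked and
#' N runs with exponential lengths (means \code{meanRun} and
#' \code{meanGap}); the defaults mask roughly 45% of the sequence, close
#' to the masked fraction of the human assembly.
#'
#' @param length chromosome length (nt).
#' @param meanRun mean unmasked run length (default 1000).
#' @param meanGap mean N-run length (default 800).
#' @param capLength terminal N-cap length (default 10000).
#' @return two-column matrix (start, length), 0-based, of N-runs.
#' @export
randomMask <- function(length, meanRun = 1000, meanGap = 800,
                       capLength = 10000) {
    stopifnot(length > 2 * capLength)
    nruns <- list()
    if (capLength > 0) nruns[[1L]] <- c(0, capLength)
    pos <- capLength
    lim <- length - capLength
    while (pos < lim) {
        pos <- pos + max(1, round(stats::rexp(1, 1 / meanRun)))
        if (pos >= lim) break
        gap <- max(1, round(stats::rexp(1, 1 / meanGap)))
        gap <- min(gap, lim - pos)
        nruns[[length(nruns) + 1L]] <- c(pos, gap)
        pos <- pos + gap
    }
    if (capLength > 0)
        nruns[[length(nruns) + 1L]] <- c(length - capLength, capLength)
    do.call(rbind, nruns)
}

#' Specify a synthetic test genome
#'
#' The default world: 4 chromosomes of 2 Mb, windows of 1e5 nt, a
#' GC-skewed i.i.d. background expressed as an order-3 model, a
#' hard-mask-like N layout (\code{\link{randomMask}}), and no plants.
#'
#' @param nChroms number of chromosomes (default 4).
#' @param chromLength chromosome length (default 2e6).
#' @param windowSize analysis window (default 1e5).
#' @param background a \linkS4class{MarkovModel} or preset name
#'   ("uniform" / "gcskew"; default "gcskew" at order \code{k}).
#' @param k background model order when a preset is named (default 3).
#' @param mask NULL (draw with \code{\link{randomMask}}, deterministically
#'   from \code{seed}) or a list of (start, length) matrices, one per
#'   chromosome.
#' @param plants list of \linkS4class{PlantDirective} (default none).
#' @param seed RNG seed (default 1).
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(nChroms = 4L, chromLength = 2e6,
                          windowSize = 1e5, background = "gcskew",
                          k = 3L, mask = NULL, plants = list(),
                          seed = 1L) {
    if (is.character(background))
        background <- presetModel(background, k = k)
    if (is.null(mask)) {
        set.seed(childSeed(seed, 999983L))
        mask <- lapply(seq_len(nChroms), function(i)
            randomMask(chromLength))
    }
    if (methods::is(plants, "PlantDirective")) plants <- list(plants)
    new("SyntheticSpec", nChroms = as.integer(nChroms),
        chromLength = chromLength, windowSize = windowSize,
        mask = mask, background = background, plants = plants,
        seed = as.integer(seed))
}

.apply_mask <- function(codes, maskmat) {
    if (is.null(maskmat) || nrow(maskmat) == 0L) return(codes)
    for (r in seq_len(nrow(maskmat))) {
        s <- maskmat[r, 1L]
        codes[(s + 1L):(s + maskmat[r, 2L])] <- 4L
    }
    codes
}

.sample_stem <- function(model, len) {
    # stem of arbitrary length from the background law: a pi-drawn word,
    # truncated or extended by the transition chain
    w <- sample.int(length(model@pi), 1L, prob = model@pi) - 1L
    k <- model@k
    out <- integer(max(len, k))
    ww <- w
    for (j in k:1) { out[j] <- ww %% 4L; ww <- ww %/% 4L }
    if (len > k) {
        keep <- 4L^(k - 1L)
        for (j in (k + 1L):len) {
            b <- sample.int(4L, 1L, prob = model@trans[w + 1L, ]) - 1L
            out[j] <- b
            w <- (w %% keep) * 4L + b
        }
    }
    out[seq_len(len)]
}

.draw_loop <- function(loop) {
    if (length(loop) == 1L) loop
    else if (length(loop) == 2L) sample(loop[1L]:loop[2L], 1L)
    else sample(loop, 1L)
}

#' Generate a synthetic genome with ground truth
#'
#' Background sequence is simulated per chromosome from the background
#' model with the specified N-mask; every plant directive then overwrites
#' stem and reverse-complement-stem positions (the loop keeps its
#' background content) at non-overlapping positions wholly inside one
#' unambiguous run of the target window.  Stems are sampled from the
#' background word distribution, so enrichment lives in the pairing
#' structure, not the composition.  Fully deterministic in
#' \code{spec@seed}.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param maxTries rejection-sampling attempts per planted unit.
#' @return list with \code{chroms} (list of
#'   \linkS4class{MaskedChromosome}, named chrS1..) and \code{truth}
#'   (data.frame chrom, window, start, d: one row per planted pair).
#' @export
generateGenome <- function(spec, maxTries = 200L) {
    validObject(spec)
    model <- spec@background
    if (model@k > spec@windowSize)
        stop("background order exceeds the window size")
    chroms <- vector("list", spec@nChroms)
    names(chroms) <- paste0("chrS", seq_len(spec@nChroms))
    for (i in seq_len(spec@nChroms)) {
        template <- .masked_chromosome(names(chroms)[i],
            .apply_mask(rep(0L, spec@chromLength), spec@mask[[i]]))
        chroms[[i]] <- simulateSequence(model, template,
                                        seed = childSeed(spec@seed, i),
                                        name = names(chroms)[i])
    }
    truth <- list()
    if (length(spec@plants)) {
        set.seed(childSeed(spec@seed, 424243L))
        for (pd in spec@plants) {
            ci <- pd@chrom
            if (ci < 1L || ci > spec@nChroms)
                stop("plant directive references chromosome ", ci)
            ch <- chroms[[ci]]
            codes <- ch@codes
            w0 <- pd@window * spec@windowSize
            w1 <- min(w0 + spec@windowSize, spec@chromLength)
            if (w0 >= spec@chromLength)
                stop("plant directive references window ", pd@window,
                     " beyond the chromosome")
            k <- pd@stemLength
            occupied <- IRanges::IRanges()
            for (u in seq_len(pd@count)) {
                placed <- FALSE
                for (t in seq_len(maxTries)) {
                    g <- .draw_loop(pd@loop)
                    span <- 2L * k + g
                    if (w1 - w0 < span) break
                    s <- w0 + sample.int(w1 - w0 - span + 1L, 1L) - 1L
                    seg <- codes[(s + 1L):(s + span)]
                    if (any(seg > 3L)) next       # span must sit in one run
                    words <- IRanges::IRanges(
                        start = c(s + 1L, s + k + g + 1L), width = k)
                    if (length(occupied) &&
                        sum(IRanges::countOverlaps(words, occupied)) > 0)
                        next
                    stem <- .sample_stem(model, k)
                    codes[(s + 1L):(s + k)] <- stem
                    codes[(s + k + g + 1L):(s + span)] <-
                        reverseComplementCodes(stem)
                    occupied <- c(occupied, words)
                    truth[[length(truth) + 1L]] <- data.frame(
                        chrom = names(chroms)[ci], window = pd@window,
                        start = s, d = k + g)
                    placed <- TRUE
                    break
                }
                if (!placed)
                    stop("could not place planted repeat ", u,
                         " in window ", pd@window,
                         " (overlaps or N-runs everywhere)")
            }
            chroms[[ci]] <- .masked_chromosome(names(chroms)[ci], codes)
        }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(chrom = character(), window = integer(),
                   start = numeric(), d = integer())
    list(chroms = chroms, truth = truth)
}

#' Write a synthetic genome, its truth table and its spec to disk
#'
#' @param genome result of \code{\link{generateGenome}}.
#' @param dir output directory (created if needed).
#' @param gzip compress the FASTA.
#' @param spec the \linkS4class{SyntheticSpec} used (recorded as JSON for
#'   reproducibility; optional).
#' @return named character vector of the written paths, invisibly.
#' @export
writeGenome <- function(genome, dir, gzip = FALSE, spec = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, if (gzip) "genome.fa.gz" else "genome.fa")
    writeMaskedFasta(genome$chroms, fa)
    tt <- file.path(dir, "truth.tsv")
    write.table(genome$truth, tt, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(fasta = fa, truth = tt)
    if (!is.null(spec)) {
        sj <- file.path(dir, "spec.json")
        jsonlite::write_json(list(
            format = "irscape-synthetic-spec", version = 1L,
            nChroms = spec@nChroms, chromLength = spec@chromLength,
            windowSize = spec@windowSize, seed = spec@seed,
            background = list(k = spec@background@k,
                              source = spec@background@source),
            mask = lapply(spec@mask, function(m)
                apply(m, 1L, as.numeric, simplify = FALSE)),
            plants = lapply(spec@plants, function(p) list(
                chrom = p@chrom, window = p@window, count = p@count,
                stemLength = p@stemLength, loop = as.numeric(p@loop)))),
            sj, auto_unbox = TRUE, digits = NA)
        paths <- c(paths, spec = sj)
    }
    invisible(paths)
}
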