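#' Scan a genome for inverted-repeat enrichment per window
#'
#' Tiles every chromosome into successive windows, computes the observed
#' and possible pair spectra, standardises them into T(d) against the
#' Markov null and sums T over the length classes into the S statistic.
#' By default one model (and hence one p(d) curve) is fitted per
#' chromosome and shared by all its windows; pass \code{models} to reuse
#' a null fitted elsewhere (e.g. to score a control replicate against the
#' null of the original genome).
#'
#' @param chroms list of \linkS4class{MaskedChromosome}.
#' @param k word (stem) length, default 7.
#' @param dmax maximum distance, default 4000.
#' @param windowSize window size in nt, default 1e5.
#' @param classes data.frame of length classes (default
#'   \code{\link{defaultLengthClasses}(k, dmax)}).
#' @param horizon exact-propagation horizon for p(d) (gap steps).
#' @param models optional: a named list of \linkS4class{MarkovModel}
#'   (names = chromosome names), a single model used for all chromosomes,
#'   or NULL to fit per chromosome.
#' @param modelScope "chromosome" (fit one model per chromosome) or
#'   "global" (pool all chromosomes); ignored when \code{models} given.
#' @return an \linkS4class{IRScanResult} with assay "S" (windows x
#'   classes), rowRanges carrying window index and nTotal (total possible
#'   pairs; 0 for fully masked windows).
#' @export
irScan <- function(chroms, k = 7L, dmax = 4000L, windowSize = 1e5,
                   classes = NULL, horizon = 50L, models = NULL,
                   modelScope = c("chromosome", "global")) {
    modelScope <- match.arg(modelScope)
    if (methods::is(chroms, "MaskedChromosome")) chroms <- list(chroms)
    if (is.null(classes)) classes <- defaultLengthClasses(k, dmax)
    .check_classes(classes, k, dmax)
    if (methods::is(models, "MarkovModel")) {
        models <- setNames(rep(list(models),length(chroms)),
                           vapply(chroms, chromName, character(1)))
    }
    if (is.null(models) && modelScope == "global") {
        gm <- fitMarkov(chroms, k, source = "global")
        models <- setNames(rep(list(gm), length(chroms)),
                           vapply(chroms, chromName, character(1)))
    }
    rows <- list()
    Smat <- list()
    for (ch in chroms) {
        nm <- chromName(ch)
        model <- if (is.null(models)) fitMarkov(ch, k) else models[[nm]]
        if (is.null(model)) stop("no model supplied for chromosome ", nm)
        p <- pairProbability(model, dmax = dmax, horizon = horizon)
        wins <- makeWindows(ch, windowSize, dmax = dmax, k = k)
        Sw <- matrix(0, nrow(wins), nrow(classes),
                     dimnames = list(NULL, classes$label))
        nTotal <- numeric(nrow(wins))
        for (i in seq_len(nrow(wins))) {
            sp <- pairCountSpectrum(ch, wins$start[i], wins$end[i],
                                    k = k, dmax = dmax)
            nTotal[i] <- sum(sp@n)
            T <- adjustedZScores(sp, p)
            Sw[i, ] <- vapply(seq_len(nrow(classes)), function(j)
                classScore(T, k, classes$d1[j], classes$d2[j]), numeric(1))
        }
        wins$nTotal <- nTotal
        rows[[nm]] <- wins
        Smat[[nm]] <- Sw
    }
    allw <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(allw$chrom,
        IRanges::IRanges(start = allw$start + 1L, end = allw$end))
    gr$index <- allw$index
    gr$nTotal <- allw$nTotal
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(S = do.call(rbind, Smat)),
        rowRanges = gr,
        colData = S4Vectors::DataFrame(classes, row.names = classes$label),
        metadata = list(k = k, dmax = dmax, windowSize = windowSize,
                        horizon = horizon))
    new("IRScanResult", se)
}

#' Simulate control replicates and derive critical values
#'
#' Fits the null per chromosome (or takes \code{models}), simulates
#' \code{replicates} control genomes preserving each chromosome's length
#' and N-mask, scans them against the same null, and returns the
#' nearest-rank critical-value table (plus the control scans,
#' invisibly attached as attribute \code{"scans"}).
#'
#' @inheritParams irScan
#' @param alpha significance level.
#' @param replicates number of control genomes pooled (paper: 1).
#' @param seed run seed; per-chromosome, per-replicate child seeds are
#'   derived with \code{\link{childSeed}} so results do not depend on
#'   processing order.
#' @param scope critical-value scope, "chromosome" or "global".
#' @return a \linkS4class{CriticalValueTable}.
#' @export
simulateCriticalValues <- function(chroms, k = 7L, dmax = 4000L,
                                   windowSize = 1e5, classes = NULL,
                                   horizon = 50L, models = NULL,
                                   alpha = 0.05, replicates = 1L,
                                   seed = 1L,
                                   scope = c("chromosome", "global")) {
    scope <- match.arg(scope)
    if (methods::is(chroms, "MaskedChromosome")) chroms <- list(chroms)
    nms <- vapply(chroms, chromName, character(1))
    if (is.null(models))
        models <- setNames(lapply(chroms, fitMarkov, k = k), nms)
    else if (methods::is(models, "MarkovModel"))
        models <- setNames(rep(list(models), length(chroms)), nms)
    scans <- lapply(seq_len(replicates), function(r) {
        sim <- lapply(seq_along(chroms), function(i)
            simulateSequence(models[[nms[i]]], chroms[[i]],
                             seed = childSeed(seed, (r - 1L) *
                                              length(chroms) + i)))
        irScan(sim, k = k, dmax = dmax, windowSize = windowSize,
               classes = classes, horizon = horizon, models = models)
    })
    cvt <- criticalValueTable(scans, alpha = alpha, scope = scope)
    attr(cvt, "scans") <- scans
    cvt
}

#' Per-window score table
#'
#' @param scan an \linkS4class{IRScanResult}, called or not.
#' @return data.frame: chrom, start, end, index, region label, one S
#'   column per class and (if called) one enriched column per class.
#' @export
scoreTable <- function(scan) {
    rr <- SummarizedExperiment::rowRanges(scan)
    S <- SummarizedExperiment::assay(scan, "S")
    out <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(rr)),
        start = GenomicRanges::start(rr) - 1L,
        end = GenomicRanges::end(rr),
        index = rr$index,
        region = regionLabel(as.character(GenomicRanges::seqnames(rr)),
                             GenomicRanges::start(rr) - 1L,
                             GenomicRanges::end(rr)),
        stringsAsFactors = FALSE, check.names = FALSE)
    colnames(S) <- paste0("S.", colnames(S))
    out <- cbind(out, S)
    if ("enriched" %in% SummarizedExperiment::assayNames(scan)) {
        fl <- SummarizedExperiment::assay(scan, "enriched")
        colnames(fl) <- paste0("enriched.", colnames(fl))
        out <- cbind(out, fl)
    }
    out
}

#' Export per-window scores as TSV and per-class BedGraph tracks
#'
#' @param scan an \linkS4class{IRScanResult}.
#' @param path TSV path for the score table.
#' @param bedgraphDir if non-NULL, one BedGraph per class
#'   (\code{S_<label>.bedgraph}) is written there.
#' @return \code{path}, invisibly.
#' @export
exportScores <- function(scan, path, bedgraphDir = NULL) {
    write.table(scoreTable(scan), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(bedgraphDir)) {
        dir.create(bedgraphDir, showWarnings = FALSE, recursive = TRUE)
        rr <- SummarizedExperiment::rowRanges(scan)
        S <- SummarizedExperiment::assay(scan, "S")
        for (cl in colnames(S)) {
            gr <- GenomicRanges::granges(rr)
            gr$score <- S[, cl]
            rtracklayer::export.bedGraph(gr,
                file.path(bedgraphDir, paste0("S_", cl, ".bedgraph")))
        }
    }
    invisible(path)
}

#' Heatmap matrix export: windows x classes S values
#'
#' The tabular data behind a per-chromosome S heatmap (rows in genome
#' order, one column per class).
#'
#' @param scan an \linkS4class{IRScanResult}.
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
exportHeatmapMatrix <- function(scan, path) {
    rr <- SummarizedExperiment::rowRanges(scan)
    S <- SummarizedExperiment::assay(scan, "S")
    tab <- cbind(data.frame(region = regionLabel(
        as.character(GenomicRanges::seqnames(rr)),
        GenomicRanges::start(rr) - 1L, GenomicRanges::end(rr))), S)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Length profile of one window
#'
#' The data behind a per-window length-profile plot: observed m(d),
#' possible n(d) and the expected count n(d) p(d) for every distance.
#'
#' @param chrom a \linkS4class{MaskedChromosome}.
#' @param start,end 0-based half-open window bounds.
#' @param p a \linkS4class{PairProbability} for the chromosome's null.
#' @return data.frame (d, m, n, expected).
#' @export
windowProfile <- function(chrom, start, end, p) {
    sp <- pairCountSpectrum(chrom, start, end, k = p@k, dmax = p@dmax)
    data.frame(d = distances(sp), m = sp@m, n = sp@n,
               expected = sp@n * p@p)
}

#' Select the profile windows of a chromosome
#'
#' The reporting convention: the windows with the highest total-class S,
#' the highest S in a chosen middle class, and the lowest total-class S.
#'
#' @param scan an \linkS4class{IRScanResult}.
#' @param chrom chromosome name.
#' @param middleClass label of the middle-length class (default "I_5").
#' @return data.frame (criterion, index, region, S).
#' @export
selectProfileWindows <- function(scan, chrom, middleClass = "I_5") {
    rr <- SummarizedExperiment::rowRanges(scan)
    sel <- as.character(GenomicRanges::seqnames(rr)) == chrom
    if (!any(sel)) stop("no windows for chromosome ", chrom)
    S <- SummarizedExperiment::assay(scan, "S")[sel, , drop = FALSE]
    rr <- rr[sel]
    total <- colnames(S)[1L]
    if (!middleClass %in% colnames(S)) middleClass <- total
    pick <- c(highest_total = which.max(S[, total]),
              highest_middle = which.max(S[, middleClass]),
              lowest_total = which.min(S[, total]))
    data.frame(criterion = names(pick),
               index = rr$index[pick],
               region = regionLabel(chrom,
                                    GenomicRanges::start(rr)[pick] - 1L,
                                    GenomicRanges::end(rr)[pick]),
               S = c(S[pick[1L], total], S[pick[2L], middleClass],
                     S[pick[3L], total]),
               stringsAsFactors = FALSE)
}

#' Serialize / restore a critical-value table as JSON
#'
#' @param cvtable a \linkS4class{CriticalValueTable}.
#' @param path JSON path.
#' @return \code{writeCriticalValues}: \code{path} invisibly;
#'   \code{readCriticalValues}: the restored table.
#' @export
writeCriticalValues <- function(cvtable, path) {
    obj <- list(format = "irscape-cv", version = 1L,
                alpha = cvtable@alpha, replicates = cvtable@replicates,
                scopes = rownames(cvtable@cv),
                classes = colnames(cvtable@cv),
                cv = apply(cvtable@cv, 1L, as.numeric, simplify = FALSE),
                window_counts = as.list(cvtable@windowCounts))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCriticalValues
#' @export
readCriticalValues <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$format, "irscape-cv"))
        stop("not an irscape critical-value file: ", path)
    cv <- do.call(rbind, obj$cv)
    dimnames(cv) <- list(obj$scopes, obj$classes)
    new("CriticalValueTable", cv = cv, alpha = obj$alpha,
        windowCounts = setNames(as.integer(unlist(obj$window_counts)),
                                names(obj$window_counts)),
        replicates = as.integer(obj$replicates))
}
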