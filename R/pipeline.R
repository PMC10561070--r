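#' Two-replicate control calibration
#'
#' The self-consistency experiment behind the empirical critical values:
#' fit the null per chromosome from \code{chroms}, simulate two
#' independent control replicates preserving each chromosome's N-mask,
#' derive per-chromosome nearest-rank critical values from replicate 1,
#' and call replicate 2 against them.  Under a well-specified null the
#' flagged fraction estimates the nominal significance level (up to the
#' finite-sample bias of the nearest-rank quantile).
#'
#' @inheritParams irScan
#' @param alpha significance level.
#' @param seed run seed; the two replicates use disjoint child-seed
#'   blocks.
#' @return list: \code{percentFlagged} (named by class, over all
#'   replicate-2 windows), \code{calls} (the called
#'   \linkS4class{IRScanResult} of replicate 2), \code{cvtable},
#'   \code{nWindows}.
#' @export
controlCalibration <- function(chroms, k = 3L, dmax = 1000L,
                               windowSize = 1e5, classes = NULL,
                               horizon = 50L, alpha = 0.05, seed = 1L) {
    if (methods::is(chroms, "MaskedChromosome")) chroms <- list(chroms)
    nms <- vapply(chroms, chromName, character(1))
    models <- setNames(lapply(chroms, fitMarkov, k = k), nms)
    reps <- lapply(1:2, function(r) {
        lapply(seq_along(chroms), function(i)
            simulateSequence(models[[i]], chroms[[i]],
                             seed = childSeed(seed,
                                              (r - 1L) * length(chroms) + i)))
    })
    scan1 <- irScan(reps[[1L]], k = k, dmax = dmax,
                    windowSize = windowSize, classes = classes,
                    horizon = horizon, models = models)
    scan2 <- irScan(reps[[2L]], k = k, dmax = dmax,
                    windowSize = windowSize, classes = classes,
                    horizon = horizon, models = models)
    cvt <- criticalValueTable(scan1, alpha = alpha, scope = "chromosome")
    called <- callEnrichment(scan2, cvt)
    flags <- SummarizedExperiment::assay(called, "enriched")
    list(percentFlagged = 100 * colMeans(flags), calls = called,
         cvtable = cvt, nWindows = nrow(flags))
}

#' Default run configuration
#'
#' The standard parameterisation: k = 7, distances up to 4000, windows of
#' 1e5 nt, significance level 5%, per-chromosome critical values, one
#' control replicate.
#'
#' @return named list of defaults.
#' @export
defaultRunConfig <- function() {
    list(k = 7L, dmax = 4000L, windowSize = 1e5, alpha = 0.05,
         cvScope = "chromosome", horizon = 50L, replicates = 1L,
         seed = 1L)
}
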