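#' Binomial z-score of an observed pair count
#'
#' Z = (M - n p) / sqrt(n p (1 - p)), the standardisation of a
#' Binomial(n, p) count; 0 when n = 0 (no information).  Vectorised over
#' all arguments.
#'
#' @param M observed count(s).
#' @param n possible pair positions.
#' @param p expected pair probability, strictly inside (0, 1).
#' @return numeric z-score(s).
#' @export
zScore <- function(M, n, p) {
    if (any(p <= 0) || any(p >= 1))
        stop("p must lie strictly inside (0,1); clip upstream")
    z <- (M - n * p) / sqrt(n * p * (1 - p))
    z[n == 0] <- 0
    z
}

#' Ambiguity-adjusted z-scores T(d) for one window
#'
#' T(d) is the binomial z-score of m(d) against n(d) p(d), with the
#' ambiguity adjustment living entirely in the N-aware n(d): positions
#' whose pair span would cross an N are not possible trials.  Distances
#' with n(d) = 0 contribute T(d) = 0, as does a degenerate null.
#'
#' @param spectrum a \linkS4class{DistanceSpectrum}.
#' @param p a \linkS4class{PairProbability} with matching k and dmax.
#' @return numeric vector T(d), d = k..dmax.
#' @export
adjustedZScores <- function(spectrum, p) {
    stopifnot(spectrum@k == p@k, spectrum@dmax == p@dmax)
    if (p@degenerate) return(numeric(length(spectrum@m)))
    zScore(spectrum@m, spectrum@n, p@p)
}

#' Default distance (length) classes
#'
#' The total class I_t covers [k, dmax]; I_1..I_8 split (0, dmax] into
#' eight equal-width bands, the first starting at k.  With the standard
#' parameters (k = 7, dmax = 4000) this reproduces I_1 = [7, 500],
#' I_2 = [501, 1000], ..., I_8 = [3501, 4000].
#'
#' @param k word length.
#' @param dmax maximum distance.
#' @param nClasses number of bands (default 8).
#' @return data.frame with columns label, d1, d2 (inclusive bounds).
#' @export
defaultLengthClasses <- function(k = 7L, dmax = 4000L, nClasses = 8L) {
    edges <- round(seq_len(nClasses) * dmax / nClasses)
    d1 <- c(k, head(edges, -1L) + 1L)
    data.frame(label = c("I_t", paste0("I_", seq_len(nClasses))),
               d1 = c(k, d1), d2 = c(dmax, edges),
               stringsAsFactors = FALSE)
}

#' Parse a classes string like "7:500,501:1000"
#'
#' @param text comma-separated d1:d2 pairs.
#' @param k,dmax used to validate bounds.
#' @return data.frame like \code{\link{defaultLengthClasses}}.
#' @export
parseLengthClasses <- function(text, k, dmax) {
    if (!nzchar(text)) stop("empty class list")
    parts <- strsplit(strsplit(text, ",")[[1L]], ":")
    cls <- data.frame(
        label = vapply(parts, function(p) paste0("S_", p[1L], "_", p[2L]),
                       character(1)),
        d1 = vapply(parts, function(p) as.integer(p[1L]), integer(1)),
        d2 = vapply(parts, function(p) as.integer(p[2L]), integer(1)),
        stringsAsFactors = FALSE)
    .check_classes(cls, k, dmax)
    cls
}

.check_classes <- function(classes, k, dmax) {
    stopifnot(is.data.frame(classes),
              all(c("label", "d1", "d2") %in% names(classes)))
    if (any(classes$d1 < k) || any(classes$d2 > dmax) ||
        any(classes$d1 > classes$d2))
        stop("class bounds must satisfy k <= d1 <= d2 <= dmax")
    invisible(classes)
}

#' Class score S[d1, d2]
#'
#' Inclusive sum of T(d) over a distance class.
#'
#' @param T numeric vector indexed d = k..dmax.
#' @param k word length (index origin of \code{T}).
#' @param d1,d2 inclusive class bounds.
#' @return numeric scalar.
#' @export
classScore <- function(T, k, d1, d2) {
    dmax <- k + length(T) - 1L
    if (d1 < k || d2 > dmax || d1 > d2)
        stop("class bounds outside the spectrum range")
    sum(T[(d1 - k + 1L):(d2 - k + 1L)])
}

#' Nearest-rank empirical upper quantile
#'
#' Sorts ascending and returns the element at 1-based rank
#' ceiling((1 - alpha) * N); alpha = 0 returns the maximum.  This is the
#' critical value construction: conservative and always an observed
#' value.
#'
#' @param values numeric vector of control S values.
#' @param alpha significance level in [0, 1).
#' @return numeric scalar.
#' @export
empiricalCriticalValue <- function(values, alpha = 0.05) {
    if (length(values) == 0L) stop("empty value set")
    if (alpha == 0) return(max(values))
    stopifnot(alpha > 0, alpha < 1)
    s <- sort(values)
    s[max(1L, ceiling((1 - alpha) * length(s)))]
}

#' Critical-value table from a control-scenario scan
#'
#' Per-(scope, class) nearest-rank 1-alpha quantiles of the S values of
#' all control windows in each chromosome (scope "chromosome") or of all
#' windows pooled (scope "global").  Several control replicates may be
#' supplied; their windows are pooled.
#'
#' @param scans an \linkS4class{IRScanResult} or list of them (control
#'   replicates).
#' @param alpha significance level (default 0.05).
#' @param scope "chromosome" or "global".
#' @return a \linkS4class{CriticalValueTable}.
#' @export
criticalValueTable <- function(scans, alpha = 0.05,
                               scope = c("chromosome", "global")) {
    scope <- match.arg(scope)
    if (methods::is(scans, "IRScanResult")) scans <- list(scans)
    S <- do.call(rbind, lapply(scans, function(x)
        SummarizedExperiment::assay(x, "S")))
    chrom <- unlist(lapply(scans, function(x)
        as.character(GenomicRanges::seqnames(
            SummarizedExperiment::rowRanges(x)))))
    groups <- if (scope == "global") rep("global", nrow(S)) else chrom
    scopes <- unique(groups)
    cv <- matrix(0, length(scopes), ncol(S),
                 dimnames = list(scopes, colnames(S)))
    for (g in scopes)
        cv[g, ] <- apply(S[groups == g, , drop = FALSE], 2L,
                         empiricalCriticalValue, alpha = alpha)
    new("CriticalValueTable", cv = cv, alpha = alpha,
        windowCounts = setNames(as.integer(table(groups)[scopes]), scopes),
        replicates = length(scans))
}

#' Flag enriched windows against critical values
#'
#' A window is enriched in a class iff its S strictly surpasses the
#' critical value of its scope; windows with no possible pair positions
#' at all (fully masked) are never flagged.
#'
#' @param scan an \linkS4class{IRScanResult}.
#' @param cvtable a \linkS4class{CriticalValueTable}.
#' @return the scan with a logical assay \code{"enriched"} added.
#' @export
callEnrichment <- function(scan, cvtable) {
    S <- SummarizedExperiment::assay(scan, "S")
    rr <- SummarizedExperiment::rowRanges(scan)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    scopes <- rownames(cvtable@cv)
    key <- if (identical(scopes, "global")) rep("global", nrow(S)) else chrom
    missing <- setdiff(unique(key), scopes)
    if (length(missing))
        stop("no critical values for scope(s): ",
             paste(missing, collapse = ", "))
    if (!setequal(colnames(S), colnames(cvtable@cv)))
        stop("length classes of scan and critical-value table differ")
    cv <- cvtable@cv[key, colnames(S), drop = FALSE]
    flags <- S > cv
    flags[rr$nTotal == 0, ] <- FALSE
    SummarizedExperiment::assay(scan, "enriched") <- flags
    S4Vectors::metadata(scan)$alpha <- cvtable@alpha
    scan
}

#' Per-chromosome enrichment summary
#'
#' One row per chromosome with the window count and the percentage of
#' enriched windows per length class (fully masked windows count in the
#' denominator), plus a "Global %" row over all windows and a "Mean cv"
#' row, the window-count-weighted mean of the per-chromosome critical
#' values.
#'
#' @param scan an \linkS4class{IRScanResult} with the \code{"enriched"}
#'   assay (see \code{\link{callEnrichment}}).
#' @param cvtable the \linkS4class{CriticalValueTable} used for calling.
#' @return data.frame in the layout described above.
#' @export
summarizeEnrichment <- function(scan, cvtable) {
    flags <- SummarizedExperiment::assay(scan, "enriched")
    chrom <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(scan)))
    chroms <- unique(chrom)
    per <- matrix(0, length(chroms), ncol(flags),
                  dimnames = list(chroms, colnames(flags)))
    for (g in chroms)
        per[g, ] <- 100 * colMeans(flags[chrom == g, , drop = FALSE])
    wins <- as.integer(table(chrom)[chroms])
    out <- data.frame(Chr = chroms, Wins = wins, per,
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (identical(rownames(cvtable@cv), "global")) {
        meancv <- cvtable@cv["global", colnames(flags)]
    } else {
        w <- wins[match(rownames(cvtable@cv), chroms)]
        keep <- !is.na(w)
        meancv <- colSums(cvtable@cv[keep, colnames(flags), drop = FALSE] *
                          w[keep]) / sum(w[keep])
    }
    out <- rbind(out,
                 data.frame(Chr = "Global %", Wins = NA_integer_,
                            t(100 * colMeans(flags)), check.names = FALSE),
                 data.frame(Chr = "Mean cv", Wins = NA_integer_,
                            t(meancv), check.names = FALSE))
    rownames(out) <- NULL
    out
}
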