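#' Reverse complement of a word in code space
#'
#' Positionally reverses the word and complements each base (A<->T,
#' C<->G; in codes, b -> 3 - b).  Applying it twice returns the input.
#'
#' @param word integer vector of codes in 0..3.
#' @return integer vector, the reverse complement.
#' @examples
#' # CCTTACG -> CGTAAGG
#' reverseComplementCodes(c(1L,1L,3L,3L,0L,1L,2L))
#' @export
reverseComplementCodes <- function(word) {
    if (any(word > 3L) || any(word < 0L))
        stop("ambiguous code in word; reverse complement undefined")
    rev(3L - word)
}

#' Rolling k-word codes of a code sequence
#'
#' Word code at position i encodes codes[i..i+k-1] base-4, first base most
#' significant; NA where the word would contain an ambiguous symbol.
#' Internal workhorse shared by model fitting and counting.
#'
#' @param codes integer vector over 0..4.
#' @param k word length.
#' @return integer vector of length \code{length(codes) - k + 1} (empty if
#'   shorter than k).
#' @keywords internal
wordCodes <- function(codes, k) {
    L <- length(codes)
    if (L < k) return(integer(0))
    n <- L - k + 1L
    w <- integer(n)
    bad <- logical(n)
    for (j in seq_len(k)) {
        cj <- codes[j:(j + n - 1L)]
        bad <- bad | cj > 3L
        w <- w * 4L + cj
    }
    w[bad] <- NA_integer_
    w
}

#' Reverse-complement map over word codes
#'
#' @param k word length.
#' @return integer vector v with v[w + 1] = code of the reverse complement
#'   of word w.
#' @keywords internal
rcWordMap <- function(k) {
    nw <- 4L^k
    w <- 0:(nw - 1L)
    r <- integer(nw)
    for (j in seq_len(k)) {
        digit <- w %% 4L         # j-th digit from the right = word position k-j+1
        r <- r * 4L + (3L - digit)
        w <- w %/% 4L
    }
    r
}

#' N-aware count of possible pair positions per distance
#'
#' n(d) = sum over unambiguous runs (clipped to the window) of
#' max(0, L_run - d - k + 1): both words and the enclosed loop must lie in
#' one run.
#'
#' @param runWidths integer vector of run lengths after clipping to the
#'   window.
#' @param k word length.
#' @param dmax maximum distance.
#' @return numeric vector n(d), d = k..dmax.
#' @export
validPairCounts <- function(runWidths, k, dmax) {
    d <- seq(k, dmax)
    if (length(runWidths) == 0L) return(numeric(length(d)))
    vapply(d, function(dd) sum(pmax(0, runWidths - dd - k + 1)), numeric(1))
}

.clip_runs <- function(runs, start0, end0) {
    # runs: IRanges (1-based); window [start0, end0) 0-based half-open
    cl <- IRanges::restrict(runs, start = as.integer(start0) + 1L,
                            end = as.integer(end0))
    cl[IRanges::width(cl) > 0L]
}

#' Observed inverted-repeat pair spectrum of one window
#'
#' Counts, for every distance d in [k, dmax], the ordered position pairs
#' (i, i+d) with both k-words wholly inside the window and inside a single
#' unambiguous run, such that word(i) equals the reverse complement of
#' word(i+d).  Every qualifying pair counts, not only nearest neighbours;
#' d is the difference of start positions, so d = k means adjacent words
#' and the loop length is d - k.
#'
#' @param chrom a \linkS4class{MaskedChromosome}.
#' @param start,end 0-based half-open window bounds (defaults: the whole
#'   chromosome).
#' @param k word (stem) length.
#' @param dmax maximum distance (default 4000).
#' @return a \linkS4class{DistanceSpectrum}.
#' @export
pairCountSpectrum <- function(chrom, start = 0, end = chromLength(chrom),
                              k = 7L, dmax = 4000L) {
    stopifnot(k >= 1L, dmax >= k, start >= 0, end <= chromLength(chrom))
    codes <- chrom@codes[(start + 1L):end]
    m <- .pair_count_core(codes, as.integer(k), as.integer(dmax))
    runs <- .clip_runs(chrom@runs, start, end)
    n <- validPairCounts(IRanges::width(runs), k, dmax)
    new("DistanceSpectrum", k = as.integer(k), dmax = as.integer(dmax),
        m = m, n = n, chrom = chromName(chrom),
        start = as.numeric(start), end = as.numeric(end))
}

#' Per-window spectrum table export
#'
#' One row per distance: window id, d, m(d), n(d).
#'
#' @param spectra list of \linkS4class{DistanceSpectrum}.
#' @param path TSV output path.
#' @return \code{path}, invisibly.
#' @export
exportSpectra <- function(spectra, path) {
    if (methods::is(spectra, "DistanceSpectrum")) spectra <- list(spectra)
    tab <- do.call(rbind, lapply(spectra, function(sp) {
        data.frame(window_id = regionLabel(sp@chrom, sp@start, sp@end),
                   d = distances(sp), m = sp@m, n = sp@n)
    }))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
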