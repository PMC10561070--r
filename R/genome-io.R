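CODE_LETTERS <- c("A", "C", "G", "T")

# IUPAC ambiguity letters (everything legal beyond ACGT), all mapped to
# the separator code 4.
IUPAC_AMBIGUOUS <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V",
                     "U", "-", "+", ".")

.code_lookup <- local({
    lk <- rep(NA_integer_, 256L)
    for (i in seq_along(CODE_LETTERS)) {
        lk[utf8ToInt(CODE_LETTERS[i]) + 1L] <- i - 1L
        lk[utf8ToInt(tolower(CODE_LETTERS[i])) + 1L] <- i - 1L
    }
    for (ch in IUPAC_AMBIGUOUS) {
        lk[utf8ToInt(ch) + 1L] <- 4L
        low <- tolower(ch)
        lk[utf8ToInt(low) + 1L] <- 4L
    }
    lk
})

.codes_from_string <- function(s, hard_mask_lower = FALSE, name = "sequence") {
    ints <- utf8ToInt(s)
    codes <- .code_lookup[ints + 1L]
    bad <- which(is.na(codes))
    if (length(bad))
        stop("non-IUPAC character '", intToUtf8(ints[bad[1L]]),
             "' at position ", bad[1L], " of record '", name, "'")
    if (hard_mask_lower) {
        lower <- ints >= utf8ToInt("a")
        codes[lower] <- 4L
    }
    codes
}

.string_from_codes <- function(codes) {
    letters5 <- c(CODE_LETTERS, "N")
    paste(letters5[codes + 1L], collapse = "")
}

#' Segment a code sequence into maximal unambiguous runs
#'
#' Ambiguous symbols (code 4) split the sequence into the maximal runs of
#' A/C/G/T within which all word counting happens.
#'
#' @param codes integer vector over 0..4.
#' @return an \link[IRanges]{IRanges} of maximal runs (1-based, sorted).
#' @examples
#' segmentRuns(c(0L, 1L, 4L, 2L, 3L))  # two runs: [1,2] and [4,5]
#' @export
segmentRuns <- function(codes) {
    if (length(codes) == 0L) return(IRanges::IRanges())
    r <- S4Vectors::Rle(codes < 4L)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(1L, head(ends, -1L) + 1L)
    keep <- S4Vectors::runValue(r)
    IRanges::IRanges(start = starts[keep], end = ends[keep])
}

.masked_chromosome <- function(name, codes) {
    new("MaskedChromosome", name = name, codes = codes,
        runs = segmentRuns(codes))
}

#' Read a hard-masked FASTA file
#'
#' Loads each record into a \linkS4class{MaskedChromosome}: lower case is
#' folded to upper case (soft-masking is ignored unless
#' \code{hardMaskLower}), A/C/G/T become codes 0..3 and every other IUPAC
#' symbol (N, R, Y, ...) becomes the separator code 4.  Gzip-compressed
#' files are handled transparently.
#'
#' @param path FASTA file, optionally .gz.
#' @param hardMaskLower treat lower-case (soft-masked) bases as ambiguous
#'   instead of folding them to upper case.
#' @return list of \linkS4class{MaskedChromosome}, in file order.
#' @export
readMaskedFasta <- function(path, hardMaskLower = FALSE) {
    if (!file.exists(path)) stop("no such file: ", path)
    seqs <- Biostrings::readBStringSet(path)
    if (length(seqs) == 0L) stop("empty FASTA file: ", path)
    nm <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(nm))
        stop("duplicate record name: ", nm[duplicated(nm)][1L])
    lapply(seq_along(seqs), function(i) {
        codes <- .codes_from_string(as.character(seqs[[i]]),
                                    hard_mask_lower = hardMaskLower,
                                    name = nm[i])
        .masked_chromosome(nm[i], codes)
    })
}

#' Write MaskedChromosome objects back to FASTA
#'
#' Ambiguous positions are written as \code{N}.  The written file
#' round-trips through \code{\link{readMaskedFasta}} to identical codes.
#'
#' @param chroms list of \linkS4class{MaskedChromosome}.
#' @param path output path; a \code{.gz} suffix triggers compression.
#' @return \code{path}, invisibly.
#' @export
writeMaskedFasta <- function(chroms, path) {
    if (methods::is(chroms, "MaskedChromosome")) chroms <- list(chroms)
    ss <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
        .string_from_codes(ch@codes), character(1)))
    names(ss) <- vapply(chroms, chromName, character(1))
    Biostrings::writeXStringSet(ss, path,
        compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Tile a chromosome into successive fixed-size windows
#'
#' Windows are non-overlapping, 0-based half-open; the trailing partial
#' window is kept, so the count is ceiling(length / windowSize).
#'
#' @param chrom a \linkS4class{MaskedChromosome}.
#' @param windowSize window size in nucleotides (default 1e5).
#' @param dmax,k if supplied, a warning is raised when
#'   \code{windowSize < dmax + 2*k} (the spectrum would be dominated by
#'   window truncation).
#' @return data.frame with columns chrom, index (0-based), start, end
#'   (0-based half-open).
#' @export
makeWindows <- function(chrom, windowSize = 1e5, dmax = NULL, k = NULL) {
    stopifnot(windowSize >= 1)
    if (!is.null(dmax) && !is.null(k) && windowSize < dmax + 2 * k)
        warning("windowSize < dmax + 2k: spectrum truncation dominates")
    L <- chromLength(chrom)
    nwin <- ceiling(L / windowSize)
    start <- (seq_len(nwin) - 1) * windowSize
    data.frame(chrom = chromName(chrom), index = seq_len(nwin) - 1L,
               start = start, end = pmin(start + windowSize, L),
               stringsAsFactors = FALSE)
}

#' Export a window table as BED3+1
#'
#' Tab-separated chrom, start, end, window index (0-based half-open, as
#' BED requires).
#'
#' @param windows data.frame from \code{\link{makeWindows}} (possibly
#'   concatenated over chromosomes).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
exportWindowsBed <- function(windows, path) {
    write.table(windows[, c("chrom", "start", "end", "index")], path,
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Human-readable 1-based region label for a window
#'
#' Mirrors the browser-style "chrX:53000001:53100000" convention.
#' @param chrom,start,end chromosome name and 0-based half-open bounds.
#' @return character label.
#' @export
regionLabel <- function(chrom, start, end) {
    sprintf("%s:%d:%d", chrom, as.integer(start) + 1L, as.integer(end))
}
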