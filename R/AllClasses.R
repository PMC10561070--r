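#' MaskedChromosome: one sequence with its ambiguity mask
#'
#' A chromosome is stored as integer symbol codes (A=0, C=1, G=2, T=3,
#' any ambiguous/IUPAC symbol=4) together with the maximal runs of
#' unambiguous bases derived from the mask.  Ambiguous symbols act as
#' separators: no word, loop or pair may cross them.
#'
#' @slot name single chromosome label.
#' @slot codes integer vector of symbol codes, one per position.
#' @slot runs \link[IRanges]{IRanges} of maximal unambiguous runs
#'   (1-based, as conventional for IRanges; converters to the package's
#'   0-based half-open convention are internal).
#'
#' @seealso \code{\link{readMaskedFasta}}, \code{\link{segmentRuns}}
#' @export
setClass("MaskedChromosome",
    representation(name = "character", codes = "integer", runs = "ANY"))

setValidity("MaskedChromosome", function(object) {
    msg <- NULL
    if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
    if (length(object@codes) &&
        (min(object@codes) < 0L || max(object@codes) > 4L))
        msg <- c(msg, "codes must lie in 0..4")
    r <- object@runs
    if (!methods::is(r, "IRanges")) {
        msg <- c(msg, "'runs' must be an IRanges")
    } else {
        if (length(r) && is.unsorted(IRanges::start(r)))
            msg <- c(msg, "runs must be sorted by start")
        if (sum(IRanges::width(r)) + sum(object@codes == 4L) !=
            length(object@codes))
            msg <- c(msg, "run widths + ambiguous count must equal length")
    }
    if (is.null(msg)) TRUE else msg
})

#' DistanceSpectrum: observed and possible pair counts for one window
#'
#' Holds m(d), the number of ordered stem/reverse-complement pairs whose
#' start positions differ by d (both words inside the window and inside a
#' single unambiguous run), and n(d), the number of positions such a pair
#' could occupy, for d = k .. d_max.  d = k means the two words are
#' adjacent; the loop length is d - k.
#'
#' @slot k stem (word) length in nucleotides.
#' @slot dmax maximum start-to-start distance considered.
#' @slot m integer vector of observed pair counts, index 1 is d = k.
#' @slot n numeric vector of possible pair positions, same indexing.
#' @slot chrom chromosome name of the window.
#' @slot start,end 0-based half-open window bounds.
#' @export
setClass("DistanceSpectrum",
    representation(k = "integer", dmax = "integer", m = "integer",
                   n = "numeric", chrom = "character",
                   start = "numeric", end = "numeric"))

setValidity("DistanceSpectrum", function(object) {
    nd <- object@dmax - object@k + 1L
    if (length(object@m) != nd || length(object@n) != nd)
        return("m and n must have length dmax - k + 1")
    if (any(object@m > object@n)) return("m(d) must not exceed n(d)")
    if (any(object@m < 0) || any(object@n < 0)) return("counts must be >= 0")
    TRUE
})

#' MarkovModel: order-k word and transition probabilities
#'
#' The null model for pair probabilities and the generator for
#' control-scenario genomes.  Words are indexed by their base-4 code
#' (A=0 .. T=3, first base most significant) plus one.
#'
#' @slot k model order = stem length.
#' @slot pi numeric vector of length 4^k, empirical word probabilities.
#' @slot trans 4^k x 4 matrix of transition probabilities; rows of words
#'   never observed in a transition context are uniform (1/4).
#' @slot source label: a chromosome name or "global".
#' @export
setClass("MarkovModel",
    representation(k = "integer", pi = "numeric", trans = "matrix",
                   source = "character"))

setValidity("MarkovModel", function(object) {
    nw <- 4L^object@k
    msg <- NULL
    if (length(object@pi) != nw) msg <- c(msg, "pi must have length 4^k")
    if (!all(dim(object@trans) == c(nw, 4L)))
        msg <- c(msg, "trans must be 4^k x 4")
    if (any(object@pi < 0) || any(object@trans < 0))
        msg <- c(msg, "probabilities must be >= 0")
    if (abs(sum(object@pi) - 1) > 1e-9) msg <- c(msg, "pi must sum to 1")
    rs <- rowSums(object@trans)
    if (any(abs(rs - 1) > 1e-9)) msg <- c(msg, "trans rows must sum to 1")
    if (is.null(msg)) TRUE else msg
})

#' PairProbability: expected inverted-repeat pair probability per distance
#'
#' p(d) for d = k .. dmax under an order-k Markov chain, computed by exact
#' state propagation through the loop for gaps up to \code{horizon} and by
#' the stationary approximation beyond it.
#'
#' @slot k word length.
#' @slot dmax maximum distance.
#' @slot p numeric vector, index 1 is d = k; clipped to [1e-12, 1-1e-12].
#' @slot horizon gap length beyond which p(d) is constant.
#' @slot degenerate TRUE when clipping was active (degenerate null); the
#'   z-scores are forced to 0 downstream in that case.
#' @export
setClass("PairProbability",
    representation(k = "integer", dmax = "integer", p = "numeric",
                   horizon = "integer", degenerate = "logical"))

setValidity("PairProbability", function(object) {
    if (length(object@p) != object@dmax - object@k + 1L)
        return("p must have length dmax - k + 1")
    if (any(object@p < 0) || any(object@p > 1)) return("p must lie in [0,1]")
    TRUE
})

#' CriticalValueTable: empirical S thresholds from the control scenario
#'
#' Per-(scope, length class) nearest-rank upper quantiles of control S
#' values; scope is a chromosome name or "global".
#'
#' @slot cv numeric matrix, scopes x classes (dimnames set).
#' @slot alpha significance level (paper default 0.05).
#' @slot windowCounts named integer, control windows per scope (pooled over
#'   replicates).
#' @slot replicates number of control replicates pooled.
#' @export
setClass("CriticalValueTable",
    representation(cv = "matrix", alpha = "numeric",
                   windowCounts = "integer", replicates = "integer"))

setValidity("CriticalValueTable", function(object) {
    if (object@alpha <= 0 || object@alpha >= 1)
        return("alpha must be in (0,1)")
    if (any(!is.finite(object@cv))) return("critical values must be finite")
    TRUE
})

#' IRScanResult: per-window S scores as a RangedSummarizedExperiment
#'
#' Rows are genome windows (rowRanges carries chrom/start/end and the
#' window index plus the total pair opportunity nTotal); columns are
#' length classes; assay \code{"S"} holds the class scores and, after
#' \code{\link{callEnrichment}}, assay \code{"enriched"} the calls.
#'
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @export
setClass("IRScanResult", contains = "RangedSummarizedExperiment")

#' PlantDirective: inverted repeats to plant in one synthetic window
#'
#' @slot window 0-based window ordinal within its chromosome.
#' @slot chrom chromosome ordinal (1-based) the directive applies to.
#' @slot count number of stem/loop/stem' units to plant.
#' @slot stemLength stem length (defaults to the analysis k).
#' @slot loop either a single loop length, a length-2 range sampled
#'   uniformly, or a longer vector sampled with replacement (a periodic
#'   set of loop lengths).
#' @export
setClass("PlantDirective",
    representation(window = "integer", chrom = "integer", count = "integer",
                   stemLength = "integer", loop = "integer"))

setValidity("PlantDirective", function(object) {
    if (object@count < 1L) return("count must be >= 1")
    if (any(object@loop < 0L)) return("loop lengths must be >= 0")
    TRUE
})

#' SyntheticSpec: a fully specified synthetic test genome
#'
#' @slot nChroms number of chromosomes.
#' @slot chromLength chromosome length (nt), identical across chromosomes.
#' @slot windowSize analysis window size (nt).
#' @slot mask list (one element per chromosome) of two-column matrices
#'   (start, length), 0-based, giving the N-runs.
#' @slot background a \linkS4class{MarkovModel} used to draw the
#'   unambiguous background sequence.
#' @slot plants list of \linkS4class{PlantDirective}.
#' @slot seed integer RNG seed; everything downstream is deterministic in it.
#' @export
setClass("SyntheticSpec",
    representation(nChroms = "integer", chromLength = "numeric",
                   windowSize = "numeric", mask = "list",
                   background = "MarkovModel", plants = "list",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    if (object@windowSize > object@chromLength)
        return("windowSize must not exceed chromLength")
    if (length(object@mask) != object@nChroms)
        return("mask must have one entry per chromosome")
    TRUE
})
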