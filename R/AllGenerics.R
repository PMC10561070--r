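#' @rdname MaskedChromosome-class
#' @param x,object a \linkS4class{MaskedChromosome}.
#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))

#' @rdname MaskedChromosome-class
#' @export
setGeneric("chromLength", function(x) standardGeneric("chromLength"))

#' @rdname MaskedChromosome-class
#' @export
setGeneric("symbolCodes", function(x) standardGeneric("symbolCodes"))

#' @rdname MaskedChromosome-class
#' @export
setGeneric("runRanges", function(x) standardGeneric("runRanges"))

#' @rdname MarkovModel-class
#' @param x,object a \linkS4class{MarkovModel}.
#' @export
setGeneric("modelOrder", function(x) standardGeneric("modelOrder"))

#' @rdname MarkovModel-class
#' @export
setGeneric("wordProbs", function(x) standardGeneric("wordProbs"))

#' @rdname MarkovModel-class
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname DistanceSpectrum-class
#' @param x,object a \linkS4class{DistanceSpectrum}.
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname DistanceSpectrum-class
#' @export
setGeneric("observedPairs", function(x) standardGeneric("observedPairs"))

#' @rdname DistanceSpectrum-class
#' @export
setGeneric("possiblePairs", function(x) standardGeneric("possiblePairs"))

#' @rdname PairProbability-class
#' @param x,object a \linkS4class{PairProbability}.
#' @export
setGeneric("pairProbs", function(x) standardGeneric("pairProbs"))

#' @rdname CriticalValueTable-class
#' @param x,object a \linkS4class{CriticalValueTable}.
#' @export
setGeneric("criticalValues", function(x) standardGeneric("criticalValues"))

setMethod("chromName", "MaskedChromosome", function(x) x@name)
setMethod("chromLength", "MaskedChromosome", function(x) length(x@codes))
setMethod("symbolCodes", "MaskedChromosome", function(x) x@codes)
setMethod("runRanges", "MaskedChromosome", function(x) x@runs)

setMethod("modelOrder", "MarkovModel", function(x) x@k)
setMethod("wordProbs", "MarkovModel", function(x) x@pi)
setMethod("transitionProbs", "MarkovModel", function(x) x@trans)

setMethod("distances", "DistanceSpectrum", function(x) seq(x@k, x@dmax))
setMethod("observedPairs", "DistanceSpectrum", function(x) x@m)
setMethod("possiblePairs", "DistanceSpectrum", function(x) x@n)

setMethod("pairProbs", "PairProbability", function(x) x@p)
setMethod("distances", "PairProbability", function(x) seq(x@k, x@dmax))

setMethod("criticalValues", "CriticalValueTable", function(x) x@cv)

setMethod("show", "MaskedChromosome", function(object) {
    nr <- length(object@runs)
    cat("MaskedChromosome '", object@name, "': ",
        length(object@codes), " nt, ", nr, " unambiguous run",
        if (nr == 1L) "" else "s", ", ",
        sum(object@codes == 4L), " ambiguous positions\n", sep = "")
})

setMethod("show", "MarkovModel", function(object) {
    cat("MarkovModel order k =", object@k, "(", 4L^object@k,
        "words ), source:", object@source, "\n")
})

setMethod("show", "DistanceSpectrum", function(object) {
    cat("DistanceSpectrum ", object@chrom, ":[", object@start, ",",
        object@end, ") k=", object@k, " d in [", object@k, ",",
        object@dmax, "], total pairs m=", sum(object@m), "\n", sep = "")
})

setMethod("show", "PairProbability", function(object) {
    cat("PairProbability k=", object@k, ", d in [", object@k, ",",
        object@dmax, "], horizon ", object@horizon,
        if (object@degenerate) " [degenerate null]" else "", "\n", sep = "")
})

setMethod("show", "CriticalValueTable", function(object) {
    cat("CriticalValueTable alpha=", object@alpha, ", ",
        nrow(object@cv), " scope(s) x ", ncol(object@cv), " class(es), ",
        object@replicates, " control replicate(s)\n", sep = "")
})
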