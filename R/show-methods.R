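#' @importFrom GenomicRanges seqnames
NULL

setMethod("show", "EmissionParams", function(object) {
    cat("EmissionParams\n")
    cat(sprintf("  neutral state: alphaN = %.4g, betaN = %.4g\n",
                object@alphaN, object@betaN))
    cat(sprintf("  linked state : alphaP = %.4g, betaP = %.4g (ratio %.3g)\n",
                object@alphaP, object@betaP, object@alphaP / object@betaP))
})

setMethod("show", "TransitionParams", function(object) {
    cat("TransitionParams\n")
    cat(sprintf("  rate = %.4g per bp, sExp = %.4g, pi = (N %.3g, P %.3g)\n",
                object@rate, object@sExp, object@piN, object@piP))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  chromosome %d bp, %d markers, %d segregants, coverage %d (%s)\n",
                object@chromLength, object@nMarkers, object@nSegregants,
                object@coverage, object@coverageMode))
    cat(sprintf("  psc = %.3g, crossover %.3g cM/kb, seqError %.3g, seed %s\n",
                object@psc, object@crossoverRate, object@seqError,
                ifelse(is.na(object@seed), "<unset>", object@seed)))
})

setMethod("show", "SimulatedPool", function(object) {
    cat("SimulatedPool\n")
    cat(sprintf("  %d markers on %d bp, pool of %d segregants (%d carriers)\n",
                length(object@positions), object@config@chromLength,
                length(object@carriers), sum(object@carriers)))
    cat(sprintf("  causal site at %d bp (marker %d)\n",
                causalPos(object), object@causalIndex))
})

setMethod("show", "BsaFit", function(object) {
    cat("BsaFit\n")
    cat(sprintf("  %d markers decoded, %d linked region(s) at posterior > %.3g\n",
                length(object@posteriors), length(object@regions),
                object@cutoff))
    cat(sprintf("  neutral fit: step 1 (%.4g, %.4g) -> step 2 (%.4g, %.4g)\n",
                object@emissionStep1@alphaN, object@emissionStep1@betaN,
                object@emissionStep2@alphaN, object@emissionStep2@betaN))
})
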