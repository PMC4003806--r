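#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

#' MarkerSet: per-site allele counts from a pooled sequencing experiment
#'
#' A \code{MarkerSet} holds marker sites (width-1 genomic positions) together
#' with the observed allele counts oriented toward the superior parent:
#' \code{superiorCount} is the number of reads supporting the superior-parent
#' variant and \code{totalCount} the total read count at the site.  An
#' optional \code{qual} column carries upstream genotype-quality scores.
#' The class extends \link[GenomicRanges]{GRanges}, so all range machinery
#' (subsetting, \code{split} by seqname, coercion) applies.
#'
#' Validity requires \code{0 <= superiorCount <= totalCount} at every site,
#' positions >= 1, and within each chromosome strictly increasing, duplicate-free
#' positions.
#'
#' @seealso [readMarkerTable()], [filterByCoverage()], [runBsaHmm()]
#' @export
setClass("MarkerSet", contains = "GRanges")

.validMarkerSet <- function(object) {
    msg <- character()
    mc <- mcols(object)
    if (!all(c("superiorCount", "totalCount") %in% colnames(mc)))
        return("mcols must contain 'superiorCount' and 'totalCount'")
    sc <- mc$superiorCount
    tc <- mc$totalCount
    if (anyNA(sc) || anyNA(tc))
        msg <- c(msg, "counts must not contain NA")
    else {
        if (any(sc < 0) || any(tc < 0))
            msg <- c(msg, "counts must be non-negative")
        if (any(sc > tc))
            msg <- c(msg, "superiorCount must not exceed totalCount")
    }
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "marker sites must have width 1")
        if (any(start(object) < 1L))
            msg <- c(msg, "positions must be >= 1")
        bychr <- split(start(object), as.character(seqnames(object)))
        if (any(vapply(bychr, function(p) is.unsorted(p, strictly = TRUE),
                       logical(1))))
            msg <- c(msg, "positions must be strictly increasing within each chromosome")
    }
    if (length(msg)) msg else TRUE
}
setValidity("MarkerSet", .validMarkerSet)

#' Construct a MarkerSet
#'
#' @param chrom character vector of chromosome identifiers.
#' @param pos 1-based physical positions (bp).
#' @param superiorCount reads supporting the superior-parent variant.
#' @param totalCount total reads covering each site.
#' @param qual optional numeric quality scores.
#' @return A \linkS4class{MarkerSet}, sorted by chromosome then position.
#' @examples
#' ms <- MarkerSet("chrI", c(100, 500, 900), c(12, 30, 18), c(25, 60, 40))
#' totalCount(ms)
#' @export
MarkerSet <- function(chrom, pos, superiorCount, totalCount, qual = NULL) {
    chrom <- as.character(chrom)
    if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
    mc <- DataFrame(superiorCount = as.integer(superiorCount),
                    totalCount = as.integer(totalCount))
    if (!is.null(qual)) mc$qual <- as.numeric(qual)
    gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
    mcols(gr) <- mc
    o <- order(as.character(seqnames(gr)), start(gr))
    new("MarkerSet", gr[o])
}

#' @describeIn MarkerSet reads supporting the superior-parent variant
#' @param x a \code{MarkerSet}
#' @export
superiorCount <- function(x) mcols(x)$superiorCount

#' @describeIn MarkerSet total read counts
#' @export
totalCount <- function(x) mcols(x)$totalCount

#' @describeIn MarkerSet genotype quality scores (NULL when absent)
#' @export
markerQual <- function(x) mcols(x)$qual

#' PosteriorSet: marker sites annotated with linkage posteriors
#'
#' A \linkS4class{MarkerSet} whose \code{posterior} metadata column stores, for
#' every site, the posterior probability that the site is in the
#' phenotype-linked (P) state given all counts on its chromosome.  The
#' complementary neutral-state posterior is \code{1 - posterior}.
#'
#' @seealso [forwardBackward()], [callLinkedRegions()]
#' @export
setClass("PosteriorSet", contains = "MarkerSet")

setValidity("PosteriorSet", function(object) {
    p <- mcols(object)$posterior
    if (is.null(p))
        return("mcols must contain 'posterior'")
    if (anyNA(p) || any(p < 0) || any(p > 1))
        return("posterior values must lie in [0, 1]")
    TRUE
})

#' @describeIn PosteriorSet per-site P-state posterior probabilities
#' @param x a \code{PosteriorSet}
#' @export
posterior <- function(x) mcols(x)$posterior

#' Beta-binomial emission parameters
#'
#' Shape parameters of the two beta-binomial emission distributions: the
#' neutral state (N) uses \code{(alphaN, betaN)}, fitted from the data, and
#' the phenotype-linked state (P) uses \code{(alphaP, betaP)}.  The
#' \code{alphaP/betaP} ratio is the stringency knob: larger ratios demand a
#' stronger skew toward the superior allele before a site is called linked.
#' By convention \code{betaP} is fixed at 1 and \code{alphaP} is varied.
#'
#' @slot alphaN,betaN,alphaP,betaP positive beta-binomial shapes.
#' @export
setClass("EmissionParams",
    representation(alphaN = "numeric", betaN = "numeric",
                   alphaP = "numeric", betaP = "numeric"))

setValidity("EmissionParams", function(object) {
    v <- c(object@alphaN, object@betaN, object@alphaP, object@betaP)
    if (length(v) != 4L || anyNA(v) || any(v <= 0) || any(!is.finite(v)))
        return("all four shape parameters must be positive and finite")
    TRUE
})

#' @rdname EmissionParams-class
#' @param alphaN,betaN neutral-state shapes (typically near-equal).
#' @param alphaP,betaP linked-state shapes; default \code{alphaP = 10},
#'   \code{betaP = 1} (a permissive stringency; 15 and 30 are common
#'   stricter presets).
#' @return An \code{EmissionParams} object.
#' @examples
#' EmissionParams(alphaN = 20, betaN = 20, alphaP = 15)
#' @export
EmissionParams <- function(alphaN, betaN, alphaP = 10, betaP = 1) {
    new("EmissionParams", alphaN = as.numeric(alphaN),
        betaN = as.numeric(betaN), alphaP = as.numeric(alphaP),
        betaP = as.numeric(betaP))
}

#' Distance-dependent transition parameters
#'
#' Parameters of the linkage-disequilibrium transition model.  Between
#' neighboring markers separated by \code{l} bp the chain stays in the
#' neutral state with probability \code{exp(-rate * l)} and in the linked
#' state with probability \code{exp(-rate * l * sExp)}; the complements are
#' the switch probabilities.  \code{rate} plays the role of a per-bp
#' recombination rate (default 3.5e-6, a yeast-scale estimate); \code{sExp}
#' rescales persistence of the linked state (default 1, symmetric states).
#' \code{piN}, \code{piP} are the initial state probabilities at the first
#' marker of each chromosome.
#'
#' @slot rate positive per-bp rate.
#' @slot sExp positive exponent scale for the P state.
#' @slot piN,piP initial state probabilities, summing to 1.
#' @export
setClass("TransitionParams",
    representation(rate = "numeric", sExp = "numeric",
                   piN = "numeric", piP = "numeric"))

setValidity("TransitionParams", function(object) {
    msg <- character()
    if (!(length(object@rate) == 1L && is.finite(object@rate) && object@rate > 0))
        msg <- c(msg, "rate must be a single positive number")
    if (!(length(object@sExp) == 1L && is.finite(object@sExp) && object@sExp > 0))
        msg <- c(msg, "sExp must be a single positive number")
    pi <- c(object@piN, object@piP)
    if (length(pi) != 2L || any(pi <= 0) || any(pi >= 1) ||
        abs(sum(pi) - 1) > 1e-9)
        msg <- c(msg, "piN and piP must lie in (0,1) and sum to 1")
    if (length(msg)) msg else TRUE
})

#' @rdname TransitionParams-class
#' @param rate recombination-scale rate per bp.
#' @param sExp linked-state exponent scale.
#' @param piN,piP initial state distribution.
#' @return A \code{TransitionParams} object.
#' @examples
#' TransitionParams()
#' @export
TransitionParams <- function(rate = 3.5e-6, sExp = 1, piN = 0.5, piP = 0.5) {
    new("TransitionParams", rate = as.numeric(rate), sExp = as.numeric(sExp),
        piN = as.numeric(piN), piP = as.numeric(piP))
}

#' Configuration of one synthetic BSA experiment
#'
#' Describes a single simulated bulk-segregant experiment: one artificial
#' chromosome of \code{chromLength} bp carrying \code{nMarkers} random
#' polymorphic sites, one of which is causal.  Haploid segregants are
#' generated by recombining the two parental genomes at
#' \code{crossoverRate} cM/kb; carriers of the causal superior allele enter
#' the selected pool with probability \code{psc} (non-carriers with
#' \code{1 - psc}) until \code{nSegregants} are pooled; the pool is then
#' sequenced at per-site coverage \code{coverage} (fixed, or Poisson-drawn
#' when \code{coverageMode = "poisson"}) with symmetric per-read error
#' \code{seqError}.
#'
#' @slot chromLength chromosome length in bp.
#' @slot nMarkers number of polymorphic marker sites.
#' @slot nSegregants pool size n.
#' @slot coverage per-site sequencing coverage c.
#' @slot psc proportion-of-selected-carriers acceptance probability.
#' @slot crossoverRate meiotic crossover rate in cM per kb.
#' @slot seqError per-read allele flip probability.
#' @slot coverageMode "fixed" or "poisson".
#' @slot seed integer RNG seed (NA for current RNG state).
#' @export
setClass("SimulationConfig",
    representation(chromLength = "integer", nMarkers = "integer",
                   nSegregants = "integer", coverage = "integer",
                   psc = "numeric", crossoverRate = "numeric",
                   seqError = "numeric", coverageMode = "character",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nMarkers < 2L)
        msg <- c(msg, "nMarkers must be >= 2")
    if (object@nMarkers > object@chromLength)
        msg <- c(msg, "nMarkers must not exceed chromLength")
    if (!(object@psc > 0 && object@psc <= 1))
        msg <- c(msg, "psc must lie in (0, 1]")
    if (!(object@seqError >= 0 && object@seqError < 0.5))
        msg <- c(msg, "seqError must lie in [0, 0.5)")
    if (object@crossoverRate < 0)
        msg <- c(msg, "crossoverRate must be >= 0")
    if (!object@coverageMode %in% c("fixed", "poisson"))
        msg <- c(msg, "coverageMode must be 'fixed' or 'poisson'")
    if (object@nSegregants < 1L || object@coverage < 1L)
        msg <- c(msg, "nSegregants and coverage must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param chromLength,nMarkers,nSegregants,coverage,psc,crossoverRate,seqError,coverageMode,seed
#'   see the slot descriptions.
#' @return A \code{SimulationConfig}.
#' @examples
#' SimulationConfig(psc = 0.95, seed = 7)
#' @export
SimulationConfig <- function(chromLength = 750000L, nMarkers = 2500L,
                             nSegregants = 30L, coverage = 200L, psc = 0.95,
                             crossoverRate = 0.37, seqError = 0.01,
                             coverageMode = c("fixed", "poisson"),
                             seed = NA_integer_) {
    coverageMode <- match.arg(coverageMode)
    new("SimulationConfig", chromLength = as.integer(chromLength),
        nMarkers = as.integer(nMarkers), nSegregants = as.integer(nSegregants),
        coverage = as.integer(coverage), psc = as.numeric(psc),
        crossoverRate = as.numeric(crossoverRate),
        seqError = as.numeric(seqError), coverageMode = coverageMode,
        seed = as.integer(seed))
}

#' One simulated pooled-sequencing dataset
#'
#' Output of [simulateDataset()]: the marker map with its causal index, the
#' per-segregant parental-origin matrix of the pooled segregants (1 =
#' superior parent), their carrier flags, and the resulting
#' \linkS4class{MarkerSet} of sequenced counts.
#'
#' @slot config the generating \linkS4class{SimulationConfig}.
#' @slot positions sorted marker coordinates (bp).
#' @slot causalIndex index of the causal marker in \code{positions}.
#' @slot originMatrix nSegregants x nMarkers binary matrix of parental origin.
#' @slot carriers logical; whether each pooled segregant carries the causal
#'   superior allele.
#' @slot markers the sequenced allele-count \linkS4class{MarkerSet}.
#' @export
setClass("SimulatedPool",
    representation(config = "SimulationConfig", positions = "integer",
                   causalIndex = "integer", originMatrix = "matrix",
                   carriers = "logical", markers = "MarkerSet"))

setValidity("SimulatedPool", function(object) {
    msg <- character()
    if (ncol(object@originMatrix) != length(object@positions))
        msg <- c(msg, "originMatrix columns must match positions")
    if (nrow(object@originMatrix) != length(object@carriers))
        msg <- c(msg, "originMatrix rows must match carriers")
    if (length(object@markers) != length(object@positions))
        msg <- c(msg, "markers must align with positions")
    ci <- object@causalIndex
    if (length(ci) != 1L || ci < 1L || ci > length(object@positions))
        msg <- c(msg, "causalIndex out of range")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulatedPool physical position (bp) of the causal site
#' @param x a \code{SimulatedPool}
#' @export
causalPos <- function(x) x@positions[x@causalIndex]

#' @describeIn SimulatedPool the sequenced allele-count MarkerSet
#' @export
poolMarkers <- function(x) x@markers

#' Fitted BSA-HMM result
#'
#' Returned by [runBsaHmm()].  Bundles the per-site linkage posteriors, the
#' called linked regions, the neutral emission parameters from both
#' estimation steps, the transition parameters, and a run report (marker
#' counts surviving each filter, cutoff, stringency).
#'
#' @slot posteriors a \linkS4class{PosteriorSet}.
#' @slot regions a \link[GenomicRanges]{GRanges} of called linked regions
#'   with metadata columns \code{nMarkers}, \code{maxPosterior},
#'   \code{meanPosterior}.
#' @slot emissionStep1,emissionStep2 \linkS4class{EmissionParams} before and
#'   after excluding linked sites from the neutral fit.
#' @slot transition \linkS4class{TransitionParams} used for decoding.
#' @slot cutoff posterior significance cutoff.
#' @slot report named list of run metadata.
#' @export
setClass("BsaFit",
    representation(posteriors = "PosteriorSet", regions = "GRanges",
                   emissionStep1 = "EmissionParams",
                   emissionStep2 = "EmissionParams",
                   transition = "TransitionParams",
                   cutoff = "numeric", report = "list"))

#' @describeIn BsaFit the per-site posterior track
#' @param x a \code{BsaFit}
#' @export
fitPosteriors <- function(x) x@posteriors

#' @describeIn BsaFit the called linked regions
#' @export
linkedRegions <- function(x) x@regions

#' @describeIn BsaFit neutral emission parameters (refined, step 2)
#' @export
fitEmission <- function(x) x@emissionStep2

#' @describeIn BsaFit the run report list
#' @export
runReport <- function(x) x@report
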