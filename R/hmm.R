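#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' Distance-dependent stay probabilities
#'
#' For each interval between consecutive markers, the probability that the
#' hidden state persists across the interval.  Linkage disequilibrium makes
#' nearby markers likely to share a state, decaying exponentially with
#' physical distance: stay-in-N = \code{exp(-rate * l)}, stay-in-P =
#' \code{exp(-rate * l * sExp)}; the complements are the switch
#' probabilities.
#'
#' @param positions strictly increasing marker coordinates (bp), length >= 2.
#' @param transition a \linkS4class{TransitionParams}.
#' @return A two-column matrix with one row per interval and columns
#'   \code{tauN}, \code{tauP}.
#' @examples
#' stayProbabilities(c(100, 1100), TransitionParams(rate = 3.5e-6))
#' @export
stayProbabilities <- function(positions, transition = TransitionParams()) {
    if (length(positions) < 2L || is.unsorted(positions, strictly = TRUE))
        stop("positions must be >= 2 strictly increasing coordinates")
    l <- diff(as.numeric(positions))
    cbind(tauN = exp(-transition@rate * l),
          tauP = exp(-transition@rate * l * transition@sExp))
}

# Scaled forward-backward for one chromosome; logEN/logEP are per-site
# emission log-likelihoods, tau the per-interval stay probabilities.
.fbChrom <- function(logEN, logEP, tauN, tauP, piN, piP) {
    T <- length(logEN)
    # per-site rescaling keeps exp() in range for any coverage/shape
    m <- pmax(logEN, logEP)
    eN <- exp(logEN - m)
    eP <- exp(logEP - m)
    aN <- numeric(T); aP <- numeric(T)
    fN <- piN * eN[1L]; fP <- piP * eP[1L]
    s <- fN + fP
    aN[1L] <- fN / s; aP[1L] <- fP / s
    for (t in seq_len(T - 1L)) {
        tn <- tauN[t]; tp <- tauP[t]
        fN <- (aN[t] * tn + aP[t] * (1 - tp)) * eN[t + 1L]
        fP <- (aN[t] * (1 - tn) + aP[t] * tp) * eP[t + 1L]
        s <- fN + fP
        aN[t + 1L] <- fN / s; aP[t + 1L] <- fP / s
    }
    bN <- numeric(T); bP <- numeric(T)
    bN[T] <- 1; bP[T] <- 1
    if (T > 1L) for (t in (T - 1L):1L) {
        tn <- tauN[t]; tp <- tauP[t]
        nN <- eN[t + 1L] * bN[t + 1L]
        nP <- eP[t + 1L] * bP[t + 1L]
        vN <- tn * nN + (1 - tn) * nP
        vP <- (1 - tp) * nN + tp * nP
        s <- vN + vP
        bN[t] <- vN / s; bP[t] <- vP / s
    }
    gP <- aP * bP
    gP / (aN * bN + gP)
}

#' Forward-backward linkage posteriors
#'
#' Exact smoothing posteriors of the two-state chain (neutral N vs
#' phenotype-linked P) with beta-binomial emissions and distance-dependent
#' transitions.  Each chromosome is decoded independently, starting from
#' the initial distribution \code{(piN, piP)}.  The returned per-site value
#' is the normalized linkage probability
#' P(P_i | D) / (P(P_i | D) + P(N_i | D)), which for a two-state chain is
#' simply the P-state smoothing posterior; the N-posterior is its
#' complement.
#'
#' @param markers a non-empty \linkS4class{MarkerSet}.
#' @param emission \linkS4class{EmissionParams}.
#' @param transition \linkS4class{TransitionParams}.
#' @return A \linkS4class{PosteriorSet} aligned with \code{markers}.
#' @examples
#' ms <- MarkerSet("chr", c(100, 400, 900), c(48, 50, 20), c(50, 50, 40))
#' em <- EmissionParams(alphaN = 20, betaN = 20, alphaP = 10, betaP = 1)
#' posterior(forwardBackward(ms, em, TransitionParams()))
#' @export
forwardBackward <- function(markers, emission, transition = TransitionParams()) {
    stopifnot(is(markers, "MarkerSet"), is(emission, "EmissionParams"),
              is(transition, "TransitionParams"))
    validObject(emission); validObject(transition)
    if (length(markers) == 0L)
        stop("cannot decode an empty MarkerSet")
    sc <- superiorCount(markers)
    tc <- totalCount(markers)
    logEN <- betaBinomLogPmf(sc, tc, emission@alphaN, emission@betaN)
    logEP <- betaBinomLogPmf(sc, tc, emission@alphaP, emission@betaP)
    chrom <- as.character(seqnames(markers))
    pos <- start(markers)
    post <- numeric(length(markers))
    for (idx in split(seq_along(markers), chrom)) {
        if (length(idx) == 1L) {
            num <- transition@piP * exp(logEP[idx] - max(logEP[idx], logEN[idx]))
            den <- transition@piN * exp(logEN[idx] - max(logEP[idx], logEN[idx]))
            post[idx] <- num / (num + den)
        } else {
            tau <- stayProbabilities(pos[idx], transition)
            post[idx] <- .fbChrom(logEN[idx], logEP[idx],
                                  tau[, "tauN"], tau[, "tauP"],
                                  transition@piN, transition@piP)
        }
    }
    out <- markers
    mcols(out)$posterior <- post
    new("PosteriorSet", out)
}

#' Call linked regions from a posterior track
#'
#' Maximal runs of consecutive markers with posterior strictly greater than
#' \code{cutoff} become regions; any sub-threshold marker breaks a run (no
#' gap tolerance).  Region coordinates span the first to the last marker of
#' the run.
#'
#' @param posteriors a \linkS4class{PosteriorSet}.
#' @param cutoff posterior significance threshold (default 0.95, strict
#'   inequality).
#' @return A \link[GenomicRanges]{GRanges} in genomic order with metadata
#'   columns \code{nMarkers}, \code{maxPosterior}, \code{meanPosterior}.
#' @export
callLinkedRegions <- function(posteriors, cutoff = 0.95) {
    stopifnot(is(posteriors, "PosteriorSet"))
    if (!(cutoff >= 0 && cutoff < 1))
        stop("cutoff must lie in [0, 1)")
    chrom <- as.character(seqnames(posteriors))
    pos <- start(posteriors)
    p <- posterior(posteriors)
    out <- list()
    for (chr in unique(chrom)) {
        idx <- which(chrom == chr)
        sig <- p[idx] > cutoff
        if (!any(sig)) next
        r <- rle(sig)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- which(r$values)
        for (k in runs) {
            sub <- idx[starts[k]:ends[k]]
            out[[length(out) + 1L]] <- GRanges(
                chr, IRanges(pos[sub[1L]], pos[sub[length(sub)]]),
                nMarkers = length(sub),
                maxPosterior = max(p[sub]),
                meanPosterior = mean(p[sub]))
        }
    }
    if (length(out) == 0L)
        return(GRanges(nMarkers = integer(), maxPosterior = numeric(),
                       meanPosterior = numeric()))
    do.call(c, out)
}

#' Run the full BSA-HMM pipeline
#'
#' Orchestrates the complete analysis: optional marker filters (quality,
#' then coverage, then spacing), a first method-of-moments fit of the
#' neutral emission parameters, posterior decoding, a second neutral fit
#' excluding sites decoded as linked, a final decoding, and region calling.
#' The result is deterministic given the input and parameters.
#'
#' Filters are applied only when their arguments are non-NULL; on simulated
#' data with fixed coverage you typically run with no filters.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @param alphaP,betaP linked-state emission shapes; \code{alphaP/betaP}
#'   is the stringency (default 10/1, permissive).
#' @param rate,sExp,piN,piP transition parameters (see
#'   \linkS4class{TransitionParams}).
#' @param cutoff posterior significance threshold (default 0.95).
#' @param minQual,minCov,maxCov,minSpacing optional filter settings;
#'   \code{NULL} disables the corresponding filter.
#' @return A \linkS4class{BsaFit}.
#' @examples
#' pool <- simulateDataset(SimulationConfig(nMarkers = 300, seed = 1))
#' fit <- runBsaHmm(poolMarkers(pool), alphaP = 15)
#' linkedRegions(fit)
#' @export
runBsaHmm <- function(markers, alphaP = 10, betaP = 1, rate = 3.5e-6,
                      sExp = 1, piN = 0.5, piP = 0.5, cutoff = 0.95,
                      minQual = NULL, minCov = NULL, maxCov = NULL,
                      minSpacing = NULL) {
    stopifnot(is(markers, "MarkerSet"))
    if (!(cutoff >= 0 && cutoff < 1))
        stop("cutoff must lie in [0, 1)")
    report <- list(nInput = length(markers))
    if (!is.null(minQual)) {
        markers <- filterByQuality(markers, minQual)
        report$nAfterQuality <- length(markers)
    }
    if (!is.null(minCov) || !is.null(maxCov)) {
        markers <- filterByCoverage(markers,
                                    minCov = if (is.null(minCov)) 0 else minCov,
                                    maxCov = if (is.null(maxCov)) Inf else maxCov)
        report$nAfterCoverage <- length(markers)
    }
    if (!is.null(minSpacing)) {
        markers <- filterBySpacing(markers, minSpacing)
        report$nAfterSpacing <- length(markers)
    }
    report$nAnalyzed <- length(markers)
    tr <- TransitionParams(rate = rate, sExp = sExp, piN = piN, piP = piP)
    if (length(markers) == 0L) {
        warning("no markers left after filtering; returning empty fit")
        emptyPost <- new("PosteriorSet", {
            g <- MarkerSet(character(), integer(), integer(), integer())
            mcols(g)$posterior <- numeric()
            g
        })
        em <- EmissionParams(1, 1, alphaP, betaP)
        return(new("BsaFit", posteriors = emptyPost,
                   regions = callLinkedRegions(emptyPost, cutoff),
                   emissionStep1 = em, emissionStep2 = em, transition = tr,
                   cutoff = cutoff, report = report))
    }
    step1 <- estimateNeutralParams(markers)
    em1 <- EmissionParams(step1[["alphaN"]], step1[["betaN"]], alphaP, betaP)
    step2 <- refineNeutralParams(markers, em1, tr, cutoff)
    em2 <- EmissionParams(step2[["alphaN"]], step2[["betaN"]], alphaP, betaP)
    post <- forwardBackward(markers, em2, tr)
    regions <- callLinkedRegions(post, cutoff)
    report$neutralFitStep1 <- as.list(step1)
    report$neutralFitStep2 <- as.list(step2)
    report$alphaP <- alphaP; report$betaP <- betaP
    report$rate <- rate; report$cutoff <- cutoff
    report$nRegions <- length(regions)
    new("BsaFit", posteriors = post, regions = regions,
        emissionStep1 = em1, emissionStep2 = em2, transition = tr,
        cutoff = cutoff, report = report)
}
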