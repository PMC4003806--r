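#' @importFrom stats rpois runif rbinom
NULL

#' Draw a random marker map
#'
#' Places \code{nMarkers} distinct polymorphic sites uniformly on
#' \code{[1, length]} and picks one of them, uniformly, to be causal.
#'
#' @param length chromosome length in bp.
#' @param nMarkers number of marker sites.
#' @return List with sorted integer \code{positions} and \code{causalIndex}.
#' @export
drawMarkerMap <- function(length, nMarkers) {
    if (nMarkers > length)
        stop("cannot place ", nMarkers, " distinct markers on ", length, " bp")
    positions <- sort(sample.int(length, nMarkers, replace = FALSE))
    list(positions = positions,
         causalIndex = sample.int(nMarkers, 1L))
}

#' Simulate one haploid segregant
#'
#' Meiotic recombination is modeled as a Poisson process of crossovers
#' along the chromosome with intensity \code{crossoverRate / 1e5} per bp
#' (0.37 cM/kb corresponds to 3.7e-6 crossovers per bp in the
#' small-distance Haldane limit).  The starting parent is Bernoulli(0.5)
#' and parental origin alternates at each crossover breakpoint; each
#' marker's origin is read off from its containing interval.
#'
#' @param positions sorted marker coordinates (bp).
#' @param chromLength chromosome length in bp.
#' @param crossoverRate crossover rate in cM per kb.
#' @return Integer vector over markers; 1 = superior-parent origin.
#' @export
simulateSegregant <- function(positions, chromLength, crossoverRate = 0.37) {
    startParent <- sample(0:1, 1L)
    breaks <- drawCrossovers(chromLength, crossoverRate)
    if (length(breaks) == 0L)
        return(rep.int(startParent, length(positions)))
    # parity of breakpoints to the left of each marker flips the parent
    nLeft <- findInterval(positions, breaks)
    as.integer((startParent + nLeft) %% 2L)
}

#' Draw meiotic crossover breakpoints
#'
#' Poisson process along \code{[1, chromLength]} with intensity
#' \code{crossoverRate / 1e5} per bp (cM/kb to Morgans/bp).
#'
#' @param chromLength chromosome length in bp.
#' @param crossoverRate crossover rate in cM per kb.
#' @return Sorted numeric vector of breakpoint positions (possibly empty).
#' @export
drawCrossovers <- function(chromLength, crossoverRate = 0.37) {
    if (crossoverRate < 0)
        stop("crossoverRate must be >= 0")
    rho <- crossoverRate / 100 / 1000
    nBreaks <- rpois(1L, rho * chromLength)
    sort(runif(nBreaks, min = 1, max = chromLength))
}

#' Build a selected segregant pool
#'
#' Repeatedly draws segregants; a segregant carrying the superior allele at
#' the causal marker is accepted into the pool with probability \code{psc},
#' a non-carrier with \code{1 - psc}, until \code{nSegregants} are pooled.
#' Because carriers arise with prior 1/2, the expected carrier fraction in
#' the pool equals \code{psc}.
#'
#' @param positions sorted marker coordinates.
#' @param causalIndex index of the causal marker.
#' @param nSegregants pool size.
#' @param psc carrier acceptance probability in (0, 1].
#' @param chromLength chromosome length (bp).
#' @param crossoverRate crossover rate (cM/kb).
#' @param maxAttempts guard against non-termination for extreme settings.
#' @return List with \code{originMatrix} (nSegregants x nMarkers) and
#'   logical \code{carriers}.
#' @export
selectPool <- function(positions, causalIndex, nSegregants, psc,
                       chromLength, crossoverRate = 0.37,
                       maxAttempts = 1000L * nSegregants) {
    if (!(psc > 0 && psc <= 1))
        stop("psc must lie in (0, 1]")
    origin <- matrix(0L, nrow = nSegregants, ncol = length(positions))
    carriers <- logical(nSegregants)
    accepted <- 0L
    attempts <- 0L
    while (accepted < nSegregants) {
        attempts <- attempts + 1L
        if (attempts > maxAttempts)
            stop("pool selection did not terminate within ", maxAttempts,
                 " attempts")
        seg <- simulateSegregant(positions, chromLength, crossoverRate)
        carrier <- seg[causalIndex] == 1L
        pAccept <- if (carrier) psc else 1 - psc
        if (runif(1L) < pAccept) {
            accepted <- accepted + 1L
            origin[accepted, ] <- seg
            carriers[accepted] <- carrier
        }
    }
    list(originMatrix = origin, carriers = carriers)
}

#' Sequence a pooled sample
#'
#' Per marker, the total read count is the fixed coverage \code{c} (or
#' Poisson(c)); each read samples one pooled segregant uniformly with
#' replacement and reports its allele, flipped with probability
#' \code{seqError}.  Marginally the superior count is
#' Binomial(total, f(1 - e) + (1 - f)e) with f the pool's superior-origin
#' fraction at the marker, which is how the counts are drawn.
#'
#' @param originMatrix pool origin matrix from [selectPool()].
#' @param positions marker coordinates.
#' @param chrom chromosome name for the output track.
#' @param coverage per-site coverage c.
#' @param seqError per-read flip probability.
#' @param coverageMode "fixed" or "poisson".
#' @return A \linkS4class{MarkerSet} of simulated counts.
#' @export
sequencePool <- function(originMatrix, positions, chrom = "sim",
                         coverage = 200L, seqError = 0.01,
                         coverageMode = c("fixed", "poisson")) {
    coverageMode <- match.arg(coverageMode)
    if (nrow(originMatrix) == 0L)
        stop("empty pool")
    nM <- length(positions)
    f <- colMeans(originMatrix)
    pRead <- f * (1 - seqError) + (1 - f) * seqError
    total <- if (coverageMode == "fixed") rep.int(as.integer(coverage), nM)
             else rpois(nM, coverage)
    sup <- rbinom(nM, total, pRead)
    MarkerSet(chrom, positions, sup, total)
}

#' Simulate one complete BSA dataset
#'
#' Composes [drawMarkerMap()], [selectPool()] and [sequencePool()] into one
#' synthetic experiment.  Fully reproducible: when \code{config@seed} is
#' set, the RNG is seeded locally and the caller's RNG state is untouched.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param chrom chromosome name used in the output (default "sim").
#' @return A \linkS4class{SimulatedPool}.
#' @examples
#' pool <- simulateDataset(SimulationConfig(nMarkers = 100, seed = 42))
#' causalPos(pool)
#' @export
simulateDataset <- function(config = SimulationConfig(), chrom = "sim") {
    validObject(config)
    if (!is.na(config@seed)) {
        if (exists(".Random.seed", envir = globalenv())) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()))
        }
        set.seed(config@seed)
    }
    map <- drawMarkerMap(config@chromLength, config@nMarkers)
    pool <- selectPool(map$positions, map$causalIndex, config@nSegregants,
                       config@psc, config@chromLength, config@crossoverRate)
    markers <- sequencePool(pool$originMatrix, map$positions, chrom = chrom,
                            coverage = config@coverage,
                            seqError = config@seqError,
                            coverageMode = config@coverageMode)
    new("SimulatedPool", config = config, positions = map$positions,
        causalIndex = map$causalIndex, originMatrix = pool$originMatrix,
        carriers = pool$carriers, markers = markers)
}
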