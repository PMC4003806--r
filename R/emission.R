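#' @importFrom stats var
NULL

#' Beta-binomial log probability mass
#'
#' Log of P(K = k | n, alpha, beta) for the beta-binomial distribution,
#' computed with log-gamma throughout so extreme shapes and large n stay
#' finite.  Vectorized over all arguments.
#'
#' @param k observed successes, 0 <= k <= n.
#' @param n number of trials.
#' @param alpha,beta positive shape parameters.
#' @return Log probabilities.
#' @examples
#' exp(betaBinomLogPmf(3, 7, 1, 1))   # uniform on 0..7 -> 1/8
#' @export
betaBinomLogPmf <- function(k, n, alpha, beta) {
    if (any(alpha <= 0) || any(beta <= 0))
        stop("alpha and beta must be positive")
    if (any(k < 0) || any(k > n))
        stop("k must lie in [0, n]")
    lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

#' Method-of-moments fit of the neutral emission parameters
#'
#' Estimates \code{(alphaN, betaN)} from the per-site superior-allele
#' fractions under the assumption that most of the genome is neutral.  With
#' \code{p_i = superiorCount_i / totalCount_i}, sample mean \code{mu} and
#' variance \code{v}, and mean coverage \code{nbar}, the intraclass
#' correlation is estimated as
#' \code{rho = (v * nbar / (mu * (1 - mu)) - 1) / (nbar - 1)},
#' clamped to \code{[1e-6, 1 - 1e-6]}; the concentration
#' \code{alphaN + betaN = 1/rho - 1} is capped at 1e6 (near-binomial for
#' underdispersed data) and split as \code{alphaN = mu * (alphaN + betaN)}.
#'
#' @param markers a \linkS4class{MarkerSet} with at least 2 covered sites.
#' @return Named numeric vector \code{c(alphaN = , betaN = )}.
#' @seealso [refineNeutralParams()] for the second estimation step.
#' @export
estimateNeutralParams <- function(markers) {
    stopifnot(is(markers, "MarkerSet"))
    tc <- totalCount(markers)
    keep <- tc >= 1L
    if (sum(keep) < 2L)
        stop("need at least 2 sites with positive coverage")
    sc <- superiorCount(markers)[keep]
    tc <- tc[keep]
    p <- sc / tc
    mu <- mean(p)
    if (mu <= 0 || mu >= 1)
        stop("degenerate allele fractions (all 0 or all 1); cannot fit")
    v <- var(p)
    nbar <- mean(tc)
    rho <- (v * nbar / (mu * (1 - mu)) - 1) / (nbar - 1)
    rho <- min(max(rho, 1e-6), 1 - 1e-6)
    conc <- min(1 / rho - 1, 1e6)
    c(alphaN = mu * conc, betaN = (1 - mu) * conc)
}

#' Refine the neutral fit by excluding linked sites
#'
#' Second step of the two-step neutral estimation: decode the data with the
#' current parameters, drop every site whose linkage posterior exceeds
#' \code{cutoff}, and re-fit \code{(alphaN, betaN)} on the remainder.  If
#' nothing survives (or too little to fit), the step-1 estimates are
#' returned with a warning.
#'
#' @param markers a \linkS4class{MarkerSet}.
#' @param emission current \linkS4class{EmissionParams}.
#' @param transition \linkS4class{TransitionParams}.
#' @param cutoff posterior threshold above which a site is treated as
#'   linked and excluded (default 0.95).
#' @return Named numeric vector \code{c(alphaN = , betaN = )}.
#' @export
refineNeutralParams <- function(markers, emission, transition,
                                cutoff = 0.95) {
    post <- forwardBackward(markers, emission, transition)
    keep <- posterior(post) <= cutoff
    if (sum(keep & totalCount(markers) >= 1L) < 2L) {
        warning("all sites excluded as linked; keeping step-1 estimates")
        return(c(alphaN = emission@alphaN, betaN = emission@betaN))
    }
    estimateNeutralParams(markers[keep])
}
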