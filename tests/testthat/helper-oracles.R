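# Independent oracles used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Beta-binomial pmf by direct gamma-function evaluation (no logs).
bbPmfDirect <- function(k, n, a, b) {
    choose(n, k) * beta(k + a, n - k + b) / beta(a, b)
}

# Exact smoothing posteriors by exhaustive enumeration over all 2^L state
# paths (0 = N, 1 = P).  Independent of the forward-backward code path.
bruteForcePosterior <- function(sc, tc, pos, em, tr) {
    L <- length(sc)
    logEN <- betaBinomLogPmf(sc, tc, em@alphaN, em@betaN)
    logEP <- betaBinomLogPmf(sc, tc, em@alphaP, em@betaP)
    l <- diff(as.numeric(pos))
    tauN <- exp(-tr@rate * l)
    tauP <- exp(-tr@rate * l * tr@sExp)
    states <- as.matrix(expand.grid(rep(list(0:1), L)))
    logp <- ifelse(states[, 1L] == 0L, log(tr@piN), log(tr@piP))
    logp <- logp + states %*% logEP + (1 - states) %*% logEN
    if (L > 1L) for (t in seq_len(L - 1L)) {
        from <- states[, t]; to <- states[, t + 1L]
        logp <- logp + log(ifelse(from == 0L,
                                  ifelse(to == 0L, tauN[t], 1 - tauN[t]),
                                  ifelse(to == 1L, tauP[t], 1 - tauP[t])))
    }
    w <- exp(logp - max(logp))
    as.numeric(crossprod(w, states) / sum(w))
}

# Random small marker track on one chromosome.
randomTrack <- function(L, maxCov = 60, chrom = "chr", withQual = FALSE) {
    pos <- sort(sample.int(100000L, L))
    tc <- sample(5:maxCov, L, replace = TRUE)
    sc <- rbinom(L, tc, runif(L))
    qual <- if (withQual) round(runif(L, 0, 99), 2) else NULL
    MarkerSet(chrom, pos, sc, tc, qual = qual)
}

# Draw beta-binomial counts (for method-of-moments recovery checks).
rBetaBinom <- function(nSites, n, a, b) {
    p <- rbeta(nSites, a, b)
    rbinom(nSites, n, p)
}

writeTempMarkerTsv <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}
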