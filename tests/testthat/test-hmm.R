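test_that("stay probabilities follow the exponential distance decay", {
    r <- 3.5e-6
    halfLife <- log(2) / r
    tau <- stayProbabilities(c(1, 1 + halfLife), TransitionParams(rate = r))
    expect_equal(tau[1, "tauN"], 0.5, tolerance = 1e-9, ignore_attr = TRUE)

    # frozen high-precision evaluation of 1 - exp(-3.5e-6 * 1000)
    tau2 <- stayProbabilities(c(1000, 2000), TransitionParams(rate = r))
    expect_equal(1 - tau2[1, "tauN"], 3.493882139585104e-3,
                 tolerance = 1e-12, ignore_attr = TRUE)

    # sExp rescales only the P-state exponent
    tau3 <- stayProbabilities(c(0, 1000), TransitionParams(rate = r, sExp = 2))
    expect_equal(tau3[1, "tauP"], tau3[1, "tauN"]^2, ignore_attr = TRUE)

    expect_error(stayProbabilities(c(200, 100), TransitionParams()), "increasing")
    expect_error(stayProbabilities(500, TransitionParams()), "increasing|2")
})

test_that("posteriors collapse to symmetry and Bayes limits", {
    # identical emissions in both states: posterior is the prior everywhere
    ms <- withr::with_seed(41, randomTrack(20))
    em <- EmissionParams(7, 7, 7, 7)
    expect_equal(posterior(forwardBackward(ms, em)), rep(0.5, 20))

    # single site: plain Bayes rule, no transitions involved
    single <- MarkerSet("c", 1000, 45, 50)
    em2 <- EmissionParams(20, 20, 10, 1)
    eN <- exp(betaBinomLogPmf(45, 50, 20, 20))
    eP <- exp(betaBinomLogPmf(45, 50, 10, 1))
    expect_equal(posterior(forwardBackward(single, em2)),
                 0.5 * eP / (0.5 * eN + 0.5 * eP), tolerance = 1e-12)
})

test_that("forward-backward matches exhaustive path enumeration", {
    withr::with_seed(42, {
        for (i in 1:20) {
            L <- sample(2:10, 1)
            ms <- randomTrack(L, maxCov = 40)
            em <- EmissionParams(runif(1, 1, 30), runif(1, 1, 30),
                                 runif(1, 5, 30), runif(1, 0.5, 2))
            tr <- TransitionParams(rate = 10^runif(1, -6, -3),
                                   sExp = runif(1, 0.5, 2))
            got <- posterior(forwardBackward(ms, em, tr))
            want <- bruteForcePosterior(superiorCount(ms), totalCount(ms),
                                        GenomicRanges::start(ms), em, tr)
            expect_equal(got, want, tolerance = 1e-10)
        }
    })
})

test_that("posteriors stay finite and normalized at extreme settings", {
    ms <- MarkerSet("c", c(100, 200, 300), c(0, 100, 50), c(100, 100, 100))
    em <- EmissionParams(0.2, 0.2, 500, 1)
    p <- posterior(forwardBackward(ms, em))
    expect_true(all(is.finite(p)))
    expect_true(all(p >= 0 & p <= 1))
})

test_that("region calling finds maximal supra-threshold runs", {
    ms <- MarkerSet("c", c(100, 200, 300, 400, 500),
                    rep(1, 5), rep(2, 5))
    post <- new("PosteriorSet", {
        g <- ms; S4Vectors::mcols(g)$posterior <- c(0.2, 0.97, 0.99, 0.3, 0.96); g
    })
    regions <- callLinkedRegions(post, 0.95)
    expect_length(regions, 2L)
    expect_equal(GenomicRanges::start(regions), c(200L, 500L))
    expect_equal(GenomicRanges::end(regions), c(300L, 500L))
    expect_equal(regions$nMarkers, c(2L, 1L))
    expect_equal(regions$maxPosterior, c(0.99, 0.96))

    S4Vectors::mcols(post)$posterior <- rep(0.5, 5)
    expect_length(callLinkedRegions(post, 0.95), 0L)

    S4Vectors::mcols(post)$posterior <- rep(0.99, 5)
    all <- callLinkedRegions(post, 0.95)
    expect_length(all, 1L)
    expect_equal(c(GenomicRanges::start(all), GenomicRanges::end(all)),
                 c(100L, 500L))

    # the cutoff is strict: a posterior exactly at the cutoff is not called
    S4Vectors::mcols(post)$posterior <- rep(0.95, 5)
    expect_length(callLinkedRegions(post, 0.95), 0L)
})

test_that("raising the stringency never enlarges called regions", {
    pool <- simulateDataset(SimulationConfig(nMarkers = 1000L, seed = 43))
    ms <- poolMarkers(pool)
    sizes <- sapply(c(10, 15, 30), function(aP) {
        fit <- runBsaHmm(ms, alphaP = aP)
        sum(GenomicRanges::width(linkedRegions(fit)))
    })
    expect_true(all(diff(sizes) <= 0))
})

test_that("transition rate limits bridge consensus and site independence", {
    ms <- withr::with_seed(44, randomTrack(12, maxCov = 30))
    em <- EmissionParams(10, 10, 8, 1)
    # r -> 0: the chain cannot switch, every site shares the chromosome-wide
    # consensus posterior
    pLow <- posterior(forwardBackward(ms, em, TransitionParams(rate = 1e-15)))
    expect_lt(diff(range(pLow)), 1e-6)
    # stay probability exactly 1/2 (r * l = ln 2 on an equally spaced
    # track): every transition row is uniform, the chain forgets its
    # neighbors, and the posterior equals the per-site Bayes value
    spacing <- 1000
    eq <- MarkerSet("c", seq(1, by = spacing, length.out = 12),
                    superiorCount(ms), totalCount(ms))
    pInd <- posterior(forwardBackward(eq, em,
                                      TransitionParams(rate = log(2) / spacing)))
    eN <- exp(betaBinomLogPmf(superiorCount(ms), totalCount(ms), 10, 10))
    eP <- exp(betaBinomLogPmf(superiorCount(ms), totalCount(ms), 8, 1))
    expect_equal(pInd, eP / (eN + eP), tolerance = 1e-12)
})

test_that("chromosomes are decoded independently", {
    withr::with_seed(45, {
        a <- randomTrack(15, chrom = "chrA")
        b <- randomTrack(15, chrom = "chrB")
    })
    both <- MarkerSet(c(rep("chrA", 15), rep("chrB", 15)),
                      c(GenomicRanges::start(a), GenomicRanges::start(b)),
                      c(superiorCount(a), superiorCount(b)),
                      c(totalCount(a), totalCount(b)))
    em <- EmissionParams(10, 10, 8, 1)
    pBoth <- posterior(forwardBackward(both, em))
    expect_equal(pBoth[1:15], posterior(forwardBackward(a, em)))
    expect_equal(pBoth[16:30], posterior(forwardBackward(b, em)))
})

test_that("the full pipeline recovers a strong simulated QTL", {
    pool <- simulateDataset(SimulationConfig(seed = 46))
    fit <- runBsaHmm(poolMarkers(pool), alphaP = 15)
    sc <- scorePredictions(linkedRegions(fit), causalPos(pool))
    expect_true(sc$recovered)
    rep <- runReport(fit)
    expect_named(rep$neutralFitStep1, c("alphaN", "betaN"))
    expect_named(rep$neutralFitStep2, c("alphaN", "betaN"))
    # identical reruns are deterministic
    fit2 <- runBsaHmm(poolMarkers(pool), alphaP = 15)
    expect_equal(posterior(fitPosteriors(fit)), posterior(fitPosteriors(fit2)))
})
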