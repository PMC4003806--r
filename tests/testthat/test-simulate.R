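test_that("simulations are reproducible from (config, seed)", {
    cfg <- SimulationConfig(nMarkers = 150L, seed = 7)
    a <- simulateDataset(cfg)
    b <- simulateDataset(cfg)
    expect_identical(a@positions, b@positions)
    expect_identical(a@causalIndex, b@causalIndex)
    expect_identical(superiorCount(poolMarkers(a)), superiorCount(poolMarkers(b)))

    fa <- tempfile(); fb <- tempfile()
    writeMarkerTable(poolMarkers(a), fa)
    writeMarkerTable(poolMarkers(b), fb)
    expect_identical(readLines(fa), readLines(fb))

    # seeding is local: the caller's RNG stream is untouched
    set.seed(99); x1 <- runif(1)
    set.seed(99); invisible(simulateDataset(cfg)); x2 <- runif(1)
    expect_identical(x1, x2)
})

test_that("marker maps are uniform, distinct, and sorted", {
    withr::with_seed(51, {
        map <- drawMarkerMap(1000L, 1000L)
        expect_identical(map$positions, 1:1000)

        map2 <- drawMarkerMap(750000L, 2500L)
        expect_false(is.unsorted(map2$positions, strictly = TRUE))
        expect_true(all(map2$positions >= 1 & map2$positions <= 750000))

        expect_error(drawMarkerMap(10L, 11L), "distinct")

        # causal index roughly uniform over markers
        draws <- replicate(2000, drawMarkerMap(5000L, 20L)$causalIndex)
        expect_gt(chisq.test(tabulate(draws, 20))$p.value, 1e-4)
    })
})

test_that("segregants recombine as a Poisson crossover process", {
    withr::with_seed(52, {
        # no crossovers: one parent throughout, balanced across segregants
        pos <- sort(sample.int(750000L, 50))
        segs <- replicate(400, simulateSegregant(pos, 750000L, 0))
        expect_true(all(apply(segs, 2, function(s) length(unique(s)) == 1L)))
        expect_lt(abs(mean(segs[1, ]) - 0.5), 3 * 0.5 / sqrt(400))

        # breakpoint count: mean rho * L = 2.775 on 750 kbp at 0.37 cM/kb
        nb <- replicate(4000, length(drawCrossovers(750000L, 0.37)))
        expect_lt(abs(mean(nb) - 2.775), 3 * sqrt(2.775 / 4000))

        # discordance between two markers l apart = (1 - exp(-2 rho l)) / 2
        l <- 100000
        rho <- 0.37 / 1e5
        two <- replicate(4000, simulateSegregant(c(1, 1 + l), 750000L, 0.37))
        disc <- mean(two[1, ] != two[2, ])
        want <- (1 - exp(-2 * rho * l)) / 2
        expect_lt(abs(disc - want), 3 * sqrt(want * (1 - want) / 4000))
    })
})

test_that("pool selection enriches carriers at rate PSC", {
    withr::with_seed(53, {
        map <- drawMarkerMap(750000L, 100L)
        full <- selectPool(map$positions, map$causalIndex, 200L, 1,
                           750000L)
        expect_true(all(full$carriers))
        expect_true(all(full$originMatrix[, map$causalIndex] == 1L))

        half <- selectPool(map$positions, map$causalIndex, 400L, 0.5,
                           750000L)
        expect_lt(abs(mean(half$carriers) - 0.5), 3 * 0.5 / sqrt(400))
    })
})

test_that("pooled sequencing has the closed-form expected allele fraction", {
    withr::with_seed(54, {
        map <- drawMarkerMap(750000L, 200L)
        pool <- selectPool(map$positions, map$causalIndex, 30L, 0.9, 750000L)

        # error-free, all-carrier pool: causal marker is fixed
        allCar <- selectPool(map$positions, map$causalIndex, 30L, 1, 750000L)
        ms0 <- sequencePool(allCar$originMatrix, map$positions,
                            coverage = 100L, seqError = 0)
        expect_equal(superiorCount(ms0)[map$causalIndex], 100L)

        # fixed mode pins the total count; poisson mode scatters around c
        msF <- sequencePool(pool$originMatrix, map$positions, coverage = 80L)
        expect_true(all(totalCount(msF) == 80L))
        msP <- sequencePool(pool$originMatrix, map$positions, coverage = 80L,
                            coverageMode = "poisson")
        expect_gt(var(totalCount(msP)), 0)
        expect_lt(abs(mean(totalCount(msP)) - 80), 3 * sqrt(80 / 200))

        # E[superior fraction] = f (1 - e) + (1 - f) e at each site
        e <- 0.01
        f <- colMeans(pool$originMatrix)
        reps <- replicate(60, superiorCount(
            sequencePool(pool$originMatrix, map$positions, coverage = 100L,
                         seqError = e)) / 100)
        want <- f * (1 - e) + (1 - f) * e
        se <- sqrt(want * (1 - want) / (100 * 60))
        expect_true(mean(abs(rowMeans(reps) - want) <= 4 * se) > 0.95)
    })
})

test_that("allele-frequency signal peaks at the causal site and decays", {
    # average over replicates: frequency near the causal site approaches
    # psc, and is ~0.5 at markers >= 300 kbp away
    withr::with_seed(55, {
        nearF <- c(); farF <- c()
        for (i in 1:20) {
            pool <- simulateDataset(SimulationConfig(nMarkers = 500L,
                                                     psc = 0.95,
                                                     seed = 5500 + i))
            f <- superiorCount(poolMarkers(pool)) / totalCount(poolMarkers(pool))
            d <- abs(pool@positions - causalPos(pool))
            nearF <- c(nearF, f[pool@causalIndex])
            farF <- c(farF, mean(f[d >= 300000]))
        }
        expect_gt(mean(nearF), 0.9)
        expect_lt(abs(mean(farF) - 0.5), 0.03)
    })
})

test_that("pool selection cannot loop forever", {
    map <- withr::with_seed(56, drawMarkerMap(10000L, 10L))
    # an extreme psc makes carrier acceptance astronomically rare; the
    # attempt guard turns non-termination into an error
    expect_error(withr::with_seed(57,
        selectPool(map$positions, map$causalIndex, 50L, 1e-12, 10000L,
                   crossoverRate = 0, maxAttempts = 60L)),
        "did not terminate")
})
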