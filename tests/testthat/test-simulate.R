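test_that("degenerate detection and death settings behave exactly", {
    # no detection: nothing is ever captured, but the bait still kills
    s0 <- simulateSite(
        simulationSpec(
            nPoints = 4, nSurveys = 10, trueC = 0, trueD = 0.5,
            mu = 30, sigma = 1, trapLossRate = 0, chemPolicy = "always_on"
        ),
        seed = 1
    )
    expect_true(all(countMatrix(s0$counts) == 0))
    expect_gt(sum(s0$truth$deaths), 0)

    # certain first-survey capture removes everyone at once
    s1 <- simulateSite(
        simulationSpec(
            nPoints = 4, nSurveys = 5, trueC = 1, trueD = 0,
            mu = 30, sigma = 1, trapLossRate = 0, chemPolicy = "always_on"
        ),
        seed = 2
    )
    expect_equal(countMatrix(s1$counts)[1, ], s1$truth$N)
    expect_true(all(countMatrix(s1$counts)[-1, ] == 0))
})

test_that("truth record accounts for every individual every month", {
    sim <- fixtureSim()
    tr <- sim$truth
    Tn <- nSurveys(sim$design)
    for (t in seq_len(Tn)) {
        upTo <- function(m) colSums(m[seq_len(t), , drop = FALSE])
        expect_equal(
            upTo(tr$captures) + upTo(tr$deaths) + tr$survivors[t, ],
            tr$N
        )
    }
    # counts object mirrors the truth captures
    expect_equal(countMatrix(sim$counts), tr$captures)
})

test_that("simulator and probability model agree in expectation", {
    # exogenous design (no trap loss, bait always on) so pi' is fixed
    spec <- simulationSpec(
        nPoints = 23, nSurveys = 59, trueC = 0.279, trueD = 0.00539,
        mu = 1400 / 23, sigma = 1, trapLossRate = 0, chemPolicy = "always_on"
    )
    nRep <- 200
    totals <- numeric(nRep)
    perSurvey <- matrix(0, 59, nRep)
    for (r in seq_len(nRep)) {
        sim <- simulateSite(spec, seed = 5000 + r)
        totals[r] <- sum(pointTotals(sim$counts))
        perSurvey[, r] <- rowSums(countMatrix(sim$counts))
    }
    rp <- removalProbabilities(
        matrix(0.279, 59, 23), matrix(0.00539, 59, 23)
    )
    expected <- sum(1400 / 23 * piPrime(rp)[, 1]) * 23
    se <- sd(totals) / sqrt(nRep)
    expect_lt(abs(mean(totals) - expected), 3 * se)

    # per-survey frequencies: chi-square goodness of fit on aggregated bins
    expMonth <- 1400 * piPrime(rp)[, 1]
    obs <- rowSums(perSurvey)
    bins <- pmin(findInterval(seq_len(59), c(1, 3, 5, 8, 12, 18, 26)), 7)
    obsB <- tapply(obs, bins, sum)
    expB <- tapply(expMonth * nRep, bins, sum)
    chi <- sum((obsB - expB)^2 / expB)
    expect_gt(pchisq(chi, df = length(obsB) - 1, lower.tail = FALSE), 0.01)
})

test_that("six-month bait rule follows plot-level detection history", {
    spec <- simulationSpec(
        nPoints = 6, nSurveys = 30, trueC = 0.5, trueD = 0.1,
        mu = 15, sigma = 2, trapLossRate = 0,
        plotOf = rep(1:2, each = 3)
    )
    sim <- simulateSite(spec, seed = 3)
    chem <- chemMatrix(sim$design)
    y <- countMatrix(sim$counts)
    for (pl in 1:2) {
        cols <- which(rep(1:2, each = 3) == pl)
        det <- which(rowSums(y[, cols, drop = FALSE]) > 0)
        for (t in 2:30) {
            recent <- length(det) && any(det >= t - 6 & det < t)
            if (t <= 6) recent <- recent || TRUE # start counts as a finding
            expect_equal(unique(chem[t, cols]), as.integer(recent))
        }
    }
})

test_that("delayed bait start overrides the application rule", {
    spec <- simulationSpec(
        nPoints = 4, nSurveys = 20, trueC = 0.3, trueD = 0.05,
        mu = 40, sigma = 1, trapLossRate = 0,
        delayMonths = c(11L, 11L, 0L, 0L)
    )
    sim <- simulateSite(spec, seed = 4)
    chem <- chemMatrix(sim$design)
    expect_true(all(chem[1:11, 1:2] == 0))
    expect_true(all(chem[1, 3:4] == 1))
})

test_that("site presets have the program's shape and are seed-deterministic", {
    tk <- tokaiLike(seed = 7)
    expect_equal(nPoints(tk$design), 23L)
    expect_equal(nSurveys(tk$design), 59L)
    jn <- jonanLike(seed = 7)
    expect_equal(nPoints(jn$design), 28L)
    expect_true(all(chemMatrix(jn$design)[1:11, 1:2] == 0))
    pg <- programLike(seed = 7)
    expect_equal(nPoints(pg$design), 51L)

    tk2 <- tokaiLike(seed = 7)
    expect_identical(countMatrix(tk$counts), countMatrix(tk2$counts))
    expect_identical(holdMatrix(tk$design), holdMatrix(tk2$design))
    tk3 <- tokaiLike(seed = 8)
    expect_false(identical(countMatrix(tk$counts), countMatrix(tk3$counts)))

    # dropping the lost first survey re-bases to 58 months
    tkd <- tokaiLike(seed = 7, dropFirst = TRUE)
    expect_equal(nSurveys(tkd$design), 58L)
    expect_equal(
        countMatrix(tkd$counts),
        countMatrix(tk$counts)[-1, ]
    )
})

test_that("sustained treatment eventually clears most replicates", {
    extinct <- 0L
    nRep <- 40L
    for (r in seq_len(nRep)) {
        sim <- tokaiLike(seed = 9000 + r)
        if (all(sim$truth$survivors[59, ] == 0)) extinct <- extinct + 1L
    }
    expect_gte(extinct / nRep, 0.95)
})

test_that("pooling sites aligns columns and preserves counts", {
    tk <- tokaiLike(seed = 11)
    jn <- jonanLike(seed = 12)
    pool <- poolSites(tk, jn)
    expect_equal(nPoints(pool$design), 51L)
    expect_equal(pool$siteCols[[1]], 1:23)
    expect_equal(pool$siteCols[[2]], 24:51)
    expect_equal(
        pointTotals(pool$counts),
        c(pointTotals(tk$counts), pointTotals(jn$counts))
    )
})
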