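test_that("cloglog detection link matches closed form and rejects bad input", {
    expect_equal(detectionLink(0, 0, 17), 1 - exp(-1), tolerance = 1e-12)
    expect_lt(detectionLink(-50, 0, 0), 1e-20)
    expect_equal(detectionLink(-2, 0.05, 20), 1 - exp(-exp(-1)),
        tolerance = 1e-12
    )
    expect_error(detectionLink(NA, 0, 1), "finite")
    expect_error(detectionLink(0, Inf, 1), "finite")
})

test_that("effective probabilities apply hold and chem corrections", {
    hold <- matrix(c(1, 0, 1, 1), 2, 2)
    chem <- matrix(c(1, 1, 0, 0), 2, 2)
    des <- surveyDesign(hold, chem)
    p <- modelParams(cConst = 0.279, dConst = 0.00539)
    eff <- effectiveProbs(p, des)
    expect_equal(eff$c[1, 1], 0.279)
    expect_equal(eff$c[2, 1], 0) # lost trap -> detection zeroed
    expect_equal(eff$d[1, 1], 0.00539)
    expect_equal(eff$d[1, 2], 0) # bait discontinued -> death zeroed
    # a lost trap does not protect from bait
    expect_equal(eff$d[2, 1], 0.00539)

    # original model: death term switched off entirely
    p0 <- modelParams(cConst = 0.279, chemicalTerm = FALSE)
    expect_true(all(effectiveProbs(p0, des)$d == 0))

    # temperature variant uses the link per survey
    desT <- surveyDesign(1, 1,
        nSurveys = 3, nPoints = 2,
        temperature = c(5, 15, 25)
    )
    pT <- modelParams(beta0 = -2, beta1 = 0.05, useTemperature = TRUE)
    effT <- effectiveProbs(pT, desT)
    expect_equal(effT$c[, 1], detectionLink(-2, 0.05, c(5, 15, 25)))
    expect_error(
        effectiveProbs(pT, surveyDesign(1, 1, nSurveys = 3, nPoints = 2)),
        "temperature"
    )
})

test_that("removal recursion reproduces worked joint-death and capture cases", {
    # pesticide-only: first-removal-by-death at the second survey
    rp <- removalProbabilities(c = c(0, 0), d = c(0.9, 0.9))
    expect_equal(deathProb(rp)[2, 1], (1 - 0.9) * 0.9, tolerance = 1e-15)

    # certain capture at the first survey exhausts the cohort
    rp1 <- removalProbabilities(c = c(1, 0.5, 0.5), d = rep(0, 3))
    expect_equal(piPrime(rp1)[, 1], c(1, 0, 0))
    expect_equal(phiMatrix(rp1)[1, 1], 0)

    # program point estimates over three surveys, against the fate oracle
    rp3 <- removalProbabilities(rep(0.279, 3), rep(0.00539, 3))
    o <- oracleFates(rep(0.279, 3), rep(0.00539, 3))
    expect_equal(piPrime(rp3)[, 1], o$pi, tolerance = 1e-12)
    expect_equal(deathProb(rp3)[, 1], o$delta, tolerance = 1e-12)
    expect_equal(piPrime(rp3)[1, 1], (1 - 0.00539) * 0.279, tolerance = 1e-12)
    expect_error(removalProbabilities(c = 1.2, d = 0.1), "\\[0, 1\\]")
})

test_that("fate partition conserves probability and phi is monotone", {
    set.seed(101)
    for (rep in 1:20) {
        Tn <- sample(1:60, 1)
        P <- sample(1:5, 1)
        cM <- matrix(runif(Tn * P), Tn, P)
        dM <- matrix(runif(Tn * P, 0, 0.5), Tn, P)
        rp <- removalProbabilities(cM, dM)
        cons <- colSums(piPrime(rp)) + colSums(deathProb(rp)) +
            phiMatrix(rp)[Tn, ]
        expect_true(all(abs(cons - 1) <= 1e-12))
        expect_true(all(diff(rbind(1, phiMatrix(rp))) <= 1e-15))
        expect_true(all(piPrime(rp) >= 0 & piPrime(rp) <= 1))
    }
})

test_that("raising an early death probability never raises later captures", {
    set.seed(7)
    cv <- runif(8, 0.1, 0.5)
    dv <- runif(8, 0, 0.2)
    base <- piPrime(removalProbabilities(cv, dv))[, 1]
    dv2 <- dv
    dv2[3] <- dv[3] + 0.3
    bumped <- piPrime(removalProbabilities(cv, dv2))[, 1]
    expect_true(all(bumped[3:8] <= base[3:8] + 1e-15))
    expect_equal(bumped[1:2], base[1:2])
})

test_that("switching the chemical term off recovers the capture-only model", {
    des <- surveyDesign(1, 1, nSurveys = 5, nPoints = 2)
    p0 <- modelParams(cConst = 0.3, chemicalTerm = FALSE)
    eff <- effectiveProbs(p0, des)
    rp <- removalProbabilities(eff$c, eff$d)
    # base model: pi_t = (1-c)^(t-1) c
    expect_equal(
        piPrime(rp)[, 1], (1 - 0.3)^(0:4) * 0.3,
        tolerance = 1e-12
    )
    expect_true(all(deathProb(rp) == 0))
})

test_that("marginal log-likelihood equals brute-force N-summation", {
    set.seed(202)
    for (rep in 1:8) {
        Tn <- sample(2:6, 1)
        P <- sample(1:3, 1)
        cc <- runif(1, 0.2, 0.7)
        dd <- runif(1, 0.001, 0.15)
        mu <- runif(1, 1, 10)
        sg <- runif(1, 0.5, 3)
        hold <- matrix(rbinom(Tn * P, 1, 0.9), Tn, P)
        chem <- matrix(rbinom(Tn * P, 1, 0.7), Tn, P)
        des <- surveyDesign(hold, chem)
        y <- matrix(rpois(Tn * P, 1.5), Tn, P)
        y[hold == 0] <- 0
        mp <- modelParams(cConst = cc, dConst = dd, mu = mu, sigma = sg)
        eff <- effectiveProbs(mp, des)
        ll <- marginalLogLik(mp, des, countData(y, des))
        bf <- oracleMarginalLL(eff$c, eff$d, mu, sg, y)
        expect_equal(ll, bf, tolerance = 1e-8)
    }
})

test_that("all-zero counts match the thinned negative-binomial zero mass", {
    des <- surveyDesign(1, 1, nSurveys = 4, nPoints = 3)
    y <- matrix(0L, 4, 3)
    mp <- modelParams(cConst = 0.4, dConst = 0.05, mu = 3, sigma = 2)
    ll <- marginalLogLik(mp, des, countData(y))
    eff <- effectiveProbs(mp, des)
    p <- sum(oracleFates(eff$c[, 1], eff$d[, 1])$pi)
    byHand <- 3 * log(sum(dbinom(0, 0:2000, p) * dnbinom(0:2000, size = 2, mu = 3)))
    expect_equal(ll, byHand, tolerance = 1e-8)
})

test_that("survey-order permutation moves only the multinomial term", {
    # constant probabilities: total capture probability is permutation
    # invariant, so the n_i marginal term must not change
    des <- surveyDesign(1, 1, nSurveys = 4, nPoints = 1)
    mp <- modelParams(cConst = 0.35, dConst = 0.02, mu = 6, sigma = 1)
    y1 <- matrix(c(5L, 3L, 1L, 0L))
    y2 <- matrix(c(0L, 1L, 3L, 5L)) # same n, different cells
    eff <- effectiveProbs(mp, des)
    pi <- piPrime(removalProbabilities(eff$c, eff$d))[, 1]
    ll1 <- marginalLogLik(mp, des, countData(y1))
    ll2 <- marginalLogLik(mp, des, countData(y2))
    expect_equal(
        ll1 - ll2,
        sum((y1 - y2) * log(pi)),
        tolerance = 1e-10
    )
})

test_that("impossible data yield -Inf rather than an error", {
    # capture probability zero everywhere but a positive count
    des <- surveyDesign(
        hold = matrix(0, 2, 1), chem = matrix(1, 2, 1)
    )
    mp <- modelParams(cConst = 0.3, dConst = 0.01, mu = 5, sigma = 1)
    cd <- countData(matrix(0L, 2, 1))
    cd@y[1, 1] <- 2
    cd@n <- colSums(cd@y)
    expect_error(marginalLogLik(mp, des, cd), "lost trap")
    expect_identical(marginalLogLik(mp, des, cd, strict = FALSE), -Inf)
})

test_that("design and count validity checks catch malformed inputs", {
    expect_error(surveyDesign(matrix(2, 2, 2), matrix(1, 2, 2)), "0/1")
    expect_error(
        surveyDesign(1, 1, nSurveys = 3, nPoints = 2, temperature = c(1, 2)),
        "temperature"
    )
    des <- surveyDesign(matrix(c(1, 0), 2, 1), matrix(1, 2, 1))
    expect_error(countData(matrix(c(0L, 3L), 2, 1), des), "lost")
    expect_error(countData(matrix(-1L, 1, 1)), "nonnegative")
})
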