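# Independent oracles: deliberately naive step-by-step / enumeration
# implementations used to verify the package's vectorized log-space code.

# Enumerate one individual's fate month by month in plain linear arithmetic.
oracleFates <- function(cv, dv) {
    Tn <- length(cv)
    alive <- 1
    pi <- del <- numeric(Tn)
    for (t in seq_len(Tn)) {
        del[t] <- alive * dv[t]
        pi[t] <- alive * (1 - dv[t]) * cv[t]
        alive <- alive * (1 - dv[t]) * (1 - cv[t])
    }
    list(pi = pi, delta = del, phiT = alive)
}

# Brute-force marginal log-likelihood: truncated sum over N per point,
# multinomial cell term via dmultinom.
oracleMarginalLL <- function(cM, dM, mu, sigma, y, nMax = 3000) {
    total <- 0
    for (i in seq_len(ncol(y))) {
        fate <- oracleFates(cM[, i], dM[, i])
        p <- sum(fate$pi)
        n <- sum(y[, i])
        Ns <- 0:nMax
        marg <- sum(dbinom(n, Ns, p) * dnbinom(Ns, size = sigma, mu = mu))
        mult <- if (n > 0) dmultinom(y[, i], prob = fate$pi / p) else 1
        total <- total + log(mult) + log(marg)
    }
    total
}

# Normalized conditional pmf of N given n by brute-force enumeration.
oracleLatentNpmf <- function(n, p, mu, sigma, nMax = n + 5000) {
    Ns <- n:nMax
    w <- dbinom(n, Ns, p) * dnbinom(Ns, size = sigma, mu = mu)
    data.frame(N = Ns, pmf = w / sum(w))
}

# Small deterministic fixture dataset used by several suites.
fixtureSim <- function(seed = 42) {
    simulateSite(
        simulationSpec(
            nPoints = 6, nSurveys = 20, trueC = 0.3, trueD = 0.02,
            mu = 25, sigma = 1, trapLossRate = 0.05
        ),
        seed = seed
    )
}
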