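#' Prior specification
#'
#' Priors follow the original analysis: uniform priors on the detection and
#' death probabilities and gamma priors on the negative-binomial abundance
#' parameters. The gamma hyperparameters default to shape = rate = 0.01
#' (near-non-informative); when the temperature covariate is used the cloglog
#' coefficients get independent Normal(0, betaSd) priors.
#'
#' @param cBounds,dBounds support of the uniform priors on c' and d'.
#' @param muShape,muRate gamma prior on mu.
#' @param sigmaShape,sigmaRate gamma prior on sigma.
#' @param betaSd normal prior standard deviation for beta0/beta1.
#' @return a named list of class `PriorSpec`.
#' @export
priorSpec <- function(cBounds = c(0, 1), dBounds = c(0, 1),
                      muShape = 0.01, muRate = 0.01,
                      sigmaShape = 0.01, sigmaRate = 0.01,
                      betaSd = 10) {
    stopifnot(
        length(cBounds) == 2L, cBounds[1] < cBounds[2],
        cBounds[1] >= 0, cBounds[2] <= 1,
        length(dBounds) == 2L, dBounds[1] < dBounds[2],
        dBounds[1] >= 0, dBounds[2] <= 1,
        muShape > 0, muRate > 0, sigmaShape > 0, sigmaRate > 0, betaSd > 0
    )
    structure(
        list(
            cBounds = cBounds, dBounds = dBounds,
            muShape = muShape, muRate = muRate,
            sigmaShape = sigmaShape, sigmaRate = sigmaRate,
            betaSd = betaSd
        ),
        class = "PriorSpec"
    )
}

#' MCMC configuration
#'
#' The original analysis ran 220,000 iterations after a 20,000-iteration
#' burn-in, thinning at 100, with three chains. The defaults here are a
#' ten-fold desk-scale reduction (22,000 / 2,000 / thin 10, three chains);
#' pass the full settings for a paper-faithful run.
#'
#' @param nIter post-burn-in iterations per chain.
#' @param nBurnin burn-in iterations (adaptation happens here and is then
#'   frozen).
#' @param thin retain every `thin`-th post-burn-in iteration.
#' @param nChains number of chains (>= 2 needed for [rhat()]).
#' @param seed integer seed; all randomness in the fit flows from it.
#' @return a named list of class `MCMCConfig`.
#' @export
mcmcConfig <- function(nIter = 22000, nBurnin = 2000, thin = 10,
                       nChains = 3, seed = 1) {
    stopifnot(
        nIter > 0, nBurnin >= 0, thin >= 1, nChains >= 1,
        nIter %% thin == 0 || TRUE
    )
    structure(
        list(
            nIter = as.integer(nIter), nBurnin = as.integer(nBurnin),
            thin = as.integer(thin), nChains = as.integer(nChains),
            seed = as.integer(seed)
        ),
        class = "MCMCConfig"
    )
}

#' Exact draw of the latent initial abundance
#'
#' Samples N_i from its conditional given the observed total n_i, the total
#' capture probability p_i and the negative-binomial prior NegBin(mu, sigma):
#' `Pr(N | n) \propto Binomial(n | p, N) NegBin(N | mu, sigma)`. The
#' conditional has closed form: `N - n ~ NegBin(size = n + sigma,
#' prob = 1 - (1 - p) mu / (mu + sigma))`, so `N >= n` always.
#'
#' @param n observed total removals (vectorized).
#' @param captureTotal total capture probability p in (0, 1]; recycled.
#' @param mu,sigma negative-binomial abundance parameters.
#' @param nDraws draws per element of `n` (default 1; >1 returns a matrix
#'   with `nDraws` rows).
#' @return integer draw(s) of N.
#' @examples
#' set.seed(1)
#' sampleLatentN(5, captureTotal = 1, mu = 10, sigma = 1) # == 5
#' @export
sampleLatentN <- function(n, captureTotal, mu, sigma, nDraws = 1) {
    stopifnot(mu > 0, sigma > 0, all(n >= 0), all(captureTotal >= 0),
        all(captureTotal <= 1))
    if (any(captureTotal == 0 & n > 0)) {
        stop("captureTotal = 0 with n > 0: impossible data", call. = FALSE)
    }
    k <- max(length(n), length(captureTotal))
    n <- rep_len(n, k)
    p <- rep_len(captureTotal, k)
    prob <- 1 - (1 - p) * mu / (mu + sigma)
    draw <- function() n + stats::rnbinom(k, size = n + sigma, prob = prob)
    if (nDraws == 1L) {
        draw()
    } else {
        t(vapply(seq_len(nDraws), function(i) draw(), numeric(k)))
    }
}

## ---- fast likelihood evaluator ------------------------------------------

## Precomputes the data-dependent constants of the marginal log-likelihood so
## an MCMC sweep only pays a few vectorized ops per evaluation. Exploits
## c_{t,i} = c'_t * hold and d_{t,i} = d' * chem:
##   log pi'_{t,i} = sum_{k<t} hold * log(1-c'_k) + (sum_{k<=t} chem) log(1-d')
##                   + log c'_t   (defined where hold_{t,i} = 1)
## Returns function(cPrime, dPrime, mu, sigma) -> list(ll, p).
makeLogLikFun <- function(design, data, useTemperature = FALSE) {
    hold <- holdMatrix(design)
    chem <- chemMatrix(design)
    y <- countMatrix(data)
    n <- pointTotals(data)
    Tn <- nrow(hold)
    if (any(y > 0 & hold == 0)) {
        stop("positive count at a lost trap (hold = 0)", call. = FALSE)
    }
    Hprev <- rbind(0, apply(hold, 2L, cumsum)[-Tn, , drop = FALSE])
    Dcum <- apply(chem, 2L, cumsum)
    if (!is.matrix(Dcum)) Dcum <- matrix(Dcum, nrow = Tn)
    A <- sum(y * Hprev)
    B <- sum(y * Dcum)
    nTot <- sum(n)
    ok <- n > 0
    coefTerm <- sum(lgamma(n[ok] + 1)) - sum(lgamma(y[y > 0] + 1))
    yRow <- rowSums(y)

    if (!useTemperature) {
        function(cPrime, dPrime, mu, sigma) {
            l1c <- log1p(-cPrime)
            l1d <- log1p(-dPrime)
            p <- cPrime * colSums(exp(Hprev * l1c + Dcum * l1d) * hold)
            if (any(p == 0 & n > 0)) {
                return(list(ll = -Inf, p = p))
            }
            cell <- A * l1c + B * l1d + nTot * log(cPrime)
            ll <- cell - sum(n[ok] * log(p[ok])) + coefTerm +
                sum(stats::dnbinom(n, size = sigma, mu = p * mu, log = TRUE))
            list(ll = ll, p = p)
        }
    } else {
        function(cPrime, dPrime, mu, sigma) {
            ## cPrime is a length-T vector here
            l1c <- log1p(-cPrime)
            l1d <- log1p(-dPrime)
            M <- hold * l1c
            Lc <- apply(M, 2L, cumsum)
            if (!is.matrix(Lc)) Lc <- matrix(Lc, nrow = Tn)
            Lprev <- rbind(0, Lc[-Tn, , drop = FALSE])
            p <- colSums(exp(Lprev + Dcum * l1d) * (hold * cPrime))
            if (any(p == 0 & n > 0)) {
                return(list(ll = -Inf, p = p))
            }
            cell <- sum(y * Lprev) + B * l1d + sum(yRow * log(cPrime))
            ll <- cell - sum(n[ok] * log(p[ok])) + coefTerm +
                sum(stats::dnbinom(n, size = sigma, mu = p * mu, log = TRUE))
            list(ll = ll, p = p)
        }
    }
}

## ---- the sampler ---------------------------------------------------------

#' Fit the chemical-eradication removal model by MCMC
#'
#' Metropolis-within-Gibbs: random-walk Metropolis updates on transformed
#' parameters (logit c' or raw cloglog coefficients, logit d', log mu,
#' log sigma) against the likelihood with the latent abundances N_i
#' marginalized out, followed by an exact conditional draw of every N_i at
#' each retained iteration via [sampleLatentN()]. Proposal scales adapt
#' during burn-in toward ~30% acceptance and are frozen afterwards. Chains
#' start from independent overdispersed draws constrained to finite
#' likelihood.
#'
#' @param data a [CountData-class].
#' @param design a matching [SurveyDesign-class].
#' @param priors a [priorSpec()] list.
#' @param config an [mcmcConfig()] list.
#' @param chemicalTerm include the pesticide death probability d'? `FALSE`
#'   fits the original capture-only removal model.
#' @param useTemperature model detection with the cloglog temperature
#'   regression instead of a constant c'?
#' @param verbose print progress per chain?
#' @return a [PosteriorDraws-class] object.
#' @export
fitEradication <- function(data, design, priors = priorSpec(),
                           config = mcmcConfig(),
                           chemicalTerm = TRUE, useTemperature = FALSE,
                           verbose = FALSE) {
    stopifnot(
        is(data, "CountData"), is(design, "SurveyDesign"),
        inherits(priors, "PriorSpec"), inherits(config, "MCMCConfig")
    )
    if (sum(pointTotals(data)) == 0) {
        ## degenerate all-zero data is allowed; c' is then prior-driven
        if (verbose) message("no detections in the data; c' is weakly identified")
    }
    if (useTemperature && is.null(temperature(design))) {
        stop("useTemperature = TRUE requires a temperature vector in the design",
            call. = FALSE
        )
    }
    logLikFun <- makeLogLikFun(design, data, useTemperature = useTemperature)
    temp <- temperature(design)

    ## parameter bookkeeping on the transformed scale
    parNames <- c(
        if (useTemperature) c("beta0", "beta1") else "c",
        if (chemicalTerm) "d",
        "mu", "sigma"
    )
    k <- length(parNames)
    cb <- priors$cBounds
    db <- priors$dBounds

    natural <- function(theta) {
        i <- 1L
        out <- list()
        if (useTemperature) {
            out$beta0 <- theta[1L]
            out$beta1 <- theta[2L]
            out$cPrime <- detectionLink(theta[1L], theta[2L], temp)
            i <- 3L
        } else {
            out$cPrime <- cb[1] + diff(cb) * stats::plogis(theta[1L])
            i <- 2L
        }
        if (chemicalTerm) {
            out$dPrime <- db[1] + diff(db) * stats::plogis(theta[i])
            i <- i + 1L
        } else {
            out$dPrime <- 0
        }
        out$mu <- exp(theta[i])
        out$sigma <- exp(theta[i + 1L])
        out
    }

    logPost <- function(theta) {
        nat <- natural(theta)
        if (any(!is.finite(unlist(nat[c("mu", "sigma")])))) {
            return(list(lp = -Inf, p = NULL))
        }
        lp <- 0
        i <- 1L
        if (useTemperature) {
            lp <- lp + sum(stats::dnorm(theta[1:2], 0, priors$betaSd, log = TRUE))
            i <- 3L
        } else {
            ## uniform prior on (a,b) + logit Jacobian
            z <- stats::plogis(theta[1L])
            lp <- lp - log(diff(cb)) + log(diff(cb)) + log(z) + log1p(-z)
            i <- 2L
        }
        if (chemicalTerm) {
            z <- stats::plogis(theta[i])
            lp <- lp - log(diff(db)) + log(diff(db)) + log(z) + log1p(-z)
            i <- i + 1L
        }
        lp <- lp + stats::dgamma(nat$mu, priors$muShape, priors$muRate,
            log = TRUE
        ) + theta[i]
        lp <- lp + stats::dgamma(nat$sigma, priors$sigmaShape, priors$sigmaRate,
            log = TRUE
        ) + theta[i + 1L]
        if (!is.finite(lp)) {
            return(list(lp = -Inf, p = NULL))
        }
        fit <- logLikFun(nat$cPrime, nat$dPrime, nat$mu, nat$sigma)
        list(lp = lp + fit$ll, p = fit$p)
    }

    nRetain <- config$nIter %/% config$thin
    P <- nPoints(design)
    natNames <- c(
        if (useTemperature) c("beta0", "beta1") else "c",
        if (chemicalTerm) "d",
        "mu", "sigma"
    )
    allParams <- matrix(NA_real_, nRetain * config$nChains, length(natNames),
        dimnames = list(NULL, natNames)
    )
    allN <- matrix(NA_real_, nRetain * config$nChains, P)
    chainId <- integer(nRetain * config$nChains)
    accCount <- accTot <- numeric(k)

    set.seed(config$seed)
    nBar <- mean(pmax(pointTotals(data), 1))
    for (chain in seq_len(config$nChains)) {
        ## overdispersed start with finite posterior density
        theta <- NULL
        for (try in 1:100) {
            cand <- numeric(k)
            i <- 1L
            if (useTemperature) {
                cand[1:2] <- stats::rnorm(2, c(-1, 0), c(1, 0.05))
                i <- 3L
            } else {
                cand[1L] <- stats::qlogis(stats::runif(1, 0.1, 0.9))
                i <- 2L
            }
            if (chemicalTerm) {
                cand[i] <- stats::runif(1, -7, -1)
                i <- i + 1L
            }
            cand[i] <- log(nBar) + stats::runif(1, -1, 2)
            cand[i + 1L] <- stats::runif(1, -1, 1.5)
            if (is.finite(logPost(cand)$lp)) {
                theta <- cand
                break
            }
        }
        if (is.null(theta)) {
            stop("could not find a finite-likelihood starting point",
                call. = FALSE
            )
        }
        cur <- logPost(theta)
        scales <- rep(0.3, k)
        batchAcc <- numeric(k)
        batchN <- 0L
        nTotal <- config$nBurnin + config$nIter
        keepAt <- config$nBurnin + seq_len(nRetain) * config$thin
        keepPtr <- 1L
        base <- (chain - 1L) * nRetain
        for (it in seq_len(nTotal)) {
            for (j in seq_len(k)) {
                prop <- theta
                prop[j] <- prop[j] + scales[j] * stats::rnorm(1)
                cand <- logPost(prop)
                if (is.finite(cand$lp) &&
                    log(stats::runif(1)) < cand$lp - cur$lp) {
                    theta <- prop
                    cur <- cand
                    batchAcc[j] <- batchAcc[j] + 1
                    if (it > config$nBurnin) accCount[j] <- accCount[j] + 1
                }
                if (it > config$nBurnin) accTot[j] <- accTot[j] + 1
            }
            batchN <- batchN + 1L
            if (it <= config$nBurnin && batchN == 50L) {
                rate <- batchAcc / batchN
                step <- min(0.25, 2 / sqrt(it))
                scales <- scales * exp(step * (rate - 0.3) / 0.3)
                batchAcc[] <- 0
                batchN <- 0L
            }
            if (keepPtr <= nRetain && it == keepAt[keepPtr]) {
                nat <- natural(theta)
                row <- base + keepPtr
                allParams[row, ] <- unlist(nat[c(
                    if (useTemperature) c("beta0", "beta1") else "cPrime",
                    if (chemicalTerm) "dPrime",
                    "mu", "sigma"
                )], use.names = FALSE)
                allN[row, ] <- sampleLatentN(
                    pointTotals(data), cur$p, nat$mu, nat$sigma
                )
                chainId[row] <- chain
                keepPtr <- keepPtr + 1L
            }
        }
        if (verbose) {
            message(sprintf(
                "chain %d done (acceptance %s)", chain,
                paste(sprintf("%.2f", accCount / pmax(accTot, 1)), collapse = " ")
            ))
        }
    }
    accept <- accCount / pmax(accTot, 1)
    names(accept) <- parNames
    new("PosteriorDraws",
        params = allParams, N = allN, chain = chainId,
        config = c(unclass(config), list(
            chemicalTerm = chemicalTerm,
            useTemperature = useTemperature
        )),
        seed = config$seed, accept = accept
    )
}

## ---- accessors and diagnostics ------------------------------------------

#' @rdname paramDraws
#' @export
setMethod("paramDraws", "PosteriorDraws", function(x) x@params)

#' @rdname abundanceDraws
#' @export
setMethod("abundanceDraws", "PosteriorDraws", function(x) x@N)

#' @rdname chainIndex
#' @export
setMethod("chainIndex", "PosteriorDraws", function(x) x@chain)

setMethod("show", "PosteriorDraws", function(object) {
    cat(sprintf(
        "PosteriorDraws: %d retained draws (%d chains) of {%s} + N over %d points\n",
        nrow(object@params), max(object@chain),
        paste(colnames(object@params), collapse = ", "), ncol(object@N)
    ))
    cat(sprintf(
        "  acceptance rates: %s\n",
        paste(sprintf("%s %.2f", names(object@accept), object@accept),
            collapse = ", "
        )
    ))
})

## classic Gelman-Rubin on a draws-by-chain split of one scalar series
gelmanRubin <- function(values, chain) {
    chains <- split(values, chain)
    m <- length(chains)
    n <- min(lengths(chains))
    chains <- lapply(chains, function(x) x[seq_len(n)])
    means <- vapply(chains, mean, 0)
    vars <- vapply(chains, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W == 0) {
        return(if (B == 0) 1 else Inf)
    }
    sqrt(((n - 1) / n * W + B / n) / W)
}

#' @describeIn rhat per-parameter Gelman-Rubin diagnostic across the fitted
#'   chains; requires at least two chains and ten retained draws per chain.
#' @export
setMethod("rhat", "PosteriorDraws", function(x, ...) {
    nChains <- length(unique(x@chain))
    if (nChains < 2L) {
        stop("R-hat needs at least two chains; re-run the fit with nChains >= 2",
            call. = FALSE
        )
    }
    if (min(table(x@chain)) < 10L) {
        stop("R-hat needs at least 10 retained draws per chain", call. = FALSE)
    }
    apply(x@params, 2L, gelmanRubin, chain = x@chain)
})

#' Restrict posterior draws to a subset of points
#'
#' After a joint multi-site fit (see [poolSites()]), extracts the draws for
#' one site's point columns so the eradication pathway can be run per site.
#' Parameter draws are shared; only the latent abundances are subset.
#'
#' @param draws a [PosteriorDraws-class].
#' @param points integer vector of point columns to keep.
#' @return a [PosteriorDraws-class] over the selected points.
#' @export
subsetPosterior <- function(draws, points) {
    stopifnot(is(draws, "PosteriorDraws"))
    stopifnot(all(points >= 1), all(points <= ncol(draws@N)))
    new("PosteriorDraws",
        params = draws@params,
        N = draws@N[, points, drop = FALSE],
        chain = draws@chain, config = draws@config,
        seed = draws@seed, accept = draws@accept
    )
}

#' Posterior summary table
#'
#' Posterior mean, standard deviation and equal-tailed 95% credible interval
#' for every model parameter, every latent abundance N_i, and the summed
#' initial abundance over all points (`Ntotal`).
#'
#' @param draws a [PosteriorDraws-class].
#' @return a data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper` (2.5% and 97.5% quantiles).
#' @export
summarizePosterior <- function(draws) {
    stopifnot(is(draws, "PosteriorDraws"))
    if (nrow(draws@params) == 0L) stop("no retained draws", call. = FALSE)
    mat <- cbind(
        draws@params,
        structure(draws@N, dimnames = list(
            NULL, paste0("N[", seq_len(ncol(draws@N)), "]")
        )),
        Ntotal = rowSums(draws@N)
    )
    qs <- t(apply(mat, 2L, stats::quantile, probs = c(0.025, 0.975)))
    data.frame(
        parameter = colnames(mat),
        mean = colMeans(mat),
        sd = apply(mat, 2L, stats::sd),
        lower = qs[, 1L],
        upper = qs[, 2L],
        row.names = NULL
    )
}
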