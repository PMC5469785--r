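#' Model parameters of the chemical-eradication removal model
#'
#' Bundles the per-capita detection and death probabilities with the
#' negative-binomial abundance parameters. Detection can either be a constant
#' c' or follow the complementary log-log temperature regression
#' `c'_t = 1 - exp(-exp(beta0 + beta1 * Temperature_t))`; the death
#' probability d' is a constant, and setting `chemicalTerm = FALSE` fixes it
#' at zero, which recovers the original capture-only removal model.
#'
#' @param cConst per-capita detection probability c' in (0,1); ignored when
#'   `useTemperature = TRUE`.
#' @param dConst per-capita death probability d' in (0,1).
#' @param mu mean of the negative-binomial initial abundance N_i.
#' @param sigma negative-binomial size; the variance is `mu + mu^2/sigma`.
#' @param beta0,beta1 cloglog regression coefficients, used when
#'   `useTemperature = TRUE`.
#' @param useTemperature use the temperature covariate for detection?
#' @param chemicalTerm include the pesticide death term? `FALSE` gives the
#'   original model (d' = 0).
#'
#' @return a named list of class `ModelParams`.
#' @examples
#' modelParams(cConst = 0.279, dConst = 0.00539, mu = 110, sigma = 1)
#' @export
modelParams <- function(cConst = 0.5, dConst = 0.01, mu = 10, sigma = 1,
                        beta0 = 0, beta1 = 0,
                        useTemperature = FALSE, chemicalTerm = TRUE) {
    if (!useTemperature) {
        stopifnot(
            is.numeric(cConst), length(cConst) == 1L,
            cConst > 0, cConst < 1
        )
    }
    if (chemicalTerm) {
        stopifnot(
            is.numeric(dConst), length(dConst) == 1L,
            dConst > 0, dConst < 1
        )
    }
    stopifnot(mu > 0, sigma > 0, is.finite(beta0), is.finite(beta1))
    structure(
        list(
            cConst = cConst, dConst = dConst, mu = mu, sigma = sigma,
            beta0 = beta0, beta1 = beta1,
            useTemperature = isTRUE(useTemperature),
            chemicalTerm = isTRUE(chemicalTerm)
        ),
        class = "ModelParams"
    )
}

#' Complementary log-log detection link
#'
#' Detection probability as a function of monthly mean temperature:
#' `1 - exp(-exp(beta0 + beta1 * temperature))`.
#'
#' @param beta0,beta1 regression coefficients.
#' @param temperature covariate value(s), degrees C.
#' @return probability in (0, 1) for finite arguments (vectorized over
#'   `temperature`).
#' @examples
#' detectionLink(0, 0, 15) # 1 - exp(-1)
#' @export
detectionLink <- function(beta0, beta1, temperature) {
    if (any(!is.finite(beta0)) || any(!is.finite(beta1)) ||
        any(!is.finite(temperature))) {
        stop("detectionLink requires finite arguments", call. = FALSE)
    }
    -expm1(-exp(beta0 + beta1 * temperature))
}

#' Effective per-survey detection and death probabilities
#'
#' Applies the two observation-process corrections: detection is zeroed in
#' months a trap was lost (`c_{t,i} = c'_t * hold_{t,i}`), and pesticide death
#' is zeroed in months bait application was discontinued
#' (`d_{t,i} = d' * chem_{t,i}`). A lost trap does not protect an ant from the
#' bait: only detection is corrected.
#'
#' @param params a [modelParams()] list.
#' @param design a [SurveyDesign-class].
#' @return list with matrices `c` and `d` (surveys x points).
#' @export
effectiveProbs <- function(params, design) {
    stopifnot(inherits(params, "ModelParams"), is(design, "SurveyDesign"))
    Tn <- nSurveys(design)
    if (params$useTemperature) {
        temp <- temperature(design)
        if (is.null(temp)) {
            stop("useTemperature = TRUE but the design has no temperature vector",
                call. = FALSE
            )
        }
        cPrime <- detectionLink(params$beta0, params$beta1, temp)
    } else {
        cPrime <- rep(params$cConst, Tn)
    }
    dPrime <- if (params$chemicalTerm) params$dConst else 0
    list(
        c = cPrime * holdMatrix(design),
        d = dPrime * chemMatrix(design)
    )
}

#' Joint removal probabilities
#'
#' Computes, for every survey t and point i, the exhaustive partition of an
#' individual's fate under the monthly death-then-capture removal process:
#' \describe{
#'   \item{delta}{first removal by pesticide death at t:
#'     `phi_{t-1} * d_t`}
#'   \item{piPrime}{first removal by trap capture at t:
#'     `phi_{t-1} * (1 - d_t) * c_t`}
#'   \item{phi}{neither killed nor captured through t:
#'     `prod_{k<=t} (1 - d_k)(1 - c_k)`}
#' }
#' with `phi_0 = 1`. Death is applied before capture within each survey.
#' Products are accumulated in log space to avoid underflow over long
#' monitoring horizons; per point,
#' `sum(piPrime) + sum(delta) + phi_T = 1` to numerical tolerance.
#'
#' @param c surveys x points matrix (or vector for one point) of effective
#'   detection probabilities, entries in `[0, 1]`.
#' @param d matching matrix of effective death probabilities.
#' @return a [RemovalProbabilities-class] object.
#' @examples
#' # pesticide only: joint death probability at the second survey
#' rp <- removalProbabilities(c = c(0, 0), d = c(0.9, 0.9))
#' deathProb(rp)[2, 1] # (1 - 0.9) * 0.9 = 0.09
#' @export
removalProbabilities <- function(c, d) {
    if (!is.matrix(c)) c <- matrix(c, ncol = 1L)
    if (!is.matrix(d)) d <- matrix(d, ncol = 1L)
    if (!all(dim(c) == dim(d))) {
        stop("c and d must have matching dimensions", call. = FALSE)
    }
    if (any(c < 0 | c > 1) || any(d < 0 | d > 1)) {
        stop("all entries of c and d must lie in [0, 1]", call. = FALSE)
    }
    Tn <- nrow(c)
    ## log survival increment per survey; cumulate down columns
    logStep <- log1p(-c) + log1p(-d)
    logPhi <- if (Tn == 1L) logStep else apply(logStep, 2L, cumsum)
    if (!is.matrix(logPhi)) logPhi <- matrix(logPhi, nrow = Tn)
    logPhiPrev <- rbind(0, logPhi[-Tn, , drop = FALSE])
    piPrime <- exp(logPhiPrev + log1p(-d)) * c
    delta <- exp(logPhiPrev) * d
    phi <- exp(logPhi)
    new("RemovalProbabilities",
        c = c, d = d, piPrime = piPrime, delta = delta, phi = phi,
        captureTotal = colSums(piPrime)
    )
}

#' @rdname captureTotal
#' @export
setMethod("captureTotal", "RemovalProbabilities", function(x) x@captureTotal)

#' @rdname piPrime
#' @export
setMethod("piPrime", "RemovalProbabilities", function(x) x@piPrime)

#' @rdname deathProb
#' @export
setMethod("deathProb", "RemovalProbabilities", function(x) x@delta)

#' @rdname phiMatrix
#' @export
setMethod("phiMatrix", "RemovalProbabilities", function(x) x@phi)

setMethod("show", "RemovalProbabilities", function(object) {
    Tn <- nrow(object@piPrime)
    P <- ncol(object@piPrime)
    cat(sprintf("RemovalProbabilities: %d surveys x %d points\n", Tn, P))
    cat(sprintf(
        "  capture total: [%.4f, %.4f]; phi_T: [%.3g, %.3g]\n",
        min(object@captureTotal), max(object@captureTotal),
        min(object@phi[Tn, ]), max(object@phi[Tn, ])
    ))
})

#' Marginal log-likelihood of the removal model
#'
#' Log-likelihood of the observed counts with the latent abundances N_i
#' integrated out. Per point i, the likelihood factorizes as a multinomial
#' over survey cells (conditional on the total n_i) times the marginal of
#' n_i, which by closure of the negative binomial under binomial thinning is
#' `NegBin(size = sigma, mean = p_i * mu)` with `p_i = sum_t piPrime_{t,i}`.
#'
#' A point with `p_i = 0` but `n_i > 0` is impossible under the model and
#' yields `-Inf` (so MCMC proposals there are rejected rather than erroring).
#'
#' @param params a [modelParams()] list.
#' @param design a [SurveyDesign-class].
#' @param data a [CountData-class] compatible with `design`.
#' @param strict check that counts are zero wherever `hold = 0`? (`TRUE`
#'   errors on violation; `FALSE` lets the likelihood go to `-Inf`.)
#' @return a single numeric log-likelihood value.
#' @export
marginalLogLik <- function(params, design, data, strict = TRUE) {
    stopifnot(
        inherits(params, "ModelParams"), is(design, "SurveyDesign"),
        is(data, "CountData")
    )
    y <- countMatrix(data)
    if (!all(dim(y) == dim(holdMatrix(design)))) {
        stop("count and design dimensions differ", call. = FALSE)
    }
    if (strict && any(y > 0 & holdMatrix(design) == 0)) {
        stop("positive count at a lost trap (hold = 0); impossible data",
            call. = FALSE
        )
    }
    eff <- effectiveProbs(params, design)
    rp <- removalProbabilities(eff$c, eff$d)
    logLikFromRemoval(rp, data, params$mu, params$sigma)
}

## Shared kernel: multinomial cell term + thinned-NegBin marginal of n_i.
logLikFromRemoval <- function(rp, data, mu, sigma) {
    y <- countMatrix(data)
    n <- pointTotals(data)
    p <- captureTotal(rp)
    logPi <- log(piPrime(rp))
    pos <- y > 0
    cellTerm <- sum(y[pos] * logPi[pos])
    if (!is.finite(cellTerm)) {
        return(-Inf)
    }
    if (any(p == 0 & n > 0)) {
        return(-Inf)
    }
    ok <- n > 0
    coefTerm <- sum(lgamma(n[ok] + 1)) - sum(lgamma(y[pos] + 1))
    margTerm <- sum(stats::dnbinom(n, size = sigma, mu = p * mu, log = TRUE))
    cellTerm - sum(n[ok] * log(p[ok])) + coefTerm + margTerm
}
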