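#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Survey design for a monitored site
#'
#' Describes the monitoring grid of one site: which traps were in place
#' (`hold`) and whether toxic bait was applied (`chem`) at every survey and
#' point, plus an optional monthly mean temperature covariate for the
#' detection probability.
#'
#' @slot hold binary matrix, surveys x points; 1 = trap retained, 0 = lost.
#' @slot chem binary matrix, surveys x points; 1 = bait applied, 0 = stopped.
#' @slot temperature optional numeric vector of length `nSurveys(x)`
#'   (monthly mean air temperature, degrees Celsius).
#' @slot surveyLabels optional calendar labels, one per survey.
#'
#' @seealso [surveyDesign()] for the user constructor.
#' @exportClass SurveyDesign
setClass("SurveyDesign",
    slots = c(
        hold = "matrix",
        chem = "matrix",
        temperature = "numericOrNULL",
        surveyLabels = "character"
    )
)

setValidity("SurveyDesign", function(object) {
    msgs <- character()
    h <- object@hold
    ch <- object@chem
    if (!is.numeric(h) || !is.numeric(ch)) {
        msgs <- c(msgs, "hold and chem must be numeric matrices")
    } else {
        if (!all(dim(h) == dim(ch))) {
            msgs <- c(msgs, "hold and chem must have identical dimensions")
        }
        if (nrow(h) < 1L || ncol(h) < 1L) {
            msgs <- c(msgs, "design needs at least one survey and one point")
        }
        if (!all(h %in% c(0, 1))) msgs <- c(msgs, "hold must contain only 0/1")
        if (!all(ch %in% c(0, 1))) msgs <- c(msgs, "chem must contain only 0/1")
    }
    if (!is.null(object@temperature)) {
        if (length(object@temperature) != nrow(h)) {
            msgs <- c(msgs, sprintf(
                "temperature must have length %d (one value per survey), not %d",
                nrow(h), length(object@temperature)
            ))
        }
        if (any(!is.finite(object@temperature))) {
            msgs <- c(msgs, "temperature must be finite")
        }
    }
    if (length(object@surveyLabels) > 0L &&
        length(object@surveyLabels) != nrow(h)) {
        msgs <- c(msgs, "surveyLabels must have one entry per survey")
    }
    if (length(msgs)) msgs else TRUE
})

#' Observed removal counts
#'
#' Worker counts removed by trapping, per survey and point, together with the
#' per-point totals n_i (the multinomial sample sizes).
#'
#' @slot y nonnegative integer matrix, surveys x points.
#' @slot n numeric vector of per-point totals; must equal `colSums(y)`.
#'
#' @seealso [countData()]
#' @exportClass CountData
setClass("CountData",
    slots = c(y = "matrix", n = "numeric")
)

setValidity("CountData", function(object) {
    msgs <- character()
    y <- object@y
    if (!is.numeric(y)) {
        msgs <- c(msgs, "y must be a numeric matrix")
    } else {
        if (any(y < 0) || any(y != round(y))) {
            msgs <- c(msgs, "y must contain nonnegative integers")
        }
        if (length(object@n) != ncol(y)) {
            msgs <- c(msgs, "n must have one entry per point")
        } else if (any(object@n != colSums(y))) {
            msgs <- c(msgs, "n must equal the column sums of y")
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Joint removal probabilities of the chemical-eradication model
#'
#' Per-survey, per-point probabilities of an individual's fate under the
#' death-then-capture removal recursion: `piPrime` (first removal by capture
#' at survey t), `delta` (first removal by pesticide death at survey t), and
#' `phi` (neither killed nor captured through survey t). For every point,
#' `colSums(piPrime) + colSums(delta) + phi[T, ] == 1`.
#'
#' @slot c effective detection probabilities (after the trap-loss correction).
#' @slot d effective death probabilities (after the bait-application correction).
#' @slot piPrime joint first-capture probabilities.
#' @slot delta joint first-death probabilities.
#' @slot phi joint survival-and-nondetection probabilities.
#' @slot captureTotal per-point total capture probability, `colSums(piPrime)`;
#'   the binomial success probability linking n_i to the latent N_i.
#'
#' @seealso [removalProbabilities()]
#' @exportClass RemovalProbabilities
setClass("RemovalProbabilities",
    slots = c(
        c = "matrix", d = "matrix",
        piPrime = "matrix", delta = "matrix", phi = "matrix",
        captureTotal = "numeric"
    )
)

setValidity("RemovalProbabilities", function(object) {
    msgs <- character()
    mats <- list(object@c, object@d, object@piPrime, object@delta, object@phi)
    dims <- lapply(mats, dim)
    if (length(unique(dims)) != 1L) {
        msgs <- c(msgs, "all probability matrices must share dimensions")
    }
    for (m in mats) {
        if (any(m < -1e-12 | m > 1 + 1e-12)) {
            msgs <- c(msgs, "probabilities must lie in [0, 1]")
            break
        }
    }
    if (length(object@captureTotal) != ncol(object@piPrime)) {
        msgs <- c(msgs, "captureTotal must have one entry per point")
    }
    if (length(msgs)) msgs else TRUE
})

#' Posterior draws from the eradication-model fit
#'
#' Retained MCMC samples of the model parameters and, for each retained draw,
#' an exact draw of the latent initial abundances N_i from their conditional
#' given the parameters and the observed totals.
#'
#' @slot params numeric matrix, draws x parameters (columns named; natural
#'   scale: probabilities in (0,1), mu and sigma positive).
#' @slot N integer-valued matrix, draws x points, latent initial abundances.
#' @slot chain integer vector mapping each retained draw to its chain.
#' @slot config the MCMC configuration used (list).
#' @slot seed the seed that produced the draws.
#' @slot accept named numeric vector of post-burn-in acceptance rates.
#'
#' @seealso [fitEradication()], [rhat()], [summarizePosterior()]
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
    slots = c(
        params = "matrix",
        N = "matrix",
        chain = "integer",
        config = "list",
        seed = "integer",
        accept = "numeric"
    )
)

setValidity("PosteriorDraws", function(object) {
    msgs <- character()
    if (nrow(object@params) != nrow(object@N)) {
        msgs <- c(msgs, "params and N must have one row per retained draw")
    }
    if (length(object@chain) != nrow(object@params)) {
        msgs <- c(msgs, "chain must map every draw to a chain")
    }
    if (is.null(colnames(object@params))) {
        msgs <- c(msgs, "params columns must be named")
    }
    if (length(msgs)) msgs else TRUE
})

#' Posterior survivor trajectories
#'
#' Binomial draws of the number of survivors s_{t,i} ~ Bin(N_i, phi_{t,i})
#' per retained posterior draw, and the site-level totals S_t.
#'
#' @slot S integer matrix, draws x surveys; total survivors per month.
#' @slot s optional 3-d array draws x surveys x points (kept only when
#'   requested; can be large).
#'
#' @seealso [survivorDraws()], [presenceProbability()]
#' @exportClass SurvivorDraws
setClass("SurvivorDraws",
    slots = c(S = "matrix", s = "ANY")
)

#' Net-expected-cost curve
#'
#' NEC(m) = (m - 1) * Cs + presence(m) * Ce over candidate stopping months m
#' (months since the last sighting), with its minimizer.
#'
#' @slot m candidate stopping months (1-based; m = 1 is the first monitoring
#'   month after the last sighting).
#' @slot presence probability ants persist after m detection-free months.
#' @slot nec net expected cost at each m.
#' @slot mOpt the optimal (cost-minimizing) month; ties go to the smaller m.
#' @slot necMin the minimum of the curve.
#' @slot Cs,Ce the cost inputs.
#'
#' @seealso [necCurve()], [costSensitivity()]
#' @exportClass NECCurve
setClass("NECCurve",
    slots = c(
        m = "integer", presence = "numeric", nec = "numeric",
        mOpt = "integer", necMin = "numeric",
        Cs = "numeric", Ce = "numeric"
    )
)

setValidity("NECCurve", function(object) {
    msgs <- character()
    k <- length(object@m)
    if (length(object@presence) != k || length(object@nec) != k) {
        msgs <- c(msgs, "m, presence and nec must have equal length")
    }
    if (k > 0L) {
        if (abs(object@necMin - min(object@nec)) > 1e-9) {
            msgs <- c(msgs, "necMin must be the minimum of nec")
        }
        if (!object@mOpt %in% object@m) {
            msgs <- c(msgs, "mOpt must be one of the candidate months")
        }
    }
    if (length(msgs)) msgs else TRUE
})
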