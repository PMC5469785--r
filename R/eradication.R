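#' Posterior survivor trajectories
#'
#' For every retained posterior draw, recomputes the joint
#' survival-and-nondetection probabilities phi_{t,i} from that draw's
#' parameters (with the design's trap-loss and bait-application corrections)
#' and draws the survivor counts `s_{t,i} ~ Binomial(N_i, phi_{t,i})`. Each
#' month is an independent marginal binomial draw, mirroring the survivor
#' posterior construction of the model; site totals `S_t = sum_i s_{t,i}`
#' are accumulated.
#'
#' @param posterior a [PosteriorDraws-class].
#' @param design the [SurveyDesign-class] the model was fitted to.
#' @param seed integer seed for the binomial draws.
#' @param keepPoints retain the full draws x surveys x points array of
#'   per-point survivors? (memory-heavy; site totals are always kept).
#' @return a [SurvivorDraws-class].
#' @export
survivorDraws <- function(posterior, design, seed = 1, keepPoints = FALSE) {
    stopifnot(is(posterior, "PosteriorDraws"), is(design, "SurveyDesign"))
    params <- paramDraws(posterior)
    Nmat <- abundanceDraws(posterior)
    if (ncol(Nmat) != nPoints(design)) {
        stop("posterior and design disagree on the number of points",
            call. = FALSE
        )
    }
    nDraws <- nrow(params)
    Tn <- nSurveys(design)
    P <- nPoints(design)
    useTemp <- isTRUE(posterior@config$useTemperature)
    chemTerm <- isTRUE(posterior@config$chemicalTerm)
    S <- matrix(0L, nDraws, Tn)
    sArr <- if (keepPoints) array(0L, c(nDraws, Tn, P)) else NULL
    set.seed(seed)
    for (g in seq_len(nDraws)) {
        pars <- params[g, ]
        mp <- if (useTemp) {
            modelParams(
                beta0 = pars[["beta0"]], beta1 = pars[["beta1"]],
                dConst = if (chemTerm) pars[["d"]] else 0.5,
                mu = pars[["mu"]], sigma = pars[["sigma"]],
                useTemperature = TRUE, chemicalTerm = chemTerm
            )
        } else {
            modelParams(
                cConst = pars[["c"]],
                dConst = if (chemTerm) pars[["d"]] else 0.5,
                mu = pars[["mu"]], sigma = pars[["sigma"]],
                chemicalTerm = chemTerm
            )
        }
        eff <- effectiveProbs(mp, design)
        logPhi <- apply(log1p(-eff$c) + log1p(-eff$d), 2L, cumsum)
        if (!is.matrix(logPhi)) logPhi <- matrix(logPhi, nrow = Tn)
        phi <- exp(logPhi)
        Ng <- rep(Nmat[g, ], each = Tn)
        s <- matrix(stats::rbinom(Tn * P, size = Ng, prob = as.vector(phi)),
            nrow = Tn
        )
        S[g, ] <- rowSums(s)
        if (keepPoints) sArr[g, , ] <- s
    }
    new("SurvivorDraws", S = S, s = sArr)
}

#' @rdname totalSurvivors
#' @export
setMethod("totalSurvivors", "SurvivorDraws", function(x) x@S)

setMethod("show", "SurvivorDraws", function(object) {
    cat(sprintf(
        "SurvivorDraws: %d draws x %d surveys%s\n",
        nrow(object@S), ncol(object@S),
        if (is.null(object@s)) "" else " (per-point draws kept)"
    ))
})

#' Posterior presence probability over time
#'
#' `Ps_t`, the posterior probability that at least one ant is still alive at
#' month t at the site: the fraction of survivor draws with `S_t >= 1`.
#' (The model description writes this threshold as `Pr(S_t < 1)`, but reads
#' and uses it as the probability of continued presence — eradication is
#' declared when it drops below 0.05 / 0.01 — so presence is what is
#' computed here.)
#'
#' @param survivors a [SurvivorDraws-class].
#' @return numeric vector of length `nSurveys`, values in `[0, 1]`.
#' @export
presenceProbability <- function(survivors) {
    stopifnot(is(survivors, "SurvivorDraws"))
    S <- totalSurvivors(survivors)
    if (nrow(S) == 0L) stop("no survivor draws", call. = FALSE)
    colMeans(S >= 1)
}

#' Eradication declaration times
#'
#' For each threshold, the first month t such that `Ps_k < threshold` for all
#' `k >= t` — a sustained crossing, so isolated Monte-Carlo blips below a
#' threshold do not trigger a premature declaration. A threshold never
#' sustainedly crossed yields `NA` with `reached = FALSE` rather than an
#' error ("not yet eradicated").
#'
#' @param Ps presence-probability vector from [presenceProbability()].
#' @param thresholds declaration thresholds; the defaults are the 95% and 99%
#'   eradication criteria.
#' @return data.frame with columns `threshold`, `month` (NA when not
#'   reached), `reached`.
#' @examples
#' declarationTimes(c(0.5, 0.2, 0.04, 0.008, 0.003))
#' @export
declarationTimes <- function(Ps, thresholds = c(0.05, 0.01)) {
    stopifnot(all(Ps >= 0 & Ps <= 1))
    month <- vapply(thresholds, function(th) {
        below <- Ps < th
        ## last month NOT below, +1; sustained means all later months below
        if (!below[length(below)]) {
            return(NA_integer_)
        }
        notBelow <- which(!below)
        if (length(notBelow) == 0L) 1L else max(notBelow) + 1L
    }, integer(1))
    data.frame(
        threshold = thresholds,
        month = month,
        reached = !is.na(month)
    )
}

#' Eradication summary of a fitted program
#'
#' Convenience wrapper: survivor draws, presence probabilities, declaration
#' months at the 95%/99% thresholds, and months elapsed since the last
#' detection.
#'
#' @param posterior a [PosteriorDraws-class].
#' @param design the matching [SurveyDesign-class].
#' @param counts the [CountData-class] used for the fit (for the last
#'   detection month).
#' @param seed seed for the survivor draws.
#' @return list with elements `Ps`, `declarations` (data.frame with an extra
#'   `monthsSinceLastDetection` column), `lastDetection`.
#' @export
eradicationSummary <- function(posterior, design, counts, seed = 1) {
    surv <- survivorDraws(posterior, design, seed = seed)
    Ps <- presenceProbability(surv)
    decl <- declarationTimes(Ps)
    ld <- lastDetection(counts)
    decl$monthsSinceLastDetection <- decl$month - ld
    list(Ps = Ps, declarations = decl, lastDetection = ld)
}
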