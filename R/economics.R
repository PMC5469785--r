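#' Net expected cost of declaring eradication
#'
#' `NEC(m) = (m - 1) * Cs + presence * Ce`: the accumulated monitoring cost
#' of waiting m detection-free months plus the expected escape cost if
#' eradication is declared while ants in fact persist.
#'
#' @param m months since the last sighting (m >= 1; vectorized).
#' @param Cs monthly cost of management.
#' @param Ce cost of declaring eradication while the ants are still present.
#' @param presence probability the ants persist after m detection-free
#'   months (vectorized with m).
#' @return the net expected cost.
#' @examples
#' nec(1, Cs = 40000, Ce = 59.8 * 40000, presence = 0)
#' @export
nec <- function(m, Cs, Ce, presence) {
    if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
    stopifnot(Cs > 0, Ce >= 0, all(presence >= 0 & presence <= 1))
    (m - 1) * Cs + presence * Ce
}

#' NEC curve and optimal stopping month
#'
#' Evaluates the net expected cost over all candidate stopping months and
#' returns the curve together with its minimizer. Ties are broken toward the
#' smaller month (stop earlier when indifferent). An optional per-month
#' surcharge vector (e.g. the extra pesticide applications in the first six
#' months after a sighting) is added cumulatively to the monitoring cost.
#'
#' @param presence vector of persistence probabilities, element m giving the
#'   probability ants are still present after m detection-free months.
#' @param Cs monthly monitoring cost.
#' @param Ce escape cost (alternatively give `ceRatio`).
#' @param ceRatio Ce as a multiple of Cs; used when `Ce` is missing.
#' @param surcharge optional vector of extra monthly costs; element k is
#'   added for every month k actually monitored (recycled/padded with 0).
#' @return an [NECCurve-class].
#' @examples
#' necCurve(c(0.5, 0.2, 0.05, 0.01, 0.005), Cs = 1, Ce = 100)
#' @export
necCurve <- function(presence, Cs, Ce = NULL, ceRatio = NULL,
                     surcharge = NULL) {
    stopifnot(length(presence) >= 1, all(presence >= 0 & presence <= 1))
    if (is.null(Ce)) {
        if (is.null(ceRatio)) stop("give Ce or ceRatio", call. = FALSE)
        Ce <- ceRatio * Cs
    }
    m <- seq_along(presence)
    cost <- nec(m, Cs, Ce, presence)
    if (!is.null(surcharge)) {
        extra <- rep_len(c(surcharge, rep(0, length(m))), length(m))
        ## surcharge for month k is paid when monitoring covers month k,
        ## i.e. for all stopping months m >= k (m - 1 months monitored)
        cost <- cost + c(0, cumsum(extra))[m]
    }
    mOpt <- m[which.min(cost)] # which.min takes the first minimum: earlier m
    new("NECCurve",
        m = as.integer(m), presence = as.numeric(presence),
        nec = cost, mOpt = as.integer(mOpt), necMin = min(cost),
        Cs = Cs, Ce = Ce
    )
}

#' @rdname optimalMonth
#' @export
setMethod("optimalMonth", "NECCurve", function(x) x@mOpt)

setMethod("show", "NECCurve", function(object) {
    cat(sprintf(
        "NECCurve over m = 1..%d (Cs = %g, Ce = %g)\n",
        length(object@m), object@Cs, object@Ce
    ))
    cat(sprintf(
        "  optimal stopping month: %d (NEC = %g)\n",
        object@mOpt, object@necMin
    ))
})

#' Convert an NEC curve to a data.frame
#'
#' @param x an [NECCurve-class].
#' @param row.names,optional,... passed through (unused).
#' @return data.frame with columns `m`, `presence`, `nec`.
#' @export
as.data.frame.NECCurve <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(m = x@m, presence = x@presence, nec = x@nec)
}

#' Cost-ratio sensitivity of the optimal stopping month
#'
#' Recomputes the optimal month over a grid of escape-to-monitoring cost
#' ratios Ce/Cs (the original analysis explored 1:25 to 1:200). For a fixed
#' non-increasing presence series the optimal month is non-decreasing in the
#' ratio.
#'
#' @param presence persistence-probability series (as in [necCurve()]).
#' @param Cs monthly monitoring cost.
#' @param ratios vector of Ce/Cs ratios.
#' @param surcharge optional surcharge vector, see [necCurve()].
#' @return data.frame with columns `ratio`, `mOpt`, `necMin`.
#' @export
costSensitivity <- function(presence, Cs = 40000,
                            ratios = c(25, 50, 100, 150, 200),
                            surcharge = NULL) {
    stopifnot(all(ratios > 0))
    res <- lapply(ratios, function(r) {
        cv <- necCurve(presence, Cs, ceRatio = r, surcharge = surcharge)
        data.frame(ratio = r, mOpt = cv@mOpt, necMin = cv@necMin)
    })
    do.call(rbind, res)
}

#' Escape cost as a multiple of the monthly monitoring cost
#'
#' The baseline escape cost Ce is set from the total program expenditure up
#' to the 99% eradication month, expressed as a multiple of the monthly
#' monitoring cost Cs.
#'
#' @param totalCost total program cost.
#' @param Cs monthly monitoring cost.
#' @return the ratio Ce / Cs.
#' @examples
#' costRatio(2393969, 40000) # 59.8 to one decimal
#' @export
costRatio <- function(totalCost, Cs) {
    stopifnot(Cs > 0, totalCost >= 0)
    totalCost / Cs
}

#' Align a presence series to months since last detection
#'
#' Maps the calendar presence series `Ps_t` to the stopping-rule time axis:
#' m = 1 is the first monitoring month after the last sighting, so
#' `presence[m] = Ps[lastDetection + m]`.
#'
#' @param Ps calendar presence probabilities from [presenceProbability()].
#' @param lastDetectionMonth 1-based calendar month of the last sighting.
#' @return the persistence series indexed by detection-free months m.
#' @export
presenceAfterLastDetection <- function(Ps, lastDetectionMonth) {
    stopifnot(
        lastDetectionMonth >= 0,
        lastDetectionMonth < length(Ps)
    )
    Ps[(lastDetectionMonth + 1):length(Ps)]
}
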