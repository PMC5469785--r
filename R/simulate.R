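#' Simulation specification
#'
#' The stated world of the simulator mirrors the monitoring program: latent
#' per-point initial abundances `N_i ~ NegBin(mu, sigma)`; each month every
#' living individual first dies from the bait with probability
#' `d * chem_{t,i}` and, if it survives and the trap is in place, is captured
#' with probability `c`; traps are lost independently with probability
#' `trapLossRate` per trap-month; bait application follows either a fixed
#' policy or the program's six-month rule (apply while there was a detection
#' in the plot within the previous six months, stop after six consecutive
#' detection-free months).
#'
#' @param nPoints,nSurveys design dimensions.
#' @param trueC per-capita detection probability (constant c'), or use
#'   `beta0`/`beta1` with a `temperature` series.
#' @param trueD per-capita monthly death probability under bait application.
#' @param mu,sigma negative-binomial initial-abundance parameters
#'   (variance `mu + mu^2/sigma`).
#' @param trapLossRate probability a trap is lost in a given month.
#' @param chemPolicy `"always_on"`, `"six_month_rule"`, or an explicit
#'   surveys x points 0/1 matrix.
#' @param plotOf integer vector mapping each point to a plot (the six-month
#'   rule operates at plot level). Default: plots of three consecutive
#'   points, emulating the program's ~1-ha plots of a few traps each.
#' @param delayMonths integer vector (length `nPoints` or 1): bait
#'   application at a point starts only after this many months (the program
#'   had one plot whose applications started 11 months late). Combined with
#'   whatever `chemPolicy` says.
#' @param beta0,beta1,temperature optional cloglog detection regression.
#' @return a named list of class `SimulationSpec`.
#' @export
simulationSpec <- function(nPoints, nSurveys, trueC = 0.279, trueD = 0.00539,
                           mu = 60, sigma = 1, trapLossRate = 0.02,
                           chemPolicy = "six_month_rule",
                           plotOf = ((seq_len(nPoints) - 1L) %/% 3L) + 1L,
                           delayMonths = 0L,
                           beta0 = NULL, beta1 = NULL, temperature = NULL) {
    stopifnot(
        nPoints >= 1, nSurveys >= 1,
        trueD >= 0, trueD <= 1, mu > 0, sigma > 0,
        trapLossRate >= 0, trapLossRate <= 1,
        length(plotOf) == nPoints,
        all(delayMonths >= 0),
        length(delayMonths) %in% c(1L, nPoints)
    )
    if (is.null(beta0)) stopifnot(trueC >= 0, trueC <= 1)
    if (is.matrix(chemPolicy)) {
        stopifnot(
            all(dim(chemPolicy) == c(nSurveys, nPoints)),
            all(chemPolicy %in% c(0, 1))
        )
    } else {
        chemPolicy <- match.arg(chemPolicy, c("six_month_rule", "always_on"))
    }
    structure(
        list(
            nPoints = as.integer(nPoints), nSurveys = as.integer(nSurveys),
            trueC = trueC, trueD = trueD, mu = mu, sigma = sigma,
            trapLossRate = trapLossRate, chemPolicy = chemPolicy,
            plotOf = as.integer(plotOf),
            delayMonths = rep_len(as.integer(delayMonths), nPoints),
            beta0 = beta0, beta1 = beta1, temperature = temperature
        ),
        class = "SimulationSpec"
    )
}

#' Simulate one monitored site
#'
#' Individual-based forward simulation of the eradication program under a
#' [simulationSpec()]. Death is applied before capture within each month.
#' The returned truth record keeps, per point and month, the number of
#' pesticide deaths, captures, and true survivors, so per point
#' `captures + deaths + survivors == N_i` at every month.
#'
#' @param spec a [simulationSpec()].
#' @param seed integer seed.
#' @return list with elements `design` ([SurveyDesign-class]), `counts`
#'   ([CountData-class]) and `truth` (list with `N`, `deaths`, `captures`,
#'   `survivors` matrices and the month of true extinction per point).
#' @examples
#' sim <- simulateSite(simulationSpec(nPoints = 3, nSurveys = 12, mu = 20),
#'     seed = 1
#' )
#' colSums(countMatrix(sim$counts))
#' @export
simulateSite <- function(spec, seed = 1) {
    stopifnot(inherits(spec, "SimulationSpec"))
    set.seed(seed)
    P <- spec$nPoints
    Tn <- spec$nSurveys
    N <- stats::rnbinom(P, size = spec$sigma, mu = spec$mu)
    if (!is.null(spec$beta0)) {
        stopifnot(length(spec$temperature) == Tn)
        cSeries <- detectionLink(spec$beta0, spec$beta1, spec$temperature)
    } else {
        cSeries <- rep(spec$trueC, Tn)
    }
    hold <- matrix(
        stats::rbinom(Tn * P, 1L, 1 - spec$trapLossRate),
        Tn, P
    )
    explicitChem <- is.matrix(spec$chemPolicy)
    sixMonth <- identical(spec$chemPolicy, "six_month_rule")
    chem <- if (explicitChem) spec$chemPolicy else matrix(1L, Tn, P)
    plots <- spec$plotOf
    ## detection history per plot; the program starts because ants were
    ## found, so month 0 counts as a detection for the six-month rule
    lastDetPlot <- rep(0L, max(plots))

    alive <- rep(seq_len(P), N) # point id of each living individual
    y <- deaths <- survivors <- matrix(0L, Tn, P)
    tab <- function(ids) tabulate(ids, nbins = P)
    for (t in seq_len(Tn)) {
        if (sixMonth) {
            chem[t, ] <- as.integer((t - lastDetPlot[plots]) <= 6L)
        }
        chem[t, t <= spec$delayMonths] <- 0L
        nAlive <- length(alive)
        if (nAlive) {
            dieP <- spec$trueD * chem[t, alive]
            died <- stats::runif(nAlive) < dieP
            deaths[t, ] <- tab(alive[died])
            alive <- alive[!died]
            nAlive <- length(alive)
        }
        if (nAlive) {
            capP <- cSeries[t] * hold[t, alive]
            caught <- stats::runif(nAlive) < capP
            y[t, ] <- tab(alive[caught])
            alive <- alive[!caught]
        }
        survivors[t, ] <- tab(alive)
        detected <- unique(plots[which(y[t, ] > 0)])
        lastDetPlot[detected] <- t
    }
    extinctMonth <- apply(survivors, 2L, function(s) {
        z <- which(s == 0)
        if (length(z) && all(s[min(z):Tn] == 0)) min(z) else NA_integer_
    })
    design <- surveyDesign(
        hold = hold, chem = chem,
        temperature = spec$temperature
    )
    list(
        design = design,
        counts = countData(y, design),
        truth = list(
            N = N, deaths = deaths, captures = y, survivors = survivors,
            extinctMonth = extinctMonth, spec = spec, seed = seed
        )
    )
}

#' Site presets modelled on the two Tokyo program sites
#'
#' Convenience scenarios at the scale of the two monitored sites: 59 monthly
#' surveys; 23 points with expected total initial abundance ~1400
#' (`tokaiLike`) or 28 points with ~4200 (`jonanLike`); detection and death
#' probabilities default to the program's point estimates (0.279 and
#' 0.00539). Points are grouped into ~1-ha plots as in the program (plots of
#' three points at the smaller site, two at the larger); `jonanLike` starts
#' bait application 11 months late in its first plot, mirroring the plot
#' whose treatment began in the program's second year. That staggered
#' exposure is what makes the death probability identifiable separately from
#' detection (see the package vignette).
#'
#' @param seed integer seed.
#' @param dropFirst drop the first survey (mimicking the lost first-month
#'   trap data)? The returned design then has 58 surveys.
#' @param ... overrides passed to [simulationSpec()].
#' @return as [simulateSite()].
#' @export
tokaiLike <- function(seed = 1, dropFirst = FALSE, ...) {
    sitePreset(
        nPoints = 23L, totalAbundance = 1400, seed = seed,
        dropFirst = dropFirst,
        plotOf = ((seq_len(23L) - 1L) %/% 3L) + 1L, ...
    )
}

#' @rdname tokaiLike
#' @export
jonanLike <- function(seed = 1, dropFirst = FALSE, ...) {
    sitePreset(
        nPoints = 28L, totalAbundance = 4200, seed = seed,
        dropFirst = dropFirst,
        plotOf = ((seq_len(28L) - 1L) %/% 2L) + 1L,
        delayMonths = rep(c(11L, 0L), c(2L, 26L)), ...
    )
}

#' @describeIn tokaiLike the pooled 51-point program (both sites fitted as
#'   one model, as in the published analysis): mean initial abundance 110 per
#'   point, the smaller site's plots of three followed by the larger site's
#'   plots of two, with the delayed-start plot included.
#' @export
programLike <- function(seed = 1, dropFirst = FALSE, ...) {
    plots <- c(
        ((seq_len(23L) - 1L) %/% 3L) + 1L,
        ((seq_len(28L) - 1L) %/% 2L) + 9L
    )
    sitePreset(
        nPoints = 51L, totalAbundance = 110 * 51, seed = seed,
        dropFirst = dropFirst,
        plotOf = plots,
        delayMonths = rep(c(0L, 11L, 0L), c(23L, 2L, 26L)), ...
    )
}

sitePreset <- function(nPoints, totalAbundance, seed, dropFirst, ...) {
    args <- list(
        nPoints = nPoints, nSurveys = 59L,
        mu = totalAbundance / nPoints, sigma = 1,
        trueC = 0.279, trueD = 0.00539
    )
    override <- list(...)
    args[names(override)] <- override
    sim <- simulateSite(do.call(simulationSpec, args), seed = seed)
    if (dropFirst) {
        keep <- -1L
        d <- sim$design
        sim$design <- surveyDesign(
            hold = holdMatrix(d)[keep, , drop = FALSE],
            chem = chemMatrix(d)[keep, , drop = FALSE],
            temperature = temperature(d)[keep]
        )
        sim$counts <- countData(
            countMatrix(sim$counts)[keep, , drop = FALSE], sim$design
        )
    }
    sim
}
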