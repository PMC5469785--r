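#' Number of monitoring points
#' @param x a [SurveyDesign-class], [CountData-class] or related object.
#' @return integer.
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Number of monthly surveys
#' @param x a [SurveyDesign-class], [CountData-class] or related object.
#' @return integer.
#' @export
setGeneric("nSurveys", function(x) standardGeneric("nSurveys"))

#' Trap-retention indicator matrix
#' @param x a [SurveyDesign-class].
#' @return surveys x points binary matrix.
#' @export
setGeneric("holdMatrix", function(x) standardGeneric("holdMatrix"))

#' Bait-application indicator matrix
#' @param x a [SurveyDesign-class].
#' @return surveys x points binary matrix.
#' @export
setGeneric("chemMatrix", function(x) standardGeneric("chemMatrix"))

#' Temperature covariate
#' @param x a [SurveyDesign-class].
#' @return numeric vector of monthly mean temperatures, or `NULL`.
#' @export
setGeneric("temperature", function(x) standardGeneric("temperature"))

#' Removal count matrix
#' @param x a [CountData-class].
#' @return surveys x points matrix of removal counts.
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' Per-point removal totals
#' @param x a [CountData-class].
#' @return numeric vector n with n[i] the total workers removed at point i.
#' @export
setGeneric("pointTotals", function(x) standardGeneric("pointTotals"))

#' Total capture probability per point
#' @param x a [RemovalProbabilities-class].
#' @return numeric vector, `colSums(piPrime)`.
#' @export
setGeneric("captureTotal", function(x) standardGeneric("captureTotal"))

#' Joint first-capture probabilities
#' @param x a [RemovalProbabilities-class].
#' @return surveys x points matrix of pi' values.
#' @export
setGeneric("piPrime", function(x) standardGeneric("piPrime"))

#' Joint first-death probabilities
#' @param x a [RemovalProbabilities-class].
#' @return surveys x points matrix.
#' @export
setGeneric("deathProb", function(x) standardGeneric("deathProb"))

#' Joint survival-and-nondetection probabilities
#' @param x a [RemovalProbabilities-class].
#' @return surveys x points matrix of phi values.
#' @export
setGeneric("phiMatrix", function(x) standardGeneric("phiMatrix"))

#' Retained posterior parameter draws
#' @param x a [PosteriorDraws-class].
#' @return draws x parameters matrix on the natural scale.
#' @export
setGeneric("paramDraws", function(x) standardGeneric("paramDraws"))

#' Latent initial-abundance draws
#' @param x a [PosteriorDraws-class].
#' @return draws x points matrix of N_i samples.
#' @export
setGeneric("abundanceDraws", function(x) standardGeneric("abundanceDraws"))

#' Chain index of each retained draw
#' @param x a [PosteriorDraws-class].
#' @return integer vector.
#' @export
setGeneric("chainIndex", function(x) standardGeneric("chainIndex"))

#' Gelman-Rubin potential scale reduction factor
#'
#' @param x a [PosteriorDraws-class] (or a draws x chains numeric matrix via
#'   the internal workhorse).
#' @param ... unused.
#' @return named numeric vector of R-hat values, one per parameter.
#' @export
setGeneric("rhat", function(x, ...) standardGeneric("rhat"))

#' Total-survivor draws
#' @param x a [SurvivorDraws-class].
#' @return draws x surveys integer matrix of S_t.
#' @export
setGeneric("totalSurvivors", function(x) standardGeneric("totalSurvivors"))

#' Optimal stopping month of an NEC curve
#' @param x an [NECCurve-class].
#' @return integer month (ties broken toward the smaller month).
#' @export
setGeneric("optimalMonth", function(x) standardGeneric("optimalMonth"))
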