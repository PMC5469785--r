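#' Construct a survey design
#'
#' @param hold surveys x points binary matrix (1 = trap retained that month,
#'   0 = trap lost). A single value is recycled.
#' @param chem surveys x points binary matrix (1 = toxic bait applied,
#'   0 = application discontinued). A single value is recycled.
#' @param nSurveys,nPoints dimensions, required when `hold`/`chem` are scalars.
#' @param temperature optional numeric vector of monthly mean air
#'   temperatures (degrees C), one per survey; covariate for the detection
#'   probability via the complementary log-log link.
#' @param surveyLabels optional character vector of calendar labels.
#'
#' @return a [SurveyDesign-class] object.
#' @examples
#' d <- surveyDesign(hold = 1, chem = 1, nSurveys = 12, nPoints = 4)
#' nSurveys(d)
#' @export
surveyDesign <- function(hold = 1, chem = 1, nSurveys = NULL, nPoints = NULL,
                         temperature = NULL, surveyLabels = character()) {
    expand <- function(x, what) {
        if (is.matrix(x)) {
            return(x)
        }
        if (length(x) != 1L) {
            stop(what, " must be a matrix or a single value", call. = FALSE)
        }
        if (is.null(nSurveys) || is.null(nPoints)) {
            stop("nSurveys and nPoints are required when ", what,
                " is scalar",
                call. = FALSE
            )
        }
        matrix(x, nrow = nSurveys, ncol = nPoints)
    }
    hold <- expand(hold, "hold")
    chem <- expand(chem, "chem")
    new("SurveyDesign",
        hold = hold, chem = chem,
        temperature = if (is.null(temperature)) NULL else as.numeric(temperature),
        surveyLabels = as.character(surveyLabels)
    )
}

#' Construct observed count data
#'
#' @param y surveys x points matrix of nonnegative integer removal counts.
#' @param design optional [SurveyDesign-class]; when supplied, counts at
#'   surveys where the trap was lost (`hold == 0`) must be zero.
#' @return a [CountData-class] object; per-point totals are computed.
#' @examples
#' cd <- countData(matrix(c(3L, 1L, 0L, 2L), nrow = 2))
#' pointTotals(cd)
#' @export
countData <- function(y, design = NULL) {
    y <- as.matrix(y)
    storage.mode(y) <- "double"
    obj <- new("CountData", y = y, n = colSums(y))
    if (!is.null(design)) {
        if (!all(dim(y) == dim(holdMatrix(design)))) {
            stop("count matrix dimensions do not match the design",
                call. = FALSE
            )
        }
        bad <- which(y > 0 & holdMatrix(design) == 0, arr.ind = TRUE)
        if (nrow(bad)) {
            stop(sprintf(
                "positive count where the trap was lost (hold = 0): survey %d, point %d",
                bad[1, 1], bad[1, 2]
            ), call. = FALSE)
        }
    }
    obj
}

## ---- accessors -----------------------------------------------------------

#' @describeIn nPoints points in a design
#' @export
setMethod("nPoints", "SurveyDesign", function(x) ncol(x@hold))

#' @describeIn nSurveys surveys in a design
#' @export
setMethod("nSurveys", "SurveyDesign", function(x) nrow(x@hold))

#' @describeIn nPoints points in a count table
#' @export
setMethod("nPoints", "CountData", function(x) ncol(x@y))

#' @describeIn nSurveys surveys in a count table
#' @export
setMethod("nSurveys", "CountData", function(x) nrow(x@y))

#' @rdname holdMatrix
#' @export
setMethod("holdMatrix", "SurveyDesign", function(x) x@hold)

#' @rdname chemMatrix
#' @export
setMethod("chemMatrix", "SurveyDesign", function(x) x@chem)

#' @rdname temperature
#' @export
setMethod("temperature", "SurveyDesign", function(x) x@temperature)

#' @rdname countMatrix
#' @export
setMethod("countMatrix", "CountData", function(x) x@y)

#' @rdname pointTotals
#' @export
setMethod("pointTotals", "CountData", function(x) x@n)

setMethod("show", "SurveyDesign", function(object) {
    cat(sprintf(
        "SurveyDesign: %d surveys x %d points\n",
        nSurveys(object), nPoints(object)
    ))
    cat(sprintf(
        "  traps lost: %d cell(s); bait off: %d cell(s)\n",
        sum(object@hold == 0), sum(object@chem == 0)
    ))
    cat(sprintf(
        "  temperature covariate: %s\n",
        if (is.null(object@temperature)) "absent" else "present"
    ))
})

setMethod("show", "CountData", function(object) {
    cat(sprintf(
        "CountData: %d surveys x %d points, %d workers removed in total\n",
        nSurveys(object), nPoints(object), sum(object@n)
    ))
    det <- which(rowSums(object@y) > 0)
    if (length(det)) {
        cat(sprintf("  last detection: survey %d\n", max(det)))
    } else {
        cat("  no detections\n")
    }
})

#' Pool several sites into one model dataset
#'
#' Column-binds the designs and counts of multiple sites surveyed over the
#' same months so they can be fitted jointly with shared detection and death
#' probabilities (the published analysis reports a single c', d' pair for
#' both program sites). The returned `siteCols` maps each site to its point
#' columns in the pooled matrices.
#'
#' @param ... two or more `list(design =, counts =)` pairs (as returned by
#'   [simulateSite()] or [readSurvey()]).
#' @return list with `design`, `counts`, `siteCols`.
#' @export
poolSites <- function(...) {
    sites <- list(...)
    stopifnot(length(sites) >= 2L)
    Tn <- vapply(sites, function(s) nSurveys(s$design), integer(1))
    if (length(unique(Tn)) != 1L) {
        stop("all sites must cover the same survey months", call. = FALSE)
    }
    design <- surveyDesign(
        hold = do.call(cbind, lapply(sites, function(s) holdMatrix(s$design))),
        chem = do.call(cbind, lapply(sites, function(s) chemMatrix(s$design)))
    )
    counts <- countData(
        do.call(cbind, lapply(sites, function(s) countMatrix(s$counts))),
        design
    )
    P <- vapply(sites, function(s) nPoints(s$design), integer(1))
    ends <- cumsum(P)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    list(
        design = design, counts = counts,
        siteCols = Map(seq, starts, ends)
    )
}

#' Last month with a detection
#'
#' @param counts a [CountData-class].
#' @return the 1-based index of the last survey with a positive count, or
#'   `NA_integer_` if nothing was ever caught.
#' @export
lastDetection <- function(counts) {
    stopifnot(is(counts, "CountData"))
    det <- which(rowSums(countMatrix(counts)) > 0)
    if (length(det)) max(det) else NA_integer_
}
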