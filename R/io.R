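#' Read a long-format survey table
#'
#' Reads the monitoring CSV (columns `site`, `point_id`, `month_index`,
#' `count`, `hold`, `chem`, optional `calendar_label` and `temperature`) into
#' per-site [SurveyDesign-class] / [CountData-class] pairs. Month indices
#' must be 1-based and gapless per site after dropping any excluded months;
#' excluded months (e.g. a first survey whose traps were lost) are removed
#' and the remaining months re-based to 1..T.
#'
#' @param path CSV file path.
#' @param exclusions integer vector of month indices to drop.
#' @param quiet suppress the per-site validation summary message?
#' @return named list (one element per site) of lists with `design`,
#'   `counts`.
#' @export
readSurvey <- function(path, exclusions = integer(), quiet = TRUE) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("site", "point_id", "month_index", "count", "hold", "chem")
    missing <- setdiff(required, names(df))
    if (length(missing)) {
        stop("missing required column(s): ", paste(missing, collapse = ", "),
            call. = FALSE
        )
    }
    rowId <- seq_len(nrow(df)) + 1L # +1: header line, for error messages
    checkBinary <- function(col) {
        bad <- which(!df[[col]] %in% c(0, 1))
        if (length(bad)) {
            stop(sprintf(
                "non-binary %s at line %d (value %s)",
                col, rowId[bad[1]], df[[col]][bad[1]]
            ), call. = FALSE)
        }
    }
    checkBinary("hold")
    checkBinary("chem")
    bad <- which(df$count < 0 | df$count != round(df$count))
    if (length(bad)) {
        stop(sprintf("count must be a nonnegative integer (line %d)",
            rowId[bad[1]]), call. = FALSE)
    }
    bad <- which(df$count > 0 & df$hold == 0)
    if (length(bad)) {
        stop(sprintf(
            "line %d: positive count where hold = 0 (site %s, point %s, month %d)",
            rowId[bad[1]], df$site[bad[1]], df$point_id[bad[1]],
            df$month_index[bad[1]]
        ), call. = FALSE)
    }
    key <- paste(df$site, df$point_id, df$month_index)
    if (anyDuplicated(key)) {
        stop(sprintf(
            "duplicate (site, point, month) key at line %d",
            rowId[which(duplicated(key))[1]]
        ), call. = FALSE)
    }
    df <- df[!df$month_index %in% exclusions, , drop = FALSE]

    out <- lapply(split(df, df$site), function(sd) {
        months <- sort(unique(sd$month_index))
        if (!all(diff(months) == 1L)) {
            stop(sprintf(
                "site %s: month_index not gapless after exclusions (%s)",
                sd$site[1], paste(months, collapse = ",")
            ), call. = FALSE)
        }
        points <- sort(unique(sd$point_id))
        Tn <- length(months)
        P <- length(points)
        if (nrow(sd) != Tn * P) {
            stop(sprintf(
                "site %s: expected %d rows (%d months x %d points), found %d",
                sd$site[1], Tn * P, Tn, P, nrow(sd)
            ), call. = FALSE)
        }
        ti <- match(sd$month_index, months)
        pi <- match(sd$point_id, points)
        fill <- function(v, int = TRUE) {
            m <- matrix(if (int) 0L else 0, Tn, P)
            m[cbind(ti, pi)] <- v
            m
        }
        temp <- NULL
        if ("temperature" %in% names(sd) && !all(is.na(sd$temperature))) {
            temp <- vapply(
                months,
                function(mo) sd$temperature[sd$month_index == mo][1],
                numeric(1)
            )
        }
        labels <- character()
        if ("calendar_label" %in% names(sd)) {
            labels <- vapply(
                months,
                function(mo) as.character(sd$calendar_label[sd$month_index == mo][1]),
                character(1)
            )
        }
        design <- surveyDesign(
            hold = fill(sd$hold), chem = fill(sd$chem),
            temperature = temp, surveyLabels = labels
        )
        counts <- countData(fill(sd$count), design)
        if (!quiet) {
            message(sprintf(
                "site %s: %d rows, %d points, %d months, %d detection month(s)",
                sd$site[1], nrow(sd), P, Tn,
                sum(rowSums(countMatrix(counts)) > 0)
            ))
        }
        list(design = design, counts = counts)
    })
    out
}

#' Write a survey table
#'
#' Inverse of [readSurvey()]: serializes per-site design/count pairs to the
#' long-format CSV schema (UTF-8, comma-separated, header row).
#'
#' @param sites named list of `list(design =, counts =)` per site, or a
#'   single such list (then `siteName` is used).
#' @param path output CSV path.
#' @param siteName site label when `sites` is a single design/count pair.
#' @return `path`, invisibly.
#' @export
writeSurvey <- function(sites, path, siteName = "site1") {
    if (!is.null(sites$design)) sites <- stats::setNames(list(sites), siteName)
    rows <- lapply(names(sites), function(nm) {
        design <- sites[[nm]]$design
        counts <- sites[[nm]]$counts
        Tn <- nSurveys(design)
        P <- nPoints(design)
        df <- data.frame(
            site = nm,
            point_id = rep(seq_len(P), each = Tn),
            month_index = rep(seq_len(Tn), P),
            count = as.vector(countMatrix(counts)),
            hold = as.vector(holdMatrix(design)),
            chem = as.vector(chemMatrix(design))
        )
        if (!is.null(temperature(design))) {
            df$temperature <- rep(temperature(design), P)
        }
        if (length(design@surveyLabels)) {
            df$calendar_label <- rep(design@surveyLabels, P)
        }
        df
    })
    common <- Reduce(intersect, lapply(rows, names))
    rows <- lapply(rows, function(d) d[common])
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' Serialize posterior draws
#'
#' Writes one CSV row per retained draw (chain, parameters, then
#' `N_1..N_P`) plus a JSON metadata sidecar (`<path>.json`) recording the
#' seed, MCMC configuration, acceptance rates and R-hat values.
#'
#' @param draws a [PosteriorDraws-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePosterior <- function(draws, path) {
    stopifnot(is(draws, "PosteriorDraws"))
    df <- data.frame(chain = chainIndex(draws), paramDraws(draws))
    Nmat <- abundanceDraws(draws)
    colnames(Nmat) <- paste0("N_", seq_len(ncol(Nmat)))
    utils::write.csv(cbind(df, Nmat), path, row.names = FALSE)
    rh <- tryCatch(as.list(rhat(draws)), error = function(e) NULL)
    meta <- list(
        seed = draws@seed,
        config = draws@config,
        accept = as.list(draws@accept),
        rhat = rh,
        package = "eradmix",
        version = as.character(utils::packageVersion("eradmix"))
    )
    jsonlite::write_json(meta, paste0(path, ".json"),
        auto_unbox = TRUE, digits = NA
    )
    invisible(path)
}

#' Read serialized posterior draws
#'
#' @param path CSV written by [writePosterior()].
#' @return a [PosteriorDraws-class] (acceptance rates restored from the
#'   sidecar when present).
#' @export
readPosterior <- function(path) {
    df <- utils::read.csv(path)
    nCols <- grep("^N_", names(df))
    parCols <- setdiff(seq_along(df), c(1L, nCols))
    meta <- list(seed = NA_integer_, config = list(), accept = numeric())
    side <- paste0(path, ".json")
    if (file.exists(side)) {
        m <- jsonlite::read_json(side, simplifyVector = TRUE)
        meta$seed <- as.integer(m$seed)
        meta$config <- as.list(m$config)
        meta$accept <- unlist(m$accept)
    }
    new("PosteriorDraws",
        params = as.matrix(df[parCols]),
        N = as.matrix(df[nCols]),
        chain = as.integer(df$chain),
        config = meta$config, seed = meta$seed,
        accept = if (length(meta$accept)) meta$accept else numeric()
    )
}

#' Write an eradication report
#'
#' Emits the monthly presence-probability CSV (`month`, `Ps`,
#' `detected`) and a JSON summary with the declaration months and months
#' since last detection.
#'
#' @param summary result of [eradicationSummary()].
#' @param counts the [CountData-class] (for per-month detection flags).
#' @param csvPath,jsonPath output paths.
#' @return `jsonPath`, invisibly.
#' @export
writeEradicationReport <- function(summary, counts, csvPath, jsonPath) {
    Ps <- summary$Ps
    detected <- rowSums(countMatrix(counts)) > 0
    utils::write.csv(
        data.frame(
            month = seq_along(Ps), Ps = Ps,
            detected = as.integer(detected[seq_along(Ps)])
        ),
        csvPath,
        row.names = FALSE
    )
    decl <- summary$declarations
    jsonlite::write_json(
        list(
            lastDetection = summary$lastDetection,
            t95 = decl$month[decl$threshold == 0.05],
            t99 = decl$month[decl$threshold == 0.01],
            reached95 = decl$reached[decl$threshold == 0.05],
            reached99 = decl$reached[decl$threshold == 0.01],
            monthsSinceLastDetection95 =
                decl$monthsSinceLastDetection[decl$threshold == 0.05],
            monthsSinceLastDetection99 =
                decl$monthsSinceLastDetection[decl$threshold == 0.01],
            package = "eradmix",
            version = as.character(utils::packageVersion("eradmix"))
        ),
        jsonPath,
        auto_unbox = TRUE, digits = NA, na = "null"
    )
    invisible(jsonPath)
}
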