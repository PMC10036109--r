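#' @include AllClasses.R AllGenerics.R
NULL

## CSV/JSON readers and writers for the pipeline's table and parameter
## objects. Column headers are the documented field names; all values are
## written in base units (um^3, keV/um, mm, fractions).

#' Read / write pipeline tables as CSV
#'
#' Plain-CSV persistence for the three measurement tables. Headers match
#' the documented columns of each class; objects round-trip exactly up to
#' numeric printing precision.
#'
#' @param file path to a CSV file
#' @param x the object to write
#' @return readers return the corresponding table object; writers return
#'   \code{x} invisibly
#' @name tableIO
NULL

#' @rdname tableIO
#' @export
readFociTable <- function(file)
    FociTable(utils::read.csv(file, stringsAsFactors = FALSE))

#' @rdname tableIO
#' @export
writeFociTable <- function(x, file) {
    stopifnot1(is(x, "FociTable"), "'x' must be a FociTable")
    utils::write.csv(tableData(x), file, row.names = FALSE)
    invisible(x)
}

#' @rdname tableIO
#' @export
readOccupancyTable <- function(file)
    OccupancyTable(utils::read.csv(file, stringsAsFactors = FALSE))

#' @rdname tableIO
#' @export
writeOccupancyTable <- function(x, file) {
    stopifnot1(is(x, "OccupancyTable"), "'x' must be an OccupancyTable")
    utils::write.csv(tableData(x), file, row.names = FALSE)
    invisible(x)
}

#' @rdname tableIO
#' @export
readSurvivalTable <- function(file) {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    d$control <- as.logical(d$control)
    SurvivalTable(d)
}

#' @rdname tableIO
#' @export
writeSurvivalTable <- function(x, file) {
    stopifnot1(is(x, "SurvivalTable"), "'x' must be a SurvivalTable")
    utils::write.csv(tableData(x), file, row.names = FALSE)
    invisible(x)
}

#' @rdname tableIO
#' @export
readDepthProfile <- function(file) {
    d <- utils::read.csv(file, stringsAsFactors = FALSE)
    DepthProfile(d$depth_mm, d$let_kev_um, d$dose_rel)
}

#' @rdname tableIO
#' @export
writeDepthProfile <- function(x, file) {
    stopifnot1(is(x, "DepthProfile"), "'x' must be a DepthProfile")
    utils::write.csv(
        data.frame(depth_mm = x@depth, let_kev_um = x@letMono,
                   dose_rel = x@doseMono),
        file, row.names = FALSE)
    invisible(x)
}

#' Read / write parameter laws and specs as JSON
#'
#' JSON persistence for fitted laws and ridge-filter specifications.
#'
#' @param file path to a JSON file
#' @param x the object to write
#' @return readers return the object; writers return \code{x} invisibly
#' @name lawIO
NULL

#' @rdname lawIO
#' @export
writeLETLaws <- function(x, file) {
    stopifnot1(is(x, "LETLaws"), "'x' must be an LETLaws")
    jsonlite::write_json(
        list(mu_slope = x@muSlope, mu_intercept = x@muIntercept,
             sigma_slope = x@sigmaSlope, sigma_intercept = x@sigmaIntercept),
        file, auto_unbox = TRUE, digits = NA)
    invisible(x)
}

#' @rdname lawIO
#' @export
readLETLaws <- function(file) {
    j <- jsonlite::read_json(file)
    LETLaws(j$mu_slope, j$mu_intercept, j$sigma_slope, j$sigma_intercept)
}

#' @rdname lawIO
#' @export
writeUnhitLaw <- function(x, file) {
    stopifnot1(is(x, "UnhitLaw"), "'x' must be an UnhitLaw")
    jsonlite::write_json(list(c = x@c), file, auto_unbox = TRUE, digits = NA)
    invisible(x)
}

#' @rdname lawIO
#' @export
readUnhitLaw <- function(file) UnhitLaw(jsonlite::read_json(file)$c)

#' @rdname lawIO
#' @export
writeSOBPSpec <- function(x, file) {
    stopifnot1(is(x, "SOBPSpec"), "'x' must be an SOBPSpec")
    jsonlite::write_json(
        list(weights = x@weights, shifts = x@shifts, width = x@width,
             eval_depth = x@evalDepth),
        file, auto_unbox = TRUE, digits = NA)
    invisible(x)
}

#' @rdname lawIO
#' @export
readSOBPSpec <- function(file) {
    j <- jsonlite::read_json(file, simplifyVector = TRUE)
    SOBPSpec(j$weights, j$shifts, j$width, j$eval_depth)
}

#' Write a concordance result as a long-format CSV
#'
#' One row per (condition, threshold) pair with the clustering probability,
#' the normalized killing effect and their absolute difference.
#'
#' @param x a [ConcordanceResult-class]
#' @param file path to a CSV file
#' @return \code{x}, invisibly
#' @export
writeConcordanceResult <- function(x, file) {
    stopifnot1(is(x, "ConcordanceResult"), "'x' must be a ConcordanceResult")
    long <- data.frame(
        condition = rep(x@conditions, times = length(x@vthGrid)),
        v_th = rep(x@vthGrid, each = length(x@conditions)),
        p = as.vector(x@p),
        killing = rep(x@killing, times = length(x@vthGrid)),
        diff = as.vector(x@diffs))
    utils::write.csv(long, file, row.names = FALSE)
    invisible(x)
}
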