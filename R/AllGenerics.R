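#' @include AllClasses.R
NULL

#' Evaluate the mean law at a LET
#' @param laws an [LETLaws-class]
#' @param let LET in keV/um (vectorized)
#' @return mean maximum focus volume, um^3
#' @export
setGeneric("muAt", function(laws, let) standardGeneric("muAt"))

#' Evaluate the standard-deviation law at a LET
#' @param laws an [LETLaws-class]
#' @param let LET in keV/um (vectorized)
#' @return standard deviation of the maximum focus volume, um^3
#' @export
setGeneric("sigmaAt", function(laws, let) standardGeneric("sigmaAt"))

#' Extract the underlying data.frame of a table object
#' @param x a [FociTable-class], [OccupancyTable-class] or
#'   [SurvivalTable-class]
#' @return the wrapped data.frame
#' @export
setGeneric("tableData", function(x) standardGeneric("tableData"))

#' Total dose of an LET spectrum
#' @param spec an [LETSpectrum-class]
#' @return sum of the component dose contributions
#' @export
setGeneric("totalDose", function(spec) standardGeneric("totalDose"))

#' Locate the threshold minimizing the mean concordance difference
#' @param result a [ConcordanceResult-class]
#' @return the threshold in um^3 with the smallest mean |p - killing|;
#'   ties are broken toward the smaller threshold
#' @export
setGeneric("optimalThreshold", function(result) standardGeneric("optimalThreshold"))

#' @rdname muAt
setMethod("muAt", "LETLaws", function(laws, let)
    laws@muSlope * let + laws@muIntercept)

#' @rdname sigmaAt
setMethod("sigmaAt", "LETLaws", function(laws, let)
    laws@sigmaSlope * let + laws@sigmaIntercept)

#' @rdname tableData
setMethod("tableData", "FociTable", function(x) x@data)
#' @rdname tableData
setMethod("tableData", "OccupancyTable", function(x) x@data)
#' @rdname tableData
setMethod("tableData", "SurvivalTable", function(x) x@data)

#' @rdname totalDose
setMethod("totalDose", "LETSpectrum", function(spec) sum(spec@dose))

setMethod("show", "LETLaws", function(object) {
    cat("LETLaws\n")
    cat(sprintf("  mu(L)    = %.5g * L + %.5g  [um^3]\n",
                object@muSlope, object@muIntercept))
    cat(sprintf("  sigma(L) = %.5g * L + %.5g  [um^3]\n",
                object@sigmaSlope, object@sigmaIntercept))
})

setMethod("show", "GaussianFit", function(object) {
    cat(sprintf(
        "GaussianFit (LET = %g keV/um): mu = %.4g, sigma = %.4g um^3 (n = %d, bin = %g, sse = %.3g)\n",
        object@let, object@mu, object@sigma, object@n, object@binWidth,
        object@sse))
})

setMethod("show", "MaxVolumeSample", function(object) {
    cat(sprintf(
        "MaxVolumeSample (LET = %g keV/um): %d nuclei, %d foci excluded\n",
        object@let, length(object@values), object@nExcluded))
    if (length(object@values))
        cat(sprintf("  range %.3g - %.3g um^3, mean %.3g\n",
                    min(object@values), max(object@values),
                    mean(object@values)))
})

setMethod("show", "FociTable", function(object) {
    d <- object@data
    cat(sprintf("FociTable: %d foci, %d nuclei, LET panel {%s} keV/um\n",
                nrow(d), length(unique(paste(d$let, d$nucleus_id))),
                paste(sort(unique(d$let)), collapse = ", ")))
})

setMethod("show", "OccupancyTable", function(object) {
    d <- object@data
    cat(sprintf("OccupancyTable: %d cells, LET panel {%s} keV/um\n",
                nrow(d), paste(sort(unique(d$let)), collapse = ", ")))
})

setMethod("show", "SurvivalTable", function(object) {
    d <- object@data
    cat(sprintf("SurvivalTable: %d wells (%d controls), conditions {%s}\n",
                nrow(d), sum(d$control),
                paste(sort(unique(d$condition[!d$control])), collapse = ", ")))
})

setMethod("show", "UnhitLaw", function(object) {
    cat(sprintf("UnhitLaw: R_unhit(L) = (%.4g * L)^2 / 100, valid for L <= %.4g keV/um\n",
                object@c, domainMaxLET(object)))
})

setMethod("show", "DepthProfile", function(object) {
    cat(sprintf(
        "DepthProfile: %d points, depth %.1f - %.1f mm, entrance LET %.3g keV/um\n",
        length(object@depth), min(object@depth), max(object@depth),
        object@letMono[1L]))
})

setMethod("show", "SOBPSpec", function(object) {
    cat(sprintf(
        "SOBPSpec: width %g mm, %d components, eval depth %.1f mm\n",
        object@width, length(object@weights), object@evalDepth))
})

setMethod("show", "LETSpectrum", function(object) {
    cat(sprintf("LETSpectrum: %d components, total dose %.4g\n",
                length(object@let), sum(object@dose)))
    if (length(object@let))
        cat(sprintf("  LET range %.3g - %.3g keV/um\n",
                    min(object@let), max(object@let)))
})

setMethod("show", "ConcordanceResult", function(object) {
    i <- which.min(object@meanDiff)
    cat(sprintf(
        "ConcordanceResult: %d conditions x %d thresholds; optimum v_th = %g um^3 (mean diff %.3g +/- %.3g)\n",
        length(object@conditions), length(object@vthGrid),
        object@vthGrid[i], object@meanDiff[i], object@sdDiff[i]))
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig\n")
    cat(sprintf("  LET panel: {%s} keV/um; %d nuclei/LET, %d cells/LET, %d x %d seeded\n",
                paste(object@letValues, collapse = ", "),
                object@nNucleiPerLET, object@nCellsOccupancy,
                object@replicates, object@nSeeded))
    cat(sprintf("  truth: threshold %g um^3, unhit c %.4g, PE %.2f, seed %d\n",
                object@trueLethalThreshold, object@trueUnhitCoefficient,
                object@platingEfficiency, object@seed))
})
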