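#' @import methods
NULL

## Central value classes of the pipeline. All physical quantities are kept in
## base units internally: volumes in cubic micrometres, LET in keV/um, depths
## in mm, fractions in [0, 1] (percent appears only at I/O edges).

#' Linear-in-LET laws for the Gaussian focus-volume parameters
#'
#' Holds the four coefficients of the linear laws
#' \deqn{\mu(L) = a_\mu L + b_\mu, \qquad \sigma(L) = a_\sigma L + b_\sigma}
#' relating the mean and standard deviation of the per-nucleus maximum
#' gammaH2AX focus volume (in um^3) to the beam LET \eqn{L} (in keV/um).
#'
#' @slot muSlope slope of the mean law, um^3 per keV/um
#' @slot muIntercept intercept of the mean law, um^3
#' @slot sigmaSlope slope of the standard-deviation law, um^3 per keV/um
#' @slot sigmaIntercept intercept of the standard-deviation law, um^3
#'
#' @seealso [defaultLETLaws()] for the reference coefficients,
#'   [muAt()], [sigmaAt()], [fociDensity()], [clusteringProbability()]
#' @exportClass LETLaws
setClass("LETLaws",
    representation(
        muSlope = "numeric", muIntercept = "numeric",
        sigmaSlope = "numeric", sigmaIntercept = "numeric"
    )
)

setValidity("LETLaws", function(object) {
    for (s in c("muSlope", "muIntercept", "sigmaSlope", "sigmaIntercept")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v))
            return(sprintf("'%s' must be a single finite number", s))
    }
    ## note: positivity of the sigma law is enforced where the law is
    ## evaluated, not here — noisy small-sample fits may produce a line
    ## that dips non-positive at the domain edge, and such a fit must
    ## still be representable to report its coefficients
    TRUE
})

#' Construct an LETLaws object
#'
#' @param muSlope,muIntercept,sigmaSlope,sigmaIntercept law coefficients;
#'   see the class description for units.
#' @return an [LETLaws-class] object
#' @examples
#' laws <- LETLaws(0.0158, 0.126, 0.00724, 0.0312)
#' muAt(laws, 60)
#' @export
LETLaws <- function(muSlope, muIntercept, sigmaSlope, sigmaIntercept) {
    new("LETLaws",
        muSlope = as.numeric(muSlope), muIntercept = as.numeric(muIntercept),
        sigmaSlope = as.numeric(sigmaSlope),
        sigmaIntercept = as.numeric(sigmaIntercept))
}

#' Gaussian fit to a binned max-volume histogram
#'
#' Result of fitting the normal density to the density-normalized histogram
#' of per-nucleus maximum focus volumes at one LET.
#'
#' @slot let beam LET of the fitted sample, keV/um
#' @slot mu fitted mean, um^3
#' @slot sigma fitted standard deviation, um^3
#' @slot binWidth histogram bin width used for the fit, um^3
#' @slot n number of nuclei in the sample
#' @slot sse sum of squared residuals in density units
#' @exportClass GaussianFit
setClass("GaussianFit",
    representation(let = "numeric", mu = "numeric", sigma = "numeric",
                   binWidth = "numeric", n = "integer", sse = "numeric"))

setValidity("GaussianFit", function(object) {
    if (object@sigma <= 0) return("'sigma' must be positive")
    if (object@binWidth <= 0) return("'binWidth' must be positive")
    if (object@n < 1L) return("'n' must be at least 1")
    TRUE
})

#' Per-nucleus maximum focus volumes at one LET
#'
#' The per-nucleus maxima of focus volume after removal of sub-floor foci.
#' Nuclei whose foci were all below the exclusion floor contribute no value.
#'
#' @slot let beam LET, keV/um
#' @slot values per-nucleus maximum volumes, um^3 (one per hit nucleus)
#' @slot nExcluded number of individual foci removed by the volume floor
#' @exportClass MaxVolumeSample
setClass("MaxVolumeSample",
    representation(let = "numeric", values = "numeric", nExcluded = "integer"))

setValidity("MaxVolumeSample", function(object) {
    if (length(object@let) != 1L || object@let <= 0)
        return("'let' must be a single positive number")
    if (object@nExcluded < 0L) return("'nExcluded' must be non-negative")
    TRUE
})

#' Per-focus volume records
#'
#' Tidy table of individual gammaH2AX focus volumes: one row per rendered
#' focus, keyed by cell line, LET, nucleus and focus.
#'
#' @slot data data.frame with columns \code{cell_line}, \code{let} (keV/um),
#'   \code{nucleus_id}, \code{focus_id}, \code{volume} (um^3)
#' @exportClass FociTable
setClass("FociTable", representation(data = "data.frame"))

.fociCols <- c("cell_line", "let", "nucleus_id", "focus_id", "volume")

setValidity("FociTable", function(object) {
    d <- object@data
    if (!all(.fociCols %in% names(d)))
        return(paste("data must have columns:", paste(.fociCols, collapse = ", ")))
    if (nrow(d)) {
        if (any(d$volume <= 0)) return("all volumes must be positive")
        if (any(d$let <= 0)) return("all LET values must be positive")
        key <- paste(d$cell_line, d$let, d$nucleus_id, d$focus_id)
        if (anyDuplicated(key))
            return("(cell_line, let, nucleus_id, focus_id) must be unique")
    }
    TRUE
})

#' @rdname FociTable-class
#' @param data data.frame of per-focus records; see the class description
#' @return a [FociTable-class]
#' @export
FociTable <- function(data) new("FociTable", data = as.data.frame(data))

#' Per-cell gammaH2AX occupancy records
#'
#' One row per scored cell: the nuclear area and the area covered by the
#' gammaH2AX signal, from which intranuclear occupancy (signal/nucleus) and
#' the unhit classification are derived.
#'
#' @slot data data.frame with columns \code{let} (keV/um), \code{cell_id},
#'   \code{signal_area}, \code{nucleus_area} (same areal units, e.g. um^2)
#' @exportClass OccupancyTable
setClass("OccupancyTable", representation(data = "data.frame"))

.occCols <- c("let", "cell_id", "signal_area", "nucleus_area")

setValidity("OccupancyTable", function(object) {
    d <- object@data
    if (!all(.occCols %in% names(d)))
        return(paste("data must have columns:", paste(.occCols, collapse = ", ")))
    if (nrow(d)) {
        if (any(d$nucleus_area <= 0)) return("nucleus_area must be positive")
        if (any(d$signal_area < 0)) return("signal_area must be non-negative")
        if (any(d$signal_area > d$nucleus_area))
            return("signal_area cannot exceed nucleus_area")
    }
    TRUE
})

#' @rdname OccupancyTable-class
#' @param data data.frame of per-cell records; see the class description
#' @return an [OccupancyTable-class]
#' @export
OccupancyTable <- function(data) new("OccupancyTable", data = as.data.frame(data))

#' Clonogenic assay counts
#'
#' One row per well: colonies counted, cells seeded, the experimental
#' condition (LET in keV/um for monoenergetic beams or SOBP width in mm for
#' clinical beams), the replicate label, and whether the well is an
#' unirradiated plating-efficiency control.
#'
#' @slot data data.frame with columns \code{condition}, \code{replicate},
#'   \code{colonies}, \code{n_seeded}, \code{control} (logical)
#' @exportClass SurvivalTable
setClass("SurvivalTable", representation(data = "data.frame"))

.survCols <- c("condition", "replicate", "colonies", "n_seeded", "control")

setValidity("SurvivalTable", function(object) {
    d <- object@data
    if (!all(.survCols %in% names(d)))
        return(paste("data must have columns:", paste(.survCols, collapse = ", ")))
    if (nrow(d)) {
        if (any(d$n_seeded <= 0)) return("n_seeded must be positive")
        if (any(d$colonies < 0) || any(d$colonies > d$n_seeded))
            return("colonies must lie in [0, n_seeded]")
        if (!is.logical(d$control)) return("'control' must be logical")
    }
    TRUE
})

#' @rdname SurvivalTable-class
#' @param data data.frame of per-well records; see the class description
#' @return a [SurvivalTable-class]
#' @export
SurvivalTable <- function(data) new("SurvivalTable", data = as.data.frame(data))

#' Quadratic unhit-cell law
#'
#' One-parameter law for the fraction of cells not traversed by any particle
#' track at 1 Gy: \deqn{R_{unhit}(L) = (cL)^2 / 100} with \eqn{L} the LET in
#' keV/um and \eqn{R_{unhit}} a fraction. The law reaches 1 at
#' \eqn{L = 10/c}, which bounds its validity domain.
#'
#' @slot c the quadratic coefficient (per keV/um)
#' @seealso [defaultUnhitLaw()], [hitFraction()], [unhitProbability()]
#' @exportClass UnhitLaw
setClass("UnhitLaw", representation(c = "numeric"))

setValidity("UnhitLaw", function(object) {
    if (length(object@c) != 1L || !is.finite(object@c) || object@c < 0)
        return("'c' must be a single finite non-negative number")
    TRUE
})

#' @rdname UnhitLaw-class
#' @param c quadratic coefficient, non-negative
#' @return an [UnhitLaw-class]
#' @export
UnhitLaw <- function(c) new("UnhitLaw", c = as.numeric(c))

#' Monoenergetic depth profile
#'
#' LET and relative dose of a monoenergetic carbon-ion beam on a regular
#' 0.1 mm depth grid in water, as recorded by particle-transport codes.
#'
#' @slot depth depth grid in mm, strictly increasing, uniform 0.1 mm spacing
#' @slot letMono LET at each depth, keV/um, positive
#' @slot doseMono relative dose at each depth, non-negative
#' @exportClass DepthProfile
setClass("DepthProfile",
    representation(depth = "numeric", letMono = "numeric",
                   doseMono = "numeric"))

setValidity("DepthProfile", function(object) {
    n <- length(object@depth)
    if (n < 2L) return("depth grid needs at least 2 points")
    if (length(object@letMono) != n || length(object@doseMono) != n)
        return("depth, letMono and doseMono must have equal length")
    dz <- diff(object@depth)
    if (any(dz <= 0)) return("depths must be strictly increasing")
    if (any(abs(dz - 0.1) > 1e-9)) return("depth spacing must be 0.1 mm")
    if (any(object@letMono <= 0)) return("letMono must be positive")
    if (any(object@doseMono < 0)) return("doseMono must be non-negative")
    TRUE
})

#' @rdname DepthProfile-class
#' @param depth,letMono,doseMono numeric vectors; see the class description
#' @return a [DepthProfile-class]
#' @export
DepthProfile <- function(depth, letMono, doseMono)
    new("DepthProfile", depth = as.numeric(depth),
        letMono = as.numeric(letMono), doseMono = as.numeric(doseMono))

#' Ridge-filter specification of an SOBP beam
#'
#' Weights and range shifts of the monoenergetic components composing a
#' spread-out Bragg peak, plus the depth at which the mixed LET spectrum is
#' evaluated (by convention the SOBP center).
#'
#' @slot weights component weights, non-negative, summing to a positive value
#' @slot shifts range shifts in mm, one per component
#' @slot width SOBP width in mm
#' @slot evalDepth evaluation depth in mm (SOBP center)
#' @exportClass SOBPSpec
setClass("SOBPSpec",
    representation(weights = "numeric", shifts = "numeric",
                   width = "numeric", evalDepth = "numeric"))

setValidity("SOBPSpec", function(object) {
    if (length(object@weights) != length(object@shifts))
        return("weights and shifts must have equal length")
    if (length(object@weights) < 1L) return("at least one component required")
    if (any(object@weights < 0)) return("weights must be non-negative")
    if (sum(object@weights) <= 0) return("weights must sum to a positive value")
    if (object@width <= 0) return("width must be positive")
    TRUE
})

#' @rdname SOBPSpec-class
#' @param weights,shifts,width,evalDepth see the class description
#' @return an [SOBPSpec-class]
#' @export
SOBPSpec <- function(weights, shifts, width, evalDepth)
    new("SOBPSpec", weights = as.numeric(weights), shifts = as.numeric(shifts),
        width = as.numeric(width), evalDepth = as.numeric(evalDepth))

#' Mixed-beam LET spectrum at one depth
#'
#' Discrete LET spectrum of a mixed beam: component LET values and their
#' dose contributions, from which the dose-averaged LET is computed.
#'
#' @slot let component LET values, keV/um
#' @slot dose dose contribution of each component, non-negative
#' @exportClass LETSpectrum
setClass("LETSpectrum", representation(let = "numeric", dose = "numeric"))

setValidity("LETSpectrum", function(object) {
    if (length(object@let) != length(object@dose))
        return("let and dose must have equal length")
    if (any(object@dose < 0)) return("dose contributions must be non-negative")
    TRUE
})

#' @rdname LETSpectrum-class
#' @param let,dose numeric vectors of equal length
#' @return an [LETSpectrum-class]
#' @export
LETSpectrum <- function(let, dose)
    new("LETSpectrum", let = as.numeric(let), dose = as.numeric(dose))

#' Threshold-concordance sweep result
#'
#' For each candidate lethal-volume threshold v_th, the absolute difference
#' between the clustering probability p and the hit-normalized killing
#' effect per condition, with the across-condition mean and standard
#' deviation and the minimizing threshold.
#'
#' @slot vthGrid candidate thresholds, um^3
#' @slot conditions condition labels (LET or SOBP width)
#' @slot p matrix of clustering probabilities, conditions x thresholds
#' @slot killing hit-normalized killing effect per condition
#' @slot diffs matrix |p - killing|, conditions x thresholds
#' @slot meanDiff mean of diffs across conditions, per threshold
#' @slot sdDiff sample standard deviation of diffs across conditions
#' @exportClass ConcordanceResult
setClass("ConcordanceResult",
    representation(vthGrid = "numeric", conditions = "character",
                   p = "matrix", killing = "numeric", diffs = "matrix",
                   meanDiff = "numeric", sdDiff = "numeric"))

setValidity("ConcordanceResult", function(object) {
    k <- length(object@vthGrid)
    m <- length(object@conditions)
    if (!all(dim(object@diffs) == c(m, k))) return("diffs has wrong dimensions")
    if (!all(dim(object@p) == c(m, k))) return("p has wrong dimensions")
    if (length(object@killing) != m) return("killing has wrong length")
    if (length(object@meanDiff) != k || length(object@sdDiff) != k)
        return("meanDiff/sdDiff have wrong length")
    if (any(object@diffs < 0)) return("differences must be non-negative")
    TRUE
})

#' Configuration of the synthetic-data generator
#'
#' Bundles the study conditions emulated by the generators: the LET panel,
#' sample sizes per assay, the true parameter laws, the true lethal-volume
#' threshold driving survival, and the master seed.
#'
#' @slot letValues LET panel in keV/um
#' @slot nNucleiPerLET nuclei imaged per LET
#' @slot nCellsOccupancy cells scored for occupancy per LET
#' @slot nSeeded cells seeded per clonogenic well
#' @slot replicates clonogenic replicates per condition
#' @slot dose absorbed dose in Gy (informational; all laws are at 1 Gy)
#' @slot trueLaws [LETLaws-class] used as generator truth
#' @slot trueUnhitCoefficient quadratic unhit coefficient used as truth
#' @slot trueLethalThreshold lethal volume threshold in um^3 driving survival
#' @slot platingEfficiency control plating efficiency, in (0, 1]
#' @slot fociCountScale expected focus count of a hit nucleus at the
#'   reference (entrance) LET of 13 keV/um; counts scale as 13/LET
#' @slot exclusionFloor minimum recordable focus volume, um^3
#' @slot seed master integer seed; all generators derive substreams from it
#' @seealso [GeneratorConfig()]
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
    representation(letValues = "numeric", nNucleiPerLET = "integer",
                   nCellsOccupancy = "integer", nSeeded = "integer",
                   replicates = "integer", dose = "numeric",
                   trueLaws = "LETLaws", trueUnhitCoefficient = "numeric",
                   trueLethalThreshold = "numeric",
                   platingEfficiency = "numeric", fociCountScale = "numeric",
                   exclusionFloor = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
    if (any(object@letValues <= 0)) return("LET values must be positive")
    if (object@nNucleiPerLET < 1L || object@nCellsOccupancy < 1L ||
        object@nSeeded < 1L || object@replicates < 1L)
        return("all counts must be at least 1")
    if (object@dose <= 0) return("dose must be positive")
    if (object@platingEfficiency <= 0 || object@platingEfficiency > 1)
        return("platingEfficiency must lie in (0, 1]")
    if (object@trueUnhitCoefficient < 0)
        return("trueUnhitCoefficient must be non-negative")
    if (object@trueLethalThreshold < 0)
        return("trueLethalThreshold must be non-negative")
    if (object@fociCountScale <= 0) return("fociCountScale must be positive")
    if (object@exclusionFloor < 0) return("exclusionFloor must be non-negative")
    TRUE
})

#' Construct a generator configuration
#'
#' Defaults reproduce the reference study conditions: six monoenergetic LET
#' values spanning the clinical carbon-ion range, 30 imaged nuclei per LET,
#' at least 200 occupancy-scored cells per LET, triplicate clonogenic wells
#' at 1 Gy, and generator truths equal to the reference fitted laws (see
#' [defaultLETLaws()], [defaultUnhitLaw()]) with a lethal threshold of
#' 0.7 um^3.
#'
#' @param letValues LET panel, keV/um
#' @param nNucleiPerLET nuclei imaged per LET
#' @param nCellsOccupancy occupancy-scored cells per LET
#' @param nSeeded cells seeded per clonogenic well
#' @param replicates clonogenic replicates
#' @param dose absorbed dose, Gy
#' @param trueLaws generator-truth [LETLaws-class]
#' @param trueUnhitCoefficient generator-truth unhit coefficient
#' @param trueLethalThreshold generator-truth lethal volume, um^3
#' @param platingEfficiency control plating efficiency in (0, 1]
#' @param fociCountScale expected hit-nucleus focus count at 13 keV/um
#' @param exclusionFloor minimum recordable focus volume, um^3
#' @param seed master integer seed
#' @return a [GeneratorConfig-class]
#' @examples
#' cfg <- GeneratorConfig(seed = 1)
#' foci <- genFociTable(cfg)
#' @export
GeneratorConfig <- function(letValues = c(13, 20, 40, 60, 80, 100),
                            nNucleiPerLET = 30L, nCellsOccupancy = 200L,
                            nSeeded = 2000L, replicates = 3L, dose = 1,
                            trueLaws = defaultLETLaws(),
                            trueUnhitCoefficient = defaultUnhitLaw()@c,
                            trueLethalThreshold = 0.7,
                            platingEfficiency = 0.7, fociCountScale = 44,
                            exclusionFloor = 0.01, seed = 1L) {
    new("GeneratorConfig", letValues = as.numeric(letValues),
        nNucleiPerLET = as.integer(nNucleiPerLET),
        nCellsOccupancy = as.integer(nCellsOccupancy),
        nSeeded = as.integer(nSeeded), replicates = as.integer(replicates),
        dose = as.numeric(dose), trueLaws = trueLaws,
        trueUnhitCoefficient = as.numeric(trueUnhitCoefficient),
        trueLethalThreshold = as.numeric(trueLethalThreshold),
        platingEfficiency = as.numeric(platingEfficiency),
        fociCountScale = as.numeric(fociCountScale),
        exclusionFloor = as.numeric(exclusionFloor), seed = as.integer(seed))
}
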