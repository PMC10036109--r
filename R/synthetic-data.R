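#' @include AllClasses.R AllGenerics.R
NULL

## Generator truths -> per-LET quantities, with domain guard.
.trueUnhit <- function(config, let) {
    r <- (config@trueUnhitCoefficient * let)^2 / 100
    if (any(r >= 1))
        stop(sprintf(
            "LET %g keV/um is beyond the unhit law's domain (R_unhit >= 1)",
            let[which(r >= 1)[1L]]), call. = FALSE)
    r
}

## Per-nucleus maximum volume: Normal(mu, sigma) truncated below at the
## exclusion floor by resampling, so every hit nucleus keeps a recordable
## maximum and the sample size stays fixed.
.drawMaxVolumes <- function(n, mu, sigma, floor) {
    v <- rnorm(n, mu, sigma)
    while (any(bad <- v < floor))
        v[bad] <- rnorm(sum(bad), mu, sigma)
    v
}

#' Generate a synthetic per-focus volume table
#'
#' Emulates the high-resolution microscopy dataset. For each LET in the
#' panel, \code{nNucleiPerLET} nuclei are simulated; a fraction
#' \eqn{R_{unhit}(L)} of them (Bernoulli per nucleus) carries no focus and
#' contributes no rows. Each hit nucleus receives a maximum focus volume
#' drawn from Normal(mu(L), sigma(L)) under the generator-truth laws,
#' truncated below at the exclusion floor by resampling, plus a number of
#' smaller foci: the focus count is 1 + Poisson with mean
#' \code{fociCountScale * 13/L - 1} (focus counts per nucleus fall roughly
#' inversely with LET because fewer tracks traverse a nucleus per unit
#' dose), and non-maximum volumes are log-normal, clamped to the interval
#' [exclusion floor, nucleus maximum].
#'
#' @param config a [GeneratorConfig-class]
#' @return a [FociTable-class]
#' @examples
#' genFociTable(GeneratorConfig(seed = 42))
#' @export
genFociTable <- function(config) {
    stopifnot1(is(config, "GeneratorConfig"),
               "'config' must be a GeneratorConfig")
    runhit <- .trueUnhit(config, config@letValues)
    withSeed(substreamSeed(config@seed, 1L), {
        rows <- lapply(seq_along(config@letValues), function(k) {
            l <- config@letValues[k]
            n <- config@nNucleiPerLET
            hit <- which(runif(n) >= runhit[k])
            if (!length(hit)) return(NULL)
            mu <- muAt(config@trueLaws, l)
            sg <- sigmaAt(config@trueLaws, l)
            maxv <- .drawMaxVolumes(length(hit), mu, sg,
                                    config@exclusionFloor)
            lambda <- max(config@fociCountScale * 13 / l - 1, 0)
            nSub <- rpois(length(hit), lambda)
            nFoci <- 1L + nSub
            sub <- exp(rnorm(sum(nSub), rep(log(maxv) - 1, nSub), 0.8))
            sub <- pmin(pmax(sub, config@exclusionFloor), rep(maxv, nSub))
            vol <- numeric(sum(nFoci))
            maxPos <- cumsum(nFoci) - nSub   # first focus of each nucleus
            vol[maxPos] <- maxv
            vol[-maxPos] <- sub
            data.frame(
                cell_line = "A549", let = l,
                nucleus_id = rep(sprintf("L%03d_n%04d", as.integer(l), hit),
                                 nFoci),
                focus_id = sprintf("f%03d", sequence(nFoci)),
                volume = vol)
        })
        FociTable(do.call(rbind, c(rows, list(make.row.names = FALSE))))
    })
}

#' Generate a synthetic gammaH2AX occupancy table
#'
#' Emulates the conventional-microscopy occupancy dataset. For each LET,
#' \code{nCellsOccupancy} cells are simulated; with probability
#' \eqn{R_{unhit}(L)} a cell's intranuclear occupancy is drawn uniformly
#' below 1% (unhit), otherwise from a Beta distribution shifted to at
#' least 1% (hit). Nucleus areas are Normal around 150 um^2, mimicking
#' G0/G1-synchronized fibroblast monolayers.
#'
#' @param config a [GeneratorConfig-class]
#' @return an [OccupancyTable-class]
#' @export
genOccupancyTable <- function(config) {
    stopifnot1(is(config, "GeneratorConfig"),
               "'config' must be a GeneratorConfig")
    runhit <- .trueUnhit(config, config@letValues)
    withSeed(substreamSeed(config@seed, 2L), {
        rows <- lapply(seq_along(config@letValues), function(k) {
            l <- config@letValues[k]
            n <- config@nCellsOccupancy
            unhit <- runif(n) < runhit[k]
            area <- pmax(rnorm(n, 150, 15), 50)
            occ <- ifelse(unhit,
                          runif(n, 0, 0.0099),
                          0.01 + rbeta(n, 2, 8) * 0.4)
            data.frame(let = l,
                       cell_id = sprintf("L%03d_c%04d", as.integer(l),
                                         seq_len(n)),
                       signal_area = occ * area, nucleus_area = area)
        })
        OccupancyTable(do.call(rbind, c(rows, list(make.row.names = FALSE))))
    })
}

#' True surviving fraction implied by the generator parameters
#'
#' \eqn{SF(L) = 1 - R_{hit}(L)\,p_L(v_{th})}: survival is complete for
#' unhit cells and, among hit cells, death occurs exactly when the maximum
#' focus volume reaches the lethal threshold.
#'
#' @param config a [GeneratorConfig-class]
#' @param let LET in keV/um (vectorized)
#' @return surviving fraction in [0, 1]
#' @export
trueSurvivingFraction <- function(config, let) {
    rhit <- 1 - .trueUnhit(config, let)
    p <- clusteringProbability(config@trueLethalThreshold, let,
                               config@trueLaws)
    sf <- 1 - rhit * p
    if (any(sf < 0 | sf > 1))
        stop("configuration implies a surviving fraction outside [0, 1]",
             call. = FALSE)
    sf
}

#' Generate a synthetic clonogenic assay table
#'
#' Emulates the colony-formation dataset. Per LET and replicate, the colony
#' count is Binomial(\code{nSeeded}, PE * SF(L)) with SF from
#' [trueSurvivingFraction()]; unirradiated control wells (condition 0,
#' \code{control = TRUE}) are Binomial(\code{nSeeded}, PE).
#'
#' @param config a [GeneratorConfig-class]
#' @return a [SurvivalTable-class]
#' @export
genClonogenicTable <- function(config) {
    stopifnot1(is(config, "GeneratorConfig"),
               "'config' must be a GeneratorConfig")
    sf <- trueSurvivingFraction(config, config@letValues)
    pe <- config@platingEfficiency
    withSeed(substreamSeed(config@seed, 3L), {
        reps <- seq_len(config@replicates)
        ctrl <- data.frame(condition = 0, replicate = sprintf("r%d", reps),
                           colonies = rbinom(length(reps), config@nSeeded, pe),
                           n_seeded = config@nSeeded, control = TRUE)
        irr <- do.call(rbind, lapply(seq_along(config@letValues), function(k) {
            data.frame(condition = config@letValues[k],
                       replicate = sprintf("r%d", reps),
                       colonies = rbinom(length(reps), config@nSeeded,
                                         pe * sf[k]),
                       n_seeded = config@nSeeded, control = FALSE)
        }))
        SurvivalTable(rbind(ctrl, irr))
    })
}

#' Generate a parametric monoenergetic depth profile
#'
#' Bragg-curve-like stand-in for particle-transport output on an exact
#' 0.1 mm depth grid: the relative dose rises gently along a ramp, peaks
#' sharply at the beam range and falls off steeply beyond it; the LET rises
#' monotonically from the entrance value to the peak value at the range and
#' stays at the peak value beyond it (where the dose is negligible).
#'
#' @param range beam range (Bragg-peak depth) in mm, positive (default 150,
#'   about the range of a 290 MeV/n carbon beam in water)
#' @param entranceLET LET at z = 0 in keV/um (default 13, the entrance LET
#'   of clinical carbon-ion beams)
#' @param peakLET LET at the Bragg peak in keV/um (default 180)
#' @param gridMax deepest grid point in mm (default \code{range + 130}, deep
#'   enough for ridge-filter shifted lookups of SOBPs up to 120 mm wide)
#' @param peakDose relative dose at the Bragg peak, entrance dose = 1
#'   (default 4)
#' @param peakWidth Gaussian width of the Bragg peak in mm (default 3)
#' @return a [DepthProfile-class]
#' @examples
#' genMonoDepthProfile()
#' @export
genMonoDepthProfile <- function(range = 150, entranceLET = 13,
                                peakLET = 180, gridMax = range + 130,
                                peakDose = 4, peakWidth = 3) {
    stopifnot1(range > 0, "'range' must be positive")
    stopifnot1(entranceLET > 0 && peakLET >= entranceLET,
               "need 0 < entranceLET <= peakLET")
    z <- seq(0, gridMax, by = 0.1)
    ramp <- ifelse(z <= range, 1 + 0.004 * z,
                   (1 + 0.004 * range) * exp(-(z - range) / 2))
    peak <- (peakDose - (1 + 0.004 * range)) *
        exp(-((z - range) / peakWidth)^2)
    dose <- ramp + peak
    let <- ifelse(z <= range,
                  entranceLET + (peakLET - entranceLET) * (z / range)^8,
                  peakLET)
    DepthProfile(depth = z, letMono = let, doseMono = dose)
}

#' Design a ridge-filter specification for a flat SOBP
#'
#' Places range-shifted copies of the monoenergetic beam at regular shift
#' spacing spanning the requested width and solves for non-negative
#' component weights by least squares against a flat unit-dose target over
#' the plateau (the depth interval of one SOBP width ending at the Bragg
#' peak). Weights are normalized to sum to 1. The evaluation depth is the
#' dose-weighted midpoint of the composed plateau. The construction is
#' deterministic for a given width and profile.
#'
#' @param width SOBP width in mm, positive (clinical widths are 30-120 mm
#'   in 10 mm increments)
#' @param mono the [DepthProfile-class] to compose from (default
#'   [genMonoDepthProfile()])
#' @param spacing shift spacing in mm (default 2)
#' @return an [SOBPSpec-class]
#' @examples
#' spec <- genSOBPSpec(30)
#' sum(spec@weights)
#' @export
genSOBPSpec <- function(width, mono = genMonoDepthProfile(), spacing = 2) {
    stopifnot1(length(width) == 1L && width > 0, "'width' must be positive")
    stopifnot1(is(mono, "DepthProfile"), "'mono' must be a DepthProfile")
    peakDepth <- mono@depth[which.max(mono@doseMono)]
    shifts <- seq(0, width, length.out = max(2L, ceiling(width / spacing) + 1L))
    plateau <- seq(peakDepth - width, peakDepth, by = 0.5)
    A <- vapply(shifts, function(s)
        .profileAt(mono, plateau + s, "doseMono"), numeric(length(plateau)))
    w <- pracma::lsqnonneg(A, rep(1, length(plateau)))$x
    w <- w / sum(w)
    ## dose-weighted midpoint of the plateau as the SOBP-center depth
    spec0 <- new("SOBPSpec", weights = w, shifts = shifts, width = width,
                 evalDepth = peakDepth - width / 2)
    d <- sobpDose(mono, spec0, plateau)
    SOBPSpec(weights = w, shifts = shifts, width = width,
             evalDepth = sum(plateau * d) / sum(d))
}
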