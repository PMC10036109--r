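#' @include AllClasses.R AllGenerics.R
NULL

## Linear interpolation on the 0.1 mm grid; extrapolation is an error.
.profileAt <- function(profile, z, what) {
    rng <- range(profile@depth)
    if (any(z < rng[1L] - 1e-9 | z > rng[2L] + 1e-9))
        stop(sprintf("depth outside profile grid [%.1f, %.1f] mm",
                     rng[1L], rng[2L]), call. = FALSE)
    approx(profile@depth, slot(profile, what), xout = z, rule = 1)$y
}

#' Compose the mixed LET spectrum at the SOBP center
#'
#' Evaluates each ridge-filter component at the shifted depth
#' \eqn{z + s_j} of the monoenergetic profile: component \eqn{j}
#' contributes LET \eqn{L_j = L_{mono}(z + s_j)} and dose
#' \eqn{d_j = w_j \, dose_{mono}(z + s_j)}. Depths between grid points are
#' linearly interpolated; depths outside the grid are an error.
#'
#' @param mono a [DepthProfile-class] of the underlying monoenergetic beam
#' @param spec an [SOBPSpec-class] with weights, shifts and the evaluation
#'   depth
#' @return an [LETSpectrum-class] with one component per ridge-filter leg
#' @examples
#' mono <- genMonoDepthProfile()
#' spec <- genSOBPSpec(30, mono)
#' composeSpectrum(mono, spec)
#' @export
composeSpectrum <- function(mono, spec) {
    stopifnot1(is(mono, "DepthProfile"), "'mono' must be a DepthProfile")
    stopifnot1(is(spec, "SOBPSpec"), "'spec' must be an SOBPSpec")
    z <- spec@evalDepth + spec@shifts
    LETSpectrum(let = .profileAt(mono, z, "letMono"),
                dose = spec@weights * .profileAt(mono, z, "doseMono"))
}

#' Apply the overkill LET cap to a spectrum
#'
#' Components with LET above the cap are treated as having LET equal to the
#' cap (default 100 keV/um, the conventional lower limit of the overkill
#' region, where the death fate of traversed cells is taken as immutable).
#' Dose contributions are unchanged.
#'
#' @param spec an [LETSpectrum-class]
#' @param cap LET cap in keV/um, positive (default 100)
#' @return the capped [LETSpectrum-class]
#' @export
capSpectrum <- function(spec, cap = 100) {
    stopifnot1(is(spec, "LETSpectrum"), "'spec' must be an LETSpectrum")
    stopifnot1(length(cap) == 1L && cap > 0, "'cap' must be a single positive number")
    LETSpectrum(let = pmin(spec@let, cap), dose = spec@dose)
}

#' Dose-averaged LET of a mixed beam
#'
#' \deqn{L_{mix} = \sum_i L_i d_i / D} with \eqn{D = \sum_i d_i}: the
#' dose-weighted mean LET over the spectrum components. Invariant to
#' uniform rescaling of the doses, and always within the range of the
#' component LET values.
#'
#' @param spec an [LETSpectrum-class] with positive total dose
#' @return dose-averaged LET in keV/um
#' @examples
#' doseAveragedLET(LETSpectrum(c(50, 100), c(0.5, 0.5)))
#' @export
doseAveragedLET <- function(spec) {
    stopifnot1(is(spec, "LETSpectrum"), "'spec' must be an LETSpectrum")
    D <- sum(spec@dose)
    if (D <= 0) stop("total dose must be positive", call. = FALSE)
    sum(spec@let * spec@dose) / D
}

#' Dose of the composed SOBP at arbitrary depths
#'
#' Superposes the shifted, weighted monoenergetic dose profiles:
#' \eqn{dose(z) = \sum_j w_j \, dose_{mono}(z + s_j)}. Used to check
#' plateau flatness and locate the SOBP center.
#'
#' @param mono a [DepthProfile-class]
#' @param spec an [SOBPSpec-class]
#' @param z depths in mm (vectorized); all shifted depths must lie inside
#'   the mono grid
#' @return composed relative dose at each depth
#' @export
sobpDose <- function(mono, spec, z) {
    vapply(z, function(zz)
        sum(spec@weights * .profileAt(mono, zz + spec@shifts, "doseMono")),
        numeric(1))
}
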