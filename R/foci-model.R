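#' @include AllClasses.R AllGenerics.R
NULL

#' Per-nucleus maximum focus volumes after the exclusion floor
#'
#' Applies the minimum-volume exclusion rule to a focus table and reduces
#' each nucleus to the maximum volume of its surviving foci. Foci smaller
#' than \code{floor} are removed before the maximum is taken; nuclei whose
#' foci are all sub-floor contribute no sample (they still count toward
#' \code{nExcluded} through their removed foci).
#'
#' @param table a [FociTable-class]
#' @param floor exclusion floor in um^3; foci with \code{volume < floor}
#'   are discarded (default 0.01)
#' @return a named list of [MaxVolumeSample-class] objects, one per LET,
#'   named by the LET value and sorted by LET
#' @examples
#' foci <- genFociTable(GeneratorConfig(seed = 7))
#' samples <- extractMaxVolumes(foci)
#' samples[["60"]]
#' @export
extractMaxVolumes <- function(table, floor = 0.01) {
    stopifnot1(is(table, "FociTable"), "'table' must be a FociTable")
    d <- tableData(table)
    stopifnot1(nrow(d) > 0, "focus table is empty")
    stopifnot1(length(floor) == 1L && floor >= 0,
               "'floor' must be a single non-negative number")
    lets <- sort(unique(d$let))
    out <- lapply(lets, function(l) {
        dl <- d[d$let == l, , drop = FALSE]
        keep <- dl$volume >= floor
        nExcluded <- sum(!keep)
        dl <- dl[keep, , drop = FALSE]
        vals <- if (nrow(dl))
            as.numeric(tapply(dl$volume, paste(dl$cell_line, dl$nucleus_id),
                              max))
        else numeric(0)
        new("MaxVolumeSample", let = l, values = unname(vals),
            nExcluded = as.integer(nExcluded))
    })
    names(out) <- as.character(lets)
    out
}

## Histogram of max volumes: bins of width `binWidth` anchored at zero,
## normalized to density (bin fraction / bin width). Empty bins inside the
## data range are kept; they carry information for the least-squares fit.
.maxVolumeHistogram <- function(values, binWidth) {
    upper <- ceiling(max(values) / binWidth + 1e-9) * binWidth
    breaks <- seq(0, upper, by = binWidth)
    if (breaks[length(breaks)] < upper) breaks <- c(breaks, upper)
    counts <- hist(values, breaks = breaks, plot = FALSE,
                   right = FALSE)$counts
    centers <- (breaks[-length(breaks)] + breaks[-1L]) / 2
    density <- counts / length(values) / binWidth
    data.frame(center = centers, density = density, count = counts)
}

#' Fit a Gaussian to the binned max-volume histogram
#'
#' Histograms the per-nucleus maximum volumes with bins of width
#' \code{binWidth} anchored at zero, converts counts to density (bin
#' fraction divided by bin width), and fits the normal density
#' \deqn{f(v) = \frac{1}{\sqrt{2\pi}\sigma}
#'   \exp\left(-\frac{(v-\mu)^2}{2\sigma^2}\right)}
#' to the bin centers by nonlinear least squares (Levenberg-Marquardt),
#' initialized at the sample mean and standard deviation. The amplitude is
#' fixed by the density normalization, so \eqn{\mu} and \eqn{\sigma} are the
#' only free parameters; \eqn{\sigma > 0} is enforced by a box constraint.
#'
#' @param sample a [MaxVolumeSample-class] with at least 5 values
#' @param binWidth histogram bin width in um^3 (default 0.1)
#' @return a [GaussianFit-class]
#' @examples
#' laws <- defaultLETLaws()
#' vals <- rnorm(500, muAt(laws, 60), sigmaAt(laws, 60))
#' s <- new("MaxVolumeSample", let = 60, values = vals[vals > 0],
#'          nExcluded = 0L)
#' fitMaxVolumeGaussian(s)
#' @export
fitMaxVolumeGaussian <- function(sample, binWidth = 0.1) {
    stopifnot1(is(sample, "MaxVolumeSample"),
               "'sample' must be a MaxVolumeSample")
    v <- sample@values
    stopifnot1(length(v) >= 5L, "need at least 5 max-volume samples to fit")
    stopifnot1(binWidth > 0, "'binWidth' must be positive")
    if (sd(v) == 0)
        stop("degenerate sample: all maximum volumes identical", call. = FALSE)
    h <- .maxVolumeHistogram(v, binWidth)
    fit <- minpack.lm::nlsLM(
        density ~ dnorm(center, mu, sigma),
        data = h,
        start = list(mu = mean(v), sigma = sd(v)),
        lower = c(mu = -Inf, sigma = 1e-8),
        control = minpack.lm::nls.lm.control(
            ftol = 1e-10, ptol = 1e-10, maxiter = 1000, maxfev = 100000))
    est <- coef(fit)
    if (fit$convInfo$stopCode %in% c(0L, 5L))  # bad input / maxiter exhausted
        stop("Gaussian histogram fit did not converge", call. = FALSE)
    new("GaussianFit", let = sample@let, mu = unname(est[["mu"]]),
        sigma = unname(est[["sigma"]]), binWidth = binWidth,
        n = length(v), sse = sum(residuals(fit)^2))
}

#' Fit the linear-in-LET laws to per-LET Gaussian fits
#'
#' Ordinary least-squares regression of the fitted \eqn{\mu} and
#' \eqn{\sigma} on LET, giving the four coefficients of an
#' [LETLaws-class].
#'
#' @param fits list of [GaussianFit-class] objects at 3 or more distinct
#'   LET values
#' @return an [LETLaws-class]
#' @examples
#' foci <- genFociTable(GeneratorConfig(seed = 3))
#' fits <- lapply(extractMaxVolumes(foci), fitMaxVolumeGaussian)
#' fitLETLaws(fits)
#' @export
fitLETLaws <- function(fits) {
    stopifnot1(is.list(fits) && all(vapply(fits, is, TRUE, "GaussianFit")),
               "'fits' must be a list of GaussianFit objects")
    let <- vapply(fits, slot, numeric(1), "let")
    stopifnot1(length(unique(let)) >= 3L,
               "need fits at 3 or more distinct LET values")
    mu <- vapply(fits, slot, numeric(1), "mu")
    sigma <- vapply(fits, slot, numeric(1), "sigma")
    cm <- coef(lm(mu ~ let))
    cs <- coef(lm(sigma ~ let))
    LETLaws(muSlope = cm[["let"]], muIntercept = cm[["(Intercept)"]],
            sigmaSlope = cs[["let"]], sigmaIntercept = cs[["(Intercept)"]])
}

.checkSigma <- function(laws, let) {
    s <- sigmaAt(laws, let)
    if (any(s <= 0))
        stop("sigma law is non-positive at the requested LET", call. = FALSE)
    s
}

#' Gaussian density of the per-nucleus maximum focus volume
#'
#' Evaluates the normal density with mean \code{muAt(laws, let)} and
#' standard deviation \code{sigmaAt(laws, let)} at volume \code{v}.
#'
#' @param v volume in um^3 (vectorized)
#' @param let LET in keV/um
#' @param laws an [LETLaws-class]
#' @return density per um^3
#' @export
fociDensity <- function(v, let, laws) {
    s <- .checkSigma(laws, let)
    dnorm(v, mean = muAt(laws, let), sd = s)
}

#' Probability of inducing a focus of at least a threshold volume
#'
#' Upper-tail probability \eqn{p(v_{th}) = \int_{v_{th}}^{\infty} f(v)\,dv}
#' of the Gaussian max-volume law: the probability that 1 Gy of carbon ions
#' of the given LET induces a maximum focus of volume \code{vth} or greater
#' in a nucleus. Computed in closed form from the normal upper tail
#' (complementary error function); the boundary is inclusive.
#'
#' @param vth threshold volume in um^3 (vectorized)
#' @param let LET in keV/um
#' @param laws an [LETLaws-class]
#' @return probability in [0, 1]
#' @examples
#' clusteringProbability(0.7, 60, defaultLETLaws())
#' @export
clusteringProbability <- function(vth, let, laws) {
    s <- .checkSigma(laws, let)
    pnorm(vth, mean = muAt(laws, let), sd = s, lower.tail = FALSE)
}

#' Empirical threshold-exceedance probability
#'
#' Fraction of hit nuclei whose measured maximum focus volume is
#' \code{vth} or greater: the measured-value counterpart of
#' [clusteringProbability()]. The denominator is the number of nuclei
#' contributing a max-volume sample (unhit nuclei are handled separately by
#' the hit-fraction normalization).
#'
#' @param sample a non-empty [MaxVolumeSample-class]
#' @param vth threshold volume in um^3 (vectorized)
#' @return probability in [0, 1]
#' @export
empiricalProbability <- function(sample, vth) {
    stopifnot1(is(sample, "MaxVolumeSample"),
               "'sample' must be a MaxVolumeSample")
    stopifnot1(length(sample@values) > 0, "sample is empty")
    vapply(vth, function(t) mean(sample@values >= t), numeric(1))
}
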