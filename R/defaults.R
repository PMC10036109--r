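#' Reference linear laws for the focus-volume Gaussian parameters
#'
#' The fitted laws for the A549 reference dataset at 1 Gy:
#' mu(L) = 0.0158 L + 0.126 and sigma(L) = 0.00724 L + 0.0312 (um^3, L in
#' keV/um). These are the generator truths used by [GeneratorConfig()] by
#' default and the benchmark against which parameter-recovery experiments
#' are scored.
#'
#' @return an [LETLaws-class]
#' @examples
#' muAt(defaultLETLaws(), c(13, 60, 100))
#' @export
defaultLETLaws <- function() LETLaws(0.0158, 0.126, 0.00724, 0.0312)

#' Reference quadratic unhit-cell law
#'
#' The fitted coefficient for 1BR hTERT monolayers at 1 Gy:
#' R_unhit(L) = (0.0618 L)^2 / 100, giving e.g. an unhit fraction of about
#' 38% at 100 keV/um. Valid up to L = 10/0.0618 ~ 162 keV/um where the
#' law saturates at 1.
#'
#' @return an [UnhitLaw-class]
#' @examples
#' hitFraction(100, defaultUnhitLaw())
#' @export
defaultUnhitLaw <- function() UnhitLaw(0.0618)
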