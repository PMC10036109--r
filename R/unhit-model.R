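#' @include AllClasses.R AllGenerics.R
NULL

#' Classify unhit cells from gammaH2AX occupancy
#'
#' A cell is unhit when the intranuclear occupancy of its gammaH2AX signal
#' (signal area over nucleus area) is strictly less than the threshold:
#' cells sitting exactly at the threshold are hit.
#'
#' @param signalArea gammaH2AX signal area (vectorized)
#' @param nucleusArea nucleus area, same units, positive
#' @param threshold occupancy threshold as a fraction (default 0.01, i.e. 1%)
#' @return logical vector, TRUE for unhit cells
#' @examples
#' classifyUnhit(c(0, 1, 5), 100)
#' @export
classifyUnhit <- function(signalArea, nucleusArea, threshold = 0.01) {
    stopifnot1(all(nucleusArea > 0), "nucleus area must be positive")
    signalArea / nucleusArea < threshold
}

#' Unhit-cell fraction at one LET
#'
#' Fraction of cells at the given LET classified as unhit: the ratio of
#' unhit cells to the entire scored cell population.
#'
#' @param table an [OccupancyTable-class]
#' @param let LET in keV/um; must be present in the table
#' @param threshold occupancy threshold, fraction (default 0.01)
#' @return fraction in [0, 1]
#' @export
unhitFraction <- function(table, let, threshold = 0.01) {
    stopifnot1(is(table, "OccupancyTable"),
               "'table' must be an OccupancyTable")
    d <- tableData(table)
    d <- d[d$let == let, , drop = FALSE]
    stopifnot1(nrow(d) > 0, sprintf("no cells at LET = %g", let))
    mean(classifyUnhit(d$signal_area, d$nucleus_area, threshold))
}

#' Fit the quadratic unhit law
#'
#' One-parameter least squares of \eqn{R(L) = (cL)^2/100} to the observed
#' per-LET unhit fractions, constrained to \eqn{c \ge 0}. Writing
#' \eqn{a = c^2}, the model is linear in \eqn{a} and the minimizer has the
#' closed form \eqn{a = 100\sum_k R_k L_k^2 / \sum_k L_k^4}, clipped at
#' zero.
#'
#' @param let LET values in keV/um, positive
#' @param fraction observed unhit fractions at each LET
#' @return an [UnhitLaw-class]
#' @examples
#' L <- c(13, 20, 40, 60, 80, 100)
#' fitUnhitLaw(L, (0.0618 * L)^2 / 100)
#' @export
fitUnhitLaw <- function(let, fraction) {
    stopifnot1(length(let) == length(fraction) && length(let) >= 2L,
               "need at least 2 (let, fraction) points")
    stopifnot1(any(let > 0), "all LET values are non-positive")
    keep <- let > 0
    L <- let[keep]; R <- fraction[keep]
    a <- 100 * sum(R * L^2) / sum(L^4)
    UnhitLaw(sqrt(max(a, 0)))
}

#' LET above which the unhit law saturates
#' @param law an [UnhitLaw-class]
#' @return the LET (keV/um) where R_unhit reaches 1, i.e. 10/c;
#'   Inf when c = 0
#' @export
domainMaxLET <- function(law) {
    stopifnot1(is(law, "UnhitLaw"), "'law' must be an UnhitLaw")
    if (law@c == 0) Inf else 10 / law@c
}

#' Unhit probability under the quadratic law
#'
#' Evaluates \eqn{R_{unhit}(L) = (cL)^2/100}. LET values beyond the law's
#' domain (where the unhit fraction would exceed 1) are an error.
#'
#' @param let LET in keV/um (vectorized), within [0, [domainMaxLET()]]
#' @param law an [UnhitLaw-class]
#' @return unhit fraction in [0, 1]
#' @export
unhitProbability <- function(let, law) {
    stopifnot1(is(law, "UnhitLaw"), "'law' must be an UnhitLaw")
    stopifnot1(all(let >= 0), "LET must be non-negative")
    r <- (law@c * let)^2 / 100
    if (any(r > 1))
        stop(sprintf(
            "LET beyond the unhit law's domain (max %.4g keV/um)",
            domainMaxLET(law)), call. = FALSE)
    r
}

#' Hit fraction
#'
#' The complement of the unhit fraction, \eqn{R_{hit} = 1 - R_{unhit}}:
#' the fraction of cells actually traversed by at least one particle track,
#' used to normalize the clonogenic killing effect.
#'
#' @inheritParams unhitProbability
#' @return hit fraction in [0, 1]
#' @examples
#' hitFraction(100, defaultUnhitLaw())
#' @export
hitFraction <- function(let, law) 1 - unhitProbability(let, law)
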