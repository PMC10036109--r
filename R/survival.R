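#' @include AllClasses.R AllGenerics.R
NULL

#' Plating efficiency from unirradiated controls
#'
#' Pools all control wells and returns total colonies over total seeded
#' cells. Pooling (rather than averaging per-well ratios) minimizes
#' variance and is robust to unequal seeding.
#'
#' @param table a [SurvivalTable-class] containing at least one control well
#' @return plating efficiency as a fraction
#' @export
platingEfficiency <- function(table) {
    stopifnot1(is(table, "SurvivalTable"), "'table' must be a SurvivalTable")
    d <- tableData(table)
    d <- d[d$control, , drop = FALSE]
    stopifnot1(nrow(d) > 0, "no control wells in the table")
    colonies <- sum(d$colonies)
    if (colonies == 0)
        stop("zero colonies in control wells: plating efficiency undefined",
             call. = FALSE)
    colonies / sum(d$n_seeded)
}

#' Surviving fraction of a clonogenic well
#'
#' Colonies over seeded cells, divided by the plating efficiency. Values
#' above 1 are possible in noisy data and produce a warning, not an error.
#'
#' @param colonies colony count (vectorized)
#' @param nSeeded cells seeded
#' @param pe plating efficiency, positive
#' @return surviving fraction
#' @examples
#' survivingFraction(60, 200, 0.6)
#' @export
survivingFraction <- function(colonies, nSeeded, pe) {
    stopifnot1(length(pe) == 1L && pe > 0, "'pe' must be a single positive number")
    sf <- (colonies / nSeeded) / pe
    if (any(sf > 1))
        warning("surviving fraction exceeds 1 for some wells", call. = FALSE)
    sf
}

#' Cell killing effect
#'
#' The complementary event of clonogenic survival, \eqn{1 - SF}.
#'
#' @param sf surviving fraction in [0, 1] (vectorized)
#' @return killing effect in [0, 1]
#' @export
killingEffect <- function(sf) {
    if (any(sf < 0 | sf > 1))
        stop("surviving fraction must lie in [0, 1]", call. = FALSE)
    1 - sf
}

#' Hit-fraction-normalized killing effect
#'
#' Divides the killing effect by the hit fraction so that killing reflects
#' only cells actually traversed by a particle track. Normalized values
#' above 1 warn rather than error.
#'
#' @param killing killing effect in [0, 1] (vectorized)
#' @param rHit hit fraction in (0, 1]
#' @return normalized killing effect
#' @examples
#' normalizedKilling(0.5, hitFraction(100, defaultUnhitLaw()))
#' @export
normalizedKilling <- function(killing, rHit) {
    if (any(rHit <= 0))
        stop("hit fraction must be positive", call. = FALSE)
    nk <- killing / rHit
    if (any(nk > 1))
        warning("normalized killing exceeds 1", call. = FALSE)
    nk
}

#' Per-condition survival summary
#'
#' Computes the surviving fraction of every irradiated well using the
#' pooled-control plating efficiency, then the replicate mean and sample
#' standard deviation of the surviving fraction and killing effect per
#' condition.
#'
#' @param table a [SurvivalTable-class] with control and irradiated wells
#' @param pe optional plating efficiency; computed from the table's
#'   controls when NULL
#' @return data.frame with columns \code{condition}, \code{n},
#'   \code{sf_mean}, \code{sf_sd}, \code{killing_mean}, \code{killing_sd},
#'   one row per condition sorted by condition
#' @examples
#' surv <- genClonogenicTable(GeneratorConfig(seed = 11))
#' summarizeSurvival(surv)
#' @export
summarizeSurvival <- function(table, pe = NULL) {
    stopifnot1(is(table, "SurvivalTable"), "'table' must be a SurvivalTable")
    if (is.null(pe)) pe <- platingEfficiency(table)
    d <- tableData(table)
    d <- d[!d$control, , drop = FALSE]
    stopifnot1(nrow(d) > 0, "no irradiated wells in the table")
    sf <- survivingFraction(d$colonies, d$n_seeded, pe)
    conds <- sort(unique(d$condition))
    out <- do.call(rbind, lapply(conds, function(cc) {
        s <- sf[d$condition == cc]
        data.frame(condition = cc, n = length(s), sf_mean = mean(s),
                   sf_sd = sd(s), killing_mean = mean(1 - s),
                   killing_sd = sd(1 - s))
    }))
    rownames(out) <- NULL
    out
}
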