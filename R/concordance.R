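#' @include AllClasses.R AllGenerics.R
NULL

#' Concordance between clustering probability and normalized killing
#'
#' For every candidate lethal-volume threshold, computes the absolute
#' difference between the clustering probability \eqn{p} and the
#' hit-normalized killing effect in each condition, then the mean and
#' sample standard deviation of those differences across conditions. The
#' threshold minimizing the mean difference is the concordance optimum.
#'
#' @param p matrix of clustering probabilities with one row per condition
#'   and one column per threshold; rownames are condition labels and
#'   colnames the threshold values (as produced by [clusteringProbability()]
#'   over a grid)
#' @param killing named vector of hit-normalized killing effects, one per
#'   condition; names must match \code{rownames(p)}
#' @return a [ConcordanceResult-class]
#' @examples
#' laws <- defaultLETLaws(); law <- defaultUnhitLaw()
#' lets <- c(13, 20, 40, 60, 80, 100)
#' grid <- seq(0.1, 2, 0.1)
#' p <- t(sapply(lets, function(L) clusteringProbability(grid, L, laws)))
#' dimnames(p) <- list(lets, grid)
#' k <- sapply(lets, function(L) clusteringProbability(0.7, L, laws))
#' names(k) <- lets
#' optimalThreshold(differenceProfile(p, k))
#' @export
differenceProfile <- function(p, killing) {
    stopifnot1(is.matrix(p) && !is.null(rownames(p)) && !is.null(colnames(p)),
               "'p' must be a matrix with condition rownames and threshold colnames")
    stopifnot1(nrow(p) >= 2L, "need at least 2 conditions")
    stopifnot1(!is.null(names(killing)),
               "'killing' must be named by condition")
    if (!setequal(rownames(p), names(killing)) ||
        length(killing) != nrow(p))
        stop("conditions of 'p' and 'killing' do not match", call. = FALSE)
    killing <- killing[rownames(p)]
    grid <- as.numeric(colnames(p))
    diffs <- abs(p - killing)   # recycles killing down columns
    new("ConcordanceResult",
        vthGrid = grid, conditions = rownames(p), p = p,
        killing = unname(killing), diffs = unname2(diffs),
        meanDiff = unname(colMeans(diffs)),
        sdDiff = unname(apply(diffs, 2L, sd)))
}

unname2 <- function(m) { dimnames(m) <- NULL; m }

#' @rdname optimalThreshold
#' @examples
#' # see ?differenceProfile for a worked example
setMethod("optimalThreshold", "ConcordanceResult", function(result) {
    stopifnot1(length(result@vthGrid) > 0, "empty concordance result")
    ## which.min already returns the first (smallest-threshold) minimum on a
    ## sorted grid; sort defensively for unsorted input
    o <- order(result@vthGrid)
    result@vthGrid[o][which.min(result@meanDiff[o])]
})

#' Spearman rank correlation
#'
#' Spearman's rank correlation with mid-ranks for ties and a two-sided
#' p-value (asymptotic t approximation, appropriate in the presence of
#' ties). Constant input has no defined ranks and is an error.
#'
#' @param x,y paired observations, at least 3 pairs
#' @return list with elements \code{rho} and \code{p.value}
#' @examples
#' rankCorrelation(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
rankCorrelation <- function(x, y) {
    stopifnot1(length(x) == length(y) && length(x) >= 3L,
               "need at least 3 paired observations")
    if (sd(x) == 0 || sd(y) == 0)
        stop("constant input: rank correlation undefined", call. = FALSE)
    ct <- suppressWarnings(
        cor.test(x, y, method = "spearman", exact = FALSE,
                 alternative = "two.sided"))
    list(rho = unname(ct$estimate), p.value = ct$p.value)
}
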