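mkP <- function(values, conditions, grid) {
    p <- matrix(values, nrow = length(conditions),
                dimnames = list(conditions, grid))
    p
}

test_that("differenceProfile computes per-threshold mean and sd", {
    grid <- c(0.6, 0.7)
    p <- mkP(c(0.50, 0.80, 0.46, 0.74), c("13", "60"), grid)
    killing <- c("13" = 0.46, "60" = 0.80)
    res <- differenceProfile(p, killing)
    ## diffs at 0.6: {0.04, 0}; at 0.7: {0, 0.06}
    expect_equal(res@diffs, matrix(c(0.04, 0, 0, 0.06), 2))
    expect_equal(res@meanDiff, c(0.02, 0.03))
    expect_equal(res@sdDiff, c(sd(c(0.04, 0)), sd(c(0, 0.06))))
})

test_that("identical p and killing give zero differences", {
    grid <- seq(0.1, 1, 0.1)
    k <- c("a" = 0.3, "b" = 0.6)
    p <- mkP(rep(c(0.3, 0.6), length(grid)), c("a", "b"), grid)
    res <- differenceProfile(p, k)
    expect_true(all(res@diffs == 0))
    expect_equal(res@sdDiff, rep(0, length(grid)))
})

test_that("hand-computed mean and sd of two-condition differences", {
    ## diffs {0.04, 0.06} -> mean 0.05, sample sd 0.0141
    p <- mkP(c(0.54, 0.66), c("a", "b"), 0.7)
    res <- differenceProfile(p, c(a = 0.5, b = 0.6))
    expect_equal(res@meanDiff, 0.05)
    expect_equal(res@sdDiff, 0.01414214, tolerance = 1e-6)
    expect_equal(optimalThreshold(res), 0.7)  # single-point grid
})

test_that("condition mismatch and too-few conditions are errors", {
    p <- mkP(c(0.5, 0.6), c("a", "b"), 0.7)
    expect_error(differenceProfile(p, c(a = 0.5, z = 0.6)), "do not match")
    expect_error(differenceProfile(p[1, , drop = FALSE], c(a = 0.5)),
                 "at least 2")
})

test_that("optimalThreshold takes the argmin with ties toward smaller", {
    grid <- c(0.6, 0.7, 0.8)
    mk <- function(meanDiff) {
        p <- mkP(rep(meanDiff, each = 2) + c(0, 0), c("a", "b"), grid)
        differenceProfile(p, c(a = 0, b = 0))
    }
    expect_equal(optimalThreshold(mk(c(0.10, 0.047, 0.09))), 0.7)
    expect_equal(optimalThreshold(mk(c(0.01, 0.05, 0.09))), 0.6)
    expect_equal(optimalThreshold(mk(c(0.05, 0.05, 0.09))), 0.6)  # tie
})

test_that("concordance is invariant to condition ordering", {
    laws <- defaultLETLaws()
    grid <- seq(0.1, 2, 0.1)
    p <- t(vapply(letPanel, function(l)
        clusteringProbability(grid, l, laws), numeric(length(grid))))
    dimnames(p) <- list(letPanel, grid)
    k <- clusteringProbability(0.7, letPanel, laws) + 0.02
    names(k) <- letPanel
    r1 <- differenceProfile(p, k)
    o <- c(4, 2, 6, 1, 3, 5)
    r2 <- differenceProfile(p[o, ], k[o])
    expect_equal(r1@meanDiff, r2@meanDiff)
    expect_equal(optimalThreshold(r1), optimalThreshold(r2))
})

test_that("noise-free killing generated at a threshold is recovered exactly", {
    laws <- defaultLETLaws()
    grid <- seq(0.1, 2, 0.1)
    p <- t(vapply(letPanel, function(l)
        clusteringProbability(grid, l, laws), numeric(length(grid))))
    dimnames(p) <- list(letPanel, grid)
    for (tstar in c(0.3, 0.7, 1.2)) {
        k <- clusteringProbability(tstar, letPanel, laws)
        names(k) <- letPanel
        expect_equal(optimalThreshold(differenceProfile(p, k)), tstar)
    }
})

test_that("Spearman correlation handles monotone, reversed and null cases", {
    x <- c(1, 2, 3, 5, 8, 13)
    expect_equal(rankCorrelation(x, x^2 + 1)$rho, 1)
    expect_equal(rankCorrelation(x, -x)$rho, -1)
    set.seed(31)
    r <- rankCorrelation(rnorm(2000), rnorm(2000))
    expect_lt(abs(r$rho), 0.06)
    expect_gt(r$p.value, 0.001)
    expect_error(rankCorrelation(c(1, 1, 1), c(1, 2, 3)), "constant")
    expect_error(rankCorrelation(1:2, 2:3), "at least 3")
})

test_that("ties get mid-ranks in the Spearman statistic", {
    r <- rankCorrelation(c(1, 2, 2, 3), c(1, 2, 3, 4))
    expect_equal(r$rho,
                 cor(rank(c(1, 2, 2, 3)), rank(c(1, 2, 3, 4))))
})
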