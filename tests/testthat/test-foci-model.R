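test_that("extractMaxVolumes applies the exclusion floor before maxima", {
    tab <- FociTable(data.frame(
        cell_line = "A549", let = 60,
        nucleus_id = rep(c("n1", "n2"), c(3, 2)),
        focus_id = c("f1", "f2", "f3", "f1", "f2"),
        volume = c(0.005, 0.30, 0.72, 0.004, 0.006)))
    s <- extractMaxVolumes(tab, floor = 0.01)
    ## n1: sub-floor focus dropped, max of the rest; n2: fully sub-floor,
    ## contributes no sample
    expect_equal(s[["60"]]@values, 0.72)
    expect_equal(s[["60"]]@nExcluded, 3L)
    expect_error(extractMaxVolumes(FociTable(tab@data[0, ])), "empty")
    expect_error(extractMaxVolumes(tab, floor = -1), "non-negative")
})

test_that("extracted samples never exceed the nucleus count", {
    cfg <- GeneratorConfig(seed = 17)
    s <- extractMaxVolumes(genFociTable(cfg))
    expect_true(all(vapply(s, function(x) length(x@values), numeric(1))
                    <= cfg@nNucleiPerLET))
    expect_true(all(unlist(lapply(s, slot, "values")) >= 0.01))
})

test_that("Gaussian histogram fit recovers generating parameters", {
    set.seed(41)
    v <- rnorm(1e4, 1.074, 0.4656)
    fit <- fitMaxVolumeGaussian(mkSample(v[v > 0]))
    expect_lt(abs(fit@mu / 1.074 - 1), 0.02)
    expect_lt(abs(fit@sigma / 0.4656 - 1), 0.03)
})

test_that("Gaussian fit is translation-equivariant and order-invariant", {
    set.seed(42)
    v <- rnorm(200, 1.0, 0.3)
    f0 <- fitMaxVolumeGaussian(mkSample(v))
    fs <- fitMaxVolumeGaussian(mkSample(v + 0.5))
    expect_equal(fs@mu - f0@mu, 0.5, tolerance = 0.05)
    expect_equal(fs@sigma, f0@sigma, tolerance = 0.05)
    fp <- fitMaxVolumeGaussian(mkSample(sample(v)))
    expect_identical(fp@mu, f0@mu)
    expect_identical(fp@sigma, f0@sigma)
})

test_that("Gaussian fit rejects tiny or degenerate samples", {
    expect_error(fitMaxVolumeGaussian(mkSample(c(0.5, 0.6, 0.7, 0.8))),
                 "at least 5")
    expect_error(fitMaxVolumeGaussian(mkSample(rep(0.5, 10))), "degenerate")
})

test_that("fitLETLaws reproduces exact linear inputs to machine precision", {
    laws0 <- defaultLETLaws()
    fits <- lapply(letPanel, function(l)
        mkFit(l, muAt(laws0, l), sigmaAt(laws0, l)))
    laws <- fitLETLaws(fits)
    expect_equal(laws@muSlope, 0.0158, tolerance = 1e-12)
    expect_equal(laws@muIntercept, 0.126, tolerance = 1e-12)
    expect_equal(laws@sigmaSlope, 0.00724, tolerance = 1e-12)
    expect_equal(laws@sigmaIntercept, 0.0312, tolerance = 1e-12)
})

test_that("fitLETLaws handles constant response and too-few LETs", {
    fits <- lapply(c(20, 60, 100), function(l) mkFit(l, 0.8, 0.1 + l / 1e3))
    laws <- fitLETLaws(fits)
    expect_equal(laws@muSlope, 0, tolerance = 1e-12)
    expect_equal(laws@muIntercept, 0.8, tolerance = 1e-12)
    expect_error(fitLETLaws(fits[1:2]), "3 or more")
})

test_that("fociDensity is a unit-mass symmetric Gaussian", {
    laws <- defaultLETLaws()
    mu <- muAt(laws, 60); sg <- sigmaAt(laws, 60)
    expect_equal(fociDensity(mu, 60, laws), 1 / (sqrt(2 * pi) * sg))
    expect_equal(fociDensity(mu, 60, laws), 0.8568348, tolerance = 1e-6)
    expect_equal(fociDensity(mu + 0.3, 60, laws),
                 fociDensity(mu - 0.3, 60, laws))
    mass <- integrate(fociDensity, mu - 8 * sg, mu + 8 * sg,
                      let = 60, laws = laws, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
    badLaws <- LETLaws(0, 1, 0.00724, 0.0312)
    expect_error(fociDensity(1, -200, badLaws), "non-positive")
})

test_that("clusteringProbability matches frozen quadrature values", {
    laws <- defaultLETLaws()
    ## values frozen from quadratureTail() of the density at the reference
    ## laws: p(0.7 | LET 60) and p(0.7 | LET 13)
    expect_equal(clusteringProbability(0.7, 60, laws), 0.7890891,
                 tolerance = 1e-6)
    expect_equal(clusteringProbability(0.7, 13, laws), 0.001634346,
                 tolerance = 1e-5)
    expect_equal(clusteringProbability(muAt(laws, 40), 40, laws), 0.5)
})

test_that("clusteringProbability is monotone in threshold and LET", {
    laws <- defaultLETLaws()
    grid <- seq(0, 3, by = 0.05)
    for (l in letPanel) {
        p <- clusteringProbability(grid, l, laws)
        expect_true(all(diff(p) <= 0))
        expect_true(all(p >= 0 & p <= 1))
    }
    pAcross <- clusteringProbability(0.7, letPanel, laws)
    expect_true(all(diff(pAcross) > 0))
})

test_that("empiricalProbability counts inclusively", {
    s <- mkSample(c(0.2, 0.7, 1.5))
    expect_equal(empiricalProbability(s, 0.7), 2 / 3)
    expect_equal(empiricalProbability(s, 0), 1)
    expect_equal(empiricalProbability(s, 99), 0)
    expect_error(empiricalProbability(mkSample(numeric(0)), 0.7), "empty")
})
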