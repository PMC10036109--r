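test_that("generators are byte-identical under a fixed seed", {
    cfg <- GeneratorConfig(seed = 1234)
    expect_identical(genFociTable(cfg), genFociTable(cfg))
    expect_identical(genOccupancyTable(cfg), genOccupancyTable(cfg))
    expect_identical(genClonogenicTable(cfg), genClonogenicTable(cfg))
    cfg2 <- GeneratorConfig(seed = 1235)
    expect_false(identical(genFociTable(cfg), genFociTable(cfg2)))
})

test_that("generators do not disturb the caller's RNG stream", {
    set.seed(77); a <- runif(1)
    set.seed(77); invisible(genFociTable(GeneratorConfig(seed = 3)))
    expect_identical(runif(1), a)
})

test_that("max-volume draws follow the configured normal law", {
    ## unhit coefficient 0 so every nucleus contributes; large n at LET 60
    cfg <- GeneratorConfig(letValues = 60, nNucleiPerLET = 10000L,
                           trueUnhitCoefficient = 0, seed = 8,
                           fociCountScale = 1)
    s <- extractMaxVolumes(genFociTable(cfg))[["60"]]
    expect_length(s@values, 10000L)
    ## the generator truncates below the exclusion floor, so the oracle is
    ## the left-truncated normal: moments via the hazard at the floor
    alpha <- (0.01 - 1.074) / 0.4656
    lam <- dnorm(alpha) / (1 - pnorm(alpha))
    meanTr <- 1.074 + 0.4656 * lam
    sdTr <- 0.4656 * sqrt(1 + alpha * lam - lam^2)
    se <- sdTr / sqrt(10000)
    expect_lt(abs(mean(s@values) - meanTr), 3 * se)
    expect_lt(abs(sd(s@values) - sdTr), 3 * se)
    ## truncation is a small correction: still near the untruncated mean
    expect_equal(mean(s@values), 1.074, tolerance = 0.02)
    expect_true(all(s@values >= cfg@exclusionFloor))
})

test_that("zero unhit coefficient yields no unhit cells anywhere", {
    cfg <- GeneratorConfig(seed = 10, trueUnhitCoefficient = 0)
    foci <- genFociTable(cfg)
    s <- extractMaxVolumes(foci)
    expect_true(all(vapply(s, function(x) length(x@values), numeric(1))
                    == cfg@nNucleiPerLET))
    occ <- genOccupancyTable(cfg)
    d <- tableData(occ)
    expect_true(all(d$signal_area / d$nucleus_area >= 0.01))
})

test_that("generated unhit fraction converges to the quadratic law", {
    cfg <- GeneratorConfig(letValues = 100, nCellsOccupancy = 100000L,
                           seed = 6)
    fr <- unhitFraction(genOccupancyTable(cfg), 100)
    truth <- (0.0618 * 100)^2 / 100  # 0.381924
    se <- sqrt(truth * (1 - truth) / 1e5)
    expect_lt(abs(fr - truth), 3 * se)
})

test_that("LET beyond the unhit law's domain is rejected", {
    cfg <- GeneratorConfig(letValues = c(60, 200), seed = 2)
    expect_error(genFociTable(cfg), "domain")
    expect_error(genOccupancyTable(cfg), "domain")
    expect_error(genClonogenicTable(cfg), "domain")
})

test_that("true surviving fraction matches the quadrature oracle", {
    cfg <- GeneratorConfig(seed = 1)
    ## SF(L) = 1 - R_hit(L) * p(0.7 | L), evaluated independently
    for (l in c(13, 60, 100)) {
        rhit <- 1 - (0.0618 * l)^2 / 100
        p <- quadratureTail(0.7, 0.0158 * l + 0.126, 0.00724 * l + 0.0312)
        expect_equal(trueSurvivingFraction(cfg, l), 1 - rhit * p,
                     tolerance = 1e-9)
    }
    expect_equal(trueSurvivingFraction(cfg, 100), 0.4384249,
                 tolerance = 1e-6)
})

test_that("huge lethal threshold gives full survival", {
    cfg <- GeneratorConfig(seed = 14, trueLethalThreshold = 1e6,
                           replicates = 10L)
    expect_equal(trueSurvivingFraction(cfg, cfg@letValues),
                 rep(1, length(cfg@letValues)))
    d <- tableData(genClonogenicTable(cfg))
    irr <- d[!d$control, ]
    expect_equal(mean(irr$colonies),
                 cfg@nSeeded * cfg@platingEfficiency, tolerance = 0.02)
})

test_that("clonogenic colony means converge to PE * SF", {
    cfg <- GeneratorConfig(letValues = 100, seed = 15, nSeeded = 5000L,
                           replicates = 50L)
    d <- tableData(genClonogenicTable(cfg))
    sfHat <- mean(d$colonies[!d$control]) / cfg@nSeeded /
        cfg@platingEfficiency
    expect_equal(sfHat, trueSurvivingFraction(cfg, 100), tolerance = 0.02)
})
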