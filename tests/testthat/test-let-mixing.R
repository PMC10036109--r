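test_that("single-component composition reproduces the mono profile", {
    mono <- genMonoDepthProfile()
    z <- 120  # a grid depth
    spec <- SOBPSpec(weights = 1, shifts = 0, width = 30, evalDepth = z)
    sp <- composeSpectrum(mono, spec)
    i <- which(abs(mono@depth - z) < 1e-9)
    expect_equal(sp@let, mono@letMono[i])
    expect_equal(sp@dose, mono@doseMono[i])
})

test_that("duplicated equal-weight components leave the average unchanged", {
    mono <- genMonoDepthProfile()
    one <- composeSpectrum(mono, SOBPSpec(1, 0, 30, 120))
    two <- composeSpectrum(mono, SOBPSpec(c(0.5, 0.5), c(0, 0), 30, 120))
    expect_equal(doseAveragedLET(two), doseAveragedLET(one))
})

test_that("off-grid depths interpolate linearly and out-of-grid errors", {
    mono <- genMonoDepthProfile()
    sp <- composeSpectrum(mono, SOBPSpec(1, 0, 30, 120.05))
    i <- which(abs(mono@depth - 120) < 1e-9)
    expect_equal(sp@let, mean(mono@letMono[i + 0:1]))
    expect_error(composeSpectrum(mono, SOBPSpec(1, 0, 30, 1e5)),
                 "outside")
})

test_that("the overkill cap clips LET and preserves dose", {
    sp <- LETSpectrum(c(120, 99, 100.1), c(0.2, 0.3, 0.5))
    capped <- capSpectrum(sp)
    expect_equal(capped@let, c(100, 99, 100))
    expect_equal(capped@dose, sp@dose)
    empty <- capSpectrum(LETSpectrum(numeric(0), numeric(0)))
    expect_length(empty@let, 0)
})

test_that("dose-averaged LET is the dose-weighted mean", {
    expect_equal(doseAveragedLET(LETSpectrum(c(50, 100), c(0.5, 0.5))), 75)
    expect_equal(doseAveragedLET(LETSpectrum(42, 3)), 42)
    capped <- capSpectrum(LETSpectrum(c(90, 120), c(0.5, 0.5)))
    expect_equal(doseAveragedLET(capped), 95)
    expect_error(doseAveragedLET(LETSpectrum(c(50), c(0))), "positive")
})

test_that("dose-averaged LET is scale- and permutation-invariant and bounded", {
    set.seed(9)
    for (i in 1:25) {
        n <- sample(2:8, 1)
        sp <- LETSpectrum(runif(n, 10, 150), runif(n, 0, 2))
        lm1 <- doseAveragedLET(sp)
        expect_equal(doseAveragedLET(LETSpectrum(sp@let, sp@dose * 7)), lm1)
        o <- sample(n)
        expect_equal(doseAveragedLET(LETSpectrum(sp@let[o], sp@dose[o])),
                     lm1)
        expect_gte(lm1, min(sp@let)); expect_lte(lm1, max(sp@let))
        expect_lte(doseAveragedLET(capSpectrum(sp)), 100)
    }
})

test_that("mono depth profiles have the documented grid and shape", {
    mono <- genMonoDepthProfile()
    expect_equal(diff(mono@depth), rep(0.1, length(mono@depth) - 1),
                 tolerance = 1e-9)
    expect_equal(mono@letMono[1], 13)
    peakIdx <- which.max(mono@doseMono)
    expect_equal(mono@depth[peakIdx], 150, tolerance = 0.2)
    expect_gte(mono@letMono[peakIdx], mono@letMono[1])
    ## LET monotone non-decreasing up to the peak; dose single-peaked
    expect_true(all(diff(mono@letMono[seq_len(peakIdx)]) >= 0))
    expect_true(all(diff(mono@doseMono[seq_len(peakIdx)]) > 0))
    expect_true(all(diff(mono@doseMono[peakIdx:length(mono@doseMono)]) < 0))
    expect_true(all(mono@doseMono >= 0))
    expect_error(genMonoDepthProfile(range = -5), "positive")
})

test_that("SOBP specs span the width with normalized weights", {
    mono <- genMonoDepthProfile()
    for (w in c(30, 60, 120)) {
        spec <- genSOBPSpec(w, mono)
        expect_equal(max(spec@shifts) - min(spec@shifts), w)
        expect_equal(sum(spec@weights), 1)
        expect_true(all(spec@weights >= 0))
    }
    expect_error(genSOBPSpec(-10), "positive")
})

test_that("composed SOBP dose is flat across the plateau", {
    mono <- genMonoDepthProfile()
    peak <- mono@depth[which.max(mono@doseMono)]
    for (w in c(30, 90)) {
        spec <- genSOBPSpec(w, mono)
        z <- seq(peak - w, peak, by = 1)
        d <- sobpDose(mono, spec, z)
        expect_lt(max(abs(d / mean(d) - 1)), 0.05)
        ## the spectrum's total dose matches the mid-plateau composed dose
        sp <- composeSpectrum(mono, spec)
        expect_equal(totalDose(sp), mean(d), tolerance = 0.05)
    }
})

test_that("SOBP construction is deterministic", {
    mono <- genMonoDepthProfile()
    expect_identical(genSOBPSpec(50, mono), genSOBPSpec(50, mono))
})
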