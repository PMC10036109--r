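## Shared fixtures for the test suite. Everything is generated in code.

letPanel <- c(13, 20, 40, 60, 80, 100)

## Independent quadrature oracle for the upper-tail clustering probability:
## integrates the Gaussian density written out explicitly, so it shares no
## code with the closed-form implementation under test.
quadratureTail <- function(vth, mu, sigma) {
    f <- function(v) exp(-(v - mu)^2 / (2 * sigma^2)) /
        (sqrt(2 * pi) * sigma)
    integrate(f, vth, Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

## Build a MaxVolumeSample directly from values.
mkSample <- function(values, let = 60, nExcluded = 0L)
    new("MaxVolumeSample", let = let, values = values,
        nExcluded = as.integer(nExcluded))

## Build a GaussianFit carrying exact (mu, sigma) at a LET.
mkFit <- function(let, mu, sigma)
    new("GaussianFit", let = let, mu = mu, sigma = sigma, binWidth = 0.1,
        n = 30L, sse = 0)

## The 500-replicate law-recovery experiment, cached so the mu-law and
## sigma-law checks share one computation. Returns the mean fitted
## coefficients (muSlope, muIntercept, sigmaSlope, sigmaIntercept).
lawRecoveryMeans <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        set.seed(123)
        seeds <- sample.int(2^31 - 2, 500)
        res <- vapply(seeds, function(s) {
            cfg <- GeneratorConfig(seed = s, trueUnhitCoefficient = 0)
            fits <- lapply(extractMaxVolumes(genFociTable(cfg)),
                           fitMaxVolumeGaussian)
            laws <- fitLETLaws(fits)
            c(laws@muSlope, laws@muIntercept, laws@sigmaSlope,
              laws@sigmaIntercept)
        }, numeric(4))
        cache <<- rowMeans(res)
        cache
    }
})
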