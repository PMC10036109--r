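## Internal helpers.

## Evaluate expr under a local RNG stream seeded from `seed`, restoring the
## caller's RNG state afterwards. Generators derive per-stream seeds from the
## master seed so that each generated table is reproducible independently of
## call order.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

## Deterministic substream seed: keeps results below 2^31 - 1 so the value
## is always a valid integer seed.
substreamSeed <- function(seed, stream) {
    as.integer((as.double(seed) * 7919 + stream * 104729) %% 2147483647)
}

stopifnot1 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
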