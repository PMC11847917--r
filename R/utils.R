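# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded helpers do not perturb user code.
withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    if (had) {
        old <- get(".Random.seed", envir = genv, inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Derive a reproducible per-stage seed from one global seed; stage names are
# hashed by their character codes so every pipeline stage consumes an
# independent, documented stream. Kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629)
}

# Row standard deviations with the n-1 denominator, without copying rows.
rowSdsFast <- function(x) matrixStats::rowSds(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
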