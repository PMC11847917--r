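# Independent oracles, deliberately written from first principles so they
# share no code path with the package implementation.

# Mid-ranks (average rank for ties) computed by counting comparisons.
oracleMidRank <- function(x) {
    vapply(seq_along(x), function(i)
        sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, 0)
}

# Pearson correlation from the explicit sum formula.
oraclePearson <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
}

oracleSpearman <- function(x, y)
    oraclePearson(oracleMidRank(x), oracleMidRank(y))

# Benjamini-Hochberg step-up computed directly from its definition.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# All permutations of 1..n by recursive insertion (independent of pracma).
oraclePerms <- function(n) {
    if (n == 1L) return(list(1L))
    sub <- oraclePerms(n - 1L)
    out <- list()
    for (p in sub)
        for (pos in seq_len(n))
            out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    out
}

# A small cohort used across tests where the exact scale does not matter.
quickConfig <- function(...) {
    args <- list(...)
    defaults <- list(nTissues = 2L, samplesPerTissue = 50L, nGenes = 40L,
                     nPanAgeGenes = 1L, seed = 1L)
    do.call(SimConfig, utils::modifyList(defaults, args))
}
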