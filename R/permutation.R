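#' Donor-age permutation test for one gene
#'
#' Assesses the observed Pearson correlation between a gene's expression and
#' donor age against the null distribution obtained by reshuffling the age
#' vector (expression held fixed) and recomputing the correlation. The
#' empirical p-value is the proportion of permuted correlations at least as
#' large as the observed one (`alternative = "greater"`, the default; ties
#' count as exceedance); `"less"` mirrors with `<=`, and `"two_sided"`
#' compares absolute values. Because a raw proportion can be exactly zero,
#' the add-one estimate `(nGe + 1) / (nPerm + 1)` is reported alongside.
#'
#' When the number of distinct orderings is small (`n! <= 10000`) and
#' `exact = "auto"` (or `"always"`), all permutations are enumerated instead
#' of sampled, giving the exact permutation p-value; `n_perm` is then `n!`
#' and no seed is consumed.
#'
#' @param expression numeric vector of one gene's expression (>= 3 values,
#'   non-constant).
#' @param ages numeric vector of equal length, non-constant.
#' @param nPerm number of Monte-Carlo permutations (default 1000).
#' @param seed integer seed for the Monte-Carlo draw.
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`.
#' @param exact `"auto"` (enumerate when `n! <= 10000`), `"never"` or
#'   `"always"`.
#' @param geneId,tissue labels stamped on the result row.
#' @return a [PermutationResult-class] with one row.
#' @examples
#' set.seed(1)
#' age <- runif(12, 20, 70)
#' permutationTest(2 * age + rnorm(12, sd = 5), age, nPerm = 500, seed = 4)
#' @export
permutationTest <- function(expression, ages, nPerm = 1000L, seed = 1L,
                            alternative = c("greater", "less", "two_sided"),
                            exact = c("auto", "never", "always"),
                            geneId = "gene", tissue = NA_character_) {
    alternative <- match.arg(alternative)
    exact <- match.arg(exact)
    n <- length(expression)
    if (length(ages) != n)
        stopf("'expression' and 'ages' must have equal length")
    if (n < 3L)
        stopf("need at least 3 observations")
    if (any(!is.finite(expression)) || any(!is.finite(ages)))
        stopf("inputs must be finite")
    if (sd(expression) == 0)
        stopf("zero-variance expression")
    if (sd(ages) == 0)
        stopf("no age variance")
    rObs <- cor(expression, ages)
    doExact <- exact == "always" ||
        (exact == "auto" && factorial(n) <= 10000)
    if (doExact) {
        P <- pracma::perms(seq_len(n))
        rPerm <- apply(P, 1L, function(p) cor(expression, ages[p]))
        nPerm <- nrow(P)
        seedUsed <- NA_integer_
    } else {
        rPerm <- withSeed(seed, {
            vapply(seq_len(nPerm), function(i)
                cor(expression, ages[sample.int(n)]), 0)
        })
        seedUsed <- as.integer(seed)
    }
    nGe <- switch(alternative,
        greater = sum(rPerm >= rObs),
        less = sum(rPerm <= rObs),
        two_sided = sum(abs(rPerm) >= abs(rObs)))
    tab <- data.frame(gene_id = geneId, tissue = tissue, r_obs = rObs,
                      n_perm = as.integer(nPerm), n_ge = as.integer(nGe),
                      p_emp = nGe / nPerm,
                      p_emp_plus1 = (nGe + 1) / (nPerm + 1),
                      stringsAsFactors = FALSE)
    new("PermutationResult", table = tab, alternative = alternative,
        seed = if (is.na(seedUsed)) NA_integer_ else seedUsed,
        exact = doExact)
}

#' Permutation screen over all genes of one tissue
#'
#' Applies the donor-age permutation test to every row of a gene-by-sample
#' matrix using one shared permutation schedule: the same `nPerm` reshuffles
#' of the age vector are applied to all genes, which lets the permuted
#' correlations be computed as a single standardized matrix product and
#' leaves each gene's marginal null distribution unchanged. Genes with zero
#' expression variance are reported with missing statistics.
#'
#' @param x gene-by-sample numeric matrix.
#' @param ages numeric vector of donor ages aligned to columns (or named by
#'   sample id).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the schedule.
#' @param alternative as in [permutationTest()].
#' @param tissue tissue label stamped on the rows.
#' @return a [PermutationResult-class] with one row per gene.
#' @export
batchPermutationScreen <- function(x, ages, nPerm = 1000L, seed = 1L,
                                   alternative = c("greater", "less",
                                                   "two_sided"),
                                   tissue = NA_character_) {
    alternative <- match.arg(alternative)
    x <- as.matrix(x)
    n <- ncol(x)
    if (n < 3L)
        stopf("need at least 3 samples")
    if (!is.null(names(ages)) && !is.null(colnames(x)))
        ages <- ages[colnames(x)]
    if (length(ages) != n)
        stopf("'ages' must align with the matrix columns")
    if (sd(ages) == 0)
        stopf("no age variance")
    nPerm <- as.integer(nPerm)
    s <- rowSdsFast(x)
    ok <- s > 0
    ac <- (ages - mean(ages)) / sd(ages)
    Xc <- (x - rowMeans(x)) / ifelse(s > 0, s, 1)
    rObs <- as.vector(Xc %*% ac) / (n - 1)
    rObs[!ok] <- NA_real_
    A <- withSeed(seed, {
        vapply(seq_len(nPerm), function(i) ac[sample.int(n)], numeric(n))
    })
    Rperm <- (Xc %*% A) / (n - 1)
    nGe <- switch(alternative,
        greater = rowSums(Rperm >= rObs),
        less = rowSums(Rperm <= rObs),
        two_sided = rowSums(abs(Rperm) >= abs(rObs)))
    nGe[!ok] <- NA_integer_
    ids <- rownames(x)
    if (is.null(ids))
        ids <- as.character(seq_len(nrow(x)))
    tab <- data.frame(gene_id = ids, tissue = tissue, r_obs = rObs,
                      n_perm = nPerm, n_ge = as.integer(nGe),
                      p_emp = nGe / nPerm,
                      p_emp_plus1 = (nGe + 1) / (nPerm + 1),
                      row.names = NULL, stringsAsFactors = FALSE)
    new("PermutationResult", table = tab, alternative = alternative,
        seed = as.integer(seed), exact = FALSE)
}

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult: ", nrow(object@table), " gene(s), ",
        "alternative = ", object@alternative,
        if (object@exact) ", exhaustive enumeration" else
            paste0(", n_perm = ", object@table$n_perm[1L],
                   ", seed = ", object@seed),
        "\n", sep = "")
    print(head(object@table, 5L), row.names = FALSE)
    if (nrow(object@table) > 5L)
        cat("  ... and", nrow(object@table) - 5L, "more rows\n")
})

#' @describeIn permutationTest extract the result table of a
#'   [PermutationResult-class].
#' @param object a [PermutationResult-class].
#' @export
permutationTable <- function(object) {
    stopifnot(is(object, "PermutationResult"))
    object@table
}
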