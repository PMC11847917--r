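#' Median-of-ratios size factors
#'
#' Per-sample library-size factors by the median-of-ratios method: each
#' sample's counts are divided by the per-gene geometric mean over samples
#' (computed on genes with no zero count anywhere), and the sample's factor is
#' the median of those ratios. Factors are rescaled so their geometric mean is
#' exactly 1, which fixes the otherwise arbitrary overall scale.
#'
#' @param x non-negative gene-by-sample count matrix.
#' @return named positive numeric vector of per-sample size factors with
#'   geometric mean 1.
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' computeSizeFactors(m)  # proportional to 1 : 2
#' @export
computeSizeFactors <- function(x) {
    x <- as.matrix(x)
    if (any(x < 0))
        stopf("counts must be non-negative")
    ref <- rowSums(x > 0) == ncol(x)
    if (!any(ref))
        stopf("no reference genes: every gene has a zero count in some sample")
    logGeo <- rowMeans(log(x[ref, , drop = FALSE]))
    logRatio <- log(x[ref, , drop = FALSE]) - logGeo
    sf <- exp(apply(logRatio, 2L, median))
    bad <- !is.finite(sf) | sf <= 0
    if (any(bad))
        stopf("cannot estimate a size factor for sample(s): %s",
              paste(colnames(x)[bad], collapse = ", "))
    sf <- sf / exp(mean(log(sf)))
    setNames(sf, colnames(x))
}

#' Variance-stabilizing log transform
#'
#' Normalizes counts by median-of-ratios size factors and applies
#' `log2(count / sizeFactor + 1)`. The transform is monotone within each
#' sample, so every rank-based downstream statistic (the Spearman screen in
#' particular) is unaffected by its exact shape; it serves to put counts on a
#' roughly homoskedastic log scale for the linear batch-residualization step.
#'
#' @param x gene-by-sample count matrix, or a
#'   [SummarizedExperiment::SummarizedExperiment] with a `"counts"` assay.
#' @param sizeFactors optional precomputed factors from
#'   [computeSizeFactors()], aligned to samples; computed when `NULL`.
#' @param ... unused.
#' @return for a matrix, the transformed matrix; for a SummarizedExperiment,
#'   the object with a `"transformed"` assay added.
#' @examples
#' m <- matrix(c(0, 7, 0, 7), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' vstTransform(m, sizeFactors = c(a = 1, b = 1))
#' @rdname vstTransform
#' @export
setMethod("vstTransform", "matrix", function(x, sizeFactors = NULL, ...) {
    if (any(x < 0))
        stopf("counts must be non-negative")
    if (is.null(sizeFactors))
        sizeFactors <- computeSizeFactors(x)
    if (length(sizeFactors) != ncol(x))
        stopf("'sizeFactors' must supply one factor per sample")
    if (!is.null(names(sizeFactors)) && !is.null(colnames(x)))
        sizeFactors <- sizeFactors[colnames(x)]
    log2(sweep(x, 2L, sizeFactors, `/`) + 1)
})

#' @rdname vstTransform
#' @export
setMethod("vstTransform", "SummarizedExperiment",
    function(x, sizeFactors = NULL, ...) {
    counts <- SummarizedExperiment::assay(x, "counts")
    SummarizedExperiment::assay(x, "transformed") <-
        vstTransform(counts, sizeFactors = sizeFactors)
    x
})

# Treatment-coded dummy columns (first lexicographic level = reference) for
# one categorical covariate; constant covariates yield zero columns.
batchDummies <- function(v, name) {
    f <- factor(v, levels = sort(unique(as.character(v))))
    if (nlevels(f) < 2L)
        return(NULL)
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(name, levels(f)[-1L])
    mm
}

#' Remove categorical batch structure while protecting age
#'
#' Fits, per gene, an ordinary least-squares model containing an intercept,
#' the protected numeric covariates (chronological age by default) and
#' treatment-coded dummies for every categorical batch variable, then
#' subtracts only the fitted batch terms. The intercept and the protected
#' covariates' contributions are retained, so age-related differences are not
#' absorbed by the correction: refitting the same design on the output leaves
#' the age coefficient unchanged and drives every batch coefficient to zero.
#' The fit-and-subtract step is delegated to [limma::removeBatchEffect()]
#' with the batch dummies passed as covariates and the protected design as
#' its `design` argument.
#'
#' Batch variables that are constant across the supplied samples carry no
#' batch variance and are ignored (the output then equals the input).
#'
#' @param x gene-by-sample matrix on the transformed (log) scale, or a
#'   [SummarizedExperiment::SummarizedExperiment] carrying a `"transformed"`
#'   assay.
#' @param samples data.frame of per-sample covariates aligned to the columns
#'   of `x` (matched by `sample_id` when present, positional otherwise).
#' @param batchVars character names of categorical covariates to remove.
#' @param protectVars character names of numeric covariates to protect
#'   (default `"age_years"`).
#' @param byTissue for the SummarizedExperiment method: correct within each
#'   tissue separately (default), matching a per-tissue screening workflow in
#'   which subsites are nested within tissue.
#' @param ... unused.
#' @return same shape as `x`, residualized; the SummarizedExperiment method
#'   adds a `"residualized"` assay.
#' @seealso [limma::removeBatchEffect()]
#' @rdname residualizeBatch
#' @export
setMethod("residualizeBatch", "matrix",
    function(x, samples, batchVars, protectVars = "age_years", ...) {
    samples <- as.data.frame(samples)
    if (!is.null(samples$sample_id) && !is.null(colnames(x))) {
        if (!all(colnames(x) %in% samples$sample_id))
            stopf("samples table does not cover all matrix columns")
        samples <- samples[match(colnames(x), samples$sample_id), ,
                           drop = FALSE]
    }
    if (nrow(samples) != ncol(x))
        stopf("'samples' must have one row per matrix column")
    missing <- setdiff(c(batchVars, protectVars), names(samples))
    if (length(missing))
        stopf("covariate(s) not in samples table: %s",
              paste(missing, collapse = ", "))
    if (length(intersect(batchVars, protectVars)))
        stopf("batch and protected covariates must be disjoint")
    dummies <- lapply(batchVars, function(v) batchDummies(samples[[v]], v))
    dummies <- do.call(cbind, dummies[!vapply(dummies, is.null, TRUE)])
    if (is.null(dummies) || ncol(dummies) == 0L)
        return(x)
    prot <- as.matrix(samples[protectVars])
    storage.mode(prot) <- "double"
    if (anyNA(prot) || any(!is.finite(prot)))
        stopf("protected covariates must be finite")
    design <- cbind(`(Intercept)` = 1, prot)
    full <- cbind(design, dummies)
    if (qr(full)$rank < ncol(full))
        stopf(paste0("design is rank-deficient: batch variable(s) are ",
                     "collinear with the intercept/protected covariates ",
                     "(e.g. a batch level confounded with a single age value)"))
    limma::removeBatchEffect(x, covariates = dummies, design = design)
})

#' @rdname residualizeBatch
#' @export
setMethod("residualizeBatch", "SummarizedExperiment",
    function(x, batchVars = c("sex", "subsite"), protectVars = "age_years",
             byTissue = TRUE, ...) {
    mat <- SummarizedExperiment::assay(x, "transformed")
    samples <- as.data.frame(SummarizedExperiment::colData(x))
    out <- mat
    if (byTissue && !is.null(samples$tissue)) {
        for (t in unique(samples$tissue)) {
            j <- which(samples$tissue == t)
            out[, j] <- residualizeBatch(mat[, j, drop = FALSE],
                                         samples[j, , drop = FALSE],
                                         batchVars = batchVars,
                                         protectVars = protectVars)
        }
    } else {
        out <- residualizeBatch(mat, samples, batchVars = batchVars,
                                protectVars = protectVars)
    }
    SummarizedExperiment::assay(x, "residualized") <- out
    x
})

#' Top variable genes
#'
#' Genes ordered by decreasing per-gene variance, ties broken by gene id
#' (lexicographic) so the selection is reproducible. This is the gene
#' selection conventionally fed to a PCA diagnostic of batch structure.
#'
#' @param x gene-by-sample numeric matrix with gene ids as rownames, or a
#'   [SummarizedExperiment::SummarizedExperiment] (uses the `"transformed"`
#'   assay when present, else the first assay).
#' @param n number of genes to return (default 1000).
#' @param ... unused.
#' @return character vector of `n` gene ids.
#' @rdname topVariableGenes
#' @export
setMethod("topVariableGenes", "matrix", function(x, n = 1000L, ...) {
    n <- as.integer(n)
    if (n > nrow(x))
        stopf("'n' (%d) exceeds the number of genes (%d)", n, nrow(x))
    ids <- rownames(x)
    if (is.null(ids))
        ids <- as.character(seq_len(nrow(x)))
    v <- rowSdsFast(x)^2
    ids[order(-v, ids)][seq_len(n)]
})

#' @rdname topVariableGenes
#' @export
setMethod("topVariableGenes", "SummarizedExperiment",
    function(x, n = 1000L, ...) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if ("transformed" %in% nm) "transformed" else 1L
    topVariableGenes(SummarizedExperiment::assay(x, a), n = n)
})

#' Collapse samples to per-group medians
#'
#' Replaces each group of samples by its per-gene median (the mean of the two
#' central values for even group sizes), one output column per group label in
#' order of first appearance. Used to collapse replicate samples per age group
#' before correlating expression with age in designs with few, replicated age
#' points.
#'
#' @param x gene-by-sample numeric matrix.
#' @param groups vector of group labels, one per column of `x`.
#' @return gene-by-group matrix of medians.
#' @examples
#' m <- matrix(c(1, 5, 100, 2, 4, 6), 1, dimnames = list("g1", paste0("s", 1:6)))
#' collapseByGroupMedian(m, c("a", "a", "a", "b", "b", "b"))
#' @export
collapseByGroupMedian <- function(x, groups) {
    x <- as.matrix(x)
    if (length(groups) != ncol(x))
        stopf("'groups' must assign a label to every sample")
    groups <- as.character(groups)
    if (anyNA(groups) || any(!nzchar(groups)))
        stopf("empty or missing group label")
    labs <- unique(groups)  # first-appearance order
    out <- vapply(labs, function(g)
        matrixStats::rowMedians(x[, groups == g, drop = FALSE]),
        numeric(nrow(x)))
    out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), labs))
    out
}
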