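#' Pairwise sample-correlation matrix
#'
#' Pearson correlation over genes for every pair of sample expression
#' profiles; the basis of the MAD-scaled sample-quality statistic
#' ([qcDStatistic()]).
#'
#' @param x gene-by-sample numeric matrix (>= 3 samples), or a
#'   [SummarizedExperiment::SummarizedExperiment] (first assay).
#' @return symmetric samples x samples correlation matrix with unit diagonal.
#' @export
pairwiseSampleCorrelations <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, 1L)
    x <- as.matrix(x)
    if (ncol(x) < 3L)
        stopf("need at least 3 samples")
    s <- matrixStats::colSds(x)
    if (any(s == 0))
        stopf("zero-variance expression profile for sample(s): %s",
              paste(colnames(x)[s == 0], collapse = ", "))
    cc <- cor(x)
    diag(cc) <- 1
    cc
}

#' MAD-scaled correlation-profile quality statistic
#'
#' For each sample i, let `r_i` be the mean of its correlations to all other
#' samples and `r` the mean of all the `r_k`. The quality statistic is
#'
#'   `D_i = |r_i - r| / median_k(|r_k - r|)`,
#'
#' the deviation of a sample's mean correlation from the cohort centre in
#' units of the median absolute deviation of those means. Large `D_i` marks a
#' sample whose expression profile decorrelates from the rest of the cohort;
#' samples with `D > 5` are conventionally removed. When every sample has an
#' identical mean correlation the MAD is zero and all `D_i` are defined as 0
#' (a perfectly homogeneous batch passes QC).
#'
#' @param corr symmetric correlation matrix from
#'   [pairwiseSampleCorrelations()] or [simulateSampleCorrMatrix()].
#' @return data.frame with columns `sample_id`, `r_i`, `D_i`.
#' @seealso [flagLowQuality()]
#' @examples
#' cm <- simulateSampleCorrMatrix(30, nDegraded = 2, seed = 1)
#' head(flagLowQuality(qcDStatistic(cm)))
#' @export
qcDStatistic <- function(corr) {
    corr <- as.matrix(corr)
    n <- nrow(corr)
    if (n < 3L || ncol(corr) != n)
        stopf("'corr' must be a square matrix with >= 3 samples")
    if (max(abs(corr - t(corr))) > 1e-12)
        stopf("'corr' must be symmetric")
    ids <- rownames(corr)
    if (is.null(ids))
        ids <- sprintf("sample%d", seq_len(n))
    ri <- (rowSums(corr) - diag(corr)) / (n - 1)
    rbar <- mean(ri)
    dev <- abs(ri - rbar)
    md <- median(dev)
    D <- if (md == 0) rep(0, n) else dev / md
    data.frame(sample_id = ids, r_i = ri, D_i = D,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag low-quality samples by the D statistic
#'
#' Marks samples whose quality statistic strictly exceeds the threshold
#' (`D > threshold`; a sample sitting exactly at the threshold is kept).
#'
#' @param records data.frame from [qcDStatistic()].
#' @param threshold positive flagging threshold (default 5).
#' @return `records` with a logical `flagged` column appended.
#' @export
flagLowQuality <- function(records, threshold = 5) {
    if (!is.data.frame(records) || is.null(records$D_i))
        stopf("'records' must be the output of qcDStatistic()")
    if (!isTRUE(threshold > 0))
        stopf("'threshold' must be > 0")
    records$flagged <- records$D_i > threshold
    records
}

#' Per-gene expression outlier mask
#'
#' Single-pass 3-SD rule: an observation is retained when it lies within
#' `nSd` sample standard deviations (n-1 denominator) of the mean, both
#' computed once on the full input vector (no iteration). A zero-variance
#' vector retains everything.
#'
#' @param values numeric vector of one gene's expression (>= 3 finite values).
#' @param nSd number of standard deviations (default 3).
#' @return logical vector, `TRUE` = retained.
#' @examples
#' expressionOutlierMask(c(0, 0, 0, 0, 100))   # all retained: sd is large
#' @export
expressionOutlierMask <- function(values, nSd = 3) {
    if (length(values) < 3L || any(!is.finite(values)))
        stopf("'values' must hold at least 3 finite values")
    s <- sd(values)
    if (s == 0)
        return(rep(TRUE, length(values)))
    abs(values - mean(values)) <= nSd * s
}
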