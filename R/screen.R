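#' Draw Leave-Half-Out resampling folds
#'
#' Draws `k` independent random subsets of `floor(fraction * n)` samples each,
#' without replacement within a subset, from one tissue's samples. The
#' subsets deliberately overlap (they are redraws, not a partition): the
#' screen computes a rank correlation on every subset and averages, which
#' damps the influence of any individual sample.
#'
#' @param sampleIds character vector of the tissue's sample ids (n >= 4).
#' @param k number of folds (default 10).
#' @param fraction fraction of samples per fold, in `(0, 1]` (default 0.5;
#'   `fraction = 1` reduces every fold to the full sample set).
#' @param seed integer seed; folds are reproducible from it.
#' @param tissue optional tissue label carried into the result.
#' @return a [FoldSpec-class].
#' @examples
#' fs <- makeLHOFolds(sprintf("s%03d", 1:100), k = 10, seed = 3)
#' lengths(fs@folds)
#' @export
makeLHOFolds <- function(sampleIds, k = 10L, fraction = 0.5, seed = 1L,
                         tissue = NA_character_) {
    sampleIds <- as.character(sampleIds)
    n <- length(sampleIds)
    if (anyDuplicated(sampleIds))
        stopf("'sampleIds' must be unique")
    if (n < 4L)
        stopf("need at least 4 samples to resample")
    if (!isTRUE(fraction > 0 && fraction <= 1))
        stopf("'fraction' must lie in (0, 1]")
    k <- as.integer(k)
    if (k < 1L)
        stopf("'k' must be >= 1")
    m <- floor(fraction * n)
    if (m < 3L)
        stopf("fold size floor(%g * %d) = %d is below 3; a correlation needs at least 3 points",
              fraction, n, m)
    folds <- withSeed(seed,
        lapply(seq_len(k), function(i) sample(sampleIds, m)))
    new("FoldSpec", tissue = as.character(tissue), k = k,
        fraction = as.numeric(fraction), seed = as.integer(seed),
        folds = folds)
}

setMethod("show", "FoldSpec", function(object) {
    cat("FoldSpec: ", object@k, " folds of ",
        length(object@folds[[1L]]), " samples (fraction ", object@fraction,
        ", seed ", object@seed, ")",
        if (!is.na(object@tissue)) paste0(" for ", object@tissue), "\n",
        sep = "")
})

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank).
#' Returns `NA` -- not 0 -- when either vector has no rank variance, so a
#' constant gene or a constant-age subset is recorded as missing rather than
#' as evidence of no association.
#'
#' @param ages numeric vector.
#' @param expression numeric vector of equal length (>= 3).
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearmanRho <- function(ages, expression) {
    if (length(ages) != length(expression))
        stopf("'ages' and 'expression' must have equal length")
    if (length(ages) < 3L)
        stopf("need at least 3 observations")
    if (any(!is.finite(ages)) || any(!is.finite(expression)))
        stopf("inputs must be finite")
    ra <- rank(ages)
    re <- rank(expression)
    if (sd(ra) == 0 || sd(re) == 0)
        return(NA_real_)
    cor(ra, re)
}

# Vectorized mid-rank Spearman of every row of `m` against `y`.
# Rows with zero rank variance yield NA.
rowSpearman <- function(m, y) {
    R <- matrixStats::rowRanks(m, ties.method = "average")
    ry <- rank(y)
    ryc <- ry - mean(ry)
    deny <- sum(ryc^2)
    Rc <- R - rowMeans(R)
    den <- sqrt(rowSums(Rc^2) * deny)
    num <- as.vector(Rc %*% ryc)
    out <- ifelse(den > 0, num / den, NA_real_)
    out
}

#' Per-fold Spearman correlations with outlier exclusion
#'
#' The per-tissue core of the screen. For every gene and every fold: apply
#' the single-pass `outlierSD`-SD exclusion ([expressionOutlierMask()]) to
#' the gene's expression within the fold's samples, drop the masked samples
#' (their ages are dropped pairwise), and compute the mid-rank Spearman
#' correlation between the retained expression values and donor age. A fold
#' is recorded as missing for a gene when fewer than 3 samples remain or the
#' retained values carry no rank variance; a fold whose ages are constant is
#' missing for every gene. The per-gene summary is the mean over non-missing
#' folds.
#'
#' The outlier mask is computed within each fold on the same expression layer
#' that is correlated, and is a single pass (not iterated).
#'
#' @param x gene-by-sample numeric matrix whose columns cover all fold
#'   sample ids (typically the residualized layer).
#' @param ages named numeric vector of donor ages, names = sample ids (an
#'   unnamed vector is matched positionally to `colnames(x)`).
#' @param folds a [FoldSpec-class] from [makeLHOFolds()].
#' @param outlierSD SD multiple for the exclusion rule (default 3).
#' @param maskOutliers disable the exclusion entirely with `FALSE`.
#' @return a [TissueScreen-class].
#' @seealso [panTissueAggregate()]
#' @export
foldCorrelations <- function(x, ages, folds, outlierSD = 3,
                             maskOutliers = TRUE) {
    stopifnot(is(folds, "FoldSpec"))
    x <- as.matrix(x)
    if (is.null(colnames(x)))
        stopf("'x' must carry sample ids as colnames")
    if (is.null(names(ages))) {
        if (length(ages) != ncol(x))
            stopf("unnamed 'ages' must align with the matrix columns")
        names(ages) <- colnames(x)
    }
    allIds <- unique(unlist(folds@folds))
    if (!all(allIds %in% colnames(x)))
        stopf("matrix columns do not cover all fold sample ids")
    if (!all(allIds %in% names(ages)))
        stopf("'ages' does not cover all fold sample ids")
    G <- nrow(x)
    geneIds <- rownames(x)
    if (is.null(geneIds))
        geneIds <- as.character(seq_len(G))
    k <- folds@k
    rho <- matrix(NA_real_, G, k, dimnames = list(geneIds, paste0("fold", seq_len(k))))
    nUsed <- matrix(0L, G, k, dimnames = dimnames(rho))

    for (j in seq_len(k)) {
        ids <- folds@folds[[j]]
        f <- x[, ids, drop = FALSE]
        af <- ages[ids]
        nS <- length(ids)
        if (maskOutliers) {
            mu <- rowMeans(f)
            s <- rowSdsFast(f)
            keep <- abs(f - mu) <= outlierSD * s
            keep[s == 0, ] <- TRUE
        } else {
            keep <- matrix(TRUE, G, nS)
        }
        nUsed[, j] <- as.integer(rowSums(keep))
        if (sd(af) == 0)
            next  # no age variation: fold missing for every gene
        full <- nUsed[, j] == nS
        if (any(full))
            rho[full, j] <- rowSpearman(f[full, , drop = FALSE], af)
        # lean mid-rank Spearman for genes with masked samples (hot loop)
        part <- which(!full)
        for (g in part) {
            idx <- keep[g, ]
            if (sum(idx) < 3L)
                next
            ra <- rank(af[idx])
            re <- rank(f[g, idx])
            rac <- ra - mean(ra)
            rec <- re - mean(re)
            den <- sqrt(sum(rac^2) * sum(rec^2))
            if (den > 0)
                rho[g, j] <- sum(rac * rec) / den
        }
    }
    mr <- rowMeans(rho, na.rm = TRUE)
    mr[is.nan(mr)] <- NA_real_
    new("TissueScreen", tissue = folds@tissue, foldSpec = folds,
        rho = rho, nUsed = nUsed, meanRho = setNames(mr, geneIds))
}

#' @rdname screen-accessors
#' @export
setMethod("meanRho", "TissueScreen", function(object) object@meanRho)

setMethod("show", "TissueScreen", function(object) {
    cat("TissueScreen", if (!is.na(object@tissue)) object@tissue else "",
        ": ", nrow(object@rho), " genes x ", ncol(object@rho), " folds\n",
        sep = "")
    cat("  mean rho range: ",
        paste(signif(range(object@meanRho, na.rm = TRUE), 3), collapse = " .. "),
        "\n", sep = "")
})

#' Aggregate per-tissue screens into a pan-tissue ranking
#'
#' For every gene, averages the per-tissue mean fold correlations over the
#' tissues where the gene was observed, and ranks genes by descending
#' pan-tissue mean (rank 1 = strongest tissue-independent positive
#' association with age). Ties are broken lexicographically by gene id so the
#' ranking is bit-stable. Genes observed in fewer than `minTissues` tissues
#' are excluded and reported in the `dropped` slot.
#'
#' @param screens list of [TissueScreen-class] objects (one per tissue).
#' @param minTissues minimum tissues a gene must be observed in (default:
#'   all tissues in the run).
#' @return a [PanTissueScreen-class].
#' @export
panTissueAggregate <- function(screens, minTissues = length(screens)) {
    if (length(screens) < 1L)
        stopf("need at least one tissue screen")
    stopifnot(all(vapply(screens, is, TRUE, "TissueScreen")))
    if (!isTRUE(minTissues >= 1))
        stopf("'minTissues' must be >= 1")
    tissues <- vapply(screens, function(s) s@tissue, "")
    if (anyNA(tissues) || anyDuplicated(tissues))
        tissues <- make.unique(ifelse(is.na(tissues),
                                      sprintf("tissue%d", seq_along(screens)),
                                      tissues))
    genes <- sort(unique(unlist(lapply(screens, function(s) names(s@meanRho)))))
    perTissue <- matrix(NA_real_, length(genes), length(screens),
                        dimnames = list(genes, tissues))
    for (i in seq_along(screens)) {
        mr <- screens[[i]]@meanRho
        perTissue[names(mr), i] <- mr
    }
    nObs <- rowSums(!is.na(perTissue))
    keep <- nObs >= minTissues
    dropped <- genes[!keep]
    pm <- rowMeans(perTissue, na.rm = TRUE)
    pm[nObs == 0L] <- NA_real_
    kg <- genes[keep]
    ord <- order(-pm[keep], kg)
    rk <- integer(length(kg))
    rk[ord] <- seq_along(kg)
    new("PanTissueScreen",
        perTissue = perTissue[keep, , drop = FALSE],
        panMeanRho = setNames(pm[keep], kg),
        nTissuesObserved = setNames(as.integer(nObs[keep]), kg),
        rank = setNames(rk, kg),
        direction = setNames(ifelse(pm[keep] < 0, "down", "up"), kg),
        dropped = dropped)
}

#' @rdname screen-accessors
#' @export
setMethod("meanRho", "PanTissueScreen", function(object) object@perTissue)

#' @rdname screen-accessors
#' @export
setMethod("panMeanRho", "PanTissueScreen", function(object) object@panMeanRho)

#' @rdname screen-accessors
#' @export
setMethod("geneRanks", "PanTissueScreen", function(object) object@rank)

setMethod("show", "PanTissueScreen", function(object) {
    cat("PanTissueScreen: ", length(object@panMeanRho), " genes x ",
        ncol(object@perTissue), " tissues",
        if (length(object@dropped))
            paste0(" (", length(object@dropped), " dropped)"), "\n", sep = "")
    top <- names(sort(object@rank))[seq_len(min(3L, length(object@rank)))]
    cat("  top ranked: ",
        paste(sprintf("%s (%.3f)", top, object@panMeanRho[top]),
              collapse = ", "), "\n", sep = "")
})

#' Ranked pan-tissue report table
#'
#' Flattens a [PanTissueScreen-class] into a data.frame sorted by rank, with
#' one column of per-tissue mean Spearman rho per tissue, the pan-tissue
#' mean, the rank and the direction of the association.
#'
#' @param object a [PanTissueScreen-class].
#' @param ... unused.
#' @return data.frame ordered by `rank`.
#' @rdname rankTable
#' @export
setMethod("rankTable", "PanTissueScreen", function(object, ...) {
    if (length(object@panMeanRho) == 0L)
        stopf("empty ranking")
    ord <- order(object@rank)
    out <- data.frame(gene_id = names(object@panMeanRho)[ord],
                      stringsAsFactors = FALSE)
    pt <- object@perTissue[ord, , drop = FALSE]
    colnames(pt) <- paste0("rho_", colnames(pt))
    out <- cbind(out, as.data.frame(pt, row.names = NULL))
    out$n_tissues_observed <- unname(object@nTissuesObserved[ord])
    out$pan_mean_rho <- unname(object@panMeanRho[ord])
    out$rank <- unname(object@rank[ord])
    out$direction <- unname(object@direction[ord])
    rownames(out) <- NULL
    out
})

#' Per-tissue screen table
#'
#' Flattens a [TissueScreen-class] into a data.frame with the per-gene mean
#' correlation, the number of non-missing folds, and a flag for genes whose
#' mean rests on fewer than half the folds.
#'
#' @param object a [TissueScreen-class].
#' @param ... unused.
#' @return data.frame with columns `gene_id`, `tissue`, `mean_rho`,
#'   `n_folds_used`, `low_fold_support`.
#' @rdname rankTable
#' @export
setMethod("rankTable", "TissueScreen", function(object, ...) {
    nf <- rowSums(!is.na(object@rho))
    data.frame(gene_id = names(object@meanRho),
               tissue = object@tissue,
               mean_rho = unname(object@meanRho),
               n_folds_used = as.integer(nf),
               low_fold_support = nf < object@foldSpec@k / 2,
               row.names = NULL, stringsAsFactors = FALSE)
})

#' Non-resampled Pearson screen with BH adjustment
#'
#' The conventional companion to the resampled screen: per tissue, the
#' Pearson correlation between each gene's expression and age over all
#' samples, a two-sided p-value from the t distribution with n - 2 degrees
#' of freedom, and Benjamini-Hochberg adjusted q-values computed within each
#' tissue. Zero-variance genes yield missing `r`, `p` and `q`.
#'
#' @param x gene-by-sample numeric matrix.
#' @param ages numeric vector of donor ages aligned to columns (or named by
#'   sample id).
#' @param tissue tissue label stamped on the rows.
#' @return data.frame with columns `gene_id`, `tissue`, `r`, `p`, `q`.
#' @export
pearsonScreen <- function(x, ages, tissue = NA_character_) {
    x <- as.matrix(x)
    n <- ncol(x)
    if (n < 3L)
        stopf("need at least 3 samples per tissue")
    if (!is.null(names(ages)) && !is.null(colnames(x)))
        ages <- ages[colnames(x)]
    if (length(ages) != n)
        stopf("'ages' must align with the matrix columns")
    if (sd(ages) == 0)
        stopf("no age variance in this tissue")
    s <- rowSdsFast(x)
    ac <- (ages - mean(ages)) / sd(ages)
    r <- as.vector((x - rowMeans(x)) %*% ac) / ((n - 1) * s)
    r[s == 0] <- NA_real_
    r <- pmin(1, pmax(-1, r))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p[abs(r) == 1] <- 0
    q <- p.adjust(p, method = "BH")
    ids <- rownames(x)
    if (is.null(ids))
        ids <- as.character(seq_len(nrow(x)))
    data.frame(gene_id = ids, tissue = tissue, r = r, p = p, q = q,
               row.names = NULL, stringsAsFactors = FALSE)
}
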