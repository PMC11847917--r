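#' Configuration of a synthetic multi-tissue cohort
#'
#' `SimConfig` captures every knob of the negative-binomial cohort simulator:
#' cohort geometry (tissues, samples, genes), the planted age signal (how many
#' genes trend with age in all tissues or in a single tissue, and how strongly),
#' the nuisance structure (per-gene sex and anatomical-subsite effects), the
#' count noise model (baseline expression range and NB dispersion), a rate of
#' injected 10x outlier entries, and the RNG seed.
#'
#' Effect sizes are on the natural-log scale of the NB mean and multiply the
#' standardized donor age, so `betaAgePan = 0.3` means one standard deviation
#' of age shifts the expected count of a pan-age gene by `exp(0.3)`-fold.
#'
#' @slot nTissues number of tissues simulated.
#' @slot samplesPerTissue one count, or a `c(min, max)` range sampled per tissue.
#' @slot ageRange donor age range in years, `c(min, max)`.
#' @slot nGenes total genes.
#' @slot nPanAgeGenes genes carrying the age effect in every tissue.
#' @slot nTissueSpecificAgeGenes genes carrying an age effect in exactly one tissue.
#' @slot betaAgePan log-fold change per standardized-age unit for pan-age genes.
#' @slot betaAgeSpecific same units, for tissue-specific age genes.
#' @slot sexEffectSD SD of the per-gene log-scale sex effect.
#' @slot subsiteLevels anatomical subsites per tissue.
#' @slot subsiteEffectSD SD of per-gene, per-subsite log-scale effects.
#' @slot baselineLogMeanRange range of per-gene baseline log mean counts.
#' @slot dispersion NB dispersion (variance = mu + dispersion * mu^2), > 0.
#' @slot outlierRate fraction of count entries multiplied by 10, in [0, 0.05).
#' @slot seed integer RNG seed.
#'
#' @seealso [SimConfig()] for the user constructor, [simulateCohort()].
#' @export
setClass("SimConfig", representation(
    nTissues = "integer",
    samplesPerTissue = "integer",
    ageRange = "numeric",
    nGenes = "integer",
    nPanAgeGenes = "integer",
    nTissueSpecificAgeGenes = "integer",
    betaAgePan = "numeric",
    betaAgeSpecific = "numeric",
    sexEffectSD = "numeric",
    subsiteLevels = "integer",
    subsiteEffectSD = "numeric",
    baselineLogMeanRange = "numeric",
    dispersion = "numeric",
    outlierRate = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    chkCount <- function(x, name, min = 1L) {
        if (length(x) < 1L || anyNA(x) || any(x < min))
            sprintf("'%s' must be a count >= %d", name, min) else NULL
    }
    msg <- c(msg,
        chkCount(object@nTissues, "nTissues"),
        chkCount(object@samplesPerTissue, "samplesPerTissue", 2L),
        chkCount(object@nGenes, "nGenes"),
        chkCount(object@nPanAgeGenes, "nPanAgeGenes", 0L),
        chkCount(object@nTissueSpecificAgeGenes, "nTissueSpecificAgeGenes", 0L),
        chkCount(object@subsiteLevels, "subsiteLevels"))
    if (length(object@samplesPerTissue) > 2L)
        msg <- c(msg, "'samplesPerTissue' must be a count or a c(min, max) range")
    if (length(object@ageRange) != 2L || anyNA(object@ageRange) ||
        object@ageRange[1L] >= object@ageRange[2L])
        msg <- c(msg, "'ageRange' must be c(min, max) with min < max")
    if (length(object@baselineLogMeanRange) != 2L ||
        anyNA(object@baselineLogMeanRange) ||
        object@baselineLogMeanRange[1L] > object@baselineLogMeanRange[2L])
        msg <- c(msg, "'baselineLogMeanRange' must be c(min, max) with min <= max")
    if (!isTRUE(object@dispersion > 0))
        msg <- c(msg, "'dispersion' must be > 0")
    if (!isTRUE(object@outlierRate >= 0 && object@outlierRate < 0.05))
        msg <- c(msg, "'outlierRate' must lie in [0, 0.05)")
    if (!anyNA(c(object@nPanAgeGenes, object@nTissueSpecificAgeGenes,
                 object@nGenes)) &&
        object@nPanAgeGenes + object@nTissueSpecificAgeGenes > object@nGenes)
        msg <- c(msg, "'nPanAgeGenes' + 'nTissueSpecificAgeGenes' must not exceed 'nGenes'")
    for (nm in c("betaAgePan", "betaAgeSpecific", "sexEffectSD",
                 "subsiteEffectSD")) {
        v <- slot(object, nm)
        if (length(v) != 1L || !is.finite(v))
            msg <- c(msg, sprintf("'%s' must be a single finite number", nm))
    }
    if (length(msg)) msg else TRUE
})

#' A seeded Leave-Half-Out fold specification for one tissue
#'
#' Each of the `k` folds is an independent random draw, without replacement,
#' of `floor(fraction * n)` of the tissue's samples. Folds are independent
#' redraws rather than a partition: with the default `fraction = 0.5` the
#' ten half-cohorts overlap, which is what stabilizes the averaged Spearman
#' estimate against individual outlying samples.
#'
#' @slot tissue tissue label the folds belong to.
#' @slot k number of folds.
#' @slot fraction fraction of samples per fold.
#' @slot seed integer seed the draws are reproducible from.
#' @slot folds list of `k` character vectors of sample ids.
#'
#' @seealso [makeLHOFolds()]
#' @export
setClass("FoldSpec", representation(
    tissue = "character",
    k = "integer",
    fraction = "numeric",
    seed = "integer",
    folds = "list"
))

setValidity("FoldSpec", function(object) {
    msg <- character()
    if (length(object@folds) != object@k)
        msg <- c(msg, "'folds' must hold exactly k sample sets")
    sizes <- lengths(object@folds)
    if (length(sizes) && length(unique(sizes)) != 1L)
        msg <- c(msg, "all folds must have equal size")
    if (any(vapply(object@folds, anyDuplicated, 0L) > 0L))
        msg <- c(msg, "samples within a fold must be distinct")
    if (!isTRUE(object@fraction > 0 && object@fraction <= 1))
        msg <- c(msg, "'fraction' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Per-tissue Leave-Half-Out screen result
#'
#' Holds, for one tissue, the per-fold Spearman correlations between gene
#' expression and donor age (genes x folds), the per-fold retained sample
#' counts after the 3-SD outlier exclusion, and the per-gene mean over
#' non-missing folds.
#'
#' @slot tissue tissue label.
#' @slot foldSpec the [FoldSpec-class] the screen was run on.
#' @slot rho genes x folds matrix of Spearman correlations (`NA` = fold
#'   missing for that gene, e.g. fewer than 3 retained samples).
#' @slot nUsed genes x folds matrix of retained sample counts.
#' @slot meanRho named per-gene mean over non-missing folds.
#'
#' @seealso [foldCorrelations()], [panTissueAggregate()]
#' @export
setClass("TissueScreen", representation(
    tissue = "character",
    foldSpec = "FoldSpec",
    rho = "matrix",
    nUsed = "matrix",
    meanRho = "numeric"
))

#' Pan-tissue aggregate ranking
#'
#' The cross-tissue aggregation of per-tissue screens: for every gene the
#' per-tissue mean correlations, their arithmetic mean over the tissues where
#' the gene was observed, and the rank (1 = largest pan-tissue mean, i.e. the
#' strongest tissue-independent positive age association).
#'
#' @slot perTissue genes x tissues matrix of per-tissue mean Spearman rho.
#' @slot panMeanRho named per-gene mean over available tissues.
#' @slot nTissuesObserved per-gene count of tissues with a non-missing mean.
#' @slot rank named integer ranks, 1 = largest `panMeanRho`; ties broken by
#'   gene id (lexicographic).
#' @slot direction `"up"` or `"down"` by the sign of `panMeanRho`.
#' @slot dropped gene ids excluded for falling below `minTissues`.
#'
#' @seealso [panTissueAggregate()], [rankTable()]
#' @export
setClass("PanTissueScreen", representation(
    perTissue = "matrix",
    panMeanRho = "numeric",
    nTissuesObserved = "integer",
    rank = "integer",
    direction = "character",
    dropped = "character"
))

#' Donor-age permutation test outcome
#'
#' One row per gene (x tissue, when produced by [batchPermutationScreen()]):
#' the observed Pearson correlation between expression and age, the number of
#' age permutations, the exceedance count, the raw empirical p-value
#' `nGe / nPerm` (which can be exactly 0), and the add-one corrected
#' `(nGe + 1) / (nPerm + 1)`.
#'
#' @slot table data.frame with columns `gene_id`, `tissue`, `r_obs`,
#'   `n_perm`, `n_ge`, `p_emp`, `p_emp_plus1`.
#' @slot alternative `"greater"`, `"less"` or `"two_sided"`.
#' @slot seed the seed the permutation schedule was drawn from (`NA` in
#'   exhaustive-enumeration mode, which is deterministic).
#' @slot exact `TRUE` when all permutations were enumerated.
#'
#' @seealso [permutationTest()], [batchPermutationScreen()]
#' @export
setClass("PermutationResult", representation(
    table = "data.frame",
    alternative = "character",
    seed = "integer",
    exact = "logical"
))
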