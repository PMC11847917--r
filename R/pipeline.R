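#' Run the pan-tissue age screen on an in-memory cohort
#'
#' The end-to-end driver: optional sample QC, normalization and
#' variance-stabilizing transform, per-tissue batch residualization with age
#' protected, the Leave-Half-Out resampled Spearman screen per tissue,
#' pan-tissue aggregation and ranking, the parallel Pearson + BH path, and
#' donor-age permutation tests for the top-ranked genes. All randomness is
#' derived deterministically from one `seed`, so identical inputs and seed
#' give identical outputs.
#'
#' With `stratify` set to a categorical sample covariate (e.g. `"sex"`), the
#' screen and aggregation run separately within each stratum (the stratified
#' variable is then dropped from `batchVars`), and the result carries one
#' ranking per stratum.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with a `"counts"`
#'   assay and `colData` columns `sample_id`, `age_years`, `tissue` (plus any
#'   batch covariates), e.g. from [simulateCohort()] or [readCohort()].
#' @param k,fraction Leave-Half-Out folds per tissue and the fraction of
#'   samples per fold (defaults 10 and 0.5).
#' @param outlierSD SD multiple of the per-gene within-fold outlier
#'   exclusion (default 3).
#' @param minTissues minimum tissues per gene for the pan-tissue ranking
#'   (default: all tissues).
#' @param stratify optional name of a categorical covariate to stratify by.
#' @param batchVars categorical covariates residualized away (defaults to
#'   those of `c("sex", "subsite")` present in the colData).
#' @param protectVars numeric covariates protected during residualization.
#' @param qcThreshold when non-`NULL`, run the correlation-profile QC per
#'   tissue first and drop samples with `D > qcThreshold`.
#' @param nPerm permutations for the top genes (0 disables the stage).
#' @param permTopN number of top-ranked genes carried into permutation
#'   testing (default 50).
#' @param alternative permutation alternative, see [permutationTest()].
#' @param seed single integer seed; per-stage seeds are derived from it.
#' @return a list with elements `tissueScreens` (list of
#'   [TissueScreen-class]), `pan` ([PanTissueScreen-class]), `ranking`
#'   (data.frame from [rankTable()]), `pearson`, `permutation`, `qc`, and
#'   `params`; under stratification, instead a list with `strata` (one such
#'   list per stratum) and `params`.
#' @examples
#' se <- simulateCohort(SimConfig(nTissues = 2, samplesPerTissue = 40,
#'                                nGenes = 60, seed = 5))
#' res <- screenCohort(se, k = 5, nPerm = 0, seed = 5)
#' head(res$ranking, 3)
#' @export
screenCohort <- function(se, k = 10L, fraction = 0.5, outlierSD = 3,
                         minTissues = NULL, stratify = NULL,
                         batchVars = c("sex", "subsite"),
                         protectVars = "age_years", qcThreshold = NULL,
                         nPerm = 1000L, permTopN = 50L,
                         alternative = "greater", seed = 1L) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    need <- c("sample_id", "age_years", "tissue")
    missing <- setdiff(need, names(cd))
    if (length(missing))
        stopf("colData lacks required column(s): %s",
              paste(missing, collapse = ", "))
    batchVars <- intersect(batchVars, names(cd))

    qcTab <- NULL
    if (!is.null(qcThreshold)) {
        logCounts <- log2(SummarizedExperiment::assay(se, "counts") + 1)
        qcTab <- do.call(rbind, lapply(unique(cd$tissue), function(t) {
            j <- cd$tissue == t
            rec <- flagLowQuality(
                qcDStatistic(pairwiseSampleCorrelations(
                    logCounts[, j, drop = FALSE])),
                threshold = qcThreshold)
            rec$tissue <- t
            rec
        }))
        keep <- !cd$sample_id %in% qcTab$sample_id[qcTab$flagged]
        se <- se[, keep]
        cd <- cd[keep, , drop = FALSE]
    }

    strata <- if (is.null(stratify)) {
        list(all = rep(TRUE, nrow(cd)))
    } else {
        if (!stratify %in% names(cd))
            stopf("stratification variable '%s' not in colData", stratify)
        batchVars <- setdiff(batchVars, stratify)
        split(seq_len(nrow(cd)), cd[[stratify]])
    }

    se <- vstTransform(se)
    layer <- "transformed"
    if (length(batchVars)) {
        se <- residualizeBatch(se, batchVars = batchVars,
                               protectVars = protectVars, byTissue = TRUE)
        layer <- "residualized"
    }
    mat <- SummarizedExperiment::assay(se, layer)
    ages <- setNames(cd$age_years, cd$sample_id)

    runStratum <- function(idx, stratumName) {
        cds <- cd[idx, , drop = FALSE]
        tissues <- unique(cds$tissue)
        screens <- lapply(tissues, function(t) {
            ids <- cds$sample_id[cds$tissue == t]
            folds <- makeLHOFolds(ids, k = k, fraction = fraction,
                                  seed = deriveSeed(seed,
                                      paste("folds", stratumName, t)),
                                  tissue = t)
            foldCorrelations(mat[, ids, drop = FALSE], ages[ids], folds,
                             outlierSD = outlierSD)
        })
        names(screens) <- tissues
        pan <- panTissueAggregate(screens,
            minTissues = if (is.null(minTissues)) length(screens)
                         else minTissues)
        ranking <- rankTable(pan)
        pearson <- do.call(rbind, lapply(tissues, function(t) {
            ids <- cds$sample_id[cds$tissue == t]
            pearsonScreen(mat[, ids, drop = FALSE], ages[ids], tissue = t)
        }))
        permutation <- NULL
        if (nPerm > 0L && length(pan@rank)) {
            top <- names(sort(pan@rank))[seq_len(min(permTopN,
                                                     length(pan@rank)))]
            permutation <- do.call(rbind, lapply(tissues, function(t) {
                ids <- cds$sample_id[cds$tissue == t]
                permutationTable(batchPermutationScreen(
                    mat[top, ids, drop = FALSE], ages[ids], nPerm = nPerm,
                    seed = deriveSeed(seed, paste("perm", stratumName, t)),
                    alternative = alternative, tissue = t))
            }))
        }
        list(tissueScreens = screens, pan = pan, ranking = ranking,
             pearson = pearson, permutation = permutation)
    }

    params <- list(k = k, fraction = fraction, outlierSD = outlierSD,
                   minTissues = minTissues, stratify = stratify,
                   batchVars = batchVars, protectVars = protectVars,
                   qcThreshold = qcThreshold, nPerm = nPerm,
                   permTopN = permTopN, alternative = alternative,
                   seed = seed, layer = layer)
    if (is.null(stratify)) {
        out <- runStratum(which(strata$all), "all")
        out$qc <- qcTab
        out$params <- params
        out
    } else {
        res <- lapply(names(strata), function(s) runStratum(strata[[s]], s))
        names(res) <- names(strata)
        list(strata = res, qc = qcTab, params = params)
    }
}

#' Load and validate a run configuration
#'
#' The run configuration is a YAML file with blocks `paths` (`matrix`,
#' `samples`, `outdir`, optional `format`), `screen` (`k`, `fraction`,
#' `outlier_sd`, `min_tissues`, optional `stratify`, `batch_vars`),
#' `permutation` (`n_perm`, `alternative`, `top_n`), optional `qc`
#' (`threshold`), and `seed`. Referenced input paths must exist at load time
#' and numeric parameters are checked against their documented ranges; the
#' validated configuration round-trips losslessly through
#' [writeRunConfig()].
#'
#' @param path YAML file path.
#' @return validated configuration list (class `"panAgeRunConfig"`).
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stopf("config file not found: %s", path)
    cfg <- yaml::read_yaml(path)
    validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg configuration list to validate or write.
#' @export
validateRunConfig <- function(cfg) {
    defaults <- list(
        paths = list(format = "tsv"),
        screen = list(k = 10L, fraction = 0.5, outlier_sd = 3,
                      min_tissues = "all", stratify = NULL,
                      batch_vars = c("sex", "subsite")),
        permutation = list(n_perm = 1000L, alternative = "greater",
                           top_n = 50L),
        qc = list(threshold = NULL),
        seed = 1L, log_level = "info")
    cfg <- utils::modifyList(defaults, cfg, keep.null = TRUE)
    for (f in c("matrix", "samples", "outdir"))
        if (is.null(cfg$paths[[f]]))
            stopf("config paths.%s is required", f)
    for (f in c("matrix", "samples"))
        if (!file.exists(cfg$paths[[f]]))
            stopf("config paths.%s does not exist: %s", f, cfg$paths[[f]])
    with(cfg$screen, {
        if (!isTRUE(k >= 1)) stopf("screen.k must be >= 1")
        if (!isTRUE(fraction > 0 && fraction <= 1))
            stopf("screen.fraction must lie in (0, 1]")
        if (!isTRUE(outlier_sd > 0)) stopf("screen.outlier_sd must be > 0")
    })
    if (!isTRUE(cfg$permutation$n_perm >= 0))
        stopf("permutation.n_perm must be >= 0")
    if (!cfg$permutation$alternative %in% c("greater", "less", "two_sided"))
        stopf("permutation.alternative must be greater, less or two_sided")
    if (!is.null(cfg$qc$threshold) && !isTRUE(cfg$qc$threshold > 0))
        stopf("qc.threshold must be > 0")
    class(cfg) <- c("panAgeRunConfig", "list")
    cfg
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' Run the full pipeline from a configuration file
#'
#' File-based front end to [screenCohort()]: reads the expression matrix and
#' sample table named in the configuration, runs QC (optional), preprocessing,
#' the Leave-Half-Out screen, pan-tissue ranking, the Pearson path and
#' permutation tests, writes every result table as TSV into the output
#' directory, and finishes by atomically writing a reproducibility manifest
#' (`manifest.yaml`) holding the configuration snapshot, derived stage seeds,
#' package version, md5 checksums of all outputs and timestamps. A failure in
#' any stage aborts with the stage named.
#'
#' @param config a configuration list from [readRunConfig()] /
#'   [validateRunConfig()], or a path to a YAML configuration file.
#' @return the manifest list, invisibly.
#' @seealso [screenCohort()]
#' @export
runPipeline <- function(config) {
    if (is.character(config))
        config <- readRunConfig(config)
    if (!inherits(config, "panAgeRunConfig"))
        config <- validateRunConfig(config)
    started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    }
    se <- stage("read", readCohort(config$paths$matrix, config$paths$samples,
                                   format = config$paths$format))
    minTissues <- config$screen$min_tissues
    if (identical(minTissues, "all")) minTissues <- NULL
    res <- stage("screen", screenCohort(
        se,
        k = config$screen$k, fraction = config$screen$fraction,
        outlierSD = config$screen$outlier_sd,
        minTissues = minTissues,
        stratify = config$screen$stratify,
        batchVars = unlist(config$screen$batch_vars),
        qcThreshold = config$qc$threshold,
        nPerm = config$permutation$n_perm,
        permTopN = config$permutation$top_n,
        alternative = config$permutation$alternative,
        seed = config$seed))

    outdir <- config$paths$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    emit <- function(df, name) {
        if (is.null(df)) return()
        p <- file.path(outdir, name)
        write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
        written <<- c(written, p)
    }
    stage("write", {
        emitStratum <- function(r, prefix = "") {
            for (t in names(r$tissueScreens))
                emit(rankTable(r$tissueScreens[[t]]),
                     paste0(prefix, "screen_", t, ".tsv"))
            emit(r$ranking, paste0(prefix, "pan_ranking.tsv"))
            emit(r$pearson, paste0(prefix, "pearson.tsv"))
            emit(r$permutation, paste0(prefix, "permutation.tsv"))
        }
        if (is.null(config$screen$stratify)) {
            emitStratum(res)
        } else {
            for (s in names(res$strata))
                emitStratum(res$strata[[s]], paste0(s, "_"))
        }
        emit(res$qc, "qc.tsv")
    })

    manifest <- list(
        config = unclass(config),
        seed = config$seed,
        package_version = as.character(packageVersion("panAgeScreen")),
        started = started,
        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        outputs = lapply(setNames(written, basename(written)),
                         function(p) unname(tools::md5sum(p))))
    mpath <- file.path(outdir, "manifest.yaml")
    tmp <- paste0(mpath, ".tmp")
    yaml::write_yaml(manifest, tmp)
    file.rename(tmp, mpath)
    invisible(manifest)
}
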