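#' Construct a synthetic-cohort configuration
#'
#' User-facing constructor for [SimConfig-class]. The defaults describe the
#' cohort the package's validation suite runs on: 8 solid tissues drawn from a
#' shared donor pool aged 20-70, 200 samples per tissue, 2000 genes of which
#' one is a planted pan-tissue age gene whose effect size (`betaAgePan = 0.3`
#' on the log scale per standardized-age unit, with NB dispersion 0.2) puts
#' its per-tissue Spearman correlation with age near 0.5 -- a strong but not
#' overwhelming signal, comparable to the best pan-tissue age markers in bulk
#' human data. Sex and anatomical subsite act as per-gene log-scale batch
#' effects, emulating the dominant nuisance axes of real multi-tissue cohorts.
#'
#' @param nTissues,samplesPerTissue,ageRange,nGenes cohort geometry (see
#'   [SimConfig-class]); `samplesPerTissue` may be a single count or a
#'   `c(min, max)` range sampled independently per tissue.
#' @param nPanAgeGenes,nTissueSpecificAgeGenes,betaAgePan,betaAgeSpecific
#'   planted age signal. Tissue-specific age genes are assigned round-robin
#'   to tissues.
#' @param sexEffectSD,subsiteLevels,subsiteEffectSD nuisance batch structure.
#' @param baselineLogMeanRange,dispersion NB count model: baseline natural-log
#'   mean counts are uniform over this range (default `exp(2)` to `exp(6)`,
#'   i.e. roughly 7 to 400 counts) and the NB variance is
#'   `mu + dispersion * mu^2`.
#' @param outlierRate fraction of count entries multiplied by 10 to emulate
#'   technical outliers the screen's 3-SD rule must absorb.
#' @param seed integer RNG seed; the whole cohort is reproducible from it.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(nTissues = 3, samplesPerTissue = 60, nGenes = 100, seed = 7)
#' cfg
#' @export
SimConfig <- function(nTissues = 8L, samplesPerTissue = 200L,
                      ageRange = c(20, 70), nGenes = 2000L,
                      nPanAgeGenes = 1L, nTissueSpecificAgeGenes = 0L,
                      betaAgePan = 0.3, betaAgeSpecific = 0.3,
                      sexEffectSD = 0.5, subsiteLevels = 3L,
                      subsiteEffectSD = 0.3,
                      baselineLogMeanRange = c(2, 6), dispersion = 0.2,
                      outlierRate = 0, seed = 1L) {
    asCount <- function(x, name) {
        if (!is.numeric(x) || anyNA(x) || any(x != floor(x)))
            stopf("invalid SimConfig field '%s': must be whole-numbered", name)
        as.integer(x)
    }
    obj <- new("SimConfig",
        nTissues = asCount(nTissues, "nTissues"),
        samplesPerTissue = asCount(samplesPerTissue, "samplesPerTissue"),
        ageRange = as.numeric(ageRange),
        nGenes = asCount(nGenes, "nGenes"),
        nPanAgeGenes = asCount(nPanAgeGenes, "nPanAgeGenes"),
        nTissueSpecificAgeGenes = asCount(nTissueSpecificAgeGenes,
                                          "nTissueSpecificAgeGenes"),
        betaAgePan = as.numeric(betaAgePan),
        betaAgeSpecific = as.numeric(betaAgeSpecific),
        sexEffectSD = as.numeric(sexEffectSD),
        subsiteLevels = asCount(subsiteLevels, "subsiteLevels"),
        subsiteEffectSD = as.numeric(subsiteEffectSD),
        baselineLogMeanRange = as.numeric(baselineLogMeanRange),
        dispersion = as.numeric(dispersion),
        outlierRate = as.numeric(outlierRate),
        seed = asCount(seed, "seed"))
    msg <- validObject(obj, test = TRUE)
    if (is.character(msg))
        stopf("invalid SimConfig: %s", paste(msg, collapse = "; "))
    obj
}

setMethod("show", "SimConfig", function(object) {
    spt <- object@samplesPerTissue
    cat("SimConfig:", object@nTissues, "tissues x",
        if (length(spt) == 1L) spt else paste0(spt[1L], "-", spt[2L]),
        "samples,", object@nGenes, "genes\n")
    cat("  planted: ", object@nPanAgeGenes, " pan-age (beta=",
        object@betaAgePan, "), ", object@nTissueSpecificAgeGenes,
        " tissue-specific (beta=", object@betaAgeSpecific, ")\n", sep = "")
    cat("  ages ", object@ageRange[1L], "-", object@ageRange[2L],
        " y; sex SD ", object@sexEffectSD, "; ", object@subsiteLevels,
        " subsites (SD ", object@subsiteEffectSD, "); dispersion ",
        object@dispersion, "; outlier rate ", object@outlierRate,
        "; seed ", object@seed, "\n", sep = "")
})

#' Simulate a multi-tissue expression cohort
#'
#' Draws a negative-binomial gene-by-sample count matrix for a multi-tissue
#' cohort whose donors are shared across tissues (as in post-mortem
#' multi-tissue collections), with a planted age signal and per-gene sex and
#' subsite batch effects. Counts for gene g in sample j follow
#' `NB(mean = exp(b_g + beta_g * ageStd_j + sex_g * male_j + site_{g,s(j)}),
#' size = 1/dispersion)`, where `ageStd` is donor age standardized over the
#' donor pool. Pan-age genes carry `betaAgePan` in every tissue,
#' tissue-specific genes carry `betaAgeSpecific` in exactly one tissue, and
#' null genes carry no age term. A fraction `outlierRate` of entries is then
#' multiplied by 10. The output is byte-identical across runs with the same
#' configuration.
#'
#' @param config a [SimConfig-class].
#' @return a [SummarizedExperiment::SummarizedExperiment] with a `"counts"`
#'   assay; `colData` columns `sample_id`, `donor_id`, `age_years`, `sex`,
#'   `tissue`, `subsite`; and ground-truth `rowData` columns `gene_id`,
#'   `class` (`pan_age_up`, `pan_age_down`, `tissue_specific:<tissue>` or
#'   `null`), `beta_age` and `target_tissue`. The configuration is stored in
#'   `metadata(se)$simConfig`.
#' @examples
#' se <- simulateCohort(SimConfig(nTissues = 2, samplesPerTissue = 30,
#'                                nGenes = 50, seed = 42))
#' table(SummarizedExperiment::rowData(se)$class)
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    withSeed(config@seed, {
        nT <- config@nTissues
        tissues <- sprintf("tissue%02d", seq_len(nT))
        spt <- config@samplesPerTissue
        nPerTissue <- if (length(spt) == 1L) rep(spt, nT) else
            sample(seq(spt[1L], spt[2L]), nT, replace = TRUE)
        nDonors <- max(nPerTissue)
        donorIds <- sprintf("donor%04d", seq_len(nDonors))
        donorAge <- runif(nDonors, config@ageRange[1L], config@ageRange[2L])
        donorSex <- sample(c("male", "female"), nDonors, replace = TRUE)
        ageStd <- (donorAge - mean(donorAge)) / sd(donorAge)

        G <- config@nGenes
        geneIds <- sprintf("g%05d", seq_len(G))
        nPan <- config@nPanAgeGenes
        nSpec <- config@nTissueSpecificAgeGenes
        class <- rep("null", G)
        betaTrue <- numeric(G)
        targetTissue <- rep(NA_character_, G)
        if (nPan > 0L) {
            class[seq_len(nPan)] <-
                if (config@betaAgePan >= 0) "pan_age_up" else "pan_age_down"
            betaTrue[seq_len(nPan)] <- config@betaAgePan
        }
        if (nSpec > 0L) {
            idx <- nPan + seq_len(nSpec)
            tt <- tissues[((seq_len(nSpec) - 1L) %% nT) + 1L]
            class[idx] <- paste0("tissue_specific:", tt)
            betaTrue[idx] <- config@betaAgeSpecific
            targetTissue[idx] <- tt
        }

        baseline <- runif(G, config@baselineLogMeanRange[1L],
                          config@baselineLogMeanRange[2L])
        sexEff <- rnorm(G, 0, config@sexEffectSD)

        counts <- vector("list", nT)
        colDat <- vector("list", nT)
        size <- 1 / config@dispersion
        for (t in seq_len(nT)) {
            nS <- nPerTissue[t]
            dIdx <- sort(sample.int(nDonors, nS))
            subsite <- sample(sprintf("%s_site%d", tissues[t],
                                      seq_len(config@subsiteLevels)),
                              nS, replace = TRUE)
            siteEff <- matrix(rnorm(G * config@subsiteLevels, 0,
                                    config@subsiteEffectSD),
                              nrow = G,
                              dimnames = list(NULL,
                                  sprintf("%s_site%d", tissues[t],
                                          seq_len(config@subsiteLevels))))
            beta <- betaTrue
            if (nSpec > 0L)  # zero out planted effects not active here
                beta[!is.na(targetTissue) & targetTissue != tissues[t]] <- 0
            logMu <- outer(baseline, rep(1, nS)) +
                outer(beta, ageStd[dIdx]) +
                outer(sexEff, as.numeric(donorSex[dIdx] == "male")) +
                siteEff[, subsite, drop = FALSE]
            cnt <- matrix(rnbinom(G * nS, mu = exp(logMu), size = size),
                          nrow = G)
            if (config@outlierRate > 0) {
                hit <- runif(G * nS) < config@outlierRate
                cnt[hit] <- cnt[hit] * 10L
            }
            dimnames(cnt) <- list(geneIds,
                                  paste(tissues[t], donorIds[dIdx], sep = "."))
            counts[[t]] <- cnt
            colDat[[t]] <- data.frame(
                sample_id = colnames(cnt),
                donor_id = donorIds[dIdx],
                age_years = donorAge[dIdx],
                sex = donorSex[dIdx],
                tissue = tissues[t],
                subsite = subsite,
                stringsAsFactors = FALSE)
        }
        counts <- do.call(cbind, counts)
        colDat <- do.call(rbind, colDat)
        rownames(colDat) <- colDat$sample_id
        rowDat <- S4Vectors::DataFrame(
            gene_id = geneIds, class = class, beta_age = betaTrue,
            target_tissue = targetTissue, row.names = geneIds)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(colDat),
            rowData = rowDat)
        S4Vectors::metadata(se)$simConfig <- config
        se
    })
}

#' Simulate a sample-correlation matrix with degraded samples
#'
#' Builds a symmetric pairwise-correlation matrix in which `nSamples -
#' nDegraded` good samples are mutually correlated around `goodCor` and
#' `nDegraded` degraded samples correlate around 0 with everything -- the
#' situation the MAD-scaled D statistic (see [qcDStatistic()]) is designed to
#' flag. Used as a self-contained fixture for the sample-quality workflow.
#'
#' @param nSamples number of samples (>= 3).
#' @param nDegraded number of degraded samples, `0 <= nDegraded < nSamples`.
#' @param seed integer RNG seed.
#' @param goodCor centre of the good-good correlations.
#' @param noiseSD SD of the correlation noise.
#' @return a symmetric `nSamples x nSamples` matrix with unit diagonal,
#'   entries in `[-1, 1]`, sample ids in dimnames; degraded sample ids are in
#'   `attr(, "degraded")`.
#' @examples
#' cm <- simulateSampleCorrMatrix(20, nDegraded = 2, seed = 7)
#' attr(cm, "degraded")
#' @export
simulateSampleCorrMatrix <- function(nSamples, nDegraded = 0L, seed = 1L,
                                     goodCor = 0.9, noiseSD = 0.02) {
    nSamples <- as.integer(nSamples)
    nDegraded <- as.integer(nDegraded)
    if (nSamples < 3L)
        stopf("'nSamples' must be >= 3")
    if (nDegraded < 0L || nDegraded >= nSamples)
        stopf("'nDegraded' must satisfy 0 <= nDegraded < nSamples")
    withSeed(seed, {
        ids <- sprintf("s%03d", seq_len(nSamples))
        degraded <- if (nDegraded > 0L)
            sample(ids, nDegraded) else character()
        m <- matrix(0, nSamples, nSamples, dimnames = list(ids, ids))
        up <- upper.tri(m)
        vals <- goodCor + rnorm(sum(up), 0, noiseSD)
        m[up] <- vals
        bad <- ids %in% degraded
        # any pair touching a degraded sample correlates near zero
        badPair <- outer(bad, bad, `|`)
        m[up & badPair] <- rnorm(sum(up & badPair), 0, noiseSD)
        m <- m + t(m)
        diag(m) <- 1
        m[m > 1] <- 1; m[m < -1] <- -1
        attr(m, "degraded") <- degraded
        m
    })
}
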