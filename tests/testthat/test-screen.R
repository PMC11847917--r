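test_that("Leave-Half-Out folds have the stated size, uniqueness and determinism", {
    ids <- sprintf("s%03d", 1:100)
    fs <- makeLHOFolds(ids, k = 10, fraction = 0.5, seed = 3)
    expect_length(fs@folds, 10L)
    expect_true(all(lengths(fs@folds) == 50L))
    expect_true(all(vapply(fs@folds, anyDuplicated, 0L) == 0L))
    expect_true(all(unlist(fs@folds) %in% ids))
    # folds are redraws, not a partition: consecutive folds overlap w.h.p.
    expect_gt(length(intersect(fs@folds[[1]], fs@folds[[2]])), 0L)
    expect_identical(makeLHOFolds(ids, seed = 3)@folds,
                     makeLHOFolds(ids, seed = 3)@folds)
    expect_false(identical(makeLHOFolds(ids, seed = 3)@folds,
                           makeLHOFolds(ids, seed = 4)@folds))
    expect_error(makeLHOFolds(ids[1:5], fraction = 0.5), "below 3")
    expect_error(makeLHOFolds(ids[1:3]), "at least 4")
})

test_that("spearmanRho equals the brute-force mid-rank oracle, ties included", {
    # explicit tied example
    ages <- c(1, 2, 3, 4)
    expr <- c(10, 10, 5, 1)
    expect_equal(spearmanRho(ages, expr), oracleSpearman(ages, expr),
                 tolerance = 1e-12)
    # monotone invariance and perfect ordering
    a <- c(21, 35, 44, 58, 66)
    expect_equal(spearmanRho(a, a^3), 1)
    expect_identical(spearmanRho(a, exp(a / 10)), spearmanRho(a, a / 10))
    # randomized cases with ties forced by rounding
    set.seed(101)
    for (i in 1:1000) {
        n <- sample(3:12, 1)
        x <- round(rnorm(n), sample(0:1, 1))
        y <- round(rnorm(n), sample(0:1, 1))
        if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
            expect_true(is.na(spearmanRho(x, y)))
        } else {
            expect_equal(spearmanRho(x, y), oracleSpearman(x, y),
                         tolerance = 1e-12)
        }
    }
    expect_error(spearmanRho(1:4, 1:5), "equal length")
    expect_true(is.na(spearmanRho(c(1, 1, 1), c(1, 2, 3))))
})

test_that("a single full-sized fold reduces to plain Spearman", {
    se <- simulateCohort(quickConfig(nTissues = 1L, nGenes = 25L, seed = 6L))
    x <- vstTransform(SummarizedExperiment::assay(se, "counts"))
    ages <- setNames(SummarizedExperiment::colData(se)$age_years,
                     colnames(x))
    fs <- makeLHOFolds(colnames(x), k = 1, fraction = 1, seed = 1,
                       tissue = "t")
    ts <- foldCorrelations(x, ages, fs, maskOutliers = FALSE)
    direct <- vapply(rownames(x), function(g)
        spearmanRho(ages, x[g, ]), 0)
    expect_equal(unname(meanRho(ts)), unname(direct), tolerance = 1e-15)
})

test_that("fold correlations are null-centered on a zero-effect tissue", {
    cfg <- quickConfig(nTissues = 1L, samplesPerTissue = 200L,
                       nGenes = 2000L, nPanAgeGenes = 0L, sexEffectSD = 0,
                       subsiteEffectSD = 0, seed = 31L)
    se <- vstTransform(simulateCohort(cfg))
    x <- SummarizedExperiment::assay(se, "transformed")
    ages <- setNames(SummarizedExperiment::colData(se)$age_years,
                     colnames(x))
    fs <- makeLHOFolds(colnames(x), k = 10, fraction = 0.5, seed = 1,
                       tissue = "t1")
    ts <- foldCorrelations(x, ages, fs)
    expect_lt(abs(mean(meanRho(ts), na.rm = TRUE)), 0.02)
})

test_that("outlier masking recovers the trend broken by an injected 10x entry", {
    set.seed(23)
    n <- 40
    ages <- sort(runif(n, 20, 70))
    expr <- 10 + 0.2 * ages + rnorm(n, sd = 0.3)  # clean monotone trend
    expr[3] <- expr[3] * 10                        # young sample blown up 10x
    x <- rbind(planted = expr)
    colnames(x) <- sprintf("s%03d", 1:n)
    ages <- setNames(ages, colnames(x))
    fs <- makeLHOFolds(colnames(x), k = 1, fraction = 1, seed = 1,
                       tissue = "t")
    masked <- meanRho(foldCorrelations(x, ages, fs, outlierSD = 3))
    unmasked <- meanRho(foldCorrelations(x, ages, fs, maskOutliers = FALSE))
    expect_false(expressionOutlierMask(expr)[3])
    expect_gt(masked["planted"], unmasked["planted"])
})

test_that("fold correlations mark degenerate folds missing, not failed", {
    x <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4),
                                              paste0("s", 1:10)))
    ages <- setNames(rep(50, 10), colnames(x))  # constant age
    fs <- makeLHOFolds(colnames(x), k = 2, fraction = 0.5, seed = 1)
    ts <- foldCorrelations(x, ages, fs)
    expect_true(all(is.na(ts@rho)))
    expect_true(all(is.na(meanRho(ts))))
})

test_that("pan-tissue aggregation averages, ranks and breaks ties as documented", {
    mkScreen <- function(tissue, rho) {
        fs <- makeLHOFolds(sprintf("%s_s%02d", tissue, 1:20), k = 1,
                           fraction = 1, seed = 1, tissue = tissue)
        new("TissueScreen", tissue = tissue, foldSpec = fs,
            rho = matrix(rho, ncol = 1,
                         dimnames = list(names(rho), "fold1")),
            nUsed = matrix(20L, length(rho), 1,
                           dimnames = list(names(rho), "fold1")),
            meanRho = rho)
    }
    s1 <- mkScreen("t1", c(gA = 0.4, gB = 0.2, gC = 0.2))
    s2 <- mkScreen("t2", c(gA = -0.2, gB = 0.2, gC = 0.2))
    pan <- panTissueAggregate(list(s1, s2))
    expect_equal(panMeanRho(pan), c(gA = 0.1, gB = 0.2, gC = 0.2))
    # gB and gC tie at 0.2: lexicographic order puts gB first
    expect_identical(geneRanks(pan), c(gA = 3L, gB = 1L, gC = 2L))
    expect_identical(unname(pan@direction["gA"]), "up")
    # constancy: equal per-tissue values pass through
    expect_equal(unname(panMeanRho(pan)["gB"]), 0.2)
    # minTissues drops genes with partial coverage
    s3 <- mkScreen("t3", c(gA = 0.5))
    pan2 <- panTissueAggregate(list(s1, s2, s3), minTissues = 3)
    expect_identical(names(panMeanRho(pan2)), "gA")
    expect_setequal(pan2@dropped, c("gB", "gC"))
})

test_that("the planted pan-age gene wins the ranking and a tissue-specific gene does not", {
    wins <- vapply(1:20, function(s) {
        cfg <- quickConfig(nTissues = 8L, samplesPerTissue = 60L,
                           nGenes = 30L, nPanAgeGenes = 1L,
                           nTissueSpecificAgeGenes = 1L,
                           betaAgePan = 0.3, betaAgeSpecific = 0.3,
                           seed = s)
        res <- screenCohort(simulateCohort(cfg), k = 5, nPerm = 0, seed = s)
        rk <- geneRanks(res$pan)
        c(pan = unname(rk["g00001"]) == 1L,
          spec = unname(rk["g00002"]) > unname(rk["g00001"]))
    }, c(pan = TRUE, spec = TRUE))
    expect_gte(sum(wins["pan", ]), 19L)
    expect_gte(sum(wins["spec", ]), 19L)
})

test_that("rank table is ordered, complete, and antisymmetric under sign flip", {
    se <- simulateCohort(quickConfig(seed = 12L))
    x <- vstTransform(SummarizedExperiment::assay(se, "counts"))
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    ages <- setNames(cd$age_years, cd$sample_id)
    runPan <- function(mat) {
        screens <- lapply(unique(cd$tissue), function(t) {
            ids <- cd$sample_id[cd$tissue == t]
            fs <- makeLHOFolds(ids, k = 3, seed = 5, tissue = t)
            foldCorrelations(mat[, ids], ages[ids], fs,
                             maskOutliers = FALSE)
        })
        panTissueAggregate(screens)
    }
    pan <- runPan(x)
    tab <- rankTable(pan)
    expect_identical(tab$rank, seq_len(nrow(tab)))
    expect_identical(sort(tab$gene_id), sort(names(panMeanRho(pan))))
    expect_true(all(c("pan_mean_rho", "direction",
                      "rho_tissue01") %in% names(tab)))
    # reversing the sign of all values reverses direction and ordering
    panNeg <- runPan(-x)
    expect_equal(panMeanRho(panNeg), -panMeanRho(pan), tolerance = 1e-12)
    expect_identical(names(sort(geneRanks(panNeg))),
                     names(sort(panMeanRho(pan))))   # ascending original rho
    expect_true(all(panNeg@direction[panMeanRho(pan) > 0] == "down"))
})

test_that("fold-mean variability shrinks with tissue sample size", {
    sdAt <- function(n, seed) {
        cfg <- quickConfig(nTissues = 1L, samplesPerTissue = n,
                           nGenes = 30L, nPanAgeGenes = 1L, seed = seed)
        se <- vstTransform(simulateCohort(cfg))
        x <- SummarizedExperiment::assay(se, "transformed")
        ages <- setNames(SummarizedExperiment::colData(se)$age_years,
                         colnames(x))
        fs <- makeLHOFolds(colnames(x), k = 10, seed = seed, tissue = "t")
        ts <- foldCorrelations(x, ages, fs)
        mean(apply(ts@rho, 1L, sd, na.rm = TRUE))
    }
    sds <- vapply(c(50L, 200L, 800L), function(n)
        mean(vapply(1:3, function(s) sdAt(n, s), 0)), 0)
    expect_true(all(diff(sds) < 0))
})

test_that("the Pearson screen matches the closed-form t-test and BH step-up", {
    # hand 5-point dataset
    age <- c(25, 34, 41, 55, 68)
    y <- c(3.1, 2.9, 4.2, 4.8, 5.5)
    x <- rbind(g1 = y)
    colnames(x) <- paste0("s", 1:5)
    out <- pearsonScreen(x, age, tissue = "t1")
    r <- oraclePearson(age, y)
    tstat <- r * sqrt((5 - 2) / (1 - r^2))
    expect_equal(out$r, r, tolerance = 1e-12)
    expect_equal(out$p, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)
    # perfectly linear gene
    lin <- pearsonScreen(rbind(g1 = age), age)
    expect_equal(lin$r, 1)
    expect_equal(lin$p, 0)
    # zero-variance gene is missing, not zero
    flat <- pearsonScreen(rbind(g1 = rep(2, 5), g2 = y), age)
    expect_true(is.na(flat$r[1]) && is.na(flat$p[1]) && is.na(flat$q[1]))
    # BH agreement: the textbook example and random vectors
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
    set.seed(41)
    for (i in 1:50) {
        p <- runif(sample(3:20, 1))
        expect_equal(p.adjust(p, "BH"), oracleBH(p), tolerance = 1e-12)
    }
    # q-values within the screen come from BH within tissue
    multi <- pearsonScreen(rbind(g1 = y, g2 = rev(y), g3 = y + rnorm(5)),
                           age, tissue = "t1")
    expect_equal(multi$q, oracleBH(multi$p), tolerance = 1e-12)
})
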