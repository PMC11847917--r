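#' Read a gene-by-sample expression matrix
#'
#' Reads a dense TSV (header row of sample ids, first column gene ids, `.`
#' or empty cells = missing) or a MatrixMarket coordinate file with row/col
#' id sidecars (`<path>.rows`, `<path>.cols`, one id per line). Identifiers
#' are validated to be unique, cells to be numeric, and rows to be
#' rectangular; violations raise parse errors naming the offending line or
#' identifier. A counts layer must be complete and non-negative.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"mtx"`.
#' @param layer `"counts"` (missing values rejected) or any other layer tag.
#' @param rowIdsPath,colIdsPath sidecar paths for `format = "mtx"`.
#' @return numeric matrix with gene ids as rownames, sample ids as colnames.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, format = c("tsv", "mtx"), layer = "counts",
                           rowIdsPath = paste0(path, ".rows"),
                           colIdsPath = paste0(path, ".cols")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stopf("file not found: %s", path)
    if (format == "tsv") {
        lines <- readLines(path)
        if (length(lines) < 2L)
            stopf("%s: need a header and at least one gene row", path)
        fields <- strsplit(lines, "\t", fixed = TRUE)
        header <- fields[[1L]]
        sampleIds <- header[-1L]
        if (length(sampleIds) < 1L)
            stopf("%s: header has no sample columns", path)
        dup <- sampleIds[duplicated(sampleIds)]
        if (length(dup))
            stopf("%s: duplicated sample id(s): %s", path,
                  paste(unique(dup), collapse = ", "))
        nf <- length(header)
        body <- fields[-1L]
        lens <- lengths(body)
        if (any(lens != nf))
            stopf("%s: line %d has %d fields, expected %d", path,
                  which(lens != nf)[1L] + 1L, lens[lens != nf][1L], nf)
        geneIds <- vapply(body, `[[`, "", 1L)
        dup <- geneIds[duplicated(geneIds)]
        if (length(dup))
            stopf("%s: duplicated gene id(s): %s", path,
                  paste(unique(dup), collapse = ", "))
        cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
        isMissing <- cells == "." | cells == ""
        vals <- suppressWarnings(as.numeric(cells))
        badCell <- is.na(vals) & !isMissing & cells != "NA"
        if (any(badCell)) {
            i <- which(badCell)[1L]
            stopf("%s: non-numeric value '%s' at line %d", path,
                  cells[i], (i - 1L) %/% length(sampleIds) + 2L)
        }
        m <- matrix(vals, nrow = length(geneIds), byrow = TRUE,
                    dimnames = list(geneIds, sampleIds))
    } else {
        for (p in c(rowIdsPath, colIdsPath))
            if (!file.exists(p))
                stopf("missing MTX id sidecar: %s", p)
        mm <- tryCatch(Matrix::readMM(path), error = function(e)
            stopf("%s: MatrixMarket parse error: %s", path,
                  conditionMessage(e)))
        geneIds <- readLines(rowIdsPath)
        sampleIds <- readLines(colIdsPath)
        if (nrow(mm) != length(geneIds) || ncol(mm) != length(sampleIds))
            stopf("%s: dimensions %d x %d do not match sidecar ids (%d x %d)",
                  path, nrow(mm), ncol(mm), length(geneIds),
                  length(sampleIds))
        for (ids in list(geneIds, sampleIds)) {
            dup <- ids[duplicated(ids)]
            if (length(dup))
                stopf("%s: duplicated id(s) in sidecar: %s", path,
                      paste(unique(dup), collapse = ", "))
        }
        m <- as.matrix(mm)
        dimnames(m) <- list(geneIds, sampleIds)
    }
    if (layer == "counts") {
        if (anyNA(m))
            stopf("%s: missing values are not allowed in a counts layer", path)
        if (any(m < 0))
            stopf("%s: negative values are not allowed in a counts layer", path)
    }
    m
}

#' Write a gene-by-sample expression matrix
#'
#' @param x numeric matrix with gene and sample ids in dimnames.
#' @param path output file path.
#' @param format `"tsv"` (dense, first column `gene_id`) or `"mtx"`
#'   (MatrixMarket coordinate plus `<path>.rows` / `<path>.cols` sidecars).
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    x <- as.matrix(x)
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stopf("'x' must carry gene and sample ids in dimnames")
    if (format == "tsv") {
        df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                         stringsAsFactors = FALSE)
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
        Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                    "generalMatrix"), path)
        writeLines(rownames(x), paste0(path, ".rows"))
        writeLines(colnames(x), paste0(path, ".cols"))
    }
    invisible(path)
}

#' Read and write the sample metadata table
#'
#' The sample table is a TSV with one row per sample; `sample_id`,
#' `age_years` and `tissue` are required, `donor_id`, `sex` and `subsite`
#' conventionally present. Sample ids must be unique and ages finite.
#'
#' @param path file path.
#' @return data.frame of per-sample covariates.
#' @export
readSampleTable <- function(path) {
    if (!file.exists(path))
        stopf("file not found: %s", path)
    df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("sample_id", "age_years", "tissue")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stopf("%s: missing required column(s): %s", path,
              paste(missing, collapse = ", "))
    dup <- df$sample_id[duplicated(df$sample_id)]
    if (length(dup))
        stopf("%s: duplicated sample id(s): %s", path,
              paste(unique(dup), collapse = ", "))
    if (any(!is.finite(df$age_years)))
        stopf("%s: non-finite age_years", path)
    df
}

#' @rdname readSampleTable
#' @param df data.frame to write.
#' @export
writeSampleTable <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a simulated cohort to disk
#'
#' Writes the counts matrix (TSV or MTX), the sample table and the
#' ground-truth gene table of a [simulateCohort()] object to a directory.
#'
#' @param se SummarizedExperiment from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param format matrix format, `"tsv"` or `"mtx"`.
#' @return named vector of written paths, invisibly.
#' @export
exportCohort <- function(se, dir, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (format == "tsv") "tsv" else "mtx"
    paths <- c(counts = file.path(dir, paste0("counts.", ext)),
               samples = file.path(dir, "samples.tsv"),
               truth = file.path(dir, "ground_truth.tsv"))
    writeExpression(SummarizedExperiment::assay(se, "counts"),
                    paths[["counts"]], format = format)
    writeSampleTable(as.data.frame(SummarizedExperiment::colData(se)),
                     paths[["samples"]])
    write.table(as.data.frame(SummarizedExperiment::rowData(se)),
                paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(paths)
}

#' Assemble a SummarizedExperiment from matrix and sample-table files
#'
#' @param matrixPath expression matrix path.
#' @param samplesPath sample table path.
#' @param format matrix format.
#' @return SummarizedExperiment with a `"counts"` assay and the sample table
#'   as `colData`, columns ordered as in the matrix.
#' @export
readCohort <- function(matrixPath, samplesPath, format = c("tsv", "mtx")) {
    m <- readExpression(matrixPath, format = match.arg(format))
    samples <- readSampleTable(samplesPath)
    if (!all(colnames(m) %in% samples$sample_id))
        stopf("sample table does not cover all matrix columns")
    samples <- samples[match(colnames(m), samples$sample_id), , drop = FALSE]
    rownames(samples) <- samples$sample_id
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(samples))
}
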