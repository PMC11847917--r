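#' @rdname vstTransform
#' @export
setGeneric("vstTransform", function(x, ...) standardGeneric("vstTransform"))

#' @rdname residualizeBatch
#' @export
setGeneric("residualizeBatch", function(x, ...)
    standardGeneric("residualizeBatch"))

#' @rdname topVariableGenes
#' @export
setGeneric("topVariableGenes", function(x, n = 1000L, ...)
    standardGeneric("topVariableGenes"))

#' Accessors for screen result objects
#'
#' `meanRho()` returns the per-gene mean fold correlation of a
#' [TissueScreen-class], or the genes x tissues matrix of per-tissue means of
#' a [PanTissueScreen-class]. `panMeanRho()` and `geneRanks()` return the
#' pan-tissue aggregate correlation and the 1-based ranking (1 = strongest
#' positive age association).
#'
#' @param object a screen result object.
#' @return a named numeric vector (or matrix for `meanRho()` on a
#'   [PanTissueScreen-class]).
#' @examples
#' se <- simulateCohort(SimConfig(nTissues = 2, samplesPerTissue = 40,
#'                                nGenes = 50, seed = 1))
#' scr <- screenCohort(se, k = 3, seed = 1, nPerm = 0)
#' head(panMeanRho(scr$pan))
#' @name screen-accessors
#' @export
setGeneric("meanRho", function(object) standardGeneric("meanRho"))

#' @rdname screen-accessors
#' @export
setGeneric("panMeanRho", function(object) standardGeneric("panMeanRho"))

#' @rdname screen-accessors
#' @export
setGeneric("geneRanks", function(object) standardGeneric("geneRanks"))

#' @rdname rankTable
#' @export
setGeneric("rankTable", function(object, ...) standardGeneric("rankTable"))
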