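#' Accessors for epitwas classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an epitwas object.
#' @return The corresponding slot content: `dosages()` the samples x SNPs
#'   matrix, `snpInfo()` the per-SNP DataFrame, `sampleIds()` the sample
#'   identifiers, `zScores()`/`gwasN()` the summary-statistic vectors,
#'   `geneId()`/`modelWeights()`/`modelSnps()`/`cvR2()`/`cisH2()` the
#'   weight-model fields, and `nSnps()`/`nSamples()` dimensions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setGeneric("gwasN", function(x) standardGeneric("gwasN"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setGeneric("modelSnps", function(x) standardGeneric("modelSnps"))
#' @rdname accessors
#' @export
setGeneric("cvR2", function(x) standardGeneric("cvR2"))
#' @rdname accessors
#' @export
setGeneric("cisH2", function(x) standardGeneric("cisH2"))

#' @rdname accessors
setMethod("dosages", "GenotypePanel", function(x) x@dosages)
#' @rdname accessors
setMethod("snpInfo", "GenotypePanel", function(x) x@snps)
#' @rdname accessors
setMethod("sampleIds", "GenotypePanel", function(x) x@sampleIds)
#' @rdname accessors
setMethod("nSnps", "GenotypePanel", function(x) nrow(x@snps))
#' @rdname accessors
setMethod("nSamples", "GenotypePanel", function(x) length(x@sampleIds))
#' @rdname accessors
setMethod("snpInfo", "GwasSummary", function(x) x@snps)
#' @rdname accessors
setMethod("zScores", "GwasSummary", function(x) x@z)
#' @rdname accessors
setMethod("gwasN", "GwasSummary", function(x) x@n)
#' @rdname accessors
setMethod("nSnps", "GwasSummary", function(x) nrow(x@snps))
#' @rdname accessors
setMethod("geneId", "WeightModel", function(x) x@geneId)
#' @rdname accessors
setMethod("modelWeights", "WeightModel", function(x) x@weights)
#' @rdname accessors
setMethod("modelSnps", "WeightModel", function(x) x@snps)
#' @rdname accessors
setMethod("cvR2", "WeightModel", function(x) x@cvR2)
#' @rdname accessors
setMethod("cisH2", "WeightModel", function(x) x@cisH2)

#' Subset a panel to selected SNPs
#'
#' @param x a [GenotypePanel-class].
#' @param snpIdx integer indices or SNP id character vector.
#' @return A new [GenotypePanel-class] restricted to the selected SNPs, in
#'   the order given.
#' @export
subsetSnps <- function(x, snpIdx) {
  stopifnot(is(x, "GenotypePanel"))
  if (is.character(snpIdx)) snpIdx <- match(snpIdx, x@snps$id)
  if (anyNA(snpIdx)) stop("unknown SNP id in subset")
  GenotypePanel(x@dosages[, snpIdx, drop = FALSE], x@snps[snpIdx, ],
                x@sampleIds)
}
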