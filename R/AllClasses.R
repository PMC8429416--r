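#' Genotype reference panel
#'
#' Holds a samples-by-SNPs dosage matrix (ALT-allele counts in `[0, 2]`)
#' together with per-SNP metadata. The panel is the source of linkage
#' disequilibrium (LD) information for all summary-statistic computations.
#'
#' @slot dosages numeric matrix, samples in rows, SNPs in columns.
#' @slot snps [S4Vectors::DataFrame] with columns `id`, `chrom`, `pos`
#'   (1-based), `a1` (effect/ALT allele) and `a2` (other/REF allele).
#' @slot sampleIds character vector of sample identifiers.
#'
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  slots = c(dosages = "matrix", snps = "DataFrame", sampleIds = "character"))

setValidity("GenotypePanel", function(object) {
  msg <- NULL
  d <- object@dosages
  s <- object@snps
  need <- c("id", "chrom", "pos", "a1", "a2")
  if (!all(need %in% colnames(s)))
    msg <- c(msg, paste("snps must have columns", paste(need, collapse = ", ")))
  else {
    if (ncol(d) != nrow(s))
      msg <- c(msg, "dosage column count must equal SNP count")
    if (anyDuplicated(s$id))
      msg <- c(msg, "SNP ids must be unique within a panel")
    if (any(s$a1 == s$a2))
      msg <- c(msg, "effect and other allele must differ")
    if (any(s$pos < 1))
      msg <- c(msg, "positions are 1-based and must be >= 1")
  }
  if (nrow(d) != length(object@sampleIds))
    msg <- c(msg, "dosage row count must equal sample count")
  if (length(d) && (min(d) < 0 || max(d) > 2))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypePanel
#'
#' @param dosages samples x SNPs numeric matrix with entries in `[0, 2]`.
#' @param snps data.frame or DataFrame with columns `id`, `chrom`, `pos`,
#'   `a1`, `a2`.
#' @param sampleIds sample identifiers; defaults to rownames of `dosages`
#'   or `sample1..n`.
#' @return A [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(dosages, snps, sampleIds = NULL) {
  if (is.null(sampleIds))
    sampleIds <- rownames(dosages) %||% paste0("sample", seq_len(nrow(dosages)))
  snps <- S4Vectors::DataFrame(snps)
  snps$id <- as.character(snps$id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$a1 <- as.character(snps$a1)
  snps$a2 <- as.character(snps$a2)
  colnames(dosages) <- snps$id
  new("GenotypePanel", dosages = dosages, snps = snps,
      sampleIds = as.character(sampleIds))
}

#' GWAS summary statistics
#'
#' Per-SNP z-scores with allele information and GWAS sample size,
#' harmonizable against expression-weight models.
#'
#' @slot snps [S4Vectors::DataFrame] with columns `id`, `chrom`, `pos`,
#'   `a1`, `a2` (`chrom`/`pos` may be `NA` when absent from the input).
#' @slot z numeric z-scores (finite).
#' @slot n numeric GWAS sample size per SNP.
#'
#' @aliases GwasSummary-class
#' @exportClass GwasSummary
setClass("GwasSummary",
  slots = c(snps = "DataFrame", z = "numeric", n = "numeric"))

setValidity("GwasSummary", function(object) {
  msg <- NULL
  if (nrow(object@snps) != length(object@z))
    msg <- c(msg, "one z-score per SNP required")
  if (any(!is.finite(object@z)))
    msg <- c(msg, "z-scores must be finite")
  if (any(is.na(object@snps$a1)) || any(is.na(object@snps$a2)))
    msg <- c(msg, "alleles must be non-missing")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GwasSummary
#'
#' @param snps data.frame or DataFrame with `id`, `a1`, `a2` and optional
#'   `chrom`, `pos`.
#' @param z numeric z-scores, one per SNP.
#' @param n GWAS sample size (scalar or per SNP).
#' @return A [GwasSummary-class] object.
#' @export
GwasSummary <- function(snps, z, n) {
  snps <- S4Vectors::DataFrame(snps)
  if (is.null(snps$chrom)) snps$chrom <- NA_character_
  if (is.null(snps$pos)) snps$pos <- NA_integer_
  snps$id <- as.character(snps$id)
  snps$a1 <- as.character(snps$a1)
  snps$a2 <- as.character(snps$a2)
  if (length(n) == 1L) n <- rep(as.numeric(n), nrow(snps))
  new("GwasSummary", snps = snps, z = as.numeric(z), n = n)
}

#' Per-gene expression prediction model
#'
#' The final penalized-regression weights for one gene in one tissue,
#' with the training metadata needed downstream: the winning SNP-set
#' parameters (eQTL P-value threshold and annotation filter), the mean
#' cross-validated prediction R-squared, and the cis-heritability estimate
#' with its standard error. Weights are per standard deviation of dosage,
#' on standardized expression.
#'
#' @slot geneId,tissue character scalars.
#' @slot snps [S4Vectors::DataFrame] of model SNPs (`id`, `chrom`, `pos`,
#'   `a1`, `a2`).
#' @slot weights numeric weight vector, one per model SNP, not all zero.
#' @slot method `"lasso"` or `"enet"`.
#' @slot eqtlPThreshold,cvR2,cisH2,cisH2Se numeric scalars.
#' @slot annotationFilter character scalar (`"all"`, `"any_feature"` or a
#'   feature name).
#'
#' @aliases WeightModel-class
#' @exportClass WeightModel
setClass("WeightModel",
  slots = c(geneId = "character", tissue = "character", snps = "DataFrame",
            weights = "numeric", method = "character",
            eqtlPThreshold = "numeric", annotationFilter = "character",
            cvR2 = "numeric", cisH2 = "numeric", cisH2Se = "numeric"))

setValidity("WeightModel", function(object) {
  msg <- NULL
  if (nrow(object@snps) != length(object@weights))
    msg <- c(msg, "one weight per model SNP required")
  if (length(object@weights) == 0L || all(object@weights == 0))
    msg <- c(msg, "at least one nonzero weight required")
  if (length(object@cvR2) && is.finite(object@cvR2) && object@cvR2 > 1)
    msg <- c(msg, "cvR2 cannot exceed 1")
  if (!object@method %in% c("lasso", "enet"))
    msg <- c(msg, "method must be 'lasso' or 'enet'")
  if (is.null(msg)) TRUE else msg
})

#' Construct a WeightModel
#'
#' @param geneId,tissue identifiers.
#' @param snps data.frame/DataFrame of model SNPs (`id`, `chrom`, `pos`,
#'   `a1`, `a2`).
#' @param weights numeric vector, one per SNP.
#' @param method `"lasso"` or `"enet"`.
#' @param eqtlPThreshold,annotationFilter winning SNP-set parameters.
#' @param cvR2 mean cross-validated R-squared of the winning model.
#' @param cisH2,cisH2Se cis-heritability estimate and standard error.
#' @return A [WeightModel-class] object.
#' @export
WeightModel <- function(geneId, snps, weights, method = "lasso",
                        tissue = "synthetic", eqtlPThreshold = 1,
                        annotationFilter = "all", cvR2 = NA_real_,
                        cisH2 = NA_real_, cisH2Se = NA_real_) {
  snps <- S4Vectors::DataFrame(snps)
  snps$id <- as.character(snps$id)
  new("WeightModel", geneId = as.character(geneId), tissue = as.character(tissue),
      snps = snps, weights = as.numeric(weights), method = method,
      eqtlPThreshold = as.numeric(eqtlPThreshold),
      annotationFilter = as.character(annotationFilter),
      cvR2 = as.numeric(cvR2), cisH2 = as.numeric(cisH2),
      cisH2Se = as.numeric(cisH2Se))
}

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", length(object@sampleIds), "samples x",
      nrow(object@snps), "SNPs\n")
  if (nrow(object@snps)) {
    chr <- unique(object@snps$chrom)
    cat("  chromosomes:", paste(head(chr, 5), collapse = ", "),
        if (length(chr) > 5) "..." else "", "\n")
  }
})

setMethod("show", "GwasSummary", function(object) {
  cat("GwasSummary:", length(object@z), "SNPs, N =",
      format(max(object@n)), "\n")
})

setMethod("show", "WeightModel", function(object) {
  cat("WeightModel", object@geneId, "(", object@tissue, "):",
      length(object@weights), "SNPs,", sum(object@weights != 0), "nonzero;",
      "method =", object@method,
      sprintf("(p<=%g, filter=%s)", object@eqtlPThreshold,
              object@annotationFilter), "\n")
  cat(sprintf("  cv R2 = %.3f; cis h2 = %.3f (se %.3f)\n",
              object@cvR2, object@cisH2, object@cisH2Se))
})
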