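#' Count known disease genes below a TWAS p cutoff
#'
#' @param geneP named numeric vector: per-gene TWAS p (minimum across
#'   tissues when a gene was tested in several).
#' @param known character vector of known disease-associated genes.
#' @param pCut p-value cutoff, default 0.01.
#' @return Number of known genes among the tested genes with `p < pCut`.
#' @export
countKnownHits <- function(geneP, known, pCut = 0.01) {
  tested <- names(geneP)
  sum(tested %in% known & geneP < pCut, na.rm = TRUE)
}

#' Permutation enrichment of known disease genes among TWAS results
#'
#' Compares the observed count of known genes with TWAS `p < pCut` to a
#' null built from `nDraws` random gene sets of the same size drawn
#' uniformly (without replacement) from all tested genes. The empirical p
#' is `(#{null >= observed} + 1) / (nDraws + 1)`, floored at
#' `1 / (nDraws + 1)`.
#'
#' @inheritParams countKnownHits
#' @param nDraws number of random gene sets, default 10,000.
#' @param seed integer seed.
#' @return list with `observed`, `nullCounts`, `expected` (null mean) and
#'   `empiricalP`.
#' @export
enrichmentPermutation <- function(geneP, known, nDraws = 10000, pCut = 0.01,
                                  seed = 1L) {
  tested <- names(geneP)
  k <- sum(tested %in% known)
  if (k == 0) stop("no known genes among the tested genes")
  observed <- countKnownHits(geneP, known, pCut)
  hit <- geneP < pCut & !is.na(geneP)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "catalog-enrichment"))
  nullCounts <- vapply(seq_len(nDraws), function(i) {
    sum(hit[sample.int(length(tested), k)])
  }, integer(1))
  list(observed = observed, nullCounts = nullCounts,
       expected = mean(nullCounts),
       empiricalP = empiricalP(sum(nullCounts >= observed), nDraws))
}
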