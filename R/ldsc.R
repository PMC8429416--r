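#' Gene-set SNP annotation for partitioned heritability
#'
#' Marks every panel SNP lying within `window` bp of any listed gene's
#' transcript span (`pos` in `[start - window, end + window]`, inclusive).
#'
#' @param genes `GRanges` of gene spans (e.g. TWAS-identified genes at
#'   p < 0.01).
#' @param panel a [GenotypePanel-class].
#' @param window bp flank, default 2,000.
#' @return Logical vector over the panel SNPs.
#' @export
geneSetSnpAnnotation <- function(genes, panel, window = 2000) {
  s <- snpInfo(panel)
  snpGr <- GRanges(s$chrom, IRanges(s$pos, s$pos))
  ext <- GRanges(GenomicRanges::seqnames(genes),
                 IRanges(pmax(GenomicRanges::start(genes) - window, 1),
                         GenomicRanges::end(genes) + window))
  IRanges::overlapsAny(snpGr, ext, ignore.strand = TRUE)
}

#' Stratified LD scores
#'
#' `l(j, c) = sum over k in c with |k - j| <= window of r2_adj(j, k)`,
#' where `r2_adj = r2 - (1 - r2) / (n - 2)` is the standard finite-sample
#' bias adjustment, floored at 0 term by term (which also guarantees that
#' a sub-category's score never exceeds the base score). The window is
#' counted in SNPs and never crosses a chromosome boundary; the self term
#' contributes 1.
#'
#' @param panel reference [GenotypePanel-class].
#' @param categories logical/0-1 matrix, SNPs x categories (include a base
#'   column of all `TRUE` for the standard model).
#' @param windowSnps one-sided window size in SNPs, default 100.
#' @return list with `ell` (SNPs x categories matrix of LD scores),
#'   `M` (per-category SNP counts) and `nRef`.
#' @export
ldScores <- function(panel, categories, windowSnps = 100) {
  A <- as.matrix(categories) * 1
  m <- nSnps(panel)
  stopifnot(nrow(A) == m)
  n <- nSamples(panel)
  Xs <- standardizeColumns(dosages(panel))
  chrom <- snpInfo(panel)$chrom
  ell <- A * 1  # self term: r2_adj(j, j) = 1
  for (d in seq_len(min(windowSnps, m - 1))) {
    j <- seq_len(m - d)
    k <- j + d
    ok <- chrom[j] == chrom[k]
    if (!any(ok)) next
    r <- colSums(Xs[, j, drop = FALSE] * Xs[, k, drop = FALSE]) / n
    r2 <- r^2
    adj <- pmax(r2 - (1 - r2) / (n - 2), 0)
    adj[!ok] <- 0
    # pair (j, k) contributes to l(j, .) if k in category, and vice versa
    ell[j, ] <- ell[j, ] + adj * A[k, , drop = FALSE]
    ell[k, ] <- ell[k, ] + adj * A[j, , drop = FALSE]
  }
  colnames(ell) <- colnames(A)
  list(ell = ell, M = colSums(A), nRef = n)
}

# Weighted least squares of chi2 on N * ell with free or fixed intercept;
# returns tau (per category) and the intercept.
ldscWls <- function(chi2, N, ell, w, intercept = TRUE) {
  X <- N * ell
  if (intercept) X <- cbind(`(intercept)` = 1, X)
  sw <- sqrt(w)
  fit <- lm.fit(X * sw, chi2 * sw)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  if (intercept) list(tau = b[-1], intercept = b[1])
  else list(tau = b, intercept = 1)
}

# Per-category h2 and enrichment from tau and the annotation matrix.
ldscSummaries <- function(tau, A) {
  perSnp <- drop(A %*% tau)            # per-SNP heritability
  h2Tot <- sum(perSnp)
  h2Cat <- drop(t(A) %*% perSnp)       # sum of per-SNP h2 over members
  propH2 <- h2Cat / h2Tot
  propSnps <- colSums(A) / nrow(A)
  list(h2Tot = h2Tot, h2Cat = h2Cat, propH2 = propH2, propSnps = propSnps,
       enrichment = propH2 / propSnps)
}

#' Stratified LD score regression
#'
#' Regresses per-SNP GWAS chi-squared statistics on category-stratified LD
#' scores (`E[chi2_j] = 1 + N sum_c tau_c l(j,c)`, free intercept by
#' default), derives each category's heritability share and its enrichment
#' relative to its SNP share, and attaches block-jackknife standard errors
#' (delete-one over contiguous SNP blocks) with a two-sided normal p-value
#' on `(enrichment - 1) / se`.
#'
#' @param chi2 per-SNP chi-squared statistics (`z^2`).
#' @param N GWAS sample size.
#' @param scores list from [ldScores()].
#' @param categories the SNPs x categories matrix used for the scores.
#' @param nBlocks jackknife blocks, default 200.
#' @param intercept estimate the intercept freely (default) or fix it at 1.
#' @return data.frame, one row per category: category, prop_snps, prop_h2,
#'   prop_h2_se, enrichment, enrichment_se, enrichment_p, tau; attribute
#'   `"h2Total"` carries the total heritability estimate. Flagged
#'   non-estimable (all `NA` enrichment) when the total h2 estimate is
#'   not positive.
#' @export
stratifiedLdsc <- function(chi2, N, scores, categories, nBlocks = 200,
                           intercept = TRUE) {
  A <- as.matrix(categories) * 1
  ell <- scores$ell
  m <- length(chi2)
  stopifnot(nrow(ell) == m, nrow(A) == m)
  base <- pmax(ell[, 1], 1)
  # two-step LDSC-style weights: heteroscedasticity x LD redundancy
  w0 <- 1 / base
  f0 <- ldscWls(chi2, N, ell, w0, intercept)
  pred <- pmax(f0$intercept + N * drop(ell %*% f0$tau), 0.1)
  w <- 1 / (base * 2 * pred^2)
  fit <- ldscWls(chi2, N, ell, w, intercept)
  sm <- ldscSummaries(fit$tau, A)

  nBlocks <- min(nBlocks, m %/% 2)
  blk <- ceiling(seq_len(m) / (m / nBlocks))
  enrJack <- matrix(NA_real_, nBlocks, ncol(A))
  propJack <- matrix(NA_real_, nBlocks, ncol(A))
  for (b in seq_len(nBlocks)) {
    keep <- blk != b
    fb <- ldscWls(chi2[keep], N, ell[keep, , drop = FALSE], w[keep],
                  intercept)
    sb <- ldscSummaries(fb$tau, A[keep, , drop = FALSE])
    enrJack[b, ] <- sb$enrichment
    propJack[b, ] <- sb$propH2
  }
  jackSe <- function(est) {
    mn <- colMeans(est, na.rm = TRUE)
    sqrt((nBlocks - 1) / nBlocks *
           colSums(sweep(est, 2, mn)^2, na.rm = TRUE))
  }
  enrSe <- jackSe(enrJack)
  propSe <- jackSe(propJack)
  # a category containing every SNP has enrichment identically 1 (se 0)
  enrP <- ifelse(enrSe < 1e-12 & abs(sm$enrichment - 1) < 1e-8, 1,
                 2 * pnorm(-abs((sm$enrichment - 1) / enrSe)))
  out <- data.frame(
    category = colnames(A) %||% paste0("cat", seq_len(ncol(A))),
    prop_snps = sm$propSnps,
    prop_h2 = sm$propH2,
    prop_h2_se = propSe,
    enrichment = sm$enrichment,
    enrichment_se = enrSe,
    enrichment_p = enrP,
    tau = fit$tau,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "h2Total") <- sm$h2Tot
  attr(out, "intercept") <- fit$intercept
  if (!is.finite(sm$h2Tot) || sm$h2Tot <= 0) {
    out$enrichment <- NA_real_
    out$enrichment_p <- NA_real_
    attr(out, "nonEstimable") <- TRUE
  }
  out
}
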