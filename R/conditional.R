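# Ridge-regularized inverse used for near-collinear predictor correlation
# matrices: add eps to the diagonal and rescale back to unit diagonal.
ridgeRegularize <- function(C, eps = 0.05) {
  (C + eps * diag(nrow(C))) / (1 + eps)
}

#' Merge significant genes into conditional-analysis regions
#'
#' Genes whose transcribed spans fall within 1 Mb of a common anchor are
#' merged into one region, transitively until a fixpoint: spans extended by
#' `flank` on each side are unioned, and genes sharing a union interval
#' share a region.
#'
#' @param genes `GRanges` of (significant) gene transcript spans, named by
#'   gene id.
#' @param flank bp added to each side before merging, default 1 Mb.
#' @return data.frame with `gene_id` and integer `region`.
#' @export
defineRegions <- function(genes, flank = 1e6) {
  ext <- GRanges(GenomicRanges::seqnames(genes),
                 IRanges(pmax(GenomicRanges::start(genes) - flank, 1),
                         GenomicRanges::end(genes) + flank))
  red <- reduce(ext, ignore.strand = TRUE)
  hit <- findOverlaps(ext, red, ignore.strand = TRUE)
  data.frame(gene_id = names(genes),
             region = S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))],
             stringsAsFactors = FALSE)
}

# Zero-pad model weights onto a SNP-id union.
padWeights <- function(model, unionIds) {
  w <- numeric(length(unionIds))
  idx <- match(as.character(modelSnps(model)$id), unionIds)
  w[idx] <- modelWeights(model)
  w
}

#' Correlation between two genes' predicted expression
#'
#' `corr = w1' R w2 / sqrt(w1'Rw1 * w2'Rw2)` with both weight vectors
#' zero-padded onto the union of model SNPs and `R` the reference LD over
#' that union. Equals the correlation of the individual-level predicted
#' expressions on the reference panel (up to the standardization
#' convention).
#'
#' @param m1,m2 [WeightModel-class] objects.
#' @param panel LD reference [GenotypePanel-class].
#' @return numeric scalar in `[-1, 1]`.
#' @export
predictorCorrelation <- function(m1, m2, panel) {
  unionIds <- union(as.character(modelSnps(m1)$id),
                    as.character(modelSnps(m2)$id))
  R <- ldCorrelation(panel, unionIds)
  w1 <- padWeights(m1, unionIds)
  w2 <- padWeights(m2, unionIds)
  drop(t(w1) %*% R %*% w2) /
    sqrt(drop(t(w1) %*% R %*% w1) * drop(t(w2) %*% R %*% w2))
}

# Predictor correlation matrix over a list of models.
predictorCorrelationMatrix <- function(models, panel) {
  unionIds <- Reduce(union, lapply(models, function(m)
    as.character(modelSnps(m)$id)))
  R <- ldCorrelation(panel, unionIds)
  W <- vapply(models, padWeights, numeric(length(unionIds)),
              unionIds = unionIds)
  S <- t(W) %*% R %*% W
  d <- sqrt(diag(S))
  C <- S / outer(d, d)
  diag(C) <- 1
  dimnames(C) <- list(vapply(models, geneId, character(1)),
                      vapply(models, geneId, character(1)))
  C
}

#' Forward-stepwise joint gene selection within a region
#'
#' Seeds with the gene of smallest marginal p, then repeatedly adds the
#' gene with the smallest conditional p — where
#' `z_cond = (z_g - rho' Ck^{-1} z_kept) / sqrt(1 - rho' Ck^{-1} rho)` and
#' `rho` is the predictor correlation of the candidate with the kept set —
#' while that conditional p stays below `threshold`. Inversions use the
#' ridge-regularized kept-set correlation. The joint z-scores reported for
#' the kept genes are `Ck^{-1} z_kept`.
#'
#' @param z named marginal TWAS z-scores, one per gene in the region.
#' @param C predictor correlation matrix (genes x genes).
#' @param threshold significance threshold on the conditional p, e.g. the
#'   study-wise Bonferroni threshold.
#' @param ridge diagonal regularization added before inversion.
#' @return list with `kept` (gene names in selection order), `jointZ`
#'   (per kept gene) and `conditionalP` (p at entry per kept gene).
#' @export
jointSelectGenes <- function(z, C, threshold, ridge = 0.05) {
  genes <- names(z)
  stopifnot(!is.null(genes), all(genes %in% rownames(C)))
  p <- 2 * pnorm(-abs(z))
  kept <- genes[which.min(p)]
  entryP <- p[kept]
  if (entryP >= threshold)
    return(list(kept = character(0), jointZ = numeric(0),
                conditionalP = numeric(0)))
  repeat {
    rest <- setdiff(genes, kept)
    if (!length(rest)) break
    Ck <- ridgeRegularize(C[kept, kept, drop = FALSE], ridge)
    Cinv <- solve(Ck)
    zc <- vapply(rest, function(g) {
      rho <- C[g, kept]
      den <- 1 - drop(t(rho) %*% Cinv %*% rho)
      if (den <= 1e-6) return(0)
      (z[g] - drop(t(rho) %*% Cinv %*% z[kept])) / sqrt(den)
    }, numeric(1))
    pc <- 2 * pnorm(-abs(zc))
    bestG <- rest[which.min(pc)]
    if (pc[bestG] >= threshold) break
    # collinearity guard: drop the later-added gene if the kept-set
    # correlation becomes numerically singular
    Ctry <- C[c(kept, bestG), c(kept, bestG), drop = FALSE]
    if (kappa(ridgeRegularize(Ctry, ridge)) > 1e8) break
    kept <- c(kept, bestG)
    entryP <- c(entryP, pc[bestG])
  }
  Ck <- ridgeRegularize(C[kept, kept, drop = FALSE], ridge)
  jointZ <- drop(solve(Ck, z[kept]))
  names(jointZ) <- kept
  list(kept = kept, jointZ = jointZ, conditionalP = entryP)
}

#' Conditional per-SNP GWAS scan given a joint gene model
#'
#' Conditions each SNP's GWAS z-score on the predicted expression of the
#' kept genes, one SNP at a time:
#' `rho_s,i = (R w_i)_s / sqrt(w_i' R w_i)`,
#' `z_cond(s) = (z_s - rho_s' C^{-1} z_genes) / sqrt(1 - rho_s' C^{-1} rho_s)`.
#' SNPs whose signal is fully explained (`1 - rho' C^{-1} rho <= 1e-6`)
#' report `z_cond = 0`, `p = 1` and are flagged.
#'
#' @param models list of kept [WeightModel-class] objects.
#' @param gwas [GwasSummary-class].
#' @param panel LD reference [GenotypePanel-class].
#' @param flank bp around the gene spans defining the region, default 1 Mb.
#' @param ridge regularization for the gene-correlation inversion.
#' @param region optional `list(chrom, start, end)` overriding the region
#'   derived from the models' SNP spans; required when `models` is empty
#'   (conditioning on an empty gene set is the identity on z).
#' @return data.frame: snp, chrom, pos, z_marg, p_marg, z_cond, p_cond,
#'   explained (logical flag).
#' @export
conditionalSnpScan <- function(models, gwas, panel, flank = 1e6,
                               ridge = 0.05, region = NULL) {
  s <- snpInfo(panel)
  if (is.null(region)) {
    if (!length(models)) stop("empty gene set requires an explicit region")
    spans <- do.call(rbind, lapply(models, function(m) {
      ms <- as.data.frame(modelSnps(m))
      data.frame(chrom = ms$chrom[1], start = min(ms$pos), end = max(ms$pos))
    }))
    region <- list(chrom = spans$chrom[1], start = min(spans$start),
                   end = max(spans$end))
  }
  regionIdx <- which(s$chrom == region$chrom &
                     s$pos >= region$start - flank &
                     s$pos <= region$end + flank)
  if (!length(regionIdx)) stop("no panel SNPs in region")
  h <- harmonizeAlleles(s[regionIdx, ], gwas)
  regionIdx <- regionIdx[h$kept]
  ids <- s$id[regionIdx]
  z <- h$z
  chr <- region$chrom
  if (!length(models)) {
    return(data.frame(snp = ids, chrom = chr, pos = s$pos[regionIdx],
                      z_marg = z, p_marg = 2 * pnorm(-abs(z)),
                      z_cond = z, p_cond = 2 * pnorm(-abs(z)),
                      explained = FALSE, stringsAsFactors = FALSE))
  }
  R <- ldCorrelation(panel, regionIdx)
  W <- vapply(models, padWeights, numeric(length(ids)), unionIds = ids)
  qf <- sqrt(diag(t(W) %*% R %*% W))       # per-gene sd of predicted expr
  zg <- drop(t(W) %*% z) / qf              # marginal TWAS z of kept genes
  P <- (R %*% W) / rep(qf, each = length(ids))  # rho_{s,i}
  C <- t(W) %*% R %*% W / outer(qf, qf)
  diag(C) <- 1
  Cinv <- solve(ridgeRegularize(C, ridge))
  num <- z - drop(P %*% Cinv %*% zg)
  den <- 1 - rowSums((P %*% Cinv) * P)
  explained <- den <= 1e-6
  zc <- ifelse(explained, 0, num / sqrt(pmax(den, 1e-12)))
  data.frame(snp = ids, chrom = chr, pos = s$pos[regionIdx],
             z_marg = z, p_marg = 2 * pnorm(-abs(z)),
             z_cond = zc, p_cond = ifelse(explained, 1, 2 * pnorm(-abs(zc))),
             explained = explained, stringsAsFactors = FALSE)
}

#' Proportion of the lead-SNP GWAS signal explained by expression
#'
#' `1 - chi2_cond(s*) / chi2_marg(s*)` at the marginal lead SNP `s*` of the
#' region, clamped to `[0, 1]`.
#'
#' @param scan data.frame from [conditionalSnpScan()].
#' @return Proportion in `[0, 1]`.
#' @export
signalExplained <- function(scan) {
  lead <- which.max(abs(scan$z_marg))
  prop <- 1 - scan$z_cond[lead]^2 / scan$z_marg[lead]^2
  min(max(prop, 0), 1)
}
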