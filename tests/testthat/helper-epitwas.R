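# Shared builders for in-code fixtures.

# Panel from an explicit samples x SNPs dosage matrix.
makePanel <- function(dosages, pos = NULL, chrom = "chr1",
                      a1 = "A", a2 = "G", ids = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(ids)) ids <- paste0("s", seq_len(m))
  GenotypePanel(dosages,
    data.frame(id = ids, chrom = rep_len(chrom, m), pos = pos,
               a1 = rep_len(a1, m), a2 = rep_len(a2, m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent-SNP panel with binomial dosages.
randPanel <- function(n, m, maf = 0.3, seed = 1) {
  set.seed(seed)
  makePanel(matrix(rbinom(n * m, 2, maf), n, m))
}

# GwasSummary sharing a panel's SNP metadata.
gwasFromZ <- function(panel, z, n = 10000) {
  GwasSummary(as.data.frame(snpInfo(panel))[, c("id", "chrom", "pos", "a1", "a2")],
              z = z, n = n)
}

# Light-weight weight model: eQTL prefilter + lasso on the full reference
# data (no outer CV) — used where a test exercises downstream machinery,
# not model selection.
quickWeightModel <- function(panel, cisIdx, expression, gid, seed = 1,
                             pThreshold = 0.5) {
  X <- dosages(panel)[, cisIdx, drop = FALSE]
  eq <- eqtlScan(X, expression)
  memb <- which(eq$p <= pThreshold)
  if (!length(memb)) return(NULL)
  Xs <- epitwas:::standardizeColumns(X[, memb, drop = FALSE])
  ys <- epitwas:::standardizeVector(expression)
  f <- fitPenalizedModel(Xs, ys, "lasso", seed = seed)
  if (!f$usable || all(f$w == 0)) return(NULL)
  keep <- which(f$w != 0)
  WeightModel(gid,
              as.data.frame(snpInfo(panel)[cisIdx[memb][keep],
                            c("id", "chrom", "pos", "a1", "a2")]),
              f$w[keep])
}

# Reconstructs the exact GWAS cohort and phenotype that simulateGwas() drew
# for a config (same derived seeds), so individual-level regressions can
# serve as an oracle for summary-statistic computations.
gwasCohort <- function(cfg, truth) {
  meta <- epitwas:::snpMeta(cfg)
  X <- epitwas:::drawDosages(cfg, meta, cfg$nGwas,
                             epitwas:::deriveSeed(cfg$seed, "gwas-cohort"))
  Xs <- epitwas:::standardizeColumns(X)
  set.seed(epitwas:::deriveSeed(cfg$seed, "gwas-pheno"))
  gsum <- numeric(cfg$nGwas)
  alpha <- cfg$genes$alpha
  for (i in seq_len(nrow(cfg$genes))) {
    if (alpha[i] == 0) next
    tr <- truth[[as.character(cfg$genes$gene_id[i])]]
    if (all(tr$trueWeights == 0)) next
    gen <- drop(Xs[, tr$cisIdx, drop = FALSE] %*% tr$trueWeights)
    gsum <- gsum + alpha[i] * epitwas:::standardizeVector(gen)
  }
  vg <- mean((gsum - mean(gsum))^2)
  y <- gsum + rnorm(cfg$nGwas, 0, sqrt(max(1 - vg, 0.02)))
  list(Xs = Xs, y = y)
}
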