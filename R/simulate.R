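#' Simulation configuration
#'
#' Describes a synthetic study: a block-LD genotype process shared by the
#' reference panel and an independent GWAS cohort, and a table of gene loci
#' with sparse cis effects on expression and (optionally) expression-mediated
#' effects on the phenotype. Each locus lives on its own chromosome so gene
#' cis windows are disjoint unless two genes deliberately share a locus.
#'
#' @param nRef reference-panel sample count.
#' @param nGwas GWAS cohort sample count.
#' @param snpsPerLocus SNPs simulated per locus.
#' @param blockSize SNPs per LD block (AR(1) within block, blocks
#'   independent).
#' @param rho within-block adjacent-SNP latent correlation, `0 <= rho < 1`.
#' @param mafRange minor allele frequency range, each SNP's MAF drawn
#'   uniformly.
#' @param snpSpacing base pairs between adjacent SNPs.
#' @param genes data.frame with columns `gene_id`, `locus` (integer; genes
#'   sharing a locus share cis SNPs), `kCausal`, `cisH2` (`0 <= cisH2 < 1`),
#'   `enrichment` (odds multiplier for causal SNPs to fall in annotated
#'   positions) and `alpha` (per-SD effect of the gene's genetic expression
#'   component on the phenotype).
#' @param seed integer master seed; fully determines all output.
#' @return A `SimConfig` (validated list).
#' @export
simConfig <- function(nRef = 300, nGwas = 5000, snpsPerLocus = 20,
                      blockSize = 5, rho = 0.7, mafRange = c(0.05, 0.5),
                      snpSpacing = 1000L,
                      genes = data.frame(gene_id = "gene1", locus = 1L,
                                         kCausal = 3L, cisH2 = 0.3,
                                         enrichment = 1, alpha = 0),
                      seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must satisfy 0 <= rho < 1")
  if (any(genes$cisH2 < 0 | genes$cisH2 >= 1))
    stop("cisH2 must satisfy 0 <= cisH2 < 1")
  if (any(genes$kCausal < 1)) stop("kCausal must be >= 1")
  if (any(genes$kCausal > snpsPerLocus)) stop("kCausal exceeds locus size")
  if (sum(genes$alpha^2) >= 1)
    stop("sum of squared gene effects must be < 1 (unit phenotype variance)")
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must lie in (0, 0.5]")
  cfg <- list(nRef = as.integer(nRef), nGwas = as.integer(nGwas),
              snpsPerLocus = as.integer(snpsPerLocus),
              blockSize = as.integer(blockSize), rho = rho,
              mafRange = mafRange, snpSpacing = as.integer(snpSpacing),
              genes = genes, seed = as.integer(seed))
  cfg$loci <- sort(unique(as.integer(genes$locus)))
  cfg$m <- length(cfg$loci) * cfg$snpsPerLocus
  class(cfg) <- "SimConfig"
  cfg
}

# Deterministic SNP metadata shared by every cohort drawn from a config:
# ids, positions, non-ambiguous allele pairs, per-SNP MAF and LD block.
snpMeta <- function(cfg) {
  withr_seed <- deriveSeed(cfg$seed, "snp-meta")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  nl <- length(cfg$loci)
  k <- cfg$snpsPerLocus
  m <- cfg$m
  locus <- rep(cfg$loci, each = k)
  within <- rep(seq_len(k), nl)
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                    "G", "A", "C", "A", "G", "T", "C", "T"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), m, replace = TRUE)
  data.frame(
    id = paste0("rs", seq_len(m)),
    chrom = paste0("chr", locus),
    pos = as.integer(1e6 + (within - 1L) * cfg$snpSpacing),
    a1 = pairs[pick, 1], a2 = pairs[pick, 2],
    maf = runif(m, cfg$mafRange[1], cfg$mafRange[2]),
    block = (seq_len(m) - 1L) %/% cfg$blockSize + 1L,
    locus = locus, stringsAsFactors = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# One cohort of hard-call dosages: latent Gaussian AR(1) within LD block,
# thresholded at the MAF quantile per haplotype, two haplotypes summed.
drawDosages <- function(cfg, meta, n, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- nrow(meta)
  d <- matrix(0, n, m)
  thr <- qnorm(meta$maf)
  for (hap in 1:2) {
    z <- matrix(rnorm(n * m), n, m)
    if (cfg$rho > 0 && cfg$blockSize > 1) {
      s <- sqrt(1 - cfg$rho^2)
      for (j in 2:m) {
        if (meta$block[j] == meta$block[j - 1L])
          z[, j] <- cfg$rho * z[, j - 1L] + s * z[, j]
      }
    }
    d <- d + (z < rep(thr, each = n))
  }
  # guard against monomorphic columns (possible at small n and low MAF)
  cst <- which(apply(d, 2, function(x) max(x) == min(x)))
  for (j in cst) d[sample.int(n, 1), j] <- if (d[1, j] == 0) 1 else d[1, j] - 1
  storage.mode(d) <- "double"
  d
}

#' Simulate a genotype reference panel
#'
#' Dosages arise from a latent Gaussian AR(1) process per LD block,
#' thresholded by MAF-derived quantiles into two haplotypes that are summed;
#' blocks are independent. The same configuration deterministically yields
#' the same SNP metadata (ids, positions, alleles, MAFs), so independent
#' cohorts drawn from one config are allele-compatible.
#'
#' @param cfg a [simConfig()].
#' @param cohort `"reference"` (seeded by `cfg$seed`) or `"gwas"` (an
#'   independent cohort of `nGwas` samples from the same process).
#' @return A [GenotypePanel-class]; its `snpInfo()` carries `maf`, `block`
#'   and `locus` columns.
#' @export
simulateGenotypes <- function(cfg, cohort = c("reference", "gwas")) {
  stopifnot(inherits(cfg, "SimConfig"))
  cohort <- match.arg(cohort)
  meta <- snpMeta(cfg)
  n <- if (cohort == "reference") cfg$nRef else cfg$nGwas
  seed <- if (cohort == "reference") deriveSeed(cfg$seed, "ref-cohort")
          else deriveSeed(cfg$seed, "gwas-cohort")
  d <- drawDosages(cfg, meta, n, seed)
  prefix <- if (cohort == "reference") "ref" else "gwas"
  GenotypePanel(d, meta, sampleIds = paste0(prefix, seq_len(n)))
}

#' Simulate epigenetic annotation features over a panel
#'
#' Each feature independently covers approximately the requested fraction of
#' SNP positions: every SNP is included with probability `density`, and
#' included SNPs are emitted as width-1 intervals at their positions.
#'
#' @param panel a [GenotypePanel-class].
#' @param featureDensities named numeric vector, fraction of SNP positions
#'   each feature should cover (e.g. `c(TFBS = 0.2, DHS = 0.3)`).
#' @param seed integer seed.
#' @return A named [GenomicRanges::GRangesList], one element per feature.
#' @export
simulateAnnotations <- function(panel, featureDensities, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "annotations"))
  s <- snpInfo(panel)
  grl <- lapply(names(featureDensities), function(f) {
    keep <- runif(nrow(s)) < featureDensities[[f]]
    GRanges(s$chrom[keep], IRanges(s$pos[keep], s$pos[keep]))
  })
  names(grl) <- names(featureDensities)
  GRangesList(grl)
}

#' Gene coordinates implied by a configuration
#'
#' Every gene spans the SNP range of its locus (genes sharing a locus share
#' the span, hence their cis windows coincide).
#'
#' @param cfg a [simConfig()].
#' @return A `GRanges` with `gene_id` metadata, one range per gene.
#' @export
configGenes <- function(cfg) {
  meta <- snpMeta(cfg)
  g <- cfg$genes
  gr <- GRanges(paste0("chr", g$locus),
                IRanges(rep(1e6L, nrow(g)),
                        as.integer(1e6 + (cfg$snpsPerLocus - 1L) * cfg$snpSpacing)),
                strand = "+")
  mcols(gr)$gene_id <- as.character(g$gene_id)
  names(gr) <- g$gene_id
  gr
}

#' Simulate expression for one gene
#'
#' Picks `kCausal` causal SNPs among the gene's cis SNPs, preferentially
#' from annotated positions with odds multiplier `enrichment`, draws their
#' effects from N(0,1), and adds Gaussian noise scaled so the genetic
#' component explains exactly `cisH2` of the expression variance. With
#' `cisH2 = 0` the true weights are all zero and expression is pure noise.
#'
#' @param panel the reference [GenotypePanel-class].
#' @param cfg the [simConfig()] the panel came from.
#' @param geneId gene to simulate (row of `cfg$genes`).
#' @param annotations optional `GRangesList` of features used for causal-SNP
#'   enrichment.
#' @return list with `expression` (length `nRef`), `trueWeights` (per cis
#'   SNP, standardized-dosage scale), `cisIdx` (panel SNP indices) and
#'   `causalIdx` (panel SNP indices of causal SNPs).
#' @export
simulateExpression <- function(panel, cfg, geneId, annotations = NULL) {
  g <- cfg$genes[cfg$genes$gene_id == geneId, ]
  if (!nrow(g)) stop("unknown gene: ", geneId)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(cfg$seed, paste0("expr-", geneId)))
  gr <- configGenes(cfg)[geneId]
  cisIdx <- cisSnps(gr, panel)
  k <- g$kCausal
  w <- numeric(length(cisIdx))
  if (g$cisH2 > 0) {
    prob <- rep(1, length(cisIdx))
    if (!is.null(annotations) && length(annotations) && g$enrichment != 1) {
      feat <- annotateSnpFeatures(snpInfo(panel)[cisIdx, ], annotations)
      prob[rowSums(feat) > 0] <- g$enrichment
    }
    causal <- sample(seq_along(cisIdx), k, prob = prob)
    w[causal] <- rnorm(k)
    Xs <- standardizeColumns(dosages(panel)[, cisIdx, drop = FALSE])
    gen <- drop(Xs %*% w)
    vg <- mean((gen - mean(gen))^2)
    expr <- gen + rnorm(nSamples(panel), 0, sqrt(vg * (1 - g$cisH2) / g$cisH2))
  } else {
    causal <- integer(0)
    expr <- rnorm(nSamples(panel))
  }
  list(expression = expr, trueWeights = w, cisIdx = cisIdx,
       causalIdx = cisIdx[causal])
}

#' Simulate all genes of a configuration
#'
#' @inheritParams simulateExpression
#' @return list with `expression` (genes x samples matrix) and `truth`
#'   (per-gene output of [simulateExpression()]).
#' @export
simulateAllExpression <- function(panel, cfg, annotations = NULL) {
  ids <- as.character(cfg$genes$gene_id)
  truth <- lapply(ids, function(g) simulateExpression(panel, cfg, g, annotations))
  names(truth) <- ids
  expr <- do.call(rbind, lapply(truth, `[[`, "expression"))
  rownames(expr) <- ids
  colnames(expr) <- sampleIds(panel)
  list(expression = expr, truth = truth)
}

#' Simulate GWAS summary statistics from an explicit cohort
#'
#' Draws an independent cohort of `nGwas` individuals from the same LD
#' process as the reference panel, constructs the phenotype as the sum of
#' standardized genetic expression components weighted by each gene's
#' `alpha` plus Gaussian noise (unit total variance), and computes per-SNP
#' marginal regression z-scores.
#'
#' @param cfg a [simConfig()].
#' @param truth per-gene truth list from [simulateAllExpression()] (uses
#'   `cisIdx` and `trueWeights`).
#' @return A [GwasSummary-class] over all panel SNPs with `n = nGwas`.
#' @export
simulateGwas <- function(cfg, truth) {
  meta <- snpMeta(cfg)
  X <- drawDosages(cfg, meta, cfg$nGwas, deriveSeed(cfg$seed, "gwas-cohort"))
  Xs <- standardizeColumns(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(cfg$seed, "gwas-pheno"))
  gsum <- numeric(cfg$nGwas)
  alpha <- cfg$genes$alpha
  for (i in seq_len(nrow(cfg$genes))) {
    if (alpha[i] == 0) next
    tr <- truth[[as.character(cfg$genes$gene_id[i])]]
    if (all(tr$trueWeights == 0)) next
    gen <- drop(Xs[, tr$cisIdx, drop = FALSE] %*% tr$trueWeights)
    gsum <- gsum + alpha[i] * standardizeVector(gen)
  }
  vg <- mean((gsum - mean(gsum))^2)
  y <- gsum + rnorm(cfg$nGwas, 0, sqrt(max(1 - vg, 0.02)))
  ys <- standardizeVector(y)
  r <- drop(crossprod(Xs, ys)) / cfg$nGwas
  r <- pmin(pmax(r, -0.999), 0.999)
  z <- r * sqrt((cfg$nGwas - 2) / (1 - r^2))
  GwasSummary(meta[, c("id", "chrom", "pos", "a1", "a2")], z = z,
              n = cfg$nGwas)
}

#' Fast multivariate-normal GWAS z-scores
#'
#' Direct summary-statistic sampling `Z ~ N(sqrt(N) R beta, R)` using the
#' reference panel's LD, block by block. A fast path for large simulations
#' where no individual-level oracle is needed; `beta = 0` gives calibrated
#' null z-scores consistent with the panel LD.
#'
#' @param panel a [GenotypePanel-class] whose `snpInfo()` has a `block`
#'   column (as produced by [simulateGenotypes()]); panels without one are
#'   treated as a single block.
#' @param beta per-SNP true joint effects on the standardized scale
#'   (default all zero).
#' @param nGwas GWAS sample size.
#' @param seed integer seed.
#' @param ridge small diagonal inflation for the Cholesky factor.
#' @return A [GwasSummary-class].
#' @export
simulateGwasZ <- function(panel, beta = NULL, nGwas = 5000, seed = 1L,
                          ridge = 1e-4) {
  s <- snpInfo(panel)
  m <- nrow(s)
  if (is.null(beta)) beta <- numeric(m)
  block <- if ("block" %in% colnames(s)) s$block else rep(1L, m)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "mvn-z"))
  Xs <- standardizeColumns(dosages(panel))
  n <- nrow(Xs)
  z <- numeric(m)
  for (b in unique(block)) {
    idx <- which(block == b)
    R <- crossprod(Xs[, idx, drop = FALSE]) / n
    diag(R) <- 1
    mu <- sqrt(nGwas) * drop(R %*% beta[idx])
    L <- chol(R + ridge * diag(length(idx)))
    z[idx] <- mu + drop(crossprod(L, rnorm(length(idx))))
  }
  GwasSummary(s[, c("id", "chrom", "pos", "a1", "a2")], z = z, n = nGwas)
}

#' Emit a complete synthetic scenario to disk
#'
#' Writes the fixture bundle (VCF reference panel, expression and gene
#' tables, annotation BEDs, GWAS summary statistics, JSON truth record)
#' that exercises every stage of the pipeline.
#'
#' Scenarios: `"null"` (no gene affects the phenotype), `"one_gene"` (one
#' causal gene among null genes), `"two_genes_shared_locus"` (two genes
#' with overlapping cis windows and correlated predictors, one causal —
#' exercises joint/conditional analysis).
#'
#' @param name scenario name.
#' @param dir output directory (created).
#' @param seed integer master seed; output files are byte-identical for a
#'   fixed seed.
#' @param nGenes number of genes for the `"null"` scenario.
#' @return Invisibly, a list with the in-memory objects (`cfg`, `panel`,
#'   `annotations`, `expression`, `truth`, `gwas`) and file `paths`.
#' @export
makeScenario <- function(name = c("null", "one_gene", "two_genes_shared_locus"),
                         dir, seed = 1L, nGenes = 30L) {
  name <- match.arg(name)
  cfg <- switch(name,
    null = simConfig(
      nRef = 300, nGwas = 4000, snpsPerLocus = 12, blockSize = 4, rho = 0.6,
      genes = data.frame(gene_id = paste0("gene", seq_len(nGenes)),
                         locus = seq_len(nGenes), kCausal = 2L, cisH2 = 0.3,
                         enrichment = 3, alpha = 0),
      seed = seed),
    one_gene = simConfig(
      nRef = 400, nGwas = 5000, snpsPerLocus = 18, blockSize = 6, rho = 0.7,
      genes = data.frame(gene_id = paste0("gene", 1:5), locus = 1:5,
                         kCausal = 3L, cisH2 = c(0.3, 0.3, 0.5, 0.3, 0.3),
                         enrichment = 3,
                         alpha = c(0, 0, 0.25, 0, 0)),
      seed = seed),
    two_genes_shared_locus = simConfig(
      nRef = 400, nGwas = 5000, snpsPerLocus = 24, blockSize = 12, rho = 0.9,
      genes = data.frame(gene_id = c("geneA", "geneB"), locus = 1L,
                         kCausal = 3L, cisH2 = 0.4, enrichment = 1,
                         alpha = c(0.25, 0)),
      seed = seed))
  panel <- simulateGenotypes(cfg)
  ann <- simulateAnnotations(panel, c(TFBS = 0.25, DHS = 0.35), seed = seed)
  sim <- simulateAllExpression(panel, cfg, ann)
  gwas <- simulateGwas(cfg, sim$truth)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "ref.vcf"),
                expr = file.path(dir, "expr.tsv"),
                genes = file.path(dir, "genes.tsv"),
                tfbs = file.path(dir, "tfbs.bed"),
                dhs = file.path(dir, "dhs.bed"),
                gwas = file.path(dir, "gwas.tsv"),
                truth = file.path(dir, "truth.json"))
  writeDosageVcf(panel, paths$vcf)
  writeExpression(sim$expression, paths$expr)
  writeGeneTable(configGenes(cfg), paths$genes)
  writeAnnotationBed(ann[["TFBS"]], paths$tfbs)
  writeAnnotationBed(ann[["DHS"]], paths$dhs)
  writeGwasSumstats(gwas, paths$gwas)
  truthJson <- lapply(sim$truth, function(t) {
    list(causal_snps = snpInfo(panel)$id[t$causalIdx],
         true_weights = t$trueWeights[t$trueWeights != 0])
  })
  jsonlite::write_json(list(scenario = name, seed = seed,
                            alpha = as.list(setNames(cfg$genes$alpha,
                                                     cfg$genes$gene_id)),
                            genes = truthJson),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(cfg = cfg, panel = panel, annotations = ann,
                 expression = sim$expression, truth = sim$truth,
                 gwas = gwas, paths = paths))
}
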