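#' Cis SNPs of a gene
#'
#' SNPs whose position lies within `window` bp of the gene's transcript
#' span, i.e. `pos` in `[start - window, end + window]` (inclusive on both
#' boundaries), on the gene's chromosome.
#'
#' @param gene a single-range `GRanges` (transcript span, 1-based
#'   inclusive).
#' @param panel a [GenotypePanel-class].
#' @param window cis window in bp, default 1 Mb.
#' @return Integer vector of panel SNP indices (possibly empty).
#' @export
cisSnps <- function(gene, panel, window = 1e6) {
  stopifnot(length(gene) == 1L)
  s <- snpInfo(panel)
  chr <- as.character(GenomicRanges::seqnames(gene))
  which(s$chrom == chr &
        s$pos >= GenomicRanges::start(gene) - window &
        s$pos <= GenomicRanges::end(gene) + window)
}

#' Single-SNP eQTL scan
#'
#' Per-SNP simple linear regression of standardized expression on each
#' standardized dosage column; two-sided p-values from the t distribution
#' with n - 2 degrees of freedom. Constant SNP columns get `beta = 0`,
#' `p = 1` and are flagged.
#'
#' @param X dosage matrix (samples x cis SNPs); standardized internally.
#' @param y expression vector; standardized internally.
#' @return data.frame with `beta`, `se`, `p`, `constant` per SNP.
#' @export
eqtlScan <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("eQTL scan needs at least 10 samples")
  Xs <- standardizeColumns(X)
  ys <- standardizeVector(y)
  cst <- attr(Xs, "constant")
  r <- drop(crossprod(Xs, ys)) / n          # = beta on standardized scale
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  se <- ifelse(abs(tstat) > 0, abs(r / tstat), sqrt(1 / (n - 2)))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  beta <- r
  beta[cst] <- 0
  p[cst] <- 1
  se[cst] <- NA_real_
  data.frame(beta = beta, se = se, p = p, constant = cst)
}

#' Binary SNP-by-feature annotation matrix
#'
#' A SNP is labeled with a feature when its position overlaps at least one
#' interval of that feature.
#'
#' @param snps data.frame/DataFrame with `chrom` and `pos` (1-based).
#' @param annotations named `GRangesList` of features.
#' @return Integer 0/1 matrix, SNPs x features.
#' @export
annotateSnpFeatures <- function(snps, annotations) {
  snps <- as.data.frame(snps)
  gr <- GRanges(snps$chrom, IRanges(snps$pos, snps$pos))
  out <- sapply(names(annotations), function(f) {
    as.integer(IRanges::overlapsAny(gr, annotations[[f]]))
  })
  out <- matrix(out, nrow = nrow(snps),
                dimnames = list(snps$id, names(annotations)))
  out
}

#' Annotation-stratified candidate SNP sets
#'
#' Builds the Cartesian grid of eQTL P-value thresholds and annotation
#' filters (`all` SNPs, SNPs in `any_feature`, and each single feature).
#' A SNP belongs to a set when its eQTL p is at or below the threshold and
#' it satisfies the annotation filter. Empty sets are dropped; sets with
#' identical membership are deduplicated keeping the least restrictive
#' spec (broadest filter, then highest threshold).
#'
#' @param eqtl data.frame from [eqtlScan()] over the cis SNPs.
#' @param features 0/1 matrix from [annotateSnpFeatures()] (or `NULL` for
#'   no annotations, in which case only the `all` filter is used).
#' @param thresholds ascending eQTL P-value thresholds.
#' @return list of specs, each `list(threshold, filter, members)` with
#'   `members` indices into the cis SNP list.
#' @export
buildSnpSets <- function(eqtl, features = NULL,
                         thresholds = c(0.001, 0.01, 0.05, 0.1, 0.5, 1)) {
  stopifnot(!is.unsorted(thresholds))
  filters <- "all"
  if (!is.null(features) && ncol(features) > 0)
    filters <- c("all", "any_feature", colnames(features))
  # least-restrictive-first order so deduplication keeps the broadest spec
  grid <- expand.grid(threshold = rev(thresholds), filter = filters,
                      stringsAsFactors = FALSE)
  sets <- list()
  seen <- character(0)
  for (i in seq_len(nrow(grid))) {
    thr <- grid$threshold[i]
    fil <- grid$filter[i]
    memb <- which(eqtl$p <= thr)
    if (fil == "any_feature") {
      memb <- memb[rowSums(features[memb, , drop = FALSE]) > 0]
    } else if (fil != "all") {
      memb <- memb[features[memb, fil] > 0]
    }
    if (!length(memb)) next
    key <- paste(memb, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    sets[[length(sets) + 1L]] <- list(threshold = thr, filter = fil,
                                      members = memb)
  }
  sets
}

# 100-point log-spaced lambda grid from the null point lambda_max down.
lambdaGrid <- function(X, y, alpha, nLambda = 100, minRatio = 1e-3) {
  n <- nrow(X)
  lmax <- max(abs(crossprod(X, y))) / (n * max(alpha, 1e-3))
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * minRatio), length.out = nLambda))
}

#' Fit a penalized expression prediction model
#'
#' Coordinate-descent elastic net minimizing
#' `(1/2n)||y - Xw||^2 + lambda (alpha ||w||_1 + (1-alpha)/2 ||w||^2)`
#' with `alpha = 1` (lasso) or `alpha = 0.5` (elastic net). When `lambda`
#' is not supplied it is chosen on a 100-point log grid by inner 5-fold
#' cross-validation within the training data, using the 1-SE rule (largest
#' lambda whose CV error is within one standard error of the minimum).
#'
#' @param X standardized dosage matrix of the candidate SNP set.
#' @param y standardized expression vector.
#' @param method `"lasso"` or `"enet"`.
#' @param lambda optional fixed penalty; skips the inner CV.
#' @param nfolds inner CV folds, default 5.
#' @param seed seed for the inner fold assignment.
#' @param tol,maxit coordinate-descent convergence controls.
#' @return list with `w` (weights), `lambda`, and `usable` (`FALSE` when
#'   the solution is all-zero at every candidate lambda).
#' @export
fitPenalizedModel <- function(X, y, method = c("lasso", "enet"),
                              lambda = NULL, nfolds = 5, seed = 1L,
                              tol = 1e-7, maxit = 100000L) {
  method <- match.arg(method)
  alpha <- if (method == "lasso") 1 else 0.5
  X <- as.matrix(X)
  n <- nrow(X)
  if (!is.null(lambda)) {
    W <- enet_path_cpp(X, y, sort(as.numeric(lambda), decreasing = TRUE),
                       alpha, tol, maxit)
    w <- W[, ncol(W)]
    return(list(w = w, lambda = lambda[length(lambda)], usable = any(w != 0)))
  }
  lam <- lambdaGrid(X, y, alpha)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(deriveSeed(seed, "inner-cv"))
  fold <- sample(rep(seq_len(nfolds), length.out = n))
  mse <- matrix(NA_real_, nfolds, length(lam))
  for (f in seq_len(nfolds)) {
    tr <- fold != f
    W <- enet_path_cpp(X[tr, , drop = FALSE], y[tr], lam, alpha, tol, maxit)
    pred <- X[!tr, , drop = FALSE] %*% W
    mse[f, ] <- colMeans((y[!tr] - pred)^2)
  }
  cvm <- colMeans(mse)
  cvse <- apply(mse, 2, sd) / sqrt(nfolds)
  imin <- which.min(cvm)
  ise <- which(cvm <= cvm[imin] + cvse[imin])[1]  # largest lambda within 1 SE
  W <- enet_path_cpp(X, y, lam, alpha, tol, maxit)
  w <- W[, ise]
  usable <- any(W != 0)
  if (all(w == 0) && usable) {
    # 1-SE pick degenerate but the path has nonzero solutions: fall back to
    # the CV minimum
    w <- W[, imin]
    ise <- imin
  }
  list(w = w, lambda = lam[ise], usable = any(w != 0))
}

# Held-out R2: squared Pearson correlation between prediction and observed;
# defined as 0 when the prediction is constant.
heldOutR2 <- function(pred, obs) {
  if (sd(pred) < 1e-12 || sd(obs) < 1e-12) return(0)
  cor(pred, obs)^2
}

#' Ten-fold cross-validated model selection for one gene
#'
#' Within each training split, runs the eQTL scan, builds the
#' annotation-stratified SNP sets, fits lasso and elastic net on every set,
#' and scores held-out prediction R2 (squared Pearson correlation; constant
#' predictions score 0). Candidates are the (threshold, filter, method)
#' grid; membership is recomputed per fold from that fold's eQTL p-values.
#' The candidate with the highest mean R2 across the 10 folds wins; ties
#' break toward fewer member SNPs, then toward lasso.
#'
#' @param gene single-range `GRanges`.
#' @param panel reference [GenotypePanel-class].
#' @param expression numeric expression vector over the panel's samples.
#' @param annotations named `GRangesList` or `NULL`.
#' @param thresholds ascending eQTL P-value thresholds.
#' @param seed integer; the fold partition is assigned once per gene from
#'   this seed.
#' @param nfolds outer folds, default 10.
#' @param window cis window in bp.
#' @return list with `report` (data.frame: threshold, filter, method,
#'   meanR2, meanSize, per-fold R2 matrix as attribute), `best` (winning
#'   spec), `folds` (fold assignment), `cisIdx`; or `NULL` when no usable
#'   candidate exists.
#' @export
crossValidateGene <- function(gene, panel, expression, annotations = NULL,
                              thresholds = c(0.001, 0.01, 0.05, 0.1, 0.5, 1),
                              seed = 1L, nfolds = 10, window = 1e6) {
  cisIdx <- cisSnps(gene, panel, window)
  if (!length(cisIdx)) return(NULL)
  X <- dosages(panel)[, cisIdx, drop = FALSE]
  n <- nrow(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  gid <- if (!is.null(names(gene))) names(gene)[1] else "gene"
  gseed <- deriveSeed(seed, paste0("cv-", gid))
  set.seed(gseed)
  fold <- sample(rep(seq_len(nfolds), length.out = n))

  features <- if (!is.null(annotations) && length(annotations))
    annotateSnpFeatures(snpInfo(panel)[cisIdx, ], annotations) else NULL
  filters <- if (is.null(features)) "all"
             else c("all", "any_feature", colnames(features))
  grid <- expand.grid(threshold = thresholds, filter = filters,
                      method = c("lasso", "enet"), stringsAsFactors = FALSE)
  r2 <- matrix(0, nrow(grid), nfolds)
  size <- matrix(NA_real_, nrow(grid), nfolds)
  everBuilt <- logical(nrow(grid))

  for (f in seq_len(nfolds)) {
    tr <- fold != f
    Xtr <- standardizeColumns(X[tr, , drop = FALSE])
    ytr <- standardizeVector(expression[tr])
    Xte <- standardizeColumns(X[!tr, , drop = FALSE],
                              center = attr(Xtr, "center"),
                              scale = attr(Xtr, "scale"))
    eq <- eqtlScan(X[tr, , drop = FALSE], expression[tr])
    sets <- buildSnpSets(eq, features, thresholds)
    keys <- vapply(sets, function(s) paste(s$members, collapse = ","),
                   character(1))
    fitCache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(grid))) {
      thr <- grid$threshold[i]; fil <- grid$filter[i]
      memb <- which(eq$p <= thr)
      if (fil == "any_feature")
        memb <- memb[rowSums(features[memb, , drop = FALSE]) > 0]
      else if (fil != "all")
        memb <- memb[features[memb, fil] > 0]
      if (!length(memb)) next
      everBuilt[i] <- TRUE
      size[i, f] <- length(memb)
      ckey <- paste(grid$method[i], paste(memb, collapse = ","))
      fit <- fitCache[[ckey]]
      if (is.null(fit)) {
        fit <- fitPenalizedModel(Xtr[, memb, drop = FALSE], ytr,
                                 method = grid$method[i],
                                 seed = deriveSeed(gseed, paste0("f", f)))
        fitCache[[ckey]] <- fit
      }
      if (!fit$usable || all(fit$w == 0)) next
      pred <- drop(Xte[, memb, drop = FALSE] %*% fit$w)
      r2[i, f] <- heldOutR2(pred, expression[!tr])
    }
  }
  if (!any(everBuilt)) return(NULL)
  report <- grid[everBuilt, , drop = FALSE]
  report$meanR2 <- rowMeans(r2[everBuilt, , drop = FALSE])
  report$meanSize <- rowMeans(size[everBuilt, , drop = FALSE], na.rm = TRUE)
  attr(report, "foldR2") <- r2[everBuilt, , drop = FALSE]
  ord <- order(-report$meanR2, report$meanSize,
               match(report$method, c("lasso", "enet")))
  best <- report[ord[1], ]
  if (best$meanR2 <= 0) return(NULL)
  list(report = report,
       best = list(threshold = best$threshold, filter = best$filter,
                   method = best$method, meanR2 = best$meanR2),
       folds = fold, cisIdx = cisIdx)
}

#' REML estimate of cis-heritability
#'
#' Single-variance-component model `y = g + e`, `g ~ N(0, sg2 K)`,
#' `e ~ N(0, se2 I)` with cis GRM `K = X_std X_std' / m`, fitted by profile
#' restricted maximum likelihood on the spectral decomposition of `K`
#' (computed from the SVD of the standardized dosage matrix, so only
#' `min(n, m)` eigenvalues are handled explicitly). The standard error
#' comes from the observed information (numeric curvature of the profile
#' log-likelihood at the optimum). A gene passes the heritability filter
#' when the 95% CI excludes zero, i.e. `h2 - 1.96 se > 0`.
#'
#' @param X cis dosage matrix (samples x SNPs); standardized internally.
#' @param y expression vector.
#' @return list with `h2`, `se`, `ci95` (truncated to `[0, 1]`), `pass`.
#' @export
estimateCisH2 <- function(X, y) {
  X <- as.matrix(X)
  Xs <- standardizeColumns(X)
  Xs <- Xs[, !attr(Xs, "constant"), drop = FALSE]
  m <- ncol(Xs)
  n <- nrow(Xs)
  if (m == 0) return(list(h2 = 0, se = Inf, ci95 = c(0, 1), pass = FALSE))
  y <- standardizeVector(y)
  sv <- svd(Xs, nu = min(n, m), nv = 0)
  keep <- sv$d^2 > 1e-8
  lam <- sv$d[keep]^2 / m
  u2 <- drop(crossprod(sv$u[, keep, drop = FALSE], y))^2
  ssRes <- max(sum(y^2) - sum(u2), 0)
  k0 <- (n - 1) - length(lam)  # residual contrasts with zero GRM eigenvalue
  df <- length(lam) + max(k0, 0)
  negll <- function(h2) {
    v <- h2 * lam + (1 - h2)
    q <- sum(u2 / v) + if (k0 > 0) ssRes / (1 - h2) else 0
    s2 <- q / df
    0.5 * (sum(log(v)) + max(k0, 0) * log(1 - h2) + df * log(s2))
  }
  opt <- optimize(negll, c(0, 0.999))
  h2 <- opt$minimum
  eps <- 1e-3
  lo <- max(h2 - eps, 0); hi <- min(h2 + eps, 0.999)
  hess <- (negll(lo) - 2 * negll((lo + hi) / 2) + negll(hi)) / ((hi - lo) / 2)^2
  se <- if (is.finite(hess) && hess > 0) 1 / sqrt(hess) else Inf
  ci <- pmin(pmax(c(h2 - 1.96 * se, h2 + 1.96 * se), 0), 1)
  list(h2 = h2, se = se, ci95 = ci, pass = is.finite(se) && h2 - 1.96 * se > 0)
}

#' Final full-data weight model for a gene
#'
#' Re-runs the eQTL scan on all samples, rebuilds the SNP set under the
#' winning (threshold, annotation filter), and refits the winning method on
#' all samples (standardizing on the full data).
#'
#' @param gene single-range `GRanges` (named by gene id).
#' @param panel reference [GenotypePanel-class].
#' @param expression expression vector.
#' @param best winning spec from [crossValidateGene()] (`$best`).
#' @param annotations named `GRangesList` or `NULL`.
#' @param tissue tissue label stored in the model.
#' @param h2 optional list from [estimateCisH2()] stored in the model.
#' @param seed seed for the refit's inner CV.
#' @param window cis window in bp.
#' @return A [WeightModel-class], or `NULL` when the rebuilt set is empty
#'   or the refit has no nonzero weights.
#' @export
finalizeWeights <- function(gene, panel, expression, best,
                            annotations = NULL, tissue = "synthetic",
                            h2 = NULL, seed = 1L, window = 1e6) {
  cisIdx <- cisSnps(gene, panel, window)
  if (!length(cisIdx)) return(NULL)
  X <- dosages(panel)[, cisIdx, drop = FALSE]
  eq <- eqtlScan(X, expression)
  memb <- which(eq$p <= best$threshold)
  if (best$filter != "all") {
    features <- annotateSnpFeatures(snpInfo(panel)[cisIdx, ], annotations)
    if (best$filter == "any_feature")
      memb <- memb[rowSums(features[memb, , drop = FALSE]) > 0]
    else memb <- memb[features[memb, best$filter] > 0]
  }
  if (!length(memb)) return(NULL)
  Xs <- standardizeColumns(X[, memb, drop = FALSE])
  ys <- standardizeVector(expression)
  gid <- if (!is.null(names(gene))) names(gene)[1] else "gene"
  fit <- fitPenalizedModel(Xs, ys, method = best$method,
                           seed = deriveSeed(seed, paste0("final-", gid)))
  if (!fit$usable || all(fit$w == 0)) return(NULL)
  keep <- fit$w != 0
  s <- snpInfo(panel)[cisIdx[memb][keep], c("id", "chrom", "pos", "a1", "a2")]
  WeightModel(geneId = gid, tissue = tissue, snps = s,
              weights = fit$w[keep], method = best$method,
              eqtlPThreshold = best$threshold,
              annotationFilter = best$filter,
              cvR2 = best$meanR2,
              cisH2 = if (is.null(h2)) NA_real_ else h2$h2,
              cisH2Se = if (is.null(h2)) NA_real_ else h2$se)
}

#' Train expression weights for a set of genes
#'
#' Full per-gene pipeline: cis SNP lookup, cis-heritability filter
#' (optional), ten-fold cross-validated selection over annotation-stratified
#' SNP sets and penalized methods, and the full-data refit.
#'
#' @param panel reference [GenotypePanel-class].
#' @param expression genes x samples matrix (rownames = gene ids).
#' @param genes `GRanges` with `gene_id` metadata (names = gene ids).
#' @param annotations named `GRangesList` or `NULL`.
#' @param thresholds eQTL P-value grid.
#' @param seed master seed.
#' @param tissue tissue label.
#' @param h2Filter apply the cis-heritability filter (default `TRUE`).
#' @param window cis window in bp.
#' @return list with `models` (list of [WeightModel-class]) and `log`
#'   (per-gene data.frame: gene_id, status, nCis, h2, h2Se, cvR2, method,
#'   threshold, filter).
#' @export
trainWeights <- function(panel, expression, genes, annotations = NULL,
                         thresholds = c(0.001, 0.01, 0.05, 0.1, 0.5, 1),
                         seed = 1L, tissue = "synthetic", h2Filter = TRUE,
                         window = 1e6) {
  ids <- names(genes)
  models <- list()
  logRows <- list()
  for (g in ids) {
    gene <- genes[g]
    row <- data.frame(gene_id = g, status = "ok", nCis = NA_integer_,
                      h2 = NA_real_, h2Se = NA_real_, cvR2 = NA_real_,
                      method = NA_character_, threshold = NA_real_,
                      filter = NA_character_, stringsAsFactors = FALSE)
    cisIdx <- cisSnps(gene, panel, window)
    row$nCis <- length(cisIdx)
    if (!length(cisIdx)) {
      row$status <- "no_cis_snps"; logRows[[g]] <- row; next
    }
    y <- expression[g, ]
    h2 <- estimateCisH2(dosages(panel)[, cisIdx, drop = FALSE], y)
    row$h2 <- h2$h2; row$h2Se <- h2$se
    if (h2Filter && !h2$pass) {
      row$status <- "h2_filter"; logRows[[g]] <- row; next
    }
    cv <- crossValidateGene(gene, panel, y, annotations, thresholds,
                            seed = seed, window = window)
    if (is.null(cv)) {
      row$status <- "no_usable_model"; logRows[[g]] <- row; next
    }
    row$cvR2 <- cv$best$meanR2; row$method <- cv$best$method
    row$threshold <- cv$best$threshold; row$filter <- cv$best$filter
    model <- finalizeWeights(gene, panel, y, cv$best, annotations,
                             tissue = tissue, h2 = h2, seed = seed,
                             window = window)
    if (is.null(model)) {
      row$status <- "empty_final_set"; logRows[[g]] <- row; next
    }
    models[[g]] <- model
    logRows[[g]] <- row
  }
  list(models = models, log = do.call(rbind, logRows))
}
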