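test_that("cis window boundaries are inclusive at exactly 1 Mb", {
  pos <- c(999999L, 1000000L, 2005000L, 3010000L, 3010001L)
  p <- makePanel(matrix(rbinom(50, 2, 0.3), 10, 5), pos = pos)
  gene <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(2000000, 2010000))
  idx <- cisSnps(gene, p)
  # [start - 1e6, end + 1e6] = [1,000,000, 3,010,000] inclusive
  expect_equal(idx, c(2L, 3L, 4L))
  # different chromosome: nothing
  gene2 <- GenomicRanges::GRanges("chr9", IRanges::IRanges(2000000, 2010000))
  expect_equal(length(cisSnps(gene2, p)), 0)
})

test_that("eQTL scan matches the closed-form simple-regression oracle", {
  set.seed(8)
  n <- 20
  X <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  X[, 4] <- 1   # constant column
  y <- 0.8 * X[, 1] + rnorm(n)
  eq <- eqtlScan(X, y)
  # oracle: lm() on standardized variables, SNP by SNP
  Xs <- scale(X[, 1:3]) * sqrt((n - 1) / n)
  ys0 <- drop(scale(y)) * sqrt((n - 1) / n)
  for (j in 1:3) {
    fit <- summary(lm(ys0 ~ Xs[, j]))
    expect_equal(eq$beta[j], unname(coef(fit)[2, 1]), tolerance = 1e-10)
    expect_equal(eq$p[j], unname(coef(fit)[2, 4]), tolerance = 1e-8)
  }
  expect_true(eq$constant[4])
  expect_equal(eq$beta[4], 0)
  expect_equal(eq$p[4], 1)
})

test_that("perfect and orthogonal predictors bound the eQTL scan", {
  set.seed(9)
  x <- rbinom(40, 2, 0.5)
  eqPerfect <- eqtlScan(cbind(x, rbinom(40, 2, 0.5)), x)
  expect_equal(eqPerfect$beta[1], 1, tolerance = 1e-12)
  expect_lt(eqPerfect$p[1], 1e-10)
  # residualized response is orthogonal to the SNP
  z <- rnorm(40)
  yOrth <- residuals(lm(z ~ x))
  eqOrth <- eqtlScan(cbind(x), yOrth)
  expect_lt(abs(eqOrth$beta[1]), 1e-10)
})

test_that("SNP feature matrix matches an interval-by-interval hand check", {
  snps <- data.frame(id = paste0("s", 1:6), chrom = "chr1",
                     pos = c(50L, 150L, 250L, 350L, 450L, 550L))
  ann <- GenomicRanges::GRangesList(
    TFBS = GenomicRanges::GRanges("chr1",
             IRanges::IRanges(c(100, 400), c(200, 460))),
    DHS = GenomicRanges::GRanges("chr1", IRanges::IRanges(340, 360)),
    HMM = GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 1000)))
  feat <- annotateSnpFeatures(snps, ann)
  expect_equal(dim(feat), c(6L, 3L))
  expect_equal(unname(feat[, "TFBS"]), c(0L, 1L, 0L, 0L, 1L, 0L))
  expect_equal(unname(feat[, "DHS"]),  c(0L, 0L, 0L, 1L, 0L, 0L))
  expect_equal(unname(feat[, "HMM"]),  rep(0L, 6))   # wrong chromosome
  expect_equal(unname(rowSums(feat)[1]), 0)          # all-zero row
})

test_that("SNP sets follow the threshold x annotation grid with dedup", {
  eq <- data.frame(p = c(0.001, 0.02, 0.2, 0.6, 0.9))
  feat <- matrix(c(1L, 0L, 1L, 0L, 0L), ncol = 1,
                 dimnames = list(NULL, "TFBS"))
  sets <- buildSnpSets(eq, feat, thresholds = c(0.05, 1))
  members <- lapply(sets, `[[`, "members")
  has <- function(x) any(vapply(members, identical, logical(1), y = x))
  expect_equal(length(sets), 4)
  expect_true(has(c(1L, 2L)))        # p <= 0.05, all
  expect_true(has(1L))               # p <= 0.05, TFBS
  expect_true(has(1:5))              # p <= 1, all
  expect_true(has(c(1L, 3L)))        # p <= 1, TFBS
  # vacuous filter at threshold 1 returns the full cis list
  full <- buildSnpSets(eq, NULL, thresholds = 1)
  expect_equal(full[[1]]$members, 1:5)
  expect_equal(full[[1]]$filter, "all")
  # empty sets are dropped
  featNone <- matrix(0L, 5, 1, dimnames = list(NULL, "TFBS"))
  setsNone <- buildSnpSets(data.frame(p = rep(0.5, 5)), featNone,
                           thresholds = c(0.001, 1))
  expect_false(any(vapply(setsNone, `[[`, "", "filter") == "TFBS"))
  # deduplication keeps the least restrictive spec
  eq2 <- data.frame(p = c(0.001, 0.002))
  sets2 <- buildSnpSets(eq2, NULL, thresholds = c(0.05, 1))
  expect_equal(length(sets2), 1)
  expect_equal(sets2[[1]]$threshold, 1)
})

test_that("lasso reduces to soft thresholding for one predictor", {
  set.seed(10)
  n <- 100
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.4 * x + rnorm(n, 0, 0.5)
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  bhat <- sum(x * y) / n
  for (lam in c(0.05, 0.2, abs(bhat) + 0.1)) {
    f <- fitPenalizedModel(cbind(x), y, "lasso", lambda = lam)
    expect_equal(f$w[1], sign(bhat) * max(abs(bhat) - lam, 0),
                 tolerance = 1e-8)
  }
})

test_that("zero penalty recovers OLS and lambda_max kills all weights", {
  set.seed(11)
  n <- 80; m <- 5
  X <- epitwas:::standardizeColumns(matrix(rnorm(n * m), n, m))
  y <- epitwas:::standardizeVector(drop(X %*% c(0.5, -0.3, 0, 0, 0.2)) + rnorm(n))
  fOls <- fitPenalizedModel(X, y, "lasso", lambda = 0)
  ols <- coef(lm(y ~ X - 1))
  expect_equal(unname(fOls$w), unname(ols), tolerance = 1e-6)
  lmax <- max(abs(crossprod(X, y))) / n
  fNull <- fitPenalizedModel(X, y, "lasso", lambda = lmax * 1.0001)
  expect_true(all(fNull$w == 0))
  expect_false(fNull$usable)
})

test_that("solutions satisfy the KKT conditions and match glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  n <- 120; m <- 15
  X <- epitwas:::standardizeColumns(matrix(rnorm(n * m), n, m))
  beta <- c(rnorm(3), rep(0, m - 3))
  y <- epitwas:::standardizeVector(drop(X %*% beta) + rnorm(n))
  for (method in c("lasso", "enet")) {
    alpha <- if (method == "lasso") 1 else 0.5
    f <- fitPenalizedModel(X, y, method, seed = 3)
    r <- y - drop(X %*% f$w)
    g <- drop(crossprod(X, r)) / n - f$lambda * (1 - alpha) * f$w
    zero <- f$w == 0
    expect_true(all(abs(g[zero]) <= f$lambda * alpha + 1e-6),
                label = paste("KKT inactive", method))
    expect_true(all(abs(g[!zero] - f$lambda * alpha * sign(f$w[!zero])) < 1e-6),
                label = paste("KKT active", method))
    gl <- glmnet::glmnet(X, y, alpha = alpha, lambda = f$lambda,
                         standardize = FALSE, thresh = 1e-12)
    expect_equal(unname(f$w), unname(as.numeric(gl$beta)), tolerance = 1e-4)
  }
})

test_that("fitted weights are invariant to SNP column order", {
  set.seed(13)
  n <- 100; m <- 8
  X <- epitwas:::standardizeColumns(matrix(rnorm(n * m), n, m))
  y <- epitwas:::standardizeVector(drop(X[, 1:2] %*% c(0.6, -0.4)) + rnorm(n))
  f1 <- fitPenalizedModel(X, y, "lasso", lambda = 0.05)
  perm <- sample(m)
  f2 <- fitPenalizedModel(X[, perm], y, "lasso", lambda = 0.05)
  expect_equal(f2$w[order(perm)], f1$w, tolerance = 1e-6)
})

test_that("cross-validation is deterministic and the winner is the argmax", {
  cfg <- simConfig(nRef = 200, snpsPerLocus = 15, blockSize = 5, rho = 0.7,
                   genes = data.frame(gene_id = "g", locus = 1, kCausal = 3L,
                                      cisH2 = 0.5, enrichment = 1, alpha = 0),
                   seed = 31)
  p <- simulateGenotypes(cfg)
  sim <- simulateExpression(p, cfg, "g")
  genes <- configGenes(cfg)
  ann <- simulateAnnotations(p, c(TFBS = 0.3), seed = 31)
  cv1 <- crossValidateGene(genes["g"], p, sim$expression, ann,
                           thresholds = c(0.05, 0.5, 1), seed = 5)
  cv2 <- crossValidateGene(genes["g"], p, sim$expression, ann,
                           thresholds = c(0.05, 0.5, 1), seed = 5)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$report$meanR2, cv2$report$meanR2)
  expect_equal(cv1$best$meanR2, max(cv1$report$meanR2))
})

test_that("cross-validated R2 brackets the simulated heritability ceiling", {
  cfg <- simConfig(nRef = 400, snpsPerLocus = 18, blockSize = 6, rho = 0.7,
                   genes = data.frame(gene_id = "g", locus = 1, kCausal = 3L,
                                      cisH2 = 0.5, enrichment = 1, alpha = 0),
                   seed = 32)
  p <- simulateGenotypes(cfg)
  sim <- simulateExpression(p, cfg, "g")
  genes <- configGenes(cfg)
  cv <- crossValidateGene(genes["g"], p, sim$expression, NULL,
                          thresholds = c(0.05, 0.5, 1), seed = 6)
  expect_gte(cv$best$meanR2, 0.3)
  expect_lte(cv$best$meanR2, 0.55)
})

test_that("pure-noise genes rarely earn a meaningful CV R2", {
  exceed <- 0L
  for (s in 1:8) {
    cfg <- simConfig(nRef = 200, snpsPerLocus = 12, blockSize = 4, rho = 0.6,
                     genes = data.frame(gene_id = "g", locus = 1,
                                        kCausal = 1L, cisH2 = 0,
                                        enrichment = 1, alpha = 0),
                     seed = 40 + s)
    p <- simulateGenotypes(cfg)
    y <- rnorm(200)
    cv <- crossValidateGene(configGenes(cfg)["g"], p, y, NULL,
                            thresholds = c(0.05, 0.5, 1), seed = s)
    if (!is.null(cv) && cv$best$meanR2 > 0.05) exceed <- exceed + 1L
  }
  expect_lte(exceed, 1)
})

test_that("cis-h2 is near one for deterministic expression and reruns agree", {
  set.seed(15)
  X <- matrix(rbinom(500 * 10, 2, 0.4), 500, 10)
  y <- drop(scale(X[, 3]))
  e1 <- estimateCisH2(X, y)
  e2 <- estimateCisH2(X, y)
  expect_gte(e1$h2, 0.9)
  expect_identical(e1, e2)
  # a strongly heritable but noisy gene passes the filter with an interior
  # optimum and a finite standard error
  yNoisy <- drop(scale(X[, 3])) + rnorm(500, 0, 0.4)
  eN <- estimateCisH2(X, yNoisy)
  expect_gt(eN$h2, 0.7)
  expect_true(is.finite(eN$se))
  expect_true(eN$pass)
  expect_equal(e1$ci95, pmin(pmax(c(e1$h2 - 1.96 * e1$se,
                                    e1$h2 + 1.96 * e1$se), 0), 1))
})

test_that("final models recover the strongest causal SNP and are stable", {
  hits <- 0L; n <- 0L
  best <- list(threshold = 1, filter = "all", method = "lasso",
               meanR2 = NA_real_)
  for (s in 1:12) {
    cfg <- simConfig(nRef = 400, snpsPerLocus = 18, blockSize = 6, rho = 0.7,
                     genes = data.frame(gene_id = "g", locus = 1,
                                        kCausal = 3L, cisH2 = 0.5,
                                        enrichment = 1, alpha = 0),
                     seed = 700 + s)
    p <- simulateGenotypes(cfg)
    sim <- simulateExpression(p, cfg, "g")
    m <- finalizeWeights(configGenes(cfg)["g"], p, sim$expression, best,
                         seed = s)
    if (is.null(m)) next
    n <- n + 1L
    nz <- which(sim$trueWeights != 0)
    top <- sim$cisIdx[nz[which.max(abs(sim$trueWeights[nz]))]]
    if (snpInfo(p)$id[top] %in% as.character(modelSnps(m)$id))
      hits <- hits + 1L
  }
  expect_gte(hits / n, 0.7)
  # refit determinism
  cfg <- simConfig(nRef = 200, snpsPerLocus = 12,
                   genes = data.frame(gene_id = "g", locus = 1, kCausal = 2L,
                                      cisH2 = 0.4, enrichment = 1, alpha = 0),
                   seed = 77)
  p <- simulateGenotypes(cfg)
  sim <- simulateExpression(p, cfg, "g")
  m1 <- finalizeWeights(configGenes(cfg)["g"], p, sim$expression, best, seed = 1)
  m2 <- finalizeWeights(configGenes(cfg)["g"], p, sim$expression, best, seed = 1)
  expect_equal(modelWeights(m1), modelWeights(m2))
  # a threshold no full-data SNP meets exercises the exclusion path
  mNone <- finalizeWeights(configGenes(cfg)["g"], p, rnorm(200),
                           list(threshold = 1e-12, filter = "all",
                                method = "lasso", meanR2 = NA_real_),
                           seed = 1)
  expect_null(mNone)
})

test_that("trainWeights logs excluded genes and returns valid models", {
  cfg <- simConfig(nRef = 250, snpsPerLocus = 15, blockSize = 5, rho = 0.7,
                   genes = data.frame(gene_id = c("hi", "null"), locus = 1:2,
                                      kCausal = 3L, cisH2 = c(0.6, 0),
                                      enrichment = 1, alpha = 0),
                   seed = 51)
  p <- simulateGenotypes(cfg)
  sim <- simulateAllExpression(p, cfg)
  tr <- trainWeights(p, sim$expression, configGenes(cfg), NULL,
                     thresholds = c(0.05, 1), seed = 4)
  expect_true("hi" %in% names(tr$models))
  expect_false("null" %in% names(tr$models))
  expect_equal(tr$log$status[tr$log$gene_id == "null"], "h2_filter")
  m <- tr$models[["hi"]]
  expect_s4_class(m, "WeightModel")
  expect_true(validObject(m))
  expect_true(cvR2(m) > 0 && cvR2(m) <= 1)
})
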