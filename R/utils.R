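`%||%` <- function(a, b) if (is.null(a)) b else a

# Column standardization with divisor n (population scaling), matching the
# objective used by the coordinate-descent solver. Constant columns map to
# all-zero columns. Returns the matrix with centers/scales as attributes so
# held-out data can be standardized with training statistics.
standardizeColumns <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(center)) center <- colMeans(X)
  Xc <- sweep(X, 2, center, "-")
  if (is.null(scale)) scale <- sqrt(colMeans(Xc^2))
  ok <- scale > 1e-12
  Xs <- sweep(Xc, 2, ifelse(ok, scale, 1), "/")
  Xs[, !ok] <- 0
  attr(Xs, "center") <- center
  attr(Xs, "scale") <- scale
  attr(Xs, "constant") <- !ok
  Xs
}

standardizeVector <- function(y) {
  y <- as.numeric(y)
  s <- sqrt(mean((y - mean(y))^2))
  if (s < 1e-12) return(rep(0, length(y)))
  (y - mean(y)) / s
}

# Stable per-gene seed derived from a master seed and the gene identifier,
# kept inside 32-bit integer range.
deriveSeed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer((as.numeric(seed) * 100003 + h) %% .Machine$integer.max)
}

# Permutation/empirical p with the (b + 1) / (n + 1) pseudocount estimator;
# never returns 0, floor is 1 / (n + 1).
empiricalP <- function(nExtreme, nDraws) (nExtreme + 1) / (nDraws + 1)

#' Bonferroni-corrected significance threshold
#'
#' @param nTests number of tests performed (>= 1).
#' @param alpha family-wise error rate, default 0.05.
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(19632)   # 2.55e-6
#' bonferroniThreshold(46)      # 1.09e-3
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  stopifnot(nTests >= 1)
  alpha / nTests
}
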