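#' t-SNE embedding of samples
#'
#' Exact (dense) t-distributed stochastic neighbor embedding of the samples,
#' computed from the full principal-component score matrix of the
#' standardized input. With the small sample counts this package targets
#' (tens of samples) the exact O(n^2) gradient is cheap, so no tree
#' approximation is used. The embedding is initialized from the first two
#' PCs (plus a tiny seeded jitter), which keeps runs reproducible for a
#' fixed seed.
#'
#' The returned components serve downstream as single-value response
#' variables summarising the metabolome (for the randomized-GLM scorer and
#' the random-forest cluster association stage) and as the trait scores for
#' hub-gene calling.
#'
#' @param m standardized feature-by-sample matrix.
#' @param perplexity effective neighbor count; needs
#'   `n_samples >= 3 * perplexity + 1`.
#' @param seed integer seed (recorded in the result).
#' @param n_iter gradient-descent iterations.
#' @return list with `scores` (samples x 2), `method = "tsne"`, `seed`,
#'   `perplexity`.
#' @export
tsne_embed <- function(m, perplexity = 10, seed = 1, n_iter = 1000) {
  n <- ncol(m)
  max_perp <- floor((n - 1) / 3)
  if (n < 3 * perplexity + 1) {
    stop(sprintf("perplexity %g too large for %d samples (maximum feasible: %d)",
                 perplexity, n, max_perp))
  }
  pca <- pca_embed(m)
  X <- pca$scores
  D2 <- as.matrix(stats::dist(X))^2

  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p[] <- 1 / length(p); sp <- 1 }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-7) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, .Machine$double.xmin)

  # deterministic PCA initialization, scaled to sd 1e-4 as is conventional
  Y <- X[, 1:2, drop = FALSE]
  Y <- sweep(Y, 2, apply(Y, 2, sd), "/") * 1e-4
  Y <- with_seed(seed, Y + matrix(rnorm(n * 2, sd = 1e-6), n, 2))

  lr <- 200
  momentum <- 0.5
  update <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exaggeration <- 12
  stop_exag <- min(250, n_iter)
  Pe <- P * exaggeration
  for (it in seq_len(n_iter)) {
    if (it == stop_exag + 1) Pe <- P
    if (it == 251) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(0.01, ifelse(sign(grad) != sign(update), gains + 0.2, gains * 0.8))
    update <- momentum * update - lr * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
  }
  rownames(Y) <- colnames(m)
  colnames(Y) <- c("tSNE1", "tSNE2")
  list(scores = Y, method = "tsne", seed = seed, perplexity = perplexity)
}
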