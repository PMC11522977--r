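#' Multi-response partial least squares (PLS2) by NIPALS
#'
#' Iterative NIPALS decomposition with deflation of both blocks per
#' component. The per-component explained Y sum of squares feeds the VIP
#' importance score.
#'
#' @param X samples x genes matrix (standardized upstream; centered again
#'   defensively here).
#' @param Y samples x metabolites matrix.
#' @param n_components number of latent components
#'   (`<= min(n_samples - 1, n_genes)`).
#' @param keep_per_component for the sparse variant: number of genes with
#'   nonzero weight per component (`NULL` = dense PLS).
#' @return list of class `cn_pls` with `weights` (genes x A, unit norm),
#'   `scores`, `x_loadings`, `y_loadings`, `ssy` (explained Y sum of squares
#'   per component), `total_ssy`, centers and `sparse` flag.
#' @export
pls_fit <- function(X, Y, n_components, keep_per_component = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(nrow(Y) == n)
  if (n_components > min(n - 1, p)) stop("n_components too large for the data")
  if (all(apply(Y, 2, sd) == 0)) stop("Y has zero variance")
  sparse <- !is.null(keep_per_component)
  if (sparse && (keep_per_component < 1 || keep_per_component > p)) {
    stop("keep_per_component must be in 1..n_genes")
  }
  x_center <- colMeans(X); y_center <- colMeans(Y)
  E <- sweep(X, 2, x_center); F <- sweep(Y, 2, y_center)
  total_ssy <- sum(F^2)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  C <- matrix(0, ncol(Y), n_components)
  Tm <- matrix(0, n, n_components)
  ssy <- numeric(n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    u <- F[, which.max(colSums(F^2))]
    if (sum(u^2) < 1e-12) break
    t_old <- rep(Inf, n)
    for (it in 1:500) {
      w <- drop(crossprod(E, u))
      if (sparse) w <- soft_threshold_keep(w, keep_per_component)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      tt <- drop(E %*% w)
      cc <- drop(crossprod(F, tt)) / sum(tt^2)
      u <- drop(F %*% cc) / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-10 * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (sum(w^2) < 1e-300 || sum(tt^2) < 1e-12) break
    pl <- drop(crossprod(E, tt)) / sum(tt^2)
    before <- sum(F^2)
    E <- E - tcrossprod(tt, pl)
    F <- F - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- pl; C[, a] <- cc; Tm[, a] <- tt
    ssy[a] <- before - sum(F^2)
    a_used <- a
  }
  keep_a <- seq_len(a_used)
  structure(list(weights = W[, keep_a, drop = FALSE],
                 x_loadings = P[, keep_a, drop = FALSE],
                 y_loadings = C[, keep_a, drop = FALSE],
                 scores = Tm[, keep_a, drop = FALSE],
                 ssy = ssy[keep_a], total_ssy = total_ssy,
                 x_center = x_center, y_center = y_center,
                 n_components = a_used, sparse = sparse,
                 gene_ids = colnames(X)),
            class = "cn_pls")
}

# keep the `keep` largest |w|, soft-shrink them by the largest dropped |w|
soft_threshold_keep <- function(w, keep) {
  if (keep >= length(w)) return(w)
  aw <- abs(w)
  lambda <- sort(aw, decreasing = TRUE)[keep + 1]
  out <- sign(w) * pmax(aw - lambda, 0)
  out
}

#' Sparse PLS
#'
#' [pls_fit()] with per-component soft-thresholding of the X-weight vector
#' so that exactly `keep_per_component` genes carry nonzero weight. With
#' `keep_per_component = n_genes` it reduces to dense PLS.
#'
#' @inheritParams pls_fit
#' @export
spls_fit <- function(X, Y, n_components, keep_per_component) {
  pls_fit(X, Y, n_components, keep_per_component = keep_per_component)
}

#' Predict Y from a fitted PLS model
#' @param model a `cn_pls` fit.
#' @param newX samples x genes matrix on the training scale.
#' @param n_components number of components to use (default: all fitted).
#' @return predicted Y matrix.
#' @export
pls_predict <- function(model, newX, n_components = model$n_components) {
  a <- seq_len(n_components)
  W <- model$weights[, a, drop = FALSE]
  P <- model$x_loadings[, a, drop = FALSE]
  C <- model$y_loadings[, a, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(C))
  sweep(sweep(as.matrix(newX), 2, model$x_center) %*% B, 2, model$y_center, "+")
}

#' Variable importance in projection (the importance score S)
#'
#' `VIP_j = sqrt(p * sum_a ssy_a w_aj^2 / sum_a ssy_a)` with unit-norm
#' per-component weights, so that the mean of the squared scores over genes
#' is exactly 1: scores above 1 mark genes contributing more than an average
#' gene to the explained metabolome variance.
#'
#' @param model a `cn_pls` fit.
#' @return named numeric vector of scores (one per gene; 0 for genes never
#'   weighted by any component).
#' @export
vip_scores <- function(model) {
  W2 <- model$weights^2
  # guard: sparse weights are already renormalized per component
  denom <- sum(model$ssy)
  p <- nrow(W2)
  s <- sqrt(p * drop(W2 %*% model$ssy) / denom)
  names(s) <- model$gene_ids
  s
}

#' Choose the number of PLS components by cross-validation
#'
#' K-fold cross-validated Y prediction error (PRESS) over 1..`max_comp`
#' components with a fixed fold seed; returns the component count with the
#' smallest PRESS.
#'
#' @param X,Y as in [pls_fit()].
#' @param max_comp largest component count tried.
#' @param folds number of folds.
#' @param keep_per_component sparsity (NULL = dense).
#' @param seed fold-assignment seed.
#' @return integer number of components.
#' @export
cv_n_components <- function(X, Y, max_comp = 10, folds = 5,
                            keep_per_component = NULL, seed = 1) {
  n <- nrow(X)
  max_comp <- min(max_comp, n - ceiling(n / folds) - 1, ncol(X))
  if (max_comp < 1) return(1L)
  fold <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  press <- numeric(max_comp)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- pls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], max_comp,
                   keep_per_component)
    for (a in seq_len(max_comp)) {
      aa <- min(a, fit$n_components)
      pred <- pls_predict(fit, X[!tr, , drop = FALSE], aa)
      press[a] <- press[a] + sum((Y[!tr, , drop = FALSE] - pred)^2)
    }
  }
  which.min(press)
}

#' Randomized-GLM ensemble importance
#'
#' Fits `n_bags` linear models, each on a bootstrap sample with forward
#' AIC selection over a random candidate subset of
#' `ceiling(candidate_frac * p)` genes, and counts how often each gene ends
#' up in a final model. The importance score is the mean-1 normalized
#' selection count `S_j = c_j * p / sum(c)`, so S > 1 marks genes selected
#' more often than an average gene.
#'
#' @param X samples x genes matrix (standardized).
#' @param y single response vector (e.g. one metabolome t-SNE component).
#' @param n_bags ensemble size (>= 100).
#' @param candidate_frac fraction of genes offered to each bag.
#' @param candidate_cap upper bound on the candidate subset per bag
#'   (ensemble-GLM convention; keeps the ensemble fast and diverse when p is
#'   large).
#' @param max_terms forward-selection cap per bag. Shallow models (the
#'   default of 2 terms) keep the selection counts dominated by the
#'   strongest predictors: with deep forward selection most bag slots go to
#'   bootstrap-stable chance correlates, which destroys the
#'   false-discovery control of the downstream S > 1 and p < 0.01 rule.
#' @param seed integer seed.
#' @return named numeric vector of scores.
#' @export
rglm_scores <- function(X, y, n_bags = 500, candidate_frac = 0.2,
                        max_terms = 2, seed = 1, candidate_cap = 50) {
  if (n_bags < 100) stop("n_bags must be >= 100")
  X <- as.matrix(X)
  n_cand <- min(as.integer(candidate_cap),
                as.integer(ceiling(candidate_frac * ncol(X))))
  counts <- rglm_bag_counts(X, as.numeric(y), as.integer(n_bags),
                            n_cand,
                            as.integer(max_terms), as.integer(seed))
  if (sum(counts) == 0) stop("no bag selected any gene; response may be degenerate")
  s <- counts * ncol(X) / sum(counts)
  names(s) <- colnames(X)
  s
}

#' Permutation p-values for importance scores
#'
#' Re-computes the score under `n_perm` joint permutations of the sample
#' order of `Y` (preserving the metabolome's internal covariance while
#' destroying the transcriptome link). The null pool collects all scores
#' across genes and permutations for the model/stratum, and
#' `p_j = (1 + #[SB >= S_j]) / (1 + pool size)`. Pooling across genes is
#' what makes p < 0.01 resolvable at a couple of hundred permutations.
#'
#' @param score_fn `function(X, Y) -> named scores`.
#' @param X samples x genes matrix.
#' @param Y samples x responses matrix (or vector).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `S` (observed scores), `p` (per gene) and `n_null`.
#' @export
permutation_pvalues <- function(score_fn, X, Y, n_perm = 199, seed = 1) {
  if (n_perm < 99) stop("n_perm must be >= 99 to resolve p < 0.01")
  S <- score_fn(X, Y)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  pool <- numeric(0)
  perms <- with_seed(derive_seed(seed, "perm"),
                     replicate(n_perm, sample.int(n), simplify = FALSE))
  pool <- unlist(lapply(perms, function(pr) {
    score_fn(X, Y[pr, , drop = FALSE])
  }), use.names = FALSE)
  sp <- sort(pool)
  # #(pool >= S_j) via position in the sorted null pool
  ge <- length(sp) - findInterval(S, sp, left.open = TRUE)
  p <- (1 + ge) / (1 + length(sp))
  list(S = S, p = setNames(p, names(S)), n_null = length(sp))
}

#' Select putative metabolome-related genes
#'
#' Strict double criterion: importance score `S > s_min` (default 1) and
#' permutation `p < p_max` (default 0.01).
#'
#' @param scores `data.frame` with columns `S` and `p`.
#' @param s_min,p_max thresholds.
#' @return the input with a logical `selected` column.
#' @export
select_genes <- function(scores, s_min = 1, p_max = 0.01) {
  scores$selected <- scores$S > s_min & scores$p < p_max
  scores
}

#' Run the full gene-to-metabolite association stage
#'
#' Genes are stratified by mean expression (> `threshold` FPKM = high). The
#' high stratum is scored by dense multi-response PLS against the full
#' metabolite profiles; the low stratum by sparse PLS (full profiles) and by
#' the randomized-GLM ensemble against each metabolome t-SNE component
#' separately (a gene counts as rGLM-selected when either component selects
#' it). Every score gets a pooled permutation p-value, the `S > 1 and
#' p < 0.01` rule is applied, and the per-fraction putative set is the union
#' over the three models.
#'
#' @param expr unstandardized FPKM expression matrix (genes x samples),
#'   already filtered for low expression.
#' @param metabolomes named list (`lcw`, `wax`) of metabolite matrices.
#' @param tsne_scores named list (`lcw`, `wax`) of samples x 2 t-SNE score
#'   matrices for the same fractions.
#' @param threshold FPKM stratification cutoff.
#' @param n_perm permutations for the null pool.
#' @param max_comp,cv_folds component-selection controls.
#' @param spls_keep_frac fraction of low-stratum genes kept per sPLS
#'   component.
#' @param n_bags,candidate_frac,max_terms rGLM controls.
#' @param s_min,p_max selection thresholds.
#' @param seed integer seed.
#' @param verbose print stage progress.
#' @return `data.frame` (gene, model, stratum, fraction, component, S, p,
#'   selected) with attribute `"putative"`: named list of per-fraction
#'   selected gene sets (union over models).
#' @export
run_gene_association <- function(expr, metabolomes, tsne_scores,
                                 threshold = 100, n_perm = 199,
                                 max_comp = 10, cv_folds = 5,
                                 spls_keep_frac = 0.1,
                                 n_bags = 500, candidate_frac = 0.2,
                                 max_terms = 2,
                                 s_min = 1, p_max = 0.01, seed = 1,
                                 verbose = FALSE) {
  stopifnot(is.list(metabolomes), all(names(metabolomes) %in% c("lcw", "wax")))
  strata <- stratify_by_expression(expr, threshold)
  out <- list()
  Xs <- lapply(strata, function(s) if (nrow(s) >= 2) t(standardize(s)) else NULL)
  for (frac in names(metabolomes)) {
    Y <- t(standardize(metabolomes[[frac]]))
    # --- PLS on the high stratum ---
    if (is.null(Xs$high)) {
      warning("high-expression stratum empty; PLS stage skipped")
    } else {
      X <- Xs$high
      nc <- cv_n_components(X, Y, max_comp, cv_folds,
                            seed = derive_seed(seed, paste0("cvp", frac)))
      cn_log("PLS [%s]: %d genes, %d components", frac, ncol(X), nc,
             verbose = verbose)
      res <- permutation_pvalues(
        function(X, Y) vip_scores(pls_fit(X, Y, nc)),
        X, Y, n_perm, derive_seed(seed, paste0("pls", frac)))
      out[[length(out) + 1L]] <- data.frame(
        gene = names(res$S), model = "pls", stratum = "high",
        fraction = frac, component = NA_character_,
        S = unname(res$S), p = unname(res$p))
    }
    # --- sPLS on the low stratum ---
    if (is.null(Xs$low)) {
      warning("low-expression stratum empty; sPLS/rGLM stages skipped")
    } else {
      X <- Xs$low
      keep <- max(1L, ceiling(spls_keep_frac * ncol(X)))
      nc <- cv_n_components(X, Y, max_comp, cv_folds, keep_per_component = keep,
                            seed = derive_seed(seed, paste0("cvs", frac)))
      cn_log("sPLS [%s]: %d genes, keep %d, %d components", frac, ncol(X),
             keep, nc, verbose = verbose)
      res <- permutation_pvalues(
        function(X, Y) vip_scores(spls_fit(X, Y, nc, keep)),
        X, Y, n_perm, derive_seed(seed, paste0("spls", frac)))
      out[[length(out) + 1L]] <- data.frame(
        gene = names(res$S), model = "spls", stratum = "low",
        fraction = frac, component = NA_character_,
        S = unname(res$S), p = unname(res$p))
      # --- rGLM on the low stratum, per t-SNE component ---
      ts <- as.matrix(tsne_scores[[frac]])
      for (k in seq_len(ncol(ts))) {
        comp <- colnames(ts)[k] %||% paste0("component_", k)
        rg_seed <- derive_seed(seed, paste0("rglm", frac, k))
        cn_log("rGLM [%s] %s: %d genes", frac, comp, ncol(X), verbose = verbose)
        res <- permutation_pvalues(
          function(X, Y) rglm_scores(X, drop(Y), n_bags, candidate_frac,
                                     max_terms, rg_seed),
          X, ts[, k, drop = FALSE], n_perm,
          derive_seed(seed, paste0("rglmperm", frac, k)))
        out[[length(out) + 1L]] <- data.frame(
          gene = names(res$S), model = "rglm", stratum = "low",
          fraction = frac, component = comp,
          S = unname(res$S), p = unname(res$p))
      }
    }
  }
  tab <- select_genes(do.call(rbind, out), s_min, p_max)
  putative <- lapply(split(tab, tab$fraction), function(d) {
    sort(unique(d$gene[d$selected]))
  })
  attr(tab, "putative") <- putative
  tab
}
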