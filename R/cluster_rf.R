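#' Regression performance metrics
#'
#' The three metrics used to judge predictor importance: predictive
#' R-squared (`1 - SSE/TSS`, TSS about the mean of `actual`), root mean
#' square error, and mean absolute percentage error
#' (`100 * |predicted - actual| / |actual|`, with the denominator guarded at
#' `1e-8 * max(|actual|)` because embedding coordinates can sit near zero).
#'
#' @param actual,predicted equal-length numeric vectors (n >= 2).
#' @return list with `r2`, `rmse`, `mape`.
#' @export
regression_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  n <- length(actual)
  if (n < 2) stop("need at least 2 observations")
  sse <- sum((actual - predicted)^2)
  tss <- sum((actual - mean(actual))^2)
  eps <- 1e-8 * max(abs(actual), 1e-300)
  list(r2 = 1 - sse / tss,
       rmse = sqrt(sse / n),
       mape = mean(100 * abs(predicted - actual) / pmax(abs(actual), eps)))
}

#' Random-forest fit with out-of-bag predictions
#'
#' Fits a regression random forest and returns the out-of-bag prediction
#' for every sample, i.e. each sample predicted only by trees whose
#' bootstrap did not contain it. Deterministic for a fixed seed.
#'
#' @param predictors samples x p numeric matrix.
#' @param response numeric vector.
#' @param n_trees number of trees.
#' @param seed integer seed.
#' @return numeric vector of OOB predictions.
#' @export
rf_fit_oob <- function(predictors, response, n_trees = 1000, seed = 1) {
  predictors <- as.matrix(predictors)
  if (nrow(predictors) < 10) stop("need at least 10 samples")
  fit <- with_seed(seed, randomForest::randomForest(
    x = predictors, y = response, ntree = n_trees))
  pred <- fit$predicted
  if (anyNA(pred)) {
    stop("some samples have no out-of-bag trees; increase n_trees")
  }
  unname(pred)
}

#' Leave-one-predictor-out random-forest importance
#'
#' The cluster-to-metabolome association stage: a random forest predicts
#' each metabolome embedding component from cluster eigengenes plus
#' unclustered genes. For every predictor a second forest is fitted without
#' it, and the degradation of out-of-bag performance is measured with the
#' three [regression_metrics()]. Significance comes from a paired bootstrap
#' over samples (the same resample indices evaluate the full and reduced
#' OOB predictions), with one-sided p-values
#' `p = (1 + #[delta* <= 0]) / (n_boot + 1)` and Benjamini-Hochberg
#' correction across predictors per metric and response. A predictor is
#' selected when at least two metrics have corrected p below `alpha` for
#' some response component.
#'
#' @param predictors samples x p matrix (columns named).
#' @param responses samples x k matrix of embedding components (e.g. the two
#'   t-SNE components of one metabolome fraction).
#' @param n_boot bootstrap resamples (>= 50).
#' @param alpha per-metric significance level on the corrected p-values.
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return `data.frame` with one row per predictor x response: deltas,
#'   p-values, q-values, `n_significant_metrics`, `selected`; plus the
#'   per-predictor summary attribute `"selected_predictors"`.
#' @export
cluster_importance <- function(predictors, responses, n_boot = 1000,
                               alpha = 0.01, n_trees = 1000, seed = 1) {
  if (n_boot < 50) stop("n_boot must be >= 50 (p-value resolution)")
  predictors <- as.matrix(predictors)
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) {
    colnames(responses) <- paste0("component_", seq_len(ncol(responses)))
  }
  p <- ncol(predictors)
  n <- nrow(predictors)
  rows <- list()
  for (rc in colnames(responses)) {
    y <- responses[, rc]
    full <- rf_fit_oob(predictors, y, n_trees, derive_seed(seed, paste0(rc, "_full")))
    boot_idx <- with_seed(derive_seed(seed, paste0(rc, "_boot")),
                          matrix(sample.int(n, n * n_boot, replace = TRUE), n))
    for (j in seq_len(p)) {
      red <- rf_fit_oob(predictors[, -j, drop = FALSE], y, n_trees,
                        derive_seed(seed, paste0(rc, "_red", j)))
      mf <- regression_metrics(y, full)
      mr <- regression_metrics(y, red)
      deltas <- boot_deltas(y, full, red, boot_idx)
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = colnames(predictors)[j],
        response = rc,
        delta_r2 = mf$r2 - mr$r2,
        delta_rmse = mr$rmse - mf$rmse,
        delta_mape = mr$mape - mf$mape,
        p_r2 = (1 + sum(deltas$r2 <= 0)) / (n_boot + 1),
        p_rmse = (1 + sum(deltas$rmse <= 0)) / (n_boot + 1),
        p_mape = (1 + sum(deltas$mape <= 0)) / (n_boot + 1)
      )
    }
  }
  tab <- do.call(rbind, rows)
  for (m in c("r2", "rmse", "mape")) {
    q <- rep(NA_real_, nrow(tab))
    for (rc in unique(tab$response)) {
      idx <- tab$response == rc
      q[idx] <- p.adjust(tab[[paste0("p_", m)]][idx], "BH")
    }
    tab[[paste0("q_", m)]] <- q
  }
  tab$n_significant_metrics <- (tab$q_r2 < alpha) + (tab$q_rmse < alpha) +
    (tab$q_mape < alpha)
  tab$selected <- tab$n_significant_metrics >= 2
  sel <- tapply(tab$selected, tab$predictor, any)
  attr(tab, "selected_predictors") <- names(sel)[sel]
  tab
}

# Paired bootstrap of the three metric differences, harmful direction.
# Vectorized: per-sample error components are resampled once and reduced by
# column sums, so tens of thousands of resamples stay cheap.
boot_deltas <- function(y, full, red, boot_idx) {
  n <- nrow(boot_idx)
  seF <- (y - full)^2
  seR <- (y - red)^2
  eps <- 1e-8 * max(abs(y), 1e-300)
  apeF <- 100 * abs(full - y) / pmax(abs(y), eps)
  apeR <- 100 * abs(red - y) / pmax(abs(y), eps)
  sseF <- colSums(matrix(seF[boot_idx], n))
  sseR <- colSums(matrix(seR[boot_idx], n))
  yb <- matrix(y[boot_idx], n)
  tss <- colSums(sweep(yb, 2, colMeans(yb))^2)
  tss[tss <= 0] <- .Machine$double.xmin
  list(r2 = (1 - sseF / tss) - (1 - sseR / tss),
       rmse = sqrt(sseR / n) - sqrt(sseF / n),
       mape = colMeans(matrix(apeR[boot_idx], n)) -
         colMeans(matrix(apeF[boot_idx], n)))
}

#' Associate co-expression clusters with both metabolome fractions
#'
#' Runs [cluster_importance()] once per fraction (each with its own t-SNE
#' response components) and labels every predictor with the fraction(s) it
#' is selected for.
#'
#' @param predictors samples x p matrix (eigengenes + unclustered genes).
#' @param responses_by_fraction named list (`lcw`, `wax`) of samples x k
#'   response matrices.
#' @param ... passed to [cluster_importance()].
#' @return list with per-fraction tables and a `data.frame`
#'   `association` (predictor, associated_fraction in
#'   `none|lcw|wax|both`).
#' @export
cluster_fraction_association <- function(predictors, responses_by_fraction, ...) {
  stopifnot(all(c("lcw", "wax") %in% names(responses_by_fraction)))
  tabs <- lapply(names(responses_by_fraction), function(frac) {
    cluster_importance(predictors, responses_by_fraction[[frac]], ...)
  })
  names(tabs) <- names(responses_by_fraction)
  sel <- lapply(tabs, attr, "selected_predictors")
  preds <- colnames(as.matrix(predictors))
  fraction <- vapply(preds, function(pd) {
    in_l <- pd %in% sel$lcw
    in_w <- pd %in% sel$wax
    if (in_l && in_w) "both" else if (in_l) "lcw" else if (in_w) "wax" else "none"
  }, character(1))
  list(tables = tabs,
       association = data.frame(predictor = preds,
                                associated_fraction = unname(fraction)))
}
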