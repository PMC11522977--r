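test_that("PLS recovers a one-gene driver and matches an independent fit", {
  x <- matrix(rnorm(20), 20, 1)
  y <- 2 * x
  fit <- pls_fit(x, y, 1)
  expect_gt(fit$ssy[1] / fit$total_ssy, 1 - 1e-10)

  # independent oracle: mixOmics' PLS on a small random pair
  skip_if_not_installed("mixOmics")
  set.seed(23)
  X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, paste0("g", 1:4)))
  Y <- matrix(rnorm(6 * 3), 6, 3)
  mine <- pls_fit(X, Y, 2)
  ref <- mixOmics::pls(X, Y, ncomp = 2, scale = FALSE, mode = "regression")
  for (a in 1:2) {
    w_ref <- ref$loadings$X[, a]
    w_my <- mine$weights[, a]
    expect_lt(min(sum((w_my - w_ref)^2), sum((w_my + w_ref)^2)), 1e-8)
  }
})

test_that("gene exchangeability permutes the scores", {
  set.seed(24)
  n <- 40
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("g", 1:5)))
  Y <- matrix(rnorm(n * 3), n, 3)
  s <- vip_scores(pls_fit(X, Y, 2))
  perm <- c(3, 1, 5, 2, 4)
  s_perm <- vip_scores(pls_fit(X[, perm], Y, 2))
  expect_equal(unname(s_perm), unname(s[perm]), tolerance = 1e-10)
})

test_that("VIP scores satisfy their mean-square identity", {
  x <- matrix(rnorm(30), 30, 1)
  expect_equal(unname(vip_scores(pls_fit(x, 2 * x + rnorm(30), 1))), 1)
  set.seed(25)
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    Y <- matrix(rnorm(20 * 3), 20, 3)
    expect_equal(mean(vip_scores(pls_fit(X, Y, 3))^2), 1, tolerance = 1e-8)
    expect_equal(mean(vip_scores(spls_fit(X, Y, 3, 4))^2), 1, tolerance = 1e-8)
  }
})

test_that("sparse PLS reduces to PLS at full keep and isolates drivers", {
  set.seed(26)
  X <- matrix(rnorm(25 * 6), 25, 6, dimnames = list(NULL, paste0("g", 1:6)))
  Y <- matrix(rnorm(25 * 2), 25, 2)
  dense <- pls_fit(X, Y, 2)
  full_keep <- spls_fit(X, Y, 2, keep_per_component = 6)
  expect_equal(dense$weights, full_keep$weights, tolerance = 1e-10)

  y1 <- X[, 3] + 0.05 * rnorm(25)
  sp <- spls_fit(X, cbind(y1), 1, keep_per_component = 1)
  expect_equal(unname(which(sp$weights[, 1] != 0)), 3L)
  s <- vip_scores(sp)
  expect_true(all(s[setdiff(names(s), "g3")] == 0))
  expect_error(spls_fit(X, Y, 2, keep_per_component = 10), "keep_per_component")
})

test_that("rGLM scores are normalized selection frequencies", {
  set.seed(27)
  X <- matrix(rnorm(72 * 200), 72, 200, dimnames = list(NULL, paste0("g", 1:200)))
  y <- rnorm(72)
  s <- rglm_scores(X, y, seed = 7)
  expect_equal(mean(s), 1)
  expect_true(any(s == 0))    # plenty of genes never enter a model

  yd <- X[, 7] + rnorm(72, sd = 0.3)
  sd_ <- rglm_scores(X, yd, seed = 8)
  expect_gt(sd_["g7"], 1)
  expect_equal(names(which.max(sd_)), "g7")
  expect_error(rglm_scores(X, y, n_bags = 50), "n_bags")
})

test_that("pooled permutation p-values are exchangeable and exact at the top", {
  set.seed(28)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("g", 1:10)))
  X[, 2] <- X[, 1]                       # duplicated gene column
  Y <- matrix(rnorm(30 * 4), 30, 4)
  res <- permutation_pvalues(function(X, Y) vip_scores(pls_fit(X, Y, 2)),
                             X, Y, n_perm = 99, seed = 3)
  expect_equal(res$p[["g1"]], res$p[["g2"]])
  res2 <- permutation_pvalues(function(X, Y) vip_scores(pls_fit(X, Y, 2)),
                              X, Y, n_perm = 99, seed = 3)
  expect_identical(res$p, res2$p)

  # a score above every null value gets exactly 1 / (1 + pool size)
  fake_fn <- function(X, Y) {
    s <- abs(cor(X, Y[, 1]))[, 1]
    if (identical(Y, attr(fake_fn, "obs"))) s[1] <- 1e6
    s
  }
  attr(fake_fn, "obs") <- Y
  r3 <- permutation_pvalues(fake_fn, X, Y, n_perm = 99, seed = 5)
  expect_equal(unname(r3$p[1]), 1 / (1 + r3$n_null))
  expect_error(permutation_pvalues(fake_fn, X, Y, n_perm = 50), "n_perm")
})

test_that("selection applies both strict thresholds", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    S = c(1.0, 1.5, 1.5),
                    p = c(0.005, 0.02, 0.005))
  out <- select_genes(tab)
  expect_identical(out$selected, c(FALSE, FALSE, TRUE))
  # monotonicity: tightening thresholds never adds genes
  loose <- select_genes(tab, s_min = 0.5, p_max = 0.05)
  expect_true(all(tab$gene[out$selected] %in% tab$gene[loose$selected]))
})

test_that("the full association stage unions its three models", {
  set.seed(29)
  ds <- generate_dataset(design_config(
    seed = 31, n_genes = 300, module_sizes = c(40L, 35L, 30L),
    n_assoc_genes = 35L, n_assoc_both = 30L))
  expr_f <- filter_low_expression(ds$expression)
  metab <- list(lcw = ds$metabolome_lcw, wax = ds$metabolome_wax)
  tsne <- lapply(metab, function(m)
    tsne_embed(standardize(m), perplexity = 20, seed = 11)$scores)
  tab <- run_gene_association(expr_f, metab, tsne, n_perm = 99,
                              n_bags = 150, max_comp = 4, seed = 6)
  expect_setequal(unique(tab$model), c("pls", "spls", "rglm"))
  expect_setequal(unique(tab$fraction), c("lcw", "wax"))
  put <- attr(tab, "putative")
  for (frac in c("lcw", "wax")) {
    manual <- sort(unique(tab$gene[tab$selected & tab$fraction == frac]))
    expect_identical(put[[frac]], manual)
  }
  # a gene selected by a single model is in the putative set
  one_model <- tab[tab$selected & tab$fraction == "lcw", ]
  if (nrow(one_model)) {
    expect_true(all(one_model$gene %in% put$lcw))
  }
})
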