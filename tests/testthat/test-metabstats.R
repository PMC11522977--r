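md72 <- generate_metadata(design_config())

test_that("type-I partition attributes pure organ signal to organ", {
  organ_means <- c(0, 2, 4, 6, 8, 10)
  y <- organ_means[as.integer(md72$organ)]
  part <- anova_partition(y, md72)
  expect_equal(part$partial_R2_organ, 1)
  expect_equal(part$partial_R2_genotype, 0)
  expect_equal(part$partial_R2_interaction, 0)
})

test_that("partition shares always sum to one and factors are orthogonal", {
  set.seed(7)
  for (i in 1:5) {
    y <- rnorm(nrow(md72)) + rnorm(6)[as.integer(md72$organ)] +
      rnorm(4)[as.integer(md72$genotype)]
    part <- anova_partition(y, md72)
    expect_equal(part$partial_R2_genotype + part$partial_R2_organ +
                   part$partial_R2_interaction + part$partial_R2_residual, 1,
                 tolerance = 1e-10)
    # balanced design: swapping the roles of the two factors leaves each
    # term's share unchanged
    swapped <- md72
    names(swapped)[names(swapped) == "organ"] <- "tmp"
    names(swapped)[names(swapped) == "genotype"] <- "organ"
    names(swapped)[names(swapped) == "tmp"] <- "genotype"
    part2 <- anova_partition(y, swapped)
    expect_equal(part$partial_R2_organ, part2$partial_R2_genotype, tolerance = 1e-10)
    expect_equal(part$partial_R2_genotype, part2$partial_R2_organ, tolerance = 1e-10)
    expect_equal(part$partial_R2_interaction, part2$partial_R2_interaction,
                 tolerance = 1e-10)
  }
})

test_that("null responses split variance by degrees of freedom", {
  # chi-square oracle: each term's expected share of the total SS under an
  # iid response is its dof / (n - 1); residual = 48/71 here
  set.seed(11)
  parts <- replicate(200, unlist(anova_partition(rnorm(72), md72)[1:4]))
  got <- rowMeans(parts)
  want <- c(3, 5, 15, 48) / 71
  expect_lt(max(abs(got - want)), 0.03)
  expect_gt(median(parts["partial_R2_residual", ]), 0.6)
})

test_that("aliased designs are refused", {
  md <- md72[md72$genotype == "B73" | md72$organ == "root", ]
  expect_error(anova_partition(rnorm(nrow(md)), md), "alias")
})

test_that("Tukey letters separate what the studentized range separates", {
  set.seed(2)
  # all groups from one distribution: a single shared letter
  y <- rnorm(30)
  g <- gl(3, 10)
  expect_true(all(tukey_hsd(y, g)$letters == "a"))

  # two groups far apart relative to the pooled sd: distinct letters
  y2 <- c(rnorm(10), rnorm(10) + 50)
  out2 <- tukey_hsd(y2, gl(2, 10))
  expect_false(out2$letters[1] == out2$letters[2])

  # near-tied pair plus one distant group
  y3 <- c(rnorm(3, 0, 0.01), rnorm(3, 0.01, 0.01), rnorm(3, 10, 0.01))
  out3 <- tukey_hsd(y3, gl(3, 3))
  expect_equal(out3$letters[1], out3$letters[2])
  expect_false(out3$letters[3] %in% out3$letters[1:2])

  # oracle: the pair separation must agree with the studentized-range test
  fit <- aov(y3 ~ gl(3, 3))
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  qcrit <- qtukey(0.95, 3, 6)
  sep12 <- abs(mean(y3[1:3]) - mean(y3[4:6])) / sqrt(mse / 3) > qcrit
  expect_identical(sep12, out3$letters[1] != out3$letters[2])

  expect_error(tukey_hsd(c(1, 2, 3), factor(c("a", "a", "b"))), "single")
})

test_that("PCA concentrates duplicated signal and reconstructs the input", {
  set.seed(4)
  base <- rnorm(10)
  m <- standardize(rbind(f1 = base, f2 = base * 2 + 1e-9 * rnorm(10)))
  colnames(m) <- paste0("s", 1:10)
  p <- pca_embed(m)
  expect_gt(p$explained_variance[1], 0.999)

  r <- standardize(matrix(rnorm(6 * 12), 6, 12,
                          dimnames = list(paste0("f", 1:6), paste0("s", 1:12))))
  pr <- pca_embed(r)
  recon <- t(pr$scores %*% t(pr$rotation)) + pr$center
  expect_lt(max(abs(recon - r)), 1e-8)
  # pairwise score covariances vanish
  cv <- cov(pr$scores[, 1:5])
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_true(all(diff(pr$explained_variance) < 1e-12))
})

test_that("2-feature PCA matches the analytic eigenvector", {
  set.seed(9)
  x <- rnorm(200)
  m <- rbind(f1 = x, f2 = 0.6 * x + 0.8 * rnorm(200))
  colnames(m) <- paste0("s", 1:200)
  mc <- m - rowMeans(m)
  p <- pca_embed(mc)
  cv <- cov(t(mc)) * (200 - 1) / 200
  # closed-form leading eigenvector of a 2x2 symmetric matrix
  tr <- cv[1, 1] + cv[2, 2]
  det_ <- cv[1, 1] * cv[2, 2] - cv[1, 2]^2
  lam <- (tr + sqrt(tr^2 - 4 * det_)) / 2
  v <- c(cv[1, 2], lam - cv[1, 1])
  v <- v / sqrt(sum(v^2))
  got <- p$rotation[, 1]
  expect_lt(min(sum((got - v)^2), sum((got + v)^2)), 1e-12)
})

test_that("t-SNE is reproducible, 2-D, and separates planted groups", {
  set.seed(21)
  groups <- rep(1:4, each = 10)
  m <- standardize(matrix(rnorm(30 * 40), 30, 40,
                          dimnames = list(paste0("f", 1:30), paste0("s", 1:40))) +
                     20 * matrix(rnorm(30 * 4), 30, 4)[, groups])
  e1 <- tsne_embed(m, perplexity = 12, seed = 3)
  e2 <- tsne_embed(m, perplexity = 12, seed = 3)
  expect_identical(e1$scores, e2$scores)
  expect_equal(dim(e1$scores), c(40L, 2L))
  expect_gt(silhouette_mean(dist(e1$scores), groups), 0.5)
  expect_error(tsne_embed(m, perplexity = 20), "maximum feasible: 13")
})
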