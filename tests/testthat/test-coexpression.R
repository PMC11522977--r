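test_that("bicor behaves like a correlation and resists outliers", {
  set.seed(6)
  x <- rnorm(72)
  m <- rbind(a = x, b = -x, c = rnorm(72))
  colnames(m) <- paste0("s", 1:72)
  bc <- bicor_matrix(m)
  expect_equal(bc["a", "a"], 1)
  expect_equal(bc["a", "b"], -1)
  expect_true(all(abs(bc) <= 1))

  # clean Gaussian pairs: bicor tracks Pearson closely
  for (i in 1:5) {
    z <- matrix(rnorm(2 * 72), 2, 72)
    z[2, ] <- 0.6 * z[1, ] + 0.8 * z[2, ]
    colnames(z) <- paste0("s", 1:72)
    rownames(z) <- c("u", "v")
    expect_lt(abs(bicor_matrix(z)["u", "v"] - cor(z[1, ], z[2, ])), 0.05)
  }

  # one gross outlier: bicor stays near the clean-data Pearson value
  set.seed(8)
  u <- rnorm(72); v <- 0.7 * u + rnorm(72, sd = 0.5)
  r_clean <- cor(u, v)
  u_bad <- u; v_bad <- v
  u_bad[1] <- 30; v_bad[1] <- -30
  r_dirty <- cor(u_bad, v_bad)
  bc_dirty <- bicor_matrix(rbind(u = u_bad, v = v_bad))["u", "v"]
  expect_lt(abs(bc_dirty - r_clean), abs(r_dirty - r_clean))

  expect_error(bicor_matrix(m[, 1:3]), "4 samples")
})

test_that("soft adjacency is |cor|^beta with zero diagonal", {
  cm <- matrix(c(1, 0.5, -0.9, 0.5, 1, 0, -0.9, 0, 1), 3, 3)
  a <- soft_adjacency(cm, 16)
  expect_identical(diag(a), c(0, 0, 0))
  expect_equal(a[1, 2], 0.5^16)
  expect_equal(a[1, 2], 1.52587890625e-05)
  expect_equal(a[1, 3], 0.9^16)
  expect_error(soft_adjacency(cm, 0.5), "beta")
})

test_that("topological overlap matches hand and brute-force evaluation", {
  ones <- matrix(1, 3, 3) - diag(3)
  tm <- topological_overlap(ones)
  expect_equal(tm[1, 2], 1)   # (1 + 1) / (2 + 1 - 1)

  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 0.5
  tm2 <- topological_overlap(a)
  expect_equal(unname(tm2[3, -3]), c(0, 0, 0))  # isolated node overlaps nothing

  set.seed(10)
  for (i in 1:5) {
    r <- matrix(runif(64), 8, 8)
    adj <- (r + t(r)) / 2
    diag(adj) <- 0
    expect_lt(max(abs(topological_overlap(adj) - tom_brute(adj))), 1e-12)
  }

  bad <- matrix(runif(9), 3, 3)
  diag(bad) <- 0
  expect_error(topological_overlap(bad), "symmetric")
})

test_that("dynamic cut recovers planted modules and ignores noise", {
  for (seed in 1:3) {
    mm <- make_module_matrix(c(60, 50, 40), n_noise = 100, share = 0.8,
                             seed = seed)
    es <- standardize(mm$x)
    tom <- topological_overlap(soft_adjacency(bicor_matrix(es), 16))
    mods <- detect_modules(tom, es)
    expect_equal(max(mods$labels), 3)
    expect_gte(ari_index(mm$labels, mods$labels), 0.9)
    expect_equal(sum(table(mods$labels)), length(mods$labels))
  }
})

test_that("modules with one shared latent are merged", {
  set.seed(12)
  n <- 72
  lat <- rnorm(n)
  x <- rbind(sqrt(0.8) * matrix(lat, 80, n, byrow = TRUE) +
               sqrt(0.2) * matrix(rnorm(80 * n), 80, n),
             matrix(rnorm(60 * n), 60, n))
  dimnames(x) <- list(sprintf("g%03d", 1:140), sprintf("s%02d", 1:n))
  es <- standardize(x)
  tom <- topological_overlap(soft_adjacency(bicor_matrix(es), 16))
  mods <- detect_modules(tom, es, min_module_size = 30)
  # the 80 latent-sharing genes end up in a single module even if the
  # dendrogram split them: their eigengenes correlate near 1
  lab <- mods$labels[sprintf("g%03d", 1:80)]
  expect_equal(length(setdiff(unique(lab), 0L)), 1)
})

test_that("pure noise stays unclustered", {
  set.seed(13)
  x <- matrix(rnorm(400 * 72), 400, 72,
              dimnames = list(sprintf("g%03d", 1:400), sprintf("s%02d", 1:72)))
  tom <- topological_overlap(soft_adjacency(bicor_matrix(x), 16))
  mods <- detect_modules(tom, x)
  expect_gte(mean(mods$labels == 0), 0.9)
  expect_error(detect_modules(tom, x, min_module_size = 2), "min_module_size")
})

test_that("eigengenes are the leading singular profile with positive mean loading", {
  n <- 24
  prof <- rnorm(n)
  prof <- (prof - mean(prof)) / sd(prof)
  x <- matrix(prof, 5, n, byrow = TRUE)
  dimnames(x) <- list(paste0("g", 1:5), paste0("s", 1:n))
  labels <- setNames(rep(1L, 5), rownames(x))
  e <- module_eigengenes(x, labels)
  expect_equal(abs(cor(e[, "ME1"], prof)), 1, tolerance = 1e-12)
  expect_gte(mean(cor(e[, "ME1"], t(x))), 0)
  expect_equal(sum(e[, 1]^2), 1)

  # 2-gene toy against the closed-form 2x2 SVD
  set.seed(14)
  y <- standardize(matrix(rnorm(2 * 6), 2, 6,
                          dimnames = list(c("a", "b"), paste0("s", 1:6))))
  ey <- module_eigengenes(y, setNames(c(1L, 1L), c("a", "b")))[, 1]
  sv <- svd(y)
  v1 <- sv$v[, 1]
  expect_lt(min(sum((ey - v1)^2), sum((ey + v1)^2)), 1e-12)
  # maximality: no unit combination of the two genes explains more variance
  expect_gte(sv$d[1]^2 + 1e-9,
             max(replicate(50, {
               w <- rnorm(2); w <- w / sqrt(sum(w^2))
               sum((drop(w %*% y))^2)
             })))

  expect_error(module_eigengenes(y, setNames(c(1L, 2L), c("a", "b"))),
               "singleton")
})

test_that("eigengene classes split at correlation 0.5", {
  set.seed(15)
  n <- 30
  mk <- function(r, base) {
    v <- r * base + sqrt(1 - r^2) * rnorm(n)
    v / sqrt(sum(v^2))
  }
  base <- rnorm(n); base <- base / sqrt(sum(base^2))
  # construct exact-correlation pairs by Gram mixing of orthonormal parts
  orth <- residuals(lm(rnorm(n) ~ base + 0)); orth <- orth / sqrt(sum(orth^2))
  e06 <- 0.6 * base + sqrt(1 - 0.36) * orth
  e04 <- 0.4 * base + sqrt(1 - 0.16) * orth * -1
  E <- cbind(ME1 = base, ME2 = e06)
  E <- sweep(E, 2, colMeans(E))       # classify uses Pearson on columns
  cls <- classify_modules(cbind(ME1 = base - mean(base),
                                ME2 = e06 - mean(e06)))
  # correlation after centering may shift slightly; rebuild to hit it exactly
  b2 <- base - mean(base); b2 <- b2 / sd(b2)
  o2 <- orth - mean(orth); o2 <- residuals(lm(o2 ~ b2 + 0)); o2 <- o2 / sd(o2)
  pair <- function(r) cbind(ME1 = b2, ME2 = r * b2 + sqrt(1 - r^2) * o2)
  expect_equal(unname(classify_modules(pair(0.6))), c(1L, 1L))
  expect_equal(length(unique(classify_modules(pair(0.4)))), 2)
  expect_equal(unname(classify_modules(pair(0.6)[, 1, drop = FALSE])), 1L)
})

test_that("hub genes satisfy all three criteria with an adaptive cutoff", {
  set.seed(16)
  n <- 48
  lat <- rnorm(n); lat <- (lat - mean(lat)) / sd(lat)
  n_genes <- 100
  noise_sd <- c(rep(0.25, 20), rep(0.9, 80))   # 20 tight genes, 80 loose
  x <- t(vapply(noise_sd, function(s) sqrt(1 - s^2) * lat + s * rnorm(n),
                numeric(n)))
  dimnames(x) <- list(sprintf("g%03d", 1:n_genes), paste0("s", 1:n))
  es <- standardize(x)
  labels <- setNames(rep(1L, n_genes), rownames(es))
  tom <- topological_overlap(soft_adjacency(bicor_matrix(es), 6))
  eig <- module_eigengenes(es, labels)
  traits <- cbind(t1 = lat + rnorm(n, sd = 0.3), t2 = rnorm(n))
  rownames(traits) <- colnames(es)
  hub <- identify_hub_genes(es, labels, eig, tom, traits)
  expect_true(all(names(hub$hub_flags)[hub$hub_flags] %in% rownames(es)))
  # the chosen fraction approximates the 5% quota on this 100-gene module
  expect_lte(abs(hub$cutoffs$n_hub / hub$cutoffs$n_genes - 0.05), 0.04)
  expect_true(hub$cutoffs$cutoff %in% seq(0.05, 0.95, by = 0.05))
  # hubs pass every criterion
  hubs <- names(hub$hub_flags)[hub$hub_flags]
  expect_true(all(abs(hub$eigengene_cor[hubs]) > 0.8))
  mem_conn <- hub$connectivity[rownames(es)]
  expect_true(all(hub$connectivity[hubs] > mean(mem_conn)))

  # monotonicity at a fixed trait cutoff: a stricter eigengene threshold
  # never adds hubs
  fixed <- setNames(hub$cutoffs$cutoff, "ME1")
  h1 <- identify_hub_genes(es, labels, eig, tom, traits,
                           eigen_cor_min = 0.8, trait_cutoffs = fixed)
  h2 <- identify_hub_genes(es, labels, eig, tom, traits,
                           eigen_cor_min = 0.9, trait_cutoffs = fixed)
  expect_true(all(names(h2$hub_flags)[h2$hub_flags] %in%
                    names(h1$hub_flags)[h1$hub_flags]))

  # degenerate module: identical genes have no above-average connectivity
  same <- matrix(rep(lat, 10), 10, n, byrow = TRUE) +
    matrix(rnorm(10 * n, sd = 1e-8), 10, n)
  dimnames(same) <- list(paste0("d", 1:10), paste0("s", 1:n))
  es2 <- standardize(same)
  lab2 <- setNames(rep(1L, 10), rownames(es2))
  tom2 <- topological_overlap(soft_adjacency(bicor_matrix(es2), 6))
  h3 <- identify_hub_genes(es2, lab2, module_eigengenes(es2, lab2), tom2,
                           traits, trait_cutoffs = c(ME1 = 0.05))
  expect_lte(sum(h3$hub_flags), 5)   # near-ties: at most half, typically none
  expect_error(identify_hub_genes(es, labels, eig, tom, NULL), "trait")
})
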