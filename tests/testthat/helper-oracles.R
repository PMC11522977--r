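# Independent oracles and small fixture builders shared across test files.

# adjusted Rand index between two label vectors
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (si - expected) / ((sa + sb) / 2 - expected)
}

# brute-force O(n^3) topological overlap
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
    num <- num - 2 * a[i, i] * a[i, j]   # diag is zero anyway
    out[i, j] <- (sum(a[i, ] * a[, j]) + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exact one-sided hypergeometric tail by direct log-binomial summation
hyper_tail <- function(k, K, n, N) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(exp(lchoose(K, k:upper) + lchoose(N - K, n - (k:upper)) - lchoose(N, n)))
}

# mean silhouette width from a distance matrix and labels
silhouette_mean <- function(d, labels) {
  d <- as.matrix(d)
  vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)) |> mean()
}

# genes-by-samples block with planted latent-driven modules + noise genes
make_module_matrix <- function(sizes, n_noise, n_samples = 72, share = 0.8,
                               seed = 1) {
  set.seed(seed)
  n_genes <- sum(sizes) + n_noise
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  labels <- integer(n_genes)
  pos <- 0
  for (m in seq_along(sizes)) {
    lat <- rnorm(n_samples)
    lat <- (lat - mean(lat)) / sd(lat)
    rows <- (pos + 1):(pos + sizes[m])
    x[rows, ] <- sqrt(share) * matrix(lat, sizes[m], n_samples, byrow = TRUE) +
      sqrt(1 - share) * x[rows, ]
    labels[rows] <- m
    pos <- pos + sizes[m]
  }
  dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%02d", seq_len(n_samples)))
  list(x = x, labels = setNames(labels, rownames(x)))
}

# tiny two-factor metadata
tiny_metadata <- function(n_org = 3, n_gen = 2, n_rep = 3) {
  md <- expand.grid(replicate = seq_len(n_rep),
                    genotype = paste0("G", seq_len(n_gen)),
                    organ = paste0("O", seq_len(n_org)))
  md$sample_id <- sprintf("%s_%s_r%d", md$organ, md$genotype, md$replicate)
  md$organ <- factor(md$organ)
  md$genotype <- factor(md$genotype)
  md[, c("sample_id", "organ", "genotype", "replicate")]
}
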