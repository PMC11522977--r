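#' Type-I ANOVA variance partition for one response
#'
#' Fits the sequential (type-I) two-factor model
#' `y ~ genotype + organ + genotype:organ` and reports each term's share of
#' the total sum of squares (partial R-squared) together with its F-test
#' p-value. Under a balanced design the factors are orthogonal, so the
#' genotype/organ order does not change the shares.
#'
#' @param y numeric vector, one value per sample (e.g. the summed abundance
#'   of a metabolite class).
#' @param metadata sample metadata with `organ` and `genotype` factors, rows
#'   aligned with `y`.
#' @return one-row `data.frame` with partial R-squared and p-value per term;
#'   the four shares sum to 1.
#' @export
anova_partition <- function(y, metadata) {
  stopifnot(length(y) == nrow(metadata))
  genotype <- droplevels(factor(metadata$genotype))
  organ <- droplevels(factor(metadata$organ))
  if (nlevels(genotype) < 2 || nlevels(organ) < 2) {
    stop("anova_partition needs >= 2 levels for both organ and genotype")
  }
  if (nlevels(droplevels(interaction(genotype, organ, drop = FALSE))) <
      nlevels(genotype) * nlevels(organ)) {
    # some cells empty: interaction cannot be separated from main effects
    stop("organ and genotype are aliased (empty design cells)")
  }
  fit <- lm(y ~ genotype + organ + genotype:organ)
  tab <- anova(fit)
  ss <- tab[["Sum Sq"]]
  total <- sum(ss)
  shares <- if (total > 0) ss / total else rep(0, length(ss))
  data.frame(
    partial_R2_genotype = shares[1],
    partial_R2_organ = shares[2],
    partial_R2_interaction = shares[3],
    partial_R2_residual = shares[4],
    p_genotype = tab[["Pr(>F)"]][1],
    p_organ = tab[["Pr(>F)"]][2],
    p_interaction = tab[["Pr(>F)"]][3]
  )
}

#' Variance partition for every metabolite class
#'
#' Class abundance is the per-sample sum of the member metabolite
#' concentrations; each class is then passed to [anova_partition()].
#'
#' @param metab metabolite matrix (metabolites x samples) with a
#'   `feature_meta` annotation containing a `class` column.
#' @param metadata sample metadata aligned with the matrix columns.
#' @return `data.frame`, one row per class.
#' @export
anova_partition_classes <- function(metab, metadata) {
  fm <- feature_meta(metab)
  if (is.null(fm) || is.null(fm$class)) stop("metabolite matrix lacks class annotation")
  cls <- fm$class[match(rownames(metab), fm$feature)]
  out <- lapply(split(seq_len(nrow(metab)), cls), function(idx) {
    y <- colSums(metab[idx, , drop = FALSE])
    anova_partition(y, metadata)
  })
  res <- do.call(rbind, out)
  data.frame(class = names(out), res, row.names = NULL)
}

#' Tukey HSD test with compact letter display
#'
#' All pairwise comparisons by the studentized-range test, summarised as a
#' compact letter display: groups sharing a letter are not significantly
#' different at `alpha`. Letters are assigned by the insert-and-absorb
#' algorithm with ties broken by group order.
#'
#' @param y numeric response.
#' @param group grouping factor (>= 2 groups, each with >= 2 observations).
#' @param alpha significance level.
#' @return `data.frame` with group, mean, n and letter columns, in the
#'   factor's level order.
#' @export
tukey_hsd <- function(y, group, alpha = 0.05) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  sizes <- table(group)
  if (any(sizes < 2)) {
    stop("group(s) with a single observation: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  fit <- aov(y ~ group)
  cmp <- stats::TukeyHSD(fit, "group", conf.level = 1 - alpha)$group
  lv <- levels(group)
  k <- length(lv)
  sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  pairs <- strsplit(rownames(cmp), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    s <- cmp[i, "p adj"] < alpha
    sig[a, b] <- s; sig[b, a] <- s
  }
  letters_out <- compact_letter_display(sig)
  data.frame(group = lv,
             mean = as.numeric(tapply(y, group, mean)[lv]),
             n = as.integer(sizes[lv]),
             letters = letters_out,
             stringsAsFactors = FALSE)
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix: TRUE = significantly different. Returns one letter string per group.
compact_letter_display <- function(sig) {
  lv <- rownames(sig)
  k <- length(lv)
  cols <- list(rep(TRUE, k)) # letter columns: membership vectors
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i || !sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        # duplicate the column, remove i from one copy and j from the other
        c1 <- col; c1[i] <- FALSE
        c2 <- col; c2[j] <- FALSE
        cols[[ci]] <- c1
        cols[[length(cols) + 1]] <- c2
        # absorb columns contained in another
        keep <- rep(TRUE, length(cols))
        for (a in seq_along(cols)) for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] && all(cols[[a]] <= cols[[b]]) &&
              any(cols[[b]] & !cols[[a]])) {
            keep[a] <- FALSE
          }
        }
        cols <- cols[keep]
      }
    }
  }
  # order columns by first member for a deterministic letter assignment
  ord <- order(vapply(cols, function(cc) which(cc)[1], integer(1)))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(cc) cc[i], logical(1)))],
          collapse = "")
  }, character(1))
  names(out) <- lv
  out
}

#' PCA embedding of samples
#'
#' Singular value decomposition of the (already feature-standardized)
#' matrix, giving sample scores on all principal components. The per-PC sign
#' is fixed so that the score of largest magnitude on each component is
#' positive, making results deterministic.
#'
#' @param m standardized feature-by-sample matrix.
#' @return list with `scores` (samples x k), `explained_variance`
#'   (fractions, nonincreasing) and `method = "pca"`.
#' @export
pca_embed <- function(m) {
  if (ncol(m) < 2) stop("PCA needs at least 2 samples")
  x <- t(m)                           # samples x features
  center <- colMeans(x)
  x <- sweep(x, 2, center)            # defensive re-centering
  sv <- svd(x)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rotation <- sv$v
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) {
      scores[, j] <- -scores[, j]
      rotation[, j] <- -rotation[, j]
    }
  }
  ev <- sv$d^2
  rownames(scores) <- colnames(m)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(rotation) <- rownames(m)
  colnames(rotation) <- colnames(scores)
  list(scores = scores, rotation = rotation, center = center,
       explained_variance = if (sum(ev) > 0) ev / sum(ev) else ev,
       method = "pca")
}
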