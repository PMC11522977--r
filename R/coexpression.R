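#' Biweight midcorrelation matrix
#'
#' Robust correlation between all gene pairs. Each row is median-centered
#' and weighted by a Tukey biweight with observations further than 9 median
#' absolute deviations from the median receiving zero weight. Rows whose MAD
#' is zero fall back to the Pearson transform.
#'
#' @param expr feature-by-sample matrix (>= 4 samples).
#' @return symmetric correlation matrix in `[-1, 1]` with unit diagonal.
#' @export
bicor_matrix <- function(expr) {
  if (ncol(expr) < 4) stop("bicor needs at least 4 samples")
  n <- nrow(expr)
  A <- matrix(0, n, ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(n)) {
    x <- expr[i, ]
    med <- median(x)
    madx <- mad(x, constant = 1)
    if (madx == 0 || !is.finite(madx)) {
      xt <- x - mean(x)                     # Pearson fallback
    } else {
      u <- (x - med) / (9 * madx)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      xt <- (x - med) * w
    }
    nrm <- sqrt(sum(xt^2))
    A[i, ] <- if (nrm > 0) xt / nrm else 0
  }
  cmat <- tcrossprod(A)
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  diag(cmat) <- 1
  cmat
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted-network adjacency `a = |cor|^beta`. The diagonal is set
#' to 0, the convention expected by [topological_overlap()].
#'
#' @param cor correlation matrix in `[-1, 1]`.
#' @param beta soft-threshold power (>= 1); 16 by default.
#' @return adjacency matrix in `[0, 1]`, zero diagonal.
#' @export
soft_adjacency <- function(cor, beta = 16) {
  if (!is.numeric(beta) || beta < 1) stop("beta must be >= 1")
  if (any(abs(cor) > 1 + 1e-8)) stop("correlations must lie in [-1, 1]")
  a <- abs(cor)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `TOM[i,j] = (sum_u a[i,u] a[u,j] + a[i,j]) / (min(k_i, k_j) + 1 - a[i,j])`
#' with `k` the adjacency row sums; `TOM[i,i] = 1`. Two genes overlap when
#' they share network neighbors, which makes the matrix a smoother
#' clustering substrate than raw adjacency.
#'
#' @param adjacency symmetric matrix with zero diagonal.
#' @return symmetric TOM in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (max(abs(adjacency - t(adjacency))) > 1e-12) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be 0")
  k <- rowSums(adjacency)
  L <- adjacency %*% adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  tom <- (L + adjacency) / denom
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# deepSplit presets for the dynamic cut, in the style of dynamic hybrid tree
# cutting: larger deep_split tolerates more within-branch scatter and
# smaller gaps, i.e. splits more aggressively.
deep_split_params <- function(deep_split) {
  if (!deep_split %in% 0:4) stop("deep_split must be an integer in 0..4")
  max_core_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1]
  list(max_core_scatter = max_core_scatter,
       min_gap = (1 - max_core_scatter) * 3 / 4)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' followed by a dynamic cut of the dendrogram: branches are accepted as
#' modules only when they are large enough, internally tight (low core
#' scatter) and separated from the rest of the tree by a clear merge-height
#' gap, all judged relative to the spread of joining heights. Genes on
#' rejected branches stay unclustered (label 0). When `expr` is supplied,
#' modules whose eigengenes correlate above `1 - merge_cut_height` are
#' merged and eigengenes recomputed until stable.
#'
#' @param tom topological overlap matrix.
#' @param expr standardized expression matrix (genes x samples) used for the
#'   eigengene-based merge step; `NULL` skips merging.
#' @param min_module_size smallest accepted module (>= 3).
#' @param deep_split split aggressiveness, integer 0-4.
#' @param merge_cut_height eigengene dissimilarity below which modules merge.
#' @return list with `labels` (named integer, 0 = unclustered, modules
#'   numbered by decreasing size), `dendrogram` (the `hclust` object),
#'   `eigengenes` (samples x modules, `NULL` if `expr` missing) and the
#'   parameters used.
#' @export
detect_modules <- function(tom, expr = NULL, min_module_size = 30,
                           deep_split = 2, merge_cut_height = 0.25) {
  if (min_module_size < 3) stop("min_module_size must be >= 3")
  n <- nrow(tom)
  gene_ids <- rownames(tom) %||% paste0("g", seq_len(n))
  diss <- 1 - tom
  hc <- hclust(as.dist(diss), method = "average")
  h <- hc$height
  ref_h <- as.numeric(quantile(h, 0.05))
  max_h <- max(h)
  cut_h <- ref_h + 0.99 * (max_h - ref_h)
  scale <- cut_h - ref_h
  ds <- deep_split_params(deep_split)

  labels <- rep(0L, n)
  if (scale <= 0) {
    # degenerate tree: everything joins at one height; single module if large
    if (n >= min_module_size) labels <- rep(1L, n)
  } else {
    labels <- cut_branches(hc, cut_h, ref_h, scale, min_module_size,
                           ds$min_gap, ds$max_core_scatter)
  }
  labels <- relabel_by_size(labels)
  names(labels) <- gene_ids

  eig <- NULL
  if (!is.null(expr) && max(labels) >= 1) {
    for (it in 1:10) {
      eig <- module_eigengenes(expr, labels)
      if (ncol(eig) < 2) break
      ec <- cor(eig)
      grp <- cutree(hclust(as.dist(1 - ec), method = "average"),
                    h = merge_cut_height)
      if (max(table(grp)) == 1) break
      map <- setNames(as.integer(grp), colnames(eig))
      old_ids <- sub("^ME", "", names(map))
      new_lab <- labels
      for (i in seq_along(map)) {
        new_lab[labels == as.integer(old_ids[i])] <- map[i]
      }
      labels <- relabel_by_size(new_lab)
      names(labels) <- gene_ids
    }
    eig <- module_eigengenes(expr, labels)
  }
  list(labels = labels, dendrogram = hc, eigengenes = eig,
       min_module_size = min_module_size, deep_split = deep_split,
       merge_cut_height = merge_cut_height, cut_height = cut_h)
}

# Walk the merge tree: static cut at cut_h, then recursive gap/scatter-based
# branch evaluation. Returns integer labels (0 = unassigned).
cut_branches <- function(hc, cut_h, ref_h, scale, min_size, min_gap,
                         max_core_scatter) {
  n <- length(hc$order)
  merge <- hc$merge
  h <- hc$height
  sizes <- integer(n - 1)
  members <- vector("list", n - 1)
  node_parent <- integer(n - 1)
  for (k in seq_len(n - 1)) {
    get_m <- function(x) if (x < 0) -x else members[[x]]
    members[[k]] <- c(get_m(merge[k, 1]), get_m(merge[k, 2]))
    sizes[k] <- length(members[[k]])
    for (ch in merge[k, ]) if (ch > 0) node_parent[ch] <- k
  }
  child_height <- function(x) if (x < 0) 0 else h[x]
  child_size <- function(x) if (x < 0) 1L else sizes[x]
  child_members <- function(x) if (x < 0) -x else members[[x]]
  # heights of all merges inside a node's subtree
  sub_heights <- function(k) {
    out <- h[k]
    for (ch in merge[k, ]) if (ch > 0) out <- c(out, sub_heights(ch))
    out
  }
  labels <- rep(0L, n)
  next_label <- 0L

  accept <- function(k, attach_h) {
    hs <- sort(sub_heights(k))
    # measure the branch top at the 75th percentile of its merge heights so
    # that straggler members joining just below the attach point do not
    # erase the separating gap; dense (noise-like) branches keep their top
    # next to the attach height and still fail
    top <- as.numeric(quantile(hs, 0.75))
    gap_ok <- (attach_h - top) >= min_gap * scale
    core <- hs[seq_len(min(length(hs), min_size - 1))]
    scatter_ok <- (mean(core) - ref_h) <= max_core_scatter * scale
    gap_ok && scatter_ok
  }
  evaluate <- function(k, attach_h) {
    if (sizes[k] < min_size) return(invisible(NULL))
    c1 <- merge[k, 1]; c2 <- merge[k, 2]
    s1 <- child_size(c1); s2 <- child_size(c2)
    splittable <- s1 >= min_size && s2 >= min_size &&
      (h[k] - child_height(c1)) >= min_gap * scale &&
      (h[k] - child_height(c2)) >= min_gap * scale
    if (splittable) {
      evaluate(c1, h[k])
      evaluate(c2, h[k])
    } else if (accept(k, attach_h)) {
      next_label <<- next_label + 1L
      labels[members[[k]]] <<- next_label
    }
    invisible(NULL)
  }

  clus <- cutree(hc, h = cut_h)
  for (cl in unique(clus)) {
    idx <- which(clus == cl)
    if (length(idx) < min_size) next
    root <- which(sizes == length(idx) &
                    vapply(members, function(m) all(m %in% idx) &&
                             length(m) == length(idx), logical(1)))
    root <- root[1]
    attach_h <- if (node_parent[root] > 0) h[node_parent[root]] else max(h)
    evaluate(root, max(attach_h, cut_h))
  }
  labels
}

relabel_by_size <- function(labels) {
  ids <- setdiff(unique(labels), 0L)
  if (!length(ids)) return(as.integer(labels))
  tab <- table(factor(labels[labels != 0], levels = ids))
  ord <- ids[order(-as.integer(tab), ids)]
  out <- integer(length(labels))
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of the
#' module's standardized gene-by-sample submatrix: the unit-norm sample
#' profile explaining the most expression variance in the module. Its sign
#' is fixed so that its mean correlation with the member genes is
#' nonnegative.
#'
#' @param expr standardized expression matrix (genes x samples).
#' @param labels integer module labels named by gene (0 ignored).
#' @return samples x modules matrix with columns `ME<k>`.
#' @export
module_eigengenes <- function(expr, labels) {
  ids <- sort(setdiff(unique(labels), 0L))
  if (!length(ids)) stop("no modules to summarise")
  E <- matrix(0, ncol(expr), length(ids),
              dimnames = list(colnames(expr), paste0("ME", ids)))
  for (j in seq_along(ids)) {
    genes <- names(labels)[labels == ids[j]]
    if (length(genes) < 2) stop("singleton cluster ", ids[j])
    X <- expr[genes, , drop = FALSE]
    sv <- svd(X, nu = 1, nv = 1)
    v <- sv$v[, 1]
    if (mean(cor(v, t(X))) < 0) v <- -v
    E[, j] <- v
  }
  E
}

#' Group module eigengenes into classes
#'
#' Average-linkage hierarchical clustering of the eigengenes on
#' `1 - Pearson r`, cut at height `1 - r_min`: modules ending up in the same
#' class correlate above `r_min`.
#'
#' @param eigengenes samples x modules matrix.
#' @param r_min correlation threshold (default 0.5).
#' @return named integer vector: module column -> class id.
#' @export
classify_modules <- function(eigengenes, r_min = 0.5) {
  k <- ncol(eigengenes)
  if (k == 0) stop("no eigengenes")
  if (k == 1) return(setNames(1L, colnames(eigengenes)))
  d <- 1 - cor(eigengenes)
  grp <- cutree(hclust(as.dist(d), method = "average"), h = 1 - r_min)
  setNames(as.integer(grp), colnames(eigengenes))
}

#' Three-criterion hub genes
#'
#' A module member is a hub gene when it (i) has intramodular connectivity
#' (within-module TOM row sum) strictly above the module average, (ii)
#' correlates with the module eigengene above `eigen_cor_min` in absolute
#' value, and (iii) correlates with at least one metabolome trait component
#' above a module-specific cutoff. The cutoff is picked from the grid
#' `0.05, 0.10, ..., 0.95` so that the resulting hub fraction is as close as
#' possible to `target_frac` (ties resolved towards the larger, more
#' stringent cutoff).
#'
#' @param expr standardized expression matrix (genes x samples).
#' @param labels named module labels.
#' @param eigengenes samples x modules matrix from [module_eigengenes()].
#' @param tom topological overlap matrix aligned with `expr` rows.
#' @param trait_scores samples x components matrix of metabolome embedding
#'   scores (e.g. both t-SNE components of both cuticle fractions).
#' @param target_frac desired hub fraction per module (default 0.05).
#' @param eigen_cor_min eigengene-correlation threshold (default 0.8).
#' @param trait_cutoffs optional named numeric vector (module -> cutoff)
#'   overriding the adaptive grid search.
#' @return list with `hub_flags` (named logical), `cutoffs` (data.frame:
#'   cluster, cutoff, n_hub, n_genes) and per-gene `eigengene_cor`,
#'   `connectivity`, `trait_cor`.
#' @export
identify_hub_genes <- function(expr, labels, eigengenes, tom, trait_scores,
                               target_frac = 0.05, eigen_cor_min = 0.8,
                               trait_cutoffs = NULL) {
  if (is.null(trait_scores)) stop("trait_scores (metabolome embedding) required")
  trait_scores <- as.matrix(trait_scores)
  genes <- rownames(expr)
  hub <- setNames(rep(FALSE, length(genes)), genes)
  ecor <- setNames(rep(NA_real_, length(genes)), genes)
  conn <- setNames(rep(NA_real_, length(genes)), genes)
  tcor <- setNames(rep(NA_real_, length(genes)), genes)
  grid <- seq(0.05, 0.95, by = 0.05)
  rows <- list()
  for (me in colnames(eigengenes)) {
    id <- as.integer(sub("^ME", "", me))
    mem <- names(labels)[labels == id]
    X <- expr[mem, , drop = FALSE]
    conn_m <- rowSums(tom[mem, mem, drop = FALSE]) - 1  # drop the unit diagonal
    crit1 <- conn_m > mean(conn_m)
    ec <- as.vector(cor(t(X), eigengenes[, me]))
    crit2 <- abs(ec) > eigen_cor_min
    tc <- apply(abs(cor(t(X), trait_scores)), 1, max)
    ecor[mem] <- ec; conn[mem] <- conn_m; tcor[mem] <- tc
    if (!is.null(trait_cutoffs) && me %in% names(trait_cutoffs)) {
      cut <- trait_cutoffs[[me]]
    } else {
      frac <- vapply(grid, function(g) mean(crit1 & crit2 & tc > g), numeric(1))
      err <- abs(frac - target_frac)
      cand <- which(err == min(err))
      cut <- grid[max(cand)]                     # ties -> larger cutoff
    }
    sel <- crit1 & crit2 & tc > cut
    hub[mem] <- sel
    rows[[me]] <- data.frame(cluster = id, cutoff = cut,
                             n_hub = sum(sel), n_genes = length(mem))
  }
  list(hub_flags = hub,
       cutoffs = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       eigengene_cor = ecor, connectivity = conn, trait_cor = tcor)
}
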