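#' Categorize genes by metabolome-fraction association
#'
#' @param lcw_set,wax_set character vectors of putative genes per fraction.
#' @return list with disjoint sets `lcw_only`, `wax_only`, `both`.
#' @export
classify_associations <- function(lcw_set, wax_set) {
  list(lcw_only = sort(setdiff(lcw_set, wax_set)),
       wax_only = sort(setdiff(wax_set, lcw_set)),
       both = sort(intersect(lcw_set, wax_set)))
}

#' Build the integrated co-expression gene networks
#'
#' Intersects the two pipelines: network nodes are putative genes (from the
#' multi-omics stage) that reside in a co-expression cluster selected by the
#' random-forest stage for the matching fraction(s) — `lcw_only` genes need
#' a cluster associated with lcw or both, `wax_only` with wax or both, and
#' `both` genes need a cluster associated with both fractions. Edges
#' connect node pairs of the same cluster whose topological overlap reaches
#' the `edge_quantile` of that cluster's full within-cluster TOM
#' distribution (ties included, so an all-equal cluster is fully
#' connected).
#'
#' @param putative named list (`lcw`, `wax`) of putative gene sets.
#' @param labels named module labels (from [detect_modules()]).
#' @param cluster_assoc `data.frame` with `predictor` (e.g. `"ME3"`) and
#'   `associated_fraction` columns from [cluster_fraction_association()].
#' @param tom topological overlap matrix over the clustered genes.
#' @param hub_flags optional named logical vector of hub calls.
#' @param classes optional named vector module -> class id.
#' @param edge_quantile within-cluster TOM quantile defining edges.
#' @return list of class `cn_network` with `nodes` and `edges` data frames
#'   (`category` in `lcw_only|wax_only|both`).
#' @export
build_network <- function(putative, labels, cluster_assoc, tom,
                          hub_flags = NULL, classes = NULL,
                          edge_quantile = 0.95) {
  cats <- classify_associations(putative$lcw, putative$wax)
  assoc <- setNames(cluster_assoc$associated_fraction, cluster_assoc$predictor)
  cluster_frac <- function(cl) {
    key <- paste0("ME", cl)
    if (key %in% names(assoc)) assoc[[key]] else "none"
  }
  ok_cluster <- function(category, frac) {
    switch(category,
           lcw_only = frac %in% c("lcw", "both"),
           wax_only = frac %in% c("wax", "both"),
           both = frac == "both")
  }
  nodes <- list()
  for (category in names(cats)) {
    for (g in cats[[category]]) {
      cl <- if (g %in% names(labels)) unname(labels[[g]]) else NA_integer_
      if (is.na(cl) || cl == 0) next
      if (!ok_cluster(category, cluster_frac(cl))) next
      nodes[[length(nodes) + 1L]] <- data.frame(
        gene = g, cluster = cl,
        class = if (!is.null(classes)) unname(classes[[paste0("ME", cl)]]) else NA_integer_,
        is_hub = if (!is.null(hub_flags)) isTRUE(hub_flags[[g]]) else NA,
        category = category)
    }
  }
  if (!length(nodes)) {
    warning("no genes pass the cluster/putative intersection; empty network")
    return(structure(list(nodes = data.frame(gene = character(0)),
                          edges = data.frame(from = character(0))),
                     class = "cn_network"))
  }
  nodes <- do.call(rbind, nodes)
  edges <- list()
  for (cl in unique(nodes$cluster)) {
    mem_all <- names(labels)[labels == cl]
    tom_cl <- tom[mem_all, mem_all, drop = FALSE]
    vals <- tom_cl[upper.tri(tom_cl)]
    thr <- as.numeric(quantile(vals, edge_quantile))
    for (category in unique(nodes$category)) {
      sub <- nodes$gene[nodes$cluster == cl & nodes$category == category]
      if (length(sub) < 2) next
      pr <- which(upper.tri(matrix(0, length(sub), length(sub))), arr.ind = TRUE)
      w <- tom[cbind(sub[pr[, 1]], sub[pr[, 2]])]
      keep <- w >= thr
      if (any(keep)) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = sub[pr[keep, 1]], to = sub[pr[keep, 2]],
          weight = w[keep], cluster = cl, category = category)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), weight = numeric(0),
               cluster = integer(0), category = character(0))
  structure(list(nodes = nodes, edges = edges), class = "cn_network")
}

#' Export a network to GraphML and TSV
#'
#' @param network a `cn_network` from [build_network()].
#' @param prefix output path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and `<prefix>.graphml`.
#' @return `prefix`, invisibly.
#' @export
write_network <- function(network, prefix) {
  utils::write.table(network$nodes, paste0(prefix, "_nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, paste0(prefix, "_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(network$nodes)) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("from", "to", "weight")],
      directed = FALSE, vertices = network$nodes)
    igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  }
  invisible(prefix)
}

#' Fisher-exact (hypergeometric) term enrichment
#'
#' One-sided enrichment test per annotation term: the probability of
#' drawing at least `k` term genes when sampling `n` genes from a
#' background of `N` containing `K` term genes, followed by
#' Benjamini-Hochberg correction. Terms with fewer than `min_term_size`
#' background genes are skipped.
#'
#' @param selected gene set to test (must be a subset of `background`).
#' @param background the gene universe (e.g. all filtered genes).
#' @param annotation named list term -> character vector of genes, or a
#'   two-column `data.frame` (gene, term).
#' @param alpha corrected-p significance threshold (0.05 for pathway bins;
#'   a stricter threshold such as 1e-4 suits large ontologies).
#' @param min_term_size smallest background term tested.
#' @return `data.frame` per term: k, K, n, N, odds_ratio, p, q, significant.
#' @export
fisher_enrichment <- function(selected, background, annotation,
                              alpha = 0.05, min_term_size = 3) {
  if (!all(selected %in% background)) {
    stop("selected genes must be a subset of the background")
  }
  if (is.data.frame(annotation)) {
    annotation <- split(annotation[[1]], annotation[[2]])
  }
  N <- length(unique(background))
  n <- length(unique(selected))
  rows <- lapply(names(annotation), function(term) {
    tg <- intersect(annotation[[term]], background)
    K <- length(tg)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(tg, selected))
    orat <- (k * (N - K - n + k)) / max((K - k) * (n - k), .Machine$double.xmin)
    data.frame(term = term, k = k, K = K, n = n, N = N,
               odds_ratio = orat,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0), significant = logical(0)))
  }
  tab <- do.call(rbind, rows)
  tab$q <- p.adjust(tab$p, "BH")
  tab$significant <- tab$q < alpha
  tab[order(tab$p), , drop = FALSE]
}

#' Read a GMT or two-column gene-term annotation file
#'
#' GMT lines are `term<TAB>description<TAB>gene1<TAB>gene2...`; the
#' two-column format is a headered TSV with gene and term columns.
#'
#' @param path file path; `.gmt` extension selects the GMT parser.
#' @return named list term -> gene vector.
#' @export
load_annotation <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- strsplit(readLines(path, encoding = "UTF-8"), "\t", fixed = TRUE)
    out <- lapply(lines, function(f) unique(f[-(1:2)]))
    names(out) <- vapply(lines, `[`, character(1), 1)
    out
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    split(df[[1]], df[[2]])
  }
}
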