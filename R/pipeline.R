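#' Default pipeline configuration
#'
#' All stage hyperparameters in one list: data filtering, co-expression
#' (soft power, dynamic-cut controls, hub criteria), embeddings, the
#' random-forest cluster association stage, the multivariate gene
#' association stage and network integration. Every value is echoed into
#' the run manifest so that defaults are always auditable.
#'
#' @param ... named overrides.
#' @return configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    simulate = list(),          # design_config() overrides; NULL = use paths
    paths = NULL,               # list(metadata=, expression=, metabolome_wax=, metabolome_lcw=)
    annotation = NULL,          # optional gene->term file for enrichment
    seed = 1L,
    min_fraction = 0.5,         # expressed-in->50%-of-samples filter
    beta = 16,                  # soft-threshold power
    min_module_size = 30L,
    deep_split = 2L,
    merge_cut_height = 0.25,
    eigen_cor_min = 0.8,
    target_hub_frac = 0.05,
    perplexity = 20,
    tsne_iter = 1000L,
    n_trees = 500L,
    n_boot = 4000L,
    rf_alpha = 0.01,
    max_unclustered = 20L,      # cap on unclustered-gene RF predictors
    fpkm_threshold = 100,
    n_perm = 199L,
    max_comp = 10L,
    cv_folds = 5L,
    spls_keep_frac = 0.1,
    n_bags = 500L,
    candidate_frac = 0.2,
    max_terms = 2L,
    s_min = 1,
    p_max = 0.01,
    edge_quantile = 0.95,
    enrich_alpha = 0.05,
    min_term_size = 3L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "))
  modifyList(cfg, over, keep.null = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stage order: load or simulate -> low-expression filter -> standardize ->
#' metabolome statistics (class-level ANOVA partition, PCA, t-SNE) ->
#' co-expression network (bicor, soft adjacency, TOM, dynamic modules,
#' eigengenes, classes, hub genes) -> random-forest cluster association ->
#' multivariate gene association (PLS/sPLS/rGLM + permutation) -> network
#' integration (and enrichment when an annotation is supplied). Each
#' stage's outputs are written as TSV before the next stage begins, and a
#' JSON manifest records the configuration, per-stage timings, output
#' checksums and headline counts.
#'
#' @param config list from [pipeline_config()], or the path to a YAML file
#'   with the same fields.
#' @param out output directory.
#' @param force overwrite an existing output directory.
#' @param verbose print stage progress.
#' @return invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out, force = FALSE,
                         verbose = TRUE) {
  if (is.character(config)) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  if (dir.exists(out) && length(list.files(out)) && !force) {
    stop("output directory not empty (use force = TRUE): ", out)
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("cuticlenet")),
                   config = config, stages = list(), counts = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    cn_log("stage %-14s %6.1fs", name, manifest$stages[[name]], verbose = verbose)
    res
  }
  tsv <- function(df, name) {
    path <- file.path(out, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  # ---- load or simulate -------------------------------------------------
  ds <- t_stage("input", {
    if (!is.null(config$paths)) {
      p <- config$paths
      md <- load_metadata(p$metadata)
      al <- align_samples(list(expression = load_matrix(p$expression, "expression"),
                               metabolome_wax = load_matrix(p$metabolome_wax, "metabolite"),
                               metabolome_lcw = load_matrix(p$metabolome_lcw, "metabolite")),
                          md)
      c(al$matrices, list(metadata = al$metadata, truth = NULL))
    } else {
      dc <- do.call(design_config, c(config$simulate,
                                     if (is.null(config$simulate$seed))
                                       list(seed = config$seed)))
      sim <- generate_dataset(dc)
      write_dataset(sim, file.path(out, "data"))
      sim
    }
  })

  # ---- filter + standardize --------------------------------------------
  expr_f <- t_stage("filter", filter_low_expression(ds$expression, config$min_fraction))
  expr_std <- standardize(expr_f)
  manifest$counts$n_samples <- ncol(ds$expression)
  manifest$counts$n_genes_input <- nrow(ds$expression)
  manifest$counts$n_genes_filtered <- nrow(expr_f)

  # ---- metabolome statistics -------------------------------------------
  metab <- list(wax = ds$metabolome_wax, lcw = ds$metabolome_lcw)
  stats_res <- t_stage("metab_stats", {
    lapply(names(metab), function(frac) {
      m <- metab[[frac]]
      part <- anova_partition_classes(m, ds$metadata)
      tsv(part, sprintf("anova_partition_%s.tsv", frac))
      std <- standardize(m)
      pca <- pca_embed(std)
      ts <- tsne_embed(std, perplexity = config$perplexity,
                       seed = derive_seed(config$seed, paste0("tsne", frac)),
                       n_iter = config$tsne_iter)
      sc <- data.frame(sample_id = rownames(ts$scores), ts$scores)
      tsv(sc, sprintf("tsne_%s.tsv", frac))
      list(anova = part, pca = pca, tsne = ts)
    }) -> r
    names(r) <- names(metab)
    r
  })
  tsne_scores <- lapply(stats_res, function(x) x$tsne$scores)

  # ---- co-expression network -------------------------------------------
  coexp <- t_stage("coexpression", {
    cmat <- bicor_matrix(expr_std)
    adj <- soft_adjacency(cmat, config$beta)
    tom <- topological_overlap(adj)
    mods <- detect_modules(tom, expr_std, config$min_module_size,
                           config$deep_split, config$merge_cut_height)
    classes <- if (!is.null(mods$eigengenes)) classify_modules(mods$eigengenes) else NULL
    traits <- do.call(cbind, tsne_scores)
    colnames(traits) <- paste(rep(names(tsne_scores), each = 2),
                              c("tSNE1", "tSNE2"), sep = "_")
    hubs <- if (!is.null(mods$eigengenes)) {
      identify_hub_genes(expr_std, mods$labels, mods$eigengenes, tom, traits,
                         config$target_hub_frac, config$eigen_cor_min)
    } else {
      NULL
    }
    list(tom = tom, modules = mods, classes = classes, hubs = hubs)
  })
  mods <- coexp$modules
  manifest$counts$n_clusters <- max(mods$labels)
  manifest$counts$n_unclustered <- sum(mods$labels == 0)
  manifest$counts$n_hub_genes <- if (!is.null(coexp$hubs)) sum(coexp$hubs$hub_flags) else 0L
  lab_df <- data.frame(
    gene = names(mods$labels), cluster = unname(mods$labels),
    class = if (!is.null(coexp$classes))
      unname(coexp$classes[paste0("ME", mods$labels)]) else NA_integer_,
    is_hub = if (!is.null(coexp$hubs)) unname(coexp$hubs$hub_flags) else NA,
    eigengene_cor = if (!is.null(coexp$hubs)) unname(coexp$hubs$eigengene_cor) else NA_real_,
    connectivity = if (!is.null(coexp$hubs)) unname(coexp$hubs$connectivity) else NA_real_)
  tsv(lab_df, "module_labels.tsv")
  if (!is.null(mods$eigengenes)) {
    tsv(data.frame(sample_id = rownames(mods$eigengenes), mods$eigengenes),
        "eigengenes.tsv")
  }
  if (!is.null(coexp$hubs)) tsv(coexp$hubs$cutoffs, "hub_cutoffs.tsv")

  # ---- cluster-to-metabolome RF stage ----------------------------------
  rf_res <- t_stage("cluster_rf", {
    if (is.null(mods$eigengenes)) return(NULL)
    uncl <- names(mods$labels)[mods$labels == 0]
    uncl <- intersect(uncl, rownames(expr_std))
    if (length(uncl) > config$max_unclustered) {
      vr <- apply(expr_f[uncl, , drop = FALSE], 1, var)
      uncl <- uncl[order(-vr)][seq_len(config$max_unclustered)]
    }
    preds <- cbind(mods$eigengenes,
                   if (length(uncl)) t(expr_std[uncl, , drop = FALSE]))
    cluster_fraction_association(
      preds, tsne_scores, n_boot = config$n_boot, alpha = config$rf_alpha,
      n_trees = config$n_trees, seed = derive_seed(config$seed, "rf"))
  })
  if (!is.null(rf_res)) {
    tsv(do.call(rbind, lapply(names(rf_res$tables), function(f)
      data.frame(fraction = f, rf_res$tables[[f]]))), "cluster_association.tsv")
    tsv(rf_res$association, "cluster_fractions.tsv")
    manifest$counts$n_clusters_associated <-
      sum(rf_res$association$associated_fraction != "none" &
            grepl("^ME", rf_res$association$predictor))
  }

  # ---- gene-to-metabolite association ----------------------------------
  assoc_tab <- t_stage("gene_assoc", run_gene_association(
    expr_f, metab[c("lcw", "wax")], tsne_scores[c("lcw", "wax")],
    threshold = config$fpkm_threshold, n_perm = config$n_perm,
    max_comp = config$max_comp, cv_folds = config$cv_folds,
    spls_keep_frac = config$spls_keep_frac, n_bags = config$n_bags,
    candidate_frac = config$candidate_frac, max_terms = config$max_terms,
    s_min = config$s_min, p_max = config$p_max,
    seed = derive_seed(config$seed, "assoc"), verbose = verbose))
  tsv(assoc_tab, "gene_association.tsv")
  putative <- attr(assoc_tab, "putative")
  manifest$counts$n_putative_lcw <- length(putative$lcw)
  manifest$counts$n_putative_wax <- length(putative$wax)

  # ---- integration (+ optional enrichment) -----------------------------
  network <- t_stage("integrate", {
    if (is.null(rf_res)) return(NULL)
    net <- build_network(putative, mods$labels, rf_res$association,
                         coexp$tom,
                         hub_flags = coexp$hubs$hub_flags,
                         classes = coexp$classes,
                         edge_quantile = config$edge_quantile)
    write_network(net, file.path(out, "network"))
    net
  })
  if (!is.null(network)) {
    manifest$counts$n_network_nodes <- nrow(network$nodes)
    manifest$counts$n_network_edges <- nrow(network$edges)
    for (ct in c("lcw_only", "wax_only", "both")) {
      manifest$counts[[paste0("n_nodes_", ct)]] <-
        sum(network$nodes$category == ct)
    }
  }
  enrich <- NULL
  if (!is.null(config$annotation) && !is.null(network) && nrow(network$nodes)) {
    enrich <- t_stage("enrich", {
      ann <- load_annotation(config$annotation)
      do.call(rbind, lapply(unique(network$nodes$category), function(ct) {
        sel <- intersect(network$nodes$gene[network$nodes$category == ct],
                         rownames(expr_f))
        if (!length(sel)) return(NULL)
        data.frame(category = ct,
                   fisher_enrichment(sel, rownames(expr_f), ann,
                                     config$enrich_alpha, config$min_term_size))
      }))
    })
    if (!is.null(enrich)) tsv(enrich, "enrichment.tsv")
  }

  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(file.path(out, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dataset = ds, expr_filtered = expr_f, stats = stats_res,
                 coexpression = coexp, cluster_rf = rf_res,
                 gene_association = assoc_tab, putative = putative,
                 network = network, enrichment = enrich,
                 manifest = manifest))
}
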