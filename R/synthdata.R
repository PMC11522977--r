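#' Configuration for the synthetic seedling multi-omics generator
#'
#' Defaults emulate the study design the package targets: 6 seedling organs
#' x 4 genotypes x 3 replicates (72 samples), ~2000 genes with three planted
#' organ-driven co-expression modules, and two metabolome fractions
#' (cuticular waxes, lipidized cell wall monomers) of 50 metabolites each
#' whose variance is dominated by organ with a smaller genotype share.
#' Gene-to-metabolite ground truth is planted as standardized slopes from a
#' set of associated genes onto a handful of target metabolites per gene.
#'
#' Effect-size vectors of length 2 are interpreted as
#' `c(wax = ..., lcw = ...)`; a scalar applies to both fractions. The
#' defaults put the wax fraction's organ share of variance in the high
#' (45-88%) band with genotype below 10%, and give the LCW fraction a more
#' balanced organ/genotype/interaction split, mirroring the organ-dominant
#' variance structure the generator is meant to emulate.
#'
#' @param ... named overrides of any default field.
#' @return a `list` of class `cn_config`.
#' @export
design_config <- function(...) {
  cfg <- list(
    organs = c("root", "coleoptile", "leaf_sheath_1", "encased_leaves",
               "leaf_blade_1", "leaf_blade_2"),
    genotypes = c("B73", "Mo17", "B73xMo17", "Mo17xB73"),
    n_reps = 3L,
    n_genes = 2000L,
    n_modules = 3L,
    module_sizes = c(70L, 60L, 35L),
    module_latent_share = 0.72,    # expected within-module gene-gene r
    module_genotype_sd = 0.2,      # genotype modulation of module latents
    assoc_module_genotype_sd = 0.35, # genotype modulation of the association
                                   # module's latent (it propagates into the
                                   # metabolome through the planted slopes)
    module_rep_sd = 0.3,           # replicate-level wobble of module latents
    assoc_module_rep_sd = 0.5,     # replicate wobble of the association
                                   # module: its sample-level variation is
                                   # the module's unique (non-redundant)
                                   # signature in the metabolome
    bg_organ_sd = 0.05,            # organ effect of background genes
    bg_genotype_sd = 0.1,
    noise_sd_gene = 1,
    high_expr_frac = 0.2,          # fraction of genes on the >100 FPKM scale
    lognorm_sd = 0.4,              # spread of the FPKM exp-transform
    silent_fraction = 0.05,        # genes expressed in <50% of samples
    n_metabolites_per_fraction = 50L,
    organ_effect_sd = c(wax = 3.7, lcw = 2.0),
    genotype_effect_sd = c(wax = 0.4, lcw = 1.4),
    interaction_effect_sd = c(wax = 0.4, lcw = 0.8),
    noise_sd = c(wax = 1.0, lcw = 1.0),
    n_assoc_genes = 40L,           # truly associated genes per fraction
    n_assoc_both = 30L,            # of which shared by both fractions
    assoc_effect = 2.5,            # |standardized slope| gene -> metabolite
    n_target_metabolites = 3L,     # metabolites hit by each associated gene
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (length(cfg$organs) < 1 || length(cfg$genotypes) < 1) {
    stop("organs and genotypes must be non-empty")
  }
  if (anyDuplicated(cfg$organs)) stop("duplicate organ label in config")
  if (anyDuplicated(cfg$genotypes)) stop("duplicate genotype label in config")
  if (cfg$n_reps < 2) stop("n_reps must be >= 2")
  if (length(cfg$module_sizes) != cfg$n_modules) {
    stop("module_sizes must have n_modules entries")
  }
  if (sum(cfg$module_sizes) > cfg$n_genes) stop("module_sizes exceed n_genes")
  if (cfg$n_modules > length(cfg$organs) - 1) {
    stop("n_modules must be < number of organs (orthogonal organ profiles)")
  }
  sds <- c(frac2(cfg$organ_effect_sd), frac2(cfg$genotype_effect_sd),
           frac2(cfg$interaction_effect_sd), frac2(cfg$noise_sd))
  if (any(sds < 0)) stop("effect standard deviations must be nonnegative")
  if (!all(frac2(cfg$organ_effect_sd) > frac2(cfg$genotype_effect_sd))) {
    stop("organ_effect_sd must exceed genotype_effect_sd (organ-dominant design)")
  }
  if (cfg$n_assoc_both > cfg$n_assoc_genes) stop("n_assoc_both exceeds n_assoc_genes")
  if (cfg$n_modules > 0 && cfg$n_assoc_both > cfg$module_sizes[cfg$n_modules]) {
    stop("n_assoc_both exceeds the size of the last (association) module")
  }
  structure(cfg, class = "cn_config")
}

# per-fraction effect sizes: scalar applies to both fractions
frac2 <- function(x) {
  if (length(x) == 1) return(c(wax = unname(x), lcw = unname(x)))
  stopifnot(all(c("wax", "lcw") %in% names(x)))
  x[c("wax", "lcw")]
}

#' Generate the sample metadata for a design
#'
#' @param config a [design_config()].
#' @return `data.frame` with `sample_id`, `organ`, `genotype`, `replicate`;
#'   one row per organ x genotype x replicate.
#' @export
generate_metadata <- function(config) {
  config <- validate_config(config)
  md <- expand.grid(replicate = seq_len(config$n_reps),
                    genotype = config$genotypes,
                    organ = config$organs,
                    stringsAsFactors = FALSE)
  md <- md[, c("organ", "genotype", "replicate")]
  md$sample_id <- sprintf("%s_%s_r%d", md$organ, md$genotype, md$replicate)
  md$organ <- factor(md$organ, levels = config$organs)
  md$genotype <- factor(md$genotype, levels = config$genotypes)
  validate_metadata(md[, c("sample_id", "organ", "genotype", "replicate")])
}

# Orthonormal organ profiles for the module latents: random Gaussian organ
# vectors, centered (orthogonal to the intercept) and Gram-Schmidt
# orthogonalized so that distinct modules represent unrelated organ
# programs. Ground truth for "not associated" is only well defined when the
# non-associated modules carry no metabolome-aligned organ signal.
module_organ_profiles <- function(n_organs, n_modules) {
  if (n_modules == 0) return(matrix(0, n_organs, 0))
  O <- matrix(rnorm(n_organs * n_modules), n_organs, n_modules)
  O <- sweep(O, 2, colMeans(O))
  for (j in seq_len(n_modules)) {
    v <- O[, j]
    if (j > 1) for (i in seq_len(j - 1)) v <- v - sum(v * O[, i]) * O[, i]
    O[, j] <- v / sqrt(sum(v^2))
  }
  O
}

#' Generate synthetic expression with planted modules
#'
#' Module member genes share an organ-driven latent profile (fraction
#' `module_latent_share` of their variance), background genes have small
#' independent organ/genotype effects plus noise, and everything is mapped
#' to an FPKM-like nonnegative scale by exponentiating the Gaussian core. A
#' `high_expr_frac` fraction of genes is placed on a >100 FPKM scale so the
#' high-expression stratum is populated; a `silent_fraction` of genes is
#' expressed in under half the samples so the low-expression filter has
#' something to do.
#'
#' @param metadata from [generate_metadata()].
#' @param config a [design_config()].
#' @return list with `expression` (FPKM matrix) and `truth` (list:
#'   `module_membership`, `assoc_genes_lcw`, `assoc_genes_wax`,
#'   `effect_map`, `latents`).
#' @export
generate_expression <- function(metadata, config) {
  config <- validate_config(config)
  n <- nrow(metadata)
  ng <- config$n_genes
  gene_ids <- sprintf("gene_%04d", seq_len(ng))
  with_seed(derive_seed(config$seed, "expression"), {
    organ_idx <- as.integer(metadata$organ)
    geno_idx <- as.integer(metadata$genotype)
    K <- config$n_modules
    O <- module_organ_profiles(length(config$organs), K)
    membership <- integer(ng)
    core <- matrix(rnorm(ng * n, sd = config$noise_sd_gene), ng, n,
                   dimnames = list(gene_ids, metadata$sample_id))
    latents <- matrix(0, n, K)
    pos <- 0L
    for (m in seq_len(K)) {
      sz <- config$module_sizes[m]
      gsd <- if (m == K) config$assoc_module_genotype_sd else config$module_genotype_sd
      rsd <- if (m == K) config$assoc_module_rep_sd else config$module_rep_sd
      gmod <- rnorm(length(config$genotypes), sd = gsd)
      lat <- O[organ_idx, m] * sqrt(length(config$organs)) +
        gmod[geno_idx] + rnorm(n, sd = rsd)
      lat <- (lat - mean(lat)) / sd(lat)
      latents[, m] <- lat
      rows <- (pos + 1L):(pos + sz)
      share <- config$module_latent_share
      core[rows, ] <- sqrt(share) * matrix(lat, sz, n, byrow = TRUE) +
        sqrt(1 - share) * matrix(rnorm(sz * n), sz, n)
      membership[rows] <- m
      pos <- pos + sz
    }
    bg <- which(membership == 0)
    if (length(bg)) {
      bo <- matrix(rnorm(length(bg) * length(config$organs),
                         sd = config$bg_organ_sd), length(bg))
      bgg <- matrix(rnorm(length(bg) * length(config$genotypes),
                          sd = config$bg_genotype_sd), length(bg))
      core[bg, ] <- core[bg, ] + bo[, organ_idx] + bgg[, geno_idx]
    }

    n_silent <- floor(config$silent_fraction * ng)
    silent <- if (n_silent > 0) sample(bg, n_silent) else integer(0)

    mu <- ifelse(runif(ng) < config$high_expr_frac, log(250), log(8)) +
      rnorm(ng, sd = 0.3)
    mu[silent] <- log(2)
    fpkm <- exp(mu + config$lognorm_sd * core)
    for (g in silent) {
      on <- sample(n, max(2L, floor(0.3 * n)))
      fpkm[g, setdiff(seq_len(n), on)] <- 0
    }

    # ground-truth associations: the last module is the shared ("both")
    # association module; fraction-specific genes come from the expressed
    # background.
    membership <- setNames(membership, gene_ids)
    both <- if (config$n_assoc_both > 0 && K > 0) {
      names(membership)[membership == K][seq_len(config$n_assoc_both)]
    } else {
      character(0)
    }
    n_only <- config$n_assoc_genes - config$n_assoc_both
    pool <- setdiff(gene_ids[bg], gene_ids[silent])
    only <- sample(pool, 2 * n_only)
    lcw_only <- only[seq_len(n_only)]
    wax_only <- setdiff(only, lcw_only)
    # Fraction-specific associated genes form a small co-regulated program:
    # they share a sample-level latent (too few genes to be clusterable),
    # so their collective metabolite signal is a coherent direction rather
    # than a scatter of weak independent effects.
    for (gset in list(lcw_only, wax_only)) {
      if (length(gset) >= 2) {
        lat_o <- rnorm(n); lat_o <- (lat_o - mean(lat_o)) / sd(lat_o)
        share <- config$module_latent_share
        core[gset, ] <- sqrt(share) * matrix(lat_o, length(gset), n, byrow = TRUE) +
          sqrt(1 - share) * matrix(rnorm(length(gset) * n), length(gset), n)
        fpkm[gset, ] <- exp(mu[match(gset, gene_ids)] +
                              config$lognorm_sd * core[gset, ])
      }
    }
    assoc_lcw <- c(both, lcw_only)
    assoc_wax <- c(both, wax_only)

    nm <- config$n_metabolites_per_fraction
    # Targets are assigned round-robin (even coverage of the fraction's
    # metabolites). Slope signs are a property of the target metabolite:
    # within one metabolite all planted contributions share a sign, so the
    # shared-module signal stays coherent per metabolite (visible to the
    # embedding-based stages), while the sign alternates between successive
    # members of each metabolite class, so class-level sums cancel and the
    # planted signal does not distort the organ/genotype variance structure.
    n_classes <- if (exists("classes_of")) length(classes_of) else
      c(wax = 6L, lcw = 5L)
    met_sign <- function(j, fraction) {
      ncl <- if (fraction == "wax") 6L else 5L
      ifelse(((j - 1) %/% ncl) %% 2 == 0, 1, -1)
    }
    mk_map <- function(genes, fraction) {
      if (!length(genes) || config$assoc_effect == 0) {
        return(data.frame(gene = character(0), metabolite = character(0),
                          fraction = character(0), slope = numeric(0)))
      }
      nt <- min(config$n_target_metabolites, nm)
      do.call(rbind, lapply(seq_along(genes), function(i) {
        tgt <- ((i - 1) * nt + seq_len(nt) - 1) %% nm + 1
        data.frame(gene = genes[i],
                   metabolite = sprintf("%s_%03d", fraction, tgt),
                   fraction = fraction,
                   slope = config$assoc_effect * met_sign(tgt, fraction))
      }))
    }
    effect_map <- rbind(mk_map(assoc_lcw, "lcw"), mk_map(assoc_wax, "wax"))

    truth <- list(module_membership = membership,
                  assoc_genes_lcw = assoc_lcw,
                  assoc_genes_wax = assoc_wax,
                  effect_map = effect_map,
                  module_organ_profiles = O,
                  latents = latents)
    list(expression = omics_matrix(fpkm, nonnegative = TRUE), truth = truth)
  })
}

#' Generate a synthetic metabolome fraction
#'
#' Metabolite concentration = organ effect + genotype effect + interaction
#' + planted slopes times standardized expression of the associated genes
#' + replicate noise, shifted to be nonnegative. Metabolite organ effects
#' are drawn from the organ subspace orthogonal to all module latent organ
#' profiles, so that non-associated modules are genuinely unassociated with
#' the metabolome and the planted slopes are the only transcriptome link.
#' Metabolite class labels are assigned round-robin over the fraction's
#' standard classes.
#'
#' @param metadata sample metadata.
#' @param expression FPKM matrix from [generate_expression()].
#' @param truth_in ground-truth list carrying `effect_map` and the module
#'   organ profiles.
#' @param config a [design_config()].
#' @param fraction `"wax"` or `"lcw"`.
#' @return metabolite matrix with class/fraction annotations.
#' @export
generate_metabolome <- function(metadata, expression, truth_in, config,
                                fraction = c("wax", "lcw")) {
  config <- validate_config(config)
  fraction <- match.arg(fraction)
  stopifnot(identical(colnames(expression), metadata$sample_id))
  emap <- truth_in$effect_map
  emap <- emap[emap$fraction == fraction, , drop = FALSE]
  missing <- setdiff(emap$gene, rownames(expression))
  if (length(missing)) {
    stop("associated gene(s) absent from expression: ",
         paste(head(missing, 5), collapse = ", "))
  }
  n <- nrow(metadata)
  nm <- config$n_metabolites_per_fraction
  met_ids <- sprintf("%s_%03d", fraction, seq_len(nm))
  s_organ <- frac2(config$organ_effect_sd)[fraction]
  s_geno <- frac2(config$genotype_effect_sd)[fraction]
  s_int <- frac2(config$interaction_effect_sd)[fraction]
  s_noise <- frac2(config$noise_sd)[fraction]

  with_seed(derive_seed(config$seed, paste0("metabolome_", fraction)), {
    n_org <- length(config$organs)
    n_gen <- length(config$genotypes)
    organ_idx <- as.integer(metadata$organ)
    geno_idx <- as.integer(metadata$genotype)
    # Organ-effect basis. With planted gene effects, metabolite organ
    # effects are drawn along the association module's own organ profile
    # (random coefficient per metabolite): the cuticle metabolome's organ
    # program is, by construction, the organ program of the associated
    # module, so every organ-structured direction of the metabolome is
    # genuinely predictable from associated-gene expression and ground
    # truth stays identifiable. With no planted effects (null data) the
    # basis is the organ subspace orthogonal to the intercept and to every
    # module profile, making modules and metabolome independent.
    Om <- truth_in$module_organ_profiles %||% matrix(0, n_org, 0)
    if (nrow(emap) > 0 && ncol(Om) > 0) {
      basis <- Om[, ncol(Om), drop = FALSE]
    } else {
      proj <- cbind(rep(1 / sqrt(n_org), n_org), Om)
      B <- diag(n_org) - proj %*% t(proj)
      eb <- eigen(B, symmetric = TRUE)
      basis <- eb$vectors[, eb$values > 0.5, drop = FALSE]
    }
    d <- ncol(basis)
    organ_eff <- basis %*% matrix(rnorm(d * nm, sd = s_organ * sqrt(n_org / d)),
                                  d, nm)                      # organs x mets
    geno_eff <- matrix(rnorm(n_gen * nm, sd = s_geno), n_gen, nm)
    geno_eff <- sweep(geno_eff, 2, colMeans(geno_eff))
    int_eff <- array(rnorm(n_org * n_gen * nm, sd = s_int),
                     dim = c(n_org, n_gen, nm))
    for (j in seq_len(nm)) {                 # double-center: pure interaction
      ic <- int_eff[, , j]
      ic <- ic - rowMeans(ic)
      ic <- sweep(ic, 2, colMeans(ic))
      int_eff[, , j] <- ic
    }

    Y <- matrix(0, nm, n, dimnames = list(met_ids, metadata$sample_id))
    for (j in seq_len(nm)) {
      Y[j, ] <- organ_eff[organ_idx, j] + geno_eff[geno_idx, j] +
        int_eff[cbind(organ_idx, geno_idx, j)] + rnorm(n, sd = s_noise)
    }
    if (nrow(emap)) {
      for (r in seq_len(nrow(emap))) {
        x <- expression[emap$gene[r], ]
        sdx <- sd(x)
        if (sdx > 0) Y[emap$metabolite[r], ] <-
            Y[emap$metabolite[r], ] + emap$slope[r] * (x - mean(x)) / sdx
      }
    }
    Y <- Y - apply(Y, 1, min)          # shift to a nonnegative concentration scale
    classes <- if (fraction == "wax") {
      c("VLCFA", "fatty_alcohol", "fatty_aldehyde", "wax_ester",
        "hydrocarbon", "terpene")
    } else {
      c("phenolics", "fatty_acid", "omega_hydroxy_FA", "2_hydroxy_FA",
        "polyhydroxy_FA")
    }
    fm <- data.frame(feature = met_ids,
                     class = rep(classes, length.out = nm),
                     fraction = fraction)
    omics_matrix(Y, feature_meta = fm)
  })
}

#' Generate a full synthetic dataset
#'
#' Bundles metadata, FPKM expression, both metabolome fractions and the
#' ground truth (module membership, associated gene sets per fraction and
#' the planted effect map).
#'
#' @param config a [design_config()].
#' @return list of class `cn_dataset` with elements `metadata`,
#'   `expression`, `metabolome_wax`, `metabolome_lcw`, `truth`, `config`.
#' @export
generate_dataset <- function(config = design_config()) {
  config <- validate_config(config)
  md <- generate_metadata(config)
  ex <- generate_expression(md, config)
  wax <- generate_metabolome(md, ex$expression, ex$truth, config, "wax")
  lcw <- generate_metabolome(md, ex$expression, ex$truth, config, "lcw")
  structure(list(metadata = md, expression = ex$expression,
                 metabolome_wax = wax, metabolome_lcw = lcw,
                 truth = ex$truth, config = config),
            class = "cn_dataset")
}

#' Planted per-metabolite variance shares
#'
#' Expected type-I ANOVA partial R-squared for a fraction generated with
#' `assoc_effect = 0`, derived from the generator's effect scales: the
#' organ term contributes `organ_sd^2` per sample, the (centered) genotype
#' term `0.75 * genotype_sd^2`, the (double-centered) interaction term
#' `0.625 * interaction_sd^2` and the residual `noise_sd^2`.
#'
#' @param config a [design_config()].
#' @param fraction `"wax"` or `"lcw"`.
#' @return named numeric vector of shares summing to 1.
#' @export
expected_variance_shares <- function(config, fraction = c("wax", "lcw")) {
  fraction <- match.arg(fraction)
  v <- c(organ = unname(frac2(config$organ_effect_sd)[fraction])^2,
         genotype = 0.75 * unname(frac2(config$genotype_effect_sd)[fraction])^2,
         interaction = 0.625 * unname(frac2(config$interaction_effect_sd)[fraction])^2,
         residual = unname(frac2(config$noise_sd)[fraction])^2)
  v / sum(v)
}

#' Ground-truth association categories
#'
#' @param truth the `truth` element of a [generate_dataset()] result.
#' @return list with `lcw_only`, `wax_only`, `both` gene sets (disjoint).
#' @export
truth_categories <- function(truth) {
  list(lcw_only = setdiff(truth$assoc_genes_lcw, truth$assoc_genes_wax),
       wax_only = setdiff(truth$assoc_genes_wax, truth$assoc_genes_lcw),
       both = intersect(truth$assoc_genes_lcw, truth$assoc_genes_wax))
}

#' Write or read a synthetic dataset as plain text
#'
#' Matrices go through [write_matrix()] (exact decimal serialization),
#' metadata through [write_metadata()], and the ground truth to a JSON file.
#'
#' @param ds dataset from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory (write) or a reassembled dataset list (read).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_metadata(ds$metadata, file.path(dir, "metadata.tsv"))
  write_matrix(ds$expression, file.path(dir, "expression.tsv"))
  write_matrix(ds$metabolome_wax, file.path(dir, "metabolome_wax.tsv"))
  write_matrix(ds$metabolome_lcw, file.path(dir, "metabolome_lcw.tsv"))
  for (frac in c("wax", "lcw")) {
    fm <- feature_meta(ds[[paste0("metabolome_", frac)]])
    utils::write.table(fm, file.path(dir, paste0("classes_", frac, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tr <- ds$truth
  jsonlite::write_json(
    list(module_membership = as.list(tr$module_membership),
         assoc_genes_lcw = tr$assoc_genes_lcw,
         assoc_genes_wax = tr$assoc_genes_wax,
         effect_map = tr$effect_map),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  md <- load_metadata(file.path(dir, "metadata.tsv"))
  expr <- load_matrix(file.path(dir, "expression.tsv"), "expression")
  read_frac <- function(frac) {
    m <- load_matrix(file.path(dir, paste0("metabolome_", frac, ".tsv")),
                     "metabolite")
    fm <- utils::read.delim(file.path(dir, paste0("classes_", frac, ".tsv")),
                            stringsAsFactors = FALSE)
    omics_matrix(m, feature_meta = fm)
  }
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    tj <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth <- list(module_membership = unlist(tj$module_membership),
                  assoc_genes_lcw = tj$assoc_genes_lcw,
                  assoc_genes_wax = tj$assoc_genes_wax,
                  effect_map = tj$effect_map)
  }
  structure(list(metadata = md, expression = expr,
                 metabolome_wax = read_frac("wax"),
                 metabolome_lcw = read_frac("lcw"),
                 truth = truth),
            class = "cn_dataset")
}
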