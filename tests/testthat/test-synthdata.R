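# small configs used throughout: fewer genes, same 72-sample design
small_cfg <- function(seed, ...) {
  design_config(seed = seed, n_genes = 150L, module_sizes = c(40L, 35L, 30L),
                n_assoc_genes = 35L, n_assoc_both = 30L,
                n_metabolites_per_fraction = 20L, ...)
}

test_that("metadata generation matches the crossed design", {
  md <- generate_metadata(design_config())
  expect_equal(nrow(md), 72)
  expect_equal(length(unique(md$sample_id)), 72)
  expect_true(all(table(md$organ, md$genotype) == 3))

  tiny <- design_config(organs = "root", genotypes = "B73", n_reps = 2,
                        n_modules = 0L, module_sizes = integer(0),
                        n_assoc_genes = 0L, n_assoc_both = 0L)
  expect_equal(nrow(generate_metadata(tiny)), 2)

  expect_error(design_config(organs = c("root", "root")), "duplicate")
  expect_error(design_config(n_reps = 1), "n_reps")
  expect_error(design_config(module_sizes = c(4000L, 100L, 35L)), "exceed")
})

test_that("within-module correlation lands in the designed band", {
  rbar <- vapply(1:50, function(seed) {
    cfg <- small_cfg(seed)
    ex <- generate_expression(generate_metadata(cfg), cfg)
    g <- names(ex$truth$module_membership)[ex$truth$module_membership == 1]
    cc <- cor(t(ex$expression[g, ]))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_gte(mean(rbar), 0.6)
  expect_lte(mean(rbar), 0.8)
})

test_that("a full latent share makes module genes perfectly correlated", {
  cfg <- small_cfg(2, module_latent_share = 1)
  ex <- generate_expression(generate_metadata(cfg), cfg)
  g <- names(ex$truth$module_membership)[ex$truth$module_membership == 1]
  cc <- cor(t(ex$expression[g, ]))
  expect_equal(min(cc), 1)
})

test_that("generation is bit-identical for a fixed seed", {
  d1 <- generate_dataset(small_cfg(5))
  d2 <- generate_dataset(small_cfg(5))
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$metabolome_wax, d2$metabolome_wax)
  expect_identical(d1$metabolome_lcw, d2$metabolome_lcw)
  expect_identical(d1$truth$effect_map, d2$truth$effect_map)
})

test_that("metabolome structure follows the planted effects", {
  cfg <- design_config(seed = 3)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$metabolome_wax >= 0))
  expect_true(all(ds$metabolome_lcw >= 0))

  # round-robin class labels: counts differ by at most one
  for (frac in c("wax", "lcw")) {
    fm <- feature_meta(ds[[paste0("metabolome_", frac)]])
    counts <- table(fm$class)
    expect_lte(diff(range(counts)), 1)
  }
  expect_equal(nrow(feature_meta(ds$metabolome_wax)), 50)
  expect_equal(length(unique(feature_meta(ds$metabolome_wax)$class)), 6)
  expect_equal(length(unique(feature_meta(ds$metabolome_lcw)$class)), 5)

  # a planted gene correlates with its target metabolites
  em <- ds$truth$effect_map
  em_wax <- em[em$fraction == "wax", ]
  g <- em_wax$gene[1]
  tgt <- em_wax$metabolite[em_wax$gene == g]
  r <- abs(cor(ds$expression[g, ], t(ds$metabolome_wax[tgt, , drop = FALSE])))
  expect_gt(max(r), 0.3)

  # association categories partition cleanly
  cats <- truth_categories(ds$truth)
  expect_length(intersect(cats$lcw_only, cats$wax_only), 0)
  expect_length(intersect(cats$both, c(cats$lcw_only, cats$wax_only)), 0)
  expect_setequal(c(cats$lcw_only, cats$both), ds$truth$assoc_genes_lcw)
  expect_setequal(c(cats$wax_only, cats$both), ds$truth$assoc_genes_wax)

  # planted genes must exist in the expression matrix
  bad_truth <- ds$truth
  wax_row <- which(bad_truth$effect_map$fraction == "wax")[1]
  bad_truth$effect_map$gene[wax_row] <- "gene_9999x"
  expect_error(generate_metabolome(ds$metadata, ds$expression, bad_truth,
                                   cfg, "wax"), "absent")
})

test_that("null generation decouples metabolome from transcriptome", {
  mean_cor <- vapply(1:8, function(seed) {
    ds <- generate_dataset(small_cfg(seed, assoc_effect = 0))
    mean(cor(t(ds$expression), t(ds$metabolome_wax)))
  }, numeric(1))
  expect_lt(abs(mean(mean_cor)), 0.02)
})

test_that("ANOVA recovers the planted variance shares on null data", {
  cfg0 <- small_cfg(1, assoc_effect = 0)
  want <- expected_variance_shares(cfg0, "lcw")
  got <- rowMeans(vapply(1:20, function(seed) {
    cfg <- small_cfg(seed, assoc_effect = 0)
    ds <- generate_dataset(cfg)
    part <- anova_partition_classes(ds$metabolome_lcw, ds$metadata)
    c(organ = mean(part$partial_R2_organ),
      genotype = mean(part$partial_R2_genotype),
      interaction = mean(part$partial_R2_interaction),
      residual = mean(part$partial_R2_residual))
  }, numeric(4)))
  expect_lt(max(abs(got - want)), 0.07)
})

test_that("datasets survive a write/read round trip", {
  ds <- generate_dataset(small_cfg(9))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(unname(back$expression), unname(ds$expression + 0))
  expect_equal(unname(back$metabolome_lcw), unname(ds$metabolome_lcw + 0))
  expect_identical(back$metadata$sample_id, ds$metadata$sample_id)
  expect_setequal(back$truth$assoc_genes_wax, ds$truth$assoc_genes_wax)
})
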