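test_that("invalid configurations fail before any sampling", {
  expect_error(simulation_config(replicates = 1L), "replicates")
  expect_error(simulation_config(frac_subthreshold = 1.2), "proportions")
  expect_error(simulation_config(frac_nuclear_shifted = 0.8,
                                 frac_cytoplasmic_shifted = 0.3), "sum to < 1")
  expect_error(simulation_config(shift_log2 = 1.5), "shift_log2")
  expect_error(simulation_config(noise_log2_sd = -0.1), "standard deviations")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_genes = 200L, seed = 5L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a, b)
  expect_false(identical(a$matrix,
                         simulate_dataset(simulation_config(n_genes = 200L, seed = 6L))$matrix))

  expect_identical(simulate_genesets(a$truth, seed = 3L),
                   simulate_genesets(a$truth, seed = 3L))
  tg <- a$truth$gene[1:2]
  expect_identical(simulate_qpcr(a$truth, tg, cfg),
                   simulate_qpcr(a$truth, tg, cfg))
})

test_that("dataset shape, truth partition and subthreshold contract hold", {
  cfg <- simulation_config(n_genes = 500L, seed = 2L)
  ds <- simulate_dataset(cfg)
  expect_identical(ncol(ds$matrix), 12L)  # 2 conditions x 2 fractions x 3 reps
  expect_gte(nrow(ds$matrix), 500L)       # multi-locus splitting only adds rows
  expect_setequal(ds$locus_map$locus_id, rownames(ds$matrix))
  expect_identical(sort(unique(ds$locus_map$gene_symbol)), sort(ds$truth$gene))
  expect_true(all(ds$truth$true_class %in%
                    c("nuclear_shifted", "cytoplasmic_shifted", "null", "subthreshold")))
  expect_identical(sum(ds$truth$true_class == "nuclear_shifted"), 25L)  # 0.05 * 500

  gene_mat <- aggregate_by_gene(ds$matrix, ds$locus_map)
  sub <- ds$truth$gene[ds$truth$true_class == "subthreshold"]
  expect_true(all(apply(gene_mat[sub, , drop = FALSE], 1L, min) <= 0.5))
})

test_that("zero shift degenerates to a pure null simulation", {
  ds <- simulate_dataset(simulation_config(n_genes = 300L, shift_log2 = 0, seed = 4L))
  expect_false(any(ds$truth$true_class %in% c("nuclear_shifted", "cytoplasmic_shifted")))
  expect_true(all(ds$truth$true_shift_log2 == 0))
})

test_that("multi-locus weights preserve C/N ratios through aggregation", {
  cfg <- simulation_config(n_genes = 200L, frac_multilocus = 0.2, seed = 9L)
  ds <- simulate_dataset(cfg)
  gene_mat <- aggregate_by_gene(ds$matrix, ds$locus_map)
  multi <- names(which(table(ds$locus_map$gene_symbol) > 1L))
  expect_gt(length(multi), 10L)
  g <- multi[1L]
  loci <- ds$locus_map$locus_id[ds$locus_map$gene_symbol == g]
  # constant per-locus weights: column ratios of the aggregate equal those of
  # any single locus
  agg <- gene_mat[g, ] / gene_mat[g, 1L]
  one <- ds$matrix[loci[1L], ] / ds$matrix[loci[1L], 1L]
  expect_equal(agg, one, tolerance = 1e-12)
})

test_that("planted shifts are realized at the configured magnitude", {
  cfg <- simulation_config(n_genes = 2000L, seed = 1L)
  ds <- simulate_dataset(cfg)
  gene_mat <- aggregate_by_gene(ds$matrix, ds$locus_map)
  r <- nucyto:::cn_ratio_matrices(gene_mat, ds$samples)
  diff <- rowMeans(log2(r$`repeat`)) - rowMeans(log2(r$control))
  planted <- ds$truth$true_class == "nuclear_shifted"
  m <- mean(diff[planted])
  se <- stats::sd(diff[planted]) / sqrt(sum(planted))
  expect_lt(abs(m - (-1.5)), 3 * se)

  # abundance and realized localization are orthogonal by construction
  null <- ds$truth$true_class == "null"
  ab <- log2(rowMeans(gene_mat[ds$truth$gene, ]))
  loc <- rowMeans(log2(r$control))
  fit <- stats::lm(loc[null] ~ ab[null])
  expect_lt(abs(stats::coef(fit)[2L]), 0.05)
})

test_that("simulate_genesets plants one enriched set; fraction 0 gives pure decoys", {
  ds <- simulate_dataset(simulation_config(n_genes = 400L, seed = 3L))
  shifted <- ds$truth$gene[ds$truth$true_class == "nuclear_shifted"]
  coll <- simulate_genesets(ds$truth, n_sets = 10L, set_size = 40L,
                            enriched_set_fraction = 0.6, seed = 3L)
  expect_length(coll$sets, 11L)
  planted <- coll$sets$membrane_trafficking_like
  expect_gte(length(intersect(planted, shifted)), min(24L, length(shifted)) - 1L)

  none <- simulate_genesets(ds$truth, n_sets = 5L, set_size = 40L,
                            enriched_set_fraction = 0, seed = 3L)
  expect_length(intersect(none$sets$membrane_trafficking_like, shifted), 0L)
})

test_that("simulate_qpcr is consistent with planted shifts (noise-free exactness)", {
  truth <- data.frame(gene = c("gA", "gB"),
                      true_class = c("nuclear_shifted", "null"),
                      true_shift_log2 = c(-1, 0), stringsAsFactors = FALSE)
  cfg <- simulation_config(n_genes = 10L, seed = 1L)
  cq <- simulate_qpcr(truth, c("gA", "gB"), cfg, cq_noise_sd = 0)
  fc <- qpcr_fold_changes(cq)
  expect_equal(fc$fc_vs_control[fc$target == "gA"], 0.5)
  expect_equal(fc$fc_vs_control[fc$target == "gB"], 1)
  expect_error(simulate_qpcr(truth, "missing_gene", cfg), "absent from truth")
})

test_that("count mode produces integer-grid FPKM and still recovers shifts", {
  cfg <- simulation_config(n_genes = 300L, count_mode = TRUE, seed = 6L)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$matrix * 10 == round(ds$matrix * 10)))
})
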