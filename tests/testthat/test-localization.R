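cfg_default <- localization_config()

test_that("filter_expressed applies the strict coordinate-expression rule", {
  sheet <- make_sheet(3L)
  n_s <- nrow(sheet)
  mat <- rbind(
    all_one = rep(1.0, n_s),       # log2 = 0 everywhere -> retained
    one_low = c(0.4, rep(1, n_s - 1L)),  # one sample at log2 ~ -1.32 -> out
    boundary = rep(0.5, n_s)       # log2 = -1 exactly: strict ">" -> out
  )
  colnames(mat) <- sheet$sample_id
  kept <- filter_expressed(mat, sheet, cfg_default)
  expect_identical(kept, "all_one")
})

test_that("filter is monotone in the threshold", {
  fx <- make_random_matrix(n_genes = 200L, seed = 2)
  thresholds <- c(2, 1, 0, -1, -2, -5)
  sets <- lapply(thresholds, function(th)
    filter_expressed(fx$matrix, fx$sheet,
                     localization_config(expression_log2_threshold = th)))
  for (i in seq_along(sets)[-1L])
    expect_true(all(sets[[i - 1L]] %in% sets[[i]]))
})

test_that("cn_ratios pairs fractions by replicate index", {
  sheet <- make_sheet(3L)
  mat <- matrix(0, nrow = 1L, ncol = nrow(sheet),
                dimnames = list("g1", sheet$sample_id))
  # nuclear 2, cytoplasmic 4 in every sample -> ratio 2 everywhere
  mat[1L, sheet$sample_id[sheet$fraction == "nuclear"]] <- 2
  mat[1L, sheet$sample_id[sheet$fraction == "cytoplasmic"]] <- 4
  r <- cn_ratios(mat, sheet, "g1")
  expect_equal(unname(r$control), rep(2, 3))
  expect_equal(unname(r$`repeat`), rep(2, 3))
  expect_equal(mean(r$control), 2)

  # equal fractions -> ratio 1
  mat[] <- 5
  expect_equal(unname(cn_ratios(mat, sheet, "g1")$control), rep(1, 3))

  # missing fraction partner -> hard error (caught by design validation)
  expect_error(cn_ratios(mat, sheet[sheet$sample_id != "ctrl_nuc_r2", ], "g1"),
               "incomplete design|missing nuclear sample")
})

test_that("localization_test matches the textbook oracle on the frozen case", {
  # control log2 ratios (0, 0.1, -0.1); repeat (-1.0, -0.9, -1.1)
  rc <- 2^c(0, 0.1, -0.1)
  rr <- 2^c(-1.0, -0.9, -1.1)
  got <- localization_test(rc, rr, cfg_default)
  orc <- oracle_t_test(log2(rr), log2(rc))
  expect_equal(orc$df, 4)
  expect_equal(got$p_value, orc$p, tolerance = 1e-10)
  expect_equal(got$fc, mean(rr) / mean(rc), tolerance = 1e-12)
})

test_that("localization_test handles identical and degenerate groups", {
  r <- c(1, 2, 4)
  same <- localization_test(r, r, cfg_default)
  expect_equal(same$fc, 1)
  expect_equal(same$p_value, 1)

  # zero pooled variance, unequal means: p pinned to the smallest double
  deg <- localization_test(c(2, 2, 2), c(1, 1, 1), cfg_default)
  expect_true(deg$degenerate)
  expect_identical(deg$p_value, .Machine$double.xmin)

  # zero pooled variance, equal means: p = 1
  flat <- localization_test(c(2, 2, 2), c(2, 2, 2), cfg_default)
  expect_false(flat$degenerate)
  expect_identical(flat$p_value, 1)

  expect_error(localization_test(c(1), c(1, 2), cfg_default), "2 replicates")
})

test_that("fc and p are invariant to rescaling all cytoplasmic values (log2 scale)", {
  withr::local_seed(5)
  for (i in 1:5) {
    rc <- 2^rnorm(3); rr <- 2^rnorm(3)
    a <- localization_test(rc, rr, cfg_default)
    b <- localization_test(2 * rc, 2 * rr, cfg_default)
    expect_equal(a$fc, b$fc, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("geometric-mean aggregation and linear-scale testing are available", {
  rc <- c(1, 2, 4); rr <- c(2, 4, 8)
  geo <- localization_test(rc, rr, localization_config(fc_aggregation = "geometric_mean"))
  expect_equal(geo$fc, 2, tolerance = 1e-12)
  lin <- localization_test(rc, rr, localization_config(ratio_scale = "linear"))
  tt <- stats::t.test(rr, rc, var.equal = TRUE)
  expect_equal(lin$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("classify follows the strict direction/significance rule", {
  cfg <- cfg_default
  expect_identical(classify(0.5, 0.01, cfg), "nuclear_accumulated")
  expect_identical(classify(2.0, 0.30, cfg), "unchanged")
  expect_identical(classify(2.0, 0.01, cfg), "cytoplasmic_accumulated")
  expect_identical(classify(1.0, 1e-6, cfg), "unchanged")  # no direction at fc = 1
  expect_identical(classify(0.5, 0.05, cfg), "unchanged")  # p == alpha not significant
})

test_that("localize returns consistent records and flags filtered genes", {
  fx <- make_random_matrix(n_genes = 100L, seed = 3)
  fx$matrix[1:10, 1L] <- 0.2  # force some genes under the filter
  res <- localize(fx$matrix, fx$sheet)
  expect_s3_class(res, "localization_result")
  expect_identical(res$gene, rownames(fx$matrix))
  filt <- res[res$class == "filtered", ]
  expect_true(all(is.na(filt$fc)) && all(is.na(filt$p_value)))
  tested <- res[res$class != "filtered", ]
  expect_equal(tested$fc, tested$cn_mean_repeat / tested$cn_mean_control)
  expect_equal(tested$log2fc, log2(tested$fc))
  expect_identical(tested$class,
                   classify(tested$fc, tested$p_value, cfg_default))
  # spot-check one gene against the scalar path
  g <- tested$gene[1L]
  r <- cn_ratios(fx$matrix, fx$sheet, g)
  one <- localization_test(r$control, r$`repeat`, cfg_default)
  expect_equal(tested[tested$gene == g, "p_value"], one$p_value, tolerance = 1e-12)
  expect_equal(tested[tested$gene == g, "fc"], one$fc, tolerance = 1e-12)
})

test_that("volcano_table omits filtered genes and sorts by log2fc", {
  fx <- make_random_matrix(n_genes = 50L, seed = 8)
  fx$matrix[1:5, 2L] <- 0.1
  res <- localize(fx$matrix, fx$sheet)
  v <- volcano_table(res)
  expect_identical(nrow(v), sum(res$class != "filtered"))
  expect_false(is.unsorted(v$log2fc))
  expect_equal(v$neg_log10_p, -log10(res[v$gene, "p_value"]))
  # closed-form checks
  expect_equal(-log10(0.05), 1.30103, tolerance = 1e-5)
  p1 <- res[v$gene, "p_value"]
  expect_true(all(v$neg_log10_p[p1 == 1] == 0))
})

test_that("heatmap z-scores standardize rows; constant rows become zeros", {
  sheet <- make_sheet(3L)
  # gene with log2 C/N = (1,2,3) control, (4,5,6) repeat; plus a constant gene
  fx <- make_ratio_matrix(list(
    gA = list(control = c(1, 2, 3), "repeat" = c(4, 5, 6)),
    gB = list(control = c(2, 2, 2), "repeat" = c(2, 2, 2))))
  z <- heatmap_zscore(fx$matrix, fx$sheet, c("gA", "gB"))
  expect_equal(unname(z["gA", ]),
               as.numeric(scale(1:6)), tolerance = 1e-12)
  expect_equal(unname(z["gB", ]), rep(0, 6))
  expect_equal(mean(z["gA", ]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z["gA", ]), 1, tolerance = 1e-12)
  expect_error(heatmap_zscore(fx$matrix, fx$sheet, "nope"), "not in matrix")

  # every row of a random selection is standardized
  r <- make_random_matrix(n_genes = 20L, seed = 6)
  z <- heatmap_zscore(r$matrix, r$sheet, rownames(r$matrix))
  expect_equal(unname(rowMeans(z)), rep(0, 20L), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1L, stats::sd)), rep(1, 20L), tolerance = 1e-12)
})

test_that("BH-adjusted classification is available behind the flag", {
  fx <- make_random_matrix(n_genes = 300L, seed = 10)
  raw <- localize(fx$matrix, fx$sheet)
  bh <- localize(fx$matrix, fx$sheet, localization_config(apply_bh = TRUE))
  n_raw <- sum(raw$class != "unchanged" & raw$class != "filtered")
  n_bh <- sum(bh$class != "unchanged" & bh$class != "filtered")
  expect_lte(n_bh, n_raw)  # adjustment can only prune calls
  expect_equal(bh$p_value, raw$p_value)  # reported p stays raw
})
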