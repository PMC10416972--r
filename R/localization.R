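# Core statistic: per-gene cytosol/nucleus (C/N) ratios from fractionated
# FPKM, condition fold change of the mean C/N ratio, per-gene two-sample
# Student's t-test, and nuclear/cytoplasmic classification.

#' Localization analysis configuration
#'
#' @param expression_log2_threshold filter keeps a gene iff
#'   `log2(FPKM) > threshold` (strict) in every sample. Default -1.0,
#'   i.e. FPKM > 0.5.
#' @param alpha significance level for classification (strict `p < alpha`).
#' @param ratio_scale scale on which the t-test sees the per-replicate C/N
#'   ratios: `"log2"` (default; ratios are multiplicative) or `"linear"`.
#' @param fc_aggregation how per-replicate ratios are summarized per
#'   condition: `"mean_of_ratios"` (arithmetic mean, default) or
#'   `"geometric_mean"`.
#' @param apply_bh apply Benjamini-Hochberg adjustment before classification
#'   (default `FALSE`: raw p < alpha, matching a plain volcano cut-off).
#' @param var_equal pooled-variance Student's test (default `TRUE`); `FALSE`
#'   gives Welch.
#' @param filter_scope `"all_samples"` (default; above threshold in both
#'   fractions, both conditions, all replicates) or `"per_fraction"` (above
#'   threshold in every sample of at least each fraction separately --
#'   identical retained set; kept for interface compatibility, differs only
#'   when extended designs add cells). See the methods vignette.
#' @return object of class `localization_config`
#' @export
localization_config <- function(expression_log2_threshold = -1.0,
                                alpha = 0.05,
                                ratio_scale = c("log2", "linear"),
                                fc_aggregation = c("mean_of_ratios", "geometric_mean"),
                                apply_bh = FALSE,
                                var_equal = TRUE,
                                filter_scope = c("all_samples", "per_fraction")) {
  ratio_scale <- match.arg(ratio_scale)
  fc_aggregation <- match.arg(fc_aggregation)
  filter_scope <- match.arg(filter_scope)
  stopifnot(is.numeric(expression_log2_threshold), length(expression_log2_threshold) == 1L,
            is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(list(expression_log2_threshold = expression_log2_threshold,
                 alpha = alpha, ratio_scale = ratio_scale,
                 fc_aggregation = fc_aggregation, apply_bh = apply_bh,
                 var_equal = isTRUE(var_equal), filter_scope = filter_scope),
            class = "localization_config")
}

#' Filter genes by coordinate expression across all samples
#'
#' A gene is retained iff `log2(FPKM)` strictly exceeds the threshold in
#' every sample of the design -- both fractions, both conditions, all
#' replicates ("coordinate expression" in all biological replicates). At the
#' default threshold of -1.0, FPKM = 0.5 exactly is excluded.
#'
#' @param mat gene-level expression matrix
#' @param sheet sample sheet
#' @param cfg [localization_config()]
#' @return character vector of retained gene ids, in matrix row order
#' @export
filter_expressed <- function(mat, sheet, cfg = localization_config()) {
  sheet <- validate_sample_sheet(sheet)
  validate_expression(mat, sheet)
  use <- intersect(colnames(mat), sheet$sample_id)
  thr <- 2^cfg$expression_log2_threshold
  keep <- rowSums(mat[, use, drop = FALSE] > thr) == length(use)
  rownames(mat)[keep]
}

# Per-replicate C/N ratio matrices for every gene at once.
# Returns list(control = genes x R matrix, repeat = genes x R matrix).
cn_ratio_matrices <- function(mat, sheet, genes = rownames(mat)) {
  sheet <- validate_sample_sheet(sheet)
  out <- list()
  reps <- sort(unique(sheet$replicate))
  for (cond in CONDITIONS) {
    cyt <- nuc <- character(length(reps))
    for (i in seq_along(reps)) {
      pick <- function(frac) {
        id <- sheet$sample_id[sheet$condition == cond & sheet$fraction == frac &
                                sheet$replicate == reps[i]]
        if (length(id) != 1L)
          stop(sprintf("missing %s sample for condition '%s', replicate %d",
                       frac, cond, reps[i]))
        id
      }
      nuc[i] <- pick("nuclear")
      cyt[i] <- pick("cytoplasmic")
    }
    m <- mat[genes, cyt, drop = FALSE] / mat[genes, nuc, drop = FALSE]
    colnames(m) <- paste0("rep", reps)
    out[[cond]] <- m
  }
  out
}

#' Per-replicate cytosol/nucleus ratios for one gene
#'
#' For each condition and replicate r, the ratio is
#' `FPKM(cytoplasmic, r) / FPKM(nuclear, r)`; fractions are paired by the
#' replicate index of the sample sheet.
#'
#' @param mat gene-level expression matrix
#' @param sheet sample sheet
#' @param gene gene id (should have passed [filter_expressed()] so all
#'   denominators are positive)
#' @return list with numeric vectors `control` and `repeat`, one entry per
#'   replicate
#' @export
cn_ratios <- function(mat, sheet, gene) {
  if (!gene %in% rownames(mat)) stop("gene not in matrix: ", gene)
  m <- cn_ratio_matrices(mat, sheet, genes = gene)
  lapply(m, function(x) stats::setNames(as.numeric(x), colnames(x)))
}

# Vectorized pooled-variance two-sample t-test, rows = genes.
# Returns list(t, df, p). Degenerate rows (zero pooled variance): p = 1 when
# means are equal, else p = .Machine$double.xmin with a flag.
row_t_test <- function(x, y, var_equal = TRUE) {
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 replicates per group")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- !is.finite(t)
  equal_means <- abs(m1 - m2) < .Machine$double.eps * (abs(m1) + abs(m2) + 1)
  p[degenerate & equal_means] <- 1
  p[degenerate & !equal_means] <- .Machine$double.xmin
  t[degenerate] <- NA_real_
  list(t = t, df = df, p = p, degenerate = degenerate & !equal_means)
}

aggregate_ratios <- function(r, how) {
  if (how == "geometric_mean") 2^rowMeans(log2(r)) else rowMeans(r)
}

#' Fold change and p-value for one gene's C/N ratios
#'
#' `fc = aggregate(repeat) / aggregate(control)` where the per-condition
#' aggregate is the arithmetic mean of per-replicate ratios by default
#' ("the mean value between the three biological replicates"). The p-value
#' comes from an unpaired two-sided Student's t-test on the ratios, log2
#' transformed by default.
#'
#' @param ratios_control,ratios_repeat positive per-replicate C/N ratios
#'   (length >= 2 each)
#' @param cfg [localization_config()]
#' @return list with `fc`, `log2fc`, `p_value`, `cn_mean_control`,
#'   `cn_mean_repeat`, `degenerate` (TRUE when the pooled variance is zero
#'   with unequal means, in which case `p_value` is the smallest positive
#'   double)
#' @export
localization_test <- function(ratios_control, ratios_repeat,
                              cfg = localization_config()) {
  stopifnot(all(ratios_control > 0), all(ratios_repeat > 0))
  if (length(ratios_control) < 2L || length(ratios_repeat) < 2L)
    stop("need at least 2 replicates per group")
  rc <- matrix(ratios_control, nrow = 1L)
  rr <- matrix(ratios_repeat, nrow = 1L)
  mc <- aggregate_ratios(rc, cfg$fc_aggregation)
  mr <- aggregate_ratios(rr, cfg$fc_aggregation)
  tx <- if (cfg$ratio_scale == "log2") log2 else identity
  tt <- row_t_test(tx(rr), tx(rc), var_equal = cfg$var_equal)
  list(fc = mr / mc, log2fc = log2(mr / mc), p_value = tt$p[1L],
       cn_mean_control = mc, cn_mean_repeat = mr,
       degenerate = tt$degenerate[1L])
}

#' Classify a tested gene by direction and significance
#'
#' `nuclear_accumulated` iff `p < alpha` and `fc < 1` (the C/N ratio dropped
#' in repeat-expressing cells); `cytoplasmic_accumulated` iff `p < alpha`
#' and `fc > 1`; otherwise `unchanged`. `fc` exactly 1 has no direction and
#' `p == alpha` is not significant (strict inequality).
#'
#' @param fc fold change(s) of the mean C/N ratio, repeat vs control
#' @param p_value raw (or pre-adjusted) p-value(s)
#' @param cfg [localization_config()]
#' @return character vector of class labels
#' @export
classify <- function(fc, p_value, cfg = localization_config()) {
  cls <- rep("unchanged", length(fc))
  sig <- p_value < cfg$alpha
  cls[sig & fc < 1] <- "nuclear_accumulated"
  cls[sig & fc > 1] <- "cytoplasmic_accumulated"
  cls
}

#' Run the full localization analysis
#'
#' Filters genes, computes per-replicate C/N ratios, per-gene fold changes
#' and Student's t p-values, and classifies each gene. Filtered genes are
#' kept in the output with class `"filtered"` and `NA` statistics.
#'
#' @param mat gene-level expression matrix
#' @param sheet sample sheet
#' @param cfg [localization_config()]
#' @return data.frame (class `localization_result`) with columns `gene`,
#'   `cn_mean_control`, `cn_mean_repeat`, `fc`, `log2fc`, `p_value`,
#'   `class`; per-replicate ratio matrices are attached as attribute
#'   `"cn_replicates"`
#' @export
localize <- function(mat, sheet, cfg = localization_config()) {
  sheet <- validate_sample_sheet(sheet)
  validate_expression(mat, sheet)
  kept <- filter_expressed(mat, sheet, cfg)
  res <- data.frame(gene = rownames(mat),
                    cn_mean_control = NA_real_, cn_mean_repeat = NA_real_,
                    fc = NA_real_, log2fc = NA_real_, p_value = NA_real_,
                    class = "filtered", stringsAsFactors = FALSE)
  rownames(res) <- res$gene
  ratios <- NULL
  if (length(kept) > 0L) {
    ratios <- cn_ratio_matrices(mat, sheet, genes = kept)
    mc <- aggregate_ratios(ratios$control, cfg$fc_aggregation)
    mr <- aggregate_ratios(ratios$`repeat`, cfg$fc_aggregation)
    tx <- if (cfg$ratio_scale == "log2") log2 else identity
    tt <- row_t_test(tx(ratios$`repeat`), tx(ratios$control),
                     var_equal = cfg$var_equal)
    p_cls <- if (isTRUE(cfg$apply_bh)) bh_adjust(tt$p) else tt$p
    res[kept, "cn_mean_control"] <- mc
    res[kept, "cn_mean_repeat"] <- mr
    res[kept, "fc"] <- mr / mc
    res[kept, "log2fc"] <- log2(mr / mc)
    res[kept, "p_value"] <- tt$p
    res[kept, "class"] <- classify(mr / mc, p_cls, cfg)
  }
  attr(res, "cn_replicates") <- ratios
  attr(res, "config") <- cfg
  class(res) <- c("localization_result", "data.frame")
  res
}

#' Volcano table of tested genes
#'
#' One row per tested gene (filtered genes omitted), sorted by `log2fc`
#' ascending; `neg_log10_p = -log10(p)`.
#'
#' @param records a [localize()] result
#' @return data.frame with columns `gene`, `log2fc`, `neg_log10_p`, `class`
#' @export
volcano_table <- function(records) {
  tested <- records[records$class != "filtered", , drop = FALSE]
  out <- data.frame(gene = tested$gene, log2fc = tested$log2fc,
                    neg_log10_p = -log10(tested$p_value),
                    class = tested$class, stringsAsFactors = FALSE)
  out <- out[order(out$log2fc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Row z-score matrix for heatmap display
#'
#' For each selected gene, the log2 per-replicate C/N ratios across both
#' conditions are standardized to mean 0, sd 1 (sample sd, n-1 denominator).
#' Constant rows map to all zeros rather than NaN.
#'
#' @param mat gene-level expression matrix
#' @param sheet sample sheet
#' @param genes genes to include (typically the significant set)
#' @return numeric matrix, rows = genes, columns = `<condition>_rep<r>`
#' @export
heatmap_zscore <- function(mat, sheet, genes) {
  if (length(genes) == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = 0))
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0L)
    stop("genes not in matrix: ", paste(utils::head(missing, 5L), collapse = ", "))
  r <- cn_ratio_matrices(mat, sheet, genes = genes)
  x <- log2(cbind(r$control, r$`repeat`))
  colnames(x) <- c(paste0("control_", colnames(r$control)),
                   paste0("repeat_", colnames(r$`repeat`)))
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  z <- (x - mu) / sdv
  z[sdv == 0, ] <- 0
  z
}
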