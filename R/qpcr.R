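# qPCR validation statistic: 2^-dCt relative expression against a
# fraction-specific housekeeping reference (nuclear lncRNA Malat1, cytoplasmic
# GAPDH by default), per-condition C/N ratio, and fold change with the
# control condition normalized to 1.

#' Default fraction-to-housekeeping mapping
#' @export
default_housekeeping <- c(nuclear = "Malat1", cytoplasmic = "GAPDH")

#' Relative expression from Cq values
#'
#' `2^-(Cq_target - Cq_reference)`, the standard delta-Ct quantification.
#'
#' @param cq_target,cq_reference finite Cq scalars or vectors
#' @return relative expression value(s)
#' @export
relative_expression <- function(cq_target, cq_reference) {
  stopifnot(all(is.finite(cq_target)), all(is.finite(cq_reference)))
  2^-(cq_target - cq_reference)
}

# Fetch one Cq cell, hard error naming the missing cell.
cq_cell <- function(table, target, fraction, condition, replicate) {
  v <- table$cq[table$target == target & table$fraction == fraction &
                  table$condition == condition & table$replicate == replicate]
  if (length(v) != 1L)
    stop(sprintf("qPCR table has %d entries for (%s, %s, %s, replicate %s); need exactly 1",
                 length(v), target, fraction, condition, replicate))
  v
}

#' C/N fold change of a qPCR target, control normalized to 1
#'
#' For each condition, the per-replicate C/N ratio is the cytoplasmic
#' relative expression (vs the cytoplasmic housekeeping gene) divided by the
#' nuclear relative expression (vs the nuclear housekeeping gene); replicate
#' ratios are averaged arithmetically and the fold change is
#' `C/N(repeat) / C/N(control)`, so the control bar is exactly 1 by
#' construction. A Student's t-test on the per-replicate log2 C/N values
#' (same test as the localization module) annotates the fold change.
#'
#' @param table qPCR Cq table (see [read_qpcr()])
#' @param target target gene symbol
#' @param housekeeping named character vector mapping fraction to reference
#'   gene; default [default_housekeeping]
#' @return list with `fc_vs_control`, `cn_control`, `cn_repeat` (condition
#'   means), `per_replicate` (data.frame of condition, replicate, cn_ratio,
#'   normalized value), and `p_value`
#' @export
cn_fold_change <- function(table, target, housekeeping = default_housekeeping) {
  stopifnot(all(FRACTIONS %in% names(housekeeping)))
  reps <- sort(unique(table$replicate[table$target == target]))
  if (length(reps) < 2L)
    stop("target '", target, "' needs at least 2 replicates")
  grid <- expand.grid(replicate = reps, condition = CONDITIONS,
                      stringsAsFactors = FALSE)
  ratio <- mapply(function(cond, r) {
    rel <- vapply(FRACTIONS, function(frac) {
      relative_expression(
        cq_cell(table, target, frac, cond, r),
        cq_cell(table, housekeeping[[frac]], frac, cond, r))
    }, numeric(1))
    rel[["cytoplasmic"]] / rel[["nuclear"]]
  }, grid$condition, grid$replicate)
  grid$cn_ratio <- as.numeric(ratio)
  cn_control <- mean(grid$cn_ratio[grid$condition == "control"])
  cn_repeat <- mean(grid$cn_ratio[grid$condition == "repeat"])
  grid$normalized <- grid$cn_ratio / cn_control
  tt <- row_t_test(matrix(log2(grid$cn_ratio[grid$condition == "repeat"]), nrow = 1L),
                   matrix(log2(grid$cn_ratio[grid$condition == "control"]), nrow = 1L))
  list(fc_vs_control = cn_repeat / cn_control,
       cn_control = cn_control, cn_repeat = cn_repeat,
       per_replicate = grid, p_value = tt$p[1L])
}

#' Fold-change table for several qPCR targets
#'
#' @param table qPCR Cq table
#' @param targets target symbols; default every non-housekeeping target
#' @param housekeeping fraction-to-reference mapping
#' @return data.frame with one row per target: `target`, `cn_control`,
#'   `cn_repeat`, `fc_vs_control`, `p_value` (control normalized value is 1
#'   for every target)
#' @export
qpcr_fold_changes <- function(table, targets = NULL,
                              housekeeping = default_housekeeping) {
  if (is.null(targets))
    targets <- setdiff(unique(table$target), unname(housekeeping))
  rows <- lapply(targets, function(tg) {
    r <- cn_fold_change(table, tg, housekeeping)
    data.frame(target = tg, cn_control = r$cn_control, cn_repeat = r$cn_repeat,
               fc_vs_control = r$fc_vs_control, control_normalized = 1,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
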