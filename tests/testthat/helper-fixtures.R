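# Fixture builders shared across test files. Everything is built in code;
# no binary fixtures.

# A complete 2-condition x 2-fraction sample sheet with R replicates.
make_sheet <- function(R = 3L) {
  g <- expand.grid(replicate = seq_len(R),
                   fraction = c("nuclear", "cytoplasmic"),
                   condition = c("control", "repeat"),
                   stringsAsFactors = FALSE)
  g$sample_id <- sprintf("%s_%s_r%d",
                         c(control = "ctrl", "repeat" = "rep")[g$condition],
                         c(nuclear = "nuc", cytoplasmic = "cyt")[g$fraction],
                         g$replicate)
  g[, c("sample_id", "condition", "fraction", "replicate")]
}

# Expression matrix from per-gene C/N log2 ratios: nuclear FPKM fixed at
# `nuclear`, cytoplasmic = nuclear * 2^log2_ratio. log2_ratios is a list of
# per-gene lists: list(control = c(...R...), repeat = c(...R...)).
make_ratio_matrix <- function(log2_ratios, R = 3L, nuclear = 4) {
  sheet <- make_sheet(R)
  genes <- names(log2_ratios)
  mat <- matrix(NA_real_, nrow = length(genes), ncol = nrow(sheet),
                dimnames = list(genes, sheet$sample_id))
  for (g in genes) {
    for (j in seq_len(nrow(sheet))) {
      lr <- log2_ratios[[g]][[sheet$condition[j]]][sheet$replicate[j]]
      mat[g, j] <- if (sheet$fraction[j] == "nuclear") nuclear
                   else nuclear * 2^lr
    }
  }
  list(matrix = mat, sheet = sheet)
}

# Random positive expression matrix over a complete design.
make_random_matrix <- function(n_genes = 20L, R = 3L, seed = 1L) {
  sheet <- make_sheet(R)
  withr::with_seed(seed, {
    mat <- matrix(2^stats::rnorm(n_genes * nrow(sheet), 3, 2),
                  nrow = n_genes,
                  dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                  sheet$sample_id))
    list(matrix = mat, sheet = sheet)
  })
}

# qPCR Cq table: per-condition per-replicate target Cq offsets against a
# flat housekeeping baseline. `cn_log2` gives the log2 C/N per condition.
make_qpcr_table <- function(target = "Tgt",
                            cn_log2 = c(control = 0, "repeat" = 0),
                            R = 3L, hk_cq = 18, base_cq = 22) {
  rows <- list()
  for (cond in c("control", "repeat")) {
    for (frac in c("nuclear", "cytoplasmic")) {
      sign <- if (frac == "cytoplasmic") 1 else -1
      for (r in seq_len(R)) {
        rows[[length(rows) + 1L]] <- data.frame(
          target = c(target, nucyto::default_housekeeping[[frac]]),
          fraction = frac, condition = cond, replicate = r,
          cq = c(base_cq - sign * cn_log2[[cond]] / 2, hk_cq),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
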