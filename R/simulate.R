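# Synthetic fractionation-RNA-seq generator with known ground truth.
#
# Generative model, per gene g:
#   abundance          A_g  = 2^Normal(abundance_log2_mean, abundance_log2_sd)
#   baseline log2 C/N  L_g  ~ Normal(baseline_cn_log2_mean, baseline_cn_log2_sd)
#   condition value    L_gc = L_g (+ shift in the repeat condition for
#                             planted genes)
#   nuclear FPKM       A_g * 2^(-L_gc / 2) * eps
#   cytoplasmic FPKM   A_g * 2^(+L_gc / 2) * eps'
# with eps, eps' independent 2^Normal(0, noise_log2_sd) multiplicative noise
# per fraction/condition/replicate. The half-shift split keeps the product
# nuclear * cytoplasmic independent of L_g: relocalization conserves total
# abundance (retention, not degradation), and abundance is orthogonal to
# localization by construction.

#' Simulation configuration
#'
#' Defaults emulate the structure of a triplicate nuclear/cytoplasmic
#' fractionation experiment in repeat-expressing vs control cells: log-normal
#' gene abundance, a minority of genes shifted toward the nucleus in the
#' repeat condition with a much smaller minority shifted toward the
#' cytoplasm (25:1), a few multi-locus genes, and a tranche of
#' sub-threshold genes that the expression filter should drop.
#'
#' @param n_genes number of genes
#' @param replicates biological replicates per condition x fraction (>= 2)
#' @param abundance_log2_mean,abundance_log2_sd log2-FPKM abundance law
#' @param baseline_cn_log2_mean,baseline_cn_log2_sd baseline log2 C/N law
#' @param noise_log2_sd replicate-level multiplicative noise, log2 units
#' @param frac_nuclear_shifted,frac_cytoplasmic_shifted proportions of genes
#'   given a condition-specific localization shift
#' @param shift_log2 negative log2 C/N shift applied to nuclear-shifted genes
#'   in the repeat condition; cytoplasmic-shifted genes get `abs(shift_log2)`
#' @param frac_multilocus proportion of genes split into 2-3 loci
#' @param frac_subthreshold proportion of genes drawn below the expression
#'   filter (at least one sample with FPKM <= 0.5)
#' @param count_mode if `TRUE`, FPKM values are Poisson-resampled on a scaled
#'   grid (robustness checks); default off
#' @param seed integer seed; all randomness flows from it
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(n_genes = 2000L, replicates = 3L,
                              abundance_log2_mean = 3, abundance_log2_sd = 2,
                              baseline_cn_log2_mean = 0, baseline_cn_log2_sd = 1,
                              noise_log2_sd = 0.2,
                              frac_nuclear_shifted = 0.05,
                              frac_cytoplasmic_shifted = 0.002,
                              shift_log2 = -1.5,
                              frac_multilocus = 0.02,
                              frac_subthreshold = 0.1,
                              count_mode = FALSE,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), replicates = as.integer(replicates),
              abundance_log2_mean = abundance_log2_mean,
              abundance_log2_sd = abundance_log2_sd,
              baseline_cn_log2_mean = baseline_cn_log2_mean,
              baseline_cn_log2_sd = baseline_cn_log2_sd,
              noise_log2_sd = noise_log2_sd,
              frac_nuclear_shifted = frac_nuclear_shifted,
              frac_cytoplasmic_shifted = frac_cytoplasmic_shifted,
              shift_log2 = shift_log2,
              frac_multilocus = frac_multilocus,
              frac_subthreshold = frac_subthreshold,
              count_mode = isTRUE(count_mode),
              seed = as.integer(seed))
  props <- c(cfg$frac_nuclear_shifted, cfg$frac_cytoplasmic_shifted,
             cfg$frac_multilocus, cfg$frac_subthreshold)
  if (any(props < 0) || any(props > 1))
    stop("proportions must lie in [0, 1]")
  if (cfg$frac_nuclear_shifted + cfg$frac_cytoplasmic_shifted >= 1)
    stop("shifted fractions must sum to < 1")
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (cfg$replicates < 2L) stop("replicates must be >= 2")
  if (cfg$noise_log2_sd < 0 || cfg$abundance_log2_sd < 0 || cfg$baseline_cn_log2_sd < 0)
    stop("standard deviations must be >= 0")
  if (cfg$shift_log2 > 0)
    stop("shift_log2 is the nuclear-shift and must be <= 0")
  structure(cfg, class = "simulation_config")
}

#' Simulate a fractionation-RNA-seq dataset with ground truth
#'
#' @param cfg [simulation_config()]
#' @return list with elements `matrix` (locus-level FPKM matrix), `samples`
#'   (sample sheet), `locus_map`, and `truth` (data.frame `gene`,
#'   `true_class` in nuclear_shifted/cytoplasmic_shifted/null/subthreshold,
#'   `true_shift_log2`)
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, simulate_dataset_impl(cfg))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_genes
  R <- cfg$replicates
  genes <- sprintf("gene%05d", seq_len(n))

  n_nuc <- round(cfg$frac_nuclear_shifted * n)
  n_cyt <- round(cfg$frac_cytoplasmic_shifted * n)
  n_sub <- round(cfg$frac_subthreshold * n)
  cls <- rep("null", n)
  pool <- sample.int(n)  # random class assignment
  cls[pool[seq_len(n_nuc)]] <- "nuclear_shifted"
  cls[pool[n_nuc + seq_len(n_cyt)]] <- "cytoplasmic_shifted"
  cls[pool[n_nuc + n_cyt + seq_len(n_sub)]] <- "subthreshold"

  shift <- rep(0, n)
  shift[cls == "nuclear_shifted"] <- cfg$shift_log2
  shift[cls == "cytoplasmic_shifted"] <- abs(cfg$shift_log2)
  if (cfg$shift_log2 == 0) cls[cls %in% c("nuclear_shifted", "cytoplasmic_shifted")] <- "null"

  a_log2 <- stats::rnorm(n, cfg$abundance_log2_mean, cfg$abundance_log2_sd)
  # subthreshold genes live near/below the filter boundary
  a_log2[cls == "subthreshold"] <- stats::rnorm(sum(cls == "subthreshold"), -2.5, 0.5)
  A <- 2^a_log2
  L <- stats::rnorm(n, cfg$baseline_cn_log2_mean, cfg$baseline_cn_log2_sd)

  sheet <- expand.grid(replicate = seq_len(R), fraction = FRACTIONS,
                       condition = CONDITIONS, stringsAsFactors = FALSE)
  abbr <- c(control = "ctrl", "repeat" = "rep", nuclear = "nuc", cytoplasmic = "cyt")
  sheet$sample_id <- sprintf("%s_%s_r%d", abbr[sheet$condition],
                             abbr[sheet$fraction], sheet$replicate)
  sheet <- sheet[, c("sample_id", "condition", "fraction", "replicate")]

  mat <- matrix(NA_real_, nrow = n, ncol = nrow(sheet),
                dimnames = list(genes, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    Lc <- L + if (sheet$condition[j] == "repeat") shift else 0
    sign <- if (sheet$fraction[j] == "cytoplasmic") +1 else -1
    eps <- 2^stats::rnorm(n, 0, cfg$noise_log2_sd)
    mat[, j] <- A * 2^(sign * Lc / 2) * eps
  }
  # enforce the subthreshold contract: at least one sample with FPKM <= 0.5
  # (bound 0.3 so multi-locus weighting cannot push it back above 0.5)
  sub <- which(cls == "subthreshold")
  if (length(sub) > 0L) {
    mn <- apply(mat[sub, , drop = FALSE], 1L, min)
    fix <- mn > 0.3
    mat[sub[fix], ] <- mat[sub[fix], , drop = FALSE] * (0.3 / mn[fix])
  }

  # split a fraction of genes into 2-3 loci with sample-constant weights;
  # aggregate_by_gene's mean then preserves every C/N ratio exactly
  n_multi <- round(cfg$frac_multilocus * n)
  multi <- sort(sample.int(n, n_multi))
  locus_rows <- vector("list", n)
  locus_ids <- vector("list", n)
  for (g in seq_len(n)) {
    if (g %in% multi) {
      k <- sample(2:3, 1L)
      w <- stats::runif(k, 0.5, 1.5)
      locus_rows[[g]] <- outer(w, mat[g, ])
      locus_ids[[g]] <- sprintf("%s_L%d", genes[g], seq_len(k))
    } else {
      locus_rows[[g]] <- matrix(mat[g, ], nrow = 1L)
      locus_ids[[g]] <- sprintf("%s_L1", genes[g])
    }
  }
  loc_mat <- do.call(rbind, locus_rows)
  rownames(loc_mat) <- unlist(locus_ids)
  colnames(loc_mat) <- sheet$sample_id
  if (cfg$count_mode) {
    # Poisson resampling on a 0.1-FPKM grid, applied at the locus level so
    # counting noise survives aggregation; re-enforce the subthreshold
    # contract on the grid afterwards (0.5 lies on the grid)
    depth <- 10
    loc_mat[] <- stats::rpois(length(loc_mat), lambda = loc_mat * depth) / depth
    gene_of <- rep(seq_len(n), vapply(locus_ids, length, integer(1)))
    for (g in sub) {
      rows <- which(gene_of == g)
      agg <- colMeans(loc_mat[rows, , drop = FALSE])
      if (min(agg) > 0.5) {
        j <- which.min(agg)
        loc_mat[rows, j] <- pmin(loc_mat[rows, j], 0.5)
      }
    }
  }
  locus_map <- data.frame(locus_id = unlist(locus_ids),
                          gene_symbol = rep(genes, vapply(locus_ids, length, integer(1))),
                          stringsAsFactors = FALSE)

  truth <- data.frame(gene = genes, true_class = cls,
                      true_shift_log2 = shift, stringsAsFactors = FALSE)
  list(matrix = loc_mat, samples = validate_sample_sheet(sheet),
       locus_map = locus_map, truth = truth)
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Emits `n_sets` decoy sets drawn uniformly from the truth-table universe,
#' plus one "membrane-trafficking-like" set whose members are drawn from the
#' planted nuclear-shifted genes at the stated fraction (decoy-only when the
#' fraction is 0).
#'
#' @param truth truth table from [simulate_dataset()]
#' @param n_sets number of decoy sets
#' @param set_size members per set
#' @param enriched_set_fraction fraction of the planted set drawn from
#'   shifted genes
#' @param seed integer seed
#' @return [gene_set_collection()] over the truth universe
#' @export
simulate_genesets <- function(truth, n_sets = 20L, set_size = 50L,
                              enriched_set_fraction = 0.6, seed = 1L) {
  stopifnot(enriched_set_fraction >= 0, enriched_set_fraction <= 1)
  # offset keeps this stream distinct from simulate_dataset (seed) and
  # simulate_qpcr (seed + 1) when all three share one base seed
  withr::with_seed(as.integer(seed) + 2L, {
    universe <- truth$gene
    sets <- lapply(seq_len(n_sets), function(i)
      sample(universe, min(set_size, length(universe))))
    names(sets) <- sprintf("decoy_set_%02d", seq_len(n_sets))
    shifted <- truth$gene[truth$true_class == "nuclear_shifted"]
    n_in <- round(enriched_set_fraction * set_size)
    n_in <- min(n_in, length(shifted))
    planted <- c(sample(shifted, n_in),
                 sample(setdiff(universe, shifted), set_size - n_in))
    sets[["membrane_trafficking_like"]] <- planted
    gene_set_collection(sets, universe = universe)
  })
}

#' Simulate a qPCR Cq table consistent with planted localization shifts
#'
#' Models `Cq = intercept - log2(relative abundance) + Normal(0, cq_noise_sd)`
#' with fraction-specific housekeeping references (Malat1 nuclear, GAPDH
#' cytoplasmic). Control-condition log2 C/N is 0 for every target; the
#' repeat condition applies the target's `true_shift_log2`, so with zero
#' noise [cn_fold_change()] recovers `2^true_shift_log2` exactly.
#'
#' @param truth truth table from [simulate_dataset()]
#' @param targets target genes (must appear in `truth`)
#' @param cfg [simulation_config()] supplying `replicates` and `seed`
#' @param cq_noise_sd Cq measurement noise, cycles (default 0.15)
#' @return qPCR Cq data.frame (targets plus housekeeping rows)
#' @export
simulate_qpcr <- function(truth, targets, cfg = simulation_config(),
                          cq_noise_sd = 0.15) {
  missing <- setdiff(targets, truth$gene)
  if (length(missing) > 0L)
    stop("target(s) absent from truth table: ", paste(missing, collapse = ", "))
  withr::with_seed(cfg$seed + 1L, {
    R <- cfg$replicates
    hk <- default_housekeeping
    grid <- expand.grid(replicate = seq_len(R), condition = CONDITIONS,
                        fraction = FRACTIONS, stringsAsFactors = FALSE)
    rows <- list()
    for (i in seq_len(nrow(grid))) {
      cond <- grid$condition[i]; frac <- grid$fraction[i]; r <- grid$replicate[i]
      shift <- if (cond == "repeat")
        truth$true_shift_log2[match(targets, truth$gene)] else rep(0, length(targets))
      sign <- if (frac == "cytoplasmic") +1 else -1
      cq_t <- 22 - sign * shift / 2 + stats::rnorm(length(targets), 0, cq_noise_sd)
      cq_h <- 18 + stats::rnorm(1L, 0, cq_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        target = c(targets, hk[[frac]]), fraction = frac, condition = cond,
        replicate = r, cq = c(cq_t, cq_h), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
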