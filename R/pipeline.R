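# End-to-end orchestration: (simulate |) load -> aggregate -> localize ->
# enrich -> qpcr, written as a reproducible run directory. Outputs are
# written to "<name>.partial" and renamed only when every stage has
# succeeded, so an aborted run leaves its partial outputs marked.

#' Build a run configuration
#'
#' Two input modes: file mode (paths to `matrix`, `samples`, and optionally
#' `locus_map`, `gmt`, `cq`) or simulation mode (`simulate = TRUE`, inputs
#' generated from `sim` + `seed`).
#'
#' @param outdir output directory (created if absent)
#' @param matrix,samples,locus_map,gmt,cq input file paths (file mode)
#' @param simulate generate inputs with [simulate_dataset()] instead
#' @param sim [simulation_config()] used when `simulate = TRUE`
#' @param localization [localization_config()]
#' @param top_k top enrichment rows kept in `enrich.tsv`
#' @param qpcr_targets targets for the simulated qPCR table (simulation
#'   mode; default: first 3 planted nuclear-shifted genes)
#' @param seed integer seed (overrides `sim$seed` in simulation mode)
#' @return object of class `run_config`
#' @export
run_config <- function(outdir,
                       matrix = NULL, samples = NULL, locus_map = NULL,
                       gmt = NULL, cq = NULL,
                       simulate = is.null(matrix),
                       sim = simulation_config(),
                       localization = localization_config(),
                       top_k = 10L,
                       qpcr_targets = NULL,
                       seed = sim$seed) {
  structure(list(outdir = outdir, matrix = matrix, samples = samples,
                 locus_map = locus_map, gmt = gmt, cq = cq,
                 simulate = isTRUE(simulate), sim = sim,
                 localization = localization, top_k = as.integer(top_k),
                 qpcr_targets = qpcr_targets, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from JSON
#'
#' JSON keys mirror the [run_config()] arguments; `sim` and `localization`
#' are nested objects of their constructors' arguments.
#'
#' @param path JSON file path
#' @param outdir optional override of the configured output directory
#' @return `run_config`
#' @export
load_run_config <- function(path, outdir = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(simulation_config, as.list(j$sim %||% list()))
  loc <- do.call(localization_config, as.list(j$localization %||% list()))
  run_config(outdir = outdir %||% j$outdir,
             matrix = j$matrix, samples = j$samples,
             locus_map = j$locus_map, gmt = j$gmt, cq = j$cq,
             simulate = j$simulate %||% is.null(j$matrix),
             sim = sim, localization = loc,
             top_k = j$top_k %||% 10L,
             qpcr_targets = j$qpcr_targets,
             seed = j$seed %||% sim$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stage_stop(stage, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Writes `results.tsv`, `volcano.tsv`, `heatmap.tsv`, `enrich.tsv` (if gene
#' sets are available), `qpcr_fc.tsv` (if Cq data are available),
#' `summary.json` and the resolved configuration `run_config.json` into the
#' output directory. Identical config + seed gives a byte-identical
#' `summary.json`. Any stage error aborts with a stage-named message and
#' leaves already-produced outputs marked `.partial`.
#'
#' @param config [run_config()]
#' @return the output directory path, invisibly; the summary list is
#'   attached as attribute `"summary"`
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  partial <- function(name) file.path(config$outdir, paste0(name, ".partial"))
  written <- character(0)
  emit <- function(name, writer) {
    writer(partial(name))
    written <<- c(written, name)
  }
  flat_cfg <- list(seed = config$seed,
                   localization = unclass(config$localization),
                   sim = if (config$simulate) unclass(config$sim))

  # -- stage: inputs ---------------------------------------------------------
  inputs <- run_stage("io", {
    if (config$simulate) {
      sim <- config$sim
      sim$seed <- config$seed
      ds <- simulate_dataset(sim)
      collection <- simulate_genesets(ds$truth, seed = config$seed)
      targets <- config$qpcr_targets %||%
        utils::head(ds$truth$gene[ds$truth$true_class == "nuclear_shifted"], 3L)
      cq <- if (length(targets) > 0L) simulate_qpcr(ds$truth, targets, sim)
      list(matrix = ds$matrix, samples = ds$samples, locus_map = ds$locus_map,
           truth = ds$truth, collection = collection, cq = cq)
    } else {
      if (is.null(config$matrix) || is.null(config$samples))
        stop("file mode needs 'matrix' and 'samples' paths")
      list(matrix = read_expression(config$matrix),
           samples = read_sample_sheet(config$samples),
           locus_map = if (!is.null(config$locus_map)) read_locus_map(config$locus_map),
           truth = NULL,
           collection = if (!is.null(config$gmt)) read_gmt(config$gmt),
           cq = if (!is.null(config$cq)) read_qpcr(config$cq))
    }
  })

  # -- stage: aggregate ------------------------------------------------------
  gene_mat <- run_stage("aggregate", {
    if (!is.null(inputs$locus_map))
      aggregate_by_gene(inputs$matrix, inputs$locus_map)
    else inputs$matrix
  })

  # -- stage: localize -------------------------------------------------------
  res <- run_stage("localize", localize(gene_mat, inputs$samples, config$localization))
  tested <- res[res$class != "filtered", , drop = FALSE]
  nuclear <- tested$gene[tested$class == "nuclear_accumulated"]
  cytoplasmic <- tested$gene[tested$class == "cytoplasmic_accumulated"]
  run_stage("localize", {
    emit("results.tsv", function(p) write_result_table(res, p, flat_cfg))
    emit("volcano.tsv", function(p) write_result_table(volcano_table(res), p, flat_cfg))
    sig <- sort(c(nuclear, cytoplasmic))
    z <- heatmap_zscore(gene_mat, inputs$samples, sig)
    zdf <- data.frame(gene = rownames(z), z, check.names = FALSE)
    emit("heatmap.tsv", function(p) write_result_table(zdf, p, flat_cfg))
  })

  # -- stage: enrich ---------------------------------------------------------
  enr <- run_stage("enrich", {
    if (is.null(inputs$collection)) NULL else {
      e <- enrich(nuclear, inputs$collection, top_k = config$top_k,
                  universe = tested$gene)
      emit("enrich.tsv", function(p) write_result_table(e, p, flat_cfg))
      e
    }
  })

  # -- stage: qpcr -----------------------------------------------------------
  qp <- run_stage("qpcr", {
    if (is.null(inputs$cq)) NULL else {
      q <- qpcr_fold_changes(inputs$cq)
      emit("qpcr_fc.tsv", function(p) write_result_table(q, p, flat_cfg))
      q
    }
  })

  # -- stage: summarize ------------------------------------------------------
  summary <- run_stage("summarize", {
    s <- list(tool = "nucyto",
              version = as.character(utils::packageVersion("nucyto")),
              seed = config$seed,
              config_hash = config_fingerprint(flat_cfg),
              n_input_rows = nrow(inputs$matrix),
              n_genes = nrow(gene_mat),
              tested_genes = nrow(tested),
              n_filtered = sum(res$class == "filtered"),
              n_nuclear = length(nuclear),
              n_cytoplasmic = length(cytoplasmic),
              top_enrichment_term = if (!is.null(enr) && nrow(enr) > 0L)
                enr$set_name[1L] else NA_character_)
    emit("summary.json", function(p)
      jsonlite::write_json(s, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null"))
    emit("run_config.json", function(p) {
      cfg_out <- unclass(config)
      cfg_out$sim <- unclass(cfg_out$sim)
      cfg_out$localization <- unclass(cfg_out$localization)
      jsonlite::write_json(cfg_out, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
    })
    s
  })

  # all stages succeeded: strip the .partial suffix
  for (name in written)
    file.rename(partial(name), file.path(config$outdir, name))
  out <- config$outdir
  attr(out, "summary") <- summary
  invisible(out)
}
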