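# Tabular IO: expression matrices, sample sheets, locus maps, GMT gene sets,
# qPCR Cq tables, and stamped result tables. The expression container is a
# plain numeric matrix (row ids = loci or gene symbols, column ids = samples),
# the convention of limma/edgeR-style workflows.

#' Read a gene-level expression matrix
#'
#' Reads a TSV (or CSV) file whose first column holds row identifiers (locus
#' or gene symbol) and whose header names the samples. Values are FPKM and
#' must be non-negative, finite and non-missing; absence of expression must
#' be encoded as 0.
#'
#' @param path file path
#' @param dialect `"tsv"` (canonical) or `"csv"`
#' @return numeric matrix, rows = genes/loci in file order, columns = samples
#' @export
read_expression <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  if (ncol(df) < 2L) stop("expression matrix needs a row-id column plus at least one sample")
  ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, sample_ids))
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid expression value %s at row '%s', column '%s' (must be finite and >= 0)",
      df[bad[1L, 1L], bad[1L, 2L] + 1L], ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  validate_expression(vals)
  vals
}

#' Write an expression matrix
#'
#' @param mat numeric matrix as returned by [read_expression()]
#' @param path output path
#' @param dialect `"tsv"` or `"csv"`
#' @param digits significant digits; `NA` (default) writes `%.17g` so that a
#'   write/read round trip is bit-exact
#' @param id_col name of the first column (default `"gene_id"`)
#' @return `path`, invisibly
#' @export
write_expression <- function(mat, path, dialect = c("tsv", "csv"),
                             digits = NA, id_col = "gene_id") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  fmt <- if (is.na(digits)) "%.17g" else paste0("%.", digits, "g")
  chr <- matrix(sprintf(fmt, mat), nrow = nrow(mat))
  lines <- c(
    paste(c(id_col, colnames(mat)), collapse = sep),
    vapply(seq_len(nrow(mat)), function(i)
      paste(c(rownames(mat)[i], chr[i, ]), collapse = sep), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Validate an expression matrix against its invariants
#' @param mat numeric matrix
#' @param sheet optional sample sheet; if given, every matrix column must be
#'   listed in it
#' @return `mat`, invisibly
#' @export
validate_expression <- function(mat, sheet = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must have row and column names")
  if (anyDuplicated(colnames(mat))) stop("duplicate sample ids")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("expression values must be finite and >= 0")
  if (!is.null(sheet)) {
    missing <- setdiff(colnames(mat), sheet$sample_id)
    if (length(missing) > 0L)
      stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  }
  invisible(mat)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `condition` (control/repeat), `fraction`
#' (nuclear/cytoplasmic) and `replicate` (positive integer). The design must
#' be complete: every condition x fraction cell carries the same replicate
#' set, with at least two replicates.
#'
#' @param path file path
#' @return data.frame with factor-typed condition and fraction columns
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to validate/normalize
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "condition", "fraction", "replicate")
  missing <- setdiff(need, colnames(sheet))
  if (length(missing) > 0L)
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(sheet$condition %in% CONDITIONS))
    stop("condition must be one of: ", paste(CONDITIONS, collapse = ", "))
  if (!all(sheet$fraction %in% FRACTIONS))
    stop("fraction must be one of: ", paste(FRACTIONS, collapse = ", "))
  sheet$condition <- factor(sheet$condition, levels = CONDITIONS)
  sheet$fraction <- factor(sheet$fraction, levels = FRACTIONS)
  sheet$replicate <- as.integer(sheet$replicate)
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1L))
    stop("replicate must be a positive integer index")
  key <- interaction(sheet$condition, sheet$fraction, sheet$replicate, drop = FALSE)
  if (anyDuplicated(key[!is.na(key)]))
    stop("(condition, fraction, replicate) triples must be unique")
  cells <- split(sheet$replicate, list(sheet$condition, sheet$fraction))
  reps <- lapply(cells, function(r) sort(unique(r)))
  if (length(unique(lapply(reps, identity))) != 1L)
    stop("incomplete design: every condition x fraction cell needs the same replicate set")
  if (length(reps[[1L]]) < 2L) stop("at least 2 replicates per cell are required")
  sheet
}

#' Write a sample sheet
#' @param sheet sample sheet data.frame
#' @param path output path
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus-to-gene-symbol map
#'
#' TSV with columns `locus_id`, `gene_symbol`; every locus maps to exactly
#' one gene symbol.
#'
#' @param path file path
#' @return data.frame with columns locus_id, gene_symbol
#' @export
read_locus_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("locus_id", "gene_symbol")
  if (!all(need %in% colnames(df)))
    stop("locus map needs columns: ", paste(need, collapse = ", "))
  df$locus_id <- as.character(df$locus_id)
  df$gene_symbol <- as.character(df$gene_symbol)
  if (anyDuplicated(df$locus_id))
    stop("locus map assigns some locus to more than one gene symbol")
  df[need]
}

#' Write a locus map
#' @param map locus map data.frame
#' @param path output path
#' @export
write_locus_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate locus-level expression to gene symbols
#'
#' Rows belonging to the same gene symbol are averaged arithmetically on the
#' linear FPKM scale (genes mapped to several genomic loci are "aggregated by
#' the average"); single-locus genes pass through unchanged. Gene order
#' follows first appearance of each symbol in the input.
#'
#' @param mat locus-level expression matrix
#' @param map locus map (see [read_locus_map()])
#' @param unmapped `"error"` (default) or `"passthrough"` to keep unmapped
#'   loci under their own ids
#' @return gene-level expression matrix
#' @export
aggregate_by_gene <- function(mat, map, unmapped = c("error", "passthrough")) {
  unmapped <- match.arg(unmapped)
  sym <- map$gene_symbol[match(rownames(mat), map$locus_id)]
  if (anyNA(sym)) {
    if (unmapped == "error")
      stop("unmapped locus id(s): ",
           paste(utils::head(rownames(mat)[is.na(sym)], 5L), collapse = ", "))
    sym[is.na(sym)] <- rownames(mat)[is.na(sym)]
  }
  genes <- unique(sym)
  idx <- split(seq_len(nrow(mat)), factor(sym, levels = genes))
  out <- t(vapply(idx, function(i) colMeans(mat[i, , drop = FALSE]),
                  numeric(ncol(mat))))
  dimnames(out) <- list(genes, colnames(mat))
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols. Duplicate members within a line are deduplicated;
#' duplicate set names are an error.
#'
#' @param path file path
#' @param universe optional character vector; if given, set members are
#'   restricted to it and it becomes the collection universe. Default: the
#'   union of all members.
#' @return object of class `gene_set_collection`: list with elements `sets`
#'   (named list of character vectors) and `universe`
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(fields)))
    name <- fields[1L]
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name)
    sets[[name]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets, universe = universe)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors (may be empty)
#' @param universe optional universe; defaults to the union of all members
#' @return `gene_set_collection` object
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0L && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("gene sets must have unique names")
  if (is.null(universe)) universe <- sort(unique(unlist(sets, use.names = FALSE)))
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d set(s) over a universe of %d symbols\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection `gene_set_collection`
#' @param path output path
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Cq table
#'
#' TSV with columns `target`, `fraction`, `condition`, `replicate`, `cq`.
#'
#' @param path file path
#' @return data.frame
#' @export
read_qpcr <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("target", "fraction", "condition", "replicate", "cq")
  if (!all(need %in% colnames(df)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$fraction %in% FRACTIONS) || !all(df$condition %in% CONDITIONS))
    stop("qPCR fraction/condition levels must be ",
         paste(FRACTIONS, collapse = "/"), " and ", paste(CONDITIONS, collapse = "/"))
  df$cq <- as.numeric(df$cq)
  if (any(!is.finite(df$cq))) stop("Cq values must be finite")
  df[need]
}

#' Write a qPCR Cq table
#' @param table qPCR data.frame
#' @param path output path
#' @export
write_qpcr <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table with a provenance header
#'
#' Result tables are TSV with a leading `#` comment recording the package
#' version and a hash of the configuration that produced them.
#'
#' @param df data.frame
#' @param path output path
#' @param config flat list of options; hashed into the header
#' @export
write_result_table <- function(df, path, config = list()) {
  header <- sprintf("# nucyto %s config_hash=%s",
                    as.character(utils::packageVersion("nucyto")),
                    config_fingerprint(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path file path
#' @return data.frame (header comment skipped)
#' @export
read_result_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE)
}
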