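FORMAT_HEADER <- "# pwfrank %s tsv v1"

write_tsv_with_header <- function(df, path, kind, row_names_as = NULL) {
  con <- file(path, "wb")                     # Unix newlines everywhere
  on.exit(close(con))
  writeLines(sprintf(FORMAT_HEADER, kind), con)
  if (!is.null(row_names_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                row_names_as),
                as.data.frame(df, stringsAsFactors = FALSE))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids;
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stopf("empty expression matrix in %s", path)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stopf("duplicated gene id(s): %s", paste(unique(dup), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad))
      stopf("non-numeric value '%s' at data row %d, column '%s'",
            vals[[j]][bad[1L]], bad[1L], names(vals)[j])
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a log2 expression matrix to TSV
#'
#' @param expression Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  write_tsv_with_header(as.data.frame(expression), path, "expression",
                        row_names_as = "gene")
}

#' Read a sample design sheet from TSV
#'
#' @param path File path; columns sample, experiment, sorted, treatment.
#' @return Data frame.
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("sample", "experiment", "sorted", "treatment")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("design file is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  df[, required]
}

#' Write a sample design sheet to TSV
#' @param design Data frame (sample, experiment, sorted, treatment).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  write_tsv_with_header(design, path, "design")
}

#' Read a gene-set catalog from a GMT file
#'
#' One set per line: name, description and members, tab-separated. Blank
#' lines are ignored; duplicate members within a set are dropped with a
#' warning.
#'
#' @param path File path.
#' @return A `"gene_set_catalog"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list(); desc <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stopf("GMT line %d has %d field(s); need name, description, members",
            i, length(fields))
    nm <- fields[1L]
    if (nm %in% names(sets)) stopf("duplicated set name '%s' (line %d)", nm, i)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sets[[nm]] <- members
    desc[nm] <- fields[2L]
  }
  if (length(sets) == 0L) stopf("no gene sets in %s", path)
  gene_set_catalog(sets, desc)
}

#' Write a gene-set catalog to a GMT file
#' @param catalog A `"gene_set_catalog"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  if (!inherits(catalog, "gene_set_catalog"))
    stopf("`catalog` must be a gene_set_catalog")
  lines <- vapply(names(catalog$sets), function(nm)
    paste(c(nm, catalog$description[[nm]], catalog$sets[[nm]]),
          collapse = "\t"), character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a qPCR Ct table from TSV
#'
#' @param path File path; columns gene, condition, ct.
#' @param reference_gene,reference_condition Reference labels attached to
#'   the returned table for [delta_delta_ct()].
#' @return A `"ct_table"` data frame.
#' @export
read_ct_tsv <- function(path, reference_gene = NULL,
                        reference_condition = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("gene", "condition", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("Ct file is missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stopf("Ct values must be finite and > 0")
  structure(df[, required], reference_gene = reference_gene,
            reference_condition = reference_condition,
            class = c("ct_table", "data.frame"))
}

#' Write a qPCR Ct table to TSV
#' @param ct A Ct data frame (gene, condition, ct).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ct_tsv <- function(ct, path) {
  write_tsv_with_header(as.data.frame(ct)[, c("gene", "condition", "ct")],
                        path, "ct")
}

#' Write a per-term ranking to TSV
#' @param ranking A `"pwf_ranking"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  write_tsv_with_header(as.data.frame(ranking), path,
                        sprintf("ranking_%s", attr(ranking, "term")))
}

#' Read a per-term ranking from TSV
#'
#' Quantiles are recomputed from the stored ranks (never trusted stale).
#'
#' @param path File path.
#' @param term The ranked term recorded in the file name/metadata.
#' @return A `"pwf_ranking"` data frame.
#' @export
read_ranking_tsv <- function(path, term) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  df$quantile <- df$rank / nrow(df)
  structure(df, term = term, n = nrow(df),
            class = c("pwf_ranking", "data.frame"))
}

#' Pipeline configuration
#'
#' Collects file paths, thresholds and the seed for [run_pipeline()]. The
#' same fields can be read from a YAML file with [read_pipeline_config()].
#'
#' @param expression,design,gene_sets Input paths (or in-memory objects:
#'   matrix / data frame / catalog).
#' @param out_dir Output directory (created if needed).
#' @param term Model term whose ranking feeds enrichment (default "sorted").
#' @param n_permutations Permutations for the null envelope.
#' @param set_q_max,gene_quantile_max DSM selection thresholds.
#' @param fold_threshold,p_threshold miRNA filter thresholds.
#' @param phospho_threshold_pct Phosphoprotein ratio threshold, percent.
#' @param skip_permutation Skip the envelope stage.
#' @param seed Integer seed.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, design, gene_sets = NULL,
                            out_dir = tempfile("pwfrank_"),
                            term = "sorted", n_permutations = 500,
                            set_q_max = 1e-4, gene_quantile_max = 0.01,
                            fold_threshold = 2, p_threshold = 1e-4,
                            phospho_threshold_pct = 20,
                            skip_permutation = FALSE, seed = 1L) {
  if (!term %in% PWF_TERMS)
    stopf("`term` must be one of: %s", paste(PWF_TERMS, collapse = ", "))
  if (set_q_max <= 0 || set_q_max > 1 || gene_quantile_max <= 0 ||
      gene_quantile_max > 1)
    stopf("selection thresholds must lie in (0, 1]")
  structure(list(expression = expression, design = design,
                 gene_sets = gene_sets, out_dir = out_dir, term = term,
                 n_permutations = n_permutations, set_q_max = set_q_max,
                 gene_quantile_max = gene_quantile_max,
                 fold_threshold = fold_threshold, p_threshold = p_threshold,
                 phospho_threshold_pct = phospho_threshold_pct,
                 skip_permutation = isTRUE(skip_permutation),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}
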