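pipeline_stage <- function(name, code) {
  tryCatch(code, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full ranking / envelope / enrichment pipeline
#'
#' Executes, in order: per-transcript model fitting and PWF ranking,
#' permutation-null envelopes (unless skipped), CERNO enrichment with BH
#' FDR, DSM selection and clustering. Every stage writes its result as TSV
#' under `config$out_dir`, and a manifest of output files with MD5 content
#' hashes is written last; the same configuration and seed always reproduce
#' identical manifest hashes.
#'
#' @param config A [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return Invisibly, the manifest data frame (file, md5), of class
#'   `"pipeline_manifest"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stopf("`config` must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...)
    message(sprintf(paste0("[pwfrank] ", fmt), ...))

  expression <- config$expression
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  design <- config$design
  if (is.character(design)) design <- read_design_tsv(design)

  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  log_stage("rank: fitting %d genes x %d samples (seed %d)",
            nrow(expression), ncol(expression), config$seed)
  fit <- pipeline_stage("rank", pwf_fit(expression, design))
  for (term in PWF_TERMS) {
    p <- file.path(config$out_dir, sprintf("ranking_%s.tsv", term))
    write_ranking_tsv(fit$rankings[[term]], p)
    emit(p)
  }

  if (!config$skip_permutation) {
    log_stage("permtest: %d permutations", config$n_permutations)
    env <- pipeline_stage("permtest",
      permutation_envelope(expression, design,
                           n_permutations = config$n_permutations,
                           seed = config$seed))
    env_df <- do.call(rbind, lapply(names(env$terms), function(term)
      cbind(term = term, env$terms[[term]])))
    p <- file.path(config$out_dir, "envelope.tsv")
    write_tsv_with_header(env_df, p, "envelope"); emit(p)
    exc <- exceedance_summary(fit, env)
    p <- file.path(config$out_dir, "exceedance.tsv")
    write_tsv_with_header(exc, p, "exceedance"); emit(p)
  } else log_stage("permtest: skipped")

  if (!is.null(config$gene_sets)) {
    catalog <- config$gene_sets
    if (is.character(catalog)) {
      if (!file.exists(catalog))
        stopf("pipeline stage 'cerno' failed: gene-set file not found: %s",
              catalog)
      catalog <- read_gmt(catalog)
    }
    log_stage("cerno: %d sets against the %s ranking", length(catalog$sets),
              config$term)
    ranking <- fit$rankings[[config$term]]
    cr <- pipeline_stage("cerno", cerno_test(ranking, catalog))
    p <- file.path(config$out_dir, "cerno.tsv")
    write_tsv_with_header(as.data.frame(cr), p, "cerno"); emit(p)

    sel <- pipeline_stage("dsm-select",
      select_for_dsm(cr, ranking, catalog, set_q_max = config$set_q_max,
                     gene_quantile_max = config$gene_quantile_max))
    p <- file.path(config$out_dir, "selection.tsv")
    write_tsv_with_header(
      data.frame(kind = c(rep("set", length(sel$sets)),
                          rep("gene", length(sel$genes))),
                 id = c(sel$sets, sel$genes), stringsAsFactors = FALSE),
      p, "selection"); emit(p)

    if (length(sel$sets) && length(sel$genes)) {
      log_stage("dsm: %d sets x %d genes", length(sel$sets), length(sel$genes))
      dsm <- pipeline_stage("dsm", design_structure_matrix(sel, catalog))
      M <- dsm$membership[dsm$row_order, dsm$col_order, drop = FALSE]
      p <- file.path(config$out_dir, "dsm_membership.tsv")
      write_tsv_with_header(as.data.frame(M), p, "dsm", row_names_as = "set")
      emit(p)
    } else log_stage("dsm: empty selection, skipped")
  } else log_stage("cerno: no gene sets supplied, skipped")

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  p <- file.path(config$out_dir, "manifest.tsv")
  write_tsv_with_header(manifest, p, "manifest")
  log_stage("done: %d output files in %s", nrow(manifest), config$out_dir)
  invisible(structure(manifest, class = c("pipeline_manifest", "data.frame")))
}
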