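#' Gene-set catalog
#'
#' A named list of gene-id vectors with per-set descriptions — the in-memory
#' form of a GMT file.
#'
#' @param sets Named list of character vectors (unique non-empty names;
#'   every set non-empty). Duplicate members within a set are dropped with
#'   a warning.
#' @param description Optional named character vector of descriptions.
#' @return An object of class `"gene_set_catalog"`.
#' @seealso [read_gmt()], [write_gmt()]
#' @export
gene_set_catalog <- function(sets, description = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("`sets` must be a named list of gene-id vectors")
  if (anyDuplicated(names(sets)))
    stopf("set names must be unique")
  if (any(lengths(sets) == 0L))
    stopf("every set must be non-empty")
  ndup <- sum(vapply(sets, anyDuplicated, 0L) > 0L)
  if (ndup > 0L) {
    warnf("%d set(s) contained duplicate members; de-duplicated", ndup)
    sets <- lapply(sets, unique)
  }
  if (is.null(description))
    description <- stats::setNames(rep("", length(sets)), names(sets))
  description <- description[names(sets)]
  description[is.na(description)] <- ""
  names(description) <- names(sets)
  structure(list(sets = sets, description = description),
            class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("Gene-set catalog: %d sets, sizes %d-%d\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_catalog <- function(x) length(x$sets)

#' CERNO rank-based gene-set enrichment test
#'
#' Tests each set for coincident extreme ranks of its members in a
#' transcript ranking via the Fisher combination of rank fractions:
#' `S = -2 * sum(log(rank_i / N))` over the set's `k` members with measured
#' ranks, compared against the upper tail of the chi-square distribution
#' with `2k` degrees of freedom. p-values are adjusted across the family of
#' testable sets by the Benjamini-Hochberg step-up ([bh_fdr()]).
#'
#' @param ranking A `"pwf_ranking"` data frame ([compute_pwf()]).
#' @param catalog A `"gene_set_catalog"`.
#' @return A `"cerno_result"` data frame, ordered by p-value: set, k, S, df,
#'   p_value, q_value, untestable. Sets with no member in the ranking are
#'   flagged untestable (NA statistics) and excluded from the BH family.
#' @examples
#' sim <- simulate_expression(sim_config(300, seed = 1))
#' gs <- simulate_gene_sets(sim$truth, n_sets = 10, set_size = 12,
#'                          n_enriched = 2, seed = 2)
#' fit <- pwf_fit(sim)
#' head(cerno_test(pwf_ranking(fit, "sorted"), gs$catalog))
#' @export
cerno_test <- function(ranking, catalog) {
  if (!inherits(ranking, "pwf_ranking"))
    stopf("`ranking` must be a pwf_ranking")
  if (!inherits(catalog, "gene_set_catalog"))
    stopf("`catalog` must be a gene_set_catalog")
  N <- nrow(ranking)
  rank_of <- stats::setNames(ranking$rank, ranking$gene)
  rows <- lapply(names(catalog$sets), function(nm) {
    rk <- rank_of[intersect(catalog$sets[[nm]], ranking$gene)]
    k <- length(rk)
    if (k == 0L)
      return(data.frame(set = nm, k = 0L, S = NA_real_, df = NA_integer_,
                        p_value = NA_real_, untestable = TRUE,
                        stringsAsFactors = FALSE))
    S <- -2 * sum(log(rk / N))
    data.frame(set = nm, k = k, S = S, df = 2L * k,
               p_value = stats::pchisq(S, df = 2 * k, lower.tail = FALSE),
               untestable = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  testable <- !out$untestable
  out$q_value[testable] <- bh_fdr(out$p_value[testable])
  out <- out[order(out$p_value, out$set),
             c("set", "k", "S", "df", "p_value", "q_value", "untestable")]
  rownames(out) <- NULL
  structure(out, term = attr(ranking, "term"), n_genes = N,
            class = c("cerno_result", "data.frame"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped
#' at 1, returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stopf("`p` must be numeric")
  if (any(is.na(p))) stopf("`p` must not contain NA")
  if (any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select sets and genes for the design structure matrix
#'
#' Applies the two-stage selection: gene sets with BH-adjusted CERNO
#' q-value strictly below `set_q_max`, then genes that belong to at least
#' one selected set and have transcript PWF quantile strictly below
#' `gene_quantile_max`.
#'
#' @param results A `"cerno_result"`.
#' @param ranking The `"pwf_ranking"` the results were computed on.
#' @param catalog The `"gene_set_catalog"` tested.
#' @param set_q_max Strict upper bound on the set q-value (default 1e-4).
#' @param gene_quantile_max Strict upper bound on the gene PWF quantile
#'   (default 0.01; the stricter companion threshold is 0.001).
#' @return A `"dsm_selection"`: list with `sets` and `genes` character
#'   vectors (empty, with a warning, when nothing passes).
#' @export
select_for_dsm <- function(results, ranking, catalog, set_q_max = 1e-4,
                           gene_quantile_max = 0.01) {
  if (!inherits(results, "cerno_result"))
    stopf("`results` must be a cerno_result")
  sets <- results$set[!results$untestable & results$q_value < set_q_max]
  if (length(sets) == 0L) {
    warnf("no gene set passes q < %g; returning an empty selection", set_q_max)
    return(structure(list(sets = character(0), genes = character(0)),
                     class = "dsm_selection"))
  }
  member_pool <- unique(unlist(catalog$sets[sets], use.names = FALSE))
  qn <- stats::setNames(ranking$quantile, ranking$gene)
  genes <- ranking$gene[ranking$gene %in% member_pool &
                          ranking$quantile < gene_quantile_max]
  if (length(genes) == 0L)
    warnf("no gene passes quantile < %g within the selected sets",
          gene_quantile_max)
  structure(list(sets = sets, genes = genes,
                 set_q_max = set_q_max,
                 gene_quantile_max = gene_quantile_max),
            class = "dsm_selection")
}

#' @export
print.dsm_selection <- function(x, ...) {
  cat(sprintf("DSM selection: %d sets (q < %g), %d genes (quantile < %g)\n",
              length(x$sets), x$set_q_max %||% NA,
              length(x$genes), x$gene_quantile_max %||% NA))
  invisible(x)
}
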