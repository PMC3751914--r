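#' Signed fold change from a log2 difference
#'
#' Maps a log2 expression difference to the signed ratio convention used in
#' validation tables: up-regulation x-fold is written `+x`, down-regulation
#' x-fold is written `-x`, so no numeric fold change has magnitude below 1.
#'
#' @param delta_log2 Numeric vector of log2 differences.
#' @return Signed fold changes (`2^d` for `d >= 0`, `-2^(-d)` for `d < 0`).
#' @seealso [fold_change_to_log2()] for the inverse.
#' @export
signed_fold_change <- function(delta_log2) {
  if (any(!is.finite(delta_log2))) stopf("`delta_log2` must be finite")
  ifelse(delta_log2 >= 0, 2^delta_log2, -(2^(-delta_log2)))
}

#' Log2 difference from a signed fold change
#'
#' Inverse of [signed_fold_change()]. `+1` and `-1` both map to 0.
#'
#' @param fc Signed fold changes, every `|fc| >= 1`.
#' @return Log2 differences.
#' @export
fold_change_to_log2 <- function(fc) {
  if (any(!is.finite(fc))) stopf("`fc` must be finite")
  if (any(abs(fc) < 1))
    stopf("signed fold changes must have |fc| >= 1")
  sign(fc) * log2(abs(fc))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes `dCt = Ct_gene - Ct_reference` in each condition,
#' `ddCt = dCt_condition - dCt_reference_condition`, the relative quantity
#' `2^(-ddCt)` and the corresponding signed fold change.
#'
#' @param ct A Ct table: data frame with columns `gene`, `condition`, `ct`
#'   (e.g. from [simulate_ct_table()] or [read_ct_tsv()]).
#' @param gene Target gene id.
#' @param condition Condition of interest.
#' @param reference_condition Baseline condition (defaults to the table's
#'   `reference_condition` attribute).
#' @param reference_gene Housekeeping gene (defaults to the table's
#'   `reference_gene` attribute).
#' @return List: `delta_delta_ct`, `relative_quantity`, `fold_change`.
#' @examples
#' ct <- simulate_ct_table(c(Ccr7 = -2.70), reference_gene = "Gapdh")
#' delta_delta_ct(ct, "Ccr7", "TMpos")
#' @export
delta_delta_ct <- function(ct, gene, condition,
                           reference_condition = attr(ct, "reference_condition"),
                           reference_gene = attr(ct, "reference_gene")) {
  if (is.null(reference_condition) || is.null(reference_gene))
    stopf("reference condition/gene must be given or carried by the table")
  lookup <- function(g, cond) {
    v <- ct$ct[ct$gene == g & ct$condition == cond]
    if (length(v) == 0L)
      stopf("no Ct value for gene '%s' in condition '%s'", g, cond)
    if (length(v) > 1L) mean(v) else v
  }
  d_cond <- lookup(gene, condition) - lookup(reference_gene, condition)
  d_ref <- lookup(gene, reference_condition) -
    lookup(reference_gene, reference_condition)
  ddct <- d_cond - d_ref
  list(delta_delta_ct = ddct, relative_quantity = 2^(-ddct),
       fold_change = signed_fold_change(-ddct))
}

# signed log10 transform of a signed fold change (no values in (-1, 1),
# so the transform is continuous through +/-1 -> 0)
signed_log10 <- function(fc) sign(fc) * log10(abs(fc))

#' Cross-platform fold-change regression
#'
#' Ordinary least squares of qPCR on microarray signed fold changes after
#' transforming both to signed log10 magnitudes (`sign(fc) * log10|fc|`; the
#' signed-ratio convention has no values in (-1, 1), so the transform is
#' continuous). Genes with several microarray probe values for one qPCR
#' value contribute one point at the mean of their transformed microarray
#' values; pairs with a missing (ND) value are excluded.
#'
#' @param data Data frame with one row per printed value pair, containing
#'   the gene/pair id column and the two fold-change columns.
#' @param x,y Names of the predictor (microarray) and response (qPCR)
#'   fold-change columns.
#' @param gene Name of the pair-id column used to group multi-probe rows.
#' @param exclude Optional gene ids to drop before fitting.
#' @return A `"fc_regression"`: list with `slope`, `intercept`, `r_squared`,
#'   `n_points`, `points` (the transformed pairs) and `model` (the `lm` fit).
#' @examples
#' tab <- validation_fold_changes()
#' crossplatform_regression(tab)
#' @export
crossplatform_regression <- function(data, x = "microarray", y = "qpcr",
                                     gene = "gene", exclude = NULL) {
  for (col in c(gene, x, y))
    if (!col %in% names(data)) stopf("column '%s' not found", col)
  data <- data[!is.na(data[[x]]) & !is.na(data[[y]]), , drop = FALSE]
  if (!is.null(exclude)) data <- data[!data[[gene]] %in% exclude, , drop = FALSE]
  if (any(abs(c(data[[x]], data[[y]])) < 1))
    stopf("fold changes must follow the signed convention (|fc| >= 1)")
  tx <- tapply(signed_log10(data[[x]]), data[[gene]], mean)
  ty <- tapply(signed_log10(data[[y]]), data[[gene]], mean)
  genes <- names(tx)
  if (length(genes) < 3L)
    stopf("need at least 3 paired fold changes (got %d)", length(genes))
  fit <- stats::lm(ty ~ tx)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n_points = length(genes),
                 points = data.frame(gene = genes, log10_x = as.numeric(tx),
                                     log10_y = as.numeric(ty),
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
                 model = fit),
            class = "fc_regression")
}

#' @export
print.fc_regression <- function(x, ...) {
  cat(sprintf("log10(y) = %.3f * log10(x) + %.3f   (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Direction-of-change concordance between two platforms
#'
#' Flags, per shared gene, whether the sign of change agrees between two
#' fold-change records. Numeric entries use their sign; the direction
#' markers `"up"`/`"down"` map to +/-. `NA` (not determined) entries are
#' skipped.
#'
#' @param a,b Named vectors of signed fold changes, or of `"up"`/`"down"`
#'   markers (names are gene ids).
#' @return A `"concordance"` data frame (gene, sign_a, sign_b, concordant)
#'   with attribute `discordant`, the discordant gene ids.
#' @export
direction_concordance <- function(a, b) {
  to_sign <- function(v) {
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      bad <- !(v %in% c("up", "down") | is.na(v))
      if (any(bad)) stopf("direction markers must be 'up' or 'down'")
      ifelse(is.na(v), NA_real_, ifelse(v == "up", 1, -1))
    } else sign(v)
  }
  if (is.null(names(a)) || is.null(names(b)))
    stopf("`a` and `b` must be named by gene")
  sa <- stats::setNames(to_sign(a), names(a))
  sb <- stats::setNames(to_sign(b), names(b))
  genes <- intersect(names(sa), names(sb))
  genes <- genes[!is.na(sa[genes]) & !is.na(sb[genes])]
  if (length(genes) == 0L) stopf("no shared genes with determined directions")
  out <- data.frame(gene = genes, sign_a = unname(sa[genes]),
                    sign_b = unname(sb[genes]),
                    concordant = unname(sa[genes] == sb[genes]),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, discordant = out$gene[!out$concordant],
            class = c("concordance", "data.frame"))
}

#' Phosphoprotein ratio filter
#'
#' Flags proteins whose pos/neg signal ratio changed by more than
#' `threshold_pct` percent in either direction, with the symmetric
#' multiplicative rule: pass iff `ratio > 1 + threshold/100` or
#' `ratio < 1 / (1 + threshold/100)` (both strict).
#'
#' @param ratios Positive numeric vector of signal ratios, optionally named.
#' @param threshold_pct Percent-change threshold (20 for the screen-wide
#'   filter, 25 for the reported shortlist).
#' @return Logical vector (same names) — `TRUE` for proteins passing.
#' @export
phospho_ratio_filter <- function(ratios, threshold_pct = 20) {
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stopf("`ratios` must be positive and finite")
  hi <- 1 + threshold_pct / 100
  ratios > hi | ratios < 1 / hi
}

#' Printed microarray/qPCR/protein validation fold changes
#'
#' The bundled validation table of signed fold changes (pos-sorted relative
#' to neg-sorted cells) measured for the same genes by microarray and by
#' qPCR, plus the direction of the protein-level change. Multi-probe genes
#' (the two MHC II loci and the two IL-12 chains) appear as one row per
#' printed microarray value; `NA` marks values not determined.
#'
#' @return Data frame: gene, probe, microarray, qpcr, protein.
#' @export
validation_fold_changes <- function() {
  path <- system.file("extdata", "table1_fold_changes.tsv",
                      package = "pwfrank", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
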