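#' ANOVA / fold-change filter for differential miRNA expression
#'
#' For every miRNA, tests the sorted-group difference by one-way ANOVA
#' (equal-variance F test) on log2 values and computes the signed fold
#' change of the pos group relative to the neg group (negative values mean
#' lower expression in the pos group). A miRNA passes when `|fc| >
#' fold_threshold` and `p < p_threshold`, both strict.
#'
#' @param expression Numeric log2 matrix, miRNAs x samples.
#' @param design Sample sheet with at least `sample` and `sorted` columns.
#' @param fold_threshold Fold-change threshold (default 2).
#' @param p_threshold ANOVA p-value threshold (default 1e-4).
#' @return A `"mirna_result"` data frame: mirna, p_value, fold_change, pass.
#' @export
differential_mirna <- function(expression, design, fold_threshold = 2,
                               p_threshold = 1e-4) {
  if (!"sorted" %in% names(design))
    stopf("design must contain a 'sorted' column")
  if (!is.null(design$sample)) {
    if (!setequal(colnames(expression), design$sample))
      stopf("expression columns and design samples do not match")
    design <- design[match(colnames(expression), design$sample), , drop = FALSE]
  } else if (nrow(design) != ncol(expression)) {
    stopf("design rows and expression columns do not match")
  }
  g <- factor(design$sorted, levels = c("pos", "neg"))
  if (any(table(g) < 2L))
    stopf("each sorted group needs at least 2 samples")
  p <- apply(expression, 1L, function(y)
    stats::oneway.test(y ~ g, var.equal = TRUE)$p.value)
  delta <- rowMeans(expression[, g == "pos", drop = FALSE]) -
    rowMeans(expression[, g == "neg", drop = FALSE])
  fc <- signed_fold_change(delta)
  structure(data.frame(mirna = rownames(expression), p_value = p,
                       fold_change = fc,
                       pass = abs(fc) > fold_threshold & p < p_threshold,
                       row.names = NULL, stringsAsFactors = FALSE),
            fold_threshold = fold_threshold, p_threshold = p_threshold,
            class = c("mirna_result", "data.frame"))
}
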