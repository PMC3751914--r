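#' @keywords internal
"_PACKAGE"

# stop() with sprintf formatting and no call in the message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Seeds the global RNG, evaluates `code`, then restores the RNG state that
#' was in place before the call, so seeded operations do not perturb the
#' caller's random stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# validate a sample design sheet against an expression matrix
check_design <- function(expression, design) {
  required <- c("sample", "experiment", "sorted", "treatment")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols))
    stopf("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(design$sample))
    stopf("design contains duplicated sample ids")
  if (!setequal(colnames(expression), design$sample))
    stopf("expression columns and design samples do not match")
  design <- design[match(colnames(expression), design$sample), , drop = FALSE]
  if (!all(design$sorted %in% c("pos", "neg")))
    stopf("design$sorted must be 'pos' or 'neg'")
  if (!all(design$treatment %in% c("treated", "untreated")))
    stopf("design$treatment must be 'treated' or 'untreated'")
  if (length(unique(design$sorted)) < 2L || length(unique(design$treatment)) < 2L)
    stopf("both levels of 'sorted' and 'treatment' must be present")
  if (any(table(design$experiment) < 2L))
    stopf("every experiment must contain at least 2 samples")
  design
}

# TRUE when every experiment contains every (sorted, treatment) cell
# the same number of times -- the case with a closed-form REML solution
is_balanced_design <- function(design) {
  tab <- table(design$experiment, design$sorted, design$treatment)
  all(tab == tab[1L])
}

# numeric contrast codes (+1/2, -1/2): coefficients are level-mean differences
design_codes <- function(design) {
  list(s  = ifelse(design$sorted == "pos", 0.5, -0.5),
       t  = ifelse(design$treatment == "treated", 0.5, -0.5))
}
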