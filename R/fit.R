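PWF_TERMS <- c("sorted", "treatment", "interaction")

# Closed-form REML engine for balanced designs.
#
# When every experiment contains every (sorted x treatment) cell equally
# often, the contrast columns for the three fixed terms are within-block
# contrasts, orthogonal to the experiment (block) space. The GLS estimates
# and their Wald F statistics under the random-intercept model then coincide
# exactly with OLS using experiment as fixed blocks, for any value of the
# variance ratio; only the intercept is affected by the random effect. The
# REML between-experiment variance component is still estimated (from the
# block-mean mean square) to flag boundary fits, which are refit as fixed
# blocks per the fallback contract (numerically identical F values here).
fit_engine_balanced <- function(Y, design) {
  n <- ncol(Y)
  codes <- design_codes(design)
  E <- stats::model.matrix(~ 0 + factor(design$experiment))
  J <- ncol(E)
  X <- cbind(E, s = codes$s, t = codes$t, st = codes$s * codes$t)
  p <- ncol(X)
  XtX_inv <- solve(crossprod(X))
  B <- Y %*% X %*% XtX_inv                      # genes x p coefficients
  fitted <- tcrossprod(B, X)
  res <- Y - fitted
  RSS <- rowSums(res^2)
  df <- n - p
  sigma2 <- RSS / df
  dvar <- diag(XtX_inv)[(J + 1):p]              # unit variances of s, t, st
  tc <- (J + 1):p
  Fmat <- (B[, tc, drop = FALSE]^2) /
    (sigma2 * matrix(dvar, nrow(Y), 3, byrow = TRUE))
  colnames(Fmat) <- PWF_TERMS
  eint <- B[, seq_len(J), drop = FALSE]
  colnames(eint) <- levels(factor(design$experiment))

  # between-experiment variance component (method-of-moments == REML here)
  X0 <- cbind(1, X[, tc, drop = FALSE])
  B0 <- Y %*% X0 %*% solve(crossprod(X0))
  RSS0 <- rowSums((Y - tcrossprod(B0, X0))^2)
  m <- n / J                                    # samples per experiment
  sigma_b2 <- ((RSS0 - RSS) / (J - 1) - sigma2) / m
  list(F = Fmat,
       coefficients = structure(B[, tc, drop = FALSE],
                                dimnames = list(rownames(Y), PWF_TERMS)),
       sigma2 = sigma2, residual_df = rep(df, nrow(Y)),
       fit_method = ifelse(sigma_b2 > 0, "mixed", "fixed-fallback"),
       residuals = res, fitted = fitted, experiment_intercepts = eint)
}

# Per-gene lme4 engine for general (unbalanced) designs, with a
# fixed-blocks OLS fallback on error or singular (boundary) fits.
fit_engine_lme4 <- function(Y, design) {
  n <- ncol(Y)
  codes <- design_codes(design)
  J <- length(unique(design$experiment))
  df <- n - 3L - J
  dat <- data.frame(s = codes$s, t = codes$t,
                    experiment = factor(design$experiment))
  levs <- levels(dat$experiment)
  grid0 <- data.frame(s = 0, t = 0, experiment = factor(levs, levels = levs))
  ng <- nrow(Y)
  Fmat <- matrix(NA_real_, ng, 3, dimnames = list(rownames(Y), PWF_TERMS))
  Bmat <- Fmat
  sigma2 <- numeric(ng)
  fit_method <- character(ng)
  res <- matrix(NA_real_, ng, n, dimnames = dimnames(Y))
  eint <- matrix(NA_real_, ng, length(levs),
                 dimnames = list(rownames(Y), levs))
  for (g in seq_len(ng)) {
    dat$y <- Y[g, ]
    fit <- tryCatch(
      suppressMessages(lme4::lmer(y ~ s + t + s:t + (1 | experiment),
                                  data = dat, REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit)) {
      cf <- stats::coef(summary(fit))[c("s", "t", "s:t"), , drop = FALSE]
      Fmat[g, ] <- cf[, "t value"]^2
      Bmat[g, ] <- cf[, "Estimate"]
      sigma2[g] <- stats::sigma(fit)^2
      fit_method[g] <- "mixed"
      res[g, ] <- stats::residuals(fit)
      eint[g, ] <- stats::predict(fit, newdata = grid0,
                                  re.form = ~ (1 | experiment))
    } else {
      lmf <- stats::lm(y ~ experiment + s + t + s:t, data = dat)
      cf <- stats::coef(summary(lmf))[c("s", "t", "s:t"), , drop = FALSE]
      Fmat[g, ] <- cf[, "t value"]^2
      Bmat[g, ] <- cf[, "Estimate"]
      sigma2[g] <- summary(lmf)$sigma^2
      fit_method[g] <- "fixed-fallback"
      res[g, ] <- stats::residuals(lmf)
      eint[g, ] <- stats::predict(lmf, newdata = grid0)
    }
  }
  list(F = Fmat, coefficients = Bmat, sigma2 = sigma2,
       residual_df = rep(df, ng), fit_method = fit_method, residuals = res,
       fitted = Y - res, experiment_intercepts = eint)
}

#' Fit per-transcript mixed-effects models and rank by proportion-weighted F
#'
#' For every gene, fits the linear mixed-effects model
#' `log2 expression ~ sorted + treatment + sorted:treatment + (1 | experiment)`
#' by REML and computes the Wald F statistic of each 1-df fixed term (equal to
#' the squared t statistic of its coefficient, with the residual denominator
#' degrees of freedom). Genes whose random-intercept fit fails or lands on the
#' variance-component boundary are refit with experiment as fixed blocks and
#' flagged `fit_method = "fixed-fallback"`.
#'
#' Per-term rankings use the proportion-weighted F statistic
#' `PWF_t = F_t * F_t / (F_sorted + F_treatment + F_interaction)`:
#' each term's F weighted by its share of the gene's total F across the three
#' terms, so that genes driven by a single factor keep (almost) their full F
#' for that factor while genes dominated by another factor are de-emphasized.
#'
#' For balanced designs (every experiment contains every condition cell
#' equally often) the REML solution is closed form and all genes are fit in
#' a single vectorized pass; unbalanced designs are fit gene-by-gene with
#' \pkg{lme4}.
#'
#' Constant (zero-variance) genes are flagged degenerate: they receive no F
#' statistics and are excluded from the rankings and from the quantile
#' denominator `N`.
#'
#' @param expression Numeric matrix of log2 expression, genes x samples, with
#'   gene ids as rownames and sample ids as colnames; or a `"pwf_sim"` object
#'   from [simulate_expression()].
#' @param design Sample sheet: data frame with columns `sample`, `experiment`,
#'   `sorted` (`"pos"`/`"neg"`) and `treatment` (`"treated"`/`"untreated"`).
#'   Ignored when `expression` is a `"pwf_sim"`.
#' @param method `"auto"` (closed form when balanced, lme4 otherwise),
#'   `"mixed"` (synonym of `"auto"`) or `"fixed"` (experiment as fixed blocks
#'   for every gene).
#' @return An object of class `"pwf_fit"` with components `F` (genes x 3
#'   matrix of per-term F statistics), `coefficients` (genes x 3 log2 effect
#'   estimates), `pwf` (genes x 3 PWF values), `rankings` (per-term
#'   [pwf_ranking] data frames), `sigma2`, `residual_df`, `fit_method`,
#'   `degenerate`, `design` and `residuals`.
#' @examples
#' sim <- simulate_expression(sim_config(100, seed = 1))
#' fit <- pwf_fit(sim)
#' fit
#' head(pwf_ranking(fit, "sorted"))
#' @export
pwf_fit <- function(expression, design = NULL,
                    method = c("auto", "mixed", "fixed")) {
  method <- match.arg(method)
  if (inherits(expression, "pwf_sim")) {
    design <- expression$design
    expression <- expression$expression
  }
  if (!is.matrix(expression) || !is.numeric(expression))
    stopf("`expression` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stopf("`expression` must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(expression)))
    stopf("duplicated gene ids in `expression`")
  if (!all(is.finite(expression)))
    stopf("`expression` contains non-finite values")
  design <- check_design(expression, design)
  if (ncol(expression) < 8L)
    stopf("at least 8 samples are required (got %d)", ncol(expression))
  cells <- table(design$sorted, design$treatment)
  if (any(cells == 0L))
    stopf("all 4 (sorted x treatment) condition cells must be represented")

  rng <- apply(expression, 1L, function(y) max(y) - min(y))
  degenerate <- rng <= 1e-12
  Y <- expression[!degenerate, , drop = FALSE]

  ng <- nrow(expression)
  empty <- matrix(NA_real_, ng, 3,
                  dimnames = list(rownames(expression), PWF_TERMS))
  levs <- levels(factor(design$experiment))
  out <- list(F = empty, coefficients = empty, pwf = empty,
              sigma2 = rep(NA_real_, ng), residual_df = rep(NA_integer_, ng),
              fit_method = rep(NA_character_, ng), degenerate = degenerate,
              residuals = matrix(0, ng, ncol(expression),
                                 dimnames = dimnames(expression)),
              fitted = expression,
              experiment_intercepts = matrix(NA_real_, ng, length(levs),
                                             dimnames = list(rownames(expression), levs)),
              design = design, method = method, call = match.call())
  names(out$sigma2) <- names(out$residual_df) <- names(out$fit_method) <-
    rownames(expression)

  if (nrow(Y)) {
    eng <- if (method == "fixed" || is_balanced_design(design))
      fit_engine_balanced(Y, design) else fit_engine_lme4(Y, design)
    if (method == "fixed") eng$fit_method <- rep("fixed", nrow(Y))
    keep <- !degenerate
    out$F[keep, ] <- eng$F
    out$coefficients[keep, ] <- eng$coefficients
    out$sigma2[keep] <- eng$sigma2
    out$residual_df[keep] <- eng$residual_df
    out$fit_method[keep] <- eng$fit_method
    out$residuals[keep, ] <- eng$residuals
    out$fitted[keep, ] <- eng$fitted
    out$experiment_intercepts[keep, ] <- eng$experiment_intercepts
  }
  out$pwf <- pwf_values(out$F)
  class(out) <- "pwf_fit"
  out$rankings <- compute_pwf(out)
  out
}

# PWF matrix from an F matrix: F_t^2 / sum_t F_t, 0 when all three F are 0
pwf_values <- function(Fmat) {
  tot <- rowSums(Fmat)
  pwf <- Fmat^2 / tot
  pwf[tot == 0, ] <- 0
  pwf
}

#' Per-term PWF rankings
#'
#' Computes proportion-weighted F values and descending rankings for each
#' model term from a set of per-gene F statistics. `PWF_t = F_t^2 / sum(F)`,
#' with PWF defined as 0 for genes whose three F statistics are all zero.
#' Ties are broken by lexicographic gene id; degenerate genes (missing F)
#' are excluded from the ranking and from the quantile denominator.
#'
#' @param stats A `"pwf_fit"` object, or a genes x 3 numeric matrix of F
#'   statistics with columns sorted/treatment/interaction and gene rownames.
#' @return A named list of three `"pwf_ranking"` data frames (one per term)
#'   with columns gene, F_sorted, F_treatment, F_interaction, pwf, rank,
#'   quantile, fit_method, ordered by rank; attribute `n` is the number of
#'   rankable genes and `term` the ranked term.
#' @export
compute_pwf <- function(stats) {
  if (inherits(stats, "pwf_fit")) {
    Fmat <- stats$F
    fit_method <- stats$fit_method
  } else {
    Fmat <- as.matrix(stats)
    if (ncol(Fmat) != 3L) stopf("`stats` must have 3 term columns")
    colnames(Fmat) <- PWF_TERMS
    fit_method <- rep(NA_character_, nrow(Fmat))
  }
  if (is.null(rownames(Fmat)))
    rownames(Fmat) <- sprintf("g%d", seq_len(nrow(Fmat)))
  ok <- stats::complete.cases(Fmat)
  Fok <- Fmat[ok, , drop = FALSE]
  if (any(Fok < 0)) stopf("F statistics must be >= 0")
  pwf <- pwf_values(Fok)
  N <- nrow(Fok)
  lapply(stats::setNames(PWF_TERMS, PWF_TERMS), function(term) {
    v <- pwf[, term]
    ord <- order(-v, rownames(Fok), method = "radix")
    df <- data.frame(gene = rownames(Fok)[ord],
                     F_sorted = Fok[ord, "sorted"],
                     F_treatment = Fok[ord, "treatment"],
                     F_interaction = Fok[ord, "interaction"],
                     pwf = v[ord],
                     rank = seq_len(N),
                     quantile = seq_len(N) / N,
                     fit_method = fit_method[ok][ord],
                     row.names = NULL, stringsAsFactors = FALSE)
    structure(df, term = term, n = N,
              class = c("pwf_ranking", "data.frame"))
  })
}

#' Extract one term's PWF ranking from a fit
#'
#' @param fit A `"pwf_fit"` object.
#' @param term One of `"sorted"`, `"treatment"`, `"interaction"`.
#' @return A `"pwf_ranking"` data frame (see [compute_pwf()]).
#' @export
pwf_ranking <- function(fit, term = c("sorted", "treatment", "interaction")) {
  term <- match.arg(term)
  if (!inherits(fit, "pwf_fit")) stopf("`fit` must be a pwf_fit object")
  fit$rankings[[term]]
}

#' Per-gene model term statistics
#'
#' @param fit A `"pwf_fit"` object.
#' @return Data frame: gene, F and coefficient per term, sigma2, residual_df,
#'   fit_method, degenerate.
#' @export
term_stats <- function(fit) {
  if (!inherits(fit, "pwf_fit")) stopf("`fit` must be a pwf_fit object")
  data.frame(gene = rownames(fit$F),
             F_sorted = fit$F[, "sorted"],
             F_treatment = fit$F[, "treatment"],
             F_interaction = fit$F[, "interaction"],
             coef_sorted = fit$coefficients[, "sorted"],
             coef_treatment = fit$coefficients[, "treatment"],
             coef_interaction = fit$coefficients[, "interaction"],
             sigma2 = fit$sigma2, residual_df = fit$residual_df,
             fit_method = fit$fit_method, degenerate = fit$degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top-ranked genes from a PWF ranking
#'
#' @param ranking A `"pwf_ranking"` data frame.
#' @param k Number of genes (0 <= k <= N).
#' @return Character vector of the first `k` gene ids in rank order.
#' @export
top_genes <- function(ranking, k) {
  if (!inherits(ranking, "pwf_ranking"))
    stopf("`ranking` must be a pwf_ranking")
  if (k < 0 || k > nrow(ranking))
    stopf("`k` must lie in [0, %d]", nrow(ranking))
  ranking$gene[seq_len(k)]
}

#' Row-standardized (Z-score) expression matrix
#'
#' Rescales each listed gene's expression row to mean 0, sd 1 across
#' samples — the scaling used for heat-map display.
#'
#' @param expression Numeric genes x samples matrix.
#' @param genes Character vector of gene ids to include (default: all rows).
#' @return Matrix of the same shape restricted to `genes`, each row with
#'   mean 0 and sd 1.
#' @export
zscore_matrix <- function(expression, genes = rownames(expression)) {
  missing_genes <- setdiff(genes, rownames(expression))
  if (length(missing_genes))
    stopf("gene(s) not in expression matrix: %s",
          paste(utils::head(missing_genes, 5), collapse = ", "))
  x <- expression[genes, , drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance gene(s): %s",
          paste(utils::head(genes[sds == 0], 5), collapse = ", "))
  sweep(sweep(x, 1L, rowMeans(x)), 1L, sds, `/`)
}

#' @export
print.pwf_fit <- function(x, ...) {
  cat(sprintf("Per-transcript mixed-model PWF fit: %d genes x %d samples\n",
              nrow(x$F), nrow(x$design)))
  cat(sprintf("  fit method: %d mixed, %d fixed-fallback, %d degenerate\n",
              sum(x$fit_method == "mixed", na.rm = TRUE),
              sum(x$fit_method != "mixed", na.rm = TRUE),
              sum(x$degenerate)))
  for (term in PWF_TERMS) {
    r <- x$rankings[[term]]
    cat(sprintf("  top %-11s: %s\n", term,
                paste(utils::head(r$gene, 5), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.pwf_fit <- function(object, ...) {
  pwf_top <- sapply(object$rankings, function(r) r$pwf[1L])
  out <- list(n_genes = nrow(object$F), n_samples = nrow(object$design),
              n_degenerate = sum(object$degenerate),
              fit_method = table(object$fit_method),
              F_summary = apply(object$F, 2L, summary),
              top = lapply(object$rankings, utils::head, 5L),
              pwf_top = pwf_top)
  class(out) <- "summary.pwf_fit"
  out
}

#' @export
print.summary.pwf_fit <- function(x, ...) {
  cat(sprintf("pwf_fit: %d genes, %d samples, %d degenerate\n",
              x$n_genes, x$n_samples, x$n_degenerate))
  cat("F statistics by term:\n")
  print(round(x$F_summary, 2))
  for (term in names(x$top)) {
    cat(sprintf("\nTop genes, %s term (max PWF %.1f):\n", term, x$pwf_top[term]))
    print(x$top[[term]][, c("gene", "pwf", "rank", "quantile")], digits = 4)
  }
  invisible(x)
}

#' @export
coef.pwf_fit <- function(object, ...) object$coefficients

#' @export
residuals.pwf_fit <- function(object, ...) object$residuals

#' @export
fitted.pwf_fit <- function(object, ...) object$fitted

#' Predicted cell means from a per-transcript fit
#'
#' @param object A `"pwf_fit"` object.
#' @param newdesign Data frame with columns `experiment`, `sorted`,
#'   `treatment` (experiments must be among those fitted). Defaults to the
#'   fitted design.
#' @param ... Unused.
#' @return Genes x rows matrix of predicted log2 means. Degenerate genes
#'   predict their (constant) observed value regardless of design.
#' @export
predict.pwf_fit <- function(object, newdesign = NULL, ...) {
  design <- if (is.null(newdesign)) object$design else newdesign
  bad <- setdiff(unique(design$experiment),
                 colnames(object$experiment_intercepts))
  if (length(bad))
    stopf("unknown experiment level(s): %s", paste(bad, collapse = ", "))
  codes <- design_codes(design)
  Xc <- rbind(codes$s, codes$t, codes$s * codes$t)
  pred <- object$experiment_intercepts[, design$experiment, drop = FALSE] +
    object$coefficients %*% Xc
  deg <- object$degenerate
  if (any(deg)) pred[deg, ] <- object$fitted[deg, 1L]
  colnames(pred) <- design$sample %||% NULL
  pred
}

#' @export
plot.pwf_fit <- function(x, terms = PWF_TERMS, log = "y", ...) {
  old <- graphics::par(mfrow = c(1, length(terms)))
  on.exit(graphics::par(old))
  for (term in terms) {
    r <- x$rankings[[term]]
    v <- pmax(r$pwf, .Machine$double.xmin)
    graphics::plot(r$rank, v, type = "l", log = log, xlab = "rank",
                   ylab = "PWF", main = term, ...)
  }
  invisible(x)
}

#' Parametric-bootstrap replicate matrices from a fit
#'
#' Draws new expression matrices as fitted means plus Gaussian noise at each
#' gene's estimated residual sd. Degenerate genes are reproduced unchanged.
#'
#' @param object A `"pwf_fit"` object.
#' @param nsim Number of replicate matrices.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A matrix when `nsim = 1`, else a list of matrices.
#' @export
simulate.pwf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ok <- !object$degenerate
  sds <- sqrt(object$sigma2[ok])
  out <- replicate(nsim, {
    y <- object$fitted
    y[ok, ] <- y[ok, ] + matrix(stats::rnorm(sum(ok) * ncol(y)),
                                sum(ok), ncol(y)) * sds
    y
  }, simplify = FALSE)
  if (nsim == 1) out[[1L]] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
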