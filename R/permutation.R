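#' Permute condition labels within experiment blocks
#'
#' Shuffles the (sorted, treatment) label pairs uniformly at random across
#' the samples of each experiment, leaving experiment assignment untouched.
#' Restricting permutation to blocks preserves the random-intercept
#' structure the per-transcript model conditions on.
#'
#' @param design Sample sheet (sample, experiment, sorted, treatment).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so a seeded caller controls the sequence).
#' @return A design data frame with permuted sorted/treatment columns.
#' @export
permute_design <- function(design, seed = NULL) {
  do_permute <- function() {
    out <- design
    for (e in unique(design$experiment)) {
      idx <- which(design$experiment == e)
      perm <- if (length(idx) > 1L) sample(idx) else idx
      out$sorted[idx] <- design$sorted[perm]
      out$treatment[idx] <- design$treatment[perm]
    }
    out
  }
  if (is.null(seed)) do_permute() else with_seed(seed, do_permute())
}

# a design is usable when all 4 condition cells occur somewhere globally
design_has_all_cells <- function(design) {
  all(table(design$sorted, design$treatment) > 0L) &&
    length(unique(design$sorted)) == 2L &&
    length(unique(design$treatment)) == 2L
}

#' Permutation-null envelopes of the PWF-by-rank curve
#'
#' Re-fits the per-transcript model under `n_permutations` within-block
#' label permutations, sorts each permutation's PWF values in decreasing
#' order, and summarizes, at every rank position, the mean and the empirical
#' 95th percentile (nearest-rank) across permutations. The observed ranking
#' is compared curve-wise against these envelopes: under the null the
#' observed curve should exceed the 95th-percentile curve at about 5% of
#' ranks, while genuine factor effects push the top of the observed curve
#' far above it.
#'
#' Permutations that leave a condition cell globally unrepresented are
#' rejected and redrawn (counted in `n_rejected`); with every cell present
#' in every experiment this cannot occur.
#'
#' @param expression Log2 matrix (genes x samples) or a `"pwf_sim"`.
#' @param design Sample sheet (ignored for a `"pwf_sim"`).
#' @param n_permutations Number of permutations, >= 2 (default 500).
#' @param seed Integer seed for the permutation stream.
#' @param method Fitting method passed to [pwf_fit()].
#' @return A `"pwf_envelope"`: list with `terms` (per-term data frame of
#'   rank, mean_pwf, pct95_pwf), `n_permutations`, `n_rejected`, `seed`, `n`.
#' @examples
#' sim <- simulate_expression(sim_config(60, seed = 1))
#' env <- permutation_envelope(sim, n_permutations = 20, seed = 1)
#' env
#' @export
permutation_envelope <- function(expression, design = NULL,
                                 n_permutations = 500, seed = 1L,
                                 method = "auto") {
  if (inherits(expression, "pwf_sim")) {
    design <- expression$design
    expression <- expression$expression
  }
  if (n_permutations < 2) stopf("`n_permutations` must be >= 2")
  design <- check_design(expression, design)
  fit0 <- pwf_fit(expression, design, method = method)
  N <- attr(fit0$rankings[[1L]], "n")
  curves <- lapply(PWF_TERMS, function(t)
    matrix(NA_real_, n_permutations, N))
  names(curves) <- PWF_TERMS
  n_rejected <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      repeat {
        dperm <- permute_design(design)
        if (design_has_all_cells(dperm)) break
        n_rejected <- n_rejected + 1L
        if (n_rejected > 1000L * n_permutations)
          stopf("could not draw a non-degenerate permutation")
      }
      fitp <- pwf_fit(expression, dperm, method = method)
      for (term in PWF_TERMS)
        curves[[term]][b, ] <- sort(fitp$pwf[!fitp$degenerate, term],
                                    decreasing = TRUE)
    }
  })
  i95 <- ceiling(0.95 * n_permutations)        # nearest-rank 95th percentile
  terms <- lapply(curves, function(M) {
    sorted_cols <- apply(M, 2L, sort)
    data.frame(rank = seq_len(N), mean_pwf = colMeans(M),
               pct95_pwf = sorted_cols[i95, ])
  })
  structure(list(terms = terms, n_permutations = as.integer(n_permutations),
                 n_rejected = n_rejected, seed = as.integer(seed), n = N),
            class = "pwf_envelope")
}

#' @export
print.pwf_envelope <- function(x, ...) {
  cat(sprintf("Permutation PWF envelope: %d permutations over %d ranks (seed %d, %d rejected draws)\n",
              x$n_permutations, x$n, x$seed, x$n_rejected))
  for (term in names(x$terms)) {
    e <- x$terms[[term]]
    cat(sprintf("  %-11s rank-1 mean %.2f, 95th pct %.2f\n", term,
                e$mean_pwf[1L], e$pct95_pwf[1L]))
  }
  invisible(x)
}

#' @export
plot.pwf_envelope <- function(x, fit = NULL, terms = names(x$terms),
                              log = "y", ...) {
  old <- graphics::par(mfrow = c(1, length(terms)))
  on.exit(graphics::par(old))
  for (term in terms) {
    e <- x$terms[[term]]
    obs <- if (!is.null(fit)) fit$rankings[[term]]$pwf else NULL
    ylim <- range(c(e$mean_pwf, e$pct95_pwf, obs), finite = TRUE)
    ylim[1L] <- max(ylim[1L], .Machine$double.xmin)
    graphics::plot(e$rank, pmax(e$mean_pwf, ylim[1L]), type = "l",
                   log = log, ylim = ylim, xlab = "rank", ylab = "PWF",
                   main = term, col = "black", ...)
    graphics::lines(e$rank, pmax(e$pct95_pwf, ylim[1L]), col = "red")
    if (!is.null(obs))
      graphics::lines(seq_along(obs), pmax(obs, ylim[1L]), col = "blue")
  }
  invisible(x)
}

#' Exceedance of the observed PWF curve over the permutation envelope
#'
#' Counts, per term, the rank positions at which the observed PWF (sorted
#' descending) strictly exceeds the envelope's 95th-percentile curve, and
#' the length of the contiguous exceedance run starting at rank 1.
#'
#' @param fit A `"pwf_fit"` (all terms) or a single `"pwf_ranking"`.
#' @param envelope A `"pwf_envelope"` built on the same gene universe.
#' @return Data frame: term, n_exceed, frac_exceed, top_run.
#' @export
exceedance_summary <- function(fit, envelope) {
  rankings <- if (inherits(fit, "pwf_fit")) fit$rankings
  else if (inherits(fit, "pwf_ranking"))
    stats::setNames(list(fit), attr(fit, "term"))
  else stopf("`fit` must be a pwf_fit or pwf_ranking")
  out <- lapply(names(rankings), function(term) {
    r <- rankings[[term]]
    e <- envelope$terms[[term]]
    if (is.null(e)) stopf("envelope has no term '%s'", term)
    if (nrow(r) != nrow(e))
      stopf("observed ranking (N=%d) and envelope (N=%d) differ in size",
            nrow(r), nrow(e))
    exceed <- r$pwf > e$pct95_pwf
    run <- if (exceed[1L]) rle(exceed)$lengths[1L] else 0L
    data.frame(term = term, n_exceed = sum(exceed),
               frac_exceed = mean(exceed), top_run = run,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
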