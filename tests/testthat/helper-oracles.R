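# Independent oracles and small fixture builders shared across tests.

# Brute-force per-gene F statistics: plain lm() with experiment as fixed
# blocks and +/-1/2 contrast codes -- independent of the package engine.
oracle_fixed_f <- function(y, design) {
  s <- ifelse(design$sorted == "pos", 0.5, -0.5)
  t <- ifelse(design$treatment == "treated", 0.5, -0.5)
  e <- factor(design$experiment)
  f <- stats::lm(y ~ e + s + t + s:t)
  cf <- stats::coef(summary(f))
  stats::setNames(cf[c("s", "t", "s:t"), "t value"]^2,
                  c("sorted", "treatment", "interaction"))
}

# Brute-force Benjamini-Hochberg step-up, written from the definition
# (not via p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  res <- numeric(m)
  res[o] <- pmin(q_sorted, 1)
  res
}

# Chi-square upper-tail probability by numerical integration of the density
# (independent of pchisq's tail computation).
chisq_tail_oracle <- function(S, df) {
  stats::integrate(function(x) stats::dchisq(x, df), S, Inf,
                   rel.tol = 1e-10)$value
}

# Exact permutation p-value of the CERNO statistic: enumerate every k-subset
# of ranks 1..N and count subsets at least as extreme.
cerno_exact_p <- function(S_obs, k, N) {
  subsets <- utils::combn(N, k)
  S_all <- apply(subsets, 2L, function(rk) -2 * sum(log(rk / N)))
  mean(S_all >= S_obs - 1e-12)
}

# Minimal pwf_ranking from an ordered gene vector (rank 1 first).
make_ranking <- function(genes, term = "sorted") {
  N <- length(genes)
  structure(data.frame(gene = genes,
                       pwf = rev(seq_len(N)),
                       rank = seq_len(N), quantile = seq_len(N) / N,
                       stringsAsFactors = FALSE),
            term = term, n = N, class = c("pwf_ranking", "data.frame"))
}

# Shared moderate-size simulation used by several files.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_expression(sim_config(
        400, prop_sorted = 0.1, prop_treatment = 0.05,
        prop_interaction = 0.02, effect_size = 2, noise_sd = 0.25,
        experiment_sd = 0.5, seed = 101))
    cache
  }
})
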