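test_that("per-gene F statistics match a brute-force OLS oracle", {
  sim <- shared_sim()
  fit <- pwf_fit(sim)
  for (g in sample(rownames(sim$expression), 25)) {
    expect_equal(fit$F[g, ], oracle_fixed_f(sim$expression[g, ], sim$design),
                 tolerance = 1e-10)
  }
  # F of a 1-df term is the squared t statistic of its coefficient
  g <- rownames(sim$expression)[1]
  se2 <- fit$sigma2[g] * (1 / 6 + 1 / 6)  # var of a balanced mean difference
  expect_equal(fit$F[g, "sorted"], fit$coefficients[g, "sorted"]^2 / se2,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("interior mixed fits agree exactly with lme4 REML", {
  sim <- shared_sim()
  fit <- pwf_fit(sim)
  dat <- data.frame(
    s = ifelse(sim$design$sorted == "pos", 0.5, -0.5),
    t = ifelse(sim$design$treatment == "treated", 0.5, -0.5),
    experiment = factor(sim$design$experiment))
  mixed_genes <- names(which(fit$fit_method == "mixed"))[1:10]
  for (g in mixed_genes) {
    dat$y <- sim$expression[g, ]
    m <- lme4::lmer(y ~ s + t + s:t + (1 | experiment), data = dat,
                    REML = TRUE)
    expect_false(lme4::isSingular(m))
    tv <- coef(summary(m))[c("s", "t", "s:t"), "t value"]
    # lme4's numeric optimizer limits agreement to ~1e-4 relative
    expect_equal(unname(fit$F[g, ]), unname(tv^2), tolerance = 1e-3)
  }
})

test_that("boundary variance components are flagged as fixed-fallback", {
  sim <- simulate_expression(sim_config(60, experiment_sd = 0, seed = 45))
  fit <- pwf_fit(sim)
  dat <- data.frame(
    s = ifelse(sim$design$sorted == "pos", 0.5, -0.5),
    t = ifelse(sim$design$treatment == "treated", 0.5, -0.5),
    experiment = factor(sim$design$experiment))
  fb <- head(names(which(fit$fit_method == "fixed-fallback")), 5)
  expect_gt(length(fb), 0)
  for (g in fb) {
    dat$y <- sim$expression[g, ]
    m <- suppressMessages(
      lme4::lmer(y ~ s + t + s:t + (1 | experiment), data = dat, REML = TRUE))
    expect_true(lme4::isSingular(m))
  }
})

test_that("a pure single-factor gene yields a dominant F for that factor", {
  sim <- simulate_expression(sim_config(
    50, prop_sorted = 0.2, prop_treatment = 0, prop_interaction = 0,
    effect_size = 2, noise_sd = 0.1, experiment_sd = 0.3, seed = 41))
  fit <- pwf_fit(sim)
  sorted_genes <- sim$truth$gene[sim$truth$effect_class == "sorted"]
  Fs <- fit$F[sorted_genes, ]
  expect_true(all(Fs[, "sorted"] > 100))
  expect_true(all(Fs[, "sorted"] >
                    10 * pmax(Fs[, "treatment"], Fs[, "interaction"])))
})

test_that("constant genes are flagged degenerate, not errors", {
  sim <- simulate_expression(sim_config(20, seed = 5))
  sim$expression[3, ] <- 7
  fit <- pwf_fit(sim$expression, sim$design)
  g <- rownames(sim$expression)[3]
  expect_true(fit$degenerate[g])
  expect_true(all(is.na(fit$F[g, ])))
  # excluded from rankings and quantile denominator
  r <- pwf_ranking(fit, "sorted")
  expect_false(g %in% r$gene)
  expect_equal(attr(r, "n"), 19L)
  expect_equal(r$rank, 1:19)
})

test_that("F values are invariant to joint sample/design reordering", {
  sim <- simulate_expression(sim_config(30, seed = 6))
  fit1 <- pwf_fit(sim$expression, sim$design)
  perm <- sample(ncol(sim$expression))
  fit2 <- pwf_fit(sim$expression[, perm], sim$design[perm, ])
  expect_equal(fit1$F, fit2$F, tolerance = 1e-10)
})

test_that("type-I error is calibrated on all-null data", {
  sim <- simulate_expression(sim_config(
    2000, prop_sorted = 0, prop_treatment = 0, prop_interaction = 0,
    noise_sd = 0.3, experiment_sd = 0.4, seed = 51))
  fit <- pwf_fit(sim)
  p <- pf(fit$F, 1, fit$residual_df[1], lower.tail = FALSE)
  for (alpha in c(0.05, 0.01)) {
    for (term in colnames(p)) {
      n_sig <- sum(p[, term] < alpha)
      bounds <- qbinom(c(0.005, 0.995), 2000, alpha)
      expect_gte(n_sig, bounds[1])
      expect_lte(n_sig, bounds[2])
    }
  }
})

test_that("without experiment variance, mixed and fixed fits agree", {
  sim <- simulate_expression(sim_config(
    300, prop_sorted = 0.1, experiment_sd = 0, seed = 61))
  fa <- pwf_fit(sim$expression, sim$design, method = "auto")
  ff <- pwf_fit(sim$expression, sim$design, method = "fixed")
  rel <- abs(fa$F - ff$F) / pmax(fa$F, 1e-12)
  expect_true(mean(rel < 0.01) >= 0.95)
})

test_that("unbalanced designs take the lme4 path and match lmer", {
  sim <- simulate_expression(sim_config(12, seed = 71))
  # unbalance: duplicate two samples of experiment e1 with fresh noise
  extra <- sim$expression[, 1:2] + rnorm(2 * nrow(sim$expression), 0, 0.1)
  colnames(extra) <- paste0(colnames(sim$expression)[1:2], "_rep")
  expr <- cbind(sim$expression, extra)
  design <- rbind(sim$design, transform(sim$design[1:2, ],
                                        sample = colnames(extra)))
  fit <- pwf_fit(expr, design)
  dat <- data.frame(
    s = ifelse(design$sorted == "pos", 0.5, -0.5)[match(colnames(expr), design$sample)],
    t = ifelse(design$treatment == "treated", 0.5, -0.5)[match(colnames(expr), design$sample)],
    experiment = factor(design$experiment[match(colnames(expr), design$sample)]))
  for (g in rownames(expr)[1:4]) {
    dat$y <- expr[g, ]
    m <- tryCatch(suppressMessages(
      lme4::lmer(y ~ s + t + s:t + (1 | experiment), data = dat, REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(m) && !lme4::isSingular(m)) {
      tv <- coef(summary(m))[c("s", "t", "s:t"), "t value"]
      expect_equal(unname(fit$F[g, ]), unname(tv^2), tolerance = 1e-6)
      expect_identical(unname(fit$fit_method[g]), "mixed")
    } else {
      expect_identical(unname(fit$fit_method[g]), "fixed-fallback")
    }
  }
})

test_that("input validation catches malformed fits", {
  sim <- simulate_expression(sim_config(10, seed = 8))
  expect_error(pwf_fit(sim$expression[, 1:6], sim$design[1:6, ]),
               "at least 8 samples|experiment")
  bad <- sim$expression; bad[1, 1] <- NA
  expect_error(pwf_fit(bad, sim$design), "non-finite")
  expect_error(pwf_fit(sim$expression, sim$design[rev(seq_len(12)), ]), NA)
})

test_that("fitted, residuals, predict and simulate are mutually consistent", {
  sim <- simulate_expression(sim_config(40, seed = 9))
  fit <- pwf_fit(sim)
  expect_equal(fitted(fit) + residuals(fit), sim$expression, tolerance = 1e-10)
  pr <- predict(fit)
  expect_equal(dim(pr), dim(sim$expression))
  expect_equal(pr, fitted(fit), tolerance = 1e-8, ignore_attr = TRUE)
  y2 <- simulate(fit, seed = 1)
  expect_equal(dim(y2), dim(sim$expression))
  expect_false(identical(y2, sim$expression))
  expect_equal(dim(coef(fit)), c(40L, 3L))
  expect_error(predict(fit, data.frame(experiment = "e9", sorted = "pos",
                                       treatment = "treated")),
               "unknown experiment")
})
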