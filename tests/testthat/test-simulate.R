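test_that("simulation is deterministic and respects the factorial layout", {
  cfg <- sim_config(50, seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$design, b$design)
  expect_identical(a$truth, b$truth)

  # all 4 condition cells in every experiment
  tab <- table(a$design$experiment, a$design$sorted, a$design$treatment)
  expect_true(all(tab == 1L))
  expect_equal(ncol(a$expression), 12L)
  expect_true(all(is.finite(a$expression)))
  expect_false(anyDuplicated(rownames(a$expression)) > 0)

  # seeding does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_expression(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero-noise all-null genes are constant across samples", {
  sim <- simulate_expression(sim_config(
    20, prop_sorted = 0, prop_treatment = 0, prop_interaction = 0,
    noise_sd = 0, experiment_sd = 0, seed = 5))
  expect_true(all(apply(sim$expression, 1, function(x) max(x) - min(x)) == 0))
  expect_true(all(sim$truth$effect_class == "null"))
})

test_that("sorted-class group-mean differences match the generating effect", {
  sim <- simulate_expression(sim_config(
    1000, prop_sorted = 0.1, prop_treatment = 0, prop_interaction = 0,
    effect_size = 2, noise_sd = 0.25, seed = 21))
  pos <- sim$design$sample[sim$design$sorted == "pos"]
  neg <- sim$design$sample[sim$design$sorted == "neg"]
  sorted_genes <- sim$truth$gene[sim$truth$effect_class == "sorted"]
  d <- rowMeans(sim$expression[sorted_genes, pos]) -
    rowMeans(sim$expression[sorted_genes, neg])
  se <- 0.25 * sqrt(1 / 6 + 1 / 6)
  expect_true(mean(abs(abs(d) - 2) <= 3 * se) >= 0.97)
  expect_equal(mean(abs(d)), 2, tolerance = 0.05)
  # signs agree with the recorded signed effect
  eff <- sim$truth$effect_size[match(sorted_genes, sim$truth$gene)]
  expect_true(all(sign(d) == sign(eff)))
})

test_that("interaction-class effect is confined to the pos x treated cell", {
  sim <- simulate_expression(sim_config(
    50, prop_sorted = 0, prop_treatment = 0, prop_interaction = 0.2,
    effect_size = 3, noise_sd = 0, experiment_sd = 0, baseline_mean = 7,
    seed = 3))
  g <- sim$truth$gene[sim$truth$effect_class == "interaction"][1]
  eff <- sim$truth$effect_size[sim$truth$gene == g]
  cell <- sim$design$sorted == "pos" & sim$design$treatment == "treated"
  expect_equal(unname(sim$expression[g, cell]), rep(7 + eff, 3))
  expect_equal(unname(sim$expression[g, !cell]), rep(7, 9))
})

test_that("null-gene sample variance averages to noise_sd^2", {
  sim <- simulate_expression(sim_config(
    10000, prop_sorted = 0, prop_treatment = 0, prop_interaction = 0,
    noise_sd = 0.25, experiment_sd = 0, seed = 31))
  v <- apply(sim$expression, 1, var)
  expect_equal(mean(v), 0.25^2, tolerance = 0.05)
})

test_that("malformed configurations are rejected", {
  expect_error(sim_config(0), "positive count")
  expect_error(sim_config(10, prop_sorted = 0.7, prop_treatment = 0.4),
               "sum to <= 1")
  expect_error(sim_config(10, noise_sd = -1), ">= 0")
  expect_error(sim_config(10, n_experiments = 1), ">= 2")
})

test_that("gene-set simulation plants enrichment and respects bounds", {
  sim <- shared_sim()
  gs <- simulate_gene_sets(sim$truth, n_sets = 10, set_size = 20,
                           n_enriched = 3, seed = 7)
  expect_length(gs$catalog$sets, 10)
  expect_true(all(lengths(gs$catalog$sets) == 20))
  expect_identical(gs$set_truth$enriched, rep(c(TRUE, FALSE), c(3, 7)))
  sorted_genes <- sim$truth$gene[sim$truth$effect_class == "sorted"]
  frac <- vapply(gs$catalog$sets[1:3],
                 function(s) mean(s %in% sorted_genes), 0)
  expect_true(all(frac >= 0.5))  # generator guarantee

  # determinism
  gs2 <- simulate_gene_sets(sim$truth, n_sets = 10, set_size = 20,
                            n_enriched = 3, seed = 7)
  expect_identical(gs$catalog$sets, gs2$catalog$sets)

  # null catalog: no planted sets
  gs0 <- simulate_gene_sets(sim$truth, n_sets = 5, set_size = 10,
                            n_enriched = 0, seed = 8)
  expect_false(any(gs0$set_truth$enriched))

  # singleton sets survive a GMT round trip
  gs1 <- simulate_gene_sets(sim$truth, n_sets = 3, set_size = 1,
                            n_enriched = 0, seed = 9)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs1$catalog, path)
  back <- read_gmt(path)
  expect_identical(back$sets, gs1$catalog$sets)

  expect_error(simulate_gene_sets(sim$truth, 3, 10, n_enriched = 5),
               "exceeds")
  expect_error(simulate_gene_sets(sim$truth, 3, 10^6, 0), "set_size")
})

test_that("ct-table simulation realizes requested fold changes exactly", {
  ct <- simulate_ct_table(c(A = 4, B = 1, C = -2), seed = 1)
  expect_equal(delta_delta_ct(ct, "A", "TMpos")$delta_delta_ct, -2)
  expect_equal(delta_delta_ct(ct, "A", "TMpos")$fold_change, 4)
  expect_equal(delta_delta_ct(ct, "B", "TMpos")$delta_delta_ct, 0)
  expect_equal(delta_delta_ct(ct, "B", "TMpos")$fold_change, 1)
  rc <- delta_delta_ct(ct, "C", "TMpos")
  expect_equal(rc$relative_quantity, 0.5)
  expect_equal(rc$fold_change, -2)
  expect_error(simulate_ct_table(c(A = 0.5)), "\\|fc\\| >= 1")
  expect_error(simulate_ct_table(c(4)), "named")
})
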