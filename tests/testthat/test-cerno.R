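test_that("CERNO statistic matches its closed form and tail oracle", {
  r <- make_ranking(paste0("g", 1:10))
  catalog <- gene_set_catalog(list(top = c("g1", "g2"), worst = "g10"))
  res <- cerno_test(r, catalog)
  S_expected <- -2 * (log(0.1) + log(0.2))
  expect_equal(res$S[res$set == "top"], S_expected, tolerance = 1e-12)
  expect_equal(res$df[res$set == "top"], 4L)
  expect_equal(res$p_value[res$set == "top"],
               chisq_tail_oracle(S_expected, 4), tolerance = 1e-8)
  # all members at the worst rank: S = 0, p = 1
  expect_equal(res$S[res$set == "worst"], 0)
  expect_equal(res$p_value[res$set == "worst"], 1)
})

test_that("members outside the ranking shrink k; empty sets are untestable", {
  r <- make_ranking(paste0("g", 1:10))
  catalog <- gene_set_catalog(list(mixed = c("g1", "absent1", "absent2"),
                                   gone = c("x1", "x2")))
  res <- cerno_test(r, catalog)
  expect_equal(res$k[res$set == "mixed"], 1L)
  expect_true(res$untestable[res$set == "gone"])
  expect_true(is.na(res$p_value[res$set == "gone"]))
  # untestable sets are excluded from the BH family
  expect_true(is.na(res$q_value[res$set == "gone"]))
  expect_equal(res$q_value[res$set == "mixed"],
               res$p_value[res$set == "mixed"])
})

test_that("improving a member's rank increases S and never p", {
  N <- 50
  S_at <- function(rk) -2 * sum(log(rk / N))
  base <- c(10, 20, 30)
  for (better in c(5, 9)) {
    S1 <- S_at(base); S2 <- S_at(c(better, 20, 30))
    expect_gt(S2, S1)
    expect_lte(pchisq(S2, 6, lower.tail = FALSE),
               pchisq(S1, 6, lower.tail = FALSE))
  }
})

test_that("null CERNO p-values are calibrated", {
  N <- 1000; k <- 10; nsets <- 2000
  sets <- withr::with_seed(7, replicate(nsets, sample(N, k), simplify = FALSE))
  names(sets) <- sprintf("s%04d", seq_len(nsets))
  r <- make_ranking(sprintf("g%04d", 1:N))
  catalog <- gene_set_catalog(lapply(sets, function(i) r$gene[i]))
  res <- cerno_test(r, catalog)
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.02)
  ks <- suppressWarnings(ks.test(res$S, pchisq, df = 2 * k))
  expect_gt(ks$p.value, 0.01)
})

test_that("chi-square null is near-exact for discrete ranks and converges", {
  # Exhaustive comparison with the exact subset-permutation distribution.
  # With very few rankable genes the continuous chi-square reference departs
  # from the discrete truth in the extreme upper tail, but always in the
  # conservative direction (chi-square p >= exact p - 0.01); the departure
  # shrinks as the gene universe grows.
  gaps <- function(k, N) {
    r <- make_ranking(sprintf("g%02d", seq_len(N)))
    subsets <- utils::combn(N, k)
    d <- apply(subsets, 2L, function(idx) {
      res <- cerno_test(r, gene_set_catalog(list(s = r$gene[idx])))
      res$p_value - cerno_exact_p(res$S, k, N)
    })
    d
  }
  d_small <- c(gaps(2, 8), gaps(3, 12))
  expect_gte(min(d_small), -0.01)       # never materially anti-conservative
  expect_lte(max(abs(d_small)), 0.15)   # worst-case departure at tiny N
  d_large <- gaps(2, 50)
  expect_lte(max(abs(d_large)), 0.025)  # approximation tightens with N
})

test_that("bh_fdr reproduces hand and brute-force step-up results", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "NA")
  withr::with_seed(11, {
    for (i in 1:50) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
    }
  })
})

test_that("DSM selection honors strict thresholds and nests by quantile", {
  sim <- shared_sim()
  fit <- pwf_fit(sim)
  r <- pwf_ranking(fit, "sorted")
  gs <- simulate_gene_sets(sim$truth, n_sets = 30, set_size = 20,
                           n_enriched = 3, seed = 13)
  res <- cerno_test(r, gs$catalog)
  sel1 <- select_for_dsm(res, r, gs$catalog, set_q_max = 1e-4,
                         gene_quantile_max = 0.05)
  sel2 <- select_for_dsm(res, r, gs$catalog, set_q_max = 1e-4,
                         gene_quantile_max = 0.01)
  expect_true(all(sel2$genes %in% sel1$genes))
  expect_identical(sel1$sets, sel2$sets)

  # planted sets take the smallest q-values
  planted <- gs$set_truth$set[gs$set_truth$enriched]
  expect_setequal(res$set[1:3], planted)

  # boundary semantics: q exactly at the threshold is excluded
  res_b <- res
  res_b$q_value[res_b$set == res$set[1]] <- 1e-4
  sel_b <- suppressWarnings(
    select_for_dsm(res_b, r, gs$catalog, set_q_max = 1e-4))
  expect_false(res$set[1] %in% sel_b$sets)

  expect_warning(sel0 <- select_for_dsm(res, r, gs$catalog,
                                        set_q_max = 1e-30),
                 "empty selection")
  expect_length(sel0$sets, 0)
})
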