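#' Configuration for the factorial expression simulator
#'
#' Describes a `n_experiments` x {pos, neg sorted} x {treated, untreated}
#' expression study on the log2 scale. Genes fall into four effect classes:
#' `sorted` (level-mean difference between sorted groups), `treatment`,
#' `interaction` (effect confined to the pos x treated cell), or `null`.
#' Each experiment contributes an additive random intercept shared by all
#' genes, and i.i.d. Gaussian noise is added to every measurement.
#'
#' Defaults emulate the study conditions the package targets: 3 independent
#' experiments (12 arrays), effects of 2 log2 units, residual noise of
#' 0.25 log2 units (a typical post-normalization residual scale), an
#' experiment-to-experiment intercept spread of 0.5 log2 units and a
#' baseline intensity of 7 log2 units.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_experiments Number of independent experiments (blocks), >= 2.
#' @param prop_sorted,prop_treatment,prop_interaction Proportions of genes in
#'   each effect class; the remainder are null. Must sum to <= 1.
#' @param effect_size Mean absolute effect, log2 units.
#' @param effect_sd Spread of per-gene effect magnitudes, log2 units.
#' @param experiment_sd SD of the per-experiment random intercept, log2 units.
#' @param noise_sd SD of the residual Gaussian noise, log2 units.
#' @param baseline_mean Baseline log2 intensity.
#' @param seed Integer seed; identical configurations reproduce identical data.
#' @return An object of class `"sim_config"`.
#' @seealso [simulate_expression()]
#' @export
sim_config <- function(n_genes, n_experiments = 3L,
                       prop_sorted = 0.05, prop_treatment = 0.05,
                       prop_interaction = 0.02,
                       effect_size = 2, effect_sd = 0,
                       experiment_sd = 0.5, noise_sd = 0.25,
                       baseline_mean = 7, seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stopf("`n_genes` must be a positive count")
  if (!is.numeric(n_experiments) || n_experiments < 2)
    stopf("`n_experiments` must be >= 2")
  props <- c(sorted = prop_sorted, treatment = prop_treatment,
             interaction = prop_interaction)
  if (any(props < 0) || any(props > 1) || sum(props) > 1 + 1e-12)
    stopf("effect-class proportions must lie in [0,1] and sum to <= 1")
  if (effect_sd < 0 || experiment_sd < 0 || noise_sd < 0)
    stopf("standard deviations must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_experiments = as.integer(n_experiments),
                 prop_sorted = prop_sorted, prop_treatment = prop_treatment,
                 prop_interaction = prop_interaction,
                 effect_size = effect_size, effect_sd = effect_sd,
                 experiment_sd = experiment_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d genes, %d experiments x 4 conditions\n",
              x$n_genes, x$n_experiments))
  cat(sprintf("  class proportions: sorted %.3f, treatment %.3f, interaction %.3f, null %.3f\n",
              x$prop_sorted, x$prop_treatment, x$prop_interaction,
              1 - x$prop_sorted - x$prop_treatment - x$prop_interaction))
  cat(sprintf("  effect %.2f (sd %.2f), experiment sd %.2f, noise sd %.2f, baseline %.2f [log2]\n",
              x$effect_size, x$effect_sd, x$experiment_sd, x$noise_sd,
              x$baseline_mean))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate a factorial expression study with ground truth
#'
#' Generates a genes x samples log2 expression matrix under the model
#' `baseline + experiment intercept + class effect + noise`. Sorted-class
#' genes receive +/- effect/2 by sorted level, treatment-class genes by
#' treatment level, and interaction-class genes receive the full effect in
#' the pos x treated cell only (producing the crossed expression pattern
#' characteristic of a pure interaction). Effect signs are random per gene.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"pwf_sim"`: a list with components
#'   `expression` (numeric matrix, genes x samples), `design` (data frame
#'   with columns sample, experiment, sorted, treatment) and `truth`
#'   (data frame with columns gene, effect_class, effect_size).
#' @examples
#' sim <- simulate_expression(sim_config(200, seed = 1))
#' dim(sim$expression)
#' table(sim$truth$effect_class)
#' @export
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("`config` must be a sim_config object")
  with_seed(config$seed, {
    nexp <- config$n_experiments
    design <- expand.grid(sorted = c("pos", "neg"),
                          treatment = c("treated", "untreated"),
                          experiment = sprintf("e%d", seq_len(nexp)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    design <- design[, c("experiment", "sorted", "treatment")]
    design$sample <- sprintf("%s_%s_%s", design$experiment, design$sorted,
                             design$treatment)
    design <- design[, c("sample", "experiment", "sorted", "treatment")]
    n_samp <- nrow(design)

    n <- config$n_genes
    counts <- c(sorted = floor(config$prop_sorted * n),
                treatment = floor(config$prop_treatment * n),
                interaction = floor(config$prop_interaction * n))
    classes <- rep(c(names(counts), "null"),
                   times = c(counts, n - sum(counts)))
    genes <- sprintf("g%0*d", nchar(n), seq_len(n))

    sign_eff <- sample(c(-1, 1), n, replace = TRUE)
    magnitude <- config$effect_size +
      if (config$effect_sd > 0) stats::rnorm(n, 0, config$effect_sd) else 0
    effect <- ifelse(classes == "null", 0, sign_eff * magnitude)

    exp_int <- stats::rnorm(nexp, 0, config$experiment_sd)
    names(exp_int) <- sprintf("e%d", seq_len(nexp))

    codes <- design_codes(design)
    # per-sample multiplier of the gene effect, by class
    mult <- rbind(sorted = codes$s,
                  treatment = codes$t,
                  interaction = as.numeric(codes$s == 0.5 & codes$t == 0.5),
                  null = rep(0, n_samp))
    values <- config$baseline_mean +
      matrix(exp_int[design$experiment], n, n_samp, byrow = TRUE) +
      effect * mult[classes, , drop = FALSE] +
      matrix(stats::rnorm(n * n_samp, 0, config$noise_sd), n, n_samp)
    dimnames(values) <- list(genes, design$sample)

    truth <- data.frame(gene = genes, effect_class = classes,
                        effect_size = effect, stringsAsFactors = FALSE)
    structure(list(expression = values, design = design, truth = truth,
                   config = config),
              class = "pwf_sim")
  })
}

#' @export
print.pwf_sim <- function(x, ...) {
  cat(sprintf("Simulated expression study: %d genes x %d samples (%d experiments)\n",
              nrow(x$expression), ncol(x$expression),
              length(unique(x$design$experiment))))
  print(table(effect_class = x$truth$effect_class))
  invisible(x)
}

#' Simulate a gene-set catalog with planted enrichment
#'
#' Builds `n_sets` gene sets over the simulated gene universe. The first
#' `n_enriched` sets draw at least `enrich_frac` of their members from genes
#' of `enriched_class`; the remaining sets are uniform draws. Set-level
#' ground truth is returned alongside the catalog.
#'
#' @param truth Truth data frame from [simulate_expression()].
#' @param n_sets Number of sets.
#' @param set_size Members per set (must be <= number of genes).
#' @param n_enriched Number of enriched sets (<= `n_sets`).
#' @param enriched_class Effect class enriched sets draw from.
#' @param enrich_frac Fraction of members drawn from the class, >= 0.5.
#' @param seed Integer seed.
#' @return A list with `catalog` (a [gene_set_catalog()]) and `set_truth`
#'   (data frame: set, enriched, class).
#' @export
simulate_gene_sets <- function(truth, n_sets, set_size, n_enriched,
                               enriched_class = "sorted", enrich_frac = 0.7,
                               seed = 1L) {
  if (n_enriched > n_sets)
    stopf("`n_enriched` (%d) exceeds `n_sets` (%d)", n_enriched, n_sets)
  if (set_size > nrow(truth))
    stopf("`set_size` exceeds the number of genes")
  if (set_size < 1) stopf("`set_size` must be >= 1")
  if (n_enriched > 0 && (enrich_frac < 0.5 || enrich_frac > 1))
    stopf("`enrich_frac` must lie in [0.5, 1]")
  genes <- truth$gene
  class_pool <- genes[truth$effect_class == enriched_class]
  n_class <- if (set_size > 1) ceiling(enrich_frac * set_size) else 1L
  if (n_enriched > 0 && length(class_pool) < n_class)
    stopf("not enough '%s'-class genes (%d) to fill enriched sets (need %d)",
          enriched_class, length(class_pool), n_class)
  with_seed(seed, {
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("set%0*d", nchar(n_sets), seq_len(n_sets))
    enriched <- seq_len(n_sets) <= n_enriched
    for (i in seq_len(n_sets)) {
      if (enriched[i]) {
        core <- sample(class_pool, n_class)
        rest <- sample(setdiff(genes, core), set_size - n_class)
        sets[[i]] <- sort(c(core, rest))
      } else {
        sets[[i]] <- sort(sample(genes, set_size))
      }
    }
    desc <- ifelse(enriched, sprintf("planted %s-enriched", enriched_class),
                   "uniform draw")
    names(desc) <- names(sets)
    list(catalog = gene_set_catalog(sets, desc),
         set_truth = data.frame(set = names(sets), enriched = enriched,
                                class = ifelse(enriched, enriched_class, "none"),
                                stringsAsFactors = FALSE))
  })
}

#' Simulate a qPCR Ct table realizing requested fold changes
#'
#' Generates threshold-cycle (Ct) values for a set of target genes and a
#' reference gene in two conditions such that the delta-delta-Ct method
#' recovers the requested signed fold changes (exactly when `noise_sd = 0`).
#' Signed fold changes follow the ratio convention: down-regulation x-fold
#' is written -x, so no magnitude is below 1.
#'
#' @param fold_changes Named numeric vector of signed fold changes
#'   (names are gene ids; every |fc| must be >= 1).
#' @param reference_gene Reference (housekeeping) gene id.
#' @param base_ct Ct of the reference gene, cycles.
#' @param conditions Length-2 character vector: the condition of interest
#'   and the reference condition, in that order.
#' @param target_offset Baseline delta-Ct of targets vs the reference, cycles.
#' @param noise_sd SD of Gaussian noise added to each Ct, cycles.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A `"ct_table"` data frame (gene, condition, ct) with attributes
#'   `reference_gene` and `reference_condition`.
#' @seealso [delta_delta_ct()]
#' @export
simulate_ct_table <- function(fold_changes, reference_gene = "Gapdh",
                              base_ct = 20, conditions = c("TMpos", "TMneg"),
                              target_offset = 5, noise_sd = 0, seed = 1L) {
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes))))
    stopf("`fold_changes` must be a named vector")
  if (any(abs(fold_changes) < 1))
    stopf("signed fold changes must have |fc| >= 1 (down x-fold is written -x)")
  if (length(conditions) != 2L) stopf("`conditions` must have length 2")
  with_seed(seed, {
    genes <- names(fold_changes)
    # relative quantity in condition[1] vs condition[2]
    rq <- ifelse(fold_changes >= 0, fold_changes, -1 / fold_changes)
    # RQ = 2^(-ddCt)  =>  dCt_cond = dCt_ref - log2(RQ)
    d_ct_ref <- rep(target_offset, length(genes))
    d_ct_cond <- d_ct_ref - log2(rq)
    tab <- rbind(
      data.frame(gene = genes, condition = conditions[1L],
                 ct = base_ct + d_ct_cond, stringsAsFactors = FALSE),
      data.frame(gene = genes, condition = conditions[2L],
                 ct = base_ct + d_ct_ref, stringsAsFactors = FALSE),
      data.frame(gene = reference_gene, condition = conditions,
                 ct = c(base_ct, base_ct), stringsAsFactors = FALSE))
    if (noise_sd > 0) tab$ct <- tab$ct + stats::rnorm(nrow(tab), 0, noise_sd)
    rownames(tab) <- NULL
    structure(tab, reference_gene = reference_gene,
              reference_condition = conditions[2L],
              class = c("ct_table", "data.frame"))
  })
}
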