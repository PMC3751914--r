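---
title: "Ranking factorial expression studies by proportion-weighted F"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking factorial expression studies by proportion-weighted F}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwfrank)
```

## The design and the model

pwfrank targets a small but heavily structured design: a 2 × 2 factorial
(a cell-sorting status crossed with a culture treatment) replicated across a
few independent experiments, each experiment contributing one sample per
condition cell. With three experiments this gives twelve arrays. The
experiments are genuine biological replicates — different animals, different
culture batches — and their samples are correlated, so experiment enters
the per-transcript model as a random intercept:

$$y_{gij} = \mu_g + \beta^{s}_g s_i + \beta^{t}_g t_i + \beta^{st}_g s_i t_i
          + b_{gj} + \varepsilon_{gij},
\qquad b_{gj} \sim N(0, \sigma_b^2),\;
\varepsilon_{gij} \sim N(0, \sigma_g^2).$$

`s` and `t` are ±1/2 contrast codes, so each coefficient is directly the
level-mean difference in log2 units, and each of the three fixed terms has
one degree of freedom. The test statistic per term is the Wald F — the
squared t of the coefficient with the residual denominator degrees of
freedom (six, for the twelve-sample design). With 1-df terms, nothing is
gained by nested-model refits, and F = t² holds by construction.
Satterthwaite-style denominator approximations would move p-values slightly
at this sample size; we use plain residual df and report F values, which the
downstream ranking consumes directly, so the choice does not affect ranks.

### Closed-form REML for balanced designs

When every experiment contains every condition cell equally often, the three
contrast columns sum to zero within each experiment: they are within-block
contrasts, orthogonal to the block (experiment) space. Two consequences
follow exactly, not approximately:

* the GLS estimates of the three term coefficients equal their OLS estimates
  with experiment as fixed blocks, for *any* value of the variance ratio;
* their Wald F statistics under the random-intercept model equal the F
  statistics from that fixed-blocks OLS.

Only the intercept feels the random effect. The between-experiment variance
component is still estimated (from the block-mean mean square) to detect
boundary fits: transcripts whose estimate is non-positive are flagged
`fixed-fallback`, the refit-with-fixed-blocks contract — numerically
identical F values here, but an honest label for "no usable between-
experiment variance". This identity is what makes the permutation stage
practical: all genes are fit in one vectorized pass (a single QR per
design), and 500 label permutations of 1 000 genes take seconds rather than
the hours that per-gene iterative mixed fits would need. The identity is
verified against `lme4::lmer` in the test suite (agreement to the
optimizer's ~1e-4 relative precision for interior fits). Unbalanced designs
fall back to per-gene `lme4` fits automatically.

Constant (zero-variance) transcripts are flagged degenerate: they get no F
values, are excluded from every ranking, and do not count toward the
quantile denominator `N` — quantiles describe rankable genes only.

## Proportion-weighted F

Ranking by raw F does not isolate transcripts that respond to a *single*
factor. The proportion-weighted F multiplies each term's F by that term's
share of the transcript's total:

$$\mathrm{PWF}_t(g) = F_t(g)\cdot
  \frac{F_t(g)}{F_{s}(g)+F_{t}(g)+F_{st}(g)}.$$

Three properties (tested exhaustively over random F triples) justify it:
PWF never exceeds F; the per-gene sum of PWF across terms never exceeds the
largest F (a transcript cannot be "top everywhere"); and the leading term
under PWF is always the leading term under F. A transcript with all its
signal in one factor keeps essentially its full F for that factor; one whose
F is split in a 9:1 ratio keeps 81% and 1% respectively. When all three F
values are zero, PWF is defined as zero. Ranks are descending in PWF with
lexicographic gene-id tie-breaks, which makes every downstream artifact
byte-reproducible across platforms.

## Permutation-null envelopes

Significance of the PWF-by-rank curves is judged against label permutations.
Two decisions are deliberate:

* **Permutation scope.** The (sorted, treatment) label pairs are permuted
  *within* each experiment block. Global permutation would also destroy the
  block structure that the model conditions on and make the null too easy.
  Within-block permutation of a balanced design stays balanced, so every
  permuted fit takes the fast path. (Whether the original analysis permuted
  within or across experiments is not stated; this is our interpretation,
  and the conservative one.)
* **Alignment by rank, not by gene.** Each permutation's PWF values are
  sorted descending and aggregated position-wise: the envelope is a null
  distribution of *curves*. The 95th percentile uses the nearest-rank
  estimator (the ⌈0.95 n⌉-th order statistic), which avoids interpolation
  ambiguity and is reproducible by inspection.

Both envelope curves are non-increasing in rank, because order statistics of
sorted curves inherit monotonicity. Under a fully null dataset the observed
curve is simply one more draw from the null, so it exceeds the 95th-
percentile curve at about 5% of ranks *in expectation*; because exceedances
are strongly correlated along the curve, the realized fraction for any one
dataset is variable (roughly ±5 percentage points), which is worth knowing
before reading too much into a single null comparison. Permutations that
would leave a condition cell globally empty are rejected and redrawn
(impossible for balanced blocks, counted in `n_rejected` otherwise).

## CERNO enrichment and FDR

The set statistic is the Fisher combination of rank fractions,
$S = -2\sum_{i \in \text{set}} \ln(r_i / N)$, referred to $\chi^2_{2k}$.
The source analysis names the idea (coincident extreme ranks) without
printing the formula; this is the canonical definition from the cited
methodology. Members absent from the ranking are dropped from `k`; sets
with `k = 0` are flagged untestable and excluded from the BH family (the
family is all testable sets of one catalog, corrected separately per term).
BH adjustment is the standard step-up via `p.adjust`; an independent
brute-force implementation serves as the oracle in the tests.

For realistic catalogs the chi-square null is accurate (type-I error within
±0.02 of nominal at `N = 1000`). With very few rankable genes the discrete
rank distribution departs from the continuous reference in the extreme
upper tail — by up to ~0.13 at `N = 8–12`, shrinking to ≤ 0.025 by
`N = 50` — but always in the conservative direction (never anti-conservative
by more than 0.01). The tests pin down exactly these measured bounds.

Selection for the design structure matrix is two-stage and strict: sets
with `q < 1e-4`, then genes in at least one selected set with PWF quantile
`< 0.01` (display variant: `< 0.001`). Equality at a threshold excludes.

## Design structure matrix and clustering

The membership matrix (sets × genes, 1 iff the gene belongs to the set) is
ordered on both axes by agglomerative clustering with **average linkage** on
**Canberra distances** of the membership vectors. Three sub-decisions:

* The distance is implemented from its definition
  $d(u,v)=\sum_i |u_i-v_i|/(|u_i|+|v_i|)$ with both-zero coordinates
  contributing 0. Base R's `dist(method = "canberra")` rescales the sum by
  `n/n_nonzero` when coordinates are dropped, which changes values on sparse
  binary data; on inputs without both-zero coordinates the two agree to
  machine precision (tested). On binary vectors the definition reduces to
  Hamming distance over coordinates not both zero.
* Linkage is not stated in the source; average linkage is the conventional
  default for binary membership profiles and is what we fix.
* Genes are clustered on their membership columns, not on expression —
  the matrix being ordered *is* the membership structure. The companion
  heat map of expression uses per-gene Z-scores (`zscore_matrix()`, mean 0
  / sd 1 per row), the usual display scaling.

`hclust` leaf order is deterministic for a given distance matrix, so
repeated runs reproduce identical figures.

## Validation arithmetic

Fold changes follow the signed-ratio convention (down x-fold written −x; no
magnitudes in (−1, 1)), with `signed_fold_change()` /
`fold_change_to_log2()` an exact inverse pair. The delta-delta-Ct chain
(ΔCt per condition against the housekeeping gene, ΔΔCt across conditions,
relative quantity $2^{-\Delta\Delta Ct}$) recovers generator-requested fold
changes to machine precision at zero noise — the generator and validator are
inverse by construction, which the tests enforce.

The cross-platform regression transforms both platforms' signed fold
changes to signed log10 magnitudes (continuous through ±1 → 0 because of
the ratio convention), averages multiple probe values that map to one qPCR
measurement, drops not-determined pairs, and fits OLS of qPCR on
microarray. On the bundled 14-pair validation table this yields slope 1.56
and R² 0.52; excluding the IL-10 pair — whose qPCR value is a >150-fold
outlier against a 1.4-fold microarray value — gives R² 0.787. The published
figure for this comparison reports slope 0.99, intercept 1.16, R² 0.79: the
R² is reproduced exactly by the IL-10-excluded fit, while no pairing or
log-base convention we examined reproduces the slope/intercept pair
(slope is invariant to the common log base; swapped axes give ≈ 0.5;
magnitude-only regression gives slope 0.93 but R² 0.41). We therefore treat
the printed equation's axes as being in units not recoverable from the
printed table, keep the stated convention as the package's definition, and
report both fits. Direction-of-change concordance on the same table flags
exactly one microarray/qPCR disagreement (TNF-α). Against the protein
arrows, the table as printed implies discordance for CCR5, CD206, IL-10 and
both MHC II loci; we report what the table implies and do not special-case
CCR5 even though the source narrative lists only three.

The phosphoprotein filter is multiplicative and symmetric: a ratio passes
the x% threshold iff it exceeds `1 + x/100` or falls below `1/(1 + x/100)`,
both strict. A subtractive lower bound (`1 - x/100`) would treat up- and
down-changes asymmetrically on a ratio scale.

## The synthetic generator: what it emulates, what it does not

`simulate_expression()` reproduces the statistical skeleton the analysis
assumes: the factorial design with per-experiment additive intercepts
shared across genes, gene classes driven by exactly one term (sorted and
treatment effects as ±effect/2 level shifts; interaction effects confined
to the pos × treated cell, which produces the crossed
"effect-of-treatment-only-in-one-subpopulation" pattern), and i.i.d.
Gaussian noise on the log2 scale. Defaults are fixed at the study scale:
3 experiments (12 arrays), effect 2 log2 units, residual sd 0.25 log2 units,
experiment sd 0.5, baseline 7 — values a microarray analyst would call
typical for RMA-scale data. One sample per condition per experiment is
assumed (the source does not state within-culture replication).

It deliberately does **not** model: probe-level effects or RMA itself,
mean–variance trends, heavy-tailed or outlier noise, correlated gene
modules beyond the planted classes, or array-level artifacts. Passing
recovery tests therefore demonstrates that the chain of statistics behaves
as designed under its own assumptions — not that those assumptions hold for
any particular real dataset.

## Numerical choices and problem sizes

* Tie-breaks: descending PWF, then lexicographic gene id; CERNO consumes
  final integer ranks, so ties cannot reach it.
* Degenerate inputs: constant transcripts are flagged, never errors;
  zero-variance rows *are* errors in `zscore_matrix` (a heat map of a flat
  row is undefined) and name the offending gene.
* Threshold boundaries are strict everywhere (`>` fold, `<` p, `<` q,
  `<` quantile), matching the printed filter definitions.
* All writers emit a `# pwfrank <kind> tsv v1` header line; readers skip
  `#` comments; ranks are serialized at full precision and quantiles are
  recomputed on read.
* Test and acceptance problem sizes — 1 000 genes × 12 samples × 500
  permutations for envelopes, 10⁴ null sets for CERNO calibration, 10⁵
  random triples for the PWF properties — are the package's chosen standard
  verification scale: large enough for the binomial tolerances quoted above,
  small enough that the whole suite runs in well under a minute for the
  deterministic parts and a few minutes end to end.

## Known limitations

* The residual-df Wald F is anti-conservative relative to
  Kenward–Roger/Satterthwaite corrections when the between-experiment
  variance is large and the design small; rankings are unaffected, absolute
  p-values should be read with that in mind.
* The one-way ANOVA miRNA filter ignores the experiment blocking and is
  therefore conservative in the presence of block effects (the blocks
  inflate its denominator); with the strict `p < 1e-4` and two-fold
  thresholds this only makes the filter stricter.
* CERNO's chi-square reference is continuous; with fewer than a few dozen
  rankable genes its extreme tail is conservative by up to ~0.13 (see
  above).
* The permutation envelope summarizes curve-level behavior; it does not
  provide per-gene permutation p-values, by design.
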