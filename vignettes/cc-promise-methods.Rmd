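---
title: "Integrated two-omics endpoint association: model, statistics, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated two-omics endpoint association: model, statistics, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccpromise)
```

## The problem

Studies that collect two forms of molecular data (say, DNA methylation
and mRNA expression) together with several biologically related clinical
endpoints face two integration problems at once: the two molecular data
types must be related to each other, and both must be related to all
endpoints jointly. The common "list overlap" shortcut — intersecting the
top hits of separate per-endpoint, per-data-type analyses — has no
single significance statement per gene and loses power rapidly as lists
multiply.

`ccpromise` addresses both problems at the gene level. For each gene
$g$ with expression features $x_{gf}$ ($f = 1, \dots, F_g$) and
methylation markers $m_{gl}$ ($l = 1, \dots, L_g$):

1. **Canonical correlation** summarises the two blocks. CCA finds the
   linear combinations of the (standardized) expression columns and
   methylation columns that are maximally correlated, giving the
   canonical correlation $\tilde r_g$ and a pair of per-sample scores
   $\tilde x_{gi}, \tilde m_{gi}$, each scaled to unit variance.
2. **Projection onto the most interesting evidence.** For a molecular
   variable $v$ (a score or a single feature) and endpoints
   $k = 1, \dots, K$, let $a_k(v)$ be a rank-based association
   statistic of $v$ with endpoint $k$ on a correlation-like scale
   ($\pm 1$ = deterministic association). A predefined direction
   $\lambda = (\lambda_1, \dots, \lambda_K)$ encodes which joint sign
   pattern of associations is biologically interesting; the composite
   statistic is the projection
   $t(v) = \sum_k \lambda_k\, a_k(v)$.
3. **Combination.** The gene-level combined statistic adds the two
   score projections with the sign of their correlation:
   $t^\* = t(\tilde x_g) + \mathrm{sign}(\tilde r_g)\, t(\tilde m_g)$.
   After score orientation (below) that sign is $+1$. `sign(0) = 0` by
   mathematical convention, dropping the methylation term in the
   measure-zero case of exactly uncorrelated blocks.
4. **Adaptive permutation.** All significance statements come from
   permuting the assignment of endpoint rows to molecular rows, with
   early stopping, and with one shared permutation stream for every
   statistic of a dataset.

## Association statistics and endpoint kinds

All statistics live on a correlation-like scale so they can share one
projection:

* **quantitative / ordinal** endpoints: Spearman correlation, average
  ranks for ties;
* **binary** endpoints: Spearman correlation with the 0/1 indicator (a
  rank-biserial form);
* **censored time-to-event** endpoints: minus the Spearman correlation
  of the variable with the null-model martingale residuals (event
  indicator minus Nelson–Aalen cumulative hazard at the observed time),
  so positive values mean higher values go with longer survival. The
  residuals are computed once from the observed endpoint; as a set they
  are invariant under sample permutation, which keeps this statistic
  inside the fast permutation path.

Unordered categorical endpoints with more than two levels are rejected
with an explanatory error: a composite statistic built on a
correlation-like scale needs a direction of association, which an
unordered factor does not have. The packages' applications use
ordered, binary, or survival endpoints.

Each endpoint declares a `direction_sign` ($\pm 1$) that makes an
"interesting" association positive (e.g. $-1$ for a drug-resistance
endpoint where smaller is better). The evidence direction is then
$\lambda_k = \text{sign}_k / \text{sign}_1$, fixing $\lambda_1 = +1$ by
symmetry. By default entries are scaled by $1/K$ (`normalized = TRUE`),
which keeps $|t| \le 1$ for single-source statistics and $|t^\*| \le 2$;
permutation p-values are invariant to this scaling, so it is purely a
reporting convention that keeps gene-level statistics comparable across
endpoint panels of different size.

## Missing data

The handling rules are deliberately simple and local:

* molecular features with any missing value are dropped from that
  gene's CCA (complete case per gene — CCA needs complete blocks);
* samples missing a given endpoint are excluded pairwise from that
  endpoint's association statistic only;
* a missing per-endpoint statistic contributes zero evidence to the
  projection (with a warning), keeping $t$ defined when one endpoint is
  partially observed.

When every endpoint is fully observed the permutation loop runs through
a batched rank-crossproduct path; with missing endpoint values it falls
back to an explicit per-permutation recomputation with pairwise
deletion, which is slower but applies exactly the same definitions.

## Score orientation

Canonical score pairs are defined only up to a joint sign flip, which
would make the sign of $t(\tilde x_g)$ arbitrary. The package fixes a
canonical form: expression scores are flipped, if needed, to correlate
non-negatively with the mean standardized expression column (exact zero
correlation: no flip), then methylation scores are flipped so the two
score vectors correlate non-negatively. The combined statistic's sign
multiplier is therefore $+1$. This orientation is this package's
resolution of an ambiguity the combined-statistic definition leaves
implicit; tests assert it is a canonical form (orientation after any
sign flip gives identical output).

## Adaptive permutation

With observed statistic $t_0$, permutations $b = 1, 2, \dots$ are
scanned counting $|t_b| \ge |t_0|$ (with a relative tolerance of
$10^{-12}$ against floating-point ties). The scan stops at $B_0$
exceedances (default 100) or $B_1$ permutations (default 10,000), and
$p = \text{exceedances}/\text{performed}$: reaching 100 exceedances at
permutation 200 reports $p = 0.50$ and stops. A clearly null gene
therefore costs $\approx B_0/p$ permutations instead of $B_1$. Two
details worth noting:

* when *no* permutation exceeds — possible only for an extreme $t_0$ —
  the count is floored at 1, so $p \ge 1/B_1$ and p-values are never 0;
* the permutation unit is the joint endpoint row: all $K$ endpoint
  values of a sample move together, preserving the endpoint–endpoint
  correlation under the null. The molecular side is never permuted, so
  the canonical weights and scores (functions of molecular data only)
  are fitted once and never refitted inside the loop.

The stream is generated in fixed blocks of 512 permutations whose seeds
derive from (stream seed, block index), so permutation $b$ is
addressable without replaying earlier draws and is identical for every
statistic regardless of where each stops — the property that makes the
seven per-gene p-values (below) comparable.

## The method family

For each gene the package reports, from one shared stream:

| summary | definition |
|---|---|
| CCPR | combined-statistic p of the canonical score pair |
| UXPR / UMPR | min over features of the per-feature projection p (expression / methylation) |
| AXPR / AMPR | min Bonferroni-adjusted per-feature p |
| UOV / AOV | max of the two unadjusted / adjusted single-source summaries |

The unadjusted minimum-p summaries are intentionally anti-conservative
(they ignore the number of features) and serve as negative controls in
the calibration study. The overlap rules sit at the other extreme: they
reject only when *both* single-source summaries reject at once, so
their null rejection rate is near the product of two level-$\alpha$
events — they control the level but are markedly conservative. Genome-wide results are reported as raw
permutation p-values together with the expected-false-discovery count
(threshold × number of genes) rather than an imposed FDR procedure.

## The simulation generator

The generator emulates one gene measured on $n$ subjects with $L = 10$
methylation markers, $F = 2$ expression features and $K = 2$
quantitative endpoints:

$$m_1 \sim N(0,1), \quad m_l = \beta_m m_{l-1} + e, \quad
x_j = \beta_x m_j + e, \quad y_j = \beta_y x_j + e,$$

all innovations $e$ independent standard normal. $\beta_y = 0$ is the
null of no molecular–endpoint association. The chain is *not*
variance-stationary: marker variances propagate as
$\mathrm{var}(m_l) = 1 + \beta_m^2 \mathrm{var}(m_{l-1})$ from
$\mathrm{var}(m_1) = 1$, and the package's moment checks use these
exact per-index variances rather than a stationarity approximation
(closed forms in `theoretical_moments()`). Both endpoints are
concordant by construction, so the simulations use
$\lambda = (1, 1)/2$. The full study grid crosses
$\beta_m, \beta_x, \beta_y \in \{-0.5, -0.3, 0, 0.3, 0.5\}$ with
$n \in \{30, 50, 100, 500\}$ — 500 settings, 100 of them null.

What the generator does *not* emulate about real data: bounded
methylation beta-values, heavy-tailed expression intensities, batch
effects, endpoint missingness, and genes whose two data blocks have
heterogeneous within-block correlation structure. Passing calibration
and power checks on this generator therefore demonstrate correctness of
the statistical machinery under its stated model, not robustness to
array artefacts — the rank-based statistics provide the latter only
qualitatively.

Per-replicate seeds derive from (master seed, replicate index), so any
single replicate is reproducible in isolation and grid runs checkpoint
and resume per setting.

## Numerical choices

* CCA whitening truncates singular values below $10^{-8}$ relative to
  the largest (columns with variance below $10^{-12}$ are dropped
  first), giving pseudoinverse behaviour for rank-deficient or
  many-marker genes.
* The CCA significance test is Bartlett's chi-square approximation to
  Wilks' Lambda over the retained ranks. It is asymptotic and assumes
  approximate normality; the package treats it as a descriptive
  gene-level screen, while all projection statistics use permutation
  p-values.
* Ties are averaged in every rank computation, making results
  deterministic.
* Exceedance comparisons use a $10^{-12}$ relative tolerance so that
  permutations reproducing $t_0$ exactly (e.g. the identity) count as
  exceedances regardless of floating-point noise.

## Problem sizes used in the shipped checks

The package's test suite estimates type I error at the global null
($n = 100$) with 1000 replicates and power at the $n = 500$
strong-autoregression settings with 500 replicates (the Monte-Carlo
standard error at a power of 0.35 and 500 replicates is about 0.021,
so the checks use a ±0.07 band); the power-ordering check at
$\beta_m = \beta_x = \beta_y = 0.5$, $n = 100$ uses 500 replicates.
These sizes were chosen so the whole suite runs comfortably on a
laptop while keeping Monte-Carlo noise well inside the asserted
tolerances.

## Known limitations

* Only the first canonical pair is used; genes whose second canonical
  direction carries the endpoint association will be summarised
  sub-optimally.
* The canonical score is chosen to correlate with the *other molecular
  block*, not with the endpoints. When the endpoints load on a single
  feature, the score dilutes that feature and the best single-feature
  test can out-power the score-level analysis; the integrated analysis
  earns its power when the endpoint signal is spread across the block.
  The sign structure of the generator makes this concrete: with a
  negative marker autoregression the two endpoints' evidence partially
  cancels in every statistic, and the integrated analysis loses least.
* Covariate adjustment and stratified association statistics are out of
  scope, as are sparse or multi-block CCA extensions.
* The evidence direction $\lambda$ is prior knowledge, not estimated
  from data; a misspecified direction costs power by construction
  (the projection is linear in the per-endpoint statistics).
* With very small samples ($n < 10$) the permutation space is small;
  `exact_reference_pvalue()` enumerates it and is the better tool
  below $n = 8$.
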