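---
title: "Methods behind the allomacro pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the allomacro pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`allomacro` implements a complete comparative-phylogenetics workflow for
allometric scaling studies: estimating the scaling exponent of a trait
(metabolic rate) on body mass across species while correcting for shared
ancestry and within-species measurement error, and then characterising the
macroevolutionary dynamics of the traits with explicit models of adaptive
regimes. This vignette explains the statistical machinery behind each stage
and the reasoning behind the package defaults. For a quick tour, see the
README; every stage is an ordinary exported function, so the pipeline can be
run whole (`run_pipeline()`) or piecemeal.

## Species summaries and measurement error

Allometry data arrive as one row per individual. `summarize_species()`
collapses them to per-species means of log10 mass and log10 metabolic rate,
together with the *sampling variances of those means* (`s^2 / n`). Species
measured once cannot supply a within-species variance, so theirs is imputed
as the pooled within-species variance over species with `n >= 2` and flagged
in `var_imputed`.

Measurement error in the predictor attenuates regression slopes. The package
offers two complementary corrections:

* **Reliability division.** The classical errors-in-variables result says the
  expected naive slope is the true slope times the reliability (repeatability)
  of the predictor. `repeatability_icc()` estimates the intraclass correlation
  by the one-way ANOVA estimator with Lessells & Boag's `n0` correction for
  unequal group sizes, and `attenuation_correct()` divides the observed slope
  by it.
* **Ives-style measurement-error PGLS.** `fit_pgls_ives()` iterates the
  generalized-least-squares slope
  `beta = x'W y / (x'W x - sum(W_ii) * vx)` with
  `W = [sigma^2 V(lambda) + diag(vy + beta^2 vx)]^{-1}`, where `vx`, `vy` are
  the per-species sampling variances. The subtraction in the denominator is
  the bias correction: without it the estimator would inherit the usual
  attenuation. Confidence intervals come from a parametric bootstrap.

## PGLS with profile Pagel's lambda

`fit_pgls()` fits `y = X beta + e`, `e ~ N(0, sigma^2 V(lambda))`, where `V`
is the phylogenetic variance-covariance matrix of the (pruned) tree and
`lambda` multiplies its off-diagonals. `beta` and `sigma^2` have closed-form
profiles, leaving a one-dimensional likelihood search over `lambda` in
`[0, 1]`. On ultrametric trees the code exploits a single eigendecomposition
of `V` so the profile costs one `O(n^2)` pass per `lambda` value. Variants:
a mean-centred quadratic mass term (curvilinear allometry) and a grouping
factor that adds intercept and slope contrasts (phylogenetic ANCOVA with
interaction). A grouping level needs at least two species; with a single
species its intercept and slope offsets are collinear, and `fit_pgls()`
refuses rather than return an unidentifiable fit.

`pagel_lambda_signal()` applies the same machinery to a single trait
(intercept-only design) and reports the ML `lambda` with a likelihood-ratio
test against `lambda = 0`.

## Discrete regimes: Mk models and stochastic character maps

Behavioural regimes (e.g. perchers versus fliers) are modelled as a binary
continuous-time Markov chain. `fit_mk()` computes the likelihood by
Felsenstein pruning with per-node rescaling, under four transition
structures: equal rates, all rates different, and the two irreversible
models. `fit_mk_models()` fits all four and assigns Akaike (AICc) weights.

`stochastic_map()` draws full character histories *exactly* (no rejection):
internal node states come from their joint conditional distribution computed
inside-out, and within-edge paths from uniformization bridges conditioned on
the edge's endpoint states. Under a model set, each map picks its generating
model with probability equal to the model's Akaike weight, so mapped
quantities are automatically model-averaged. The summary painting assigns
each edge its modal midpoint state across maps; it is a display/refit
convenience and is deliberately *not* constrained to reproduce the tip states
on terminal edges whose histories flip near the tip.

## Continuous-trait models: multi-rate BM and multi-optimum OU

Regime paintings (`regime_painting` objects) map every instant of every edge
to a regime, either from stochastic maps or from hypothesised shift points
(`painting_from_shifts()`).

`fit_bm()` fits Brownian motion with one diffusion rate per regime; the trait
covariance is `sum_r sigma2_r V_r`, where `V_r` is the shared path time in
regime r (the `V_r` add up exactly to the ordinary `V`). Root state and
overall scale are profiled analytically.

`fit_ou()` fits Hansen's multi-optimum Ornstein-Uhlenbeck model with a
common pull `alpha` and diffusion `sigma2`. The expected tip values are
regime-history weights that decay exponentially with `alpha`, computed
segment-exactly so mid-edge transitions from stochastic maps are honoured.
Two root treatments are available: `"stationary"` (the root is a draw from
the root regime's stationary distribution; the natural choice for ultrametric
trees) and `"fixed"` (the root is clamped at the root regime's optimum; this
is the parameterisation whose `alpha -> 0` limit is exactly BM). Optima and
scale are profiled, leaving a one-dimensional search over `log(alpha)`.
`half_life()` converts `alpha` to the phylogenetic half-life `ln(2)/alpha`,
and `compare_models()` ranks any collection of BM/OU fits by AICc, refusing
to compare fits that were not given identical data.

## Reversible-jump shift detection

`run_rjmcmc_trait()` samples the number, placement and values of
adaptive-optimum shifts without predefining regimes. The prior is: shift
count `k` from a conditional (truncated, renormalised) Poisson with mean 1;
given `k`, the shifts occupy `k` distinct edges with probability proportional
to the product of edge lengths (at most one shift per branch) and uniform
position within the edge; Normal priors on optima; half-Cauchy priors on
`alpha` and `sigma2`. Placement normalising constants use elementary
symmetric polynomials of the edge lengths, so birth/death acceptance ratios
are exact. `run_rjmcmc_allometry()` is the same sampler where each regime
carries an intercept *and a mass slope*, so it hunts for shifts in the
allometry itself.

Practical notes:

* `iterations` is **per chain**; at least two chains are required because the
  convergence report (split-free R-hat, clamped at 1, and Geyer
  initial-positive-sequence effective sample sizes) needs them.
* Every retained sample's likelihood is the exact multi-optimum OU density;
  the test suite cross-checks sampled states against the standalone
  `ou_loglik()` on the equivalent painting.
* **Identifiability caveat for validation studies.** Two shift
  configurations can produce identical likelihoods: if the planted shifts
  cover a whole root-child clade (or sibling edges whose union is one), a
  relabelling of the background optimum is an exact posterior mode with a
  different `k`. Simulation studies that plant shifts should put them on long
  internal edges in *different* root clades, subtending moderate clades with
  a sizeable sibling clade left over. Under null (shiftless) data, note that
  the conditional Poisson(1) prior puts equal mass on `k = 0` and `k = 1`
  while a vacuous shift's Bayes factor is near 1, so the posterior mode is
  close to a coin flip between 0 and 1 by construction; per-branch posterior
  probabilities stay diffuse and are the quantity to monitor.

## Phylogenetic path analysis

`causal_dag()` declares candidate causal structures; `basis_set()` derives
one conditional-independence claim per non-adjacent node pair (conditioning
on the union of the pair's parents, regressing the later node in topological
order so the tested coefficient is causally oriented). Each claim is tested
by profile-lambda PGLS, combined by Fisher's `C = -2 sum(log p)` (chi-squared
with `2 * #claims` df under the model), and ranked by the small-sample
criterion `CICc = C + 2 q n / (n - 1 - q)` with `q` = edges + nodes.
`rank_and_average()` conditionally averages standardized path coefficients
over the `delta CICc <= 2` supported set with renormalised weights.

## The synthetic study generator

`simulation_config()` encodes a study-shaped generator: a Yule tree scaled to
237 MY with 63 species; a binary behaviour regime simulated with exact
transition times; species-level true log10 mass by BM (`x_sigma2 = 0.5^2/237`
gives a tip standard deviation of 0.5, i.e. about 3 orders of magnitude of
mass range across the clade); true log10 metabolic rate as
`intercept + slope * mass + OU deviation`, with the OU optima differing by
behaviour regime; and individual rows with independent within-species noise
on both axes. The OU defaults follow the same logic:
`ou_alpha = log(2)/1256.5` (a half-life around five tree heights, i.e. weak
pull) and `ou_sigma2 = 7e-5`, chosen so the stationary standard deviation
`sqrt(sigma2/(2 alpha)) ~ 0.25` — residual deviations of about a quarter of
a log10 decade around the allometry, comparable to the regime optimum
difference (0.15). Every stochastic stage derives its seed deterministically
from the study seed via `derive_seed()`, so a config reproduces its report
bit for bit.

## Running the pipeline

The "CLI" is a pair of functions: `run_config()` validates the inputs and
`run_pipeline()` executes the stages, returning a `run_report` whose pieces
are the ordinary fit objects described above; `generate_report()` serialises
the headline numbers (JSON), the main tables (TSV) and a plain-text summary.

```{r pipeline}
library(allomacro)
cfg <- run_config(
  synthetic = simulation_config(seed = 1),
  stages = c("summarize", "allometry", "residuals", "signal",
             "repeatability", "outliers", "regimes", "macroevol", "rjmcmc"),
  seed = 1
)
report <- run_pipeline(cfg)
generate_report(report, "run1")
```

Real data enter through the same gate: `run_config(tree = "study.nwk",
traits = "individuals.tsv", ...)`, with optional `tip_substitutions` to map
congeneric stand-ins onto the tree's tip labels and `min_n` to drop sparsely
measured species.
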