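# allomacro

Comparative phylogenetics for allometric scaling studies: phylogenetic
regression with measurement-error correction, discrete-regime modelling with
stochastic character maps, multi-optimum Ornstein–Uhlenbeck (OU) fitting,
reversible-jump MCMC detection of adaptive shifts, and phylogenetic path
analysis — plus a synthetic study generator and a reproducible pipeline that
strings the stages together.

Everything is tidyverse-shaped: functions take and return tibbles, fits are
S3 objects with `tidy()`, `glance()`, `autoplot()` and `print()` methods, and
trees are ordinary `ape::phylo` objects.

## Worked example

Simulate a study at the default scale (63 species, a 237-MY tree, 10
individuals per species, a percher/flier behavioural regime), then walk the
analysis by hand. All numbers below are the actual output of this code.

```r
library(allomacro)

study <- simulate_allometry_study(simulation_config(seed = 1))
s <- summarize_species(study$data)   # per-species means + sampling variances

pgls <- fit_pgls(s, study$tree)      # profile-lambda PGLS of log10 SMR on mass
pgls
#> <gls_fit> method: pgls (lambda = 0.603)
#> # A tibble: 2 × 7
#>   term        estimate std_error conf_low conf_high statistic  p_value
#>   <chr>          <dbl>     <dbl>    <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept)    -4.54    0.0970   -4.73      -4.35     -46.7 1.76e-49
#> 2 x               1.09    0.0715    0.946      1.23      15.2 2.04e-22
```

The generator's true slope is 1.0 with intercept −4.33; the naive PGLS slope
(1.09, CI 0.95–1.23) covers it. Correct for within-species sampling error in
both variables with the iterative Ives estimator:

```r
fit_pgls_ives(s, study$tree, nboot = 200, seed = 2)
#> <gls_fit> method: pgls_ives (lambda = 0.740)
#> # A tibble: 2 × 7
#>   term        estimate std_error conf_low conf_high statistic   p_value
#>   <chr>          <dbl>     <dbl>    <dbl>     <dbl>     <dbl>     <dbl>
#> 1 (Intercept)    -4.46   NA        NA         NA         NA   NA
#> 2 x               1.16    0.0799    0.982      1.31      14.5  2.02e-47
```

Or benchmark attenuation with the repeatability (intraclass correlation) of
the predictor:

```r
repeatability_icc(study$data, body_mass_g, log10_transform = TRUE)
#> # A tibble: 1 × 6
#>   var_among var_within    n0     R k_groups     N
#>       <dbl>      <dbl> <dbl> <dbl>    <int> <int>
#> 1    0.0358     0.0106    10 0.772       63   630
```

Fit the Mk model set to the behavioural states and draw model-averaged
stochastic character maps:

```r
tips <- setNames(study$truth$behaviour, study$truth$species)
mk <- fit_mk_models(study$tree, tips)
mk$table
#> # A tibble: 4 × 6
#>   model     k logLik  AICc delta_AICc   weight
#>   <chr> <dbl>  <dbl> <dbl>      <dbl>    <dbl>
#> 1 ER        1  -25.4  52.9      0     0.571
#> 2 ARD       2  -24.7  53.6      0.683 0.406
#> 3 IRR12     1  -28.6  59.3      6.42  0.0230
#> 4 IRR21     1  -32.8  67.6     14.8   0.000355

maps <- stochastic_map(study$tree, tips, mk, n_maps = 100, seed = 3)
maps$mean_transitions
#> [1] 12.42
```

Compare macroevolutionary models on the mass-independent SMR residuals —
Brownian motion, single-optimum OU, and behaviour-regime OU over the mapped
regimes:

```r
r <- mass_independent_residuals(s, study$tree)
resid <- setNames(r$residual, r$species)
compare_models(list(
  BM  = fit_bm(resid, study$tree),
  OU1 = fit_ou(resid, study$tree),
  OUM = fit_ou(resid, study$tree, painting = maps$summary_painting)
))
#> # A tibble: 3 × 6
#>   model     k logLik   AICc delta_AICc    weight
#> * <chr> <dbl>  <dbl>  <dbl>      <dbl>     <dbl>
#> 1 OU1       3   61.6 -117.        0    0.737
#> 2 OUM       4   61.7 -115.        2.06 0.263
#> 3 BM        2   50.3  -96.4      20.4  0.0000268

glance(fit_ou(resid, study$tree))
#> # A tibble: 1 × 9
#>   model  alpha   sigma2 half_life stationary_variance logLik  AICc     k     n
#>   <chr>  <dbl>    <dbl>     <dbl>               <dbl>  <dbl> <dbl> <dbl> <int>
#> 1 OU    0.0285 0.000577      24.3              0.0101   61.6 -117.     3    63
```

Hunt for adaptive-optimum shifts without pre-specifying regimes (here a quick
run; the defaults are longer):

```r
post <- run_rjmcmc_trait(resid, study$tree, iterations = 5000, thin = 10,
                         burn_in = 0.3, chains = 2, seed = 4)
post
#> <shift_posterior> trait flavour: 700 retained samples
#> k median 1.0 (95% HPD 0-3); 0 branch(es) with pp >= 0.2
```

No strongly supported shifts — consistent with the model comparison above:
the generator's regime effect (optima 0.15 apart) is small relative to the
OU stationary spread, and single-optimum OU already won on AICc. `autoplot(post)` draws the per-branch
posterior shift probabilities and the posterior of the shift count.

Finally, compare causal orderings by phylogenetic path analysis:

```r
rank_and_average(list(
  mass_to_smr = causal_dag("mean_x -> mean_y"),
  smr_to_mass = causal_dag("mean_y -> mean_x")
), s, study$tree)$table
#> # A tibble: 2 × 9
#>   model           C     q     n model_p  CICc delta_CICc weight supported
#>   <chr>       <dbl> <dbl> <dbl>   <dbl> <dbl>      <dbl>  <dbl> <lgl>
#> 1 mass_to_smr     0     3    63       1  6.41          0    0.5 TRUE
#> 2 smr_to_mass     0     3    63       1  6.41          0    0.5 TRUE
```

(Both saturated two-node models fit equally — d-separation cannot orient a
single edge; it discriminates structures with testable independencies.)

The whole analysis can be run as one reproducible pipeline instead:

```r
cfg <- run_config(synthetic = simulation_config(seed = 1),
                  stages = c("summarize", "allometry", "residuals", "signal",
                             "repeatability", "outliers", "regimes",
                             "macroevol", "rjmcmc"),
                  seed = 1)
report <- run_pipeline(cfg)
generate_report(report, "run1")   # writes report.json, TSV tables, summary.txt
```

Real data enter the same way, from files:
`run_config(tree = "study.nwk", traits = "individuals.tsv", ...)`.

See `vignette("allomacro-methods")` for the statistics behind each stage.

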