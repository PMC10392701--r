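# wqs2i — two-index weighted quantile sum regression

Environmental and nutritional epidemiology increasingly asks about the
joint effect of an exposure *mixture* — dozens of correlated chemicals or
nutrients — rather than one exposure at a time. Weighted quantile sum
(WQS) regression summarizes a mixture by a single empirically weighted
index of quantile-scored exposures, but a single index can point in only
one direction. When a mixture contains both harmful and protective
components, `wqs2i` estimates the two directions *jointly*:

    g(mu) = beta0 + beta1p * sum_i( w_pi * q_i )
                  + beta1n * sum_i( w_ni * q_i ) + z' phi

with `beta1p >= 0`, `beta1n <= 0`, and each weight vector on the simplex
(`w_i >= 0`, `sum w_i = 1`, parameterized as `w_i = v_i^2 / sum(v^2)`).
Weights are estimated on training splits by minimizing the GLM loss plus
an L1 shrinkage penalty on the unit-normalized raw weight parameters
(`lambda * sum sqrt(w_i)` per index), averaged over a bootstrap ensemble
with collinearity-tolerance signal weights `(tol_b / sum tol)^k`
(tolerance = 1/VIF of the index in that bootstrap's joint model), and the
final model is fitted on held-out validation data. The whole two-step
procedure is repeated over `H` random splits and summarized by medians
and 95% percentile intervals. Components whose median weight exceeds
`1/c` are reported as carrying the mixture effect.

The package also provides the standard single-index WQS estimator, an
AIC-based rule for the shrinkage parameter, quantile g-computation as a
comparator (directional sums of per-component GLM coefficients), a
synthetic-data generator for correlated exposure mixtures, and a
simulation benchmark measuring bias, sensitivity and specificity of all
estimators against a known truth.

## Worked example

Simulate a 38-component nutrient-style mixture (exchangeable correlation
0.4) whose outcome is driven by a positive index (weight 0.5 on sodium,
smaller weights on polyunsaturated fat, cholesterol, caffeine, calcium)
and a negative index (led by magnesium), then fit the two-index model:

```r
library(wqs2i)

corr <- build_correlation(list(type = "exchangeable", rho = 0.4, c = 38))
d    <- simulate_dataset(corr, default_truth(), n = 1000, seed = 2024)
df   <- data.frame(y = d$y, d$Q, check.names = FALSE)

fit <- wqs2i(y ~ 1, df, mixture = colnames(d$Q), lambda = 10,
             H = 10, B = 10, seed = 1)
summary(fit)
```

```
Two-index weighted quantile sum regression
n = 1000, 38 components (q = 4), lambda = 10, H = 10, B = 10
   term  median   lower   upper n_splits significant
 beta1p  0.4837  0.2803  0.5435       10        TRUE
 beta1n -0.5287 -0.6338 -0.3486       10        TRUE

Components with median weight above 1/c = 0.026:
  positive index: sodium (0.356), null_11 (0.100), polyunsaturated_fat (0.090),
    calcium (0.074), null_8 (0.039), cholesterol (0.027)
  negative index: magnesium (0.154), vitamin_B6 (0.066), beta_carotene (0.063),
    null_4 (0.053), vitamin_E (0.049), vitamin_D (0.048), fiber (0.048), ...
```

Both generating coefficients (0.5 and −0.5) are recovered by the median
estimates with 95% percentile intervals excluding 0, and the leading true
components head both weight lists (at `n = 1000` with `H = B = 10` a few
null components also clear the low `1/c` cutoff; larger `n`, `H` and `B`
clean this up). `coef()`, `predict()`, `plot()` (weight box-plots with the
`1/c` cutoff line), `residuals()` and `simulate()` methods are available,
and `wqs2i(lambda = "aic")` selects the shrinkage parameter
automatically. Lower-level building blocks (`fit_single_wqs()`,
`fit_two_index_bootstrap()`, `run_repeated_holdout()`, `fit_qgcomp()`,
`run_benchmark()`) are exported, and `run_wqs_pipeline()` plus the thin
script in `inst/cli/` drive the same analyses from a JSON/YAML config.

See the vignette in `vignettes/two-index-wqs.Rmd` for the model, the
estimation pipeline, and every numerical design choice.

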