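# ribart

Causal inference for **multiple treatments on clustered, right-censored
survival outcomes**, for analysts working with registry or multi-site
observational data (patients nested in hospitals, subjects nested in
centres) who want treatment effects on interpretable survival scales plus
a principled account of unmeasured confounding.

## The model

`ribart` fits a random-intercept accelerated failure time model whose
regression function is a Bayesian sum of trees (BART):

```
log T_ik = f(A_ik, X_ik) + b_k + eps_ik,
b_k  ~ N(0, alpha * tau^2),   eps_ik ~ N(0, sigma^2),
f(A, X) = sum_{h=1}^{H} g(A, X; W_h, M_h)
```

for subject *i* in cluster *k* with treatment `A` (J >= 2 arms) and
covariates `X`. The trees learn nonlinearities and treatment-covariate
interactions; the random intercepts absorb institutional variation; a
redundant scale `alpha` (parameter expansion) keeps the variance updates
well mixed. Right censoring is handled inside the Gibbs loop by imputing
latent log failure times from truncated normal conditionals.

Treatment effects are posterior conditional average treatment effects:
per posterior draw *d*,

```
CATE_d(a_j, a_j') = (1/N) * sum_ik [ f_d(a_j, x_ik) - f_d(a_j', x_ik) ]
```

on the log-time scale, with survival-probability and restricted-mean
survival time (RMST) versions at a horizon `t*` (default 60 months)
computed through the lognormal survival curve
`S(t) = 1 - Phi((log t - f - b_k) / sigma)`.

A confounding-function sensitivity analysis quantifies how conclusions
move under individual-level unmeasured confounding: per ordered arm pair,
a function `c(a_j, a_j')` bounded by `omega` residual SDs shifts each
subject's log time by its propensity-weighted correction, and the model
is refit over a nested grid of Q1 propensity-score draws x Q2
confounding-function draws, pooling all posterior draws.

A simulation engine generates the reference design: 10 mixed-type
confounders, random-intercept multinomial treatment assignment calibrated
to a 6:3:1 allocation, Weibull counterfactual outcomes under proportional
or non-proportional hazards, and exponential censoring calibrated to a
target proportion (10%/40%).

## Worked example

```r
library(ribart)

# a clustered trial from the reference design: 10 clusters of 100,
# 10% censoring, proportional hazards
cfg <- dgp_config(K = 10, n_k = 100)
set.seed(5); cfg$xi0 <- calibrate_intercepts(cfg)
sim <- simulate_trial(cfg, censoring = 0.1, seed = 7)

fit <- riaft_bart(sim$data, n_burn = 250, n_draws = 500, H = 50, seed = 1)
for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
  ct <- estimate_cate(fit, p, scale = "rmst", t_star = 60)
  cat(sprintf("pair %s-%s est %.2f [%.2f, %.2f] truth %.2f\n", p[1], p[2],
      ct$estimate, ct$ci[1], ct$ci[2], sample_true_cate(sim, p, "rmst", 60)))
}
```

prints

```
pair 1-2 est 6.72 [5.24, 8.49] truth 6.78
pair 1-3 est 2.93 [0.50, 5.05] truth 3.12
pair 2-3 est -3.79 [-6.20, -1.37] truth -3.66
```

i.e. the posterior mean difference in 5-year restricted mean survival
between arms 1 and 2 is 6.72 months (95% credible interval 5.24 to 8.49),
against a closed-form truth of 6.78 months for this replicate; all three
pairwise intervals cover their truths. `estimate_cate(fit, c(1, 2))`
gives the same contrast in expected log survival months, and
`run_sensitivity()` reports how the estimates move under postulated
unmeasured confounding.

A thin command-line interface wraps the same functions:

```sh
inst/cli/ribart simulate --k 10 --nk 100 --seed 7 --out sim_out
inst/cli/ribart fit --data sim_out/simulated.csv --seed 1 --out fit_out
inst/cli/ribart cate --fit fit_out/fit.rds --pair 1,2 --scale rmst
```

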