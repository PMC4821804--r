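# conflearn

Perceptual learning without external feedback, modelled as
reinforcement learning on an internally generated teaching signal:
**confidence**. `conflearn` is an R package for researchers in
computational cognitive neuroscience and psychophysics who want to
simulate, fit and analyse this learning account end to end at desk
scale.

## The model in brief

An observer judges whether a noise-embedded Gabor patch is tilted
clockwise (cw) or counterclockwise (ccw) of a reference axis. Each
stimulus is reduced to two normalised orientation energies
E<sub>cw</sub>, E<sub>ccw</sub>, pooled by decision units through
*signal* weights (same orientation) and *noise* weights (opposite
orientation):

    A_ccw = E_ccw * w_ccw,ccw + E_cw * w_cw,ccw
    A_cw  = E_cw  * w_cw,cw  + E_ccw * w_ccw,cw
    DV    = A_cw - A_ccw

Choices follow a softmax on the decision value, `p(cw) = 1 / (1 +
exp(-beta * DV))`; reported confidence is a censored Gaussian around the
decisional certainty `c' = lambda * |DV|`. Learning needs no external
feedback: a *confidence prediction error* `delta = c - c_bar` — the gap
between this trial's confidence and a Rescorla–Wagner running average
`c_bar` of past confidence — gates a three-factor (Hebbian ×
reinforcement) update of the two connections into the chosen unit:

    w_i,choice <- w_i,choice + alpha_w * delta * E_i * A_choice

Better-than-expected confidence strengthens the circuitry that produced
the percept; worse-than-expected confidence weakens it. Signal weights
drift up and noise weights down, improving contrast thresholds with
practice.

The package implements the full study analogue around this core:
Gabor-in-noise stimulus synthesis, a quadrature-filter orientation
energy front end, weighted one-up/two-down adaptive staircases (holding
performance at 80.35% correct), a two-stage maximum-likelihood fitting
procedure, a synthetic-observer experiment generator (pre-test, nine
48-trial training runs with an interleaved constant-contrast condition,
post-test), and the summary analyses: confidence–performance
calibration curves, run-wise weight and threshold slopes, perceptual
learning indices, Fisher-z group tests, simulated BOLD time courses and
model-based parametric regressors.

## Worked example

Simulate a learning observer through the whole experiment, summarise
its weight trajectories, and refit the generating model from its
behaviour alone:

```r
library(conflearn)

obs <- observer_spec(true_params = model_params(alpha_w = 0.02))
ex  <- simulate_experiment(obs, experiment_design(), seed = 11)
ex
#> <experiment> 634 trials (432 training); trained axis: vertical
#> # A tibble: 4 × 4
#>   session   axis       threshold n_trials
#>   <chr>     <chr>          <dbl>    <int>
#> 1 pre_test  vertical        5.08       40
#> 2 pre_test  horizontal      3.94       35
#> 3 post_test vertical        4.50       37
#> 4 post_test horizontal      7.58       42

training <- dplyr::filter(ex$trials, session == "training")
training$signal <- (training$w_ccw_ccw + training$w_cw_cw) / 2
training$noise  <- (training$w_ccw_cw + training$w_cw_ccw) / 2
slope_per_run(training, "signal")$slope   # 0.00623  (rises)
slope_per_run(training, "noise")$slope    # -0.00177 (falls)

curve <- confidence_performance_curve(training, window_fraction = 0.05)
cor(curve$confidence, curve$prop_correct, method = "spearman")
#> 0.72   # confidence tracks accuracy

fitdat <- normalize_energies(dplyr::select(training, -E_ccw, -E_cw),
                             "session_max")
fit <- fit_subject(fitdat, w0 = c(0.5, 0.1), n_restarts = 6, seed = 1)
tidy(fit)
#> # A tibble: 7 × 2
#>   term      estimate
#> 1 alpha_w     0.0196   # generated at 0.02
#> 2 alpha_c     0.195
#> 3 beta       11.1      # generated at 10
#> 4 lambda      2.89     # generated at 3
#> 5 sigma_c     0.199    # generated at 0.2
#> 6 w0_signal   0.5
#> 7 w0_noise    0.1
```

The staircase mathematics is available analytically:

```r
equilibrium_performance(0.5488, n_down = 2)
#> 0.8035304   # the 80.35%-correct convergence point of the task
```

`autoplot()` methods exist for calibration curves and BOLD time
courses, plus `plot_stimulus()`, `plot_staircase()` and
`plot_weight_trajectories()`; `run_pipeline()` chains cohort
simulation, the two fitting stages and all analyses into one
reproducible bundle with a seed/hash manifest.

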