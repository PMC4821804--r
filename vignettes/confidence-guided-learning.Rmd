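---
title: "Confidence-guided reinforcement learning for perceptual learning without feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-guided reinforcement learning for perceptual learning without feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflearn)
```

## The scientific problem

Perceptual learning — the slow improvement of performance in demanding
visual tasks with practice — reliably occurs even when observers receive
no external feedback about their accuracy. Classical reinforcement
learning cannot explain this: there is no reward signal to propagate.
`conflearn` implements a computational account in which observers
generate their *own* teaching signal by monitoring decision confidence.
Trials that feel more confident than usual act like positive feedback
and strengthen the sensory read-out that produced them; trials that feel
less confident than usual weaken it.

The package provides every stage of a desk-scale study of this idea:
stimulus synthesis (oriented Gabor patches embedded in bandpass noise),
an orientation-energy front end, the trial-by-trial learning model,
adaptive contrast staircases, maximum-likelihood model fitting, a
synthetic-observer generator standing in for human participants, and the
summary analyses (confidence calibration, weight trajectories, learning
indices, simulated BOLD time courses).

## The model

On each trial the stimulus is reduced to two normalised orientation
energies, $E_\mathrm{cw}$ and $E_\mathrm{ccw}$, one per candidate
orientation. Two decision units pool them through a 2×2 weight matrix
with *signal* weights (same-orientation connections) and *noise* weights
(opposite-orientation connections):

$$A_\mathrm{ccw} = E_\mathrm{ccw} w_{\mathrm{ccw,ccw}} + E_\mathrm{cw} w_{\mathrm{cw,ccw}},
\qquad
A_\mathrm{cw} = E_\mathrm{cw} w_{\mathrm{cw,cw}} + E_\mathrm{ccw} w_{\mathrm{ccw,cw}}.$$

Their difference is the decision value $DV = A_\mathrm{cw} -
A_\mathrm{ccw}$. Choices follow a softmax rule,
$p(\mathrm{cw}) = (1 + e^{-\beta\, DV})^{-1}$, and the model's internal
confidence — *decisional certainty* — is $c' = \lambda\,|DV|$. Reported
confidence is a censored Gaussian around $c'$ with SD $\sigma_c$:
reports of exactly 0 or 1 carry the corresponding tail mass, so the
likelihood is a proper mixed distribution on $[0,1]$.

Learning is driven by the *confidence prediction error* (CPE)
$\delta = c - \bar c$, where $\bar c$ is a running (Rescorla–Wagner)
average of past confidence, $\bar c \leftarrow \bar c + \alpha_c\,\delta$.
The weights into the *chosen* decision unit are updated by a three-factor
(Hebbian × reinforcement) rule:

$$w_{i,\mathrm{choice}} \leftarrow w_{i,\mathrm{choice}}
  + \alpha_w\, \delta\, E_i\, A_\mathrm{choice}, \qquad i \in \{\mathrm{cw}, \mathrm{ccw}\}.$$

High-confidence trials ($\delta > 0$) strengthen the connections that
produced the choice in proportion to how strongly detector and decision
unit co-activated; low-confidence trials weaken them. Because
high-energy designated-orientation trials produce both large $|DV|$
(hence positive $\delta$) and large Hebbian products, signal weights
drift up and noise weights down on average — without any external
feedback. Within a trial the order is: activities → $DV$ → choice and
confidence → $\delta$ against the *pre-update* $\bar c$ → weight update →
$\bar c$ update (`update_order = "delta_first"`; the alternative
ordering is exposed as `"cbar_first"`). Expected confidence is carried
continuously across runs by default; passing the returned state back
into `run_session()` (or a `reset`) makes either convention available.

### Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `alpha_w` | weight learning rate | 0.0018 | cohort median scale of the task; ≥ 0 |
| `alpha_c` | confidence learning rate | 0.533 | Rescorla–Wagner rate in [0, 1] |
| `beta` | softmax inverse temperature | 10 | chosen so the default observer is ~80% correct at 8% contrast |
| `lambda` | certainty scaling | 3 | puts typical certainty mid-scale (~0.4–0.6) |
| `sigma_c` | confidence report noise SD | 0.2 | confidence units (scale is [0, 1]) |
| `w0_signal`, `w0_noise` | initial weights | 0.5, 0.1 | signal > noise: a weakly informative initial read-out |

`c_bar0` (initial expected confidence) defaults to mid-scale 0.5 and is
configurable.

### Identifiability

Two structural facts matter when fitting. First, the likelihood is
*exactly* invariant under scaling all four weights by $k$ while dividing
$\beta$ and $\lambda$ by $k$ — so initial weights are identified only up
to this equivalence class, which is why the group stage
(`fit_group_initial_weights()`) is judged by the pooled likelihood it
attains rather than by a pointwise weight recovery, and why the
per-subject stage fixes the weights. Second, $\alpha_c$ (and $\bar c$)
enters the likelihood *only* through the weight trajectory: at
$\alpha_w = 0$ the likelihood is perfectly flat in $\alpha_c$. For
near-median learners (432 trials, $\alpha_w \approx 0.002$) the total
log-likelihood range across the whole $\alpha_c$ interval is well below
one unit, so $\alpha_c$ is effectively unidentifiable at single-subject
scale; $\beta$, $\lambda$ and $\sigma_c$, by contrast, recover with rank
correlations above 0.9 in the package's recovery tests. The acceptance
suite states these checks at face value, and the recovery limits are a
property of the model class, not of the optimiser.

## Stimuli and orientation energy

`stimulus_spec()` fixes the stimulus physics: luminance
$L(x,y) = \big(1 + \tfrac{c_p}{100} G(x,y) + \tfrac{c_n}{100} N(x,y)\big) L_0$
with a unit Gabor $G$ (spatial frequency 1.25 cyc/deg, envelope SD 0.6
deg, phase 0.25 cycles, i.e. carrier phase $\pi/2$; values below 0.005
trimmed), bandpass noise $N$ and background $L_0 = 51.9$ cd/m². The noise
is built per the literal recipe: the difference of two order-3
Butterworth low-pass filters with cut-offs one octave below and above
the carrier (0.625 and 2.5 cyc/deg) is used directly as the Fourier
magnitude, combined with i.i.d. uniform phases, inverse-transformed, DC
zeroed, and standardised to unit peak so that the noise contrast is a
peak contrast like the Gabor's (a `"sd"` standardisation is available;
no published normalisation exists). A radial window
$W(r) = \big(1 + (2 \cdot 0.275\, r)^{14}\big)^{-1}$ — the "inverse
Butterworth" aperture, half-amplitude at 1.82 deg — fades the patch into
the background, with a hard crop at 2.5 deg. Note the envelope-threshold
closed form gives a trimmed Gabor radius of
$\sigma\sqrt{2\ln 200} = 1.95$ deg; both the trim level and the aperture
parameters are exposed.

The energy front end (`build_filter_bank()`, `orientation_energy()`) is
a quadrature-pair Gabor energy model: per orientation × frequency
channel, a cosine- and a sine-phase zero-DC kernel (half-amplitude
bandwidth 1 octave by default) are convolved with the
contrast-normalised image, squared, summed, and pooled over space (sum
by default, max available). This honours the published contract of the
original multi-layer V1 toolbox — raw image in, location-tolerant
unnormalised energy per channel out — without reproducing its internals
version-exactly; pooling operator and bandwidth are configuration
because no published values exist. Energies are normalised per session
by the session maximum when fitting (`normalize_energies()`), or by a
fixed calibration constant in generative mode, where a session maximum
would be acausal.

## Staircases

Threshold sessions run a two-phase staircase in 16-trial blocks with
alternating reference axes: a coarse one-up-one-down phase with 0.05
log-unit steps from 20% contrast, switching after 3 reversals to a
weighted one-up-two-down phase (down step 0.33 contrast points, down/up
ratio 0.5488), terminating at the 9th reversal. The weighted phase's
equilibrium solves $p^2\,s_\downarrow = (1-p^2)\,s_\uparrow$, giving
$p = (1/(1+0.5488))^{1/2} = 0.8035$ — the procedure holds observers at
80.35% correct. Reversals are counted over both phases by default
(`reset_reversals_at_switch` flips the convention, which the source
leaves open); every change of movement direction counts as a reversal;
the threshold estimate is the mean of weighted-phase reversal contrasts,
a field-standard estimator the source does not specify. A free-running
configuration (`terminate_at_reversal = Inf`, weighted start) serves the
continuously adaptive training condition.

## The synthetic observer

No behavioural data are deposited, so `observer_spec()` +
`simulate_experiment()` generate the full study analogue: pre-test
thresholds on both axes, an adjustment run, nine 48-trial training runs
on the trained axis — staircase-controlled trials holding performance at
80.35% interleaved with a constant-contrast condition on half the trials
(fixed at the adjustment run's final staircase contrast) — and a
post-test. Choices and confidence always come from the generating model
with learning on; read-out weights are kept separately per reference
axis (orientation-specific learning), while expected confidence is a
single observer-level quantity shared across axes.

Trial-wise energies use a rectified-Gaussian surrogate instead of the
image pipeline: designated-orientation raw energy
$\sim \max(0, \mathcal N(0.2 + g\,c_p,\ 0.15))$, opposite-orientation
$\sim \max(0, \mathcal N(0.2,\ 0.15))$. The gain $g = 0.0525$ was set
once by bisection so the default observer scores ≈ 80% correct at 8%
contrast (the mean training contrast regime), and the generative
normalisation constant 1.067 is the fixed-point expected session maximum
of a 432-trial stream there, keeping generative and fitting energy
scales within a few percent. Event timings draw the 2000 ± 1000 ms
fixation and post-stimulus intervals uniformly over the stated ranges
(no distribution is published) and response durations from a log-normal
around the reported median response time.

What the surrogate does *and does not* emulate matters for interpreting
green tests: it reproduces the energy–correctness asymmetry, the
confidence–accuracy calibration, and axis-specific threshold learning as
*consequences of the model's own decision rule*, but its psychometric
function is shallower than a typical human's, its energies are
independent across trials (no slow drifts or fatigue), and it contains
no lapses, response times, or eye movements. In particular the
9-reversal staircase estimate carries ~3 percentage points of
measurement noise for this observer — dominated by where the coarse
phase happens to stop — so single-simulation pre/post threshold
differences are noisy even when learning is real; run-averaged
quantities (weight slopes, in-training contrast decline) are the stable
readouts. A slow-path check in the test suite confirms the surrogate's
designated > opposite energy ordering against energies computed from
actually synthesised images. Large weight learning rates
($\alpha_w \gtrsim 0.03$ at these scales) destabilise the model:
certainty saturates the confidence scale, prediction errors stay
positive, and noise weights grow until discrimination degrades — a
regime the simulator exposes rather than hides.

## Fitting

`negative_log_likelihood()` runs the model in conditioned mode — the
observed choices and confidence reports drive the updates — and sums the
softmax choice log-likelihood and the censored-Gaussian confidence
log-likelihood (interior densities floored at $10^{-300}$ before the
log; non-finite values return a large penalty so optimisers never see
`NaN`). The sequential recursion is implemented in compiled code; the R
primitives reproduce it exactly and serve as the independent oracle in
the tests. `fit_subject()` estimates the five free parameters with
Nelder–Mead in transformed space (log for positive parameters, logit for
$\alpha_c$), restarted from Latin-hypercube draws (10 by default,
relative tolerance $10^{-8}$, iteration cap 2000), keeping the best
restart. `fit_group_initial_weights()` implements the two-stage scheme's
first stage: shared initial weights estimated on the pooled data with
per-subject nuisance parameters profiled by alternating optimisation
(two sweeps by default, then a final per-subject pass at the returned
weights, which the second stage consumes).

## Analyses

`confidence_performance_curve()` slides a window of 5% of all trials
(step: one trial — only the window size is published) across
confidence-sorted trials and reports proportion correct per window.
`perceptual_learning_index()` regresses threshold improvements on
pre-test thresholds and returns the (negated) zero-mean residuals, so
larger values mean more learning than the baseline predicts — the sign
convention is stated in the output header. `slope_per_run()` fits
run-mean trajectories; `fisher_z_group_test()` is the
$z' = \operatorname{atanh}(r)$ one-sample group test.
`simulate_bold()` builds the three outcome scenarios (positive, absent,
negative prediction error) as impulse vectors on a 10 Hz grid from −4 s
to +20 s around stimulus onset (+1 anticipation at trial onset, −2 s;
±1/0 at stimulus onset) convolved with a canonical double-gamma HRF
(response peak 6 s, undershoot 16 s, dispersions 1, ratio 6, unit peak —
the standard parameter set, since the source defers to a package
default; shape assertions are therefore qualitative: peak window and
deflection sign). `build_parametric_regressors()` constructs the two
model-based regressors — expected confidence at trial onsets, CPE at
stimulus onsets — mean-centred, HRF-convolved, sampled at TR = 2 s.

## Numerical and design notes

* Image grid: centre at (0, 0) degrees, x rightward, y downward, pixel
  centres at half-integer offsets; 300 px over 5.3 deg.
* Out-of-range luminances (possible at extreme contrast mixtures) clip
  to zero with a warning.
* Stimulus PNG export is 16-bit grayscale with a JSON sidecar carrying
  the spec and luminance scaling; a built-in encoder is used because the
  available raster writers emit 8-bit only.
* All simulation entry points take integer seeds; cohort seeds fan out
  deterministically from a master seed and every dataset is
  bit-reproducible from (spec, design, seed).
* Problem sizes in the shipped tests are the package's study-analogue
  choices: 432-trial training sessions, cohorts of 8–30 synthetic
  subjects, 20-seed simulation batches, 100-seed staircase convergence
  runs.

## Limitations

The package is a modelling workbench, not an fMRI analysis suite: it
simulates BOLD predictions and builds regressors but does not estimate
GLMs on volumes, and the multivariate decoding, ROI and group-inference
machinery of the original study are out of scope. Parameter recovery
results should be read with the identifiability caveats above; the
synthetic observer is a deliberately simple surrogate whose green tests
certify the pipeline's internal consistency, not human behaviour.
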