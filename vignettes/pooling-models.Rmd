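---
title: "Population pooling models of crowded orientation matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pooling models of crowded orientation matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdpool)
```

## The model

`crowdpool` simulates a crowded orientation-matching trial in three stages.

**Stage 1 — population response.** A bank of orientation channels at 1°
spacing covers the circular axis [−180°, 180°). The noiseless response of
the bank to a stimulus at orientation $\mu$ is a Gaussian tuning profile
$r(\theta) = \alpha\,e^{-d(\theta,\mu)^2 / 2\sigma^2}$ with circular
distance $d$, peak height $\alpha = 1$ and bandwidth $\sigma = 30°$,
matching the orientation selectivity of V1 neurons. Gaussian noise is added
to this profile: the target response receives noise of magnitude
`early_noise` and, on flanked trials, the flanker response receives noise
of magnitude `late_noise`. Trials are simulated on the error axis — the
target sits at 0°, the flankers at the condition's offset (+30° or +90°
after sign folding) — so the decided orientation *is* the response error.

**Stage 2 — pooling.** Crowding is the weighted channelwise combination
$y_c = (1-w_f)\,y_t + w_f\,y_f$. Because the data show weaker interference
at 90° than at 30° target–flanker differences, the flanker weight is free
per condition (`wf30`, `wf90`), giving the four-parameter pooling model;
a three-parameter variant shares one weight across both conditions. The
rival noise-only model has no pooling stage: flanked trials add a fresh
noise field of magnitude $\beta$ to the target response,
$y_c = y_t + \beta\eta$, ignoring the flanker identity entirely.

**Stage 3 — readout.** The perceived orientation is the channel with the
maximal combined activity; exact ties are broken uniformly at random so the
readout carries no directional bias. With moderate weights this architecture
produces the two signature regimes: at 30° offsets the two broad profiles
merge into a unimodal bump whose peak lies *between* target and flankers
(assimilation), and at 90° offsets the profiles stay separate, so noise
flips the global maximum between the two modes (substitution mixed with
correct reports).

## The noise field

The model description leaves the structure of the additive noise open, and
the choice matters: independent noise per channel makes the argmax readout
depend on the channel spacing (finer grids give more chances for a stray
channel to win), and at realistic magnitudes it swamps the signal, pushing
every condition toward uniform errors. We therefore draw i.i.d. standard
normal values per channel, circularly convolve them with the (unit-peak)
Gaussian tuning kernel, and standardize the result back to unit per-channel
SD before scaling. The noise field is then smooth at the tuning bandwidth —
grid-independent, as if it entered before the tuning stage — and the noise
magnitudes are expressed in units of the tuning-curve peak: `early_noise =
0.45` means the noise SD is 45% of the unflanked peak response. At the
representative magnitudes (early ≈ 0.45, late ≈ 1) this yields the narrow
unflanked distributions, shifted unimodal 30° distributions, and bimodal 90°
distributions that motivate the model, with a small uniform floor of distant
errors caused by occasional remote noise bumps outcompeting the signal.

One consequence of the smooth field worth knowing: in the *noiseless* 90°
condition the two pooled modes sit at 1° and 89°, not exactly 0° and 90°,
because each Gaussian's tail tilts the opposite peak slightly inward. The
package's tests compare readouts against a dense-grid analytic oracle
rather than idealized mode positions.

## Error statistics

Errors are circular differences `response − target` wrapped to (−180°,
180°]. Mirror-image conditions (±30°, ±90°) produce mirror-symmetric
distributions, so errors in negative-offset conditions have their sign
reversed before the conditions are merged (`fold_trials()`), leaving three
analysis conditions: unflanked, f30, f90. Histograms use 36 bins of 10°,
half-open on the left, with +180° wrapping into the [−180°, −170°) bin.
For small datasets — children contribute only 24 folded trials per crowded
condition — a three-point circular boxcar average smooths the data
histogram before fitting (`fit_matching_table()` applies it automatically
at ≤ 50 folded trials per crowded condition; model histograms are never
smoothed). The data–model discrepancy is the least-squares error on bin
*proportions*, summed over the three conditions, which keeps 12–100-trial
data comparable to 1,000-trial model simulations.

## Fitting

The objective simulates `sim_n = 1000` trials per condition at the
candidate parameters, bins them, and returns the summed squared difference
from the data proportions. Because the objective is stochastic, each fit
fixes one seed and reuses the same noise fields for every evaluation
(common random numbers), making the objective a deterministic, piecewise-
constant function of the parameters that grid search and simplex descent
can minimize meaningfully.

* **Coarse stage.** A full-factorial grid: early noise 0.1–1.5 in steps of
  0.2 (to 2.5 for children's wider range), late noise 0.2–3.0 in steps of
  0.4 (to 4.2 for children), weights 0–1 in steps of 0.1. The least-squares
  error is additive over conditions and the unflanked term depends only on
  the early noise, so the factorial minimum is computed by decomposition —
  identical result (including first-in-lexicographic-order tie-breaking) at
  a fraction of the evaluations.
* **Refinement.** Nelder–Mead from the grid best (`stats::optim`), with
  weights clamped to [0, 1] and noise magnitudes to ≥ 0 inside the
  objective, plus a penalty proportional to the excursion so the simplex is
  steered back rather than stopped. The refined fit never reports a worse
  value than its initialization.
* **Comparison.** Models are scored with the least-squares AIC,
  $n\ln(\mathrm{LSE}/n) + 2k$ with $n = 108$ bins (3 conditions × 36).
  Only AIC *differences* between models fitted to the same data are
  interpreted. A perfect (zero-LSE) fit — possible only for degenerate
  noiseless data — degenerates to −∞ and is reported with a warning.
* **Reporting.** `model_envelope()` re-runs the fitted model to give the
  mean curve and the 95% range of simulated histograms across 1,000
  iterations of 1,000 trials. The per-iteration histogram of an
  independent-trials simulation is exactly a multinomial draw on the
  model's bin probabilities, so the envelope estimates those probabilities
  from one large run (20,000 trials) and samples the iterations as
  multinomials — distributionally identical to brute-force re-simulation.

## Synthetic cohorts

With no raw per-trial data deposited, the package generates synthetic
observers that stand in for the study's three groups. Generative parameters
are drawn per observer from the published per-group means and ranges
(`cohort_parameter_table()`): truncated normals on the printed range with
SD = range/4, with the location parameter solved so that the *truncated*
mean equals the printed mean (centering the location naively would bias
the mean by over 10% for the more asymmetric ranges). Adult early-noise
means are printed only as a band (0.44–0.47); we use 0.45 with the printed
individual range 0.32–0.64 at every eccentricity. Parameters are sampled
independently — the marginal means and ranges are all that is published.

Schedules mirror the task designs: children complete 12 trials in each of
five conditions (unflanked, ±30°, ±90°; 60 trials, foveal), adults five
blocks of 100 trials (20 per condition) at each of 2.5°, 5°, 10° and 15°
eccentricity — 2,000 trials. Targets are uniform within ±45° of vertical.
Negative-offset trials are generated by negating the flanker offset, so the
generative model is mirror-symmetric by construction, as the folding
analysis assumes.

For model-selection checks a complementary noise-generated cohort is used:
no noise-model parameter table is published, so those observers draw early
noise uniformly from the adults' individual early-noise range (0.32–0.64)
and β uniformly from 1–3, the magnitude scale of the published late-noise
values — chosen once as a realistic regime, not tuned.

What the generator does *not* emulate: attentional lapses and response-dial
motor noise in children beyond what the noise parameters capture,
correlations among an observer's parameters, and any dependence of the
early noise on eccentricity. Passing recovery and model-selection tests on
these cohorts therefore demonstrates that the pipeline is correct and
well-powered at the study's trial counts — not that real observers obey the
model.

## Staircase simulation

The acuity and crowding-extent tasks are 4AFC (chance 25%) with gap size as
the stimulus dimension. Simulated observers follow a Weibull psychometric
function `0.25 + (0.75 − lapse)(1 − exp(−(gap/α)^β))`. The staircase is a
Bayesian (QUEST-style) procedure over log10 gap: Gaussian prior (SD 0.5 log
units), Weibull likelihood (slope 3.5, lapse 0.01, grain 0.002 log units),
trials placed at the posterior-mean threshold shifted to the task's
convergence level — 62.5% correct for acuity, 80% for crowding extent. The
tailoring follows the children's protocol: three practice trials at twice a
nominal acuity, an easier trial (twice the current estimate) every fifth
trial, and an exit once the SD of the running threshold estimates over the
preceding eight trials drops below 0.03 log units, with a hard cap of 60
trials. Where the protocol is silent we chose the simpler reading: practice
and easy trials *do* update the posterior, and the threshold readout is the
posterior mean (exponentiated), reported at the convergence level.
Recovery is validated against the gap at which the simulated observer's
psychometric function truly crosses the convergence level; bias is below
0.05 log units over hundreds of runs.

The crowding extent follows from a gap threshold as `1.1 × 5 × gap`
(diameter is five gaps; separation is 1.1 diameters), converted to degrees.
The matching-task size rule selects the largest multiplier in
{3, 2.5, 2, 1.5} of the acuity gap whose implied separation stays within
the measured extent, warning when even 1.5× exceeds it.

## Numerical choices and problem sizes

Channel spacing is 1° (360 channels), finer than the 10° analysis bins;
the fitting path maps channel indices to bins arithmetically. The batch
simulate-and-decide loop is implemented in C++ (Rcpp) since every objective
evaluation touches 360 × 1,000 activities per condition. Default problem
sizes used by the package's own validation: 1,000 simulated trials per
condition per objective evaluation (the published choice), cohorts of 20
synthetic observers for recovery and model-selection checks, 4,000-trial
regime summaries, and 200 staircase runs. Degenerate inputs are handled
explicitly: empty histograms flag undefined proportions, zero LSE yields a
−∞ AIC with a warning, and all-tied population responses read out uniformly
at random.

## Known limitations

* The noise-field construction (smooth, unit-SD) is an engineering
  decision; other correlation structures consistent with the verbal model
  description would rescale the fitted noise magnitudes.
* The noiseless wf90 < 0.5 region is unidentifiable (the readout always
  sits at the target); identification comes from noise, so very-low-noise
  observers yield wide wf90 confidence regions.
* AIC constants depend on the adopted least-squares form; only ΔAIC between
  models on the same data is meaningful, which is all the package reports.
* Staircase recovery is validated against simulated Weibull observers, not
  human data; the 62.5%/80% convergence levels are taken as given.
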