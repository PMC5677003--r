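---
title: "Modeling serial dependence and working-memory noise in delayed-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling serial dependence and working-memory noise in delayed-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
library(dplyr)
```

## The problem

In a spatial delayed-response task, an observer remembers the polar angle of
a briefly flashed stimulus across a retention delay and then reports it.
Responses carry several separable error components:

* **random circular noise** whose dispersion grows with the memory delay;
* **systematic error** that depends smoothly on the stimulus location
  (anisotropies of perception and motor response);
* a **trial-history bias**: the response is pulled toward (serial
  dependence) or pushed away from (adaptation) the *previous* trial's
  stimulus location.

`serialdep` implements the full analysis chain for such data — filtering,
detrending, tuning-curve fitting of the history bias with resampling
inference, and maximum-likelihood comparison of working-memory noise models
— together with a synthetic session generator so that every stage can be
validated against known ground truth.

Throughout, angles are degrees of polar angle. The history predictor for
trial $i$ is $x_i = \mathrm{wrap}(s_{i-1} - s_i) \in (-180, 180]$, the
relative angle of the previous stimulus; positive errors are
counterclockwise, so *attraction means the error has the same sign as*
$x$. The matching future-trial control predictor is
$x^{\mathrm{next}}_i = \mathrm{wrap}(s_{i+1} - s_i)$.

## Preprocessing

`preprocess_trials()` chains four steps.

1. **History annotation** on the complete table. This happens *before*
   any filtering so that a trial whose own response is later discarded
   still donates its stimulus to the next trial's $x$ (the stimulus was
   seen regardless of how the response ended).
2. **Validity filters**: responses within 5 degrees of visual angle of the
   origin (aborted clicks) are dropped; then, per subject, trials whose
   signed error lies more than 3 SD from the subject mean are dropped.
   The mean and SD are computed once, on the origin-filtered data — the
   rule is not iterated, so it is a single, well-defined pass.
3. **Systematic-error removal**: signed error is regressed on stimulus
   angle with LOESS (degree 1, tricube weights). Circularity is handled
   by concatenating the data shifted by ±360° and predicting on the
   central copy; `span` refers to the fraction of one copy (internally
   `span/3` on the tripled data). The estimate is recentred so its mean
   over the circle equals the mean raw error, which makes the
   decomposition "systematic + residual" exact in the mean; LOESS alone
   does not guarantee that. The residual
   $y_i = \mathrm{wrap}(e_i - \hat{b}(s_i))$ is the quantity all
   serial-dependence statistics operate on. Subjects with fewer than 50
   usable trials get the degenerate constant estimate (their mean error).
4. **Subject exclusion**: subjects with overall mean absolute error
   strictly greater than 10° are flagged and excluded from group fits.

## Tuning curves and the peak-to-peak

The bias as a function of $x$ is modeled by two curves:

* the **derivative of Gaussian (DoG)**,
  $y = x\,a\,w\,c\,e^{-(wx)^2}$ with $c = \sqrt{2}\,e^{0.5}$, whose
  peaks sit at $x = \pm 1/(w\sqrt{2})$ with height exactly $\pm a$;
* the **Clifford curve**, defined implicitly by
  $\sin(y+x) = \sin x / \sqrt{(s\cos x - c)^2 + \sin^2 x}$, which can
  express "peripheral bumps" (repulsion at large $|x|$). The implicit
  equation has two arcsine branches; `clifford_curve()` resolves the
  ambiguity with the vector-angle construction
  $y = \operatorname{atan2}(\sin x,\; s\cos x - c) - x$, which satisfies
  the equation exactly, is continuous, odd, and passes through
  $y(0)=0$. It requires $s > c$ and $|c| \neq s$; in raw form the curve
  models repulsion, and `sign = -1` flips it for attraction.

The effect size is the **signed peak-to-peak**: max minus min of the
fitted curve, signed by the curve's value at its extremum nearest zero on
the positive-$x$ side (positive = attraction). For a DoG with on-domain
peaks this equals $2a$ exactly, an identity the test suite checks against
the grid-based evaluation.

**Fitting.** The DoG is linear in $a$ given $w$, so `fit_tuning()`
profiles $a$ exactly and minimizes over $w$ with a deterministic staged
grid search on $[10^{-4}, 0.2]$ per degree (a bound that keeps the peaks
on-domain and stops the curve collapsing to a spike), followed by a local
polish. This is a global search over the grid, needs no starting values,
and vectorizes across thousands of permutation or bootstrap replicates —
the property that makes the resampling stack affordable. The Clifford fit
is genuinely two-dimensional and uses multi-start Nelder-Mead over
$(s, c)$ (and both orientations) with the reparametrization
$s = e^{t_1}$, $c = 0.999\,s\tanh t_2$ that keeps every iterate valid.

One consequence of a free width deserves emphasis: on pure noise the
fitted curve may lock onto a narrow fluctuation near $x = 0$ (width at the
search bound), so null peak-to-peaks have a heavier spread than intuition
suggests (SD ≈ 0.5° at $n \approx 10^4$ trials). The permutation test is
built on exactly this statistic, so its null distribution absorbs the
inflation; but point estimates of near-zero effects should be read with
that spread in mind, and amplitude recovery at $n = 1000$, noise SD 5°,
carries an SD of about 0.38° — close to the information bound for this
design.

`auto_model_select()` renders the "DoG unless it fits poorly" policy
reproducible: both curves are fit, converted to AICc via the Gaussian-error
equivalence ($n \log(\mathrm{SSE}/n) + 2k$ with the finite-sample
correction, $k = 2$ for both), and the Clifford is chosen only when it wins
by more than a margin (default 2); ties keep the DoG.

## Resampling inference

* `permutation_test()` shuffles $x$ while leaving the errors in place,
  refits, and uses the proportion of null peak-to-peaks at or above the
  observed one. The default tail is fixed (`"greater"`, i.e. a test for
  attraction), under which the p-value is uniform on null data;
  `"less"` tests adaptation. The `"auto"` option picks the tail from the
  observed sign — convenient for description, but because the tail is
  data-selected its null rejection rate is twice nominal, which the
  documentation states plainly. Zero proportions are stored as 0 and
  printed as `< 1/n_perm`.
* `permutation_compare()` shuffles within each of two conditions and
  compares the difference of peak-to-peaks. Shuffles are independent per
  condition; pairing permutations across conditions by index would add a
  coupling the procedure does not need.
* `bootstrap_ci()` resamples $(x, y)$ *pairs* with replacement (case
  bootstrap, not residual bootstrap) and reports the percentile interval.
* `bonferroni()` divides the family-wise level by the family size.

Defaults are 10,000 resamples for production runs; the test suite and the
acceptance script use 250–2,000 to keep runtimes in minutes at the problem
sizes they simulate.

## Working-memory noise models

Residual errors (in radians for all densities) are modeled by:

* **EP** (equal precision): a single von Mises,
  $p(e) = e^{\kappa\cos e} / (2\pi I_0(\kappa))$; one parameter
  $\kappa$.
* **VP** (variable precision): precision varies across trials,
  $J \sim \Gamma(\bar J/\tau, \tau)$, mapped to a concentration through
  the Fisher-information relation $J = \kappa I_1(\kappa)/I_0(\kappa)$
  (inverted numerically; `J_to_kappa()` round-trips below $10^{-8}$),
  and the von Mises densities are averaged over draws.
* **VMRW** (von Mises random walk): the number of steps
  $m \sim \mathrm{Poisson}(\xi)$, the $m$ step directions are i.i.d.
  von Mises$(0, \kappa)$; conditional on the walk's resultant length $r$
  the behavioral error is von Mises with concentration $\kappa r$
  ($m = 0$ gives the uniform density). Marginalizing over $(m, r)$ by
  Monte Carlo gives the density. Note the step directions are *not*
  uniform: the joint law of a uniform walk tilted by
  $e^{\kappa r \cos\theta}$ — which is what the $I_0(\kappa r)/I_0(\kappa)^m$
  factor in the step-count mixture expresses — is exactly a walk with
  von Mises steps, and sampling it directly keeps the estimator unbiased.
  `rvmrw()` is an independent forward sampler (rejection sampling per
  step) used both by the generator and as an oracle against the density.

**Monte-Carlo policy.** VP and VMRW densities are evaluated on a 721-point
grid over $(-180, 180]$ with linear interpolation, using *common random
numbers*: fixed uniforms transformed by the gamma quantile (VP) or by a
von Mises inverse-CDF grid (VMRW steps), so the likelihood surface is a
smooth, deterministic function of the parameters — without this, simplex
optimization on a re-randomized objective stalls. Default draw counts
(2,000 for standalone density calls, 500–1,000 inside fits) were chosen by
convergence checks against the forward-simulation oracle (total-variation
distance < 0.05 at 72 bins is reached already near 1,000 draws).

**History extensions.** Each base model extends two ways:

* `dog_shift` — the density mean slides trial-by-trial by the DoG curve
  evaluated at that trial's $x$ (two extra parameters $a, w$ per delay
  condition): the serial-dependence hybrid.
* `swap` — with probability $\alpha$ the response is centered on the
  *previous* trial's location:
  $p(e) = (1-\alpha)f(e) + \alpha f(\mathrm{wrap}(e - x))$: memory
  confusion over time, with no tuning curve.

Trials with undefined $x$ (first of a subject) contribute the base
density.

**Fitting and comparison.** `fit_wm_model()` maximizes the log-likelihood
with Nelder-Mead, independently per delay condition (a separate parameter
set per delay), with positive parameters on the log scale and $\alpha$ on
the logit scale. Starts are a moment-based center (concentration from the
mean resultant length via Fisher's approximation) plus fixed
perturbations; extended models get two extra sign-alternating starts. AICc
is $2k - 2\ell + 2k(k+1)/(n-k-1)$ with $k$ counting parameters across all
conditions. `compare_models()` averages per-subject AICc differences and
reports mean ± SEM, positive values favoring the first-named model.
A uniform-lapse (guess) component is deliberately omitted: in a one-item
spatial task guess rates are near zero, and the swap extension already
supplies the "response unrelated to the target" alternative.

## The synthetic generator and what passing tests mean

`generate_session()` simulates the study conditions the analysis assumes:
uniform stimulus angles at eccentricity 12, delays drawn from
$\{0, 1, 3, 6, 10\}$ s (ITIs configurable likewise), ~1,000 trials per
subject, and a response error composed of systematic + history bias +
model noise, wrapped to $(-180, 180]$. Defaults, fixed once:

* **noise**: EP with per-delay $\kappa$ calibrated so response variance
  follows $17.3\,(d+1)^{0.47}$ deg² — a sublinear power law anchored at
  ≈ 43 deg² for the 6-s and ≈ 52 deg² for the 10-s delay;
* **bias**: DoG with width 0.02/deg and amplitude schedule
  $(-0.86, 0.42, 1.0, 1.7, 1.45)$° over the five delays — repulsion at
  0 s flipping to attraction that peaks at 6 s (peak-to-peaks of half
  those of a strong empirical effect, a deliberately conservative
  regime);
* **systematic error**: harmonics 1 and 4 with amplitudes 1.5° and 0.8°
  — smooth, as the LOESS step assumes;
* **nuisances**: 0.2% near-origin clicks (eccentricity < 5), 0.2%
  outliers substituted beyond 3.5 SD of the noise. The distribution of
  real outliers is unknown; uniform tails beyond the 3-SD region are a
  stand-in that guarantees the filter has something to catch.

Each subject's stream is seeded by (seed, subject index), so any subject
regenerates in isolation.

The generator deliberately omits features of real data: reaction times,
eye movements, block effects, slow drifts of attention or calibration,
non-stationary bias amplitudes, and any dependence of errors on more than
one trial back. Passing tests therefore demonstrate that the *pipeline*
recovers what it assumes, with correct error calibration, on data obeying
those assumptions — not that real data obey them.

## Numerical choices and degenerate inputs

* Angles wrap to $(-180, 180]$ by `180 - ((180 - x) %% 360)`; the
  closed upper end makes the wrapped value of exactly 180 well defined.
* Exponentially scaled Bessel functions keep all von Mises densities
  finite up to $\kappa r$ in the thousands.
* Width bounds $[10^{-4}, 0.2]$ and the DoG grid (25 coarse log-spaced
  points, two 15-point refinement stages, then an `optimize()` polish for
  single fits) give width resolution below 1%; amplitude is always exact
  given width.
* Degenerate cases error loudly rather than silently: all-identical
  stimulus angles, fewer than 50 trials for the smoother (constant
  fallback inside `preprocess_trials()`), fewer than 20 pairs for a
  tuning fit, fewer than $k+2$ trials per delay for a likelihood fit,
  invalid Clifford parameter pairs ($|c| = s$ or $s \le c$).
* Permutation/bootstrap chunking bounds memory at ~16 MB per block
  regardless of `n_perm`.
* `run_analysis()` derives a sub-seed per (grouping, level) from the
  master seed, records every one in its manifest, and is byte-identical
  on rerun.

## Problem sizes used by the validation suites

The test suite exercises the study-scale conditions in scaled form chosen
once: tuning recovery at $n = 1000$ over 100 seeds; permutation type-I
error on 200 null datasets ($n = 500$, 1,000 permutations each); bootstrap
coverage on 200 datasets (500 replicates each); the 3×3 model-recovery
confusion at $n = 1000$ over 20 seeds with 500 Monte-Carlo draws per
likelihood evaluation; and an end-to-end cohort of 12 subjects × 1,000
trials. The acceptance script analyzes the same cohort with 2,000
resamples per statistic and fits the noise models per delay on three
subjects.

## Known limitations

* The DoG width is weakly identified at small amplitudes; near-null
  effects show the narrow-width overfitting described above. Estimates
  of *where* the bias peaks are far noisier than estimates of its size.
* The VP and VMRW families are close relatives; at $n = 1000$ trials per
  condition their AICc separation on each other's data is a few units,
  so single-subject rankings between those two are unstable even when
  the group-mean ranking is correct.
* The Clifford fit's peak-to-peak is obtained by grid + refinement on
  the fitted curve; for parameter pairs approaching $|c| \to s$ the
  curve steepens and the reported peak-to-peak becomes sensitive to the
  parameters — the validity reparametrization keeps fits away from the
  singular set but cannot make the statistic well-conditioned near it.
* Likelihood fits assume trials are independent given the one-back
  predictor; slow autocorrelated drifts in real data would be absorbed
  partly by the noise parameters and partly by the LOESS step.
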