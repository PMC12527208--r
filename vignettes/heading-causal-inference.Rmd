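---
title: "Contextual causal inference in visual-vestibular heading perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextual causal inference in visual-vestibular heading perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headingci)
```

## The problem

A passively moved observer who watches a moving environment faces an
attribution problem: motion on the retina may come from their own
movement, from motion in the world, or both. If the environment was
already moving *before* the observer started to move, that pre-motion
epoch is informative — but only under the hypothesis that the
environmental motion stayed the same across the two epochs. `headingci`
implements a family of Bayesian ideal-observer models of this inference,
a synthetic-experiment generator matching the factorial design used to
study it, the Monte-Carlo/KDE machinery to fit the models to per-trial
reports, and the behavioral analyses (bias surfaces, cue-regression
decomposition, adaptive-weight diagnostic) used to compare them.

## Generative model

All signals live on a single lateral-velocity axis (deg/s). A heading
angle $\theta$ (degrees from vertically upward, positive rightward) maps
to its lateral component through the platform's peak speed $v_{\mathrm{ref}}$:
$s_{\mathrm{self}} = v_{\mathrm{ref}} \sin\theta$, with
$v_{\mathrm{ref}} = 8.5$ deg/s by default. The inverse mapping clamps to
$\pm 90^\circ$. The source study never states how heading angle and
visual velocity are placed on a common scale; this mapping is the
package's declared choice (`reference_speed` is configurable everywhere
it matters, and passing the lateral estimates straight through amounts
to an angle-as-velocity reading).

Latent states per trial: self-motion $s_{\mathrm{self}}$, environmental
motion before ($s_{\mathrm{env}0}$) and during ($s_{\mathrm{env}}$)
self-motion. The three visual-motion conditions fix the pre-motion
state: Acceleration ($s_{\mathrm{env}0}=0$), Constant
($s_{\mathrm{env}0}=s_{\mathrm{env}}$), Deceleration
($s_{\mathrm{env}0}=2 s_{\mathrm{env}}$).

Measurements:

* $x_{\mathrm{vest}} \sim N(s_{\mathrm{self}}, \sigma_{\mathrm{vest}}^2)$,
* $x_{\mathrm{vis}} \sim N(s_{\mathrm{self}} - s_{\mathrm{env}}, \sigma_{\mathrm{vis}}^2)$
  with Weber-law noise
  $\sigma_{\mathrm{vis}} = w_{\mathrm{vis}}\,|s_{\mathrm{self}} - s_{\mathrm{env}}|$,
* $x_{\mathrm{vis}0} \sim N(-s_{\mathrm{env}0}, \sigma_{\mathrm{vis}0}^2)$
  with $\sigma_{\mathrm{vis}0} = w_{\mathrm{vis}}\,|s_{\mathrm{env}0}|$.

Weber-law noise is exactly zero when the generating signal is zero (the
pre-motion epoch of the Acceleration condition, or nulled retinal
motion), which would make densities degenerate during fitting. Both
Weber SDs are therefore floored at `noise_floor` ($10^{-3}$ deg/s by
default) — small enough to change no prediction visibly, large enough to
keep every measurement distribution proper. The observer's assumed
likelihood widths equal the generative widths: one parameterization
serves simulation and inference.

Priors are zero-mean Gaussians (the slow-speed prior):
$s_{\mathrm{self}} \sim N(0, \sigma_{\mathrm{self}}^2)$ and
$s_{\mathrm{env}0}, s_{\mathrm{env}} \sim N(0, \sigma_{\mathrm{env}}^2)$.

## Observer models

The contextual causal-inference (CCI) observer entertains two causal
structures: $C=1$, the environmental motion stayed constant
($s_{\mathrm{env}0} = s_{\mathrm{env}}$), and $C=2$, it changed
(independent draws), with prior $p(C=1) = p_{\mathrm{constant}}$. Under
squared-error loss the optimal estimate is the posterior-weighted
average

$$\hat s_{\mathrm{self}} = p(C=1 \mid x)\,\hat s_{C=1} + p(C=2 \mid x)\,\hat s_{C=2},$$

with each per-structure estimate a reliability-weighted combination of
the vestibular cue, an *effective visual cue* $(\mu_K, \sigma_K^2)$, and
the prior:

$$\hat s_{C} = \frac{x_{\mathrm{vest}}/\sigma_{\mathrm{vest}}^2 + \mu_K/\sigma_K^2}
  {1/\sigma_{\mathrm{vest}}^2 + 1/\sigma_K^2 + 1/\sigma_{\mathrm{self}}^2}.$$

Under $C=1$ the pre-motion signal estimates the environmental motion and
is subtracted ("contextual vision"); under $C=2$ it is discarded and the
during-motion signal is read with prior-inflated uncertainty ("momentary
vision"). The structure posterior uses the analytic marginal likelihood
of the cues (a Gaussian in $x_{\mathrm{vest}}$ and $\mu_K$); the factor
shared by both structures — the prior-predictive density of
$x_{\mathrm{vis}0}$ — cancels and is omitted from both branches. All
posterior arithmetic runs in log space.

Alternatives implemented with the same vectorized interface
(`estimate_heading()`): Integration ($p_{\mathrm{constant}}=1$),
Segregation ($p_{\mathrm{constant}}=0$), Covariance (bivariate
environmental prior with correlation $\rho$; $\rho = 1$ and $\rho = 0$
reproduce Integration and Segregation — note the package follows the
printed formulas here), Fixed Weight (descriptive weighted cue sum),
Heuristic (commits to the structure selected by comparing raw cue
discrepancies; implemented exactly as printed, where the
constant-structure branch fires when its discrepancy is the *larger*
one, with `heuristic_invert = TRUE` offering the intuitive direction —
model comparison on data can disambiguate the two readings),
Winner-Take-All (commits to the a-posteriori more probable structure;
ties at $p = 0.5$ go to the constant branch, following the printed
"$\geq$"), and Momentary Causal Inference (MCI; ignores the pre-motion
signal and infers whether the two during-motion cues share a cause; both
latent states use the $\sigma_{\mathrm{self}}$ prior as printed, and its
assumed visual noise is $w_{\mathrm{vis}}|s_{\mathrm{env}}|$ per its own
generative story).

Whether $\rho$ may be negative is unstated in the source; the package
bounds it to $[0, 1]$.

Every closed form is verified in the test suite against
`numeric_posterior_mean()`, a brute-force quadrature oracle that
integrates the generative densities directly (adaptive quadrature,
relative tolerance $10^{-11}$, integration windows $\pm 12$ SDs around
every Gaussian factor).

## Synthetic experiment

`build_design()` crosses 5 visual velocities ($0, \pm 5, \pm 10$ deg/s),
10 headings ($\pm 5 \ldots \pm 45^\circ$), 3 conditions and 5
repetitions: 750 trials over 150 distinct stimulus conditions, in a
uniformly shuffled trial order (the original block structure has no
bearing on trial-independent observer models and is omitted).
`simulate_observer()` draws measurements, applies an estimator, and maps
estimates back to reported headings (clamped to $\pm 90^\circ$ through
the arcsine; estimates can exceed the reference speed in magnitude).

`make_cohort()` draws observers around field-plausible values: prior
SDs near 3 deg/s, vestibular noise log-normal around 1.5 deg/s, Weber
fraction around 0.15, and a constancy prior uniform on $[0.3, 0.8]$ —
chosen once as realistic psychophysical magnitudes (vestibular heading
thresholds of a degree or two per second; visual speed Weber fractions
of 10–20%) and spread widely enough that observers genuinely differ.
What the generator does *not* emulate: report/motor noise (the response
is the estimate itself), inter-trial adaptation, session effects, or
lapses. Passing recovery tests therefore demonstrates the estimation
machinery, not robustness to those human nuisances.

## Fitting

The estimator maps measurements deterministically to an estimate, so the
response distribution per stimulus condition comes from marginalizing
the unobservable measurements: draw `n_mc` measurement triples (default
1000), push them through the estimator, and evaluate the observed
responses under a Gaussian KDE of the simulated estimates. Bandwidth is
a Silverman-type rule on the simulated sample,
$0.9\,\hat\sigma\,n^{-1/5}$, floored at `bw_floor` ($10^{-6}$) so a
degenerate (noise-free) sample collapses to a narrow kernel rather than
a point mass; densities are floored at $10^{-9}$ to keep the objective
finite. Responses and simulated estimates are both expressed on the
lateral-velocity scale and clamped to the representable range.

The MAP objective adds log-normal priors on $\sigma_{\mathrm{self}},
\sigma_{\mathrm{env}}, \sigma_{\mathrm{vest}}$ (log-mean 1, log-SD 1)
and $w_{\mathrm{vis}}$ (log-mean $-2$, log-SD 1); parameters bounded by
definition get flat priors. Default bounds: SDs in $[10^{-3}, 50]$
deg/s (log-scaled search), $w_{\mathrm{vis}} \in [10^{-3}, 2]$,
probabilities and $\rho$ in $[0,1]$, fixed weights in $[-2, 2]$ (their
bounds are not stated in the source; signed weights keep the
descriptive model flexible).

The objective is stochastic. The package makes it deterministic *within*
a search by common random numbers — one set of standard-normal draws is
reused for every evaluation — and optimizes with multi-start
Nelder-Mead on unbounded (scaled-logit) coordinates, restarting the
simplex at the optimum up to twice (collapsed-simplex stalls are the
main NM failure mode here). Restarts begin from Latin-hypercube points.
After optimization the reported log-likelihood is the mean of
`n_final_evals` fresh-draw evaluations (default 100) minus the log
prior, and $\mathrm{AIC} = 2k - 2\log L$ with $k$ the model's free
parameter count (5 for cci/wta/covariance/fixed, 4 for
integration/segregation/heuristic/mci). `compare_models()` reports
per-observer AIC differences from a reference model with percentile
bootstrap confidence intervals over observers.

## Analyses

`heading_bias()` computes per-trial reported-minus-true heading,
flips the sign on leftward-visual-motion trials so that positive bias
points along the visual motion, and aggregates by condition and unsigned
speed. Trials at 0 deg/s have no visual direction and enter unflipped;
by symmetry their expected bias is zero, so the convention is neutral.

`regression_decomposition()` regresses the per-trial estimate on the
three cue predictions — vestibular ($s_{\mathrm{self}}$), momentary
vision ($s_{\mathrm{self}} - s_{\mathrm{env}}$) and contextual vision
($s_{\mathrm{self}} - s_{\mathrm{env}} + s_{\mathrm{env}0}$) — per
observer, with signed predictors (no mirroring) and group-level
one-sample t statistics. A single-condition dataset makes the
predictors collinear; this is reported as a rank-deficiency error, never
silently dropped. Simulated datasets carry the unclamped lateral
estimate and the regression uses it; for real data the reported angle is
mapped back through the arcsine.

`variable_weight_fit()` is the adaptive-weight diagnostic: the structure
posterior is replaced by one of two free weights on the
constant-structure estimate, chosen by the *true* state of the world —
$\alpha_1$ where $s_{\mathrm{env}0} = s_{\mathrm{env}}$ (the Constant
condition, and all 0 deg/s trials, where the equality holds literally)
and $\alpha_2$ elsewhere — and $\{\sigma_{\mathrm{self}},
\sigma_{\mathrm{env}}, \sigma_{\mathrm{vest}}, w_{\mathrm{vis}},
\alpha_1, \alpha_2\}$ are fitted with the same MC/KDE machinery. It is
not an observer model (observers cannot see the true structure); it is
a lens: causal-inference data yield $\alpha_1 > \alpha_2$, linear
integration yields $\alpha_1 \approx \alpha_2$. The weights are bounded
to $[0, 1]$ as convex combinations.

## Numerical and performance choices

The MC/KDE likelihood is the inner loop of every fit, so it is
implemented once in C++ (`src/loglik.cpp`) and mirrored by a plain-R
reference path; the test suite asserts the two agree to $10^{-9}$ on
every model. Log-sum-exp and log-space posteriors avoid underflow at
small noise. Ties in the heuristic and winner-take-all rules go to the
constant-structure branch as printed.

Problem sizes used by the shipped tests: the recovery cohort is 14
observers × 750 trials fitted with `n_mc = 500`, 3 restarts and a
200-iteration NM budget over two passes (the alternative-model and
variable-weight fits use 2 restarts, and the weight fits `n_mc = 250`);
bias surfaces use 200 repetitions per distinct condition; the
acceptance script fits a 6-observer cohort with the same per-fit
settings. These sizes are the package's own choices for a reproducible
desk-scale run; all of them are plain configuration arguments.

## Motion-cloud stimuli

`motion_cloud()` synthesizes the non-rigid texture stimulus by
bandpass-filtering uniform white noise in the 3-D frequency domain with
the product of (a) a Gaussian speed envelope
$\exp\!\big(-\tfrac12 ((f_x V_x + f_y V_y + f_t)/(B_v f_r))^2\big)$
concentrating energy on the plane $f_x V_x + f_y V_y + f_t = 0$ — the
typeset placement of $B_v$ is ambiguous in the source; the standard
motion-cloud construction (temporal width proportional to $B_v f_r$) is
used and isolated in one function — and (b) the printed log-scale radial
term $\tfrac{1}{f_r}\exp\!\big(-\tfrac12 (\ln(f_r/sf_0) /
\ln((sf_0+B_{sf})/sf_0))^2\big)$. The DC component is excluded
(undefined $1/f_r$) and the envelope is averaged with its
frequency-reversed copy so the self-conjugate Nyquist bins of even-sized
grids stay symmetric; filtering a real noise field then yields an
exactly real stack (imaginary residue at machine precision). Frames are
normalized to $[0,1]$. Defaults: $128^2$ pixels spanning a 50-degree
field, 60 Hz, $B_v = 2.1$ deg/s, $sf_0 = B_{sf} = 0.5$ cpd.
`cloud_velocity_estimate()` (energy-weighted spectral plane fit) and
`cloud_radial_spectrum()` (temporal-peak power in log-spaced radial
bins, whose mode sits at $sf_0$) are the independent validation tools.

`raised_cosine_profile()` builds the platform/stimulus velocity
schedule: raised-cosine ramps around a held plateau (8.5 deg/s held for
0.4 s within a 2-s profile by default), and `condition_schedule()`
derives the per-condition pre-/during-motion visual velocity pair.

## Known limitations

* The fitted response distribution ignores report/motor noise; with
  human data some response variability will be absorbed into the sensory
  parameters.
* The KDE response likelihood is biased at very small `n_mc`; values
  below a few hundred samples per condition trade accuracy for speed.
* The Nelder-Mead search is a portable stand-in for a
  Gaussian-process-aware noisy optimizer; common random numbers make it
  reliable here, but a handful of restarts remains advisable, and the
  per-restart traces are kept in the fit object.
* Heavy-tailed or point-mass slow-speed priors are out of scope; the
  closed forms rely on Gaussian priors throughout.
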