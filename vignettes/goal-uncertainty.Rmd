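---
title: "Methods: sigmoid latency analysis and optimal control under goal uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sigmoid latency analysis and optimal control under goal uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the modelling assumptions, parameter choices and
numerical decisions behind `hedgereach`, at the level of detail a maintainer
or reviewer needs. The README shows the user-facing workflow.

## The behavioral model

On jump trials the frame-normalized initial reach direction θ is assumed to
follow a sigmoidal function of re-preparation time t (the jump-to-onset
delay, in ms):

$$\theta = S(t) = \frac{A}{1 + e^{-(t - t_{50})/\tau}},$$

with the amplitude A **fixed to the jump size** — only the latency
$t_{50}$ and timescale $\tau$ are estimated. Fixing A reflects the design:
for long re-preparation times behavior fully compensates the jump, so the
asymptote is known and estimating it would only leak variance into τ.
Derived latencies are closed forms, $t_{05/95} = t_{50} \mp \tau \ln 19$,
hence $t_{95}-t_{05} = 2\ln(19)\,\tau$.

### Errors in variables

Both coordinates of a trial are noisy: the direction (execution plus
measurement noise, SD $\sigma_\theta$) and the rPT itself (onset detection
is a thresholded estimate; event clocks jitter, SD $\sigma_t$). Ordinary
least squares on a noisy predictor flattens the estimated transition —
a classical attenuation-style bias that here *inflates* τ, which the test
suite demonstrates by simulation (least squares exceeds the EIV estimate in
at least 16 of 20 replicates at $\sigma_t$ = 30 ms). The per-trial
likelihood therefore marginalizes a Gaussian latent timing error $e$:

$$L_i = \int \mathcal N(e;\, t_i, \sigma_t^2)\;
        \mathcal N(\theta_i;\, S(e), \sigma_\theta^2)\, de .$$

Defaults: $\sigma_\theta$ = 10.7° (the dispersion of non-jump-trial
directions at matched conditions, also the generator's direction-noise
default) and $\sigma_t$ = 10 ms. Densities are normalized per degree so
totals are comparable across predictors and against the outlier density.

### Shallow-slope penalty

Sessions need not cover the transition region of the sigmoid with data; in
that case a whole range of (t50, τ) fits equally well. The penalized
objective $\Lambda = \sum_i \log L_i + \alpha\tau$ (α = 0.02 per ms of τ)
resolves the ambiguity towards the *shallowest* slope consistent with the
data. The direction of the penalty is deliberate and conservative: sparse
coverage occurs mostly where behavior is abrupt (large jumps), where an
unpenalized fit could return an arbitrarily steep, data-free slope.

### Outlier mixture and EM

Each trial may instead come from a uniform "outlier" component with fixed
density $L_0$. $L_0$ defaults to 1/315 per degree — uniform over
[−90°, 225°], the normalized range the synthetic generator also uses for
its outlier draws; the bracket covers every direction from well past the
anti-target side to beyond the largest (135°) jump. The mixture weight is
estimated, initialized at 0.05. EM alternates posterior outlier weights
(E-step) with a closed-form weight update plus Nelder–Mead refinement of
(t50, log τ) of the weighted penalized objective (M-step). Because each
M-step starts from the incumbent vertex it can never return a worse value,
so the penalized mixture objective is non-decreasing across iterations;
every fit records its trace and the tests assert monotonicity on every run.
Trials with posterior above 0.5 are *reported* as outliers; the totals used
for model comparison are mixture totals over **all** trials, so no point is
silently dropped.

Numerical details: the e-integral uses an 81-node trapezoid over
$t_i \pm 5\sigma_t$ (validated against a 100×-finer quadrature to 1e-6
relative); per-trial log densities are computed by log-sum-exp and floored
at −690 (below the smallest normal double) so that a single extreme
residual cannot produce −∞ arithmetic — the mixture dominates such points
regardless. Initialization scans a 21 × 13 grid over (t50 quantiles,
log-spaced τ in [1, 500] ms); τ is bounded to that interval throughout. EM
stops when the objective changes by less than 1e-6, or errs if more than
90% of trials go to the outlier component (a degenerate fit, not a result).
Fits require at least 20 trials.

### rPT versus absolute time

`compare_time_bases()` refits the same model with the jump-to-go-tone delay
as the predictor. With initiation-time jitter (generator default SD 79 ms)
the two clocks decouple, and if behavior truly depends on the realized
onset, the rPT fit attains the higher mixture total. With zero jitter the
predictors coincide trial-by-trial and the totals agree exactly — both
directions are asserted in the tests.

## Kinematic preprocessing

Positions are smoothed and differentiated with a 2nd-order Savitzky–Golay
filter of 54 ms half-width — 7 samples at 130 Hz, a 15-sample window
(forced odd). Onset is the latest sample below 0.02 m/s before the global
speed peak; the initial direction is the smoothed-velocity heading 100 ms
after onset; the curvature statistic is the central circular difference of
the heading around that point, $|\hat\theta(100+\Delta) -
\hat\theta(100-\Delta)| / 2\Delta$, with Δ defaulting to one inter-sample
interval (1/130 s ≈ 7.69 ms). Trials are excluded for excursion below 5 cm
or a heading rate above 1.3°/ms; per-trial failures set flags rather than
raise errors. All angle arithmetic is circular on (−180°, 180°].

Two consequences of these definitions are worth stating plainly:

- **The smoothed onset is early relative to the physical onset.** A
  115 ms quadratic window spanning the onset kink leaks movement backwards;
  for the generator's 229 ms minimum-jerk reach the smoothed speed crosses
  0.02 m/s roughly 30 ms before the raw profile does. This is a property of
  the definition, not an implementation error; the tests therefore verify
  `detect_onset()` to within one sample of the *continuous-time crossing of
  the filtered profile*, computed by an independent fine-grid least-squares
  construction. A near-constant onset shift translates the fitted t50 but
  leaves τ and all comparisons intact; the residual trial-to-trial
  variation is precisely what the EIV σ_t absorbs.
- **Heading rates are attenuated.** The same window smears an injected
  heading ramp to about 0.74 of its instantaneous rate, so the 1.3 °/ms
  exclusion threshold refers to the *estimated* (smoothed) direction, and
  the curvature tests compare against the filtered-profile oracle.

The direction at onset + 100 ms is read from the filtered velocity (not a
local tangent refit); with the frame normalization, a perfect pre-jump
movement scores 0 and a perfect post-jump movement +|A|, pooling ± jumps.

## The synthetic generator

`simulate_reach_session()` emulates the timed-response paradigm: four tones
500 ms apart, target onset at the first tone on a 0.08 m ring (8
directions), movement at the fourth tone with Gaussian initiation jitter
(SD 79 ms), jumps on 30% of trials at ±45/90/135°, jump times uniform
150–550 ms before the go tone, 130 Hz sampling, 0.9 m/s required peak
speed. The realized rPT is onset minus jump time; jitter makes small and
negative rPTs possible, and the ground-truth sigmoid is evaluated at the
realized value. Default ground truth uses τ = 30/20/10 ms and t50 =
250/285/310 ms for 45/90/135°, i.e. steeper and later transitions for
larger jumps with nearly aligned t95 — the qualitative pattern the analysis
is designed to quantify. Outliers (default 4% of trials) draw directions
uniformly from [−90°, 225°], matching the fitter's outlier component.

Trajectories are straight minimum-jerk reaches (bell speed profile
$v \propto s^2(1-s)^2$) whose extent (default 0.11 m) and peak speed fix
the duration; the trajectory's heading equals the *observed* (noisy)
direction, so the generator-to-estimator round trip is exact up to
filtering. Pre-onset positional noise (SD 0.5 mm) keeps the smoothed speed
two orders of magnitude below the onset threshold. An optional heading ramp
localized in a ±30 ms window around onset + 100 ms injects curvature for
exclusion tests; the window is localized because a whole-movement ramp curls
the path into a short-excursion spiral and exercises the wrong rule.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: online within-movement corrections (each
synthetic trial's direction is drawn once), barrier collisions,
biomechanics beyond the speed profile, visual latencies, and any
trial-to-trial learning or drift. It is a measurement model of the
paradigm, not of the arm.

## The control model

State: hand angle x (integrator dynamics, command = angular velocity) and
belief log-odds r (belief that the target jumped; `belief_from_logodds()`
maps r to the probability of the post-jump target g2). r follows a
zero-drift Gaussian random walk, SD σ_r = 1 per 10 ms step: the actor
expects its belief to keep evolving during the movement but has no reason
to expect a particular direction. Terminal cost
$\alpha_1 (1-p)\, J_x(x - g_1) + p\, J_x(x - g_2)$ with $J_x$ a step of
width a = 1°; running effort $w_t u_t^2$ with $w_t$ linear from 0 to
w_MAX = 0.001 at T = 200 ms (late corrections require larger Cartesian
velocities far from the start, so they are the costly ones). These
parameter values are fixed as the model's reference configuration — they
were selected to place the three separations (45/90/135°) in the
qualitatively distinct hedging/committing regimes, not tuned to any data
set quantitatively; effort units are degrees-per-step squared.

Discretization: x at 0.1° covering both targets with a 2.5° margin, r at
0.5 over [−10, 10] (|r| = 10 is within 5·10⁻⁵ of certainty), t at 10 ms.
Actions are integer grid multiples up to u_max = 3°/step (300°/s); the
bound exists because a finite dynamic program needs one, and the shipped
configurations are insensitive to it (a 45° separation is crossable in 8 of
20 steps). The belief kernel integrates the Gaussian over grid bins with
edge bins absorbing the tails, so rows sum to one exactly; construction
fails with advice to widen the grid if a single step from r = 0 would lose
more than 1% of its mass beyond the boundary. σ_r = 0 yields the identity
kernel. With the barrier flag, x is restricted at every step to channels of
half-width a/2 around the targets, which reduces the t = 0 decision to a
discrete choice; `Inf` values entering the expectation through zero-mass
kernel entries are restored from NaN to `Inf` explicitly.

Tie handling in the policy curve is deliberate and symmetric: because the
first step is free (w_0 = 0), V(·, r, 0) is flat within one step-reach of
the optimum and argmin sets are genuine. The full tie set is reported;
the resolved curve takes the member closest to the currently favored target
and the set midpoint at r0 = 0, which preserves the mirror symmetry
x*(−r0) = 1 − x*(r0) and monotonicity in r0. `transition_width()` reports
the r0 interval between the first grid points reaching 5% and 95%
normalized compensation — crossings are not interpolated below the belief
grid's resolution, so a pure step has width one grid step. The width is
+∞ if a level is never reached, which genuinely occurs: with α₁ = 10 at
45° separation the curve saturates below 0.95 inside |r0| ≤ 10, because a
~1% chance of belief reversal times a tenfold miss penalty keeps the
optimal angle within correction range of the original target.

The solver is validated against `solve_ofc_enum()`, a deliberately naive
recursive enumeration (no memoization, scalar arithmetic) on randomized
tiny instances — 2–3 steps, ≤ 21 x-points, ≤ 7 r-points — where the two
agree to 1e-12 and, wherever the optimal first action is unique, choose the
same action. No mapping from r0 to wall-clock time after the jump is
attempted: the model-data comparison lives at the level of curve shapes
(transition-width ordering across separations, barrier collapse,
asymmetric-cost shifts), since the belief timecourse is assumed monotone
but is otherwise unidentified.

## Problem sizes and tolerances used in the test suite

Stochastic properties run at the sessions the analysis targets: 600 jump
trials per fit, 20 seeds for parameter recovery (median relative τ error
below 20%, median t50 error below 10 ms), 20 seeds each for the
least-squares comparison (≥ 16/20) and the time-base comparison (≥ 18/20).
Dynamic-programming cross-checks use 25 randomized tiny instances; policy
curves for the width ordering run at the full default grids and are
re-checked on a refined (0.25) belief grid. End-to-end pipeline tests use
260–2000-trial sessions. Exact identities (derived latencies, terminal
values, mirror symmetry) are asserted at 1e-9 or tighter; quadrature
agreement at 1e-6 relative.

## Known limitations

- The control model is one-dimensional by construction; it predicts initial
  angles only, not trajectories, and the general high-dimensional problem
  with uncontrollable noisy belief dynamics is intractable here.
- The EM fit reports no per-parameter uncertainty; comparisons across
  conditions should be made across sessions or seeds.
- The onset estimator's filter-induced bias (above) shifts fitted t50 by a
  near-constant amount relative to generative time; analyses that compare
  latencies across conditions processed identically are unaffected.
- The generator's outlier model is uniform and stationary; structured
  artifacts (e.g., returns to the start box) are not emulated.
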