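---
title: "Quantifying the gating force of hair-cell transduction channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the gating force of hair-cell transduction channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatingspring)
```

## The model

Mechanoelectrical transduction in hair cells is described by the
gating-spring model: deflecting the hair bundle by `X` tensions elastic
gating springs in series with the tip links, and that tension gates the
transduction channels directly. Because channel opening relaxes
gating-spring tension, gating feeds back on bundle mechanics. With a
two-state channel of open probability

$$P_o(X) = \frac{1}{1 + e^{-(X - X_0)/\delta}},$$

the force required to hold the bundle at `X` is

$$F(X) = K X - F_G\, P_o(X) + F_\varnothing ,$$

where `K` (pN/nm) is the linear stiffness, `X_0` (nm) the set point at
which half the channels are open, `delta` (nm) the width of the gating
curve, and `F_G` (pN) the whole-bundle gating force — the product of the
combined gating-spring stiffness `K_GS = K - K_SP` and the gating swing.
`F_null` pins `F(0) = 0`. The relation has two parallel asymptotic limbs
offset vertically by exactly `F_G`; its slope dips by `F_G/(4 delta)` at
the set point (gating compliance), and when `F_G > 4 K delta` the slope
turns negative over a range of displacements, making the bundle bistable.
`classify_regime()` labels these three cases. The gating swing along the
tip-link axis is `d = gamma * F_G / (K - K_SP)`, with projection factor
`gamma = 0.14` and pivot stiffness `K_SP = 0.17` pN/nm (the stiffness that
survives tip-link disruption, about 20% of `K`).

```{r model}
p <- control_params()          # K = 0.85 pN/nm, F_G = 17 pN, X_0 = -2 nm
classify_regime(p)
gating_swing(p$F_G, p$K, bundle_geometry())$d   # nm along the tip link
```

## What the simulators emulate

All inputs the analysis consumes are generated in code; each generator is
deterministic given a seed.

* **Step protocols** (`gen_fd_step_protocol()`): a fiber of stiffness
  `k_F` (default 0.5 pN/nm) stepped through growing pairs of opposite
  displacements; each recorded point is a steady-state root of the force
  balance `k_F(Delta - X) = F(X)`. In the bistable regime the root is
  chosen by continuation from the previous position, which is what a real
  bundle does without displacement-clamp feedback and what produces
  hysteretic jumps. Adaptation is out of scope, so steady-state roots
  stand in for sampling a few ms after the step.
* **Triangular cycles** (`simulate_cycle()`): overdamped bundle dynamics
  (drag `xi`, default 1e-4 pN s/nm, a literature-typical order — neither
  `xi` nor `k_F` is pinned by the measurements this package emulates)
  coupled to first-order channel kinetics with activation time `tau_a`.
  Delayed gating produces gating friction; with `tau_a = 0` and slow
  stimulation the cycle collapses onto the quasi-static relation.
* **Spontaneous oscillations** (`gen_oscillation_trace()`): linear
  spectral surrogates whose expected two-sided power spectrum is the
  double Lorentzian
  $$\tilde C(f) = \frac{A}{(f_0/2Q)^2 + (f - f_0)^2}
               + \frac{A}{(f_0/2Q)^2 + (f + f_0)^2},$$
  with full-line integral (variance) `4 pi A Q / f0`. This reproduces the
  second-order statistics of an oscillating bundle without committing to a
  mechanistic oscillator; waveform nonlinearity and adaptation dynamics of
  real oscillations are deliberately not reproduced.
* **Position histograms** (`gen_bimodal_positions()`): a two-Gaussian
  mixture for the channels-closed/channels-open dwell positions.
* **RC steps** (`gen_rc_step()`): the transepithelial circuit as a
  parallel RC, `U(t) = I R (1 - e^{-t/RC})`, with kOhm x nF = us.
* **Ensembles** (`gen_ensemble()`): per-cell condition deltas drawn from
  linear current-dependence models with residual variance
  `slope^2 Var(I) (1 - R^2)/R^2`, so the expected OLS `R^2` equals the
  configured value and the expected slope is the configured slope. Default
  models: `dX0 = 4.6 I - 9.6` (R^2 0.75), `dK = -0.01 I + 0.04` (R^2
  0.33), `dFG = -2.3 I + 5` (R^2 0.74), `dd/d0 [%] = -11 I + 22` (R^2
  0.78); control-condition scatter uses the between-cell SDs (K: 0.2,
  F_G: 4, X_0: 7). Below the transition current (default -5 uA descending,
  plus a 2.3-uA hysteresis on ascending approaches) the row switches to
  the weak state with `F_G = 0`, `d = 0`, and the convention
  `dFG = -F_G(0)`, `dd/d0 = -100%`. The same `state_transition_model()`
  drives `gen_transition_ramp()`, and serves unchanged when the control
  axis is an iontophoretic current rather than a transepithelial one.

Passing tests on these surrogates show that the estimators recover known
generating parameters under realistic noise; they do not certify behaviour
on features the generators omit (adaptation, drift, fiber vibrational
modes, non-Gaussian measurement noise).

## Fitting choices

`fit_gating_spring()` is nonlinear least squares with data-driven starts:
`K` from the pooled slope of the outer thirds of the displacement range,
`F_G` from their intercept gap (an exact property of the model), and `X_0`
from the dip of a running local slope — the residual-from-a-line start is
unreliable when the sampled window is asymmetric about the set point.
Because step-protocol data do not constrain `delta` (bundles with strong
gating jump across the gating region), `delta` is a free but bounded
parameter (1-100 nm) explored by a five-point log-spaced multistart, each
start fitted in two stages (first with `delta` held fixed, then released);
the best sum of squares wins. Reported standard errors are conditional on
`delta`: along the near-degenerate `F_G`-`delta` ridge the unconditional
covariance inflates SE(`F_G`) without conveying information the data
actually contain.

Model selection between the 5-parameter gated fit and a 2-parameter line
uses small-sample AICc plus a resolvability rule: "gated" requires both an
AICc improvement and `F_G > 2 SE(F_G)`. When the line wins, `F_G` is
reported as 0 and flagged undetectable — matching how cells whose relation
turns linear are treated in the delta conventions above. The selection
criterion itself is this package's operationalization; only the outcome
(gated vs linear) is prescribed by the underlying analysis.

## Cycle reduction choices

`average_cycles()` folds the record on the stimulus phase, splits samples
by the sign of the fiber-base velocity, bin-averages each half-cycle
(bin width = stimulus peak-to-peak / 100, resolution-matched to 25-kHz
sampling), and interpolates both branches onto shared grid centres —
comparing the branches at identical displacements, otherwise sub-bin
misalignment leaks the cycle slope into the friction profile. The friction
profile is `phi(X) = [F_+(X) - F_-(X)]/2`; the outermost 5% of the range
is excluded from its statistics (fiber-reversal artifacts), a profile with
less than 5% interior relative spread is flagged flat (pure viscous drag),
and the sign convention is fixed by requiring `phi >= 0` for dissipative
cycles. The activation time is `tau = dX / (2 V_MAX)` from the shift
between the positions of maximal bundle speed on the two half-cycles,
computed on the phase-averaged trajectory after 5-sample moving-average
smoothing (finite differences on raw samples are degenerate under noise).
The estimate is monotone in the generating `tau_a` but is not an unbiased
estimator of it: the bundle's own mechanical relaxation time adds to the
apparent lag, and `V_MAX` exceeds the mean sweep speed.

The dissipated-work identity (loop area equals the friction-profile path
integral) is verified on the interior support for the same reason the
profile statistics exclude the turning caps.

## Spectral choices

`power_spectrum()` averages raw periodograms of non-overlapping, demeaned
segments; the density is two-sided, stored on positive frequencies, so
that twice its integral over `f > 0` is the trace variance (Parseval,
held to 1% in tests). Smoothing is a 1-Hz boxcar whose window shrinks at
the edges, preserving the integral. The double-Lorentzian fit initialises
`f0` at the spectral argmax, `Q` from `f0/FWHM`, and `A` from the peak
height; `x_rms()` is the closed form `sqrt(4 pi A Q / f0)`, checked
against quadrature of the fitted density. The parameterization adopted
here is the unique sum of two Lorentzian lines whose full-line integral
is exactly `4 pi A Q / f0`, keeping the closed-form `X_RMS` dimensionally
consistent with a density in nm²/Hz. The bimodal open probability is
the open-mode weight of a two-Gaussian mixture (EM via mclust, unequal
variances, deterministic initialisation on an order-statistic subset);
the fit is declared unreliable unless the modes are separated by at least
one component SD, both weights exceed 5%, and the fitted mixture density
itself has a dip between the means.

## Transition and kinetics choices

`detect_drop()` needs operational pre- and post-drop levels on each ramp
branch; plateau medians (samples within 1 uA of each current extreme) are
used, a declared generalization of marking single points just before and
after the drop. The transition current is the first midpoint crossing with
linear interpolation, the hysteresis shift the difference of crossings,
and a branch pair whose plateaus differ by less than 5% is reported as
having no transition. `t10_90()` takes baseline and plateau as medians of
the first and last 10% of the analysis window — so kinetics windows should
start half a second before the step edge — and flags changes smaller than
three baseline noise SDs as undefined. No multiple-testing correction is
applied anywhere; p-values are reported raw.

## Numerical details

* Cycle integration: exponential (unconditionally stable) updates for both
  the bundle position and the channel open probability at fixed
  `dt = 1e-5` s; the contract is that halving `dt` moves `phi_MAX` by less
  than 1%, which the tests check directly.
* Quasi-static roots: bracketed scan (4001 points) refined by `uniroot` to
  1e-12; stability requires total stiffness `k_F + F'(X) > 0`; the
  continuation rule picks the stable root nearest the previous position.
  Tests compare every reported position against an independent dense
  0.01-nm root scan.
* Spectral synthesis: Hermitian complex-Gaussian coefficients scaled to
  the target density; traces are exactly zero-mean and seed-deterministic.
* Degenerate inputs are flagged rather than silently fitted: flat RC
  traces, peakless spectra, unimodal histograms, zero-amplitude steps,
  cycles with no shared displacement support.

## Problem sizes

The test-suite and acceptance computations use 3-10 cycle simulations at
40 Hz (25-kHz output), 20-30 s oscillation traces at 250-500 Hz, 34-pair
ensembles averaged over up to 200 seeds, and 40-50-replicate Monte-Carlo
harnesses — sizes chosen to keep estimator sampling error a few times
smaller than the tolerances being verified.

## Known limitations

* `delta` is reported but should not be interpreted quantitatively; only
  its bounds are honoured.
* The activation-time estimator is a relative, not absolute, measure of
  channel kinetics (see above).
* The ensemble generator draws each observable's residuals independently;
  real per-cell parameters co-vary (e.g. `d` is computed from `F_G` and
  `K` in the control rows but follows its own regression in condition
  rows, mirroring how the published regressions were estimated
  independently per observable).
* The oscillation surrogate is linear; estimators that depend on phase
  coherence or waveform asymmetry cannot be validated against it.
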