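---
title: "Hydration sensing from FRAP lateral diffusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration sensing from FRAP lateral diffusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrasense)
```

`hydrasense` turns lipid lateral mobility into a hydration readout for
supported lipid bilayers (SLBs). This vignette is the package's own account
of the science and of the design choices behind it: the recovery model and
its assumptions, what the synthetic-data generator does and does not
emulate, the numerical decisions, and the known limitations.

## The recovery model

A FRAP experiment bleaches a circular spot of radius $w$ in a fluorescently
labelled bilayer and records the return of fluorescence as unbleached
lipids diffuse in. For an ideal uniform disk bleached instantaneously and
free two-dimensional Brownian diffusion, the fractional recovery of the
spot mean has the closed form

$$f(t) = e^{-2\tau_D/t}\left[I_0\!\left(\tfrac{2\tau_D}{t}\right) +
I_1\!\left(\tfrac{2\tau_D}{t}\right)\right], \qquad
\tau_D = \frac{w^2}{4D},$$

with $I_0, I_1$ modified Bessel functions of the first kind. The fitted
trace model is the affine wrap

$$F(t) = b + a\,f(t),$$

where $b$ is the fluorescence remaining in the spot right after the bleach
and $a$ the diffusively recovered amplitude. The plateau $a + b$ is below
the pre-bleach level of 1 when part of the fluorophore pool is immobile;
the mobile fraction is $a/(1-b)$.

Assumptions worth keeping in mind: the bleach profile is a sharp-edged
uniform disk (no Gaussian-beam correction), the bleach is instantaneous
relative to diffusion, diffusion is free and Brownian (no anomalous
exponent, no reaction term), and the membrane is effectively infinite
compared with the spot. Anomalous/subdiffusion and reaction–diffusion
variants are deliberately out of scope.

### Geometry and timing defaults

The default `bleach_geometry()` is a 10&nbsp;µm-diameter spot in a
50&nbsp;µm × 50&nbsp;µm field imaged every 0.5&nbsp;s, with 100 post-bleach
frames — the acquisition this package was designed around. At the fully
hydrated single-component reference value $D = 5.35$&nbsp;µm²/s this gives
$\tau_D \approx 1.17$&nbsp;s and a predicted 97.7% recovery at 50&nbsp;s;
at the dried-membrane value $D = 0.04$&nbsp;µm²/s, $\tau_D \approx
156$&nbsp;s and only ~31% of the recovery falls inside the window.

### Numerical evaluation

$f$ depends on $x = 2\tau_D/t$, which is huge at early times for slow
diffusion. The package evaluates $e^{-x}[I_0(x)+I_1(x)]$ with
exponentially scaled Bessel routines for $x \le 700$ and switches to the
four-term large-argument asymptotic expansion beyond, where R's scaled
Bessel implementation degrades (it underflows to zero near $x \sim 10^5$).
The two branches agree to $10^{-10}$ at the switch point, and $f$ is never
evaluated at $t = 0$: the first frame sits at mid-exposure,
$t_1 = \Delta t/2$. The half-recovery time satisfies
$t_{1/2} = 0.8946\,\tau_D$ (a universal constant of the curve, computed
once by root finding and cached).

## Fitting

`fit_recovery()` estimates the parameters by bounded Levenberg–Marquardt
least squares. Internally the model is parameterized as
$(m, b, \tau_D)$ with $m = a + b$ the plateau, bounded by $m \le 1.02$:
the recovery cannot overshoot the pre-bleach level beyond noise. This
bound is not cosmetic. For traces where only a small fraction of the
recovery falls in-window, the likelihood surface has a long, nearly flat
valley trading amplitude against $\tau_D$; leaving the plateau free lets
ordinary least squares wander along that valley and bias $D$ upward
substantially. The plateau bound removes most of that freedom while still
allowing genuinely immobile pools ($m < 1$).

Starting values are derivative-free and robust: $b_0$ is the first
post-bleach intensity, the starting plateau the mean of the last five
frames, and $\tau_{D,0}$ the empirical half-recovery time divided by
0.8946. Bounds are $m \in (0, 1.02]$, $b \in [0, 1)$,
$\tau_D \in [10^{-3}, 10^4]$&nbsp;s; a parameter landing on a bound is
flagged in `$at_bounds` rather than silently accepted. Note that a fully
mobile, fully recovering trace legitimately pins the plateau bound — the
flag is information, not necessarily an error.

Confidence bounds on $D$ are 95% intervals from the linearized parameter
covariance at the optimum, propagated from $\tau_D$ to
$D = w^2/(4\tau_D)$ by the delta method — the same construction used to
put error bars on per-trace $D$ estimates. A trace whose first intensity
is at or above 0.95 carries no usable bleach signature and raises a
dedicated no-bleach error.

## Trace extraction and double normalization

For image-stack input, the ROI trace is the per-frame arithmetic mean over
pixels whose centers lie within the bleach radius of the spot center
(pixel-center membership, no partial-pixel weighting — adequate at the
default 128² grid). The reference trace is the mean over the whole field
outside the ROI disk, optionally excluding a guard annulus (off by
default). Normalization is the standard double scheme: divide the ROI
trace frame-wise by the reference (cancelling global acquisition
photobleaching — exactly, as the paired-simulation test shows), then by
the mean of the pre-bleach corrected values so the pre-bleach level is 1.

One genuine physical subtlety: the reference region is not an infinite
reservoir. While the bleached deficit diffuses outward it passes through
the reference region and depresses it by up to a few percent
mid-recovery, so the double-normalized trace slightly overshoots the ideal
$F(t)$ — this happens for a real microscope field just as for the
simulation, and it biases the fitted $D$ by roughly −5% to +5% depending
on how fast the deficit transits the field. The package therefore
validates simulator-versus-theory agreement on the reference-free ROI
recovery (≤1% absolute across the reference $D$ range) and treats the
end-to-end stack pipeline as accurate to ~5% at moderate $D$ and ~10%
across the full range. Analytic-trace simulations, which bypass imaging,
carry no such bias.

## The synthetic-data generator

`simulate_trace()` draws directly from the forward model: $F(t_i)$ plus
multiplicative Gaussian noise (`noise_sd` is the SD *relative to the local
intensity*; fluorescence noise scales with signal). The defaults encode
the reference conditions: bleach depth 0.95 (a deep but not total bleach,
as maximum-power bleaching achieves in practice), no immobile pool, 1%
noise, 5 pre-bleach and 100 post-bleach frames.

`simulate_stack()` forward-simulates the imaging experiment. The membrane
is a uniform fluorophore field on a periodic domain; at the bleach the
concentration inside the ideal disk is multiplied by $1-\text{depth}$;
the mobile pool then evolves by multiplication with the Gaussian Green's
function in Fourier space (spectral evolution, exact for periodic
boundaries, each frame computed in one step from the bleach snapshot so no
error accumulates), while the immobile pool stays frozen. Optional
per-frame exponential acquisition bleaching, Poisson shot noise and
Gaussian read noise are applied in that order, frame by frame, under a
single integer seed; identical seeds give bit-identical stacks.

The simulation domain is `pad_factor` (default 2) times the camera field
at the same pixel size, and the returned stack is the central crop. The
field of view thus behaves as a window into a larger membrane — which is
what a microscope sees. On a periodic domain equal to the field itself,
wrap-around images of the bleached spot contaminate the late recovery at
fast $D$ by just over 1%; with the default padding the reference-free ROI
recovery matches the closed form to ≤0.7% absolute across
$D \in \{0.05, 0.25, 1.66, 5.35\}$&nbsp;µm²/s, the residual being pixel
discretization of the disk edge. Diffusion conserves total fluorophore on
the simulation domain to machine precision (verified to $10^{-6}$
relative); the cropped field is deliberately open, so mass bookkeeping is
exposed in the ground-truth record, not on the camera frames.

What the generator does *not* emulate: the confocal point-spread function,
photophysics (blinking, reversible bleaching), stage drift, and spatially
resolved two-phase membranes with distinct $D$ per phase. Passing tests
therefore certify the analysis chain against the stated forward model, not
against every complication of real data.

### Reference D(RH) tables

`default_d_rh_table()` encodes the study conditions the simulator
reproduces. The single-component dehydration branch honors the reported
end points — 5.35&nbsp;µm²/s fully hydrated (bulk), 4.75 at 85% RH, 0.25
at ~0% RH — and places the transition knee at 50% RH with a near-flat
branch below, reflecting the observed structure that most of the change in
$D$ happens between full hydration and ~50% RH:

| RH (%) | 0 | 30 | 45 | 65 | 85 | 100 |
|---|---|---|---|---|---|---|
| D (µm²/s) | 0.25 | 0.30 | 0.50 | 1.80 | 4.75 | 5.35 |

The phase-separated table scales the same shape to its end points (1.66
bulk, 1.52 at 85%, 0.04 at ~0%). The rehydration branch runs 15% below the
dehydration branch at intermediate humidity — stepwise rehydration leaves
the membrane transiently drier than equilibrium — and rejoins the bulk
value at RH 100, where lipids regain their native mobility. The
intermediate knots are the package's choice of a realistic profile
consistent with those constraints; they are inputs to the simulator, not
measured values. `simulate_rh_series()` adds an optional first-order
equilibration lag (time constant `lag_tau_s` over the dwell at each
set-point), which reproduces the observed de/rehydration hysteresis:
during stepwise drying the membrane lags wet (higher $D$ than
equilibrium), during rewetting it lags dry.

## Calibration, inversion, and the waters-per-lipid map

`build_calibration()` aggregates replicate fits per RH level (mean, SD,
n) and interpolates the means with a shape-preserving monotone piecewise
cubic (Fritsch–Carlson). Monotone interpolation — rather than a smoothing
spline — is a requirement, not a taste: the sensing step inverts the curve,
and the inverse must be single-valued. Dips in the means larger than one
pooled replicate SD reject the calibration; smaller dips (replicate noise)
are leveled by isotonic regression before interpolation. Queries outside
the knot range are clamped to the end knots and flagged, never
extrapolated. Branches (dehydration/rehydration/bulk) are never pooled;
the branch is an explicit label, and "fully hydrated" is encoded as RH =
100 for calibration purposes since the bulk state has no meaningful
humidity value of its own.

`sense()` inverts the interpolant by bracketed root finding (`uniroot`,
tolerance $10^{-10}$; verified against an exhaustive $10^4$-point grid
scan), propagates a D confidence interval through the inverse endpoint by
endpoint (valid because the map is monotone), and converts RH to water
molecules per lipid head group via `rh_to_waters()`: a monotone
interpolation through the literature anchors

| RH (%) | 25 | 50 | 75 | 95 |
|---|---|---|---|---|
| waters per lipid | 2.4 | 3.6 | 6.3 | 10.5 |

Below 25% RH the anchors no longer apply; molecular-dynamics work puts a
residual 3–4 strongly hydrogen-bonded waters on the carbonyl/phosphate
groups even after drastic drying, so the package reports the bound —
point value 4, interval [3, 4], `floor_applied = TRUE` — rather than
extrapolating the anchor curve downward (which would cross below the
physical floor). This makes the map deliberately non-monotone at the 25%
boundary: the floor is an upper bound on a poorly determined quantity,
not a curve point. Above 95% RH the last anchor is reported as a lower
bound with `extrapolated = TRUE`.

## Breakpoint and hysteresis

`detect_breakpoint()` fits a continuous two-segment linear model (hinge)
of mean $D$ versus RH for every candidate breakpoint on a 1%-RH grid and
returns the SSE-minimizing knee, lowest RH on ties. A curve whose
single-line SSE is already at numerical zero, or where the hinge improves
SSE by less than 5%, is flagged `no_breakpoint`. The estimator is
unweighted by default (replicate counts are small and similar); a
replicate-count-weighted option exists. On the default single-component
profile the knee lands at 50% RH — the humidity where the ordered
(clathrate-like) water cage around the phosphocholine group breaks down.

`hysteresis_metric()` evaluates both branches on a common-domain grid and
summarizes $\Delta D(\mathrm{RH}) = D_{\text{dehydration}} -
D_{\text{rehydration}}$ (mean, max, sign pattern), plus a reversibility
verdict: branches whose highest-RH (bulk) knots agree within combined
replicate SD are "reversible", with or without hysteresis depending on
the mean $\Delta D$.

## Problem sizes and test design

The test-suite simulations use the default acquisition (105 frames at
128² camera pixels, 256² simulation grid) for stack-based checks, 50
seeded replicates for parameter-recovery and coverage properties, and 5
replicate traces per humidity level for calibration — matching the minimum
five FRAP measurements per RH level that replicate-based calibration
assumes. These sizes were chosen so every property is exercised at full
fidelity while the whole suite runs in well under a minute; all randomness
flows through explicit integer seeds, and the acceptance script derives
every seed from its single `--seed` argument.

## Known limitations

- Diffusion coefficients from traces with far-sub-plateau recovery
  (e.g. $D \sim 0.04$&nbsp;µm²/s in a 50&nbsp;s window) are intrinsically
  ill-conditioned: amplitude and $\tau_D$ trade off, and even the bounded
  fit carries a noise-dependent upward median bias of order 10%. Treat
  such values as order-of-magnitude.
- The double normalization is faithful to practice but not to the ideal
  model; fitted $D$ from image stacks carries a few-percent bias that
  analytic traces do not (see above).
- The waters-per-lipid anchors come from stacked PC multilayers; applying
  them to a supported bilayer on mica assumes the hydration-RH relation
  transfers. They are PC-specific: other head groups need their own
  anchor set.
- Hydration is sensed via RH as the intermediate variable, and RH levels
  are data, not constants: calibrations are only as good as the humidity
  control and equilibration time (~10 min in practice) behind them.
- Temperature, ionic strength, cholesterol content and phase state all
  shift absolute $D$; the calibration holds them fixed. Within one
  homogeneous system the method can also be used self-referentially
  (comparing sites), which removes the need for absolute calibration.
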