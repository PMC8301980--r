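# hydrasense

Quantify the hydration state of a lipid membrane — down to water molecules
per lipid head group — from how fast its lipids diffuse.

## The problem

The hydration shell around a phospholipid head group governs membrane
processes from fusion to macromolecule adsorption, but there is no routine
way to read out the local hydration state of a bilayer. Lipid lateral
mobility offers one: in a supported lipid bilayer (SLB) equilibrated to a
nitrogen atmosphere of known relative humidity (RH), the lateral diffusion
coefficient *D* drops by more than an order of magnitude between full
hydration and dryness, changes reversibly, and tracks the number of water
molecules hydrating each lipid. Calibrate *D* against RH once, and a FRAP
measurement becomes a hydration sensor.

`hydrasense` implements that sensing chain for anyone analysing FRAP data
on supported bilayers: microscopists with TIFF time series, and method
developers who want a fully synthetic, ground-truth-controlled testbed.

## The model

A circular spot of radius *w* is bleached instantaneously and its
normalized fluorescence recovers by free 2-D Brownian diffusion:

    F(t) = b + a · f(t),
    f(t) = exp(−2τ_D/t) · [ I₀(2τ_D/t) + I₁(2τ_D/t) ],      τ_D = w² / (4D)

where *b* is the fluorescence remaining right after the bleach, *a* the
recovered amplitude (so the plateau `a + b` reveals the mobile fraction
`a/(1−b)`), I₀ and I₁ are modified Bessel functions, and τ_D the
characteristic diffusion time. Fitting `(a, b, τ_D)` to a trace yields
`D = w²/(4τ_D)` with confidence bounds from the fit covariance.

Sensing then proceeds through two monotone maps: a shape-preserving
calibration curve `RH ↦ D` built from replicate fits (inverted by root
finding), and the literature anchor curve `RH ↦ waters per lipid`
(10.5, 6.3, 3.6, 2.4 waters at 95, 75, 50, 25% RH, with a residual 3–4
strongly bound waters below 25% RH). A hinge fit on the calibration locates
the breaking point near 50% RH where the ordered water cage around the
phosphocholine group collapses.

## Worked example

Simulate a confocal FRAP stack (10 µm spot in a 50 µm field, 100 frames at
0.5 s, 1% noise) at a known D, recover D from the images, and sense the
membrane's hydration against the reference calibration:

```r
library(hydrasense)

geom  <- bleach_geometry()                       # w = 5 um, 0.5 s, 50 um field
sim   <- simulate_stack(frap_sim_config(d_true = 1.8, seed = 42))
trace <- stack_to_trace(sim$stack)               # extract + double normalization
fit   <- fit_recovery(trace, geom)
fit
#> <soumpasis_fit>
#>   D        = 1.88014 um^2/s  [1.84567, 1.9146] (95% CI)
#>   tau_D    = 3.32423 s   (w = 5 um)
#>   a = 0.99, b = 0.02997, mobile fraction = 1
#>   residual RMS = 0.00331 over 100 frames
#>   warning: parameter(s) at bounds: plateau

curve <- build_calibration(calibration_points_from_table(default_d_rh_table()))
sense(fit$d, curve, ci = c(fit$ci_low_d, fit$ci_high_d))
#> <hydration_estimate>
#>   RH     = 65.72% [65.42, 66.01] (branch 'dehydration')
#>   waters per lipid = 5.05 [5.01, 5.08]

detect_breakpoint(curve)$breakpoint_rh
#> [1] 50
```

The fitted D (1.88 µm²/s) sits within ~4% of the simulated truth; the
at-bounds note flags that the recovery plateau touched the pre-bleach
ceiling, as expected for a fully mobile membrane. Inverting the calibration
places the membrane at ~66% RH, i.e. about 5 water molecules per lipid head
group; the interval propagates the D confidence bounds through both
monotone maps. The hinge fit puts the calibration knee at 50% RH.

A command-line interface wraps the same steps
(`inst/cli/hydrasense simulate|extract|fit|calibrate|sense|run`); see the
script header for flags and exit codes.

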