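---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroquant)
```

This vignette is the package's own account of the science it implements:
the constitutive model and its assumptions, the data-reduction steps, the
tunable parameters, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was genuinely
open.

## The mechanical model

Unconfined cyclic compression of an ultrasoft, nearly incompressible
hydrogel or tissue sample is idealized as a homogeneous uniaxial
deformation: the sample is assumed to slide freely on the platens, so no
barreling correction is applied. With axial displacement $\Delta z$ (mm,
negative in compression) and initial height $h$, the axial stretch is
$\lambda = 1 + \Delta z / h$; isotropy and incompressibility
($J = \lambda_1\lambda_2\lambda_3 = 1$) force the lateral stretches to
$\lambda^{-1/2}$. The nominal (Piola) stress is the measured force over
the *undeformed* cross-section, $P_{zz} = f_z/A$, converted once at the
input boundary from N/mm² to Pa.

The constitutive law is the incompressible one-term modified Ogden
strain-energy function

$$\psi_O = \frac{2\mu}{\alpha^2}\left(\lambda_1^\alpha + \lambda_2^\alpha
  + \lambda_3^\alpha - 3\right),$$

with classical shear modulus $\mu > 0$ (Pa) and dimensionless nonlinearity
$\alpha$. Because the uniaxial deformation is diagonal, the full spectral
Piola-stress machinery collapses to the scalar form

$$P_{zz} = \frac{2\mu}{\alpha}\left(\lambda^{\alpha-1} -
  \lambda^{-\alpha/2-1}\right),$$

with the hydrostatic pressure $p = (2\mu/\alpha)\lambda^{-\alpha/2}$ fixed
by the traction-free lateral boundary. The reduction is guarded by a
finite-difference test: the analytic stress must match the central
difference of the uniaxial energy
$\psi(\lambda) = (2\mu/\alpha^2)(2\lambda^{-\alpha/2}+\lambda^\alpha-3)$
to a relative error below $10^{-6}$ across a grid of parameter
combinations including strongly negative $\alpha$, and the lateral Piola
stress computed from the spectral form with the analytic pressure must
vanish. At $\alpha = 2$ the model reduces exactly to the neo-Hookean
uniaxial response $\mu(\lambda - \lambda^{-2})$. The stiffness summary is
the apparent Young's modulus $E_\mathrm{app} = 2\mu(1+\nu) = 3\mu$ at the
incompressible Poisson ratio $\nu = 0.5$; the package checks numerically
that $dP_{zz}/d\lambda$ at $\lambda = 1$ equals $3\mu$ for every tested
parameter pair, which is the link between the finite-strain model and the
small-strain summary.

### Preprocessing

Cyclic recordings (three cycles to 15% strain at 0.01/s are the protocol
defaults carried in `run_config()`) are segmented by locating turning
points on a moving-median-smoothed displacement (window 5 samples —
robust to sensor jitter; the smoothed signal classifies top/trough
regions, the raw signal supplies the exact extremal sample so that
noise-free waveforms segment exactly). A cycle counts as complete only if
its trough is followed by a return top; a monotone ramp therefore reports
zero complete cycles. Loading and unloading curves of a cycle are
linearly interpolated onto a uniform 100-point stretch grid over their
common range and averaged pointwise — the standard approximation of the
hyperelastic backbone from a hysteretic loop. Averaging happens in
$(\lambda, P_{zz})$ space after the kinematic conversion; for exact
geometry this is equivalent to averaging raw signals first. Cycle 1 is
labeled *unconditioned* and cycle 3 *conditioned*; headline fits use the
unconditioned curve, with conditioned fits reported alongside.
Per-condition averaged curves, not per-replicate parameter averages, are
the intended fit target: averaging fitted parameters across samples can
produce curves that match no observed response.

### Calibration

`fit_ogden()` minimizes $\chi^2 = \sum_i (P_{zz} - P_{zz}^\psi)_i^2$ by
bounded Levenberg-Marquardt least squares (via minpack.lm), with
$\mu \in (10^{-3}, 10^7)$ Pa and $|\alpha| \in [0.01, 50]$. The band
$|\alpha| < 0.01$ is excluded because the energy divides by $\alpha^2$;
the neo-Hookean-like regime is reachable at $\alpha = 2$, so nothing of
practical interest lives near the removable boundary. The $\alpha$ axis
is therefore split into a negative and a positive branch, and each of the
default start magnitudes $\{20, 5, 2, 10\}$ is optimized in both branches
(eight bounded sub-problems); $\mu_0$ is seeded from the small-strain
secant slope divided by three, clipped to bounds. The best converged run
wins and the full start audit is kept on the result object. The
multi-start is not decorative: the profiled objective can possess a
genuine secondary minimum in $\alpha$ (e.g. a shallow basin near
$\alpha \approx 3.5$ when the generating value is $10$ on a 15% strain
window), so single-start fits can stall; the procedure's answer is
independent of start ordering, which is what the tests assert. Soft
brain-like tissues commonly calibrate to negative $\alpha$, so the sign
is left free. Degenerate inputs (all-zero stress, under 5 points,
constant data making $R^2$ undefined) are rejected or flagged rather than
silently fitted. Fit quality is reported as $\chi^2$,
$\mathrm{RMSE} = \sqrt{\chi^2/n}$ and $R^2$.

## Morphometry

The traced neuron skeleton (SWC nodes with radii, µm) defines a capsule
union: each parent-child segment is a cone frustum with linearly
interpolated radius, and the endpoint clamp of the point-to-segment
distance supplies spherical caps. The surface distance of a punctum is
the minimum over segments of (distance to segment − local radius),
clamped at zero, and the inclusion rule is *inclusive*: a punctum at
exactly the 2.5 µm threshold counts. The threshold defaults to 2.5 µm —
the axial step of a typical confocal stack — and is exposed as a
parameter. Volume is the frustum sum with no overlap correction at branch
points (a documented simplification; branch-point overlap correction
would be an extension). Density is reported under both conventions in
use, puncta per 100 µm³ of neuronal volume and per 100 µm of neurite
length, privileging neither. The vectorized counter is verified against
an exhaustive per-segment brute-force loop on seeded scenes, exactly, and
distances are checked to be rigid-motion invariant to $10^{-9}$ µm.

## Calcium activity

Traces (ROI × frame, 10 Hz default) are normalized as
$\Delta F/F_0 = (F - F_0)/F_0$ with $F_0$ the 10th percentile of the raw
trace — a standard, testable baseline choice; the quantile is
configurable. Detection honors the three published parameters
(signal-to-noise ratio 2.2, noise window 1000 frames, minimum activity
count 2) and fills in the unpublished mechanics with documented choices:

- the noise scale $\sigma(t)$ is a rolling median absolute deviation
  (Gaussian-scaled, ×1.4826) over the window, robust to the transients
  that contaminate it; traces shorter than the window fall back to a
  global estimate with a warning;
- thresholding is applied to the rolling-median-*subtracted* signal —
  a percentile baseline leaves a small positive offset under noise that
  would otherwise corrupt an absolute threshold;
- candidate events must exceed threshold for at least 0.3 s (3 frames at
  10 Hz), which suppresses single-frame noise excursions that a 2.2σ
  threshold would otherwise admit in abundance over a 3000-frame trace;
- events closer than 0.5 s are merged, then extended to the baseline
  crossing on both sides, so the integrated area does not depend
  sharply on the exact threshold level.

Per ROI, AUC is the summed trapezoidal integral of $\Delta F/F_0$ above
zero within event windows (units $\Delta F/F_0\cdot$s), amplitude the
mean baseline-corrected event peak, frequency the event count per second.
A ROI is *active* only with at least 2 events; inactive ROIs stay in the
output, flagged, so group summaries can exclude them explicitly. All
scores are invariant under rescaling of the raw fluorescence.

## Group statistics

The routing contract: every group is screened with Shapiro-Wilk at
$\alpha = 0.05$; all-normal one-way designs go to one-way ANOVA with
Tukey-Kramer (Holm-Šídák on request), otherwise Kruskal-Wallis with
Dunn's test. Constant groups cannot be called normal and route
nonparametric, where fully tied data yields no rejection. Two-way
condition × day designs fit `value ~ condition * day` and report both
main effects and the interaction with Tukey tables (the post hoc is not
gated on the interaction; all terms are reported). The omnibus tests,
ANOVA and Tukey machinery are base R; Dunn's z statistics (with tie
correction, Bonferroni-adjusted by default — the adjustment is
configurable since the convention is not fixed in the field) and the
step-down Holm-Šídák adjustment are implemented and unit-tested here. A
Monte-Carlo harness (`type_i_error_check()`) verifies that the routed
omnibus holds its nominal level within binomial error under normal and
heavy-tailed nulls (2000 replicates in the acceptance suite).

## What the generators emulate — and what they do not

`generate_cyclic_recording()` produces a triangular displacement waveform
at the protocol strain rate around the exact Ogden baseline, with three
idealizations chosen to make preprocessing correctness a sharp identity
rather than an approximation: hysteresis is symmetric and multiplicative
(loading $(1+\eta)$, unloading $(1-\eta)$, default $\eta = 0.1$), the
loop closes at the turning points (turning samples carry the unscaled
baseline, as physical hysteresis loops do), and each phase is sampled on
100 uniformly spaced stretch values so the default 100-point averaging
grid lands exactly on sample points. Under these conditions the averaged
unconditioned curve must equal the baseline to machine precision, and the
tests demand better than $10^{-9}$ Pa. Conditioning is a single
multiplicative softening of cycle 3 (default 0.85) — enough structure to
test the unconditioned/conditioned bookkeeping, deliberately not a
Mullins damage law. Real rheometer data have rate-dependent,
asymmetric hysteresis, inertia and contact artifacts; passing these tests
shows the reduction pipeline is exact under its stated assumptions, not
that those assumptions hold for any instrument.

`generate_scene()` places puncta in or out of the 2.5 µm capsule shell by
construction (outside points clear a 2.6 µm margin), so counts are known
exactly; it does not emulate imaging noise, detection misses or tracing
errors. `generate_calcium_traces()` uses Poisson event times with
exponential decays (default rate 0.02/s, $\tau = 2$ s, amplitudes 0.3–0.5
in $\Delta F/F_0$, i.e. 6–10× the default 0.05 noise, over 300 s at
10 Hz — a 50-ROI recording); it omits bleaching, drift and overlapping
compound transients beyond linear superposition. `generate_group_data()`
draws labeled samples from stated families. Every generator takes one
explicit seed and returns its ground truth with the data.

## Problem sizes and numerical tolerances

The verification studies use 100-point curves on $\lambda \in [0.85, 1]$,
a 3 × 4 truth grid for clean recovery (0.1% relative), 200 seeded noisy
replicates at $(\mu, \alpha) = (150, -15)$ with 5% multiplicative noise
(relative RMSE of $\hat\mu$ under 10%, median bias within ±3%), 20 seeded
scenes of 1000 puncta for the brute-force counting comparison, 50 ROIs ×
300 s for frequency recovery (within 15%), and 2000 Monte-Carlo
replicates for the type-I error band [0.04, 0.06]. Optimizer tolerances
are $10^{-12}$ (ftol/ptol); the end-to-end study simulates three
conditions at apparent moduli 538/173/148 Pa with five replicates each
and 5% noise, and requires the recovered stiffness ordering plus a
significant largest-vs-smallest contrast.

## Known limitations

- One strain rate, hyperelastic-only: no viscoelasticity, no multi-term
  Ogden, no compressible or anisotropic formulation.
- No uncertainty quantification on $(\mu, \alpha)$; bootstrap intervals
  would be a natural extension.
- Capsule volumes double-count overlaps at branch points.
- The calcium detector is a documented re-interpretation constrained by
  three published parameters; it does not claim to reproduce any
  proprietary tool's exact outputs, and AUC additivity under trace
  concatenation holds only to integration tolerance because the rolling
  noise window couples neighbouring segments.
- The statistics layer reproduces procedures, not any specific published
  p-values, which would require the underlying per-sample data.
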