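---
title: "Field-modulated IR difference nanospectroscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-modulated IR difference nanospectroscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starkir)
```

This vignette is the package's own account of the science it
implements: the measurement protocol it assumes, the Stark model and
its unit bookkeeping, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely
open.

## The measurement and the difference protocol

A conductive AFM tip in contact mode applies a bias $V_i$ across a thin
film (thickness $d$) on a metallic substrate while photothermal IR
absorption spectra $A(\nu)$ are recorded through the same tip. Because
the field-induced change is small — a few percent of the band maximum —
spectra are acquired in interleaved pairs, at bias and at zero bias,
and single-shot differences
$\delta A(\nu)_i = A(\nu)|_{V_i} - A(\nu)|_0$ are averaged over $N$
repeat cycles (about 10 in routine use) into $\Delta A(\nu)_i$ with a
per-point standard error. Pairing each at-bias acquisition with the
zero-bias acquisition of the *same* cycle cancels drift that is slow on
the cycle timescale; `build_schedule()` encodes exactly this
interleaving, and `series_differences()` performs the pairing and the
averaging. Whether the reference is re-acquired each cycle or shared
across cycles is not dictated by the protocol itself; the package
adopts per-cycle references (the stronger drift-cancelling choice) and
keeps the pairing rule in one place.

For a flat tip wider than the gap, the static field is well
approximated by the parallel-plate value $F = V/d$
(`parallel_plate_field()`); both gap geometries of interest here — 16.5
V across 55 nm and 3 V across 10 nm — give 0.3 V/nm. The local field
correction factor $f$ multiplies this nominal field; flat tips sit in
$1 \le f \le 2$, and sharper tips concentrate the field further
(`field_model()` permits $f > 2$ with a warning).

## The Stark model in the Liptay derivative basis

For an isotropic, immobilized ensemble the field cannot pick a shift
direction; it broadens the band, quadratically in the field. The
package uses the standard Liptay expansion of the field-induced
absorbance change in three line shapes derived from the zero-field
band:

$$\Delta A(\nu) = (f F)^2\left[a\, b_0 + b\, b_1 + C_\chi\, b_2\right],
\qquad b_0 = A,\quad b_1 = \nu \frac{d}{d\nu}\frac{A}{\nu},\quad
b_2 = \nu \frac{d^2}{d\nu^2}\frac{A}{\nu},$$

$$C_\chi = \frac{\Delta\mu^2}{30\,h^2c^2}
\left[5 + (3\cos^2\zeta - 1)(3\cos^2\chi - 1)\right].$$

The $b_0$ term carries transition-moment effects and the $b_1$ term
polarizability changes; both are typically negligible against the
dipole-moment-change term and default to zero in the forward model but
are always carried in the fit. The geometric factor involves $\chi$,
the angle between static and IR fields, and $\zeta$, the angle between
$\Delta\vec\mu$ and the transition moment. In the tip geometry both
fields are enhanced along the tip axis and the C=O transition moment
is taken parallel to $\Delta\vec\mu$, so the defaults are
$\chi = \zeta = 0$ and the factor is 9; both angles remain explicit
parameters of `vse_forward()` and `extract_delta_mu()` because the
geometry is an assumption, not a measurement.

With $\Delta\mu$ in Debye and $F$ in V/nm, $\Delta\mu\, fF/(hc)$ is a
wavenumber, so $C_\chi (fF)^2$ is in cm$^{-2}$ and multiplies $b_2$
(a.u. cm$^2$). The same expression is implemented in SI and in cgs-esu
units from one constants table (`stark_constants`); the two routes
agree to machine precision and are cross-checked in the tests. The
Debye is carried as its exact esu definition
($10^{-21}/c \approx 3.33564 \times 10^{-30}$ C·m, conventionally
rounded to $3.34 \times 10^{-30}$); any self-consistent choice cancels
in the parameter-recovery round trips that anchor the package's
validation, because the exact numerical prefactor convention of the
Liptay form cancels between forward model and inverse analysis.

`fit_vse()` solves the weighted linear least-squares projection of
$\Delta A$ onto $\{b_0, b_1, b_2\}$, weighting by $1/\mathrm{sem}^2$
when repeat statistics are available. First-order perturbation theory
makes $\Delta\mu$ field independent, so $c_2 = C_\chi (fF)^2$ must be
linear in $F^2$; `extract_delta_mu()` regresses $c_2$ on $F^2$
*through the origin* — $\Delta A$ vanishes at zero field by
construction — and reports a free-intercept fit only as a diagnostic,
together with an uncentered $r^2$. The slope converts to $\Delta\mu$
via the same forward constants; the confidence interval comes from
first-order (delta-method) propagation through the square root. A
negative fitted slope, which noise can produce, maps to
$\Delta\mu = 0$ with a `degenerate` flag rather than an error, so
pipelines never abort on a weak series. With a calibration sample of
known $\Delta\mu$, `estimate_local_field_factor()` inverts the same
relation for $f$.

## Derivatives, smoothing, and why the reference is smoothed

Derivatives are estimated on the native wavenumber grid with 5-point
finite-difference stencils built from interpolating-polynomial
(Fornberg) weights — centered in the interior, shifted at the edges.
On the 0.5 cm$^{-1}$ preset grids this is 4th-order accurate; plain
3-point stencils would leave errors of several $10^{-4}$ of
$\max|b_2|$ for a 24 cm$^{-1}$-wide band, which the refined-grid oracle
tests would reject. Grids are treated as arbitrary monotone sequences
and all integrals are trapezoidal.

Second differencing amplifies point noise as $1/h^2$: on a 0.5
cm$^{-1}$ grid, even the $\sim 10^{-3}$-level noise that survives
averaging 40 zero-bias acquisitions would dominate $b_2$ and, because
the noise sits in the *regressors*, attenuate the fitted coefficients
(classical errors-in-variables). The acquisition protocol's
smoothing-spline step resolves this: `run_pipeline()` passes the
averaged zero-bias reference through a cubic smoothing spline with the
penalty chosen by generalized cross-validation
(`smooth_spectrum(..., "auto")`, built on `stats::smooth.spline`)
before the basis is computed. GCV on a noiseless band is nearly the
identity (deviations $\sim 10^{-5}$ of the peak), so exact round trips
survive the default; `ref_smoothing = 0` disables the step entirely.
Smoothing of the averaged differences themselves is off by default —
the weighted fit handles their noise correctly — and available for
display.

## Line-shape classification

A rigid band shift $s$ produces $\Delta A \approx -s\,dA/d\nu$, a
first-derivative shape, whereas Stark broadening is second-derivative
like. `decompose_shape()` projects $\Delta A$ onto
$\mathrm{span}\{b_0, b_1, b_2\}$ by least squares under the
trapezoidal inner product and attributes the explained energy by the
covariance decomposition
$f_k = c_k\langle\Delta A, b_k\rangle / \lVert\Delta A\rVert^2$, which
sums with the residual fraction to exactly 1. The attribution question
is real: $b_0$ and $b_2$ are strongly correlated (both even about the
band center), so squared projections onto any Gram–Schmidt
orthogonalization would split a pure $b_2$ signal across components
according to the chosen ordering; the covariance attribution instead
assigns all energy to $b_2$ whenever $\Delta A \propto b_2$, which is
the behavior a classifier should have. The dominance rule
(`classify_mechanism()`) requires the leading component to carry at
least twice the energy of the other two combined (threshold 2 by
default); it is deliberately conservative — an ambiguous mixture is
labelled `mixed`, never flipped between mechanisms.

## Membrane-protein features

For oriented protein stacks three quantities summarize the amide-I
difference response:

* **Orientation.** Absorption scales as $\cos^2\theta$ in the angle
  between transition dipole and IR field;
  `orientation_response(theta0, dtheta)` returns the relative
  amplitude change of a tilt. The package applies the $\cos^2$ law to
  the transition-dipole angle; statements about the static dipole's
  angle to the IR field involve the protein's internal geometry and are
  outside what this simple selection-rule model can resolve, a
  limitation stated here deliberately.
* **Apparent shift.** `peak_shift()` estimates the displacement that,
  applied to the reference band, reproduces the windowed centroid of
  reference-plus-difference. The *raw* windowed-centroid difference is
  biased low whenever the window truncates the band asymmetrically —
  for a 45 cm$^{-1}$-wide amide-I band in the 1600–1700 cm$^{-1}$
  window a genuine 9 cm$^{-1}$ shift would read as ~7.1 — so the
  matched-centroid inversion (root finding on the shift, exact for a
  rigid shift) is the primary estimate, with the raw difference and the
  first-derivative projection $-\langle\Delta A, A'\rangle /
  \lVert A'\rVert^2$ reported as diagnostics.
* **Protonation marker.** `window_features()` integrates $\Delta A$
  over named windows (defaults 1500–1560, 1600–1700, 1730–1780
  cm$^{-1}$ for retinal, amide-I and carboxyl-protonation regions; the
  bounds are conventional and configurable) and flags a window when
  its integral exceeds 3 times its propagated standard error, matching
  the averaging model of the acquisition module.

## What the generator emulates — and what it does not

The synthetic presets define the study conditions under which the
package validates itself:

| preset | band (center/fwhm, cm⁻¹) | d (nm) | bias (V) | response |
|---|---|---|---|---|
| `pmma55` | Gaussian 1731 / 24 | 55 | 6, 9, 12, 16.5 | VSE, Δμ = 0.065 D, f = 1 |
| `pmma23` | Gaussian 1731 / 24 | 23 | 6, 9, 12, 16.5 | shift, 0.06 cm⁻¹/V |
| `br10` | Gaussian 1665 / 45 | 10 | ±3 | polarity-asymmetric |

The PMMA band parameters are conventional values for the PMMA carbonyl
(the shape matters more than the exact numbers for every test, since
all validation is by round trip); the amide-I width of 45 cm$^{-1}$ is
a typical value for membrane proteins, and the protonation marker is a
12 cm$^{-1}$-wide band at 1760 cm$^{-1}$. The bacteriorhodopsin preset
maps polarity to mechanism phenomenologically — cos² amplitude response
at one polarity ($\theta_0 = 38°$, a typical amide-I transition-dipole
tilt for helical bundles, +1° per 3 V), a 9 cm$^{-1}$ apparent shift at
the other, marker only at the negative polarity — and the mapping is
configuration, not code.

Noise is white with $\sigma = 0.005$ of the unit band peak per point
plus a smooth quadratic baseline wander bounded by 0.002, chosen so
that a difference signal of a few percent of the band maximum is
cleanly resolved after 10-repeat averaging — the regime the protocol is
designed for. Order 2 for the drift mimics slow photothermal baseline
wander without introducing band-like artifacts. Every generator is a
pure function of (preset, repeats, seed), drawn from a private RNG
stream that leaves the caller's state untouched.

The generator deliberately does **not** model photothermal expansion
physics, cantilever mechanics, tip electrostatics, static-charge
dynamics, electroporation, or the retinal photocycle. Passing tests
therefore demonstrate the *analysis chain* — difference construction,
fitting, regression, classification, feature extraction — under the
statistical structure the protocol assumes, not the instrument physics
upstream of it.

## Numerical choices and problem sizes

* Spectra must have ≥ 8 points, strictly increasing positive
  wavenumbers; the basis needs ≥ 5 points (the stencil width).
* Degenerate references (e.g. $A \propto \nu$, which annihilates $b_1$
  and $b_2$) are rejected by a singular-value test after
  nondimensionalizing the basis columns with powers of the grid step.
* The through-origin $r^2$ is uncentered ($1 - \sum w r^2 / \sum w
  c_2^2$); with a free intercept the usual definition would be
  inconsistent with the origin constraint.
* Ties in `classify_mechanism()` (both dominance conditions met, only
  possible at thresholds ≤ 1) resolve to the larger fraction.
* `peak_shift()` brackets its root at ±(grid span)/4 and falls back to
  the raw centroid difference if root finding fails.
* Validation problem sizes: preset grids of 321 (PMMA) and 401 (BR)
  points; the repeat-averaging and recovery suites use up to 100
  replicates of 10-repeat, 4-bias series, which keeps the full test
  suite in the low minutes on a single core.

## Known limitations

* The Liptay prefactor convention is fixed by the package's own
  forward model; absolute $C_\chi$ values quoted across conventions
  differ by constant factors, though $\Delta\mu$ recovered by round
  trip does not.
* `fit_vse()` assumes the reference band is noise-free after
  smoothing; residual reference noise biases coefficients toward zero
  (attenuation), which matters below ~10 repeats at the default noise.
* The cos² orientation model treats the band as a single rigid
  transition dipole; secondary-structure decomposition of amide-I is
  out of scope.
* JCAMP-DX support covers AFFN `(X++(Y..Y))` and `(XY..XY)` blocks
  only (no ASDF/DIF compression).
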