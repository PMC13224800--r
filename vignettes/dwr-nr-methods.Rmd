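---
title: "Methods: flow-field-based DWR rheology and constrained monolayer reflectometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow-field-based DWR rheology and constrained monolayer reflectometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwrnr)
```

This vignette documents the models, conventions and numerical choices
behind `dwrnr`, in the spirit of a methods section: what is computed, under
which assumptions, and what the synthetic tests do and do not demonstrate.

## The measurement and its model

A double wall–ring (DWR) interfacial shear cell is a ring of diamond cross
section suspended at a fluid interface inside an annular double-gap
channel.  The sheared interface spans the two annular gaps
`[R_i, R4]` and `[R5, R_o]`; the ring touches the interface only along the
two contact-line circles `R4` and `R5`.  In oscillatory operation the raw
observables are the torque and angular-displacement waveforms, condensed at
the fundamental into the complex amplitude ratio
`AR* = (T0/θ0) e^{iφ}`.  With the time convention `e^{+iωt}` and the
angular displacement as phase reference, the rotor+probe equation of motion
gives

```
AR* = −I ω² + iω (K_i* + K_b*)
```

with `I` the rotor+probe inertia and `K_i*`, `K_b*` the interfacial and
bulk drag torque coefficients per unit angular velocity (drag convention:
torque on the probe is `−(K_i*+K_b*)·Ω`, so viscous drags have positive
real part).  The interface enters through the complex Boussinesq number

```
Bo* = η_s* / (η a),    G* = G′ + iG″ = iω η_s*,
```

where `η` is the subphase viscosity and `a` the probe's area-to-perimeter
length scale (`a = L = diagonal/√2` for the diamond, two contact lines).
Sign conventions are pinned down by two physical checks that the test
suite enforces: a purely elastic interface produces torque in phase
opposition to the displacement, a purely viscous one in quadrature.

Because drags depend on the flow field and the flow field on `Bo*`, the
moduli cannot be read off the equation of motion directly; the package
solves the hydrodynamic problem and iterates (flow-field-based data
analysis).

### Assumptions

* Newtonian bulk phases, linear viscoelastic interface, single azimuthal
  velocity component (axisymmetric small-amplitude oscillation); no
  Marangoni stresses, no meniscus curvature, contact lines pinned at the
  diamond's lateral vertices.
* Frequency dependence of the momentum-decay length scales inside `Bo*`
  is neglected (narrow frequency window of interfacial rheometry).
* The upper phase (air) is negligible by default; a two-phase solve
  (`build_mesh(..., two_phase = TRUE)`) adds the upper-layer stress and
  drag terms when the upper viscosity matters.
* Strain control is idealized in the simulator: the angular amplitude is
  set exactly from the target average strain; the rheometer's internal
  feedback loop is not modelled (its internals are proprietary and do not
  affect the analysis of the steady-state fundamental).

## The flow solver

The azimuthal velocity amplitude `u(r, z)` (per unit probe angular
velocity) obeys `∇²u − u/r² = (iωρ/η) u` in the bulk, `u = r` on the
probe, `u = 0` on walls and bottom, and the Boussinesq–Scriven balance
`η_s^*(u_rr + u_r/r − u/r²) = η u_z|₀₋ − η_top u_z|₀₊` on the free
interface.

Internally the solver works in the reduced variable `φ = u/r`, for which
both the bulk operator and the surface operator take conservation form:

```
∂_r(r³ φ_r) + ∂_z(r³ φ_z) = (iωρ/η) r³ φ,
η_s* ∂_r(r³ φ_r) + [η r³ φ_z] = 0  at z = 0,
```

and the azimuthal traction is `η r ∂φ/∂n`, so the torque across any
contour is `2πη` times the flux of `r³∇φ`.  A finite-volume scheme on this
form is discretely conservative.  The grid is piecewise uniform in `r`
with nodes snapped exactly onto `R_i, R4, R5, R_o`; in the ring band the
radial spacing equals the vertical spacing so the diamond's 45° faces pass
exactly through grid nodes (no staircase geometry error).  The complex
system is solved as an equivalent real block system by sparse LU after row
equilibration; relative residuals are checked against 1e-8.

### Drag evaluation

* `K_i*`: Boussinesq–Scriven stress at the two contact lines,
  `2π η_s* (R4³ φ′(R4⁻) − R5³ φ′(R5⁺))`, with one-sided second-order
  stencils on each side.
* `K_b*`: the default is the discretely conservative route — the
  finite-volume stencil summed over the probe node set telescopes to the
  flux through the dividing surface; subtracting the fluid-inertia content
  of the cells straddling the wetted faces moves that surface onto the
  true probe boundary, and `K_b* = K_total − K_i*`.  A direct one-sided
  traction integration over the wetted faces is available
  (`compute_drags(..., method = "surface")`) as a cross-check.

The direct surface integral is *not* the default because the traction is
singular at the contact lines (mixed boundary-condition corners) and at
the ring's lower vertex (re-entrant corner), which caps its observed
convergence near first order.  The conservative route restores clean
second-order behaviour in the high-Bo regime (refinement-ratio ≈ 4 per
mesh halving for both coefficients, verified in the tests together with
the analytic annular-Couette limit).  At moderate Bo (|Bo| of order 1–100)
the corner singularities still slow the convergence of `K_b*` (observed
ratios 2–3); this is a known limitation.  It matters little in practice:
the inversion's accuracy is dominated by `K_i*` wherever the interface is
measurable, and forward-simulation/inversion pairs share the same mesh so
discretization bias cancels in round-trip studies.

## The inversion

`invert_ar()` iterates

```
Bo_{k+1} = Bo_k · (AR* + Iω² − iω K_b*(Bo_k)) / (iω K_i*(Bo_k))
```

seeded from the analytic high-Bo inversion `G* = (AR* + Iω²)/g1`.  The
multiplicative update is chosen because `K_i*` is asymptotically linear in
`Bo*` at frozen flow field, making the map a first-order fixed point;
empirically it converges monotonically over `|Bo| ∈ [1e-2, 1e6]` on the
default geometry in a handful of iterations (tolerance `1e-6` on `Bo`,
cap 100 iterations, flow solutions cached per `(mesh, ω, Bo)`).  Results
are flagged `inertia_limited` when `|G*| < Iω²/g1`; recovered `G″ < 0`
beyond the propagated noise is flagged as unphysical.  Measurement
uncertainty on `AR*` maps to the moduli at first order through
`dG*/dAR* = G*/(iω K_i*)`.

`g1`, the high-Bo geometric drag coefficient, uses the annular-Couette
closed form `4π[R_i²R4²/(R4²−R_i²) + R5²R_o²/(R_o²−R5²)]`; it is not
asserted but validated against the PDE solver's high-Bo elastic limit
(<1% on three geometries in the tests).

## Signal digitization

Raw records carry four channels: angle (600 V/rad), two torque channels of
different gain, and a trigger.  The chain is: rising-edge segmentation;
discard of the leading 20% of each segment (start-up transient,
configurable); selection of the longest whole-period suffix; single-bin
DFT at the fundamental (exact for integer periods); dual-gain merge (the
high-gain channel is used unless its raw peak exceeds 95% of the ADC
range); ratio and phase difference (a common time origin cancels).  Noise
is estimated from the spectrum itself — the bins excluding DC, the
fundamental and its first three harmonics give the noise density, and
`σ_amp = sqrt(2 P_noise / N)`, `σ_phase = σ_amp / amplitude`.  This
periodogram estimator is validated against Monte-Carlo spreads (within
~20%) rather than asserted exactly, since its constants depend on
windowing conventions.

## The synthetic instrument

`simulate_record()` realizes the second-order dynamic model: steady-state
`θ(t) = θ0 cos ωt`, `T(t) = |AR*| θ0 cos(ωt + arg AR*)` with `AR*` from
the full forward model, channel gains, white Gaussian noise per channel
(either explicit volts or a target SNR), 16-bit quantization over ±10 V,
and a trigger edge per waveform.  Defaults mirror the study conditions:
frequencies 0.3–3 Hz, 3% average strain, 16 periods per waveform,
`fs = 500 Hz`.  Torque-channel gains (1e4 / 1e6 V/(N m)) and the rotor
inertia `I = 1e-5 kg m²` are placeholders at realistic magnitudes for an
air-bearing rotational rheometer — neither is printed in instrument
datasheets at this precision; `calibrate_inertia()` fits `I` from a
clean-interface sweep (and its residuals flag interfacial contamination).

What the simulator does *not* emulate: 1/f noise, motor torque ripple,
bearing drift, trough vibrations, feedback-loop dynamics, nonlinear
(large-amplitude) response.  Passing round-trip tests therefore
demonstrates the correctness of the analysis chain, not robustness to
every instrumental artefact.

## Reflectometry

`abeles_reflectivity()` is the standard optical transfer matrix over a
slab stack with Névot–Croce Gaussian-roughness factors; tests pin it to
the Fresnel closed form, the critical edge `Qc = (16π·SLD)^{1/2}` of bare
D₂O, and zero reflectivity at zero contrast.  Wavelength resolution
(`dλ/λ` constant for a time-of-flight instrument, 7% default) is mapped to
constant `dQ/Q` Gaussian smearing in FWHM convention, evaluated by
Gauss–Hermite quadrature on the model function (angular-divergence
contributions are out of scope).

The monolayer model is two slabs sharing one area per molecule: tail
thickness `V_AC/A_mol` with full occupancy, head hydration
`1 − V_head/(A_mol·d_head)`; a single roughness σ at all three interfaces
follows the capillary-wave picture (per-interface override available).
Defaults are literature values for chain-deuterated DPPC: `V_AC = 759 ų`
(condensed phase), `V_head = 344 ų`, `d_head = 9 Å`, tail SLD 8.08,
head SLD 1.74 (1e-6 Å⁻²); the D₂O SLD is fitted per contrast (isotope
exchange with atmospheric water lowers it), backgrounds are fixed per
contrast.  Co-refinement minimizes the pooled χ² with Levenberg–Marquardt
from three starts (±10% in `A_mol`) to avoid fringe-aliasing minima;
uncertainties come from the local quadratic approximation.  Synthetic
curves use a logarithmic grid 0.01–0.35 Å⁻¹ (120 points, a typical
horizontal-reflectometer span) with relative Gaussian noise as a proxy for
counting statistics.

ACMW (air-contrast-matched water) composition: solving
`x·SLD_D2O + (1−x)·SLD_H2O = 0` with 6.36/−0.56 gives x = 8.09% by
volume (8.9% by mass); `acmw_fraction()` returns both conversions since
quoted recipes do not always state which convention they use.

## Numerical parameters and degenerate inputs

| parameter | default | notes |
|---|---|---|
| mesh `resolution` | 24 | radial intervals across the inner gap; halving error ≈ 4× per doubling (high Bo) |
| channel `depth` | 5 mm | ≥3× gap width so bottom effects are <1% |
| `R4`, `R5` | 23.0 / 24.0 mm | not manufacturer-printed; chosen near the equal-contact-line-strain condition, overridable |
| fixed-point `tol` | 1e-6 | relative, on `Bo` |
| solver residual | <1e-8 | relative, after row equilibration |
| discard fraction | 0.2 | transient part of each waveform |
| `dq_over_q` | 0.07 | FWHM, time-of-flight wavelength resolution |

Degenerate inputs raise errors rather than returning garbage: zero-width
gaps, over-packed headgroups (`solvent fraction ∉ [0,1]`), saturated dual
channels, segments shorter than one period, non-monotone `Qz` grids,
unknown configuration keys.

## Problem sizes used by the test suite

The shipped tests run the solver at resolutions 12–48 (up to ~11k nodes),
the end-to-end recovery study over `f ∈ {0.3, 0.5, 1, 3}` Hz ×
`G″ ∈ {1e-4, 1e-3, 1e-2}` N/m at SNR 100 (median `G″` error <2% outside
the inertia-limited region), DFT Monte-Carlo studies with 300–1000 draws,
and two-contrast reflectivity co-refinements at 5% noise (A_mol recovered
within 1%).  These sizes were chosen so the full suite runs in well under
a minute on a laptop while still resolving every quoted tolerance.

## Known limitations

* The channel bottom is modelled flat; the real cell has a double-step
  radial profile (meniscus pinning), so very shallow channels are not
  represented exactly.
* `K_b*` convergence at moderate Bo is corner-singularity limited (see
  above); absolute drag accuracy there is set by the default resolution
  rather than the asymptotic order.
* The spectral-noise estimator's constants are convention-dependent; it
  is validated statistically, not bit-exactly.
* Nonlinear viscoelasticity (higher harmonics), creep and stress
  relaxation are out of scope; harmonics are computed for diagnostics
  only.
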