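---
title: "Modelling a 434 MHz coaxial TEM applicator for in vitro hyperthermia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a 434 MHz coaxial TEM applicator for in vitro hyperthermia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

coaxtherm models an open-ended coaxial TEM applicator for laboratory
hyperthermia: a hollow inner conductor (outer diameter `d`) with a
circumferential aperture of width `w`, inside an outer conductor (inner
diameter `D`, height `h`) with an HDPE-filled annulus, fed at 434 MHz from a
50 Ω source. A salt-doped agar phantom with muscle-like electrical
properties (σ = 0.755 S/m, ε~r~ = 74 at 434 MHz) sits in a PVC tube in the
bore; the design goal is a controlled, uniform temperature rise in a 1 cm³
cubic volume of interest (VOI) centred on the aperture. This vignette is
the package's own account of the models, the numerical choices, and the
places where the device geometry is under-determined and a convention had
to be chosen.

## Electromagnetic model

The device is a body of revolution and the fed mode is TEM, so the full 3D
Maxwell problem reduces exactly to the azimuthal-mode-zero field set
(E~r~, E~z~, H~φ~) on an (r, z) half-plane. `run_fdtd()` integrates this
set with a leap-frog finite-difference time-domain scheme on a staggered,
non-uniform grid; on-axis E~z~ uses the Ampère contour update. Media enter
through per-cell permittivity and conductivity (`default_materials()`),
metals as perfect electric conductors. Phasors are extracted by projecting
the fields onto the drive frequency over one full period after the feed
current amplitude has stabilised (relative cycle-to-cycle change below
`tol`, default 1e-4, at most `max_periods` = 60 periods). The ohmic loss
density is then `p_loss = σ (|E_r|² + |E_z|²)/2` and SAR = `p_loss/ρ`
(point SAR per cell, no mass averaging).

Key numerical choices:

* **Time step** — `courant` (default 0.95) times the cylindrical stability
  limit computed from the smallest cell; the on-axis contour update
  contributes a factor 2 on the radial term, which the limit includes. The
  step is then rounded so that an integer number of steps covers one source
  period, keeping the phasor projection exact.
* **Boundaries** — first-order Mur absorbing conditions on the padded
  domain boundary, using the local wave speed of the boundary cells. On a
  uniform dielectric-filled line this termination reflects about 0.01 % in
  amplitude, which is what makes the matched-line validation below
  meaningful. The default padding is 17.3 cm of air on every open side.
* **Conductors as sheets** — conductors are zero-thickness perfectly
  conducting sheets on mesh faces at radii d/2 and D/2 (plus the closure
  plates). This keeps the TEM line radii — and hence the 50 Ω sizing rule
  `Z = 138 log10(D/d)/sqrt(eps_r)` — exact at any resolution, and it makes
  the nominal wall thickness a recorded parameter (`conductor_wall`)
  rather than a meshing constraint. The documented wall/tube defaults are
  mutually inconsistent as volumes (3.0 cm phantom + 2.5 mm tube wall +
  2 mm brass ≠ 3.5 cm bore); the sheet representation is the one reading
  that makes them consistent.
* **Feed** — the "edge source with a 50 Ω load" is realized as a ~4 mm
  gap between the bottom plate and the inner conductor, driven by a
  semi-implicit lumped voltage source split in series over the gap cells.
  A one-cell delta gap was tried first and carries several pF of parasitic
  shunt capacitance; the distributed gap reduces it substantially. Feed
  voltage and current are measured at a reference plane about 1 cm up the
  line (annulus line-voltage integral and an H-field current loop on the
  same z-edge), outside the evanescent near-field of the gap. On a
  matched uniform line this reproduces the analytic characteristic
  impedance to better than 1 %.
* **Top closure** — the device description leaves the top of the
  annulus open, but an open-top model is almost purely reactive at
  434 MHz with no reflection dip anywhere in 100–1000 MHz, contradicting
  the device's measured matching behaviour. With the annulus shorted by a
  top plate the model shows the documented broad dip across 300–500 MHz
  (the classic shorted-stub topology of this applicator family), so
  `top = "closed"` is the default; `"open"` remains available. Even so,
  the converged model reaches S11 ≈ −3.9 dB at 434 MHz against the
  measured −8.5 dB: the series coupling resistance of the
  aperture-plus-phantom stays near 12 Ω in every convention we tried
  (open/closed top, volumetric walls, closed bore bottom). We attribute
  the remaining difference to hardware that is deliberately out of scope
  (epoxy support insulators, polycarbonate plates, the N-connector
  transition), and report the reflection level honestly.

## Thermal model

`run_transient()` integrates ρ C~p~ ∂T/∂t = ∇·k∇T + P~loss~ with a
conservative finite-volume discretization on the same (r, z) grid:
harmonic-mean face conductivities, full-revolution cell volumes, Dirichlet
temperature `T_ext` on the outer domain boundary, initial state `T_ext`
everywhere, and unconditionally stable implicit-Euler stepping (default
`dt` = 1 s; the per-step linear system is factorised once with a sparse
Cholesky decomposition and reused). There is no perfusion, convection or
radiation term and material properties are temperature-independent. The
loss field is computed once per geometry and linearly rescaled to the
effectively supplied power of each schedule segment (`scale_loss()`,
`power_schedule()`).

The metal question deserves a note. The documented treatment "excludes"
the thin metal walls from the thermal stage. With sheet conductors there
are literally no metal cells, so exclusion is automatic; but a 2 mm brass
tube is also a strong in-plane heat spreader, and including its in-plane
conduction and heat capacity along the sheet faces (`metal =
"conducting"`, the default, using the nominal `conductor_wall` thickness
and the brass entry of the material table) moves the simulated
40-minute probe temperatures onto the measured ones (the VOI-centre peak
shifts by about −3 °C). `metal = "transparent"` recovers the strict
exclusion reading.

Validation anchors (all in the test suite): the steady uniformly heated
cylinder with a cold surface matches the parabolic closed form
ΔT = q(R²−r²)/4k within 1 %; the discrete energy balance closes to solver
precision each step; halving the time step changes a 40-minute transient
by less than 0.05 °C; cooling obeys the maximum principle.

## Dosimetry over the cubic VOI

The cube is not axisymmetric, so VOI statistics sample the (r, z) field on
a regular lattice inside the cube (default 40³ points, bilinear
interpolation, equal volumes). Percentiles use the exceedance-volume
convention standard in hyperthermia dosimetry: P5 is the highest loss
density exceeded in at least 5 % of the volume, P95 in at least 95 %;
`eta_P = (P5−P95)/P5` and `eta_T = (T5−T95)/T5` with temperatures in
**degrees Celsius** (a Kelvin convention would shrink `eta_T` by an order
of magnitude and is not what the reported 0.06 means). The
deposited-power fraction `alpha` uses the delivered (input minus
reflected) power at the feed as denominator — the quantity the
experimental power meters report — not the total absorbed power; the two
differ by the small boundary outflow.

## Virtual instrumentation

The synthetic-data layer reproduces the measurement chain, so every
comparison in the package runs without physical data:

* `probe_layout()` — three fiber-optic thermometers at r = 0, 0.5 and
  1 cm with points on a 2 cm axial grid (14 points). The constrained ids
  are honoured exactly (#3 at the VOI centre, #2/#4 at ±2 cm, #9 at
  (0.5, 0), #12 at (1, 0)); a strictly monotone id ordering along fibers
  B and C is impossible inside a 10 cm phantom with those constraints, so
  the ordering of the unconstrained ids is a package convention.
* `sample_probes()` — exact bilinear samples plus Gaussian reading noise;
  the stated ±0.1 °C instrument accuracy is mapped to a 0.05 °C standard
  deviation (±2σ covers the accuracy band).
* `ir_snapshot()` — the split-phantom infrared image: the cooled state at
  power-off + delay (default 180 s), mirrored into a full longitudinal
  section, with 0.2 °C pixel noise. Only conduction acts during the
  delay; evaporative and contact cooling of the freshly opened surface
  are deliberately not modelled, which matters when comparing measured
  spatial gradients (see Limitations).
* `sample_phantom_properties()` and `power_trace()` — lognormal batch
  variability of the agar properties and a 1 % multiplicative power-meter
  noise. Every generator is a pure function of its inputs and an integer
  seed; identical seeds give bit-identical output.

## Design study and experiment protocols

`run_sweep()` reruns the design space: d ∈ {2.2, 3.5, 4.3} cm,
w ∈ {0.7, 1.2, 1.7, 2.2} cm, h = 8 cm, with D solved per combination from
the 50 Ω constraint and the tube/phantom adapted to fill the bore
(phantom diameter d − 0.5 cm). `select_design()` implements the documented
rule: within 0.005 of the per-diameter optimum of `eta_P` (a near-tie in
uniformity), require the aperture and bore to accommodate standard vials
(w ≥ 1.2 cm, d ≥ 3 cm), then maximise `alpha`; on the default sweep this
returns the built prototype (3.5, 1.7).

The three characterization protocols mirror the laboratory ones:
`experiment_transients()` (40 min at 2.5/3/3.6 W effective + 10 min
cooling, one field solve reused across levels),
`experiment_steady_state()` (43 °C hold: ~18 W preheat for 2 min, then
proportional–integral feedback on the VOI-centre point, gain 5 W/°C,
integral time 60 s, output clipped to 0–20 W, anti-windup; the controller
settles on a hold power of ≈3.4 W, inside the documented 3–3.4 W band)
and `experiment_focus()` (5 W for 5 min, virtual infrared image 3 min
after power-off, `eta_T` and longitudinal decay of the rise).
Point-to-point percentage reductions are reported in both circulating
conventions (`temp_reduction()`): on the Celsius temperatures themselves
and on the rises above ambient.

## Problem sizes

Default characterization runs use 1 mm cells in the bore/aperture region
(2 mm over the rest of the applicator, geometric grading to 5 mm across
the padding, ~13 000 cells) — profile shapes and probe temperatures change
by under 0.2 °C when refined to 0.5 mm, which the test suite checks — and
1 s thermal steps. The acceptance script runs the full pipeline (one field
solve, three 50-minute transients, the controlled hold and the focus
protocol) in well under a minute at these sizes; the 12-combination sweep
uses 1 mm cells as its own default and 1.5 mm in the test suite.

## Known limitations

* The reflection level: the model reproduces the shape of the matching
  dip but reaches −3.9 dB rather than the measured −8.5 dB at 434 MHz
  (support dielectrics and the connector transition are not modelled).
  Because every thermal protocol rescales the loss field to the
  *effective* power, this does not propagate into the temperature
  predictions.
* Axial spread: the simulated temperature falls off along the phantom
  axis somewhat faster than the measured ±2 cm points suggest at 3.6 W
  (the reported reductions at the two lower powers bracket the model),
  and the local radial curvature between the VOI centre and boundary is
  steeper than the measured 0.4 °C.
* The split-phantom image is idealized: without evaporative/contact
  cooling of the opened surface the virtual image is smoother than a real
  one, so image-derived heterogeneity (`eta_T`) and steep near-boundary
  decay statistics sit below measured values.
* No perfusion or thermoregulation: the thermal model is for phantoms,
  not tissue.
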