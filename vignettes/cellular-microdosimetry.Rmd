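---
title: "Cellular microdosimetry of radioactive gold nanoparticles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular microdosimetry of radioactive gold nanoparticles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celldosim)
```

`celldosim` estimates, by Monte-Carlo simulation, the energy that decays of
radioactive ¹⁹⁸Au gold nanoparticles (AuNP) deposit in the organelles of a
spherical cell. This vignette is the package's own account of the model:
its assumptions, the tunable parameters and their defaults, the numerical
choices, and what the simulation can and cannot say about real cells.

## The cell world

The cell is a nest of spheres in nm coordinates with the cell centre at
the origin:

| region        | default size            | material (bookkeeping)   |
|---------------|-------------------------|--------------------------|
| cell          | radius 6000 nm          | —                        |
| membrane      | shell [5990, 6000] nm   | H/C/N/O, 1.0 g/cm³       |
| cytosol       | inside 5990 nm          | H/C/N/O, 1.0 g/cm³       |
| nucleus       | radius 3300 nm, centred | H/C/N/O/S/P, 1.0 g/cm³   |
| mitochondria  | 90 × radius 463 nm      | as nucleus               |
| nanoparticles | r = 3–5 nm, gold        | Au, 19.32 g/cm³          |

The tabulated total radius of 6000 nm is read as the *outer* cell radius,
with the 10 nm membrane as the outermost shell. This convention keeps the
whole-cell sphere at its quoted size, and the whole-cell mass
(`cell_mass_kg()`, 9.05×10⁻¹³ kg) then converts 10⁵ decays at the
reference deposits of 1810–1913 eV/decay into the expected 32–35 Gy.

Mitochondria are placed by rejection sampling, uniformly over the cytosol,
with analytic overlap checks against the nucleus and each other.
Nanoparticles are placed either uniformly in the cytosol or *attached* to
an organelle: an attached nanoparticle's centre sits at exactly
`R_target + r_np` from the target centre along a uniformly random
direction, i.e. tangent to the surface. Overlap is strict
(`|c1−c2| < r1+r2`), so tangency is legal — without this convention
surface-attached nanoparticles could never validate. Nanoparticle–
nanoparticle overlap is forbidden too, including among surface-attached
ones, and resolved by resampling the placement angles (up to `max_attempts`
= 10⁴ per particle); at the default loadings the nucleus surface is only
~0.6% covered, so resampling is rare. When mitochondria are targeted, the
host mitochondrion is drawn independently and uniformly per nanoparticle.
Boundary classification gives the innermost region precedence
(nanoparticle > mitochondrion > nucleus > membrane > cytosol) with a
1 nm·10⁻⁹ tolerance.

The gold mass percentage of a loading is
`100 · n·r³·ρ_Au / (R_cell³·ρ_cell)` against the whole-cell sphere at
1.0 g/cm³. This denominator convention is the one that reproduces all the
reference loadings (10⁴ particles at r = 3/4/5 nm ↦ 2.4·10⁻³, 5.7·10⁻³,
1.1·10⁻² %); a cytosol-only denominator does not (it would give 1.4·10⁻²
for the last case).

## The ¹⁹⁸Au source

Each decay emits exactly one β⁻ (endpoint 961 keV with 99% probability,
285 keV with 1%) and each γ line (412, 676, 1088 keV) independently with
its intensity. The two minor γ intensities are only bounded ("<1%") in the
nuclide records used here; the default takes the upper bound 0.01, which
is conservative and numerically irrelevant because photons of these
energies almost always leave the cell (interaction probability across a
cell diameter ≈ 10⁻⁴). β energies are drawn from the allowed spectrum
shape N(E) ∝ p·W·(Q−E)² by rejection sampling, without the Fermi–Coulomb
correction: the correction shifts the spectrum mean by a few per cent,
below the transport surrogate's own error budget, and a monoenergetic
debug mode is available for validation runs. Specific activity uses
1 u = 1 g/mol and 1 d = 86 400 s.

Decay positions: in the *discrete* mode a nanoparticle is chosen
volume-weighted (uniform when all share one radius) and the decay is
uniform inside it; in the *continuous* mode the decay position is uniform
over the cytosol, and the gold is instead mixed into the cytosol medium as
a mass fraction.

## Electron and photon transport

The transport is a deliberately simple condensed-history surrogate,
adequate for scoring on the micrometre scale of organelles:

* **Stopping power.** Berger–Seltzer (Bethe) collision stopping power
  evaluated from each medium's effective Z/A and mean excitation energy I
  (water-equivalent media: I = 78 eV at 1.0 g/cm³; gold: I = 790 eV at
  19.32 g/cm³). Below 10 keV a power law matched in value and log-slope at
  10 keV keeps S(E) positive and continuous. All cell compartments are
  transported as water-equivalent medium — their tabulated compositions
  differ from water by <2% in stopping power — while nanoparticle interiors
  use gold. In the continuous model the cytosol medium mixes water and gold
  mass stopping powers by Bragg additivity.
* **Steps.** Each condensed step is the minimum of 5% of the remaining CSDA
  range, the analytic distance to the next sphere boundary, and `max_step`
  (10⁴ nm). The energy lost in a step comes from the tabulated range–energy
  relation (6000-point log grid, interpolation error <10⁻³ even for the
  10 nm membrane sliver), is deposited in the region containing the step,
  and conservation is exact by construction: deposits plus escaped energy
  equal the initial energy to rounding.
* **Multiple scattering.** After each step the direction is deflected by a
  Gaussian polar angle of Highland width
  θ₀ = 13.6 MeV/(βcp)·√(x/X₀)·(1+0.038·ln(x/X₀)) (X₀ = 36.08 g/cm² water,
  6.46 g/cm² gold) with uniform azimuth. For extremely short boundary-
  limited steps the bracketed correction would go negative; it is clamped
  at zero, i.e. such slivers produce no deflection.
* **Cutoffs and termination.** Tracks stop at 1 keV (residual range tens
  of nm, far below organelle sizes) with the residual deposited locally,
  or at the cell surface, where the remaining energy is booked as escaped.
* **Photons.** Default `single_interaction`: a free path is drawn from the
  water attenuation coefficient (an embedded three-point µ/µ_en table at
  the γ line energies, log-interpolated, valid 100–2000 keV); if the
  interaction falls inside the cell, the energy-absorption fraction
  E·(µ_en/µ) is deposited at that point. An `escape` mode ignores photons
  entirely; the difference is a few eV/decay.

## Scoring conventions

Tallies record per-role energies. In summaries, `cytosol` includes the
nanoparticle deposit (the particles reside in the cytosol, and published
organelle tabulations count their self-absorption toward it),
`cytosol_no_np` excludes it, and
`cell` is the sum of everything inside the outer membrane surface. Batch
summaries use the sample standard deviation over `n_batches` independent
runs (default 10, each with a derived seed `base_seed + 100000·j + i`).
Relative enhancement is E_rel(x) = 100%·E(x)/E(0%) with the all-random
condition as baseline; linear fits are ordinary least squares with
R² = 1 − SS_res/SS_tot (defined as 1 when SS_tot = 0, the degenerate flat
case).

Because decays are independent, E(x) is exactly the mixture
x·E(100%) + (1−x)·E(0%) in expectation; the simulated sweep's deviation
from that line shrinks as 1/√n. This exact-in-expectation linearity is the
tight invariant the test-suite asserts; the R² > 0.99 check on the
simulated sweep is its noisy observable.

## Default problem sizes

The shipped experiments default to 10⁵ decays per condition in 10 batches,
the sample size at which batch standard deviations resolve per-mille
differences between conditions; at those sizes the whole targeting
sweep runs in seconds thanks to the compiled core (uniform-grid
acceleration makes the per-step boundary search insensitive to the 10⁴
nanoparticles). The unit tests use 10²–10⁴ decays — enough for their
3-standard-error assertions.

## What the surrogate does and does not reproduce

Geometry-driven, *relative* quantities are faithfully reproduced: the
nucleus enhancement E_rel(100%) ≈ 260%, the ~20–26% whole-cell increase,
linearity in the targeted fraction, the insensitivity of the continuous
model to the gold mass percentage (<2% over 0.001–1%), and the volume
sharing between organelles.

Absolute eV/decay values are *systematically underestimated by roughly a
third* relative to full condensed-history transport with complete
low-energy physics. A straight-chord estimate makes the point: a ~380 keV
electron loses ≈0.22 eV/nm in water and the mean chord from a cytosol
point to the cell surface is ≈4.7 µm, giving ≈1.2 keV per decay in the
cell, which is what the simulator produces. Reference values near
1.8 keV/decay include processes this surrogate deliberately omits — δ-ray
generation and transport, Auger cascades and conversion electrons
(which also dominate the nanoparticle self-dose), sub-keV electron
transport, and track re-entry from the surrounding medium. Model
experiments with the prototype showed re-entry alone contributes only a
few per cent, so the gap is attributable to the omitted low-energy
electron physics. Consequently absolute doses derived from simulated
deposits inherit this bias, while enhancement ratios do not.

The synthetic cell itself idealises reality: organelles are spheres,
mitochondria do not cluster, the nucleus is centred, membranes are
water-like shells, and nanoparticle uptake is frozen rather than dynamic.
Passing tests therefore demonstrate correctness of the *model*, not
fidelity to any particular cell line beyond the geometric parameters used.
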