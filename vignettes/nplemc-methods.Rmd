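---
title: "Reduced-model ion transport with NP+LEMC: models, algorithms, choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-model ion transport with NP+LEMC: models, algorithms, choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nplemc)
```

## The model

`nplemc` computes steady-state ionic currents through a pore connecting two
baths, using a reduced model: the solvent is implicit and only the degrees
of freedom that shape the device function are explicit — the ions, the pore
geometry, and the pore charges.

**Electrolyte.** Ions are charged hard spheres in a uniform dielectric
continuum (the Primitive Model).  The pair energy is infinite below contact
(`Ri + Rj`) and `zi zj lB / r` (in kT) beyond it, where
`lB = e^2/(4 pi eps0 eps kT)` is the Bjerrum length (0.714 nm in water at
298.15 K, eps = 78.45).  The solvent survives in two response functions:
the dielectric constant and the diffusion-coefficient profile `Di(z)`.

**Geometry.** The simulation cell is a finite cylinder; a hard membrane
slab carries a pore described by a rotationally symmetric wall profile
R(z).  There are no periodic boundaries and no Ewald sums: all Coulomb
interactions are direct pairwise sums in the finite cell, as appropriate
for a closed cylindrical cell.  Hard walls exclude an ion *center* from
coming closer to any wall than its radius; at the pore mouth the corner
ring is treated exactly for cylindrical faces.  The flat cell end planes
are the bath boundaries and do not exclude ion centers.

**Pore charges.** Three builders cover the model families:

* `build_region_charge_pore()` — two axial wall regions with surface
  densities sigma_L, sigma_R, discretized into rows of point charges whose
  per-site charge is sigma times the exact tile area, so every interior
  row reproduces its region's density exactly; a row straddling the region
  boundary is split site-by-site.  The pattern is summarized by the
  dimensionless net charge `Q = xL sigma_L/sigma0 + (1-xL) sigma_R/sigma0`
  (`net_charge_Q()`).
* `build_localized_charge_pore()` — a square surface grid of pitch dz with
  *fixed* site charges sigma dz^2 (at dz = 1 nm and sigma = -1 e/nm^2,
  full -1 e charges, the discrete-carboxylate limit).  We deliberately do
  not rescale the site charge to the ring area: the physical statement of
  the localized-charge model is that each site is a chemical group with an
  integer (or fixed fractional) charge, and the axial charge per unit
  length is then exact while the total charge matches the surface integral
  within one ring's azimuthal rounding.
* `build_ryr_model()` — the reduced calcium-release-channel model: four
  groups of eight half-charged hard-sphere oxygens (O1/2-, radius
  0.14 nm), each group confined to an axial interval representing one
  charged residue ring (D4945, D4938, D4899, E4900), plus eight fixed
  -0.5 e point charges in a luminal ring (E4902).  The published geometry
  is available only graphically, so `ryr_default_config()` ships
  approximate dimensions (selectivity-filter radius 0.35 nm) and is meant
  to be overridden where better dimensions are known.

## Local Equilibrium Monte Carlo

The cell is partitioned (`build_subvolume_grid()`) into nz axial slabs ×
nr equal-area rings; slab edges snap to the membrane faces so every
subvolume is entirely bath or entirely pore.  Local equilibrium is assumed
per subvolume: one electrochemical potential `mu[i, alpha]` per species
per cell.

The engine (C++) runs grand-canonical-style sampling against this spatially
varying field:

* insertion into cell alpha at a uniform point of its geometric volume,
  accepted with `min(1, c0 V_alpha/(N+1) exp(mu - dU))`;
* deletion of a uniformly chosen ion of the species in the cell, accepted
  with `min(1, N/(c0 V_alpha) exp(-mu - dU))`;
* displacement with the Metropolis rule, the mu difference entering only
  when the move crosses cells.  Structural ions move by displacement only
  (their count is conserved exactly) inside hard confinement walls.

Wall rejection is folded into `dU = Inf`, which keeps `V_alpha` purely
geometric and the acceptance rule exact.  A practical consequence is that
the sampled concentration of a cell touching a hard wall includes the
depletion shell of width one ion radius — bulk measurements therefore use
interior cells only.  Default move mix is 1/3 insert / 1/3 delete /
1/3 displace with a 0.3 nm maximum step (acceptance 30–60 % in the tested
systems); these are sampling choices, not physics, and both satisfy
detailed balance against the target measure.  Sampling is bit-reproducible
for a fixed seed (the engine draws from R's RNG stream).

Toy-system validation: ideal-gas occupancy (`c = c0 e^mu`), the Boltzmann
ratio of a two-cell potential step, and a few-hard-spheres cell checked
against a brute-force configuration-integral oracle (truncated
grand-canonical sum with Monte Carlo integrated `Q_N`).

## Chemical-potential calibration

Transport boundary conditions are bath concentrations, but the sampler
consumes chemical potentials; `calibrate_chemical_potentials()` closes the
loop.  Chemical potentials are measured in kT relative to an ideal gas at
c0 = 1 mol/L, which eliminates the thermal wavelength — only differences
and the mu <-> c closure matter.

The calibration iterates the damped per-species update
`mu <- mu + omega * (ln(c_target) + mu_excess - mu)`, where `mu_excess`
is measured by Widom test insertions in the interior of the box, then
averages the last iterates and runs a 4× longer validation that records
the concentrations the returned potentials actually reproduce.  Three
choices deserve comment:

* *Widom insertions as the estimator.*  The grand-canonical identity
  `rho(r) = e^mu <exp(-dU/kT)>` holds pointwise, so correcting mu with
  the Widom excess and correcting it with the sampled concentration share
  the same fixed point — but the Widom average has far smaller variance
  in dilute systems, where a cell may hold only tens of ions.
* *Per-ion, not per-salt, updates.*  A salt-level update (projecting out
  the valence direction) looks attractive because individual-ion
  activities are not bulk-thermodynamically separable, but in the finite
  open cell the sampled cation/anion ratio can sit off-stoichiometry and
  the projected update cannot correct it: for a 3:1 salt it plateaued
  ~26 % off target.  The per-ion update converges (the finite cell's
  charging penalty supplies the missing restoring force); residual
  closure is ~1 % for 1:1 salts and a few percent for 3:1 at 0.1 M.
* *Damping and iterate averaging.*  For multivalent ions the excess
  chemical potential is strongly state-dependent and the undamped fixed
  point oscillates; omega = 0.5 with averaging of the last iterates tames
  both the oscillation and the stochastic wander.

The calibration box is sized to hold at least three Debye lengths *and*
roughly 15 ions of the least-abundant species; at 1 mM this matters
because the ionic atmosphere extends ~10 nm and truncating it biases the
excess chemical potential (the residual finite-box bias is a few percent
of the excess).  At 1 mM the calibrated excess agrees with the
Debye–Hückel limiting law within about 10 %.

## Nernst–Planck coupling

Fluxes follow `j = -(1/kT) D c grad(mu)` in finite-volume form: face
conductance `g = D_face c_face A_face / d_face` with arithmetic-mean face
values and a concentration floor of 1e-8 mol/L so depletion zones (which
legitimately approach zero) never make the system singular.  Steady state
is the discrete continuity equation, a sparse linear solve for mu given c
(`solve_mu_given_c()`, Dirichlet values on the two boundary slabs).  The
same face network evaluates fluxes and assembles the solve, so a solved
field is divergence-free by construction and the species currents are
constant along z — the conservation check in the tests verifies this
property end-to-end on a converged stochastic run.

`npl_iterate()` alternates LEMC (c given mu) and the continuity solve (mu
given c) with under-relaxation (`omega = 0.5`).  Two numerical choices:

* *Voltage enters as a symmetric split*: `mu(left) = mu_bath + z eU/2kT`,
  `mu(right) = mu_bath - z eU/2kT`.  Only the difference is physical, but
  in a finite cell the split matters: applying the full voltage on one
  side forces a net charging of the cell that is not antisymmetric under
  `U -> -U`, and we measured it as a ~5 % spurious rectification of a
  perfectly symmetric pore.  The symmetric split restores the mirror
  identity `I(U) = -I(-U)` in distribution.
* *Convergence is judged on the drift across a 3-iteration window*, with
  a minimum of eight outer iterations, against the block-resampled noise
  of the currents.  Under-relaxation makes successive-iterate changes
  small even while the solution is still drifting, so a
  consecutive-iteration test declares victory far too early.

Standard errors of the currents are obtained by re-solving the potential
for each concentration block of the final production run and taking the
spread of the resulting block currents.

## Device analysis

`cation_selectivity()` is `|I+|/(|I+|+|I-|)` (0.5 = non-selective),
`rectification()` is `|I_on|/|I_off|`, `summarize_device()` attaches Q,
the chord conductance `G = I/U` and the double-layer-overlap scaling
parameter `xi = Rpore/(lambda z+ |z-|)` with either the Debye or the MSA
screening length.  Note the MSA length of the restricted Primitive Model,
`1/(2 Gamma)` with `2 Gamma d = sqrt(1+2 kappa d) - 1`, *exceeds* the
Debye length and grows with the ion diameter — finite cores weaken
screening.

`slope_resistance()` implements the small-voltage series-resistor picture:
the resistance a pore offers species i is
`R_i = kT/(z_i^2 e^2) * integral dz / (D_i(z) A(z) cbar_i(z))` over
cross-section-averaged axial profiles (`axial_profile()`), so depletion
zones dominate exactly as large resistors dominate a series circuit.  The
`kT/(z^2 e^2)` prefactor is the completion that makes `1/R_i` the species'
slope conductance; on a radially near-uniform (neutral) pore the summed
`1/R_i` agrees with the chord conductance of a full 20 mV NP+LEMC run to
a few percent.  For strongly charged pores the radial structure makes the
quasi-1D integral an approximation, which is why the quantitative
consistency test uses the neutral symmetric fixture.

## Fixtures: what they emulate and what they do not

`make_fixture()` builds the study systems at desk scale: the two-region
nanopore family (`tiny-nn`, `tiny-np`, `tiny-n0`, `tiny-00`) keeps the
published conditions — 1 M NaCl, sigma0 = 0.4835 e/nm^2, ±200 mV ON/OFF
states, pore radius 0.97 nm — at a shortened pore (H = 3.2 nm instead of
6.4 nm) and a compact cell; `tiny-localized` keeps the localized-charge
study's sigma = -1 e/nm^2, 0.1 M z+:1 electrolyte and 0.15 nm ion radii
at H = 3 nm.  The in-pore diffusion coefficient of the NaCl fixtures is
set to 0.3 of the bulk value: the published in-pore values were fitted to
molecular-dynamics currents per charge pattern and are not reproducible
here, and none of the qualitative device checks depend on the value.

Problem sizes were chosen so a full coupled run samples a few hundred ions
over a few thousand sweeps per outer iteration, i.e. minutes per fixture
on one CPU.  What passing tests show: the sampler's stationary measure is
right (toy oracles), the coupled loop conserves current, the bipolar pore
rectifies (ON/OFF ≈ 2–3 at ±200 mV), the symmetric pore does not, and
coarsening the localized-charge grid from 0.2 nm to 1 nm depresses the
cation selectivity of the 3:1 electrolyte — the direction behind
charge-inversion-driven selectivity inversion.  What they do not show:
quantitative agreement with the published currents, which depends on the
full pore length, MD-fitted diffusion profiles and production-scale
sampling; radial layering physics beyond what the (z, r) grid resolves;
and any dielectric inhomogeneity (eps is uniform everywhere by design).

## Known limitations

* Individual-ion chemical potentials are an operational device of the
  finite-cell calibration, not bulk thermodynamic observables; only the
  neutral-combination values are physically meaningful.
* The quasi-1D slope-resistance integral ignores radial concentration
  structure; use it quantitatively only where profiles are radially mild.
* Boundary slabs pin mu over a whole slab (not a mathematical surface), a
  first-order discretization of the bath boundary.
* No preferential sampling: deeply depleted zones converge slowly; the
  concentration floor keeps the solve stable but the statistical error of
  a depletion-zone current is dominated by rare visits.
* The shipped channel geometry is approximate (graphical source); results
  for it are structural/qualitative only.
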