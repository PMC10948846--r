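---
title: "Methods: desk-scale FSI computation of intracranial pressure and compliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale FSI computation of intracranial pressure and compliance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package computes

`icpfsi` computes intracranial pressure (ICP) non-invasively by simulating
the two-way interaction between pulsatile cerebrospinal fluid (CSF) and a
poro-viscoelastic brain, and derives from per-stage ICP two longitudinal
clinical quantities:

* **intracranial compliance** `ICC = dV / dICP` (ml/cmH2O), the slope of the
  pressure-volume relation between consecutive monthly stages, and
* **force-deformation brain stiffness**
  `k = d(ICP x brain surface area) / d(brain deformation)` (N/m),

followed by a dual (Pearson + Spearman) correlation analysis between the
two across a 14-patient, 8-stage shunt-response cohort, with Shapiro-Wilk
normality screening at a significance threshold of 0.05.

## Governing equations

**CSF** is an incompressible Newtonian fluid (density 998.2 kg/m^3,
dynamic viscosity 0.001 Pa s) on a moving mesh (arbitrary
Lagrangian-Eulerian form):

$$\rho_F \partial_t u_F + \rho_F ((u_F - W)\cdot\nabla) u_F =
  -\nabla p + \mu \nabla^2 u_F + f_B,$$

with continuity $\nabla \cdot u_F = S$ in the ventricular CSF (production
source) and $\nabla \cdot u_F = 0$ in the subarachnoid space (SAS).  Both
a boundary-inlet mode (the default: a pulsatile inflow waveform at the
ventricular inlet, `S = 0`) and a volumetric-source mode
(`apply_production_source()`) are provided, because production can be
modelled either way and the two are not reconciled a priori; they are not
used simultaneously by default.

**Brain tissue** satisfies momentum balance
$\nabla\cdot\sigma_S + f_B = \rho_S \ddot u_S$ with a poro-viscoelastic
constitutive model: Biot pore-pressure coupling (Biot coefficient 1,
incompressible constituents, Darcy permeability
$4.08\times10^{-12}$ m^4/(N s)) and deviatoric shear relaxation by a
Prony series

$$G_r(t) = G_0\Big(1 - \sum_k g_k\,(1 - e^{-t/\tau_k})\Big),$$

with $\tau_k$ = 3.1, 27, 410 s and $g_k$ = 0.285 per term, and
$G_0 = E/(2(1+\nu))$ from E = 584.4 Pa and $\nu$ = 0.35 (so
$G_0 \approx 216.44$ Pa).  The published parameter set prints a single
relaxation modulus value for three relaxation times; whether it applies
per term (sum 0.855) or in total is ambiguous.  The default applies it
per term; `prony_mode = "total"` divides it equally across the terms.
The volumetric response does not relax.  The printed permeability unit
"M^4/N.s" is read as the standard Darcy-type m^4/(N s).  Tissue density
is not printed; the near-unity default is 1000 kg/m^3.

**Interface conditions** on both brain-CSF surfaces are displacement
compatibility ($d_S = d_F$), traction equilibrium
($\sigma_S n = \sigma_F n$) and kinematic velocity matching
($u_S = u_F$).  The source text describes the matched quantity of the
third condition as a local acceleration while writing a velocity
identity; the package enforces velocity matching, the physically standard
no-slip kinematic condition.

## Idealized geometry

Patient-specific image-reconstructed anatomy is replaced by a concentric
idealization so that the strongly-coupled solve runs in minutes on one
CPU: a central inlet hole (choroid-plexus stand-in, radius 2 mm),
ventricular CSF to 20 mm, brain parenchyma to 70 mm, a 3 mm SAS, and a
rigid no-slip dura.  An annular "aqueduct" channel of controllable
half-width represents stenosis severity and is fully closed by default
(non-communicating hydrocephalus).  Arcs on the dura carry the spinal and
sagittal-sinus outlets.

Because the cohort consists of shunted patients and the shunt valve is
represented by an outlet pressure, the ventricular wall of the inlet hole
carries a `shunt` pressure-outlet facet (default 5 cmH2O, configurable;
the published model cites a manufacturer catalog without printing a
value).  This choice is also what makes the partitioned coupling
well-posed: every connected CSF component has a pressure boundary, so no
enclosed incompressible cavity appears.  With the aqueduct closed, both
SAS outlets default to the same prescribed pressure; when the aqueduct is
open, the spinal outlet can instead be driven by its outflow waveform
(`outlet_mode = "sinus_pressure"`), which is the configuration used to
verify the steady production-absorption balance 0.35 = 0.17 + 0.18
ml/min.

Fields are solved on a plane 2-D cross-section through the center.
Volumes and areas are reported by revolving the upper half of the
cross-section about the axis (Pappus), which converges to the closed-form
sphere volume and area for this geometry; clinical volumes are therefore
in ml and areas in cm^2.  Flow-rate boundary data (ml/min) are converted
to 2-D fluxes with an effective out-of-plane depth (default 0.02 m, the
ventricular length scale); all mass-balance statements use the same
depth, so conservation checks are independent of its value.  Lengths are
mm at the interface, SI internally; 1 cmH2O = 98.0665 Pa, fixed in one
place.

## Discretization and numerical choices

* **Fluid**: P1-P1 triangles with Brezzi-Pitkaranta pressure
  stabilization (constant 0.05 on h^2/mu), backward Euler, convection
  linearized at the last committed velocity (CSF Reynolds numbers are far
  below 1, so one Oseen solve per step suffices); the factorized system
  is reused across coupling subiterations.  A weak pseudo-compressibility
  term (numerical bulk modulus 1e6 Pa) regularizes the pressure in
  velocity-constrained subregions; its added compliance is about four
  orders of magnitude below the brain-wall compliance, and the rigid-limit
  benchmark bounds its effect on ICP below 1%.
* **Solid**: P1 displacement + P1 pore pressure with a fluid-pressure
  Laplacian stabilization (coefficient h^2 / 4(K + 4G/3)), dt-scaled and
  row-equilibrated so that stiff (rigid-limit) parameter sets factor
  cleanly; Prony terms advance by the standard per-term exponential
  recurrence, which is exact for constant strain between steps and first
  order in dt for ramps.  Inertia uses backward differences.  A weak
  mass-proportional damping (3 s^-1) represents the tethering of the
  brain (falx, vessels, spinal cord) that the idealized geometry omits;
  without it the floating brain's rigid modes are restrained only by
  inertia and start-up transients persist indefinitely.  A tiny specific
  storage (1e-10 1/Pa) keeps fully-undrained problems non-singular.
* **Coupling**: partitioned Dirichlet-Neumann iteration (fluid receives
  wall velocities, solid receives fluid tractions) with Aitken dynamic
  relaxation (initial factor 0.3), relative interface tolerance 1e-4 on
  displacement with a traction-change criterion alongside, subiteration
  cap 60.  Fluid mesh motion is a harmonic extension of the interface
  displacement, updated once per step from the previous converged
  displacement (geometry-explicit); the mesh velocity W is a backward
  difference.  Interface tractions are evaluated with reference-
  configuration normals, consistent with the small-strain solid: letting
  the pressure load follow the deformed fluid normals while the solid
  carries no geometric stiffness creates a spurious follower-load
  instability (a slowly growing torsional mode), which this
  linearization removes.
* **Time step**: cardiac period / 32 by default; three cycles, with the
  final cycle as the reporting window (the temporal-convergence test
  bounds the dt-halving change of cycle-mean ICP below 0.1%).
* **Degenerate inputs**: compliance and stiffness intervals with
  denominators below 1e-9 working units are flagged undefined and
  excluded (with a logged count) rather than returned as huge finite
  values; constant vectors and sub-minimum sample sizes are flagged in
  the statistics layer rather than computed.

## The synthetic cohort

No patient data is consumed anywhere.  The generator emulates three
things the study obtained from patients:

* **Pulsatile boundary waveforms**: a truncated Fourier series (three
  harmonics by default) over one cardiac cycle on top of the constant
  production/absorption components 0.35 / 0.17 / 0.18 ml/min, with
  seeded amplitudes scaled so that peak-to-peak pulsatility is a few
  times the constant component, as in cardiac-gated CSF flow
  measurements.  The published study never tabulates its per-patient
  waveforms, so heart rate, shape and amplitude are free synthetic
  parameters; the sampled cycle mean equals the constant component
  exactly by construction.
* **Longitudinal stage trajectories**: 14 patients x 8 stages
  (pre-surgery plus 7 monthly follow-ups).  ICP, ventricular volume,
  deformation and pulsatility decline exponentially toward a post-shunt
  plateau - an exponential approach is used because CSF dynamics are
  reported to stabilize 6-9 months after shunting - modulated by seeded
  multiplicative oscillation (default relative sd 0.08) that produces
  the oscillatory, sign-changing stage-to-stage ICC and stiffness values
  seen in such cohorts.  Baseline ICP is drawn from 20-30 cmH2O
  (elevated, pre-treatment); plateaus, volumes (1400-1600 ml), areas
  (1500-2000 cm^2) and deformations (0.5-1.5 mm) are
  literature-plausible defaults chosen once.
* **Monitored ICP**: multiplicative Gaussian noise
  (`reading = true (1 + e)`, `e ~ N(0, 0.02)`) for a 10-patient
  pre-surgery validation subset.  The 2% default makes synthetic
  calculated-vs-measured differences land naturally in the few-percent
  band without being tuned to any published number.

What passing tests on this cohort do **not** show: the generator carries
no vascular pulsation, no autoregulation, no imaging noise or
segmentation error, and its stage-to-stage variability is stationary
log-normal rather than physiologic.  Cohort-level conclusions from it are
statements about the analysis machinery (e.g. type-I control of the
correlation verdicts), not about patients.

## Verification suite

Every solver is checked against an independent closed form: the sampled
Fourier synthesis against direct term-by-term summation; revolved mesh
measures against sphere volume/area; steady and oscillatory channel flow
against Poiseuille and Womersley; step-strain shear relaxation against
the Prony modulus; 1-D consolidation against the Terzaghi series;
bending against beam theory; the coupled solver against its rigid-cavity
limit, steady forcing, periodicity, temporal refinement and a four-level
grid-independence study; and the correlation layer against the exact
rank-formula and transform-invariance identities.  Problem sizes are
desk-scale by design: the default coarse head mesh has a few hundred
cells, benchmark channels run at 40x16 to 80x32, and the grid study spans
four levels from ~400 to ~39 000 triangles with two to three cardiac
cycles.

## Known limitations

* The idealization is concentric and 2-D; no patient anatomy, no
  gray/white heterogeneity, no spinal compartment beyond the outlet
  condition, no contact with the skull.
* Small-strain kinematics: monthly deformations enter the stiffness
  metric only through differences, but large ventricular collapse is
  outside the model.
* ICP in this configuration is dominated by the prescribed outlet
  (shunt) pressure with small dynamic excursions; that is the expected
  equilibrium of a shunted, pressure-gauged system, and it makes the
  grid-independence statistic an agreement check between discretizations
  rather than a prediction of absolute ICP.
* The correlation analysis applies no multiple-testing correction,
  matching the published analysis it mirrors.
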