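# icpfsi

Non-invasive intracranial pressure (ICP) computation by desk-scale
fluid–structure interaction (FSI), with downstream intracranial compliance
and brain-stiffness analysis.

## The problem

Intracranial compliance (ICC) — the change in intracranial volume per unit
change in ICP — is clinically valuable but can only be *measured* by
invasive fluid addition/removal. A two-way FSI simulation of pulsatile
cerebrospinal fluid (CSF) interacting with brain tissue offers a
non-invasive route: simulate ICP per imaging stage, then form

- **ICC** `= ΔV / ΔICP` (ml/cmH₂O), and
- **FSI-based brain stiffness** `= Δ(ICP × brain surface area) / Δ(brain
  deformation)` (N/m),

between consecutive monthly stages of shunt-treated non-communicating
hydrocephalus patients, and ask whether the two are related (Pearson +
Spearman, Shapiro–Wilk screening, α = 0.05).

This package re-implements that pipeline at desk scale on an idealized
concentric head geometry (ventricular CSF – brain parenchyma –
subarachnoid space inside a rigid dura, complete aqueductal stenosis by
default, a ventricular shunt represented by an outlet pressure). It is
aimed at researchers in intracranial fluid dynamics who want a fully
reproducible, dependency-light reference implementation of the method —
not a patient-specific clinical tool.

## The model

- **CSF**: incompressible Newtonian fluid (μ = 0.001 Pa·s,
  ρ = 998.2 kg/m³) in arbitrary Lagrangian–Eulerian form,
  `ρ_F ∂u/∂t + ρ_F((u−W)·∇)u = −∇p + μ∇²u + f_B`, with `∇·u = S`
  (production) in the ventricles and `∇·u = 0` in the subarachnoid space.
  Constant production/absorption components are 0.35 / 0.17 / 0.18 ml/min
  (inlet / spinal / sinus), with a seeded truncated-Fourier pulsatile
  component superposed.
- **Brain**: small-strain Biot poroelasticity (Biot coefficient 1,
  permeability 4.08×10⁻¹² m⁴/(N·s), void ratio 0.2) with Prony-series
  shear relaxation `G_r(t) = G₀(1 − Σ g_k(1 − e^(−t/τ_k)))`,
  τ = 3.1 / 27 / 410 s, g = 0.285, G₀ = E/(2(1+ν)) with E = 584.4 Pa,
  ν = 0.35.
- **Coupling**: displacement compatibility, traction equilibrium and
  velocity matching on both brain–CSF interfaces, enforced by partitioned
  Dirichlet–Neumann subiterations with Aitken relaxation; harmonic-
  extension mesh motion; P1 finite elements throughout.

Every solver component is verified against a closed form (Poiseuille,
Womersley, Terzaghi consolidation, the Prony relaxation function, sphere
measures, beam bending, the rigid-cavity limit); see the methods vignette
(`vignettes/icpfsi-methods.Rmd`) for the numerical choices and their
rationale.

## Worked example

```r
library(icpfsi)

mesh <- generate_mesh(head_geometry(), "coarse")
waves <- list(
  inlet  = generate_pulsatile_waveform(70, 0.35, n_samples = 64, seed = 1),
  spinal = generate_pulsatile_waveform(70, 0.17, n_samples = 64, seed = 2,
                                       site = "spinal_outlet"),
  sinus  = generate_pulsatile_waveform(70, 0.18, n_samples = 64, seed = 3,
                                       site = "sinus_outlet"))
res <- run_fsi(mesh, fluid_properties(), poro_viscoelastic_material(),
               waves, coupling_config(n_cycles = 2))
res
extract_deformation(res)

rec <- generate_stage_records(cohort_spec(seed = 1))   # 14 x 8 synthetic cohort
tab <- build_cohort_table(rec)                         # per-interval ICC, stiffness
correlation_analysis(tab$icc_ml_cmH2O, tab$stiffness_N_m,
                     var_names = c("ICC", "stiffness"))
```

which prints:

```
FSI simulation: 2 cycles x 32 steps (dt = 0.02679 s)
  converged steps: 64/64; final-cycle mean ICP 5.000 cmH2O
deformation (cycle mean): 0.00046 mm
Correlation report (ICC vs stiffness), n = 98
  Pearson  r   = -0.0242 (p = 0.8133) -> not_significant
  Spearman rho = -0.1210 (p = 0.2354) -> not_significant
  Shapiro-Wilk: ICC W = 0.4368 (p = 1.22e-17); stiffness W = 0.4358 (p = 1.18e-17)
  alpha = 0.05
```

Read: every coupled time step converged; the cycle-mean ventricular ICP
settles at the shunt operating pressure (5 cmH₂O) with sub-millimetre
cyclic brain deformation, as expected for a pressure-gauged shunted
system; and across the 98 patient-intervals of the synthetic cohort the
derived ICC and stiffness show no statistically significant relationship —
the machinery reproduces a null result when the underlying quantities are
unrelated.

A thin command-line wrapper with `simulate`, `grid-study`, `synth`,
`cohort` and `analyze` subcommands is installed at `inst/cli/icpfsi.R`;
every run writes a manifest with the configuration hash and seed.

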