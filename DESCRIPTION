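Package: icpfsi
Title: Non-Invasive Intracranial Pressure and Compliance via Desk-Scale
    Fluid-Structure Interaction Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale computation of intracranial pressure (ICP) by
    two-way fluid-structure interaction between pulsatile cerebrospinal
    fluid (CSF) and a poro-viscoelastic brain on an idealized head
    geometry, with downstream derivation of intracranial compliance
    (ICC), force-deformation brain stiffness, and the longitudinal
    correlation analysis relating them.  Includes a seeded synthetic
    cohort generator (pulsatile CSF flow waveforms, longitudinal
    post-shunt stage trajectories, noisy monitored ICP), a structured
    triangle mesher for the concentric ventricle-brain-subarachnoid
    idealization, a stabilized finite-element ALE Navier-Stokes solver,
    a Biot poroelastic solver with Prony-series shear relaxation, a
    partitioned Dirichlet-Neumann coupler with Aitken relaxation, and
    normality/correlation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
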