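## Shared fixtures: small seeded waveform triplets, meshes, closed-form
## oracles, and a memoized coarse coupled run reused across tests.

fixture_env <- new.env(parent = emptyenv())

fix_waveforms <- function(seed = 1) {
  list(
    inlet = generate_pulsatile_waveform(70, 0.35, n_samples = 64,
                                        seed = seed),
    spinal = generate_pulsatile_waveform(70, 0.17, n_samples = 64,
                                         seed = seed + 1L,
                                         site = "spinal_outlet"),
    sinus = generate_pulsatile_waveform(70, 0.18, n_samples = 64,
                                        seed = seed + 2L,
                                        site = "sinus_outlet"))
}

constant_waveform <- function(const, site = "ventricular_inlet", hr = 70) {
  generate_pulsatile_waveform(hr, const, harmonic_amplitudes = 0,
                              harmonic_phases = 0, n_samples = 64,
                              site = site)
}

## memoize expensive objects within one test run
memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

coarse_head_mesh <- function() memo("coarse_mesh",
                                    generate_mesh(head_geometry(), "coarse"))

## converged coarse coupled run, 2 cardiac cycles
cached_fsi_run <- function() memo("fsi_coarse", {
  run_fsi(coarse_head_mesh(), fluid_properties(),
          poro_viscoelastic_material(), fix_waveforms(),
          coupling_config(n_cycles = 2))
})

## rigid-limit pair on the same mesh/waveforms
cached_rigid_pair <- function() memo("fsi_rigid", {
  cc <- coupling_config(n_cycles = 2)
  list(
    fsi = run_fsi(coarse_head_mesh(), fluid_properties(),
                  poro_viscoelastic_material(youngs_modulus = 584.4e6),
                  fix_waveforms(), cc),
    rigid = run_rigid_cavity(coarse_head_mesh(), fluid_properties(),
                             fix_waveforms(), cc))
})

## plane Womersley closed form: channel height h, pressure difference
## dp*cos(w t) over length L, no-slip plates at y = 0 and y = h
womersley_profile <- function(y, t, h, L, dp, omega, rho, mu) {
  nu <- mu / rho
  G <- dp / L
  lam <- sqrt(1i * omega / nu)
  Re(G / (1i * rho * omega) *
       (1 - cosh(lam * (y - h / 2)) / cosh(lam * h / 2)) *
       exp(1i * omega * t))
}

## peak velocity magnitude of the Womersley solution over one cycle
womersley_amp <- function(h, L, dp, omega, rho, mu) {
  ys <- seq(0, h, length.out = 200)
  ts <- seq(0, 2 * pi / omega, length.out = 64)
  max(abs(vapply(ts, function(t)
    max(abs(womersley_profile(ys, t, h, L, dp, omega, rho, mu))),
    numeric(1))))
}

## Terzaghi 1-D consolidation series: excess pore pressure fraction at
## depth z below the drained surface (drainage path L)
terzaghi_fraction <- function(z, Tv, L, n_terms = 200) {
  m <- 0:n_terms
  M <- (2 * m + 1) * pi / 2
  vapply(z, function(zz) sum(2 / M * sin(M * zz / L) * exp(-M^2 * Tv)),
         numeric(1))
}

## homogeneous step-shear relaxation run: applies gamma instantaneously
## (one tiny step), then samples the shear stress trace at the given times
shear_relaxation_trace <- function(times, dt_first = 1e-8, gamma = 0.01) {
  mesh <- rectangle_mesh(2, 2, 3, 3, region = "brain")
  mat <- poro_viscoelastic_material()
  st <- init_solid(mesh, mat, dt = dt_first,
                   fixed = list("left", "right", "top", "bottom"),
                   drained = c("left", "right", "top", "bottom"),
                   inertia = FALSE)
  n <- nrow(st$sub$vertices)
  vals <- numeric(length(st$fixed_dofs))
  xdofs <- st$fixed_dofs <= n
  vals[xdofs] <- gamma * st$sub$vertices[st$fixed_dofs[xdofs], 2] * 1e-3
  st <- step_solid(st, dt_first, bc_displacement = vals)
  out <- numeric(length(times)); tprev <- dt_first
  for (i in seq_along(times)) {
    st <- step_solid(st, times[i] - tprev, bc_displacement = vals)
    tprev <- times[i]
    out[i] <- mean(solid_stress(st)[, 3])
  }
  out
}

## final-cycle indices of an fsi_result-like list
last_cycle <- function(res) {
  n <- length(res$icp_mean_cmH2O)
  seq(n - res$n_steps_cycle + 1, n)
}
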