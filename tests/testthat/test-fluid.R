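test_that("quiescent fluid stays at rest with uniform outlet pressure", {
  mesh <- rectangle_mesh(10, 2, 10, 4)
  bc <- list(left = bc_pressure(0), right = bc_pressure(0),
             top = bc_noslip(), bottom = bc_noslip())
  st <- init_fluid(mesh, fluid_properties(), bc, effective_depth = 1)
  for (i in 1:3) st <- step_fluid(st, 0.1)
  expect_lt(max(abs(st$u)), 1e-12)
  expect_lt(max(abs(st$p)), 1e-9)
  expect_error(step_fluid(st, -0.1), "dt must be positive")
})

test_that("steady channel flow matches the plane Poiseuille closed form", {
  mesh <- rectangle_mesh(10, 1, 80, 32)
  dp <- 1
  bc <- list(left = bc_pressure(dp), right = bc_pressure(0),
             top = bc_noslip(), bottom = bc_noslip())
  st <- init_fluid(mesh, fluid_properties(), bc, effective_depth = 1,
                   numerical = list(cfl_bound = Inf))  # quasi-steady stepping
  for (i in 1:5) st <- step_fluid(st, 50)
  G <- dp / 0.01; h <- 1e-3; mu <- 1e-3
  u_max <- G * h^2 / (8 * mu)
  q_exact <- G * h^3 / (12 * mu)
  v <- st$sub$vertices
  center <- which(abs(v[, 2] - 0.5) < 1e-9)
  expect_lt(abs(max(st$u[center]) - u_max) / u_max, 0.02)
  mb <- global_mass_balance(st)
  q_num <- mb$flux_by_tag[["right"]] * icp_units$mlmin_m3s
  expect_lt(abs(q_num - q_exact) / q_exact, 0.02)
  expect_lt(mb$imbalance_ml_min, 1e-6)
})

test_that("oscillatory channel flow matches the Womersley series", {
  mesh <- rectangle_mesh(10, 1, 40, 16)
  h <- 1e-3; L <- 0.01; dp <- 1; omega <- 2 * pi
  rho <- 998.2; mu <- 1e-3
  bc <- list(left = bc_pressure(function(t) dp * cos(omega * t)),
             right = bc_pressure(0),
             top = bc_noslip(), bottom = bc_noslip())
  st <- init_fluid(mesh, fluid_properties(), bc, effective_depth = 1)
  dt <- 1 / 64
  for (i in seq_len(3 * 64)) st <- step_fluid(st, dt)
  v <- st$sub$vertices
  col <- which(abs(v[, 1] - 5) < 1e-9)
  amp <- womersley_amp(h, L, dp, omega, rho, mu)
  for (k in 1:4) {       # four phases across the next cycle
    for (i in 1:16) st <- step_fluid(st, dt)
    exact <- womersley_profile(v[col, 2] * 1e-3, st$time, h, L, dp,
                               omega, rho, mu)
    expect_lt(max(abs(st$u[col] - exact)) / amp, 0.05)
  }
})

test_that("Womersley error decreases under mesh refinement", {
  h <- 1e-3; L <- 0.01; omega <- 2 * pi; rho <- 998.2; mu <- 1e-3
  err_at <- function(nx, ny) {
    mesh <- rectangle_mesh(10, 1, nx, ny)
    bc <- list(left = bc_pressure(function(t) cos(omega * t)),
               right = bc_pressure(0),
               top = bc_noslip(), bottom = bc_noslip())
    st <- init_fluid(mesh, fluid_properties(), bc, effective_depth = 1)
    dt <- 1 / 64
    for (i in seq_len(2 * 64 + 16)) st <- step_fluid(st, dt)
    v <- st$sub$vertices
    col <- which(abs(v[, 1] - 5) < 1e-9)
    exact <- womersley_profile(v[col, 2] * 1e-3, st$time, h, L, 1,
                               omega, rho, mu)
    max(abs(st$u[col] - exact)) / womersley_amp(h, L, 1, omega, rho, mu)
  }
  e_coarse <- err_at(10, 4)
  e_fine <- err_at(20, 8)
  expect_lt(e_fine, e_coarse)
})

test_that("production source integrates to the requested rate", {
  mesh <- coarse_head_mesh()
  S <- apply_production_source(mesh, 0.35)
  areas <- with(list(v = mesh$vertices * 1e-3, cl = mesh$cells), {
    0.5 * abs((v[cl[, 2], 1] - v[cl[, 1], 1]) *
                (v[cl[, 3], 2] - v[cl[, 1], 2]) -
              (v[cl[, 3], 1] - v[cl[, 1], 1]) *
                (v[cl[, 2], 2] - v[cl[, 1], 2]))
  })
  rate_back <- sum(S * areas) * 0.02 / icp_units$mlmin_m3s
  expect_lt(abs(rate_back - 0.35) / 0.35, 1e-10)
  expect_true(all(S[mesh$region != "ventricle_csf"] == 0))
  expect_true(all(apply_production_source(mesh, 0) == 0))
  expect_error(apply_production_source(mesh, -1), "rate")
  ## uniform density scaling: smaller ventricle at fixed rate -> larger S
  small <- generate_mesh(head_geometry(ventricle_radius = 14), "coarse")
  S2 <- apply_production_source(small, 0.35)
  s1 <- unique(round(S[mesh$region == "ventricle_csf"], 14))
  s2 <- unique(round(S2[small$region == "ventricle_csf"], 14))
  expect_length(s1, 1)     # uniform within the ventricle
  expect_gt(s2, s1)
})

test_that("constant-component flow balances: 0.35 in = 0.17 + 0.18 out", {
  g <- head_geometry(aqueduct_radius = 2, shunt_arc = c(0, 0))
  mesh <- generate_mesh(g, "medium")
  bc <- list(inlet = bc_waveform(constant_waveform(0.35), 1),
             spinal_outlet = bc_waveform(
               constant_waveform(0.17, "spinal_outlet"), -1),
             sinus_outlet = bc_pressure(cmH2O_to_Pa(5)),
             dura = bc_noslip(), fsi_inner = bc_noslip(),
             fsi_outer = bc_noslip())
  st <- init_fluid(mesh, fluid_properties(), bc)
  for (i in 1:40) st <- step_fluid(st, 0.5)
  mb <- global_mass_balance(st)
  expect_lt(mb$imbalance_ml_min, 1e-6)
  expect_equal(mb$flux_by_tag[["inlet"]], -0.35, tolerance = 1e-6)
  expect_equal(mb$flux_by_tag[["spinal_outlet"]], 0.17, tolerance = 1e-6)
  ## the free pressure outlet carries the remaining absorption
  expect_equal(mb$flux_by_tag[["sinus_outlet"]], 0.18, tolerance = 1e-4)
})
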