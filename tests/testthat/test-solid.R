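test_that("relaxation modulus reproduces the Prony closed form", {
  mat <- poro_viscoelastic_material()
  ## G0 = E / (2 (1 + nu)) with E = 584.4 Pa, nu = 0.35
  expect_equal(relaxation_modulus(0, mat), 584.4 / (2 * 1.35),
               tolerance = 1e-12)
  expect_equal(relaxation_modulus(0, mat), 216.44, tolerance = 1e-4)
  ## long-time limit G0 (1 - sum g_k) with three terms of 0.285
  expect_equal(relaxation_modulus(1e9, mat) / mat$shear_modulus, 0.145,
               tolerance = 1e-9)
  ## strictly decreasing, convex
  t <- seq(0, 2000, by = 2)
  g <- relaxation_modulus(t, mat)
  expect_true(all(diff(g) < 0))
  expect_true(all(diff(diff(g)) > 0))
  expect_error(relaxation_modulus(-1, mat), "non-negative")
  ## "total" mode splits the printed 0.285 across the relaxation times
  mt <- poro_viscoelastic_material(prony_moduli = 0.285,
                                   prony_mode = "total")
  expect_equal(sum(mt$prony_moduli), 0.285)
  expect_equal(relaxation_modulus(1e9, mt) / mt$shear_modulus, 0.715,
               tolerance = 1e-9)
})

test_that("material invariants are enforced on construction", {
  expect_error(poro_viscoelastic_material(youngs_modulus = -1), "positive")
  expect_error(poro_viscoelastic_material(poisson_ratio = 0.5), "poisson")
  expect_error(poro_viscoelastic_material(prony_moduli = rep(0.4, 3)),
               "below 1")
  expect_error(poro_viscoelastic_material(permeability = 0), "positive")
  expect_error(poro_viscoelastic_material(
    prony_relaxation_times = c(3.1, -27, 410)), "positive")
})

test_that("step-strain shear stress follows G_r(t) within 0.5%", {
  mat <- poro_viscoelastic_material()
  times <- exp(seq(log(0.05), log(1000), length.out = 40))
  sxy <- shear_relaxation_trace(times)
  exact <- 0.01 * relaxation_modulus(times, mat)
  expect_lt(max(abs(sxy - exact) / exact), 0.005)
  ## relaxation-only loading dissipates monotonically toward the
  ## equilibrium plateau
  expect_true(all(diff(sxy) < 0))
  expect_true(all(sxy > 0.01 * mat$shear_modulus * 0.145))
})

test_that("Prony recurrence error is first order in dt", {
  ## apply the step strain over one full step of size dt (not
  ## instantaneously): the recurrence error at fixed t then scales ~ dt
  err_at <- function(dt) {
    mesh <- rectangle_mesh(2, 2, 2, 2, region = "brain")
    mat <- poro_viscoelastic_material()
    st <- init_solid(mesh, mat, dt = dt,
                     fixed = list("left", "right", "top", "bottom"),
                     drained = c("left", "right", "top", "bottom"),
                     inertia = FALSE)
    n <- nrow(st$sub$vertices)
    vals <- numeric(length(st$fixed_dofs))
    xdofs <- st$fixed_dofs <= n
    vals[xdofs] <- 0.01 * st$sub$vertices[st$fixed_dofs[xdofs], 2] * 1e-3
    t_end <- 2
    for (i in seq_len(round(t_end / dt)))
      st <- step_solid(st, dt, bc_displacement = vals)
    abs(mean(solid_stress(st)[, 3]) -
          0.01 * relaxation_modulus(t_end - dt / 2, mat))
  }
  e1 <- err_at(0.2); e2 <- err_at(0.1)
  expect_lt(e2, e1)
  expect_lt(e2 / e1, 0.75)    # ~ first-order decay
})

test_that("1-D consolidation matches the Terzaghi series within 2%", {
  mat <- poro_viscoelastic_material(prony_moduli = c(0, 0, 0))
  mesh <- rectangle_mesh(2, 10, 2, 40, region = "brain")
  st <- init_solid(mesh, mat, dt = 1,
                   fixed = list("bottom",
                                list(tag = "left", comp = 1),
                                list(tag = "right", comp = 1)),
                   drained = "top", inertia = FALSE)
  sig0 <- 100
  E <- 584.4; nu <- 0.35
  E_oed <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  cv <- mat$permeability * E_oed
  L <- 0.01
  tv_check <- c(0.05, 0.1, 0.2, 0.5)
  t_check <- tv_check * L^2 / cv
  ts <- unique(sort(c(exp(seq(log(5), log(max(t_check)),
                              length.out = 100)), t_check)))
  tprev <- 0
  v <- st$sub$vertices
  for (t in ts) {
    st <- step_solid(st, t - tprev,
                     surface_tractions = list(top = c(0, -sig0)))
    tprev <- t
    hit <- which(abs(t - t_check) < 1e-9)
    if (length(hit)) {
      Tv <- t * cv / L^2
      z <- (10 - v[, 2]) * 1e-3
      exact <- sig0 * terzaghi_fraction(z, Tv, L)
      expect_lt(max(abs(st$pore_pressure - exact)) / sig0, 0.02)
    }
  }
  ## drained boundary held at zero excess pressure
  top_nodes <- which(abs(v[, 2] - 10) < 1e-9)
  expect_lt(max(abs(st$pore_pressure[top_nodes])), 1e-6 * sig0)
})

test_that("zero load keeps the state identically zero", {
  mesh <- rectangle_mesh(4, 4, 3, 3, region = "brain")
  st <- init_solid(mesh, poro_viscoelastic_material(), dt = 0.01,
                   fixed = list("bottom"), drained = "top")
  for (i in 1:3) st <- step_solid(st, 0.01)
  expect_equal(max(abs(st$d)), 0)
  expect_equal(max(abs(st$pore_pressure)), 0)
  expect_error(step_solid(st, -1), "dt must be positive")
})

test_that("total-stress traction decomposes into effective and pore parts", {
  mesh <- rectangle_mesh(4, 4, 4, 4, region = "brain")
  st <- init_solid(mesh, poro_viscoelastic_material(), dt = 0.01,
                   fixed = list("bottom"))
  ## hydrostatic pore pressure at zero strain: traction = -p0 n
  p0 <- 250
  st$pore_pressure <- rep(p0, nrow(st$sub$vertices))
  tr <- interface_traction(st, facet_tags = c("top", "left"))
  expect_equal(tr$tx, -p0 * tr$nx, tolerance = 1e-9)
  expect_equal(tr$ty, -p0 * tr$ny, tolerance = 1e-9)
  expect_error(interface_traction(st, "nonexistent_tag"), "tags")
})

test_that("confined uniaxial compression carries the oedometer stress", {
  mesh <- rectangle_mesh(4, 8, 4, 8, region = "brain")
  mat <- poro_viscoelastic_material(prony_moduli = c(0, 0, 0),
                                    permeability = 1e-3)
  st <- init_solid(mesh, mat, dt = 1e6,
                   fixed = list("bottom",
                                list(tag = "left", comp = 1),
                                list(tag = "right", comp = 1)),
                   drained = "top", inertia = FALSE)
  sig0 <- 50
  st <- step_solid(st, 1e6, surface_tractions = list(top = c(0, -sig0)))
  E_oed <- 584.4 * 0.65 / (1.35 * 0.3)
  v <- st$sub$vertices; n <- nrow(v)
  uy_top <- mean(st$d[n + which(abs(v[, 2] - 8) < 1e-9)])
  expect_equal(uy_top, -sig0 * 8e-3 / E_oed, tolerance = 1e-3)
  tr <- interface_traction(st, facet_tags = "top")
  expect_equal(mean(tr$ty), -sig0, tolerance = 1e-6)
})

test_that("elastic limit reproduces beam bending of a cantilever strip", {
  tip_err <- function(nx, ny) {
    L <- 60; th <- 6
    mesh <- rectangle_mesh(L, th, nx, ny, region = "brain")
    mat <- poro_viscoelastic_material(prony_moduli = c(0, 0, 0),
                                      permeability = 1e-3)
    st <- init_solid(mesh, mat, dt = 1e6, fixed = list("left"),
                     drained = c("left", "right", "top", "bottom"),
                     inertia = FALSE)
    P <- 0.001
    st <- step_solid(st, 1e6,
                     surface_tractions = list(right = c(0, P / (th * 1e-3))))
    v <- st$sub$vertices; n <- nrow(v)
    tip <- which(abs(v[, 1] - L) < 1e-9 & abs(v[, 2] - th / 2) < 1e-9)
    E <- 584.4; nu <- 0.35
    Ep <- E / (1 - nu^2); G <- E / (2 * (1 + nu))
    I <- (th * 1e-3)^3 / 12; A <- th * 1e-3; Lm <- L * 1e-3
    d_beam <- P * Lm^3 / (3 * Ep * I) + 6 * P * Lm / (5 * G * A)
    abs(st$d[n + tip] - d_beam) / d_beam
  }
  e_coarse <- tip_err(60, 8)
  e_fine <- tip_err(120, 16)
  expect_lt(e_fine, e_coarse)
  expect_lt(e_fine, 0.05)
})
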