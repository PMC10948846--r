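## Poro-viscoelastic solid (brain) solver: small-strain Biot poroelasticity
## (Biot coefficient 1, incompressible constituents) with Prony-series
## deviatoric relaxation integrated by the standard per-term exponential
## recurrence.  P1 displacement + P1 pore pressure with a fluid-pressure
## Laplacian stabilization; backward Euler in time; optional inertia by
## backward differences.

#' Poro-viscoelastic material constants for brain tissue
#'
#' Defaults are the validated hydrocephalic-brain values: Young's modulus
#' 584.4 Pa, Poisson ratio 0.35, Darcy permeability 4.08e-12 m^4/(N s),
#' void ratio 0.2, Prony relaxation times 3.1 / 27 / 410 s with relaxation
#' modulus 0.285 per term.  The shear modulus G0 = E / (2(1+nu)) is derived
#' on construction.
#'
#' @param youngs_modulus Pa.
#' @param poisson_ratio dimensionless, in (0, 0.5).
#' @param permeability Darcy coefficient, m^4/(N s) (= m^2/(Pa s)).
#' @param void_ratio dimensionless (recorded; enters porosity bookkeeping
#'   only).
#' @param density kg/m^3.  The printed tissue parameters do not include a
#'   density; near-unity tissue density 1000 is the default.
#' @param prony_relaxation_times seconds, one per Prony term.
#' @param prony_moduli dimensionless g_k, one per term; their sum must stay
#'   below 1.
#' @param prony_mode \code{"per_term"} applies each listed g_k as given
#'   (default); \code{"total"} divides the listed total equally across the
#'   relaxation times.
#' @return Object of class \code{poro_viscoelastic_material} with derived
#'   \code{shear_modulus} (G0) and \code{bulk_modulus}.
#' @examples
#' mat <- poro_viscoelastic_material()
#' mat$shear_modulus      # 584.4 / 2.7 = 216.44 Pa
#' @export
poro_viscoelastic_material <- function(youngs_modulus = 584.4,
                                       poisson_ratio = 0.35,
                                       permeability = 4.08e-12,
                                       void_ratio = 0.2,
                                       density = 1000,
                                       prony_relaxation_times = c(3.1, 27, 410),
                                       prony_moduli = rep(0.285, 3),
                                       prony_mode = c("per_term", "total")) {
  prony_mode <- match.arg(prony_mode)
  if (youngs_modulus <= 0) stop("youngs_modulus must be positive")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (0, 0.5)")
  if (permeability <= 0) stop("permeability must be positive")
  if (any(prony_relaxation_times <= 0))
    stop("relaxation times must be positive")
  if (prony_mode == "total") {
    stopifnot(length(prony_moduli) == 1)
    prony_moduli <- rep(prony_moduli / length(prony_relaxation_times),
                        length(prony_relaxation_times))
  }
  if (length(prony_moduli) != length(prony_relaxation_times))
    stop("one Prony modulus per relaxation time required")
  if (sum(prony_moduli) >= 1)
    stop("sum of Prony moduli must be below 1")
  G0 <- youngs_modulus / (2 * (1 + poisson_ratio))
  Kb <- youngs_modulus / (3 * (1 - 2 * poisson_ratio))
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio,
                 permeability = permeability, void_ratio = void_ratio,
                 density = density,
                 prony_relaxation_times = prony_relaxation_times,
                 prony_moduli = prony_moduli,
                 shear_modulus = G0, bulk_modulus = Kb),
            class = "poro_viscoelastic_material")
}

#' @exportS3Method base::print
print.poro_viscoelastic_material <- function(x, ...) {
  cat(sprintf("Poro-viscoelastic material: E = %g Pa, nu = %g, G0 = %.4g Pa\n",
              x$youngs_modulus, x$poisson_ratio, x$shear_modulus))
  cat(sprintf("  permeability %g m^4/(N s), void ratio %g, rho %g kg/m^3\n",
              x$permeability, x$void_ratio, x$density))
  cat(sprintf("  Prony: tau = [%s] s, g = [%s]\n",
              paste(x$prony_relaxation_times, collapse = ", "),
              paste(x$prony_moduli, collapse = ", ")))
  invisible(x)
}

#' Prony-series shear relaxation modulus
#'
#' \deqn{G_r(t) = G_0 (1 - \sum_k g_k (1 - e^{-t/\tau_k}))}
#'
#' @param t time in seconds, >= 0 (vectorized).
#' @param material a \code{\link{poro_viscoelastic_material}}.
#' @return G_r(t) in Pa.
#' @examples
#' relaxation_modulus(0, poro_viscoelastic_material())  # G0 = 216.44 Pa
#' @export
relaxation_modulus <- function(t, material = poro_viscoelastic_material()) {
  if (any(t < 0)) stop("t must be non-negative")
  g <- material$prony_moduli; tau <- material$prony_relaxation_times
  decay <- vapply(seq_along(g),
                  function(k) g[k] * (1 - exp(-t / tau[k])),
                  numeric(length(t)))
  if (length(t) == 1) decay <- matrix(decay, nrow = 1)
  material$shear_modulus * (1 - rowSums(decay))
}

## deviatoric and volumetric plane-strain D-matrices, Voigt (exx, eyy, gxy)
D_dev <- function(G) G * matrix(c(4 / 3, -2 / 3, 0,
                                  -2 / 3, 4 / 3, 0,
                                  0, 0, 1), 3, 3)
D_vol <- function(K) K * matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0), 3, 3)

## vector-elasticity stiffness for uniform D; dof order (all x, all y)
assemble_elasticity <- function(geom, D) {
  n <- geom$n_nodes
  m <- nrow(geom$cells)
  Brow <- function(comp, i) {
    ## rows of the strain-displacement matrix for local node i:
    ## comp 1: exx gets bx (x-dof); comp 2: eyy gets by (y-dof);
    ## comp 3: gxy gets (by on x-dof, bx on y-dof)
    switch(comp,
           cbind(geom$bx[, i], 0),
           cbind(0, geom$by[, i]),
           cbind(geom$by[, i], geom$bx[, i]))
  }
  ii <- jj <- xx <- vector("list", 36)
  q <- 0
  for (i in 1:3) for (j in 1:3) {
    Bi <- lapply(1:3, Brow, i = i)   # 3 strain comps x (m x 2)
    Bj <- lapply(1:3, Brow, i = j)
    for (ci in 1:2) for (cj in 1:2) {
      val <- numeric(m)
      for (si in 1:3) for (sj in 1:3) {
        if (D[si, sj] != 0)
          val <- val + D[si, sj] * Bi[[si]][, ci] * Bj[[sj]][, cj]
      }
      q <- q + 1
      ii[[q]] <- geom$cells[, i] + (ci - 1L) * n
      jj[[q]] <- geom$cells[, j] + (cj - 1L) * n
      xx[[q]] <- val * geom$area
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2 * n, 2 * n))
}

## coupling  Q[dof, pnode] = int phi_p * div(v)  (virtual work of pore
## pressure against displacement test functions)
assemble_biot_coupling <- function(geom) {
  n <- geom$n_nodes
  ii <- jj <- xx <- vector("list", 18)
  q <- 0
  for (i in 1:3) for (j in 1:3) for (comp in 1:2) {
    q <- q + 1
    d <- if (comp == 1) geom$bx[, i] else geom$by[, i]
    ii[[q]] <- geom$cells[, i] + (comp - 1L) * n
    jj[[q]] <- geom$cells[, j]
    xx[[q]] <- d * geom$area / 3
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2 * n, n))
}

## per-cell strains from a displacement vector (exx, eyy, exy tensorial)
cell_strain <- function(geom, d) {
  n <- geom$n_nodes
  dx <- d[seq_len(n)]; dy <- d[n + seq_len(n)]
  exx <- eyy <- exy <- 0
  for (i in 1:3) {
    ni <- geom$cells[, i]
    exx <- exx + geom$bx[, i] * dx[ni]
    eyy <- eyy + geom$by[, i] * dy[ni]
    exy <- exy + 0.5 * (geom$by[, i] * dx[ni] + geom$bx[, i] * dy[ni])
  }
  cbind(exx, eyy, exy)
}

## internal force from a per-cell stress table (sxx, syy, sxy)
stress_internal_force <- function(geom, s) {
  n <- geom$n_nodes
  f <- numeric(2 * n)
  for (i in 1:3) {
    ni <- geom$cells[, i]
    fx <- (s[, 1] * geom$bx[, i] + s[, 3] * geom$by[, i]) * geom$area
    fy <- (s[, 2] * geom$by[, i] + s[, 3] * geom$bx[, i]) * geom$area
    f[seq_len(n)] <- f[seq_len(n)] + tabulate_add(ni, fx, n)
    f[n + seq_len(n)] <- f[n + seq_len(n)] + tabulate_add(ni, fy, n)
  }
  f
}

#' Initialize a poro-viscoelastic solid state on a mesh
#'
#' Builds the solid subproblem over all \code{brain} cells of the mesh,
#' assembles the constant matrices, and returns the zero state.  Boundary
#' conditions are declared once: displacement constraints per facet tag,
#' drained facets (pore-pressure Dirichlet), everything else is
#' traction-free / no-flux.
#'
#' @param mesh an \code{icp_mesh} containing \code{brain} cells.
#' @param material a \code{\link{poro_viscoelastic_material}}.
#' @param dt time step in seconds (matrices are factorized for this step).
#' @param fixed list of facet tags whose nodes are clamped (both
#'   displacement components zero), e.g. \code{list("bottom")}; entries may
#'   also be \code{list(tag = , comp = 1 or 2)} for single-component
#'   (roller) constraints.
#' @param drained character vector of facet tags where the pore pressure is
#'   prescribed (default value 0, overridden per step via \code{bc_pore}).
#' @param inertia logical; include the rho_S * d^2 u / dt^2 term.
#' @param storage specific storage coefficient (1/Pa) of the pore fluid;
#'   the tiny default keeps the flow equation non-singular on fully
#'   undrained domains while adding negligible compressibility.
#' @param mass_damping mass-proportional damping rate (1/s) representing
#'   the tethering of the brain (falx, vessels, spinal cord) that the
#'   idealized geometry omits; restrains the otherwise free rigid-body
#'   modes of the floating brain.  Default 3/s with inertia, 0 without
#'   (damping ratio ~0.2 at cardiac frequency, decay time ~0.3 s for
#'   rigid drift).
#' @return Object of class \code{solid_state}.
#' @export
init_solid <- function(mesh, material = poro_viscoelastic_material(),
                       dt = 0.01, fixed = list(), drained = character(),
                       inertia = TRUE, storage = 1e-10,
                       mass_damping = NULL) {
  if (is.null(mass_damping)) mass_damping <- if (inertia) 3 else 0
  sub <- submesh(mesh, "brain")
  geom <- fem_geom(sub$vertices * icp_units$mm_m, sub$cells)
  n <- geom$n_nodes
  centroids <- sub_centroids(sub) * icp_units$mm_m
  ## displacement constraints
  fixed_dofs <- integer(0)
  for (f in fixed) {
    if (is.character(f)) {
      nodes <- tagged_nodes(sub, f)
      fixed_dofs <- c(fixed_dofs, nodes, nodes + n)
    } else {
      nodes <- tagged_nodes(sub, f$tag)
      fixed_dofs <- c(fixed_dofs, nodes + (f$comp - 1L) * n)
    }
  }
  fixed_dofs <- sort(unique(fixed_dofs))
  drained_nodes <- tagged_nodes(sub, drained)
  state <- structure(list(
    sub = sub, geom = geom, material = material, dt = dt,
    centroids_m = centroids,
    fixed_dofs = fixed_dofs, drained_nodes = drained_nodes,
    inertia = inertia, storage = storage, mass_damping = mass_damping,
    d = numeric(2 * n), d_prev = numeric(2 * n),
    velocity = numeric(2 * n), acceleration = numeric(2 * n),
    pore_pressure = numeric(n),
    prony_h = lapply(material$prony_relaxation_times,
                     function(.) matrix(0, nrow(sub$cells), 3)),
    strain_prev = matrix(0, nrow(sub$cells), 3),
    time = 0), class = "solid_state")
  build_solid_system(state, dt)
}

## assemble + factorize the constant system for step dt
build_solid_system <- function(state, dt) {
  geom <- state$geom; mat <- state$material
  n <- geom$n_nodes
  tau <- mat$prony_relaxation_times
  Gk <- mat$shear_modulus * mat$prony_moduli
  Ginf <- mat$shear_modulus * (1 - sum(mat$prony_moduli))
  alpha <- exp(-dt / tau)
  beta <- (1 - alpha) / (dt / tau)
  G_eff <- Ginf + sum(beta * Gk)
  K <- assemble_elasticity(geom, D_dev(G_eff) + D_vol(mat$bulk_modulus))
  Q <- assemble_biot_coupling(geom)
  Kp <- assemble_stiffness(geom)
  ## fluid-pressure-Laplacian stabilization coefficient per cell scale
  h2 <- 4 * mean(geom$area)                 # ~ h^2
  eps_stab <- h2 / (4 * (mat$bulk_modulus + 4 * G_eff / 3))
  ## flow equation assembled in dt-scaled form (multiplied through by dt)
  ## for conditioning:  Q^T (d - d_n) + dt k Kp p + eps Kp (p - p_n)
  ##                    + c0 Mp (p - p_n) = 0
  Mp <- assemble_mass(geom, 1)
  App <- dt * mat$permeability * Kp + eps_stab * Kp + state$storage * Mp
  Mv <- NULL
  Add <- K
  if (state$inertia || state$mass_damping > 0) {
    Ms <- assemble_mass(geom, mat$density)
    Mv <- Matrix::bdiag(Ms, Ms)
    if (state$inertia) Add <- Add + Mv / dt^2
    if (state$mass_damping > 0)
      Add <- Add + (state$mass_damping / dt) * Mv
  }
  A <- rbind(cbind(Add, -Q), cbind(Matrix::t(Q), App))
  pdofs <- 2 * n + seq_len(n)
  bc_rows <- c(state$fixed_dofs, 2 * n + state$drained_nodes)
  A <- methods::as(A, "CsparseMatrix")
  if (length(bc_rows)) {
    A[bc_rows, ] <- 0
    A[cbind(bc_rows, bc_rows)] <- 1
  }
  state$alpha_k <- alpha; state$beta_k <- beta
  state$Gk <- Gk; state$Ginf <- Ginf; state$G_eff <- G_eff
  state$Q <- Q; state$Kp <- Kp; state$Mp <- Mp; state$eps_stab <- eps_stab
  state$Mv <- Mv
  eq <- row_equilibrate(A)
  state$row_scale <- eq$scale
  state$lu <- Matrix::lu(methods::as(eq$A, "CsparseMatrix"))
  state$dt <- dt
  state
}

## resolve per-step surface loads into a 2n force vector.
## tractions: named list  tag -> c(tx, ty) Pa,  tag -> list(pressure = p),
## or an interface table  list(ifc = data.frame(ifc_row, tx, ty))
solid_surface_force <- function(state, tractions) {
  sub <- state$sub; geom <- state$geom; n <- geom$n_nodes
  f <- numeric(2 * n)
  if (is.null(tractions)) return(f)
  bnd <- sub$boundary
  eg <- edge_geom(sub$vertices * icp_units$mm_m, bnd, state$centroids_m)
  add_edge_force <- function(rows, tx, ty) {
    fx <- edge_load(bnd[rows, ], list(len = eg$len[rows]), tx, n)
    fy <- edge_load(bnd[rows, ], list(len = eg$len[rows]), ty, n)
    f[seq_len(n)] <<- f[seq_len(n)] + fx
    f[n + seq_len(n)] <<- f[n + seq_len(n)] + fy
  }
  for (nm in names(tractions)) {
    if (nm == "ifc") next
    rows <- which(bnd$tag == nm)
    if (length(rows) == 0) stop("no facets tagged '", nm, "' on solid")
    tr <- tractions[[nm]]
    if (is.list(tr) && !is.null(tr$pressure)) {
      add_edge_force(rows, -tr$pressure * eg$nx[rows],
                     -tr$pressure * eg$ny[rows])
    } else {
      add_edge_force(rows, rep(tr[1], length(rows)), rep(tr[2], length(rows)))
    }
  }
  if (!is.null(tractions$ifc)) {
    tab <- tractions$ifc
    rows <- match(tab$ifc_row, bnd$ifc_row)
    if (anyNA(rows)) stop("unknown interface rows in traction table")
    add_edge_force(rows, tab$tx, tab$ty)
  }
  f
}

#' Advance the poro-viscoelastic solid by one time step
#'
#' Solves the coupled momentum / pore-fluid system implicitly; the Prony
#' internal variables are advanced by the per-term exponential recurrence
#' \eqn{h_k \leftarrow e^{-dt/\tau_k} h_k + 2 G_k \beta_k \Delta e}, which
#' reproduces the relaxation function exactly for piecewise-constant strain.
#'
#' @param state a \code{solid_state}.
#' @param dt step in seconds (refactorizes if it differs from the cached
#'   step).
#' @param surface_tractions per-step surface loads; see
#'   \code{\link{init_solid}} details: named list \code{tag -> c(tx, ty)}
#'   (Pa), \code{tag -> list(pressure = p)}, and/or \code{ifc = data.frame(
#'   ifc_row, tx, ty)} for FSI facets.
#' @param bc_pore optional named values for drained facet pore pressure
#'   (default 0 on all drained nodes); a single number applies everywhere.
#' @param body_force c(fx, fy) N/m^3.
#' @param bc_displacement prescribed values (m) for the constrained
#'   displacement dofs, aligned with \code{state$fixed_dofs} (dof <= n is
#'   the x-component of node dof, else the y-component of node dof - n);
#'   default all zero.
#' @return The advanced \code{solid_state}.
#' @export
step_solid <- function(state, dt = state$dt, surface_tractions = NULL,
                       bc_pore = 0, body_force = c(0, 0),
                       bc_displacement = 0) {
  if (dt <= 0) stop("dt must be positive")
  if (abs(dt - state$dt) > 1e-14 * dt) state <- build_solid_system(state, dt)
  geom <- state$geom; n <- geom$n_nodes
  ## history stress: sum_k alpha_k h_k - 2 beta_k G_k e_prev (Voigt tensorial)
  s_hist <- matrix(0, nrow(state$sub$cells), 3)
  dev_prev <- dev_part(state$strain_prev)
  for (k in seq_along(state$Gk)) {
    s_hist <- s_hist + state$alpha_k[k] * state$prony_h[[k]] -
      2 * state$beta_k[k] * state$Gk[k] * dev_prev
  }
  f_ext <- solid_surface_force(state, surface_tractions)
  if (any(body_force != 0)) {
    f_ext[seq_len(n)] <- f_ext[seq_len(n)] +
      assemble_source(geom, rep(body_force[1], nrow(geom$cells)))
    f_ext[n + seq_len(n)] <- f_ext[n + seq_len(n)] +
      assemble_source(geom, rep(body_force[2], nrow(geom$cells)))
  }
  ## history stress enters as internal force on the RHS (Voigt with gxy row:
  ## convert tensorial exy-stress to the gxy convention used by B)
  f_hist <- stress_internal_force(geom, s_hist)
  rhs_mom <- f_ext - f_hist
  if (state$inertia)
    rhs_mom <- rhs_mom + (state$Mv %*% (2 * state$d - state$d_prev))[, 1] / dt^2
  if (state$mass_damping > 0)
    rhs_mom <- rhs_mom +
      (state$mass_damping / dt) * (state$Mv %*% state$d)[, 1]
  rhs_mass <- (Matrix::t(state$Q) %*% state$d)[, 1] +
    state$eps_stab * (state$Kp %*% state$pore_pressure)[, 1] +
    state$storage * (state$Mp %*% state$pore_pressure)[, 1]
  rhs <- c(rhs_mom, rhs_mass)
  rhs[state$fixed_dofs] <- bc_displacement
  if (length(state$drained_nodes))
    rhs[2 * n + state$drained_nodes] <- bc_pore
  sol <- solve_lu(state$lu, rhs * state$row_scale)
  d_new <- sol[seq_len(2 * n)]
  p_new <- sol[2 * n + seq_len(n)]
  ## update internal variables with the realized strain increment
  e_new <- cell_strain(geom, d_new)
  dev_new <- dev_part(e_new)
  dev_old <- dev_part(state$strain_prev)
  for (k in seq_along(state$Gk)) {
    state$prony_h[[k]] <- state$alpha_k[k] * state$prony_h[[k]] +
      2 * state$beta_k[k] * state$Gk[k] * (dev_new - dev_old)
  }
  state$velocity <- (d_new - state$d) / dt
  state$acceleration <- (d_new - 2 * state$d + state$d_prev) / dt^2
  state$d_prev <- state$d
  state$d <- d_new
  state$pore_pressure <- p_new
  state$strain_prev <- e_new
  state$time <- state$time + dt
  state
}

dev_part <- function(e) {
  tr <- e[, 1] + e[, 2]
  cbind(e[, 1] - tr / 3, e[, 2] - tr / 3, e[, 3])
}

#' Per-cell total Cauchy stress of the current solid state
#'
#' Effective viscoelastic stress minus the pore-pressure contribution
#' (Biot coefficient 1).  Returned in Voigt order (sxx, syy, sxy), Pa.
#'
#' @param state a \code{solid_state}.
#' @return Matrix with one row per brain cell.
#' @export
solid_stress <- function(state) {
  e <- state$strain_prev
  dev <- dev_part(e)
  tr <- e[, 1] + e[, 2]
  s <- 2 * state$Ginf * dev
  for (k in seq_along(state$Gk)) s <- s + state$prony_h[[k]]
  ## volumetric part + pore pressure (cell-average of nodal p)
  p_cell <- rowMeans(matrix(state$pore_pressure[t(state$sub$cells)],
                            ncol = 3, byrow = TRUE))
  sxx <- s[, 1] + state$material$bulk_modulus * tr - p_cell
  syy <- s[, 2] + state$material$bulk_modulus * tr - p_cell
  sxy <- s[, 3]
  cbind(sxx, syy, sxy)
}

#' Total-stress traction on tagged solid facets
#'
#' Returns \eqn{\sigma_S \cdot n} (outward normal of the solid) per facet.
#'
#' @param state a \code{solid_state}.
#' @param facet_tags character vector of facet tags (e.g.
#'   \code{c("fsi_inner", "fsi_outer")}).
#' @return data.frame with facet midpoints, normals, traction components
#'   (Pa) and the parent interface row when applicable.
#' @export
interface_traction <- function(state, facet_tags = c("fsi_inner",
                                                     "fsi_outer")) {
  bnd <- state$sub$boundary
  rows <- which(bnd$tag %in% facet_tags)
  if (length(rows) == 0) stop("no solid facets with the requested tags")
  eg <- edge_geom(state$sub$vertices * icp_units$mm_m, bnd,
                  state$centroids_m)
  s <- solid_stress(state)
  cl <- bnd$cell[rows]
  tx <- s[cl, 1] * eg$nx[rows] + s[cl, 3] * eg$ny[rows]
  ty <- s[cl, 3] * eg$nx[rows] + s[cl, 2] * eg$ny[rows]
  data.frame(mx = eg$mx[rows], my = eg$my[rows],
             nx = eg$nx[rows], ny = eg$ny[rows],
             tx = tx, ty = ty, len = eg$len[rows],
             ifc_row = bnd$ifc_row[rows], tag = bnd$tag[rows])
}
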