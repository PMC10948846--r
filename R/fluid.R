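## Incompressible Newtonian CSF on a moving (ALE) mesh: stabilized P1-P1
## finite elements, backward Euler, convection linearized at the last
## committed velocity (Oseen; CSF Reynolds numbers are well below 1).
## Continuity carries an optional ventricular production source and a weak
## pseudo-compressibility term that (a) regularizes enclosed CSF cavities in
## the partitioned coupling and (b) contributes a compliance orders of
## magnitude below the brain-wall compliance.

#' CSF fluid properties
#'
#' @param density kg/m^3 (default 998.2).
#' @param dynamic_viscosity kg/(m s) (default 0.001).
#' @param body_force c(fx, fy) N/m^3.
#' @return Object of class \code{fluid_properties}.
#' @export
fluid_properties <- function(density = 998.2, dynamic_viscosity = 0.001,
                             body_force = c(0, 0)) {
  if (density <= 0 || dynamic_viscosity <= 0)
    stop("density and dynamic_viscosity must be positive")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity,
                 body_force = body_force), class = "fluid_properties")
}

#' Boundary-condition constructors for the fluid solver
#'
#' \describe{
#'   \item{\code{bc_waveform(wf, direction)}}{plug-profile normal velocity
#'     carrying the waveform's flow rate through the tagged facets;
#'     \code{direction} +1 = inflow, -1 = outflow.}
#'   \item{\code{bc_pressure(value)}}{natural (traction) condition with
#'     prescribed pressure in Pa; \code{value} may be a function of time.}
#'   \item{\code{bc_noslip()}}{velocity equals the wall (mesh) velocity;
#'     zero on rigid walls.}
#'   \item{\code{bc_fsi()}}{Dirichlet velocity supplied per coupling
#'     iteration.}
#' }
#' @param wf a \code{\link{flow_waveform}}.
#' @param direction +1 inflow, -1 outflow.
#' @param value pressure in Pa, or \code{function(t)} returning Pa.
#' @return A bc descriptor list.
#' @export
bc_waveform <- function(wf, direction = 1) {
  stopifnot(inherits(wf, "flow_waveform"))
  list(type = "waveform", waveform = wf, direction = direction)
}

#' @rdname bc_waveform
#' @export
bc_pressure <- function(value) list(type = "pressure", value = value)

#' @rdname bc_waveform
#' @export
bc_noslip <- function() list(type = "noslip")

#' @rdname bc_waveform
#' @export
bc_fsi <- function() list(type = "fsi")

#' Volumetric CSF production source field
#'
#' Distributes a production rate uniformly over the ventricular CSF cells.
#' In the 2-D cross-section the rate is converted with the model's
#' effective out-of-plane depth, giving a source density in 1/s whose area
#' integral reproduces the requested rate.
#'
#' @param mesh an \code{icp_mesh}.
#' @param rate ml/min, >= 0.
#' @param effective_depth out-of-plane depth in m.
#' @return Numeric vector, one entry per mesh cell (1/s), with attribute
#'   \code{rate_ml_min}.
#' @examples
#' m <- generate_mesh(head_geometry(), "coarse")
#' S <- apply_production_source(m, 0.35)
#' @export
apply_production_source <- function(mesh, rate, effective_depth = 0.02) {
  if (!is.numeric(rate) || rate < 0) stop("production rate must be >= 0")
  S <- numeric(nrow(mesh$cells))
  vent <- mesh$region == "ventricle_csf"
  if (rate > 0) {
    A <- cell_areas(mesh)[vent] * icp_units$mm_m^2
    q2d <- mlmin_to_m3s(rate) / effective_depth     # m^2/s
    S[vent] <- q2d / sum(A)                          # 1/s, uniform
  }
  attr(S, "rate_ml_min") <- rate
  S
}

#' Initialize the CSF fluid state on a mesh
#'
#' Builds the fluid subproblem over all CSF cells.  Boundary conditions are
#' declared per facet tag with the \code{bc_*} constructors; FSI facets
#' default to no-slip rigid walls until the coupler supplies wall
#' velocities.
#'
#' @param mesh an \code{icp_mesh}.
#' @param props a \code{\link{fluid_properties}}.
#' @param bc named list: facet tag -> bc descriptor.
#' @param production ml/min distributed over the ventricular CSF (volumetric
#'   source mode); default 0 (boundary-inlet mode).
#' @param effective_depth out-of-plane depth in m for 2-D flux conversion.
#' @param numerical list: \code{stab_alpha} (pressure-stabilization
#'   constant), \code{bulk_modulus} (pseudo-compressibility, Pa),
#'   \code{cfl_bound} (advective Courant warning threshold).
#' @return Object of class \code{fluid_state}.
#' @export
init_fluid <- function(mesh, props = fluid_properties(), bc = list(),
                       production = 0, effective_depth = 0.02,
                       numerical = list()) {
  num <- utils::modifyList(list(stab_alpha = 0.05, bulk_modulus = 1e6,
                                cfl_bound = 5), numerical)
  sub <- submesh(mesh, FLUID_REGIONS)
  n <- nrow(sub$vertices)
  S_all <- apply_production_source(mesh, production, effective_depth)
  S_sub <- S_all[sub$cell_map]
  structure(list(
    sub = sub, props = props, bc = bc, numerical = num,
    effective_depth = effective_depth,
    vertices_mm = sub$vertices,        # current (ALE) coordinates
    vertices_ref_mm = sub$vertices,    # reference coordinates
    W = numeric(2 * n),                # mesh velocity, m/s
    production_cell = S_sub,
    production_rate = production,
    u = numeric(2 * n), p = numeric(n),
    u_n = numeric(2 * n), p_n = numeric(n),
    time = 0, sys = NULL), class = "fluid_state")
}

## nodes and outward unit normals for a facet tag set of the fluid submesh
fluid_tag_nodes <- function(state, tags) {
  bnd <- state$sub$boundary
  rows <- which(bnd$tag %in% tags)
  eg <- edge_geom(state$vertices_mm * icp_units$mm_m, bnd,
                  sub_centroids_m(state))
  nodes <- unique(c(bnd$n1[rows], bnd$n2[rows]))
  ## node normal: length-weighted mean of adjacent tagged edge normals
  nx <- tabulate_add(c(bnd$n1[rows], bnd$n2[rows]),
                     rep(eg$nx[rows] * eg$len[rows], 2), nrow(state$sub$vertices))
  ny <- tabulate_add(c(bnd$n1[rows], bnd$n2[rows]),
                     rep(eg$ny[rows] * eg$len[rows], 2), nrow(state$sub$vertices))
  nrm <- sqrt(nx^2 + ny^2); nrm[nrm == 0] <- 1
  list(nodes = nodes, nx = (nx / nrm)[nodes], ny = (ny / nrm)[nodes],
       rows = rows, eg = eg)
}

sub_centroids_ref_m <- function(state) {
  v <- state$vertices_ref_mm; cl <- state$sub$cells
  cbind((v[cl[, 1], 1] + v[cl[, 2], 1] + v[cl[, 3], 1]) / 3,
        (v[cl[, 1], 2] + v[cl[, 2], 2] + v[cl[, 3], 2]) / 3) * icp_units$mm_m
}

sub_centroids_m <- function(state) {
  v <- state$vertices_mm; cl <- state$sub$cells
  cbind((v[cl[, 1], 1] + v[cl[, 2], 1] + v[cl[, 3], 1]) / 3,
        (v[cl[, 1], 2] + v[cl[, 2], 2] + v[cl[, 3], 2]) / 3) * icp_units$mm_m
}

## assemble + factorize the fluid system for the step ending at time + dt
build_fluid_system <- function(state, dt) {
  sub <- state$sub; props <- state$props; num <- state$numerical
  geom <- fem_geom(state$vertices_mm * icp_units$mm_m, sub$cells)
  n <- geom$n_nodes
  rho <- props$density; mu <- props$dynamic_viscosity
  M <- assemble_mass(geom, rho)
  Kv <- assemble_stiffness(geom, mu)
  ## Oseen advection at the last committed velocity relative to the mesh
  un <- state$u_n
  ax <- rowMeans(matrix((un[seq_len(n)] - state$W[seq_len(n)])[t(sub$cells)],
                        ncol = 3, byrow = TRUE))
  ay <- rowMeans(matrix((un[n + seq_len(n)] -
                         state$W[n + seq_len(n)])[t(sub$cells)],
                        ncol = 3, byrow = TRUE))
  C <- assemble_advection(geom, rho * ax, rho * ay)
  Auu <- M / dt + Kv + C
  Bx <- assemble_grad_coupling(geom, "x")
  By <- assemble_grad_coupling(geom, "y")
  h2 <- 4 * geom$area                      # ~ h^2 per cell
  Stab <- assemble_stiffness(geom, num$stab_alpha * h2 / mu)
  Mp <- assemble_mass(geom, 1)
  App <- Stab + Mp / (num$bulk_modulus * dt)
  Z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(n, n))
  A <- rbind(cbind(Auu, Z, -Matrix::t(Bx)),
             cbind(Z, Auu, -Matrix::t(By)),
             cbind(Bx, By, App))
  A <- methods::as(A, "CsparseMatrix")
  ## classify Dirichlet velocity nodes
  t_new <- state$time + dt
  diri_nodes <- integer(0); diri_vx <- numeric(0); diri_vy <- numeric(0)
  f_u <- numeric(2 * n)
  for (tag in names(state$bc)) {
    b <- state$bc[[tag]]
    info <- fluid_tag_nodes(state, tag)
    if (length(info$rows) == 0) next
    if (b$type == "waveform") {
      L <- sum(info$eg$len[info$rows])
      q2d <- mlmin_to_m3s(waveform_rate_at(b$waveform, t_new)) /
        state$effective_depth
      vmag <- q2d / L
      sgn <- -b$direction        # inflow: against the outward normal
      diri_nodes <- c(diri_nodes, info$nodes)
      diri_vx <- c(diri_vx, sgn * vmag * info$nx)
      diri_vy <- c(diri_vy, sgn * vmag * info$ny)
    } else if (b$type == "noslip" || b$type == "fsi") {
      diri_nodes <- c(diri_nodes, info$nodes)
      diri_vx <- c(diri_vx, state$W[info$nodes])
      diri_vy <- c(diri_vy, state$W[n + info$nodes])
    } else if (b$type == "pressure") {
      pv <- if (is.function(b$value)) b$value(t_new) else b$value
      rows <- info$rows; eg <- info$eg
      f_u[seq_len(n)] <- f_u[seq_len(n)] +
        tabulate_add(c(sub$boundary$n1[rows], sub$boundary$n2[rows]),
                     rep(-pv * eg$nx[rows] * eg$len[rows] / 2, 2), n)
      f_u[n + seq_len(n)] <- f_u[n + seq_len(n)] +
        tabulate_add(c(sub$boundary$n1[rows], sub$boundary$n2[rows]),
                     rep(-pv * eg$ny[rows] * eg$len[rows] / 2, 2), n)
    } else stop("unknown bc type: ", b$type)
  }
  ## later declarations win on shared nodes (fsi listed last wins)
  keep <- !duplicated(diri_nodes, fromLast = TRUE)
  diri <- list(nodes = diri_nodes[keep], vx = diri_vx[keep],
               vy = diri_vy[keep])
  ## rescale each waveform tag so the discrete trapezoid flux through its
  ## facets matches the target exactly even where wall conditions claimed
  ## shared corner nodes
  for (tag in names(state$bc)) {
    b <- state$bc[[tag]]
    if (b$type != "waveform") next
    info <- fluid_tag_nodes(state, tag)
    if (length(info$rows) == 0) next
    t_new <- state$time + dt
    q2d <- mlmin_to_m3s(waveform_rate_at(b$waveform, t_new)) /
      state$effective_depth
    target <- -b$direction * q2d       # sign in outward-normal convention
    vxn <- vyn <- numeric(nrow(state$sub$vertices))
    vxn[diri$nodes] <- diri$vx; vyn[diri$nodes] <- diri$vy
    rows <- info$rows; eg <- info$eg
    n1 <- state$sub$boundary$n1[rows]; n2 <- state$sub$boundary$n2[rows]
    flux <- sum(eg$len[rows] * 0.5 *
                ((vxn[n1] + vxn[n2]) * eg$nx[rows] +
                 (vyn[n1] + vyn[n2]) * eg$ny[rows]))
    if (abs(flux) > 1e-300 && abs(target) > 0) {
      sel <- which(diri$nodes %in% info$nodes)
      ## only rescale nodes whose winning assignment came from this tag
      ## (nodes overridden by walls have zero velocity and stay zero)
      live <- sel[abs(diri$vx[sel]) + abs(diri$vy[sel]) > 0]
      fac <- target / flux
      diri$vx[live] <- diri$vx[live] * fac
      diri$vy[live] <- diri$vy[live] * fac
    }
  }
  if (any(props$body_force != 0)) {
    f_u[seq_len(n)] <- f_u[seq_len(n)] +
      assemble_source(geom, rep(props$body_force[1], nrow(sub$cells)))
    f_u[n + seq_len(n)] <- f_u[n + seq_len(n)] +
      assemble_source(geom, rep(props$body_force[2], nrow(sub$cells)))
  }
  f_p <- assemble_source(geom, state$production_cell) +
    (Mp %*% state$p_n)[, 1] / (num$bulk_modulus * dt)
  rhs0 <- c(f_u + (Matrix::bdiag(M, M) %*% state$u_n)[, 1] / dt, f_p)
  bc_rows <- c(diri$nodes, n + diri$nodes)
  A[bc_rows, ] <- 0
  A[cbind(bc_rows, bc_rows)] <- 1
  list(lu = Matrix::lu(A), rhs0 = rhs0, diri = diri, geom = geom,
       dt = dt, n = n)
}

#' Advance the CSF flow field by one time step
#'
#' Solves the stabilized ALE Oseen system for the step ending at
#' \code{state$time + dt}.  During partitioned FSI subiterations call with
#' \code{commit = FALSE} and supply wall velocities for the FSI facets; the
#' assembled system is cached and only the Dirichlet data changes, so
#' repeated solves reuse the factorization.
#'
#' @param state a \code{fluid_state}.
#' @param dt time step, s.
#' @param fsi_velocity optional list with \code{nodes} (fluid submesh node
#'   ids), \code{vx}, \code{vy} (m/s) prescribing wall velocities on FSI
#'   facets.
#' @param commit if \code{TRUE}, accept the solution (advance time).
#' @return The updated \code{fluid_state}.
#' @export
step_fluid <- function(state, dt, fsi_velocity = NULL, commit = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(state$sys) || abs(state$sys$dt - dt) > 1e-14 * dt)
    state$sys <- build_fluid_system(state, dt)
  sys <- state$sys; n <- sys$n
  rhs <- sys$rhs0
  vx <- sys$diri$vx; vy <- sys$diri$vy; nodes <- sys$diri$nodes
  if (!is.null(fsi_velocity)) {
    hit <- match(fsi_velocity$nodes, nodes)
    if (anyNA(hit)) stop("fsi_velocity nodes are not Dirichlet wall nodes")
    vx[hit] <- fsi_velocity$vx; vy[hit] <- fsi_velocity$vy
  }
  rhs[nodes] <- vx
  rhs[n + nodes] <- vy
  sol <- solve_lu(sys$lu, rhs)
  state$u <- sol[seq_len(2 * n)]
  state$p <- sol[2 * n + seq_len(n)]
  ## advective Courant diagnostic (relative to the mesh)
  rel <- sqrt((state$u[seq_len(n)] - state$W[seq_len(n)])^2 +
              (state$u[n + seq_len(n)] - state$W[n + seq_len(n)])^2)
  h_min <- sqrt(2 * min(sys$geom$area))
  courant <- max(rel) * dt / h_min
  if (is.finite(courant) && courant > state$numerical$cfl_bound)
    warning(sprintf(
      "advective Courant number %.2f exceeds the configured bound %g",
      courant, state$numerical$cfl_bound))
  if (commit) state <- fluid_commit(state)
  state
}

#' @rdname step_fluid
#' @export
fluid_commit <- function(state) {
  state$u_n <- state$u; state$p_n <- state$p
  state$time <- state$time + state$sys$dt
  state$sys <- NULL
  state
}

#' Move the fluid mesh (ALE) and set the mesh velocity
#'
#' @param state a \code{fluid_state}.
#' @param new_vertices_mm matrix of updated fluid submesh coordinates (mm).
#' @param dt time step over which the motion happens, s.
#' @return Updated state with mesh velocity \code{W} by backward difference.
#' @export
move_fluid_mesh <- function(state, new_vertices_mm, dt) {
  disp_m <- (new_vertices_mm - state$vertices_mm) * icp_units$mm_m
  state$W <- c(disp_m[, 1], disp_m[, 2]) / dt
  state$vertices_mm <- new_vertices_mm
  state$sys <- NULL
  state
}

#' Net CSF mass-flux imbalance of the current fluid state
#'
#' Integrates \eqn{u \cdot n} over the whole fluid boundary and subtracts
#' the volumetric production integral; with wall velocities equal to the
#' mesh velocity this equals inflow + production - outflow - d/dt(volume).
#' Converted to ml/min with the model's effective depth.
#'
#' @param state a \code{fluid_state}.
#' @return List with \code{imbalance_ml_min} (absolute), per-tag boundary
#'   fluxes in ml/min (\code{flux_by_tag}, positive outward), and
#'   \code{production_ml_min}.
#' @export
global_mass_balance <- function(state) {
  sub <- state$sub; n <- nrow(sub$vertices)
  bnd <- sub$boundary
  eg <- edge_geom(state$vertices_mm * icp_units$mm_m, bnd,
                  sub_centroids_m(state))
  u1x <- state$u[bnd$n1]; u2x <- state$u[bnd$n2]
  u1y <- state$u[n + bnd$n1]; u2y <- state$u[n + bnd$n2]
  flux <- eg$len * 0.5 * ((u1x + u2x) * eg$nx + (u1y + u2y) * eg$ny)
  by_tag <- vapply(split(flux, bnd$tag), sum, numeric(1))
  geom <- fem_geom(state$vertices_mm * icp_units$mm_m, sub$cells)
  prod_int <- sum(state$production_cell * geom$area)
  to_mlmin <- state$effective_depth / icp_units$mlmin_m3s
  list(imbalance_ml_min = abs(sum(flux) - prod_int) * to_mlmin,
       flux_by_tag = by_tag * to_mlmin,
       production_ml_min = prod_int * to_mlmin)
}

#' Fluid traction on the FSI facets
#'
#' \eqn{\sigma_F \cdot n = (-p I + \mu (\nabla u + \nabla u^T)) \cdot n}
#' per facet, with the outward normal of the fluid.  Normals are taken on
#' the reference configuration, consistent with the small-strain solid the
#' traction is handed to (evaluating the pressure load on deformed normals
#' without geometric stiffness on the solid side creates a spurious
#' follower-load instability).
#'
#' @param state a \code{fluid_state}.
#' @return data.frame with \code{ifc_row}, midpoints, fluid outward
#'   normals, and traction components in Pa.
#' @export
fluid_interface_traction <- function(state) {
  sub <- state$sub; n <- nrow(sub$vertices)
  bnd <- sub$boundary
  rows <- which(bnd$tag %in% c("fsi_inner", "fsi_outer"))
  if (length(rows) == 0) stop("fluid submesh has no FSI facets")
  eg <- edge_geom(state$vertices_ref_mm * icp_units$mm_m, bnd,
                  sub_centroids_ref_m(state))
  geom <- fem_geom(state$vertices_mm * icp_units$mm_m, sub$cells)
  mu <- state$props$dynamic_viscosity
  ## P0 velocity gradient on the adjacent cell
  cl <- bnd$cell[rows]
  gxx <- gxy <- gyx <- gyy <- numeric(length(rows))
  for (i in 1:3) {
    ni <- sub$cells[cl, i]
    gxx <- gxx + geom$bx[cl, i] * state$u[ni]
    gxy <- gxy + geom$by[cl, i] * state$u[ni]
    gyx <- gyx + geom$bx[cl, i] * state$u[n + ni]
    gyy <- gyy + geom$by[cl, i] * state$u[n + ni]
  }
  p_edge <- 0.5 * (state$p[bnd$n1[rows]] + state$p[bnd$n2[rows]])
  nx <- eg$nx[rows]; ny <- eg$ny[rows]
  tx <- -p_edge * nx + mu * (2 * gxx * nx + (gxy + gyx) * ny)
  ty <- -p_edge * ny + mu * ((gxy + gyx) * nx + 2 * gyy * ny)
  data.frame(ifc_row = bnd$ifc_row[rows], mx = eg$mx[rows], my = eg$my[rows],
             nx = nx, ny = ny, tx = tx, ty = ty, len = eg$len[rows],
             tag = bnd$tag[rows])
}

#' Area-weighted pressure summaries over a fluid region
#'
#' @param state a \code{fluid_state}.
#' @param region \code{"ventricle_csf"} or \code{"sas_csf"}.
#' @return List with \code{mean_Pa} and \code{max_Pa}.
#' @export
fluid_pressure_probe <- function(state, region = "ventricle_csf") {
  sel <- state$sub$region == region
  if (!any(sel)) stop("no cells in region ", region)
  geom <- fem_geom(state$vertices_mm * icp_units$mm_m, state$sub$cells)
  p_cell <- rowMeans(matrix(state$p[t(state$sub$cells)], ncol = 3,
                            byrow = TRUE))
  w <- geom$area[sel]
  list(mean_Pa = sum(p_cell[sel] * w) / sum(w),
       max_Pa = max(state$p[unique(as.vector(state$sub$cells[sel, ]))]))
}
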