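## Two-way partitioned Dirichlet-Neumann coupling on the brain-CSF
## interfaces: the fluid receives wall velocities, the solid receives fluid
## tractions, and the interface displacement is relaxed with Aitken's
## dynamic factor until displacement-compatibility and traction-equilibrium
## residuals fall below tolerance.  Fluid mesh motion is a harmonic
## extension of the interface displacement (geometry updated explicitly at
## the start of each step).

#' Coupling configuration for a two-way FSI run
#'
#' @param max_subiterations cap on Dirichlet-Neumann subiterations per step.
#' @param interface_tolerance relative residual tolerance on interface
#'   displacement and traction.
#' @param relaxation_factor initial relaxation factor in (0, 1]; Aitken's
#'   method adapts it dynamically.
#' @param dt time step in seconds; \code{NULL} = cardiac period / 32.
#' @param n_cycles cardiac cycles to simulate (>= 1); the last cycle is the
#'   reporting window.
#' @param outlet_pressure cmH2O prescribed at the pressure outlets - the
#'   stand-in for the shunt valve's operating pressure (applied at the
#'   ventricular shunt facet and at the SAS pressure outlets).
#' @param outlet_mode \code{"both_pressure"} (both SAS outlets at the
#'   prescribed pressure; default for the non-communicating geometry) or
#'   \code{"sinus_pressure"} (spinal outlet driven by its outflow waveform,
#'   sinus outlet at the prescribed pressure; the natural choice when the
#'   aqueduct is open).
#' @param abort_on_stall abort the run when a step hits the subiteration cap
#'   (otherwise the step is flagged and the run continues).
#' @return Object of class \code{coupling_config}.
#' @export
coupling_config <- function(max_subiterations = 60,
                            interface_tolerance = 1e-4,
                            relaxation_factor = 0.3,
                            dt = NULL, n_cycles = 3,
                            outlet_pressure = 5,
                            outlet_mode = c("both_pressure",
                                            "sinus_pressure"),
                            abort_on_stall = FALSE) {
  outlet_mode <- match.arg(outlet_mode)
  stopifnot(interface_tolerance > 0, is.null(dt) || dt > 0, n_cycles >= 1,
            relaxation_factor > 0, relaxation_factor <= 1)
  structure(list(max_subiterations = max_subiterations,
                 interface_tolerance = interface_tolerance,
                 relaxation_factor = relaxation_factor,
                 dt = dt, n_cycles = n_cycles,
                 outlet_pressure = outlet_pressure,
                 outlet_mode = outlet_mode,
                 abort_on_stall = abort_on_stall),
            class = "coupling_config")
}

## interface node bookkeeping shared by fluid and solid submeshes
interface_maps <- function(mesh, fluid_sub, solid_sub) {
  ifc <- mesh$interfaces
  nodes_g <- sort(unique(c(ifc$n1, ifc$n2)))
  fl <- match(nodes_g, fluid_sub$nodes_global)
  so <- match(nodes_g, solid_sub$nodes_global)
  if (anyNA(fl) || anyNA(so))
    stop("FSI interface nodes must belong to both fluid and solid submeshes")
  ## outward (from the fluid) nodal normals and inner-interface mask from
  ## the reference configuration
  v <- mesh$vertices
  len <- sqrt((v[ifc$n1, 1] - v[ifc$n2, 1])^2 +
              (v[ifc$n1, 2] - v[ifc$n2, 2])^2)
  inner <- ifc$tag == "fsi_inner"
  node_inner <- nodes_g %in% unique(c(ifc$n1[inner], ifc$n2[inner]))
  ## radial normals of the concentric reference geometry
  r <- sqrt(v[nodes_g, 1]^2 + v[nodes_g, 2]^2)
  list(nodes_global = nodes_g, fluid_local = fl, solid_local = so,
       node_inner = node_inner,
       nx = v[nodes_g, 1] / pmax(r, 1e-12),
       ny = v[nodes_g, 2] / pmax(r, 1e-12),
       ifc = ifc, ifc_len_mm = len)
}

## harmonic-extension operator for the fluid mesh: Laplace solve on the
## reference fluid submesh with Dirichlet on every fluid boundary node
make_extension <- function(fluid_sub) {
  geom <- fem_geom(fluid_sub$vertices, fluid_sub$cells)  # mm is fine here
  K <- assemble_stiffness(geom)
  bnodes <- sort(unique(c(fluid_sub$boundary$n1, fluid_sub$boundary$n2)))
  K <- methods::as(K, "CsparseMatrix")
  K[bnodes, ] <- 0
  K[cbind(bnodes, bnodes)] <- 1
  list(lu = Matrix::lu(K), bnodes = bnodes, n = nrow(fluid_sub$vertices))
}

extend_displacement <- function(ext, values_x, values_y) {
  rx <- numeric(ext$n); ry <- numeric(ext$n)
  rx[ext$bnodes] <- values_x[ext$bnodes]
  ry[ext$bnodes] <- values_y[ext$bnodes]
  cbind(solve_lu(ext$lu, rx), solve_lu(ext$lu, ry))
}

#' Run a two-way strongly-coupled FSI simulation
#'
#' Per time step the fluid (wall velocities prescribed) and the solid
#' (fluid tractions prescribed) are solved alternately with Aitken-relaxed
#' interface displacement updates until the interface residual falls below
#' tolerance; the fluid mesh follows a harmonic extension of the interface
#' motion.  The ventricular CSF pressure probe gives the ICP series.
#'
#' @param mesh an \code{icp_mesh} of the head geometry.
#' @param fluid_props a \code{\link{fluid_properties}}.
#' @param material a \code{\link{poro_viscoelastic_material}}.
#' @param waveform_triplet list with elements \code{inlet}, \code{spinal},
#'   \code{sinus} (\code{\link{flow_waveform}}s sharing one heart rate).
#' @param coupling a \code{\link{coupling_config}}.
#' @param effective_depth out-of-plane depth (m) for 2-D flux conversion.
#' @param numerical_fluid optional numerical overrides for
#'   \code{\link{init_fluid}}.
#' @param verbose print per-step convergence info.
#' @return Object of class \code{fsi_result}: time series of ICP (mean and
#'   peak probes, cmH2O), interface displacement (mm), deformation (mm),
#'   ventricular volume (ml), per-step subiteration counts, residuals and
#'   convergence flags, plus static geometry measures (intracranial volume,
#'   brain surface area).
#' @export
run_fsi <- function(mesh, fluid_props = fluid_properties(),
                    material = poro_viscoelastic_material(),
                    waveform_triplet, coupling = coupling_config(),
                    effective_depth = 0.02, numerical_fluid = list(),
                    verbose = FALSE) {
  wf <- waveform_triplet
  stopifnot(inherits(wf$inlet, "flow_waveform"))
  period <- wf$inlet$period
  dt <- if (is.null(coupling$dt)) period / 32 else coupling$dt
  n_steps_cycle <- round(period / dt)
  if (abs(n_steps_cycle * dt - period) > 1e-9 * period)
    stop("dt must divide the cardiac period")
  n_steps <- n_steps_cycle * coupling$n_cycles
  p_out <- cmH2O_to_Pa(coupling$outlet_pressure)
  bc <- list(
    inlet = bc_waveform(wf$inlet, direction = 1),
    spinal_outlet = if (coupling$outlet_mode == "sinus_pressure")
      bc_waveform(wf$spinal, direction = -1) else bc_pressure(p_out),
    sinus_outlet = bc_pressure(p_out),
    dura = bc_noslip(),
    fsi_inner = bc_fsi(), fsi_outer = bc_fsi())
  if ("shunt" %in% mesh$boundary$tag) bc$shunt <- bc_pressure(p_out)
  fluid <- init_fluid(mesh, fluid_props, bc,
                      effective_depth = effective_depth,
                      numerical = numerical_fluid)
  solid <- init_solid(mesh, material, dt = dt, inertia = TRUE)
  maps <- interface_maps(mesh, fluid$sub, solid$sub)
  ext <- make_extension(fluid$sub)
  n_ifc <- length(maps$nodes_global)
  nf <- nrow(fluid$sub$vertices); ns <- nrow(solid$sub$vertices)
  geo <- measure_volume_and_area(mesh)
  ref_mm <- fluid$sub$vertices
  d_ifc <- matrix(0, n_ifc, 2)      # converged interface displacement, m
  times <- icp_mean <- icp_peak <- disp_series <- def_series <-
    vvol_series <- numeric(n_steps)
  subiter_count <- integer(n_steps)
  converged <- logical(n_steps)
  res_hist <- vector("list", n_steps)
  tol <- coupling$interface_tolerance
  for (s in seq_len(n_steps)) {
    ## geometry-explicit ALE update from the last converged displacement
    vals_x <- numeric(nf); vals_y <- numeric(nf)
    vals_x[maps$fluid_local] <- d_ifc[, 1]
    vals_y[maps$fluid_local] <- d_ifc[, 2]
    ext_disp <- extend_displacement(ext, vals_x, vals_y)   # metres
    fluid <- move_fluid_mesh(fluid, ref_mm + ext_disp / icp_units$mm_m, dt)
    d_step0 <- d_ifc
    d_k <- d_ifc
    omega <- coupling$relaxation_factor
    r_prev <- NULL
    tr_prev <- NULL
    resid <- numeric(0)
    ok <- FALSE
    for (it in seq_len(coupling$max_subiterations)) {
      v_ifc <- (d_k - d_step0) / dt
      fluid <- step_fluid(fluid, dt,
                          fsi_velocity = list(nodes = maps$fluid_local,
                                              vx = v_ifc[, 1],
                                              vy = v_ifc[, 2]),
                          commit = FALSE)
      tr <- fluid_interface_traction(fluid)
      ord <- order(tr$ifc_row)
      tr <- tr[ord, ]
      solid_trial <- step_solid(
        solid, dt,
        surface_tractions = list(ifc = data.frame(ifc_row = tr$ifc_row,
                                                  tx = -tr$tx,
                                                  ty = -tr$ty)))
      d_new <- cbind(solid_trial$d[maps$solid_local],
                     solid_trial$d[ns + maps$solid_local])
      r <- d_new - d_k
      scale <- max(max(abs(d_new)), 1e-9)
      res <- max(abs(r)) / scale
      tr_vec <- c(tr$tx, tr$ty)
      tr_res <- if (is.null(tr_prev)) Inf else
        max(abs(tr_vec - tr_prev)) / max(max(abs(tr_vec)), 1e-12)
      tr_prev <- tr_vec
      resid <- c(resid, res)
      if (res <= tol && tr_res <= 10 * tol) {
        solid <- solid_trial
        d_k <- d_new
        ok <- TRUE
        break
      }
      if (!is.null(r_prev)) {
        dr <- as.vector(r - r_prev)
        den <- sum(dr * dr)
        if (den > 0)
          omega <- max(min(-omega * sum(as.vector(r_prev) * dr) / den,
                           1), 0.01)
      }
      r_prev <- r
      d_k <- d_k + omega * r
    }
    if (!ok && coupling$abort_on_stall)
      stop("FSI subiterations stalled at step ", s,
           " (residual ", signif(utils::tail(resid, 1), 3), ")")
    d_ifc <- d_k
    times[s] <- fluid$time + dt
    probe <- fluid_pressure_probe(fluid, "ventricle_csf")
    icp_mean[s] <- Pa_to_cmH2O(probe$mean_Pa)
    icp_peak[s] <- Pa_to_cmH2O(probe$max_Pa)
    dmag <- sqrt(d_ifc[, 1]^2 + d_ifc[, 2]^2)
    disp_series[s] <- mean(dmag) / icp_units$mm_m
    dn <- abs(d_ifc[, 1] * maps$nx + d_ifc[, 2] * maps$ny)
    def_series[s] <- mean(dn[maps$node_inner]) / icp_units$mm_m
    vvol_series[s] <- deformed_ventricle_volume(fluid)
    subiter_count[s] <- it
    converged[s] <- ok
    res_hist[[s]] <- resid
    fluid <- fluid_commit(fluid)
    if (verbose)
      message(sprintf(
        "step %d/%d t=%.3f s: %d subiters, res %.2e, ICP %.3f cmH2O",
        s, n_steps, times[s], it, utils::tail(resid, 1), icp_mean[s]))
  }
  structure(list(
    times = times, dt = dt, n_steps_cycle = n_steps_cycle,
    n_cycles = coupling$n_cycles,
    icp_mean_cmH2O = icp_mean, icp_peak_cmH2O = icp_peak,
    interface_displacement_mm = disp_series,
    deformation_mm = def_series,
    ventricular_volume_ml = vvol_series,
    intracranial_volume_ml = geo$volume_ml,
    brain_surface_area_cm2 = geo$area_cm2,
    subiterations = subiter_count, converged = converged,
    residual_history = res_hist,
    coupling = coupling, fluid = fluid, solid = solid,
    maps = maps), class = "fsi_result")
}

## revolved (Pappus) volume of the deformed ventricular CSF cells, ml
deformed_ventricle_volume <- function(fluid) {
  sel <- fluid$sub$region == "ventricle_csf"
  v <- fluid$vertices_mm; cl <- fluid$sub$cells[sel, , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  a <- cl[, 1]; b <- cl[, 2]; c3 <- cl[, 3]
  A <- 0.5 * abs((x[b] - x[a]) * (y[c3] - y[a]) -
                 (x[c3] - x[a]) * (y[b] - y[a]))
  yc <- (y[a] + y[b] + y[c3]) / 3
  up <- yc > 0
  2 * pi * sum(yc[up] * A[up]) / 1000
}

#' @exportS3Method base::print
print.fsi_result <- function(x, ...) {
  cat(sprintf("FSI simulation: %d cycles x %d steps (dt = %.4g s)\n",
              x$n_cycles, x$n_steps_cycle, x$dt))
  cat(sprintf("  converged steps: %d/%d; final-cycle mean ICP %.3f cmH2O\n",
              sum(x$converged), length(x$converged),
              extract_icp(x, "cycle_mean")))
  invisible(x)
}

final_cycle_index <- function(result) {
  n <- length(result$times)
  seq(n - result$n_steps_cycle + 1, n)
}

#' Scalar ICP from an FSI result
#'
#' Reduces the ventricular pressure probe over the final simulated cycle.
#'
#' @param result an \code{fsi_result} (or any list with the same series).
#' @param reducer \code{"cycle_mean"} or \code{"cycle_peak"}.
#' @param require_converged refuse when steps of the final cycle did not
#'   converge.
#' @return ICP in cmH2O.
#' @export
extract_icp <- function(result, reducer = c("cycle_mean", "cycle_peak"),
                        require_converged = TRUE) {
  reducer <- match.arg(reducer)
  idx <- final_cycle_index(result)
  if (require_converged && !all(result$converged[idx]))
    stop("final cycle contains non-converged steps; refusing to reduce")
  series <- result$icp_mean_cmH2O[idx]
  if (reducer == "cycle_mean") mean(series) else max(series)
}

#' Scalar brain deformation from an FSI result
#'
#' Reduces the mean normal interface displacement magnitude over the
#' inner (ventricular) FSI facets over the final cycle.
#'
#' @inheritParams extract_icp
#' @return Deformation in mm.
#' @export
extract_deformation <- function(result,
                                reducer = c("cycle_mean", "cycle_peak"),
                                require_converged = TRUE) {
  reducer <- match.arg(reducer)
  idx <- final_cycle_index(result)
  if (require_converged && !all(result$converged[idx]))
    stop("final cycle contains non-converged steps; refusing to reduce")
  series <- result$deformation_mm[idx]
  if (reducer == "cycle_mean") mean(series) else max(series)
}

#' Rigid-cavity fluid-only reference run
#'
#' Runs the fluid solver alone on the same geometry and boundary data with
#' all FSI facets treated as rigid no-slip walls.  Serves as the oracle for
#' the rigid-solid limit of the coupled solver.
#'
#' @inheritParams run_fsi
#' @return List with \code{times}, \code{icp_mean_cmH2O},
#'   \code{icp_peak_cmH2O} and the final \code{fluid_state}.
#' @export
run_rigid_cavity <- function(mesh, fluid_props = fluid_properties(),
                             waveform_triplet,
                             coupling = coupling_config(),
                             effective_depth = 0.02,
                             numerical_fluid = list()) {
  wf <- waveform_triplet
  period <- wf$inlet$period
  dt <- if (is.null(coupling$dt)) period / 32 else coupling$dt
  n_steps <- round(period / dt) * coupling$n_cycles
  p_out <- cmH2O_to_Pa(coupling$outlet_pressure)
  bc <- list(
    inlet = bc_waveform(wf$inlet, direction = 1),
    spinal_outlet = if (coupling$outlet_mode == "sinus_pressure")
      bc_waveform(wf$spinal, direction = -1) else bc_pressure(p_out),
    sinus_outlet = bc_pressure(p_out),
    dura = bc_noslip(),
    fsi_inner = bc_noslip(), fsi_outer = bc_noslip())
  if ("shunt" %in% mesh$boundary$tag) bc$shunt <- bc_pressure(p_out)
  fluid <- init_fluid(mesh, fluid_props, bc,
                      effective_depth = effective_depth,
                      numerical = numerical_fluid)
  times <- icp_mean <- icp_peak <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    fluid <- step_fluid(fluid, dt, commit = TRUE)
    probe <- fluid_pressure_probe(fluid, "ventricle_csf")
    times[s] <- fluid$time
    icp_mean[s] <- Pa_to_cmH2O(probe$mean_Pa)
    icp_peak[s] <- Pa_to_cmH2O(probe$max_Pa)
  }
  list(times = times, icp_mean_cmH2O = icp_mean, icp_peak_cmH2O = icp_peak,
       n_steps_cycle = round(period / dt), n_cycles = coupling$n_cycles,
       converged = rep(TRUE, n_steps), fluid = fluid)
}
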