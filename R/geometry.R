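## Idealized head geometry: concentric ventricle - brain - subarachnoid
## space (SAS) bands around a small central inlet hole (choroid-plexus
## stand-in), with an optional annular "aqueduct" channel through the brain
## band whose width models stenosis severity (0 = complete stenosis,
## non-communicating).

#' Idealized head geometry parameters
#'
#' The cranium is idealized as concentric regions in a 2-D cross-section:
#' a central inlet hole of radius \code{inlet_radius} (where the ventricular
#' inflow waveform is applied), ventricular CSF out to
#' \code{ventricle_radius}, brain parenchyma out to
#' \code{brain_outer_radius}, and a CSF-filled subarachnoid space of
#' thickness \code{sas_thickness} bounded by the rigid dura.  An aqueduct
#' channel of half-width \code{aqueduct_radius} may cut through the brain
#' band to connect the two CSF spaces; \code{aqueduct_radius = 0} is the
#' default non-communicating (complete aqueductal stenosis) configuration.
#'
#' @param ventricle_radius mm (> inlet_radius).
#' @param brain_outer_radius mm (> ventricle_radius).
#' @param sas_thickness mm (> 0).
#' @param aqueduct_radius mm, >= 0; 0 means complete stenosis.
#' @param inlet_radius mm (> 0, < ventricle_radius).
#' @param spinal_outlet_arc radians \code{c(lo, hi)} on the dura where the
#'   spinal outlet sits (default around -pi/2).
#' @param sinus_outlet_arc radians for the sagittal-sinus outlet
#'   (default around +pi/2).
#' @param shunt_arc radians on the central hole carrying the shunt-catheter
#'   pressure outlet (the stand-in for the ventriculoperitoneal shunt
#'   valve); the rest of the hole is the production inflow.
#' @param symmetry flag, currently \code{"plane2d"} (cross-section solve
#'   with revolved volume/area measurement).
#' @return Object of class \code{head_geometry}.
#' @examples
#' g <- head_geometry()          # defaults: 20 / 70 / 3 mm, closed aqueduct
#' @export
head_geometry <- function(ventricle_radius = 20,
                          brain_outer_radius = 70,
                          sas_thickness = 3,
                          aqueduct_radius = 0,
                          inlet_radius = 2,
                          spinal_outlet_arc = -pi / 2 + c(-0.28, 0.28),
                          sinus_outlet_arc = pi / 2 + c(-0.28, 0.28),
                          shunt_arc = -pi / 2 + c(-0.7, 0.7),
                          symmetry = "plane2d") {
  if (!is.numeric(ventricle_radius) || !is.numeric(brain_outer_radius) ||
      ventricle_radius <= 0 || brain_outer_radius <= ventricle_radius)
    stop("invalid geometry: need 0 < ventricle_radius < brain_outer_radius")
  if (sas_thickness <= 0) stop("invalid geometry: sas_thickness must be > 0")
  if (aqueduct_radius < 0) stop("invalid geometry: aqueduct_radius >= 0")
  if (inlet_radius <= 0 || inlet_radius >= ventricle_radius)
    stop("invalid geometry: need 0 < inlet_radius < ventricle_radius")
  structure(list(ventricle_radius = ventricle_radius,
                 brain_outer_radius = brain_outer_radius,
                 sas_thickness = sas_thickness,
                 aqueduct_radius = aqueduct_radius,
                 inlet_radius = inlet_radius,
                 spinal_outlet_arc = spinal_outlet_arc,
                 sinus_outlet_arc = sinus_outlet_arc,
                 shunt_arc = shunt_arc,
                 symmetry = symmetry),
            class = "head_geometry")
}

#' Build the analytic boundary description of the idealized head
#'
#' Turns the raw parameters into a closed region description: radial bands
#' with region roles, the aqueduct sector (if open), and the boundary arcs
#' carrying each facet role.  All six roles used by the solvers (inlet,
#' spinal_outlet, sinus_outlet, dura, fsi_inner, fsi_outer) are assignable.
#'
#' @param params a \code{\link{head_geometry}}.
#' @return Object of class \code{head_region}: list with \code{radii}
#'   (named: inlet, ventricle, brain, dura), \code{aqueduct_half_angle}
#'   (radians; 0 when stenosed shut), outlet arcs, and the original params.
#' @export
build_geometry <- function(params) {
  stopifnot(inherits(params, "head_geometry"))
  r_dura <- params$brain_outer_radius + params$sas_thickness
  r_mid <- 0.5 * (params$ventricle_radius + params$brain_outer_radius)
  half_angle <- if (params$aqueduct_radius > 0)
    params$aqueduct_radius / r_mid else 0
  structure(list(
    radii = c(inlet = params$inlet_radius,
              ventricle = params$ventricle_radius,
              brain = params$brain_outer_radius,
              dura = r_dura),
    aqueduct_half_angle = half_angle,
    aqueduct_center_angle = 0,
    spinal_outlet_arc = params$spinal_outlet_arc,
    sinus_outlet_arc = params$sinus_outlet_arc,
    shunt_arc = params$shunt_arc,
    params = params), class = "head_region")
}

#' @exportS3Method base::print
print.head_geometry <- function(x, ...) {
  cat(sprintf(
    "Idealized head geometry: ventricle %g mm, brain %g mm, SAS %g mm, %s\n",
    x$ventricle_radius, x$brain_outer_radius, x$sas_thickness,
    if (x$aqueduct_radius > 0)
      sprintf("aqueduct half-width %g mm", x$aqueduct_radius)
    else "aqueduct closed (non-communicating)"))
  invisible(x)
}
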