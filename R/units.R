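#' Unit conversion constants
#'
#' All solvers work in SI (m, s, Pa, kg).  Clinical units -- mm for lengths,
#' ml/min for CSF flow rates, cmH2O for pressures, cm^2 for areas -- appear
#' only at the I/O boundary.  The conversions are fixed here and nowhere else.
#'
#' @format A named list with components
#'   \describe{
#'     \item{cmH2O_Pa}{pascal per centimetre of water (98.0665)}
#'     \item{mlmin_m3s}{cubic metre per second per ml/min}
#'     \item{mm_m}{metre per millimetre}
#'     \item{ml_m3}{cubic metre per millilitre}
#'     \item{cm2_m2}{square metre per square centimetre}
#'   }
#' @export
icp_units <- list(
  cmH2O_Pa  = 98.0665,
  mlmin_m3s = 1e-6 / 60,
  mm_m      = 1e-3,
  ml_m3     = 1e-6,
  cm2_m2    = 1e-4
)

#' Convert pressure between cmH2O and Pa
#'
#' @param x numeric vector of pressures.
#' @return Converted numeric vector.
#' @examples
#' cmH2O_to_Pa(1)   # 98.0665
#' Pa_to_cmH2O(98.0665)
#' @export
cmH2O_to_Pa <- function(x) x * icp_units$cmH2O_Pa

#' @rdname cmH2O_to_Pa
#' @export
Pa_to_cmH2O <- function(x) x / icp_units$cmH2O_Pa

#' Convert volumetric flow rate between ml/min and m^3/s
#'
#' @param x numeric vector of flow rates.
#' @return Converted numeric vector.
#' @export
mlmin_to_m3s <- function(x) x * icp_units$mlmin_m3s

#' @rdname mlmin_to_m3s
#' @export
m3s_to_mlmin <- function(x) x / icp_units$mlmin_m3s
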