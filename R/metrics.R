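## Derived clinical quantities from per-stage simulation outputs:
## intracranial compliance ICC = dV / dICP (ml/cmH2O) and force-deformation
## brain stiffness = d(ICP x brain surface area) / d(deformation) (N/m),
## taken between consecutive monthly stages (or versus the pre-surgery
## baseline).  Signed values are meaningful: negative ICC and stiffness
## track direction-of-change reversals across stages.

DENOM_EPS <- 1e-9

check_records <- function(records) {
  need <- c("patient_id", "stage", "icp_cmH2O", "intracranial_volume_ml",
            "brain_surface_area_cm2", "deformation_mm")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("stage records missing columns: ", paste(miss, collapse = ", "))
  if (any(records$intracranial_volume_ml <= 0) ||
      any(records$brain_surface_area_cm2 <= 0))
    stop("volumes and areas must be positive")
  if (any(!is.finite(records$icp_cmH2O))) stop("ICP values must be finite")
  records
}

sort_one_patient <- function(records) {
  if (length(unique(records$patient_id)) != 1)
    stop("records must belong to a single patient")
  if (anyDuplicated(records$stage)) stop("duplicated stages")
  records[order(records$stage), , drop = FALSE]
}

interval_pairs <- function(stages, mode) {
  if (mode == "consecutive") {
    if (any(diff(stages) != 1))
      stop("consecutive mode requires consecutive stages")
    cbind(from = seq_len(length(stages) - 1),
          to = seq_len(length(stages) - 1) + 1)
  } else {
    cbind(from = rep(1L, length(stages) - 1), to = seq_along(stages)[-1])
  }
}

#' Per-interval intracranial compliance for one patient
#'
#' \eqn{ICC_i = \Delta V_i / \Delta ICP_i} in ml/cmH2O between consecutive
#' stages (default) or each stage versus the pre-surgery baseline.
#' Intervals whose ICP change is below a degeneracy threshold are flagged
#' undefined rather than returned as huge finite values.
#'
#' @param records data.frame of one patient's stage records (columns
#'   \code{patient_id, stage, icp_cmH2O, intracranial_volume_ml,
#'   brain_surface_area_cm2, deformation_mm}).
#' @param mode \code{"consecutive"} or \code{"vs_baseline"}.
#' @return data.frame with \code{interval} labels, \code{icc_ml_cmH2O} and
#'   \code{defined}.
#' @examples
#' rec <- data.frame(patient_id = 1, stage = 0:2, icp_cmH2O = c(20, 18, 17),
#'                   intracranial_volume_ml = c(1500, 1496, 1495),
#'                   brain_surface_area_cm2 = 1800,
#'                   deformation_mm = c(1.2, 1.0, 0.9))
#' compute_icc(rec)
#' @export
compute_icc <- function(records, mode = c("consecutive", "vs_baseline")) {
  mode <- match.arg(mode)
  rec <- sort_one_patient(check_records(records))
  if (nrow(rec) < 2) stop("need at least two stages")
  pr <- interval_pairs(rec$stage, mode)
  d_icp <- rec$icp_cmH2O[pr[, "to"]] - rec$icp_cmH2O[pr[, "from"]]
  d_vol <- rec$intracranial_volume_ml[pr[, "to"]] -
    rec$intracranial_volume_ml[pr[, "from"]]
  defined <- abs(d_icp) >= DENOM_EPS
  icc <- ifelse(defined, d_vol / d_icp, NA_real_)
  data.frame(patient_id = rec$patient_id[1],
             interval = sprintf("%d-%d", rec$stage[pr[, "from"]],
                                rec$stage[pr[, "to"]]),
             icc_ml_cmH2O = icc, defined = defined)
}

#' Per-interval FSI-based brain stiffness for one patient
#'
#' \eqn{k_i = \Delta(ICP \times A) / \Delta(deformation)} converted to N/m
#' (cmH2O to Pa, cm^2 to m^2, mm to m).  The surface area is the
#' stage-specific area, so the force difference uses each stage's own
#' geometry.  Zero-deformation-change intervals are flagged undefined.
#'
#' @inheritParams compute_icc
#' @return data.frame with \code{interval}, \code{stiffness_N_m},
#'   \code{defined}.
#' @export
compute_stiffness <- function(records,
                              mode = c("consecutive", "vs_baseline")) {
  mode <- match.arg(mode)
  rec <- sort_one_patient(check_records(records))
  if (nrow(rec) < 2) stop("need at least two stages")
  pr <- interval_pairs(rec$stage, mode)
  force_N <- cmH2O_to_Pa(rec$icp_cmH2O) *
    rec$brain_surface_area_cm2 * icp_units$cm2_m2
  d_force <- force_N[pr[, "to"]] - force_N[pr[, "from"]]
  d_def <- (rec$deformation_mm[pr[, "to"]] -
            rec$deformation_mm[pr[, "from"]]) * icp_units$mm_m
  defined <- abs(d_def) >= DENOM_EPS * icp_units$mm_m
  k <- ifelse(defined, d_force / d_def, NA_real_)
  data.frame(patient_id = rec$patient_id[1],
             interval = sprintf("%d-%d", rec$stage[pr[, "from"]],
                                rec$stage[pr[, "to"]]),
             stiffness_N_m = k, defined = defined)
}

#' Flat per-interval analysis table for a cohort
#'
#' One row per patient-interval with defined ICC and stiffness; undefined
#' intervals are dropped and their count reported via the
#' \code{n_dropped} attribute (and a message).
#'
#' @param records stage records for the whole cohort.
#' @param mode interval mode, see \code{\link{compute_icc}}.
#' @return data.frame with \code{patient_id}, \code{interval},
#'   \code{icc_ml_cmH2O}, \code{stiffness_N_m}; attribute \code{n_dropped}.
#' @export
build_cohort_table <- function(records,
                               mode = c("consecutive", "vs_baseline")) {
  mode <- match.arg(mode)
  check_records(records)
  out <- lapply(split(records, records$patient_id), function(rec) {
    icc <- compute_icc(rec, mode)
    stf <- compute_stiffness(rec, mode)
    data.frame(patient_id = icc$patient_id, interval = icc$interval,
               icc_ml_cmH2O = icc$icc_ml_cmH2O,
               stiffness_N_m = stf$stiffness_N_m,
               defined = icc$defined & stf$defined)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  n_dropped <- sum(!tab$defined)
  if (n_dropped > 0)
    message(n_dropped, " undefined interval(s) dropped from cohort table")
  tab <- tab[tab$defined, c("patient_id", "interval", "icc_ml_cmH2O",
                            "stiffness_N_m")]
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Write / read a cohort analysis table as CSV (lossless round trip)
#'
#' Numeric columns are serialized with 17 significant digits so doubles
#' round-trip bit-identically; units are embedded in the column names.
#'
#' @param tab a \code{\link{build_cohort_table}} result.
#' @param path CSV path.
#' @return \code{write_cohort_table}: \code{path} invisibly;
#'   \code{read_cohort_table}: the table.
#' @export
write_cohort_table <- function(tab, path) {
  fmt <- tab
  for (nm in names(fmt))
    if (is.double(fmt[[nm]])) fmt[[nm]] <- sprintf("%.17g", fmt[[nm]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("icc_ml_cmH2O", "stiffness_N_m"))
    if (nm %in% names(tab)) tab[[nm]] <- as.double(tab[[nm]])
  tab
}
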