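## Synthetic CSF boundary data: pulsatile flow waveforms, longitudinal
## post-shunt cohorts, and noisy "monitored" ICP readings.  Everything is
## seeded and reproducible; no patient data is read anywhere.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

WAVEFORM_SITES <- c("ventricular_inlet", "spinal_outlet", "sinus_outlet")

#' Construct a CSF flow waveform over one cardiac cycle
#'
#' A waveform is the superposition of a constant component (net CSF
#' production or absorption, ml/min) and a zero-mean pulsatile component
#' sampled uniformly over one cardiac period.
#'
#' @param times seconds, strictly increasing, starting at 0, uniform over one
#'   period (the period itself is excluded: samples live on \code{[0, T)}).
#' @param rates flow rate in ml/min at each time.
#' @param constant_component cycle-mean flow rate in ml/min.
#' @param site one of \code{"ventricular_inlet"}, \code{"spinal_outlet"},
#'   \code{"sinus_outlet"}.
#' @param heart_rate beats per minute; the period is \code{60/heart_rate}.
#' @param seed optional integer recorded for provenance.
#' @return An object of class \code{flow_waveform}.
#' @export
flow_waveform <- function(times, rates, constant_component, site,
                          heart_rate, seed = NULL) {
  site <- match.arg(site, WAVEFORM_SITES)
  stopifnot(is.numeric(times), is.numeric(rates),
            length(times) == length(rates), length(times) >= 2)
  if (!all(is.finite(rates))) stop("waveform rates must be finite")
  if (times[1] != 0) stop("waveform must start at t = 0")
  dt <- diff(times)
  if (any(dt <= 0)) stop("waveform times must be strictly increasing")
  period <- 60 / heart_rate
  if (abs((times[length(times)] + dt[1]) - period) > 1e-9 * period)
    stop("waveform samples must tile one cardiac period [0, 60/heart_rate)")
  if (abs(mean(rates) - constant_component) > 1e-9)
    stop("cycle mean of rates must equal the constant component")
  structure(
    list(times = times, rates = rates,
         constant_component = constant_component, site = site,
         heart_rate = heart_rate, period = period, seed = seed),
    class = "flow_waveform")
}

#' @exportS3Method base::print
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "CSF flow waveform [%s]: %d samples over %.3f s (%g bpm)\n",
    x$site, length(x$times), x$period, x$heart_rate))
  cat(sprintf("  constant component %.3f ml/min, peak-to-peak %.3f ml/min\n",
              x$constant_component, diff(range(x$rates))))
  invisible(x)
}

#' Generate a pulsatile CSF flow waveform as a truncated Fourier series
#'
#' The waveform is
#' \deqn{q(t) = q_0 + \sum_k a_k \sin(2\pi k f t + \phi_k)}
#' sampled at \code{n_samples} uniform points on one cardiac period.  Because
#' each harmonic has an integer number of periods per cycle, the sampled cycle
#' mean equals \code{constant_component} exactly.
#'
#' When \code{harmonic_amplitudes} is \code{NULL}, three harmonics are drawn
#' from the seed with amplitudes scaled so the peak-to-peak pulsatility is a
#' few times the constant component, the shape seen in cardiac-gated CSF flow.
#'
#' @param heart_rate beats/min (> 0).
#' @param constant_component ml/min.
#' @param harmonic_amplitudes ml/min, one per harmonic (k = 1, 2, ...).
#' @param harmonic_phases radians, same length as the amplitudes.
#' @param n_samples number of samples per cycle (>= 8).
#' @param site waveform site label.
#' @param seed integer used only when amplitudes are drawn.
#' @return A \code{\link{flow_waveform}}.
#' @examples
#' wf <- generate_pulsatile_waveform(72, 0.35, n_samples = 64, seed = 1)
#' abs(mean(wf$rates) - 0.35) < 1e-12
#' @export
generate_pulsatile_waveform <- function(heart_rate, constant_component,
                                        harmonic_amplitudes = NULL,
                                        harmonic_phases = NULL,
                                        n_samples = 64,
                                        site = "ventricular_inlet",
                                        seed = NULL) {
  if (!is.numeric(heart_rate) || heart_rate <= 0)
    stop("heart_rate must be positive")
  if (!is.numeric(n_samples) || n_samples < 8)
    stop("n_samples must be at least 8")
  if (is.null(harmonic_amplitudes)) {
    harmonic_amplitudes <- with_seed(seed, {
      scale <- max(abs(constant_component), 0.1)
      # peak-to-peak ~ 2-5 x constant component
      a1 <- stats::runif(1, 1.0, 2.0) * scale
      c(a1, a1 * stats::runif(1, 0.2, 0.5), a1 * stats::runif(1, 0.05, 0.2))
    })
  }
  if (is.null(harmonic_phases)) {
    harmonic_phases <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                                 stats::runif(length(harmonic_amplitudes),
                                              0, 2 * pi))
  }
  if (length(harmonic_amplitudes) != length(harmonic_phases))
    stop("harmonic_amplitudes and harmonic_phases must have equal length")
  period <- 60 / heart_rate
  f <- 1 / period
  times <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  rates <- rep(constant_component, n_samples)
  for (k in seq_along(harmonic_amplitudes)) {
    rates <- rates + harmonic_amplitudes[k] *
      sin(2 * pi * k * f * times + harmonic_phases[k])
  }
  # remove the (tiny) floating-point residual so the cycle-mean invariant
  # holds to 1e-9 by construction
  rates <- rates - (mean(rates) - constant_component)
  flow_waveform(times, rates, constant_component, site, heart_rate, seed)
}

#' Specification of a synthetic longitudinal shunt cohort
#'
#' Describes the study design being emulated: patients with
#' non-communicating hydrocephalus imaged once before shunt surgery and then
#' monthly, whose ICP and ventricular size decline toward a post-shunt
#' plateau with oscillatory stage-to-stage variation.
#'
#' @param n_patients number of patients (default 14).
#' @param n_stages stages per patient (default 8: pre-surgery + 7 monthly).
#' @param seed integer controlling every random draw.
#' @param baseline_icp_range cmH2O range for pre-surgery ICP.
#' @param post_shunt_decline fraction of the remaining elevation removed per
#'   stage (exponential approach to the plateau).
#' @param oscillation_amplitude relative sd of multiplicative stage-to-stage
#'   oscillation.
#' @param heart_rate_range beats/min range across patients.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 14, n_stages = 8, seed = 1,
                        baseline_icp_range = c(20, 30),
                        post_shunt_decline = 0.35,
                        oscillation_amplitude = 0.08,
                        heart_rate_range = c(60, 90)) {
  stopifnot(n_patients >= 1, n_stages >= 2,
            length(baseline_icp_range) == 2,
            all(baseline_icp_range > 0),
            post_shunt_decline >= 0, post_shunt_decline < 1,
            oscillation_amplitude >= 0,
            length(heart_rate_range) == 2, all(heart_rate_range > 0))
  structure(list(n_patients = as.integer(n_patients),
                 n_stages = as.integer(n_stages),
                 seed = as.integer(seed),
                 baseline_icp_range = baseline_icp_range,
                 post_shunt_decline = post_shunt_decline,
                 oscillation_amplitude = oscillation_amplitude,
                 heart_rate_range = heart_rate_range),
            class = "cohort_spec")
}

## exponential approach toward a plateau, optionally modulated by seeded
## multiplicative oscillation; stage 0 is pre-surgery
stage_trend <- function(baseline, plateau, decline, n_stages, osc_amp) {
  s <- seq_len(n_stages) - 1
  trend <- plateau + (baseline - plateau) * (1 - decline)^s
  if (osc_amp > 0)
    trend <- trend * exp(stats::rnorm(n_stages, 0, osc_amp))
  trend
}

#' Generate per-patient, per-stage boundary waveform triplets
#'
#' For every patient and stage, an inlet (ventricular), spinal-outlet and
#' sinus-outlet waveform is produced.  The constant components are the
#' physiological production/absorption split 0.35 = 0.17 + 0.18 ml/min at
#' every stage, so mass balance of the constant components holds exactly.
#' The pulsatile amplitude carries the longitudinal signal: it declines
#' exponentially toward a post-shunt plateau, modulated by seeded
#' oscillation.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param n_samples samples per waveform cycle.
#' @param constants named constant components in ml/min
#'   (inlet, spinal, sinus); inlet must equal spinal + sinus.
#' @return An object of class \code{csf_cohort}: a list with the spec and
#'   one entry per patient-stage, each holding the three waveforms plus
#'   metadata (patient, stage, heart rate, pulsatility scale).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 2, n_stages = 3))
#' length(coh$triplets)  # 6
#' @export
generate_cohort <- function(spec = cohort_spec(), n_samples = 64,
                            constants = c(inlet = 0.35, spinal = 0.17,
                                          sinus = 0.18)) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (abs(constants[["inlet"]] -
          (constants[["spinal"]] + constants[["sinus"]])) > 1e-12)
    stop("constant components must balance: inlet = spinal + sinus")
  triplets <- with_seed(spec$seed, {
    out <- vector("list", spec$n_patients * spec$n_stages)
    i <- 0
    for (p in seq_len(spec$n_patients)) {
      hr <- stats::runif(1, spec$heart_rate_range[1], spec$heart_rate_range[2])
      base_puls <- stats::runif(1, 2, 4)     # pre-surgery peak amplitude scale
      plateau_puls <- base_puls * stats::runif(1, 0.3, 0.6)
      puls <- stage_trend(base_puls, plateau_puls, spec$post_shunt_decline,
                          spec$n_stages, spec$oscillation_amplitude)
      phases <- stats::runif(3, 0, 2 * pi)
      rel <- c(1, stats::runif(1, 0.2, 0.5), stats::runif(1, 0.05, 0.2))
      for (s in seq_len(spec$n_stages)) {
        amps <- puls[s] * rel * constants[["inlet"]]
        # outlets carry an attenuated, phase-lagged share of the pulsation
        spl_share <- constants[["spinal"]] / constants[["inlet"]]
        sin_share <- constants[["sinus"]] / constants[["inlet"]]
        i <- i + 1
        out[[i]] <- list(
          patient = p, stage = s - 1L, heart_rate = hr,
          pulsatility = puls[s],
          inlet = generate_pulsatile_waveform(hr, constants[["inlet"]],
                                              amps, phases, n_samples,
                                              site = "ventricular_inlet"),
          spinal = generate_pulsatile_waveform(hr, constants[["spinal"]],
                                               amps * spl_share * 0.8,
                                               phases + 0.4, n_samples,
                                               site = "spinal_outlet"),
          sinus = generate_pulsatile_waveform(hr, constants[["sinus"]],
                                              amps * sin_share * 0.6,
                                              phases + 0.7, n_samples,
                                              site = "sinus_outlet"))
      }
    }
    out
  })
  structure(list(spec = spec, constants = constants, triplets = triplets),
            class = "csf_cohort")
}

#' @exportS3Method base::print
print.csf_cohort <- function(x, ...) {
  cat(sprintf("Synthetic CSF cohort: %d patients x %d stages (%d triplets)\n",
              x$spec$n_patients, x$spec$n_stages, length(x$triplets)))
  invisible(x)
}

#' Generate longitudinal per-stage scalar records for a synthetic cohort
#'
#' Emulates the scalar outputs the full simulation pipeline produces per
#' patient-stage: ventricular-CSF ICP (cmH2O), intracranial volume (ml),
#' brain surface area (cm^2) and cyclic brain deformation (mm).  ICP, volume
#' and deformation decline exponentially toward post-shunt plateaus with
#' independent seeded oscillations; the area varies weakly.  Because each
#' quantity carries independent stage-to-stage noise, derived compliance and
#' stiffness series from two differently seeded cohorts are statistically
#' independent.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A data.frame with columns \code{patient_id}, \code{stage},
#'   \code{icp_cmH2O}, \code{intracranial_volume_ml},
#'   \code{brain_surface_area_cm2}, \code{deformation_mm}.
#' @export
generate_stage_records <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed + 1000L, {
    rows <- vector("list", spec$n_patients)
    for (p in seq_len(spec$n_patients)) {
      icp0 <- stats::runif(1, spec$baseline_icp_range[1],
                           spec$baseline_icp_range[2])
      icp <- stage_trend(icp0, icp0 * stats::runif(1, 0.4, 0.6),
                         spec$post_shunt_decline, spec$n_stages,
                         spec$oscillation_amplitude)
      vol0 <- stats::runif(1, 1400, 1600)
      vol <- stage_trend(vol0, vol0 * stats::runif(1, 0.93, 0.97),
                         spec$post_shunt_decline, spec$n_stages,
                         spec$oscillation_amplitude * 0.3)
      area0 <- stats::runif(1, 1500, 2000)
      area <- stage_trend(area0, area0 * stats::runif(1, 0.97, 1.0),
                          spec$post_shunt_decline, spec$n_stages,
                          spec$oscillation_amplitude * 0.2)
      def0 <- stats::runif(1, 0.5, 1.5)
      def <- stage_trend(def0, def0 * stats::runif(1, 0.3, 0.6),
                         spec$post_shunt_decline, spec$n_stages,
                         spec$oscillation_amplitude)
      rows[[p]] <- data.frame(
        patient_id = p, stage = seq_len(spec$n_stages) - 1L,
        icp_cmH2O = icp, intracranial_volume_ml = vol,
        brain_surface_area_cm2 = area, deformation_mm = def)
    }
    do.call(rbind, rows)
  })
}

#' Generate noisy monitored ICP readings
#'
#' Emulates intraoperative micro-sensor ICP monitoring for a validation
#' subset: each reading is the true value perturbed by multiplicative
#' Gaussian noise, \code{reading = true * (1 + e)}, \code{e ~ N(0,
#' noise_fraction)}.
#'
#' @param true_icp_values positive true ICP values, cmH2O.
#' @param noise_fraction relative noise sd (>= 0).
#' @param seed integer seed.
#' @param patient_ids optional ids, defaults to \code{seq_along} the values.
#' @return An object of class \code{monitored_icp}: list with
#'   \code{patient_ids}, \code{readings} (cmH2O), \code{true_values},
#'   \code{noise_fraction}, \code{seed}.
#' @export
generate_monitored_icp <- function(true_icp_values, noise_fraction = 0.02,
                                   seed = 1, patient_ids = NULL) {
  if (any(!is.finite(true_icp_values)) || any(true_icp_values <= 0))
    stop("true ICP values must be positive and finite")
  if (!is.numeric(noise_fraction) || noise_fraction < 0)
    stop("noise_fraction must be non-negative")
  if (is.null(patient_ids)) patient_ids <- seq_along(true_icp_values)
  stopifnot(length(patient_ids) == length(true_icp_values))
  eps <- with_seed(seed,
                   stats::rnorm(length(true_icp_values), 0, noise_fraction))
  structure(list(patient_ids = patient_ids,
                 readings = true_icp_values * (1 + eps),
                 true_values = true_icp_values,
                 noise_fraction = noise_fraction, seed = seed),
            class = "monitored_icp")
}

#' Write / read a flow waveform as CSV with a JSON sidecar
#'
#' The CSV holds \code{time_s, rate_ml_min}; the sidecar \code{<path>.json}
#' holds site, constant component, heart rate and seed.
#'
#' @param wf a \code{\link{flow_waveform}}.
#' @param path CSV file path.
#' @return \code{write_waveform} returns \code{path} invisibly;
#'   \code{read_waveform} returns the reconstructed waveform.
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "flow_waveform"))
  utils::write.csv(data.frame(time_s = wf$times, rate_ml_min = wf$rates),
                   path, row.names = FALSE)
  meta <- list(site = wf$site, constant_component = wf$constant_component,
               heart_rate = wf$heart_rate, seed = wf$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  flow_waveform(tab$time_s, tab$rate_ml_min,
                meta$constant_component, meta$site, meta$heart_rate,
                seed = meta$seed)
}

#' Evaluate a waveform at arbitrary times by periodic linear interpolation
#'
#' @param wf a \code{\link{flow_waveform}}.
#' @param t times in seconds (any real values; wrapped into the period).
#' @return flow rates in ml/min.
#' @export
waveform_rate_at <- function(wf, t) {
  tau <- t %% wf$period
  xs <- c(wf$times, wf$period)
  ys <- c(wf$rates, wf$rates[1])
  stats::approx(xs, ys, xout = tau, rule = 2)$y
}
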