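test_that("pulsatile waveform matches a direct Fourier-sum oracle", {
  set.seed(42)
  amps <- runif(3, 0.1, 1)
  phis <- runif(3, 0, 2 * pi)
  hr <- 75
  wf <- generate_pulsatile_waveform(hr, 0.35, amps, phis, n_samples = 48)
  ## independent term-by-term summation
  period <- 60 / hr
  oracle <- vapply(wf$times, function(t) {
    s <- 0.35
    for (k in 1:3) s <- s + amps[k] * sin(2 * pi * k * t / period + phis[k])
    s
  }, numeric(1))
  ## constructor removes the O(eps) mean drift; compare after the same shift
  oracle <- oracle - (mean(oracle) - 0.35)
  expect_lt(max(abs(wf$rates - oracle)), 1e-12)
})

test_that("waveform degenerate and mean-value properties hold", {
  wf0 <- generate_pulsatile_waveform(70, 0.35, harmonic_amplitudes = c(0, 0),
                                     harmonic_phases = c(0, 0),
                                     n_samples = 32)
  expect_true(all(wf0$rates == 0.35))
  wf1 <- generate_pulsatile_waveform(64, 0.17, harmonic_amplitudes = 2,
                                     harmonic_phases = 0, n_samples = 64)
  expect_lt(abs(mean(wf1$rates) - 0.17), 1e-12)
  expect_equal(wf1$period, 60 / 64)
  ## seeded default amplitudes give peak-to-peak a few times the constant
  wfs <- generate_pulsatile_waveform(70, 0.35, n_samples = 64, seed = 7)
  expect_gt(diff(range(wfs$rates)), 1 * 0.35)
})

test_that("waveform argument validation signals errors", {
  expect_error(generate_pulsatile_waveform(-10, 0.35), "heart_rate")
  expect_error(generate_pulsatile_waveform(70, 0.35, n_samples = 4),
               "n_samples")
  expect_error(generate_pulsatile_waveform(70, 0.35, c(1, 2), c(0)),
               "equal length")
})

test_that("cohort triplets balance mass exactly and reproduce under seed", {
  spec <- cohort_spec(n_patients = 3, n_stages = 4, seed = 11)
  coh <- generate_cohort(spec)
  expect_length(coh$triplets, 12)
  for (tr in coh$triplets) {
    expect_identical(tr$inlet$constant_component,
                     tr$spinal$constant_component +
                       tr$sinus$constant_component)
    expect_lt(abs(mean(tr$inlet$rates) - 0.35), 1e-9)
  }
  coh2 <- generate_cohort(spec)
  expect_identical(coh, coh2)
  coh3 <- generate_cohort(cohort_spec(n_patients = 3, n_stages = 4,
                                      seed = 12))
  expect_false(identical(coh$triplets[[1]]$inlet$rates,
                         coh3$triplets[[1]]$inlet$rates))
})

test_that("default cohort design is 14 patients x 8 stages", {
  coh <- generate_cohort(cohort_spec())
  expect_length(coh$triplets, 112)
  rec <- generate_stage_records(cohort_spec())
  expect_equal(nrow(rec), 112)
  expect_setequal(unique(rec$stage), 0:7)
})

test_that("zero oscillation gives strictly monotone stage trajectories", {
  spec <- cohort_spec(n_patients = 2, n_stages = 8, seed = 5,
                      oscillation_amplitude = 0)
  coh <- generate_cohort(spec)
  for (p in 1:2) {
    puls <- vapply(Filter(function(tr) tr$patient == p, coh$triplets),
                   function(tr) tr$pulsatility, numeric(1))
    expect_true(all(diff(puls) < 0))
  }
  rec <- generate_stage_records(spec)
  for (p in 1:2)
    expect_true(all(diff(rec$icp_cmH2O[rec$patient_id == p]) < 0))
})

test_that("monitored ICP noise model is multiplicative Gaussian", {
  true_vals <- seq(15, 30, length.out = 10)
  m0 <- generate_monitored_icp(true_vals, noise_fraction = 0, seed = 3)
  expect_identical(m0$readings, true_vals)
  expect_identical(m0$patient_ids, 1:10)
  m1 <- generate_monitored_icp(true_vals, 0.02, seed = 3)
  expect_identical(m1$readings,
                   generate_monitored_icp(true_vals, 0.02, seed = 3)$readings)
  expect_error(generate_monitored_icp(true_vals, -0.1), "noise_fraction")
  expect_error(generate_monitored_icp(c(10, -1)), "positive")
  ## folded-normal mean: E|eps| = noise * sqrt(2/pi), Monte-Carlo over seeds
  rel <- unlist(lapply(1:400, function(s) {
    m <- generate_monitored_icp(true_vals, 0.02, seed = s)
    abs(m$readings - true_vals) / true_vals
  }))
  expect_lt(abs(mean(rel) - 0.02 * sqrt(2 / pi)), 0.0005)
})

test_that("waveforms round-trip through CSV + JSON sidecar", {
  wf <- generate_pulsatile_waveform(70, 0.18, n_samples = 32, seed = 2,
                                    site = "sinus_outlet")
  path <- tempfile(fileext = ".csv")
  write_waveform(wf, path)
  wf2 <- read_waveform(path)
  expect_equal(wf2$rates, wf$rates, tolerance = 1e-12)
  expect_identical(wf2$site, "sinus_outlet")
  expect_equal(wf2$constant_component, 0.18)
  ## periodic interpolation wraps
  expect_equal(waveform_rate_at(wf, wf$period + wf$times[5]),
               wf$rates[5], tolerance = 1e-9)
})
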