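test_that("simulate_emg honors amplitude scale, determinism and fs contract", {
  expect_error(simulate_emg(fs = 400), "500 Hz")

  z <- simulate_emg(breath_pattern(peak_rms_uv = 0), 10, 1000, seed = 1)
  expect_true(all(z$signal$samples == 0))

  a <- simulate_emg(seed = 7, duration_s = 10)
  b <- simulate_emg(seed = 7, duration_s = 10)
  expect_identical(a$signal$samples, b$signal$samples)

  # in-breath peak 250 ms RMS concentrates near the requested 5 uV
  em <- simulate_emg(breath_pattern(respiratory_rate = 15, duty_cycle = 0.4,
                                    peak_rms_uv = 5), 88, 1000, seed = 3)
  env <- moving_rms(em$signal)
  peaks <- vapply(seq_len(nrow(em$truth$breaths)), function(i) {
    br <- em$truth$breaths[i, ]
    t <- envelope_times(env)
    max(env$samples[t >= br$onset_s & t <= br$offset_s])
  }, numeric(1L))
  expect_gte(length(peaks), 20)
  expect_equal(mean(peaks), 5, tolerance = 0.15)
})

test_that("clean EMG spectral support lies in 25-250 Hz", {
  em <- simulate_emg(breath_pattern(duty_cycle = 0.9), 30, 1000, seed = 5)
  x <- em$signal$samples
  pw <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) / length(x) * 1000
  f <- pmin(f, 1000 - f)
  inband <- sum(pw[f >= 25 & f <= 250]) / sum(pw)
  expect_gte(inband, 0.95)
})

test_that("ground-truth landmarks are self-consistent", {
  em <- simulate_emg(seed = 11, duration_s = 40)
  act <- em$truth$activation
  t <- signal_times(act)
  for (i in seq_len(nrow(em$truth$breaths))) {
    br <- em$truth$breaths[i, ]
    expect_lt(br$onset_s, br$peak_s)
    expect_lte(br$peak_s, br$offset_s)
    seg <- act$samples[t >= br$onset_s & t <= br$offset_s]
    a_pk <- act$samples[which.min(abs(t - br$peak_s))]
    expect_gte(a_pk, 0.99 * max(seg))
  }
  expect_true(all(act$samples >= 0))
})

test_that("simulate_ecg builds exact R apexes and enforces rate limits", {
  e <- simulate_ecg(60, 100, 1000, 30, hr_jitter = 0)
  expect_length(e$rpeak_times, 30)
  expect_equal(diff(e$rpeak_times), rep(1, 29))
  expect_error(simulate_ecg(20, 100, 1000, 10), "30-220")

  flat <- simulate_ecg(60, 0, 1000, 10, hr_jitter = 0)
  expect_true(all(flat$signal$samples == 0))
  expect_length(flat$rpeak_times, 10)   # template times still reported

  # ECG at the default scene amplitudes dominates EMG power by >= 10x
  emg <- simulate_emg(seed = 2, duration_s = 30)
  ecg <- simulate_ecg(80, 100, 1000, 30, seed = 2)
  expect_gte(mean(ecg$signal$samples^2) / mean(emg$signal$samples^2), 10)
})

test_that("mix is additive with the stated components", {
  em <- simulate_emg(seed = 4, duration_s = 20)
  silent <- contamination_spec(ecg_amplitude_uv = 0, wander_amplitude_uv = 0,
                               mains_amplitude_uv = 0, white_noise_sd_uv = 0)
  m0 <- mix(em, silent, seed = 1)
  expect_identical(m0$signal$samples, em$signal$samples)

  m <- mix(em, contamination_spec(), seed = 9)
  comp <- m$truth$components
  v_sum <- stats::var(em$signal$samples) + stats::var(comp$ecg) +
    stats::var(comp$wander) + stats::var(comp$mains) + stats::var(comp$white)
  expect_equal(stats::var(m$signal$samples) / v_sum, 1, tolerance = 0.05)

  # dominant mains line shows up at the programmed frequency
  weak <- simulate_emg(breath_pattern(peak_rms_uv = 1), 20, 1000, seed = 4)
  mm <- mix(weak, contamination_spec(ecg_amplitude_uv = 0,
                                     wander_amplitude_uv = 0,
                                     mains_amplitude_uv = 10,
                                     white_noise_sd_uv = 0.1), seed = 5)
  pw <- Mod(stats::fft(mm$signal$samples))^2
  n <- length(pw)
  f <- pmin((0:(n - 1)) / n * 1000, 1000 - (0:(n - 1)) / n * 1000)
  f_peak <- f[which.max(pw[f > 0.5])]     # skip DC
  expect_lt(abs(f_peak - 50), 1)
  expect_error(contamination_spec(mains_freq_hz = 70), "50 or 60")
})

test_that("simulate_ventilator programs delays and occlusions correctly", {
  em <- simulate_emg(seed = 6, duration_s = 30)
  tb <- em$truth$breaths
  paw0 <- simulate_ventilator(tb, 1000, trigger_delay_ms = 0,
                              cycle_delay_ms = 0,
                              activation = em$truth$activation)
  pres <- detect_pressurization(paw0, threshold_cmh2o = 0.5)
  m <- match_events(pres$start_s, tb$onset_s, tol_s = 0.02)
  expect_gte(m$sensitivity, 0.9)

  # occlusion: nadir = -k_true * activation peak
  paw <- simulate_ventilator(tb, 1000, occlusion_breath_indices = 2L,
                             k_true = 2, activation = em$truth$activation)
  t <- signal_times(paw)
  w <- t >= tb$onset_s[2] & t <= tb$offset_s[2]
  a_pk <- max(em$truth$activation$samples[w])
  expect_equal(min(paw$samples[w]), -2 * a_pk, tolerance = 0.02 * 2 * a_pk)
  expect_error(simulate_ventilator(tb, 1000, occlusion_breath_indices = 99L,
                                   k_true = 2,
                                   activation = em$truth$activation),
               "out of range")
  expect_error(simulate_ventilator(tb, 1000, occlusion_breath_indices = 1L,
                                   k_true = -1,
                                   activation = em$truth$activation),
               "k_true")
})

test_that("generators are deterministic under seed", {
  s1 <- simulate_scene(duration_s = 8, seed = 123)
  s2 <- simulate_scene(duration_s = 8, seed = 123)
  expect_identical(s1$recording[["emg"]]$samples, s2$recording[["emg"]]$samples)
  expect_identical(s1$truth$rpeak_times, s2$truth$rpeak_times)
  f1 <- simulate_fatigue_emg(duration_s = 12, seed = 5)
  f2 <- simulate_fatigue_emg(duration_s = 12, seed = 5)
  expect_identical(f1$signal$samples, f2$signal$samples)
})
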