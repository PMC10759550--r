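test_that("highpass removes DC and low frequencies, preserves the pass band", {
  const <- signal(rep(5, 2000), 1000)
  expect_lt(max(abs(highpass(const, 20)$samples)), 0.05)

  s100 <- signal(sin(2 * pi * 100 * (0:4999) / 1000), 1000)
  expect_equal(rms(highpass(s100, 20)$samples) / rms(s100$samples), 1,
               tolerance = 0.01)

  # data-check mode: cutoffs up to 200 Hz allowed; 1 Hz content crushed
  s1 <- signal(sin(2 * pi * 1 * (0:9999) / 1000), 1000)
  att_db <- 20 * log10(rms(highpass(s1, 200)$samples) / rms(s1$samples))
  expect_lt(att_db, -60)
  expect_error(highpass(s100, 600), "fs/2")
})

test_that("notch_mains suppresses the line and little else", {
  line <- signal(sin(2 * pi * 50 * (0:29999) / 1000), 1000)
  expect_lt(rms(notch_mains(line, 50)$samples) / rms(line$samples), 0.03)

  s100 <- signal(sin(2 * pi * 100 * (0:4999) / 1000), 1000)
  expect_equal(rms(notch_mains(s100, 50)$samples) / rms(s100$samples), 1,
               tolerance = 0.02)
  s60 <- signal(sin(2 * pi * 60 * (0:9999) / 1000), 1000)
  expect_equal(rms(notch_mains(s60, 50)$samples) / rms(s60$samples), 1,
               tolerance = 0.05)
  expect_error(notch_mains(s100, 70), "50 or 60")
})

test_that("filters are zero-phase: a band-limited burst does not shift", {
  t <- (0:9999) / 1000
  burst <- exp(-((t - 5)^2) / (2 * 0.2^2)) * sin(2 * pi * 80 * t)
  s <- signal(burst, 1000)
  for (filt in list(function(x) highpass(x, 20),
                    function(x) notch_mains(x, 50),
                    function(x) wavelet_denoise(x, wavelet_plan("db2", 5, Inf)))) {
    y <- filt(s)$samples
    cc <- stats::ccf(y, burst, lag.max = 20, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("detect_r_peaks meets sensitivity, precision and timing targets", {
  e <- simulate_ecg(60, 100, 1000, 30, hr_jitter = 0)
  rp <- detect_r_peaks(e$signal)
  expect_true(abs(length(rp$times_s) - 30) <= 1)
  m <- match_events(rp$times_s, e$rpeak_times, tol_s = 0.01)
  expect_gte(m$sensitivity, 0.97)

  all_errs <- c()
  for (hr in c(50, 80, 120)) {
    sc <- simulate_scene(duration_s = 60, seed = 5 + hr,
                         contamination = contamination_spec(heart_rate_bpm = hr))
    rp <- detect_r_peaks(sc$recording[["emg"]])
    m <- match_events(rp$times_s, sc$truth$rpeak_times, tol_s = 0.05)
    expect_gte(m$sensitivity, 0.99)
    expect_gte(m$precision, 0.99)
    all_errs <- c(all_errs, m$errors)
  }
  expect_lt(stats::median(all_errs), 0.010)

  expect_warning(rp0 <- detect_r_peaks(signal(rep(0, 6000), 1000)), "flat")
  expect_length(rp0$times_s, 0)
  expect_error(detect_r_peaks(signal(rnorm(1000), 1000)), "5 s")
})

test_that("gate_ecg is local, merges gates and fills as requested", {
  sc <- default_scene()
  raw <- sc$recording[["emg"]]
  hp <- notch_mains(highpass(raw, 20), 50)
  rp <- detect_r_peaks(hp)

  g <- gate_ecg(hp, rp, window_ms = 150, fill = "zeros", highpassed = TRUE)
  ingate <- gate_mask_samples(g$mask, hp)
  expect_identical(g$signal$samples[!ingate], hp$samples[!ingate])
  expect_true(all(g$signal$samples[ingate] == 0))
  expect_lt(rms(g$signal$samples), rms(hp$samples))

  # gated fraction: at 80 bpm and 150 ms windows ~0.2 of the time
  expect_equal(gate_fraction(g$mask, duration(hp)),
               length(rp$times_s) * 0.150 / duration(hp), tolerance = 0.02)

  for (fill in c("hold", "linear", "median")) {
    gf <- gate_ecg(hp, rp, fill = fill, highpassed = TRUE)
    expect_identical(gf$signal$samples[!ingate], hp$samples[!ingate])
    # filled values stay within the plausible EMG range, not ECG range
    expect_lt(max(abs(gf$signal$samples[ingate])), max(abs(hp$samples[ingate])))
  }

  # tachycardia contract: window must be below the median RR
  fast <- simulate_ecg(200, 100, 1000, 30)
  hp_fast <- highpass(fast$signal, 20)
  expect_error(gate_ecg(hp_fast, fast$rpeak_times, window_ms = 400,
                        highpassed = TRUE), "tachycardia")
})

test_that("choose_wavelet_levels follows the doubling rule", {
  expect_identical(choose_wavelet_levels(1000), 5L)
  expect_identical(choose_wavelet_levels(500), 4L)
  expect_identical(choose_wavelet_levels(2000), 6L)
  expect_identical(choose_wavelet_levels(1400), 5L)
  expect_identical(choose_wavelet_levels(4000), 7L)
  expect_error(choose_wavelet_levels(200), ">= 250")
})

test_that("wavelet_denoise reconstructs perfectly at infinite threshold", {
  set.seed(3)
  x <- rnorm(4096)
  s <- signal(x, 1000)
  for (wv in c("db2", "db4")) {
    y <- wavelet_denoise(s, wavelet_plan(wv, 5, Inf))
    res <- x - y$samples                # only the approximation band remains
    pw <- Mod(stats::fft(res))^2
    f <- pmin((0:4095) / 4096 * 1000, 1000 - (0:4095) / 4096 * 1000)
    expect_gt(sum(pw[f < 32]) / sum(pw), 0.85)
  }
  expect_error(wavelet_denoise(signal(rnorm(64), 1000), wavelet_plan("db4", 5)),
               "fewer levels")
})

test_that("wavelet_denoise preserves pure EMG and suppresses ECG", {
  em <- simulate_emg(seed = 7, duration_s = 30)
  dn <- wavelet_denoise(em$signal, wavelet_plan("db2", 5, 4.5))
  expect_equal(rms(dn$samples) / rms(em$signal$samples), 1, tolerance = 0.10)
  expect_gte(stats::cor(dn$samples, em$signal$samples), 0.9)

  # idempotence in the no-ECG regime
  dn2 <- wavelet_denoise(dn, wavelet_plan("db2", 5, 4.5))
  expect_equal(rms(dn2$samples) / rms(dn$samples), 1, tolerance = 0.05)

  sc <- default_scene()
  raw <- sc$recording[["emg"]]
  pre <- notch_mains(highpass(raw, 0.5), 50)
  dns <- wavelet_denoise(pre, wavelet_plan("db2", 5, 4.5))
  t <- signal_times(raw)
  near <- near_events(t, sc$truth$rpeak_times, 0.075)
  expect_gte(1 - rms(dns$samples[near]) / rms(raw$samples[near]), 0.70)
  act <- sc$truth$activation$samples
  inb <- act > 0.8 * max(act) & !near
  expect_equal(rms(dns$samples[inb]) / rms(sc$truth$clean_emg$samples[inb]), 1,
               tolerance = 0.20)
})
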