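#' Breath pattern specification for the synthetic generator
#'
#' Describes the respiratory activation pattern to simulate.  Respiratory
#' sEMG amplitudes typically range between 1 and 10 microvolts; the default
#' in-breath peak of 5 uV sits in the middle of that range.
#'
#' @param respiratory_rate breaths per minute (> 0).
#' @param duty_cycle inspiratory fraction of the respiratory cycle, in (0,1).
#' @param activation_shape `"raised_cosine"` (smooth rise over the
#'   inspiratory time, cosine decay over 25% of the cycle) or `"trapezoid"`
#'   (linear rise over 30% of the inspiratory time, plateau, linear decay
#'   over 25% of the cycle).
#' @param peak_rms_uv target in-breath 250 ms RMS amplitude in uV (>= 0).
#' @param breath_jitter coefficient of variation of the cycle duration.
#' @return a `BreathPattern` list.
#' @export
breath_pattern <- function(respiratory_rate = 15, duty_cycle = 0.4,
                           activation_shape = c("raised_cosine", "trapezoid"),
                           peak_rms_uv = 5, breath_jitter = 0) {
  activation_shape <- match.arg(activation_shape)
  if (respiratory_rate <= 0) stop("`respiratory_rate` must be > 0")
  if (duty_cycle <= 0 || duty_cycle >= 1) stop("`duty_cycle` must be in (0, 1)")
  if (peak_rms_uv < 0) stop("`peak_rms_uv` must be >= 0")
  if (breath_jitter < 0) stop("`breath_jitter` must be >= 0")
  structure(list(respiratory_rate = respiratory_rate, duty_cycle = duty_cycle,
                 activation_shape = activation_shape, peak_rms_uv = peak_rms_uv,
                 breath_jitter = breath_jitter),
            class = "BreathPattern")
}

#' Contamination specification for the synthetic generator
#'
#' Parameters of the noise sources superposed on the clean EMG: PQRST
#' cardiac artifact (which in respiratory sEMG commonly exceeds the EMG
#' power by orders of magnitude), sinusoidal baseline wander, mains
#' interference and broadband white noise.  The defaults reproduce that
#' strong-ECG regime: a 100 uV R-wave over 5 uV EMG.
#'
#' @param ecg_amplitude_uv R-wave peak amplitude in uV.
#' @param heart_rate_bpm heart rate in beats per minute.
#' @param hr_jitter coefficient of variation of the RR interval.
#' @param wander_amplitude_uv baseline wander amplitude in uV.
#' @param wander_freq_hz baseline wander frequency (<= 0.5 Hz).
#' @param mains_freq_hz mains frequency, 50 or 60 Hz.
#' @param mains_amplitude_uv mains interference amplitude in uV.
#' @param white_noise_sd_uv standard deviation of additive white noise (uV).
#' @return a `ContaminationSpec` list.
#' @export
contamination_spec <- function(ecg_amplitude_uv = 100, heart_rate_bpm = 80,
                               hr_jitter = 0.03, wander_amplitude_uv = 20,
                               wander_freq_hz = 0.3, mains_freq_hz = 50,
                               mains_amplitude_uv = 5, white_noise_sd_uv = 0.5) {
  if (!mains_freq_hz %in% c(50, 60)) stop("`mains_freq_hz` must be 50 or 60")
  if (wander_freq_hz > 0.5) stop("`wander_freq_hz` must be <= 0.5 Hz")
  amps <- c(ecg_amplitude_uv, wander_amplitude_uv, mains_amplitude_uv,
            white_noise_sd_uv)
  if (any(amps < 0)) stop("contamination amplitudes must be >= 0")
  structure(list(ecg_amplitude_uv = ecg_amplitude_uv,
                 heart_rate_bpm = heart_rate_bpm, hr_jitter = hr_jitter,
                 wander_amplitude_uv = wander_amplitude_uv,
                 wander_freq_hz = wander_freq_hz, mains_freq_hz = mains_freq_hz,
                 mains_amplitude_uv = mains_amplitude_uv,
                 white_noise_sd_uv = white_noise_sd_uv),
            class = "ContaminationSpec")
}

# Per-breath activation profile value at in-cycle time tau (seconds).
# ti = inspiratory time, td = decay time.  Returns values in [0, 1].
.activation_profile <- function(tau, ti, td, shape) {
  a <- numeric(length(tau))
  if (shape == "raised_cosine") {
    rise <- tau >= 0 & tau <= ti
    a[rise] <- 0.5 * (1 - cos(pi * tau[rise] / ti))
    dec <- tau > ti & tau <= ti + td
    a[dec] <- 0.5 * (1 + cos(pi * (tau[dec] - ti) / td))
  } else {                               # trapezoid
    tr <- 0.3 * ti
    rise <- tau >= 0 & tau < tr
    a[rise] <- tau[rise] / tr
    plat <- tau >= tr & tau <= ti
    a[plat] <- 1
    dec <- tau > ti & tau <= ti + td
    a[dec] <- 1 - (tau[dec] - ti) / td
  }
  a
}

# Breath landmark times for a pattern over a given duration.
# Returns a data.frame(onset_s, peak_s, offset_s) where offset_s is the end
# of activation (return to zero).
.breath_schedule <- function(pattern, duration_s) {
  t_cycle <- 60 / pattern$respiratory_rate
  onsets <- numeric(0)
  t <- 0
  while (t < duration_s) {
    onsets <- c(onsets, t)
    dt <- t_cycle
    if (pattern$breath_jitter > 0)
      dt <- t_cycle * max(0.3, 1 + pattern$breath_jitter * stats::rnorm(1L))
    t <- t + dt
  }
  ti <- pattern$duty_cycle * t_cycle
  td <- 0.25 * t_cycle
  peak_tau <- if (pattern$activation_shape == "raised_cosine") ti else 0.3 * ti
  data.frame(onset_s = onsets, peak_s = onsets + peak_tau,
             offset_s = onsets + ti + td)
}

#' Simulate clean respiratory sEMG with ground truth
#'
#' The clean EMG model is zero-mean Gaussian noise band-limited to
#' 25-250 Hz (where the respiratory sEMG spectrum mainly lives) and
#' amplitude-modulated sample-wise by a smooth per-breath activation
#' profile.  The activation is scaled so the in-breath 250 ms RMS matches
#' `pattern$peak_rms_uv`.
#'
#' @param pattern a [breath_pattern()].
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz (>= 500; respiratory sEMG should be
#'   acquired at 500 Hz or more).
#' @param seed integer seed; identical seeds give identical output.
#' @return a list with `signal` (the clean EMG `Signal`), and `truth`: a
#'   `GroundTruth` list with `clean_emg`, `activation` (uV RMS scale),
#'   `breaths` (data.frame of onset/peak/offset times), `rpeak_times`
#'   (empty), `noise_floor_sd_uv` (0) and `k_true` (NA).
#' @export
simulate_emg <- function(pattern = breath_pattern(), duration_s = 60,
                         fs = 1000, seed = NULL) {
  stopifnot(inherits(pattern, "BreathPattern"))
  if (fs < 500)
    stop("fs must be >= 500 Hz: respiratory sEMG requires a sampling rate ",
         "of at least 500 Hz (ideally 1000 Hz)")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  breaths <- .breath_schedule(pattern, duration_s)
  t_cycle <- 60 / pattern$respiratory_rate
  ti <- pattern$duty_cycle * t_cycle
  td <- 0.25 * t_cycle
  act <- numeric(n)
  for (b in seq_len(nrow(breaths))) {
    on <- breaths$onset_s[b]
    idx <- which(t >= on & t <= on + ti + td)
    if (length(idx))
      act[idx] <- pmax(act[idx],
                       .activation_profile(t[idx] - on, ti, td,
                                           pattern$activation_shape))
  }
  act <- act * pattern$peak_rms_uv
  carrier <- stats::rnorm(n)
  carrier <- .zp_bandpass(carrier, fs, 25, 250, order = 4)
  rms <- sqrt(mean(carrier^2))
  if (rms > 0) carrier <- carrier / rms
  x <- carrier * act
  sig <- signal(x, fs, label = "emg", kind = "emg")
  truth <- list(clean_emg = sig,
                activation = signal(act, fs, label = "activation", kind = "other"),
                rpeak_times = numeric(0),
                breaths = breaths[breaths$offset_s <= duration_s + t_cycle, ],
                k_true = NA_real_, noise_floor_sd_uv = 0)
  list(signal = sig, truth = truth)
}

#' Simulate respiratory sEMG with progressive spectral compression
#'
#' Emulates developing muscle fatigue: each successive breath's EMG carrier
#' is band-limited to a band interpolated linearly (per breath) from
#' `band_start` to `band_end`, so the power spectrum compresses toward
#' lower frequencies over the recording while the activation pattern is
#' unchanged.  With the defaults the band narrows from the normal
#' 25-250 Hz support down to 20-180 Hz.
#'
#' @inheritParams simulate_emg
#' @param band_start,band_end numeric `c(low_hz, high_hz)` band edges of
#'   the first and last breath.
#' @return as [simulate_emg()]; `truth$breath_bands` holds the per-breath
#'   band edges.
#' @export
simulate_fatigue_emg <- function(pattern = breath_pattern(), duration_s = 80,
                                 fs = 1000, seed = NULL,
                                 band_start = c(25, 250),
                                 band_end = c(20, 180)) {
  stopifnot(inherits(pattern, "BreathPattern"))
  if (fs < 500)
    stop("fs must be >= 500 Hz: respiratory sEMG requires a sampling rate ",
         "of at least 500 Hz (ideally 1000 Hz)")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  breaths <- .breath_schedule(pattern, duration_s)
  nb <- nrow(breaths)
  t_cycle <- 60 / pattern$respiratory_rate
  ti <- pattern$duty_cycle * t_cycle
  td <- 0.25 * t_cycle
  x <- numeric(n)
  act <- numeric(n)
  bands <- matrix(NA_real_, nb, 2L)
  for (b in seq_len(nb)) {
    frac <- if (nb > 1L) (b - 1L) / (nb - 1L) else 0
    bands[b, ] <- band_start + frac * (band_end - band_start)
    on <- breaths$onset_s[b]
    idx <- which(t >= on & t <= on + ti + td)
    if (!length(idx)) next
    a <- .activation_profile(t[idx] - on, ti, td, pattern$activation_shape) *
      pattern$peak_rms_uv
    act[idx] <- pmax(act[idx], a)
    carrier <- stats::rnorm(length(idx))
    carrier <- .zp_bandpass(carrier, fs, bands[b, 1L], bands[b, 2L], order = 4)
    r <- sqrt(mean(carrier^2))
    if (r > 0) carrier <- carrier / r
    x[idx] <- x[idx] + carrier * a
  }
  sig <- signal(x, fs, label = "emg", kind = "emg")
  truth <- list(clean_emg = sig,
                activation = signal(act, fs, label = "activation", kind = "other"),
                rpeak_times = numeric(0),
                breaths = breaths,
                breath_bands = bands,
                k_true = NA_real_, noise_floor_sd_uv = 0)
  list(signal = sig, truth = truth)
}

# PQRST Gaussian template: latency (s), FWHM width (s), relative amplitude.
.ecg_template <- data.frame(
  wave = c("P", "Q", "R", "S", "T"),
  lat  = c(-0.180, -0.025, 0.000, 0.025, 0.250),
  fwhm = c( 0.040,  0.025, 0.025, 0.025, 0.070),
  amp  = c( 0.120, -0.150, 1.000, -0.250, 0.300)
)

#' Simulate a PQRST cardiac artifact train
#'
#' Each beat is a sum of Gaussian-shaped P, Q, R, S and T deflections with
#' fixed template widths, latencies and amplitude ratios; only the R-wave
#' amplitude, heart rate and rate jitter are user-facing.  The returned
#' R-peak times are the exact template R apexes, for use as a detector
#' oracle.
#'
#' @param heart_rate_bpm heart rate, 30-220 bpm.
#' @param amplitude_uv R-wave peak amplitude in uV.
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param seed integer seed.
#' @param hr_jitter coefficient of variation of the RR interval.
#' @return list with `signal` (`Signal`) and `rpeak_times` (seconds).
#' @export
simulate_ecg <- function(heart_rate_bpm = 80, amplitude_uv = 100, fs = 1000,
                         duration_s = 60, seed = NULL, hr_jitter = 0) {
  if (heart_rate_bpm < 30 || heart_rate_bpm > 220)
    stop("`heart_rate_bpm` must be within 30-220 bpm")
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  rr <- 60 / heart_rate_bpm
  beats <- numeric(0)
  tb <- rr / 2                       # first apex away from the edge
  while (tb < duration_s) {
    beats <- c(beats, tb)
    dt <- rr
    if (hr_jitter > 0) dt <- rr * max(0.4, 1 + hr_jitter * stats::rnorm(1L))
    tb <- tb + dt
  }
  x <- numeric(n)
  half_span <- 0.45
  for (tb in beats) {
    idx <- which(t >= tb - half_span & t <= tb + half_span)
    if (!length(idx)) next
    tt <- t[idx] - tb
    for (w in seq_len(nrow(.ecg_template))) {
      sd_w <- .ecg_template$fwhm[w] / (2 * sqrt(2 * log(2)))
      x[idx] <- x[idx] + .ecg_template$amp[w] *
        exp(-((tt - .ecg_template$lat[w])^2) / (2 * sd_w^2))
    }
  }
  x <- x * amplitude_uv
  list(signal = signal(x, fs, label = "ecg", kind = "other"),
       rpeak_times = beats)
}

#' Mix clean EMG with cardiac and technical contamination
#'
#' Builds `clean EMG + ECG + sinusoidal baseline wander + mains sinusoid +
#' white noise`, the additive contamination model under which raw
#' respiratory sEMG is recorded, and returns the contaminated signal along
#' with a fully updated ground truth (components included).
#'
#' @param emg_sim result of [simulate_emg()] (or a list with `signal` and
#'   `truth`).
#' @param contamination a [contamination_spec()].
#' @param seed integer seed for the contamination noise sources.
#' @return list with `signal` (contaminated `Signal`) and `truth`
#'   (`GroundTruth` with `rpeak_times`, `noise_floor_sd_uv` and a
#'   `components` list of the individual contamination signals).
#' @export
mix <- function(emg_sim, contamination = contamination_spec(), seed = NULL) {
  stopifnot(inherits(contamination, "ContaminationSpec"))
  sig <- emg_sim$signal
  truth <- emg_sim$truth
  stopifnot(inherits(sig, "Signal"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(sig$samples)
  fs <- sig$fs
  t <- signal_times(sig)
  dur <- duration(sig)

  ecg <- numeric(n); rpeaks <- numeric(0)
  if (contamination$ecg_amplitude_uv > 0) {
    e <- simulate_ecg(contamination$heart_rate_bpm,
                      contamination$ecg_amplitude_uv, fs, dur, seed = NULL,
                      hr_jitter = contamination$hr_jitter)
    ecg <- e$signal$samples
    rpeaks <- e$rpeak_times
  }
  wander_phase <- stats::runif(1L, 0, 2 * pi)
  wander <- contamination$wander_amplitude_uv *
    sin(2 * pi * contamination$wander_freq_hz * t + wander_phase)
  if (contamination$wander_amplitude_uv == 0) wander <- numeric(n)
  mains <- contamination$mains_amplitude_uv *
    sin(2 * pi * contamination$mains_freq_hz * t)
  white <- if (contamination$white_noise_sd_uv > 0)
    stats::rnorm(n, sd = contamination$white_noise_sd_uv) else numeric(n)

  mixed <- sig$samples + ecg + wander + mains + white
  out <- signal(mixed, fs, label = sig$label, kind = "emg", t0 = sig$t0)
  truth$rpeak_times <- rpeaks
  truth$noise_floor_sd_uv <- contamination$white_noise_sd_uv
  truth$components <- list(ecg = ecg, wander = wander, mains = mains,
                           white = white)
  truth$contamination <- contamination
  list(signal = out, truth = truth)
}

#' Simulate a synchronized ventilator airway-pressure channel
#'
#' For ordinary breaths a pressure-support-like square-ish pressurization
#' ramp starts `trigger_delay_ms` after the EMG onset and ends
#' `cycle_delay_ms` after the EMG offset.  Breaths listed in
#' `occlusion_breath_indices` emulate an end-expiratory occlusion: no
#' pressurization, and the airway pressure deflects by
#' `-k_true * activation`, which is how the neuromechanical efficiency is
#' measured in practice.
#'
#' @param breaths data.frame of breath landmarks (`onset_s`, `peak_s`,
#'   `offset_s`), e.g. from [simulate_emg()] ground truth.
#' @param fs sampling rate in Hz.
#' @param trigger_delay_ms ventilator trigger delay in ms.
#' @param cycle_delay_ms cycling-off delay in ms.
#' @param occlusion_breath_indices integer indices of occluded breaths.
#' @param k_true true neuromechanical conversion factor (cmH2O/uV);
#'   required (> 0) when occlusions are requested.
#' @param activation the ground-truth activation `Signal` (uV); required
#'   when occlusions are requested.
#' @param duration_s output duration; defaults to the activation duration
#'   or the last breath offset plus one second.
#' @param support_cmh2o pressure-support level of ordinary breaths (cmH2O).
#' @param ramp_ms rise/fall time of the pressurization ramp (ms).
#' @return a pressure `Signal` (cmH2O).
#' @export
simulate_ventilator <- function(breaths, fs, trigger_delay_ms = 100,
                                cycle_delay_ms = 0,
                                occlusion_breath_indices = integer(0),
                                k_true = NA_real_, activation = NULL,
                                duration_s = NULL, support_cmh2o = 10,
                                ramp_ms = 100) {
  if (!all(is.finite(c(trigger_delay_ms, cycle_delay_ms))))
    stop("delays must be finite")
  nb <- nrow(breaths)
  if (length(occlusion_breath_indices)) {
    if (any(occlusion_breath_indices < 1L | occlusion_breath_indices > nb))
      stop("occlusion breath index out of range (1..", nb, ")")
    if (!is.finite(k_true) || k_true <= 0)
      stop("`k_true` must be > 0 when occlusions are requested")
    if (is.null(activation))
      stop("`activation` signal is required when occlusions are requested")
  }
  if (is.null(duration_s)) {
    duration_s <- if (!is.null(activation)) duration(activation)
                  else max(breaths$offset_s) + 1
  }
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  paw <- numeric(n)
  ramp_s <- ramp_ms / 1000
  for (b in seq_len(nb)) {
    if (b %in% occlusion_breath_indices) {
      idx <- which(t >= breaths$onset_s[b] & t <= breaths$offset_s[b])
      idx <- idx[idx <= length(activation$samples)]
      paw[idx] <- paw[idx] - k_true * activation$samples[idx]
    } else {
      p_on <- breaths$onset_s[b] + trigger_delay_ms / 1000
      p_off <- breaths$offset_s[b] + cycle_delay_ms / 1000
      if (p_off <= p_on) next
      idx <- which(t >= p_on & t <= p_off + ramp_s)
      if (!length(idx)) next
      tt <- t[idx]
      up <- pmin(1, (tt - p_on) / ramp_s)
      down <- pmin(1, pmax(0, (p_off + ramp_s - tt) / ramp_s))
      paw[idx] <- paw[idx] + support_cmh2o * pmin(up, down)
    }
  }
  signal(paw, fs, label = "paw", kind = "pressure")
}

#' Generate the default synthetic test scene
#'
#' One call producing the package's reference condition: 1000 Hz sampling,
#' 15 breaths/min at duty cycle 0.4, 5 uV EMG, 100 uV R-wave ECG at 80 bpm,
#' 20 uV baseline wander at 0.3 Hz, 5 uV mains at 50 Hz and 0.5 uV white
#' noise -- the strong-cardiac-interference regime that motivates dedicated
#' ECG removal.
#'
#' @param duration_s scene duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param pattern a [breath_pattern()].
#' @param contamination a [contamination_spec()].
#' @param ventilator add a synchronized ventilator pressure channel?
#' @param trigger_delay_ms,cycle_delay_ms ventilator timing (ms).
#' @param occlusion_breath_indices breaths simulated as end-expiratory
#'   occlusions.
#' @param k_true true neuromechanical conversion factor (cmH2O/uV).
#' @return list with `recording` (`Recording`: channel `emg`, plus `paw`
#'   when `ventilator = TRUE`) and `truth` (`GroundTruth`).
#' @export
simulate_scene <- function(duration_s = 60, fs = 1000, seed = 1,
                           pattern = breath_pattern(),
                           contamination = contamination_spec(),
                           ventilator = FALSE, trigger_delay_ms = 100,
                           cycle_delay_ms = 0,
                           occlusion_breath_indices = integer(0),
                           k_true = 2) {
  clean <- simulate_emg(pattern, duration_s, fs, seed = seed)
  mixed <- mix(clean, contamination, seed = seed + 1000L)
  rec_sigs <- list(mixed$signal)
  truth <- mixed$truth
  if (ventilator || length(occlusion_breath_indices)) {
    paw <- simulate_ventilator(truth$breaths, fs, trigger_delay_ms,
                               cycle_delay_ms, occlusion_breath_indices,
                               k_true = k_true, activation = truth$activation,
                               duration_s = duration_s)
    rec_sigs <- c(rec_sigs, list(paw))
    truth$k_true <- k_true
    truth$trigger_delay_ms <- trigger_delay_ms
    truth$cycle_delay_ms <- cycle_delay_ms
    truth$occlusion_breath_indices <- occlusion_breath_indices
  }
  list(recording = recording(rec_sigs), truth = truth)
}
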