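# Breath-level parameter extraction: segmentation, onset/offset timing,
# magnitude, EMG-time product, neuromechanical conversion to Pmus, and
# patient-ventilator timing comparison.

#' Detect the breath offset by the 70%-of-peak rule
#'
#' End of inspiratory muscle activity is commonly defined as the drop of
#' the envelope to 70% of its per-breath peak.  The crossing is located by
#' linear interpolation between samples.  If the envelope never reaches
#' 70% before the end of the window, the time of the post-peak envelope
#' minimum is returned and flagged.
#'
#' @param env an `Envelope`.
#' @param breath_window numeric `c(start_s, end_s)` containing the peak
#'   (typically from this breath's onset to the next breath's onset).
#' @return offset time in seconds, with attribute `reached_70` (logical).
#' @export
detect_offset_70 <- function(env, breath_window) {
  stopifnot(inherits(env, "Envelope"))
  t <- envelope_times(env)
  idx <- which(t >= breath_window[1] & t <= breath_window[2])
  if (!length(idx)) stop("empty breath window")
  x <- env$samples[idx]
  ip <- which.max(x)
  peak <- x[ip]
  thr <- 0.7 * peak
  post <- if (ip < length(x)) (ip + 1L):length(x) else integer(0)
  below <- post[x[post] <= thr]
  if (length(below)) {
    j <- below[1L]
    if (x[j] == thr || j == ip + 1L && x[ip] <= thr) {
      off <- t[idx[j]]
    } else {
      # interpolate between the last sample above and the first at/below
      t1 <- t[idx[j - 1L]]; t2 <- t[idx[j]]
      v1 <- x[j - 1L]; v2 <- x[j]
      off <- if (v1 == v2) t2 else t1 + (v1 - thr) / (v1 - v2) * (t2 - t1)
    }
    reached <- TRUE
  } else {
    off <- if (length(post)) t[idx[post[which.min(x[post])]]]
           else t[idx[length(idx)]]
    reached <- FALSE
  }
  structure(off, reached_70 = reached)
}

# Changepoint refinement of the breath onset.  A threshold crossing
# necessarily lags the true onset: a smooth activation rise spends its
# first stretch below the noise floor.  The onset is therefore estimated
# by least-squares fitting of a flat-baseline-plus-quadratic-rise model
# over the quiet plateau and the early rise, with the quadratic foot
# analytically convolved with the envelope's own moving window (so the
# window's smearing does not bias the changepoint), scanning candidate
# onset times on a 10 ms grid.
.refine_onset <- function(t, x, i_run, i_end, fs, win_s, hi_frac = 0.4) {
  ipk <- i_run + which.max(x[i_run:i_end]) - 1L
  peak <- x[ipk]
  i_hi <- i_run
  while (i_hi < ipk && x[i_hi] < hi_frac * peak) i_hi <- i_hi + 1L
  i_lo <- max(1L, i_hi - round(1.5 * fs))
  sel <- seq(i_lo, i_hi, by = max(1L, round(fs / 200)))
  if (length(sel) < 8L) return(t[i_run])
  tt <- t[sel]; yy <- x[sel]
  cand <- seq(tt[1L] + 0.05, t[i_hi] - 0.05, by = 0.01)
  if (!length(cand)) return(t[i_run])
  H <- function(v) pmax(0, v)
  best <- Inf; best_t0 <- t[i_run]
  for (t0 in cand) {
    u <- tt - t0
    z <- (H(u + win_s / 2)^3 - H(u - win_s / 2)^3) / (3 * win_s)
    fit <- stats::lm.fit(cbind(1, z), yy)
    if (fit$coefficients[2L] > 0) {
      sse <- sum(fit$residuals^2)
      if (sse < best) { best <- sse; best_t0 <- t0 }
    }
  }
  best_t0
}

#' Segment an envelope into breaths
#'
#' Onsets are declared where the baseline-corrected envelope exceeds
#' `onset_k * noise` for at least `min_duration_ms`; the onset time is then
#' refined by a least-squares changepoint fit (flat baseline plus
#' quadratic rise, convolved with the envelope window) over the quiet
#' plateau and early rise, which compensates the inherent detection lag of
#' threshold crossing on a smooth activation rise.  The peak is the
#' envelope maximum
#' of the supra-threshold run, and the offset comes from
#' [detect_offset_70()].  Runs shorter than `min_duration_ms` are
#' discarded; consecutive breaths are separated by at least one
#' sub-threshold sample.
#'
#' @param env a baseline-corrected `Envelope`.
#' @param noise noise level used for the threshold (typically the
#'   pre-correction floor from [estimate_noise_floor()]).
#' @param min_duration_ms minimum supra-threshold duration (default 300).
#' @param onset_k threshold multiplier (default 3).
#' @param refine_onset back-extrapolate onsets (default TRUE)?
#' @return data.frame of class `BreathList`: `onset_s`, `peak_s`,
#'   `offset_s`, `peak_value`, `offset_reached_70`, `source`.
#' @export
detect_breaths <- function(env, noise, min_duration_ms = 300, onset_k = 3,
                           refine_onset = TRUE) {
  stopifnot(inherits(env, "Envelope"))
  if (!isTRUE(env$baseline_corrected))
    stop("envelope must be baseline-corrected before breath detection ",
         "(see correct_baseline())")
  empty <- structure(
    data.frame(onset_s = numeric(0), peak_s = numeric(0), offset_s = numeric(0),
               peak_value = numeric(0), offset_reached_70 = logical(0),
               source = character(0)),
    class = c("BreathList", "data.frame"))
  x <- env$samples
  t <- envelope_times(env)
  n <- length(x)
  thr <- onset_k * noise
  if (thr <= 0) thr <- 0.05 * max(x)
  if (thr <= 0) return(empty)
  above <- x > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  # a run covering the whole envelope is a level shift, not a breath
  runs <- runs[!(starts[runs] == 1L & ends[runs] == n)]
  if (!length(runs)) return(empty)
  min_len <- min_duration_ms / 1000 * env$fs
  runs <- runs[r$lengths[runs] >= min_len]
  if (!length(runs)) return(empty)

  out <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    a <- starts[runs[k]]; b <- ends[runs[k]]
    ip <- a + which.max(x[a:b]) - 1L
    peak <- x[ip]
    onset <- if (refine_onset)
      .refine_onset(t, x, a, b, env$fs, env$window_ms / 1000) else t[a]
    win_end <- if (k < length(runs)) t[starts[runs[k + 1L]]] else t[n]
    off <- detect_offset_70(env, c(t[a], win_end))
    out[[k]] <- data.frame(onset_s = onset, peak_s = t[ip],
                           offset_s = max(as.numeric(off), t[ip]),
                           peak_value = peak,
                           offset_reached_70 = attr(off, "reached_70"),
                           source = "envelope")
  }
  df <- do.call(rbind, out)
  # enforce non-overlap after onset refinement
  if (nrow(df) > 1L) {
    for (k in 2:nrow(df)) {
      if (df$onset_s[k] < df$offset_s[k - 1L])
        df$onset_s[k] <- df$offset_s[k - 1L]
    }
  }
  structure(df, class = c("BreathList", "data.frame"))
}

#' Per-breath amplitude
#'
#' Difference between the maximum and minimum envelope value over one
#' breath.  The percentile variant (95th minus 5th, linear-interpolation
#' percentiles) is more robust to residual artifact spikes.
#'
#' @param env an `Envelope`.
#' @param breath one row of a `BreathList` (or a list with `onset_s`,
#'   `offset_s`).
#' @param method `"p95_p5"` (default) or `"minmax"`.
#' @param include_baseline when `TRUE`, the amplitude is referenced to zero
#'   (the corrected baseline) rather than the in-breath minimum.
#' @return amplitude in envelope units (uV).
#' @export
breath_amplitude <- function(env, breath, method = c("p95_p5", "minmax"),
                             include_baseline = FALSE) {
  stopifnot(inherits(env, "Envelope"))
  method <- match.arg(method)
  t <- envelope_times(env)
  idx <- which(t >= breath$onset_s & t <= breath$offset_s)
  if (!length(idx)) stop("empty breath window for amplitude")
  x <- env$samples[idx]
  if (method == "minmax") {
    if (include_baseline) max(x) else max(x) - min(x)
  } else {
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
    if (include_baseline) q[2L] else q[2L] - q[1L]
  }
}

#' Normalize per-breath amplitudes
#'
#' @param values numeric vector of amplitudes.
#' @param mode `"recording_max"` (divide by the series maximum; output
#'   maximum is exactly 1) or `"max_maneuver"` (divide by the amplitude of
#'   a maximum inspiratory maneuver, passed as `reference`).
#' @param reference positive reference amplitude for `"max_maneuver"`.
#' @return dimensionless normalized series.
#' @export
normalize_amplitudes <- function(values, mode = c("recording_max", "max_maneuver"),
                                 reference = NULL) {
  mode <- match.arg(mode)
  if (!length(values)) stop("`values` must be nonempty")
  ref <- if (mode == "recording_max") max(values) else reference
  if (is.null(ref) || !is.finite(ref) || ref <= 0)
    stop("normalization reference must be a positive number")
  values / ref
}

#' EMG-time product of one breath
#'
#' Area under the sEMG envelope over the breath (trapezoidal rule), a
#' measure of activation intensity less sensitive to residual artifacts
#' than breathwise amplitudes.
#'
#' @param env an `Envelope` (baseline-corrected unless `include_baseline`
#'   is set explicitly).
#' @param breath one row of a `BreathList`.
#' @param include_baseline integrate the envelope as-is (`TRUE`) or above
#'   its in-breath minimum (`FALSE`, default).
#' @return area in uV.s.
#' @export
emg_time_product <- function(env, breath, include_baseline = FALSE) {
  stopifnot(inherits(env, "Envelope"))
  t <- envelope_times(env)
  idx <- which(t >= breath$onset_s & t <= breath$offset_s)
  if (length(idx) < 2L) return(0)
  x <- env$samples[idx]
  if (!include_baseline) x <- x - min(x)
  tt <- t[idx]
  sum(diff(tt) * (utils::head(x, -1L) + utils::tail(x, -1L)) / 2)
}

#' EMG-time product per minute
#'
#' Sums per-breath EMG-time products over fixed, non-overlapping one-minute
#' bins (binned by breath onset).
#'
#' @param env an `Envelope`.
#' @param breaths a `BreathList`.
#' @param include_baseline see [emg_time_product()].
#' @return data.frame with `minute` (1-based bin) and `etp_uv_s`.
#' @export
etp_per_minute <- function(env, breaths, include_baseline = FALSE) {
  if (!nrow(breaths)) return(data.frame(minute = integer(0), etp_uv_s = numeric(0)))
  etp <- vapply(seq_len(nrow(breaths)), function(i)
    emg_time_product(env, breaths[i, ], include_baseline), numeric(1L))
  bin <- floor(breaths$onset_s / 60) + 1L
  agg <- stats::aggregate(etp, list(minute = bin), sum)
  data.frame(minute = agg$minute, etp_uv_s = agg$x)
}

#' Estimate neuromechanical efficiency from an end-expiratory occlusion
#'
#' During an occlusion the airway pressure deflection is generated entirely
#' by the respiratory muscles, so the ratio of the (negative) pressure
#' deflection to the concurrent envelope peak gives the conversion factor
#' `k` (cmH2O/uV).  Because the diaphragm is more efficient during the
#' isometric contraction of an occlusion than during tidal breathing, a
#' correction factor of 0.7 or 0.8 multiplies the occlusion-derived ratio.
#'
#' @param paw airway pressure `Signal` (cmH2O).
#' @param env concurrent sEMG `Envelope` (uV).
#' @param occlusion_window numeric `c(start_s, end_s)`.
#' @param correction multiplicative correction factor in (0, 1]; default 0.8.
#' @return an `NmeEstimate`: `k`, `correction`, `occlusion_window`,
#'   `paw_deflection` (cmH2O), `emg_peak` (uV), `paw_baseline`.
#' @export
estimate_nme_occlusion <- function(paw, env, occlusion_window, correction = 0.8) {
  stopifnot(inherits(paw, "Signal"), inherits(env, "Envelope"))
  if (paw$kind != "pressure") stop("`paw` must be a pressure signal")
  if (correction <= 0 || correction > 1) stop("`correction` must be in (0, 1]")
  tp <- signal_times(paw)
  win <- which(tp >= occlusion_window[1] & tp <= occlusion_window[2])
  if (!length(win)) stop("empty occlusion window")
  pre <- which(tp >= occlusion_window[1] - 0.5 & tp < occlusion_window[1])
  baseline <- if (length(pre)) stats::median(paw$samples[pre]) else 0
  deflection <- baseline - min(paw$samples[win])
  if (deflection < 0.5)
    stop("no occlusion effort detected: airway pressure deflection ",
         sprintf("%.2f", deflection), " cmH2O is below 0.5 cmH2O")
  te <- envelope_times(env)
  wine <- which(te >= occlusion_window[1] & te <= occlusion_window[2])
  if (!length(wine)) stop("occlusion window outside the envelope span")
  emg_peak <- max(env$samples[wine])
  if (emg_peak <= 0) stop("no envelope activity in the occlusion window")
  structure(list(k = correction * deflection / emg_peak,
                 correction = correction,
                 occlusion_window = occlusion_window,
                 paw_deflection = deflection, emg_peak = emg_peak,
                 paw_baseline = baseline),
            class = "NmeEstimate")
}

#' @export
print.NmeEstimate <- function(x, ...) {
  cat(sprintf("<NmeEstimate: k = %.3f cmH2O/uV (deflection %.2f cmH2O / peak %.2f uV, correction %.2f)>\n",
              x$k, x$paw_deflection, x$emg_peak, x$correction))
  invisible(x)
}

#' Muscle-pressure waveform from an envelope
#'
#' Converts a baseline-corrected sEMG envelope into an estimated
#' respiratory muscle pressure via the linear model `Pmus = k * sEMG`.
#'
#' @param env a baseline-corrected `Envelope` (uV).
#' @param k conversion factor in cmH2O/uV (> 0), e.g. from
#'   [estimate_nme_occlusion()] (an `NmeEstimate` is accepted directly).
#' @return a pressure `Signal` (cmH2O).
#' @export
pmus_waveform <- function(env, k) {
  stopifnot(inherits(env, "Envelope"))
  if (inherits(k, "NmeEstimate")) k <- k$k
  if (!is.finite(k) || k <= 0) stop("`k` must be a positive conversion factor")
  if (!isTRUE(env$baseline_corrected))
    stop("envelope must be baseline-corrected before Pmus conversion")
  signal(k * env$samples, env$fs, label = "pmus", kind = "pressure",
         t0 = env$t0)
}

#' Compare EMG and ventilator event timing
#'
#' Signed delay and phase angle between an sEMG event (onset or offset) and
#' the corresponding ventilator event (start or end of pressurization).
#' Convention: positive values mean the ventilator event follows the EMG
#' event (the usual trigger-delay situation).
#'
#' @param emg_event_s EMG event time(s), seconds.
#' @param vent_event_s ventilator event time(s), seconds.
#' @param reference_cycle_s duration of the respiratory cycle used as the
#'   360-degree reference.
#' @return a `TimingComparison` data.frame: `delay_ms`, `phase_angle_deg`,
#'   `reference_cycle_s`, plus the input event times.
#' @export
timing_compare <- function(emg_event_s, vent_event_s, reference_cycle_s) {
  if (any(reference_cycle_s <= 0)) stop("`reference_cycle_s` must be > 0")
  delay_ms <- 1000 * (vent_event_s - emg_event_s)
  structure(
    data.frame(emg_event_s = emg_event_s, vent_event_s = vent_event_s,
               delay_ms = delay_ms,
               phase_angle_deg = 360 * (delay_ms / 1000) / reference_cycle_s,
               reference_cycle_s = reference_cycle_s),
    class = c("TimingComparison", "data.frame"),
    convention = "positive = EMG precedes ventilator event")
}

#' Time from breath onset to peak activity
#' @param breath one row of a `BreathList`.
#' @return `peak_s - onset_s`, in seconds.
#' @export
time_to_peak <- function(breath) {
  as.numeric(breath$peak_s - breath$onset_s)
}

#' Detect ventilator pressurization onsets and offsets
#'
#' Simple threshold detector on the airway-pressure channel: a
#' pressurization starts when the pressure rises above `threshold_cmh2o`
#' (sustained 100 ms) and ends when it falls back below.
#'
#' @param paw a pressure `Signal`.
#' @param threshold_cmh2o detection threshold (default 1 cmH2O).
#' @return data.frame with `start_s` and `end_s` per pressurization.
#' @export
detect_pressurization <- function(paw, threshold_cmh2o = 1) {
  stopifnot(inherits(paw, "Signal"))
  t <- signal_times(paw)
  above <- paw$samples > threshold_cmh2o
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= 0.1 * paw$fs)
  data.frame(start_s = t[starts[keep]], end_s = t[ends[keep]])
}

#' Per-breath feature table
#'
#' Computes the standard per-breath features (amplitude, normalized
#' amplitude, EMG-time product, time-to-peak, duration) and, when a
#' ventilator pressure channel is supplied, trigger delay and phase angle
#' by nearest-onset pairing within half a cycle.  Unpaired EMG breaths are
#' counted as candidate ineffective efforts.
#'
#' @param env a baseline-corrected `Envelope`.
#' @param breaths a `BreathList`.
#' @param paw optional pressure `Signal` for timing columns.
#' @param amplitude_method see [breath_amplitude()].
#' @param normalization `"recording_max"` (default) or `"max_maneuver"`.
#' @param reference reference amplitude for `"max_maneuver"`.
#' @return data.frame, one row per breath, with attribute
#'   `n_unpaired_efforts` when `paw` is given.
#' @export
breath_features <- function(env, breaths, paw = NULL,
                            amplitude_method = "p95_p5",
                            normalization = "recording_max",
                            reference = NULL) {
  stopifnot(inherits(env, "Envelope"))
  nb <- nrow(breaths)
  if (!nb) return(data.frame())
  amp <- vapply(seq_len(nb), function(i)
    breath_amplitude(env, breaths[i, ], amplitude_method), numeric(1L))
  etp <- vapply(seq_len(nb), function(i)
    emg_time_product(env, breaths[i, ]), numeric(1L))
  df <- data.frame(
    breath = seq_len(nb),
    onset_s = breaths$onset_s, peak_s = breaths$peak_s,
    offset_s = breaths$offset_s,
    amplitude_uv = amp,
    amplitude_normalized = normalize_amplitudes(amp, normalization, reference),
    etp_uv_s = etp,
    time_to_peak_s = breaths$peak_s - breaths$onset_s,
    duration_s = breaths$offset_s - breaths$onset_s)
  if (!is.null(paw)) {
    pres <- detect_pressurization(paw)
    cycle <- if (nb > 1L) stats::median(diff(breaths$onset_s))
             else duration(paw) / max(1L, nrow(pres))
    df$trigger_delay_ms <- NA_real_
    df$phase_angle_deg <- NA_real_
    paired <- logical(nb)
    for (i in seq_len(nb)) {
      if (!nrow(pres)) break
      d <- pres$start_s - breaths$onset_s[i]
      j <- which.min(abs(d))
      if (abs(d[j]) <= cycle / 2) {
        tc <- timing_compare(breaths$onset_s[i], pres$start_s[j], cycle)
        df$trigger_delay_ms[i] <- tc$delay_ms
        df$phase_angle_deg[i] <- tc$phase_angle_deg
        paired[i] <- TRUE
      }
    }
    attr(df, "n_unpaired_efforts") <- sum(!paired)
  }
  df
}
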