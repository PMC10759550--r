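# Envelope extraction: demodulate the denoised sEMG into an activity
# waveform.  The general recommendation is a centered moving window of
# 250 ms; all estimators keep the envelope sample-aligned with the input
# signal (partial windows at the edges, never NA padding).

.new_envelope <- function(samples, fs, method, window_ms, causality, step_ms,
                          t0 = 0, baseline_corrected = FALSE, noise_floor = NA_real_,
                          flags = character(0)) {
  structure(list(samples = samples, fs = fs, method = method,
                 window_ms = window_ms, causality = causality,
                 step_ms = step_ms, t0 = t0,
                 baseline_corrected = baseline_corrected,
                 noise_floor = noise_floor, flags = flags),
            class = "Envelope")
}

#' @export
print.Envelope <- function(x, ...) {
  cat(sprintf("<Envelope %s: %d samples @ %g Hz, window %g ms (%s), %s>\n",
              x$method, length(x$samples), x$fs, x$window_ms, x$causality,
              if (x$baseline_corrected) "baseline-corrected" else "raw"))
  invisible(x)
}

#' Time axis of an envelope
#' @param env an `Envelope`.
#' @return numeric vector of sample times in seconds.
#' @export
envelope_times <- function(env) {
  stopifnot(inherits(env, "Envelope"))
  env$t0 + (seq_along(env$samples) - 1L) / env$fs
}

.window_samples <- function(window_ms, fs) max(1L, round(window_ms / 1000 * fs))

# Moving mean of v with partial windows at the edges.
.moving_mean <- function(v, w, causality) {
  n <- length(v)
  cs <- cumsum(v)
  if (causality == "centered") {
    l <- (w - 1L) %/% 2L
    r <- w - 1L - l
    lo <- pmax(1L, seq_len(n) - l)
    hi <- pmin(n, seq_len(n) + r)
  } else {
    lo <- pmax(1L, seq_len(n) - w + 1L)
    hi <- seq_len(n)
  }
  prev <- c(0, cs)[lo]          # cumulative sum up to lo-1 (0 when lo == 1)
  (cs[hi] - prev) / (hi - lo + 1L)
}

.stride_interp <- function(y, fs, step) {
  if (step <= 1L) return(y)
  n <- length(y)
  at <- seq(1L, n, by = step)
  if (at[length(at)] != n) at <- c(at, n)
  stats::approx(at, y[at], xout = seq_len(n), rule = 2)$y
}

.envelope_common <- function(sig, window_ms, causality, step_ms, method, fun) {
  stopifnot(inherits(sig, "Signal"))
  causality <- match.arg(causality, c("centered", "causal"))
  w <- .window_samples(window_ms, sig$fs)
  if (w < 3L) stop("envelope window must span at least 3 samples")
  if (is.null(step_ms)) step_ms <- 1000 / sig$fs
  step <- max(1L, round(step_ms / 1000 * sig$fs))
  y <- fun(sig$samples, w, causality)
  y <- .stride_interp(y, sig$fs, step)
  .new_envelope(y, sig$fs, method, window_ms, causality,
                step * 1000 / sig$fs, t0 = sig$t0)
}

#' Moving root-mean-square envelope
#'
#' The most generally used envelope estimator: per output sample, the RMS
#' of the signal over a moving window (centered by default, 250 ms).
#'
#' @param sig a `Signal` (denoised sEMG).
#' @param window_ms window length in ms (default 250).
#' @param causality `"centered"` (default) or `"causal"` (trailing window).
#' @param step_ms moving-window step; default one sample.  Larger steps are
#'   computed at a stride and linearly interpolated back to the signal rate.
#' @return an `Envelope` (method `"rms"`, uV).
#' @export
moving_rms <- function(sig, window_ms = 250, causality = "centered",
                       step_ms = NULL) {
  .envelope_common(sig, window_ms, causality, step_ms, "rms",
                   function(x, w, c.) sqrt(pmax(0, .moving_mean(x^2, w, c.))))
}

#' Moving average-rectified-value envelope
#'
#' Mean of the rectified signal over a moving window; less affected by
#' high-amplitude peaks (such as remaining QRS artifacts) than RMS.
#'
#' @inheritParams moving_rms
#' @return an `Envelope` (method `"arv"`, uV).
#' @export
moving_arv <- function(sig, window_ms = 250, causality = "centered",
                       step_ms = NULL) {
  .envelope_common(sig, window_ms, causality, step_ms, "arv",
                   function(x, w, c.) .moving_mean(abs(x), w, c.))
}

#' Moving rectified-median envelope
#'
#' Moving median of the rectified signal: the most robust of the amplitude
#' estimators -- a single large outlier sample does not move it at all.
#'
#' @inheritParams moving_rms
#' @return an `Envelope` (method `"median_rect"`, uV).
#' @export
moving_median_rect <- function(sig, window_ms = 250, causality = "centered",
                               step_ms = NULL) {
  .envelope_common(sig, window_ms, causality, step_ms, "median_rect",
    function(x, w, caus) {
      n <- length(x)
      ax <- abs(x)
      k <- if (w %% 2L == 1L) w else w - 1L
      cen <- as.numeric(stats::runmed(ax, k, endrule = "median"))
      if (caus == "centered") return(cen)
      # causal window [i-k+1, i] == centered window around i - (k-1)/2
      k2 <- (k - 1L) %/% 2L
      out <- c(rep(NA_real_, k2), cen)[seq_len(n)]
      for (i in seq_len(min(n, k2))) out[i] <- stats::median(ax[1:i])
      out
    })
}

#' Parameters for the fixed sample entropy envelope
#'
#' @param m embedding dimension (default 1).
#' @param r_mult tolerance multiplier: the tolerance `r` is
#'   `r_mult * sd(signal)` computed once from the *whole* signal -- the
#'   "fixed" in fSampEn, and the reason the estimator tracks activity.
#'   The recommended range is 0.2-0.3; default 0.25.
#' @param window_ms moving-window length in ms (default 250; must span at
#'   least 100 samples).
#' @param step_ms window step in ms (default 50; one-sample steps are
#'   computationally expensive for fSampEn).
#' @return an `FsampenParams` list.
#' @export
fsampen_params <- function(m = 1L, r_mult = 0.25, window_ms = 250,
                           step_ms = 50) {
  if (m < 1L) stop("`m` must be >= 1")
  if (r_mult <= 0) stop("`r_mult` must be > 0")
  structure(list(m = as.integer(m), r_mult = r_mult, window_ms = window_ms,
                 step_ms = step_ms),
            class = "FsampenParams")
}

# Sample entropy of one window with fixed tolerance r (Chebyshev distance,
# self-matches excluded).  Returns NA when no template pair matches at
# either length.
.sampen_window <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  if (nt < 2L) stop("window too short for embedding dimension m = ", m)
  idx <- seq_len(nt)
  D <- abs(outer(x[idx], x[idx], "-"))
  if (m > 1L) {
    for (k in 1L:(m - 1L)) {
      D <- pmax(D, abs(outer(x[idx + k], x[idx + k], "-")))
    }
  }
  B <- (sum(D <= r) - nt) / 2
  Dm1 <- pmax(D, abs(outer(x[idx + m], x[idx + m], "-")))
  A <- (sum(Dm1 <= r) - nt) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

#' Fixed sample entropy envelope
#'
#' Moving-window sample entropy with a tolerance `r` fixed from the whole
#' signal's standard deviation.  Because `r` does not adapt per window,
#' high-activity windows produce more admissible dynamics relative to `r`
#' and hence higher entropy, which makes fSampEn an activity envelope that
#' is robust to sparse high-amplitude artifacts.  It is applied directly to
#' the raw signal; no other filtering is needed.
#'
#' Windows in which no template pair matches at one of the lengths have
#' undefined entropy; they are mapped to the maximum finite value attained
#' elsewhere and flagged (`"undefined_windows"`).
#'
#' @param sig a `Signal` (raw sEMG).
#' @param params an [fsampen_params()].
#' @return an `Envelope` (method `"fsampen"`, dimensionless), linearly
#'   interpolated from the window grid back to the signal rate.
#' @export
fsampen_envelope <- function(sig, params = fsampen_params()) {
  stopifnot(inherits(sig, "Signal"), inherits(params, "FsampenParams"))
  fs <- sig$fs
  x <- sig$samples
  n <- length(x)
  w <- .window_samples(params$window_ms, fs)
  if (w < 100L) stop("fSampEn window must span at least 100 samples")
  if (params$m >= w) stop("embedding dimension must be smaller than the window")
  r <- params$r_mult * stats::sd(x)
  step <- max(1L, round(params$step_ms / 1000 * fs))
  centers <- seq(1L + w %/% 2L, n - (w - w %/% 2L - 1L), by = step)
  if (!length(centers)) stop("signal shorter than one fSampEn window")
  ent <- vapply(centers, function(cc) {
    lo <- cc - w %/% 2L
    .sampen_window(x[lo:(lo + w - 1L)], params$m, r)
  }, numeric(1L))
  flags <- character(0)
  if (anyNA(ent)) {
    flags <- "undefined_windows"
    mx <- suppressWarnings(max(ent, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 0
    ent[is.na(ent)] <- mx
  }
  y <- stats::approx(centers, ent, xout = seq_len(n), rule = 2)$y
  .new_envelope(y, fs, "fsampen", params$window_ms, "centered",
                step * 1000 / fs, t0 = sig$t0, flags = flags)
}

#' Estimate the envelope noise floor
#'
#' Robust estimate of the residual (between-breath) envelope level, taken
#' as a low percentile of the envelope samples: between breaths muscle
#' activation is low, so the lower tail of the envelope distribution
#' reflects the noise floor.
#'
#' @param env an `Envelope` spanning several breaths.
#' @param percentile percentile in [0, 100] (default 5).
#' @return the noise level, in envelope units.
#' @export
estimate_noise_floor <- function(env, percentile = 5) {
  stopifnot(inherits(env, "Envelope"))
  if (percentile < 0 || percentile > 100) stop("`percentile` must be in [0, 100]")
  as.numeric(stats::quantile(env$samples, percentile / 100, names = FALSE,
                             type = 7))
}

#' Baseline-correct an envelope
#'
#' Removes the noise floor from the envelope.  For RMS envelopes the noise
#' *variance* is subtracted rather than the standard deviation
#' (`sqrt(max(env^2 - noise^2, 0))`), because signal and noise powers add;
#' for ARV and rectified-median envelopes the level is subtracted and the
#' result clipped at zero; for fSampEn the quiet-segment mean entropy is
#' subtracted likewise.
#'
#' @param env an `Envelope`, not yet corrected.
#' @param noise noise level (from [estimate_noise_floor()] or ground truth).
#' @return corrected `Envelope` with `baseline_corrected = TRUE` and the
#'   noise estimate stored.
#' @export
correct_baseline <- function(env, noise) {
  stopifnot(inherits(env, "Envelope"))
  if (isTRUE(env$baseline_corrected))
    stop("envelope is already baseline-corrected")
  if (!is.finite(noise) || noise < 0) stop("`noise` must be a finite value >= 0")
  y <- switch(env$method,
    rms = sqrt(pmax(env$samples^2 - noise^2, 0)),
    pmax(env$samples - noise, 0))
  out <- env
  out$samples <- y
  out$baseline_corrected <- TRUE
  out$noise_floor <- noise
  out
}

#' Write an envelope to CSV with a JSON header sidecar
#'
#' @param env an `Envelope`.
#' @param path output CSV path; a `<path>.json` sidecar stores the method
#'   and parameters.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  stopifnot(inherits(env, "Envelope"))
  df <- data.frame(time_s = envelope_times(env), value = env$samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(method = env$method, window_ms = env$window_ms,
               causality = env$causality, step_ms = env$step_ms,
               fs = env$fs, baseline_corrected = env$baseline_corrected,
               noise_floor = env$noise_floor, flags = env$flags)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
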