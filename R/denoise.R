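# ECG and technical-noise removal.
#
# Three complementary routes, matching common practice in respiratory sEMG:
#   * brute-force high-pass filtering (cheap; at high cutoffs it suppresses
#     the QRS at the cost of EMG power -- data-check use only),
#   * QRS gating driven by Pan-Tompkins R-peak detection (preserves EMG
#     amplitude, loses the gated time windows),
#   * wavelet-domain thresholding (suppresses the high-amplitude cardiac
#     transients without segment loss; the go-to method).

#' Zero-phase Butterworth high-pass filter
#'
#' For low-frequency artifact removal a cutoff in the 0.5-20 Hz range is
#' typical; as a standalone brute-force ECG suppressor for raw data checks,
#' cutoffs up to 200 Hz are used.
#'
#' @param sig a `Signal`.
#' @param cutoff_hz cutoff frequency in Hz, within (0, fs/2).
#' @param order filter order (default 4).
#' @return filtered `Signal`.
#' @export
highpass <- function(sig, cutoff_hz, order = 4) {
  stopifnot(inherits(sig, "Signal"))
  if (cutoff_hz <= 0 || cutoff_hz >= sig$fs / 2)
    stop("`cutoff_hz` must lie strictly between 0 and fs/2 = ", sig$fs / 2, " Hz")
  y <- .zp_highpass(sig$samples, sig$fs, cutoff_hz, order)
  signal(y, sig$fs, label = sig$label, kind = sig$kind, t0 = sig$t0)
}

#' Zero-phase mains notch filter
#'
#' Second-order notch at the mains frequency (50 or 60 Hz), applied with
#' zero phase.  Attenuation at the mains frequency exceeds 30 dB while the
#' response 10 Hz away changes amplitudes by less than 5%.
#'
#' @param sig a `Signal`.
#' @param mains_hz 50 or 60.
#' @param q quality factor (default 30).
#' @return filtered `Signal`.
#' @export
notch_mains <- function(sig, mains_hz = 50, q = 30) {
  stopifnot(inherits(sig, "Signal"))
  if (!mains_hz %in% c(50, 60))
    stop("`mains_hz` must be 50 or 60 (mains frequencies)")
  if (mains_hz >= sig$fs / 2) stop("mains frequency at or above Nyquist")
  y <- .zp_notch(sig$samples, sig$fs, mains_hz, q)
  signal(y, sig$fs, label = sig$label, kind = sig$kind, t0 = sig$t0)
}

#' Detect R-peaks with the Pan-Tompkins algorithm
#'
#' Classic Pan-Tompkins stages adapted to zero-phase processing: band-pass
#' 5-15 Hz, derivative, squaring, 150 ms moving-window integration,
#' adaptive dual thresholds with RR-based search-back and a 200 ms
#' refractory period.  Detected times are refined to the local extremum of
#' the band-passed signal within +/- 50 ms.
#'
#' @param sig a `Signal`, at least 5 s long, fs >= 200 Hz.
#' @return an `RPeakList`: `times_s` (strictly increasing), `detector`,
#'   `params`, and `flags` (e.g. `"flat_signal"`, `"rate_out_of_range"`).
#' @export
detect_r_peaks <- function(sig) {
  stopifnot(inherits(sig, "Signal"))
  fs <- sig$fs
  if (duration(sig) < 5) stop("R-peak detection needs at least 5 s of signal")
  if (fs < 200) stop("R-peak detection needs fs >= 200 Hz")
  x <- sig$samples
  n <- length(x)
  flags <- character(0)
  mk <- function(times, flags) {
    structure(list(times_s = times, detector = "pan_tompkins",
                   params = list(band = c(5, 15), mwi_ms = 150,
                                 refractory_ms = 200, refine_ms = 50),
                   flags = flags),
              class = "RPeakList")
  }
  if (stats::sd(x) == 0) {
    warning("flat signal: no R-peaks detectable")
    return(mk(numeric(0), "flat_signal"))
  }

  bp <- .zp_bandpass(x, fs, 5, 15, order = 2)
  der <- c(0, diff(bp)) * fs
  sq <- der^2
  w <- max(1L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate peaks: local maxima of the integrated signal
  refr <- round(0.200 * fs)
  is_peak <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(is_peak)) return(mk(numeric(0), "no_candidates"))

  spki <- max(mwi[seq_len(min(n, round(2 * fs)))]) * 0.25
  npki <- mean(mwi[seq_len(min(n, round(2 * fs)))]) * 0.5
  thr1 <- function() npki + 0.25 * (spki - npki)
  rpeaks <- integer(0)
  rr_hist <- numeric(0)
  last_r <- -Inf
  miss_anchor <- 1L

  for (p in is_peak) {
    peaki <- mwi[p]
    if (peaki > thr1() && (p - last_r) > refr) {
      rpeaks <- c(rpeaks, p)
      if (is.finite(last_r)) rr_hist <- utils::tail(c(rr_hist, p - last_r), 8L)
      last_r <- p
      spki <- 0.125 * peaki + 0.875 * spki
    } else if (peaki > thr1() && length(rpeaks) &&
               (p - last_r) <= refr && peaki > mwi[rpeaks[length(rpeaks)]]) {
      # larger integrated peak inside the refractory window: same QRS,
      # better localization -- replace the provisional detection
      rpeaks[length(rpeaks)] <- p
      last_r <- p
      spki <- 0.125 * peaki + 0.875 * spki
    } else {
      npki <- 0.125 * peaki + 0.875 * npki
    }
    # search-back: no beat for 1.66x the running RR average
    if (length(rr_hist) >= 2L) {
      rr_avg <- mean(rr_hist)
      if ((p - last_r) > 1.66 * rr_avg) {
        cand <- is_peak[is_peak > last_r + refr & is_peak <= p]
        if (length(cand)) {
          best <- cand[which.max(mwi[cand])]
          if (mwi[best] > 0.5 * thr1()) {
            rpeaks <- sort(c(rpeaks, best))
            rr_hist <- utils::tail(c(rr_hist, best - last_r), 8L)
            last_r <- max(last_r, best)
            spki <- 0.25 * mwi[best] + 0.75 * spki
          }
        }
      }
    }
  }
  if (!length(rpeaks)) return(mk(numeric(0), "no_peaks_above_threshold"))

  # refine to the local extremum of the band-passed signal within +/-50 ms
  half <- round(0.050 * fs)
  refined <- vapply(rpeaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    as.integer(lo + which.max(abs(bp[lo:hi])) - 1L)
  }, integer(1L))
  refined <- sort(unique(refined))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(refined) > refr)
  refined <- refined[keep]
  times <- sig$t0 + (refined - 1L) / fs

  if (length(times) >= 2L) {
    inst <- 60 / diff(times)
    if (any(inst < 20 | inst > 300)) flags <- c(flags, "rate_out_of_range")
  }
  mk(times, flags)
}

#' Gate (blank) QRS windows out of an sEMG signal
#'
#' Replaces the samples in a window centered on each R-peak.  Gating is a
#' local operation: samples outside all gates are bit-identical to the
#' input.  It presupposes a 20 Hz high-pass so that P- and T-waves (which
#' fall outside the gates) are already removed: pass `highpassed = TRUE`
#' when that was done, otherwise the filter is applied here first (and the
#' locality guarantee then refers to the high-passed signal).
#'
#' @param sig a `Signal`.
#' @param rpeaks an `RPeakList` (or numeric vector of times in seconds).
#' @param window_ms gate width in ms, centered on each R-peak (default 150,
#'   covering the QRS complex).  Must be shorter than the median RR
#'   interval (gating cannot be used in tachycardia regimes).
#' @param fill `"zeros"`, `"hold"` (last pre-gate value), `"linear"`
#'   (interpolation between gate edges) or `"median"` (median of ungated
#'   samples within a 1 s neighborhood).
#' @param highpassed set `TRUE` if `sig` is already high-passed at 20 Hz.
#' @return list with `signal` (gated `Signal`) and `mask` (a `GateMask`
#'   with merged half-open intervals and the fill method).
#' @export
gate_ecg <- function(sig, rpeaks, window_ms = 150,
                     fill = c("zeros", "hold", "linear", "median"),
                     highpassed = FALSE) {
  stopifnot(inherits(sig, "Signal"))
  fill <- match.arg(fill)
  times <- if (inherits(rpeaks, "RPeakList")) rpeaks$times_s else as.numeric(rpeaks)
  if (!highpassed) sig <- highpass(sig, 20)
  x <- sig$samples
  fs <- sig$fs
  n <- length(x)
  if (length(times) >= 2L) {
    med_rr <- stats::median(diff(sort(times)))
    if (window_ms / 1000 >= med_rr)
      stop("gate window (", window_ms, " ms) is not shorter than the median ",
           "RR interval (", round(med_rr * 1000), " ms): gating cannot be ",
           "used in this tachycardia regime")
  }
  half <- window_ms / 2000
  iv <- cbind(pmax(sig$t0, times - half),
              pmin(sig$t0 + n / fs, times + half))
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  # merge overlapping intervals
  if (nrow(iv) > 1L) {
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    merged <- iv[1, , drop = FALSE]
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv[i, 1] <= merged[nrow(merged), 2]) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[i, 2])
      } else merged <- rbind(merged, iv[i, ])
    }
    iv <- merged
  }
  y <- x
  gated <- .gate_sample_mask(iv, sig$t0, fs, n)
  runs <- rle(gated)
  pos <- cumsum(c(1L, runs$lengths))
  for (r in seq_along(runs$lengths)) {
    if (!runs$values[r]) next
    a <- pos[r]; b <- pos[r + 1L] - 1L
    y[a:b] <- switch(fill,
      zeros = 0,
      hold = if (a > 1L) x[a - 1L] else 0,
      linear = {
        va <- if (a > 1L) x[a - 1L] else x[b + 1L]
        vb <- if (b < n) x[b + 1L] else x[a - 1L]
        if (is.na(va)) va <- 0
        if (is.na(vb)) vb <- 0
        seq(va, vb, length.out = b - a + 3L)[2:(b - a + 2L)]
      },
      median = {
        lo <- max(1L, a - round(0.5 * fs)); hi <- min(n, b + round(0.5 * fs))
        nb <- x[lo:hi][!gated[lo:hi]]
        if (!length(nb)) 0 else stats::median(nb)
      })
  }
  mask <- structure(list(intervals = iv, fill_method = fill,
                         window_ms = window_ms),
                    class = "GateMask")
  list(signal = signal(y, fs, label = sig$label, kind = sig$kind, t0 = sig$t0),
       mask = mask)
}

.gate_sample_mask <- function(iv, t0, fs, n) {
  gated <- logical(n)
  t_idx <- function(ts) pmin(n, pmax(1L, floor((ts - t0) * fs) + 1L))
  for (i in seq_len(nrow(iv))) {
    a <- t_idx(iv[i, 1]); b <- t_idx(iv[i, 2] - 1e-9)
    gated[a:b] <- TRUE
  }
  gated
}

#' Per-sample gate membership
#'
#' @param mask a `GateMask`.
#' @param sig the `Signal` the mask was built for.
#' @return logical vector marking the samples inside gates.
#' @export
gate_mask_samples <- function(mask, sig) {
  stopifnot(inherits(mask, "GateMask"), inherits(sig, "Signal"))
  .gate_sample_mask(mask$intervals, sig$t0, sig$fs, length(sig$samples))
}

#' Gated fraction of a signal
#' @param mask a `GateMask`.
#' @param total_s total signal duration in seconds.
#' @return fraction of time covered by gates.
#' @export
gate_fraction <- function(mask, total_s) {
  sum(mask$intervals[, 2] - mask$intervals[, 1]) / total_s
}

#' Number of wavelet decomposition levels for a sampling rate
#'
#' The decomposition depth tracks the sampling rate so that the deepest
#' detail bands keep covering the P-/T-wave and motion-artifact range
#' (10-20 Hz): 5 levels at 1000 Hz, one more (fewer) each time the rate
#' doubles (halves).  Implemented as `5 + round(log2(fs/1000))` with
#' round-half-to-even at exact midpoints resolved to the nearest power.
#'
#' @param fs sampling rate in Hz (>= 250).
#' @return integer number of levels.
#' @export
choose_wavelet_levels <- function(fs) {
  if (fs < 250) stop("`fs` must be >= 250 Hz")
  as.integer(5 + round(log2(fs / 1000)))
}

#' Wavelet denoising plan
#'
#' @param wavelet `"db2"` or `"db4"` (Daubechies wavelets with demonstrated
#'   good performance on respiratory EMG).
#' @param n_levels decomposition depth (default [choose_wavelet_levels()]
#'   at 1000 Hz, i.e. 5).
#' @param threshold_multiplier per-level threshold as a multiple of the
#'   level's scale estimate sigma_k (default 4.5).
#' @param sigma_estimator `"clipped_sd"` (default: the level's standard
#'   deviation, iteratively recomputed after excluding coefficients above
#'   the resulting threshold, so sparse cardiac spikes do not inflate it
#'   while burst-modulated EMG does not deflate it), `"sd"` (plain level
#'   standard deviation) or `"mad"` (MAD/0.6745).
#' @return a `WaveletPlan`.
#' @export
wavelet_plan <- function(wavelet = c("db2", "db4"), n_levels = 5L,
                         threshold_multiplier = 4.5,
                         sigma_estimator = c("clipped_sd", "mad", "sd")) {
  wavelet <- match.arg(wavelet)
  sigma_estimator <- match.arg(sigma_estimator)
  if (n_levels < 1L) stop("`n_levels` must be >= 1")
  if (threshold_multiplier <= 0) stop("`threshold_multiplier` must be > 0")
  structure(list(wavelet = wavelet, n_levels = as.integer(n_levels),
                 threshold_multiplier = threshold_multiplier,
                 sigma_estimator = sigma_estimator),
            class = "WaveletPlan")
}

# Daubechies scaling (dec_lo) coefficients, orthonormal (sum = sqrt(2)).
.db_filters <- list(
  db2 = c(0.48296291314469025, 0.83651630373746899,
          0.22414386804185735, -0.12940952255092145),
  db4 = c(0.23037781330885523, 0.71484657055254153,
          0.63088076792959036, -0.02798376941698385,
          -0.18703481171888114, 0.03084138183598697,
          0.03288301166698295, -0.01059740178499728)
)

# Stationary (undecimated) wavelet transform via FFT-domain circular
# convolution with a-trous upsampled filters.  For orthonormal quadrature
# mirror filters |H|^2 + |G|^2 = 2 at every frequency, so synthesis with
# the conjugate responses and a factor 1/2 per level reconstructs exactly.
.swt_responses <- function(h, m, n_levels) {
  g <- rev(h) * (-1)^(seq_along(h) - 1L)       # quadrature mirror filter
  Hf <- stats::fft(c(h, rep(0, m - length(h))))
  Gf <- stats::fft(c(g, rep(0, m - length(g))))
  idx0 <- 0:(m - 1L)
  lapply(seq_len(n_levels), function(j) {
    step <- 2^(j - 1L)
    sel <- (idx0 * step) %% m + 1L
    list(H = Hf[sel], G = Gf[sel])
  })
}

#' Wavelet-domain ECG denoising
#'
#' Multilevel stationary (undecimated, shift-invariant) wavelet
#' decomposition; in each detail level k, coefficients exceeding
#' `threshold_multiplier * sigma_k` in magnitude are set to zero.  This
#' inverts the classical keep-the-large-coefficients convention because
#' here the *high-amplitude* content is the contaminant: cardiac transients
#' stand far above the EMG background in every band they touch.  The
#' approximation band (lowest frequencies: baseline wander, P/T remnants)
#' is zeroed entirely.  sigma_k defaults to an iteratively sigma-clipped
#' standard deviation of the level: a plain SD is inflated by the very ECG
#' spikes being removed, while the MAD collapses on burst-modulated EMG
#' whose between-breath floor is near zero and then clips the bursts
#' themselves (both remain available via the plan).
#'
#' @param sig a `Signal`.
#' @param plan a [wavelet_plan()].
#' @return denoised `Signal`, same length as the input.
#' @export
wavelet_denoise <- function(sig, plan = wavelet_plan()) {
  stopifnot(inherits(sig, "Signal"), inherits(plan, "WaveletPlan"))
  x <- sig$samples
  n <- length(x)
  if (plan$n_levels > floor(log2(n)))
    stop("signal too short for ", plan$n_levels,
         " decomposition levels; use fewer levels")
  h <- .db_filters[[plan$wavelet]]
  support <- (length(h) - 1L) * 2^plan$n_levels
  if (n <= support)
    stop("signal shorter than the filter support at the deepest level (",
         support, " samples); use fewer levels")
  p <- max(support * 2L, 64L)
  m <- stats::nextn(n + 2L * p, c(2L, 3L, 5L))
  p_left <- (m - n) %/% 2L
  xp <- .mirror_extend(x, p_left, m)
  resp <- .swt_responses(h, m, plan$n_levels)

  A <- stats::fft(xp)
  D <- vector("list", plan$n_levels)
  core <- (p_left + 1L):(p_left + n)
  for (j in seq_len(plan$n_levels)) {
    Dj <- Re(stats::fft(resp[[j]]$G * A, inverse = TRUE)) / m
    A <- resp[[j]]$H * A
    # threshold from the original (unpadded) span; applied everywhere
    sigma_k <- switch(plan$sigma_estimator,
      mad = stats::mad(Dj[core]),
      sd = stats::sd(Dj[core]),
      clipped_sd = {
        s <- stats::sd(Dj[core])
        for (it in 1:3) {
          keep <- abs(Dj[core]) <= plan$threshold_multiplier * s
          if (any(keep)) s <- stats::sd(Dj[core][keep])
        }
        s
      })
    if (is.finite(plan$threshold_multiplier)) {
      tk <- plan$threshold_multiplier * sigma_k
      Dj[abs(Dj) > tk] <- 0
    }
    D[[j]] <- stats::fft(Dj)
  }
  Ahat <- complex(length.out = m)                 # approximation band zeroed
  for (j in rev(seq_len(plan$n_levels))) {
    Ahat <- (Conj(resp[[j]]$H) * Ahat + Conj(resp[[j]]$G) * D[[j]]) / 2
  }
  y <- Re(stats::fft(Ahat, inverse = TRUE))[core] / m
  signal(y, sig$fs, label = sig$label, kind = sig$kind, t0 = sig$t0)
}
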