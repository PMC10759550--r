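# Spectral fatigue indices.  Muscle fatigue compresses the EMG power
# spectrum toward lower frequencies before force output drops; the indices
# here (mean/median frequency, high/low-frequency power ratio, fifth-order
# spectral moments ratio) quantify that compression per breath.  They are
# computed on the denoised raw signal, never on the envelope.

#' Welch power spectral density of a signal segment
#'
#' Welch's method with a Hann window, 50% overlap and 256-sample segments
#' (or the full segment when shorter).  The density is scaled so that its
#' integral equals the segment variance (one-sided, in units^2 per Hz).
#'
#' @param sig a `Signal`.
#' @param segment_window optional `c(start_s, end_s)`; default whole signal.
#' @param nperseg Welch segment length in samples (default 256).
#' @return a `Psd` list: `freq_hz`, `power`, `df_hz`, `fs`.
#' @export
psd_segment <- function(sig, segment_window = NULL, nperseg = 256L) {
  stopifnot(inherits(sig, "Signal"))
  x <- sig$samples
  if (!is.null(segment_window)) {
    t <- signal_times(sig)
    x <- x[t >= segment_window[1] & t <= segment_window[2]]
  }
  n <- length(x)
  if (n < 256L) stop("PSD segment must contain at least 256 samples")
  fs <- sig$fs
  L <- min(nperseg, n)
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))        # Hann
  u <- sum(w^2)
  x <- x - mean(x)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(seg)
    acc <- acc + (Mod(X[seq_len(nf)])^2) / (fs * u)
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even L)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[nf] <- 1
  p <- p * dbl
  structure(list(freq_hz = (seq_len(nf) - 1L) * fs / L, power = p,
                 df_hz = fs / L, fs = fs),
            class = "Psd")
}

#' Mean and median frequency of a power spectrum
#'
#' MNF is the power-weighted mean frequency; MDF is the frequency below
#' which half the total power lies (linear interpolation between bins).
#' Downward shifts of either index indicate the spectral compression
#' associated with muscle fatigue.
#'
#' @param psd a `Psd`, or a list with `freq_hz` and `power`.
#' @return list with `mnf_hz` and `mdf_hz`.
#' @export
mean_median_frequency <- function(psd) {
  f <- psd$freq_hz; p <- psd$power
  tot <- sum(p)
  if (tot <= 0) stop("zero total power: MNF/MDF undefined")
  mnf <- sum(f * p) / tot
  # median via the trapezoid cumulative (density semantics), linear
  # interpolation between bins -- exact on flat spectra
  cum <- c(0, cumsum(diff(f) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2))
  half <- cum[length(cum)] / 2
  j <- which(cum >= half)[1L]
  if (j == 1L) {
    mdf <- f[1L]
  } else {
    mdf <- f[j - 1L] + (half - cum[j - 1L]) / (cum[j] - cum[j - 1L]) *
      (f[j] - f[j - 1L])
  }
  list(mnf_hz = mnf, mdf_hz = mdf)
}

# trapezoidal band power of a PSD between f1 and f2 (interpolating the
# band edges onto the frequency grid)
.band_power <- function(psd, f1, f2) {
  f <- psd$freq_hz; p <- psd$power
  if (f2 <= f1) return(0)
  f1 <- max(f1, min(f)); f2 <- min(f2, max(f))   # no power outside the grid
  if (f2 <= f1) return(0)
  grid <- sort(unique(c(f1, f2, f[f > f1 & f < f2])))
  v <- stats::approx(f, p, xout = grid, rule = 2)$y
  sum(diff(grid) * (utils::head(v, -1L) + utils::tail(v, -1L)) / 2)
}

#' High/low-frequency power ratio
#'
#' Ratio of integrated power in a high band (default 150-350 Hz) to a low
#' band (default 20-46.7 Hz); the ratio falls as fatigue shifts power
#' downward.  When the Nyquist frequency cannot reach the upper H edge
#' (e.g. fs = 500 Hz), the H band is truncated at Nyquist and the result
#' flagged.
#'
#' @param psd a `Psd`.
#' @param h_band,l_band numeric `c(lo, hi)` in Hz.
#' @return ratio (numeric) with attribute `band_truncated` (logical).
#' @export
hl_ratio <- function(psd, h_band = c(150, 350), l_band = c(20, 46.7)) {
  nyq <- max(psd$freq_hz)
  truncated <- FALSE
  if (nyq < h_band[2]) {
    h_band[2] <- nyq
    truncated <- TRUE
  }
  lp <- .band_power(psd, l_band[1], l_band[2])
  if (lp <= 0) stop("zero power in the low band: H/L ratio undefined")
  hp <- .band_power(psd, h_band[1], h_band[2])
  structure(hp / lp, band_truncated = truncated)
}

#' Spectral moments ratio of order five
#'
#' Dimitrov-style fatigue index `M(-1) / M(5)`, where
#' `M(k) = sum f^k P(f) df` over the 20-350 Hz support (truncated at
#' Nyquist).  Because the fifth-order moment weights high frequencies
#' heavily, spectral compression toward lower frequencies *increases* the
#' index, opposite in direction to MNF/MDF.
#'
#' @param psd a `Psd`.
#' @param support numeric `c(lo, hi)` integration support in Hz.
#' @return the ratio (numeric) with attribute `band_truncated`.
#' @export
smr5 <- function(psd, support = c(20, 350)) {
  nyq <- max(psd$freq_hz)
  truncated <- FALSE
  if (nyq < support[2]) {
    support[2] <- nyq
    truncated <- TRUE
  }
  f <- psd$freq_hz; p <- psd$power
  sel <- f >= support[1] & f <= support[2] & f > 0
  if (!any(sel) || sum(p[sel]) <= 0)
    stop("zero power in the SMR5 support: index undefined")
  df <- psd$df_hz
  m_neg1 <- sum(f[sel]^(-1) * p[sel]) * df
  m_5 <- sum(f[sel]^5 * p[sel]) * df
  structure(m_neg1 / m_5, band_truncated = truncated)
}

#' Spectral features of one PSD
#' @param psd a `Psd`.
#' @return a `SpectralFeatures` list: `mnf_hz`, `mdf_hz`, `hl_ratio`,
#'   `smr5`, `band_truncated`.
#' @export
spectral_features <- function(psd) {
  mm <- mean_median_frequency(psd)
  hl <- hl_ratio(psd)
  s5 <- smr5(psd)
  structure(list(mnf_hz = mm$mnf_hz, mdf_hz = mm$mdf_hz,
                 hl_ratio = as.numeric(hl), smr5 = as.numeric(s5),
                 band_truncated = isTRUE(attr(hl, "band_truncated")) ||
                   isTRUE(attr(s5, "band_truncated"))),
            class = "SpectralFeatures")
}

#' Per-breath spectral fatigue trend
#'
#' Computes [spectral_features()] for each breath's inspiratory segment of
#' the denoised *raw* signal (not the envelope) and fits a least-squares
#' linear trend of each index over breath number.  Breaths whose segment
#' holds fewer than 256 samples are skipped and flagged.
#'
#' @param sig the denoised raw `Signal` (wavelet-denoised by preference:
#'   gating removes segments and distorts spectra).
#' @param breaths a `BreathList` (or data.frame with `onset_s`, `offset_s`).
#' @return list with `per_breath` (data.frame of indices), `slopes` (named
#'   vector: change per breath for `mnf_hz`, `mdf_hz`, `hl_ratio`, `smr5`)
#'   and `n_skipped`.
#' @export
fatigue_trend <- function(sig, breaths) {
  stopifnot(inherits(sig, "Signal"))
  nb <- nrow(breaths)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nb)) {
    win <- c(breaths$onset_s[i], breaths$offset_s[i])
    nsamp <- floor((win[2] - win[1]) * sig$fs)
    if (nsamp < 256L) { skipped <- skipped + 1L; next }
    sf <- spectral_features(psd_segment(sig, win))
    rows[[length(rows) + 1L]] <- data.frame(
      breath = i, mnf_hz = sf$mnf_hz, mdf_hz = sf$mdf_hz,
      hl_ratio = sf$hl_ratio, smr5 = sf$smr5,
      band_truncated = sf$band_truncated)
  }
  if (length(rows) < 3L)
    stop("fatigue trend needs at least 3 usable breaths (got ",
         length(rows), ")")
  per_breath <- do.call(rbind, rows)
  slope_of <- function(y) unname(stats::coef(
    stats::lm(y ~ b, data.frame(b = per_breath$breath, y = y)))[2L])
  slopes <- c(mnf_hz = slope_of(per_breath$mnf_hz),
              mdf_hz = slope_of(per_breath$mdf_hz),
              hl_ratio = slope_of(per_breath$hl_ratio),
              smr5 = slope_of(per_breath$smr5))
  list(per_breath = per_breath, slopes = slopes, n_skipped = skipped)
}
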