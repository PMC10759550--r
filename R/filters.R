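# Internal zero-phase filtering utilities.
#
# All filters in this package are applied in the frequency domain: the signal
# is extended by tiled mirror reflection (to suppress circular wrap-around
# artifacts), transformed with the FFT, multiplied by a real, non-negative
# magnitude response, and transformed back.  The phase response is therefore
# identically zero, so filtering never shifts onset/offset timing -- a hard
# requirement for breath-timing work.

# Odd (antisymmetric) reflection extension of x to total length m with the
# original samples occupying positions p_left+1 .. p_left+n.  Odd
# reflection (2*x_edge - mirror) is continuous in value *and* first
# derivative for smooth signals, so the extension joints leak far less
# spectral energy than a plain mirror.  Reflections are tiled as needed.
.mirror_extend <- function(x, p_left, m) {
  n <- length(x)
  if (n == 1L) return(rep(x, m))
  ext <- x
  p_right <- m - n - p_left
  while (length(ext) < n + p_right) {
    add <- 2 * ext[length(ext)] - rev(ext)[-1L]
    ext <- c(ext, add)
  }
  ext <- ext[seq_len(n + p_right)]
  while (length(ext) < m) {
    add <- rev(2 * ext[1L] - ext[-1L])
    ext <- c(add, ext)
  }
  ext[seq(to = length(ext), length.out = m)]
}

# Apply a real magnitude response to x (sampling rate fs).  mag_fun receives
# a vector of non-negative frequencies (Hz) and must return gains in [0, 1+].
.zp_apply <- function(x, fs, mag_fun, pad_factor = 1) {
  n <- length(x)
  if (n < 2L) return(x)
  p <- max(16L, ceiling(pad_factor * n))
  m <- stats::nextn(n + 2L * p, c(2L, 3L, 5L))
  p_left <- (m - n) %/% 2L
  xp <- .mirror_extend(x, p_left, m)
  # frequency axis of the length-m DFT, folded to [0, fs/2]
  k <- 0:(m - 1L)
  f <- k / m * fs
  f <- pmin(f, fs - f)
  H <- mag_fun(f)
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(p_left + 1L):(p_left + n)]
}

# Butterworth magnitude responses ----------------------------------------

.butter_lp_mag <- function(f, cutoff, order) {
  1 / sqrt(1 + (f / cutoff)^(2 * order))
}

.butter_hp_mag <- function(f, cutoff, order) {
  g <- numeric(length(f))
  nz <- f > 0
  g[nz] <- 1 / sqrt(1 + (cutoff / f[nz])^(2 * order))
  g
}

# Second-order notch magnitude |H(j2*pi*f)| for H(s) = (s^2 + w0^2) /
# (s^2 + (w0/Q) s + w0^2); frequency ratios make the w0 factors cancel so
# we can work directly in Hz.
.notch_mag <- function(f, f0, q) {
  num <- abs(f0^2 - f^2)
  den <- sqrt((f0^2 - f^2)^2 + (f0 * f / q)^2)
  out <- num / den
  out[den == 0] <- 1
  out
}

# All responses are squared (|H|^2): the forward-backward (filtfilt)
# convention, which keeps zero phase while doubling the stop-band
# attenuation of the named design.

.zp_lowpass <- function(x, fs, cutoff, order = 4) {
  .zp_apply(x, fs, function(f) .butter_lp_mag(f, cutoff, order)^2)
}

.zp_highpass <- function(x, fs, cutoff, order = 4) {
  .zp_apply(x, fs, function(f) .butter_hp_mag(f, cutoff, order)^2)
}

.zp_bandpass <- function(x, fs, low, high, order = 4) {
  .zp_apply(x, fs, function(f)
    (.butter_hp_mag(f, low, order) * .butter_lp_mag(f, high, order))^2)
}

.zp_notch <- function(x, fs, f0, q = 30) {
  .zp_apply(x, fs, function(f) .notch_mag(f, f0, q)^2)
}

# Raised-cosine spectral taper: unity below f_lo, zero above f_hi, cosine
# roll-off in between (half gain at the midpoint).  Used as the antialiasing
# filter for resampling, where a flat pass band below 0.4 * target_fs is
# required.
.taper_mag <- function(f, f_lo, f_hi) {
  g <- numeric(length(f))
  g[f <= f_lo] <- 1
  mid <- f > f_lo & f < f_hi
  g[mid] <- 0.5 * (1 + cos(pi * (f[mid] - f_lo) / (f_hi - f_lo)))
  g
}
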