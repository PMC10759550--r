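# Shared fixtures, built lazily and cached for the session so that several
# test files can reuse the same default scene without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_scene <- function(seed = 42, duration_s = 60, ...) {
  key <- paste0("scene_", seed, "_", duration_s)
  cached(key, simulate_scene(duration_s = duration_s, seed = seed, ...))
}

rms <- function(x) sqrt(mean(x^2))

# logical mask of samples within +/- tol_s of any of the given event times
near_events <- function(times_axis, events, tol_s) {
  out <- rep(FALSE, length(times_axis))
  for (e in events) out <- out | abs(times_axis - e) <= tol_s
  out
}

# match detected event times against truth at a tolerance; returns
# sensitivity, precision and the per-truth-event absolute errors
match_events <- function(detected, truth, tol_s) {
  if (!length(detected) || !length(truth))
    return(list(sensitivity = 0, precision = 0, errors = numeric(0)))
  errs <- vapply(truth, function(tt) min(abs(detected - tt)), numeric(1L))
  sens <- mean(errs <= tol_s)
  prec <- mean(vapply(detected, function(d) any(abs(truth - d) <= tol_s),
                      logical(1L)))
  list(sensitivity = sens, precision = prec, errors = errs)
}

# independent brute-force sample entropy oracle (O(n^2) template counting)
sampen_brute <- function(x, m, r) {
  n <- length(x)
  A <- 0L; B <- 0L
  for (i in seq_len(n - m)) {
    for (j in seq_len(n - m)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) B <- B + 1L
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}
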