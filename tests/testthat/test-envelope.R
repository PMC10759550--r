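test_that("moving RMS/ARV match closed forms on deterministic signals", {
  # fs 2000 so the sampled |sine| means converge to the continuous values
  t <- (0:19999) / 2000
  s <- signal(2 * sin(2 * pi * 100 * t), 2000)
  mid <- 2000:18000
  expect_equal(mean(moving_rms(s)$samples[mid]), 2 / sqrt(2), tolerance = 0.02)
  expect_equal(mean(moving_arv(s)$samples[mid]), 2 * 2 / pi, tolerance = 0.02)

  z <- signal(rep(0, 1000), 1000)
  expect_true(all(moving_rms(z)$samples == 0))
  const <- signal(rep(3, 1000), 1000)
  expect_equal(moving_rms(const)$samples, rep(3, 1000))
  expect_equal(moving_median_rect(const)$samples, rep(3, 1000))
  expect_error(moving_rms(signal(rnorm(100), 1000), window_ms = 1),
               "3 samples")
})

test_that("Gaussian-noise envelopes match folded-normal theory", {
  set.seed(4)
  g <- signal(rnorm(20000, sd = 2), 1000)
  mid <- 2000:18000
  expect_equal(mean(moving_arv(g)$samples[mid]), 2 * sqrt(2 / pi),
               tolerance = 0.05)
  expect_equal(mean(moving_median_rect(g)$samples[mid]), 2 * 0.6745,
               tolerance = 0.05)
})

test_that("robustness ordering under a single large outlier", {
  sp <- numeric(5000); sp[2500] <- 100
  s <- signal(sp, 1000)
  arv_pk <- max(moving_arv(s)$samples)
  rms_pk <- max(moving_rms(s)$samples)
  med_pk <- max(moving_median_rect(s)$samples)
  expect_equal(arv_pk, 100 / 250)              # hand computation
  expect_equal(rms_pk, 100 / sqrt(250))
  expect_identical(med_pk, 0)                  # median immune to one spike
  expect_true(med_pk <= arv_pk && arv_pk <= rms_pk)
})

test_that("scale equivariance and causality contracts hold", {
  set.seed(9)
  x <- rnorm(4000) * rep(c(0, 1, 3, 0.5), each = 1000)
  s <- signal(x, 1000)
  for (f in list(moving_rms, moving_arv, moving_median_rect)) {
    e1 <- f(s)$samples
    e2 <- f(signal(2.5 * x, 1000))$samples
    expect_equal(e2, 2.5 * e1, tolerance = 1e-10)
  }
  # deterministic symmetric burst: centered peak at center, causal lags w/2
  t <- (0:4999) / 1000
  burst <- signal(exp(-((t - 2.5)^2) / (2 * 0.15^2)), 1000)
  i_cen <- which.max(moving_rms(burst, causality = "centered")$samples)
  i_cau <- which.max(moving_rms(burst, causality = "causal")$samples)
  expect_lte(abs(i_cen - 2501), 2)
  expect_equal(i_cau - i_cen, 125, tolerance = 3)
})

test_that("fsampen matches the brute-force oracle exactly", {
  set.seed(5)
  for (m in c(1L, 2L)) {
    x <- rnorm(200)
    r <- 0.25 * stats::sd(x)
    expect_equal(respemg:::.sampen_window(x, m, r), sampen_brute(x, m, r))
  }
  expect_equal(respemg:::.sampen_window(rep(3, 200), 1L, 0.1), 0)
})

test_that("fsampen envelope discriminates bursts under a fixed tolerance", {
  set.seed(6)
  n <- 20000
  amp <- rep(rep(c(1, 10), each = 2500), 4)
  x <- rnorm(n) * amp
  env <- fsampen_envelope(signal(x, 1000),
                          fsampen_params(m = 1, r_mult = 0.25,
                                         window_ms = 250, step_ms = 50))
  expect_length(env$samples, n)
  hi <- mean(env$samples[amp == 10])
  lo <- mean(env$samples[amp == 1])
  expect_gt(hi, lo)                    # fixed r makes entropy track amplitude
  expect_equal(env$method, "fsampen")
  expect_error(
    fsampen_envelope(signal(rnorm(1000), 1000), fsampen_params(window_ms = 50)),
    "100 samples")
})

test_that("noise floor estimation and baseline correction follow the rules", {
  set.seed(7)
  g <- signal(rnorm(20000, sd = 1), 1000)
  env <- moving_rms(g)
  floor5 <- estimate_noise_floor(env)
  expect_equal(floor5, as.numeric(stats::quantile(env$samples, 0.05)))
  expect_equal(estimate_noise_floor(env, 0), min(env$samples))
  const <- moving_rms(signal(rep(2, 1000), 1000))
  expect_equal(estimate_noise_floor(const, 5), 2)

  # RMS correction subtracts variance, not standard deviation
  e5 <- moving_rms(signal(rep(5, 1000), 1000))
  expect_equal(correct_baseline(e5, 3)$samples[500], 4)
  expect_identical(correct_baseline(e5, 0)$samples, e5$samples)
  expect_error(correct_baseline(correct_baseline(e5, 1), 1), "already")

  # correcting a pure-noise RMS envelope with its own floor removes most of it
  envn <- moving_rms(g)
  corr <- correct_baseline(envn, estimate_noise_floor(envn, 50))
  expect_lt(mean(corr$samples), 0.5 * mean(envn$samples))

  # ARV correction is subtractive
  ea <- moving_arv(signal(rep(5, 1000), 1000))
  expect_equal(correct_baseline(ea, 3)$samples[500], 2)
})

test_that("envelope CSV export round-trips values and metadata", {
  env <- moving_rms(signal(rnorm(1000), 1000))
  p <- file.path(tempdir(), "env.csv")
  write_envelope(env, p)
  back <- utils::read.csv(p)
  expect_equal(back$value, env$samples, tolerance = 1e-10)
  meta <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(meta$method, "rms")
  expect_equal(meta$window_ms, 250)
})
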