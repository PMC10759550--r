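# Preset processing pipelines and parameter provenance.
#
# Every filter step alters spectrum, amplitude and timing, so the exact
# chain and its parameters must travel with the results: a pipeline run
# resolves every default into an explicit provenance record, and re-running
# a provenance record reproduces the outputs bit-for-bit for deterministic
# stages.

.stage_registry <- function() {
  list(
    check_acquisition = list(category = "check",    params = list(max_flatline = 0.2)),
    highpass          = list(category = "denoise",  params = list(cutoff_hz = 20, order = 4)),
    notch_mains       = list(category = "denoise",  params = list(mains_hz = 50, q = 30)),
    detect_r_peaks    = list(category = "detector", params = list()),
    gate_ecg          = list(category = "denoise",
                             params = list(window_ms = 150, fill = "median",
                                           highpassed = TRUE)),
    wavelet_denoise   = list(category = "denoise",
                             params = list(wavelet = "db2", n_levels = NA,
                                           threshold_multiplier = 4.5,
                                           sigma_estimator = "clipped_sd")),
    moving_rms        = list(category = "envelope",
                             params = list(window_ms = 250, causality = "centered")),
    moving_arv        = list(category = "envelope",
                             params = list(window_ms = 250, causality = "centered")),
    moving_median_rect = list(category = "envelope",
                             params = list(window_ms = 250, causality = "centered")),
    fsampen_envelope  = list(category = "envelope",
                             params = list(m = 1L, r_mult = 0.25,
                                           window_ms = 250, step_ms = 50)),
    correct_baseline  = list(category = "baseline",
                             params = list(percentile = 5))
  )
}

.preset_stages <- function(preset) {
  switch(preset,
    data_check = list(
      list(stage = "check_acquisition"),
      list(stage = "highpass", params = list(cutoff_hz = 200)),
      list(stage = "moving_arv")),
    gating = list(
      list(stage = "highpass", params = list(cutoff_hz = 20)),
      list(stage = "notch_mains"),
      list(stage = "detect_r_peaks"),
      list(stage = "gate_ecg"),
      list(stage = "moving_rms"),
      list(stage = "correct_baseline")),
    wavelet = list(
      list(stage = "highpass", params = list(cutoff_hz = 0.5)),
      list(stage = "notch_mains"),
      list(stage = "wavelet_denoise"),
      list(stage = "moving_rms"),
      list(stage = "correct_baseline")),
    fsampen = list(
      list(stage = "fsampen_envelope"),
      list(stage = "correct_baseline")),
    stop("unknown preset: ", preset)
  )
}

#' Build a pipeline configuration
#'
#' A `PipelineConfig` names a preset (or a custom ordered stage list) and
#' per-stage parameter overrides.  Presets: `data_check` (high-pass up to
#' 200 Hz, then ARV -- a brute-force first look at raw data), `gating`
#' (20 Hz high-pass, notch, Pan-Tompkins, QRS gating, RMS), `wavelet`
#' (high-pass, notch, stationary wavelet denoising, RMS -- the go-to
#' pipeline), `fsampen` (fixed sample entropy directly on raw data, no ECG
#' removal stage at all), and `custom`.
#'
#' @param preset one of `"data_check"`, `"gating"`, `"wavelet"`,
#'   `"fsampen"`, `"custom"`.
#' @param channel channel label to process; default: the first EMG channel.
#' @param params named list of per-stage overrides, e.g.
#'   `list(highpass = list(cutoff_hz = 30))`.
#' @param stages for `preset = "custom"`: ordered list of
#'   `list(stage = <name>, params = <list>)`.
#' @param seed integer seed recorded in the provenance.
#' @return a `PipelineConfig`.
#' @export
pipeline_config <- function(preset = c("wavelet", "data_check", "gating",
                                       "fsampen", "custom"),
                            channel = NULL, params = list(), stages = NULL,
                            seed = NULL) {
  preset <- match.arg(preset)
  if (preset == "custom") {
    if (is.null(stages)) stop("custom preset requires a `stages` list")
  } else {
    stages <- .preset_stages(preset)
  }
  reg <- .stage_registry()
  resolved <- lapply(stages, function(st) {
    if (is.null(st$stage) || !st$stage %in% names(reg))
      stop("unknown pipeline stage: ", st$stage)
    p <- reg[[st$stage]]$params
    for (src in list(st$params, params[[st$stage]])) {
      if (!is.null(src)) for (nm in names(src)) p[[nm]] <- src[[nm]]
    }
    list(stage = st$stage, category = reg[[st$stage]]$category, params = p)
  })
  .validate_stage_order(resolved)
  structure(list(preset = preset, channel = channel, stages = resolved,
                 seed = seed),
            class = "PipelineConfig")
}

.validate_stage_order <- function(stages) {
  cats <- vapply(stages, function(s) s$category, character(1L))
  names_ <- vapply(stages, function(s) s$stage, character(1L))
  env_at <- which(cats == "envelope")
  if (!length(env_at)) stop("configuration error: pipeline has no envelope stage")
  if (length(env_at) > 1L)
    stop("configuration error: more than one envelope stage")
  if (any(cats[seq_len(env_at - 1L)] == "baseline") ||
      any(cats[-seq_len(env_at)] %in% c("denoise", "detector")))
    stop("configuration error: denoising stages must precede the envelope ",
         "stage and baseline correction must follow it")
  if ("gate_ecg" %in% names_ &&
      !"detect_r_peaks" %in% names_[seq_len(which(names_ == "gate_ecg") - 1L)])
    stop("configuration error: gate_ecg requires detect_r_peaks earlier in ",
         "the pipeline")
  invisible(TRUE)
}

#' Run a processing pipeline on a recording
#'
#' Executes the configured stage chain on the selected EMG channel and, if
#' a pressure channel is present, appends the breath-feature stage with
#' patient-ventilator timing.  All resolved parameters are returned as a
#' provenance record; [run_provenance()] re-executes it reproducibly.
#'
#' A failed `check_acquisition` stage (flatline beyond the configured
#' fraction) halts the pipeline and returns the report with
#' `halted = TRUE`.
#'
#' @param rec a `Recording`.
#' @param config a [pipeline_config()].
#' @param features compute the per-breath feature table (default TRUE)?
#' @param spectral compute per-breath spectral features (default FALSE;
#'   requires a denoised raw stage, i.e. not the fsampen preset)?
#' @return a `PipelineResult` list: `envelope`, `denoised`, `rpeaks`,
#'   `gate_mask`, `report`, `breaths`, `features`, `spectral`,
#'   `provenance`, `halted`.
#' @export
run_pipeline <- function(rec, config = pipeline_config(), features = TRUE,
                         spectral = FALSE) {
  stopifnot(inherits(rec, "Recording"), inherits(config, "PipelineConfig"))
  labs <- channel_labels(rec)
  ch <- config$channel
  if (is.null(ch)) {
    kinds <- vapply(rec$signals, function(s) s$kind, character(1L))
    ch <- labs[kinds == "emg"][1L]
    if (is.na(ch)) stop("recording has no EMG channel")
  }
  if (!ch %in% labs) stop("channel '", ch, "' not found in recording")
  sig <- rec[[ch]]
  if (!is.null(config$seed)) set.seed(config$seed)

  paw <- NULL
  kinds <- vapply(rec$signals, function(s) s$kind, character(1L))
  if (any(kinds == "pressure")) paw <- rec$signals[[which(kinds == "pressure")[1L]]]

  res <- list(halted = FALSE, report = NULL, rpeaks = NULL, gate_mask = NULL,
              envelope = NULL, denoised = NULL, breaths = NULL,
              features = NULL, spectral = NULL)
  cur <- sig
  env <- NULL
  noise_used <- NA_real_
  for (st in config$stages) {
    p <- st$params
    switch(st$stage,
      check_acquisition = {
        rep_ <- check_acquisition(cur)
        res$report <- rep_
        if (rep_$flatline_fraction > p$max_flatline) {
          res$halted <- TRUE
          res$provenance <- .make_provenance(config, sig)
          return(structure(res, class = "PipelineResult"))
        }
      },
      highpass = { cur <- highpass(cur, p$cutoff_hz, p$order) },
      notch_mains = { cur <- notch_mains(cur, p$mains_hz, p$q) },
      detect_r_peaks = { res$rpeaks <- detect_r_peaks(cur) },
      gate_ecg = {
        g <- gate_ecg(cur, res$rpeaks, p$window_ms, p$fill,
                      highpassed = isTRUE(p$highpassed))
        cur <- g$signal
        res$gate_mask <- g$mask
      },
      wavelet_denoise = {
        nl <- if (is.null(p$n_levels) || is.na(p$n_levels))
          choose_wavelet_levels(cur$fs) else p$n_levels
        cur <- wavelet_denoise(cur, wavelet_plan(p$wavelet, nl,
                                                 p$threshold_multiplier,
                                                 p$sigma_estimator))
      },
      moving_rms = { env <- moving_rms(cur, p$window_ms, p$causality) },
      moving_arv = { env <- moving_arv(cur, p$window_ms, p$causality) },
      moving_median_rect = {
        env <- moving_median_rect(cur, p$window_ms, p$causality) },
      fsampen_envelope = {
        env <- fsampen_envelope(cur, fsampen_params(p$m, p$r_mult,
                                                    p$window_ms, p$step_ms)) },
      correct_baseline = {
        noise_used <- estimate_noise_floor(env, p$percentile)
        env <- correct_baseline(env, noise_used)
      })
  }
  res$denoised <- cur
  res$envelope <- env
  if (features && !is.null(env) && isTRUE(env$baseline_corrected)) {
    noise_thr <- if (is.finite(noise_used)) noise_used else
      estimate_noise_floor(env)
    res$breaths <- detect_breaths(env, noise_thr)
    if (nrow(res$breaths))
      res$features <- breath_features(env, res$breaths, paw = paw)
    if (spectral && nrow(res$breaths) >= 3L &&
        !identical(config$preset, "fsampen")) {
      res$spectral <- tryCatch(fatigue_trend(cur, res$breaths),
                               error = function(e) NULL)
    }
  }
  res$provenance <- .make_provenance(config, sig)
  structure(res, class = "PipelineResult")
}

.make_provenance <- function(config, sig) {
  list(toolkit = "respemg",
       version = as.character(utils::packageVersion("respemg")),
       preset = config$preset,
       channel = sig$label,
       fs = sig$fs,
       seed = config$seed,
       stages = lapply(config$stages, function(st)
         list(stage = st$stage, params = st$params)))
}

#' Write a provenance record to JSON
#' @param provenance provenance list from a `PipelineResult`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(provenance, path) {
  jsonlite::write_json(provenance, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Re-run a pipeline from a provenance record
#'
#' Reconstructs the pipeline configuration from a provenance record (in
#' memory or a JSON file) and re-executes it; for deterministic stages the
#' envelope samples reproduce exactly.
#'
#' @param rec a `Recording`.
#' @param provenance provenance list or path to a provenance JSON file.
#' @param ... passed to [run_pipeline()].
#' @return a `PipelineResult`.
#' @export
run_provenance <- function(rec, provenance, ...) {
  if (is.character(provenance))
    provenance <- jsonlite::read_json(provenance, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE)
  stages <- lapply(provenance$stages, function(st)
    list(stage = st$stage, params = st$params))
  cfg <- pipeline_config("custom", channel = provenance$channel,
                         stages = stages, seed = provenance$seed)
  cfg$preset <- provenance$preset
  run_pipeline(rec, cfg, ...)
}

#' MD5 hash of envelope samples
#'
#' Convenience for provenance-reproducibility checks: hashes the envelope
#' sample values at full precision.
#'
#' @param env an `Envelope`.
#' @return hex MD5 string.
#' @export
envelope_hash <- function(env) {
  stopifnot(inherits(env, "Envelope"))
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(env$samples, f, size = 8L)
  unname(tools::md5sum(f))
}

#' Compare processing pipelines on the same recording
#'
#' Runs two or more configurations, correlates the resulting envelopes on
#' a common grid and reports onset-time differences between matched
#' breaths.  When relative timing between channels matters, the same
#' pipeline should be used for all of them; a warning lists differing
#' presets.
#'
#' @param rec a `Recording`.
#' @param configs list of two or more [pipeline_config()] objects.
#' @return list with `correlation` (matrix), `onset_differences_s` (list of
#'   per-pair matched onset deltas), `median_abs_onset_diff_s` (matrix) and
#'   `results` (the individual `PipelineResult`s).
#' @export
compare_pipelines <- function(rec, configs) {
  if (length(configs) < 2L)
    stop("compare_pipelines needs at least 2 configurations")
  presets <- vapply(configs, function(c.) c.$preset, character(1L))
  if (length(unique(presets)) > 1L)
    warning("configurations differ (", paste(presets, collapse = ", "),
            "): relative timing between their outputs mixes methods")
  results <- lapply(configs, function(cfg) run_pipeline(rec, cfg))
  envs <- lapply(results, function(r) r$envelope)
  if (any(vapply(envs, is.null, logical(1L))))
    stop("all configurations must produce an envelope")
  n <- min(vapply(envs, function(e) length(e$samples), integer(1L)))
  mat <- vapply(envs, function(e) e$samples[seq_len(n)], numeric(n))
  k <- length(configs)
  cormat <- stats::cor(mat)
  dimnames(cormat) <- list(presets, presets)
  onset_diffs <- list()
  med <- matrix(NA_real_, k, k, dimnames = list(presets, presets))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    bi <- results[[i]]$breaths; bj <- results[[j]]$breaths
    if (is.null(bi) || is.null(bj) || !nrow(bi) || !nrow(bj)) next
    d <- vapply(bi$onset_s, function(o) {
      dd <- bj$onset_s - o
      dd[which.min(abs(dd))]
    }, numeric(1L))
    keep <- abs(d) < 2
    onset_diffs[[paste(presets[i], presets[j], sep = "_vs_")]] <- d[keep]
    med[i, j] <- med[j, i] <- stats::median(abs(d[keep]))
  }
  list(correlation = cormat, onset_differences_s = onset_diffs,
       median_abs_onset_diff_s = med, results = results)
}
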