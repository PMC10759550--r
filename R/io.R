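# Recording I/O: EDF and delimited text (CSV) with a JSON provenance sidecar.
#
# The EDF code implements the European Data Format directly (fixed-width
# ASCII header, 16-bit little-endian data records): no EDF library is
# assumed.  Only the features needed for multichannel physiological
# recordings are supported -- one data record per second, per-channel
# sampling rates, physical/digital scaling.

.edf_field <- function(x, width) {
  s <- formatC(as.character(x)[1L], width = -width)
  substr(s, 1L, width)
}

.edf_num <- function(x, width) {
  s <- formatC(format(x, digits = 8, trim = TRUE, scientific = FALSE),
               width = -width)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  s
}

.kind_to_dim <- function(kind) {
  switch(kind, emg = "uV", pressure = "cmH2O", flow = "L/s", "")
}

.dim_to_kind <- function(dim, label = "") {
  dim <- trimws(dim)
  if (dim %in% c("uV", "µV", "microV")) return("emg")
  if (dim %in% c("cmH2O", "cmH20")) return("pressure")
  if (dim %in% c("L/s", "l/s")) return("flow")
  # default per contract: unlabelled channels that look like EMG are EMG
  if (grepl("emg", label, ignore.case = TRUE)) return("emg")
  "other"
}

.write_edf <- function(rec, path) {
  sigs <- rec$signals
  ns <- length(sigs)
  fss <- vapply(sigs, function(s) s$fs, numeric(1L))
  if (any(abs(fss - round(fss)) > 1e-9))
    stop("EDF output requires integer sampling rates (1 s data records)")
  fss <- as.integer(round(fss))
  durs <- vapply(sigs, duration, numeric(1L))
  nrec <- as.integer(ceiling(max(durs)))
  if (nrec < 1L) stop("nothing to write")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8L),
    .edf_field("X X X X", 80L),
    .edf_field("Startdate X X X X", 80L),
    "01.01.00", "00.00.00",
    .edf_field(256L * (ns + 1L), 8L),
    .edf_field("", 44L),
    .edf_field(nrec, 8L),
    .edf_field(1L, 8L),
    .edf_field(ns, 4L)
  )
  writeChar(hdr, con, eos = NULL)

  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    x <- sigs[[i]]$samples
    r <- range(x)
    if (diff(r) <= 0) r <- r + c(-1, 1)
    # widen a hair so extremes stay inside the digital range after rounding
    phys_min[i] <- r[1L] - diff(r) * 1e-6
    phys_max[i] <- r[2L] + diff(r) * 1e-6
  }
  field <- function(f, width) writeChar(
    paste0(vapply(seq_len(ns), f, character(1L)), collapse = ""), con, eos = NULL)
  field(function(i) .edf_field(sigs[[i]]$label, 16L), 16L)
  field(function(i) .edf_field("", 80L), 80L)
  field(function(i) .edf_field(.kind_to_dim(sigs[[i]]$kind), 8L), 8L)
  field(function(i) .edf_num(phys_min[i], 8L), 8L)
  field(function(i) .edf_num(phys_max[i], 8L), 8L)
  field(function(i) .edf_field(-32768L, 8L), 8L)
  field(function(i) .edf_field(32767L, 8L), 8L)
  field(function(i) .edf_field("", 80L), 80L)
  field(function(i) .edf_field(fss[i], 8L), 8L)
  field(function(i) .edf_field("", 32L), 32L)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- sigs[[i]]$samples
    need <- nrec * fss[i]
    if (length(x) < need) x <- c(x, rep(x[length(x)], need - length(x)))
    scale <- (32767 - (-32768)) / (phys_max[i] - phys_min[i])
    d <- round((x - phys_min[i]) * scale) - 32768
    dig[[i]] <- as.integer(pmin(32767, pmax(-32768, d)))
  }
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * fss[i] + 1L):(r * fss[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(NULL)
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  hdr_bytes <- as.integer(rd(8L))
  rd(44L)
  nrec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("not a valid EDF file: ", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), character(1L)))
  vapply(seq_len(ns), function(i) rd(80L), character(1L))          # transducer
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  vapply(seq_len(ns), function(i) rd(80L), character(1L))          # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  vapply(seq_len(ns), function(i) rd(32L), character(1L))          # reserved

  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    stop("duplicate channel labels in EDF file: ", paste(dup, collapse = ", "))
  }
  raw_ <- vector("list", ns)
  for (i in seq_len(ns)) raw_[[i]] <- integer(nrec * spr[i])
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      raw_[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- v
    }
  }
  sigs <- vector("list", ns)
  for (i in seq_len(ns)) {
    gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    x <- (raw_[[i]] - dmin_[i]) * gain + pmin_[i]
    sigs[[i]] <- signal(x, fs = spr[i] / rec_dur, label = labels[i],
                        kind = .dim_to_kind(dims[i], labels[i]))
  }
  recording(sigs)
}

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(rec, path, provenance = NULL) {
  meta <- list(
    format_version = 1L,
    channels = lapply(rec$signals, function(s)
      list(label = s$label, kind = s$kind, fs = s$fs, t0 = s$t0,
           units = .kind_to_dim(s$kind))),
    provenance = provenance
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

#' Read a multichannel recording from disk
#'
#' Supported formats: EDF/EDF+ (binary, self-describing) and delimited text
#' (comma separator, `.` decimal, UTF-8, one header row naming the
#' channels).  Text files carry no sampling rate, so CSV input requires
#' either a JSON sidecar (`<path>.json`, written by [write_recording()]) or
#' an explicit `fs` argument.  Channels with differing sampling rates are
#' preserved as-is; nothing is silently resampled.
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`; default guessed from the extension.
#' @param fs sampling rate in Hz for CSV input without a sidecar.
#' @param kinds optional named character vector mapping channel labels to
#'   kinds (`"emg"`, `"pressure"`, `"flow"`, `"other"`) for CSV input.
#' @return a `Recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs = NULL,
                           kinds = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("edf", "bdf")) "edf" else "csv"
  }
  if (format == "edf") return(.read_edf(path))

  sidecar <- .sidecar_path(path)
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 1L || nrow(df) < 1L) stop("empty CSV recording: ", path)
  labs <- colnames(df)
  if (anyDuplicated(labs))
    stop("duplicate channel labels in CSV header: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  chmeta <- list()
  if (!is.null(meta) && !is.null(meta$channels)) {
    for (cm in meta$channels) chmeta[[cm$label]] <- cm
  }
  sigs <- lapply(labs, function(lab) {
    cm <- chmeta[[lab]]
    this_fs <- if (!is.null(cm)) cm$fs else fs
    if (is.null(this_fs))
      stop("no sampling rate available for CSV channel '", lab,
           "': provide `fs` or a JSON sidecar")
    kind <- if (!is.null(kinds) && lab %in% names(kinds)) kinds[[lab]]
            else if (!is.null(cm)) cm$kind
            else .dim_to_kind("", lab)
    t0 <- if (!is.null(cm)) cm$t0 else 0
    signal(df[[lab]], fs = this_fs, label = lab, kind = kind, t0 = t0)
  })
  recording(sigs)
}

#' Write a recording to disk
#'
#' EDF output supports per-channel sampling rates; CSV output stores one
#' column per channel and therefore refuses recordings whose channels are
#' not on a common sampling rate (resample explicitly first).  Both formats
#' get a JSON sidecar (`<path>.json`) carrying channel metadata and, when
#' supplied, the full processing provenance.
#'
#' @param rec a `Recording`.
#' @param path output file path.
#' @param format `"edf"` or `"csv"`; default guessed from the extension.
#' @param provenance optional provenance list (see [pipeline_config()]) to
#'   serialize into the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv"),
                            provenance = NULL) {
  stopifnot(inherits(rec, "Recording"))
  format <- match.arg(format)
  if (length(rec$signals) == 0L) stop("empty Recording: nothing to write")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (format == "edf") {
    .write_edf(rec, path)
  } else {
    fss <- vapply(rec$signals, function(s) s$fs, numeric(1L))
    if (length(unique(fss)) != 1L)
      stop("CSV output requires all channels at a common sampling rate; ",
           "resample() the recording first")
    ns <- vapply(rec$signals, function(s) length(s$samples), integer(1L))
    n <- max(ns)
    cols <- lapply(rec$signals, function(s) {
      x <- s$samples
      if (length(x) < n) x <- c(x, rep(NA_real_, n - length(x)))
      x
    })
    df <- as.data.frame(cols, check.names = FALSE)
    colnames(df) <- channel_labels(rec)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  .write_sidecar(rec, path, provenance = provenance)
  invisible(path)
}
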