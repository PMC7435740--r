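#' Run configuration for the processing channel
#'
#' Bundles every control parameter of the chain. By default parameters are
#' restricted to the tested sets (AF window 0.8/1/1.5/2/3 s, step 25/250 ms,
#' prediction lower base 125/250/500 ms, RMS window 100/200/250/500/1000
#' ms); `allow_nonstandard = TRUE` lifts the restriction. Defaults are the
#' optimum combination: 300-600 Hz valve band, Hilbert envelope with MA 21,
#' 1-s AF window repeated every 25 ms, prediction function with a 500-ms
#' lower base, method D2 with a 500-ms RMS starting-point window and the
#' matching algorithm enabled.
#'
#' @param band `c(low, high)` band edges in Hz.
#' @param envelope `"hilbert"` or `"rectify_lowpass"`.
#' @param cutoff_hz Low-pass cutoff for the rectify path (NULL to skip).
#' @param ma_len Moving-average length for the Hilbert path (NULL, 11, 21).
#' @param D_s,K_ms,S_ms,P_TH,pf_enabled,pf_gate,lag_range_ms See
#'   [af_config()].
#' @param method `"d2"` (segmentation + matching) or `"d1"` (duplicate
#'   correction of the 250-ms series).
#' @param rms_window_ms RMS window for the D2 starting point.
#' @param maa_enabled Matching algorithm on/off (D2).
#' @param validation A [validation_params()].
#' @param eval_window_s Analysis window for the evaluation stage.
#' @param seed Seed recorded with the run.
#' @param allow_nonstandard Permit parameter values outside the tested sets.
#' @return Object of class `run_config`.
#' @export
run_config <- function(band = c(300, 600), envelope = "hilbert",
                       cutoff_hz = 50, ma_len = 21,
                       D_s = 1, K_ms = 25, S_ms = 500, P_TH = 0.1,
                       pf_enabled = TRUE, pf_gate = 0.5,
                       lag_range_ms = c(250, 1000),
                       method = "d2", rms_window_ms = 500,
                       maa_enabled = TRUE,
                       validation = validation_params(),
                       eval_window_s = c(5, 55), seed = NULL,
                       allow_nonstandard = FALSE) {
  envelope <- match.arg(envelope, c("hilbert", "rectify_lowpass"))
  method <- match.arg(method, c("d2", "d1"))
  if (!allow_nonstandard) {
    stopifnot(D_s %in% c(0.8, 1, 1.5, 2, 3), K_ms %in% c(25, 250),
              S_ms %in% c(125, 250, 500),
              rms_window_ms %in% c(100, 200, 250, 500, 1000))
    if (!is.null(cutoff_hz)) stopifnot(cutoff_hz %in% c(25, 50, 75, 100, 150))
    if (!is.null(ma_len)) stopifnot(ma_len %in% c(11, 21))
  }
  structure(list(band = band, envelope = envelope, cutoff_hz = cutoff_hz,
                 ma_len = ma_len, D_s = D_s, K_ms = K_ms, S_ms = S_ms,
                 P_TH = P_TH, pf_enabled = pf_enabled, pf_gate = pf_gate,
                 lag_range_ms = lag_range_ms, method = method,
                 rms_window_ms = rms_window_ms, maa_enabled = maa_enabled,
                 validation = validation, eval_window_s = eval_window_s,
                 seed = seed, allow_nonstandard = allow_nonstandard),
            class = "run_config")
}

#' Read a run configuration from JSON or YAML
#'
#' @param path File ending in `.json`, `.yaml` or `.yml`; keys as in
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_run_config: the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else stop("read_run_config: unsupported extension '", ext, "'")
  if (!is.null(raw$validation))
    raw$validation <- do.call(validation_params, raw$validation)
  do.call(run_config, raw)
}

#' Write a resolved run configuration to JSON
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$validation <- unclass(out$validation)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# --- signal files ---------------------------------------------------------

wav_header_info <- function(con) {
  seek(con, 0)
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_signal: not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_signal: not a RIFF/WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("read_signal: no data chunk")
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        fs = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      if (sz > 16) seek(con, sz - 16, origin = "current")
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_signal: data chunk before fmt chunk")
      fmt$data_bytes <- sz
      return(fmt)
    } else seek(con, sz + sz %% 2, origin = "current")
  }
}

#' Read a Doppler signal from disk
#'
#' Supported formats: mono WAV (16-bit PCM or 32-bit IEEE float), or raw
#' little-endian float32 accompanied by a JSON sidecar `<path>.json` with at
#' least an `fs` field. Multichannel WAV files are rejected.
#'
#' @param path Path to a `.wav` or raw `.f32`/`.raw`/`.bin` file.
#' @return A [us_record()].
#' @export
read_signal <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "wav") {
    con <- file(path, "rb")
    on.exit(close(con))
    fmt <- wav_header_info(con)
    if (fmt$channels != 1L)
      stop("read_signal: only mono WAV is supported (file has ",
           fmt$channels, " channels)")
    n <- fmt$data_bytes %/% (fmt$bits %/% 8L)
    if (fmt$audio_format == 3L && fmt$bits == 32L) {
      x <- readBin(con, "numeric", n, size = 4, endian = "little")
    } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
      x <- readBin(con, "integer", n, size = 2, endian = "little") / 32768
    } else stop("read_signal: unsupported WAV encoding (format ",
                fmt$audio_format, ", ", fmt$bits, " bits)")
    us_record(x, fmt$fs)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("read_signal: raw signal requires a JSON sidecar '", sidecar,
           "' with an fs field")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("read_signal: sidecar missing fs")
    n <- file.size(path) %/% 4L
    con <- file(path, "rb")
    on.exit(close(con))
    us_record(readBin(con, "numeric", n, size = 4, endian = "little"),
              meta$fs)
  }
}

#' Write a Doppler signal to disk
#'
#' `.wav` paths produce a mono 32-bit float WAV; any other extension
#' produces raw little-endian float32 plus a JSON sidecar `<path>.json`
#' recording `fs`, `duration` and optionally the simulation `seed`.
#'
#' @param record A [us_record()].
#' @param path Output path.
#' @param seed Optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_signal <- function(record, path, seed = NULL) {
  stopifnot(inherits(record, "us_record"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "wav") {
    con <- file(path, "wb")
    on.exit(close(con))
    n <- length(record$samples)
    writeChar("RIFF", con, eos = NULL)
    writeBin(as.integer(36 + 4 * n), con, size = 4, endian = "little")
    writeChar("WAVEfmt ", con, eos = NULL)
    writeBin(as.integer(16), con, size = 4, endian = "little")
    writeBin(as.integer(3), con, size = 2, endian = "little")   # IEEE float
    writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
    writeBin(as.integer(record$fs), con, size = 4, endian = "little")
    writeBin(as.integer(record$fs * 4), con, size = 4, endian = "little")
    writeBin(as.integer(4), con, size = 2, endian = "little")
    writeBin(as.integer(32), con, size = 2, endian = "little")
    writeChar("data", con, eos = NULL)
    writeBin(as.integer(4 * n), con, size = 4, endian = "little")
    writeBin(record$samples, con, size = 4, endian = "little")
  } else {
    con <- file(path, "wb")
    writeBin(record$samples, con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(
      list(fs = record$fs, duration = record$duration, seed = seed),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

# --- event series CSV -----------------------------------------------------

#' Write a beat event series to CSV
#'
#' Deterministic writer: columns `tau_ms,T_ms,valid`, times with 3 decimals.
#'
#' @param events A [beat_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "beat_events"))
  df <- data.frame(tau_ms = sprintf("%.3f", events$tau_ms),
                   T_ms = sprintf("%.3f", events$T_ms),
                   valid = ifelse(events$valid, "1", "0"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a beat event series from CSV
#'
#' Inverse of [write_events()]; the round trip reproduces the series exactly
#' at 3-decimal millisecond precision. Rows with non-increasing `tau_ms` are
#' reported as an error.
#'
#' @param path CSV with header `tau_ms,T_ms,valid`.
#' @param source Source tag for the resulting series.
#' @return A [beat_events()].
#' @export
read_events <- function(path, source = "reference") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tau_ms", "T_ms", "valid")
  if (!all(need %in% names(df)))
    stop("read_events: CSV must have columns tau_ms,T_ms,valid")
  if (nrow(df) == 0L) return(beat_events(source = source))
  bad <- which(diff(df$tau_ms) <= 0)
  if (length(bad))
    stop("read_events: tau_ms not strictly increasing at row(s) ",
         paste(bad + 1L, collapse = ", "))
  beat_events(tau_ms = as.numeric(df$tau_ms), T_ms = as.numeric(df$T_ms),
              valid = as.logical(df$valid == 1 | df$valid == "TRUE"),
              source = source)
}

#' Write instantaneous measurements to CSV
#'
#' Columns `t_ms,F_ms,af_peak,predicted,valid` (3-decimal times, 4-decimal
#' amplitudes).
#'
#' @param F An `instant_measurements` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(F, path) {
  stopifnot(inherits(F, "instant_measurements"))
  df <- data.frame(t_ms = sprintf("%.3f", F$t_ms),
                   F_ms = ifelse(is.na(F$F_ms), "", sprintf("%.3f", F$F_ms)),
                   af_peak = sprintf("%.4f", F$af_peak),
                   predicted = as.integer(F$predicted),
                   valid = as.integer(F$valid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
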