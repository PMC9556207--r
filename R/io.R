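#' Write an EEG recording to disk
#'
#' Two containers are supported: EDF (16-bit European Data Format, one data
#' record holding the whole recording, physical units microvolts) and CSV
#' (a `# fs: <Hz>` comment line, a header row of channel labels, one row
#' per sample). EDF quantises each channel to 16 bits over its symmetric
#' physical range, so a round trip is exact only to
#' `max(|x|) / 32767` microvolts per channel.
#'
#' @param rec An [eeg_recording].
#' @param path Output path.
#' @param format `"edf"`, `"csv"`, or `"auto"` (from the file extension).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") write_eeg_csv(rec, path) else write_eeg_edf(rec, path)
  invisible(path)
}

#' Read an EEG recording from disk
#'
#' @param path Input path (EDF or CSV as written by [write_eeg()]).
#' @param format `"edf"`, `"csv"`, or `"auto"` (from the extension).
#' @return An [eeg_recording] in microvolts.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  assert_that(file.exists(path), "file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") read_eeg_csv(path) else read_eeg_edf(path)
}

write_eeg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %.10g", rec$fs), con)
  writeLines(paste(rec$channel_labels, collapse = ","), con)
  utils::write.table(t(rec$data), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

read_eeg_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_invalid("empty file: %s", path)
  if (!grepl("^# fs:", lines[1])) {
    stop_invalid("%s line 1: expected '# fs: <Hz>' header", path)
  }
  fs <- as.numeric(sub("^# fs:\\s*", "", lines[1]))
  if (!is.finite(fs) || fs <= 0) {
    stop_invalid("%s line 1: invalid sampling rate", path)
  }
  if (length(lines) < 3) stop_invalid("%s: no samples", path)
  labels <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  nc <- length(labels)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  vals <- strsplit(body, ",", fixed = TRUE)
  data <- matrix(NA_real_, nc, length(vals))
  for (i in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[i]]))
    if (length(v) != nc || anyNA(v)) {
      stop_invalid("%s line %d: expected %d numeric fields", path, i + 2L, nc)
    }
    data[, i] <- v
  }
  eeg_recording(data, fs, labels)
}

# --- minimal EDF (16-bit) --------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

# Short decimal form guaranteed to fit the 7 characters left for digits in
# an 8-char EDF numeric field (the sign takes the eighth).
fmt_phys <- function(p) {
  s <- sprintf("%.3g", p)
  if (nchar(s) > 7) s <- sprintf("%.2g", p)
  s
}

write_eeg_edf <- function(rec, path) {
  nc <- n_channels(rec); ns <- n_samples(rec)
  # symmetric physical range, rounded up so the stored 8-char ASCII field
  # is exactly the range used for quantization
  phys_str <- vapply(pmax(apply(abs(rec$data), 1, max), 1e-6),
                     function(p) fmt_phys(signif(p * 1.01, 3)),
                     character(1))
  phys_max <- as.numeric(phys_str)
  dig <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic subject", 80),
    pad_field("bcimusic session", 80),
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * nc, 8), pad_field("", 44),
    pad_field(1, 8),                                    # one data record
    pad_field(format(ns / rec$fs, digits = 8), 8),
    pad_field(nc, 4))
  sig <- paste0(
    paste(pad_field(rec$channel_labels, 16), collapse = ""),
    paste(rep(pad_field("synthetic", 80), nc), collapse = ""),
    paste(rep(pad_field("uV", 8), nc), collapse = ""),
    paste(pad_field(paste0("-", phys_str), 8), collapse = ""),
    paste(pad_field(phys_str, 8), collapse = ""),
    paste(rep(pad_field(-dig, 8), nc), collapse = ""),
    paste(rep(pad_field(dig, 8), nc), collapse = ""),
    paste(rep(pad_field("none", 80), nc), collapse = ""),
    paste(rep(pad_field(ns, 8), nc), collapse = ""),
    paste(rep(pad_field("", 32), nc), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (ch in seq_len(nc)) {
    digital <- as.integer(pmin(pmax(
      round(rec$data[ch, ] / phys_max[ch] * dig), -dig), dig))
    writeBin(digital, con, size = 2L, endian = "little")
  }
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  if (nchar(hdr) < 256) stop_invalid("%s: truncated EDF header", path)
  n_rec <- as.integer(substr(hdr, 237, 244))
  dur <- as.numeric(substr(hdr, 245, 252))
  nc <- as.integer(substr(hdr, 253, 256))
  if (is.na(nc) || nc < 1) stop_invalid("%s byte 253: bad signal count", path)
  sig <- readChar(con, 256 * nc, useBytes = TRUE)
  fld <- function(width, offset) {
    vapply(seq_len(nc), function(i) {
      substr(sig, offset + (i - 1L) * width + 1L, offset + i * width)
    }, character(1))
  }
  labels <- trimws(fld(16, 0))
  units <- trimws(fld(8, nc * (16 + 80)))
  if (!all(toupper(units) %in% c("UV", "µV", "MICROVOLT"))) {
    stop_invalid("%s: unknown physical units '%s'", path,
                 paste(unique(units), collapse = ","))
  }
  phys_min <- as.numeric(fld(8, nc * (16 + 80 + 8)))
  phys_max <- as.numeric(fld(8, nc * (16 + 80 + 16)))
  dig_min <- as.numeric(fld(8, nc * (16 + 80 + 24)))
  dig_max <- as.numeric(fld(8, nc * (16 + 80 + 32)))
  spr <- as.integer(fld(8, nc * 216))
  data <- matrix(0, nc, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      if (length(raw) < spr[ch]) stop_invalid("%s: truncated record", path)
      scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      vals <- phys_min[ch] + (raw - dig_min[ch]) * scale
      data[ch, ((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- vals
    }
  }
  eeg_recording(data, spr[1] / dur, labels)
}

# --- model serialization ---------------------------------------------------

#' Save or load a trained model as JSON
#'
#' Serialises `cnn_model` and `gb_model` objects (including array
#' dimensions) to a single JSON file.
#'
#' @param model A `cnn_model` or `gb_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, path) {
  assert_that(inherits(model, "cnn_model") || inherits(model, "gb_model"),
              "`model` must be a cnn_model or gb_model")
  writeLines(as.character(jsonlite::serializeJSON(model, digits = NA)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  assert_that(file.exists(path), "file not found: %s", path)
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}

# --- emotion/music writers -------------------------------------------------

#' Write an emotion sequence or music segments as CSV
#'
#' `write_emotion_csv()` emits `window_index, state`; `write_music_csv()`
#' emits one row per note event with its segment index and valence.
#'
#' @param seq An `emotion_sequence`.
#' @param segments List of `music_segment`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emotion_csv <- function(seq, path) {
  utils::write.csv(data.frame(window_index = seq_along(seq$labels),
                              state = seq$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_emotion_csv
#' @export
write_music_csv <- function(segments, path) {
  rows <- do.call(rbind, lapply(segments, function(m) {
    cbind(segment_index = m$segment_index, valence = m$valence, m$events)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# --- pipeline --------------------------------------------------------------

#' Configuration for the closed-loop session pipeline
#'
#' Validates every stage's parameters before anything runs: acquisition
#' (recording or path), denoising method, trained models (objects or JSON
#' paths), ternary thresholds, the state-to-music mapping, protocol stage
#' durations and the master seed.
#'
#' @param recording An [eeg_recording] or a path readable by [read_eeg()].
#' @param cnn,gb Trained models or paths from [save_model()] (at least one).
#' @param denoise_method `"EMD"`, `"FastICA"`, `"EMD_FastICA"` or `"none"`.
#' @param line_freq_hz Mains frequency for the denoiser.
#' @param theta_lo,theta_hi Ternary decision thresholds.
#' @param mapping State-to-valence mapping, see [segment_decision()].
#' @param stages Protocol stage durations, see [schedule_protocol()].
#' @param seed Master seed: all stage randomness derives from it.
#' @param out_dir Optional output directory for CSV reports.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(recording, cnn = NULL, gb = NULL,
                            denoise_method = "EMD_FastICA",
                            line_freq_hz = 50,
                            theta_lo = 0.4, theta_hi = 0.6,
                            mapping = c(active = "positive",
                                        passive = "negative",
                                        normal = "medium"),
                            stages = NULL, seed = 1, out_dir = NULL) {
  if (is.character(recording)) recording <- read_eeg(recording)
  assert_that(inherits(recording, "eeg_recording"),
              "`recording` must be an eeg_recording or a readable path")
  if (is.character(cnn)) cnn <- load_model(cnn)
  if (is.character(gb)) gb <- load_model(gb)
  assert_that(!is.null(cnn) || !is.null(gb),
              "need at least one trained model")
  assert_that(denoise_method %in% c("EMD", "FastICA", "EMD_FastICA", "none"),
              "unknown denoise method '%s'", denoise_method)
  assert_that(theta_lo <= theta_hi,
              "`theta_lo` must not exceed `theta_hi`")
  assert_that(all(sort(names(mapping)) == sort(emotion_states)),
              "`mapping` must name all three states")
  schedule <- schedule_protocol(stages)   # validates the 45-min cap
  structure(list(recording = recording, cnn = cnn, gb = gb,
                 denoise_method = denoise_method,
                 line_freq_hz = line_freq_hz,
                 theta_lo = theta_lo, theta_hi = theta_hi,
                 mapping = mapping, schedule = schedule,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the closed-loop session pipeline
#'
#' Executes acquire -> denoise -> classify 0.5-s windows -> decide 6-s
#' music segments -> render music, logging each stage, and returns the
#' session report bundle. Deterministic under the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage log lines (default FALSE).
#' @return List: `emotion_sequence`, `valences`, `segments` (list of
#'   `music_segment`), `fragment_counts`, `schedule`, and (when `out_dir`
#'   is set) `files` with the written CSV paths.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must come from pipeline_config()")
  log_stage <- function(fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                                 sprintf(fmt, ...)))
  }
  rec <- config$recording
  log_stage("acquire: %d ch x %.1f s @ %g Hz", n_channels(rec),
            duration_s(rec), rec$fs)
  if (config$denoise_method != "none") {
    log_stage("denoise: %s (seed %s)", config$denoise_method,
              format(config$seed))
    rec <- denoise(rec, config$denoise_method,
                   line_freq_hz = config$line_freq_hz,
                   seed = derive_seed(config$seed, 11))
  }
  log_stage("classify: thresholds [%g, %g]", config$theta_lo,
            config$theta_hi)
  seq <- classify_windows(rec, config$cnn, config$gb,
                          config$theta_lo, config$theta_hi)
  valences <- segment_decision(seq, config$mapping)
  log_stage("segments: %d decisions", length(valences))
  segments <- lapply(seq_along(valences), function(i) {
    render_music(valences[i], seed = derive_seed(config$seed, 100 + i),
                 segment_index = i)
  })
  trend <- fragment_trend(list(valences))
  out <- list(emotion_sequence = seq, valences = valences,
              segments = segments, fragment_counts = trend$counts,
              schedule = config$schedule)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      emotion = write_emotion_csv(
        seq, file.path(config$out_dir, "emotion_sequence.csv")),
      music = write_music_csv(
        segments, file.path(config$out_dir, "music_events.csv")))
    utils::write.csv(trend$counts,
                     file.path(config$out_dir, "fragment_counts.csv"),
                     row.names = FALSE)
    files["counts"] <- file.path(config$out_dir, "fragment_counts.csv")
    out$files <- files
    log_stage("wrote %d report file(s) to %s", length(files),
              config$out_dir)
  }
  out
}
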