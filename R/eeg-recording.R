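#' Multi-channel EEG recording
#'
#' Container for a block of EEG: a channels-by-samples matrix in microvolts
#' plus its sampling rate and channel labels. This is the object every stage
#' of the pipeline (denoising, windowing, classification) consumes.
#'
#' @param data Numeric matrix, `n_channels x n_samples`, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of length `n_channels`. Defaults to
#'   a frontal montage naming (`FP1`, `FP2`, `FPZ`, then `CHn`).
#' @param start_time Offset of the first sample in seconds.
#'
#' @return An object of class `eeg_recording` with fields `data`, `fs`,
#'   `channel_labels`, `start_time`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), nrow = 2), fs = 250)
#' n_samples(rec)
#' duration_s(rec)
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, start_time = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  assert_that(is.matrix(data) && is.numeric(data),
              "`data` must be a numeric matrix (channels x samples)")
  assert_that(nrow(data) >= 1L && ncol(data) >= 1L,
              "recording needs at least one channel and one sample")
  assert_that(all(is.finite(data)), "recording contains non-finite values")
  assert_that(is.numeric(fs) && length(fs) == 1L && fs > 0,
              "`fs` must be a positive sampling rate in Hz")
  if (is.null(channel_labels)) {
    channel_labels <- default_montage(nrow(data))
  }
  assert_that(length(channel_labels) == nrow(data),
              "need one channel label per row of `data`")
  structure(
    list(data = unname(data), fs = as.numeric(fs),
         channel_labels = as.character(channel_labels),
         start_time = as.numeric(start_time)),
    class = "eeg_recording"
  )
}

# Default 3-channel frontal montage; extra channels get generic names.
default_montage <- function(n) {
  base <- c("FP1", "FP2", "FPZ")
  if (n <= 3L) base[seq_len(n)] else c(base, paste0("CH", seq_len(n - 3L) + 3L))
}

#' @rdname eeg_recording
#' @param x An `eeg_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname eeg_recording
#' @export
duration_s <- function(x) ncol(x$data) / x$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, duration_s(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

# Elementwise arithmetic helpers used by the simulator and the denoisers.
rec_map <- function(x, f) {
  out <- x
  out$data <- f(x$data)
  out
}

rec_add <- function(a, b) {
  stopifnot(identical(dim(a$data), dim(b$data)), a$fs == b$fs)
  out <- a
  out$data <- a$data + b$data
  out
}

#' Split a recording into fixed-length non-overlapping windows
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds (default 0.5, the width of one
#'   emotion-state marker).
#' @return List of `eeg_recording` objects, trailing partial window dropped.
#' @export
split_windows <- function(rec, window_s = 0.5) {
  wlen <- round(window_s * rec$fs)
  assert_that(wlen >= 1, "window shorter than one sample at fs = %g", rec$fs)
  nwin <- floor(n_samples(rec) / wlen)
  assert_that(nwin >= 1, "recording shorter than one %gs window", window_s)
  lapply(seq_len(nwin), function(k) {
    idx <- ((k - 1L) * wlen + 1L):(k * wlen)
    eeg_recording(rec$data[, idx, drop = FALSE], rec$fs,
                  rec$channel_labels,
                  start_time = rec$start_time + (k - 1L) * window_s)
  })
}
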