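#' Empirical mode decomposition by classic sifting
#'
#' Decomposes a 1-D signal into intrinsic mode functions (IMFs) plus a
#' residue using Huang-style sifting: cubic-spline envelopes through the
#' local extrema with mirror-symmetric boundary extension, a Cauchy-type
#' standard-deviation stopping criterion per sifting pass, and extraction
#' stopping when the residue is monotonic (fewer than two extrema of either
#' kind) or `max_imfs` is reached. By construction the IMFs and residue sum
#' back to the input exactly.
#'
#' @param signal Numeric vector, length at least 8, finite.
#' @param max_imfs Maximum number of IMFs to extract (default 10).
#' @param sd_stop Cauchy SD threshold terminating a sift (default 0.2).
#' @param max_sift Maximum sifting passes per IMF (default 10).
#'
#' @return Object of class `imf_set`: `imfs` (list of numeric vectors, fast
#'   to slow, possibly empty) and `residue`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1/250))
#' d <- sift_imfs(x)
#' length(d$imfs)
#' @export
sift_imfs <- function(signal, max_imfs = 10, sd_stop = 0.2, max_sift = 10) {
  assert_that(is.numeric(signal) && length(signal) >= 8,
              "`signal` must be numeric with length >= 8")
  assert_that(all(is.finite(signal)), "`signal` contains non-finite values")
  residue <- as.numeric(signal)
  imfs <- list()
  for (k in seq_len(max_imfs)) {
    if (is_monotonic_residue(residue)) break
    h <- residue
    for (pass in seq_len(max_sift)) {
      env <- mean_envelope(h)
      if (is.null(env)) break
      h_new <- h - env
      denom <- sum(h^2)
      sd_k <- if (denom > 0) sum((h - h_new)^2) / denom else 0
      h <- h_new
      if (sd_k < sd_stop && is_imf_like(h)) break
    }
    imfs[[length(imfs) + 1L]] <- h
    residue <- residue - h
  }
  structure(list(imfs = imfs, residue = residue), class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residue (n = %d)\n",
              length(x$imfs), length(x$residue)))
  invisible(x)
}

# Residue with fewer than 2 maxima or 2 minima cannot be sifted further.
is_monotonic_residue <- function(x) {
  ext <- local_extrema(x)
  length(ext$max_idx) < 2L || length(ext$min_idx) < 2L
}

# |#extrema - #zero crossings| <= 1, the defining IMF property.
is_imf_like <- function(x) {
  ext <- local_extrema(x)
  nz <- count_zero_crossings(x)
  ne <- length(ext$max_idx) + length(ext$min_idx)
  abs(ne - nz) <= 1L
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

local_extrema <- function(x) {
  n <- length(x)
  d <- diff(x)
  # collapse plateaus by treating zero slopes with the previous sign
  dz <- d
  for (i in seq_along(dz)) if (dz[i] == 0 && i > 1) dz[i] <- dz[i - 1]
  s <- sign(dz)
  idx <- which(diff(s) != 0) + 1L
  max_idx <- idx[s[idx - 1L] > 0]
  min_idx <- idx[s[idx - 1L] < 0]
  list(max_idx = max_idx, min_idx = min_idx)
}

# Mean of the upper and lower cubic-spline envelopes, with mirror-symmetric
# extension of the boundary extrema; NULL when too few extrema remain.
mean_envelope <- function(x) {
  n <- length(x)
  ext <- local_extrema(x)
  if (length(ext$max_idx) < 2L || length(ext$min_idx) < 2L) return(NULL)
  upper <- envelope_through(x, ext$max_idx, n)
  lower <- envelope_through(x, ext$min_idx, n)
  (upper + lower) / 2
}

envelope_through <- function(x, idx, n) {
  # mirror the two outermost extrema beyond each edge
  ti <- c(2 - idx[2], 2 - idx[1], idx, 2 * n - idx[length(idx)],
          2 * n - idx[length(idx) - 1L])
  xi <- c(x[idx[2]], x[idx[1]], x[idx],
          x[idx[length(idx)]], x[idx[length(idx) - 1L]])
  keep <- !duplicated(ti)
  stats::spline(ti[keep], xi[keep], xout = seq_len(n), method = "fmm")$y
}

# --- FastICA ---------------------------------------------------------------

#' FastICA by symmetric fixed-point iteration
#'
#' Separates linearly mixed, statistically independent sources from
#' multi-channel data: rows are centred, whitened by PCA, and an orthonormal
#' unmixing matrix is estimated by the symmetric fixed-point algorithm with
#' the tanh contrast function. Deterministic under a fixed seed (random
#' orthonormal initialisation).
#'
#' @param data Numeric matrix, channels x samples, full rank after centring.
#' @param n_components Number of components (default: number of channels;
#'   `NULL` selects the effective rank of the centred data). Requesting
#'   more components than the rank supports is an error.
#' @param tol Convergence tolerance on the unmixing update (default 1e-6).
#' @param max_iter Maximum fixed-point iterations (default 200).
#' @param seed Integer seed for the initial rotation.
#'
#' @return Object of class `ica_decomposition`: `sources` (components x
#'   samples), `unmixing` (components x components, applied to whitened
#'   data), `whitener` (components x channels), `mixing` (channels x
#'   components, the pseudo-inverse of `unmixing %*% whitener`),
#'   `center`, `converged`, `iterations`.
#' @export
fast_ica <- function(data, n_components = nrow(data), tol = 1e-6,
                     max_iter = 200, seed = 1) {
  assert_that(is.matrix(data) && is.numeric(data), "`data` must be a matrix")
  nc <- nrow(data); ns <- ncol(data)
  center <- rowMeans(data)
  xc <- data - center
  cv <- tcrossprod(xc) / ns
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (is.null(n_components)) n_components <- sum(pos)   # effective rank
  else assert_that(n_components <= nc,
                   "`n_components` cannot exceed the number of channels")
  if (sum(pos) < n_components) {
    stop_invalid("data are rank deficient: rank %d < %d requested components",
                 sum(pos), n_components)
  }
  d <- eg$values[seq_len(n_components)]
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  whitener <- diag(1 / sqrt(d), n_components) %*% t(E)
  z <- whitener %*% xc                      # whitened: cov(z) == I

  W <- with_seed(seed, random_orthonormal(n_components))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W_new <- (g %*% t(z)) / ns - diag(rowMeans(gp), n_components) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  sources <- W %*% z
  uw <- W %*% whitener                     # components x channels
  mixing <- pseudo_inverse(uw)
  structure(
    list(sources = sources, unmixing = W, whitener = whitener,
         mixing = mixing, center = center,
         converged = converged, iterations = iter),
    class = "ica_decomposition"
  )
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat(sprintf("<ica_decomposition> %d component(s), %s in %d iteration(s)\n",
              nrow(x$sources),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

random_orthonormal <- function(p) {
  qr_d <- qr(matrix(stats::rnorm(p * p), p, p))
  q <- qr.Q(qr_d)
  q * sign(diag(qr.R(qr_d)))[col(q)]
}

# W <- (W W^T)^{-1/2} W
sym_decorrelate <- function(W) {
  s <- W %*% t(W)
  eg <- eigen(s, symmetric = TRUE)
  inv_sqrt <- eg$vectors %*% diag(1 / sqrt(pmax(eg$values, 1e-12)),
                                  nrow(W)) %*% t(eg$vectors)
  inv_sqrt %*% W
}

pseudo_inverse <- function(m, rcond = 1e-10) {
  sv <- svd(m)
  keep <- sv$d > max(sv$d) * rcond
  sv$v[, keep, drop = FALSE] %*%
    diag(1 / sv$d[keep], sum(keep)) %*% t(sv$u[, keep, drop = FALSE])
}

# --- artifact-component criteria ------------------------------------------

excess_kurtosis <- function(x) {
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(0)
  mean(xc^4) / m2^2 - 3
}

# Fraction of total spectral power within +-1 Hz of `freq`.
line_power_fraction <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]^2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  tot <- sum(sp)
  if (tot == 0) return(0)
  sum(sp[abs(f - freq) <= 1]) / tot
}

# Fraction of total spectral power above `cutoff` Hz.
highband_power_fraction <- function(x, fs, cutoff) {
  n <- length(x)
  sp <- abs(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]^2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  tot <- sum(sp)
  if (tot == 0) return(0)
  sum(sp[f > cutoff]) / tot
}

# Interior of a component: drop `margin_s` seconds per side (bounded so at
# least 3/4 of the record always remains).
interior <- function(x, fs, margin_s = 0.5) {
  n <- length(x)
  m <- min(round(margin_s * fs), floor(n / 8))
  x[(m + 1L):(n - m)]
}

# Flag artifact components of a decomposition. The rejection rule has
# three parts: (a) "transient" — spike-like ocular artifacts by excess
# kurtosis; (b) "line" — mains interference by spectral concentration at
# the line frequency; (c) "hf" — broadband sensor noise by spectral
# concentration above the EEG band of interest (theta-beta, <= 30 Hz; the
# 35-Hz cutoff leaves a margin). All statistics are computed on the
# interior of the record (decomposition edge effects can masquerade as
# spiky components), and only components whose back-projected interior
# amplitude exceeds 1 uV RMS are eligible — faint background never
# qualifies as an artifact. `row_channel` (one channel id per observed
# row) enables the spatial-spread gate on the transient criterion: ocular
# artifacts project onto several channels' rows at once, whereas
# background-EEG components concentrate in a single channel.
flag_artifact_components <- function(dec, fs, line_freq_hz, kurt_thresh,
                                     line_frac_thresh,
                                     row_channel = NULL,
                                     spread_thresh = 0.25,
                                     criteria = c("transient", "line",
                                                  "hf")) {
  nk <- nrow(dec$sources)
  src_int <- lapply(seq_len(nk), function(k) {
    interior(dec$sources[k, ], fs)
  })
  rms <- vapply(seq_len(nk), function(k) {
    sqrt(max(dec$mixing[, k]^2) * stats::var(src_int[[k]]))
  }, numeric(1))
  spread_ok <- rep(TRUE, nk)
  if (!is.null(row_channel) && length(unique(row_channel)) > 1L) {
    spread_ok <- vapply(seq_len(nk), function(k) {
      e <- tapply(dec$mixing[, k]^2, row_channel, sum)
      (1 - max(e) / sum(e)) > spread_thresh
    }, logical(1))
  }
  vapply(seq_len(nk), function(k) {
    if (rms[k] <= 1) return(FALSE)
    x <- src_int[[k]]
    ("transient" %in% criteria && spread_ok[k] &&
       excess_kurtosis(x) > kurt_thresh) ||
      ("line" %in% criteria && line_freq_hz > 0 &&
         line_power_fraction(x, fs, line_freq_hz) > line_frac_thresh) ||
      ("hf" %in% criteria &&
         highband_power_fraction(x, fs, 35) > 0.6)
  }, logical(1))
}

# --- denoising paths -------------------------------------------------------

#' Denoise an EEG recording by EMD, FastICA or their combination
#'
#' Three artifact-suppression paths over a common interface:
#' \describe{
#'   \item{EMD}{per-channel sifting; leading (fast) IMFs whose correlation
#'     with the channel is below one tenth of the best IMF-channel
#'     correlation are treated as noise-dominant and dropped.}
#'   \item{FastICA}{ICA across the raw channels; components flagged as
#'     artifact (excess kurtosis above 5, or more than 60\% of spectral
#'     power within 1 Hz of the mains frequency) are zeroed and the
#'     remainder back-projected.}
#'   \item{EMD_FastICA}{per-channel sifting, all channels' IMFs stacked into
#'     one multivariate matrix, FastICA across the stack, artifact
#'     components zeroed, IMFs reconstructed and re-summed per channel.
#'     Additionally the denoised IMFs are screened with the EMD correlation
#'     rule, so both mechanisms act.}
#' }
#'
#' @param rec An [eeg_recording].
#' @param method `"EMD"`, `"FastICA"` or `"EMD_FastICA"`.
#' @param line_freq_hz Mains frequency used by the line-power criterion
#'   (default 50; 0 disables it).
#' @param max_imfs,sd_stop Passed to [sift_imfs()].
#' @param kurt_thresh,line_frac_thresh Artifact-component thresholds.
#' @param max_iter Maximum FastICA fixed-point iterations. The combined path
#'   runs ICA over the whole IMF stack (often 20+ dimensions), which needs
#'   far more iterations than channel-space ICA, hence the high default.
#' @param seed Seed for the ICA initialisation.
#'
#' @return A denoised [eeg_recording] of the same shape and sampling rate.
#' @export
denoise <- function(rec, method = c("EMD", "FastICA", "EMD_FastICA"),
                    line_freq_hz = 50, max_imfs = 10, sd_stop = 0.2,
                    kurt_thresh = 5, line_frac_thresh = 0.6,
                    max_iter = 1000, seed = 1) {
  assert_that(inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  if (length(method) == 1L && !method %in% c("EMD", "FastICA", "EMD_FastICA")) {
    stop_invalid("unknown denoising method '%s'", method)
  }
  method <- match.arg(method)
  out <- switch(method,
    EMD = denoise_emd(rec, max_imfs, sd_stop),
    FastICA = denoise_ica(rec, line_freq_hz, kurt_thresh, line_frac_thresh,
                          max_iter, seed),
    EMD_FastICA = denoise_emd_ica(rec, line_freq_hz, max_imfs, sd_stop,
                                  kurt_thresh, line_frac_thresh, max_iter,
                                  seed)
  )
  out
}

denoise_emd <- function(rec, max_imfs, sd_stop) {
  data <- rec$data
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    dec <- sift_imfs(x, max_imfs = max_imfs, sd_stop = sd_stop)
    data[ch, ] <- sum_imfs_denoised(x, dec)
  }
  out <- rec; out$data <- data; out
}

# Correlation screen: drop *leading* IMFs whose |cor| with the input is
# below max(|cor|)/10; the first IMF passing the screen and everything
# slower is kept.
sum_imfs_denoised <- function(x, dec) {
  if (!length(dec$imfs)) return(dec$residue)
  cors <- vapply(dec$imfs, function(im) {
    if (stats::sd(im) == 0 || stats::sd(x) == 0) 0
    else abs(stats::cor(im, x))
  }, numeric(1))
  thr <- max(cors) / 10
  first_keep <- which(cors >= thr)[1]
  keep <- seq_along(dec$imfs) >= first_keep
  Reduce(`+`, dec$imfs[keep], accumulate = FALSE,
         init = dec$residue)
}

denoise_ica <- function(rec, line_freq_hz, kurt_thresh, line_frac_thresh,
                        max_iter, seed) {
  dec <- fast_ica(rec$data, max_iter = max_iter, seed = seed)
  bad <- flag_artifact_components(dec, rec$fs, line_freq_hz, kurt_thresh,
                                  line_frac_thresh)
  src <- dec$sources
  src[bad, ] <- 0
  cleaned <- dec$mixing %*% src + dec$center
  out <- rec; out$data <- cleaned; out
}

# Combined path: channel-space FastICA rejection first (ocular and mains
# artifacts are spatially rank-1 across the montage, which channel ICA
# removes exactly), then per-channel EMD with a stacked-IMF ICA pass, whose
# band-separated representation exposes broadband sensor noise that channel
# ICA cannot isolate. The two stages target complementary artifact classes.
denoise_emd_ica <- function(rec, line_freq_hz, max_imfs, sd_stop,
                            kurt_thresh, line_frac_thresh, max_iter, seed) {
  nc <- n_channels(rec)
  if (nc > 1L) {
    rec <- denoise_ica(rec, line_freq_hz, kurt_thresh, line_frac_thresh,
                       max_iter, seed)
  }
  decs <- lapply(seq_len(nc), function(ch) {
    sift_imfs(rec$data[ch, ], max_imfs = max_imfs, sd_stop = sd_stop)
  })
  counts <- vapply(decs, function(d) length(d$imfs), integer(1))
  if (sum(counts) < 2L) return(denoise_emd(rec, max_imfs, sd_stop))
  # stack all channels' IMFs plus their residues: low-frequency artifact
  # energy (ocular transients) ends up partly in the residue, which must be
  # visible to the ICA to be removable
  stack <- do.call(rbind, lapply(decs, function(d) {
    rbind(do.call(rbind, d$imfs), d$residue)
  }))
  dec <- fast_ica(stack, n_components = NULL, max_iter = max_iter,
                  seed = seed)
  row_channel <- rep(seq_len(nc), times = counts + 1L)
  # the channel-space stage has already taken the spatially coherent
  # transients; this stage only rejects band-concentrated noise
  bad <- flag_artifact_components(dec, rec$fs, line_freq_hz, kurt_thresh,
                                  line_frac_thresh,
                                  row_channel = row_channel,
                                  criteria = c("line", "hf"))
  src <- dec$sources
  src[bad, ] <- 0
  cleaned_stack <- dec$mixing %*% src + dec$center

  data <- rec$data
  offset <- 0L
  for (ch in seq_len(nc)) {
    d <- decs[[ch]]
    if (counts[ch] > 0) {
      d$imfs <- lapply(seq_len(counts[ch]), function(j) {
        cleaned_stack[offset + j, ]
      })
    }
    d$residue <- cleaned_stack[offset + counts[ch] + 1L, ]
    offset <- offset + counts[ch] + 1L
    data[ch, ] <- sum_imfs_denoised(rec$data[ch, ], d)
  }
  out <- rec; out$data <- data; out
}

# --- quality metrics -------------------------------------------------------

#' Signal-to-noise improvement ratio in decibels
#'
#' The denoiser's output SNR minus its input SNR, both in dB, where SNR is
#' the ratio of mean clean-signal power to mean residual-noise power. The
#' input noise is `noisy - clean`, the output noise `denoised - clean`, so
#' positive values mean the denoiser helped. Equivalent to
#' `10*log10(P_noise_in / P_noise_out)`.
#'
#' @param clean,noisy,denoised Numeric vectors or matrices of equal shape.
#' @param saturate_db Cap returned when the output noise power is zero
#'   (perfect reconstruction); default 300 dB.
#' @return SNIR in dB.
#' @export
snir <- function(clean, noisy, denoised, saturate_db = 300) {
  clean <- as.numeric(clean); noisy <- as.numeric(noisy)
  denoised <- as.numeric(denoised)
  assert_that(length(clean) == length(noisy) &&
                length(clean) == length(denoised),
              "snir() inputs must have equal length")
  p_in <- mean((noisy - clean)^2)
  if (p_in == 0) stop_invalid("input noise power is zero: SNIR undefined")
  p_out <- mean((denoised - clean)^2)
  if (p_out == 0) return(saturate_db)
  10 * log10(p_in / p_out)
}

#' Mean energy of a signal
#'
#' Average squared amplitude, `mean(x^2)`. For an EEG trace in microvolts
#' the value is in microvolts squared (the conventional report often labels
#' this column just "energy" in microvolt units; the formula is the squared
#' one regardless).
#'
#' @param signal Non-empty numeric vector or matrix.
#' @return Mean of squared values.
#' @export
mean_energy <- function(signal) {
  signal <- as.numeric(signal)
  assert_that(length(signal) > 0, "`signal` must be non-empty")
  mean(signal^2)
}

#' Mean absolute percentage error between a reference and a reconstruction
#'
#' `100 * mean(|A - F| / |A|)` over samples. Samples where the reference
#' magnitude is below `zero_tol` are excluded from the average (with a
#' warning) because the ratio is undefined there — zero crossings are
#' ubiquitous in EEG.
#'
#' @param actual Reference signal (vector or matrix).
#' @param denoised Reconstruction, same shape.
#' @param zero_tol Exclusion threshold on `|actual|` (default 1e-6).
#' @return MAPE in percent.
#' @export
mape <- function(actual, denoised, zero_tol = 1e-6) {
  actual <- as.numeric(actual); denoised <- as.numeric(denoised)
  assert_that(length(actual) == length(denoised),
              "mape() inputs must have equal length")
  ok <- abs(actual) >= zero_tol
  if (!all(ok)) {
    warning(sprintf("mape(): %d near-zero reference sample(s) excluded",
                    sum(!ok)), call. = FALSE)
  }
  assert_that(any(ok), "all reference samples are below `zero_tol`")
  100 * mean(abs(actual[ok] - denoised[ok]) / abs(actual[ok]))
}

#' Denoising quality report for one method
#'
#' Runs one denoising path on a contaminated session and summarises it with
#' the three quality metrics: SNIR (dB), mean energy of the denoised signal
#' and MAPE against the clean ground truth.
#'
#' @param session A `session_truth` from [contaminate()].
#' @param method Denoising path, see [denoise()].
#' @param ... Further arguments to [denoise()].
#' @return Data frame row: `method`, `snir_db`, `mean_energy`, `mape_pct`.
#' @export
denoising_report <- function(session, method, ...) {
  den <- denoise(session$noisy, method = method, ...)
  data.frame(
    method = method,
    snir_db = snir(session$clean$data, session$noisy$data, den$data),
    mean_energy = mean_energy(den$data),
    mape_pct = suppressWarnings(mape(session$clean$data, den$data))
  )
}

#' Compare the three denoising paths on one session
#'
#' @inheritParams denoising_report
#' @return Data frame with one row per method (EMD, FastICA, EMD_FastICA).
#' @export
compare_denoisers <- function(session, ...) {
  do.call(rbind, lapply(c("EMD", "FastICA", "EMD_FastICA"), function(m) {
    denoising_report(session, m, ...)
  }))
}
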