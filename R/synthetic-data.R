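#' Band-amplitude profile linking emotion states to EEG rhythms
#'
#' The simulator drives each 0.5-s window's oscillatory content from its
#' hidden emotion state. By convention here an engaged/"active" state raises
#' beta power (13--30 Hz) and a withdrawn/"passive" state raises alpha power
#' (8--13 Hz); theta (4--8 Hz) stays roughly constant. The mapping only has
#' to make the states spectrally separable, not be physiologically exact.
#'
#' @return Named list: per state, a vector of band amplitudes in microvolts
#'   (`theta`, `alpha`, `beta`), plus `pink_uv`, the RMS amplitude of the
#'   1/f background.
#' @export
default_band_profile <- function() {
  list(
    active  = c(theta = 4, alpha = 4,  beta = 12),
    passive = c(theta = 4, alpha = 12, beta = 3),
    normal  = c(theta = 4, alpha = 8,  beta = 6),
    pink_uv = 2
  )
}

band_edges <- list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))

emotion_states <- c("active", "passive", "normal")

#' Generate a clean synthetic EEG session with known emotion states
#'
#' Each channel is a sum of three band-limited oscillations (theta, alpha,
#' beta) whose amplitudes switch per 0.5-s window according to the window's
#' state label, plus a 1/f pink-noise background. Oscillator frequencies and
#' phases are drawn once per channel so the signal is coherent across
#' windows; only the amplitude envelope carries the state.
#'
#' @param n_channels Number of channels (default 3: FP1, FP2, FPZ).
#' @param duration_s Total duration in seconds; must be a multiple of 0.5.
#' @param fs Sampling rate in Hz, at least 100.
#' @param state_sequence Character vector of per-window states drawn from
#'   `active`, `passive`, `normal`; length `duration_s / 0.5`. Recycled if a
#'   single value is given.
#' @param band_profile As [default_band_profile()].
#' @param seed Integer seed; fixed seed gives a bit-identical recording.
#'
#' @return An [eeg_recording] with an extra `state_labels` field.
#' @examples
#' rec <- gen_clean_eeg(3, 10, 250, rep(c("active", "passive"), each = 10),
#'                      seed = 1)
#' @export
gen_clean_eeg <- function(n_channels = 3, duration_s = 60, fs = 250,
                          state_sequence = "normal",
                          band_profile = default_band_profile(),
                          seed = 1) {
  assert_that(duration_s > 0, "`duration_s` must be positive")
  assert_that(fs >= 100, "`fs` must be at least 100 Hz")
  assert_that(abs(duration_s / 0.5 - round(duration_s / 0.5)) < 1e-9,
              "`duration_s` must be a multiple of 0.5 s")
  n_win <- as.integer(round(duration_s / 0.5))
  if (length(state_sequence) == 1L) state_sequence <- rep(state_sequence, n_win)
  assert_that(length(state_sequence) == n_win,
              "need %d state labels (one per 0.5-s window), got %d",
              n_win, length(state_sequence))
  assert_that(all(state_sequence %in% emotion_states),
              "states must be in {active, passive, normal}")

  n_samp <- as.integer(round(duration_s * fs))
  wlen <- as.integer(round(0.5 * fs))
  tt <- (seq_len(n_samp) - 1) / fs
  # per-sample amplitude envelope index
  win_of <- pmin(rep(seq_len(n_win), each = wlen), n_win)[seq_len(n_samp)]

  data <- with_seed(seed, {
    out <- matrix(0, n_channels, n_samp)
    for (ch in seq_len(n_channels)) {
      for (bn in names(band_edges)) {
        f0 <- stats::runif(1, band_edges[[bn]][1], band_edges[[bn]][2])
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- vapply(state_sequence,
                      function(s) band_profile[[s]][[bn]], numeric(1))
        out[ch, ] <- out[ch, ] + amp[win_of] * sin(2 * pi * f0 * tt + ph)
      }
      out[ch, ] <- out[ch, ] + band_profile$pink_uv * pink_noise(n_samp)
    }
    out
  })
  rec <- eeg_recording(data, fs)
  rec$state_labels <- as.character(state_sequence)
  rec
}

# 1/f-shaped background via spectral shaping of white Gaussian noise,
# normalised to unit RMS. Returns zeros when the profile amplitude is 0,
# handled by the caller multiplying by pink_uv.
pink_noise <- function(n) {
  if (n < 2) return(stats::rnorm(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))            # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)              # mirrored frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Contaminate a clean recording with known artifacts
#'
#' Adds three additive artifact classes with stored ground truth: ocular
#' blinks (Poisson-timed 400-ms raised-cosine transients, weighted toward
#' frontal channels), sinusoidal mains interference, and white sensor noise.
#' The returned session keeps clean, noisy and artifact components so that
#' denoising quality metrics can be computed against truth.
#'
#' @param clean An [eeg_recording], typically from [gen_clean_eeg()].
#' @param blink_rate_hz Mean blink rate in events per second (Poisson).
#' @param line_freq_hz Mains frequency in Hz (0 disables line noise).
#' @param noise_sd_uv White-noise standard deviation in microvolts.
#' @param seed Integer seed.
#' @param blink_amp_uv Peak blink amplitude on frontal channels (default 80).
#' @param line_amp_uv Mains amplitude in microvolts (default 10).
#'
#' @return A `session_truth` list: `clean`, `noisy`, `artifacts` (all
#'   [eeg_recording]), `state_labels`, `blink_times` (onset seconds of the
#'   ground-truth transients), and `seed`. The additivity invariant
#'   `clean + artifacts == noisy` holds to machine precision.
#' @export
contaminate <- function(clean, blink_rate_hz = 0.25, line_freq_hz = 50,
                        noise_sd_uv = 5, seed = 1,
                        blink_amp_uv = 80, line_amp_uv = 10) {
  assert_that(inherits(clean, "eeg_recording"), "`clean` must be an eeg_recording")
  assert_that(noise_sd_uv >= 0, "`noise_sd_uv` must be non-negative")
  assert_that(blink_rate_hz >= 0, "`blink_rate_hz` must be non-negative")
  fs <- clean$fs
  n <- n_samples(clean)
  nc <- n_channels(clean)
  dur <- n / fs
  tt <- (seq_len(n) - 1) / fs

  res <- with_seed(seed, {
    art <- matrix(0, nc, n)
    # ocular blinks: frontal-weighted raised cosines, 400 ms wide
    frontal_w <- ifelse(grepl("^FP", clean$channel_labels), 1, 0.35)
    n_blinks <- stats::rpois(1, blink_rate_hz * dur)
    blink_times <- sort(stats::runif(n_blinks, 0, max(dur - 0.4, 0)))
    width <- 0.4
    for (t0 in blink_times) {
      idx <- which(tt >= t0 & tt < t0 + width)
      if (!length(idx)) next
      shape <- 0.5 * (1 - cos(2 * pi * (tt[idx] - t0) / width))
      for (ch in seq_len(nc)) {
        art[ch, idx] <- art[ch, idx] + blink_amp_uv * frontal_w[ch] * shape
      }
    }
    # mains interference: common sinusoid, slightly different gain per channel
    if (line_freq_hz > 0 && line_amp_uv > 0) {
      gains <- stats::runif(nc, 0.8, 1.2)
      ph <- stats::runif(1, 0, 2 * pi)
      line <- sin(2 * pi * line_freq_hz * tt + ph)
      art <- art + line_amp_uv * gains %o% line
    }
    # white sensor noise
    if (noise_sd_uv > 0) {
      art <- art + matrix(stats::rnorm(nc * n, sd = noise_sd_uv), nc, n)
    }
    list(art = art, blink_times = blink_times)
  })

  artifacts <- eeg_recording(res$art, fs, clean$channel_labels, clean$start_time)
  noisy <- rec_add(clean, artifacts)
  structure(
    list(clean = clean, noisy = noisy, artifacts = artifacts,
         state_labels = clean$state_labels,
         blink_times = res$blink_times, seed = seed),
    class = "session_truth"
  )
}

#' @export
print.session_truth <- function(x, ...) {
  cat(sprintf("<session_truth> %d channel(s), %.1f s, %d blink(s), seed %s\n",
              n_channels(x$clean), duration_s(x$clean),
              length(x$blink_times), format(x$seed)))
  invisible(x)
}

# --- longitudinal scale-score cohorts -------------------------------------

# Per-test target means emulating a six-occasion study: the feedback group
# declines from a mild-depression baseline toward the normal range, control
# groups stay flat. Occasions are weekly; intermediate values interpolated
# linearly where the trajectory skips a week.
scale_targets <- function() {
  list(
    feedback = list(
      scl90 = c(31.4, 29.75, 28.04, 24.3, 20.75, 17.2),
      sds   = c(56.75, 55.42, 50.59, 46.5, 42.02, 37.54),
      phq9  = c(6.37, 6.0, 4.72, 3.79, 3.02, 2.24),
      sd    = c(scl90 = 3.0, sds = 2.8, phq9 = 1.1)
    ),
    depression_control = list(
      scl90 = rep(31.2, 6), sds = rep(56.6, 6), phq9 = rep(6.4, 6),
      sd = c(scl90 = 4.5, sds = 2.5, phq9 = 1.2)
    ),
    normal_control = list(
      scl90 = rep(2.6, 6), sds = rep(34.2, 6), phq9 = rep(1.25, 6),
      sd = c(scl90 = 2.8, sds = 5.5, phq9 = 1.3)
    )
  )
}

# Admissible full ranges per scale (PHQ-9 is a 0-27 sum; SDS treated as its
# 0-100 index; SCL-90 depression factor score, non-negative).
scale_ranges <- list(scl90 = c(0, 90), sds = c(0, 100), phq9 = c(0, 27))

# Baseline eligibility windows per group (group assignment criteria).
group_baseline_box <- list(
  normal_control     = list(scl90 = c(0, 8 - 1e-9), sds = c(0, 53 - 1e-9),
                            phq9 = c(0, 5 - 1e-9)),
  depression_control = list(scl90 = c(26 + 1e-9, 90), sds = c(53, 62),
                            phq9 = c(5, 9)),
  feedback           = list(scl90 = c(26 + 1e-9, 90), sds = c(53, 62),
                            phq9 = c(5, 9))
)

rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Generate a longitudinal cohort of depression-scale scores
#'
#' Draws per-subject SCL-90, SDS and PHQ-9 scores over six weekly test
#' occasions from truncated normal distributions around group trajectories:
#' a declining trajectory for the feedback-training group, flat trajectories
#' for the depression and normal control groups. Baseline draws are truncated
#' to the group's eligibility window, so every generated subject satisfies
#' the grouping criteria checked by [assign_group()].
#'
#' @param group One of `"feedback"`, `"depression_control"`,
#'   `"normal_control"`.
#' @param n_subjects Number of subjects, at least 2. Defaults to the study
#'   sizes: 4 feedback, 8 depression control, 4 normal control.
#' @param trend Scalar multiplier on the feedback group's decline: 1 is the
#'   default trajectory, 0 makes every group flat.
#' @param seed Integer seed.
#'
#' @return Data frame with columns `subject`, `group`, `test_index` (1..6),
#'   `scl90`, `sds`, `phq9`.
#' @examples
#' head(gen_scale_cohort("normal_control", 4, seed = 7))
#' @export
gen_scale_cohort <- function(group = c("feedback", "depression_control",
                                       "normal_control"),
                             n_subjects = NULL, trend = 1, seed = 1) {
  group <- match.arg(group)
  if (is.null(n_subjects)) {
    n_subjects <- c(feedback = 4L, depression_control = 8L,
                    normal_control = 4L)[[group]]
  }
  assert_that(n_subjects >= 2, "`n_subjects` must be at least 2")
  tg <- scale_targets()[[group]]
  box <- group_baseline_box[[group]]

  with_seed(seed, {
    rows <- vector("list", n_subjects * 6L)
    k <- 0L
    for (subj in seq_len(n_subjects)) {
      for (test in 1:6) {
        k <- k + 1L
        vals <- vapply(c("scl90", "sds", "phq9"), function(sc) {
          mu <- tg[[sc]][1] + trend * (tg[[sc]][test] - tg[[sc]][1])
          lim <- if (test == 1L) box[[sc]] else scale_ranges[[sc]]
          rtruncnorm(1, mu, tg$sd[[sc]], lim[1], lim[2])
        }, numeric(1))
        rows[[k]] <- data.frame(subject = sprintf("%s_%02d", group, subj),
                                group = group, test_index = test,
                                scl90 = vals[["scl90"]], sds = vals[["sds"]],
                                phq9 = vals[["phq9"]])
      }
    }
    do.call(rbind, rows)
  })
}

#' Standard contaminated benchmark session
#'
#' The fixed session configuration used throughout the package to benchmark
#' the denoising paths: a 3-channel frontal montage, 30 s at 250 Hz with a
#' random state sequence, contaminated by blinks (0.25 Hz), 50-Hz mains
#' interference (10 uV) and 5-uV white sensor noise. Thirty seconds gives
#' the IMF-stack ICA (20+ dimensions) an adequate sample count.
#'
#' @param seed Integer seed; clean signal and contamination draw from
#'   derived independent streams.
#' @return A `session_truth`, see [contaminate()].
#' @export
standard_contamination_session <- function(seed = 1) {
  states <- with_seed(derive_seed(seed, 101),
                      sample(emotion_states, 60, replace = TRUE))
  clean <- gen_clean_eeg(3, 30, 250, states, seed = derive_seed(seed, 102))
  contaminate(clean, blink_rate_hz = 0.25, line_freq_hz = 50,
              noise_sd_uv = 5, seed = derive_seed(seed, 103))
}

#' Generate the full three-group study cohort
#'
#' Convenience wrapper drawing all three groups at the study sizes
#' (4 feedback, 8 depression control, 4 normal control).
#'
#' @inheritParams gen_scale_cohort
#' @return Combined data frame, see [gen_scale_cohort()].
#' @export
gen_study_cohort <- function(trend = 1, seed = 1) {
  rbind(
    gen_scale_cohort("feedback", trend = trend, seed = derive_seed(seed, 1)),
    gen_scale_cohort("depression_control", trend = trend,
                     seed = derive_seed(seed, 2)),
    gen_scale_cohort("normal_control", trend = trend,
                     seed = derive_seed(seed, 3))
  )
}
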