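test_that("clean EEG generator honours zero profiles, determinism and labels", {
  zero_profile <- list(active = c(theta = 0, alpha = 0, beta = 0),
                       passive = c(theta = 0, alpha = 0, beta = 0),
                       normal = c(theta = 0, alpha = 0, beta = 0),
                       pink_uv = 0)
  rec0 <- gen_clean_eeg(2, 2, 100, "normal", band_profile = zero_profile,
                        seed = 3)
  expect_true(all(rec0$data == 0))

  a <- gen_clean_eeg(3, 5, 128, "active", seed = 11)
  b <- gen_clean_eeg(3, 5, 128, "active", seed = 11)
  expect_identical(a$data, b$data)
  c <- gen_clean_eeg(3, 5, 128, "active", seed = 12)
  expect_false(identical(a$data, c$data))

  expect_length(a$state_labels, 10)            # 5 s / 0.5 s
  expect_equal(length(a$state_labels) * 0.5, duration_s(a))

  expect_error(gen_clean_eeg(3, -1, 128), "positive")
  expect_error(gen_clean_eeg(3, 4, 50), "100 Hz")
  expect_error(gen_clean_eeg(3, 4.2, 128), "multiple")
})

test_that("state-dependent beta power separates active from passive windows", {
  states <- rep(c("active", "passive"), each = 60)
  rec <- gen_clean_eeg(3, 60, 250, states, seed = 21)
  # periodogram band-power oracle per 0.5-s window
  band_power <- function(x, fs, lo, hi) {
    n <- length(x)
    sp <- abs(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]^2 / n
    f <- (seq_len(floor(n / 2)) - 1) * fs / n
    sum(sp[f >= lo & f <= hi])
  }
  wins <- split_windows(rec, 0.5)
  beta <- vapply(wins, function(w) band_power(w$data[1, ], 250, 13, 30),
                 numeric(1))
  expect_gt(min(beta[states == "active"]), max(beta[states == "passive"]))
})

test_that("contamination is additive with exact ground truth", {
  clean <- gen_clean_eeg(3, 10, 250, "normal", seed = 31)
  ses <- contaminate(clean, blink_rate_hz = 0.3, line_freq_hz = 50,
                     noise_sd_uv = 4, seed = 32)
  expect_equal(ses$clean$data + ses$artifacts$data, ses$noisy$data,
               tolerance = 1e-12)
  expect_identical(ses$state_labels, clean$state_labels)

  none <- contaminate(clean, 0, 0, 0, seed = 33)
  expect_identical(none$noisy$data, clean$data)

  a <- contaminate(clean, 0.3, 50, 4, seed = 7)
  b <- contaminate(clean, 0.3, 50, 4, seed = 7)
  expect_identical(a$noisy$data, b$noisy$data)
})

test_that("white-noise variance and blink counts match their distributions", {
  clean <- gen_clean_eeg(1, 500, 200, "normal", seed = 41)  # 1e5 samples
  ses <- contaminate(clean, 0, 0, 1, seed = 42)
  v <- stats::var(as.numeric(ses$noisy$data - ses$clean$data))
  expect_lt(abs(v - 1), 0.05)

  clean2 <- gen_clean_eeg(3, 60, 128, "normal", seed = 43)
  counts <- vapply(1:8, function(s) {
    length(contaminate(clean2, 0.2, 0, 0, seed = s)$blink_times)
  }, numeric(1))
  band <- stats::qpois(c(0.005, 0.995), 0.2 * 60)   # 99% band around 12
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("scale cohorts respect group membership and trend structure", {
  nc <- gen_scale_cohort("normal_control", 4, seed = 51)
  base <- nc[nc$test_index == 1, ]
  expect_true(all(base$scl90 < 8 & base$sds < 53 & base$phq9 < 5))
  expect_equal(sort(unique(nc$test_index)), 1:6)
  expect_equal(nrow(nc), 4 * 6)

  fb <- gen_scale_cohort("feedback", 4, seed = 52)
  fb_base <- fb[fb$test_index == 1, ]
  groups <- mapply(assign_group, fb_base$scl90, fb_base$sds, fb_base$phq9,
                   MoreArgs = list(will_train = TRUE))
  expect_true(all(groups == "feedback"))

  # flat control: per-test means stay within sampling noise of each other
  dc <- gen_scale_cohort("depression_control", 8, trend = 0, seed = 53)
  means <- tapply(dc$sds, dc$test_index, mean)
  sems <- tapply(dc$sds, dc$test_index, function(x) stats::sd(x) / sqrt(8))
  expect_true(all(abs(means - means[1]) < 2 * (sems + sems[1])))

  expect_error(gen_scale_cohort("feedback", 1), "at least 2")
})

test_that("feedback cohorts decline while controls stay level", {
  co <- gen_study_cohort(seed = 61)
  rep_ <- longitudinal_report(co)
  fb <- rep_$trends[rep_$trends$group == "feedback", ]
  expect_true(all(fb$slope < 0))
})
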