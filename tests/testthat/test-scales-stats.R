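test_that("severity bands match the scoring standards and partition ranges", {
  expect_equal(classify_severity("PHQ9", 7), "mild")
  expect_equal(classify_severity("PHQ9", 0), "normal")
  expect_equal(classify_severity("SDS", 52), "normal")
  expect_equal(classify_severity("SDS", 53), "mild")
  expect_equal(classify_severity("SCL90", 26), "normal")
  expect_equal(classify_severity("SCL90", 27), "mild")
  expect_error(classify_severity("PHQ9", 28), "admissible")

  # exhaustive sweep: every admissible integer falls in exactly one band,
  # and bands are ordered without gaps
  sweep_scale <- function(scale, top, bands) {
    got <- vapply(0:top, function(s) classify_severity(scale, s),
                  character(1))
    expect_true(all(got %in% bands))
    expect_true(all(diff(match(got, bands)) >= 0))   # monotone severity
    expect_setequal(unique(got), bands)
  }
  sweep_scale("SCL90", 90, c("normal", "mild"))
  sweep_scale("SDS", 100, c("normal", "mild", "moderate",
                            "moderate_severe"))
  sweep_scale("PHQ9", 27, c("normal", "mild", "moderate",
                            "moderately_severe", "severe"))
})

test_that("group assignment applies the eligibility conjunctions", {
  expect_equal(assign_group(5, 40, 2), "normal_control")
  expect_equal(assign_group(30, 55, 7, will_train = TRUE), "feedback")
  expect_equal(assign_group(30, 55, 7, will_train = FALSE),
               "depression_control")
  expect_equal(assign_group(20, 55, 7), "ineligible")
  expect_equal(assign_group(30, 70, 7), "ineligible")
  expect_equal(assign_group(30, 55, 12), "ineligible")
})

test_that("group summaries use sample statistics", {
  co <- data.frame(subject = c("a", "b", "c", "d"),
                   group = c("g1", "g1", "g2", "g2"),
                   test_index = 1,
                   scl90 = c(1, 3, 5, 5), sds = c(50, 52, 60, 62),
                   phq9 = c(2, 4, 6, 8))
  s <- summarize_scores(co, "scl90", 1)
  expect_equal(s$mean[s$group == "g1"], 2)
  expect_equal(s$sd[s$group == "g1"], sqrt(2), tolerance = 1e-12)
  expect_equal(s$sd[s$group == "g2"], 0)

  withr::with_seed(41, x <- stats::rnorm(12))
  co2 <- data.frame(subject = letters[1:12], group = "g",
                    test_index = 1, scl90 = x, sds = 50, phq9 = 5)
  s2 <- summarize_scores(co2, "scl90", 1)
  loop_m <- sum(x) / 12
  loop_sd <- sqrt(sum((x - loop_m)^2) / 11)
  expect_equal(s2$mean, loop_m, tolerance = 1e-12)
  expect_equal(s2$sd, loop_sd, tolerance = 1e-12)

  co3 <- co[-1, ]
  expect_error(summarize_scores(co3, "scl90", 1), "fewer than 2")
})

test_that("summary-statistic t-tests agree with the reference implementation", {
  r <- t_test_from_stats(5, 1, 4, 5, 1, 4)
  expect_equal(r$t_stat, 0)
  expect_equal(r$p_two_sided, 1)

  # hand: s_p = 1, t = 10 / (1 * sqrt(1/4 + 1/4)) = 10 * sqrt(2) = 14.142
  r2 <- t_test_from_stats(10, 1, 4, 0, 1, 4, method = "pooled")
  expect_equal(r2$t_stat, 10 * sqrt(2), tolerance = 1e-12)
  expect_equal(r2$df, 6)

  # construct samples with exact summary stats and compare against t.test
  exact_sample <- function(m, s, n) {
    z <- seq_len(n)
    z <- (z - mean(z)) / stats::sd(z)
    m + s * z
  }
  withr::with_seed(42, grid <- data.frame(
    m1 = stats::runif(25, -5, 30), s1 = stats::runif(25, 0.5, 6),
    n1 = sample(3:12, 25, TRUE),
    m2 = stats::runif(25, -5, 30), s2 = stats::runif(25, 0.5, 6),
    n2 = sample(3:12, 25, TRUE)))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    x1 <- exact_sample(g$m1, g$s1, g$n1)
    x2 <- exact_sample(g$m2, g$s2, g$n2)
    for (meth in c("pooled", "welch")) {
      ref <- stats::t.test(x1, x2, var.equal = (meth == "pooled"))
      got <- t_test_from_stats(g$m1, g$s1, g$n1, g$m2, g$s2, g$n2, meth)
      expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
    }
  }

  # a baseline-style contrast between depressed and normal groups
  for (meth in c("pooled", "welch")) {
    expect_lt(t_test_from_stats(31.40, 5.10, 4, 2.74, 3.19, 4,
                                meth)$p_two_sided, 0.001)
  }

  r3 <- t_test_from_stats(3, 0, 4, 3, 0, 4)
  expect_equal(r3$p_two_sided, 1)
})

test_that("longitudinal reports expose trends and stay calibrated under the null", {
  co <- gen_study_cohort(seed = 43)
  rep_ <- longitudinal_report(co)
  fb <- rep_$trends[rep_$trends$group == "feedback", ]
  expect_true(all(fb$slope < 0))
  expect_equal(nrow(rep_$tests), 3 * 6 * 3)
  expect_true(all(rep_$tests$p >= 0 & rep_$tests$p <= 1))

  # matched draws: feedback group replaced by depression-control draws
  flat_p <- vapply(1:20, function(s) {
    a <- gen_scale_cohort("depression_control", 4, seed = 100 + s)
    b <- gen_scale_cohort("depression_control", 8, seed = 200 + s)
    sa <- summarize_scores(a, "sds", 1)
    sb <- summarize_scores(b, "sds", 1)
    t_test_from_stats(sa$mean, sa$sd, sa$n, sb$mean, sb$sd,
                      sb$n)$p_two_sided
  }, numeric(1))
  expect_gte(mean(flat_p > 0.05), 0.9)

  expect_error(longitudinal_report(co[co$group == "feedback", ]),
               "lacks group")
  expect_error(longitudinal_report(co[co$test_index < 6, ]),
               "occasion")
})
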