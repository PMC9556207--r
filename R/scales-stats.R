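#' Severity banding for the SCL-90, SDS and PHQ-9 depression scales
#'
#' Maps a scale score to its severity band. SCL-90 (depression factor) is
#' banded normal (0-26) versus mild (>26). SDS index: normal (0-52), mild
#' (53-62), moderate (63-72), moderate-severe (>72). PHQ-9: normal (0-4),
#' mild (5-9), moderate (10-14), moderately-severe (15-19), severe (20-27).
#' Non-integer scores fall in the band of the interval containing them
#' (boundaries at the conventional integer cut points).
#'
#' @param scale One of `"SCL90"`, `"SDS"`, `"PHQ9"`.
#' @param score Numeric score within the scale's admissible range
#'   (SCL-90 >= 0, SDS 0-100, PHQ-9 0-27).
#' @return Character severity band.
#' @examples
#' classify_severity("PHQ9", 7)   # "mild"
#' classify_severity("SDS", 52)   # "normal"
#' @export
classify_severity <- function(scale = c("SCL90", "SDS", "PHQ9"), score) {
  scale <- match.arg(scale)
  assert_that(is.numeric(score) && length(score) == 1L && is.finite(score),
              "`score` must be a single finite number")
  rng <- switch(scale, SCL90 = c(0, 90), SDS = c(0, 100), PHQ9 = c(0, 27))
  assert_that(score >= rng[1] && score <= rng[2],
              "%s score %g outside admissible range [%g, %g]",
              scale, score, rng[1], rng[2])
  switch(scale,
    SCL90 = if (score < 27) "normal" else "mild",
    SDS = if (score < 53) "normal"
          else if (score < 63) "mild"
          else if (score <= 72) "moderate"
          else "moderate_severe",
    PHQ9 = if (score < 5) "normal"
           else if (score < 10) "mild"
           else if (score < 15) "moderate"
           else if (score < 20) "moderately_severe"
           else "severe"
  )
}

#' Assign a subject to a study group from baseline scale scores
#'
#' Grouping criteria: normal controls score SCL-90 < 8, SDS < 53 and
#' PHQ-9 < 5; the mild-depression band (SCL-90 > 26, SDS 53-62, PHQ-9 5-9)
#' splits into the feedback-training group or the depression control group
#' according to whether the subject undergoes feedback training. Anything
#' else is ineligible for the study.
#'
#' @param scl90,sds,phq9 Baseline scores.
#' @param will_train Logical: does the subject receive feedback training?
#' @return One of `"normal_control"`, `"feedback"`, `"depression_control"`,
#'   `"ineligible"`.
#' @examples
#' assign_group(5, 40, 2)                     # normal_control
#' assign_group(30, 55, 7, will_train = TRUE) # feedback
#' @export
assign_group <- function(scl90, sds, phq9, will_train = FALSE) {
  assert_that(all(is.finite(c(scl90, sds, phq9))), "scores must be finite")
  if (scl90 < 8 && sds < 53 && phq9 < 5) return("normal_control")
  if (scl90 > 26 && sds >= 53 && sds <= 62 && phq9 >= 5 && phq9 <= 9) {
    return(if (isTRUE(will_train)) "feedback" else "depression_control")
  }
  "ineligible"
}

#' Per-group mean and standard deviation at one test occasion
#'
#' @param cohort Cohort data frame as from [gen_scale_cohort()].
#' @param scale Column name: `"scl90"`, `"sds"` or `"phq9"`.
#' @param test_index Test occasion 1..6.
#' @return Data frame: `group`, `n`, `mean`, `sd` (sample SD, n-1).
#' @export
summarize_scores <- function(cohort, scale = c("scl90", "sds", "phq9"),
                             test_index) {
  scale <- match.arg(scale)
  sub <- cohort[cohort$test_index == test_index, , drop = FALSE]
  assert_that(nrow(sub) > 0, "no rows at test_index %d", test_index)
  out <- do.call(rbind, lapply(split(sub, sub$group), function(g) {
    assert_that(nrow(g) >= 2,
                "group '%s' has fewer than 2 subjects: SD undefined",
                g$group[1])
    data.frame(group = g$group[1], n = nrow(g),
               mean = mean(g[[scale]]), sd = stats::sd(g[[scale]]))
  }))
  rownames(out) <- NULL
  out
}

#' Independent two-sample t-test from summary statistics
#'
#' Classic pooled-variance or Welch two-sample t-test computed from group
#' means, standard deviations and sizes, with a two-sided p-value.
#'
#' @param mean1,sd1,n1 First group's mean, sample SD and size (n >= 2).
#' @param mean2,sd2,n2 Second group's.
#' @param method `"pooled"` (equal-variance, df = n1+n2-2) or `"welch"`
#'   (Welch-Satterthwaite df).
#' @return List of class `t_test_result`: `t_stat`, `df`, `p_two_sided`,
#'   `method`. Degenerate input with both SDs zero and equal means returns
#'   t = 0, p = 1 by convention.
#' @examples
#' t_test_from_stats(10, 1, 4, 0, 1, 4)
#' @export
t_test_from_stats <- function(mean1, sd1, n1, mean2, sd2, n2,
                              method = c("pooled", "welch")) {
  method <- match.arg(method)
  assert_that(n1 >= 2 && n2 >= 2, "both groups need n >= 2")
  assert_that(sd1 >= 0 && sd2 >= 0, "standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) {
      return(structure(list(t_stat = 0, df = n1 + n2 - 2, p_two_sided = 1,
                            method = method), class = "t_test_result"))
    }
    return(structure(list(t_stat = Inf * sign(mean1 - mean2),
                          df = n1 + n2 - 2, p_two_sided = 0,
                          method = method), class = "t_test_result"))
  }
  if (method == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t_stat <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(list(t_stat = t_stat, df = df, p_two_sided = p, method = method),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> t = %.4f, df = %.2f, p = %.4g (%s)\n",
              x$t_stat, x$df, x$p_two_sided, x$method))
  invisible(x)
}

#' Longitudinal group comparison report
#'
#' For each scale and test occasion: per-group mean and SD, the three
#' pairwise independent t-tests (feedback vs depression control, feedback
#' vs normal control, depression vs normal control), and a per-group trend
#' flag over occasions (sign of the least-squares slope of the group means).
#'
#' @param cohort Data frame with all three groups and all 6 test occasions
#'   (columns `group`, `test_index`, `scl90`, `sds`, `phq9`).
#' @param scales Which scales to report (default all three).
#' @param method t-test flavour, see [t_test_from_stats()].
#' @return List with `summary` (data frame: scale, test_index, group, n,
#'   mean, sd), `tests` (data frame: scale, test_index, group1, group2,
#'   t_stat, df, p), and `trends` (data frame: scale, group, slope,
#'   direction).
#' @export
longitudinal_report <- function(cohort, scales = c("scl90", "sds", "phq9"),
                                method = "pooled") {
  need_groups <- c("feedback", "depression_control", "normal_control")
  missing_g <- setdiff(need_groups, unique(cohort$group))
  assert_that(length(missing_g) == 0, "cohort lacks group(s): %s",
              paste(missing_g, collapse = ", "))
  missing_t <- setdiff(1:6, unique(cohort$test_index))
  assert_that(length(missing_t) == 0, "cohort lacks test occasion(s): %s",
              paste(missing_t, collapse = ", "))

  summ <- list(); tests <- list(); trends <- list()
  pairs <- list(c("feedback", "depression_control"),
                c("feedback", "normal_control"),
                c("depression_control", "normal_control"))
  for (sc in scales) {
    for (ti in 1:6) {
      s <- summarize_scores(cohort, sc, ti)
      summ[[length(summ) + 1L]] <- cbind(scale = sc, test_index = ti, s)
      for (pr in pairs) {
        a <- s[s$group == pr[1], ]; b <- s[s$group == pr[2], ]
        tt <- t_test_from_stats(a$mean, a$sd, a$n, b$mean, b$sd, b$n,
                                method = method)
        tests[[length(tests) + 1L]] <- data.frame(
          scale = sc, test_index = ti, group1 = pr[1], group2 = pr[2],
          t_stat = tt$t_stat, df = tt$df, p = tt$p_two_sided)
      }
    }
    for (g in need_groups) {
      means <- vapply(1:6, function(ti) {
        s <- summarize_scores(cohort, sc, ti)
        s$mean[s$group == g]
      }, numeric(1))
      slope <- unname(stats::coef(stats::lm(means ~ seq_along(means)))[2])
      trends[[length(trends) + 1L]] <- data.frame(
        scale = sc, group = g, slope = slope,
        direction = if (slope < 0) "decreasing"
                    else if (slope > 0) "increasing" else "flat")
    }
  }
  list(summary = do.call(rbind, summ),
       tests = do.call(rbind, tests),
       trends = do.call(rbind, trends))
}
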