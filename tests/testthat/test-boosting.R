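test_that("the logistic link and likelihood follow their closed forms", {
  expect_equal(predict_proba(0), 0.5)
  expect_gt(predict_proba(10), 0.999)
  Fg <- seq(-6, 6, by = 0.25)
  expect_equal(predict_proba(Fg), 1 / (1 + exp(-2 * Fg)),
               tolerance = 1e-14)
  expect_equal(predict_proba(Fg) + predict_proba(-Fg), rep(1, length(Fg)),
               tolerance = 1e-14)

  y <- c(1, 0, 1, 1, 0)
  expect_equal(gb_log_likelihood(rep(0, 5), y), 5 * log(0.5))
  expect_gt(gb_log_likelihood(ifelse(y == 1, 50, -50), y), -1e-6)
  withr::with_seed(21, Fv <- stats::rnorm(5))
  loop <- 0
  for (i in 1:5) {
    p <- exp(Fv[i]) / (exp(Fv[i]) + exp(-Fv[i]))
    loop <- loop + y[i] * log(p) + (1 - y[i]) * log(1 - p)
  }
  expect_equal(gb_log_likelihood(Fv, y), loop, tolerance = 1e-12)
})

test_that("pseudo-residuals equal twice the probability gap", {
  expect_equal(pseudo_residuals(1, 0.5), 1)
  expect_equal(pseudo_residuals(0, 0.5), -1)
  expect_equal(pseudo_residuals(1, 0.9), 0.2)
  withr::with_seed(22, {
    y <- stats::rbinom(20, 1, 0.5)
    p <- stats::runif(20, 0.05, 0.95)
  })
  expect_equal(pseudo_residuals(y, p), 2 * (y - p), tolerance = 1e-14)
})

test_that("the OLS weak learner minimises SSE over time indices", {
  r <- c(1, -1, 0.5, 2)
  wl <- fit_weak_learner(lapply(r, function(v) matrix(v, 1, 1)), r)
  expect_equal(wl$a, 1)
  expect_equal(wl$sse, 0, tolerance = 1e-12)

  # orthogonal features at t = 1, collinear at t = 2 -> picks t = 2
  withr::with_seed(23, {
    rr <- stats::rnorm(20)
    v <- stats::rnorm(20)
  })
  v <- v - sum(v * rr) / sum(rr^2) * rr
  feats <- lapply(seq_along(rr), function(i) matrix(c(v[i], rr[i]), 1, 2))
  expect_equal(fit_weak_learner(feats, rr)$t, 2)

  # SSE per time index matches the normal-equations oracle
  tg <- toy_gb_features(n = 40, seed = 24)
  r2 <- withr::with_seed(25, stats::rnorm(40))
  for (t in 1:4) {
    X <- t(vapply(tg$features, function(f) f[, t], numeric(3)))
    a_or <- solve(crossprod(X), crossprod(X, r2))
    sse_or <- sum((r2 - X %*% a_or)^2)
    Xb <- lapply(tg$features, function(f) f[, t, drop = FALSE])
    wl_t <- fit_weak_learner(Xb, r2)
    expect_equal(wl_t$sse, sse_or, tolerance = 1e-8)
  }
})

test_that("the line search maximises the likelihood in gamma", {
  y <- c(1, 1, 0, 0)
  Fp <- rep(0, 4)
  expect_warning(g0 <- line_search_gamma(Fp, rep(0, 4), y), "all-zero")
  expect_equal(g0, 0)

  f_sep <- c(1, 1, -1, -1)
  g <- line_search_gamma(Fp, f_sep, y)
  expect_gt(g, 0)
  expect_gt(gb_log_likelihood(Fp + g * f_sep, y), gb_log_likelihood(Fp, y))

  withr::with_seed(26, {
    y2 <- stats::rbinom(30, 1, 0.5)
    f2 <- stats::rnorm(30)
    Fp2 <- stats::rnorm(30, sd = 0.5)
  })
  grid <- seq(-10, 10, by = 1e-4)
  ll <- vapply(grid, function(g) gb_log_likelihood(Fp2 + g * f2, y2),
               numeric(1))
  g_or <- grid[which.max(ll)]
  expect_equal(line_search_gamma(Fp2, f2, y2), g_or, tolerance = 1e-3)
})

test_that("boosting training is monotone, accurate and respects epsilon = 0", {
  tg <- toy_gb_features()
  gb <- train_gb(tg$features, tg$labels, M = 50, epsilon = 0.1)
  h <- gb$likelihood_history
  expect_true(all(diff(h) >= -1e-9))
  p <- gb_predict_proba(gb, tg$features)
  expect_gte(mean((p > 0.5) == (tg$labels == 1)), 0.95)

  gb0 <- train_gb(tg$features, tg$labels, M = 10, epsilon = 0)
  expect_length(gb0$learners, 0)
  expect_true(all(gb_predict_proba(gb0, tg$features) == 0.5))

  expect_error(train_gb(tg$features, rep(1, length(tg$labels))),
               "both classes")
})

test_that("the first learner recovers a planted projection direction", {
  withr::with_seed(27, {
    a_true <- c(1, 2, -1) / sqrt(6)
    feats <- lapply(1:200, function(i) matrix(stats::rnorm(9), 3, 3))
    sc <- vapply(feats, function(f) sum(a_true * f[, 2]), numeric(1))
    y <- as.numeric(stats::runif(200) < predict_proba(3 * sc))
  })
  gb <- train_gb(feats, y, M = 3, epsilon = 0.1)
  l1 <- gb$learners[[1]]
  expect_equal(l1$t, 2)
  cosine <- sum(l1$a * a_true) / sqrt(sum(l1$a^2))
  expect_gt(abs(cosine), 0.9)
})
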