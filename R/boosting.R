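#' Logistic link of the boosting score
#'
#' Maps the additive score F to the positive-class probability
#' `p = e^F / (e^F + e^-F)`, algebraically `logistic(2F)`; F = 0 gives the
#' preset initial probability 0.5.
#'
#' @param F Numeric score(s), finite.
#' @return Probabilities in (0, 1).
#' @export
predict_proba <- function(F) {
  assert_that(all(is.finite(F)), "`F` must be finite")
  1 / (1 + exp(-2 * F))
}

#' Bernoulli log-likelihood of boosting scores
#'
#' `L = sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` with `p_i` from
#' [predict_proba()]; probabilities are clipped at 1e-12.
#'
#' @param F_values Numeric score vector.
#' @param labels Binary labels (0/1), same length.
#' @return Log-likelihood (a scalar, non-positive).
#' @export
gb_log_likelihood <- function(F_values, labels) {
  assert_that(length(F_values) == length(labels),
              "scores and labels must have equal length")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  p <- pmin(pmax(predict_proba(F_values), 1e-12), 1 - 1e-12)
  sum(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Pseudo-residuals of the logistic loss
#'
#' The negative gradient of the loss at the current scores:
#' `2 * (y_i - p_i)`.
#'
#' @param labels Binary labels (0/1).
#' @param probs Current probabilities in (0, 1).
#' @return Residual vector.
#' @export
pseudo_residuals <- function(labels, probs) {
  assert_that(length(labels) == length(probs),
              "labels and probs must have equal length")
  assert_that(all(probs > 0 & probs < 1), "probs must lie in (0, 1)")
  2 * (labels - probs)
}

#' Fit the time-indexed OLS weak learner
#'
#' Every sample is a feature matrix with one column per time index. For
#' each candidate time index t, the coefficient vector a(t) solves the
#' least-squares problem `min_a sum_i (r_i - a' o_i(t))^2` over samples;
#' the (a, t) pair with the smallest SSE is returned, ties broken toward
#' the smallest t. A singular design at some t falls back to a ridge
#' solution (lambda = 1e-8) with a warning.
#'
#' @param features List of per-sample matrices `[n_features, n_times]`
#'   (all the same shape).
#' @param residuals Numeric vector, one per sample.
#' @return List: `a` (coefficients), `t` (chosen time index), `sse`.
#' @export
fit_weak_learner <- function(features, residuals) {
  assert_that(length(features) >= 2, "need at least 2 samples")
  assert_that(length(features) == length(residuals),
              "one residual per sample required")
  n_times <- ncol(features[[1]])
  assert_that(n_times >= 1, "need at least one time index")
  best <- NULL
  nf <- nrow(features[[1]])
  for (t in seq_len(n_times)) {
    X <- vapply(features, function(f) f[, t], numeric(nf))
    X <- if (nf == 1L) matrix(X, ncol = 1L) else t(X)
    xtx <- crossprod(X)
    xty <- crossprod(X, residuals)
    a <- tryCatch(solve(xtx, xty), error = function(e) {
      warning(sprintf(
        "singular design at time index %d: ridge fallback applied", t),
        call. = FALSE)
      solve(xtx + diag(1e-8, ncol(X)), xty)
    })
    sse <- sum((residuals - X %*% a)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(a = as.vector(a), t = t, sse = sse)
    }
  }
  best
}

#' Line search for the weak learner's weight
#'
#' Finds `gamma` maximising the log-likelihood of `F_prev + gamma * f`,
#' exploiting that the likelihood is concave in gamma for the logistic
#' link: golden-section/parabolic search on [-10, 10] refined by bisection
#' on the derivative. All-zero weak-learner outputs return gamma = 0 with
#' a warning.
#'
#' @param F_prev Current scores.
#' @param f_m_outputs Weak-learner outputs, same length.
#' @param labels Binary labels.
#' @param lower,upper Search interval (default [-10, 10]).
#' @return Scalar gamma.
#' @export
line_search_gamma <- function(F_prev, f_m_outputs, labels,
                              lower = -10, upper = 10) {
  if (all(f_m_outputs == 0)) {
    warning("all-zero weak-learner outputs: gamma = 0", call. = FALSE)
    return(0)
  }
  obj <- function(g) gb_log_likelihood(F_prev + g * f_m_outputs, labels)
  opt <- stats::optimize(obj, c(lower, upper), maximum = TRUE,
                         tol = 1e-10)
  g <- opt$maximum
  # refine by bisection on the derivative dL/dgamma = sum f_i (y_i - p_i) * 2
  dL <- function(g) {
    p <- predict_proba(F_prev + g * f_m_outputs)
    2 * sum(f_m_outputs * (labels - p))
  }
  lo <- g - 1e-3; hi <- g + 1e-3
  if (dL(lo) > 0 && dL(hi) < 0) {
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (dL(mid) > 0) lo <- mid else hi <- mid
    }
    g2 <- (lo + hi) / 2
    if (obj(g2) >= obj(g)) g <- g2
  }
  if (obj(g) < obj(0)) g <- 0       # never decrease the likelihood
  g
}

#' Train the gradient-boosting classifier
#'
#' Stagewise additive modelling of the logistic log-likelihood: starting
#' from F0 = 0 (probability 0.5), each iteration fits the time-indexed OLS
#' weak learner to the pseudo-residuals, line-searches its weight gamma,
#' and updates `F <- F + epsilon * gamma * f` with shrinkage epsilon.
#' Training stops early when the likelihood gain drops below `min_gain`.
#'
#' @param features List of per-sample feature matrices
#'   `[n_features, n_times]`, or a plain numeric matrix `[N, n_features]`
#'   (treated as one time index per sample).
#' @param labels Binary labels (0/1), both classes present.
#' @param M Maximum number of boosting iterations (default 100).
#' @param epsilon Shrinkage in (0, 1] (default 0.1). Zero is accepted and
#'   returns the initialised model unchanged.
#' @param min_gain Early-stopping threshold on the likelihood gain.
#' @return A `gb_model`: `learners` (list of `a`, `t`, `gamma`), `epsilon`,
#'   `F0`, `likelihood_history`, and the training feature shape.
#' @export
train_gb <- function(features, labels, M = 100, epsilon = 0.1,
                     min_gain = 1e-8) {
  if (is.matrix(features) && !is.list(features)) {
    features <- lapply(seq_len(nrow(features)), function(i) {
      matrix(features[i, ], ncol = 1L)
    })
  }
  labels <- as.numeric(labels)
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  assert_that(length(unique(labels)) == 2L,
              "training data must contain both classes")
  assert_that(M >= 1, "`M` must be at least 1")
  assert_that(epsilon >= 0 && epsilon <= 1, "`epsilon` must be in [0, 1]")

  N <- length(labels)
  F_cur <- rep(0, N)
  learners <- list()
  history <- gb_log_likelihood(F_cur, labels)
  if (epsilon > 0) {
    for (m in seq_len(M)) {
      p <- pmin(pmax(predict_proba(F_cur), 1e-12), 1 - 1e-12)
      r <- pseudo_residuals(labels, p)
      wl <- fit_weak_learner(features, r)
      f_out <- vapply(features, function(f) {
        sum(wl$a * f[, wl$t])
      }, numeric(1))
      gamma <- suppressWarnings(line_search_gamma(F_cur, f_out, labels))
      F_new <- F_cur + epsilon * gamma * f_out
      ll_new <- gb_log_likelihood(F_new, labels)
      gain <- ll_new - history[length(history)]
      if (gain < -1e-9) break                  # shrinkage overshoot guard
      F_cur <- F_new
      learners[[length(learners) + 1L]] <-
        list(a = wl$a, t = wl$t, gamma = gamma)
      history <- c(history, ll_new)
      if (gain < min_gain) break
    }
  }
  structure(
    list(learners = learners, epsilon = epsilon, F0 = 0,
         likelihood_history = history,
         n_features = nrow(features[[1]]), n_times = ncol(features[[1]])),
    class = "gb_model")
}

#' @export
print.gb_model <- function(x, ...) {
  cat(sprintf(
    "<gb_model> %d learner(s), shrinkage %.3g, final log-likelihood %.4f\n",
    length(x$learners), x$epsilon,
    x$likelihood_history[length(x$likelihood_history)]))
  invisible(x)
}

#' Additive score of a gradient-boosting model
#'
#' `F(o) = F0 + epsilon * sum_m gamma_m a_m' o(t_m)` for one sample.
#'
#' @param model A `gb_model`.
#' @param feature Feature matrix `[n_features, n_times]` for one sample.
#' @return Scalar score F.
#' @export
gb_score <- function(model, feature) {
  assert_that(inherits(model, "gb_model"), "`model` must be a gb_model")
  if (is.vector(feature)) feature <- matrix(feature, ncol = 1L)
  s <- model$F0
  for (l in model$learners) {
    s <- s + model$epsilon * l$gamma * sum(l$a * feature[, l$t])
  }
  s
}

#' Positive-class probabilities from a gradient-boosting model
#'
#' @param model A `gb_model`.
#' @param features List of per-sample feature matrices, or a numeric matrix
#'   `[N, n_features]` (one time index).
#' @return Probability vector.
#' @export
gb_predict_proba <- function(model, features) {
  if (is.matrix(features) && !is.list(features)) {
    features <- lapply(seq_len(nrow(features)), function(i) {
      matrix(features[i, ], ncol = 1L)
    })
  }
  predict_proba(vapply(features, function(f) gb_score(model, f),
                       numeric(1)))
}
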