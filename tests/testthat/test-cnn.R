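test_that("input tensors are an exact reshape of the recording", {
  rec <- eeg_recording(matrix(seq_len(300) / 7, nrow = 3), fs = 100)
  x <- to_input_tensor(rec)
  expect_equal(dim(x), c(3, 100, 1))
  expect_equal(as.numeric(x), as.numeric(rec$data))
  expect_true(all(to_input_tensor(rec_map(rec, function(d) d * 0)) == 0))
  back <- tensor_to_recording(x)
  expect_identical(back$data, rec$data)
  expect_identical(back$fs, rec$fs)
})

test_that("convolution matches a quadruple-loop oracle and its edge cases", {
  inp <- matrix(abs(stats::rnorm(25, sd = 2)), 5, 5)
  idk <- array(1, c(1, 1, 1, 1))
  expect_equal(conv_forward(inp, idk, 0, "relu")[, , 1], inp)

  zk <- array(0, c(2, 2, 1, 3))
  out <- conv_forward(inp, zk, rep(-1, 3), "relu")
  expect_true(all(out == 0))

  withr::with_seed(7, {
    x <- matrix(stats::rnorm(25), 5, 5)
    W <- array(stats::rnorm(8), c(2, 2, 1, 2))
  })
  got <- conv_forward(x, W, c(0.3, -0.2), "linear")
  oracle <- array(0, c(4, 4, 2))
  for (f in 1:2) for (i in 1:4) for (j in 1:4) {
    s <- 0
    for (di in 0:1) for (dj in 0:1) {
      s <- s + x[i + di, j + dj] * W[di + 1, dj + 1, 1, f]
    }
    oracle[i, j, f] <- s + c(0.3, -0.2)[f]
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(conv_forward(matrix(1, 2, 2), array(1, c(3, 3, 1, 1)), 0),
               "larger")
})

test_that("pooling applies max/avg then the affine transform", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(as.numeric(pool_forward(m, 2, "max")), 4)
  expect_equal(as.numeric(pool_forward(m, 2, "avg")), 2.5)
  expect_equal(as.numeric(pool_forward(matrix(3, 2, 2), 2, "max",
                                       beta = 2, b = 1)), 7)
  expect_equal(as.numeric(pool_forward(matrix(3, 4, 4), 2, "avg",
                                       beta = 2, b = 1)),
               rep(7, 4))
})

test_that("softmax output is stable, normalised and exact", {
  expect_equal(softmax_out(c(0, 0), diag(2), c(0, 0)), c(0.5, 0.5))
  big <- softmax_out(1, matrix(c(1000, 0), 2, 1), c(0, 0))
  expect_true(all(is.finite(big)))
  expect_equal(big[1], 1, tolerance = 1e-12)
  withr::with_seed(13, z <- stats::rnorm(2, sd = 3))
  p <- softmax_out(z, diag(2), c(0, 0))
  expect_equal(p, exp(z) / sum(exp(z)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("cross-entropy matches the double-loop definition", {
  perfect <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(cross_entropy(perfect, c(1, 0)), 0)
  unif <- matrix(0.5, 2, 4)
  expect_equal(cross_entropy(unif, c(1, 0, 1, 1)), log(2))
  withr::with_seed(14, {
    p1 <- stats::runif(6, 0.05, 0.95)
    preds <- rbind(p1, 1 - p1)
    y <- stats::rbinom(6, 1, 0.5)
  })
  labs <- rbind(as.numeric(y == 1), as.numeric(y == 0))
  loop <- 0
  for (n in 1:6) for (i in 1:2) {
    loop <- loop - labs[i, n] * log(preds[i, n])
  }
  expect_equal(cross_entropy(preds, y), unname(loop) / 6,
               tolerance = 1e-12)
  expect_warning(cross_entropy(matrix(c(0, 1), 2, 1), c(1)), "clipped")
})

test_that("analytic gradients agree with central finite differences", {
  batch <- toy_gradcheck_batch()
  for (act in c("tanh", "sigmoid", "relu")) {
    for (pm in c("max", "avg")) {
      m <- toy_cnn_model(activation = act, pool_mode = pm)
      err <- bcimusic:::cnn_gradient_check(m, batch, n_per_layer = 6)
      expect_lt(err, 1e-4)
    }
  }
})

test_that("updates descend the loss and a zero rate is a no-op", {
  batch <- toy_gradcheck_batch()
  m <- toy_cnn_model()
  m$config$learning_rate <- 0
  m0 <- backward_and_update(m, batch)
  expect_identical(m0$layers, m$layers)

  m$config$learning_rate <- 0.05
  losses <- numeric(30)
  for (i in 1:30) {
    m <- backward_and_update(m, batch)
    losses[i] <- m$last_loss
  }
  expect_true(all(diff(losses) <= 1e-9))
})

test_that("training is deterministic, separable data overfit, L1 shrinks weights", {
  tw <- toy_window_set()
  cfg <- cnn_config(c(2, 40), conv_filters = c(4, 8),
                    conv_kernel = c(1, 5), fc_units = 8,
                    learning_rate = 0.05)
  m1 <- train_cnn(tw$x, tw$y, cfg, epochs = 60, seed = 1)
  m2 <- train_cnn(tw$x, tw$y, cfg, epochs = 60, seed = 1)
  expect_identical(m1$loss_history, m2$loss_history)

  preds <- vapply(tw$x, function(x) cnn_predict_proba(m1, x)[1],
                  numeric(1))
  expect_equal(mean((preds > 0.5) == (tw$y == 1)), 1)

  cfg_l1 <- cnn_config(c(2, 40), conv_filters = c(4, 8),
                       conv_kernel = c(1, 5), fc_units = 8,
                       learning_rate = 0.05, l1_lambda = 0.01)
  m3 <- train_cnn(tw$x, tw$y, cfg_l1, epochs = 60, seed = 1)
  sum_abs <- function(m) {
    sum(vapply(m$layers, function(ly) {
      if (!is.null(ly$W)) sum(abs(ly$W)) else 0
    }, numeric(1)))
  }
  expect_lt(sum_abs(m3), sum_abs(m1))

  expect_error(train_cnn(tw$x, rep(1, length(tw$y)), cfg, epochs = 1),
               "both classes")
})

test_that("dropout resamples per batch but keeps runs reproducible", {
  tw <- toy_window_set(n_per_class = 4)
  cfg <- cnn_config(c(2, 40), conv_filters = 4, conv_kernel = c(1, 5),
                    fc_units = 8, learning_rate = 0.02, dropout_p = 0.3)
  m1 <- train_cnn(tw$x, tw$y, cfg, epochs = 10, seed = 3)
  m2 <- train_cnn(tw$x, tw$y, cfg, epochs = 10, seed = 3)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_false(identical(
    m1$loss_history,
    train_cnn(tw$x, tw$y, cfg, epochs = 10, seed = 4)$loss_history))
})

test_that("the architecture validator enforces conv/pool alternation", {
  expect_silent(validate_architecture(c("conv", "pool", "conv", "pool",
                                        "fc", "softmax_out")))
  expect_error(validate_architecture(c("conv", "conv", "pool",
                                       "softmax_out")),
               "invalid architecture")
  expect_error(validate_architecture(c("pool", "conv", "softmax_out")),
               "invalid architecture")
  expect_error(validate_architecture(c("conv", "pool", "fc")),
               "invalid architecture")
  expect_error(cnn_config(c(2, 16), dropout_p = 1), "dropout")
})
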