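# Shared fixtures, all generated in code at test time.

# Tiny two-class window set: class 1 carries a fast (beta-band) tone, class
# 0 a slow one; amplitudes well above the additive noise floor.
toy_window_set <- function(n_per_class = 10, n_channels = 2, n_samples = 40,
                           seed = 5) {
  withr::with_seed(seed, {
    mk <- function(cls) {
      f <- if (cls == 1) 20 else 5
      base <- sin(2 * pi * f * seq_len(n_samples) / n_samples * 0.5)
      array(rep(base, each = n_channels) * 8 +
              stats::rnorm(n_channels * n_samples),
            c(n_channels, n_samples, 1))
    }
    y <- rep(c(1, 0), n_per_class)
    list(x = lapply(y, mk), y = y)
  })
}

# Small untrained net on 2 x 16 inputs for gradient checking.
toy_cnn_model <- function(activation = "tanh", pool_mode = "max",
                          seed = 2) {
  cfg <- cnn_config(c(2, 16), conv_filters = c(3, 4),
                    conv_kernel = c(1, 3), pool_size = c(1, 2),
                    fc_units = 5, activation = activation,
                    pool_mode = pool_mode, standardize = FALSE)
  bcimusic:::cnn_init(cfg, seed = seed)
}

toy_gradcheck_batch <- function(seed = 1, n = 6) {
  withr::with_seed(seed, {
    list(x = lapply(seq_len(n), function(i) {
      array(stats::rnorm(32), c(2, 16, 1))
    }),
    y = rep(c(1, 0), length.out = n))
  })
}

# Separable time-indexed boosting features: class signal at one (feature,
# time) cell.
toy_gb_features <- function(n = 100, seed = 7, delta = 2) {
  withr::with_seed(seed, {
    y <- rep(c(1, 0), n / 2)
    feats <- lapply(seq_len(n), function(i) {
      m <- matrix(stats::rnorm(12), 3, 4)
      m[2, 3] <- m[2, 3] + ifelse(y[i] == 1, delta, -delta)
      m
    })
    list(features = feats, labels = y)
  })
}

# An untrained boosting model scoring everything at p = 0.5.
null_gb_model <- function() {
  train_gb(matrix(c(0, 1, 0, 1), ncol = 1), c(0, 1, 0, 1), M = 1,
           epsilon = 0)
}
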