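#' Scaled synthetic window-classification benchmark
#'
#' The package's stand-in for a study-scale evaluation: several synthetic
#' training sessions with alternating engaged/withdrawn state blocks are
#' generated, the convolutional network is trained on their 0.5-s windows
#' (with deterministic random restarts if full-batch gradient descent lands
#' in a poor optimum), the gradient-boosting classifier is stacked on the
#' network's penultimate features, and the pair is evaluated by window
#' agreement against the ground-truth states of a held-in session drawn
#' from the same generator conditions. Training across multiple sessions is
#' essential: each session draws its own oscillator frequencies, so a
#' single session lets the network memorise frequencies instead of band
#' structure.
#'
#' @param seed Master seed; every stage derives its own stream.
#' @param n_train_sessions Training sessions (default 8).
#' @param session_s Session length in seconds (default 60).
#' @param fs Sampling rate (default 128).
#' @param epochs Training epochs per attempt (default 60).
#' @param restarts Maximum extra training attempts when training-set
#'   accuracy stays below `min_train_acc` (default 3).
#' @param min_train_acc Training-set accuracy required to accept a trained
#'   network (default 0.98).
#' @return List: `agreement` (fraction of correctly labelled test
#'   windows), `sequence` (the predicted `emotion_sequence`), `truth`
#'   (true labels), `cnn`, `gb`, `train_accuracy`.
#' @export
window_benchmark <- function(seed = 1, n_train_sessions = 8,
                             session_s = 60, fs = 128, epochs = 60,
                             restarts = 3, min_train_acc = 0.98) {
  n_blocks <- round(session_s / 6)
  states_blk <- rep(rep(c("active", "passive"), each = 6),
                    length.out = n_blocks * 12)
  trains <- lapply(seq_len(n_train_sessions), function(k) {
    gen_clean_eeg(3, session_s, fs, states_blk,
                  seed = derive_seed(seed, 300 + k))
  })
  xs <- unlist(lapply(trains, function(r) {
    lapply(split_windows(r, 0.5), to_input_tensor)
  }), recursive = FALSE)
  ys <- rep(as.numeric(states_blk == "active"), n_train_sessions)

  wlen <- round(0.5 * fs)
  cfg <- cnn_config(c(3, wlen), conv_filters = c(4, 8),
                    conv_kernel = c(1, 5), fc_units = 8,
                    learning_rate = 0.05)
  cnn <- NULL
  train_acc <- 0
  for (attempt in 0:restarts) {
    cand <- train_cnn(xs, ys, cfg, epochs = epochs,
                      seed = derive_seed(seed, 310 + attempt))
    p <- vapply(xs, function(x) cnn_predict_proba(cand, x)[1], numeric(1))
    acc <- mean((p > 0.5) == (ys == 1))
    if (acc > train_acc) {
      cnn <- cand
      train_acc <- acc
    }
    if (train_acc >= min_train_acc) break
  }

  feats <- lapply(xs, function(x) matrix(cnn_features(cnn, x), ncol = 1))
  gb <- suppressWarnings(train_gb(feats, ys, M = 30, epsilon = 0.1))

  states_te <- rep(rep(c("passive", "active"), each = 12),
                   length.out = n_blocks * 12)
  test_rec <- gen_clean_eeg(3, session_s, fs, states_te,
                            seed = derive_seed(seed, 320))
  sq <- classify_windows(test_rec, cnn, gb)
  list(agreement = mean(sq$labels == states_te), sequence = sq,
       truth = states_te, cnn = cnn, gb = gb,
       train_accuracy = train_acc)
}
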