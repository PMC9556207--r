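#' Emotion-state sequence over 0.5-second windows
#'
#' @param labels Character vector of states in `{active, passive, normal}`.
#' @param source Where the labels came from: `"cnn"`, `"gb"`, `"combined"`
#'   or `"truth"`.
#' @return Object of class `emotion_sequence` with fixed `window_s = 0.5`.
#' @export
emotion_sequence <- function(labels, source = "truth") {
  assert_that(length(labels) >= 1, "`labels` must be non-empty")
  assert_that(all(labels %in% emotion_states),
              "labels must be in {active, passive, normal}")
  structure(list(labels = as.character(labels), window_s = 0.5,
                 source = source),
            class = "emotion_sequence")
}

#' @export
print.emotion_sequence <- function(x, ...) {
  tab <- table(factor(x$labels, levels = emotion_states))
  cat(sprintf("<emotion_sequence> %d windows x %.1f s (%s): %s\n",
              length(x$labels), x$window_s, x$source,
              paste(names(tab), tab, sep = "=", collapse = " ")))
  invisible(x)
}

#' Classify a recording into 0.5-s emotion-state windows
#'
#' Splits the recording into non-overlapping 0.5-s windows, scores each with
#' the trained classifiers, and maps the positive-state probability s to a
#' ternary label by a dual threshold: `active` if s > theta_hi, `passive` if
#' s < theta_lo, `normal` otherwise. When both a convolutional network and a
#' gradient-boosting model are supplied, the boosting model scores the
#' network's penultimate-layer features (the trained stacking used by the
#' full pipeline); either model alone is also accepted.
#'
#' @param rec An [eeg_recording] of duration at least 0.5 s.
#' @param cnn A trained `cnn_model` or NULL.
#' @param gb A trained `gb_model` or NULL (requires `cnn` unless the model
#'   was trained on raw window features).
#' @param theta_lo,theta_hi Thresholds with `0 <= theta_lo <= theta_hi <= 1`.
#' @return An `emotion_sequence`, one label per 0.5-s window.
#' @export
classify_windows <- function(rec, cnn = NULL, gb = NULL,
                             theta_lo = 0.4, theta_hi = 0.6) {
  assert_that(inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  assert_that(duration_s(rec) >= 0.5, "recording shorter than one window")
  assert_that(theta_lo <= theta_hi, "`theta_lo` must not exceed `theta_hi`")
  assert_that(!is.null(cnn) || !is.null(gb),
              "need at least one trained model")
  if (!is.null(cnn)) assert_that(inherits(cnn, "cnn_model"),
                                 "`cnn` must be a cnn_model")
  if (!is.null(gb)) assert_that(inherits(gb, "gb_model"),
                                "`gb` must be a gb_model")
  wins <- split_windows(rec, 0.5)
  s <- vapply(wins, function(w) window_score(w, cnn, gb), numeric(1))
  labels <- ifelse(s > theta_hi, "active",
                   ifelse(s < theta_lo, "passive", "normal"))
  src <- if (!is.null(cnn) && !is.null(gb)) "combined"
         else if (!is.null(cnn)) "cnn" else "gb"
  emotion_sequence(labels, source = src)
}

# Positive-state probability for one window under the available models.
# With both classifiers, the boosting model scores the network's
# penultimate features and the decision takes the more decisive of the two
# probabilities (the one further from 0.5): an undecided member never
# vetoes a confident one, while two confident members agree on separable
# windows anyway.
window_score <- function(win, cnn, gb) {
  if (!is.null(cnn) && !is.null(gb)) {
    x <- to_input_tensor(win)
    p_cnn <- cnn_predict_proba(cnn, x)[1]
    feats <- cnn_features(cnn, x)
    p_gb <- predict_proba(sum(gb_score(gb, matrix(feats, ncol = 1))))
    if (abs(p_cnn - 0.5) >= abs(p_gb - 0.5)) p_cnn else p_gb
  } else if (!is.null(cnn)) {
    cnn_predict_proba(cnn, to_input_tensor(win))[1]
  } else {
    predict_proba(sum(gb_score(gb, window_features(win))))
  }
}

# Raw fallback features for a GB model used without a CNN front end:
# per-channel values on a decimated time grid.
window_features <- function(win, n_times = 8) {
  idx <- unique(round(seq(1, n_samples(win), length.out = n_times)))
  win$data[, idx, drop = FALSE]
}

#' Decide one music valence per 6-second block of emotion windows
#'
#' Each consecutive block of 12 windows (6 s at 0.5 s per window) votes by
#' majority: mostly `active` windows select positive music, mostly `passive`
#' negative music, mostly `normal` (or any tie) medium music. A trailing
#' partial block is dropped.
#'
#' @param seq An `emotion_sequence` with at least 12 labels.
#' @param mapping Named character vector state -> valence; the default maps
#'   active to positive, passive to negative, normal to medium. Supplying an
#'   inverted (compensatory) mapping is allowed.
#' @return Character vector of valences in `{positive, medium, negative}`,
#'   one per complete block.
#' @export
segment_decision <- function(seq,
                             mapping = c(active = "positive",
                                         passive = "negative",
                                         normal = "medium")) {
  assert_that(inherits(seq, "emotion_sequence"),
              "`seq` must be an emotion_sequence")
  labels <- seq$labels
  assert_that(length(labels) >= 12, "need at least 12 windows (one block)")
  n_blocks <- floor(length(labels) / 12)
  vapply(seq_len(n_blocks), function(b) {
    block <- labels[((b - 1) * 12 + 1):(b * 12)]
    counts <- table(factor(block, levels = emotion_states))
    top <- names(counts)[counts == max(counts)]
    if (length(top) > 1) "medium" else unname(mapping[[top]])
  }, character(1))
}

#' Markers implied by a number of music segments
#'
#' Pure window accounting: each segment of `segment_s` seconds contains
#' `segment_s / window_s` emotion markers. The worked study-scale example is
#' 399 six-second segments at 0.5-s windows, i.e. 4788 markers.
#'
#' @param n_segments Non-negative integer count of segments.
#' @param segment_s Segment duration (default 6).
#' @param window_s Marker window (default 0.5); must divide `segment_s`.
#' @return Integer marker count.
#' @examples
#' marker_count(399)  # 4788
#' @export
marker_count <- function(n_segments, segment_s = 6.0, window_s = 0.5) {
  assert_that(n_segments >= 0 && n_segments == round(n_segments),
              "`n_segments` must be a non-negative integer")
  ratio <- segment_s / window_s
  assert_that(abs(ratio - round(ratio)) < 1e-9,
              "`segment_s` must be divisible by `window_s`")
  as.integer(n_segments * round(ratio))
}

# Symbolic motif tables: one note row = (pitch offset within the scale,
# velocity). Tempi give note durations filling exactly 6 s.
motif_tables <- function() {
  list(
    positive = list(bpm = 120, root = 72,
                    scale = c(0, 2, 4, 5, 7, 9, 11, 12),  # major, ascending
                    direction = 1, velocity = 96),
    negative = list(bpm = 60, root = 57,
                    scale = c(12, 10, 8, 7, 5, 3),         # minor, descending
                    direction = -1, velocity = 56),
    medium = list(bpm = 90, root = 64,
                  scale = c(0, 2, 4, 7, 9),                # pentatonic drone
                  direction = 0, velocity = 72)
  )
}

#' Render one 6-second music segment for a valence
#'
#' Produces a deterministic symbolic note list (no audio): positive valence
#' is an ascending major-mode motif at 120 bpm, negative a descending
#' minor-mode motif at 60 bpm, medium a pentatonic drone at 90 bpm. The
#' seed drives small octave/velocity variation only.
#'
#' @param valence `"positive"`, `"medium"` or `"negative"`.
#' @param seed Integer seed.
#' @param segment_index Index recorded on the segment (default 1).
#' @return Object of class `music_segment`: `valence`, `duration_s` (6),
#'   `segment_index` and `events`, a data frame with `onset_s`, `pitch`
#'   (MIDI note number), `duration_s`, `velocity`, all events inside
#'   [0, 6) s.
#' @export
render_music <- function(valence = c("positive", "medium", "negative"),
                         seed = 1, segment_index = 1L) {
  valence <- match.arg(valence)
  motif <- motif_tables()[[valence]]
  beat_s <- 60 / motif$bpm
  n_notes <- floor(6 / beat_s)
  events <- with_seed(seed, {
    oct <- sample(c(0L, 12L), 1, prob = c(0.8, 0.2))
    vel <- pmin(pmax(motif$velocity +
                       sample(-4:4, n_notes, replace = TRUE), 1), 127)
    steps <- motif$scale[(seq_len(n_notes) - 1L) %% length(motif$scale) + 1L]
    data.frame(
      onset_s = (seq_len(n_notes) - 1L) * beat_s,
      pitch = motif$root + oct + steps,
      duration_s = rep(beat_s, n_notes),
      velocity = as.integer(vel)
    )
  })
  structure(list(valence = valence, duration_s = 6.0,
                 segment_index = as.integer(segment_index), events = events),
            class = "music_segment")
}

#' @export
print.music_segment <- function(x, ...) {
  cat(sprintf("<music_segment> #%d %s, %d event(s) over %.0f s\n",
              x$segment_index, x$valence, nrow(x$events), x$duration_s))
  invisible(x)
}

#' Valence counts per trial and their trend over trials
#'
#' Counts positive/medium/negative segments per trial and fits a
#' least-squares slope over trials per valence; the sign of the slope flags
#' the direction of change (e.g. positive-music segments increasing as
#' feedback training progresses).
#'
#' @param sessions List with one element per trial; each element is a
#'   character vector of valences (or a list of `music_segment`s).
#' @return List with `counts` (data frame: trial, positive, medium,
#'   negative) and `trends` (data frame: valence, slope, direction; slope is
#'   0 when there is a single trial).
#' @export
fragment_trend <- function(sessions) {
  assert_that(length(sessions) >= 1, "need at least one trial")
  counts <- do.call(rbind, lapply(seq_along(sessions), function(i) {
    v <- sessions[[i]]
    if (is.list(v)) v <- vapply(v, function(m) m$valence, character(1))
    tab <- table(factor(v, levels = c("positive", "medium", "negative")))
    data.frame(trial = i, positive = as.integer(tab[["positive"]]),
               medium = as.integer(tab[["medium"]]),
               negative = as.integer(tab[["negative"]]))
  }))
  trends <- do.call(rbind, lapply(c("positive", "medium", "negative"),
                                  function(v) {
    y <- counts[[v]]
    slope <- if (length(y) < 2) 0
             else unname(stats::coef(stats::lm(y ~ seq_along(y)))[2])
    data.frame(valence = v, slope = slope,
               direction = if (slope > 0) "increasing"
                           else if (slope < 0) "decreasing" else "flat")
  }))
  list(counts = counts, trends = trends)
}

#' Session protocol schedule with a 45-minute cap
#'
#' Builds the per-session stage schedule: scale rating (10 min), preparation
#' and electrode placement (3 min), breathing practice (3 min) and two
#' music-feedback exercises (13 min each) — 42 minutes by default. Any
#' configuration whose total exceeds the 45-minute session cap is rejected.
#'
#' @param stages Named numeric vector of stage durations in minutes;
#'   defaults as above. An empty or NULL value keeps the defaults.
#' @return Object of class `protocol_schedule`: `stages` (data frame with
#'   `name`, `minutes`) and `total_min`.
#' @examples
#' schedule_protocol()$total_min  # 42
#' @export
schedule_protocol <- function(stages = NULL) {
  if (is.null(stages) || length(stages) == 0) {
    stages <- c(scales = 10, preparation = 3, breathing = 3,
                feedback_1 = 13, feedback_2 = 13)
  }
  assert_that(is.numeric(stages) && !is.null(names(stages)) &&
                all(nzchar(names(stages))),
              "`stages` must be a named numeric vector of minutes")
  assert_that(all(stages > 0), "stage durations must be positive")
  total <- sum(stages)
  if (total > 45) {
    stop_invalid("schedule totals %.1f min, exceeding the 45-minute cap",
                 total)
  }
  structure(list(stages = data.frame(name = names(stages),
                                     minutes = unname(stages)),
                 total_min = total),
            class = "protocol_schedule")
}

#' @export
print.protocol_schedule <- function(x, ...) {
  cat(sprintf("<protocol_schedule> %d stage(s), %.0f min total (cap 45)\n",
              nrow(x$stages), x$total_min))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-12s %4.0f min\n", x$stages$name[i], x$stages$minutes[i]))
  }
  invisible(x)
}
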