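#' Convert an EEG recording to a network input tensor
#'
#' The recording's channels-by-samples matrix becomes a
#' `[n_channels, n_samples, 1]` array, treating the EEG block as a
#' one-plane grey image. Values are copied unchanged.
#'
#' @param rec An [eeg_recording].
#' @return Numeric array of dimension `c(n_channels, n_samples, 1)` with
#'   attributes `fs` and `channel_labels` for the inverse mapping.
#' @seealso [tensor_to_recording()]
#' @export
to_input_tensor <- function(rec) {
  assert_that(inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  x <- array(rec$data, dim = c(nrow(rec$data), ncol(rec$data), 1L))
  attr(x, "fs") <- rec$fs
  attr(x, "channel_labels") <- rec$channel_labels
  x
}

#' @rdname to_input_tensor
#' @param tensor An array produced by [to_input_tensor()].
#' @export
tensor_to_recording <- function(tensor) {
  assert_that(is.array(tensor) && length(dim(tensor)) == 3L &&
                dim(tensor)[3] == 1L,
              "`tensor` must be an [channels, samples, 1] array")
  eeg_recording(matrix(tensor, dim(tensor)[1], dim(tensor)[2]),
                fs = attr(tensor, "fs") %||% 1,
                channel_labels = attr(tensor, "channel_labels"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

activate <- function(x, kind) {
  switch(kind,
    relu = pmax(x, 0),
    sigmoid = 1 / (1 + exp(-x)),
    tanh = tanh(x),
    linear = x,
    stop_invalid("unknown activation '%s'", kind))
}

activate_grad <- function(pre, post, kind) {
  switch(kind,
    relu = (pre > 0) * 1,
    sigmoid = post * (1 - post),
    tanh = 1 - post^2,
    linear = array(1, dim = dim(pre) %||% length(pre)),
    stop_invalid("unknown activation '%s'", kind))
}

# --- convolution -----------------------------------------------------------

# Linear patch indices for valid-mode convolution on [h, w, c] maps.
im2col_indices <- function(h, w, c, kh, kw) {
  oh <- h - kh + 1L; ow <- w - kw + 1L
  assert_that(oh >= 1 && ow >= 1,
              "kernel (%d x %d) larger than input (%d x %d)", kh, kw, h, w)
  offs <- as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * h, `+`))
  offs <- as.vector(outer(offs, (seq_len(c) - 1L) * h * w, `+`))
  bases <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * h, `+`))
  list(idx = outer(offs, bases, `+`), oh = oh, ow = ow)
}

#' Convolution layer forward pass
#'
#' Valid-mode 2-D convolution with weight sharing: every output map `j` is
#' `activation(sum_i input_i * W_j + b_j)` over the input maps `i`.
#'
#' @param maps Input maps, array `[h, w, n_in]` (a plain matrix is treated
#'   as one map).
#' @param W Kernel array `[kh, kw, n_in, n_out]`.
#' @param b Bias vector, length `n_out`.
#' @param activation `"relu"`, `"sigmoid"`, `"tanh"` or `"linear"`.
#' @return Output maps `[h-kh+1, w-kw+1, n_out]`.
#' @export
conv_forward <- function(maps, W, b, activation = "relu") {
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  d <- dim(maps); kd <- dim(W)
  assert_that(length(kd) == 4L && kd[3] == d[3],
              "kernel shape must be [kh, kw, n_in, n_out] with n_in = %d",
              d[3])
  ii <- im2col_indices(d[1], d[2], d[3], kd[1], kd[2])
  cols <- matrix(maps[ii$idx], nrow = nrow(ii$idx))
  Wm <- matrix(W, nrow = kd[1] * kd[2] * kd[3], ncol = kd[4])
  pre <- crossprod(Wm, cols) + b            # [n_out, P]
  out <- activate(pre, activation)
  array(t(out), c(ii$oh, ii$ow, kd[4]))
}

conv_forward_cache <- function(maps, W, b, activation) {
  d <- dim(maps); kd <- dim(W)
  ii <- im2col_indices(d[1], d[2], d[3], kd[1], kd[2])
  cols <- matrix(maps[ii$idx], nrow = nrow(ii$idx))
  Wm <- matrix(W, nrow = kd[1] * kd[2] * kd[3], ncol = kd[4])
  pre <- crossprod(Wm, cols) + b
  post <- activate(pre, activation)
  list(out = array(t(post), c(ii$oh, ii$ow, kd[4])),
       cols = cols, idx = ii$idx, pre = pre, post = post,
       in_dim = d, Wm = Wm)
}

conv_backward <- function(dout, cache, W, activation) {
  kd <- dim(W)
  dpost <- t(matrix(dout, prod(dim(dout)[1:2]), kd[4]))   # [n_out, P]
  dpre <- dpost * activate_grad(cache$pre, cache$post, activation)
  dWm <- cache$cols %*% t(dpre)                            # [k, n_out]
  db <- rowSums(dpre)
  dcols <- cache$Wm %*% dpre                               # [k, P]
  dmaps <- array(0, cache$in_dim)
  idx <- cache$idx
  for (r in seq_len(nrow(idx))) {
    dmaps[idx[r, ]] <- dmaps[idx[r, ]] + dcols[r, ]
  }
  list(dW = array(dWm, kd), db = db, dmaps = dmaps)
}

# --- pooling ---------------------------------------------------------------

pad_to_multiple <- function(maps, ph, pw) {
  d <- dim(maps)
  H <- ceiling(d[1] / ph) * ph; W <- ceiling(d[2] / pw) * pw
  if (H == d[1] && W == d[2]) return(maps)
  out <- array(0, c(H, W, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- maps
  out
}

#' Pooling layer forward pass
#'
#' Per-window max or average pooling followed by the layer's affine
#' transform: `pool(window) * beta_j + b_j` per map `j`. Inputs whose
#' height/width are not multiples of the pool size are zero-padded on the
#' right/bottom.
#'
#' @param maps Array `[h, w, n_maps]` (matrix treated as one map).
#' @param size Pool window `c(ph, pw)` (a scalar means square).
#' @param mode `"max"` or `"avg"`.
#' @param beta Multiplier per map (default 1).
#' @param b Additive bias per map (default 0).
#' @return Pooled maps `[ceil(h/ph), ceil(w/pw), n_maps]`.
#' @export
pool_forward <- function(maps, size, mode = c("max", "avg"),
                         beta = 1, b = 0) {
  mode <- match.arg(mode)
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  if (length(size) == 1L) size <- c(size, size)
  pool_forward_cache(maps, size[1], size[2], mode,
                     rep_len(beta, dim(maps)[3]),
                     rep_len(b, dim(maps)[3]))$out
}

pool_forward_cache <- function(maps, ph, pw, mode, beta, b) {
  padded <- pad_to_multiple(maps, ph, pw)
  d <- dim(padded)
  oh <- d[1] %/% ph; ow <- d[2] %/% pw; nm <- d[3]
  # gather windows as rows: [ph*pw, oh*ow*nm], window entries ph-fastest
  wnd <- array(aperm(array(padded, c(ph, oh, pw, ow, nm)),
                     c(1, 3, 2, 4, 5)),
               c(ph * pw, oh * ow * nm))
  amax <- NULL
  if (mode == "avg") {
    raw <- array(colMeans(wnd), c(oh, ow, nm))
  } else {
    raw <- array(do.call(pmax, asplit(wnd, 1)), c(oh, ow, nm))
    amax <- array(max.col(t(wnd), ties.method = "first"), c(oh, ow, nm))
  }
  out <- sweep(sweep(raw, 3, beta, `*`), 3, b, `+`)
  list(out = out, raw = raw, amax = amax, in_dim = dim(maps),
       pad_dim = d, ph = ph, pw = pw, mode = mode, beta = beta)
}

pool_backward <- function(dout, cache) {
  d <- cache$pad_dim
  ph <- cache$ph; pw <- cache$pw
  oh <- d[1] %/% ph; ow <- d[2] %/% pw; nm <- d[3]
  dbeta <- vapply(seq_len(nm), function(m) {
    sum(dout[, , m] * cache$raw[, , m])
  }, numeric(1))
  db <- vapply(seq_len(nm), function(m) sum(dout[, , m]), numeric(1))
  draw <- sweep(dout, 3, cache$beta, `*`)
  dpad <- array(0, d)
  if (cache$mode == "avg") {
    per <- draw / (ph * pw)
    # spread each window's share over its ph x pw block
    wnd <- aperm(array(rep(as.vector(per), each = ph * pw),
                       c(ph, pw, oh, ow, nm)),
                 c(1, 3, 2, 4, 5))
    dpad <- array(wnd, d)
  } else {
    k <- as.vector(cache$amax) - 1L          # 0-based index within window
    pos <- seq_len(oh * ow * nm) - 1L
    a <- pos %% oh                            # output row (0-based)
    bm <- pos %/% oh
    bb <- bm %% ow                            # output col
    m <- bm %/% ow                            # map
    i <- k %% ph + a * ph                     # padded row (0-based)
    j <- k %/% ph + bb * pw                   # padded col
    dpad[1L + i + j * d[1] + m * d[1] * d[2]] <- as.vector(draw)
  }
  id <- cache$in_dim
  list(dbeta = dbeta, db = db,
       dmaps = dpad[seq_len(id[1]), seq_len(id[2]), , drop = FALSE])
}

# --- output layer and loss -------------------------------------------------

#' Softmax output layer
#'
#' Computes the two-class probability vector from the final feature vector:
#' `softmax(W f + b)`, stabilised by subtracting the maximum logit before
#' exponentiation so extreme logits cannot overflow.
#'
#' @param features Numeric feature vector.
#' @param W Weight matrix `[n_classes, n_features]`.
#' @param b Bias vector, length `n_classes`.
#' @return Probability vector summing to 1.
#' @export
softmax_out <- function(features, W, b) {
  z <- as.vector(W %*% features + b)
  assert_that(all(is.finite(z)), "non-finite logits")
  softmax_vec(z)
}

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Cross-entropy loss of probability predictions
#'
#' `E = -(1/N) sum_n sum_i y_i log p_i` over a batch. Probabilities equal to
#' zero at the true class are clipped at 1e-12 with a warning.
#'
#' @param predictions Matrix `[n_classes, N]` of probability columns, or a
#'   single probability vector.
#' @param labels Matrix of matching one-hot columns, or a vector of class
#'   indices in `{0, 1}` (1 meaning the first row of `predictions`).
#' @return Mean cross-entropy.
#' @export
cross_entropy <- function(predictions, labels) {
  if (is.vector(predictions)) predictions <- matrix(predictions, ncol = 1L)
  if (!is.matrix(labels)) labels <- one_hot(labels, nrow(predictions))
  assert_that(identical(dim(predictions), dim(labels)),
              "predictions and labels must have matching shapes")
  hit <- predictions[labels > 0]
  if (any(hit <= 0)) {
    warning("cross_entropy(): zero probability at a true class, clipped",
            call. = FALSE)
  }
  p <- pmax(predictions, 1e-12)
  -sum(labels * log(p)) / ncol(predictions)
}

# class 1 -> first row, class 0 -> second row
one_hot <- function(y, n_classes = 2L) {
  m <- matrix(0, n_classes, length(y))
  m[1, y == 1] <- 1
  m[2, y == 0] <- 1
  m
}

# --- model configuration ---------------------------------------------------

#' Configure the EEG window classifier network
#'
#' Defines the architecture: a stack of convolution layers (each followed
#' by a pooling layer, the alternation the architecture validator
#' enforces), fully connected layers, and a 2-unit softmax output. Defaults
#' give the 11-stage layout: input, four conv/pool pairs, two FC stages and
#' the output layer.
#'
#' @param input_shape `c(n_channels, n_samples)` of one window tensor.
#' @param conv_filters Filters per conv layer (default `c(8, 16, 32, 64)`).
#' @param conv_kernel Kernel `c(kh, kw)` shared by conv layers (default
#'   `c(1, 7)`: along time).
#' @param pool_size Pool window (default `c(1, 2)`).
#' @param pool_mode `"max"` or `"avg"`.
#' @param fc_units Units of the FC stages (default `c(64, 16)`).
#' @param activation Hidden activation (default `"relu"`).
#' @param dropout_p Dropout probability on FC activations, in [0, 1).
#' @param l1_lambda Non-negative L1 penalty weight.
#' @param learning_rate Gradient-descent step size (default 0.01).
#' @param standardize Standardise input tensors by training-set mean/SD
#'   before the first layer (stored in the model; default TRUE).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(input_shape,
                       conv_filters = c(8, 16, 32, 64),
                       conv_kernel = c(1, 7),
                       pool_size = c(1, 2),
                       pool_mode = "max",
                       fc_units = c(64, 16),
                       activation = "relu",
                       dropout_p = 0,
                       l1_lambda = 0,
                       learning_rate = 0.01,
                       standardize = TRUE) {
  assert_that(length(input_shape) == 2L && all(input_shape >= 1),
              "`input_shape` must be c(n_channels, n_samples)")
  assert_that(length(conv_filters) >= 1 && all(conv_filters >= 1),
              "need at least one conv layer")
  assert_that(all(conv_kernel >= 1) && all(pool_size >= 1),
              "kernel and pool dims must be >= 1")
  assert_that(dropout_p >= 0 && dropout_p < 1,
              "`dropout_p` must be in [0, 1)")
  assert_that(l1_lambda >= 0, "`l1_lambda` must be non-negative")
  cfg <- list(input_shape = as.integer(input_shape),
              conv_filters = as.integer(conv_filters),
              conv_kernel = as.integer(rep_len(conv_kernel, 2L)),
              pool_size = as.integer(rep_len(pool_size, 2L)),
              pool_mode = match.arg(pool_mode, c("max", "avg")),
              fc_units = as.integer(fc_units),
              activation = match.arg(activation,
                                     c("relu", "sigmoid", "tanh")),
              dropout_p = dropout_p, l1_lambda = l1_lambda,
              learning_rate = learning_rate,
              standardize = isTRUE(standardize))
  class(cfg) <- "cnn_config"
  validate_architecture(layer_kinds(cfg))
  cfg
}

layer_kinds <- function(cfg) {
  c(rep(c("conv", "pool"), length(cfg$conv_filters)),
    rep("fc", length(cfg$fc_units)), "softmax_out")
}

#' Validate the conv/pool alternation of a layer sequence
#'
#' Accepts one or more conv layers each immediately followed by a pooling
#' layer, then zero or more FC layers, then the softmax output; anything
#' else is rejected.
#'
#' @param kinds Character vector of layer kinds in order.
#' @return TRUE invisibly, or an error.
#' @export
validate_architecture <- function(kinds) {
  ok <- grepl("^(conv pool )+(fc )*softmax_out$",
              paste0(paste(kinds, collapse = " "), ""))
  assert_that(ok,
    "invalid architecture [%s]: need (conv pool)+ (fc)* softmax_out",
    paste(kinds, collapse = ", "))
  invisible(TRUE)
}

# He-style scaled initialisation, seeded.
cnn_init <- function(cfg, seed = 1) {
  with_seed(seed, {
    layers <- list()
    shape <- c(cfg$input_shape, 1L)
    for (f in cfg$conv_filters) {
      kh <- min(cfg$conv_kernel[1], shape[1])
      kw <- min(cfg$conv_kernel[2], shape[2])
      fan_in <- kh * kw * shape[3]
      layers[[length(layers) + 1L]] <- list(
        kind = "conv",
        W = array(stats::rnorm(kh * kw * shape[3] * f,
                               sd = sqrt(2 / fan_in)),
                  c(kh, kw, shape[3], f)),
        b = rep(0, f), activation = cfg$activation)
      shape <- c(shape[1] - kh + 1L, shape[2] - kw + 1L, f)
      ph <- min(cfg$pool_size[1], shape[1])
      pw <- min(cfg$pool_size[2], shape[2])
      layers[[length(layers) + 1L]] <- list(
        kind = "pool", ph = ph, pw = pw, mode = cfg$pool_mode,
        beta = rep(1, f), b = rep(0, f))
      shape <- c(ceiling(shape[1] / ph), ceiling(shape[2] / pw), f)
    }
    n_in <- prod(shape)
    for (u in cfg$fc_units) {
      layers[[length(layers) + 1L]] <- list(
        kind = "fc",
        W = matrix(stats::rnorm(u * n_in, sd = sqrt(2 / n_in)), u, n_in),
        b = rep(0, u), activation = cfg$activation,
        dropout_p = cfg$dropout_p)
      n_in <- u
    }
    layers[[length(layers) + 1L]] <- list(
      kind = "softmax",
      W = matrix(stats::rnorm(2L * n_in, sd = sqrt(1 / n_in)), 2L, n_in),
      b = rep(0, 2L))
    structure(list(layers = layers, config = cfg,
                   center = 0, scale = 1, seed = seed,
                   dropout_stream = 0L, trained = FALSE),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  kinds <- vapply(x$layers, `[[`, "", "kind")
  cat(sprintf("<cnn_model> %s%s\n", paste(kinds, collapse = " -> "),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# Forward pass for one sample. `masks`: optional list of dropout masks per
# fc layer (training mode); NULL means inference (no dropout).
cnn_forward <- function(model, x, masks = NULL) {
  a <- (x - model$center) / model$scale
  caches <- vector("list", length(model$layers))
  fc_i <- 0L
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    if (ly$kind == "conv") {
      cc <- conv_forward_cache(a, ly$W, ly$b, ly$activation)
      caches[[li]] <- cc
      a <- cc$out
    } else if (ly$kind == "pool") {
      cc <- pool_forward_cache(a, ly$ph, ly$pw, ly$mode, ly$beta, ly$b)
      caches[[li]] <- cc
      a <- cc$out
    } else if (ly$kind == "fc") {
      fc_i <- fc_i + 1L
      v <- as.vector(a)
      pre <- as.vector(ly$W %*% v + ly$b)
      post <- activate(pre, ly$activation)
      mask <- if (!is.null(masks)) masks[[fc_i]] else NULL
      dropped <- if (!is.null(mask)) post * mask else post
      caches[[li]] <- list(v = v, pre = pre, post = post, mask = mask,
                           in_dim = dim(a))
      a <- dropped
    } else {                                   # softmax
      v <- as.vector(a)
      z <- as.vector(ly$W %*% v + ly$b)
      p <- softmax_vec(z)
      caches[[li]] <- list(v = v, p = p)
      a <- p
    }
  }
  list(p = a, caches = caches)
}

# Gradients for one sample given its forward caches; dlogits = p - y_onehot.
cnn_backward_sample <- function(model, caches, y1) {
  L <- length(model$layers)
  grads <- vector("list", L)
  y <- c(y1, 1 - y1)
  sm <- caches[[L]]
  dz <- sm$p - y
  grads[[L]] <- list(dW = dz %o% sm$v, db = dz)
  da <- as.vector(t(model$layers[[L]]$W) %*% dz)
  for (li in (L - 1L):1L) {
    ly <- model$layers[[li]]
    cc <- caches[[li]]
    if (ly$kind == "fc") {
      if (!is.null(cc$mask)) da <- da * cc$mask
      dpre <- da * activate_grad(cc$pre, cc$post, ly$activation)
      grads[[li]] <- list(dW = dpre %o% cc$v, db = dpre)
      da <- as.vector(t(ly$W) %*% dpre)
    } else if (ly$kind == "pool") {
      dout <- array(da, dim(cc$out))
      pb <- pool_backward(dout, cc)
      grads[[li]] <- list(dbeta = pb$dbeta, db = pb$db)
      da <- pb$dmaps
    } else {                                   # conv
      dout <- array(da, dim(cc$out))
      cb <- conv_backward(dout, cc, ly$W, ly$activation)
      grads[[li]] <- list(dW = cb$dW, db = cb$db)
      da <- cb$dmaps
    }
  }
  grads
}

zero_like_grads <- function(model) {
  lapply(model$layers, function(ly) {
    switch(ly$kind,
      conv = list(dW = array(0, dim(ly$W)), db = rep(0, length(ly$b))),
      pool = list(dbeta = rep(0, length(ly$beta)),
                  db = rep(0, length(ly$b))),
      fc = list(dW = matrix(0, nrow(ly$W), ncol(ly$W)),
                db = rep(0, length(ly$b))),
      softmax = list(dW = matrix(0, nrow(ly$W), ncol(ly$W)),
                     db = rep(0, length(ly$b))))
  })
}

add_grads <- function(acc, g) {
  for (i in seq_along(acc)) {
    for (nm in names(acc[[i]])) acc[[i]][[nm]] <- acc[[i]][[nm]] + g[[i]][[nm]]
  }
  acc
}

# Mean batch gradient of the cross-entropy loss (without L1 term).
cnn_batch_gradients <- function(model, xs, ys, masks_list = NULL) {
  acc <- zero_like_grads(model)
  loss <- 0
  for (n in seq_along(xs)) {
    masks <- if (!is.null(masks_list)) masks_list[[n]] else NULL
    fw <- cnn_forward(model, xs[[n]], masks)
    loss <- loss + cross_entropy(fw$p, one_hot(ys[n]))
    acc <- add_grads(acc, cnn_backward_sample(model, fw$caches, ys[n]))
  }
  N <- length(xs)
  for (i in seq_along(acc)) {
    for (nm in names(acc[[i]])) acc[[i]][[nm]] <- acc[[i]][[nm]] / N
  }
  list(grads = acc, loss = loss / N)
}

#' One gradient-descent update from a batch
#'
#' Runs the forward and backward passes over the batch, adds the L1
#' subgradient on the weight matrices, and applies the plain
#' gradient-descent update `W <- W - eta * dE/dW`, `b <- b - eta * dE/db`
#' (pool multiplier/additive deviations included). Dropout masks, when
#' configured, are resampled for the batch from the model's stored seed
#' stream. A learning rate of zero leaves the model unchanged.
#'
#' @param model A `cnn_model`.
#' @param batch List with `x` (list of input tensors) and `y` (0/1 labels).
#' @return Updated model, with the batch loss in `model$last_loss`.
#' @export
backward_and_update <- function(model, batch) {
  xs <- batch$x; ys <- batch$y
  assert_that(length(xs) == length(ys) && length(xs) >= 1,
              "batch must pair every tensor with a label")
  p_drop <- model$config$dropout_p
  masks_list <- NULL
  if (p_drop > 0) {
    fc_sizes <- vapply(model$layers[vapply(model$layers, `[[`, "",
                                           "kind") == "fc"],
                       function(ly) length(ly$b), integer(1))
    model$dropout_stream <- model$dropout_stream + 1L
    masks_list <- with_seed(
      derive_seed(model$seed, 1000L + model$dropout_stream), {
        lapply(seq_along(xs), function(n) {
          lapply(fc_sizes, function(sz) {
            (stats::runif(sz) >= p_drop) / (1 - p_drop)
          })
        })
      })
  }
  bg <- cnn_batch_gradients(model, xs, ys, masks_list)
  grads <- bg$grads
  lam <- model$config$l1_lambda
  eta <- model$config$learning_rate
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    g <- grads[[i]]
    if (!all(vapply(g, function(v) all(is.finite(v)), logical(1)))) {
      stop_invalid("non-finite gradient in layer %d (%s): training aborted",
                   i, ly$kind)
    }
    if (ly$kind %in% c("conv", "fc", "softmax")) {
      dW <- g$dW + lam * sign(ly$W)
      model$layers[[i]]$W <- ly$W - eta * dW
      model$layers[[i]]$b <- ly$b - eta * g$db
    } else {
      model$layers[[i]]$beta <- ly$beta - eta * g$dbeta
      model$layers[[i]]$b <- ly$b - eta * g$db
    }
  }
  model$last_loss <- bg$loss
  model
}

#' Train the window classifier network
#'
#' Full-batch gradient descent on the cross-entropy loss for a fixed number
#' of epochs. Deterministic under the configuration seed.
#'
#' @param x List of input tensors (from [to_input_tensor()]) or a 3-D array
#'   `[n_channels, n_samples, N]`.
#' @param y Binary labels (0/1), both classes present.
#' @param config A [cnn_config()]; its `input_shape` must match `x`.
#' @param epochs Number of full-batch epochs.
#' @param seed Integer seed for initialisation and dropout.
#' @return Trained `cnn_model` with `loss_history` (one loss per epoch).
#' @export
train_cnn <- function(x, y, config, epochs = 100, seed = 1) {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] > 1 &&
      !is.list(x)) {
    x <- lapply(seq_len(dim(x)[3]), function(i) {
      array(x[, , i], c(dim(x)[1:2], 1L))
    })
  }
  assert_that(length(x) >= 2, "need at least 2 samples")
  y <- as.numeric(y)
  assert_that(all(y %in% c(0, 1)), "labels must be 0/1")
  assert_that(length(unique(y)) == 2L,
              "training data must contain both classes")
  model <- cnn_init(config, seed)
  if (config$standardize) {
    all_vals <- unlist(x)
    model$center <- mean(all_vals)
    model$scale <- max(stats::sd(all_vals), 1e-12)
  }
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    model <- backward_and_update(model, list(x = x, y = y))
    history[ep] <- model$last_loss
  }
  model$loss_history <- history
  model$trained <- TRUE
  model
}

#' Predict class probabilities for one window tensor
#'
#' @param model Trained `cnn_model`.
#' @param tensor Input tensor for one window.
#' @return Length-2 vector: probability of class 1 (positive/active state)
#'   then class 0.
#' @export
cnn_predict_proba <- function(model, tensor) {
  assert_that(inherits(model, "cnn_model"), "`model` must be a cnn_model")
  assert_that(isTRUE(model$trained), "model is untrained")
  cnn_forward(model, tensor)$p
}

#' Penultimate-layer features of a window tensor
#'
#' The activations feeding the softmax output — the representation the
#' gradient-boosting classifier stacks on.
#'
#' @inheritParams cnn_predict_proba
#' @return Numeric feature vector.
#' @export
cnn_features <- function(model, tensor) {
  assert_that(inherits(model, "cnn_model"), "`model` must be a cnn_model")
  fw <- cnn_forward(model, tensor)
  L <- length(model$layers)
  fw$caches[[L]]$v
}

# Central-difference gradient check across every parameter of a model,
# on a given batch. Returns the max relative error. Used by the tests.
cnn_gradient_check <- function(model, batch, eps = 1e-5, n_per_layer = 12,
                               seed = 99) {
  bg <- cnn_batch_gradients(model, batch$x, batch$y)
  loss_at <- function(m) cnn_batch_gradients(m, batch$x, batch$y)$loss
  worst <- 0
  with_seed(seed, {
    for (li in seq_along(model$layers)) {
      ly <- model$layers[[li]]
      slots <- switch(ly$kind,
        conv = c(W = "dW", b = "db"),
        fc = c(W = "dW", b = "db"),
        softmax = c(W = "dW", b = "db"),
        pool = c(beta = "dbeta", b = "db"))
      for (si in seq_along(slots)) {
        pname <- names(slots)[si]; gname <- slots[[si]]
        vals <- model$layers[[li]][[pname]]
        pick <- sample(length(vals), min(n_per_layer, length(vals)))
        for (k in pick) {
          m1 <- model; m2 <- model
          m1$layers[[li]][[pname]][k] <- vals[k] + eps
          m2$layers[[li]][[pname]][k] <- vals[k] - eps
          num <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
          ana <- bg$grads[[li]][[gname]][k]
          rel <- abs(num - ana) / max(abs(num), abs(ana), 1e-8)
          worst <- max(worst, rel)
        }
      }
    }
  })
  worst
}
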