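#' Configuration of the convolutional classifier
#'
#' The network is a fixed five-stage stack: 3x3 convolution (32 kernels,
#' stride 1, "same" padding), batch normalization, leaky ReLU (slope 0.01);
#' 3x3 convolution (64 kernels), BN, leaky ReLU; fully connected layer of
#' 2048 units on the flattened map, BN, leaky ReLU; fully connected layer
#' of `n_classes` units, BN, leaky ReLU; softmax with cross-entropy loss.
#' There is no pooling; the first dense layer attaches to the full
#' `rows x cols x 64` map.  Variants:
#'
#' * `"zpfd"` — zero-padded PSD feature input (the reference model);
#' * `"fd"` — identical network on unpadded PSD features;
#' * `"raw"` — identical network on the rescaled time-domain segment;
#' * `"separable"` — each 3x3 convolution factorised into a 3x1
#'   convolution followed by a 1x3 depthwise convolution (fewer
#'   multiplications per position: 3 + 3 instead of 9).
#'
#' @param input_rows,input_cols Input matrix dimensions (e.g. 80 x 9 for the
#'   two-band 40-target feature matrix).
#' @param n_classes Number of stimulation targets.
#' @param variant One of `"zpfd"`, `"fd"`, `"raw"`, `"separable"`.
#' @param conv_channels Kernel counts of the two convolution layers.
#' @param fc_width Width of the first fully connected layer.
#' @param leaky_slope Negative-side slope of the leaky ReLU.
#' @return Object of class `model_config`.
#' @export
model_config <- function(input_rows, input_cols, n_classes,
                         variant = c("zpfd", "fd", "raw", "separable"),
                         conv_channels = c(32L, 64L), fc_width = 2048L,
                         leaky_slope = 0.01) {
  variant <- match.arg(variant)
  stopifnot(input_rows >= 1, input_cols >= 1, n_classes >= 2,
            length(conv_channels) == 2, all(conv_channels >= 1),
            fc_width >= 1)
  structure(list(input_rows = as.integer(input_rows),
                 input_cols = as.integer(input_cols),
                 n_classes = as.integer(n_classes),
                 variant = variant,
                 conv1 = as.integer(conv_channels[1]),
                 conv2 = as.integer(conv_channels[2]),
                 fc_width = as.integer(fc_width),
                 leaky_slope = leaky_slope,
                 separable = variant == "separable"),
            class = "model_config")
}

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Build an untrained classifier with seeded weight initialization
#'
#' Convolution and dense weights use He-uniform initialization; batch-norm
#' scales start at 1 and shifts at 0 (running statistics at mean 0,
#' variance 1, so an untrained network in inference mode is an unbiased
#' softmax).  Layers followed by batch normalization carry no bias term.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return Object of class `zp_cnn`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  P <- cfg$input_rows * cfg$input_cols
  with_seed(seed, {
    if (!cfg$separable) {
      w <- list(K1 = he_uniform(9, cfg$conv1, 9),
                K2 = he_uniform(9 * cfg$conv1, cfg$conv2, 9 * cfg$conv1))
    } else {
      w <- list(K1 = he_uniform(3, cfg$conv1, 3),
                K2 = he_uniform(3 * cfg$conv1, cfg$conv2, 3 * cfg$conv1),
                K1b = he_uniform(3, cfg$conv1, 3),
                K2b = he_uniform(3, cfg$conv2, 3))
    }
    w$W1 <- he_uniform(P * cfg$conv2, cfg$fc_width, P * cfg$conv2)
    w$W2 <- he_uniform(cfg$fc_width, cfg$n_classes, cfg$fc_width)
    for (i in 1:4) {
      ch <- c(cfg$conv1, cfg$conv2, cfg$fc_width, cfg$n_classes)[i]
      w[[paste0("g", i)]] <- rep(1, ch)
      w[[paste0("b", i)]] <- rep(0, ch)
    }
    run <- list()
    for (i in 1:4) {
      ch <- c(cfg$conv1, cfg$conv2, cfg$fc_width, cfg$n_classes)[i]
      run[[paste0("rm", i)]] <- rep(0, ch)
      run[[paste0("rv", i)]] <- rep(1, ch)
    }
    structure(list(cfg = cfg, weights = w, running = run,
                   loss_trace = NULL, trained = FALSE),
              class = "zp_cnn")
  })
}

#' Training recipe
#'
#' Adam optimization of the softmax cross-entropy, mini-batches drawn by a
#' seeded per-epoch shuffle.  The defaults are the reference recipe:
#' learning rate 1e-4, 30 epochs, batch size 512 (clamped to the dataset
#' size when the dataset is smaller).
#'
#' @param learning_rate Adam step size (> 0).
#' @param epochs Number of passes over the data (>= 1).
#' @param batch_size Mini-batch size.
#' @param seed Seed controlling the shuffle (training is deterministic
#'   given seed, data and initial weights).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 30L,
                         batch_size = 512L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Train the classifier
#'
#' @param model A [build_model()] object.
#' @param x Numeric matrix, one sample per row: the row-major flattened
#'   `input_rows x input_cols` input (as produced by [featurize_epochs()]).
#' @param y Integer labels in `1..n_classes`.
#' @param tcfg A [train_config()].
#' @return The model with updated weights, batch-norm running statistics,
#'   and a per-epoch `loss_trace`.
#' @export
train_cnn <- function(model, x, y, tcfg = train_config()) {
  stopifnot(inherits(model, "zp_cnn"), inherits(tcfg, "train_config"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0) stop("empty training set")
  cfg <- model$cfg
  if (ncol(x) != cfg$input_rows * cfg$input_cols)
    stop(sprintf("input has %d features; model expects %d x %d = %d",
                 ncol(x), cfg$input_rows, cfg$input_cols,
                 cfg$input_rows * cfg$input_cols))
  y <- as.integer(y)
  if (length(y) != n) stop("length(y) must match nrow(x)")
  if (any(y < 1 | y > cfg$n_classes))
    stop(sprintf("labels must be in 1..%d", cfg$n_classes))
  perm <- with_seed(tcfg$seed,
                    t(vapply(seq_len(tcfg$epochs),
                             function(e) sample.int(n), integer(n))))
  dim(perm) <- c(tcfg$epochs, n)
  out <- .cnn_train_cpp(x, y, model$weights, model$running,
                        unclass(cfg), perm, unclass(tcfg))
  model$weights <- out$weights
  model$running <- out$running
  model$loss_trace <- as.numeric(out$loss_trace)
  model$trained <- TRUE
  model
}

#' Predict classes or class probabilities
#'
#' Inference uses the batch-norm running statistics.  The predicted label
#' is the arg-max probability; ties resolve to the lower class index.
#'
#' @param object A `zp_cnn` model.
#' @param x Sample matrix as in [train_cnn()].
#' @param type `"class"` for integer labels, `"prob"` for the
#'   `n x n_classes` probability matrix (rows sum to 1).
#' @param ... Unused.
#' @return Integer labels or a probability matrix.
#' @export
predict.zp_cnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  cfg <- object$cfg
  if (ncol(x) != cfg$input_rows * cfg$input_cols)
    stop(sprintf("input has %d features; model expects %d",
                 ncol(x), cfg$input_rows * cfg$input_cols))
  prob <- .cnn_predict_cpp(x, object$weights, object$running, unclass(cfg))
  if (type == "prob") return(prob)
  max.col(prob, ties.method = "first")
}

#' @export
print.zp_cnn <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<zp_cnn '%s'> input %d x %d, %d classes, %s; conv %d/%d, fc %d\n",
              cfg$variant, cfg$input_rows, cfg$input_cols, cfg$n_classes,
              if (x$trained) "trained" else "untrained",
              cfg$conv1, cfg$conv2, cfg$fc_width))
  invisible(x)
}

#' Count trainable weights
#'
#' @param model A `zp_cnn`.
#' @param conv_only Count only the convolution-stack weights (used to
#'   compare the separable factorisation against full 3x3 kernels).
#' @return Integer number of trainable parameters.
#' @export
count_parameters <- function(model, conv_only = FALSE) {
  w <- model$weights
  keys <- if (conv_only) intersect(c("K1", "K2", "K1b", "K2b"), names(w))
          else names(w)
  sum(vapply(keys, function(k) length(w[[k]]), numeric(1)))
}
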