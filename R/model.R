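# The GSS classifier: a three-block convolutional network over one-hot
# 299-bp windows.
#
#   conv(32, k=4) -> ReLU -> maxpool(2) -> dropout
#   conv(64, k=4) -> ReLU -> maxpool(2) -> dropout
#   conv(128, k=4) -> ReLU -> maxpool(2) -> dropout
#   flatten -> dense(128, ReLU) -> dropout -> dense(1, sigmoid)
#
# Each convolution shortens the feature map to length - kernel + 1 and each
# pool floor-halves it: 299 -> 296 -> 148 -> 145 -> 72 -> 69 -> 34.
# Training minimises class-weighted binary cross-entropy (positive term
# multiplied by CW, normally CW = Q) with Adam and early stopping.

#' Network architecture configuration
#'
#' @param conv_filters Filters per convolution block (default 32, 64, 128).
#' @param kernel_size Convolution kernel length (default 4).
#' @param pool_size Max-pooling width (default 2; odd lengths floor).
#' @param dense_width Width of the fully connected hidden layer (default 128).
#' @param dropout_rates Dropout probabilities after each pooling layer and
#'   after the dense hidden layer (default 0.2, 0.2, 0.2, 0.5).
#' @param input_channels Alphabet channels (4: A,T,C,G).
#' @param input_length Window length in bp (default 299).
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = c(32L, 64L, 128L),
                         kernel_size = 4L, pool_size = 2L,
                         dense_width = 128L,
                         dropout_rates = c(0.2, 0.2, 0.2, 0.5),
                         input_channels = 4L,
                         input_length = 299L) {
  stopifnot(length(conv_filters) == 3L, kernel_size >= 1, pool_size == 2L,
            length(dropout_rates) == 4L, all(dropout_rates >= 0),
            all(dropout_rates < 1))
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dense_width = as.integer(dense_width),
                 dropout_rates = dropout_rates,
                 input_channels = as.integer(input_channels),
                 input_length = as.integer(input_length)),
            class = "model_config")
}

#' Layer-by-layer output shapes of the network
#'
#' Walks the architecture and reports every layer's output shape
#' (channels x length), applying `length - kernel + 1` per convolution and
#' floor division per pool.
#'
#' @param config A [model_config()].
#' @return A data.frame with columns `layer`, `channels`, `length`.
#' @export
model_shapes <- function(config = model_config()) {
  k <- config$kernel_size
  m <- config$pool_size
  rows <- list(list("input", config$input_channels, config$input_length))
  len <- config$input_length
  for (i in seq_along(config$conv_filters)) {
    f <- config$conv_filters[i]
    len <- len - k + 1L
    if (len < 1) stop("conv", i, ": feature map length would be ", len)
    rows <- c(rows, list(list(paste0("conv", i), f, len)))
    len <- len %/% m
    if (len < 1) stop("pool", i, ": feature map length would be ", len)
    rows <- c(rows, list(list(paste0("pool", i), f, len)))
  }
  rows <- c(rows,
            list(list("flatten", 1L, config$conv_filters[3] * len)),
            list(list("dense", 1L, config$dense_width)),
            list(list("output", 1L, 1L)))
  data.frame(layer = vapply(rows, `[[`, "", 1),
             channels = vapply(rows, function(r) as.integer(r[[2]]), 1L),
             length = vapply(rows, function(r) as.integer(r[[3]]), 1L))
}

glorot_mat <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an (untrained) GSS network
#'
#' Initialises all layer weights (Glorot-uniform, biases zero) from the
#' given seed.  Conv filter matrices are stored flattened as
#' `filters x (channels * kernel)`, position-major, matching the internal
#' im2col layout.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `gss_model` (untrained).
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  sh <- model_shapes(config)  # validates the chain
  k <- config$kernel_size
  cf <- config$conv_filters
  cin <- c(config$input_channels, cf[1], cf[2])
  flat <- sh$length[sh$layer == "flatten"]
  weights <- withr::with_seed(seed, {
    w <- list()
    for (i in 1:3) {
      w[[paste0("W", i)]] <- glorot_mat(cf[i], cin[i] * k,
                                        fan_in = cin[i] * k,
                                        fan_out = cf[i] * k)
      w[[paste0("b", i)]] <- numeric(cf[i])
    }
    w$W4 <- glorot_mat(config$dense_width, flat, flat, config$dense_width)
    w$b4 <- numeric(config$dense_width)
    w$W5 <- glorot_mat(1L, config$dense_width, config$dense_width, 1L)
    w$b5 <- numeric(1L)
    w
  })
  structure(list(config = config, weights = weights, seed = seed,
                 trained = FALSE, history = NULL, training = NULL),
            class = "gss_model")
}

#' Training configuration
#'
#' @param max_epochs Epoch cap (default 150; models typically early-stop
#'   long before).
#' @param patience Early-stopping patience on validation loss, with
#'   best-weights restore (default 10).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 64).
#' @param class_weight Weight CW of the positive class in the loss;
#'   `NULL` means "use the sample set's Q".
#' @param threshold Decision threshold for [classify()] (default 0.5).
#' @param seed Integer seed for shuffling and dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(max_epochs = 150L, patience = 10L,
                            learning_rate = 1e-3, batch_size = 64L,
                            class_weight = NULL, threshold = 0.5,
                            seed = 1L) {
  stopifnot(patience < max_epochs, learning_rate > 0, batch_size >= 1)
  if (!is.null(class_weight) && class_weight < 1)
    stop("class_weight must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 class_weight = class_weight,
                 threshold = threshold, seed = as.integer(seed)),
            class = "training_config")
}

#' Class weights for a Q-unbalanced dataset
#'
#' The positive (GSS) class is weighted by CW = Q =
#' n_negative / n_positive; negatives keep weight 1.
#'
#' @param Q Negative:positive ratio (>= 1).
#' @return Named numeric vector `c("0" = 1, "1" = Q)`.
#' @export
class_weights <- function(Q) {
  if (Q < 1) stop("Q must be >= 1")
  c("0" = 1, "1" = as.numeric(Q))
}

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of `-[CW * y * log(yhat) + (1 - y) * log(1 - yhat)]`,
#' with predictions clipped to `[1e-7, 1 - 1e-7]`.  With `class_weight = 1`
#' this is the plain binary cross-entropy.
#'
#' @param y_true 0/1 labels.
#' @param y_hat Predicted scores in (0, 1).
#' @param class_weight Weight CW on the positive term (default 1).
#' @return The scalar loss.
#' @export
weighted_bce <- function(y_true, y_hat, class_weight = 1) {
  if (length(y_true) != length(y_hat))
    stop("y_true and y_hat have different lengths")
  yh <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  mean(-(class_weight * y_true * log(yh) + (1 - y_true) * log(1 - yh)))
}

#' Train a GSS network on a sample set
#'
#' Minimises the class-weighted binary cross-entropy with Adam on the
#' `train` partition, monitoring the (unweighted) loss on the `validation`
#' partition; stops early after `patience` epochs without improvement and
#' restores the best-validation weights.
#'
#' @param model An untrained (or previously trained) `gss_model`.
#' @param sample_set A `sample_set` from [build_dataset()].
#' @param config A [training_config()]; its `class_weight = NULL` default
#'   resolves to the sample set's Q.
#' @return The trained `gss_model`, with `$history` (per-epoch train /
#'   validation loss) and `$training` (resolved configuration) filled in.
#' @export
train_model <- function(model, sample_set, config = training_config()) {
  stopifnot(inherits(model, "gss_model"), inherits(sample_set, "sample_set"))
  tr <- get_split(sample_set, "train")
  va <- get_split(sample_set, "validation")
  if (!length(tr$y)) stop("sample set has an empty train partition")
  if (!length(va$y)) stop("sample set has an empty validation partition")
  cw <- if (is.null(config$class_weight)) sample_set$Q else config$class_weight
  fit <- cpp_cnn_train(tr$X, as.numeric(tr$y), va$X, as.numeric(va$y),
                       model$weights, cw = as.numeric(cw),
                       lr = config$learning_rate,
                       batch_size = config$batch_size,
                       max_epochs = config$max_epochs,
                       patience = config$patience,
                       dropout = model$config$dropout_rates,
                       seed = config$seed)
  model$weights <- fit$weights
  model$history <- data.frame(epoch = seq_along(fit$train_loss),
                              train_loss = fit$train_loss,
                              val_loss = fit$val_loss)
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  cfg <- config
  cfg$class_weight <- cw
  model$training <- cfg
  model
}

#' Score 299-bp windows with a trained model
#'
#' @param object A `gss_model`.
#' @param X A 4 x 299 x n one-hot array (or a single 4 x 299 matrix).
#' @param batch_size Windows scored per forward pass (default 1024).
#' @param ... Unused.
#' @return Numeric vector of scores in (0, 1), one per window, in input
#'   order.
#' @export
predict.gss_model <- function(object, X, batch_size = 1024L, ...) {
  if (is.matrix(X)) X <- array(X, dim = c(dim(X), 1L))
  stopifnot(length(dim(X)) == 3L)
  if (dim(X)[1] != object$config$input_channels ||
      dim(X)[2] != object$config$input_length)
    stop("input must be ", object$config$input_channels, " x ",
         object$config$input_length, " x n, got ",
         paste(dim(X), collapse = " x "))
  as.numeric(cpp_cnn_predict(X, object$weights, as.integer(batch_size)))
}

#' Threshold scores into class labels
#'
#' A window is called GSS-positive when its score is at or above the
#' threshold (ties at exactly the threshold go positive).
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision threshold (default 0.5).
#' @return Integer 0/1 labels.
#' @export
classify <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}

#' @export
print.gss_model <- function(x, ...) {
  cat(sprintf("<gss_model> %s, seed = %d\n",
              if (x$trained) "trained" else "untrained", x$seed))
  print(model_shapes(x$config))
  if (!is.null(x$history))
    cat(sprintf("trained %d epoch(s), best validation loss %.4f at epoch %d\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' Save / load a trained model
#'
#' The model is stored as an RDS container plus a JSON sidecar
#' (`<path>.json`) holding the architecture, training configuration, seed
#' and per-epoch loss history.
#'
#' @param model A `gss_model`.
#' @param path Output path for the RDS container.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config), seed = model$seed,
               trained = model$trained)
  if (!is.null(model$training)) side$training <- unclass(model$training)
  if (!is.null(model$history)) side$history <- model$history
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "gss_model")) stop("not a gss_model: ", path)
  m
}
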