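# MLP classification core: fully connected feed-forward network with ReLU
# hidden layers, optional inverted dropout, a softmax output over the 4
# duration classes, trained by mini-batch Adam on the cross-entropy loss.
# Implemented directly on base matrices (BLAS-backed), which is ample for
# 24-input tabular models of this size and keeps training bit-reproducible
# under a seed.

#' MLP architecture specification
#'
#' @param hidden_layers Number of hidden layers `L >= 1` (the screening grid
#'   uses 3–6).
#' @param width Units per hidden layer, uniform across layers (grid: 64, 128,
#'   256, 512).
#' @param dropout Dropout probability `0 <= p < 1` applied after each hidden
#'   layer during training; `p = 0` is exactly a dropout-free network.
#' @param input_dim,output_dim Input/output widths (24 attributes, 4 classes).
#' @param activation Hidden activation: `"relu"` (default), `"tanh"` or
#'   `"sigmoid"`.
#' @return An `mlp_architecture` object.
#' @export
#' @examples
#' mlp_architecture(4, 256)
mlp_architecture <- function(hidden_layers, width, dropout = 0,
                             input_dim = 24, output_dim = 4,
                             activation = c("relu", "tanh", "sigmoid")) {
  stop_if_not_count(hidden_layers, "hidden_layers")
  stop_if_not_count(width, "width")
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must satisfy 0 <= p < 1", call. = FALSE)
  }
  structure(list(hidden_layers = as.integer(hidden_layers),
                 width = as.integer(width), dropout = dropout,
                 input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 activation = match.arg(activation)),
            class = "mlp_architecture")
}

#' @export
format.mlp_architecture <- function(x, ...) {
  sprintf("%d-%d", x$hidden_layers, x$width)
}

#' @export
print.mlp_architecture <- function(x, ...) {
  cat(sprintf("<mlp_architecture> %s, dropout %g, %s, %d -> %d\n",
              format(x), x$dropout, x$activation, x$input_dim, x$output_dim))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs Number of passes over the training set (200 for screening,
#'   1000 for the final models).
#' @param batch_size Mini-batch size (default 100; the last partial batch is
#'   used, not dropped).
#' @param learning_rate Adam step size (default 0.001).
#' @param seed Integer seed governing initialization order, shuffling and
#'   dropout masks.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 200, batch_size = 100,
                         learning_rate = 0.001, seed = 1L) {
  stop_if_not_count(epochs, "epochs", zero_ok = TRUE)
  stop_if_not_count(batch_size, "batch_size")
  if (learning_rate <= 0) stop("`learning_rate` must be positive",
                               call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained MLP
#'
#' Weights use seeded fan-in-scaled Gaussian initialization
#' (`sd = sqrt(2 / fan_in)`, the standard choice for ReLU nets); biases start
#' at zero. Two builds with the same architecture and seed are identical.
#'
#' @param arch An [mlp_architecture()].
#' @param seed Integer seed.
#' @return An `mlp_model`: list of weight matrices `W`, bias vectors `b`, the
#'   architecture, and an (initially empty) per-epoch loss `history`.
#' @export
build_mlp <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "mlp_architecture"))
  dims <- c(arch$input_dim, rep(arch$width, arch$hidden_layers),
            arch$output_dim)
  with_seed(seed, {
    W <- vector("list", length(dims) - 1)
    b <- vector("list", length(dims) - 1)
    for (l in seq_along(W)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                    sd = sqrt(2 / dims[l])),
                       nrow = dims[l], ncol = dims[l + 1])
      b[[l]] <- numeric(dims[l + 1])
    }
    structure(list(W = W, b = b, arch = arch, history = numeric(0)),
              class = "mlp_model")
  })
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s (%d parameters)%s\n", format(x$arch),
              n_parameters(x),
              if (length(x$history)) sprintf(", trained %d epochs",
                                             length(x$history)) else ""))
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model An `mlp_model`.
#' @return Integer parameter count (weights plus biases).
#' @export
n_parameters <- function(model) {
  sum(vapply(model$W, length, numeric(1))) +
    sum(vapply(model$b, length, numeric(1)))
}

activation_fn <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0),
                     df = function(a) (a > 0) * 1),
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         sigmoid = list(f = stats::plogis, df = function(a) a * (1 - a)))
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. training = TRUE applies inverted dropout with fresh masks
# drawn from the current RNG stream; p = 0 draws nothing, so a p = 0 model
# consumes the same stream as a dropout-free one.
mlp_forward <- function(model, x, training = FALSE) {
  act <- activation_fn(model$arch$activation)
  p <- model$arch$dropout
  L <- length(model$W)
  a <- list(x)
  for (l in seq_len(L - 1)) {
    h <- act$f(sweep(a[[l]] %*% model$W[[l]], 2, model$b[[l]], "+"))
    if (training && p > 0) {
      mask <- matrix(stats::runif(length(h)) >= p, nrow = nrow(h)) / (1 - p)
      h <- h * mask
    }
    a[[l + 1]] <- h
  }
  z <- sweep(a[[L]] %*% model$W[[L]], 2, model$b[[L]], "+")
  list(probs = softmax(z), a = a)
}

#' Class scores of an MLP
#'
#' @param model A built (possibly trained) `mlp_model`.
#' @param x Input matrix, one record per row, width `input_dim`.
#' @return An `n x 4` matrix of non-negative class scores; each row sums to 1.
#' @export
predict_probs <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$arch$input_dim) {
    stop(sprintf("input width %d does not match the model's %d attributes",
                 ncol(x), model$arch$input_dim), call. = FALSE)
  }
  mlp_forward(model, x, training = FALSE)$probs
}

#' Predicted classes
#'
#' Argmax of the class scores; ties break toward the lowest class index.
#' This is a generic so that stub classifiers (see [fixed_classifier()]) can
#' stand in for a trained stage in cascade diagnostics.
#'
#' @param model A classifier (an `mlp_model` or a [fixed_classifier()]).
#' @param x Input matrix.
#' @return Integer classes in 1..4.
#' @export
predict_classes <- function(model, x) UseMethod("predict_classes")

#' @export
predict_classes.mlp_model <- function(model, x) {
  max.col(predict_probs(model, x), ties.method = "first")
}

#' A stub classifier with predetermined outputs
#'
#' Returns its stored class sequence regardless of the inputs (only the row
#' count is checked). Used to probe cascade behaviour under a perfectly
#' accurate or deliberately degraded upstream stage.
#'
#' @param classes Integer classes in 1..4, one per future input row.
#' @return A `fixed_classifier` object.
#' @export
fixed_classifier <- function(classes) {
  if (any(!(classes %in% 1:4))) stop("classes must be in 1..4", call. = FALSE)
  structure(list(classes = as.integer(classes)), class = "fixed_classifier")
}

#' @export
predict_classes.fixed_classifier <- function(model, x) {
  if (nrow(as.matrix(x)) != length(model$classes)) {
    stop("fixed_classifier holds ", length(model$classes),
         " outputs but received ", nrow(as.matrix(x)), " rows", call. = FALSE)
  }
  model$classes
}

cross_entropy <- function(probs, class) {
  -mean(log(pmax(probs[cbind(seq_along(class), class)], 1e-12)))
}

#' Train an MLP with mini-batch Adam on cross-entropy
#'
#' Runs `config$epochs` passes of seeded shuffled mini-batch gradient descent
#' with the Adam update (beta1 0.9, beta2 0.999, eps 1e-8). The per-epoch
#' mean training loss is appended to the model's `history`. Training is
#' deterministic given the data, config and seed, and the first `E` epochs of
#' a longer run coincide with an `E`-epoch run. `epochs = 0` returns the
#' model unchanged.
#'
#' @param model A built `mlp_model`.
#' @param train_set An [encoded_dataset()].
#' @param config A [train_config()].
#' @return The trained `mlp_model`.
#' @export
train_mlp <- function(model, train_set, config = train_config()) {
  stopifnot(inherits(model, "mlp_model"),
            inherits(train_set, "encoded_dataset"),
            inherits(config, "train_config"))
  n <- nrow(train_set$x)
  if (n == 0) stop("training set is empty", call. = FALSE)
  if (config$epochs == 0) return(model)
  if (ncol(train_set$x) != model$arch$input_dim) {
    stop("training data width does not match the model", call. = FALSE)
  }

  act <- activation_fn(model$arch$activation)
  L <- length(model$W)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mW <- lapply(model$W, function(w) w * 0); vW <- mW
  mb <- lapply(model$b, function(b) b * 0); vb <- mb
  t <- 0

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- train_set$x[idx, , drop = FALSE]
        yb <- train_set$y[idx, , drop = FALSE]
        fwd <- mlp_forward(model, xb, training = TRUE)
        epoch_loss <- epoch_loss +
          cross_entropy(fwd$probs, train_set$class[idx]) * length(idx)

        delta <- (fwd$probs - yb) / length(idx)
        t <- t + 1
        for (l in rev(seq_len(L))) {
          gW <- crossprod(fwd$a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(model$W[[l]])) * act$df(fwd$a[[l]])
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr <- config$learning_rate *
            sqrt(1 - beta2^t) / (1 - beta1^t)
          model$W[[l]] <- model$W[[l]] - corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
          model$b[[l]] <- model$b[[l]] - corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
        if (!is.finite(epoch_loss)) {
          stop("non-finite training loss at epoch ", epoch, call. = FALSE)
        }
      }
      model$history <- c(model$history, epoch_loss / n)
    }
  })
  model
}

#' Evaluate accuracy and loss on a dataset
#'
#' Accuracy is the fraction of records whose argmax score matches the target
#' class (argmax ties break toward the lowest index); loss is the mean
#' cross-entropy.
#'
#' @param model An `mlp_model`.
#' @param dataset A non-empty [encoded_dataset()].
#' @return A list with `accuracy` and `loss`.
#' @export
evaluate <- function(model, dataset) {
  stopifnot(inherits(dataset, "encoded_dataset"))
  if (nrow(dataset$x) == 0) {
    stop("cannot evaluate on an empty dataset", call. = FALSE)
  }
  probs <- predict_probs(model, dataset$x)
  pred <- max.col(probs, ties.method = "first")
  list(accuracy = mean(pred == dataset$class),
       loss = cross_entropy(probs, dataset$class))
}

# Note on the dropout-with-p=0 equivalence: the training=TRUE path draws no
# RNG values when p == 0, so dropout = 0 and a network built without dropout
# traverse identical RNG streams and produce identical parameters.

#' Train one replicate and evaluate it on all three splits
#'
#' @param arch An [mlp_architecture()].
#' @param data A `preprocessed_data` (or any list with `train`, `test`,
#'   `validation` encoded datasets).
#' @param config A [train_config()].
#' @return A `trial_result`: one-row data.frame with the architecture label,
#'   dropout, seed, accuracy and loss per split, and wall-clock seconds.
#' @export
run_trial <- function(arch, data, config) {
  t0 <- proc.time()[["elapsed"]]
  model <- build_mlp(arch, seed = derive_seed(config$seed, 7))
  model <- train_mlp(model, data$train, config)
  elapsed <- proc.time()[["elapsed"]] - t0
  ev <- lapply(data[c("test", "train", "validation")],
               function(d) evaluate(model, d))
  out <- data.frame(arch = format(arch), layers = arch$hidden_layers,
                    width = arch$width, dropout = arch$dropout,
                    seed = config$seed,
                    acc_test = ev$test$accuracy, acc_train = ev$train$accuracy,
                    acc_validation = ev$validation$accuracy,
                    loss_test = ev$test$loss, loss_train = ev$train$loss,
                    loss_validation = ev$validation$loss,
                    time_s = elapsed)
  attr(out, "model") <- model
  class(out) <- c("trial_result", class(out))
  out
}
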