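# Per-sample activity classifiers: a single-hidden-layer (32-unit) neural
# network trained by minibatch SGD on binary cross-entropy, and a linear SVM
# trained by SGD on the hinge loss. Both are seeded and fully deterministic.

#' Training configuration
#'
#' Hyperparameters of the per-sample classifier: a 32-unit single hidden
#' layer network (ReLU hidden activation, sigmoid output) or a linear SVM,
#' both optimized by plain minibatch stochastic gradient descent with L2
#' weight decay.
#'
#' @param hidden_units Hidden layer width (MLP only).
#' @param learning_rate SGD step size.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training set.
#' @param l2_penalty L2 regularization coefficient.
#' @param threshold Probability threshold for [binarize()].
#' @param seed Seed controlling initialization and batch shuffling.
#' @param model_kind `"mlp"` or `"svm_linear"`.
#' @param loss_reduction How the minibatch loss (and hence the gradient a
#'   step of size `learning_rate` follows) aggregates over the batch:
#'   `"sum"` (default) or `"mean"`. A learning rate quoted without naming
#'   the convention differs between the two by a factor of `batch_size`;
#'   with batches of 512 the mean convention at 0.001 makes steps 512 times
#'   smaller and the network visibly underfits the default grids within 40
#'   epochs.
#' @return Object of class `train_config`.
#' @export
train_config <- function(hidden_units = 32, learning_rate = 0.001,
                         batch_size = 512, epochs = 40, l2_penalty = 1e-4,
                         threshold = 0.5, seed = 1L,
                         model_kind = c("mlp", "svm_linear"),
                         loss_reduction = c("sum", "mean")) {
  model_kind <- match.arg(model_kind)
  loss_reduction <- match.arg(loss_reduction)
  stopifnot(hidden_units >= 1, batch_size >= 1, epochs >= 1,
            learning_rate > 0, l2_penalty >= 0,
            threshold > 0, threshold < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 l2_penalty = l2_penalty, threshold = threshold,
                 seed = as.integer(seed), model_kind = model_kind,
                 loss_reduction = loss_reduction),
            class = "train_config")
}

# Accept a semg_features bundle, a windowed_dataset, a list of them, or a
# plain matrix + labels; always hand back the transposed design (features x
# windows) the fitters work on.
as_training_matrix <- function(dataset, labels = NULL) {
  if (inherits(dataset, "semg_features")) {
    return(list(Xt = dataset$Xt, y = dataset$y))
  }
  if (inherits(dataset, "windowed_dataset")) {
    return(list(Xt = t(dataset$windows), y = dataset$labels))
  }
  if (is.matrix(dataset)) {
    stopifnot(!is.null(labels), nrow(dataset) == length(labels))
    return(list(Xt = t(dataset), y = as.integer(labels)))
  }
  if (is.list(dataset)) {
    stopifnot(all(vapply(dataset, inherits, logical(1), "windowed_dataset")))
    return(list(Xt = t(do.call(rbind, lapply(dataset, `[[`, "windows"))),
                y = unlist(lapply(dataset, `[[`, "labels"))))
  }
  stop("dataset must be a semg_features bundle, a windowed_dataset, ",
       "a list of them, or a matrix")
}

#' Train the activity classifier
#'
#' Fits either the 32-unit single-hidden-layer network (ReLU + sigmoid,
#' binary cross-entropy loss) or a linear SVM (hinge loss) with minibatch
#' SGD and L2 weight decay, using the hyperparameters in `config`. Batches
#' are reshuffled each epoch with the seeded generator; training is
#' deterministic under a fixed seed.
#'
#' @param dataset A `windowed_dataset`, a list of them, or a numeric matrix
#'   (one row per window).
#' @param config A [train_config()].
#' @param labels Binary labels, required when `dataset` is a plain matrix.
#' @return Object of class `semg_model`: list with `kind`, `weights`,
#'   `input_dim`, `config`, `loss_history` (mean loss per epoch).
#' @export
train_classifier <- function(dataset, config = train_config(), labels = NULL) {
  stopifnot(inherits(config, "train_config"))
  d <- as_training_matrix(dataset, labels)
  Xt <- d$Xt
  y <- as.numeric(d$y)
  if (ncol(Xt) == 0) stop("empty training set")
  if (length(unique(y)) < 2) stop("training set contains a single class")
  if (config$model_kind == "mlp") {
    fit_mlp_sgd(Xt, y, config)
  } else {
    fit_svm_sgd(Xt, y, config)
  }
}

# Both fitters work on the transposed design (features x windows): gathering
# a minibatch then touches contiguous columns, which matters at millions of
# windows.
fit_mlp_sgd <- function(Xt, y, config) {
  n <- ncol(Xt); p <- nrow(Xt); h <- config$hidden_units
  lr <- config$learning_rate; l2 <- config$l2_penalty
  set.seed(config$seed)
  # He-style uniform init for the ReLU layer, Glorot-style for the output
  lim1 <- sqrt(6 / p)
  W1 <- matrix(stats::runif(p * h, -lim1, lim1), p, h)
  b1 <- numeric(h)
  lim2 <- sqrt(6 / (h + 1))
  W2 <- matrix(stats::runif(h, -lim2, lim2), h, 1)
  b2 <- 0
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    total_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      B <- length(idx)
      Xb <- Xt[, idx, drop = FALSE] # p x B
      yb <- y[idx]
      A1 <- crossprod(W1, Xb) + b1 # h x B, b1 recycles down columns
      H1 <- pmax(A1, 0)
      z <- as.numeric(crossprod(H1, W2)) + b2
      pr <- stats::plogis(z)
      # binary cross-entropy, numerically stable via log1p(exp(-|z|))
      total_loss <- total_loss +
        sum((1 - yb) * z + pmax(-z, 0) + log1p(exp(-abs(z))))
      div <- if (config$loss_reduction == "sum") 1 else B
      d2 <- (pr - yb) / div
      gW2 <- H1 %*% d2 + l2 * W2
      gb2 <- sum(d2)
      d1 <- (W2 %*% rbind(d2)) * (A1 > 0) # h x B
      gW1 <- Xb %*% t(d1) + l2 * W1
      gb1 <- rowSums(d1)
      W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
      W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
    }
    loss_history[epoch] <- total_loss / n
  }
  structure(list(kind = "mlp",
                 weights = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
                 input_dim = p, config = config,
                 loss_history = loss_history),
            class = "semg_model")
}

fit_svm_sgd <- function(Xt, y, config) {
  n <- ncol(Xt); p <- nrow(Xt)
  lr <- config$learning_rate; l2 <- config$l2_penalty
  ypm <- 2 * y - 1
  set.seed(config$seed)
  lim <- sqrt(6 / p)
  w <- stats::runif(p, -lim, lim)
  b <- 0
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    total_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      B <- length(idx)
      Xb <- Xt[, idx, drop = FALSE]
      yb <- ypm[idx]
      z <- as.numeric(crossprod(Xb, w)) + b
      margin <- yb * z
      total_loss <- total_loss + sum(pmax(0, 1 - margin))
      div <- if (config$loss_reduction == "sum") 1 else B
      act <- margin < 1
      if (any(act)) {
        gw <- -as.numeric(Xb[, act, drop = FALSE] %*% yb[act]) / div + l2 * w
        gb <- -sum(yb[act]) / div
      } else {
        gw <- l2 * w
        gb <- 0
      }
      w <- w - lr * gw
      b <- b - lr * gb
    }
    loss_history[epoch] <- total_loss / n
  }
  structure(list(kind = "svm_linear", weights = list(w = w, b = b),
                 input_dim = p, config = config,
                 loss_history = loss_history),
            class = "semg_model")
}

#' @export
print.semg_model <- function(x, ...) {
  cat(sprintf("<semg_model> kind = %s, input_dim = %d, epochs = %d\n",
              x$kind, x$input_dim, x$config$epochs))
  invisible(x)
}

#' Predict per-window activity probabilities
#'
#' MLP: sigmoid network output. Linear SVM: the margin score mapped through
#' the logistic function so both model kinds share a `[0, 1]` interface; the
#' 0.5 probability threshold then coincides with the margin sign.
#'
#' @param model A trained [train_classifier()] model.
#' @param windows A `windowed_dataset`, a [featurize_dataset()] bundle, or
#'   a numeric matrix (one row per window) whose column count matches
#'   `model$input_dim`.
#' @return Numeric vector of probabilities in `[0, 1]`, one per window.
#' @export
predict_proba <- function(model, windows) {
  stopifnot(inherits(model, "semg_model"))
  Xt <- if (inherits(windows, "semg_features")) {
    windows$Xt
  } else if (inherits(windows, "windowed_dataset")) {
    t(windows$windows)
  } else {
    stopifnot(is.matrix(windows))
    t(windows)
  }
  if (nrow(Xt) != model$input_dim) {
    stop(sprintf("window dimension %d does not match model input_dim %d",
                 nrow(Xt), model$input_dim))
  }
  w <- model$weights
  if (model$kind == "mlp") {
    H1 <- pmax(crossprod(w$W1, Xt) + w$b1, 0)
    stats::plogis(as.numeric(crossprod(H1, w$W2)) + w$b2)
  } else {
    stats::plogis(as.numeric(crossprod(Xt, w$w)) + w$b)
  }
}

#' Threshold probabilities into a binary activity sequence
#'
#' @param probabilities Values in `[0, 1]`.
#' @param threshold Decision threshold; a probability equal to the threshold
#'   maps to 1.
#' @return Integer 0/1 vector.
#' @export
binarize <- function(probabilities, threshold = 0.5) {
  as.integer(probabilities >= threshold)
}

#' Serialize a trained model to JSON
#'
#' Weight values are written as `%.17g` strings — the shortest decimal form
#' guaranteed to round-trip IEEE doubles — so a reloaded model reproduces
#' predictions bit for bit.
#'
#' @param model A `semg_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "semg_model"))
  obj <- list(kind = model$kind, input_dim = model$input_dim,
              config = unclass(model$config),
              loss_history = model$loss_history,
              weights = lapply(model$weights, function(w) {
                if (is.matrix(w)) {
                  list(dim = dim(w), data = sprintf("%.17g", as.numeric(w)))
                } else {
                  list(dim = NULL, data = sprintf("%.17g", as.numeric(w)))
                }
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path File written by [save_model()].
#' @return A `semg_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(obj$weights, function(w) {
    v <- as.numeric(w$data)
    if (!is.null(w$dim) && length(w$dim)) {
      matrix(v, nrow = w$dim[1], ncol = w$dim[2])
    } else {
      v
    }
  })
  cfg <- obj$config
  config <- train_config(hidden_units = cfg$hidden_units,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, epochs = cfg$epochs,
                         l2_penalty = cfg$l2_penalty, threshold = cfg$threshold,
                         seed = cfg$seed, model_kind = cfg$model_kind,
                         loss_reduction = if (is.null(cfg$loss_reduction))
                           "sum" else cfg$loss_reduction)
  structure(list(kind = obj$kind, weights = weights,
                 input_dim = as.integer(obj$input_dim), config = config,
                 loss_history = as.numeric(obj$loss_history)),
            class = "semg_model")
}
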