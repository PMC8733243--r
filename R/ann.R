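#' Dense network topology for one tree node
#'
#' The per-node classifier is a fully connected feed-forward network:
#' dense layers with ReLU activations on the hidden layers and a 2-unit
#' linear output layer, with (inverted) dropout after the 256-unit and after
#' the 16-unit hidden layer in the reference topology
#' `input -> 512 -> 256 -> 64 -> 32 -> 16 -> 2`.  Per-unit activation
#' thresholds are absorbed into the bias terms.
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer widths.  Default
#'   `c(512, 256, 64, 32, 16)`.
#' @param dropout_after Indices into `hidden` after which dropout is applied
#'   in training mode.  Default: after the 2nd and the 5th hidden layer
#'   (the 256- and 16-unit layers of the reference topology), clipped to the
#'   layers that exist.
#' @param dropout_rate Dropout probability in `[0, 1)`, default 0.2.
#' @return An object of class `network_spec` with `layer_sizes`
#'   (`c(input_dim, hidden, 2)`), `activation`, `dropout_after`,
#'   `dropout_rate`.
#' @export
network_spec <- function(input_dim, hidden = c(512L, 256L, 64L, 32L, 16L),
                         dropout_after = NULL, dropout_rate = 0.2) {
  stopifnot(input_dim >= 1, all(hidden >= 1),
            dropout_rate >= 0, dropout_rate < 1)
  if (is.null(dropout_after)) {
    dropout_after <- intersect(c(2L, 5L), seq_along(hidden))
  }
  if (length(dropout_after) && (any(dropout_after < 1) ||
                                any(dropout_after > length(hidden)))) {
    stop("dropout_after must index hidden layers only", call. = FALSE)
  }
  structure(list(layer_sizes = as.integer(c(input_dim, hidden, 2L)),
                 activation = "relu",
                 dropout_after = as.integer(dropout_after),
                 dropout_rate = dropout_rate),
            class = "network_spec")
}

#' Training configuration for a node network
#'
#' @param epochs Number of passes over the data (>= 1).  Default 2: the
#'   networks reach a good true-positive rate within two epochs and longer
#'   training overfits the tiny positive class.
#' @param batch_size Mini-batch size, default 32.
#' @param learning_rate Gradient-descent step size (> 0), default 0.01.
#' @param lambda L2 penalty weight on the connection weights (never on the
#'   biases), default 0.
#' @param seed Integer seed for shuffling and dropout masks.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 2L, batch_size = 32L, learning_rate = 0.01,
                         lambda = 0, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  stopifnot(batch_size >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lambda = lambda,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize network parameters
#'
#' Weights are drawn from a zero-mean normal scaled by `1/sqrt(fan_in)`;
#' biases start at zero.  Deterministic for a fixed seed.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return An object of class `network_params`: `weights` (list of
#'   `size[l+1] x size[l]` matrices) and `biases` (list of vectors).
#' @export
init_params <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- spec$layer_sizes
  withr::with_seed(derive_seed(seed, "init_params"), {
    weights <- lapply(seq_len(length(sizes) - 1L), function(l) {
      matrix(rnorm(sizes[l + 1L] * sizes[l], sd = 1 / sqrt(sizes[l])),
             nrow = sizes[l + 1L], ncol = sizes[l])
    })
    biases <- lapply(seq_len(length(sizes) - 1L),
                     function(l) numeric(sizes[l + 1L]))
    structure(list(weights = weights, biases = biases),
              class = "network_params")
  })
}

# dropout masks for one batch: list, one entry per hidden layer (NULL where
# no dropout); inverted scaling so inference needs no rescale
make_dropout_masks <- function(spec, n, seed) {
  n_hidden <- length(spec$layer_sizes) - 2L
  masks <- vector("list", n_hidden)
  if (spec$dropout_rate == 0 || length(spec$dropout_after) == 0L) {
    return(masks)
  }
  withr::with_seed(derive_seed(seed, "dropout"), {
    for (h in spec$dropout_after) {
      keep <- 1 - spec$dropout_rate
      masks[[h]] <- matrix(
        (runif(n * spec$layer_sizes[h + 1L]) < keep) / keep,
        nrow = n)
    }
  })
  masks
}

# batch forward pass; x is an n x input_dim matrix
forward_batch <- function(params, spec, x, masks = NULL) {
  n_layers <- length(spec$layer_sizes) - 1L
  pre <- vector("list", n_layers)   # I_m: propagated input + bias
  act <- vector("list", n_layers)   # O_k: layer outputs
  a <- x
  for (l in seq_len(n_layers)) {
    z <- tcrossprod(a, params$weights[[l]]) +
      rep(params$biases[[l]], each = nrow(a))
    pre[[l]] <- z
    if (l < n_layers) {
      a <- pmax(z, 0)
      if (!is.null(masks) && !is.null(masks[[l]])) a <- a * masks[[l]]
    } else {
      a <- z  # linear output layer; softmax applied in the loss only
    }
    act[[l]] <- a
  }
  list(pre = pre, act = act, scores = a)
}

#' Forward pass through a node network
#'
#' Each layer computes the propagated input `I = W O_prev + b` and the ReLU
#' output `O = max(I, 0)` on hidden layers; the 2-unit output layer is
#' linear.  In `"train"` mode, inverted dropout is applied after the
#' configured hidden layers (so inference needs no rescaling); `"infer"`
#' mode is deterministic.
#'
#' @param params A [init_params()] result.
#' @param spec The matching [network_spec()].
#' @param x Numeric feature vector (length `input_dim`), or a matrix with one
#'   sample per row.
#' @param mode `"infer"` (default) or `"train"`.
#' @param seed Seed for the dropout masks in train mode.
#' @return An object of class `forward_trace`: `pre` (pre-activations per
#'   layer), `act` (outputs per layer), `masks`, and `scores` (final output
#'   scores `y`).
#' @export
forward <- function(params, spec, x, mode = c("infer", "train"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "network_params"),
            inherits(spec, "network_spec"))
  vec_in <- is.null(dim(x))
  xm <- if (vec_in) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(xm) != spec$layer_sizes[1L]) {
    stop("shape error: input has ", ncol(xm), " features, spec expects ",
         spec$layer_sizes[1L], call. = FALSE)
  }
  if (any(!is.finite(xm))) {
    stop("domain error: non-finite input", call. = FALSE)
  }
  masks <- if (mode == "train") {
    make_dropout_masks(spec, nrow(xm), seed)
  } else NULL
  fw <- forward_batch(params, spec, xm, masks)
  if (vec_in) {
    fw$pre <- lapply(fw$pre, drop)
    fw$act <- lapply(fw$act, drop)
    fw$scores <- drop(fw$scores)
  }
  structure(list(pre = fw$pre, act = fw$act, masks = masks,
                 scores = fw$scores),
            class = "forward_trace")
}

#' Class decision from output scores
#'
#' The routing rule of the hybrid tree: the inner products of the output
#' layer form the score vector `y` and the class with the maximum score is
#' chosen; ties break toward the lowest index.  Classes are indexed from 0.
#'
#' @param final_scores Numeric score vector (length >= 2), or a matrix with
#'   one score row per sample.
#' @return Integer class index (0-based), or a vector of them for matrix
#'   input.
#' @export
#' @examples
#' decision_rule(c(0.2, 0.9))  # 1
#' decision_rule(c(0.5, 0.5))  # 0 (tie toward the lowest index)
decision_rule <- function(final_scores) {
  if (is.null(dim(final_scores))) {
    if (length(final_scores) < 2L) {
      stop("domain error: score vector must have length >= 2", call. = FALSE)
    }
    if (any(!is.finite(final_scores))) {
      stop("domain error: non-finite scores", call. = FALSE)
    }
    return(which.max(final_scores) - 1L)
  }
  if (ncol(final_scores) < 2L || any(!is.finite(final_scores))) {
    stop("domain error: invalid score matrix", call. = FALSE)
  }
  max.col(final_scores, ties.method = "first") - 1L
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# softmax cross-entropy gradients for one batch.
# Returns list(grad_w, grad_b, loss).  Output-layer error signal is
# d = softmax(z) - y_onehot; weight gradients get (1/m) * accumulated
# signal + lambda * w (biases are never penalised).
ann_gradients <- function(params, spec, x, labels, lambda = 0,
                          masks = NULL) {
  m <- nrow(x)
  n_layers <- length(spec$layer_sizes) - 1L
  fw <- forward_batch(params, spec, x, masks)
  probs <- softmax_rows(fw$scores)
  y_onehot <- matrix(0, m, 2L)
  y_onehot[cbind(seq_len(m), labels + 1L)] <- 1
  loss <- -mean(log(pmax(probs[cbind(seq_len(m), labels + 1L)], 1e-12)))
  delta <- probs - y_onehot
  grad_w <- vector("list", n_layers)
  grad_b <- vector("list", n_layers)
  for (l in rev(seq_len(n_layers))) {
    a_prev <- if (l == 1L) x else fw$act[[l - 1L]]
    grad_w[[l]] <- crossprod(delta, a_prev) / m +
      lambda * params$weights[[l]]
    grad_b[[l]] <- colSums(delta) / m
    if (l > 1L) {
      delta <- delta %*% params$weights[[l]]
      delta <- delta * (fw$pre[[l - 1L]] > 0)
      if (!is.null(masks) && !is.null(masks[[l - 1L]])) {
        delta <- delta * masks[[l - 1L]]
      }
    }
  }
  for (l in seq_len(n_layers)) {
    if (any(!is.finite(grad_w[[l]])) || any(!is.finite(grad_b[[l]]))) {
      stop("numeric error: non-finite gradient in layer ", l, call. = FALSE)
    }
  }
  list(grad_w = grad_w, grad_b = grad_b, loss = loss)
}

# one gradient-descent step; internal batch = list(features, labels)
backprop_step <- function(params, spec, batch, config) {
  x <- batch$features
  masks <- make_dropout_masks(spec, nrow(x), config$seed)
  g <- ann_gradients(params, spec, x, batch$labels, config$lambda, masks)
  for (l in seq_along(params$weights)) {
    params$weights[[l]] <- params$weights[[l]] -
      config$learning_rate * g$grad_w[[l]]
    params$biases[[l]] <- params$biases[[l]] -
      config$learning_rate * g$grad_b[[l]]
  }
  list(params = params, loss = g$loss)
}

#' One backpropagation update
#'
#' Accumulates the per-example output error `softmax(z) - y` backward through
#' the layers, forms gradients `(1/m) B + lambda * W` on weight entries and
#' `(1/m) b` on bias entries (the L2 penalty is never applied to biases), and
#' applies one mini-batch gradient-descent step.  Dropout masks are drawn
#' from `config$seed`, so the update is deterministic.
#'
#' @param params A [init_params()] result.
#' @param spec The matching [network_spec()].
#' @param batch List with `features` (m x input_dim matrix) and `labels`
#'   (0/1 vector of length m).
#' @param config A [train_config()].
#' @return Updated `network_params`.
#' @export
backprop_update <- function(params, spec, batch, config) {
  stopifnot(inherits(params, "network_params"),
            inherits(spec, "network_spec"),
            inherits(config, "train_config"))
  batch$features <- as.matrix(batch$features)
  if (nrow(batch$features) == 0L) {
    stop("domain error: empty batch", call. = FALSE)
  }
  stopifnot(all(batch$labels %in% c(0L, 1L)),
            length(batch$labels) == nrow(batch$features))
  backprop_step(params, spec, batch, config)$params
}

#' Train a node network by batched backpropagation
#'
#' Runs `config$epochs` passes of mini-batch gradient descent over the table,
#' with a seeded shuffle before each epoch.  Returns the trained parameters
#' with a per-epoch mean-loss log attached.
#'
#' @param table A [feature_table()] with both classes present.
#' @param spec A [network_spec()] whose input width matches the table.
#' @param config A [train_config()].
#' @return An object of class `ann_model`: `params`, `spec`, `loss`
#'   (numeric, one mean cross-entropy per epoch), `config`.
#' @export
train_ann <- function(table, spec, config) {
  validate_feature_table(table)
  stopifnot(inherits(spec, "network_spec"), inherits(config, "train_config"))
  if (length(unique(table$labels)) < 2L) {
    stop("domain error: both classes must be present to train", call. = FALSE)
  }
  if (n_features(table) != spec$layer_sizes[1L]) {
    stop("shape error: table has ", n_features(table),
         " features, spec expects ", spec$layer_sizes[1L], call. = FALSE)
  }
  params <- init_params(spec, seed = config$seed)
  n <- n_samples(table)
  epoch_loss <- numeric(config$epochs)
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- withr::with_seed(
      derive_seed(config$seed, paste0("epoch", epoch)), sample.int(n))
    starts <- seq(1L, n, by = config$batch_size)
    losses <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- ord[starts[b]:min(starts[b] + config$batch_size - 1L, n)]
      step <- step + 1L
      step_cfg <- config
      step_cfg$seed <- derive_seed(config$seed, paste0("step", step))
      res <- backprop_step(params, spec,
                           list(features = table$features[idx, , drop = FALSE],
                                labels = table$labels[idx]),
                           step_cfg)
      params <- res$params
      losses[b] <- res$loss
    }
    epoch_loss[epoch] <- mean(losses)
    if (!is.finite(epoch_loss[epoch])) {
      stop("numeric error: training loss diverged at epoch ", epoch,
           call. = FALSE)
    }
  }
  structure(list(params = params, spec = spec, loss = epoch_loss,
                 config = config),
            class = "ann_model")
}

#' Predict class labels with a trained node network
#'
#' Deterministic inference-mode forward pass followed by the argmax decision
#' rule.
#'
#' @param object An `ann_model` from [train_ann()].
#' @param table A [feature_table()] (labels ignored) or a feature matrix.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.ann_model <- function(object, table, ...) {
  x <- if (inherits(table, "feature_table")) table$features else
    as.matrix(table)
  tr <- forward(object$params, object$spec, x, mode = "infer")
  scores <- tr$scores
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  decision_rule(scores)
}

#' @exportS3Method base::print
print.ann_model <- function(x, ...) {
  cat(sprintf("ann_model: layers [%s], final epoch loss %.4f\n",
              paste(x$spec$layer_sizes, collapse = "-"),
              x$loss[length(x$loss)]))
  invisible(x)
}
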