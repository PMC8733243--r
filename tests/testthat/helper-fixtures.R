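# Fixtures and independent oracles shared across the suite.

# small two-blob table: positives shifted by `effect` SDs on all features
make_blobs <- function(n_pos, n_neg, p = 2, effect = 6, seed = 42) {
  generate_feature_table(synthetic_config(
    n_features = p, n_positive = n_pos, n_negative = n_neg,
    effect_size = effect, n_informative = p, correlation_rho = 0,
    seed = seed))
}

small_spec <- function(input_dim, hidden = c(8L, 4L), dropout_rate = 0) {
  network_spec(input_dim, hidden = hidden, dropout_rate = dropout_rate)
}

fast_grow <- function(seed = 1L, epochs = 4L, lr = 0.1, max_depth = 3L) {
  grow_config(max_depth = max_depth, min_samples_split = 10L,
              node_train = train_config(epochs = epochs, batch_size = 32L,
                                        learning_rate = lr, seed = seed),
              seed = seed)
}

# Independent loss oracle for gradient checks: plain-loop forward pass and
# softmax cross-entropy, sharing no code with the package's implementation.
oracle_loss <- function(weights, biases, x, labels) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    a <- x[i, ]
    for (l in seq_along(weights)) {
      z <- numeric(nrow(weights[[l]]))
      for (r in seq_len(nrow(weights[[l]]))) {
        z[r] <- sum(weights[[l]][r, ] * a) + biases[[l]][r]
      }
      a <- if (l < length(weights)) ifelse(z > 0, z, 0) else z
    }
    p <- exp(a - max(a)) / sum(exp(a - max(a)))
    total <- total - log(p[labels[i] + 1L])
  }
  total / nrow(x)
}

# central finite differences of the oracle loss over every parameter entry
oracle_fd_gradients <- function(params, x, labels, h = 1e-6) {
  gw <- lapply(params$weights, function(w) array(0, dim(w)))
  gb <- lapply(params$biases, function(b) numeric(length(b)))
  for (l in seq_along(params$weights)) {
    for (j in seq_along(params$weights[[l]])) {
      wp <- params$weights; wm <- params$weights
      wp[[l]][j] <- wp[[l]][j] + h
      wm[[l]][j] <- wm[[l]][j] - h
      gw[[l]][j] <- (oracle_loss(wp, params$biases, x, labels) -
                       oracle_loss(wm, params$biases, x, labels)) / (2 * h)
    }
    for (j in seq_along(params$biases[[l]])) {
      bp <- params$biases; bm <- params$biases
      bp[[l]][j] <- bp[[l]][j] + h
      bm[[l]][j] <- bm[[l]][j] - h
      gb[[l]][j] <- (oracle_loss(params$weights, bp, x, labels) -
                       oracle_loss(params$weights, bm, x, labels)) / (2 * h)
    }
  }
  list(grad_w = gw, grad_b = gb)
}

# Draw a random small net + batch for a gradient check, rejecting draws
# whose pre-activations sit within `margin` of a ReLU kink (the loss is not
# differentiable there, so central differences are meaningless).  Biases are
# perturbed away from zero for the same reason.
gradient_check_case <- function() {
  repeat {
    n_hidden <- sample(1:2, 1)
    sizes <- sample(2:5, n_hidden, replace = TRUE)
    d <- sample(2:5, 1)
    spec <- network_spec(d, hidden = sizes, dropout_rate = 0)
    params <- init_params(spec, seed = sample.int(1e6, 1))
    params$biases <- lapply(params$biases,
                            function(b) rnorm(length(b), sd = 0.3))
    m <- sample(2:6, 1)
    x <- matrix(rnorm(m * d), m, d)
    labels <- sample(0:1, m, replace = TRUE)
    tr <- forward(params, spec, x)
    pre <- tr$pre
    if (m == 1) pre <- lapply(pre, rbind)
    margin <- min(vapply(pre, function(z) min(abs(z)), numeric(1)))
    if (margin > 1e-3) {
      return(list(spec = spec, params = params, x = x, labels = labels))
    }
  }
}

# the published per-ratio count ladders for the five benchmark datasets:
# one row per (dataset, ratio) cell, 48 standard + 12 virus cells
published_ladders <- function() {
  std <- data.frame(
    ratio = rep(c(1, 100, 500, 1000, 1500, 2000, 2500, 3000, 3500, 4000,
                  4500, 5000), times = 4),
    dataset = rep(c("animal", "plant", "human", "arabidopsis"), each = 12),
    pos = c(7053, 2182, 436, 218, 145, 109, 87, 73, 62, 55, 48, 44,
            2172, 1149, 230, 115, 77, 57, 46, 38, 33, 29, 26, 23,
            1406, 812, 162, 81, 54, 41, 32, 27, 23, 20, 18, 16,
            231, 231, 57, 28, 19, 14, 11, 9, 8, 7, 6, 6),
    neg = c(7053, rep(218154, 11),
            2172, rep(114929, 11),
            1406, rep(81228, 11),
            231, 23100, rep(28359, 10)))
  virus <- data.frame(
    ratio = c(1, 50, 100, 200, 300, 400),
    dataset = "virus",
    pos = c(237, 17, 8, 4, 3, 2),
    neg = c(237, rep(839, 5)))
  rbind(std, virus)
}
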