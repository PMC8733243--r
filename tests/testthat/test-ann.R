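test_that("init_params: shapes follow the spec, deterministic per seed", {
  spec <- network_spec(29)
  p <- init_params(spec, seed = 5)
  expect_length(p$weights, 6L)
  expect_equal(dim(p$weights[[1]]), c(512L, 29L))
  expect_equal(dim(p$weights[[6]]), c(2L, 16L))
  expect_true(all(vapply(p$biases, function(b) all(b == 0), logical(1))))
  expect_identical(p, init_params(spec, seed = 5))
  expect_false(identical(p$weights[[1]], init_params(spec, 6)$weights[[1]]))
})

test_that("initial weights are zero-mean at the 3-SE level", {
  spec <- network_spec(100, hidden = 1000L)
  w <- init_params(spec, seed = 77)$weights[[1]]  # 1e5 draws, sd 0.1
  se <- 0.1 / sqrt(length(w))
  expect_lt(abs(mean(w)), 3 * se)
})

test_that("forward pass matches hand evaluation", {
  spec <- network_spec(2, hidden = 2L, dropout_rate = 0)
  p <- init_params(spec, 1)
  # identity first layer, zero bias, identity-ish output rows
  p$weights[[1]] <- diag(2)
  p$biases[[1]] <- c(0, 0)
  p$weights[[2]] <- diag(2)
  p$biases[[2]] <- c(0, 0)
  tr <- forward(p, spec, c(1, -1))
  expect_equal(tr$act[[1]], c(1, 0))  # ReLU clips the negative unit
  expect_equal(tr$scores, c(1, 0))

  p$weights[[1]] <- matrix(c(1, 0, 1, 1), 2, 2)  # rows [1,1] and [0,1]
  p$biases[[1]] <- c(0, -5)
  tr <- forward(p, spec, c(2, 3))
  expect_equal(tr$pre[[1]], c(5, -2))
  expect_equal(tr$scores, c(5, 0))

  p$weights[[1]][] <- 0; p$weights[[2]][] <- 0
  p$biases[[1]][] <- 0; p$biases[[2]][] <- 0
  tr <- forward(p, spec, c(2, 3))
  expect_equal(tr$pre[[1]], c(0, 0))
  expect_equal(tr$scores, c(0, 0))
})

test_that("forward contract errors and purity", {
  spec <- small_spec(3)
  p <- init_params(spec, 2)
  expect_error(forward(p, spec, c(1, 2)), "shape error")
  expect_error(forward(p, spec, c(1, 2, Inf)), "domain error")
  x <- rnorm(3)
  expect_identical(forward(p, spec, x), forward(p, spec, x))
})

test_that("dropout: train mode only, inverted scaling, rate-0 coincidence", {
  spec0 <- small_spec(4, hidden = c(6L, 6L), dropout_rate = 0)
  spec2 <- network_spec(4, hidden = c(6L, 6L), dropout_after = 1L,
                        dropout_rate = 0.5)
  p <- init_params(spec2, 3)
  x <- rnorm(4)
  expect_equal(forward(p, spec0, x, mode = "train", seed = 1)$scores,
               forward(p, spec0, x, mode = "infer")$scores)
  tr <- forward(p, spec2, x, mode = "train", seed = 1)
  expect_true(all(unlist(tr$masks[[1]]) %in% c(0, 2)))  # 1/(1-0.5) scaling
  expect_identical(forward(p, spec2, x, mode = "train", seed = 9)$scores,
                   forward(p, spec2, x, mode = "train", seed = 9)$scores)
})

test_that("decision_rule: argmax, lowest-index ties, inner-product case", {
  expect_equal(decision_rule(c(0.2, 0.9)), 1L)
  expect_equal(decision_rule(c(0.5, 0.5)), 0L)
  W <- matrix(c(1, 2, 0, 0), 2, 2)  # rows [1,0], [2,0]
  y <- as.numeric(W %*% c(3, 1))
  expect_equal(y, c(3, 6))
  expect_equal(decision_rule(y), 1L)
  expect_error(decision_rule(numeric(0)), "domain error")
  expect_equal(decision_rule(rbind(c(1, 0), c(0, 1), c(2, 2))),
               c(0L, 1L, 0L))
})

test_that("backprop gradients match the finite-difference oracle", {
  set.seed(101)
  for (rep in 1:20) {
    case <- gradient_check_case()
    g <- hdnnmir:::ann_gradients(case$params, case$spec, case$x,
                                 case$labels, lambda = 0)
    fd <- oracle_fd_gradients(case$params, case$x, case$labels)
    for (l in seq_along(case$params$weights)) {
      denom <- pmax(abs(fd$grad_w[[l]]), 1e-4)
      expect_lt(max(abs(g$grad_w[[l]] - fd$grad_w[[l]]) / denom), 1e-5)
      denom_b <- pmax(abs(fd$grad_b[[l]]), 1e-4)
      expect_lt(max(abs(g$grad_b[[l]] - fd$grad_b[[l]]) / denom_b), 1e-5)
    }
  }
})

test_that("the L2 term adds exactly lambda * w to weight gradients only", {
  spec <- small_spec(3, hidden = 4L)
  params <- init_params(spec, 11)
  x <- matrix(rnorm(15), 5, 3)
  labels <- c(0L, 1L, 1L, 0L, 1L)
  g0 <- hdnnmir:::ann_gradients(params, spec, x, labels, lambda = 0)
  g1 <- hdnnmir:::ann_gradients(params, spec, x, labels, lambda = 0.1)
  for (l in seq_along(params$weights)) {
    expect_equal(g1$grad_w[[l]] - g0$grad_w[[l]], 0.1 * params$weights[[l]],
                 tolerance = 1e-12)
    expect_equal(g1$grad_b[[l]], g0$grad_b[[l]])
  }
})

test_that("zero output error with lambda 0 leaves parameters unchanged", {
  # logits of +-1000 make the softmax exactly one-hot in floating point,
  # so the output error signal vanishes identically
  spec <- network_spec(1, hidden = 1L, dropout_rate = 0)
  params <- init_params(spec, 1)
  params$weights[[1]] <- matrix(1, 1, 1)
  params$biases[[1]] <- 0
  params$weights[[2]] <- matrix(c(1000, -1000), 2, 1)
  params$biases[[2]] <- c(0, 0)
  batch <- list(features = matrix(c(1, 2), 2, 1), labels = c(0L, 0L))
  cfg <- train_config(learning_rate = 0.5, lambda = 0, seed = 1)
  out <- backprop_update(params, spec, batch, cfg)
  expect_identical(out$weights, params$weights)
  expect_identical(out$biases, params$biases)
})

test_that("train_ann separates well-separated blobs within 2 epochs", {
  tab <- make_blobs(250, 250, p = 2, effect = 6, seed = 55)
  spec <- small_spec(2)
  model <- train_ann(tab, spec, train_config(epochs = 2, batch_size = 32,
                                             learning_rate = 0.2,
                                             seed = 21))
  acc <- mean(predict(model, tab) == tab$labels)
  expect_gte(acc, 0.95)
  expect_length(model$loss, 2L)
  again <- train_ann(tab, spec, train_config(epochs = 2, batch_size = 32,
                                             learning_rate = 0.2,
                                             seed = 21))
  expect_identical(model$params, again$params)
})

test_that("training contract cases", {
  tab <- make_blobs(20, 20, p = 2, seed = 1)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_ann(tab, small_spec(5), train_config()), "shape error")
  mono <- feature_table(matrix(rnorm(10), 5, 2), labels = rep(0L, 5))
  expect_error(train_ann(mono, small_spec(2), train_config()),
               "domain error")
})
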