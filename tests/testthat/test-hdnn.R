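test_that("gini_index matches hand values", {
  expect_equal(gini_index(c(10, 0)), 0)
  expect_equal(gini_index(c(5, 5)), 0.5)
  expect_equal(gini_index(c(25, 75)), 0.375)
  expect_error(gini_index(c(0, 0)), "domain error")
  expect_error(gini_index(c(-1, 2)), "domain error")
})

test_that("gini_index agrees with the brute-force loop on 0..50 x 0..50", {
  for (a in 0:50) for (b in 0:50) {
    if (a + b == 0) next
    total <- a + b
    brute <- 1 - (a / total)^2 - (b / total)^2
    expect_equal(gini_index(c(a, b)), brute, tolerance = 1e-14)
  }
})

test_that("evaluate_split: pure, uninformative and hand-computed splits", {
  tab <- feature_table(matrix(rnorm(20), 10, 2),
                       labels = rep(c(1L, 0L), each = 5))
  expect_equal(evaluate_split(tab, 1:5, 6:10), 0)          # pure halves
  expect_equal(evaluate_split(tab, c(1:3, 6:7), c(4:5, 8:10)),
               0.5 * gini_index(c(2, 3)) + 0.5 * gini_index(c(3, 2)))
  tab2 <- feature_table(matrix(rnorm(16), 8, 2),
                        labels = rep(c(1L, 0L), each = 4))
  # (3+,1-) / (1+,3-): both children gini 0.375
  expect_equal(evaluate_split(tab2, c(1, 2, 3, 5), c(4, 6, 7, 8)), 0.375)
  expect_error(evaluate_split(tab, 1:10, integer(0)), "split error")
  expect_error(evaluate_split(tab, 1:6, 5:10), "split error")
})

test_that("no-information split of a balanced node scores 0.5", {
  tab <- feature_table(matrix(rnorm(20), 10, 2),
                       labels = rep(c(1L, 0L), 5))
  halves <- evaluate_split(tab, 1:5, 6:10)  # alternating labels
  expect_equal(halves, 0.5, tolerance = 0.11)  # (3,2)/(2,3) split
})

test_that("degenerate roots give a single-leaf model", {
  pure <- feature_table(matrix(rnorm(40), 20, 2), labels = rep(0L, 20))
  m <- grow_tree(pure, small_spec(2), fast_grow())
  expect_true(m$root$leaf)
  expect_equal(m$root$leaf_label, 0L)
  expect_equal(m$root$gini, 0)
  expect_equal(predict(m, pure), rep(0L, 20))

  mixed <- make_blobs(30, 30, seed = 12)
  m0 <- grow_tree(mixed, small_spec(2), fast_grow(max_depth = 0L))
  expect_true(m0$root$leaf)
  expect_equal(m0$root$depth, 0L)
  # tie in class counts -> negative label
  expect_equal(m0$root$leaf_label, 0L)
})

test_that("the hybrid tree separates Gaussian blobs at IR 1:9", {
  tab <- generate_feature_table(synthetic_config(
    n_features = 29, n_positive = 100, n_negative = 900,
    effect_size = 6, n_informative = 29, seed = 77))
  spec <- network_spec(29, hidden = c(16L, 8L), dropout_rate = 0)
  m <- grow_tree(tab, spec, fast_grow(seed = 19))
  expect_false(m$root$leaf)  # root split accepted
  mets <- classification_metrics(confusion(tab$labels, predict(m, tab)))
  expect_gte(mets$f1_macro, 0.95)
})

test_that("tree invariants hold on a fitted model", {
  tab <- generate_feature_table(synthetic_config(
    n_features = 5, n_positive = 150, n_negative = 450,
    effect_size = 2, n_informative = 5, seed = 33))
  m <- grow_tree(tab, small_spec(5), fast_grow(seed = 7, max_depth = 4L))
  check_node <- function(node) {
    if (node$leaf) {
      expect_true(is.null(node$children))
      expect_true(node$leaf_label %in% c(0L, 1L))
      return(invisible())
    }
    expect_false(is.null(node$network))
    l <- node$children$left; r <- node$children$right
    # children partition the parent's training samples
    expect_length(intersect(l$train_idx, r$train_idx), 0)
    expect_setequal(c(l$train_idx, r$train_idx), node$train_idx)
    expect_equal(l$class_counts + r$class_counts, node$class_counts)
    # accepted splits never increase weighted impurity
    n <- sum(node$class_counts)
    wg <- (sum(l$class_counts) / n) * gini_index(l$class_counts) +
      (sum(r$class_counts) / n) * gini_index(r$class_counts)
    expect_lte(wg, node$gini)
    expect_lte(node$depth + 1L, m$grow_config$max_depth + 1L)
    check_node(l); check_node(r)
  }
  check_node(m$root)
  max_depth_seen <- local({
    f <- function(node) {
      if (node$leaf) return(node$depth)
      max(f(node$children$left), f(node$children$right))
    }
    f(m$root)
  })
  expect_lte(max_depth_seen, m$grow_config$max_depth)
})

test_that("predictions are deterministic and shape-checked", {
  tab <- make_blobs(50, 200, p = 3, seed = 21)
  m <- grow_tree(tab, small_spec(3), fast_grow(seed = 2))
  expect_identical(predict(m, tab), predict(m, tab))
  expect_error(predict(m, matrix(rnorm(10), 5, 2)), "shape error")
})

test_that("save/load round trip preserves predictions bit-exactly", {
  tab <- make_blobs(60, 240, p = 4, seed = 8)
  m <- grow_tree(tab, small_spec(4), fast_grow(seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, tab), predict(m, tab))

  # one network per internal node, none per leaf, in the JSON document
  doc <- jsonlite::read_json(path)
  check_nets <- function(nl) {
    if (isTRUE(nl$leaf)) {
      expect_null(nl$network)
      return(invisible())
    }
    expect_false(is.null(nl$network))
    check_nets(nl$children$left)
    check_nets(nl$children$right)
  }
  check_nets(doc$tree)
  expect_false(isTRUE(doc$tree$leaf))  # the fixture model has >= 1 split
})

test_that("model files are format-checked", {
  tab <- make_blobs(30, 120, p = 2, seed = 3)
  m <- grow_tree(tab, small_spec(2), fast_grow(seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  txt <- readLines(path)
  truncated <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 100), truncated)
  expect_error(load_model(truncated), "format error")
  other <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "something-else", version = 1), other,
                       auto_unbox = TRUE)
  expect_error(load_model(other), "format error")
})
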