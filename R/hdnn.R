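#' Gini impurity of a binary class distribution
#'
#' `1 - sum(p_j^2)` with `p_j = count_j / total`; 0 for a pure node, 0.5 for
#' a perfectly balanced binary node.  Used as the cost function for split
#' evaluation in the hybrid tree.
#'
#' @param class_counts Non-negative integer vector of per-class counts
#'   (two classes here), total > 0.
#' @return Gini impurity in `[0, 0.5]` for two classes.
#' @export
#' @examples
#' gini_index(c(10, 0))   # 0
#' gini_index(c(5, 5))    # 0.5
#' gini_index(c(25, 75))  # 0.375
gini_index <- function(class_counts) {
  if (any(class_counts < 0)) {
    stop("domain error: negative class count", call. = FALSE)
  }
  total <- sum(class_counts)
  if (total <= 0) {
    stop("domain error: gini of an empty node is undefined", call. = FALSE)
  }
  1 - sum((class_counts / total)^2)
}

#' Weighted Gini impurity of a candidate split
#'
#' `(n_L/n) gini(left) + (n_R/n) gini(right)` where the two index sets must
#' partition the node's samples.
#'
#' @param node_samples A [feature_table()] holding the samples at the node.
#' @param left_idx,right_idx Integer index sets into `node_samples`, each
#'   non-empty, disjoint, jointly covering all rows.
#' @return Weighted Gini impurity of the split.
#' @export
evaluate_split <- function(node_samples, left_idx, right_idx) {
  n <- n_samples(node_samples)
  if (length(left_idx) == 0L || length(right_idx) == 0L) {
    stop("split error: both sides of a split must be non-empty",
         call. = FALSE)
  }
  if (length(intersect(left_idx, right_idx)) ||
      length(union(left_idx, right_idx)) != n) {
    stop("split error: left/right must partition the node's samples",
         call. = FALSE)
  }
  counts <- function(idx) {
    lab <- node_samples$labels[idx]
    c(sum(lab == 0L), sum(lab == 1L))
  }
  (length(left_idx) / n) * gini_index(counts(left_idx)) +
    (length(right_idx) / n) * gini_index(counts(right_idx))
}

#' Growth configuration for the hybrid tree
#'
#' @param max_depth Maximum tree depth (root = 0), default 5.
#' @param min_samples_split Minimum node size eligible for splitting
#'   (>= 2), default 20.
#' @param min_impurity_decrease Minimum drop from parent Gini to weighted
#'   child Gini for a split to be accepted (>= 0), default 1e-4.
#' @param node_train A [train_config()] used for every node network.
#' @param seed Top-level seed; each node derives its own.
#' @return An object of class `grow_config`.
#' @export
grow_config <- function(max_depth = 5L, min_samples_split = 20L,
                        min_impurity_decrease = 1e-4,
                        node_train = train_config(), seed = 1L) {
  if (max_depth < 0L) stop("domain error: max_depth must be >= 0",
                           call. = FALSE)
  if (min_samples_split < 2L) {
    stop("domain error: min_samples_split must be >= 2", call. = FALSE)
  }
  if (min_impurity_decrease < 0) {
    stop("domain error: min_impurity_decrease must be >= 0", call. = FALSE)
  }
  stopifnot(inherits(node_train, "train_config"))
  structure(list(max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 min_impurity_decrease = min_impurity_decrease,
                 node_train = node_train, seed = as.integer(seed)),
            class = "grow_config")
}

node_class_counts <- function(labels) {
  c(sum(labels == 0L), sum(labels == 1L))
}

make_leaf <- function(node_id, depth, labels, train_idx) {
  counts <- node_class_counts(labels)
  list(node_id = node_id, depth = depth, leaf = TRUE,
       class_counts = counts, gini = gini_index(counts),
       # majority label; tie -> negative (the overall majority class)
       leaf_label = if (counts[2L] > counts[1L]) 1L else 0L,
       train_idx = train_idx,
       network = NULL, children = NULL)
}

grow_node <- function(table, idx, spec, config, depth, node_env) {
  node_id <- node_env$next_id
  node_env$next_id <- node_env$next_id + 1L
  labels <- table$labels[idx]
  counts <- node_class_counts(labels)
  pure <- counts[1L] == 0L || counts[2L] == 0L
  if (pure || depth >= config$max_depth ||
      length(idx) < config$min_samples_split) {
    return(make_leaf(node_id, depth, labels, idx))
  }
  node_table <- subset_rows(table, idx)
  node_cfg <- config$node_train
  node_cfg$seed <- derive_seed(config$seed, paste0("node", node_id))
  net <- train_ann(node_table, spec, node_cfg)
  routed <- predict(net, node_table)
  left_local <- which(routed == 0L)
  right_local <- which(routed == 1L)
  if (length(left_local) == 0L || length(right_local) == 0L) {
    return(make_leaf(node_id, depth, labels, idx))
  }
  parent_gini <- gini_index(counts)
  wg <- evaluate_split(node_table, left_local, right_local)
  if (parent_gini - wg < config$min_impurity_decrease) {
    return(make_leaf(node_id, depth, labels, idx))
  }
  left <- grow_node(table, idx[left_local], spec, config, depth + 1L,
                    node_env)
  right <- grow_node(table, idx[right_local], spec, config, depth + 1L,
                     node_env)
  list(node_id = node_id, depth = depth, leaf = FALSE,
       class_counts = counts, gini = parent_gini, leaf_label = NULL,
       train_idx = idx, network = net$params,
       children = list(left = left, right = right))
}

#' Grow a hybrid neural-network decision tree
#'
#' Recursively trains a dense network on the samples reaching each node,
#' routes every sample through the network's argmax decision rule (class 0
#' to the left child, class 1 to the right), and accepts the split only if
#' the weighted child Gini improves on the parent Gini by at least
#' `min_impurity_decrease`, the depth bound allows it, the node is large
#' enough, and both sides are non-empty; otherwise the node becomes a leaf
#' labeled with its majority class (ties go to the negative class).  Child
#' nodes re-learn from the original features of their samples, with freshly
#' initialized networks under derived seeds.  A single-class input yields a
#' depth-0 single-leaf model.
#'
#' @param table A [feature_table()].
#' @param spec A [network_spec()] for the node networks.
#' @param config A [grow_config()].
#' @return An object of class `hdnn_model`: `root` (nested node list),
#'   `spec`, `grow_config`, `feature_names`.
#' @export
grow_tree <- function(table, spec, config = grow_config()) {
  validate_feature_table(table)
  stopifnot(inherits(spec, "network_spec"), inherits(config, "grow_config"))
  if (n_features(table) != spec$layer_sizes[1L]) {
    stop("shape error: table has ", n_features(table),
         " features, spec expects ", spec$layer_sizes[1L], call. = FALSE)
  }
  node_env <- new.env(parent = emptyenv())
  node_env$next_id <- 1L
  root <- grow_node(table, seq_len(n_samples(table)), spec, config, 0L,
                    node_env)
  structure(list(root = root, spec = spec, grow_config = config,
                 feature_names = table$feature_names),
            class = "hdnn_model")
}

route_node <- function(node, spec, x, idx, out) {
  if (node$leaf) {
    out[idx] <- node$leaf_label
    return(out)
  }
  tr <- forward(node$network, spec, x[idx, , drop = FALSE], mode = "infer")
  scores <- tr$scores
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  routed <- decision_rule(scores)
  left <- idx[routed == 0L]
  right <- idx[routed == 1L]
  if (length(left)) out <- route_node(node$children$left, spec, x, left, out)
  if (length(right)) out <- route_node(node$children$right, spec, x, right,
                                       out)
  out
}

#' Predict with a hybrid tree model
#'
#' Routes each sample from the root to a leaf through the argmax decision
#' rule of every internal node's network (inference-mode forward pass, no
#' dropout) and returns the leaf labels.  Deterministic.
#'
#' @param object An `hdnn_model` from [grow_tree()].
#' @param table A [feature_table()] (labels ignored) or feature matrix with
#'   the model's feature count.
#' @param ... Unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.hdnn_model <- function(object, table, ...) {
  x <- if (inherits(table, "feature_table")) table$features else
    as.matrix(table)
  if (ncol(x) != object$spec$layer_sizes[1L]) {
    stop("shape error: input has ", ncol(x), " features, model expects ",
         object$spec$layer_sizes[1L], call. = FALSE)
  }
  out <- integer(nrow(x))
  route_node(object$root, object$spec, x, seq_len(nrow(x)), out)
}

count_nodes <- function(node, what = c("all", "leaf", "internal")) {
  what <- match.arg(what)
  here <- switch(what, all = 1L, leaf = as.integer(node$leaf),
                 internal = as.integer(!node$leaf))
  if (node$leaf) return(here)
  here + count_nodes(node$children$left, what) +
    count_nodes(node$children$right, what)
}

#' @exportS3Method base::print
print.hdnn_model <- function(x, ...) {
  cat(sprintf(
    "hdnn_model: %d nodes (%d internal, %d leaves), root gini %.3f\n",
    count_nodes(x$root), count_nodes(x$root, "internal"),
    count_nodes(x$root, "leaf"), x$root$gini))
  invisible(x)
}

MODEL_FORMAT <- "hdnn-model"
MODEL_VERSION <- 1L

node_to_list <- function(node) {
  out <- list(node_id = node$node_id, depth = node$depth, leaf = node$leaf,
              class_counts = node$class_counts, gini = node$gini)
  if (node$leaf) {
    out$leaf_label <- node$leaf_label
  } else {
    out$network <- list(weights = lapply(node$network$weights, identity),
                        biases = node$network$biases)
    out$children <- list(left = node_to_list(node$children$left),
                         right = node_to_list(node$children$right))
  }
  out
}

node_from_list <- function(nl) {
  node <- list(node_id = as.integer(nl$node_id),
               depth = as.integer(nl$depth),
               leaf = isTRUE(nl$leaf),
               class_counts = as.integer(nl$class_counts),
               gini = as.numeric(nl$gini),
               leaf_label = NULL, train_idx = NULL,
               network = NULL, children = NULL)
  if (node$leaf) {
    node$leaf_label <- as.integer(nl$leaf_label)
  } else {
    weights <- lapply(nl$network$weights, function(w) {
      w <- as.matrix(w)
      storage.mode(w) <- "double"
      w
    })
    biases <- lapply(nl$network$biases, as.numeric)
    node$network <- structure(list(weights = weights, biases = biases),
                              class = "network_params")
    node$children <- list(left = node_from_list(nl$children$left),
                          right = node_from_list(nl$children$right))
  }
  node
}

#' Save / load a hybrid tree model as versioned JSON
#'
#' The file stores the tree topology, per-node class counts and Gini, and
#' the network parameters of every internal node (leaves carry none).
#' `load_model(save_model(m))` reproduces identical predictions.
#'
#' @param model An `hdnn_model`.
#' @param path Output path for the JSON document.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `hdnn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hdnn_model"))
  doc <- list(format = MODEL_FORMAT, version = MODEL_VERSION,
              spec = unclass(model$spec),
              feature_names = model$feature_names,
              tree = node_to_list(model$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE),
    error = function(e) {
      stop("format error: cannot parse model file ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (!identical(doc$format, MODEL_FORMAT)) {
    stop("format error: not an hdnn model file", call. = FALSE)
  }
  if (!identical(as.integer(doc$version), MODEL_VERSION)) {
    stop("format error: unsupported model version ", doc$version,
         call. = FALSE)
  }
  spec <- structure(list(layer_sizes = as.integer(doc$spec$layer_sizes),
                         activation = doc$spec$activation,
                         dropout_after = as.integer(doc$spec$dropout_after),
                         dropout_rate = as.numeric(doc$spec$dropout_rate)),
                    class = "network_spec")
  structure(list(root = node_from_list(doc$tree), spec = spec,
                 grow_config = NULL,
                 feature_names = as.character(doc$feature_names)),
            class = "hdnn_model")
}
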