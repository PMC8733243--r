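#' Confusion counts for binary predictions
#'
#' Label 1 (true pre-miRNA) is the positive class.
#'
#' @param truth,pred Equal-length 0/1 vectors.
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("shape error: truth and pred lengths differ", call. = FALSE)
  }
  if (length(truth) && (!all(truth %in% c(0, 1)) ||
                        !all(pred %in% c(0, 1)))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  c(tp = sum(truth == 1 & pred == 1),
    fp = sum(truth == 0 & pred == 1),
    tn = sum(truth == 0 & pred == 0),
    fn = sum(truth == 1 & pred == 0))
}

#' Macro-averaged confusion-matrix metrics
#'
#' Accuracy, sensitivity (positive-class recall), specificity
#' (negative-class recall), and macro-averaged F1 and precision: per-class
#' precision/recall/F1 are computed with the 0/0 -> 0 convention (an
#' undefined precision, i.e. no predicted positives, counts as 0) and then
#' averaged with equal class weight.  Macro averaging is what makes a
#' degenerate all-negative classifier on an extremely imbalanced test set
#' report F1 and precision of 0.50: the negative class contributes ~1 and
#' the missed positive class contributes 0.
#'
#' @param counts A named vector from [confusion()] (`tp`, `fp`, `tn`, `fn`),
#'   total > 0.
#' @return An object of class `metric_set`: `acc`, `se`, `sp`, `f1_macro`,
#'   `prec_macro`, all in `[0, 1]`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  n <- tp + fp + tn + fn
  if (n <= 0) stop("domain error: no samples evaluated", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  prec_pos <- safe_div(tp, tp + fp)
  rec_pos <- safe_div(tp, tp + fn)
  prec_neg <- safe_div(tn, tn + fn)
  rec_neg <- safe_div(tn, tn + fp)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  structure(list(acc = (tp + tn) / n,
                 se = rec_pos,
                 sp = rec_neg,
                 f1_macro = mean(c(f1(prec_pos, rec_pos),
                                   f1(prec_neg, rec_neg))),
                 prec_macro = mean(c(prec_pos, prec_neg))),
            class = "metric_set")
}

#' @exportS3Method base::print
print.metric_set <- function(x, ...) {
  cat(sprintf("Acc %.2f  SE %.2f  SP %.2f  F1 %.2f  Prec %.2f\n",
              x$acc, x$se, x$sp, x$f1_macro, x$prec_macro))
  invisible(x)
}

#' Imbalance-ratio sweep
#'
#' For every ratio in the ladder: subsample the table to the target
#' imbalance ratio, split it stratified into train/test, grow a hybrid tree
#' on the training part and measure held-out metrics.  Ratios that leave no
#' positive sample on either side of the split are recorded as skipped
#' rather than failing the sweep.
#'
#' @param table A [feature_table()].
#' @param ladder Integer vector of imbalance ratios (see [ir_ladder()]).
#' @param spec A [network_spec()] for the node networks.
#' @param config A [grow_config()].
#' @param test_fraction Held-out fraction per class, default 0.3.
#' @param seed Top-level seed; per-ratio seeds are derived from it.
#' @return A data frame with one row per ratio: `ratio`, `n_pos`, `n_neg`,
#'   `skipped`, and the metric columns (`NA` when skipped).
#' @export
ir_sweep <- function(table, ladder, spec, config = grow_config(),
                     test_fraction = 0.3, seed = 1L) {
  validate_feature_table(table)
  rows <- lapply(ladder, function(ratio) {
    rseed <- derive_seed(seed, paste0("ir", ratio))
    row <- data.frame(ratio = ratio, n_pos = NA_integer_,
                      n_neg = NA_integer_, skipped = TRUE,
                      acc = NA_real_, se = NA_real_, sp = NA_real_,
                      f1_macro = NA_real_, prec_macro = NA_real_)
    sub <- tryCatch(
      subsample_to_ir(table, imbalance_spec(ratio, seed = rseed)),
      error = function(e) NULL)
    if (is.null(sub)) return(row)
    row$n_pos <- sum(sub$labels == 1L)
    row$n_neg <- sum(sub$labels == 0L)
    if (row$n_pos == 0L || row$n_neg == 0L) return(row)
    split <- tryCatch(
      stratified_split(sub, test_fraction = test_fraction, seed = rseed),
      error = function(e) NULL)
    if (is.null(split) ||
        !any(split$test$labels == 1L) || !any(split$train$labels == 1L) ||
        !any(split$train$labels == 0L)) {
      return(row)
    }
    cfg <- config
    cfg$seed <- rseed
    model <- grow_tree(split$train, spec, cfg)
    m <- classification_metrics(
      confusion(split$test$labels, predict(model, split$test)))
    row$skipped <- FALSE
    row[c("acc", "se", "sp", "f1_macro", "prec_macro")] <-
      unclass(m)[c("acc", "se", "sp", "f1_macro", "prec_macro")]
    row
  })
  do.call(rbind, rows)
}
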