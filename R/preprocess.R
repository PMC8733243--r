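#' Pearson correlation matrix of the features
#'
#' Product-moment correlations between all feature pairs.  Constant
#' (zero-variance) features would give undefined correlations; their rows and
#' columns (including the diagonal) are set to 0 and a warning is issued, so
#' the matrix stays finite for downstream display.
#'
#' @param table A [feature_table()] with at least 2 samples.
#' @return A symmetric p x p numeric matrix with unit diagonal for
#'   non-constant features.
#' @export
correlation_matrix <- function(table) {
  validate_feature_table(table)
  if (n_samples(table) < 2L) {
    stop("correlation requires at least 2 samples", call. = FALSE)
  }
  x <- table$features
  const <- apply(x, 2, function(col) isTRUE(all.equal(var(col), 0)) ||
                   var(col) == 0)
  cm <- suppressWarnings(cor(x))
  if (any(const)) {
    warning("constant feature(s) flagged with correlation 0: ",
            paste(table$feature_names[const], collapse = ", "),
            call. = FALSE)
    cm[const, ] <- 0
    cm[, const] <- 0
  }
  diag(cm)[!const] <- 1
  cm[is.na(cm)] <- 0
  cm
}

# per-feature one-way ANOVA F statistic between the two label groups
anova_f_scores <- function(table) {
  g <- factor(table$labels, levels = c(0L, 1L))
  apply(table$features, 2, function(col) {
    if (var(col) == 0) return(0)
    f <- tryCatch(
      unname(oneway.test(col ~ g, var.equal = TRUE)$statistic),
      error = function(e) NA_real_)
    if (!is.finite(f)) f <- 0
    f
  })
}

#' Univariate feature screening with a mean-score threshold
#'
#' Scores every feature by the one-way ANOVA F statistic between the positive
#' and negative groups and selects the features whose score is greater than
#' or equal to the mean of all scores ("select-K-best" with K set by the mean
#' rule).  With `>=`, an all-equal score vector selects every feature rather
#' than none.  F statistics are invariant under per-feature affine rescaling,
#' so the selection is scale-invariant.
#'
#' @param table A [feature_table()] with both classes present.
#' @return An object of class `feature_scores`: list with `method`,
#'   `scores` (one per feature, named) and logical `selected` mask.
#' @export
select_k_best <- function(table) {
  validate_feature_table(table)
  if (length(unique(table$labels)) < 2L) {
    stop("domain error: both classes must be present to score features",
         call. = FALSE)
  }
  scores <- anova_f_scores(table)
  structure(list(method = "select_k_best",
                 scores = scores,
                 selected = scores >= mean(scores)),
            class = "feature_scores")
}

#' Recursive feature elimination with cross-validated importances
#'
#' Ranks features by recursive elimination: at each step a ridge-penalised
#' logistic regression (the base learner) is fitted on each of `folds`
#' stratified cross-validation folds on standardized features, the mean
#' absolute coefficient across folds is the importance, and the least
#' important remaining feature is eliminated.  The elimination order is
#' converted to a score in \[0, 1\]: 0 for the first feature eliminated
#' (least important), 1 for the last survivor (most important).  Features
#' with score >= 0.5 (the upper half of the ranking) are marked selected.
#'
#' @param table A [feature_table()] with both classes present.
#' @param folds Number of cross-validation folds (>= 2, default 5); must not
#'   exceed the minority-class count.
#' @param seed Integer seed for the fold assignment; results are
#'   reproducible for a fixed seed.
#' @return A `feature_scores` object (`method = "rfe_cv"`); scores in
#'   \[0, 1\].
#' @export
rfe_cv <- function(table, folds = 5L, seed = 1L) {
  validate_feature_table(table)
  if (length(unique(table$labels)) < 2L) {
    stop("domain error: both classes must be present", call. = FALSE)
  }
  if (folds < 2L) stop("domain error: folds must be >= 2", call. = FALSE)
  n_min <- min(table(table$labels))
  if (folds > n_min) {
    stop("stratification error: folds (", folds,
         ") exceed the minority class count (", n_min, ")", call. = FALSE)
  }
  p <- n_features(table)
  y <- table$labels
  fold_of <- withr::with_seed(derive_seed(seed, "rfe_cv"), {
    f <- integer(length(y))
    for (cls in c(0L, 1L)) {
      members <- which(y == cls)
      f[members] <- sample(rep_len(seq_len(folds), length(members)))
    }
    f
  })
  remaining <- seq_len(p)
  elim_order <- integer(0)
  while (length(remaining) > 1L) {
    imp <- numeric(length(remaining))
    for (k in seq_len(folds)) {
      tr <- fold_of != k
      xtr <- table$features[tr, remaining, drop = FALSE]
      fit <- glmnet::glmnet(xtr, y[tr], family = "binomial", alpha = 0,
                            lambda = 0.1, standardize = TRUE)
      imp <- imp + abs(as.numeric(coef(fit))[-1L])
    }
    drop_local <- which.min(imp / folds)
    elim_order <- c(elim_order, remaining[drop_local])
    remaining <- remaining[-drop_local]
  }
  rank_order <- c(elim_order, remaining)  # least -> most important
  scores <- numeric(p)
  scores[rank_order] <- if (p == 1L) 1 else (seq_len(p) - 1) / (p - 1)
  names(scores) <- table$feature_names
  structure(list(method = "rfe_cv",
                 scores = scores,
                 selected = scores >= 0.5),
            class = "feature_scores")
}

#' Project a feature table onto a selection mask
#'
#' @param table A [feature_table()].
#' @param mask Logical vector, one entry per feature, at least one `TRUE`.
#' @return A [feature_table()] with the masked columns only, names and order
#'   preserved.
#' @export
apply_selection <- function(table, mask) {
  validate_feature_table(table)
  if (length(mask) != n_features(table)) {
    stop("mask length (", length(mask), ") must equal the feature count (",
         n_features(table), ")", call. = FALSE)
  }
  if (!any(mask)) {
    stop("domain error: selection mask removes every feature", call. = FALSE)
  }
  feature_table(table$features[, mask, drop = FALSE], table$labels,
                feature_names = table$feature_names[mask],
                sample_ids = table$sample_ids)
}

#' Full preprocessing report
#'
#' Runs the correlation matrix, the mean-threshold univariate filter and
#' cross-validated recursive feature elimination, and combines the two
#' selection masks (element-wise AND by default).
#'
#' @inheritParams rfe_cv
#' @param combine How to combine the two masks: `"and"` (default), `"or"`,
#'   `"kbest"` or `"rfe"`.
#' @return An object of class `preprocess_report`: `correlation`, `kbest`,
#'   `rfe`, `final_mask`.
#' @export
preprocess_report <- function(table, folds = 5L, seed = 1L,
                              combine = c("and", "or", "kbest", "rfe")) {
  combine <- match.arg(combine)
  kb <- select_k_best(table)
  rf <- rfe_cv(table, folds = folds, seed = seed)
  final_mask <- switch(combine,
                       and = kb$selected & rf$selected,
                       or = kb$selected | rf$selected,
                       kbest = kb$selected,
                       rfe = rf$selected)
  structure(list(correlation = correlation_matrix(table),
                 kbest = kb, rfe = rf, final_mask = final_mask,
                 combine = combine),
            class = "preprocess_report")
}
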