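#' Construct a labeled feature table
#'
#' The universal currency of the pipeline: a numeric matrix with one row per
#' candidate hairpin, a binary label per row (1 = true precursor miRNA,
#' 0 = pseudo-hairpin), feature names and sample identifiers.
#'
#' @param features Numeric matrix, samples in rows, features in columns.
#' @param labels Integer vector of 0/1 class labels, one per row.
#' @param feature_names Character vector of column names (defaults to the
#'   matrix colnames, or `f1..fp`).
#' @param sample_ids Character vector of row identifiers (defaults to the
#'   matrix rownames, or `s1..sn`).
#'
#' @return An object of class `feature_table` with elements `features`,
#'   `labels`, `feature_names`, `sample_ids`.
#' @export
#' @examples
#' ft <- feature_table(matrix(rnorm(20), 10, 2), labels = rep(c(0, 1), 5))
#' n_samples(ft)
feature_table <- function(features, labels, feature_names = NULL,
                          sample_ids = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  feature_names <- feature_names %||% colnames(features) %||%
    paste0("f", seq_len(ncol(features)))
  sample_ids <- sample_ids %||% rownames(features) %||%
    paste0("s", seq_len(nrow(features)))
  dimnames(features) <- list(sample_ids, feature_names)
  out <- structure(
    list(features = features, labels = labels,
         feature_names = as.character(feature_names),
         sample_ids = as.character(sample_ids)),
    class = "feature_table"
  )
  validate_feature_table(out)
  out
}

validate_feature_table <- function(x) {
  if (nrow(x$features) != length(x$labels) ||
      nrow(x$features) != length(x$sample_ids)) {
    stop("feature_table: rows of `features`, `labels` and `sample_ids` ",
         "must all have equal length", call. = FALSE)
  }
  if (ncol(x$features) != length(x$feature_names)) {
    stop("feature_table: `feature_names` must match the feature columns",
         call. = FALSE)
  }
  if (length(x$labels) && !all(x$labels %in% c(0L, 1L))) {
    bad <- unique(x$labels[!x$labels %in% c(0L, 1L)])
    stop("feature_table: labels must be 0/1; found ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(x$features) && any(!is.finite(x$features))) {
    stop("feature_table: features contain NaN/Inf/NA values", call. = FALSE)
  }
  invisible(x)
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "feature_table: %d samples x %d features (%d positive, %d negative)\n",
    n_samples(x), n_features(x), sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Dimensions of a feature table
#' @param table A `feature_table`.
#' @return Integer count.
#' @export
n_samples <- function(table) nrow(table$features)

#' @rdname n_samples
#' @export
n_features <- function(table) ncol(table$features)

# row subset preserving all parallel fields
subset_rows <- function(table, idx) {
  feature_table(table$features[idx, , drop = FALSE],
                table$labels[idx],
                feature_names = table$feature_names,
                sample_ids = table$sample_ids[idx])
}

#' Read a labeled feature table from CSV/TSV
#'
#' Reads a delimited text file with a header row into a [feature_table()].
#' An identifier/serial-number column, if present, is excluded from the
#' feature matrix by explicit name (never by position heuristics).  String
#' class labels can be mapped to 0/1 through `label_map`.
#'
#' @param path Path to the delimited file.
#' @param label_column Name of the label column.
#' @param id_column Optional name of a sample-id / serial-number column to
#'   drop from the features and use as `sample_ids`.
#' @param delimiter Field delimiter, default `","` (use `"\t"` for TSV).
#' @param label_map Optional named vector mapping string labels to 0/1,
#'   e.g. `c(negative = 0, positive = 1)`.
#'
#' @return A [feature_table()]; all remaining columns become features in
#'   file order.
#' @export
read_feature_table <- function(path, label_column = "label",
                               id_column = NULL, delimiter = ",",
                               label_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = TRUE, sep = delimiter,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = NA)
  if (!label_column %in% names(df)) {
    stop("format error: label column '", label_column, "' not present in ",
         path, call. = FALSE)
  }
  sample_ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(df)) {
      stop("format error: id column '", id_column, "' not present in ",
           path, call. = FALSE)
    }
    sample_ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  labels_raw <- df[[label_column]]
  df[[label_column]] <- NULL
  if (!is.null(label_map)) {
    if (!all(labels_raw %in% names(label_map))) {
      bad <- setdiff(unique(labels_raw), names(label_map))
      stop("label error: unmapped label value(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    labels_raw <- unname(label_map[as.character(labels_raw)])
  }
  labels <- suppressWarnings(as.numeric(labels_raw))
  if (any(is.na(labels)) || !all(labels %in% c(0, 1))) {
    bad <- unique(labels_raw[is.na(labels) | !labels %in% c(0, 1)])
    stop("label error: labels must be 0/1 (or mapped via label_map); found ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (any(is.na(num) & !is.na(col))) {
        row <- which(is.na(num) & !is.na(col))[1L]
        stop("parse error: non-numeric value '", col[row],
             "' in column '", names(df)[j], "', row ", row, call. = FALSE)
      }
      df[[j]] <- num
    }
  }
  feats <- as.matrix(df)
  if (any(is.na(feats))) {
    stop("parse error: missing value in feature columns of ", path,
         call. = FALSE)
  }
  feature_table(feats, labels, feature_names = names(df),
                sample_ids = sample_ids)
}

#' Write a feature table to CSV/TSV
#'
#' Feature values are written with 17 significant digits so that a
#' write-then-read round trip reproduces the numeric matrix bit-exactly.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param delimiter Field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delimiter = ",") {
  validate_feature_table(table)
  txt <- apply(table$features, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = n_samples(table))
  df <- data.frame(id = table$sample_ids, txt, label = table$labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("id", table$feature_names, "label")
  ok <- tryCatch({
    write.table(df, path, sep = delimiter, row.names = FALSE,
                quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("I/O error writing ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits a feature table into train and test parts, per class, so that even
#' at imbalance ratios of 1:5000 the test set keeps its share of positives.
#' The number of test samples per class is `round(n_class * test_fraction)`.
#'
#' @param table A [feature_table()] with at least one sample of each class.
#' @param test_fraction Fraction of each class assigned to the test set,
#'   in (0, 1).  Default 0.3.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with `feature_table` elements `train` and `test`.
#' @export
stratified_split <- function(table, test_fraction = 0.3, seed = 1L) {
  validate_feature_table(table)
  stopifnot(test_fraction > 0, test_fraction < 1)
  for (cls in c(0L, 1L)) {
    if (!any(table$labels == cls)) {
      stop("stratification error: class ", cls, " has no members",
           call. = FALSE)
    }
  }
  test_idx <- withr::with_seed(derive_seed(seed, "stratified_split"), {
    unlist(lapply(c(0L, 1L), function(cls) {
      members <- which(table$labels == cls)
      k <- round_half_up(length(members) * test_fraction)
      k <- max(0L, min(k, length(members)))
      if (k == 0L) integer(0) else sort(sample(members, k))
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n_samples(table)), test_idx)
  list(train = subset_rows(table, train_idx),
       test = subset_rows(table, test_idx))
}
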