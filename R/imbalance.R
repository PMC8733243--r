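#' Imbalance-ratio subsampling specification
#'
#' An imbalance ratio (IR) of 1:k means one positive (true pre-miRNA) per k
#' negatives (pseudo-hairpins) in the constructed benchmark dataset.
#'
#' @param ratio Integer >= 1, negatives per positive.
#' @param seed Integer seed controlling which rows of the downsampled class
#'   are kept.
#' @return An object of class `imbalance_spec`.
#' @export
imbalance_spec <- function(ratio, seed = 1L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 1 ||
      ratio != floor(ratio)) {
    stop("domain error: ratio must be an integer >= 1", call. = FALSE)
  }
  structure(list(ratio = as.integer(ratio), seed = as.integer(seed)),
            class = "imbalance_spec")
}

#' Target class counts for an imbalance ratio
#'
#' The deterministic count rule behind the benchmark IR ladders.  The primary
#' rule keeps ALL negatives and sets the positive count to
#' `round(n_negative / ratio)` (round-half-up).  When the dataset does not
#' contain that many positives, the fallback keeps ALL positives and
#' subsamples the negatives to `n_positive * ratio` (capped at the available
#' negatives).  This single rule reproduces every cell of the published
#' animal/plant/human/arabidopsis and virus count ladders, including the
#' nearest-integer cases (218,154 / 3,000 = 72.718 -> 73) and the fallback
#' cases (arabidopsis 1:100 -> 231 positives, 23,100 negatives; all 1:1 rows).
#'
#' @param n_positive,n_negative Available class counts (integers >= 1).
#' @param ratio Integer >= 1, negatives per positive.
#' @return Named integer vector `c(n_pos_out, n_neg_out)`.
#' @export
#' @examples
#' target_counts(7053, 218154, 500)   # 436 positives, all negatives
#' target_counts(231, 28359, 100)     # fallback: all positives, 23,100 neg
target_counts <- function(n_positive, n_negative, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 ||
      ratio != floor(ratio)) {
    stop("domain error: ratio must be a positive integer", call. = FALSE)
  }
  stopifnot(n_positive >= 1, n_negative >= 1)
  n_pos_out <- round_half_up(n_negative / ratio)
  if (n_pos_out <= n_positive) {
    out <- c(n_pos_out = n_pos_out, n_neg_out = n_negative)
  } else {
    out <- c(n_pos_out = n_positive,
             n_neg_out = min(n_positive * ratio, n_negative))
  }
  as.integer(out) |> stats::setNames(c("n_pos_out", "n_neg_out"))
}

#' Subsample a feature table to a target imbalance ratio
#'
#' Applies [target_counts()] and keeps a uniform random subset (without
#' replacement) of the downsampled class; the other class is retained in
#' full.  Retained rows keep their original order.  Deterministic for a
#' fixed `spec$seed`.
#'
#' @param table A [feature_table()] with both classes present.
#' @param spec An [imbalance_spec()].
#' @return A [feature_table()] whose class counts equal [target_counts()].
#' @export
subsample_to_ir <- function(table, spec) {
  validate_feature_table(table)
  stopifnot(inherits(spec, "imbalance_spec"))
  pos <- which(table$labels == 1L)
  neg <- which(table$labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("domain error: both classes must be present to subsample",
         call. = FALSE)
  }
  tc <- target_counts(length(pos), length(neg), spec$ratio)
  keep <- withr::with_seed(derive_seed(spec$seed, "subsample_to_ir"), {
    keep_pos <- if (tc[["n_pos_out"]] < length(pos)) {
      sample(pos, tc[["n_pos_out"]])
    } else pos
    keep_neg <- if (tc[["n_neg_out"]] < length(neg)) {
      sample(neg, tc[["n_neg_out"]])
    } else neg
    sort(c(keep_pos, keep_neg))
  })
  subset_rows(table, keep)
}

#' Benchmark imbalance-ratio ladders
#'
#' The standard ladder used for the animal, plant, human and arabidopsis
#' genome benchmarks runs from 1:1 to 1:5000; the virus dataset is far
#' smaller and uses its own ladder ending at 1:400.
#'
#' @param dataset_kind `"standard"` or `"virus"`.
#' @return Integer vector of ratios.
#' @export
ir_ladder <- function(dataset_kind = c("standard", "virus")) {
  if (!is.character(dataset_kind) || length(dataset_kind) != 1L ||
      !dataset_kind %in% c("standard", "virus")) {
    stop("domain error: dataset_kind must be 'standard' or 'virus'",
         call. = FALSE)
  }
  switch(dataset_kind,
         standard = c(1L, 100L, 500L, 1000L, 1500L, 2000L, 2500L, 3000L,
                      3500L, 4000L, 4500L, 5000L),
         virus = c(1L, 50L, 100L, 200L, 300L, 400L))
}
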