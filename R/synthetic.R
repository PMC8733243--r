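#' Configuration for the synthetic feature-table generator
#'
#' Emulates the shape of the genome benchmark tables: 29 numeric hairpin
#' features per candidate, two classes, imbalance ratios up to 1:5000.
#' Negatives are drawn from a zero-mean equicorrelated Gaussian; positives
#' are identical except that the first `n_informative` features are shifted
#' by `effect_size` standard deviations.  The Gaussian is the minimal model
#' with tunable separation and correlation; it makes no attempt at
#' sequence-level realism.
#'
#' @param n_features Number of features, default 29.
#' @param n_positive,n_negative Class counts.
#' @param effect_size Mean shift of the informative features for positives,
#'   in SD units (>= 0).  Default 2.
#' @param n_informative Number of shifted features (<= `n_features`),
#'   default `min(10, n_features)`.
#' @param correlation_rho Equicorrelation among features, in `[0, 1)`.
#'   Default 0.
#' @param seed Integer seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_features = 29L, n_positive = 100L,
                             n_negative = 100L, effect_size = 2,
                             n_informative = min(10L, n_features),
                             correlation_rho = 0, seed = 1L) {
  stopifnot(n_features >= 1, n_positive >= 0, n_negative >= 0,
            effect_size >= 0, correlation_rho >= 0, correlation_rho < 1)
  if (n_informative > n_features) {
    stop("n_informative must be <= n_features", call. = FALSE)
  }
  structure(list(n_features = as.integer(n_features),
                 n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 effect_size = effect_size,
                 n_informative = as.integer(n_informative),
                 correlation_rho = correlation_rho,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic two-class feature table
#'
#' Each sample is `sqrt(rho) * z0 + sqrt(1 - rho) * z` with a shared
#' standard-normal `z0` per sample and independent standard normals `z`,
#' giving unit marginal variance and pairwise correlation `rho` between
#' features.  Positives get `effect_size` added to their first
#' `n_informative` features.  Rows are returned in a seeded random
#' permutation (no class blocks).  Deterministic per seed.
#'
#' @param config A [synthetic_config()].
#' @return A [feature_table()] with `config$n_positive + config$n_negative`
#'   rows.
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_positive + config$n_negative
  if (n == 0L) stop("domain error: zero total samples", call. = FALSE)
  p <- config$n_features
  withr::with_seed(derive_seed(config$seed, "generate_feature_table"), {
    z0 <- rnorm(n)
    z <- matrix(rnorm(n * p), n, p)
    x <- sqrt(config$correlation_rho) * z0 +
      sqrt(1 - config$correlation_rho) * z
    labels <- c(rep(1L, config$n_positive), rep(0L, config$n_negative))
    if (config$n_informative > 0L && config$n_positive > 0L) {
      shift_cols <- seq_len(config$n_informative)
      x[labels == 1L, shift_cols] <- x[labels == 1L, shift_cols] +
        config$effect_size
    }
    ord <- sample.int(n)
    feature_table(x[ord, , drop = FALSE], labels[ord],
                  feature_names = paste0("f", seq_len(p)),
                  sample_ids = sprintf("s%05d", seq_len(n)))
  })
}

#' Dataset manifest
#'
#' @param name Dataset name.
#' @param n_positive,n_negative Non-negative class counts.
#' @return An object of class `dataset_manifest` with `name`, `n_positive`,
#'   `n_negative`, `total`.
#' @export
dataset_manifest <- function(name, n_positive, n_negative) {
  stopifnot(is.character(name), length(name) == 1L,
            n_positive >= 0, n_negative >= 0)
  structure(list(name = name, n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 total = as.integer(n_positive + n_negative)),
            class = "dataset_manifest")
}

# Published sizes of the five genome benchmark collections.  The plant
# positive count is 2,172: the 1:1 ladder row and the stated grand total
# (117,101 = 2,172 + 114,929) agree on 2,172, so that value is used.
FIXTURE_MANIFESTS <- list(
  animal      = c(n_positive = 7053L,  n_negative = 218154L),
  plant       = c(n_positive = 2172L,  n_negative = 114929L),
  human       = c(n_positive = 1406L,  n_negative = 81228L),
  arabidopsis = c(n_positive = 231L,   n_negative = 28359L),
  virus       = c(n_positive = 237L,   n_negative = 839L)
)

#' Benchmark dataset manifests
#'
#' Class counts of the five genome benchmark datasets used for the
#' imbalance-ratio ladders: animal (7,053 / 218,154), plant
#' (2,172 / 114,929), human (1,406 / 81,228), arabidopsis (231 / 28,359)
#' and virus (237 / 839).
#'
#' @param name One of `"animal"`, `"plant"`, `"human"`, `"arabidopsis"`,
#'   `"virus"`.
#' @return A [dataset_manifest()].
#' @export
#' @examples
#' make_fixture_manifest("animal")$total  # 225207
make_fixture_manifest <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(FIXTURE_MANIFESTS)) {
    stop("domain error: unknown dataset name '", name, "'; expected one of ",
         paste(names(FIXTURE_MANIFESTS), collapse = ", "), call. = FALSE)
  }
  counts <- FIXTURE_MANIFESTS[[name]]
  dataset_manifest(name, counts[["n_positive"]], counts[["n_negative"]])
}

#' Read / write a dataset manifest as JSON
#'
#' @param manifest A [dataset_manifest()].
#' @param path JSON file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the `dataset_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  jsonlite::write_json(
    list(name = manifest$name, n_positive = manifest$n_positive,
         n_negative = manifest$n_negative),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dataset_manifest(doc$name, doc$n_positive, doc$n_negative)
}
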