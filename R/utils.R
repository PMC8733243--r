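#' @importFrom stats cor oneway.test rnorm runif sd var coef predict
#' @importFrom utils read.table write.table modifyList
NULL

# Deterministic seed fan-out: one top-level seed, one derived seed per named
# stage.  Kept strictly below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# round-half-up to the nearest integer (base round() is round-half-even,
# which would break the imbalance-ladder reproduction at .5 boundaries)
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
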