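#' Derive a reproducible sub-stream seed
#'
#' Expands one user-facing integer seed into independent per-operation seeds,
#' so that (for example) error injection in an evaluation fold does not
#' perturb the random stream used to build the fold itself. The derivation is
#' a fixed integer hash of the label folded into the parent seed; it is pure,
#' so the same `(seed, label)` pair always yields the same sub-seed.
#'
#' @param seed Integer parent seed.
#' @param label Character scalar naming the sub-stream.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "error-injection")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label), length(label) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% (m - 1) + 1)
}

# run `expr` under a local RNG stream seeded with `seed`; global RNG untouched
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# lexicographic argmax: index of the largest value, ties broken by the
# lexicographic order of `labels`
argmax_lex <- function(x, labels) {
  ord <- order(labels)
  x <- x[ord]
  labels <- labels[ord]
  labels[which.max(x)]
}
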