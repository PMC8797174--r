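#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# round-half-up: deterministic removal counts (round() in R is banker's
# rounding, which would map 0.5 down for even targets)
round_half_up <- function(x) floor(x + 0.5)

# run `expr` under a local RNG seeded with `seed`; global RNG untouched.
# seed = NULL uses (and advances) the current RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# canonical unordered pair key "a|b" with a <= b lexicographically
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

stopifnot_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
}
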