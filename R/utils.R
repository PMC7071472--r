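#' Run an expression under a deterministic RNG substream
#'
#' All randomness in the package flows from one root seed through counter-based
#' substreams, so that participant `i` of a cohort is reproducible in isolation
#' and no call disturbs the caller's RNG state.
#'
#' @param root integer root seed (< 2^31).
#' @param counter non-negative integer stream counter.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(root, counter, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(root, counter))
  expr
}

#' Derive a substream seed from a root seed and a counter
#'
#' Splitmix-style integer hash folded into the 31-bit range accepted by
#' `set.seed()`. Distinct (root, counter) pairs map to well-separated seeds.
#'
#' @inheritParams with_substream
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
substream_seed <- function(root, counter) {
  stopifnot(length(root) == 1, length(counter) == 1, counter >= 0)
  # 64-bit arithmetic via doubles is exact below 2^53; keep products bounded
  x <- (as.numeric(root) %% 2147483647) * 48271 %% 2147483647
  x <- (x + as.numeric(counter) * 69621 + 1) %% 2147483647
  x <- (x * 16807 + 2147483629) %% 2147483647
  as.integer(x)
}

#' Stop with a configuration error naming the offending field
#' @keywords internal
#' @noRd
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

#' @keywords internal
#' @noRd
assert_scalar_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    config_error(field, "must be a single positive finite number")
  }
  invisible(x)
}
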