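#' Round half away from zero
#'
#' Reported rates and ratios are rounded to a fixed number of decimals with
#' halves moving away from zero (so 4.25 -> 4.3), matching the convention of
#' surveillance summary tables rather than the IEEE half-to-even rule of
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.25, -0.25, 2.345), 1)
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Validate that `x` is a single finite number in [lo, hi]; `what` names the
# offending field in the error message.
check_prob <- function(x, what, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", what, lo, hi),
          class = "asdsurv_config_error")
  }
  invisible(x)
}

check_count <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d", what, min),
          class = "asdsurv_config_error")
  }
  invisible(as.integer(x))
}

check_weights <- function(w, what, names_expected = NULL, tol = 1e-9) {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0)) {
    abort(sprintf("`%s` must be nonnegative finite weights", what),
          class = "asdsurv_config_error")
  }
  if (!is.null(names_expected) && !identical(sort(names(w)),
                                             sort(names_expected))) {
    abort(sprintf("`%s` must be named over {%s}", what,
                  paste(names_expected, collapse = ", ")),
          class = "asdsurv_config_error")
  }
  if (abs(sum(w) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12f)", what, sum(w)),
          class = "asdsurv_config_error")
  }
  invisible(w)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a child stream seed from a base seed, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.double(seed) * 48271 + offset) %% 2147483629
}
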