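#' @importFrom rlang abort warn .data
#' @importFrom stats optimize pf p.adjust ks.test rnorm runif sd setNames
#' @importFrom utils head tail
NULL

# all(finite) check with a readable error naming the offending argument
check_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || !all(is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric.", what),
          class = "surfqtl_invalid_argument")
  }
  invisible(x)
}

check_scalar <- function(x, what) {
  if (length(x) != 1L) {
    abort(sprintf("`%s` must be a single value.", what),
          class = "surfqtl_invalid_argument")
  }
  check_finite(x, what)
}

# seed handling: every stochastic operation takes an explicit seed
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number.",
            class = "surfqtl_invalid_argument")
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
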