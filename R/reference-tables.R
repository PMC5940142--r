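#' Published quadratic coefficients for the eight reference surfaces
#'
#' Regression coefficients of the smoothed quadratic response surfaces for
#' the B73 and Mo17 parental inbreds and the B73/Mo17 allele groups at the
#' three mapped QTL of the B73 x Mo17 drought-by-nitrogen study. These are
#' the fitted inputs the shape-analysis stages consume; columns follow the
#' published order (paraboloid, hyperbolic, plane, constant).
#'
#' @return A tibble with columns `label`, `beta3`, `beta4`, `beta5`,
#'   `beta1`, `beta2`, `ell`.
#' @examples
#' allele_surface_coefs()
#' @export
allele_surface_coefs <- function() {
  tibble::tribble(
    ~label,       ~beta3,    ~beta4,    ~beta5,    ~beta1,    ~beta2,   ~ell,
    "B73",       -0.006042, -0.188712,  0.025567,  0.229554,  0.997363, 32.034927,
    "QTL1-B73",  -0.004447, -0.110527,  0.007851,  0.251079,  0.542153, 29.572431,
    "QTL2-Mo17", -0.005370, -0.105151,  0.007068,  0.239113,  0.497335, 30.499056,
    "QTL3-Mo17", -0.005307, -0.116559,  0.005924,  0.249475,  0.525478, 31.324343,
    "QTL1-Mo17", -0.003192, -0.049303,  0.004224,  0.215691,  0.317815, 26.144178,
    "QTL2-B73",  -0.002367, -0.068065,  0.006244,  0.237807,  0.418609, 25.779661,
    "QTL3-B73",  -0.002917, -0.063999,  0.008152,  0.228592,  0.411333, 25.720664,
    "Mo17",       0.000814, -0.001170, -0.006244, -0.009502,  0.063104,  0.266425
  )
}

#' The reference surfaces as model objects
#'
#' @return Named list of [quadratic_surface()] objects, one per row of
#'   [allele_surface_coefs()].
#' @export
allele_surfaces <- function() {
  as_surface_list(allele_surface_coefs())
}

#' Published producing-function fits for the reference surfaces
#'
#' Parameter values estimated for each reference surface by linear
#' regression of the producing function over an absolute mesh (peak
#' included, `c` preset to give the appropriate convexity), with the scalar
#' error `s` (square root of the least-squares solution norm). The exact
#' mesh used for these estimates is not published, so the values serve as
#' reference inputs (e.g. for generating model surfaces), not as a
#' reproduction target.
#'
#' @return A tibble with columns `label`, `a`, `b`, `c`, `d`, `e`, `s`.
#' @export
allele_producing_params <- function() {
  tibble::tribble(
    ~label,       ~a,      ~b,      ~c, ~d,      ~e,      ~s,
    "B73",       -0.0463, -1.8005, -1, -0.0765,  1.3540, 146.0321,
    "QTL1-B73",  -0.0429, -0.5926, -1, -0.3134, -0.9222, 127.2874,
    "QTL2-Mo17", -0.0332, -0.4362, -1, -0.3681, -2.9073, 134.1696,
    "QTL3-Mo17", -0.0636,  0.0039, -1, -0.5199, -4.0788, 112.6761,
    "QTL1-Mo17",  0.0164, -0.6201, -1,  1.2777,  1.8758,  89.4613,
    "QTL2-B73",   0.0268, -0.4119, -1,  1.7254,  1.7119,  81.4159,
    "QTL3-B73",   0.0278, -0.4450, -1,  1.6600,  1.0073,  83.2248,
    "Mo17",       0.0259,  0.2164,  1,  1.7406, -0.7203,  34.1571
  )
}

#' Illustrative producing-function parameter sets
#'
#' The two published example parameter sets: a B73-like dome and a
#' Mo17-like trough. These are the default allele effects of the
#' synthetic-data generator's causal markers.
#'
#' @param which `"B73-like"` or `"Mo17-like"`.
#' @return A [producing_function()].
#' @examples
#' example_producing_params("B73-like")
#' @export
example_producing_params <- function(which = c("B73-like", "Mo17-like")) {
  which <- match.arg(which)
  if (which == "B73-like") {
    producing_function(0.260, 0.305, -0.175, 2.575, 0.500, label = "B73-like")
  } else {
    producing_function(0.0330, 0.4250, 0.0030, -0.0025, 0.5500, label = "Mo17-like")
  }
}

#' Producing-parameter table as model objects
#'
#' @param params Data frame with columns `label`, `a`, `b`, `c`, `d`, `e`
#'   (defaults to [allele_producing_params()]).
#' @return Named list of [producing_function()] objects.
#' @export
as_producing_list <- function(params = allele_producing_params()) {
  needed <- c("label", "a", "b", "c", "d", "e")
  if (!all(needed %in% names(params))) {
    abort(paste("parameter table must have columns:",
                paste(needed, collapse = ", ")),
          class = "surfqtl_format_error")
  }
  out <- purrr::pmap(params[needed], function(label, a, b, c, d, e) {
    producing_function(a, b, c, d, e, label = label)
  })
  setNames(out, params$label)
}
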