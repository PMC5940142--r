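#' Quadratic stress-response surface
#'
#' Container for the six coefficients of the smoothed quadratic model of
#' growth response to combined water and nitrogen stress,
#' \deqn{z = \beta_1 x_w + \beta_2 x_n + \beta_3 x_w^2 + \beta_4 x_n^2 +
#'       \beta_5 x_w x_n + \ell,}
#' where \eqn{x_w} and \eqn{x_n} are the recentred water and nitrogen levels
#' (raw percentages minus 50 and 7.5 respectively) and \eqn{\ell} lumps the
#' grand mean, line effect and residual constants of the full mixed model.
#'
#' @param beta1,beta2 Linear coefficients (cm per unit water / nitrogen).
#' @param beta3,beta4 Quadratic coefficients (cm per squared unit).
#' @param beta5 Water-by-nitrogen interaction coefficient.
#' @param ell Lumped constant (cm).
#' @param label Identifier for the line or allele the surface describes.
#' @return An object of class `quadratic_surface`.
#' @examples
#' s <- quadratic_surface(beta1 = 0.23, beta2 = 1, beta3 = -0.006,
#'                        beta4 = -0.19, beta5 = 0.026, ell = 32)
#' evaluate_quadratic(s, 0, 0)
#' @export
quadratic_surface <- function(beta1, beta2, beta3, beta4, beta5, ell,
                              label = "surface") {
  for (nm in c("beta1", "beta2", "beta3", "beta4", "beta5", "ell")) {
    check_scalar(get(nm), nm)
  }
  structure(
    list(label = as.character(label), beta1 = beta1, beta2 = beta2,
         beta3 = beta3, beta4 = beta4, beta5 = beta5, ell = ell),
    class = "quadratic_surface"
  )
}

#' Producing-function parameters
#'
#' The five-parameter mechanistic shape model: an elliptical paraboloid plus
#' a tilted plane,
#' \deqn{z = c\,(a x_w^2 + b x_n^2) + d x_w + e x_n.}
#' `a` and `b` weight the water and nitrogen inputs of the paraboloid, `c`
#' scales and flips it (`c < 0` gives a convex-upward dome with a single
#' maximum, `c > 0` a concave-upward trough), and `d`, `e` tilt the plane
#' along the water and nitrogen axes. There is no constant term: the surface
#' is exactly zero at the origin.
#'
#' @param a,b Paraboloid input weights for water and nitrogen.
#' @param c Paraboloid scale/orientation.
#' @param d,e Plane tilts along water and nitrogen.
#' @param label Identifier.
#' @return An object of class `producing_function`.
#' @examples
#' p <- producing_function(0.260, 0.305, -0.175, 2.575, 0.500, label = "B73-like")
#' evaluate_producing(p, 0, 0)   # always 0 at the origin
#' @export
producing_function <- function(a, b, c, d, e, label = "model") {
  for (nm in c("a", "b", "c", "d", "e")) check_scalar(get(nm), nm)
  structure(
    list(label = as.character(label), a = a, b = b, c = c, d = d, e = e),
    class = "producing_function"
  )
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cat("<quadratic_surface> ", x$label, "\n", sep = "")
  cat(sprintf("  z = %.6g*xw + %.6g*xn + %.6g*xw^2 + %.6g*xn^2 + %.6g*xw*xn + %.6g\n",
              x$beta1, x$beta2, x$beta3, x$beta4, x$beta5, x$ell))
  invisible(x)
}

#' @export
print.producing_function <- function(x, ...) {
  cat("<producing_function> ", x$label, "\n", sep = "")
  cat(sprintf("  z = %.6g*(%.6g*xw^2 + %.6g*xn^2) + %.6g*xw + %.6g*xn\n",
              x$c, x$a, x$b, x$d, x$e))
  invisible(x)
}

#' Evaluate a quadratic response surface
#'
#' @param surface A [quadratic_surface()].
#' @param xw,xn Recentred water and nitrogen coordinates (vectorised).
#' @return Numeric vector of surface heights z (cm).
#' @export
evaluate_quadratic <- function(surface, xw, xn) {
  stopifnot(inherits(surface, "quadratic_surface"))
  check_finite(xw, "xw")
  check_finite(xn, "xn")
  surface$beta1 * xw + surface$beta2 * xn + surface$beta3 * xw^2 +
    surface$beta4 * xn^2 + surface$beta5 * xw * xn + surface$ell
}

#' Evaluate a producing function
#'
#' @param params A [producing_function()].
#' @param xw,xn Recentred water and nitrogen coordinates (vectorised).
#' @return Numeric vector of surface heights z (cm); exactly 0 at the origin.
#' @export
evaluate_producing <- function(params, xw, xn) {
  stopifnot(inherits(params, "producing_function"))
  check_finite(xw, "xw")
  check_finite(xn, "xn")
  params$c * (params$a * xw^2 + params$b * xn^2) + params$d * xw + params$e * xn
}

#' Evaluate either surface model
#'
#' Generic evaluator used by the mesh and comparison machinery so both the
#' quadratic and the producing-function models can be meshed and compared
#' interchangeably.
#'
#' @param model A `quadratic_surface` or `producing_function`.
#' @param xw,xn Coordinates.
#' @return Numeric vector of z values.
#' @export
evaluate_surface <- function(model, xw, xn) UseMethod("evaluate_surface")

#' @export
evaluate_surface.quadratic_surface <- function(model, xw, xn) {
  evaluate_quadratic(model, xw, xn)
}

#' @export
evaluate_surface.producing_function <- function(model, xw, xn) {
  evaluate_producing(model, xw, xn)
}

#' Evaluation grid over the recentred stress plane
#'
#' The default grid is the study's evaluation plane: recentred water in
#' \eqn{[-42, 42]} and nitrogen in \eqn{[-7.5, 7.5]} with step 0.5, i.e.
#' 169 x 31 = 5239 nodes. Interval endpoints must be whole multiples of the
#' step from the lower bound so the stated stress levels land exactly on
#' grid nodes.
#'
#' @param water,nitrogen Length-2 closed intervals (recentred units).
#' @param step Positive grid step.
#' @return An object of class `eval_grid` with node vectors `$water` and
#'   `$nitrogen`.
#' @examples
#' g <- eval_grid()
#' length(g$water)    # 169
#' length(g$nitrogen) # 31
#' @export
eval_grid <- function(water = c(-42, 42), nitrogen = c(-7.5, 7.5), step = 0.5) {
  check_finite(water, "water")
  check_finite(nitrogen, "nitrogen")
  check_scalar(step, "step")
  if (step <= 0) abort("`step` must be positive.", class = "surfqtl_invalid_argument")
  if (length(water) != 2L || length(nitrogen) != 2L ||
      diff(water) <= 0 || diff(nitrogen) <= 0) {
    abort("intervals must be increasing length-2 vectors.",
          class = "surfqtl_invalid_argument")
  }
  for (iv in list(water, nitrogen)) {
    k <- diff(iv) / step
    if (abs(k - round(k)) > 1e-8) {
      abort("interval endpoints must be whole multiples of `step` apart.",
            class = "surfqtl_invalid_argument")
    }
  }
  structure(
    list(water_interval = water, nitrogen_interval = nitrogen, step = step,
         water = seq(water[1], water[2], by = step),
         nitrogen = seq(nitrogen[1], nitrogen[2], by = step)),
    class = "eval_grid"
  )
}

#' @export
print.eval_grid <- function(x, ...) {
  cat(sprintf("<eval_grid> water [%g, %g] x nitrogen [%g, %g], step %g (%d x %d nodes)\n",
              x$water_interval[1], x$water_interval[2],
              x$nitrogen_interval[1], x$nitrogen_interval[2], x$step,
              length(x$water), length(x$nitrogen)))
  invisible(x)
}

#' Evaluate a surface over a grid
#'
#' @param model A `quadratic_surface` or `producing_function`.
#' @param grid An [eval_grid()].
#' @return A numeric matrix with rows indexed by ascending water nodes and
#'   columns by ascending nitrogen nodes; `dimnames` carry the coordinates.
#' @export
surface_grid <- function(model, grid = eval_grid()) {
  stopifnot(inherits(grid, "eval_grid"))
  z <- outer(grid$water, grid$nitrogen,
             function(w, n) evaluate_surface(model, w, n))
  dimnames(z) <- list(water = format(grid$water, trim = TRUE),
                      nitrogen = format(grid$nitrogen, trim = TRUE))
  z
}

#' Locate the grid maximum of a surface
#'
#' Exhaustively scans grid nodes for the maximum z. The reported peak is grid
#' quantised by construction (the study tabulates peaks on the 0.5-step
#' grid, not analytic optima). Ties are broken towards the smaller water
#' coordinate, then the smaller nitrogen coordinate.
#'
#' @param zvalues Matrix from [surface_grid()] (water rows x nitrogen columns).
#' @param grid The [eval_grid()] the matrix was computed on.
#' @return A one-row tibble: `xw`, `xn`, `zmax`, `on_boundary` (TRUE when the
#'   peak lies on a grid edge or corner).
#' @examples
#' s <- allele_surfaces()[["B73"]]
#' find_peak(surface_grid(s), eval_grid())
#' @export
find_peak <- function(zvalues, grid = eval_grid()) {
  stopifnot(inherits(grid, "eval_grid"))
  if (!is.matrix(zvalues) || length(zvalues) == 0L) {
    abort("`zvalues` must be a non-empty matrix.", class = "surfqtl_invalid_argument")
  }
  if (nrow(zvalues) != length(grid$water) || ncol(zvalues) != length(grid$nitrogen)) {
    abort("matrix dimensions do not match the grid.",
          class = "surfqtl_invalid_argument")
  }
  zmax <- max(zvalues)
  hits <- which(zvalues == zmax, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  xw <- grid$water[i]; xn <- grid$nitrogen[j]
  tibble::tibble(
    xw = xw, xn = xn, zmax = zmax,
    on_boundary = i == 1L || i == length(grid$water) ||
      j == 1L || j == length(grid$nitrogen)
  )
}

#' Curvature sign of a surface model
#'
#' The convexity convention used to preset the producing-function `c` and to
#' separate trough-type (Mo17-like) from dome-type surfaces. For a producing
#' function this is `sign(c)`; for a quadratic surface it is `sign(beta3)`,
#' the convexity along the dominant (water) axis, which splits the eight
#' reference surfaces exactly as their preset `c` does.
#'
#' @param model A surface model.
#' @return -1, 0 or +1.
#' @export
curvature_sign <- function(model) UseMethod("curvature_sign")

#' @export
curvature_sign.quadratic_surface <- function(model) sign(model$beta3)

#' @export
curvature_sign.producing_function <- function(model) sign(model$c)

#' Classify a surface shape from its grid peak
#'
#' Assigns one of the four non-disjoint shape categories used for the
#' reference surfaces. The default rule: `trough` when the curvature sign is
#' positive (concave upward); otherwise `shoulder` when the peak's water
#' coordinate is at least `shoulder`; `domed` when it exceeds `domed`; else
#' `hybrid`. Category membership genuinely depends on the classification
#' criteria, so the thresholds are exposed; `ambiguous` flags peaks within
#' one grid step of a threshold.
#'
#' @param peak One-row tibble from [find_peak()].
#' @param curvature_sign Sign of the fitted or preset paraboloid scale c
#'   (see [curvature_sign()]).
#' @param thresholds Named numeric: `domed` and `shoulder` cutoffs on the
#'   peak water coordinate.
#' @param step Grid step used for the ambiguity band.
#' @return A one-row tibble: `category` (factor) and `ambiguous`.
#' @export
classify_shape <- function(peak, curvature_sign,
                           thresholds = c(domed = 27, shoulder = 36),
                           step = 0.5) {
  stopifnot(is.data.frame(peak), nrow(peak) == 1L)
  check_scalar(curvature_sign, "curvature_sign")
  category <- if (curvature_sign > 0) {
    "trough"
  } else if (peak$xw >= thresholds[["shoulder"]]) {
    "shoulder"
  } else if (peak$xw > thresholds[["domed"]]) {
    "domed"
  } else {
    "hybrid"
  }
  ambiguous <- curvature_sign <= 0 &&
    any(abs(peak$xw - thresholds) <= step)
  tibble::tibble(
    category = factor(category, levels = c("domed", "hybrid", "shoulder", "trough")),
    ambiguous = ambiguous
  )
}

#' Sign pattern of producing-function parameters
#'
#' The ordered signs of (a, b, d, e), the shape fingerprint used to group the
#' fitted reference surfaces. Zero is reported only for exactly-zero
#' parameters.
#'
#' @param params A [producing_function()].
#' @return Named character vector over `a`, `b`, `d`, `e` with values
#'   `"-"`, `"0"`, `"+"`.
#' @export
sign_pattern <- function(params) {
  stopifnot(inherits(params, "producing_function"))
  vals <- c(a = params$a, b = params$b, d = params$d, e = params$e)
  vapply(vals, function(v) c("-", "0", "+")[sign(v) + 2], character(1))
}

#' Peak table for a set of surfaces
#'
#' Tidy wrapper: grid-maximises each surface of a coefficient table and
#' classifies its shape, producing the study-style peak summary (one row per
#' surface with peak coordinates, height, and category).
#'
#' @param coefs Data frame with columns `label`, `beta1`..`beta5`, `ell`
#'   (see [read_surface_coefs()] for the on-disk layout), or a list of
#'   surface models.
#' @param grid An [eval_grid()].
#' @param thresholds Passed to [classify_shape()].
#' @return A tibble: `label`, `xw`, `xn`, `zmax`, `on_boundary`, `category`,
#'   `ambiguous`.
#' @examples
#' surface_peaks(allele_surface_coefs())
#' @export
surface_peaks <- function(coefs, grid = eval_grid(),
                          thresholds = c(domed = 27, shoulder = 36)) {
  surfaces <- if (is.data.frame(coefs)) as_surface_list(coefs) else coefs
  purrr::map_dfr(surfaces, function(s) {
    pk <- find_peak(surface_grid(s, grid), grid)
    cl <- classify_shape(pk, curvature_sign(s), thresholds = thresholds,
                         step = grid$step)
    dplyr::bind_cols(tibble::tibble(label = s$label), pk, cl)
  })
}

#' Coerce a coefficient table to a list of quadratic surfaces
#'
#' @param coefs Data frame with columns `label`, `beta1`..`beta5`, `ell`.
#' @return Named list of [quadratic_surface()] objects.
#' @export
as_surface_list <- function(coefs) {
  needed <- c("label", "beta1", "beta2", "beta3", "beta4", "beta5", "ell")
  if (!all(needed %in% names(coefs))) {
    abort(paste("coefficient table must have columns:",
                paste(needed, collapse = ", ")),
          class = "surfqtl_format_error")
  }
  out <- purrr::pmap(coefs[needed], function(label, beta1, beta2, beta3,
                                             beta4, beta5, ell) {
    quadratic_surface(beta1, beta2, beta3, beta4, beta5, ell, label = label)
  })
  setNames(out, coefs$label)
}
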