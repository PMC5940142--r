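#' Fit producing-function parameters over a mesh
#'
#' Linear least squares of the mesh heights on the producing-function basis
#' \eqn{(c\,x_w^2,\; c\,x_n^2,\; x_w,\; x_n)} — no intercept, since the
#' model has no constant term — with the paraboloid scale `c` preset to
#' \eqn{-1} (dome-type) or \eqn{+1} (trough-type, Mo17-like). Only the
#' products \eqn{c\,a} and \eqn{c\,b} are identifiable, so the reported `a`
#' and `b` are interpretable jointly with the preset `c`. The scalar error
#' `s` is the square root of the least-squares objective at the solution;
#' `residual_norm` is the constraint-violation norm of the solver contract,
#' identically 0 for an unconstrained fit.
#'
#' @param mesh A `mesh_points` tibble (absolute or relative flavour) or any
#'   data frame with `xw`, `xn`, `z`; points with missing coordinates are
#'   dropped.
#' @param c Preset paraboloid scale, -1 or +1.
#' @return A `producing_fit`: `params` ([producing_function()]), `s`,
#'   `residual_norm`, `n_points`, `flavor`.
#' @examples
#' truth <- example_producing_params("B73-like")
#' mesh <- relative_mesh(truth, trough = FALSE)
#' fit_producing(mesh, c = -1)
#' @export
fit_producing <- function(mesh, c = -1) {
  check_scalar(c, "c")
  if (c == 0) abort("`c` must be nonzero.", class = "surfqtl_invalid_argument")
  m <- tibble::as_tibble(mesh)
  if (!all(c("xw", "xn", "z") %in% names(m))) {
    abort("mesh needs columns xw, xn, z.", class = "surfqtl_format_error")
  }
  m <- m[stats::complete.cases(m[c("xw", "xn", "z")]), ]
  if (nrow(m) < 4) {
    abort("need >= 4 mesh points.", class = "surfqtl_invalid_argument")
  }
  A <- cbind(a = c * m$xw^2, b = c * m$xn^2, d = m$xw, e = m$xn)
  qra <- qr(A)
  if (qra$rank < 4) {
    abort("rank-deficient mesh: the points do not span the producing-function basis.",
          class = "surfqtl_rank_deficiency")
  }
  beta <- qr.coef(qra, m$z)
  s <- sqrt(sum(qr.resid(qra, m$z)^2))
  label <- attr(mesh, "surface_label") %||% "fit"
  structure(
    list(
      params = producing_function(beta[["a"]], beta[["b"]], c,
                                  beta[["d"]], beta[["e"]],
                                  label = label),
      s = s,
      residual_norm = 0,
      n_points = nrow(m),
      flavor = attr(mesh, "flavor") %||% "custom"
    ),
    class = "producing_fit"
  )
}

#' @export
print.producing_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<producing_fit> %s (%s mesh, %d points)\n", p$label, x$flavor,
              x$n_points))
  cat(sprintf("  a = %.4f, b = %.4f, c = %g, d = %.4f, e = %.4f; s = %.4f\n",
              p$a, p$b, p$c, p$d, p$e, x$s))
  invisible(x)
}

#' Compare producing-function estimation variants
#'
#' Fits the producing function to the same surface over three meshes — the
#' absolute mesh including the peak, the absolute mesh omitting it, and the
#' relative mesh — and reports the parameter estimates and scalar errors
#' side by side.
#'
#' @param model A surface model (typically a fitted `quadratic_surface`).
#' @param grid An [eval_grid()].
#' @param c Preset paraboloid scale; the model's [curvature_sign()] if NULL.
#' @param ... Passed to [absolute_mesh()] (e.g. `angles`, `fractions`).
#' @return A tibble with one row per mesh variant: `variant`, `a`, `b`,
#'   `c`, `d`, `e`, `s`, `n_points`.
#' @export
compare_estimation_variants <- function(model, grid = eval_grid(), c = NULL,
                                        ...) {
  if (is.null(c)) c <- curvature_sign(model)
  if (c == 0) c <- -1
  peak <- find_peak(surface_grid(model, grid), grid)
  meshes <- list(
    absolute_with_peak = absolute_mesh(model, peak = peak, grid = grid,
                                       include_peak = TRUE, ...),
    absolute_no_peak = absolute_mesh(model, peak = peak, grid = grid,
                                     include_peak = FALSE, ...),
    relative = relative_mesh(model, peak = peak, grid = grid)
  )
  purrr::imap_dfr(meshes, function(m, nm) {
    fit <- fit_producing(m, c = c)
    p <- fit$params
    tibble::tibble(variant = nm, a = p$a, b = p$b, c = p$c, d = p$d, e = p$e,
                   s = fit$s, n_points = fit$n_points)
  })
}
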