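#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a surface mixed-model fit
#'
#' @param x A `surface_fit`.
#' @param ... Ignored.
#' @return A tibble with one row per group and coefficient.
#' @export
tidy.surface_fit <- function(x, ...) {
  tidyr::pivot_longer(x$coefficients, -"group", names_to = "term",
                      values_to = "estimate")
}

#' @rdname tidy.surface_fit
#' @export
glance.surface_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, n_fixed = x$n_fixed,
    sigma2_line = x$vc[["sigma2_line"]],
    sigma2_resid = x$vc[["sigma2_resid"]],
    weighted_rss = x$weighted_rss
  )
}

#' Tidy a marker scan
#'
#' @param x A `scan_result`.
#' @param ... Ignored.
#' @return The per-marker tibble.
#' @export
tidy.scan_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.scan_result
#' @export
glance.scan_result <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x),
    n_skipped = sum(x$skipped),
    sigma2_line = attr(x, "vc")[["sigma2_line"]],
    sigma2_resid = attr(x, "vc")[["sigma2_resid"]],
    n_sidak_sig = if (!is.null(x[["sidak_sig"]])) sum(x[["sidak_sig"]], na.rm = TRUE) else NA_integer_
  )
}

#' Tidy a producing-function fit
#'
#' @param x A `producing_fit`.
#' @param ... Ignored.
#' @return One row per parameter with its estimate and sign.
#' @export
tidy.producing_fit <- function(x, ...) {
  p <- x$params
  est <- c(a = p$a, b = p$b, c = p$c, d = p$d, e = p$e)
  sp <- sign_pattern(p)
  tibble::tibble(
    term = names(est), estimate = unname(est),
    sign = unname(sp[match(names(est), names(sp))])
  )
}

#' @rdname tidy.producing_fit
#' @export
glance.producing_fit <- function(x, ...) {
  tibble::tibble(s = x$s, residual_norm = x$residual_norm,
                 n_points = x$n_points, flavor = x$flavor)
}

#' Tidy a similarity comparison
#'
#' @param x A `similarity_scores`.
#' @param ... Ignored.
#' @return Long tibble over the three scores.
#' @export
tidy.similarity_scores <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$rho, value = "rho"), score = "rho",
                  position = .data$index),
    dplyr::mutate(dplyr::rename(x$theta[c("ray", "index", "theta")],
                                value = "theta"),
                  score = "theta", position = .data$index),
    dplyr::mutate(dplyr::rename(x$delta_zr[c("ray", "band", "delta_zr")],
                                value = "delta_zr"),
                  score = "delta_zr", position = .data$band)
  )[c("score", "ray", "position", "value")]
}
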