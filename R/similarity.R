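# Mesh-based similarity of surface shapes: three per-point scores between an
# experimental surface and a simulated (model) surface discretised on
# matching relative meshes.

check_mesh_pair <- function(exp, sim) {
  for (m in list(exp, sim)) {
    if (!all(c("ray", "index", "xw", "xn", "z") %in% names(m))) {
      abort("meshes need columns ray, index, xw, xn, z.",
            class = "surfqtl_invalid_argument")
    }
  }
  if (nrow(exp) != nrow(sim) ||
      !identical(exp$ray, sim$ray) || !identical(exp$index, sim$index)) {
    abort("meshes have mismatched ray/position structure.",
          class = "surfqtl_invalid_argument")
  }
}

#' Signed displacement score rho
#'
#' Per corresponding mesh point, the Euclidean distance between the
#' simulated and experimental points in (xw, xn, z) space, signed by the
#' direction of the z difference (positive when the simulated surface lies
#' at or above the experimental).
#'
#' @param exp,sim Matching `mesh_points` (same rays and positions).
#' @return A tibble: `ray`, `index`, `rho`.
#' @export
rho_score <- function(exp, sim) {
  check_mesh_pair(exp, sim)
  d <- sqrt((sim$xw - exp$xw)^2 + (sim$xn - exp$xn)^2 + (sim$z - exp$z)^2)
  s <- ifelse(sim$z >= exp$z, 1, -1)
  tibble::tibble(ray = exp$ray, index = exp$index, rho = s * d)
}

#' Rotation score theta
#'
#' Per corresponding mesh point, the signed angle (degrees,
#' counter-clockwise positive) subtended at the evaluation-plane origin
#' between the projected positions of the simulated and experimental
#' points. Measuring at the plane origin makes peak shifts and differing
#' ray-segment lengths show up as apparent rotation, which is the intended
#' reading of the score. Points projecting onto the origin get `NA` and an
#' `undefined` flag.
#'
#' @param exp,sim Matching `mesh_points`.
#' @return A tibble: `ray`, `index`, `theta`, `undefined`.
#' @export
theta_score <- function(exp, sim) {
  check_mesh_pair(exp, sim)
  undef <- (exp$xw == 0 & exp$xn == 0) | (sim$xw == 0 & sim$xn == 0)
  cross <- exp$xw * sim$xn - exp$xn * sim$xw
  dot <- exp$xw * sim$xw + exp$xn * sim$xn
  th <- atan2(cross, dot) * 180 / pi
  th[undef] <- NA_real_
  tibble::tibble(ray = exp$ray, index = exp$index, theta = th,
                 undefined = undef)
}

mesh_amplitude <- function(mesh) {
  amp <- attr(mesh, "amplitude")
  if (is.null(amp)) amp <- max(mesh$z) - min(mesh$z)
  amp
}

band_gradients <- function(mesh) {
  amp <- mesh_amplitude(mesh)
  m <- tibble::as_tibble(mesh)[c("ray", "index", "xw", "xn", "z")]
  m <- dplyr::arrange(m, .data$ray, .data$index)
  res <- dplyr::group_by(m, .data$ray) |>
    dplyr::reframe(
      band = .data$index[-length(.data$index)],
      dist = sqrt(diff(.data$xw)^2 + diff(.data$xn)^2),
      dz = diff(.data$z)
    )
  res$g <- ifelse(res$dist > 0 & amp > 0, res$dz / (res$dist * amp), NA_real_)
  res
}

#' Relative-gradient score delta_zr
#'
#' Per ray and band (consecutive point pair), the difference between the
#' surfaces' amplitude-normalised discrete z gradients:
#' \eqn{g = \Delta z / (\Delta_{planar} \cdot |z_{max} - z_{min}|)} per
#' surface, and \eqn{\delta z_r = g_{sim} - g_{exp}}. Amplitude
#' normalisation makes the score reflect shape, not scale; negative values
#' mean the simulation descends more steeply. Collapsed bands (zero planar
#' distance) are flagged undefined.
#'
#' @param exp,sim Matching `mesh_points`.
#' @return A tibble: `ray`, `band`, `delta_zr`, `undefined`.
#' @export
delta_zr_score <- function(exp, sim) {
  check_mesh_pair(exp, sim)
  ge <- band_gradients(exp)
  gs <- band_gradients(sim)
  tibble::tibble(
    ray = ge$ray, band = ge$band,
    delta_zr = gs$g - ge$g,
    undefined = is.na(gs$g) | is.na(ge$g)
  )
}

#' All three similarity scores for one surface pair
#'
#' @param exp,sim Matching `mesh_points` for the experimental and simulated
#'   surfaces.
#' @return A `similarity_scores` object: the three score tibbles plus the
#'   pair labels.
#' @export
compare_surfaces <- function(exp, sim) {
  structure(
    list(
      pair = c(experimental = attr(exp, "surface_label") %||% "exp",
               simulated = attr(sim, "surface_label") %||% "sim"),
      rho = rho_score(exp, sim),
      theta = theta_score(exp, sim),
      delta_zr = delta_zr_score(exp, sim)
    ),
    class = "similarity_scores"
  )
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat(sprintf("<similarity_scores> %s (e) vs %s (s): %d rho, %d theta, %d delta_zr values\n",
              x$pair[["experimental"]], x$pair[["simulated"]],
              nrow(x$rho), nrow(x$theta), nrow(x$delta_zr)))
  invisible(x)
}

# anchor point used for the displacement-exclusion rule: the analytic
# critical point for a producing function, the grid peak otherwise
surface_anchor <- function(model, grid) {
  if (inherits(model, "producing_function")) {
    ca <- model$c * model$a; cb <- model$c * model$b
    if (ca != 0 && cb != 0) {
      return(c(-model$d / (2 * ca), -model$e / (2 * cb)))
    }
  }
  pk <- find_peak(surface_grid(model, grid), grid)
  c(pk$xw, pk$xn)
}

#' All-pairs similarity matrices
#'
#' Builds the relative mesh of every experimental and simulated surface and
#' scores every admitted pair, assembling one matrix per score with rows =
#' (experimental, simulated) pairs — each experimental surface's model
#' sibling (matched by label) first — and columns ordered as concentric
#' rings around the peaks (position 1 of every ray, then position 2, ...).
#' Simulated surfaces whose anchor point (analytic critical point of the
#' producing function) falls outside the evaluation plane inflated by
#' `margin`, or whose relative mesh collapses entirely, are excluded with a
#' logged reason.
#'
#' @param experimental Named list of surface models (e.g.
#'   [allele_surfaces()]).
#' @param simulated Named list of surface models (e.g.
#'   `as_producing_list()`).
#' @param grid An [eval_grid()].
#' @param margin Fractional inflation of the plane for the displacement
#'   exclusion (default 0.1).
#' @param slopes,points_per_ray Passed to [relative_mesh()].
#' @return A `similarity_matrix`: list with matrices `rho`, `theta`,
#'   `delta_zr` (rows named "e_label|s_label"), the `pairs` tibble, and an
#'   `excluded` tibble of dropped surfaces with reasons.
#' @export
compare_all <- function(experimental, simulated, grid = eval_grid(),
                        margin = 0.1, slopes = default_ray_slopes(),
                        points_per_ray = 10) {
  stopifnot(length(experimental) >= 1, length(simulated) >= 1)
  inflate <- function(iv) iv + c(-1, 1) * margin * diff(iv) / 2
  wlim <- inflate(grid$water_interval)
  nlim <- inflate(grid$nitrogen_interval)

  build <- function(model) {
    withCallingHandlers(
      relative_mesh(model, grid = grid, slopes = slopes,
                    points_per_ray = points_per_ray),
      surfqtl_zero_length_ray = function(w) invokeRestart("muffleWarning")
    )
  }
  excluded <- tibble::tibble(label = character(), reason = character())
  admit <- function(models, check_anchor) {
    kept <- list()
    for (nm in names(models)) {
      model <- models[[nm]]
      anchor <- surface_anchor(model, grid)
      if (check_anchor &&
          (anchor[1] < wlim[1] || anchor[1] > wlim[2] ||
           anchor[2] < nlim[1] || anchor[2] > nlim[2])) {
        excluded <<- dplyr::bind_rows(excluded, tibble::tibble(
          label = nm,
          reason = sprintf("anchor (%.1f, %.1f) outside the inflated evaluation plane",
                           anchor[1], anchor[2])))
        next
      }
      mesh <- build(model)
      if (all(mesh$collapsed)) {
        excluded <<- dplyr::bind_rows(excluded, tibble::tibble(
          label = nm, reason = "relative mesh collapsed (peak on an outward plane edge)"))
        next
      }
      kept[[nm]] <- mesh
    }
    kept
  }
  exp_meshes <- admit(experimental, check_anchor = FALSE)
  sim_meshes <- admit(simulated, check_anchor = TRUE)
  if (!length(exp_meshes) || !length(sim_meshes)) {
    abort("no admissible surfaces to compare.", class = "surfqtl_invalid_argument")
  }

  # ring-major column order: position 1 of all rays, then position 2, ...
  ring_order <- function(scores, pos_col, val_col) {
    o <- order(scores[[pos_col]], scores$ray)
    v <- scores[[val_col]][o]
    names(v) <- sprintf("r%d:%d", scores$ray[o] - 1L, scores[[pos_col]][o])
    v
  }

  pairs <- purrr::map_dfr(names(exp_meshes), function(enm) {
    sims <- names(sim_meshes)
    sims <- c(intersect(enm, sims), setdiff(sims, enm))
    tibble::tibble(experimental = enm, simulated = sims)
  })
  rows <- purrr::pmap(pairs, function(experimental, simulated) {
    sc <- compare_surfaces(exp_meshes[[experimental]], sim_meshes[[simulated]])
    list(rho = ring_order(sc$rho, "index", "rho"),
         theta = ring_order(sc$theta, "index", "theta"),
         delta_zr = ring_order(sc$delta_zr, "band", "delta_zr"))
  })
  rn <- sprintf("%s (e) | %s (s)", pairs$experimental, pairs$simulated)
  as_mat <- function(which) {
    m <- do.call(rbind, purrr::map(rows, which))
    rownames(m) <- rn
    m
  }
  structure(
    list(rho = as_mat("rho"), theta = as_mat("theta"),
         delta_zr = as_mat("delta_zr"), pairs = pairs, excluded = excluded),
    class = "similarity_matrix"
  )
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d pairs; rho %d cols, theta %d cols, delta_zr %d cols\n",
              nrow(x$pairs), ncol(x$rho), ncol(x$theta), ncol(x$delta_zr)))
  if (nrow(x$excluded)) {
    cat("excluded surfaces:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat("  -", x$excluded$label[i], ":", x$excluded$reason[i], "\n")
    }
  }
  invisible(x)
}
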