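# Mesh construction on response surfaces.
#
# Two flavours: the relative mesh (six fixed-slope ray segments from the
# peak, ten points per ray at equal fractional distances) discretises a
# surface for shape comparison; the absolute mesh (contour/ray
# intersections about a local axis) anchors producing-function estimation
# in (xw, xn, z).

default_ray_slopes <- function() c(0, 0.05, 0.099, 0.175, 0.32, 0.75)

#' Local axis of a quadratic surface
#'
#' The direction the absolute-mesh rays are measured against. For an
#' elliptic quadratic part (\eqn{4\beta_3\beta_4 > \beta_5^2}) this is the
#' Hessian eigenvector with the smaller-magnitude eigenvalue — the
#' slow-curvature (major-axis) direction of the distorted ellipsoid. For a
#' hyperbolic part it is the bisector of the two asymptote directions of
#' the trough. The sign is chosen so the water component is non-negative.
#'
#' @param model A `quadratic_surface` (or `producing_function`, for which
#'   the axis-aligned slow-curvature axis is returned).
#' @return Unit length-2 numeric vector (water, nitrogen components).
#' @examples
#' local_axis(quadratic_surface(0, 0, -1, -4, 0, 0))  # c(1, 0)
#' @export
local_axis <- function(model) UseMethod("local_axis")

#' @export
local_axis.quadratic_surface <- function(model) {
  b3 <- model$beta3; b4 <- model$beta4; b5 <- model$beta5
  if (b3 == 0 && b4 == 0 && b5 == 0) {
    abort("quadratic part is identically zero.",
          class = "surfqtl_degenerate_surface")
  }
  disc <- 4 * b3 * b4 - b5^2
  scale <- max(abs(c(b3, b4, b5)))^2
  if (abs(disc) <= 1e-12 * scale) {
    abort("parabolic degenerate quadratic part (4*beta3*beta4 == beta5^2).",
          class = "surfqtl_degenerate_surface")
  }
  if (disc > 0) {
    H <- matrix(c(2 * b3, b5, b5, 2 * b4), 2)
    eig <- eigen(H, symmetric = TRUE)
    v <- eig$vectors[, which.min(abs(eig$values))]
  } else {
    # asymptote directions: b3 + b5 t + b4 t^2 = 0 with t = xn/xw slope
    if (b4 != 0) {
      t12 <- (-b5 + c(1, -1) * sqrt(b5^2 - 4 * b3 * b4)) / (2 * b4)
      u1 <- c(1, t12[1]); u2 <- c(1, t12[2])
    } else {
      # one asymptote along xw (t = -b3/b5), the other along xn
      u1 <- c(1, -b3 / b5); u2 <- c(0, 1)
    }
    u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
    if (sum(u1 * u2) < 0) u2 <- -u2
    v <- u1 + u2
  }
  v <- v / sqrt(sum(v^2))
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  unname(v)
}

#' @export
local_axis.producing_function <- function(model) {
  ca <- model$c * model$a; cb <- model$c * model$b
  if (ca == 0 && cb == 0) {
    abort("paraboloid part is identically zero.",
          class = "surfqtl_degenerate_surface")
  }
  if (abs(ca) <= abs(cb)) c(1, 0) else c(0, 1)
}

# distance from `from` to the plane boundary along unit direction `dir`
clip_to_plane <- function(from, dir, grid) {
  lims <- rbind(grid$water_interval, grid$nitrogen_interval)
  t_max <- Inf
  for (k in 1:2) {
    if (dir[k] > 0) {
      t_max <- min(t_max, (lims[k, 2] - from[k]) / dir[k])
    } else if (dir[k] < 0) {
      t_max <- min(t_max, (lims[k, 1] - from[k]) / dir[k])
    }
  }
  max(t_max, 0)
}

new_mesh_points <- function(points, flavor, label, peak, grid, ...) {
  structure(tibble::as_tibble(points),
            class = c("mesh_points", class(tibble::tibble())),
            flavor = flavor, surface_label = label, peak = peak,
            grid = grid, ...)
}

#' Relative mesh on a surface
#'
#' Places `points_per_ray` points at equal fractional distances from the
#' peak along each of six ray segments of fixed slope, each segment clipped
#' at the first evaluation-plane edge. Dome-type surfaces send rays
#' leftwards and downward from the peak (direction \eqn{(-1, -s)}); for
#' trough-type (Mo17-like) surfaces the slopes are negated and rays extend
#' rightwards. Consecutive points bound `points_per_ray - 1` bands per ray.
#'
#' @param model A surface model (used to evaluate z and, via
#'   [curvature_sign()], to default the trough flag).
#' @param peak One-row peak tibble from [find_peak()]; computed from the
#'   grid if NULL.
#' @param grid An [eval_grid()].
#' @param slopes Ray slopes (default `c(0, 0.05, 0.099, 0.175, 0.32, 0.75)`).
#' @param points_per_ray Points per ray (>= 2, default 10).
#' @param trough Logical; NULL (default) derives it from the model's
#'   curvature sign.
#' @return A `mesh_points` tibble: `ray` (1-based index), `index` (position
#'   along the ray, increasing with distance from the peak), `xw`, `xn`,
#'   `z`, `collapsed`. Peak, grid, flavor, and the surface's grid amplitude
#'   travel as attributes.
#' @examples
#' m <- relative_mesh(allele_surfaces()[["B73"]])
#' nrow(m)  # 60
#' @export
relative_mesh <- function(model, peak = NULL, grid = eval_grid(),
                          slopes = default_ray_slopes(),
                          points_per_ray = 10, trough = NULL) {
  if (points_per_ray < 2) {
    abort("`points_per_ray` must be >= 2.", class = "surfqtl_invalid_argument")
  }
  zgrid <- surface_grid(model, grid)
  if (is.null(peak)) peak <- find_peak(zgrid, grid)
  pw <- peak$xw[1]; pn <- peak$xn[1]
  if (pw < grid$water_interval[1] || pw > grid$water_interval[2] ||
      pn < grid$nitrogen_interval[1] || pn > grid$nitrogen_interval[2]) {
    abort("peak lies outside the evaluation plane.",
          class = "surfqtl_invalid_argument")
  }
  if (is.null(trough)) trough <- curvature_sign(model) > 0
  pts <- purrr::map_dfr(seq_along(slopes), function(r) {
    s <- slopes[r]
    dir <- if (trough) c(1, -s) else c(-1, -s)
    dir <- dir / sqrt(sum(dir^2))
    t_max <- clip_to_plane(c(pw, pn), dir, grid)
    frac <- seq_len(points_per_ray) / points_per_ray
    if (t_max <= 0) {
      xw <- rep(pw, points_per_ray); xn <- rep(pn, points_per_ray)
      collapsed <- TRUE
    } else {
      xw <- pw + frac * t_max * dir[1]
      xn <- pn + frac * t_max * dir[2]
      collapsed <- FALSE
    }
    tibble::tibble(ray = r, index = seq_len(points_per_ray), xw = xw, xn = xn,
                   z = evaluate_surface(model, xw, xn), collapsed = collapsed)
  })
  if (any(pts$collapsed)) {
    warn(sprintf("ray(s) %s have zero length at the plane edge; their points collapse to the peak.",
                 paste(unique(pts$ray[pts$collapsed]), collapse = ", ")),
         class = "surfqtl_zero_length_ray")
  }
  new_mesh_points(pts, flavor = "relative",
                  label = model$label %||% "surface", peak = peak, grid = grid,
                  slopes = slopes, trough = trough,
                  points_per_ray = points_per_ray,
                  amplitude = max(zgrid) - min(zgrid))
}

#' Absolute mesh on a surface
#'
#' Places points at the intersections of fixed-level contours and rays
#' drawn from the peak at fixed angles about the surface's local axis. Each
#' ray is clipped at the evaluation-plane edge; along it, the contour for
#' fraction `f` is the level \eqn{z_{peak} - f (z_{peak} - z_{end})}, and
#' the first crossing of that level is located by bisection to
#' \eqn{|\Delta z| < 10^{-6}}. Each ray is oriented (sign of the rotated
#' axis) towards the longer clipped segment so rays run into the plane
#' interior. Rays with no crossing yield a flagged missing intersection.
#'
#' @param model A surface model.
#' @param peak Peak tibble; computed from the grid if NULL.
#' @param axis Unit local axis; [local_axis()] of the model if NULL.
#' @param grid An [eval_grid()].
#' @param angles Ray angles in degrees about the local axis
#'   (default `c(-45, -30, -15, 0, 15, 30, 45)`).
#' @param fractions Contour depth fractions in (0, 1]
#'   (default `c(0.05, 0.15, 0.30, 0.50)`).
#' @param include_peak Include the peak itself as a mesh point
#'   (ray 0, index 0)? Default TRUE.
#' @param tol Bisection tolerance on z (default 1e-6).
#' @return A `mesh_points` tibble: `ray`, `index`, `xw`, `xn`, `z`,
#'   `missing_intersection`.
#' @export
absolute_mesh <- function(model, peak = NULL, axis = NULL, grid = eval_grid(),
                          angles = c(-45, -30, -15, 0, 15, 30, 45),
                          fractions = c(0.05, 0.15, 0.30, 0.50),
                          include_peak = TRUE, tol = 1e-6) {
  if (!length(fractions) || any(fractions <= 0 | fractions > 1)) {
    abort("`fractions` must be non-empty values in (0, 1].",
          class = "surfqtl_invalid_argument")
  }
  zgrid <- surface_grid(model, grid)
  if (is.null(peak)) peak <- find_peak(zgrid, grid)
  if (is.null(axis)) axis <- local_axis(model)
  pw <- peak$xw[1]; pn <- peak$xn[1]
  zpeak <- evaluate_surface(model, pw, pn)
  rot <- function(v, deg) {
    th <- deg * pi / 180
    c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
  }
  pts <- purrr::map_dfr(seq_along(angles), function(r) {
    dir <- rot(axis, angles[r])
    t_plus <- clip_to_plane(c(pw, pn), dir, grid)
    t_minus <- clip_to_plane(c(pw, pn), -dir, grid)
    if (t_minus > t_plus) { dir <- -dir; t_plus <- t_minus }
    t_max <- t_plus
    if (t_max <= 0) {
      warn(sprintf("ray %d has zero length; no intersections.", r),
           class = "surfqtl_zero_length_ray")
      return(tibble::tibble(ray = r, index = seq_along(fractions),
                            xw = NA_real_, xn = NA_real_, z = NA_real_,
                            missing_intersection = TRUE))
    }
    fz <- function(t) evaluate_surface(model, pw + t * dir[1], pn + t * dir[2])
    z_end <- fz(t_max)
    purrr::map_dfr(seq_along(fractions), function(j) {
      target <- zpeak - fractions[j] * (zpeak - z_end)
      # bracket the first crossing of the target level along the ray
      tgrid <- seq(0, t_max, length.out = 201)
      gz <- fz(tgrid) - target
      s0 <- sign(gz[1])
      cross <- which(sign(gz) != s0 | gz == 0)[1]
      if (is.na(cross)) {
        return(tibble::tibble(ray = r, index = j, xw = NA_real_, xn = NA_real_,
                              z = NA_real_, missing_intersection = TRUE))
      }
      lo <- tgrid[max(cross - 1, 1)]; hi <- tgrid[cross]
      while (abs(fz((lo + hi) / 2) - target) > tol && hi - lo > 1e-12) {
        mid <- (lo + hi) / 2
        if (sign(fz(mid) - target) == s0) lo <- mid else hi <- mid
      }
      t_hit <- (lo + hi) / 2
      tibble::tibble(ray = r, index = j, xw = pw + t_hit * dir[1],
                     xn = pn + t_hit * dir[2], z = fz(t_hit),
                     missing_intersection = FALSE)
    })
  })
  if (include_peak) {
    pts <- dplyr::bind_rows(
      tibble::tibble(ray = 0L, index = 0L, xw = pw, xn = pn, z = zpeak,
                     missing_intersection = FALSE),
      pts
    )
  }
  new_mesh_points(pts, flavor = "absolute",
                  label = model$label %||% "surface", peak = peak, grid = grid,
                  axis = axis, angles = angles, fractions = fractions,
                  include_peak = include_peak,
                  amplitude = max(zgrid) - min(zgrid))
}
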