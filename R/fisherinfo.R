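# Visual Fisher information about location.
#
# A landmark at distance d along the line of sight and eccentricity eps
# orthogonal to it carries location information that grows with the square
# of eccentricity and falls with the fourth power of distance; the
# numerical counterpart measures the Poisson-population information of the
# rendered retina directly.

#' Analytic eccentricity-squared / distance-to-the-fourth information law
#'
#' @param d distance along the line of sight, meters (> 0).
#' @param eps eccentricity orthogonal to the line of sight, meters (>= 0).
#' @param scale_const proportionality constant.
#' @return information values `scale_const * eps^2 / d^4`.
#' @export
analytic_info <- function(d, eps, scale_const = 1) {
  if (any(d <= 0)) stop("d must be positive")
  if (any(eps < 0)) stop("eps must be non-negative")
  scale_const * eps^2 / d^4
}

#' Numerical Fisher information of the Poisson retina about a location
#' coordinate
#'
#' `I = sum_i (d vbar_i / d s)^2 * dt / vbar_i`, with the derivative taken
#' by central finite differences of the rendered expected image along the
#' requested coordinate of the observer's location. Pixels whose expected
#' rate falls below `floor` times the image maximum are excluded.
#'
#' @param scene a `nav_env` or `landmark_scene`.
#' @param pose length-3 observer pose.
#' @param coord `"x"` or `"y"`: the location coordinate.
#' @param optics a `nav_optics`.
#' @param h finite-difference step, meters.
#' @param dt integration time.
#' @param floor relative rate floor for pixel exclusion.
#' @return a non-negative information value.
#' @export
numerical_info <- function(scene, pose, coord = c("x", "y"), optics,
                           h = 0.01, dt = 1, floor = 1e-6) {
  coord <- match.arg(coord)
  e <- if (coord == "x") c(h, 0, 0) else c(0, h, 0)
  poses <- rbind(pose, pose + e, pose - e)
  if (inherits(scene, "nav_env") && !all(is_inside(scene, poses[, 1:2]))) {
    stop("finite-difference stencil leaves the environment; ",
         "pose too close to a wall for step h")
  }
  V <- render_view_matrix(scene, poses, optics)
  v0 <- V[1, ]
  dv <- (V[2, ] - V[3, ]) / (2 * h)
  keep <- v0 > floor * max(v0)
  sum(dv[keep]^2 * dt / v0[keep])
}

#' Information regression against distance and eccentricity
#'
#' Places a single idealized point landmark at `(d, eps)` relative to an
#' observer at the origin facing +x, measures the numerical information
#' about the line-of-sight coordinate, and regresses `log I` on `log d`
#' (at fixed eccentricity) or on `log eps` (at fixed distance).
#'
#' @param d_range distances scanned, meters.
#' @param eps_range eccentricities scanned, meters.
#' @param eps_fixed eccentricity used for the distance scan.
#' @param d_fixed distance used for the eccentricity scan.
#' @param optics optics of the probe retina (wide field, fine sampling).
#' @param h finite-difference step.
#' @return list with `slope_d`, `slope_eps` and the per-point tables.
#' @export
info_exponents <- function(d_range = seq(2, 6, length.out = 9),
                           eps_range = seq(0.25, 1, length.out = 8),
                           eps_fixed = 0.5, d_fixed = 3,
                           optics = make_optics(width = 96, height = 12,
                                                fov_h = 160 * pi / 180,
                                                fov_v = 40 * pi / 180,
                                                blur_sigma = 0, gain = 1,
                                                eye_height = 1),
                           h = 0.01) {
  pose <- c(0, 0, 0)
  info_at <- function(d, eps) {
    scene <- make_landmark_scene(data.frame(x = d, y = eps))
    numerical_info(scene, pose, "x", optics, h = h)
  }
  i_d <- vapply(d_range, info_at, numeric(1), eps = eps_fixed)
  i_e <- vapply(eps_range, info_at, numeric(1), d = d_fixed)
  fit_d <- stats::lm(log(i_d) ~ log(d_range))
  fit_e <- stats::lm(log(i_e) ~ log(eps_range))
  list(slope_d = unname(stats::coef(fit_d)[2]),
       slope_eps = unname(stats::coef(fit_e)[2]),
       d = data.frame(d = d_range, info = i_d),
       eps = data.frame(eps = eps_range, info = i_e))
}

#' Environment-wide visual information maps
#'
#' Numerical information about the x and y coordinates at each location of
#' a grid, aggregated over a set of headings; total information is
#' reported as the sum of the per-axis values (the trace).
#'
#' @param env a `nav_env`.
#' @param optics a `nav_optics`.
#' @param bin location grid spacing, meters.
#' @param n_headings number of uniformly spaced headings.
#' @param aggregate `"mean"` or `"max"` over headings.
#' @param h finite-difference step (default half a bin).
#' @param margin locations closer than this to a wall are skipped (the
#'   stencil must stay inside).
#' @return data.frame with `x`, `y`, `info_x`, `info_y`, `info_total`,
#'   with the aggregation rule in `attr(, "aggregate")`.
#' @export
info_map <- function(env, optics, bin = 0.12, n_headings = 16,
                     aggregate = c("mean", "max"), h = bin / 2,
                     margin = NULL) {
  aggregate <- match.arg(aggregate)
  margin <- margin %||% (h * 1.5)
  grid <- make_pose_grid(env, bin = bin, n_theta = 1)
  keep <- apply(wall_distances(env, grid$cells), 1, min) > margin
  locs <- grid$cells[keep, , drop = FALSE]
  heads <- 2 * pi * (seq_len(n_headings) - 1) / n_headings
  agg <- if (aggregate == "mean") mean else max
  out <- matrix(0, nrow(locs), 2)
  for (i in seq_len(nrow(locs))) {
    ix <- vapply(heads, function(th)
      numerical_info(env, c(locs[i, ], th), "x", optics, h = h), numeric(1))
    iy <- vapply(heads, function(th)
      numerical_info(env, c(locs[i, ], th), "y", optics, h = h), numeric(1))
    out[i, ] <- c(agg(ix), agg(iy))
  }
  res <- data.frame(x = locs[, 1], y = locs[, 2],
                    info_x = out[, 1], info_y = out[, 2],
                    info_total = out[, 1] + out[, 2])
  attr(res, "aggregate") <- aggregate
  res
}
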