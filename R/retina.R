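#' Retinal optics
#'
#' Parameters of the retinotopic array: a pinhole camera with `width` x
#' `height` neurons whose centers tile the image plane uniformly (uniform
#' in tangent coordinates), Gaussian blur in pixel units, and a gain that
#' converts scene luminance into expected photon counts per unit time.
#'
#' @param width,height neuron counts (columns x rows).
#' @param fov_h,fov_v horizontal / vertical field of view, radians
#'   (`fov_h < pi`).
#' @param blur_sigma Gaussian blur standard deviation, pixels.
#' @param gain expected counts per unit luminance per unit time.
#' @param eye_height eye height above the floor, meters.
#' @return an object of class `nav_optics`.
#' @export
make_optics <- function(width = 24, height = 8,
                        fov_h = 150 * pi / 180, fov_v = 60 * pi / 180,
                        blur_sigma = 1, gain = 0.15, eye_height = 0.15) {
  stopifnot(width >= 1, height >= 1, fov_h > 0, fov_h < pi, fov_v > 0,
            blur_sigma >= 0, gain > 0, eye_height > 0)
  # image-plane coordinates of pixel centers (focal length 1)
  uh <- tan(fov_h / 2); uv <- tan(fov_v / 2)
  u <- (2 * (seq_len(width) - 0.5) / width - 1) * uh
  v <- (2 * (seq_len(height) - 0.5) / height - 1) * uv
  structure(list(width = width, height = height, fov_h = fov_h, fov_v = fov_v,
                 blur_sigma = blur_sigma, gain = gain, eye_height = eye_height,
                 u = u, v = v), class = "nav_optics")
}

optics_fingerprint <- function(optics) {
  paste(format(c(optics$width, optics$height, optics$fov_h, optics$fov_v,
                 optics$blur_sigma, optics$gain, optics$eye_height),
               digits = 12), collapse = "|")
}

# Pixel angular coordinates: azimuth offsets (per column) and elevation
# (per pixel; depends on the column through the image-plane geometry).
pixel_angles <- function(optics) {
  az <- atan(optics$u)
  el <- outer(optics$v, sqrt(1 + optics$u^2), function(v, s) atan(v / s))
  list(az = az, el = el) # el is height x width
}

#' Render expected retinal images for many poses
#'
#' Pinhole projection of the 3D scene: walls are vertical rectangles of
#' `wall_height` carrying their 1D luminance texture; rays missing the
#' walls sample the floor (below the horizon) or the sky. The result is
#' scaled by the optics gain and blurred with a Gaussian of
#' `blur_sigma` pixels. Deterministic.
#'
#' @param scene a `nav_env` or a `landmark_scene`.
#' @param poses n x 3 matrix `(x, y, theta)`.
#' @param optics a `nav_optics`.
#' @return an n x (width*height) matrix of expected rates; pixels are
#'   flattened column-major from the height x width image.
#' @export
render_view_matrix <- function(scene, poses, optics) {
  if (is.null(dim(poses))) poses <- matrix(poses, ncol = 3)
  if (inherits(scene, "landmark_scene")) {
    return(render_landmark_matrix(scene, poses, optics))
  }
  env <- scene
  W <- optics$width; H <- optics$height
  n <- nrow(poses)
  az <- atan(optics$u)                      # azimuth offset per column
  # 2D ray cast for every (pose, column)
  org <- poses[rep(seq_len(n), times = W), 1:2, drop = FALSE]
  ang <- rep(poses[, 3], times = W) + rep(az, each = n)
  hit <- cast_rays(env, org, ang)
  lum_wall <- wall_luminance(env, hit$wall, hit$along)   # n*W values
  t2 <- hit$dist
  # vertical expansion: lambda = t2 / sqrt(1 + u^2); z = eye + lambda * v
  inv <- 1 / sqrt(1 + rep(optics$u, each = n)^2)
  lam_wall <- t2 * inv                                   # n*W
  out <- matrix(env$sky_luminance, n * W, H)
  eye <- optics$eye_height
  for (r in seq_len(H)) {
    vr <- optics$v[r]
    z <- eye + lam_wall * vr
    px <- ifelse(z <= env$wall_height & z >= 0, lum_wall, env$sky_luminance)
    if (vr < 0) {
      lam_floor <- -eye / vr
      px[lam_floor < lam_wall] <- env$floor_luminance
      px[!is.finite(lam_wall)] <- env$floor_luminance
    } else if (vr == 0) {
      px[!is.finite(lam_wall)] <- env$sky_luminance
    }
    out[, r] <- px
  }
  # out is (n*W) x H; reorder to n x (H*W), image flattened column-major (H x W)
  dim(out) <- c(n, W, H)
  out <- aperm(out, c(1, 3, 2))
  dim(out) <- c(n, H * W)
  out <- out * optics$gain
  blur_image_matrix(out, optics)
}

# Separable Gaussian blur applied to row-flattened images (n x H*W).
blur_image_matrix <- function(imgs, optics) {
  if (optics$blur_sigma <= 0) return(imgs)
  H <- optics$height; W <- optics$width
  Bh <- blur_matrix(H, optics$blur_sigma)
  Bw <- blur_matrix(W, optics$blur_sigma)
  n <- nrow(imgs)
  # rows: apply Bh to each column of each image
  dim(imgs) <- c(n * 1, H, W)
  out <- array(0, c(n, H, W))
  for (w in seq_len(W)) out[, , w] <- imgs[, , w] %*% t(Bh)
  # columns: apply Bw across width
  for (h in seq_len(H)) out[, h, ] <- out[, h, ] %*% t(Bw)
  dim(out) <- c(n, H * W)
  out
}

#' Render the expected image at a single pose
#'
#' @inheritParams render_view_matrix
#' @param pose length-3 pose `(x, y, theta)`.
#' @return a `retinal_image`: list with `expected` (height x width matrix)
#'   and `counts` (`NULL` until [sample_visual()] is applied).
#' @export
render_expected_image <- function(scene, pose, optics) {
  if (inherits(scene, "nav_env") && !is_inside(scene, pose[1:2])) {
    stop("pose lies outside the environment")
  }
  v <- render_view_matrix(scene, matrix(pose, ncol = 3), optics)
  structure(list(expected = matrix(v[1, ], optics$height, optics$width),
                 counts = NULL, optics = optics),
            class = "retinal_image")
}

#' Sample Poisson photon counts
#'
#' @param image a `retinal_image` with expected rates.
#' @param dt integration time.
#' @return the image with integer `counts`, `counts[i] ~ Poisson(expected[i]*dt)`.
#' @export
sample_visual <- function(image, dt = 1) {
  rate <- image$expected * dt
  if (any(rate < 0)) stop("negative expected rates")
  image$counts <- matrix(stats::rpois(length(rate), rate),
                         nrow(rate), ncol(rate))
  image
}

#' Tactile sensor configuration
#'
#' @param probes egocentric probe angles, radians (default left and right).
#' @param x_w whisker length in meters.
#' @param p_w reliability in `[0, 1]`: a probe whose segment touches a wall
#'   reads 1 with probability `1/2 + p_w/2`, otherwise with `1/2 - p_w/2`.
#' @return a `nav_tactile` parameter object.
#' @export
make_tactile <- function(probes = c(-pi / 2, pi / 2), x_w = 0.12, p_w = 0.9) {
  stopifnot(x_w > 0, p_w >= 0, p_w <= 1)
  structure(list(probes = probes, x_w = x_w, p_w = p_w),
            class = "nav_tactile")
}

# Deterministic contact pattern: does the probe segment from each pose reach
# a wall within x_w? Returns an n x n_probes logical matrix.
tactile_contact <- function(env, poses, tact) {
  if (is.null(dim(poses))) poses <- matrix(poses, ncol = 3)
  n <- nrow(poses)
  out <- matrix(FALSE, n, length(tact$probes))
  for (k in seq_along(tact$probes)) {
    hit <- cast_rays(env, poses[, 1:2, drop = FALSE],
                     poses[, 3] + tact$probes[k])
    out[, k] <- is.finite(hit$dist) & hit$dist <= tact$x_w
  }
  out
}

#' Sample tactile readings at a pose
#'
#' @param env a `nav_env`.
#' @param pose length-3 pose.
#' @param tact a `nav_tactile`.
#' @return the `nav_tactile` with a `readings` field (0/1 per probe).
#' @export
sample_tactile <- function(env, pose, tact) {
  contact <- tactile_contact(env, matrix(pose, ncol = 3), tact)[1, ]
  p1 <- ifelse(contact, 0.5 + tact$p_w / 2, 0.5 - tact$p_w / 2)
  tact$readings <- as.integer(stats::runif(length(p1)) < p1)
  tact
}

#' Scene of idealized point landmarks
#'
#' Each landmark activates the retina as a fixed-shape, fixed-amplitude
#' Gaussian bump centered on its projected direction (azimuth relative to
#' heading; elevation 0, i.e. eye level), on top of a uniform background.
#' This idealization keeps the landmark's retinal footprint independent of
#' its distance, isolating the geometric dependence of location
#' information on distance and eccentricity.
#'
#' @param landmarks data.frame with columns `x`, `y` and optionally `amp`.
#' @param blob_sigma angular bump width, radians.
#' @param background uniform background luminance.
#' @return a `landmark_scene`.
#' @export
make_landmark_scene <- function(landmarks, blob_sigma = 3 * pi / 180,
                                background = 0.05) {
  if (is.null(landmarks$amp)) landmarks$amp <- rep(1, nrow(landmarks))
  structure(list(landmarks = landmarks, blob_sigma = blob_sigma,
                 background = background), class = "landmark_scene")
}

render_landmark_matrix <- function(scene, poses, optics) {
  n <- nrow(poses)
  ang <- pixel_angles(optics)
  npix <- optics$height * optics$width
  az_pix <- rep(ang$az, each = optics$height)  # flattened H x W
  el_pix <- as.numeric(ang$el)
  out <- matrix(scene$background, n, npix)
  s2 <- 2 * scene$blob_sigma^2
  for (i in seq_len(nrow(scene$landmarks))) {
    lx <- scene$landmarks$x[i]; ly <- scene$landmarks$y[i]
    alpha <- angle_diff(atan2(ly - poses[, 2], lx - poses[, 1]), poses[, 3])
    d_az <- outer(alpha, az_pix, angle_diff)
    bump <- exp(-(sweep(d_az^2, 2, el_pix^2, "+")) / s2)
    out <- out + scene$landmarks$amp[i] * bump
  }
  out * optics$gain
}
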