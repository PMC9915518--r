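# Grid-based recursive Bayesian filtering over pose (x, y, theta).
#
# Beliefs are ncell x n_theta matrices over the masked-in cells of a
# pose grid; the pose index of cell c at heading bin t is
# c + (t-1)*ncell (column-major flattening), and view libraries follow
# the same ordering.

.bayesnav_cache <- new.env(parent = emptyenv())

env_fingerprint <- function(env) {
  paste(env$name, paste(round(as.numeric(env$vertices), 9), collapse = ","),
        env$wall_height,
        paste(round(as.numeric(as.matrix(env$texture)), 9), collapse = ","),
        env$floor_luminance, env$sky_luminance, sep = "|")
}

#' Discretized pose grid for an environment
#'
#' Square-ish location bins tiling the environment bounding box (the bin
#' size is adjusted so a whole number of bins fits each axis) crossed with
#' uniformly spaced heading bins. Only cells whose centers fall inside
#' the environment are kept.
#'
#' @param env a `nav_env`.
#' @param bin requested location bin size, meters.
#' @param n_theta number of heading bins.
#' @return a `pose_grid`.
#' @export
make_pose_grid <- function(env, bin = 0.06, n_theta = 12) {
  bb <- env_bbox(env)
  nx <- max(1L, round(diff(bb$xlim) / bin))
  ny <- max(1L, round(diff(bb$ylim) / bin))
  binx <- diff(bb$xlim) / nx
  biny <- diff(bb$ylim) / ny
  xc <- bb$xlim[1] + (seq_len(nx) - 0.5) * binx
  yc <- bb$ylim[1] + (seq_len(ny) - 0.5) * biny
  centers <- cbind(rep(xc, times = ny), rep(yc, each = nx))
  mask <- is_inside(env, centers)
  cell_of_full <- rep(NA_integer_, nx * ny)
  cell_of_full[mask] <- seq_len(sum(mask))
  structure(list(
    xc = xc, yc = yc, binx = binx, biny = biny, nx = nx, ny = ny,
    n_theta = n_theta, theta = 2 * pi * (seq_len(n_theta) - 1) / n_theta,
    cells = centers[mask, , drop = FALSE],
    cell_ix = ((which(mask) - 1) %% nx) + 1L,
    cell_iy = ((which(mask) - 1) %/% nx) + 1L,
    cell_of_full = cell_of_full,
    env_key = env_fingerprint(env), bbox = bb
  ), class = "pose_grid")
}

grid_fingerprint <- function(grid) {
  paste(grid$env_key, grid$nx, grid$ny, grid$n_theta,
        round(grid$binx, 12), round(grid$biny, 12), sep = "#")
}

n_cells <- function(grid) nrow(grid$cells)

# Map continuous locations to masked cell ids; points landing in an
# unmasked bin (e.g. wall-clipped points in a boundary sliver) snap to the
# nearest masked cell center.
snap_to_cell <- function(grid, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  ix <- pmin(grid$nx, pmax(1L, floor((pts[, 1] - grid$bbox$xlim[1]) /
                                       grid$binx) + 1L))
  iy <- pmin(grid$ny, pmax(1L, floor((pts[, 2] - grid$bbox$ylim[1]) /
                                       grid$biny) + 1L))
  id <- grid$cell_of_full[(iy - 1L) * grid$nx + ix]
  bad <- which(is.na(id))
  for (b in bad) {
    id[b] <- which.min((grid$cells[, 1] - pts[b, 1])^2 +
                       (grid$cells[, 2] - pts[b, 2])^2)
  }
  id
}

# Nearest heading bin index.
snap_to_theta <- function(grid, th) {
  ((round(wrap_angle(th) / (2 * pi / grid$n_theta))) %% grid$n_theta) + 1L
}

#' Uniform and point-mass beliefs
#' @param grid a `pose_grid`.
#' @return an `ncell x n_theta` belief matrix summing to 1.
#' @export
uniform_belief <- function(grid) {
  matrix(1 / (n_cells(grid) * grid$n_theta), n_cells(grid), grid$n_theta)
}

#' @rdname uniform_belief
#' @param pose length-3 pose at which the mass is concentrated (snapped to
#'   the nearest grid bin).
#' @export
point_belief <- function(grid, pose) {
  b <- matrix(0, n_cells(grid), grid$n_theta)
  b[snap_to_cell(grid, pose[1:2]), snap_to_theta(grid, pose[3])] <- 1
  b
}

#' Expected-view library for a pose grid
#'
#' Renders the expected retinal image at every grid pose of an environment
#' and caches the result (in memory, keyed by environment, optics and grid
#' fingerprints).
#'
#' @param env a `nav_env`.
#' @param grid a `pose_grid` built for `env` (or for the believed
#'   environment when rendering a mismatched true environment on the
#'   believed grid is intended; the grid poses are what gets rendered).
#' @param optics a `nav_optics`.
#' @param cache logical; reuse a cached library when available.
#' @return a `view_library`: list with `V` (n_poses x n_pixels expected
#'   rates), `logV` (log rates, floored at `1e-6` of the maximum rate),
#'   `sumV` (row sums), and fingerprints.
#' @export
build_view_library <- function(env, grid, optics, cache = TRUE) {
  key <- paste(env_fingerprint(env), grid_fingerprint(grid),
               optics_fingerprint(optics), sep = "@")
  if (cache && !is.null(.bayesnav_cache[[key]])) return(.bayesnav_cache[[key]])
  nc <- n_cells(grid)
  V <- matrix(0, nc * grid$n_theta, optics$width * optics$height)
  for (t in seq_len(grid$n_theta)) {
    poses <- cbind(grid$cells, grid$theta[t])
    V[(t - 1) * nc + seq_len(nc), ] <- render_view_matrix(env, poses, optics)
  }
  floor_rate <- 1e-6 * max(V)
  lib <- structure(list(V = V, logV = log(pmax(V, floor_rate)),
                        sumV = rowSums(V), floor = floor_rate,
                        env_key = env_fingerprint(env),
                        grid_key = grid_fingerprint(grid),
                        optics_key = optics_fingerprint(optics)),
                   class = "view_library")
  if (cache) .bayesnav_cache[[key]] <- lib
  lib
}

# ---- motion kernel ---------------------------------------------------------

# Discretized heading-increment matrix: P[new, old] from the von Mises
# increment density at bin-center differences (normalized per old bin).
heading_kernel <- function(grid, u_theta, noise) {
  k <- noise$kappa * noise$dt
  mu <- u_theta * noise$dt
  d <- outer(grid$theta, grid$theta, function(new, old)
    angle_diff(new - old, mu))
  if (!is.finite(k) || k > 700) {
    P <- matrix(0, grid$n_theta, grid$n_theta)
    P[cbind(apply(abs(d), 2, which.min), seq_len(grid$n_theta))] <- 1
    return(P)
  }
  P <- exp(k * (cos(d) - 1))
  sweep(P, 2, colSums(P), "/")
}

# Ego-frame displacement support and weights for a control.
displacement_support <- function(u_x, noise, h) {
  mean <- u_x * noise$dt
  var <- noise$sigma_x^2 * u_x * noise$dt
  if (var == 0) {
    return(list(a = mean, b = 0, w = 1))
  }
  if (noise$family == "gamma") {
    shape <- mean^2 / var; rate <- mean / var
    kmax <- ceiling((mean + 4 * sqrt(var)) / h)
    a <- (0:kmax) * h
    w <- discretize_cdf(a, h, function(x) stats::pgamma(pmax(x, 0),
                                                        shape, rate))
    keep <- w > 1e-12
    list(a = a[keep], b = rep(0, sum(keep)), w = w[keep] / sum(w[keep]))
  } else {
    sd <- sqrt(var)
    kmax <- ceiling(4 * sd / h)
    off <- (-kmax:kmax) * h
    wa <- discretize_cdf(mean + off, h, function(x) stats::pnorm(x, mean, sd))
    wb <- discretize_cdf(off, h, function(x) stats::pnorm(x, 0, sd))
    g <- expand.grid(ia = seq_along(off), ib = seq_along(off))
    w <- wa[g$ia] * wb[g$ib]
    keep <- w > 1e-10
    list(a = (mean + off)[g$ia][keep], b = off[g$ib][keep],
         w = w[keep] / sum(w[keep]))
  }
}

#' Discretized motion transition kernel
#'
#' Builds (and caches) the transition kernel implied by the pose dynamics
#' on a grid: a heading-increment matrix and, per new-heading bin, a
#' sparse location-shift matrix. Out-of-environment mass is reassigned to
#' the bin containing the wall-clipped stopping point. The displacement
#' mixture is truncated at 4 standard deviations and renormalized.
#'
#' @param grid a `pose_grid`.
#' @param env the believed environment the grid discretizes.
#' @param u control `c(u_x, u_theta)`.
#' @param noise a `motion_noise`.
#' @return a `motion_kernel`: list with `Ptheta` (`n_theta x n_theta`,
#'   new by old) and `disp` (list of sparse `ncell x ncell` matrices,
#'   destination by source, one per new-heading bin).
#' @export
make_motion_kernel <- function(grid, env, u, noise) {
  key <- paste("K", grid_fingerprint(grid), paste(u, collapse = ","),
               noise$kappa, noise$sigma_x, noise$family, noise$dt, sep = "@")
  if (!is.null(.bayesnav_cache[[key]])) return(.bayesnav_cache[[key]])
  h <- min(grid$binx, grid$biny)
  sup <- displacement_support(u[1], noise, h)
  nc <- n_cells(grid)
  disp <- vector("list", grid$n_theta)
  for (t in seq_len(grid$n_theta)) {
    th <- grid$theta[t]
    dir <- c(cos(th), sin(th)); ort <- c(-sin(th), cos(th))
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    # free distance along the movement direction from each cell center,
    # used to clip mass that would cross a wall
    for (k in seq_along(sup$w)) {
      offset <- sup$a[k] * dir + sup$b[k] * ort
      tgt <- sweep(grid$cells, 2, -offset)
      r <- sqrt(sum(offset^2))
      if (r > 0) {
        ang <- atan2(offset[2], offset[1])
        free <- cast_rays(env, grid$cells, rep(ang, nc))$dist
        over <- which(free < r)
        if (length(over)) {
          scl <- free[over] / r
          tgt[over, ] <- grid$cells[over, , drop = FALSE] +
            outer(scl, offset)
        }
      }
      dest <- snap_to_cell(grid, tgt)
      ii <- c(ii, dest); jj <- c(jj, seq_len(nc))
      xx <- c(xx, rep(sup$w[k], nc))
    }
    disp[[t]] <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                      dims = c(nc, nc))
  }
  kern <- structure(list(Ptheta = heading_kernel(grid, u[2], noise),
                         disp = disp, u = u, grid_key = grid_fingerprint(grid)),
                    class = "motion_kernel")
  .bayesnav_cache[[key]] <- kern
  kern
}

#' Prediction step: push a belief through the motion kernel
#'
#' @param belief `ncell x n_theta` belief matrix (normalized).
#' @param kernel a `motion_kernel`.
#' @return the predicted belief (normalized).
#' @export
motion_predict <- function(belief, kernel) {
  if (abs(sum(belief) - 1) > 1e-6) stop("belief is not normalized")
  btheta <- belief %*% t(kernel$Ptheta)
  out <- vapply(seq_len(ncol(btheta)), function(t)
    as.numeric(kernel$disp[[t]] %*% btheta[, t]), numeric(nrow(belief)))
  out / sum(out)
}

#' Visual log likelihood over grid poses
#'
#' Per pose z: `sum_i [V_i * log(vbar_i(z)) - vbar_i(z) * dt]` up to a
#' z-independent constant. The brightness-dependent `-sum_i vbar_i(z) dt`
#' term is retained; the field is shifted so its maximum is 0.
#'
#' @param counts integer photon counts (matrix or vector, pixel order as
#'   rendered).
#' @param library a `view_library` for the believed environment.
#' @param dt integration time.
#' @return an `ncell x n_theta` matrix of shifted log likelihoods.
#' @export
visual_loglik <- function(counts, library, dt = 1) {
  v <- as.numeric(counts)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  ll <- as.numeric(library$logV %*% v) - dt * library$sumV
  ll <- ll - max(ll)
  matrix(ll, ncol = 1)[, 1] -> ll
  nc <- length(ll) %/% attr_ntheta(library)
  matrix(ll, nc, attr_ntheta(library))
}

attr_ntheta <- function(library) {
  as.integer(strsplit(library$grid_key, "#", fixed = TRUE)[[1]][4])
}

#' Tactile log likelihood over grid poses
#'
#' Evaluates the two-branch Bernoulli likelihood of the probe readings at
#' every pose of the believed environment.
#'
#' @param readings 0/1 vector, one per probe.
#' @param env believed environment.
#' @param grid a `pose_grid` for `env`.
#' @param tact a `nav_tactile`.
#' @return an `ncell x n_theta` matrix of log likelihoods.
#' @export
tactile_loglik <- function(readings, env, grid, tact) {
  key <- paste("T", grid_fingerprint(grid), paste(tact$probes, collapse = ","),
               tact$x_w, sep = "@")
  contact <- .bayesnav_cache[[key]]
  if (is.null(contact)) {
    nc <- n_cells(grid)
    contact <- matrix(FALSE, nc * grid$n_theta, length(tact$probes))
    for (t in seq_len(grid$n_theta)) {
      contact[(t - 1) * nc + seq_len(nc), ] <-
        tactile_contact(env, cbind(grid$cells, grid$theta[t]), tact)
    }
    .bayesnav_cache[[key]] <- contact
  }
  ll <- numeric(nrow(contact))
  for (k in seq_along(readings)) {
    p1 <- ifelse(contact[, k], 0.5 + tact$p_w / 2, 0.5 - tact$p_w / 2)
    ll <- ll + log(if (readings[k] == 1) p1 else 1 - p1)
  }
  matrix(ll, n_cells(grid), grid$n_theta)
}

#' One filtering step: predict, then weigh by the observation likelihood
#'
#' @param belief normalized `ncell x n_theta` belief.
#' @param kernel a `motion_kernel` for the executed control.
#' @param loglik observation log-likelihood field (`ncell x n_theta`), or
#'   `NULL` for no observation.
#' @return the posterior belief (normalized).
#' @export
filter_step <- function(belief, kernel, loglik = NULL) {
  pred <- motion_predict(belief, kernel)
  if (is.null(loglik)) return(pred)
  w <- exp(loglik - max(loglik))
  post <- pred * w
  s <- sum(post)
  if (s == 0 || !is.finite(s)) {
    stop("degenerate posterior: likelihood and prediction have no common ",
         "support (max loglik ", max(loglik), ", pred mass ", sum(pred), ")")
  }
  post / s
}

#' Marginal distribution over locations
#' @param belief `ncell x n_theta` belief.
#' @return vector of length ncell.
#' @export
location_marginal <- function(belief) rowSums(belief)

#' Moments of the location marginal
#' @param grid a `pose_grid`.
#' @param belief belief matrix or a location-marginal vector.
#' @return list with `mean`, `cov`, `var_total` (trace of `cov`) and
#'   `entropy` (of the location marginal, nats).
#' @export
belief_moments <- function(grid, belief) {
  p <- if (is.matrix(belief) && ncol(belief) > 1) rowSums(belief)
       else as.numeric(belief)
  m <- weighted_moments(grid$cells, p)
  list(mean = m$mean, cov = m$cov, var_total = sum(diag(m$cov)),
       entropy = prob_entropy(p / sum(p)))
}

#' Run the ideal observer over an episode
#'
#' True poses evolve in `env_true`; observations are rendered and sampled
#' in `env_true`; beliefs live on `env_believed`'s grid and likelihoods are
#' evaluated against `env_believed`'s view library (model mismatch when the
#' two differ).
#'
#' @param env_true,env_believed `nav_env` objects with corresponding walls.
#' @param controls T x 2 matrix of intended controls.
#' @param start_pose true starting pose (in `env_true`).
#' @param grid `pose_grid` over `env_believed`.
#' @param optics `nav_optics`, or `NULL` to disable vision.
#' @param noise `motion_noise`.
#' @param tact `nav_tactile` or `NULL` to disable touch.
#' @param init initial belief (default uniform).
#' @param vision logical, length 1 or T: per-step vision availability.
#' @param dt integration time per step.
#' @return list with `poses` ((T+1) x 3 true poses), `marginals`
#'   (ncell x (T+1) location marginals, including the initial update),
#'   `belief` (final full belief) and `entropy` (length T+1).
#' @export
run_filter <- function(env_true, env_believed, controls, start_pose, grid,
                       optics, noise, tact = NULL, init = NULL,
                       vision = TRUE, dt = 1) {
  T_ <- nrow(controls)
  vision <- rep_len(vision, T_ + 1)
  lib <- if (!is.null(optics)) build_view_library(env_believed, grid, optics)
  belief <- init %||% uniform_belief(grid)
  obs_loglik <- function(pose, see) {
    ll <- NULL
    if (see && !is.null(optics)) {
      img <- sample_visual(render_expected_image(env_true, pose, optics), dt)
      ll <- visual_loglik(img$counts, lib, dt)
    }
    if (!is.null(tact)) {
      reading <- sample_tactile(env_true, pose, tact)$readings
      tl <- tactile_loglik(reading, env_believed, grid, tact)
      ll <- if (is.null(ll)) tl else ll + tl
    }
    ll
  }
  # initial observation at the starting pose
  ll0 <- obs_loglik(start_pose, vision[1])
  if (!is.null(ll0)) {
    belief <- belief * exp(ll0 - max(ll0))
    belief <- belief / sum(belief)
  }
  poses <- matrix(0, T_ + 1, 3)
  poses[1, ] <- start_pose
  marg <- matrix(0, n_cells(grid), T_ + 1)
  marg[, 1] <- location_marginal(belief)
  ent <- numeric(T_ + 1)
  ent[1] <- prob_entropy(marg[, 1])
  pose <- start_pose
  for (t in seq_len(T_)) {
    u <- controls[t, ]
    pose <- step_pose(pose, u, noise, env_true)
    kern <- make_motion_kernel(grid, env_believed, u, noise)
    belief <- filter_step(belief, kern, obs_loglik(pose, vision[t + 1]))
    poses[t + 1, ] <- pose
    marg[, t + 1] <- location_marginal(belief)
    ent[t + 1] <- prob_entropy(marg[, t + 1])
  }
  list(poses = poses, marginals = marg, belief = belief, entropy = ent)
}
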