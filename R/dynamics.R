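#' Motion noise model
#'
#' Heading increments are von Mises with concentration `kappa * dt` around
#' the intended turn; forward displacement has mean `u_x * dt` and variance
#' `sigma_x^2 * u_x * dt`, drawn from a gamma distribution (rodent-scale
#' arenas) or, for the `"gaussian"` family, as an isotropic 2D Gaussian
#' perturbation of the intended step (large-environment protocols).
#'
#' @param kappa heading concentration parameter (> 0; `Inf` = noiseless).
#' @param sigma_x translation noise scale (>= 0).
#' @param family `"gamma"` or `"gaussian"`.
#' @param dt time step (the simulation clock; speeds are per step).
#' @return a `motion_noise` object.
#' @export
make_motion_noise <- function(kappa = 50, sigma_x = 0.15,
                              family = c("gamma", "gaussian"), dt = 1) {
  family <- match.arg(family)
  stopifnot(kappa > 0, sigma_x >= 0, dt > 0)
  structure(list(kappa = kappa, sigma_x = sigma_x, family = family, dt = dt),
            class = "motion_noise")
}

#' Von Mises sampler (Best & Fisher rejection method)
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return draws in (mu - pi, mu + pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(mu + stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    m_ok <- sum(ok)
    if (m_ok > 0) {
      out[got + seq_len(m_ok)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + m_ok
    }
  }
  mu + out
}

# Sample a forward displacement magnitude (gamma family) with mean
# u_x * dt and variance sigma_x^2 * u_x * dt.
sample_forward_gamma <- function(n, u_x, noise) {
  mean <- u_x * noise$dt
  var <- noise$sigma_x^2 * u_x * noise$dt
  if (mean == 0 || var == 0) return(rep(mean, n))
  stats::rgamma(n, shape = mean^2 / var, rate = mean / var)
}

#' One step of the generative pose dynamics
#'
#' The heading is incremented by a von Mises draw; the ego displacement is
#' drawn from the configured family, rotated into the allocentric frame by
#' the new heading, and wall-clipped with [clip_move()].
#'
#' @param pose length-3 pose `(x, y, theta)` inside `env`.
#' @param u control `c(u_x, u_theta)` with `u_x >= 0`.
#' @param noise a `motion_noise`.
#' @param env a `nav_env`.
#' @return the next pose.
#' @export
step_pose <- function(pose, u, noise, env) {
  if (u[1] < 0) stop("forward speed must be non-negative")
  if (!is_inside(env, pose[1:2])) stop("pose lies outside the environment")
  th <- wrap_angle(pose[3] +
                   rvonmises(1, u[2] * noise$dt, noise$kappa * noise$dt))
  if (noise$family == "gamma") {
    ego <- c(sample_forward_gamma(1, u[1], noise), 0)
  } else {
    sd <- noise$sigma_x * sqrt(u[1] * noise$dt)
    ego <- c(u[1] * noise$dt, 0) + stats::rnorm(2, 0, sd)
  }
  step <- c(cos(th) * ego[1] - sin(th) * ego[2],
            sin(th) * ego[1] + cos(th) * ego[2])
  c(clip_move(env, pose[1:2], pose[1:2] + step), th)
}

#' Candidate control set
#'
#' Stay, forward, and forward-with-turn in either direction:
#' `{(0,0), (dl,0), (dl,-dth), (dl,+dth)}`.
#'
#' @param dl forward step length per time step (m).
#' @param dth turn magnitude per time step (rad).
#' @return 4 x 2 matrix, one control per row (stay first).
#' @export
control_menu <- function(dl = 0.12, dth = pi / 2) {
  rbind(c(0, 0), c(dl, 0), c(dl, -dth), c(dl, dth))
}

# Noiseless successor poses of every control in `menu` from `pose`.
noiseless_successors <- function(pose, menu, env, dt = 1) {
  th <- wrap_angle(pose[3] + menu[, 2] * dt)
  out <- matrix(0, nrow(menu), 3)
  for (j in seq_len(nrow(menu))) {
    step <- menu[j, 1] * dt * c(cos(th[j]), sin(th[j]))
    out[j, ] <- c(clip_move(env, pose[1:2], pose[1:2] + step), th[j])
  }
  out
}

#' Guided trajectory toward a goal
#'
#' At each step the control whose noiseless successor is closest to the
#' goal is executed (with motion noise); ties are broken uniformly at
#' random. Terminates when the agent is within one step length of the
#' goal, or at `max_steps` (reported via `reached`).
#'
#' @param env a `nav_env`.
#' @param start length-3 starting pose.
#' @param goal length-2 goal location.
#' @param noise a `motion_noise`.
#' @param menu candidate control set (see [control_menu()]); the stay
#'   control is ignored for guidance.
#' @param max_steps step cap.
#' @return list with `poses` ((T+1) x 3), `controls` (T x 2), `reached`.
#' @export
guided_trajectory <- function(env, start, goal, noise,
                              menu = control_menu(), max_steps = 400) {
  moving <- menu[menu[, 1] > 0, , drop = FALSE]
  tol <- max(moving[, 1]) * noise$dt
  poses <- matrix(start, 1, 3)
  controls <- matrix(0, 0, 2)
  pose <- start
  reached <- FALSE
  for (t in seq_len(max_steps)) {
    if (sqrt(sum((pose[1:2] - goal)^2)) <= tol) { reached <- TRUE; break }
    succ <- noiseless_successors(pose, moving, env, noise$dt)
    d <- sqrt((succ[, 1] - goal[1])^2 + (succ[, 2] - goal[2])^2)
    best <- which(d <= min(d) + 1e-12)
    j <- if (length(best) > 1) sample(best, 1) else best
    pose <- step_pose(pose, moving[j, ], noise, env)
    poses <- rbind(poses, pose)
    controls <- rbind(controls, moving[j, ])
  }
  if (!reached && sqrt(sum((pose[1:2] - goal)^2)) <= tol) reached <- TRUE
  list(poses = poses, controls = controls, reached = reached)
}

#' Random foraging trajectory
#'
#' Persistent-heading random walk with occasional turns and wall avoidance
#' (the agent turns toward the more open side when a wall is within 2.5
#' step lengths ahead), producing near-uniform occupancy over long runs.
#'
#' @param env a `nav_env`.
#' @param n_steps number of steps (> 0).
#' @param noise a `motion_noise`.
#' @param menu candidate control set; forward speed and turn magnitude are
#'   taken from it.
#' @param p_turn per-step probability of a spontaneous turn.
#' @param start optional starting pose (default: environment centroid,
#'   random heading).
#' @return list with `poses` ((n_steps+1) x 3) and `controls`.
#' @export
foraging_trajectory <- function(env, n_steps, noise, menu = control_menu(),
                                p_turn = 0.2, start = NULL) {
  stopifnot(n_steps > 0)
  dl <- max(menu[, 1]); dth <- max(menu[, 2])
  if (is.null(start)) start <- c(0, 0, stats::runif(1, 0, 2 * pi))
  poses <- matrix(0, n_steps + 1, 3)
  controls <- matrix(0, n_steps, 2)
  pose <- start
  poses[1, ] <- pose
  turn_sign <- 0
  for (t in seq_len(n_steps)) {
    ahead <- cast_rays(env, pose[1:2], pose[3])$dist
    if (is.finite(ahead) && ahead < 2.5 * dl * noise$dt) {
      if (turn_sign == 0) {
        left <- cast_rays(env, pose[1:2], pose[3] + pi / 3)$dist
        right <- cast_rays(env, pose[1:2], pose[3] - pi / 3)$dist
        turn_sign <- if (left >= right) 1 else -1
      }
      u <- c(dl, turn_sign * dth)
    } else {
      turn_sign <- 0
      u <- c(dl, dth * sample(c(-1, 0, 0, 1), 1,
                              prob = c(p_turn / 2, (1 - p_turn) / 2,
                                       (1 - p_turn) / 2, p_turn / 2)))
    }
    pose <- step_pose(pose, u, noise, env)
    poses[t + 1, ] <- pose
    controls[t, ] <- u
  }
  list(poses = poses, controls = controls)
}

#' Random multistep outbound path ending axis-aligned with a target
#'
#' Guides the agent through `n_legs` random interior waypoints; the final
#' waypoint is placed so that the direction from the path's endpoint to
#' `target` lies along the requested axis.
#'
#' @param env a `nav_env`.
#' @param start length-3 starting pose.
#' @param n_legs number of legs (>= 1).
#' @param target length-2 target location (used to place the endpoint).
#' @param axis `"x"` or `"y"`: the axis of the final target direction.
#' @param noise a `motion_noise`.
#' @param menu candidate control set.
#' @param margin keep waypoints at least this far from the walls.
#' @param return_dist optional distance (m) between the path endpoint and
#'   the target (so matched trials in different enclosures share the true
#'   return length); default: drawn as a fraction of the axis extent.
#' @return list with `poses`, `controls`, `endpoint` (intended final
#'   waypoint) and `reached`.
#' @export
outbound_path <- function(env, start, n_legs, target, axis = c("x", "y"),
                          noise, menu = control_menu(), margin = 0.15,
                          return_dist = NULL) {
  axis <- match.arg(axis)
  stopifnot(n_legs >= 1)
  bb <- env_bbox(env)
  draw_point <- function() {
    repeat {
      p <- c(stats::runif(1, bb$xlim[1] + margin, bb$xlim[2] - margin),
             stats::runif(1, bb$ylim[1] + margin, bb$ylim[2] - margin))
      if (is_inside(env, p) &&
          min(wall_distances(env, p)) > margin) return(p)
    }
  }
  waypoints <- if (n_legs > 1) {
    t(replicate(n_legs - 1, draw_point()))
  } else matrix(0, 0, 2)
  ax <- if (axis == "x") c(1, 0) else c(0, 1)
  extent <- if (axis == "x") diff(bb$xlim) else diff(bb$ylim)
  endpoint <- NULL
  sgn <- sample(c(-1, 1), 2)
  for (try in 1:50) {
    dist <- return_dist %||% (stats::runif(1, 0.25, 0.45) * extent)
    for (s in sgn) {
      cand <- target + ax * dist * s
      if (is_inside(env, cand) && min(wall_distances(env, cand)) > margin) {
        endpoint <- cand; break
      }
    }
    if (!is.null(endpoint) || !is.null(return_dist)) break
  }
  if (is.null(endpoint)) {
    d0 <- (return_dist %||% (0.2 * extent))
    cand <- target + ax * d0
    endpoint <- if (is_inside(env, cand)) cand else target - ax * d0
  }
  waypoints <- rbind(waypoints, endpoint)
  poses <- matrix(start, 1, 3)
  controls <- matrix(0, 0, 2)
  pose <- start
  reached <- TRUE
  for (k in seq_len(nrow(waypoints))) {
    leg <- guided_trajectory(env, pose, waypoints[k, ], noise, menu)
    if (nrow(leg$poses) > 1) {
      poses <- rbind(poses, leg$poses[-1, , drop = FALSE])
      controls <- rbind(controls, leg$controls)
    }
    pose <- poses[nrow(poses), ]
    reached <- reached && leg$reached
  }
  list(poses = poses, controls = controls, endpoint = endpoint,
       reached = reached)
}
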