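# Memory encoding, the homing control policy, the distance-estimation
# task, and behavioral metrics.

#' Policy parameters for the test phase
#'
#' @param menu candidate control set (stay must be included; see
#'   [control_menu()]).
#' @param sigma_v2 softmax temperature on candidate values (squared
#'   meters; small values approach the greedy policy). Default: half the
#'   squared step length, which lets the observer escape value-neutral
#'   turns while stopping within about a step of the value optimum.
#' @param step_cap maximum number of test-phase steps (`NULL`: ten times
#'   the environment diameter in steps).
#' @return a `nav_policy`.
#' @export
make_policy <- function(menu = control_menu(), sigma_v2 = NULL,
                        step_cap = NULL) {
  sigma_v2 <- sigma_v2 %||% (max(menu[, 1])^2 / 2)
  stopifnot(sigma_v2 > 0, any(menu[, 1] == 0))
  structure(list(menu = menu, sigma_v2 = sigma_v2, step_cap = step_cap),
            class = "nav_policy")
}

#' Encode a remembered target location
#'
#' The location marginal of the belief at the target is raised elementwise
#' to `beta_learn` (tempering that models forgetting; 1 = none) and
#' renormalized; the remembered point estimate is its mean.
#'
#' @param belief `ncell x n_theta` belief at the moment of encoding.
#' @param grid the `pose_grid` the belief lives on.
#' @param beta_learn tempering exponent in (0, 1].
#' @return a `memory_trace`: list with `p` (tempered location
#'   distribution), `mean`, `beta_learn`.
#' @export
encode_memory <- function(belief, grid, beta_learn = 1) {
  if (beta_learn <= 0 || beta_learn > 1) stop("beta_learn must be in (0, 1]")
  p <- location_marginal(belief)^beta_learn
  p <- p / sum(p)
  structure(list(p = p, mean = weighted_moments(grid$cells, p)$mean,
                 beta_learn = beta_learn), class = "memory_trace")
}

# Mean and second moment (E[x^2 + y^2]) of a location distribution.
loc_moments <- function(p, locs) {
  p <- p / sum(p)
  list(mu = c(sum(p * locs[, 1]), sum(p * locs[, 2])),
       m2 = sum(p * (locs[, 1]^2 + locs[, 2]^2)))
}

#' Counterfactual values of the candidate controls
#'
#' `v_j` is the expected negative squared distance between the remembered
#' location and the counterfactual location after executing candidate j:
#' the current location marginal for the stay action, and the location
#' marginal of one application of the motion kernel (no observation) for
#' the moving candidates.
#'
#' @param belief current belief.
#' @param memory a `memory_trace`.
#' @param grid the `pose_grid`.
#' @param kernels list of `motion_kernel`s, one per row of the policy
#'   menu (the stay kernel is unused).
#' @param menu the policy's candidate controls (stay rows identified by
#'   `u_x == 0 & u_theta == 0`).
#' @return numeric values, one per candidate.
#' @export
counterfactual_values <- function(belief, memory, grid, kernels, menu) {
  if (nrow(menu) == 0) stop("empty candidate set")
  ml <- loc_moments(memory$p, grid$cells)
  vapply(seq_len(nrow(menu)), function(j) {
    pj <- if (all(menu[j, ] == 0)) location_marginal(belief)
          else location_marginal(motion_predict(belief, kernels[[j]]))
    mj <- loc_moments(pj, grid$cells)
    -(ml$m2 + mj$m2 - 2 * sum(ml$mu * mj$mu))
  }, numeric(1))
}

#' Softmax choice over candidate values
#'
#' `P(j) ∝ exp(v_j / sigma_v2)`; as `sigma_v2 -> 0` this approaches the
#' argmax with uniform tie-breaking.
#'
#' @param values finite candidate values.
#' @param sigma_v2 temperature.
#' @return chosen candidate index.
#' @export
choose_control <- function(values, sigma_v2) {
  if (any(!is.finite(values))) stop("values must be finite")
  z <- (values - max(values)) / sigma_v2
  p <- exp(z)
  sample.int(length(values), 1, prob = p / sum(p))
}

# One-heading location shift kernel along a fixed direction (used by the
# distance-estimation walk where the arrow fixes the heading).
location_shift_kernel <- function(grid, env, angle, u_x, noise) {
  h <- min(grid$binx, grid$biny)
  sup <- displacement_support(u_x, noise, h)
  dir <- c(cos(angle), sin(angle)); ort <- c(-sin(angle), cos(angle))
  nc <- n_cells(grid)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(sup$w)) {
    offset <- sup$a[k] * dir + sup$b[k] * ort
    tgt <- sweep(grid$cells, 2, -offset)
    r <- sqrt(sum(offset^2))
    if (r > 0) {
      free <- cast_rays(env, grid$cells,
                        rep(atan2(offset[2], offset[1]), nc))$dist
      over <- which(free < r)
      if (length(over)) {
        tgt[over, ] <- grid$cells[over, , drop = FALSE] +
          outer(free[over] / r, offset)
      }
    }
    dest <- snap_to_cell(grid, tgt)
    ii <- c(ii, dest); jj <- c(jj, seq_len(nc)); xx <- c(xx, rep(sup$w[k], nc))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nc, nc))
}

# Observation log-likelihood at a true pose, rendered in env_true and
# evaluated against the believed library.
trial_obs_loglik <- function(pose, env_true, lib, grid, env_believed,
                             optics, tact, vision, dt) {
  ll <- NULL
  if (vision && !is.null(lib)) {
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

#' Run one homing trial
#'
#' Learning phase: the observer is guided from `learn_start` to `target`
#' in the familiar environment with full filtering; on arrival the belief
#' is encoded into memory with tempering `beta_learn`. Test phase: the
#' observer is placed at `test_start` in the test environment (which may
#' be a scaled version of the familiar one), optionally guided along a
#' multistep outbound path, and then chooses controls by softmax over
#' counterfactual values until it chooses to stay. Inference in the test
#' phase always uses the familiar environment's internal model.
#'
#' @param env_familiar,env_test `nav_env`s with corresponding walls.
#' @param target target location (familiar frame).
#' @param learn_start,test_start starting poses for the two phases.
#' @param grid `pose_grid` on the familiar environment.
#' @param optics `nav_optics` (or `NULL` for no vision at all).
#' @param noise `motion_noise`.
#' @param policy `nav_policy`.
#' @param beta_learn memory tempering.
#' @param tact optional `nav_tactile`.
#' @param sensors `"both"`, `"vision"` (the belief is rebuilt from the
#'   current visual likelihood alone at every step) or `"selfmotion"`
#'   (vision disabled in the test phase).
#' @param outbound optional list `(n_legs, axis)`, optionally with
#'   `target` (physical goal location in the test environment; default
#'   the familiar-frame target) and `return_dist` (true endpoint-target
#'   distance, m): guided outbound path (with vision) before the return.
#' @param outbound_dark disable vision during the homing loop after an
#'   outbound path.
#' @param learn_env environment the learning phase physically happens in
#'   (default the familiar environment; pass the test environment for
#'   protocols whose probe trial is learned under model mismatch).
#' @param learn_target physical target location in `learn_env` for the
#'   guided learning walk (default `target`).
#' @param init_test `"uniform"` or `"point"` (belief at the test start).
#' @param learn_init optional initial belief for the learning phase (e.g.
#'   a point mass when the learning walk starts from a known location);
#'   default uniform.
#' @param dt integration time per step.
#' @return a `trial_record` list: `response` (true location at stop),
#'   `response_believed`, `target`, `memory`, `learn_poses`,
#'   `test_poses`, `homing_start` (true pose when the homing loop began),
#'   `stopped` (FALSE if the step cap was hit), `steps`.
#' @export
run_homing_trial <- function(env_familiar, env_test, target, learn_start,
                             test_start, grid, optics, noise, policy,
                             beta_learn = 0.8, tact = NULL,
                             sensors = c("both", "vision", "selfmotion"),
                             outbound = NULL, outbound_dark = TRUE,
                             learn_env = NULL, learn_target = NULL,
                             init_test = c("uniform", "point"),
                             learn_init = NULL, dt = 1) {
  sensors <- match.arg(sensors)
  init_test <- match.arg(init_test)
  learn_env <- learn_env %||% env_familiar
  learn_target <- learn_target %||% target
  lib <- if (!is.null(optics)) build_view_library(env_familiar, grid, optics)
  obs <- function(pose, vision) {
    trial_obs_loglik(pose, env_test, lib, grid, env_familiar, optics, tact,
                     vision, dt)
  }
  obs_learn <- function(pose, vision) {
    trial_obs_loglik(pose, learn_env, lib, grid, env_familiar, optics,
                     tact, vision, dt)
  }
  # ---- learning phase (beliefs always under the familiar model) ----
  traj <- guided_trajectory(learn_env, learn_start, learn_target, noise,
                            policy$menu)
  belief <- learn_init %||% uniform_belief(grid)
  ll <- obs_learn(learn_start, TRUE)
  if (!is.null(ll)) {
    belief <- belief * exp(ll - max(ll)); belief <- belief / sum(belief)
  }
  for (t in seq_len(nrow(traj$controls))) {
    kern <- make_motion_kernel(grid, env_familiar, traj$controls[t, ], noise)
    belief <- filter_step(belief, kern, obs_learn(traj$poses[t + 1, ], TRUE))
  }
  memory <- encode_memory(belief, grid, beta_learn)

  # ---- test phase ----
  belief <- if (init_test == "uniform") uniform_belief(grid)
            else point_belief(grid, test_start)
  pose <- test_start
  vision_now <- sensors != "selfmotion"
  ll <- obs(pose, vision_now)
  if (!is.null(ll)) {
    belief <- belief * exp(ll - max(ll)); belief <- belief / sum(belief)
  }
  test_poses <- matrix(pose, 1, 3)
  if (!is.null(outbound)) {
    ob <- outbound_path(env_test, pose, outbound$n_legs,
                        outbound$target %||% target,
                        outbound$axis, noise, policy$menu,
                        margin = outbound$margin %||% 0.15,
                        return_dist = outbound$return_dist)
    for (t in seq_len(nrow(ob$controls))) {
      kern <- make_motion_kernel(grid, env_familiar, ob$controls[t, ], noise)
      belief <- filter_step(belief, kern, obs(ob$poses[t + 1, ], vision_now))
    }
    test_poses <- rbind(test_poses, ob$poses[-1, , drop = FALSE])
    pose <- ob$poses[nrow(ob$poses), ]
    if (outbound_dark) vision_now <- FALSE
  }
  homing_start <- pose
  kernels <- lapply(seq_len(nrow(policy$menu)), function(j)
    make_motion_kernel(grid, env_familiar, policy$menu[j, ], noise))
  bb <- env_bbox(env_test)
  cap <- policy$step_cap %||%
    ceiling(10 * sqrt(diff(bb$xlim)^2 + diff(bb$ylim)^2) /
              (max(policy$menu[, 1]) * dt))
  stay <- which(policy$menu[, 1] == 0 & policy$menu[, 2] == 0)[1]
  stopped <- FALSE
  steps <- 0L
  while (steps < cap) {
    v <- counterfactual_values(belief, memory, grid, kernels, policy$menu)
    j <- choose_control(v, policy$sigma_v2)
    if (j == stay) { stopped <- TRUE; break }
    pose <- step_pose(pose, policy$menu[j, ], noise, env_test)
    ll <- obs(pose, vision_now)
    if (sensors == "vision") {
      belief <- uniform_belief(grid)
      if (!is.null(ll)) {
        belief <- belief * exp(ll - max(ll)); belief <- belief / sum(belief)
      }
    } else {
      belief <- filter_step(belief, kernels[[j]], ll)
    }
    test_poses <- rbind(test_poses, pose)
    steps <- steps + 1L
  }
  structure(list(
    response = pose[1:2],
    response_believed = belief_moments(grid, belief)$mean,
    target = target, memory = memory,
    learn_poses = traj$poses, test_poses = test_poses,
    homing_start = homing_start, stopped = stopped, steps = steps
  ), class = "trial_record")
}

#' Run one distance-estimation trial
#'
#' The observer is guided (with vision, starting from a uniform prior)
#' to the root of an arrow placed in a familiar circular arena; the
#' posterior over the root location is retained without tempering. It
#' then walks in the arrow's direction (toward the arena center),
#' deciding walk-versus-stay by softmax over the expected negative
#' squared difference between the predicted distance from the root and
#' the remembered inter-object distance. The heading is treated as fixed
#' by the arrow during the walk.
#'
#' @param arena a circular `nav_env`.
#' @param grid `pose_grid` on the arena.
#' @param optics,noise,tact sensors.
#' @param target_distance remembered distance between the object pair
#'   (e.g. distance between the memory means from two learning runs).
#' @param root arrow root location.
#' @param start_pose pose the approach starts from.
#' @param sigma_v2 softmax temperature (squared meters).
#' @param menu control menu (forward speed taken from it).
#' @param step_cap walk cap.
#' @param dt integration time.
#' @return list with `walked` (true distance from the root at stop),
#'   `target_distance`, `stopped`.
#' @export
run_distance_trial <- function(arena, grid, optics, noise,
                               target_distance, root, start_pose,
                               sigma_v2 = 0.002, menu = control_menu(),
                               step_cap = 200, dt = 1) {
  lib <- build_view_library(arena, grid, optics)
  approach <- guided_trajectory(arena, start_pose, root, noise, menu)
  belief <- uniform_belief(grid)
  ll <- trial_obs_loglik(start_pose, arena, lib, grid, arena, optics, NULL,
                         TRUE, dt)
  belief <- belief * exp(ll - max(ll)); belief <- belief / sum(belief)
  for (t in seq_len(nrow(approach$controls))) {
    kern <- make_motion_kernel(grid, arena, approach$controls[t, ], noise)
    belief <- filter_step(belief, kern,
                          trial_obs_loglik(approach$poses[t + 1, ], arena,
                                           lib, grid, arena, optics, NULL,
                                           TRUE, dt))
  }
  p_root <- location_marginal(belief)
  pose <- approach$poses[nrow(approach$poses), ]
  arrow <- atan2(-root[2], -root[1])  # the arrow points to the center
  pose[3] <- arrow
  root_true <- pose[1:2]              # walk measured from the reached root
  theta_bin <- snap_to_theta(grid, arrow)
  dl <- max(menu[, 1])
  shift <- location_shift_kernel(grid, arena, arrow, dl, noise)
  D <- sqrt(outer(grid$cells[, 1], grid$cells[, 1], "-")^2 +
            outer(grid$cells[, 2], grid$cells[, 2], "-")^2)
  p_cur <- p_root
  value_of <- function(p_pred) {
    # sum_l sum_l' P_root(l) P_pred(l') * -(|l - l'| - target)^2
    -as.numeric(p_root %*% (D - target_distance)^2 %*% p_pred)
  }
  stopped <- FALSE
  for (s in seq_len(step_cap)) {
    v_stay <- value_of(p_cur)
    v_walk <- value_of(as.numeric(shift %*% p_cur))
    j <- choose_control(c(v_stay, v_walk), sigma_v2)
    if (j == 1) { stopped <- TRUE; break }
    pose <- step_pose(pose, c(dl, 0), noise, arena)
    pose[3] <- arrow
    p_cur <- as.numeric(shift %*% p_cur)
    img <- sample_visual(render_expected_image(arena, pose, optics), dt)
    lv <- visual_loglik(img$counts, lib, dt)[, theta_bin]
    p_cur <- p_cur * exp(lv - max(lv))
    p_cur <- p_cur / sum(p_cur)
  }
  list(walked = sqrt(sum((pose[1:2] - root_true)^2)),
       target_distance = target_distance, stopped = stopped)
}

#' Rank-based memory score of a homing response
#'
#' Fraction of grid locations in the environment whose distance to the
#' target strictly exceeds the response's distance to the target
#' (1 = response at the target, 0 = worst possible).
#'
#' @param response,target locations inside `env`.
#' @param env a `nav_env`.
#' @param bin ranking grid spacing.
#' @return score in `[0, 1]`.
#' @export
memory_score <- function(response, target, env, bin = 0.05) {
  grid <- make_pose_grid(env, bin = bin, n_theta = 1)
  d_all <- sqrt((grid$cells[, 1] - target[1])^2 +
                (grid$cells[, 2] - target[2])^2)
  d_resp <- sqrt(sum((response - target)^2))
  mean(d_all > d_resp)
}

#' Relative homing bias against matched familiar controls
#'
#' `(mean(test) - mean(familiar)) / mean(familiar)` over paired return
#' lengths.
#'
#' @param test_lengths,familiar_lengths return-journey lengths from
#'   matched test and familiar trials.
#' @return the signed relative bias.
#' @export
homing_bias <- function(test_lengths, familiar_lengths) {
  if (length(test_lengths) != length(familiar_lengths)) {
    stop("test and familiar trials must be matched")
  }
  (mean(test_lengths) - mean(familiar_lengths)) / mean(familiar_lengths)
}

# Signed inward-normal distance of points from a wall of the environment.
wall_coordinate <- function(env, pts, wall) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  s <- wall_segments(env)
  p <- s$p[wall, ]; q <- s$q[wall, ]
  w <- q - p
  n_in <- c(-w[2], w[1]) / sqrt(sum(w^2))  # inward for a CCW polygon
  (pts[, 1] - p[1]) * n_in[1] + (pts[, 2] - p[2]) * n_in[2]
}

#' Scale and shift of homing responses relative to equivalent targets
#'
#' Expresses responses and equivalent targets as signed distances from
#' each trial's starting wall and regresses response coordinates on
#' target coordinates pooled across trials: the slope is the response
#' scale, the intercept the shift (positive away from the starting
#' wall).
#'
#' @param env test environment.
#' @param responses,targets n x 2 matrices of response and
#'   equivalent-target locations.
#' @param start_walls wall index per trial.
#' @return list with `scale` and `shift`.
#' @export
response_scale_shift <- function(env, responses, targets, start_walls) {
  if (nrow(unique(round(targets, 9))) < 2) stop("need >= 2 distinct targets")
  rc <- tc <- numeric(nrow(responses))
  for (i in seq_len(nrow(responses))) {
    rc[i] <- wall_coordinate(env, responses[i, ], start_walls[i])
    tc[i] <- wall_coordinate(env, targets[i, ], start_walls[i])
  }
  fit <- stats::lm(rc ~ tc)
  list(scale = unname(stats::coef(fit)[2]),
       shift = unname(stats::coef(fit)[1]))
}
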