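# Experiment protocols: each driver runs one simulated paradigm
# end-to-end (simulate -> filter -> behave and/or fit-warp -> metrics)
# at the sizes given in its configuration and returns a summary list.
# Dispatch and configuration defaults live in run_experiment().

# Random interior location with a margin from the walls.
random_interior <- function(env, margin = 0.2) {
  bb <- env_bbox(env)
  repeat {
    p <- c(stats::runif(1, bb$xlim[1] + margin, bb$xlim[2] - margin),
           stats::runif(1, bb$ylim[1] + margin, bb$ylim[2] - margin))
    if (is_inside(env, p) && min(wall_distances(env, p)) > margin) return(p)
  }
}

# Largest |y| such that (x, y) stays inside with a margin.
half_width_at <- function(env, x, margin = 0.2) {
  lo <- 0; hi <- diff(env_bbox(env)$ylim)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    ok <- is_inside(env, c(x, mid)) && min(wall_distances(env, c(x, mid))) > margin
    if (ok) lo <- mid else hi <- mid
  }
  lo
}

# ---- deformation protocols (square vs trapezoid) ---------------------------

protocol_trapezoid_homing <- function(cfg) {
  envs <- list(square = cfg$env_square, trapezoid = cfg$env_trapezoid)
  rows <- list()
  for (name in names(envs)) {
    env <- envs[[name]]
    grid <- make_pose_grid(env, cfg$grid_bin, cfg$n_theta)
    # the trapezoid contributes two conditions (broad and narrow halves),
    # so it runs n_trials per half
    n_run <- if (name == "trapezoid") 2 * cfg$n_trials else cfg$n_trials
    for (i in seq_len(n_run)) {
      # trapezoid targets alternate between the broad (x<0) and narrow
      # (x>0) halves; square targets mirror the same |x| placement
      half <- if (i %% 2 == 0) "broad" else "narrow"
      bb <- env_bbox(env)
      x <- stats::runif(1, 0.25, 0.75) * (diff(bb$xlim) / 2) *
        (if (half == "broad") -1 else 1)
      y <- stats::runif(1, -1, 1) * half_width_at(env, x, cfg$margin)
      target <- c(x, y)
      start <- random_interior(env, cfg$margin)
      rec <- run_homing_trial(env, env, target,
                              learn_start = c(random_interior(env, cfg$margin),
                                              stats::runif(1, 0, 2 * pi)),
                              test_start = c(start, stats::runif(1, 0, 2 * pi)),
                              grid = grid, optics = cfg$optics,
                              noise = cfg$noise, policy = cfg$policy,
                              beta_learn = cfg$beta_learn)
      rows[[length(rows) + 1]] <- data.frame(
        env = name, half = half,
        score = memory_score(rec$response, target, env, cfg$score_bin),
        error = sqrt(sum((rec$response - target)^2)),
        stopped = rec$stopped)
    }
  }
  trials <- do.call(rbind, rows)
  summary <- stats::aggregate(score ~ env, trials, mean)
  halves <- stats::aggregate(score ~ half, trials[trials$env == "trapezoid", ],
                             mean)
  list(trials = trials, mean_by_env = summary, mean_by_half = halves)
}

protocol_distance_estimation <- function(cfg) {
  arena <- cfg$env_circle
  agrid <- make_pose_grid(arena, cfg$grid_bin, cfg$n_theta)
  conds <- list(
    square = list(env = cfg$env_square, x = NULL),
    trap_broad = list(env = cfg$env_trapezoid, x = "broad"),
    trap_narrow = list(env = cfg$env_trapezoid, x = "narrow"))
  D <- cfg$pair_distance
  rows <- list()
  for (name in names(conds)) {
    env <- conds[[name]]$env
    grid <- make_pose_grid(env, cfg$grid_bin, cfg$n_theta)
    bb <- env_bbox(env)
    x_at <- switch(conds[[name]]$x %||% "center",
      broad = -0.55 * diff(bb$xlim) / 2,
      narrow = {
        x <- 0.7 * diff(bb$xlim) / 2
        while (half_width_at(env, x, cfg$margin) < D / 2 + 0.05 && x > 0) {
          x <- x - 0.05 * diff(bb$xlim) / 2
        }
        x
      },
      -0.55 * diff(bb$xlim) / 2)
    pair <- rbind(c(x_at, -D / 2), c(x_at, D / 2))
    for (i in seq_len(cfg$n_trials)) {
      # encode the two object locations through full learning runs
      means <- t(apply(pair, 1, function(tg) {
        tr <- guided_trajectory(env, c(random_interior(env, cfg$margin),
                                       stats::runif(1, 0, 2 * pi)),
                                tg, cfg$noise, cfg$policy$menu)
        bel <- run_filter_along(env, env, tr, grid, cfg$optics, cfg$noise)
        encode_memory(bel, grid, cfg$beta_learn)$mean
      }))
      d_remembered <- sqrt(sum((means[1, ] - means[2, ])^2))
      root <- random_interior(arena, cfg$margin + 0.4)
      res <- run_distance_trial(arena, agrid, cfg$optics, cfg$noise,
                                d_remembered, root,
                                c(random_interior(arena, cfg$margin),
                                  stats::runif(1, 0, 2 * pi)),
                                sigma_v2 = cfg$policy$sigma_v2,
                                menu = cfg$policy$menu)
      rows[[length(rows) + 1]] <- data.frame(
        condition = name, walked = res$walked, true = D,
        bias = (res$walked - D) / D)
    }
  }
  trials <- do.call(rbind, rows)
  list(trials = trials,
       mean_bias = stats::aggregate(bias ~ condition, trials, mean))
}

# Filter a belief along an already-realized trajectory (observations
# rendered at the given true poses).
run_filter_along <- function(env_true, env_believed, traj, grid, optics,
                             noise, tact = NULL, vision = TRUE, dt = 1,
                             init = NULL) {
  lib <- if (!is.null(optics)) build_view_library(env_believed, grid, optics)
  belief <- init %||% uniform_belief(grid)
  vis <- rep_len(vision, nrow(traj$poses))
  ll <- trial_obs_loglik(traj$poses[1, ], env_true, lib, grid, env_believed,
                         optics, tact, vis[1], dt)
  if (!is.null(ll)) {
    belief <- belief * exp(ll - max(ll)); belief <- belief / sum(belief)
  }
  for (t in seq_len(nrow(traj$controls))) {
    kern <- make_motion_kernel(grid, env_believed, traj$controls[t, ], noise)
    belief <- filter_step(belief, kern,
                          trial_obs_loglik(traj$poses[t + 1, ], env_true, lib,
                                           grid, env_believed, optics, tact,
                                           vis[t + 1], dt))
  }
  belief
}

# ---- scaling protocols -----------------------------------------------------

protocol_hartley_scaling <- function(cfg) {
  fam <- cfg$env_square
  test <- scale_environment(fam, cfg$expand, 1)
  grid <- make_pose_grid(fam, cfg$grid_bin, cfg$n_theta)
  # matched foraging episodes: identical controls, same seeds
  seed0 <- sample.int(1e6, 1)
  set.seed(seed0)
  traj <- foraging_trajectory(fam, cfg$n_steps, cfg$noise, cfg$policy$menu,
                              start = c(0, 0, 0))
  set.seed(seed0)
  run_fam <- run_filter(fam, fam, traj$controls, c(0, 0, 0), grid,
                        cfg$optics, cfg$noise)
  set.seed(seed0)
  run_mis <- run_filter(test, fam, traj$controls, c(0, 0, 0), grid,
                        cfg$optics, cfg$noise)
  var_axis <- function(run) {
    v <- vapply(seq_len(ncol(run$marginals)), function(t)
      belief_moments(grid, run$marginals[, t])$cov[1, 1], numeric(1))
    mean(v)
  }
  list(var_x_familiar = var_axis(run_fam),
       var_x_mismatch = var_axis(run_mis),
       entropy_familiar = mean(run_fam$entropy),
       entropy_mismatch = mean(run_mis$entropy))
}

protocol_chen_axis_bias <- function(cfg) {
  fam <- cfg$env_square
  scales <- list(expand = cfg$expand, compress = cfg$compress)
  tests <- lapply(scales, function(s) scale_environment(fam, s, 1))
  grid <- make_pose_grid(fam, cfg$grid_bin, cfg$n_theta)
  rows <- list()
  seed0 <- sample.int(1e6, 1)
  # on a probe trial the whole episode (learning walk, outbound path,
  # dark return) physically happens in the scaled room while inference
  # runs under the familiar model; the matched control repeats the trial
  # in the familiar room with the same seed and the same true
  # endpoint-to-target distance
  # a (target, return distance) draw is kept only if a margin-respecting
  # endpoint exists on either side of the target in both rooms
  draw_trial_geometry <- function(env_test, s_x, axis) {
    ax <- if (axis == "x") c(1, 0) else c(0, 1)
    repeat {
      target <- random_interior(fam,
                                cfg$margin + 0.1 * diff(env_bbox(fam)$xlim))
      target_phys <- c(target[1] * s_x, target[2])
      return_dist <- stats::runif(1, 0.3, 0.42) * diff(env_bbox(fam)$xlim)
      ok <- function(env, tg) any(vapply(c(-1, 1), function(sg) {
        p <- tg + sg * ax * return_dist
        is_inside(env, p) && min(wall_distances(env, p)) > cfg$margin
      }, logical(1)))
      if (ok(env_test, target_phys) && ok(fam, target)) {
        return(list(target = target, target_phys = target_phys,
                    return_dist = return_dist))
      }
    }
  }
  one_trial <- function(env_test, s_x, axis, tseed) {
    set.seed(tseed)
    geo <- draw_trial_geometry(env_test, s_x, axis)
    target <- geo$target; target_phys <- geo$target_phys
    return_dist <- geo$return_dist
    run_homing_trial(fam, env_test, target,
                     learn_start = c(0, 0, stats::runif(1, 0, 2 * pi)),
                     test_start = c(0, 0, stats::runif(1, 0, 2 * pi)),
                     grid = grid, optics = cfg$optics, noise = cfg$noise,
                     policy = cfg$policy, beta_learn = cfg$beta_learn,
                     outbound = list(n_legs = cfg$n_legs, axis = axis,
                                     target = target_phys,
                                     return_dist = return_dist,
                                     margin = cfg$margin),
                     outbound_dark = TRUE, learn_env = env_test,
                     learn_target = target_phys, init_test = "point",
                     learn_init = point_belief(grid, c(0, 0, 0)))
  }
  # return length along the return axis (the measured journey component)
  ret_len <- function(rec, axis) {
    abs((rec$response - rec$homing_start[1:2])[if (axis == "x") 1 else 2])
  }
  for (cond in names(tests)) for (axis in c("x", "y")) {
    for (i in seq_len(cfg$n_trials)) {
      tseed <- seed0 + i
      rec_t <- one_trial(tests[[cond]], scales[[cond]], axis, tseed)
      rec_f <- one_trial(fam, 1, axis, tseed)
      rows[[length(rows) + 1]] <- data.frame(
        test = cond, axis = axis, trial = i,
        len_test = ret_len(rec_t, axis), len_fam = ret_len(rec_f, axis))
    }
  }
  trials <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(trials, trials[c("axis", "test")]),
    function(d) data.frame(test = d$test[1], axis = d$axis[1],
                           bias = homing_bias(d$len_test, d$len_fam),
                           p_sign = stats::binom.test(
                             sum(d$len_test > d$len_fam), nrow(d))$p.value)))
  rownames(agg) <- NULL
  list(trials = trials, bias = agg)
}

protocol_keinath_tethering <- function(cfg) {
  fam <- cfg$env_square
  tests <- list(compress = scale_environment(fam, cfg$compress, 1),
                expand = scale_environment(fam, cfg$expand, 1))
  grid <- make_pose_grid(fam, cfg$grid_bin, cfg$n_theta)
  L <- diff(env_bbox(fam)$xlim)
  # targets at graded distances from the west wall along the x axis
  targets <- cbind(seq(-0.3, 0.3, length.out = 4) * L, 0)
  west <- 4L  # wall index of the west wall of a square/rectangle
  start_of <- function(env) {
    c(env_bbox(env)$xlim[1] + 0.05, 0, 0)  # center of the west wall, facing +x
  }
  run_one <- function(env_test, tg, sensors) {
    run_homing_trial(fam, env_test, tg,
                     learn_start = c(random_interior(fam, cfg$margin),
                                     stats::runif(1, 0, 2 * pi)),
                     test_start = start_of(env_test), grid = grid,
                     optics = cfg$optics, noise = cfg$noise,
                     policy = cfg$policy, beta_learn = cfg$beta_learn,
                     sensors = sensors, init_test = "point")
  }
  rows <- list()
  for (cond in names(tests)) {
    env_test <- tests[[cond]]
    for (k in seq_len(nrow(targets))) for (i in seq_len(cfg$n_trials)) {
      rec <- run_one(env_test, targets[k, ], "both")
      rows[[length(rows) + 1]] <- data.frame(
        test = cond, target_i = k, sensors = "both",
        resp_x = rec$response[1], resp_y = rec$response[2],
        tgt_x = targets[k, 1], tgt_y = targets[k, 2])
    }
  }
  # single-cue response distributions for the nearest and farthest target
  for (k in c(1, nrow(targets))) for (sensors in c("vision", "selfmotion")) {
    for (i in seq_len(cfg$n_trials)) {
      rec <- run_one(tests$compress, targets[k, ], sensors)
      rows[[length(rows) + 1]] <- data.frame(
        test = "compress", target_i = k, sensors = sensors,
        resp_x = rec$response[1], resp_y = rec$response[2],
        tgt_x = targets[k, 1], tgt_y = targets[k, 2])
    }
  }
  trials <- do.call(rbind, rows)
  fit_cond <- function(cond) {
    d <- trials[trials$test == cond & trials$sensors == "both", ]
    response_scale_shift(tests[[cond]],
                         cbind(d$resp_x, d$resp_y),
                         cbind(d$tgt_x, d$tgt_y),
                         rep(west, nrow(d)))
  }
  list(trials = trials,
       compress = fit_cond("compress"), expand = fit_cond("expand"),
       targets = targets, west_wall = west, tests = tests)
}

# ---- neural protocols ------------------------------------------------------

# Foraging episode + ideal-observer posteriors + visit-binned targets.
neural_episode <- function(env_true, env_believed, cfg, h_condition = FALSE) {
  grid <- make_pose_grid(env_believed, cfg$grid_bin, cfg$n_theta)
  traj <- foraging_trajectory(env_true, cfg$n_steps, cfg$noise,
                              cfg$policy$menu, start = c(0, 0, 0))
  run <- run_filter(env_true, env_believed, traj$controls, c(0, 0, 0), grid,
                    cfg$optics, cfg$noise, tact = cfg$tact,
                    init = point_belief(grid, c(0, 0, 0)))
  # state bins: the true location snapped onto a grid for the true env,
  # optionally crossed with the last approached wall (east/west only)
  tgrid <- make_pose_grid(env_true, cfg$z_bin %||% cfg$grid_bin, 1)
  z_cell <- snap_to_cell(tgrid, run$poses[, 1:2])
  h <- NULL
  if (h_condition) {
    h <- last_wall_series(env_true, run$poses[, 1:2], cfg$h_threshold)
    h[!h %in% cfg$h_walls] <- NA
  }
  stats <- bin_posteriors(run$marginals, z_cell, tgrid$cells, h)
  list(grid = grid, tgrid = tgrid, run = run, stats = stats, traj = traj)
}

# Analytic rate maps of the fitted encode code over the true environment.
code_maps <- function(fit, env, cells = NULL, bin = 0.035, h_index = 1) {
  cells <- cells %||% seq_len(length(fit$alpha))
  mesh <- fit$meshes[[h_index]]
  lapply(cells, function(i) {
    rate_map(env, function(locs) warped_tuning(fit$modules, mesh, locs)[i, ],
             bin = bin)
  })
}

protocol_krupic_trapezoid_grids <- function(cfg) {
  out <- list()
  for (name in c("square", "trapezoid")) {
    env <- if (name == "square") cfg$env_square else cfg$env_trapezoid
    ep <- neural_episode(env, env, cfg)
    fit <- fit_warp(ep$stats, cfg$modules, ep$grid$cells,
                    mesh_bbox = env_bbox(env), decode = "tied",
                    mesh_n = cfg$mesh_n, w_reg = cfg$w_reg, beta = cfg$beta,
                    w_len = cfg$w_len, iterations = cfg$iterations,
                    alpha0 = cfg$alpha0)
    maps <- code_maps(fit, env, cfg$metric_cells, cfg$map_bin)
    met <- lapply(maps, function(m) {
      ac <- autocorrelogram(m, max_lag = min(dim(m$rate)) - 2)
      g <- tryCatch(gridness(ac), error = function(e) NA_real_)
      sf <- tryCatch(grid_scale_and_fields(m, ac), error = function(e) NULL)
      list(gridness = g, fields = sf$fields)
    })
    g <- vapply(met, function(m) m$gridness, numeric(1))
    fields <- do.call(rbind, lapply(met, function(m) m$fields))
    out[[name]] <- list(fit = fit, gridness = g, fields = fields,
                        diagnostics = warp_diagnostics(ep$run$marginals,
                                                       ep$stats, fit))
  }
  diam_half <- function(fields, broad) {
    sel <- if (broad) fields$x < 0 else fields$x > 0
    mean(fields$diameter[sel])
  }
  list(square = out$square, trapezoid = out$trapezoid,
       gridness_square = mean(out$square$gridness, na.rm = TRUE),
       gridness_trapezoid = mean(out$trapezoid$gridness, na.rm = TRUE),
       diameter_broad = diam_half(out$trapezoid$fields, TRUE),
       diameter_narrow = diam_half(out$trapezoid$fields, FALSE))
}

protocol_barry_rescaling_grids <- function(cfg) {
  fam <- cfg$env_square
  test <- scale_environment(fam, cfg$compress, 1)
  ep_fam <- neural_episode(fam, fam, cfg)
  fit_fam <- fit_warp(ep_fam$stats, cfg$modules, ep_fam$grid$cells,
                      mesh_bbox = env_bbox(fam), decode = "tied",
                      mesh_n = cfg$mesh_n, w_reg = cfg$w_reg,
                      beta = cfg$beta, w_len = cfg$w_len,
                      iterations = cfg$iterations, alpha0 = cfg$alpha0)
  ep_test <- neural_episode(test, fam, cfg)
  # decode tuning stays the code fitted when the familiar room was the
  # test room; only the encode mesh is refitted under mismatch
  F_dec <- warped_tuning(cfg$modules, fit_fam$meshes[[1]], ep_test$grid$cells)
  fit_test <- fit_warp(ep_test$stats, cfg$modules, ep_test$grid$cells,
                       mesh_bbox = env_bbox(test), decode = "fixed",
                       F_dec_fixed = F_dec, mesh_n = cfg$mesh_n,
                       w_reg = cfg$w_reg, beta = cfg$beta,
                       w_len = cfg$w_len, iterations = cfg$iterations,
                       alpha0 = cfg$alpha0)
  maps_fam <- code_maps(fit_fam, fam, cfg$metric_cells, cfg$map_bin)
  maps_test <- code_maps(fit_test, test, cfg$metric_cells, cfg$map_bin)
  ratios <- t(vapply(seq_along(maps_fam), function(i) {
    ff <- tryCatch(grid_scale_and_fields(maps_fam[[i]])$fields,
                   error = function(e) NULL)
    ft <- tryCatch(grid_scale_and_fields(maps_test[[i]])$fields,
                   error = function(e) NULL)
    if (is.null(ff) || is.null(ft)) return(c(NA_real_, NA_real_))
    c(tryCatch(axis_scaling_ratio(ff, ft, "x"), error = function(e) NA),
      tryCatch(axis_scaling_ratio(ff, ft, "y"), error = function(e) NA))
  }, numeric(2)))
  list(fit_fam = fit_fam, fit_test = fit_test,
       ratio_changed = mean(ratios[, 1], na.rm = TRUE),
       ratio_unchanged = mean(ratios[, 2], na.rm = TRUE),
       ratios = ratios)
}

protocol_keinath_grid_tethering <- function(cfg) {
  fam <- cfg$env_square
  test <- scale_environment(fam, cfg$compress, 1)
  fit_one <- function(env_true) {
    ep <- neural_episode(env_true, fam, cfg, h_condition = TRUE)
    fit <- fit_warp(ep$stats, cfg$modules, ep$grid$cells,
                    mesh_bbox = env_bbox(env_true), decode = "regular",
                    mesh_n = cfg$mesh_n, w_reg = cfg$w_reg, beta = cfg$beta,
                    w_len = cfg$w_len, iterations = cfg$iterations,
                    alpha0 = cfg$alpha0)
    list(ep = ep, fit = fit)
  }
  ffam <- fit_one(fam)
  ftest <- fit_one(test)
  h_of <- function(f, wall) which(f$fit$h_levels == wall)
  shift_pair <- function(f, env, axis) {
    scl <- cfg$modules$modules[[1]]$scale
    vapply(cfg$metric_cells, function(i) {
      m1 <- code_maps(f$fit, env, i, cfg$map_bin,
                      h_index = h_of(f, cfg$h_walls[1]))[[1]]
      m2 <- code_maps(f$fit, env, i, cfg$map_bin,
                      h_index = h_of(f, cfg$h_walls[2]))[[1]]
      tryCatch(phase_shift(m1, m2, scl, axis), error = function(e) NA_real_)
    }, numeric(1))
  }
  shifts <- list(
    familiar = shift_pair(ffam, fam, "x"),
    changed = shift_pair(ftest, test, "x"),
    unchanged = shift_pair(ftest, test, "y"))
  west <- cfg$h_walls[which.min(wall_segments(test)$p[cfg$h_walls, 1])]
  obs <- code_maps(ftest$fit, test, cfg$metric_cells, cfg$map_bin,
                   h_index = h_of(ftest, west))
  fam_maps <- code_maps(ffam$fit, fam, cfg$metric_cells, cfg$map_bin,
                        h_index = h_of(ffam, west))
  wall_x <- env_bbox(test)$xlim[1]
  tvs <- tether_vs_scale(obs, fam_maps, s_x = cfg$compress, s_y = 1,
                         wall_x = wall_x)
  list(shifts = lapply(shifts, mean, na.rm = TRUE),
       shifts_raw = shifts, tether_vs_scale = tvs,
       fit_fam = ffam$fit, fit_test = ftest$fit)
}

protocol_info_maps <- function(cfg) {
  out <- list()
  for (name in c("square", "trapezoid")) {
    env <- if (name == "square") cfg$env_square else cfg$env_trapezoid
    m <- info_map(env, cfg$optics, bin = cfg$info_bin,
                  n_headings = cfg$n_headings)
    d_wall <- apply(wall_distances(env, cbind(m$x, m$y)), 1, min)
    near <- d_wall < stats::median(d_wall)
    out[[name]] <- list(
      map = m,
      near_wall_mean = mean(m$info_total[near]),
      center_mean = mean(m$info_total[!near]),
      broad_mean = mean(m$info_total[m$x < 0]),
      narrow_mean = mean(m$info_total[m$x > 0]))
  }
  out
}
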