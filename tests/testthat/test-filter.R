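fx <- make_fixtures(1)
w <- fx$hmm_world

test_that("view library entries equal fresh renders and counts are right", {
  lib <- build_view_library(w$env, w$grid, w$optics)
  nc <- nrow(w$grid$cells)
  expect_equal(nrow(lib$V), nc * w$grid$n_theta)
  # pose index: cell c at heading bin t -> row c + (t-1)*nc
  c_ <- 7; t_ <- 3
  fresh <- render_expected_image(w$env, c(w$grid$cells[c_, ],
                                          w$grid$theta[t_]), w$optics)
  expect_equal(lib$V[c_ + (t_ - 1) * nc, ], as.numeric(fresh$expected))
})

test_that("motion_predict is the identity for degenerate noise and advects
           point masses", {
  still <- make_motion_noise(kappa = Inf, sigma_x = 0)
  k0 <- make_motion_kernel(w$grid, w$env, c(0, 0), still)
  b <- uniform_belief(w$grid)
  expect_equal(motion_predict(b, k0), b)
  # noiseless forward step from the center moves one bin along +x
  kf <- make_motion_kernel(w$grid, w$env, c(0.1, 0), still)
  b0 <- point_belief(w$grid, c(0, 0, 0))
  b1 <- motion_predict(b0, kf)
  expect_equal(b1[bayesnav:::snap_to_cell(w$grid, c(0.1, 0)),
                  bayesnav:::snap_to_theta(w$grid, 0)], 1)
  expect_error(motion_predict(2 * b, k0), "not normalized")
})

test_that("kernel columns conserve probability mass including clipped mass", {
  kern <- make_motion_kernel(w$grid, w$env, c(0.1, pi / 2), w$noise)
  expect_equal(colSums(kern$Ptheta), rep(1, w$grid$n_theta))
  for (t in seq_len(w$grid$n_theta)) {
    expect_equal(max(abs(Matrix::colSums(kern$disp[[t]]) - 1)), 0,
                 tolerance = 1e-12)
  }
})

test_that("visual likelihood matches a hand-computed Poisson Bayes toy", {
  # 3 poses x 2 pixels with hand-specified rates and counts
  vbar <- rbind(c(2, 0.5), c(1, 1), c(0.2, 3))
  lib <- list(V = vbar, logV = log(vbar), sumV = rowSums(vbar),
              grid_key = paste("e", 3, 1, 1, 1, 1, sep = "#"))
  class(lib) <- "view_library"
  counts <- c(3, 1)
  ll <- visual_loglik(counts, lib, dt = 1)
  hand <- counts[1] * log(vbar[, 1]) + counts[2] * log(vbar[, 2]) -
    rowSums(vbar)
  post_hand <- exp(hand) / sum(exp(hand))
  post <- exp(ll[, 1]) / sum(exp(ll[, 1]))
  expect_equal(post, post_hand, tolerance = 1e-12)
  # identical rows give identical log likelihood (ambiguity preserved)
  lib$V[2, ] <- lib$V[1, ]; lib$logV[2, ] <- lib$logV[1, ]
  lib$sumV[2] <- lib$sumV[1]
  ll2 <- visual_loglik(counts, lib, 1)
  expect_equal(ll2[1, 1], ll2[2, 1])
})

test_that("the darkest pose maximizes the likelihood of an all-zero count", {
  lib <- build_view_library(w$env, w$grid, w$optics)
  zero <- visual_loglik(rep(0L, w$optics$width * w$optics$height), lib, 1)
  expect_equal(which.max(as.numeric(zero)), which.min(lib$sumV))
})

test_that("tactile likelihood fields behave at the reliability limits", {
  tact0 <- make_tactile(p_w = 0)
  f <- tactile_loglik(c(1, 0), w$env, w$grid, tact0)
  expect_lt(diff(range(f)), 1e-12)
  tact1 <- make_tactile(p_w = 1)
  f1 <- tactile_loglik(c(1, 0), w$env, w$grid, tact1)
  expect_true(any(f1 == -Inf) && any(is.finite(f1)))
  tact <- make_tactile(p_w = 0.6)
  fm <- tactile_loglik(c(1, 0), w$env, w$grid, tact)
  expect_true(all(is.finite(fm)) && sum(exp(fm)) > 0)
})

test_that("flat likelihood reduces filter_step to pure prediction", {
  kern <- make_motion_kernel(w$grid, w$env, c(0.1, 0), w$noise)
  b <- point_belief(w$grid, c(0, 0, 0))
  flat <- matrix(0, nrow(b), ncol(b))
  expect_equal(filter_step(b, kern, flat), motion_predict(b, kern))
})

test_that("the grid filter equals the exhaustive forward recursion", {
  set.seed(11)
  n_steps <- 10
  controls <- w$controls[1:n_steps, ]
  lib <- build_view_library(w$env, w$grid, w$optics)
  # simulate observations along a true trajectory
  pose <- c(0, 0, 0)
  logliks <- list()
  img <- sample_visual(render_expected_image(w$env, pose, w$optics), 1)
  logliks[[1]] <- as.numeric(visual_loglik(img$counts, lib, 1))
  poses <- pose
  for (t in seq_len(n_steps)) {
    pose <- step_pose(pose, controls[t, ], w$noise, w$env)
    img <- sample_visual(render_expected_image(w$env, pose, w$optics), 1)
    logliks[[t + 1]] <- as.numeric(visual_loglik(img$counts, lib, 1))
  }
  init <- uniform_belief(w$grid)
  ref <- oracle_forward(w$grid, w$env, controls, w$noise, logliks, init)
  belief <- init * exp(logliks[[1]] - max(logliks[[1]]))
  belief <- belief / sum(belief)
  expect_equal(as.numeric(belief), ref[, 1], tolerance = 1e-12)
  for (t in seq_len(n_steps)) {
    kern <- make_motion_kernel(w$grid, w$env, controls[t, ], w$noise)
    belief <- filter_step(belief, kern,
                          matrix(logliks[[t + 1]], nrow(belief)))
    expect_lt(max(abs(as.numeric(belief) - ref[, t + 1])), 1e-10)
  }
})

test_that("run_filter tracks the true pose with rich vision", {
  set.seed(12)
  env <- make_environment("square", 1.4)
  grid <- make_pose_grid(env, 0.07, 24)
  opt <- make_optics(eye_height = 0.05, gain = 1)
  noise <- make_motion_noise()
  traj <- foraging_trajectory(env, 60, noise, control_menu(dl = 0.07),
                              start = c(0, 0, 0))
  run <- run_filter(env, env, traj$controls, c(0, 0, 0), grid, opt, noise,
                    init = point_belief(grid, c(0, 0, 0)))
  err <- vapply(seq_len(61), function(t) {
    mu <- belief_moments(grid, run$marginals[, t])$mean
    sqrt(sum((mu - run$poses[t, 1:2])^2))
  }, numeric(1))
  expect_lt(median(err), 2 * 0.07)
  # every emitted marginal is a distribution
  expect_true(all(run$marginals >= 0))
  expect_equal(colSums(run$marginals), rep(1, 61), tolerance = 1e-9)
})

test_that("without observations the posterior entropy never decreases", {
  set.seed(13)
  env <- make_environment("square", 1.4)
  grid <- make_pose_grid(env, 0.1, 8)
  noise <- make_motion_noise(kappa = 20, sigma_x = 0.3)
  controls <- cbind(rep(0.1, 6), 0)  # stays clear of the east wall
  run <- run_filter(env, env, controls, c(-0.45, 0, 0), grid, NULL, noise,
                    init = point_belief(grid, c(-0.45, 0, 0)))
  expect_true(all(diff(run$entropy) > -1e-9))
})

test_that("posterior entropy is lower near walls than in the open", {
  set.seed(14)
  env <- make_environment("square", 1.4)
  grid <- make_pose_grid(env, 0.07, 8)
  opt <- make_optics(eye_height = 0.05, gain = 0.5)
  lib <- build_view_library(env, grid, opt)
  ent_at <- function(loc) {
    mean(replicate(8, {
      th <- runif(1, 0, 2 * pi)
      img <- sample_visual(render_expected_image(env, c(loc, th), opt), 1)
      p <- rowSums(exp(visual_loglik(img$counts, lib, 1)))
      bayesnav:::prob_entropy(p / sum(p))
    }))
  }
  expect_lt(ent_at(c(0.6, 0)), ent_at(c(0, 0)))
})

test_that("mismatched environments inflate posterior variance on the
           changed axis", {
  set.seed(15)
  res <- run_experiment("hartley_scaling", config = list(n_steps = 100),
                        seed = 15)
  expect_gt(res$var_x_mismatch, res$var_x_familiar)
})
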