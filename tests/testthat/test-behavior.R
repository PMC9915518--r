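env <- make_environment("square", 1)
grid <- make_pose_grid(env, 0.1, 4)

test_that("memory tempering follows the stated power rule", {
  b <- uniform_belief(grid)
  m1 <- encode_memory(b, grid, 1)
  expect_equal(m1$p, rowSums(b))
  # hand computation on a two-bin mass
  b2 <- matrix(0, n_cells(grid), grid$n_theta)
  b2[1, 1] <- 0.8; b2[2, 1] <- 0.2
  m <- encode_memory(b2, grid, 0.5)
  expect_equal(m$p[1], sqrt(0.8) / (sqrt(0.8) + sqrt(0.2)), tolerance = 1e-12)
  expect_equal(m$p[2], sqrt(0.2) / (sqrt(0.8) + sqrt(0.2)), tolerance = 1e-12)
  expect_equal(m$mean, as.numeric(m$p %*% grid$cells))
  # beta -> 0 tends to uniform over the support
  m0 <- encode_memory(b2, grid, 1e-9)
  expect_equal(m0$p[1], m0$p[2], tolerance = 1e-6)
  expect_error(encode_memory(b, grid, 0), "beta_learn")
  expect_error(encode_memory(b, grid, 1.2), "beta_learn")
})

test_that("counterfactual values rank a step toward a point target above
           staying", {
  still <- make_motion_noise(kappa = Inf, sigma_x = 0)
  menu <- control_menu(dl = 0.1)
  kernels <- lapply(seq_len(nrow(menu)), function(j)
    make_motion_kernel(grid, env, menu[j, ], still))
  # agent one step west of the remembered point, facing east
  belief <- point_belief(grid, c(-0.1, 0, 0))
  target_belief <- point_belief(grid, c(0, 0, 0))
  memory <- encode_memory(target_belief, grid, 1)
  v <- counterfactual_values(belief, memory, grid, kernels, menu)
  expect_gt(v[2], v[1])                      # forward beats stay
  # hand value gap: distance^2 drops from (0.1)^2 to 0
  expect_equal(v[2] - v[1], 0.1^2, tolerance = 1e-9)
  # at the target, staying is maximal
  v0 <- counterfactual_values(target_belief, memory, grid, kernels, menu)
  expect_equal(which.max(v0), 1L)
  # joint translation of belief and memory leaves values unchanged
  belief_t <- point_belief(grid, c(0.1, 0.2, 0))
  memory_t <- encode_memory(point_belief(grid, c(0.2, 0.2, 0)), grid, 1)
  v_t <- counterfactual_values(belief_t, memory_t, grid, kernels, menu)
  expect_equal(v_t[1] - v[1], 0, tolerance = 1e-9)
})

test_that("softmax choice frequencies follow the value gaps", {
  set.seed(16)
  eq <- replicate(8000, choose_control(c(1, 1, 1), 0.5))
  for (j in 1:3) expect_lt(abs(mean(eq == j) - 1 / 3), 3 * sqrt(2 / 9 / 8000))
  hard <- replicate(400, choose_control(c(0, 1, 0), 1e-9))
  expect_true(all(hard == 2))
  # two candidates with gap g: empirical odds near exp(g / sigma)
  g <- 0.7; s <- 0.5
  two <- replicate(8000, choose_control(c(g, 0), s))
  odds <- mean(two == 1) / mean(two == 2)
  expect_lt(abs(log(odds) - g / s), 0.15)
  expect_error(choose_control(c(1, NA), 1), "finite")
})

test_that("memory score ranks distances over the enclosure", {
  sq <- make_environment("square", 2)
  expect_equal(memory_score(c(0.3, 0.3), c(0.3, 0.3), sq), 1)
  # the farthest point from a corner target scores 0
  expect_equal(memory_score(c(-1, -1), c(1, 1), sq, bin = 0.1), 0)
  # brute-force rank check at an arbitrary response
  resp <- c(0.4, -0.2); tgt <- c(-0.3, 0.5)
  g <- make_pose_grid(sq, 0.05, 1)
  d <- sqrt(rowSums(sweep(g$cells, 2, tgt)^2))
  expect_equal(memory_score(resp, tgt, sq, bin = 0.05),
               mean(d > sqrt(sum((resp - tgt)^2))))
  # rigid rotation of everything leaves the score unchanged
  rot <- function(p) c(-p[2], p[1])
  expect_equal(memory_score(rot(resp), rot(tgt), sq, bin = 0.05),
               memory_score(resp, tgt, sq, bin = 0.05), tolerance = 0.02)
})

test_that("homing bias recovers constructed scalings", {
  fam <- rep(2, 30)
  expect_equal(homing_bias(fam, fam), 0)
  expect_equal(homing_bias(0.9 * fam, fam), -0.1)
  expect_error(homing_bias(1:3, 1:4), "matched")
})

test_that("response scale/shift regression separates scaling from tethering", {
  sq <- make_environment("square", 4)      # walls at +-2; west wall is 4
  targets <- cbind(seq(-1.2, 1.2, length.out = 8), 0)
  walls <- rep(4L, 8)
  # identity responses
  fit <- response_scale_shift(sq, targets, targets, walls)
  expect_equal(fit$scale, 1, tolerance = 1e-9)
  expect_equal(fit$shift, 0, tolerance = 1e-9)
  # pure scaling by 0.8 about the starting wall
  resp <- cbind(-2 + 0.8 * (targets[, 1] + 2), 0)
  fit2 <- response_scale_shift(sq, resp, targets, walls)
  expect_equal(fit2$scale, 0.8, tolerance = 1e-9)
  expect_equal(fit2$shift, 0, tolerance = 1e-9)
  # pure tethering in a compressed room: distance to the starting wall
  # preserved from a familiar room whose west wall sat 0.5 farther out
  resp3 <- cbind(targets[, 1] + 0.5, 0)
  fit3 <- response_scale_shift(sq, resp3, targets, walls)
  expect_equal(fit3$scale, 1, tolerance = 1e-9)
  expect_gt(fit3$shift, 0)                  # shifted away from the wall
  expect_error(response_scale_shift(sq, targets[c(1, 1), ],
                                    targets[c(1, 1), ], walls[1:2]),
               "distinct")
})

test_that("an ideal-limit homing trial ends near the target", {
  set.seed(17)
  sq <- make_environment("square", 1.4)
  g <- make_pose_grid(sq, 0.07, 24)
  opt <- make_optics(eye_height = 0.05, gain = 0.2)
  quiet <- make_motion_noise(kappa = Inf, sigma_x = 0)
  pol <- make_policy(menu = control_menu(dl = 0.07), sigma_v2 = 1e-4)
  errs <- replicate(3, {
    # on-grid starts and on-bin headings: the exact-limit contract is
    # about policy consistency, not discretization drift
    rec <- run_homing_trial(sq, sq, c(0.3, -0.2),
                            learn_start = c(-0.385, 0.385, 0),
                            test_start = c(-0.315, -0.315, pi / 2), grid = g,
                            optics = opt, noise = quiet, policy = pol,
                            beta_learn = 1,
                            learn_init = point_belief(g, c(-0.385, 0.385, 0)),
                            init_test = "point")
    expect_true(rec$stopped)
    sqrt(sum((rec$response - c(0.3, -0.2))^2))
  })
  # residual error is bounded by the stacked discretization tolerances
  # (guided-stop radius + policy stop radius + half-bin localization)
  expect_lt(mean(errs), 3 * 0.07)
})

test_that("distance reproduction is near-veridical in the exact limit", {
  set.seed(18)
  arena <- make_environment("circle", 0.9, n_gon = 32)
  g <- make_pose_grid(arena, 0.09, 12)
  opt <- make_optics(eye_height = 0.05, gain = 0.2)
  quiet <- make_motion_noise(kappa = Inf, sigma_x = 0)
  res <- run_distance_trial(arena, g, opt, quiet, target_distance = 0.5,
                            root = c(0.45, 0), start_pose = c(-0.4, 0.3, 0),
                            sigma_v2 = 1e-4, menu = control_menu(dl = 0.09))
  expect_true(res$stopped)
  expect_lt(abs(res$walked - 0.5), 2.5 * 0.09)
})
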