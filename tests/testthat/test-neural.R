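mods <- make_grid_modules(scales = c(0.3), n_phases = 4)

test_that("regular tuning is hexagonal with the configured scale and peak", {
  env <- make_environment("square", 1.2)
  m <- rate_map(env, function(l) regular_tuning(mods, l)[1, ], bin = 0.02)
  expect_true(all(m$rate[is.finite(m$rate)] >= 0))
  expect_equal(max(m$rate, na.rm = TRUE), 10, tolerance = 0.01)
  ac <- autocorrelogram(m, max_lag = 25)
  sf <- grid_scale_and_fields(m, ac)
  expect_lt(abs(sf$scale - 0.3), 0.03)
  # rotating the lattice orientation by 60 degrees leaves rates unchanged
  mods60 <- make_grid_modules(scales = c(0.3), n_phases = 4,
                              orientations = 0.13 + pi / 3)
  pts <- cbind(runif(50, -0.5, 0.5), runif(50, -0.5, 0.5))
  # the zero-phase cell's lattice is 60-degree rotation invariant
  expect_equal(regular_tuning(mods60, pts)[1, ], regular_tuning(mods, pts)[1, ],
               tolerance = 1e-9)
})

test_that("warp meshes interpolate bilinearly and reproduce anchors", {
  bb <- list(xlim = c(-1, 1), ylim = c(-1, 1))
  mesh <- make_warp_mesh(bb, 5)
  pts <- cbind(runif(20, -1, 1), runif(20, -1, 1))
  expect_equal(warp_apply(mesh, pts), pts)              # identity mesh
  stretch <- mesh; stretch$pos <- cbind(2 * mesh$rest[, 1], mesh$rest[, 2])
  expect_equal(warp_apply(stretch, pts), cbind(2 * pts[, 1], pts[, 2]))
  # interpolation passes through the nodes
  expect_equal(warp_apply(stretch, mesh$rest), stretch$pos)
  # a uniform compression mesh compresses the field spacing
  comp <- mesh; comp$pos <- 1.5 * mesh$rest   # tuning coords grow 1.5x
  env <- make_environment("square", 1.2)
  mw <- rate_map(env, function(l) warped_tuning(mods, comp, l)[1, ],
                 bin = 0.02)
  sfw <- grid_scale_and_fields(mw, autocorrelogram(mw, max_lag = 25))
  expect_lt(abs(sfw$scale - 0.3 / 1.5), 0.03)
  expect_equal(max(mw$rate, na.rm = TRUE), 10, tolerance = 0.05)
})

test_that("the decoder matches a hand-computed two-cell three-location toy", {
  fx <- make_fixtures(1)$decoder_toy
  out <- neural_log_posterior(fx$f_enc, fx$F_dec, fx$alpha)
  hand <- sapply(1:3, function(l) {
    sum(fx$alpha * (fx$f_enc * log(fx$F_dec[, l]) - fx$F_dec[, l]))
  })
  hand <- hand - log(sum(exp(hand)))
  expect_equal(out$log_posterior, hand, tolerance = 1e-12)
  # multiplying alpha by c sharpens: posterior^c renormalized
  c_ <- 2.5
  out2 <- neural_log_posterior(fx$f_enc, fx$F_dec, c_ * fx$alpha)
  sharp <- c_ * out$log_posterior
  sharp <- sharp - log(sum(exp(sharp)))
  expect_equal(out2$log_posterior, sharp, tolerance = 1e-10)
  # self-consistent decoding peaks at the true location
  env <- make_environment("square", 1.0)
  locs <- make_pose_grid(env, 0.05, 1)$cells
  dense <- make_grid_modules(scales = c(0.25, 0.35), n_phases = 25)
  F <- regular_tuning(dense, locs)
  z <- 117
  post <- neural_log_posterior(F[, z], F, rep(0.5, nrow(F)))$posterior
  expect_equal(which.max(post), z)
})

test_that("the angle regularizer vanishes at right angles and grows
           monotonically under shear", {
  bb <- list(xlim = c(0, 2), ylim = c(0, 2))
  mesh <- make_warp_mesh(bb, 3)
  expect_equal(reg_loss(mesh, 1, 1), 0)
  # single-angle check: a 2x2 mesh sheared so the corner angle is 60 deg
  m2 <- make_warp_mesh(list(xlim = c(0, 1), ylim = c(0, 1)), 2)
  th <- 60 * pi / 180
  m2$pos <- rbind(c(0, 0), c(1, 0), c(cos(th), sin(th)),
                  c(1 + cos(th), sin(th)))
  # all four corner angles equal 60 or 120 deg: per-angle penalty 0.25
  expect_equal(reg_loss(m2, 1, 1), 4 * (1 - sin(th)^2), tolerance = 1e-12)
  # monotone growth along a one-parameter shear path
  pen <- sapply(seq(0, 0.8, by = 0.1), function(s) {
    m <- mesh
    m$pos <- mesh$rest + cbind(s * mesh$rest[, 2], 0)
    reg_loss(m, 1, 1)
  })
  expect_true(all(diff(pen) > 0))
})

test_that("analytic fit gradients agree with finite differences", {
  set.seed(19)
  env <- make_environment("square", 1.0)
  locs <- make_pose_grid(env, 0.2, 1)$cells
  m2 <- make_grid_modules(scales = c(0.3, 0.45), n_phases = 4)
  Pbar <- exp(-as.matrix(dist(locs))^2 / (2 * 0.12^2))
  Pbar <- Pbar / rowSums(Pbar)
  stats <- list(M = rpois(nrow(locs), 3) + 1, Pbar = Pbar, z_locs = locs,
                z_h = rep(1L, nrow(locs)))
  mesh <- make_warp_mesh(bayesnav:::env_bbox(env), 4)
  B <- bayesnav:::mesh_weights(mesh, locs)
  setup <- list(stats = stats, modules = m2, dec_locs = locs,
                meshes = list(mesh), h_levels = 1L,
                z_rows_h = list(seq_len(nrow(locs))), B_enc = list(B),
                B_dec = B, F_dec_fixed = NULL, decode = "tied",
                Mw = stats$M / sum(stats$M), nz = nrow(locs),
                nloc = nrow(locs), w_reg = 0.05, beta = 1, T = 1,
                floor_frac = 1e-6, n_mod = 2, tether = list(integer(0)),
                w_tether = 5, edges = bayesnav:::mesh_edges(4), w_len = 0.3)
  np <- list(mesh$pos + matrix(rnorm(32, 0, 0.01), 16, 2))
  la <- c(0.2, -0.1)
  g <- bayesnav:::warp_objective(np, la, setup, want_grad = TRUE)
  h <- 1e-6
  for (i in c(1, 6, 11, 16)) for (d in 1:2) {
    npp <- np; npp[[1]][i, d] <- npp[[1]][i, d] + h
    npm <- np; npm[[1]][i, d] <- npm[[1]][i, d] - h
    num <- (bayesnav:::warp_objective(npp, la, setup)$loss -
              bayesnav:::warp_objective(npm, la, setup)$loss) / (2 * h)
    expect_equal(g$d_nodes[[1]][i, d], num, tolerance = 1e-4)
  }
  for (m in 1:2) {
    lap <- la; lap[m] <- lap[m] + h
    lam <- la; lam[m] <- lam[m] - h
    num <- (bayesnav:::warp_objective(np, lap, setup)$loss -
              bayesnav:::warp_objective(np, lam, setup)$loss) / (2 * h)
    expect_equal(g$d_logalpha[m], num, tolerance = 1e-4)
  }
})

test_that("fitting targets from the regular code stays at the identity and
           never worsens the objective", {
  set.seed(20)
  env <- make_environment("square", 1.0)
  locs <- make_pose_grid(env, 0.1, 1)$cells
  m2 <- make_grid_modules(scales = c(0.3, 0.42), n_phases = 9)
  F <- regular_tuning(m2, locs)
  alpha_true <- 0.2
  lp <- bayesnav:::neural_log_posterior_matrix(F, F,
                                               rep(alpha_true, nrow(F)))
  stats <- list(M = rpois(nrow(locs), 5) + 1, Pbar = exp(lp), z_locs = locs,
                z_h = rep(1L, nrow(locs)))
  fit <- fit_warp(stats, m2, locs, mesh_bbox = bayesnav:::env_bbox(env),
                  decode = "tied", mesh_n = 5, alpha0 = alpha_true,
                  iterations = 60)
  expect_lt(max(abs(fit$meshes[[1]]$pos - fit$meshes[[1]]$rest)), 1e-8)
  # the returned (best-iterate) fit never worsens the starting objective
  expect_lte(fit$fit_loss + fit$reg_loss, fit$loss_trace[1] + 1e-12)
})

test_that("the visit-binned objective equals the direct time-averaged KL
           up to the data entropy constant", {
  set.seed(21)
  env <- make_environment("square", 1.0)
  grid <- make_pose_grid(env, 0.125, 8)
  noise <- make_motion_noise()
  opt <- make_optics(width = 12, height = 4, eye_height = 0.05, gain = 0.4)
  traj <- foraging_trajectory(env, 200, noise, control_menu(dl = 0.125),
                              start = c(0, 0, 0))
  run <- run_filter(env, env, traj$controls, c(0, 0, 0), grid, opt, noise,
                    init = point_belief(grid, c(0, 0, 0)))
  z <- bayesnav:::snap_to_cell(grid, run$poses[, 1:2])
  stats <- bin_posteriors(run$marginals, z, grid$cells)
  m2 <- make_grid_modules(scales = c(0.3, 0.42), n_phases = 9)
  F_enc <- regular_tuning(m2, stats$z_locs)
  F_dec <- regular_tuning(m2, grid$cells)
  lp <- bayesnav:::neural_log_posterior_matrix(F_enc, F_dec,
                                               rep(0.1, nrow(F_enc)))
  direct <- direct_kl(run$marginals, stats, lp)
  Ttot <- sum(stats$M)
  binned <- -sum((stats$M / Ttot) * rowSums(stats$Pbar * lp))
  C <- mean(vapply(stats$t_index, function(t) {
    p <- run$marginals[, t]
    sum(p[p > 0] * log(p[p > 0]))
  }, numeric(1)))
  expect_lt(abs(direct$mean - (C + binned)), 1e-10)
})

test_that("a known warped code is recovered from an identity start and the
           diagnostics order correctly", {
  set.seed(22)
  env <- make_environment("square", 1.0)
  locs <- make_pose_grid(env, 0.0625, 1)$cells
  m2 <- make_grid_modules(scales = c(0.3, 0.42))
  bb <- bayesnav:::env_bbox(env)
  mesh_true <- make_warp_mesh(bb, 9)
  d <- 0.035
  mesh_true$pos <- mesh_true$rest + cbind(
    d * sin(pi * mesh_true$rest[, 1]) * cos(pi * mesh_true$rest[, 2] / 2),
    -d * sin(pi * mesh_true$rest[, 2]) * cos(pi * mesh_true$rest[, 1] / 2))
  onb <- mesh_true$rest[, 1] %in% bb$xlim | mesh_true$rest[, 2] %in% bb$ylim
  mesh_true$pos[onb, ] <- mesh_true$rest[onb, ]
  F_true <- warped_tuning(m2, mesh_true, locs)
  lp_true <- bayesnav:::neural_log_posterior_matrix(F_true, F_true,
                                                    rep(0.15, nrow(F_true)))
  M <- rpois(nrow(locs), 8) + 1
  stats <- list(M = M, Pbar = exp(lp_true), z_locs = locs,
                z_h = rep(1L, nrow(locs)))
  fit <- fit_warp(stats, m2, locs, mesh_bbox = bb, decode = "tied",
                  mesh_n = 9, w_reg = 0.01, w_len = 0.05, iterations = 300)
  node_err <- sqrt(rowSums((fit$meshes[[1]]$pos - mesh_true$pos)^2))
  spacing <- diff(bb$xlim) / 8
  expect_lt(max(node_err), spacing / 2)
  # synthetic episode from the states for the diagnostics
  t_seq <- sample(seq_len(nrow(locs)), 400, replace = TRUE)
  marg <- t(exp(lp_true[t_seq, ]))
  stats_ep <- bin_posteriors(marg, t_seq, locs)
  diag <- warp_diagnostics(marg, stats_ep, fit, shuffle_seed = 1)
  expect_lt(diag["optim", "kl"], diag["regular", "kl"])
  expect_lt(diag["optim", "kl"], diag["shuffle", "kl"])
  expect_lte(diag["within", "kl"], diag["optim", "kl"] + 1e-9)
  # exact posteriors give (near) zero divergence for the generating code
  gen <- fit
  gen$meshes <- list(mesh_true)
  gen$alpha <- rep(0.15, length(gen$alpha))
  gen$F_dec <- F_true
  d0 <- direct_kl(marg, stats_ep, bayesnav:::code_log_posteriors(gen, stats_ep))
  expect_lt(d0$mean, 1e-9)
})
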