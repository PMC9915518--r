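env <- make_environment("square", 1.2)
mods <- make_grid_modules(scales = c(0.35), n_phases = 4)
hexmap <- rate_map(env, function(l) regular_tuning(mods, l)[1, ], bin = 0.03)

test_that("rate maps flag unvisited bins and converge between modes", {
  flat <- rate_map(env, function(l) rep(2, nrow(l)), bin = 0.1)
  expect_true(all(abs(flat$rate[flat$valid] - 2) < 1e-12))
  set.seed(23)
  traj <- cbind(runif(4000, -0.6, 0.6), runif(4000, -0.3, 0))  # lower half
  m <- rate_map(env, function(l) regular_tuning(mods, l)[1, ], bin = 0.1,
                trajectory = traj)
  expect_true(any(!m$valid))                    # upper half never visited
  expect_true(all(is.na(m$rate[!m$valid])))
  # spike mode converges to the analytic rate at long duration
  rates <- regular_tuning(mods, traj)[1, ]
  spikes <- rpois(length(rates), rates)
  ms <- rate_map(env, NULL, bin = 0.1, trajectory = traj, spikes = spikes)
  ok <- ms$valid & m$valid
  expect_gt(cor(ms$rate[ok], m$rate[ok]), 0.97)
  expect_error(rate_map(env, NULL, bin = 0.1, trajectory = matrix(0, 0, 2)),
               "empty")
})

test_that("autocorrelograms are symmetric with a unit center", {
  ac <- autocorrelogram(hexmap, max_lag = 15)
  k <- (dim(ac$ac) + 1) / 2
  expect_equal(ac$ac[k[1], k[2]], 1)
  expect_equal(ac$ac, ac$ac[rev(seq_len(nrow(ac$ac))),
                            rev(seq_len(ncol(ac$ac)))])
  expect_error(autocorrelogram(rate_map(env, function(l) rep(1, nrow(l)),
                                        bin = 0.1)),
               "degenerate|sd")
})

test_that("gridness separates hexagonal, square and noise patterns", {
  ac <- autocorrelogram(hexmap, max_lag = 25)
  expect_gt(gridness(ac), 0.8)
  sq_map <- rate_map(env, function(l)
    pmax(1 + cos(2 * pi * l[, 1] / 0.4) + cos(2 * pi * l[, 2] / 0.4), 0),
    bin = 0.03)
  expect_lt(gridness(autocorrelogram(sq_map, max_lag = 25)), 0)
  set.seed(24)
  noise_map <- rate_map(env, function(l) runif(nrow(l)), bin = 0.06)
  g_noise <- tryCatch(gridness(autocorrelogram(noise_map, max_lag = 15)),
                      error = function(e) 0)
  expect_lt(abs(g_noise), 0.5)
  # gridness is invariant under global rate scaling
  double <- hexmap; double$rate <- 2 * double$rate
  expect_equal(gridness(autocorrelogram(double, max_lag = 25)),
               gridness(ac), tolerance = 1e-9)
})

test_that("grid scale and field diameters track a known lattice", {
  sf <- grid_scale_and_fields(hexmap)
  expect_lt(abs(sf$scale - 0.35), 0.03)
  expect_true(all(sf$fields$diameter == 2 * sqrt(sf$fields$area / pi)))
  # lattice density: about area / (sqrt(3)/2 * scale^2) fields fit inside
  n_expect <- environment_area(env) / (sqrt(3) / 2 * 0.35^2)
  expect_lt(abs(nrow(sf$fields) - n_expect) / n_expect, 0.45)
  # uniform 2x stretch doubles scale and diameters
  stretched <- make_grid_modules(scales = c(0.7), n_phases = 4)
  big_env <- make_environment("square", 2.4)
  m2 <- rate_map(big_env, function(l) regular_tuning(stretched, l)[1, ],
                 bin = 0.06)
  sf2 <- grid_scale_and_fields(m2)
  expect_lt(abs(sf2$scale / sf$scale - 2), 0.15)
  expect_lt(abs(mean(sf2$fields$diameter) / mean(sf$fields$diameter) - 2),
            0.35)
})

test_that("axis scaling ratios recover constructed deformations", {
  sf <- grid_scale_and_fields(hexmap)$fields
  expect_equal(axis_scaling_ratio(sf, sf, "x"), 1, tolerance = 1e-9)
  squeezed <- sf; squeezed$x <- 0.7 * sf$x
  expect_equal(axis_scaling_ratio(sf, squeezed, "x"), 0.7, tolerance = 1e-6)
  expect_equal(axis_scaling_ratio(sf, squeezed, "y"), 1, tolerance = 1e-6)
  expect_error(axis_scaling_ratio(sf[1, ], sf[1, ], "x"), "matched")
})

test_that("phase shifts fold displacements into [0, scale/2]", {
  shift_map <- function(dx) {
    rate_map(env, function(l)
      regular_tuning(mods, cbind(l[, 1] - dx, l[, 2]))[1, ], bin = 0.03)
  }
  expect_equal(phase_shift(hexmap, hexmap, 0.35, "x"), 0)
  s1 <- phase_shift(hexmap, shift_map(0.25 * 0.35), 0.35, "x")
  expect_lt(abs(s1 - 0.25), 0.05)
  s2 <- phase_shift(hexmap, shift_map(0.75 * 0.35), 0.35, "x")
  expect_lt(abs(s2 - 0.25), 0.05)   # periodic folding
  expect_gte(s1, 0); expect_lte(s1, 0.5)
})

test_that("tethering vs scaling correlations identify constructed codes", {
  fam_env <- make_environment("square", 1.2)
  test_env <- scale_environment(fam_env, 0.7, 1)
  wall_x <- bayesnav:::env_bbox(test_env)$xlim[1]
  fam_maps <- lapply(1:6, function(i) {
    ph <- c(0.05 * i, -0.03 * i)
    rate_map(fam_env, function(l)
      regular_tuning(mods, sweep(l, 2, ph))[1, ], bin = 0.03)
  })
  # observed maps built from pure tethering: distance to the west wall
  # preserved (familiar pattern translated by the wall displacement)
  shift <- wall_x / 0.7 - wall_x
  obs_tether <- lapply(1:6, function(i) {
    ph <- c(0.05 * i, -0.03 * i)
    rate_map(test_env, function(l)
      regular_tuning(mods, sweep(cbind(l[, 1] + shift, l[, 2]), 2, ph))[1, ],
      bin = 0.03)
  })
  res <- tether_vs_scale(obs_tether, fam_maps, s_x = 0.7, wall_x = wall_x)
  expect_true(all(res$per_cell$r_tether > 0.999))
  expect_true(all(res$per_cell$r_tether > res$per_cell$r_scale))
  expect_lt(res$p, 0.01)
  # observed maps built from pure scaling
  obs_scale <- lapply(1:6, function(i) {
    ph <- c(0.05 * i, -0.03 * i)
    rate_map(test_env, function(l)
      regular_tuning(mods, sweep(cbind(l[, 1] / 0.7, l[, 2]), 2, ph))[1, ],
      bin = 0.03)
  })
  res2 <- tether_vs_scale(obs_scale, fam_maps, s_x = 0.7, wall_x = wall_x)
  expect_true(all(res2$per_cell$r_scale > 0.999))
})
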