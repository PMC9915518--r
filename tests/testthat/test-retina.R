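test_that("rendering is deterministic and linear in gain", {
  env <- make_environment("square", 1.4)
  opt <- make_optics(width = 16, height = 6, eye_height = 0.1)
  pose <- c(0.2, -0.1, 0.7)
  a <- render_expected_image(env, pose, opt)
  b <- render_expected_image(env, pose, opt)
  expect_identical(a$expected, b$expected)
  opt2 <- opt; opt2$gain <- 2 * opt$gain; opt2$blur_sigma <- 0
  opt1 <- opt; opt1$blur_sigma <- 0
  expect_equal(render_expected_image(env, pose, opt2)$expected,
               2 * render_expected_image(env, pose, opt1)$expected)
})

test_that("a uniform wall filling the view renders constant", {
  env <- make_environment("square", 2, texture_amp = 0)
  env$texture$base <- rep(1, 4)
  env$floor_luminance <- 1; env$sky_luminance <- 1
  opt <- make_optics(width = 12, height = 6, fov_h = pi / 3, fov_v = pi / 4,
                     eye_height = 0.25, blur_sigma = 1)
  img <- render_expected_image(env, c(0.8, 0, 0), opt)  # facing east wall
  expect_lt(diff(range(img$expected)), 1e-12)
})

test_that("a known corner projects at focal * tan(azimuth)", {
  # observer at the center of a unit square facing +x: the NE corner at
  # (0.5, 0.5) sits at azimuth 45 deg, i.e. at u = tan(45) = 1 on the
  # image plane. With fov_h = 120 deg, u spans +-tan(60): the luminance
  # step from the east to the north wall must occur at that pixel.
  env <- make_environment("square", 1, texture_amp = 0)
  env$texture$base <- c(10, 10, 0.5, 10)  # north wall (3) much darker
  opt <- make_optics(width = 48, height = 3, fov_h = 2 * pi / 3,
                     fov_v = pi / 6, blur_sigma = 0, gain = 1,
                     eye_height = 0.25)
  img <- render_expected_image(env, c(0, 0, 0), opt)
  row <- img$expected[2, ]
  # expected pixel of the corner: u = tan(azimuth) = 1
  u_pix <- opt$u
  expected_col <- which.min(abs(u_pix - 1))
  jump <- which(abs(diff(row)) > 4)
  expect_true(any(abs(jump - expected_col) <= 1))
})

test_that("a nearer wall occludes a farther wall along shared rays", {
  fx <- make_fixtures(1)
  occl <- fx$occlusion_scene
  # from the west half, looking east at y = 0: the notch wall at x = 0 is
  # hit, not the far east walls at x = 1
  hit <- cast_rays(occl, c(-0.5, 0), 0)
  expect_equal(hit$dist, 0.5)
  opt <- make_optics(width = 8, height = 4, fov_h = pi / 4, fov_v = pi / 4,
                     blur_sigma = 0, gain = 1, eye_height = 0.2)
  img_near <- render_expected_image(occl, c(-0.5, 0, 0), opt)
  # center pixels carry the notch wall's texture, whose luminance differs
  # from the east wall's
  notch_lum <- wall_luminance(occl, hit$wall, hit$along)
  expect_equal(img_near$expected[2, 4], notch_lum, tolerance = 0.35)
})

test_that("uniform scene scaling with matched eye and wall height is invariant", {
  env <- make_environment("square", 1.2)
  s <- 1.7
  env2 <- scale_environment(env, s, s)
  env2$wall_height <- env$wall_height * s
  opt <- make_optics(width = 12, height = 6, eye_height = 0.2)
  opt2 <- opt; opt2$eye_height <- opt$eye_height * s
  a <- render_expected_image(env, c(0.3, -0.2, 1.1), opt)
  b <- render_expected_image(env2, c(0.3 * s, -0.2 * s, 1.1), opt2)
  expect_equal(a$expected, b$expected, tolerance = 1e-9)
})

test_that("Poisson sampling matches its first two moments", {
  set.seed(8)
  env <- make_environment("square", 1)
  opt <- make_optics(width = 6, height = 3, gain = 5, eye_height = 0.2)
  img <- render_expected_image(env, c(0, 0, 0.4), opt)
  dt <- 2
  draws <- replicate(3000, as.numeric(sample_visual(img, dt)$counts))
  m <- rowMeans(draws); v <- apply(draws, 1, var)
  lam <- as.numeric(img$expected) * dt
  expect_true(all(abs(m - lam) < 3 * sqrt(lam / 3000) + 1e-9))
  # Poisson dispersion: variance tracks the mean
  expect_lt(abs(mean(v / lam) - 1), 0.1)
  zero <- img; zero$expected[] <- 0
  expect_true(all(sample_visual(zero, 1)$counts == 0))
})

test_that("tactile readings follow the two Bernoulli branches", {
  env <- make_environment("square", 2)
  touching <- c(0.9, 0, 0)       # right probe reaches the east wall? no:
  # probes are at +-90 deg; facing +x at x=0.9 the probes point north/south
  far <- c(0, 0, 0)
  sure <- make_tactile(p_w = 1)
  set.seed(9)
  # at the center nothing is in reach: all readings 0
  expect_true(all(replicate(20, sample_tactile(env, far, sure)$readings) == 0))
  # against the east wall facing north, the right probe (at -90) points east
  at_wall <- c(0.95, 0, pi / 2)
  r <- replicate(20, sample_tactile(env, at_wall, sure)$readings[1])
  expect_true(all(r == 1))
  # p_w = 0: uninformative coin flips
  coin <- make_tactile(p_w = 0)
  set.seed(10)
  flips <- replicate(2000, sample_tactile(env, at_wall, coin)$readings[1])
  expect_lt(abs(mean(flips) - 0.5), 3 * 0.5 / sqrt(2000))
})
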