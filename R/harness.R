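# Experiment orchestration: configuration defaults, the protocol
# dispatcher, deterministic test fixtures, and YAML config round-trips.

#' Default configuration for a protocol
#'
#' Returns the full parameter set a protocol runs with: environments,
#' optics, motion noise, discretization, policy and neural-code
#' parameters, and replication counts. Every value can be overridden via
#' the `config` argument of [run_experiment()].
#'
#' @param protocol protocol name (see [run_experiment()]).
#' @return a named list.
#' @export
default_config <- function(protocol) {
  rodent <- list(
    env_square = make_environment("square", 1.4, wall_height = 0.5),
    env_trapezoid = make_environment("trapezoid", c(1.9, 0.9, 0.2),
                                     wall_height = 0.5),
    optics = make_optics(eye_height = 0.05),
    noise = make_motion_noise(kappa = 50, sigma_x = 0.15, family = "gamma"),
    tact = make_tactile(),
    grid_bin = 0.07, n_theta = 12,
    policy = make_policy(menu = control_menu(dl = 0.07)),
    margin = 0.1)
  human <- list(
    # square area matches the trapezoid's (as in the VR experiments)
    env_square = make_environment("square", 5.1, wall_height = 3),
    env_trapezoid = make_environment("trapezoid", c(9.5, 4.5, 1),
                                     wall_height = 3),
    env_circle = make_environment("circle", 3.5, wall_height = 3),
    optics = make_optics(eye_height = 1.6, gain = 0.5),
    noise = make_motion_noise(kappa = 50, sigma_x = 0.17,
                              family = "gaussian"),
    tact = NULL,
    grid_bin = 0.35, n_theta = 12,
    policy = make_policy(menu = control_menu(dl = 0.35)),
    margin = 0.5)
  neural_small <- list(
    env_square = make_environment("square", 1.0, wall_height = 0.5),
    optics = make_optics(eye_height = 0.05, gain = 0.5),
    noise = make_motion_noise(kappa = 50, sigma_x = 0.15, family = "gamma"),
    tact = make_tactile(p_w = 0.5),
    grid_bin = 0.0625, n_theta = 12, z_bin = 0.125,
    policy = make_policy(menu = control_menu(dl = 0.0625)),
    margin = 0.1,
    modules = make_grid_modules(scales = c(0.3, 0.42)),
    mesh_n = 4, w_reg = 0.1, beta = 1, w_len = 0.15, iterations = 800,
    alpha0 = 0.1,
    n_steps = 3000, map_bin = 0.025, metric_cells = 1:8,
    h_threshold = 0.12, h_walls = c(2L, 4L))
  switch(protocol,
    trapezoid_homing = c(human, list(n_trials = 40, beta_learn = 0.8,
                                     score_bin = 0.35)),
    distance_estimation = c(human, list(n_trials = 20, beta_learn = 0.8,
                                        pair_distance = 2)),
    hartley_scaling = c(human, list(expand = 1.4, n_steps = 150)),
    chen_axis_bias = utils::modifyList(human, list(
      optics = make_optics(eye_height = 1.6, gain = 1),
      expand = 1.4, compress = 0.7, n_trials = 40, n_legs = 3,
      beta_learn = 1)),
    keinath_tethering = c(human, list(compress = 0.7, expand = 1.4,
                                      n_trials = 10, beta_learn = 1)),
    krupic_trapezoid_grids = utils::modifyList(neural_small, list(
      env_square = make_environment("square", 1.4, wall_height = 0.5),
      env_trapezoid = make_environment("trapezoid", c(1.9, 0.9, 0.2),
                                       wall_height = 0.5),
      grid_bin = 0.07, z_bin = 0.14,
      policy = make_policy(menu = control_menu(dl = 0.07)),
      modules = make_grid_modules(scales = c(0.35, 0.5)),
      map_bin = 0.03)),
    barry_rescaling_grids = c(neural_small, list(compress = 0.7)),
    keinath_grid_tethering = c(neural_small, list(compress = 0.65)),
    info_maps = c(rodent, list(info_bin = 0.15, n_headings = 8)),
    stop("unknown protocol: ", protocol)
  )
}

#' Run an experiment protocol end-to-end
#'
#' Available protocols: `trapezoid_homing` (homing memory scores in
#' square vs trapezoid enclosures), `distance_estimation` (walked
#' distance reproduction), `hartley_scaling` (posterior variance under
#' environment rescaling), `chen_axis_bias` (homing biases along changed
#' and unchanged axes after a dark return), `keinath_tethering`
#' (response scale and shift relative to the starting wall),
#' `krupic_trapezoid_grids`, `barry_rescaling_grids`,
#' `keinath_grid_tethering` (fitted warped population codes and grid
#' metrics), `info_maps` (visual information maps).
#'
#' @param protocol protocol name.
#' @param config optional overrides merged over [default_config()].
#' @param seed integer seed; all randomness in the run derives from it.
#' @return protocol-specific summary list; the configuration and seed
#'   are attached as attributes.
#' @export
run_experiment <- function(protocol, config = NULL, seed = 1) {
  cfg <- default_config(protocol)
  if (!is.null(config)) cfg <- utils::modifyList(cfg, config)
  if (!is.null(cfg$replications) && cfg$replications <= 0) {
    stop("replication count must be positive")
  }
  set.seed(seed)
  out <- switch(protocol,
    trapezoid_homing = protocol_trapezoid_homing(cfg),
    distance_estimation = protocol_distance_estimation(cfg),
    hartley_scaling = protocol_hartley_scaling(cfg),
    chen_axis_bias = protocol_chen_axis_bias(cfg),
    keinath_tethering = protocol_keinath_tethering(cfg),
    krupic_trapezoid_grids = protocol_krupic_trapezoid_grids(cfg),
    barry_rescaling_grids = protocol_barry_rescaling_grids(cfg),
    keinath_grid_tethering = protocol_keinath_grid_tethering(cfg),
    info_maps = protocol_info_maps(cfg),
    stop("unknown protocol: ", protocol)
  )
  attr(out, "protocol") <- protocol
  attr(out, "seed") <- seed
  out
}

#' Deterministic fixtures for testing
#'
#' Tiny, fully specified worlds used by the test suite: a 5x5x4 pose
#' world for checking the grid filter against an exhaustive forward
#' recursion, a concave two-wall occlusion scene, a point-landmark scene,
#' toy 4x4 rate maps, and a 2-cell / 3-location decoder toy.
#'
#' @param seed seed controlling the randomized pieces.
#' @return named list of fixtures (>= 5 entries).
#' @export
make_fixtures <- function(seed = 1) {
  set.seed(seed)
  env5 <- make_environment("square", 0.5, wall_height = 0.3)
  hmm_world <- list(
    env = env5,
    grid = make_pose_grid(env5, bin = 0.1, n_theta = 4),
    noise = make_motion_noise(kappa = 4, sigma_x = 0.4, family = "gamma",
                              dt = 1),
    optics = make_optics(width = 8, height = 4, blur_sigma = 0.5,
                         gain = 0.4, eye_height = 0.1),
    controls = cbind(rep(0.1, 50),
                     sample(c(-pi / 2, 0, pi / 2), 50, replace = TRUE)))
  # concave hexagon: the notch wall (3) occludes the far east wall along
  # rays cast from the western half
  occl <- structure(list(
    vertices = rbind(c(-1, -1), c(1, -1), c(1, -0.2), c(0, -0.2),
                     c(0, 0.2), c(1, 0.2), c(1, 1), c(-1, 1)),
    wall_height = 0.5, floor_luminance = 0.3, sky_luminance = 0.1,
    name = "occlusion", shape = "polygon", dims = NA), class = "nav_env")
  occl$texture <- default_textures(occl)
  landmark <- make_landmark_scene(data.frame(x = 3, y = 0.5))
  maps4 <- list(a = matrix(c(1, 2, 3, 4, 2, 3, 4, 5, 3, 4, 5, 6,
                             4, 5, 6, 7), 4, 4),
                b = matrix(stats::runif(16), 4, 4))
  decoder_toy <- list(
    F_dec = rbind(c(2, 0.5, 0.1), c(0.2, 1, 3)),  # 2 cells x 3 locations
    f_enc = c(1.5, 0.8), alpha = c(1, 1))
  list(hmm_world = hmm_world, occlusion_scene = occl,
       landmark_scene = landmark, toy_rate_maps = maps4,
       decoder_toy = decoder_toy)
}

#' Write / read an environment or experiment configuration as YAML
#'
#' Environments are serialized as their constructor spec (shape,
#' dimensions, wall height, texture parameters), not as raw vertices.
#'
#' @param env a `nav_env`.
#' @param path file path.
#' @return `read_environment_config` returns a `nav_env`.
#' @export
write_environment_config <- function(env, path) {
  yaml::write_yaml(list(shape = env$shape, dims = as.numeric(env$dims),
                        wall_height = env$wall_height,
                        floor_luminance = env$floor_luminance,
                        sky_luminance = env$sky_luminance,
                        name = env$name,
                        texture = as.list(env$texture)), path)
  invisible(path)
}

#' @rdname write_environment_config
#' @export
read_environment_config <- function(path) {
  spec <- yaml::read_yaml(path)
  env <- make_environment(spec$shape, unlist(spec$dims),
                          wall_height = spec$wall_height,
                          floor_luminance = spec$floor_luminance,
                          sky_luminance = spec$sky_luminance,
                          name = spec$name)
  env$texture <- as.data.frame(spec$texture)
  env
}
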