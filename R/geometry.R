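#' Construct a polygonal enclosure
#'
#' Builds a closed polygonal environment centered (by centroid) at the
#' origin, with per-wall luminance textures. Coordinates are in meters,
#' x rightward and y upward; headings are counterclockwise from +x.
#'
#' @param shape one of `"square"`, `"rectangle"`, `"trapezoid"`, `"circle"`.
#' @param dims numeric dimensions in meters: side for `square`; `c(lx, ly)`
#'   for `rectangle`; `c(length, broad, narrow)` for `trapezoid` (isosceles,
#'   parallel sides perpendicular to the x axis, broad end at negative x);
#'   radius for `circle` (approximated by a regular n-gon).
#' @param wall_height wall height in meters.
#' @param floor_luminance,sky_luminance uniform luminances outside the walls.
#' @param n_gon number of sides used to approximate a circular arena.
#' @param texture_amp amplitude of the sinusoidal stripe added to each
#'   wall's base luminance. Per-wall base levels and stripe phases differ,
#'   so every wall is visually distinct (an orientation cue).
#' @param name label stored on the environment.
#' @return an object of class `nav_env`.
#' @export
make_environment <- function(shape, dims, wall_height = 0.5,
                             floor_luminance = 0.3, sky_luminance = 0.1,
                             n_gon = 64, texture_amp = 0.35, name = shape) {
  if (any(dims <= 0)) stop("dimensions must be positive")
  v <- switch(shape,
    square = {
      h <- dims[1] / 2
      rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))
    },
    rectangle = {
      hx <- dims[1] / 2; hy <- dims[2] / 2
      rbind(c(-hx, -hy), c(hx, -hy), c(hx, hy), c(-hx, hy))
    },
    trapezoid = {
      if (length(dims) < 3) stop("trapezoid needs c(length, broad, narrow)")
      l <- dims[1] / 2; b <- dims[2] / 2; n <- dims[3] / 2
      rbind(c(-l, -b), c(l, -n), c(l, n), c(-l, b))
    },
    circle = {
      th <- 2 * pi * (seq_len(n_gon) - 1) / n_gon
      cbind(dims[1] * cos(th), dims[1] * sin(th))
    },
    stop("unknown shape: ", shape)
  )
  v <- sweep(v, 2, polygon_centroid(v))
  env <- structure(list(
    vertices = v, wall_height = wall_height,
    floor_luminance = floor_luminance, sky_luminance = sky_luminance,
    name = name, shape = shape, dims = dims
  ), class = "nav_env")
  env$texture <- default_textures(env, texture_amp)
  env
}

# Per-wall texture parameters: luminance(s) = base + amp*sin(2*pi*freq*s + phase)
# with s the along-wall coordinate in meters. Bases and phases cycle so that
# adjacent walls are distinguishable.
default_textures <- function(env, amp = 0.35) {
  n <- nrow(env$vertices)
  i <- seq_len(n) - 1
  # golden-ratio sequences keep every wall pairwise distinct in base
  # luminance and stripe frequency (no rotational ambiguities)
  data.frame(
    base = 0.45 + 0.9 * ((i * 0.37 + 0.05) %% 1),
    amp = rep(amp, n),
    freq = 1.2 + 1.6 * ((i * 0.61803 + 0.21) %% 1),
    phase = 2 * pi * ((i * 0.61803) %% 1)
  )
}

#' @export
print.nav_env <- function(x, ...) {
  cat(sprintf("<nav_env '%s': %d walls, area %.3f m^2, wall height %.2f m>\n",
              x$name, nrow(x$vertices), environment_area(x), x$wall_height))
  invisible(x)
}

# Closed list of wall segments: wall i runs from vertices[i,] to vertices[i+1,].
wall_segments <- function(env) {
  v <- env$vertices
  n <- nrow(v)
  list(p = v, q = v[c(2:n, 1), , drop = FALSE])
}

wall_lengths <- function(env) {
  s <- wall_segments(env)
  sqrt(rowSums((s$q - s$p)^2))
}

polygon_centroid <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  c(sum((v[, 1] + v[j, 1]) * cr), sum((v[, 2] + v[j, 2]) * cr)) / (6 * a)
}

#' Enclosed area of an environment (shoelace formula)
#' @param env a `nav_env`.
#' @return area in square meters.
#' @export
environment_area <- function(env) {
  v <- env$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

#' Containment test
#'
#' Crossing-number test with a boundary tolerance: points within `tol` of a
#' wall count as inside (the dynamics place agents exactly on walls).
#'
#' @param env a `nav_env`.
#' @param pts an n x 2 matrix (or length-2 vector) of locations.
#' @param tol boundary tolerance in meters.
#' @return logical vector.
#' @export
is_inside <- function(env, pts, tol = 1e-9) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  s <- wall_segments(env)
  n <- nrow(s$p)
  inside <- rep(FALSE, nrow(pts))
  x <- pts[, 1]; y <- pts[, 2]
  for (i in seq_len(n)) {
    x1 <- s$p[i, 1]; y1 <- s$p[i, 2]; x2 <- s$q[i, 1]; y2 <- s$q[i, 2]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  if (tol > 0) {
    d <- do.call(pmin, as.data.frame(wall_distances(env, pts)))
    inside <- inside | (d <= tol)
  }
  inside
}

#' Distance from points to every wall segment
#' @param env a `nav_env`.
#' @param pts n x 2 matrix of locations.
#' @return n x n_walls matrix of Euclidean point-to-segment distances.
#' @export
wall_distances <- function(env, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  s <- wall_segments(env)
  n <- nrow(s$p)
  out <- matrix(NA_real_, nrow(pts), n)
  for (i in seq_len(n)) {
    p <- s$p[i, ]; w <- s$q[i, ] - p
    l2 <- sum(w^2)
    t <- ((pts[, 1] - p[1]) * w[1] + (pts[, 2] - p[2]) * w[2]) / l2
    t <- pmin(1, pmax(0, t))
    out[, i] <- sqrt((pts[, 1] - p[1] - t * w[1])^2 +
                     (pts[, 2] - p[2] - t * w[2])^2)
  }
  out
}

#' Cast rays against the walls (and optional extra occluding segments)
#'
#' @param env a `nav_env`.
#' @param origin n x 2 matrix of ray origins (or a single location recycled).
#' @param angles ray directions, radians; recycled against origins.
#' @param segments optional extra occluders: list with `p`, `q` matrices.
#' @return list with `dist` (distance to first hit, `Inf` if none), `wall`
#'   (index; extra segments follow the walls), `along` (hit coordinate along
#'   the segment, meters from its start).
#' @export
cast_rays <- function(env, origin, angles, segments = NULL) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 2)
  n <- max(nrow(origin), length(angles))
  ox <- rep_len(origin[, 1], n); oy <- rep_len(origin[, 2], n)
  a <- rep_len(angles, n)
  dx <- cos(a); dy <- sin(a)
  s <- wall_segments(env)
  P <- s$p; Q <- s$q
  if (!is.null(segments)) { P <- rbind(P, segments$p); Q <- rbind(Q, segments$q) }
  best_t <- rep(Inf, n); best_w <- rep(NA_integer_, n); best_s <- rep(NA_real_, n)
  for (i in seq_len(nrow(P))) {
    wx <- Q[i, 1] - P[i, 1]; wy <- Q[i, 2] - P[i, 2]
    den <- cross2(dx, dy, wx, wy)
    px <- P[i, 1] - ox; py <- P[i, 2] - oy
    t <- cross2(px, py, wx, wy) / den
    u <- cross2(px, py, dx, dy) / den
    ok <- is.finite(t) & t > 1e-9 & u >= -1e-12 & u <= 1 + 1e-12 & t < best_t
    best_t[ok] <- t[ok]
    best_w[ok] <- i
    best_s[ok] <- u[ok] * sqrt(wx^2 + wy^2)
  }
  list(dist = best_t, wall = best_w, along = best_s)
}

#' Move with wall clipping
#'
#' Returns `to` when it lies inside the environment; otherwise the point
#' where the segment from `from` to `to` first meets the boundary (the
#' intersection nearest `from`), i.e. the agent stops at the wall.
#'
#' @param env a `nav_env`.
#' @param from current location (inside the environment).
#' @param to intended location.
#' @return a length-2 location.
#' @export
clip_move <- function(env, from, to) {
  if (!is_inside(env, from)) stop("`from` lies outside the environment")
  if (is_inside(env, to)) return(as.numeric(to))
  d <- to - from
  len <- sqrt(sum(d^2))
  if (len == 0) return(as.numeric(from))
  hit <- cast_rays(env, from, atan2(d[2], d[1]))
  if (!is.finite(hit$dist) || hit$dist > len) return(as.numeric(from))
  as.numeric(from + d / len * hit$dist)
}

#' Scale an environment about the origin
#'
#' Vertex coordinates are multiplied by `(s_x, s_y)`; wall identities are
#' preserved and textures stretch with their wall (texture frequency is
#' expressed per meter of the original wall, rescaled to keep the pattern
#' attached to the wall material).
#'
#' @param env a `nav_env`.
#' @param s_x,s_y positive scale factors.
#' @return the scaled `nav_env`.
#' @export
scale_environment <- function(env, s_x, s_y = s_x) {
  if (s_x <= 0 || s_y <= 0) stop("scale factors must be positive")
  out <- env
  out$vertices <- cbind(env$vertices[, 1] * s_x, env$vertices[, 2] * s_y)
  ratio <- wall_lengths(out) / wall_lengths(env)
  out$texture$freq <- env$texture$freq / ratio
  out$name <- sprintf("%s_x%.3g_y%.3g", env$name, s_x, s_y)
  out
}

#' Wall luminance texture
#' @param env a `nav_env`.
#' @param wall wall indices.
#' @param along along-wall coordinates in meters from the wall start.
#' @return non-negative luminance values.
#' @export
wall_luminance <- function(env, wall, along) {
  tx <- env$texture
  v <- tx$base[wall] + tx$amp[wall] *
    sin(2 * pi * tx$freq[wall] * along + tx$phase[wall])
  pmax(v, 0)
}

#' Last wall approached along a trajectory
#'
#' Label (index) of the wall whose distance to the agent most recently
#' dropped below `near_threshold`; `NA` if no wall was ever approached.
#' When several walls are within threshold at the same step the nearest
#' one is taken.
#'
#' @param env a `nav_env`.
#' @param trajectory n x 2 matrix of locations (time-ordered).
#' @param near_threshold approach distance in meters (default 12 cm).
#' @return a single wall index, or `NA_integer_`.
#' @export
last_wall_approached <- function(env, trajectory, near_threshold = 0.12) {
  if (is.null(dim(trajectory))) trajectory <- matrix(trajectory, ncol = 2)
  if (nrow(trajectory) == 0) stop("empty trajectory")
  if (near_threshold <= 0) stop("near_threshold must be positive")
  d <- wall_distances(env, trajectory)
  lab <- NA_integer_
  for (t in seq_len(nrow(d))) {
    i <- which.min(d[t, ])
    if (d[t, i] < near_threshold) lab <- i
  }
  lab
}

# Running last-wall label per time step (NA until the first approach).
last_wall_series <- function(env, trajectory, near_threshold = 0.12) {
  d <- wall_distances(env, trajectory)
  nearest <- max.col(-d)
  near <- d[cbind(seq_len(nrow(d)), nearest)] < near_threshold
  lab <- rep(NA_integer_, nrow(d))
  cur <- NA_integer_
  for (t in seq_len(nrow(d))) {
    if (near[t]) cur <- nearest[t]
    lab[t] <- cur
  }
  lab
}

env_bbox <- function(env) {
  v <- env$vertices
  list(xlim = range(v[, 1]), ylim = range(v[, 2]))
}
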