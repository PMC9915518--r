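# Warped grid-cell population code.
#
# Tuning curves are hexagonal (sum of three cosine gratings 60 degrees
# apart) defined on a coordinate mesh; warping the mesh deforms the
# fields. A probabilistic population decoder turns the (noise-free,
# infinite-population limit) rates into a "neural posterior" over
# location, and the mesh plus per-module sharpness weights are fitted by
# gradient descent so the neural posterior matches the ideal observer's
# posterior in time-averaged KL divergence.

#' Grid module specification
#'
#' @param scales grid scale (distance between adjacent field peaks) per
#'   module, meters.
#' @param n_phases number of cells (phase offsets) per module; phases tile
#'   the lattice unit rhombus on a regular sub-grid.
#' @param peak_rate peak firing rate.
#' @param orientations lattice orientation per module, radians.
#' @return a `grid_modules` object.
#' @export
make_grid_modules <- function(scales = c(0.35, 0.5), n_phases = 16,
                              peak_rate = 10,
                              orientations = rep(0.13, length(scales))) {
  stopifnot(all(scales > 0), n_phases >= 1)
  mods <- lapply(seq_along(scales), function(m) {
    s <- scales[m]; om <- orientations[m]
    # wave vectors of the three gratings, 60 degrees apart
    kmag <- 4 * pi / (sqrt(3) * s)
    K <- kmag * cbind(cos(om + pi / 6 + (0:2) * pi / 3),
                      sin(om + pi / 6 + (0:2) * pi / 3))
    # lattice basis (adjacent peaks at distance s)
    a1 <- s * c(cos(om), sin(om))
    a2 <- s * c(cos(om + pi / 3), sin(om + pi / 3))
    nside <- ceiling(sqrt(n_phases))
    ij <- expand.grid(i = seq_len(nside) - 1, j = seq_len(nside) - 1)
    ij <- ij[seq_len(n_phases), , drop = FALSE]
    phases <- cbind(ij$i / nside * a1[1] + ij$j / nside * a2[1],
                    ij$i / nside * a1[2] + ij$j / nside * a2[2])
    list(scale = s, orientation = om, K = K, phases = phases,
         peak_rate = peak_rate)
  })
  structure(list(modules = mods, n_phases = n_phases,
                 peak_rate = peak_rate,
                 cell_module = rep(seq_along(scales), each = n_phases)),
            class = "grid_modules")
}

# Hexagonal grating sum g(x) in [-1.5, 3] for one module at given
# locations; returns n_loc x n_phases.
module_grating <- function(mod, locs) {
  P <- locs %*% t(mod$K)          # n_loc x 3
  Q <- mod$phases %*% t(mod$K)    # n_phases x 3
  cos(P) %*% t(cos(Q)) + sin(P) %*% t(sin(Q))
}

#' Regular hexagonal tuning curves
#'
#' Each cell's rate is `peak * (g + 1.5) / 4.5` where `g` is the sum of
#' three cosine gratings 60 degrees apart, so rates are non-negative and
#' the maximum equals the configured peak rate.
#'
#' @param modules a `grid_modules`.
#' @param locs n x 2 matrix of locations.
#' @return n_cells x n matrix of rates (cells ordered module-major).
#' @export
regular_tuning <- function(modules, locs) {
  if (is.null(dim(locs))) locs <- matrix(locs, ncol = 2)
  F <- lapply(modules$modules, function(mod) {
    t(mod$peak_rate * (module_grating(mod, locs) + 1.5) / 4.5)
  })
  do.call(rbind, F)
}

# Gradient helper: given dL/dF (n_cells x n_loc) for tuning evaluated at
# warped coordinates Y (n_loc x 2), return dL/dY.
tuning_coord_gradient <- function(modules, Y, dF) {
  dY <- matrix(0, nrow(Y), 2)
  row0 <- 0
  for (mod in modules$modules) {
    nph <- nrow(mod$phases)
    idx <- row0 + seq_len(nph)
    P <- Y %*% t(mod$K)
    cq <- cos(mod$phases %*% t(mod$K)); sq <- sin(mod$phases %*% t(mod$K))
    dFm <- dF[idx, , drop = FALSE]      # nph x n_loc
    scale <- mod$peak_rate / 4.5
    for (j in 1:3) {
      cj <- as.numeric(crossprod(dFm, cq[, j]))  # n_loc
      sj <- as.numeric(crossprod(dFm, sq[, j]))
      A <- sin(P[, j]) * cj - cos(P[, j]) * sj   # sum_i dF * sin(p - q)
      dY <- dY - scale * cbind(A * mod$K[j, 1], A * mod$K[j, 2])
    }
    row0 <- row0 + nph
  }
  dY
}

# ---- warp mesh -------------------------------------------------------------

#' Rectangular warp mesh
#'
#' A grid of nodes over a rectangular domain; each node maps its rest
#' (undeformed) coordinate to a warped coordinate, interpolated
#' piecewise-bilinearly in between. The identity mesh leaves coordinates
#' unchanged.
#'
#' @param bbox list with `xlim`, `ylim` (e.g. [env_bbox()]), the mesh
#'   domain.
#' @param n nodes per side.
#' @return a `warp_mesh`.
#' @export
make_warp_mesh <- function(bbox, n = 9) {
  x0 <- seq(bbox$xlim[1], bbox$xlim[2], length.out = n)
  y0 <- seq(bbox$ylim[1], bbox$ylim[2], length.out = n)
  rest <- cbind(rep(x0, times = n), rep(y0, each = n))
  structure(list(n = n, x0 = x0, y0 = y0, rest = rest, pos = rest,
                 bbox = bbox), class = "warp_mesh")
}

# Sparse bilinear weight matrix mapping node positions to warped
# coordinates of `locs` (n_loc x n_nodes). Locations are clamped into the
# mesh domain.
mesh_weights <- function(mesh, locs) {
  if (is.null(dim(locs))) locs <- matrix(locs, ncol = 2)
  n <- mesh$n
  hx <- mesh$x0[2] - mesh$x0[1]; hy <- mesh$y0[2] - mesh$y0[1]
  fx <- (locs[, 1] - mesh$x0[1]) / hx
  fy <- (locs[, 2] - mesh$y0[1]) / hy
  ix <- pmin(n - 1L, pmax(1L, floor(fx) + 1L))
  iy <- pmin(n - 1L, pmax(1L, floor(fy) + 1L))
  tx <- pmin(1, pmax(0, fx - (ix - 1L)))
  ty <- pmin(1, pmax(0, fy - (iy - 1L)))
  node <- function(i, j) (j - 1L) * n + i
  m <- nrow(locs)
  Matrix::sparseMatrix(
    i = rep(seq_len(m), 4),
    j = c(node(ix, iy), node(ix + 1L, iy), node(ix, iy + 1L),
          node(ix + 1L, iy + 1L)),
    x = c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty),
    dims = c(m, n * n))
}

#' Apply a warp mesh to locations
#' @param mesh a `warp_mesh`.
#' @param locs n x 2 matrix of locations inside the mesh domain.
#' @return n x 2 matrix of warped locations.
#' @export
warp_apply <- function(mesh, locs) {
  as.matrix(mesh_weights(mesh, locs) %*% mesh$pos)
}

#' Warped tuning curves
#'
#' The warped tuning value at a location is the regular tuning evaluated
#' at the mesh-warped coordinate.
#'
#' @param modules a `grid_modules`.
#' @param mesh a `warp_mesh`.
#' @param locs n x 2 locations.
#' @return n_cells x n matrix of rates.
#' @export
warped_tuning <- function(modules, mesh, locs) {
  regular_tuning(modules, warp_apply(mesh, locs))
}

# TRUE if every mesh quad has positive orientation (no inversion).
mesh_valid <- function(mesh) {
  n <- mesh$n
  P <- mesh$pos
  id <- function(i, j) (j - 1L) * n + i
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    a <- P[id(i + 1, j), ] - P[id(i, j), ]
    b <- P[id(i, j + 1), ] - P[id(i, j), ]
    c2 <- P[id(i, j + 1), ] - P[id(i + 1, j + 1), ]
    d2 <- P[id(i + 1, j), ] - P[id(i + 1, j + 1), ]
    if (cross2(a[1], a[2], b[1], b[2]) <= 0) return(FALSE)
    if (cross2(c2[1], c2[2], d2[1], d2[2]) <= 0) return(FALSE)
  }
  TRUE
}

# Neighbor-edge pairs used by the mesh angle regularizer: for every node,
# every adjacent (90-degree at rest) pair of edges to its grid neighbors.
mesh_angle_pairs <- function(n) {
  id <- function(i, j) (j - 1L) * n + i
  out <- matrix(0L, 0, 3)  # node, neighbor_a, neighbor_b
  for (j in seq_len(n)) for (i in seq_len(n)) {
    nb <- list(E = if (i < n) id(i + 1, j), N = if (j < n) id(i, j + 1),
               W = if (i > 1) id(i - 1, j), S = if (j > 1) id(i, j - 1))
    for (pair in list(c("E", "N"), c("N", "W"), c("W", "S"), c("S", "E"))) {
      a <- nb[[pair[1]]]; b <- nb[[pair[2]]]
      if (!is.null(a) && !is.null(b)) out <- rbind(out, c(id(i, j), a, b))
    }
  }
  out
}

#' Mesh angle regularizer
#'
#' Penalizes deviation of the angles between neighboring mesh nodes from
#' 90 degrees: `w_reg * sum (1 - sin^2(theta))^beta` over all adjacent
#' edge pairs, which is zero exactly when all angles are right angles.
#'
#' @param mesh a `warp_mesh`.
#' @param w_reg weight.
#' @param beta stiffness exponent.
#' @return scalar penalty.
#' @export
reg_loss <- function(mesh, w_reg = 1, beta = 1) {
  pr <- mesh_angle_pairs(mesh$n)
  P <- mesh$pos
  a <- P[pr[, 2], , drop = FALSE] - P[pr[, 1], , drop = FALSE]
  b <- P[pr[, 3], , drop = FALSE] - P[pr[, 1], , drop = FALSE]
  dot <- rowSums(a * b)
  c2 <- dot^2 / (rowSums(a^2) * rowSums(b^2))  # cos^2 = 1 - sin^2
  w_reg * sum(c2^beta)
}

# Gradient of reg_loss with respect to node positions (n_nodes x 2).
reg_loss_gradient <- function(mesh, w_reg = 1, beta = 1) {
  pr <- mesh_angle_pairs(mesh$n)
  P <- mesh$pos
  g <- matrix(0, nrow(P), 2)
  a <- P[pr[, 2], , drop = FALSE] - P[pr[, 1], , drop = FALSE]
  b <- P[pr[, 3], , drop = FALSE] - P[pr[, 1], , drop = FALSE]
  dot <- rowSums(a * b)
  na2 <- rowSums(a^2); nb2 <- rowSums(b^2)
  c2 <- dot^2 / (na2 * nb2)
  coef <- w_reg * beta * ifelse(c2 > 0, c2^(beta - 1), 0)
  da <- coef * (2 * dot / (na2 * nb2)) * b - coef * (2 * c2 / na2) * a
  db <- coef * (2 * dot / (na2 * nb2)) * a - coef * (2 * c2 / nb2) * b
  for (r in seq_len(nrow(pr))) {
    g[pr[r, 2], ] <- g[pr[r, 2], ] + da[r, ]
    g[pr[r, 3], ] <- g[pr[r, 3], ] + db[r, ]
    g[pr[r, 1], ] <- g[pr[r, 1], ] - da[r, ] - db[r, ]
  }
  g
}

# ---- decoder ---------------------------------------------------------------

# Row-normalized neural log posteriors for many encoding states.
# F_enc: n_cells x n_z rates; F_dec: n_cells x n_loc; alpha per cell.
neural_log_posterior_matrix <- function(F_enc, F_dec, alpha, T = 1,
                                        floor_frac = 1e-6) {
  Df <- pmax(F_dec, floor_frac * max(F_dec))
  L <- log(Df * T)
  S <- crossprod(F_enc * (alpha * T), L) -
    matrix(colSums(F_dec * (alpha * T)), nrow = ncol(F_enc),
           ncol = ncol(F_dec), byrow = TRUE)
  S - apply(S, 1, logsumexp)  # normalized log posterior per row
}

#' Neural posterior over location from a probabilistic population decoder
#'
#' In the infinite-population limit the decoded log posterior is
#' `sum_i alpha_i [f_enc_i * T * log(f_dec_i(l) * T) - f_dec_i(l) * T]`,
#' normalized over candidate locations. Decode rates are floored at
#' `floor_frac` of their maximum before the logarithm.
#'
#' @param f_enc encoding rates at the current state (length n_cells).
#' @param F_dec decode tuning, n_cells x n_loc.
#' @param alpha per-cell sharpness weights.
#' @param T integration time (fixed to 1 by default).
#' @param floor_frac relative decode-rate floor.
#' @return list with `log_posterior` and `posterior` over locations.
#' @export
neural_log_posterior <- function(f_enc, F_dec, alpha, T = 1,
                                 floor_frac = 1e-6) {
  if (all(F_dec == 0)) stop("decode tuning is identically zero")
  lp <- neural_log_posterior_matrix(matrix(f_enc, ncol = 1), F_dec,
                                    alpha, T, floor_frac)[1, ]
  list(log_posterior = lp, posterior = exp(lp))
}

# ---- fitting ---------------------------------------------------------------

#' Visit-binned targets for warp fitting
#'
#' Bins a sequence of ideal-observer location posteriors by the encoding
#' state (location bin, optionally crossed with the last approached wall)
#' and precomputes the visit counts `M(z)` and visit-averaged posteriors,
#' which makes the KL objective a single weighted cross-entropy.
#'
#' @param marginals n_loc x T matrix of location posteriors.
#' @param z_cell integer state bin per time step (1..n_z_loc).
#' @param z_locs n_z_loc x 2 matrix of state-bin locations.
#' @param h optional factor/integer of last-wall labels per time step;
#'   steps with `NA` labels are dropped.
#' @return list with `M`, `Pbar` (n_z x n_loc), `z_locs`, `z_h`,
#'   `t_index` (kept steps) and `z_of_t` (state row per kept step).
#' @export
bin_posteriors <- function(marginals, z_cell, z_locs, h = NULL) {
  T_ <- ncol(marginals)
  stopifnot(length(z_cell) == T_)
  if (is.null(h)) h <- rep(1L, T_)
  keep <- which(!is.na(h) & !is.na(z_cell))
  key <- paste(z_cell[keep], h[keep])
  uk <- unique(key)
  z_of_t <- match(key, uk)
  nz <- length(uk)
  M <- as.numeric(table(factor(z_of_t, levels = seq_len(nz))))
  Pbar <- matrix(0, nz, nrow(marginals))
  for (s in seq_along(keep)) {
    Pbar[z_of_t[s], ] <- Pbar[z_of_t[s], ] + marginals[, keep[s]]
  }
  Pbar <- Pbar / M
  first <- keep[match(uk, key)]
  list(M = M, Pbar = Pbar,
       z_locs = z_locs[z_cell[first], , drop = FALSE],
       z_h = h[first], t_index = keep, z_of_t = z_of_t)
}

#' Fit a warped population code to ideal-observer posteriors
#'
#' Minimizes the visit-weighted cross-entropy form of the time-averaged
#' KL divergence between the ideal observer's posteriors and the decoded
#' neural posteriors, plus the mesh angle regularizer, by gradient
#' descent with backtracking line search (steps that would invert a mesh
#' cell or increase the loss are rejected). Parameters are the mesh node
#' positions (one mesh per last-wall condition when `stats$z_h` has
#' several levels) and one log sharpness weight per module.
#'
#' @param stats output of [bin_posteriors()].
#' @param modules a `grid_modules`.
#' @param dec_locs n_loc x 2 decode-grid locations (the support of the
#'   posteriors in `stats$Pbar`).
#' @param mesh_bbox mesh domain (default: bounding box of `stats$z_locs`).
#' @param decode `"tied"` (decode tuning is the same warped code; familiar
#'   environment), `"regular"` (decode tuning fixed to the regular code),
#'   or `"fixed"` (decode tuning supplied in `F_dec_fixed`, e.g. the code
#'   fitted in the familiar environment).
#' @param F_dec_fixed n_cells x n_loc decode tuning for `decode = "fixed"`.
#' @param mesh_n mesh nodes per side.
#' @param w_reg,beta angle-regularizer weight and stiffness.
#' @param w_len weight of the edge-length penalty that anchors the mesh
#'   scale (see the package vignette).
#' @param alpha0 initial per-module sharpness.
#' @param iterations maximum gradient steps.
#' @param step initial learning rate.
#' @param tol stop when the relative loss improvement falls below this.
#' @param T integration time (fixed at 1).
#' @param floor_frac decode-rate floor.
#' @param init_meshes optional list of starting meshes (default identity).
#' @return a `warp_fit`: list with `meshes` (one per h level), `h_levels`,
#'   `alpha` (per cell), `alpha_module`, `loss_trace`, `fit_loss`,
#'   `reg_loss`, `logPg` (n_z x n_loc at the optimum) and the inputs
#'   needed to decode.
#' @export
fit_warp <- function(stats, modules, dec_locs, mesh_bbox = NULL,
                     decode = c("tied", "regular", "fixed"),
                     F_dec_fixed = NULL, mesh_n = 9, w_reg = 0.01, beta = 1,
                     w_len = 0.5, alpha0 = 1, iterations = 400, step = 0.02,
                     tol = 1e-7,
                     T = 1, floor_frac = 1e-6, init_meshes = NULL) {
  decode <- match.arg(decode)
  stopifnot(sum(stats$M) > 0)
  h_levels <- sort(unique(stats$z_h))
  mesh_bbox <- mesh_bbox %||% list(
    xlim = range(stats$z_locs[, 1]) + c(-1e-6, 1e-6),
    ylim = range(stats$z_locs[, 2]) + c(-1e-6, 1e-6))
  meshes <- init_meshes %||%
    lapply(h_levels, function(h) make_warp_mesh(mesh_bbox, mesh_n))
  n_mod <- length(modules$modules)
  log_alpha <- rep(log(alpha0), n_mod)
  Ttot <- sum(stats$M)
  Mw <- stats$M / Ttot
  z_rows_h <- lapply(h_levels, function(h) which(stats$z_h == h))
  B_enc <- lapply(seq_along(h_levels), function(k)
    mesh_weights(meshes[[k]], stats$z_locs[z_rows_h[[k]], , drop = FALSE]))
  B_dec <- if (decode == "tied") mesh_weights(meshes[[1]], dec_locs)
  if (decode == "regular") F_dec_fixed <- regular_tuning(modules, dec_locs)
  if (decode != "tied" && is.null(F_dec_fixed)) {
    stop("decode = 'fixed' needs F_dec_fixed")
  }
  nz <- nrow(stats$Pbar); nloc <- nrow(dec_locs)

  # nodes that support no data location (bilinear weight identically
  # zero, e.g. bounding-box corners outside a trapezoid) are weakly
  # tethered to their rest positions so they cannot wander and invert
  # mesh cells
  tether <- lapply(seq_along(h_levels), function(k) {
    w <- Matrix::colSums(B_enc[[k]])
    if (decode == "tied" && k == 1) w <- w + Matrix::colSums(B_dec)
    which(w == 0)
  })
  setup <- list(stats = stats, modules = modules, dec_locs = dec_locs,
                meshes = meshes, h_levels = h_levels, z_rows_h = z_rows_h,
                B_enc = B_enc, B_dec = B_dec, F_dec_fixed = F_dec_fixed,
                decode = decode, Mw = Mw, nz = nz, nloc = nloc,
                w_reg = w_reg, beta = beta, T = T, floor_frac = floor_frac,
                n_mod = n_mod, tether = tether, w_tether = 5,
                edges = mesh_edges(mesh_n), w_len = w_len)
  eval_all <- function(node_pos, log_alpha, want_grad = FALSE) {
    warp_objective(node_pos, log_alpha, setup, want_grad)
  }

  # Adam-style first-order descent on the stacked parameters (node
  # displacements in meters and log sharpness are on very different
  # scales, which defeats a single-step-size descent). Steps that would
  # invert a mesh cell are shrunk; the best-loss iterate is kept, so the
  # returned fit never worsens the initial objective.
  pack <- function(nodes, la) c(unlist(nodes), la)
  n_node_par <- length(unlist(lapply(meshes, function(m) m$pos)))
  unpack <- function(par) {
    nodes <- vector("list", length(meshes))
    off <- 0
    for (k in seq_along(meshes)) {
      nk <- length(meshes[[k]]$pos)
      nodes[[k]] <- matrix(par[off + seq_len(nk)], ncol = 2)
      off <- off + nk
    }
    list(nodes = nodes, la = par[n_node_par + seq_len(n_mod)])
  }
  par <- pack(lapply(meshes, function(m) m$pos), log_alpha)
  cur <- eval_all(lapply(meshes, function(m) m$pos), log_alpha, TRUE)
  trace <- cur$loss
  best <- list(loss = cur$loss, par = par, out = cur)
  m1 <- v1 <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  # per-coordinate rates: node steps are scaled to the mesh spacing so a
  # run of steps cannot cross a cell, sharpness moves on its own scale
  spacing <- min(vapply(meshes, function(m)
    min(m$x0[2] - m$x0[1], m$y0[2] - m$y0[1]), numeric(1)))
  lr0 <- c(rep(step * spacing, n_node_par), rep(step, n_mod))
  anneal <- 1
  for (it in seq_len(iterations)) {
    g <- c(unlist(cur$d_nodes), cur$d_logalpha)
    m1 <- b1 * m1 + (1 - b1) * g
    v1 <- b2 * v1 + (1 - b2) * g^2
    upd <- anneal * lr0 * (m1 / (1 - b1^it)) / (sqrt(v1 / (1 - b2^it)) + eps)
    cand_par <- par - upd
    for (shrink in 1:12) {
      u <- unpack(cand_par)
      ok <- all(vapply(seq_along(meshes), function(k) {
        m <- meshes[[k]]; m$pos <- u$nodes[[k]]; mesh_valid(m)
      }, logical(1)))
      if (ok) break
      cand_par <- (par + cand_par) / 2
    }
    if (!ok) {  # pinned against a mesh inversion: damp and re-aim
      m1[] <- 0
      anneal <- anneal * 0.5
      if (anneal < 1e-4) break
      next
    }
    par <- cand_par
    u <- unpack(par)
    cur <- eval_all(u$nodes, u$la, TRUE)
    trace <- c(trace, cur$loss)
    if (is.finite(cur$loss) && cur$loss < best$loss) {
      best <- list(loss = cur$loss, par = par, out = cur)
    }
    nt <- length(trace)
    if (nt > 60 &&
        abs(trace[nt - 50] - cur$loss) < tol * max(abs(cur$loss), 1e-12)) {
      break
    }
  }
  u <- unpack(best$par)
  cur <- best$out
  for (k in seq_along(meshes)) meshes[[k]]$pos <- u$nodes[[k]]
  alpha_mod <- exp(u$la)
  structure(list(meshes = meshes, h_levels = h_levels,
                 alpha = alpha_mod[modules$cell_module],
                 alpha_module = alpha_mod, loss_trace = trace,
                 fit_loss = cur$fit, reg_loss = cur$reg,
                 logPg = cur$lp, F_dec = cur$F_dec, modules = modules,
                 dec_locs = dec_locs, decode = decode,
                 w_reg = w_reg, beta = beta, w_len = w_len,
                 floor_frac = floor_frac),
            class = "warp_fit")
}

# Neural log posteriors (n_z x n_loc) of a fitted (or manually built)
# code for the states in `stats`.
code_log_posteriors <- function(fit, stats) {
  nz <- nrow(stats$Pbar)
  F_enc <- matrix(0, length(fit$alpha), nz)
  for (k in seq_along(fit$h_levels)) {
    rows <- which(stats$z_h == fit$h_levels[k])
    F_enc[, rows] <- warped_tuning(fit$modules, fit$meshes[[k]],
                                   stats$z_locs[rows, , drop = FALSE])
  }
  neural_log_posterior_matrix(F_enc, fit$F_dec, fit$alpha, 1, fit$floor_frac)
}

#' Time-averaged KL divergence of neural posteriors from ideal posteriors
#'
#' Direct (per time step) evaluation of the fit objective; its value
#' equals the visit-binned objective plus the data-dependent constant
#' (the average negative entropy of the ideal posteriors).
#'
#' @param marginals n_loc x T ideal posteriors.
#' @param stats the [bin_posteriors()] structure for the same episode.
#' @param logPg n_z x n_loc neural log posteriors per state.
#' @return list with `mean`, `se` (across time) and per-step `kl`.
#' @export
direct_kl <- function(marginals, stats, logPg) {
  kl <- vapply(seq_along(stats$t_index), function(s) {
    p <- marginals[, stats$t_index[s]]
    lq <- logPg[stats$z_of_t[s], ]
    i <- p > 0
    sum(p[i] * (log(p[i]) - lq[i]))
  }, numeric(1))
  list(mean = mean(kl), se = stats::sd(kl) / sqrt(length(kl)), kl = kl)
}

#' Fit diagnostics: optimized KL and its controls
#'
#' Computes the time-averaged KL divergence for the fitted code, the
#' visit-averaged lower-bound control (KL of the visit-averaged posterior
#' from the decoded posterior, which by convexity cannot exceed the
#' optimized value), the regular-grid control (identity mesh with the
#' fitted sharpness), and a time-shuffled chance control.
#'
#' @param marginals n_loc x T ideal posteriors.
#' @param stats [bin_posteriors()] structure.
#' @param fit a `warp_fit`.
#' @param shuffle_seed seed for the time shuffle.
#' @return data.frame with rows `optim`, `within`, `regular`, `shuffle`
#'   and columns `kl`, `se`.
#' @export
warp_diagnostics <- function(marginals, stats, fit, shuffle_seed = 1) {
  if (length(stats$t_index) < 100) {
    warning("episode shorter than 100 usable steps; ",
            "shuffle control may be unstable")
  }
  lp_fit <- code_log_posteriors(fit, stats)
  d_opt <- direct_kl(marginals, stats, lp_fit)
  # within-state lower bound, reported per time step for a comparable se
  kl_within <- vapply(seq_along(stats$t_index), function(s) {
    z <- stats$z_of_t[s]
    p <- stats$Pbar[z, ]
    i <- p > 0
    sum(p[i] * (log(p[i]) - lp_fit[z, i]))
  }, numeric(1))
  reg_fit <- fit
  reg_fit$meshes <- lapply(fit$meshes, function(m) { m$pos <- m$rest; m })
  if (fit$decode == "tied") {
    reg_fit$F_dec <- regular_tuning(fit$modules, fit$dec_locs)
  }
  d_reg <- direct_kl(marginals, stats, code_log_posteriors(reg_fit, stats))
  set.seed(shuffle_seed)
  perm <- sample(seq_along(stats$t_index))
  kl_sh <- vapply(seq_along(stats$t_index), function(s) {
    p <- marginals[, stats$t_index[perm[s]]]
    lq <- lp_fit[stats$z_of_t[s], ]
    i <- p > 0
    sum(p[i] * (log(p[i]) - lq[i]))
  }, numeric(1))
  data.frame(
    row.names = c("optim", "within", "regular", "shuffle"),
    kl = c(d_opt$mean, mean(kl_within), d_reg$mean, mean(kl_sh)),
    se = c(d_opt$se, stats::sd(kl_within) / sqrt(length(kl_within)),
           d_reg$se, stats::sd(kl_sh) / sqrt(length(kl_sh))))
}

# Edge-length penalty: sum over mesh edges of (len/rest_len - 1)^2.
# The angle regularizer alone is blind to rectilinear stretches, which
# makes the fit's overall scale degenerate with the sharpness weights;
# this term anchors the mesh scale so alpha absorbs global width.
mesh_edges <- function(n) {
  id <- function(i, j) (j - 1L) * n + i
  g <- expand.grid(i = seq_len(n - 1), j = seq_len(n))
  horiz <- cbind(id(g$i, g$j), id(g$i + 1L, g$j))
  g <- expand.grid(i = seq_len(n), j = seq_len(n - 1))
  vert <- cbind(id(g$i, g$j), id(g$i, g$j + 1L))
  rbind(horiz, vert)
}

length_penalty <- function(pos, rest, edges, w_len) {
  e <- pos[edges[, 2], , drop = FALSE] - pos[edges[, 1], , drop = FALSE]
  e0 <- rest[edges[, 2], , drop = FALSE] - rest[edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(e^2)); len0 <- sqrt(rowSums(e0^2))
  w_len * sum((len / len0 - 1)^2)
}

length_penalty_gradient <- function(pos, rest, edges, w_len) {
  e <- pos[edges[, 2], , drop = FALSE] - pos[edges[, 1], , drop = FALSE]
  e0 <- rest[edges[, 2], , drop = FALSE] - rest[edges[, 1], , drop = FALSE]
  len <- sqrt(rowSums(e^2)); len0 <- sqrt(rowSums(e0^2))
  coef <- 2 * w_len * (len / len0 - 1) / (len0 * pmax(len, 1e-12))
  g <- matrix(0, nrow(pos), 2)
  de <- coef * e
  for (r in seq_len(nrow(edges))) {
    g[edges[r, 2], ] <- g[edges[r, 2], ] + de[r, ]
    g[edges[r, 1], ] <- g[edges[r, 1], ] - de[r, ]
  }
  g
}

# Objective and analytic gradients of the warp fit: visit-weighted
# cross-entropy of the neural posterior against the binned ideal
# posteriors, plus the mesh angle regularizer. `setup` is assembled by
# fit_warp(); exposed as a standalone function so the gradients can be
# verified against finite differences.
warp_objective <- function(node_pos, log_alpha, setup, want_grad = FALSE) {
  s <- setup
  modules <- s$modules
  alpha_mod <- exp(log_alpha)
  alpha <- alpha_mod[modules$cell_module]
  F_enc <- matrix(0, length(alpha), s$nz)
  Y_enc <- vector("list", length(s$h_levels))
  for (k in seq_along(s$h_levels)) {
    Y <- as.matrix(s$B_enc[[k]] %*% node_pos[[k]])
    Y_enc[[k]] <- Y
    F_enc[, s$z_rows_h[[k]]] <- regular_tuning(modules, Y)
  }
  if (s$decode == "tied") {
    Y_dec <- as.matrix(s$B_dec %*% node_pos[[1]])
    F_dec <- regular_tuning(modules, Y_dec)
  } else F_dec <- s$F_dec_fixed
  lp <- neural_log_posterior_matrix(F_enc, F_dec, alpha, s$T, s$floor_frac)
  fit <- -sum(s$Mw * rowSums(s$stats$Pbar * lp))
  regs <- vapply(seq_along(s$h_levels), function(k) {
    m <- s$meshes[[k]]; m$pos <- node_pos[[k]]
    r <- reg_loss(m, s$w_reg, s$beta) +
      length_penalty(node_pos[[k]], m$rest, s$edges, s$w_len)
    if (!is.null(s$tether) && length(s$tether[[k]])) {
      d <- node_pos[[k]][s$tether[[k]], , drop = FALSE] -
        m$rest[s$tether[[k]], , drop = FALSE]
      r <- r + s$w_tether * sum(d^2)
    }
    r
  }, numeric(1))
  out <- list(fit = fit, reg = sum(regs), loss = fit + sum(regs),
              lp = lp, F_dec = F_dec)
  if (!want_grad) return(out)
  G <- s$Mw * (exp(lp) - s$stats$Pbar)         # nz x nloc
  Dfloor <- pmax(F_dec, s$floor_frac * max(F_dec))
  EG <- F_enc %*% G                            # n_cells x nloc
  sumG <- colSums(G)
  Ldec <- log(Dfloor * s$T)
  dE <- (alpha * s$T) * (Ldec %*% t(G))        # n_cells x nz
  dD <- (alpha * s$T) * (EG / Dfloor * (F_dec >= Dfloor) -
                           matrix(sumG, length(alpha), s$nloc, byrow = TRUE))
  d_ai <- s$T * (rowSums(EG * Ldec) - rowSums(
    F_dec * matrix(sumG, length(alpha), s$nloc, byrow = TRUE)))
  d_logalpha <- vapply(seq_len(s$n_mod), function(m)
    sum(d_ai[modules$cell_module == m]) * alpha_mod[m], numeric(1))
  d_nodes <- vector("list", length(s$h_levels))
  for (k in seq_along(s$h_levels)) {
    dY <- tuning_coord_gradient(modules, Y_enc[[k]],
                                dE[, s$z_rows_h[[k]], drop = FALSE])
    g <- as.matrix(Matrix::crossprod(s$B_enc[[k]], dY))
    if (s$decode == "tied" && k == 1) {
      dYd <- tuning_coord_gradient(modules, Y_dec, dD)
      g <- g + as.matrix(Matrix::crossprod(s$B_dec, dYd))
    }
    m <- s$meshes[[k]]; m$pos <- node_pos[[k]]
    g <- g + reg_loss_gradient(m, s$w_reg, s$beta) +
      length_penalty_gradient(node_pos[[k]], m$rest, s$edges, s$w_len)
    if (!is.null(s$tether) && length(s$tether[[k]])) {
      g[s$tether[[k]], ] <- g[s$tether[[k]], ] + 2 * s$w_tether *
        (node_pos[[k]][s$tether[[k]], , drop = FALSE] -
           m$rest[s$tether[[k]], , drop = FALSE])
    }
    d_nodes[[k]] <- g
  }
  out$d_nodes <- d_nodes
  out$d_logalpha <- d_logalpha
  out
}
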