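# Independent exhaustive forward-algorithm oracle for the grid filter.
#
# Builds the full dense pose-transition matrix with scalar loops straight
# from the model definitions (von Mises heading increments discretized at
# bin centers; CDF-difference displacement weights truncated at 4 sd;
# wall clipping to the boundary bin) and runs the textbook forward
# recursion p' = normalize(diag(lik) %*% T %*% p). Shares only the
# geometry primitives with the implementation under test.

oracle_heading_matrix <- function(grid, u_theta, noise) {
  nth <- grid$n_theta
  k <- noise$kappa * noise$dt
  mu <- u_theta * noise$dt
  P <- matrix(0, nth, nth)
  for (old in seq_len(nth)) {
    d <- sapply(seq_len(nth), function(new) {
      x <- (grid$theta[new] - grid$theta[old] - mu) %% (2 * pi)
      if (x > pi) x - 2 * pi else x
    })
    if (!is.finite(k) || k > 700) {
      P[which.min(abs(d)), old] <- 1
    } else {
      w <- exp(k * (cos(d) - 1))
      P[, old] <- w / sum(w)
    }
  }
  P
}

oracle_support <- function(u_x, noise, h) {
  mean <- u_x * noise$dt
  var <- noise$sigma_x^2 * u_x * noise$dt
  if (var == 0) return(list(a = mean, b = 0, w = 1))
  if (noise$family == "gamma") {
    shape <- mean^2 / var; rate <- mean / var
    kmax <- ceiling((mean + 4 * sqrt(var)) / h)
    a <- (0:kmax) * h
    w <- stats::pgamma(pmax(a + h / 2, 0), shape, rate) -
      stats::pgamma(pmax(a - h / 2, 0), shape, rate)
    w[w < 0] <- 0
    w <- w / sum(w)
    keep <- w > 1e-12
    list(a = a[keep], b = rep(0, sum(keep)), w = w[keep] / sum(w[keep]))
  } else {
    sd <- sqrt(var)
    kmax <- ceiling(4 * sd / h)
    off <- (-kmax:kmax) * h
    wa <- stats::pnorm(mean + off + h / 2, mean, sd) -
      stats::pnorm(mean + off - h / 2, mean, sd)
    wa <- wa / sum(wa)
    wb <- stats::pnorm(off + h / 2, 0, sd) - stats::pnorm(off - h / 2, 0, sd)
    wb <- wb / sum(wb)
    a <- c(); b <- c(); w <- c()
    for (i in seq_along(off)) for (j in seq_along(off)) {
      a <- c(a, mean + off[i]); b <- c(b, off[j]); w <- c(w, wa[i] * wb[j])
    }
    keep <- w > 1e-10
    list(a = a[keep], b = b[keep], w = w[keep] / sum(w[keep]))
  }
}

oracle_snap <- function(grid, pt) {
  ix <- min(grid$nx, max(1, floor((pt[1] - grid$bbox$xlim[1]) / grid$binx) + 1))
  iy <- min(grid$ny, max(1, floor((pt[2] - grid$bbox$ylim[1]) / grid$biny) + 1))
  id <- grid$cell_of_full[(iy - 1) * grid$nx + ix]
  if (is.na(id)) {
    id <- which.min((grid$cells[, 1] - pt[1])^2 + (grid$cells[, 2] - pt[2])^2)
  }
  id
}

oracle_transition <- function(grid, env, u, noise) {
  nc <- nrow(grid$cells); nth <- grid$n_theta
  h <- min(grid$binx, grid$biny)
  Pth <- oracle_heading_matrix(grid, u[2], noise)
  sup <- oracle_support(u[1], noise, h)
  Tm <- matrix(0, nc * nth, nc * nth)
  for (new_th in seq_len(nth)) {
    th <- grid$theta[new_th]
    dirv <- c(cos(th), sin(th)); ortv <- c(-sin(th), cos(th))
    for (k in seq_along(sup$w)) {
      offset <- sup$a[k] * dirv + sup$b[k] * ortv
      r <- sqrt(sum(offset^2))
      for (src in seq_len(nc)) {
        tgt <- grid$cells[src, ] + offset
        if (r > 0) {
          free <- cast_rays(env, grid$cells[src, ],
                            atan2(offset[2], offset[1]))$dist
          if (free < r) tgt <- grid$cells[src, ] + offset * free / r
        }
        dest <- oracle_snap(grid, tgt)
        for (old_th in seq_len(nth)) {
          Tm[dest + (new_th - 1) * nc, src + (old_th - 1) * nc] <-
            Tm[dest + (new_th - 1) * nc, src + (old_th - 1) * nc] +
            Pth[new_th, old_th] * sup$w[k]
        }
      }
    }
  }
  Tm
}

# Exhaustive forward recursion over a control sequence with optional
# per-step log-likelihood fields (vectors over poses).
oracle_forward <- function(grid, env, controls, noise, logliks, init) {
  p <- as.numeric(init)
  out <- matrix(0, length(p), nrow(controls) + 1)
  if (!is.null(logliks[[1]])) {
    p <- p * exp(logliks[[1]] - max(logliks[[1]]))
    p <- p / sum(p)
  }
  out[, 1] <- p
  for (t in seq_len(nrow(controls))) {
    Tm <- oracle_transition(grid, env, controls[t, ], noise)
    p <- as.numeric(Tm %*% p)
    p <- p / sum(p)
    ll <- logliks[[t + 1]]
    if (!is.null(ll)) {
      p <- p * exp(ll - max(ll))
      p <- p / sum(p)
    }
    out[, t + 1] <- p
  }
  out
}
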