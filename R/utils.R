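# Small numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into [0, 2*pi)
#' @param a angles in radians.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(a) a %% (2 * pi)

# Signed angular difference a - b folded into (-pi, pi].
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# 2D cross product of row-wise vectors (ax*by - ay*bx), vectorized.
cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

# Rotation of row-wise vectors by angles th (counterclockwise).
rotate2 <- function(xy, th) {
  cbind(cos(th) * xy[, 1] - sin(th) * xy[, 2],
        sin(th) * xy[, 1] + cos(th) * xy[, 2])
}

# Truncated, renormalized Gaussian blur matrix (n x n): row i holds the
# weights with which input pixels contribute to output pixel i.
blur_matrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- exp(-d^2 / (2 * sigma^2))
  w[abs(d) > ceiling(4 * sigma)] <- 0
  w / rowSums(w)
}

# Discretize a 1D density onto a grid of points with spacing h using CDF
# differences over the cell [x - h/2, x + h/2]; renormalized.
discretize_cdf <- function(x, h, cdf) {
  w <- cdf(x + h / 2) - cdf(x - h / 2)
  w[w < 0] <- 0
  s <- sum(w)
  if (s <= 0) stop("discretized density has no mass on the support")
  w / s
}

# Connected components of a logical matrix (4-connectivity).
# Returns an integer matrix of labels (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), ncol = 2)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = TRUE]
      queue <- queue[-1, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- p[1] + d[1]; jj <- p[2] + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  lab
}

# Weighted mean and covariance of 2D points.
weighted_moments <- function(xy, w) {
  w <- w / sum(w)
  mu <- c(sum(w * xy[, 1]), sum(w * xy[, 2]))
  dx <- xy[, 1] - mu[1]; dy <- xy[, 2] - mu[2]
  sig <- matrix(c(sum(w * dx * dx), sum(w * dx * dy),
                  sum(w * dx * dy), sum(w * dy * dy)), 2, 2)
  list(mean = mu, cov = sig)
}

# Shannon entropy (nats) of a normalized probability vector.
prob_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
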