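# Rate maps, autocorrelograms, and the grid-field measures: gridness,
# scale, field diameter, axis scaling ratio, phase shift, and the
# tethering-versus-scaling comparison.

#' Occupancy-normalized firing-rate map
#'
#' Either evaluates an analytic tuning curve directly on the bin centers
#' (`trajectory = NULL`), or averages per-step rates (or Poisson spike
#' counts) over the bins visited by a trajectory. Unvisited bins are
#' flagged (`NA` rate, `valid = FALSE`), not zero-filled.
#'
#' @param env a `nav_env`.
#' @param tuning function mapping an n x 2 location matrix to rates.
#' @param bin bin size, meters.
#' @param trajectory optional n x 2 matrix of visited locations.
#' @param spikes optional per-step spike counts (with `trajectory`); when
#'   absent the tuning rate at each visited location is averaged.
#' @return a `rate_map`: list with `rate` (nx x ny, x indexing rows),
#'   `occupancy`, `valid`, `xc`, `yc`, `bin`.
#' @export
rate_map <- function(env, tuning, bin = 0.04, trajectory = NULL,
                     spikes = NULL) {
  stopifnot(bin > 0)
  bb <- env_bbox(env)
  nx <- max(1L, round(diff(bb$xlim) / bin))
  ny <- max(1L, round(diff(bb$ylim) / bin))
  binx <- diff(bb$xlim) / nx; biny <- diff(bb$ylim) / ny
  xc <- bb$xlim[1] + (seq_len(nx) - 0.5) * binx
  yc <- bb$ylim[1] + (seq_len(ny) - 0.5) * biny
  centers <- cbind(rep(xc, times = ny), rep(yc, each = nx))
  inside <- matrix(is_inside(env, centers), nx, ny)
  if (is.null(trajectory)) {
    r <- matrix(tuning(centers), nx, ny)
    r[!inside] <- NA
    occ <- matrix(NA_real_, nx, ny)
    valid <- inside
  } else {
    if (nrow(trajectory) == 0) stop("empty trajectory")
    ix <- pmin(nx, pmax(1L, floor((trajectory[, 1] - bb$xlim[1]) / binx) + 1L))
    iy <- pmin(ny, pmax(1L, floor((trajectory[, 2] - bb$ylim[1]) / biny) + 1L))
    id <- (iy - 1L) * nx + ix
    val <- if (is.null(spikes)) tuning(trajectory) else spikes
    occ <- matrix(0, nx, ny)
    tot <- matrix(0, nx, ny)
    for (s in seq_along(id)) {
      occ[id[s]] <- occ[id[s]] + 1
      tot[id[s]] <- tot[id[s]] + val[s]
    }
    valid <- occ > 0
    r <- ifelse(valid, tot / pmax(occ, 1), NA)
  }
  structure(list(rate = r, occupancy = occ, valid = valid, xc = xc, yc = yc,
                 bin = c(binx, biny)), class = "rate_map")
}

#' Spatial autocorrelogram of a rate map
#'
#' Pearson correlation of the map with itself at every 2D lag, using the
#' overlapping valid bins only (lags with fewer than `min_overlap`
#' overlapping bins are `NA`). The center value is 1.
#'
#' @param map a `rate_map`.
#' @param max_lag maximum lag in bins per axis (default: full extent).
#' @param min_overlap minimum number of overlapping valid bins.
#' @return an `autocorrelogram`: list with `ac` matrix, `lag_x`, `lag_y`
#'   (meters), `bin`.
#' @export
autocorrelogram <- function(map, max_lag = NULL, min_overlap = 20) {
  cross_correlogram(map, map, max_lag, min_overlap)
}

#' Cross-correlogram of two rate maps over the same bins
#' @rdname autocorrelogram
#' @param map2 second `rate_map` (same binning).
#' @export
cross_correlogram <- function(map, map2, max_lag = NULL, min_overlap = 20) {
  a <- map$rate; b <- map2$rate
  if (!all(dim(a) == dim(b))) stop("maps must share binning")
  va <- is.finite(a); vb <- is.finite(b)
  if (sum(va) < 2) stop("degenerate map")
  if (stats::sd(a[va]) == 0 || stats::sd(b[vb]) == 0) {
    stop("degenerate (constant) map")
  }
  nx <- nrow(a); ny <- ncol(a)
  kx <- min(max_lag %||% (nx - 1), nx - 1)
  ky <- min(max_lag %||% (ny - 1), ny - 1)
  ac <- matrix(NA_real_, 2 * kx + 1, 2 * ky + 1)
  for (dx in -kx:kx) for (dy in -ky:ky) {
    xa <- max(1, 1 + dx):min(nx, nx + dx)
    ya <- max(1, 1 + dy):min(ny, ny + dy)
    xb <- xa - dx; yb <- ya - dy
    u <- a[xa, ya]; v <- b[xb, yb]
    ok <- is.finite(u) & is.finite(v)
    if (sum(ok) >= min_overlap && stats::sd(u[ok]) > 0 &&
        stats::sd(v[ok]) > 0) {
      ac[dx + kx + 1, dy + ky + 1] <- stats::cor(u[ok], v[ok])
    }
  }
  structure(list(ac = ac, lag_x = (-kx:kx) * map$bin[1],
                 lag_y = (-ky:ky) * map$bin[2], bin = map$bin),
            class = "autocorrelogram")
}

# Bilinear sample of a matrix field defined on centers (xc, yc); NA outside.
bilinear_sample <- function(z, xc, yc, pts) {
  nx <- length(xc); ny <- length(yc)
  hx <- xc[2] - xc[1]; hy <- yc[2] - yc[1]
  fx <- (pts[, 1] - xc[1]) / hx; fy <- (pts[, 2] - yc[1]) / hy
  ix <- floor(fx) + 1L; iy <- floor(fy) + 1L
  out <- rep(NA_real_, nrow(pts))
  ok <- ix >= 1 & ix <= nx - 1 & iy >= 1 & iy <= ny - 1
  if (!any(ok)) return(out)
  i <- ix[ok]; j <- iy[ok]
  tx <- fx[ok] - (i - 1L); ty <- fy[ok] - (j - 1L)
  v00 <- z[cbind(i, j)]; v10 <- z[cbind(i + 1L, j)]
  v01 <- z[cbind(i, j + 1L)]; v11 <- z[cbind(i + 1L, j + 1L)]
  out[ok] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

# Radially averaged autocorrelogram profile; returns data.frame(r, value).
radial_profile <- function(ac_obj, dr = NULL) {
  dr <- dr %||% min(ac_obj$bin)
  r <- sqrt(outer(ac_obj$lag_x^2, ac_obj$lag_y^2, "+"))
  idx <- floor(r / dr)
  ok <- is.finite(ac_obj$ac)
  prof <- tapply(ac_obj$ac[ok], idx[ok], mean)
  data.frame(r = (as.numeric(names(prof)) + 0.5) * dr,
             value = as.numeric(prof))
}

#' Gridness score (rotated-annulus definition)
#'
#' Within an annulus excluding the central peak, the minimum of the
#' correlations of the autocorrelogram with itself rotated by 60 and 120
#' degrees minus the maximum at 30, 90 and 150 degrees.
#'
#' @param ac_obj an `autocorrelogram`.
#' @param r_inner,r_outer annulus radii, meters; by default set from the
#'   first trough and first ring peak of the radial profile.
#' @return the gridness score.
#' @export
gridness <- function(ac_obj, r_inner = NULL, r_outer = NULL) {
  if (is.null(r_inner) || is.null(r_outer)) {
    prof <- radial_profile(ac_obj)
    n <- nrow(prof)
    trough <- NA
    for (i in 2:(n - 1)) {
      if (prof$value[i] <= prof$value[i - 1] &&
          prof$value[i] <= prof$value[i + 1]) { trough <- i; break }
    }
    if (is.na(trough)) stop("no central trough: annulus undetectable")
    r_inner <- r_inner %||% prof$r[trough]
    after <- prof[prof$r > r_inner, ]
    r_peak <- after$r[which.max(after$value)]
    r_outer <- r_outer %||% min(max(ac_obj$lag_x), 1.35 * r_peak)
  }
  r <- sqrt(outer(ac_obj$lag_x^2, ac_obj$lag_y^2, "+"))
  annulus <- r >= r_inner & r <= r_outer & is.finite(ac_obj$ac)
  if (sum(annulus) < 10) stop("annulus undetectable")
  base <- ac_obj$ac[annulus]
  pts <- cbind(outer(ac_obj$lag_x, ac_obj$lag_y * 0, "+")[annulus],
               outer(ac_obj$lag_x * 0, ac_obj$lag_y, "+")[annulus])
  rot_cor <- vapply(c(30, 60, 90, 120, 150) * pi / 180, function(th) {
    rp <- cbind(cos(th) * pts[, 1] - sin(th) * pts[, 2],
                sin(th) * pts[, 1] + cos(th) * pts[, 2])
    v <- bilinear_sample(ac_obj$ac, ac_obj$lag_x, ac_obj$lag_y, rp)
    ok <- is.finite(v)
    stats::cor(base[ok], v[ok])
  }, numeric(1))
  min(rot_cor[c(2, 4)]) - max(rot_cor[c(1, 3, 5)])
}

# Local maxima of a matrix (8-neighborhood), as index pairs.
local_maxima <- function(z, min_value = -Inf) {
  nx <- nrow(z); ny <- ncol(z)
  out <- matrix(0L, 0, 2)
  for (j in 2:(ny - 1)) for (i in 2:(nx - 1)) {
    v <- z[i, j]
    if (!is.finite(v) || v < min_value) next
    nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (v >= max(nb, na.rm = TRUE) && sum(nb == v, na.rm = TRUE) <= 2) {
      out <- rbind(out, c(i, j))
    }
  }
  out
}

#' Grid scale and field segmentation
#'
#' Scale is the median distance from the autocorrelogram center to its six
#' nearest off-center peaks. Fields are segmented on the rate map by
#' thresholding at a fraction of the map peak; components containing
#' several well-separated local maxima are split by nearest-peak
#' assignment. Field diameters are area-equivalent (`2*sqrt(area/pi)`).
#'
#' @param map a `rate_map`.
#' @param ac_obj its `autocorrelogram` (computed if missing).
#' @param threshold field threshold as a fraction of the map peak.
#' @return list with `scale` (m) and `fields` (data.frame: `x`, `y`,
#'   `peak`, `area`, `diameter`).
#' @export
grid_scale_and_fields <- function(map, ac_obj = NULL, threshold = 0.5) {
  ac_obj <- ac_obj %||% autocorrelogram(map)
  pk <- local_maxima(ac_obj$ac)
  if (nrow(pk) > 0) {
    d <- sqrt(ac_obj$lag_x[pk[, 1]]^2 + ac_obj$lag_y[pk[, 2]]^2)
    pk <- pk[d > min(ac_obj$bin) * 1.5, , drop = FALSE]
    d <- d[d > min(ac_obj$bin) * 1.5]
  }
  if (nrow(pk) < 3) stop("fewer than 3 autocorrelogram peaks")
  scale <- stats::median(sort(d)[seq_len(min(6, length(d)))])
  z <- map$rate
  thr <- threshold * max(z, na.rm = TRUE)
  mask <- is.finite(z) & z >= thr
  lab <- label_components(mask)
  seeds <- local_maxima(ifelse(mask, z, NA), min_value = thr)
  fields <- list()
  for (comp in seq_len(max(lab))) {
    idx <- which(lab == comp, arr.ind = TRUE)
    if (nrow(idx) < 2) next
    s <- seeds[lab[seeds] == comp, , drop = FALSE]
    # split merged fields: keep seeds separated by at least half a scale
    if (nrow(s) > 1) {
      keep <- 1
      for (k in 2:nrow(s)) {
        dd <- sqrt((map$xc[s[k, 1]] - map$xc[s[keep, 1]])^2 +
                   (map$yc[s[k, 2]] - map$yc[s[keep, 2]])^2)
        if (all(dd > 0.5 * scale)) keep <- c(keep, k)
      }
      s <- s[keep, , drop = FALSE]
    }
    assign <- if (nrow(s) > 1) {
      px <- map$xc[idx[, 1]]; py <- map$yc[idx[, 2]]
      apply(outer(px, map$xc[s[, 1]], "-")^2 +
              outer(py, map$yc[s[, 2]], "-")^2, 1, which.min)
    } else rep(1L, nrow(idx))
    for (k in seq_len(max(assign))) {
      sub <- idx[assign == k, , drop = FALSE]
      if (nrow(sub) < 2) next
      area <- nrow(sub) * prod(map$bin)
      fields[[length(fields) + 1]] <- data.frame(
        x = mean(map$xc[sub[, 1]]), y = mean(map$yc[sub[, 2]]),
        peak = max(z[sub]), area = area,
        diameter = 2 * sqrt(area / pi))
    }
  }
  list(scale = scale, fields = do.call(rbind, fields))
}

#' Axis scaling ratio between matched field sets
#'
#' Mutual-nearest-neighbor matching of field centroids (after subtracting
#' each set's centroid mean), then the slope of the regression through
#' the origin of test coordinates on familiar coordinates along the axis.
#'
#' @param fields_familiar,fields_test field data.frames from
#'   [grid_scale_and_fields()].
#' @param axis `"x"` or `"y"`.
#' @return the scaling ratio.
#' @export
axis_scaling_ratio <- function(fields_familiar, fields_test,
                               axis = c("x", "y")) {
  axis <- match.arg(axis)
  a <- as.matrix(fields_familiar[, c("x", "y")])
  b <- as.matrix(fields_test[, c("x", "y")])
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  d2 <- outer(ac[, 1], bc[, 1], "-")^2 + outer(ac[, 2], bc[, 2], "-")^2
  fwd <- apply(d2, 1, which.min)
  bwd <- apply(d2, 2, which.min)
  mutual <- which(bwd[fwd] == seq_len(nrow(a)))
  if (length(mutual) < 2) stop("fewer than 2 matched fields")
  f <- ac[mutual, axis == c("x", "y")]
  t <- bc[fwd[mutual], axis == c("x", "y")]
  sum(t * f) / sum(f^2)
}

#' Relative phase shift between two rate maps
#'
#' Displacement of the cross-correlogram peak nearest the origin along
#' the requested axis, folded by the grid period into `[0, scale/2]` and
#' reported as a fraction of the scale (so the result lies in
#' `[0, 0.5]`).
#'
#' @param map1,map2 `rate_map`s over the same bins.
#' @param scale grid scale, meters.
#' @param axis `"x"` or `"y"`.
#' @return the phase shift as a fraction of the grid scale.
#' @export
phase_shift <- function(map1, map2, scale, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(scale > 0)
  cc <- cross_correlogram(map1, map2,
                          max_lag = ceiling(0.75 * scale / min(map1$bin)))
  pk <- local_maxima(cc$ac)
  if (nrow(pk) == 0) stop("no cross-correlation peak")
  d <- sqrt(cc$lag_x[pk[, 1]]^2 + cc$lag_y[pk[, 2]]^2)
  best <- pk[which.min(d), ]
  disp <- if (axis == "x") cc$lag_x[best[1]] else cc$lag_y[best[2]]
  m <- abs(disp) %% scale
  if (m > scale / 2) m <- scale - m
  m / scale
}

#' Tethering versus scaling correlations
#'
#' For each cell, correlates the observed test-environment map (firing
#' conditioned on the last approached wall lying on the changed axis)
#' with two predictions built from the familiar map: pure scaling
#' (familiar map resampled by the compression factors) and pure
#' tethering (familiar map rigidly translated so the distance to the
#' conditioned wall is preserved, cropped to the test extent). A paired
#' t-test across cells compares the Fisher-transformed correlations.
#'
#' @param obs_maps,familiar_maps lists of `rate_map`s, one per cell; the
#'   observed maps define the test-environment bins.
#' @param s_x,s_y test/familiar scale factors.
#' @param wall_x x-coordinate of the conditioned wall in the test
#'   environment (tethering preserves distance to this wall; the familiar
#'   wall is at `wall_x / s_x`).
#' @return list with `per_cell` (data.frame `r_scale`, `r_tether`),
#'   `t` and `p` of the one-sided paired test in favor of tethering.
#' @export
tether_vs_scale <- function(obs_maps, familiar_maps, s_x, s_y = 1, wall_x) {
  stopifnot(length(obs_maps) == length(familiar_maps))
  rs <- rt <- numeric(length(obs_maps))
  for (c in seq_along(obs_maps)) {
    obs <- obs_maps[[c]]; fam <- familiar_maps[[c]]
    centers <- cbind(rep(obs$xc, times = length(obs$yc)),
                     rep(obs$yc, each = length(obs$xc)))
    pred_scale <- bilinear_sample(fam$rate, fam$xc, fam$yc,
                                  cbind(centers[, 1] / s_x,
                                        centers[, 2] / s_y))
    shift <- wall_x / s_x - wall_x
    pred_teth <- bilinear_sample(fam$rate, fam$xc, fam$yc,
                                 cbind(centers[, 1] + shift, centers[, 2]))
    o <- as.numeric(obs$rate)
    ok_s <- is.finite(o) & is.finite(pred_scale)
    ok_t <- is.finite(o) & is.finite(pred_teth)
    if (sum(ok_s) < 10 || sum(ok_t) < 10) {
      stop("insufficient overlapping valid bins")
    }
    rs[c] <- stats::cor(o[ok_s], pred_scale[ok_s])
    rt[c] <- stats::cor(o[ok_t], pred_teth[ok_t])
  }
  tt <- stats::t.test(atanh(pmin(pmax(rt, -0.999), 0.999)),
                      atanh(pmin(pmax(rs, -0.999), 0.999)),
                      paired = TRUE, alternative = "greater")
  list(per_cell = data.frame(r_scale = rs, r_tether = rt),
       t = unname(tt$statistic), p = tt$p.value)
}
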