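# Fixtures and independent oracles built in code.

# rasterize a filled disk by direct distance test
raster_disk <- function(R, cx, cy, dim) {
  xs <- matrix(seq_len(dim[2]) - 1, dim[1], dim[2], byrow = TRUE)
  ys <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2])
  (xs - cx)^2 + (ys - cy)^2 <= R^2
}

# rasterize a filled ellipse by the implicit equation, independent of the
# package's normalized_radius (explicit rotation written out)
raster_ellipse <- function(cx, cy, a, b, theta, dim) {
  xs <- matrix(seq_len(dim[2]) - 1, dim[1], dim[2], byrow = TRUE)
  ys <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2])
  u <- cos(theta) * (xs - cx) + sin(theta) * (ys - cy)
  v <- -sin(theta) * (xs - cx) + cos(theta) * (ys - cy)
  (u / a)^2 + (v / b)^2 <= 1
}

# brute-force moments oracle: centroid + eigen-decomposition of the pixel
# covariance matrix (distinct code path from fit_ellipse's closed form)
moment_oracle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  S <- cov(cbind(x, y)) * (length(x) - 1) / length(x)
  ev <- eigen(S, symmetric = TRUE)
  list(cx = mean(x), cy = mean(y),
       a = 2 * sqrt(ev$values[1]), b = 2 * sqrt(ev$values[2]),
       theta = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
}

# brute-force per-pixel ring binning oracle: ceiling(r * n) with r = 0 -> 1
ring_oracle <- function(ellipse, dim, n_rings = 3) {
  xs <- matrix(seq_len(dim[2]) - 1, dim[1], dim[2], byrow = TRUE)
  ys <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2])
  r <- normalized_radius(xs, ys, ellipse)
  k <- ceiling(r * n_rings)
  k[r == 0] <- 1L
  k[r > 1] <- 0L
  storage.mode(k) <- "integer"
  k
}

# a nucleus channel that is piecewise-constant over a given partition:
# inner/middle value `inner`, outermost ring value `outer`, `bg` elsewhere
piecewise_channel <- function(partition, inner = 100, outer = 100, bg = 0) {
  n <- length(partition$boundaries)
  lab <- partition$labels
  ch <- matrix(bg, nrow(lab), ncol(lab))
  ch[lab > 0L] <- inner
  ch[lab == n] <- outer
  ch
}

# standard single-nucleus geometry used across scoring tests
demo_partition <- function(dim = c(161, 161), a = 60, b = 40, theta = 0.4) {
  ell <- ellipse_model((dim[2] - 1) / 2, (dim[1] - 1) / 2, a, b, theta)
  partition_rings(ell, dim)
}

# render Gaussian puncta directly (independent of the simulator)
render_spots_direct <- function(dim, x, y, sigma, amplitude, bg = 0) {
  xs <- matrix(seq_len(dim[2]) - 1, dim[1], dim[2], byrow = TRUE)
  ys <- matrix(seq_len(dim[1]) - 1, dim[1], dim[2])
  img <- matrix(bg, dim[1], dim[2])
  for (i in seq_along(x)) {
    img <- img + amplitude * exp(-((xs - x[i])^2 + (ys - y[i])^2) /
                                   (2 * sigma^2))
  }
  img
}

# greedy truth-to-detection matching within a tolerance radius; returns
# per-truth matched distances (NA when unmatched)
match_spots <- function(truth, detected, tol = 1) {
  if (!nrow(detected)) return(rep(NA_real_, nrow(truth)))
  d <- sqrt(outer(truth$x, detected$x, "-")^2 +
              outer(truth$y, detected$y, "-")^2)
  out <- rep(NA_real_, nrow(truth))
  taken <- logical(nrow(detected))
  ord <- order(apply(d, 1, min))
  for (i in ord) {
    j <- which.min(replace(d[i, ], taken, Inf))
    if (is.finite(d[i, j]) && d[i, j] <= tol && !taken[j]) {
      out[i] <- d[i, j]
      taken[j] <- TRUE
    }
  }
  out
}
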