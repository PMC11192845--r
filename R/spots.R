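# Diffraction-limited spot detection, perinuclear overlap counting and
# two-channel colocalization area.

#' Detect diffraction-limited spots by multiscale Laplacian-of-Gaussian
#'
#' Blob detection suited to PLA-style puncta: the image is convolved with
#' scale-normalized Laplacian-of-Gaussian kernels over a range of scales,
#' local maxima of the (sign-flipped, so bright blobs are positive) response
#' above a relative threshold are kept, positions are refined to sub-pixel
#' precision by a quadratic fit around each maximum, and detections closer
#' than `min_separation` are merged keeping the stronger response.
#'
#' @param channel Numeric intensity matrix.
#' @param min_sigma,max_sigma Blob scale range in pixels (Gaussian sd);
#'   defaults 1 and 3 match diffraction-limited puncta at ~0.05-0.1 um/px.
#' @param n_scales Number of scales, linearly spaced; default 5.
#' @param rel_threshold Detection threshold as a fraction of the channel's
#'   dynamic range; default 0.1.
#' @param min_separation Minimum distance between reported spots (pixels);
#'   default `2 * min_sigma`.
#' @param noise_nsigma Robust noise gate: maxima must also exceed
#'   `noise_nsigma` times the per-scale median-absolute-deviation estimate
#'   of the response noise (inactive on noiseless images); default 5.
#' @return A `spot_set`: tibble with columns `x`, `y` (sub-pixel, 0-based
#'   pixel coordinates), `sigma`, `intensity` (peak response), plus a
#'   `detection_params` attribute. A flat image yields zero rows with a
#'   warning.
#' @export
detect_spots <- function(channel, min_sigma = 1, max_sigma = 3, n_scales = 5,
                         rel_threshold = 0.1, min_separation = NULL,
                         noise_nsigma = 5) {
  stopifnot(is.matrix(channel), min_sigma > 0, max_sigma >= min_sigma,
            rel_threshold > 0, rel_threshold < 1, noise_nsigma >= 0)
  if (is.null(min_separation)) min_separation <- 2 * min_sigma
  params <- list(min_sigma = min_sigma, max_sigma = max_sigma,
                 n_scales = n_scales, rel_threshold = rel_threshold,
                 min_separation = min_separation, noise_nsigma = noise_nsigma)
  rng <- diff(range(channel))
  if (rng == 0) {
    warn("flat image: no spots detected")
    return(new_spot_set(tibble(x = double(), y = double(), sigma = double(),
                               intensity = double()), params))
  }
  sigmas <- if (n_scales == 1) min_sigma else
    seq(min_sigma, max_sigma, length.out = n_scales)
  resp <- lapply(sigmas, function(s) log_response(channel, s))
  thr <- rel_threshold * rng

  cand <- list()
  for (k in seq_along(sigmas)) {
    r <- resp[[k]]
    floor_k <- max(thr, noise_nsigma * stats::mad(r, center = stats::median(r)))
    ismax <- r > neighbor_max(r) & r > floor_k
    if (k > 1) ismax <- ismax & r >= resp[[k - 1]]
    if (k < length(sigmas)) ismax <- ismax & r >= resp[[k + 1]]
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx)) {
      cand[[length(cand) + 1]] <- tibble(
        row = idx[, 1], col = idx[, 2], scale = k,
        intensity = r[idx]
      )
    }
  }
  if (!length(cand)) {
    return(new_spot_set(tibble(x = double(), y = double(), sigma = double(),
                               intensity = double()), params))
  }
  cand <- bind_rows(cand) %>% arrange(dplyr::desc(.data$intensity))

  # greedy non-maximum suppression at min_separation
  keep <- logical(nrow(cand))
  kx <- double(0); ky <- double(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(kx) ||
        all((kx - cand$col[i])^2 + (ky - cand$row[i])^2 >= min_separation^2)) {
      keep[i] <- TRUE
      kx <- c(kx, cand$col[i]); ky <- c(ky, cand$row[i])
    }
  }
  cand <- cand[keep, ]

  spots <- purrr::pmap(
    list(cand$row, cand$col, cand$scale, cand$intensity),
    function(i, j, k, val) {
      r <- resp[[k]]
      dx <- quad_offset(r, i, j, dj = 1)
      dy <- quad_offset(r, i, j, di = 1)
      tibble(x = (j - 1) + dx, y = (i - 1) + dy,
             sigma = sigmas[k], intensity = val)
    }) %>% bind_rows()
  new_spot_set(spots, params)
}

new_spot_set <- function(x, params) {
  structure(x, class = c("spot_set", class(tibble())),
            detection_params = params)
}

# scale-normalized LoG response, sign-flipped so bright blobs are positive
log_response <- function(channel, sigma) {
  half <- max(2L, ceiling(3.5 * sigma))
  g <- seq(-half, half)
  gauss <- exp(-g^2 / (2 * sigma^2))
  gauss <- gauss / sum(gauss)
  # separable second derivatives of the Gaussian
  d2 <- (g^2 / sigma^4 - 1 / sigma^2) * gauss
  gxx <- outer(gauss, d2)   # d2 along columns (x)
  gyy <- outer(d2, gauss)   # d2 along rows (y)
  k <- -(sigma^2) * (gxx + gyy)
  EBImage::imageData(EBImage::filter2(channel, k, boundary = "replicate"))
}

# max over the 8 spatial neighbors, borders padded with -Inf
neighbor_max <- function(r) {
  nr <- nrow(r); nc <- ncol(r)
  p <- matrix(-Inf, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- r
  out <- matrix(-Inf, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- pmax(out, p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)])
  }
  out
}

# 1D quadratic (three-point parabola) sub-pixel offset along rows or cols
quad_offset <- function(r, i, j, di = 0, dj = 0) {
  i0 <- i - di; i1 <- i + di; j0 <- j - dj; j1 <- j + dj
  if (i0 < 1 || j0 < 1 || i1 > nrow(r) || j1 > ncol(r)) return(0)
  vm <- r[i0, j0]; v0 <- r[i, j]; vp <- r[i1, j1]
  denom <- vm - 2 * v0 + vp
  if (denom >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (vm - vp) / denom))
}

#' Build the perinuclear region mask of a nucleus
#'
#' The default region is the outermost ring of the partition, dilated
#' outwards by `dilation_radius` pixels to admit signal sitting at or just
#' outside the fitted nuclear boundary, where the lamina lies. When a lamin
#' channel is supplied, the region is further intersected with the lamin
#' foreground, obtained by Otsu thresholding restricted to a band of width
#' `2 * dilation_radius` around the ellipse boundary.
#'
#' @param partition A [partition_rings()] result.
#' @param lamin Optional lamin intensity matrix congruent with the partition.
#' @param dilation_radius Outward dilation in pixels, `>= 0`; default 0.
#' @return Logical matrix marking the perinuclear region.
#' @export
perinuclear_region <- function(partition, lamin = NULL, dilation_radius = 0) {
  stopifnot(inherits(partition, "ring_partition"), dilation_radius >= 0)
  labels <- partition$labels
  n <- length(partition$boundaries)
  interior <- labels > 0L
  inner_part <- labels > 0L & labels < n
  dil <- dilate_mask(interior, dilation_radius)
  region <- dil & !inner_part
  if (!is.null(lamin)) {
    if (!identical(dim(lamin), dim(labels)))
      abort("lamin channel and partition rasters must have the same dimensions")
    band <- dil & !erode_mask(interior, dilation_radius)
    vals <- lamin[band]
    if (!length(vals) || diff(range(vals)) == 0 && all(vals == 0)) {
      warn("lamin channel empty in the boundary band; perinuclear region is empty")
      return(matrix(FALSE, nrow(labels), ncol(labels)))
    }
    thr <- otsu_threshold(vals)
    region <- region & (lamin > thr) & band
  }
  region
}

dilate_mask <- function(mask, radius) {
  if (radius < 0.5) return(mask)
  kern <- EBImage::makeBrush(2L * as.integer(round(radius)) + 1L, shape = "disc")
  EBImage::imageData(EBImage::dilate(mask * 1, kern)) > 0.5
}

erode_mask <- function(mask, radius) {
  if (radius < 0.5) return(mask)
  kern <- EBImage::makeBrush(2L * as.integer(round(radius)) + 1L, shape = "disc")
  EBImage::imageData(EBImage::erode(mask * 1, kern)) > 0.5
}

# Otsu threshold of a numeric vector (256-level histogram via EBImage)
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  img <- EBImage::Image(vals, dim = c(length(vals), 1))
  EBImage::otsu(img, range = rng, levels = 256)
}

#' Count spots overlapping the perinuclear region
#'
#' A spot counts as perinuclear iff the pixel containing its center is
#' foreground in `region`. The total counts spots lying inside the nucleus
#' ellipse (normalized radius `<= 1 + margin`) or inside the region (so a
#' spot just outside the fitted boundary but on the dilated rim still
#' counts), which guarantees `n_perinuclear <= n_total`.
#'
#' @param spots A [detect_spots()] result (or any tibble with `x`, `y`).
#' @param region Logical perinuclear-region matrix from
#'   [perinuclear_region()].
#' @param ellipse The nucleus [ellipse_model()].
#' @param margin Extra allowance on the normalized radius for the total
#'   count; default 0.
#' @param nucleus_id Identifier copied into the output.
#' @return One-row tibble: `nucleus_id`, `n_total`, `n_perinuclear`.
#' @export
count_perinuclear_spots <- function(spots, region, ellipse, margin = 0,
                                    nucleus_id = NA_integer_) {
  stopifnot(is.matrix(region), inherits(ellipse, "ellipse_model"))
  if (!nrow(spots)) {
    return(tibble(nucleus_id = nucleus_id, n_total = 0L, n_perinuclear = 0L))
  }
  row <- round(spots$y) + 1
  col <- round(spots$x) + 1
  inside <- row >= 1 & row <= nrow(region) & col >= 1 & col <= ncol(region)
  in_region <- inside
  in_region[inside] <- region[cbind(row[inside], col[inside])]
  r <- normalized_radius(spots$x, spots$y, ellipse)
  total <- (r <= 1 + margin) | in_region
  tibble(nucleus_id = nucleus_id,
         n_total = sum(total),
         n_perinuclear = sum(in_region & total))
}

#' Colocalization area of two channels within a nucleus
#'
#' Each channel is thresholded within the nucleus mask (per-channel Otsu by
#' default, or fixed values), and the overlap of the two foregrounds inside
#' the nucleus is reported as a physical area.
#'
#' @param channel_a,channel_b Numeric intensity matrices.
#' @param nucleus Logical or numeric nucleus mask, congruent with the
#'   channels.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_values Numeric length-2 vector of thresholds for channels a
#'   and b; required when `threshold_method = "fixed"`.
#' @param pixel_size Pixel edge length in micrometres; default 1 (areas then
#'   in px^2).
#' @param nucleus_id Identifier copied into the output.
#' @return One-row tibble: `nucleus_id`, `area_overlap`, `area_a`, `area_b`
#'   (um^2), `px_overlap`, `px_a`, `px_b`, `threshold_a`, `threshold_b`,
#'   `method`. The overlap never exceeds either single-channel area.
#' @export
coloc_area <- function(channel_a, channel_b, nucleus,
                       threshold_method = c("otsu", "fixed"),
                       fixed_values = NULL, pixel_size = 1,
                       nucleus_id = NA_integer_) {
  threshold_method <- match.arg(threshold_method)
  nucleus <- as_mask(nucleus)
  if (!identical(dim(channel_a), dim(channel_b)) ||
      !identical(dim(channel_a), dim(nucleus)))
    abort("channels and nucleus mask must have the same dimensions")
  if (threshold_method == "fixed") {
    if (is.null(fixed_values) || length(fixed_values) != 2)
      abort("threshold_method = \"fixed\" requires fixed_values of length 2")
    thr_a <- fixed_values[1]; thr_b <- fixed_values[2]
  } else {
    thr_a <- otsu_threshold(channel_a[nucleus])
    thr_b <- otsu_threshold(channel_b[nucleus])
  }
  fg_a <- channel_a > thr_a & nucleus
  fg_b <- channel_b > thr_b & nucleus
  px2 <- pixel_size^2
  tibble(nucleus_id = nucleus_id,
         area_overlap = sum(fg_a & fg_b) * px2,
         area_a = sum(fg_a) * px2,
         area_b = sum(fg_b) * px2,
         px_overlap = sum(fg_a & fg_b),
         px_a = sum(fg_a),
         px_b = sum(fg_b),
         threshold_a = as.numeric(thr_a),
         threshold_b = as.numeric(thr_b),
         method = threshold_method)
}
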