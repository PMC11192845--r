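# Ellipse fitting and concentric elliptic ring partitions.
#
# Conventions used throughout the package: images are base-R matrices indexed
# [row, col]; continuous pixel coordinates are 0-based with x = col - 1 and
# y = row - 1, so a pixel's center sits at integer coordinates.

#' Construct an ellipse model
#'
#' An ellipse in continuous pixel coordinates, described by its center
#' `(cx, cy)`, semi-major axis `a`, semi-minor axis `b` and the orientation
#' `theta` of the major axis (radians, measured from the +x / column axis).
#'
#' @param cx,cy Center, continuous pixel coordinates.
#' @param a,b Semi-axes in pixels; `a >= b > 0` is enforced by swapping axes
#'   and rotating `theta` by pi/2 when needed.
#' @param theta Major-axis orientation in radians; normalized to
#'   `[-pi/2, pi/2)`.
#' @return An object of class `ellipse_model`.
#' @export
ellipse_model <- function(cx, cy, a, b, theta = 0) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(a), is.finite(b),
            is.finite(theta))
  if (a <= 0 || b <= 0) abort("semi-axes must be positive")
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    theta <- theta + pi / 2
  }
  # wrap into [-pi/2, pi/2)
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "ellipse_model")
}

#' @export
print.ellipse_model <- function(x, ...) {
  cat(sprintf(
    "<ellipse_model> center (%.2f, %.2f), a = %.2f px, b = %.2f px, theta = %.3f rad\n",
    x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

#' Fit the moments-equivalent ellipse to a binary nucleus mask
#'
#' Returns the ellipse with the same centroid and the same normalized second
#' central moments as the mask foreground: the standard image-moments ellipse,
#' with semi-axes `2 * sqrt(eigenvalue)` of the pixel covariance matrix.
#' Masks with several connected components (8-connectivity) are reduced to the
#' largest one with a warning.
#'
#' @param mask Logical or numeric matrix; nonzero pixels are foreground.
#' @return An [ellipse_model()].
#' @export
fit_ellipse <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) abort("empty mask")
  mask <- largest_component(mask)
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1
  y <- idx[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2)
  mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  lam1 <- (mu20 + mu02) / 2 + common
  lam2 <- (mu20 + mu02) / 2 - common
  if (lam2 <= .Machine$double.eps) abort("degenerate mask")
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  ellipse_model(cx, cy, a = 2 * sqrt(lam1), b = 2 * sqrt(lam2), theta = theta)
}

#' Normalized elliptic radius of points
#'
#' The dimensionless coordinate used to define concentric elliptic rings:
#' 0 at the ellipse center, 1 on its boundary, growing linearly outwards.
#' `r = sqrt((u/a)^2 + (v/b)^2)` where `(u, v)` are the point's coordinates
#' after translation to the center and rotation by `-theta`.
#'
#' @param x,y Continuous pixel coordinates (vectorized).
#' @param ellipse An [ellipse_model()].
#' @return Numeric vector of normalized radii, `>= 0`.
#' @export
normalized_radius <- function(x, y, ellipse) {
  stopifnot(inherits(ellipse, "ellipse_model"))
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  dx <- x - ellipse$cx; dy <- y - ellipse$cy
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  sqrt((u / ellipse$a)^2 + (v / ellipse$b)^2)
}

#' Rasterize an ellipse interior
#'
#' Logical matrix of the given dimensions marking pixels whose centers have
#' normalized radius `<= 1`.
#'
#' @param ellipse An [ellipse_model()].
#' @param dim Integer vector `c(rows, cols)` of the target raster.
#' @return Logical matrix.
#' @export
ellipse_interior <- function(ellipse, dim) {
  radius_raster(ellipse, dim, function(r) r <= 1, FALSE)
}

# evaluate f(r) on the bounding box of the ellipse, `fill` elsewhere
radius_raster <- function(ellipse, dim, f, fill) {
  out <- matrix(fill, dim[1], dim[2])
  bb <- ellipse_bbox(ellipse, dim)
  if (is.null(bb)) return(out)
  xs <- bb$cols - 1
  ys <- bb$rows - 1
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  X <- matrix(xs - ellipse$cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys - ellipse$cy, nrow = length(ys), ncol = length(xs))
  u <- ct * X + st * Y
  v <- -st * X + ct * Y
  r <- sqrt((u / ellipse$a)^2 + (v / ellipse$b)^2)
  out[bb$rows, bb$cols] <- f(r)
  out
}

# 1-based row/col ranges of the square bounding the ellipse (side 2a), clipped
ellipse_bbox <- function(ellipse, dim, pad = 0) {
  rad <- ellipse$a + pad
  rows <- max(1, floor(ellipse$cy - rad) + 1):min(dim[1], ceiling(ellipse$cy + rad) + 1)
  cols <- max(1, floor(ellipse$cx - rad) + 1):min(dim[2], ceiling(ellipse$cx + rad) + 1)
  if (!length(rows) || !length(cols)) return(NULL)
  list(rows = rows, cols = cols)
}

#' Judge how well an ellipse fits a mask
#'
#' Computes the Jaccard index between the mask foreground and the rasterized
#' ellipse interior; nuclei whose outline an ellipse does not fit well
#' (aberrant morphology) are flagged for exclusion when the index falls below
#' `threshold`.
#'
#' @param mask Logical or numeric matrix.
#' @param ellipse An [ellipse_model()].
#' @param threshold Exclusion threshold in `(0, 1]`; default 0.85.
#' @return Object of class `fit_quality`: list with `jaccard`, `excluded`,
#'   `threshold`.
#' @export
ellipse_fit_quality <- function(mask, ellipse, threshold = 0.85) {
  mask <- as_mask(mask)
  stopifnot(threshold > 0, threshold <= 1)
  interior <- ellipse_interior(ellipse, dim(mask))
  inter <- sum(mask & interior)
  union <- sum(mask | interior)
  jaccard <- if (union == 0) 0 else inter / union
  structure(list(jaccard = jaccard, excluded = jaccard < threshold,
                 threshold = threshold),
            class = "fit_quality")
}

#' @export
print.fit_quality <- function(x, ...) {
  cat(sprintf("<fit_quality> jaccard = %.3f (threshold %.2f) -> %s\n",
              x$jaccard, x$threshold,
              if (x$excluded) "excluded" else "included"))
  invisible(x)
}

#' Partition an ellipse interior into concentric elliptic rings
#'
#' Divides the nuclear interior into `n_rings` concentric elliptic regions.
#' With the default equal spacing in normalized radius and `n_rings = 3`, the
#' ring boundaries sit at normalized radii 1/3, 2/3 and 1: region 1 is the
#' central nuclear region, region 3 the perinuclear region. Pixel membership
#' is decided by the pixel center, with half-open intervals
#' `((k-1)/n, k/n]` and `r = 0` assigned to the innermost region, so the
#' regions are pairwise disjoint and their union is exactly the set of pixels
#' with `r <= 1`.
#'
#' @param ellipse An [ellipse_model()].
#' @param dim Raster dimensions `c(rows, cols)`.
#' @param n_rings Number of rings, `>= 2`; default 3.
#' @param spacing `"radius"` (default) for equal ring thickness in normalized
#'   radius, or `"area"` for rings of equal area (boundaries `sqrt(k/n)`).
#' @return Object of class `ring_partition`: list with integer matrix
#'   `labels` (0 outside, 1..n_rings inside), `boundaries`, `ellipse`,
#'   `spacing`.
#' @export
partition_rings <- function(ellipse, dim, n_rings = 3,
                            spacing = c("radius", "area")) {
  stopifnot(inherits(ellipse, "ellipse_model"))
  if (n_rings < 2) abort("n_rings must be >= 2")
  spacing <- match.arg(spacing)
  boundaries <- switch(spacing,
                       radius = seq_len(n_rings) / n_rings,
                       area = sqrt(seq_len(n_rings) / n_rings))
  labels <- radius_raster(ellipse, dim, function(r) {
    k <- findInterval(r, boundaries, left.open = TRUE) + 1L
    k[r > 1] <- 0L
    k
  }, 0L)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, boundaries = boundaries, ellipse = ellipse,
                 spacing = spacing, bbox = ellipse_bbox(ellipse, dim)),
            class = "ring_partition")
}

#' @export
print.ring_partition <- function(x, ...) {
  n <- length(x$boundaries)
  counts <- tabulate(x$labels[x$labels > 0], nbins = n)
  cat(sprintf("<ring_partition> %d rings (%s spacing), pixel counts: %s\n",
              n, x$spacing, paste(counts, collapse = " / ")))
  invisible(x)
}

# --- mask utilities ---------------------------------------------------------

as_mask <- function(mask) {
  if (is.logical(mask)) {
    m <- mask
  } else {
    m <- mask != 0
  }
  if (!is.matrix(m)) abort("mask must be a matrix")
  m[is.na(m)] <- FALSE
  m
}

#' Keep the largest 8-connected component of a mask
#'
#' Multi-component masks are reduced to their largest connected component
#' (8-connectivity) with a warning; ties broken by the first label.
#'
#' @param mask Logical or numeric matrix.
#' @return Logical matrix with a single connected component.
#' @export
largest_component <- function(mask) {
  mask <- as_mask(mask)
  lab <- label_components8(mask)
  n <- max(lab)
  if (n <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  warn(sprintf("mask has %d connected components; keeping the largest (%d px)",
               n, max(sizes)))
  lab == which.max(sizes)
}

# 8-connected labeling: 4-connected pass (EBImage::bwlabel), then union-find
# merge of labels that touch diagonally
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    if (!any(keep)) return(invisible())
    for (k in which(keep)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  # diagonal neighbor pairs: down-right and down-left
  merge_pairs(lab[-nr, -nc], lab[-1, -1])
  merge_pairs(lab[-nr, -1], lab[-1, -nc])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}
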