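# Synthetic multi-channel nuclei with full ground truth.
#
# The generator emulates the imaging regime the scoring pipeline assumes:
# elliptic G1/S nuclei, a histone channel whose perinuclear/central intensity
# ratio is controlled exactly, a DNA fill, a lamin rim ridge at the nuclear
# boundary, point-like PLA-style puncta with controlled perinuclear
# placement, a replication-foci channel, and Poisson + Gaussian camera noise.

#' Configuration for the synthetic image generator
#'
#' Defaults emulate SIM-like sampling of cultured-cell nuclei: 0.05 um
#' pixels, 1024 x 1024 field, nuclei with major axes of 8-11 um. The histone
#' channel is piecewise-constant in normalized elliptic radius — inner value
#' `base_intensity` for r <= 2/3 (the middle ring takes the inner value, as
#' the ring statistic ignores it) and `enrichment * base_intensity` for
#' 2/3 < r <= 1 — so the noiseless perinuclear/central ratio equals
#' `enrichment` exactly. A `rim_gaussian` profile adds the enrichment as a
#' Gaussian ridge instead; its true ratio is computed numerically into the
#' ground truth.
#'
#' @param image_shape `c(rows, cols)`; default `c(1024, 1024)`.
#' @param pixel_size Pixel edge length in micrometres; default 0.05.
#' @param n_nuclei Number of nuclei to place without overlap; default 8.
#' @param a_range,b_range Semi-axis ranges in pixels.
#' @param enrichment Target perinuclear/central intensity ratio E (>= 0).
#' @param base_intensity Inner-region mean, arbitrary units; default 100.
#' @param background Off-nucleus level added to every channel; default 10.
#' @param noise List: `gaussian_sd` (additive read noise sd, default 3) and
#'   `poisson_gain` (shot-noise gain; 0 disables; default 1).
#' @param spots List: `n_per_nucleus` (20), `fraction_perinuclear` (0.5),
#'   `sigma` (1.5 px), `amplitude` (150), `min_separation` (6 px).
#' @param lamin List: `amplitude` (200), `radial_sd` (2 px).
#' @param replication List: `n_foci` (30), `sigma` (2.5 px), `amplitude`
#'   (120).
#' @param profile `"piecewise"` (default) or `"rim_gaussian"`.
#' @param seed Integer seed driving every stochastic draw.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(image_shape = c(1024, 1024),
                             pixel_size = 0.05,
                             n_nuclei = 8,
                             a_range = c(80, 110),
                             b_range = c(55, 80),
                             enrichment = 1,
                             base_intensity = 100,
                             background = 10,
                             noise = list(),
                             spots = list(),
                             lamin = list(),
                             replication = list(),
                             profile = c("piecewise", "rim_gaussian"),
                             seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    pixel_size = pixel_size,
    n_nuclei = as.integer(n_nuclei),
    a_range = a_range,
    b_range = b_range,
    enrichment = enrichment,
    base_intensity = base_intensity,
    background = background,
    noise = modifyList(list(gaussian_sd = 3, poisson_gain = 1), noise),
    spots = modifyList(list(n_per_nucleus = 20, fraction_perinuclear = 0.5,
                            sigma = 1.5, amplitude = 150,
                            min_separation = 6), spots),
    lamin = modifyList(list(amplitude = 200, radial_sd = 2), lamin),
    replication = modifyList(list(n_foci = 30, sigma = 2.5, amplitude = 120),
                             replication),
    profile = match.arg(profile),
    seed = as.integer(seed)
  )
  stopifnot(cfg$enrichment >= 0, cfg$n_nuclei >= 0,
            all(cfg$a_range > 0), all(cfg$b_range > 0),
            cfg$spots$fraction_perinuclear >= 0,
            cfg$spots$fraction_perinuclear <= 1)
  structure(cfg, class = "synthetic_config")
}

#' Generate one synthetic multi-channel image with ground truth
#'
#' @param config A [synthetic_config()].
#' @param channels Which channels to render (subset of `"histone"`, `"dna"`,
#'   `"lamin"`, `"spots"`, `"replication"`); rendering fewer is faster.
#' @return List with `channels` (named list of matrices), `mask` (integer
#'   label matrix from the true ellipses), `truth` (list of tibbles `nuclei`
#'   and `spots`), and the `config`.
#' @export
generate_image <- function(config, channels = CHANNEL_ORDER) {
  stopifnot(inherits(config, "synthetic_config"))
  channels <- match.arg(channels, CHANNEL_ORDER, several.ok = TRUE)
  if (config$n_nuclei < 1) abort("n_nuclei must be >= 1")
  with_seed(config$seed, generate_image_impl(config, channels))
}

# run code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit(if (had) assign(".Random.seed", old, envir = genv) else
    rm(".Random.seed", envir = genv), add = TRUE)
  set.seed(seed)
  force(code)
}

generate_image_impl <- function(config, channels) {
  shape <- config$image_shape
  nr <- shape[1]; nc <- shape[2]

  nuclei <- place_nuclei(config)
  img <- lapply(setNames(channels, channels),
                function(ch) matrix(config$background, nr, nc))
  mask <- matrix(0L, nr, nc)

  truth_rows <- vector("list", nrow(nuclei))
  spot_rows <- list()

  for (k in seq_len(nrow(nuclei))) {
    ell <- ellipse_model(nuclei$cx[k], nuclei$cy[k], nuclei$a[k],
                         nuclei$b[k], nuclei$theta[k])
    bb <- ellipse_bbox(ell, shape, pad = 4 * config$lamin$radial_sd)
    X <- matrix(bb$cols - 1, nrow = length(bb$rows), ncol = length(bb$cols),
                byrow = TRUE)
    Y <- matrix(bb$rows - 1, nrow = length(bb$rows), ncol = length(bb$cols))
    r <- normalized_radius(X, Y, ell)

    inside <- r <= 1
    mask[bb$rows, bb$cols][inside] <- k

    if ("histone" %in% channels) {
      h <- histone_profile(r, config)
      sub <- img$histone[bb$rows, bb$cols]
      sub[inside] <- h[inside]
      img$histone[bb$rows, bb$cols] <- sub
    }
    if ("dna" %in% channels) {
      sub <- img$dna[bb$rows, bb$cols]
      sub[inside] <- config$base_intensity
      img$dna[bb$rows, bb$cols] <- sub
    }
    if ("lamin" %in% channels) {
      # Gaussian ridge of constant physical thickness centered on the
      # boundary: (r - 1) / |grad r| approximates the Euclidean distance
      d <- boundary_distance(X, Y, r, ell)
      rim <- config$lamin$amplitude *
        exp(-0.5 * (d / config$lamin$radial_sd)^2)
      img$lamin[bb$rows, bb$cols] <- img$lamin[bb$rows, bb$cols] + rim
    }

    # ring means of the noiseless histone channel over the true partition
    hfull <- histone_profile(r, config)
    mean_inner <- mean(hfull[r <= 1 / 3])
    mean_outer <- mean(hfull[r > 2 / 3 & r <= 1])
    ratio_true <- mean_outer / mean_inner
    truth_rows[[k]] <- tibble(
      nucleus_id = k, cx = ell$cx, cy = ell$cy, a = ell$a, b = ell$b,
      theta = ell$theta, enrichment = config$enrichment,
      mean_inner_true = mean_inner, mean_outer_true = mean_outer,
      ratio_true = ratio_true,
      expected_accumulating = ratio_true > 2)

    if ("spots" %in% channels && config$spots$n_per_nucleus > 0) {
      sp <- place_spots(ell, config$spots)
      sp$nucleus_id <- k
      spot_rows[[length(spot_rows) + 1]] <- sp
      img$spots <- render_puncta(img$spots, sp$x, sp$y,
                                 config$spots$sigma, config$spots$amplitude)
    }
    if ("replication" %in% channels && config$replication$n_foci > 0) {
      rf <- sample_in_annulus(config$replication$n_foci, ell, 0, 1)
      img$replication <- render_puncta(img$replication, rf$x, rf$y,
                                       config$replication$sigma,
                                       config$replication$amplitude)
    }
  }

  img <- lapply(img, add_camera_noise, noise = config$noise)
  truth_spots <- if (length(spot_rows)) bind_rows(spot_rows) else
    tibble(x = double(), y = double(), placement = character(),
           nucleus_id = integer())
  list(channels = img, mask = mask,
       truth = list(nuclei = bind_rows(truth_rows),
                    spots = truth_spots),
       config = config)
}

histone_profile <- function(r, config) {
  base <- config$base_intensity
  E <- config$enrichment
  if (config$profile == "piecewise") {
    ifelse(r > 2 / 3, E * base, base)
  } else {
    # enrichment as a Gaussian ridge peaking at the boundary
    base * (1 + (E - 1) * exp(-0.5 * ((r - 1) / 0.15)^2))
  }
}

place_nuclei <- function(config) {
  shape <- config$image_shape
  out <- tibble(cx = double(), cy = double(), a = double(), b = double(),
                theta = double())
  margin <- 4
  for (k in seq_len(config$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(300)) {
      a <- runif(1, config$a_range[1], config$a_range[2])
      b <- runif(1, config$b_range[1], min(a, config$b_range[2]))
      theta <- runif(1, -pi / 2, pi / 2)
      lo_x <- a + margin; hi_x <- shape[2] - 1 - a - margin
      lo_y <- a + margin; hi_y <- shape[1] - 1 - a - margin
      if (hi_x <= lo_x || hi_y <= lo_y)
        abort("image too small for the requested nucleus sizes")
      cx <- runif(1, lo_x, hi_x)
      cy <- runif(1, lo_y, hi_y)
      if (!nrow(out) ||
          all(sqrt((out$cx - cx)^2 + (out$cy - cy)^2) > out$a + a + margin)) {
        out <- bind_rows(out, tibble(cx = cx, cy = cy, a = a, b = b,
                                     theta = theta))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort(paste("could not place", config$n_nuclei, "non-overlapping nuclei;",
                  "reduce n_nuclei, shrink a_range/b_range, or enlarge the image"))
  }
  out
}

# signed Euclidean distance (px) from pixels to the ellipse boundary,
# first-order: (r - 1) / |grad r|; positive outside
boundary_distance <- function(X, Y, r, ell) {
  ct <- cos(ell$theta); st <- sin(ell$theta)
  dx <- X - ell$cx; dy <- Y - ell$cy
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  gn <- sqrt((u / ell$a^2)^2 + (v / ell$b^2)^2) / pmax(r, 1e-9)
  (r - 1) / pmax(gn, 1e-9)
}

# area-uniform sample of n points in the elliptic annulus r in (r0, r1]
sample_in_annulus <- function(n, ell, r0, r1) {
  rr <- sqrt(runif(n, r0^2, r1^2))
  phi <- runif(n, 0, 2 * pi)
  ct <- cos(ell$theta); st <- sin(ell$theta)
  u <- ell$a * rr * cos(phi)
  v <- ell$b * rr * sin(phi)
  tibble(x = ell$cx + ct * u - st * v,
         y = ell$cy + st * u + ct * v)
}

place_spots <- function(ell, sp) {
  n <- sp$n_per_nucleus
  placed <- tibble(x = double(), y = double(), placement = character())
  # keep placements 2 px clear of the ring boundaries so a spot's band is
  # unambiguous even after sub-pixel detection and pixel-center rounding
  m <- 2 / ell$b
  for (i in seq_len(n)) {
    for (try in seq_len(200)) {
      peri <- runif(1) < sp$fraction_perinuclear
      p <- if (peri) sample_in_annulus(1, ell, 2 / 3 + m, 1 - m) else
        sample_in_annulus(1, ell, 0, 2 / 3 - m)
      if (!nrow(placed) ||
          all((placed$x - p$x)^2 + (placed$y - p$y)^2 >= sp$min_separation^2)) {
        placed <- bind_rows(placed, tibble(
          x = p$x, y = p$y,
          placement = if (peri) "perinuclear" else "central"))
        break
      }
    }
  }
  if (nrow(placed) < n)
    warn(sprintf("placed only %d of %d spots at min separation %.1f px",
                 nrow(placed), n, sp$min_separation))
  placed
}

# add Gaussian puncta of sd sigma at sub-pixel centers (x, y)
render_puncta <- function(img, x, y, sigma, amplitude) {
  half <- ceiling(4 * sigma)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(x)) {
    rows <- max(1, floor(y[i]) + 1 - half):min(nr, ceiling(y[i]) + 1 + half)
    cols <- max(1, floor(x[i]) + 1 - half):min(nc, ceiling(x[i]) + 1 + half)
    dx2 <- ((cols - 1) - x[i])^2
    dy2 <- ((rows - 1) - y[i])^2
    img[rows, cols] <- img[rows, cols] +
      amplitude * exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  }
  img
}

# Poisson shot noise (gain g: pixel ~ g * Pois(value / g)) then additive
# Gaussian read noise; negative input clamped at 0 before the Poisson draw
add_camera_noise <- function(img, noise) {
  g <- noise$poisson_gain
  if (g > 0) {
    lam <- pmax(img, 0) / g
    img[] <- g * rpois(length(img), lam)
  }
  if (noise$gaussian_sd > 0) {
    img <- img + rnorm(length(img), 0, noise$gaussian_sd)
  }
  img
}

#' Generate a dataset of synthetic conditions on disk
#'
#' Writes, per condition, a 5-page 16-bit TIFF (channel order histone, dna,
#' lamin, spots, replication), a 16-bit label-mask TIFF from the true
#' ellipses, and, across conditions, `truth_nuclei.csv`, `truth_spots.csv`
#' and the fully resolved configuration as `config.yaml`. Intensities are
#' stored as digital numbers 0..65535 (clamped and rounded).
#'
#' @param configs Named list of [synthetic_config()], one per condition.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a list of written paths.
#' @export
generate_dataset <- function(configs, out_dir) {
  if (!length(configs)) abort("at least one condition is required")
  if (is.null(names(configs)) || any(names(configs) == ""))
    abort("configs must be a named list (condition names)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth_n <- list(); truth_s <- list(); paths <- list()
  for (cond in names(configs)) {
    gen <- generate_image(configs[[cond]])
    img_path <- file.path(out_dir, paste0("image_", cond, ".tif"))
    mask_path <- file.path(out_dir, paste0("mask_", cond, ".tif"))
    write_intensity_tiff(gen$channels, img_path)
    write_label_tiff(gen$mask, mask_path)
    truth_n[[cond]] <- gen$truth$nuclei %>% mutate(condition = cond, .before = 1)
    truth_s[[cond]] <- gen$truth$spots %>% mutate(condition = cond, .before = 1)
    paths[[cond]] <- list(image = img_path, mask = mask_path)
  }
  nuclei_path <- file.path(out_dir, "truth_nuclei.csv")
  spots_path <- file.path(out_dir, "truth_spots.csv")
  readr::write_csv(bind_rows(truth_n), nuclei_path)
  readr::write_csv(bind_rows(truth_s), spots_path)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(lapply(configs, unclass), cfg_path)
  inform(sprintf("wrote %d condition(s) to %s (seeds: %s)",
                 length(configs), out_dir,
                 paste(vapply(configs, function(cfg) cfg$seed, integer(1)),
                       collapse = ", ")))
  invisible(c(paths, list(truth_nuclei = nuclei_path,
                          truth_spots = spots_path, config = cfg_path)))
}
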