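test_that("spot detection finds isolated Gaussian puncta with sub-pixel accuracy", {
  expect_warning(s0 <- detect_spots(matrix(0, 64, 64)), "flat")
  expect_equal(nrow(s0), 0)

  # one spot at a non-integer position, SNR 10
  set.seed(7)
  img <- render_spots_direct(c(101, 121), 60.3, 50.7, sigma = 1.5,
                             amplitude = 100, bg = 5)
  img <- img + rnorm(length(img), 0, 10)
  s <- detect_spots(img)
  expect_equal(nrow(s), 1)
  expect_lt(abs(s$x - 60.3), 0.5)
  expect_lt(abs(s$y - 50.7), 0.5)

  # two spots 10 px apart, same scale
  img2 <- render_spots_direct(c(101, 121), c(40, 50), c(60, 60), 1.5, 100)
  s2 <- detect_spots(img2)
  expect_equal(nrow(s2), 2)
  d <- match_spots(data.frame(x = c(40, 50), y = c(60, 60)), s2)
  expect_true(all(is.finite(d)))
  expect_lt(max(d), 0.5)
})

test_that("no two reported spots are closer than the minimum separation", {
  cfg <- synthetic_config(image_shape = c(400, 400), n_nuclei = 1,
                          a_range = c(110, 120), b_range = c(75, 85),
                          spots = list(n_per_nucleus = 40), seed = 21)
  g <- generate_image(cfg, channels = "spots")
  s <- detect_spots(g$channels$spots, min_separation = 3)
  if (nrow(s) > 1) {
    dm <- as.matrix(dist(cbind(s$x, s$y)))
    expect_gte(min(dm[upper.tri(dm)]), 3)
  }
  expect_gt(nrow(s), 0)
})

test_that("the perinuclear region defaults to the outer ring and follows the lamin rim", {
  p <- demo_partition()
  expect_identical(perinuclear_region(p, dilation_radius = 0),
                   p$labels == 3L)

  # dilation only grows the region outward
  r2 <- perinuclear_region(p, dilation_radius = 3)
  expect_true(all(r2[p$labels == 3L]))
  expect_false(any(r2[p$labels == 1L | p$labels == 2L]))
  expect_gt(sum(r2), sum(p$labels == 3L))

  expect_warning(
    empty <- perinuclear_region(p, lamin = matrix(0, 161, 161),
                                dilation_radius = 3),
    "empty")
  expect_false(any(empty))

  # synthetic rim: the region covers >= 95% of the rim-core ground truth
  cfg <- synthetic_config(image_shape = c(400, 400), n_nuclei = 1,
                          a_range = c(110, 120), b_range = c(75, 85),
                          noise = list(gaussian_sd = 0, poisson_gain = 0),
                          seed = 5)
  g <- generate_image(cfg, channels = "lamin")
  tr <- g$truth$nuclei
  ell <- ellipse_model(tr$cx, tr$cy, tr$a, tr$b, tr$theta)
  part <- partition_rings(ell, c(400, 400))
  reg <- perinuclear_region(part, lamin = g$channels$lamin,
                            dilation_radius = 2 * cfg$lamin$radial_sd)
  rim_core <- g$channels$lamin >=
    exp(-0.5) * cfg$lamin$amplitude + cfg$background
  expect_gte(sum(rim_core & reg) / sum(rim_core), 0.95)
})

test_that("perinuclear spot counting equals brute-force membership and is monotone in dilation", {
  p <- demo_partition()
  ell <- p$ellipse

  # 5 central spots: none perinuclear
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  central <- tibble::tibble(
    x = ell$cx + 0.2 * ell$a * cos(ang) * cos(ell$theta) -
      0.2 * ell$b * sin(ang) * sin(ell$theta),
    y = ell$cy + 0.2 * ell$a * cos(ang) * sin(ell$theta) +
      0.2 * ell$b * sin(ang) * cos(ell$theta))
  reg <- perinuclear_region(p, dilation_radius = 0)
  cnt <- count_perinuclear_spots(central, reg, ell)
  expect_equal(cnt$n_total, 5L)
  expect_equal(cnt$n_perinuclear, 0L)

  # 4 spots on the rim band
  rim <- tibble::tibble(
    x = ell$cx + 0.9 * ell$a * cos(ang[1:4]) * cos(ell$theta) -
      0.9 * ell$b * sin(ang[1:4]) * sin(ell$theta),
    y = ell$cy + 0.9 * ell$a * cos(ang[1:4]) * sin(ell$theta) +
      0.9 * ell$b * sin(ang[1:4]) * cos(ell$theta))
  cnt <- count_perinuclear_spots(rim, reg, ell)
  expect_equal(cnt$n_perinuclear, 4L)

  # brute-force membership oracle on a simulated nucleus
  cfg <- synthetic_config(image_shape = c(400, 400), n_nuclei = 1,
                          a_range = c(110, 120), b_range = c(75, 85),
                          spots = list(n_per_nucleus = 30,
                                       fraction_perinuclear = 0.5),
                          seed = 11)
  g <- generate_image(cfg, channels = "spots")
  tr <- g$truth$nuclei
  ell2 <- ellipse_model(tr$cx, tr$cy, tr$a, tr$b, tr$theta)
  part2 <- partition_rings(ell2, c(400, 400))
  reg2 <- perinuclear_region(part2, dilation_radius = 2)
  sp <- g$truth$spots
  cnt2 <- count_perinuclear_spots(sp, reg2, ell2, margin = 2 / ell2$b)
  brute <- sum(vapply(seq_len(nrow(sp)), function(i) {
    reg2[round(sp$y[i]) + 1, round(sp$x[i]) + 1]
  }, logical(1)))
  expect_equal(cnt2$n_perinuclear, brute)

  # enlarging the region never decreases the count
  counts <- vapply(c(0, 2, 4, 6), function(d) {
    r <- perinuclear_region(part2, dilation_radius = d)
    count_perinuclear_spots(sp, r, ell2, margin = d / ell2$b)$n_perinuclear
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("noiseless simulated spots are counted exactly as placed", {
  cfg <- synthetic_config(image_shape = c(400, 400), n_nuclei = 1,
                          a_range = c(110, 120), b_range = c(75, 85),
                          noise = list(gaussian_sd = 0, poisson_gain = 0),
                          spots = list(n_per_nucleus = 20,
                                       fraction_perinuclear = 0.6),
                          seed = 31)
  g <- generate_image(cfg, channels = "spots")
  detected <- detect_spots(g$channels$spots)
  tr <- g$truth$nuclei
  ell <- ellipse_model(tr$cx, tr$cy, tr$a, tr$b, tr$theta)
  part <- partition_rings(ell, c(400, 400))
  reg <- perinuclear_region(part, dilation_radius = 2)
  cnt <- count_perinuclear_spots(detected, reg, ell, margin = 2 / ell$b)
  expect_equal(cnt$n_total, nrow(g$truth$spots))
  expect_equal(cnt$n_perinuclear,
               sum(g$truth$spots$placement == "perinuclear"))
})

test_that("colocalization area is forced arithmetic on thresholded overlaps", {
  dimm <- c(80, 80)
  nuc <- raster_disk(35, 40, 40, dimm)
  a <- matrix(0, dimm[1], dimm[2])
  a[raster_disk(7.9, 40, 40, dimm)] <- 1   # 196 px, make exactly 200 below
  k <- sum(a)
  extra <- which(nuc & a == 0)[seq_len(200 - k)]
  a[extra] <- 1
  expect_equal(sum(a), 200)

  res <- coloc_area(a, a, nuc, pixel_size = 0.05)
  expect_equal(res$area_overlap, 200 * 0.05^2)
  expect_equal(res$area_overlap, 0.5)
  expect_equal(res$area_a, res$area_b)

  # disjoint foregrounds
  b <- matrix(0, dimm[1], dimm[2])
  b[raster_disk(6, 60, 40, dimm) & nuc & a == 0] <- 1
  res <- coloc_area(a, b, nuc)
  expect_equal(res$area_overlap, 0)

  # partially overlapping disks vs brute-force set arithmetic; symmetry
  c1 <- ifelse(raster_disk(12, 35, 40, dimm), 50, 2)
  c2 <- ifelse(raster_disk(12, 45, 40, dimm), 80, 3)
  res <- coloc_area(c1, c2, nuc, pixel_size = 0.1)
  brute <- sum(c1 > res$threshold_a & c2 > res$threshold_b & nuc)
  expect_equal(res$px_overlap, brute)
  expect_equal(res$area_overlap, brute * 0.01)
  expect_lte(res$area_overlap, min(res$area_a, res$area_b))
  swap <- coloc_area(c2, c1, nuc, pixel_size = 0.1)
  expect_equal(swap$area_overlap, res$area_overlap)
  expect_equal(swap$area_a, res$area_b)

  expect_error(coloc_area(c1, c2, nuc, threshold_method = "fixed"),
               "fixed_values")
  fx <- coloc_area(c1, c2, nuc, threshold_method = "fixed",
                   fixed_values = c(25, 40))
  expect_equal(fx$px_overlap, sum(c1 > 25 & c2 > 40 & nuc))
})
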