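test_that("moments ellipse recovers the generating parameters of rasterized shapes", {
  # disk
  m <- raster_disk(10, 50, 50, c(101, 101))
  e <- fit_ellipse(m)
  expect_equal(e$cx, 50, tolerance = 0.02)
  expect_equal(e$cy, 50, tolerance = 0.02)
  expect_equal(e$a, 10, tolerance = 0.02)
  expect_equal(e$b, 10, tolerance = 0.02)

  # axis-aligned ellipse
  m <- raster_ellipse(100, 100, 40, 20, 0, c(201, 201))
  e <- fit_ellipse(m)
  expect_equal(e$a, 40, tolerance = 0.02)
  expect_equal(e$b, 20, tolerance = 0.02)
  expect_lt(abs(e$theta), 0.05)

  # rotated ellipse
  m <- raster_ellipse(100, 100, 45, 25, 0.7, c(201, 201))
  e <- fit_ellipse(m)
  expect_equal(e$a, 45, tolerance = 0.02)
  expect_equal(e$b, 25, tolerance = 0.02)
  expect_equal(e$theta, 0.7, tolerance = 0.05)
})

test_that("fit_ellipse agrees with the eigen-decomposition moment oracle on an arbitrary shape", {
  # crescent: disk minus shifted disk
  m <- raster_disk(30, 60, 60, c(121, 121)) & !raster_disk(25, 72, 60, c(121, 121))
  e <- fit_ellipse(m)
  o <- moment_oracle(m)
  expect_equal(e$cx, o$cx, tolerance = 1e-10)
  expect_equal(e$cy, o$cy, tolerance = 1e-10)
  expect_equal(e$a, o$a, tolerance = 1e-8)
  expect_equal(e$b, o$b, tolerance = 1e-8)
  expect_equal(sin(2 * e$theta), sin(2 * o$theta), tolerance = 1e-6)
})

test_that("degenerate and empty masks are rejected; components handled", {
  expect_error(fit_ellipse(matrix(FALSE, 10, 10)), "empty mask")
  one <- matrix(FALSE, 10, 10); one[5, 5] <- TRUE
  expect_error(fit_ellipse(one), "degenerate mask")
  line <- matrix(FALSE, 10, 10); line[4, 2:9] <- TRUE
  expect_error(fit_ellipse(line), "degenerate mask")

  # diagonal touch is one component under 8-connectivity: no warning
  diag2 <- matrix(FALSE, 12, 12)
  diag2[3:5, 3:5] <- TRUE
  diag2[6:8, 6:8] <- TRUE
  expect_no_warning(fit_ellipse(diag2))

  # two separated blobs: reduced to the largest, with a warning
  two <- raster_disk(8, 15, 15, c(60, 60)) | raster_disk(4, 45, 45, c(60, 60))
  expect_warning(e <- fit_ellipse(two), "components")
  expect_equal(e$cx, 15, tolerance = 0.05)
})

test_that("jaccard fit quality matches brute-force set arithmetic", {
  ell <- ellipse_model(60, 60, 35, 22, 0.3)
  ras <- raster_ellipse(60, 60, 35, 22, 0.3, c(121, 121))
  q <- ellipse_fit_quality(ras, ell)
  expect_equal(q$jaccard, 1.0)
  expect_false(q$excluded)

  far <- raster_disk(5, 10, 10, c(121, 121))
  q <- ellipse_fit_quality(far, ell)
  expect_equal(q$jaccard, 0.0)
  expect_true(q$excluded)

  crescent <- raster_disk(30, 60, 60, c(121, 121)) &
    !raster_disk(25, 72, 60, c(121, 121))
  e <- fit_ellipse(crescent)
  q <- ellipse_fit_quality(crescent, e, threshold = 0.85)
  inside <- ellipse_interior(e, c(121, 121))
  expect_equal(q$jaccard, sum(crescent & inside) / sum(crescent | inside))
  expect_identical(q$excluded, q$jaccard < 0.85)
})

test_that("normalized radius is 0 at center, 1 on the boundary, and scales linearly", {
  ell <- ellipse_model(40, 30, 20, 10, 0.6)
  expect_equal(normalized_radius(40, 30, ell), 0)
  expect_equal(normalized_radius(40 + 20 * cos(0.6), 30 + 20 * sin(0.6), ell), 1)
  expect_equal(normalized_radius(40 + 40 * cos(0.6), 30 + 40 * sin(0.6), ell), 2)
  # boundary along the minor axis
  expect_equal(normalized_radius(40 - 10 * sin(0.6), 30 + 10 * cos(0.6), ell), 1)
})

test_that("ring partition is a pixel-exact partition matching the per-pixel oracle", {
  set.seed(42)
  for (i in 1:20) {
    ell <- ellipse_model(runif(1, 40, 80), runif(1, 40, 80),
                         runif(1, 15, 35), runif(1, 8, 15),
                         runif(1, -pi / 2, pi / 2))
    p <- partition_rings(ell, c(121, 121))
    expect_identical(p$labels, ring_oracle(ell, c(121, 121)))
    # conservation: union of rings is exactly the r <= 1 pixel set
    inside <- ellipse_interior(ell, c(121, 121))
    expect_identical(p$labels > 0L, inside)
  }
})

test_that("ring boundaries and counts behave for circles and alternative spacings", {
  ell <- ellipse_model(100, 100, 60, 60)
  p <- partition_rings(ell, c(201, 201))
  expect_equal(p$boundaries, c(1, 2, 3) / 3)
  counts <- tabulate(p$labels[p$labels > 0L], 3)
  fr <- counts / sum(counts)
  expect_equal(fr, c(1, 3, 5) / 9, tolerance = 0.02)

  # equal-area spacing: near-equal pixel counts
  pa <- partition_rings(ell, c(201, 201), spacing = "area")
  ca <- tabulate(pa$labels[pa$labels > 0L], 3)
  expect_equal(ca / sum(ca), rep(1 / 3, 3), tolerance = 0.02)

  p5 <- partition_rings(ell, c(201, 201), n_rings = 5)
  expect_equal(p5$boundaries, (1:5) / 5)
  expect_error(partition_rings(ell, c(201, 201), n_rings = 1), "n_rings")
})

test_that("fit and partition are equivariant under translation and rotation", {
  dimm <- c(161, 161)
  m0 <- raster_ellipse(70, 75, 35, 20, 0.3, dimm)
  e0 <- fit_ellipse(m0)
  q0 <- ellipse_fit_quality(m0, e0)
  c0 <- tabulate(partition_rings(e0, dimm)$labels + 1L, 4)

  # integer translation
  m1 <- raster_ellipse(70 + 9, 75 - 7, 35, 20, 0.3, dimm)
  e1 <- fit_ellipse(m1)
  q1 <- ellipse_fit_quality(m1, e1)
  c1 <- tabulate(partition_rings(e1, dimm)$labels + 1L, 4)
  expect_equal(q1$jaccard, q0$jaccard, tolerance = 1e-12)
  expect_identical(c1[2:4], c0[2:4])
  expect_equal(e1$cx, e0$cx + 9, tolerance = 1e-9)

  # rotation of the generating ellipse shifts recovered theta accordingly
  for (dth in c(0.5, 1.0)) {
    mr <- raster_ellipse(70, 75, 35, 20, 0.3 + dth, dimm)
    er <- fit_ellipse(mr)
    dd <- (er$theta - e0$theta - dth + pi / 2) %% pi - pi / 2
    expect_lt(abs(dd), 0.05)
  }
})
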