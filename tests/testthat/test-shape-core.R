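test_that("outline extraction places landmarks equally spaced in arc length", {
  o <- extract_outline(square_mask(10), 8)
  expect_equal(o$n_points, 8L)
  closed <- rbind(o$points, o$points[1, ])
  gaps <- sqrt(rowSums(diff(closed)^2))
  # square boundary polygon has perimeter 36 through pixel centers
  expect_equal(gaps, rep(36 / 8, 8), tolerance = 1e-12)

  # arc-length (not chord) spacing oracle on a rectangle polygon: locate each
  # resampled landmark on the boundary and difference the arc positions
  poly <- cbind(c(0, 10, 10, 0), c(0, 0, 5, 5))
  rs <- cellshaper:::resample_closed_polygon(poly, 100)$points
  arc_pos <- function(p) {
    seg_start <- poly
    seg_end <- poly[c(2:4, 1), ]
    cum <- c(0, cumsum(sqrt(rowSums((seg_end - seg_start)^2))))
    best <- Inf; pos <- NA
    for (s in 1:4) {
      d <- seg_end[s, ] - seg_start[s, ]
      t <- sum((p - seg_start[s, ]) * d) / sum(d^2)
      t <- min(max(t, 0), 1)
      proj <- seg_start[s, ] + t * d
      err <- sum((p - proj)^2)
      if (err < best) { best <- err; pos <- cum[s] + t * sqrt(sum(d^2)) }
    }
    pos
  }
  pos <- apply(rs, 1, arc_pos)
  per <- 30
  gaps_arc <- diff(c(pos, pos[1] + per)) %% per
  expect_lt(stats::sd(gaps_arc) / mean(gaps_arc), 1e-6)
})

test_that("outline of a rasterized disk stays near the analytic circle", {
  o <- extract_outline(disk_mask(20), 64)
  ctr <- colMeans(o$points)
  r <- sqrt(rowSums(sweep(o$points, 2, ctr)^2))
  expect_true(all(abs(r - 20) <= 1.0))
})

test_that("outline extraction honors n_points beyond boundary pixel count and errors cleanly", {
  m <- square_mask(4)
  o <- extract_outline(m, 500)
  expect_equal(o$n_points, 500L)
  expect_error(extract_outline(matrix(FALSE, 5, 5), 8), "empty")
  two <- matrix(FALSE, 12, 12)
  two[2:4, 2:4] <- TRUE; two[8:10, 8:10] <- TRUE
  expect_error(extract_outline(two, 8), "2 foreground components")
})

test_that("outline winding is consistent across shapes", {
  signed_area <- function(o) {
    p <- o$points
    q <- rbind(p[-1, ], p[1, ])
    sum(p[, 1] * q[, 2] - q[, 1] * p[, 2]) / 2
  }
  s1 <- signed_area(extract_outline(square_mask(10), 32))
  s2 <- signed_area(extract_outline(disk_mask(12), 32))
  s3 <- signed_area(extract_outline(generate_snl_2d(snl_params(seed = 9L)), 64))
  expect_true(all(sign(c(s1, s2, s3)) == sign(s1)))
})

test_that("align_outline centers, rotates to the major axis, and is rotation invariant", {
  e0 <- ellipse_outline(a = 30, b = 12, center = c(50, 30))
  a0 <- align_outline(e0)
  expect_equal(colMeans(a0$points), c(x = 0, y = 0), tolerance = 1e-10)
  # already axis-aligned ellipse keeps its axes
  expect_equal(max(abs(a0$points[, 1])), 30, tolerance = 1e-8)

  e40 <- ellipse_outline(a = 30, b = 12, center = c(-7, 3), angle = 40 * pi / 180)
  a40 <- align_outline(e40)
  expect_lt(hausdorff_distance(a40$points, a0$points), 1e-5)

  # flip rule: non-negative x-skewness
  set.seed(4)
  for (s in 1:5) {
    o <- align_outline(random_outline(64, seed = s))
    expect_gte(mean((o$points[, 1] - mean(o$points[, 1]))^3), -1e-9)
  }
  expect_error(align_outline(outline_2d(matrix(1, 5, 2))), "degenerate")
})

test_that("align_outline is idempotent", {
  for (s in 1:4) {
    a1 <- align_outline(random_outline(48, seed = s))
    a2 <- align_outline(a1)
    expect_lt(max(abs(a1$points - a2$points)), 1e-9)
  }
})

test_that("preshape removes location and scale and restores them exactly", {
  o <- ellipse_outline(center = c(12, -4))
  p <- to_preshape(o)
  expect_equal(colMeans(p$points), c(x = 0, y = 0), tolerance = 1e-12)
  expect_equal(sum(p$points^2), 1, tolerance = 1e-12)
  # translation/scale invariance of the preshape
  o2 <- outline_2d(sweep(o$points * 3.7, 2, c(100, 50), "+"))
  p2 <- to_preshape(o2)
  expect_equal(p$points, p2$points, tolerance = 1e-12)
  # round trip
  back <- from_preshape(p2)
  expect_equal(back$points, o2$points, tolerance = 1e-9)
})

test_that("hausdorff distance matches the brute-force oracle and is a metric", {
  expect_equal(hausdorff_distance(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  a <- matrix(c(0, 0, 1, 0, 2, 0), ncol = 2, byrow = TRUE)
  b <- matrix(c(0, 1), 1)
  expect_equal(hausdorff_distance(a, b), brute_hausdorff(a, b))
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(stats::rnorm(40), ncol = 2)
    y <- matrix(stats::rnorm(30), ncol = 2)
    z <- matrix(stats::rnorm(24), ncol = 2)
    expect_equal(hausdorff_distance(x, y), brute_hausdorff(x, y), tolerance = 1e-12)
    expect_equal(hausdorff_distance(x, y), hausdorff_distance(y, x))
    expect_equal(hausdorff_distance(x, x), 0)
    # triangle inequality
    expect_lte(hausdorff_distance(x, z),
               hausdorff_distance(x, y) + hausdorff_distance(y, z) + 1e-12)
  }
  expect_error(hausdorff_distance(matrix(numeric(0), 0, 2), matrix(0, 1, 2)))
})

test_that("mask and outline IO round-trip", {
  m <- mask_image_2d(disk_mask(9))
  fp <- tempfile(fileext = ".png")
  write_mask_2d(m, fp)
  expect_identical(read_mask_2d(fp)$pixels, m$pixels)
  ft <- tempfile(fileext = ".tif")
  write_mask_2d(m, ft)
  expect_identical(read_mask_2d(ft)$pixels, m$pixels)
  o <- extract_outline(m, 40)
  fo <- tempfile(fileext = ".txt")
  write_outline(o, fo)
  expect_equal(read_outline(fo)$points, o$points, tolerance = 1e-12,
               ignore_attr = TRUE)
})
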