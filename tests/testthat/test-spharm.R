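test_that("spherical harmonics match closed forms and reference Legendre values", {
  expect_equal(Re(spherical_harmonic(0, 0, 0.3, 1.2)), 1 / (2 * sqrt(pi)),
               tolerance = 1e-12)
  # Y_1^0 = sqrt(3/4pi) cos(theta)
  th <- c(0, pi / 2, pi)
  expect_equal(Re(spherical_harmonic(1, 0, th, 0)),
               sqrt(3 / (4 * pi)) * cos(th), tolerance = 1e-12)
  expect_error(spherical_harmonic(2, 3, 0.1, 0.1), "l")

  skip_if_not_installed("pracma")
  # associated Legendre reference (Matlab convention includes Condon-Shortley)
  x <- seq(-0.9, 0.9, length.out = 7)
  for (l in c(2, 5)) {
    P <- pracma::legendre(l, x)
    for (m in 0:l) {
      norm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      expect_equal(Re(spherical_harmonic(l, m, acos(x), 0)), norm * P[m + 1, ],
                   tolerance = 1e-10)
    }
  }
  # conjugation relation for negative orders
  y <- spherical_harmonic(3, 2, 0.7, 0.9)
  ym <- spherical_harmonic(3, -2, 0.7, 0.9)
  expect_equal(ym, Conj(y), tolerance = 1e-12)
})

test_that("the basis is orthonormal under quadrature up to l = 6", {
  skip_if_not_installed("pracma")
  gl <- pracma::gaussLegendre(48, -1, 1)
  nphi <- 32
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  TH <- rep(acos(gl$x), times = nphi)
  PH <- rep(phi, each = length(gl$x))
  W <- rep(gl$w, times = nphi) * (2 * pi / nphi)
  maxerr <- 0
  for (l1 in 0:6) for (m1 in seq(-l1, l1, by = 2)) {
    y1 <- spherical_harmonic(l1, m1, TH, PH)
    for (l2 in l1:6) for (m2 in seq(-l2, l2, by = 2)) {
      ip <- sum(Conj(y1) * spherical_harmonic(l2, m2, TH, PH) * W)
      maxerr <- max(maxerr, abs(ip - as.numeric(l1 == l2 && m1 == m2)))
    }
  }
  expect_lt(maxerr, 1e-8)
})

test_that("degree-1 descriptors are exact on spheres and translation only moves l = 0", {
  d <- sphere_descriptor(rho = 10, L = 4)
  rec <- reconstruct_surface(d, 162)
  expect_equal(sqrt(rowSums(rec$vertices^2)), rep(10, nrow(rec$vertices)),
               tolerance = 1e-6)

  # fit on a parameterized voxel sphere: translation shifts only l = 0
  mesh <- voxels_to_quad_mesh(voxel_sphere(6))
  gp <- graph_diameter_poles(mesh)
  map <- initial_parameterization(mesh, gp$poles)
  d0 <- fit_descriptor(mesh, map, 6)
  mesh2 <- mesh
  mesh2$vertices <- sweep(mesh$vertices, 2, c(5, -3, 2), "+")
  d1 <- fit_descriptor(mesh2, map, 6)
  diffc <- abs(d1$coefficients - d0$coefficients)
  expect_gt(max(diffc[1, ]), 0.1)
  expect_lt(max(diffc[-1, ]), 1e-8)
})

test_that("descriptor fits are nested: residual non-increasing in L", {
  mesh <- voxels_to_quad_mesh(voxel_sphere(7))
  gp <- graph_diameter_poles(mesh)
  map <- optimize_parameterization(
    initial_parameterization(mesh, gp$poles), list(max_iter = 10))$map
  rss <- sapply(c(0, 2, 4, 8), function(L) {
    d <- fit_descriptor(mesh, map, L, weighting = "uniform")
    B <- cellshaper:::real_sph_basis(L, map$theta, map$phi)
    A <- cellshaper:::complex_coefs_to_real(d$coefficients, L)
    sum((B %*% A - mesh$vertices)^2)
  })
  expect_true(all(diff(rss) <= 1e-6))
  # L = 0 reconstructs the mean point
  d0 <- fit_descriptor(mesh, map, 0, weighting = "uniform")
  rec0 <- reconstruct_surface(d0, 42)
  expect_lt(max(apply(rec0$vertices, 2, stats::sd)), 1e-9)
  expect_equal(colMeans(rec0$vertices), colMeans(mesh$vertices),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(fit_descriptor(mesh, map, 50), "vertex count")
})

test_that("sphere round trip reconstructs within a voxel and is sampling stable", {
  vol <- voxel_sphere(8)
  mesh <- voxels_to_quad_mesh(vol)
  gp <- graph_diameter_poles(mesh)
  opt <- optimize_parameterization(initial_parameterization(mesh, gp$poles),
                                   list(max_iter = 15))
  d <- fit_descriptor(mesh, opt$map, 15)
  e1 <- reconstruction_error_3d(vol, reconstruct_surface(d, 2562))
  expect_lt(e1, 1)
  e2 <- reconstruction_error_3d(vol, reconstruct_surface(d, 5200))
  expect_lt(abs(e2 - e1), 0.1 * max(e1, 1))
})

test_that("FOE alignment is idempotent, rotation invariant, and fixes skewness", {
  # elongated blob descriptor via the pipeline
  vol <- generate_blob_3d(size = 9, elongation = 1.7, roughness = 0.15, seed = 5)
  mesh <- voxels_to_quad_mesh(vol)
  gp <- graph_diameter_poles(mesh)
  opt <- optimize_parameterization(initial_parameterization(mesh, gp$poles),
                                   list(max_iter = 8))
  d <- fit_descriptor(mesh, opt$map, 8)
  al <- foe_align(d)
  expect_false(attr(al, "degenerate"))
  al2 <- foe_align(al)
  expect_lt(max(abs(al2$coefficients - al$coefficients)), 1e-9)
  # major axis in the XZ plane
  M <- cellshaper:::foe_matrix(al)
  v <- eigen(M %*% t(M), symmetric = TRUE)$vectors[, 1]
  expect_lt(abs(v[2]), 1e-6)
  # skewness non-negative
  expect_gte(cellshaper:::surface_x_skewness(al), -1e-9)

  # rotate the shape 30 degrees about Z, realign, compare
  rot <- cellshaper:::rotate_descriptor_z(al, 30 * pi / 180)
  back <- foe_align(rot)
  expect_lt(max(abs(back$coefficients - al$coefficients)), 1e-6)

  # unitary on each degree block (norm preserving away from l = 0)
  n0 <- sqrt(sum(abs(d$coefficients[-1, ])^2))
  n1 <- sqrt(sum(abs(al$coefficients[-1, ])^2))
  expect_equal(n0, n1, tolerance = 1e-10)

  # degenerate (spherical) case flagged and untouched
  ds <- sphere_descriptor(rho = 5, L = 2)
  als <- foe_align(ds)
  expect_true(attr(als, "degenerate"))
  expect_equal(als$coefficients, ds$coefficients)
})

test_that("descriptor IO round-trips", {
  d <- sphere_descriptor(rho = 3, L = 3)
  f <- tempfile(fileext = ".tsv")
  write_descriptor(d, f)
  d2 <- read_descriptor(f)
  expect_equal(d2$coefficients, d$coefficients, tolerance = 1e-12)
  expect_equal(d2$max_order, 3L)
})
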