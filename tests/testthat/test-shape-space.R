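blob_descriptors <- function(n, L = 4, seed = 10, size = 7) {
  lapply(seq_len(n), function(i) {
    vol <- generate_blob_3d(size = size, roughness = 0.15,
                            seed = seed + i)
    mesh <- voxels_to_quad_mesh(vol)
    map <- optimize_parameterization(
      initial_parameterization(mesh, graph_diameter_poles(mesh)$poles),
      list(max_iter = 5))$map
    fit_descriptor(mesh, map, L)
  })
}

test_that("descriptor feature stacking round-trips losslessly", {
  d <- blob_descriptors(1)[[1]]
  v <- cellshaper:::desc_to_feature(d)
  d2 <- cellshaper:::feature_to_desc(v, d$max_order)
  expect_equal(d2$coefficients, d$coefficients, tolerance = 1e-12)
})

test_that("descriptor PCA reproduces training descriptors at full rank and matches the eigen oracle", {
  descs <- blob_descriptors(8)
  m <- fit_descriptor_pca(descs, 7)
  for (d in descs) {
    rec <- decode_descriptor(m, embed(m, d))
    expect_lt(max(abs(rec$coefficients - d$coefficients)), 1e-8)
  }
  # k = 0: mean descriptor
  m0 <- fit_descriptor_pca(descs, 0)
  mu <- cellshaper:::feature_to_desc(m0$mean, descs[[1]]$max_order)
  expect_equal(decode_descriptor(m0, numeric(0))$coefficients, mu$coefficients)
  # eigen oracle
  X <- t(sapply(descs, cellshaper:::desc_to_feature))
  eg <- eigen(crossprod(sweep(X, 2, colMeans(X))), symmetric = TRUE)
  m3 <- fit_descriptor_pca(descs, 3)
  for (j in 1:3)
    expect_equal(abs(sum(m3$components[, j] * eg$vectors[, j])), 1,
                 tolerance = 1e-7)
  # mixed orders rejected
  bad <- c(descs[1:2], list(sphere_descriptor(L = 6)))
  expect_error(fit_descriptor_pca(bad, 2), "mixed")
  expect_identical(m$n_norm_params, 1L)
})

test_that("decoding embedded training shapes improves with latent dimension", {
  descs <- blob_descriptors(10, L = 6, seed = 30)
  vols <- lapply(seq_len(10), function(i)
    generate_blob_3d(size = 7, roughness = 0.15, seed = 30 + i))
  err_at <- function(k) {
    m <- fit_descriptor_pca(descs, k, n_recon_vertices = 642)
    mean(sapply(seq_along(descs), function(i)
      reconstruction_error_3d(vols[[i]], decode_shape(m, embed(m, descs[[i]])))))
  }
  errs <- sapply(c(2, 5, 9), err_at)
  expect_true(all(diff(errs) <= 0.05))
})

test_that("interpolate_path implements the discretization exactly", {
  z1 <- c(1, 2); z2 <- c(3, -2)
  p <- interpolate_path(z1, z2, 2)
  expect_equal(p$points[1, ], (z1 + z2) / 2)
  expect_equal(p$points[2, ], z1)
  # constant path
  pc <- interpolate_path(z1, z1, 5)
  expect_true(all(apply(pc$points, 1, function(r) all(r == z1))))
  # affinity: all points on the segment
  set.seed(2)
  a <- stats::rnorm(4); b <- stats::rnorm(4)
  pp <- interpolate_path(a, b, 7)
  dir <- b - a
  for (i in 1:7) {
    w <- pp$points[i, ] - a
    t <- sum(w * dir) / sum(dir^2)
    expect_lt(sqrt(sum((w - t * dir)^2)), 1e-12)
  }
  expect_error(interpolate_path(1:2, 1:3, 2), "dimension")
})

test_that("evolution energy is 0.5 for translation families and >= 0.5 in general", {
  # single-point decoder moving linearly: model over 1-point outlines
  pts <- lapply(seq(0, 9), function(i)
    outline_2d(matrix(c(i, 0, i + 1, 0, i, 1), ncol = 2, byrow = TRUE)))
  aligned <- pts  # already comparable layouts
  m <- fit_outline_pca(aligned, 1)
  z <- sapply(aligned, function(o) pca_encode(m, o))
  ev <- evolution_energy(m, z[1], z[7], N = 10)
  expect_equal(ev$normalized_energy, 0.5, tolerance = 1e-9)
  # N = 1 gives exactly half the endpoint distance
  ev1 <- evolution_energy(m, z[1], z[5], N = 1)
  expect_equal(ev1$energy, ev1$endpoint_distance / 2, tolerance = 1e-12)
  expect_equal(ev1$normalized_energy, 0.5, tolerance = 1e-12)

  # general 3D shape space: bound holds
  descs <- blob_descriptors(6, seed = 77)
  ms <- fit_descriptor_pca(descs, 4, n_recon_vertices = 162)
  Z <- t(sapply(descs, function(d) embed(ms, d)))
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    ev <- evolution_energy(ms, Z[pair[1], ], Z[pair[2], ], N = 6)
    expect_gte(ev$normalized_energy, 0.5 - 1e-9)
  }
  expect_error(evolution_energy(ms, Z[1, ], Z[1, ], N = 4), "identical")
})

test_that("joint 3D models round-trip descriptors and pose at full rank", {
  cells <- blob_descriptors(6, seed = 50)
  nucs <- blob_descriptors(6, L = 4, seed = 70, size = 5)
  set.seed(9)
  pose <- cbind(stats::rnorm(6, 5, 1), stats::rnorm(6, 0, 1),
                stats::rnorm(6, 1, 0.5), stats::runif(6, -1, 1))
  for (variant in c("separate", "joint")) {
    dims <- if (variant == "separate") 10 else 5
    m <- fit_joint_3d_model(cells, nucs, pose, dims, variant)
    code <- joint3d_encode(m, cells[[3]], nucs[[3]], pose[3, ])
    dec <- joint3d_decode(m, code)
    expect_lt(max(abs(dec$cell$coefficients - cells[[3]]$coefficients)), 1e-6)
    expect_lt(max(abs(dec$nucleus$coefficients - nucs[[3]]$coefficients)), 1e-6)
    expect_equal(dec$pose, pose[3, ], tolerance = 1e-6)
  }
  # independent populations: joint ~ separate at matched dims
  err_for <- function(variant) {
    m <- fit_joint_3d_model(cells, nucs, pose, 4, variant)
    mean(sapply(1:6, function(i) {
      dec <- joint3d_decode(m, joint3d_encode(m, cells[[i]], nucs[[i]], pose[i, ]))
      max(abs(dec$cell$coefficients - cells[[i]]$coefficients))
    }))
  }
  es <- err_for("separate"); ej <- err_for("joint")
  expect_lt(abs(es - ej), max(es, ej))
  expect_error(fit_joint_3d_model(cells, nucs, pose, 5, "separate"), "even")
})

test_that("posed nucleus mesh decode applies offset and rotation", {
  cells <- blob_descriptors(3, seed = 90)
  nucs <- blob_descriptors(3, seed = 95, size = 5)
  pose <- cbind(c(4, 5, 6), 0, 0, 0)
  m <- fit_joint_3d_model(cells, nucs, pose, 4, "separate")
  code <- joint3d_encode(m, cells[[1]], nucs[[1]], pose[1, ])
  dec <- joint3d_decode(m, code, as_mesh = TRUE, n_vertices = 42)
  plain <- reconstruct_surface(dec$nucleus, 42)
  expect_equal(dec$nucleus_mesh$vertices,
               sweep(plain$vertices, 2, pose[1, 1:3], "+"), tolerance = 1e-6)
})

test_that("model serialization round-trips outline and descriptor models", {
  outs <- lapply(1:5, function(i) align_outline(random_outline(12, seed = i)))
  m <- fit_outline_pca(outs, 3)
  f <- tempfile(fileext = ".json")
  write_shape_model(m, f)
  m2 <- read_shape_model(f)
  expect_equal(m2$mean, m$mean, tolerance = 1e-12)
  expect_equal(m2$components, m$components, tolerance = 1e-12)
  expect_equal(m2$k, m$k)
  b <- pca_encode(m, outs[[1]])
  expect_equal(pca_encode(structure(m2, class = "outline_pca_model"), outs[[1]]),
               b, tolerance = 1e-10)
})
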