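make_outlines <- function(n_shapes, n_points = 16, seed = 1) {
  lapply(seq_len(n_shapes), function(i)
    align_outline(random_outline(n_points, seed = seed + i)))
}

test_that("outline PCA reproduces training shapes at full rank and matches the covariance oracle", {
  outs <- make_outlines(5)
  model <- fit_outline_pca(outs, 4)
  for (o in outs) {
    rec <- pca_decode(model, pca_encode(model, o))
    expect_lt(hausdorff_distance(rec$points, o$points), 1e-6)
  }
  # oracle: dense covariance eigendecomposition on 10 outlines
  outs10 <- make_outlines(10)
  X <- t(sapply(outs10, function(o) as.vector(t(o$points))))
  Xc <- sweep(X, 2, colMeans(X))
  eg <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  m10 <- fit_outline_pca(outs10, 3)
  for (j in 1:3) {
    dotp <- abs(sum(m10$components[, j] * eg$vectors[, j]))
    expect_equal(dotp, 1, tolerance = 1e-8)
  }
  # encode matches the oracle projection up to component sign
  b <- pca_encode(m10, outs10[[2]])
  bo <- as.vector(crossprod(eg$vectors[, 1:3], X[2, ] - colMeans(X)))
  expect_equal(abs(b), abs(bo), tolerance = 1e-8)
})

test_that("outline PCA degenerate and error paths behave", {
  outs <- make_outlines(5)
  m0 <- fit_outline_pca(outs, 0)
  dec <- pca_decode(m0, numeric(0))
  expect_equal(as.vector(t(dec$points)), m0$mean, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(fit_outline_pca(outs, 10), "k must be")
  expect_error(fit_outline_pca(list(outs[[1]]), 1), "at least 2")
  mixed <- c(outs[1:2], list(align_outline(random_outline(20, seed = 99))))
  expect_error(fit_outline_pca(mixed, 2), "inconsistent")
  expect_error(pca_decode(m0, 1), "length")
  expect_error(pca_encode(fit_outline_pca(outs, 2),
                          align_outline(random_outline(20, seed = 98))),
               "mismatch")
})

test_that("outline PCA is linear and a projection", {
  outs <- make_outlines(8)
  m <- fit_outline_pca(outs, 4)
  b <- pca_encode(m, outs[[3]])
  expect_equal(pca_encode(m, pca_decode(m, b)), b, tolerance = 1e-9)
  # zero code decodes to the mean
  expect_equal(as.vector(t(pca_decode(m, rep(0, 4))$points)), m$mean,
               tolerance = 1e-12, ignore_attr = TRUE)
  # linearity around the mean
  b1 <- stats::rnorm(4); b2 <- stats::rnorm(4)
  d <- function(b) as.vector(t(pca_decode(m, b)$points)) - m$mean
  expect_equal(d(b1 + b2), d(b1) + d(b2), tolerance = 1e-9)
  # orthonormal components
  expect_equal(crossprod(m$components), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("training reconstruction error is non-increasing in k and variances ordered", {
  outs <- make_outlines(12, n_points = 24)
  errs <- sapply(c(1, 3, 5, 8, 11), function(k) {
    m <- fit_outline_pca(outs, k)
    mean(sapply(outs, function(o)
      hausdorff_distance(pca_decode(m, pca_encode(m, o))$points, o$points)))
  })
  expect_true(all(diff(errs) <= 1e-9))
  m <- fit_outline_pca(outs, 8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  expect_lte(sum(m$explained_variance) / m$total_variance, 1 + 1e-12)
  # dimension accounting convention
  expect_identical(m$n_norm_params, 1L)
})

test_that("SCA matches the dense eigendecomposition oracle and normalizes representations", {
  pres <- lapply(1:10, function(i) to_preshape(random_outline(16, seed = 40 + i)))
  model <- fit_sca(pres, 8)
  C <- Reduce(`+`, lapply(pres, function(p) tcrossprod(p$points)))
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  eg <- eigen(C, symmetric = TRUE)
  for (j in 1:8)
    expect_equal(abs(sum(model$rotation[, j] * eg$vectors[, j])), 1,
                 tolerance = 1e-8)
  for (p in pres) {
    enc <- sca_encode_decode(model, p)
    expect_equal(sqrt(sum(enc$b^2)), 1, tolerance = 1e-12)
  }
  expect_identical(model$n_norm_params, 2L)
})

test_that("SCA at full rank reproduces preshapes; reconstruction error matches a direct oracle at r = n/2", {
  pres <- lapply(1:8, function(i) to_preshape(random_outline(16, seed = 60 + i)))
  full <- fit_sca(pres, 16)
  for (p in pres) {
    rec <- sca_encode_decode(full, p)$reconstruction
    expect_lt(max(abs(rec$points - p$points)), 1e-8)
  }
  half <- fit_sca(pres, 8)
  C <- Reduce(`+`, lapply(pres, function(p) tcrossprod(p$points)))
  R <- eigen(C, symmetric = TRUE)$vectors[, 1:8]
  for (p in pres[1:3]) {
    x <- t(p$points)
    xr <- x %*% R
    bo <- xr / sqrt(sum(xr^2))
    oracle <- t(bo %*% t(R))
    rec <- sca_encode_decode(half, p)$reconstruction
    expect_equal(max(abs(abs(rec$points) - abs(oracle))), 0, tolerance = 1e-8)
    expect_equal(sqrt(sum((rec$points - p$points)^2)),
                 sqrt(sum((oracle - p$points)^2)), tolerance = 1e-8)
  }
  expect_error(fit_sca(pres, 17), "r must be")
})

test_that("identical preshapes yield a rank-1 SCA model with zero reconstruction error", {
  p <- to_preshape(random_outline(16, seed = 5))
  pres <- list(p, p, p)
  m <- fit_sca(pres, 1)
  rec <- sca_encode_decode(m, p)$reconstruction
  # one eigenvector cannot span a 2-row preshape in general; rank covers it at 2
  m2 <- fit_sca(pres, 2)
  rec2 <- sca_encode_decode(m2, p)$reconstruction
  expect_lt(max(abs(rec2$points - p$points)), 1e-8)
})

test_that("joint outline models round-trip pairs at full rank including pose", {
  set.seed(7)
  pairs <- lapply(1:6, function(i)
    generate_cell_nucleus_pair_2d(seed = 123, index = i))
  cells <- lapply(pairs, function(p) extract_outline(p$cell, 64))
  nucs <- lapply(pairs, function(p) extract_outline(p$nucleus, 48))
  for (variant in c("separate", "joint")) {
    m <- fit_joint_outline_model(cells, nucs, total_dims = 10,
                                 variant = variant, method = "pca")
    code <- joint_encode(m, cells[[2]], nucs[[2]])
    dec <- joint_decode(m, code)
    ca <- cellshaper:::outline_alignment(cells[[2]])
    na <- cellshaper:::outline_alignment(nucs[[2]])
    pose <- cellshaper:::relative_pose_2d(ca, na)
    expect_lt(hausdorff_distance(dec$cell$points, ca$aligned$points), 1e-6)
    expect_equal(dec$pose, pose, tolerance = 1e-6)
    # nucleus reproduced in the cell frame
    rot <- rbind(c(cos(pose[3]), -sin(pose[3])), c(sin(pose[3]), cos(pose[3])))
    nuc_cf <- sweep(na$aligned$points %*% t(rot), 2, pose[1:2], "+")
    expect_lt(hausdorff_distance(dec$nucleus$points, nuc_cf), 1e-6)
  }
  expect_error(fit_joint_outline_model(cells, nucs, 7, "separate"), "even")
})

test_that("joint and separate models agree for independent cell and nucleus populations", {
  # cells and nuclei drawn independently -> block-diagonal covariance
  set.seed(42)
  cells <- lapply(1:24, function(i) align_outline(random_outline(24, seed = 200 + i)))
  nucs <- lapply(1:24, function(i) align_outline(random_outline(24, seed = 500 + i)))
  # place nuclei at a fixed offset (independent of shapes)
  raw_nucs <- lapply(nucs, function(o) outline_2d(sweep(o$points * 0.4, 2, c(3, 1), "+")))
  raw_cells <- cells
  err_for <- function(variant) {
    m <- fit_joint_outline_model(raw_cells, raw_nucs, total_dims = 8,
                                 variant = variant, method = "pca")
    mean(sapply(seq_along(raw_cells), function(i) {
      dec <- joint_decode(m, joint_encode(m, raw_cells[[i]], raw_nucs[[i]]))
      ca <- cellshaper:::outline_alignment(raw_cells[[i]])
      hausdorff_distance(dec$cell$points, ca$aligned$points)
    }))
  }
  es <- err_for("separate"); ej <- err_for("joint")
  expect_lt(abs(es - ej), 0.5 * max(es, ej) + 0.2)
})

test_that("SCA-based joint model encodes and decodes consistently", {
  pairs <- lapply(1:5, function(i)
    generate_cell_nucleus_pair_2d(seed = 321, index = i))
  cells <- lapply(pairs, function(p) extract_outline(p$cell, 48))
  nucs <- lapply(pairs, function(p) extract_outline(p$nucleus, 48))
  m <- fit_joint_outline_model(cells, nucs, total_dims = 96, variant = "joint",
                               method = "sca")
  code <- joint_encode(m, cells[[1]], nucs[[1]])
  expect_equal(sqrt(sum(code$joint^2)), 1, tolerance = 1e-10)
  dec <- joint_decode(m, code)
  expect_s3_class(dec$cell, "outline_2d")
  expect_s3_class(dec$nucleus, "outline_2d")
})
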