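sphere_setup <- function(radius = 7) {
  mesh <- voxels_to_quad_mesh(voxel_sphere(radius))
  poles <- graph_diameter_poles(mesh)$poles
  list(mesh = mesh, poles = poles)
}

test_that("initial parameterization satisfies boundary conditions and the maximum principle", {
  s <- sphere_setup()
  map <- initial_parameterization(s$mesh, s$poles, equalize = FALSE)
  expect_identical(map$theta[s$poles], c(0, pi))
  interior <- setdiff(seq_along(map$theta), s$poles)
  expect_true(all(map$theta[interior] > 0 & map$theta[interior] < pi))
  expect_true(all(is.finite(map$phi)))
  # face orientation: nearly all spherical faces positive before optimization
  ar <- cellshaper:::spherical_face_areas(s$mesh, map)
  expect_gte(mean(ar > 0), 0.99)
  expect_equal(sum(ar), 4 * pi, tolerance = 1e-8)
  # area equalization keeps validity
  meq <- initial_parameterization(s$mesh, s$poles)
  areq <- cellshaper:::spherical_face_areas(s$mesh, meq)
  expect_gte(mean(areq > 0), 0.99)
  expect_equal(sum(areq), 4 * pi, tolerance = 1e-8)
  # adjacent poles rejected
  expect_error(initial_parameterization(s$mesh, s$mesh$edges[1, ]), "adjacent")
})

test_that("area residuals sum to zero and the analytic Jacobian matches finite differences", {
  s <- sphere_setup(5)
  map <- initial_parameterization(s$mesh, s$poles)
  out <- compute_area_residuals_and_jacobian(map)
  expect_equal(sum(out$residuals), 0, tolerance = 1e-10)
  expect_equal(sum(out$areas), 4 * pi, tolerance = 1e-10)

  nv <- nrow(s$mesh$vertices)
  set.seed(3)
  cols <- sample(2 * nv, 12)
  h <- 1e-6
  for (cc in cols) {
    perturb <- function(sgn) {
      th <- map$theta; ph <- map$phi
      if (cc <= nv) th[cc] <- th[cc] + sgn * h else ph[cc - nv] <- ph[cc - nv] + sgn * h
      compute_area_residuals_and_jacobian(
        spherical_map(th, ph, map$poles, s$mesh))$residuals
    }
    fd <- (perturb(1) - perturb(-1)) / (2 * h)
    an <- as.numeric(out$jacobian[, cc])
    scale <- max(max(abs(an)), 1e-8)
    expect_lt(max(abs(fd - an)) / scale, 1e-4)
  }

  # degenerate face rejected
  bad <- s$mesh
  bad$faces[1, 2] <- bad$faces[1, 1]
  badmap <- spherical_map(map$theta, map$phi, map$poles, bad)
  expect_error(compute_area_residuals_and_jacobian(badmap), "degenerate")
})

test_that("ADMM box-constrained least squares matches oracles", {
  set.seed(1)
  J <- matrix(stats::rnorm(80), 10, 8)
  r <- stats::rnorm(10)
  d_unc <- -solve(crossprod(J), crossprod(J, r))
  # slack bound: matches unconstrained least squares
  d <- admm_constrained_least_squares(J, r, step_bound = 10 * max(abs(d_unc)))
  expect_lt(max(abs(d - d_unc)), 1e-6)
  # active bound: feasible and no worse than the clipped unconstrained solution
  bnd <- 0.3 * max(abs(d_unc))
  d2 <- admm_constrained_least_squares(J, r, step_bound = bnd)
  expect_lte(max(abs(d2)), bnd + 1e-10)
  clipped <- pmin(pmax(d_unc, -bnd), bnd)
  obj <- function(x) sum((J %*% x + r)^2)
  expect_lte(obj(d2), obj(clipped) + 1e-8)
  # zero residual -> zero step
  expect_equal(admm_constrained_least_squares(J, rep(0, 10), 1), rep(0, 8))
  expect_error(admm_constrained_least_squares(J * 0, r, 1), "nonzero")
  expect_error(admm_constrained_least_squares(J, c(r[-1], NA), 1), "finite")
})

test_that("optimization reduces area distortion and never loses area conservation", {
  mesh <- voxels_to_quad_mesh(voxel_rod(16))
  poles <- graph_diameter_poles(mesh)$poles
  init <- initial_parameterization(mesh, poles)
  tg <- cellshaper:::target_face_areas(mesh)
  r0 <- max(cellshaper:::spherical_face_areas(mesh, init) / tg)
  opt <- optimize_parameterization(init, list(max_iter = 20))
  a1 <- cellshaper:::spherical_face_areas(mesh, opt$map)
  expect_lt(opt$diagnostics$max_area_ratio, r0)
  expect_equal(sum(a1), 4 * pi, tolerance = 1e-8)
  expect_equal(opt$diagnostics$n_inverted, 0)

  # reconstruction error decreases (weakly) with more iterations
  fit_err <- function(map) {
    d <- fit_descriptor(mesh, map, 5)
    hausdorff_distance(mesh$vertices, reconstruct_surface(d, 642)$vertices)
  }
  e0 <- fit_err(init)
  e20 <- fit_err(opt$map)
  expect_lte(e20, e0 + 0.25)
})

test_that("an equal-area map is a fixed point of the optimizer", {
  # near-perfect map: optimized sphere map re-entered
  s <- sphere_setup(5)
  opt1 <- optimize_parameterization(initial_parameterization(s$mesh, s$poles),
                                    list(max_iter = 40, tol = 0.05))
  opt2 <- optimize_parameterization(opt1$map, list(max_iter = 5, tol = 0.05))
  expect_lte(opt2$diagnostics$iterations, 1)
  expect_lt(max(abs(opt2$map$theta - opt1$map$theta)), 1e-8)
  expect_lt(max(abs(opt2$map$phi - opt1$map$phi)), 1e-8)
})

test_that("the robust pipeline parameterizes smooth and topologically dirty volumes", {
  vol <- voxel_ellipsoid()
  res <- parameterize_robust(vol, list(max_order = 15))
  expect_false(res$diagnostics$failed)
  expect_lt(res$diagnostics$reconstruction_error, 2)
  expect_equal(res$diagnostics$applied_kernel, 0L)

  # tunnel volume: needs topology fixation, recorded in diagnostics
  res2 <- parameterize_robust(tunnel_volume(), list(max_order = 5))
  expect_gte(res2$diagnostics$applied_kernel, 1L)
  expect_false(res2$diagnostics$failed)
})

test_that("spherical map serialization writes one row per vertex", {
  s <- sphere_setup(4)
  map <- initial_parameterization(s$mesh, s$poles)
  f <- tempfile(fileext = ".tsv")
  write_spherical_map(map, f)
  tab <- utils::read.table(f, header = TRUE)
  expect_equal(nrow(tab), nrow(s$mesh$vertices))
  expect_equal(tab$theta, map$theta, tolerance = 1e-12)
})
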