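# Fixtures built in code: small masks, outlines and voxel volumes used
# across the suite.

square_mask <- function(side = 10L, pad = 5L) {
  n <- side + 2L * pad
  m <- matrix(FALSE, n, n)
  m[pad + seq_len(side), pad + seq_len(side)] <- TRUE
  m
}

disk_mask <- function(radius = 20, extent = 2 * radius + 24) {
  cen <- (extent - 1) / 2
  x <- matrix(rep(0:(extent - 1), extent), nrow = extent)
  y <- t(x)
  (x - cen)^2 + (y - cen)^2 <= radius^2
}

# Analytic ellipse outline (not rasterized), n points by angle.
ellipse_outline <- function(a = 30, b = 12, center = c(0, 0), angle = 0,
                            n = 64) {
  t <- 2 * pi * (0:(n - 1)) / n
  p <- cbind(a * cos(t), b * sin(t))
  rot <- rbind(c(cos(angle), -sin(angle)), c(sin(angle), cos(angle)))
  outline_2d(sweep(p %*% t(rot), 2, center, "+"))
}

random_outline <- function(n = 16, seed = 1) {
  set.seed(seed)
  t <- 2 * pi * (0:(n - 1)) / n
  r <- 10 + stats::rnorm(1, 0, 2) +
    2 * sin(2 * t + stats::runif(1, 0, pi)) +
    1.5 * cos(3 * t + stats::runif(1, 0, pi)) +
    stats::rnorm(n, 0, 0.15)
  outline_2d(cbind(r * cos(t) * (1 + stats::runif(1, 0, 0.5)), r * sin(t)))
}

voxel_sphere <- function(radius = 8, extent = 2 * radius + 5) {
  cen <- (extent + 1) / 2
  g <- expand.grid(x = seq_len(extent), y = seq_len(extent), z = seq_len(extent))
  array((g$x - cen)^2 + (g$y - cen)^2 + (g$z - cen)^2 <= radius^2,
        c(extent, extent, extent))
}

voxel_ellipsoid <- function(a = 24, b = 14, c3 = 8,
                            extent = c(64, 40, 24)) {
  cen <- (extent + 1) / 2
  g <- expand.grid(x = seq_len(extent[1]), y = seq_len(extent[2]),
                   z = seq_len(extent[3]))
  array(((g$x - cen[1]) / a)^2 + ((g$y - cen[2]) / b)^2 +
          ((g$z - cen[3]) / c3)^2 <= 1, extent)
}

voxel_rod <- function(len = 10L) {
  v <- array(FALSE, c(len + 2L, 3L, 3L))
  v[1L + seq_len(len), 2L, 2L] <- TRUE
  v
}

tunnel_volume <- function() {
  v <- array(FALSE, c(9, 9, 9))
  v[2:8, 2:8, 3:7] <- TRUE
  v[5, 5, ] <- FALSE
  v
}

cavity_volume <- function() {
  v <- array(FALSE, c(9, 9, 9))
  v[2:8, 2:8, 2:8] <- TRUE
  v[4:6, 4:6, 4:6] <- FALSE
  v
}

# Sphere-of-radius-rho descriptor with identity parameterization: the
# degree-1 coefficients reproduce x, y, z exactly on the unit sphere.
sphere_descriptor <- function(rho = 10, L = 4) {
  C <- matrix(0i, (L + 1)^2, 3)
  k1 <- sqrt(3 / (8 * pi)); k0 <- sqrt(3 / (4 * pi))
  # x = k1 * (Y_1^-1 - Y_1^1) scaled; invert the degree-1 map used in the
  # package: f_j(u) = M[j, ] u with M from foe_matrix
  C[cellshaper:::degree_index(1, -1), 1] <- rho / (2 * k1)
  C[cellshaper:::degree_index(1, 1), 1] <- -rho / (2 * k1)
  C[cellshaper:::degree_index(1, -1), 2] <- rho / (2 * k1) * 1i
  C[cellshaper:::degree_index(1, 1), 2] <- rho / (2 * k1) * 1i
  C[cellshaper:::degree_index(1, 0), 3] <- rho / k0
  spharm_descriptor(C, L)
}

brute_hausdorff <- function(a, b) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  dm <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    dm[i, j] <- d(a[i, ], b[j, ])
  max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
}
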