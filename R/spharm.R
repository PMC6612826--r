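# Spherical harmonic basis, SPHARM descriptors, reconstruction, and
# first-order-ellipsoid (FOE) alignment.
#
# Conventions: Y_l^m(theta, phi) = N_lm P_lm(cos theta) e^{i m phi} with the
# Condon-Shortley phase folded into the associated Legendre functions, fully
# normalized so that the basis is orthonormal on the unit sphere. For m < 0,
# Y_l^{-m} = (-1)^m Conj(Y_l^m). Descriptors store the complex coefficients
# c_lm for l = 0..L, m = -l..l (row index l^2 + l + m + 1) for each of the
# three spatial coordinates.

# Fully normalized associated Legendre functions N_lm * P_lm(w) for all
# 0 <= m <= l <= L, evaluated at w = cos(theta) (vector). Returns a matrix
# with one column per (l, m) pair, index l(l+1)/2 + m + 1. Stable three-term
# recurrences; includes Condon-Shortley phase and the 1/sqrt(4*pi) factor.
legendre_normalized <- function(L, w) {
  w <- as.numeric(w)
  n <- length(w)
  s <- sqrt(pmax(1 - w^2, 0))
  np <- (L + 1) * (L + 2) / 2
  P <- matrix(0, n, np)
  idx <- function(l, m) l * (l + 1) / 2 + m + 1
  P[, 1] <- 1 / sqrt(4 * pi)
  if (L >= 1) {
    for (m in 1:L)
      P[, idx(m, m)] <- -sqrt((2 * m + 1) / (2 * m)) * s * P[, idx(m - 1, m - 1)]
    for (m in 0:(L - 1))
      P[, idx(m + 1, m)] <- sqrt(2 * m + 3) * w * P[, idx(m, m)]
    if (L >= 2) {
      for (m in 0:(L - 2)) {
        for (l in (m + 2):L) {
          a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
          b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
          P[, idx(l, m)] <- a * (w * P[, idx(l - 1, m)] - b * P[, idx(l - 2, m)])
        }
      }
    }
  }
  P
}

#' Evaluate a spherical harmonic
#'
#' Orthonormal complex spherical harmonic with Condon-Shortley phase.
#' Vectorized over points.
#'
#' @param l degree (integer >= 0).
#' @param m order, `|m| <= l`.
#' @param theta colatitude in `[0, pi]`.
#' @param phi longitude.
#' @return complex vector of `Y_l^m(theta, phi)` values.
#' @export
spherical_harmonic <- function(l, m, theta, phi) {
  l <- as.integer(l); m <- as.integer(m)
  if (l < 0 || abs(m) > l) stop("require l >= 0 and |m| <= l")
  am <- abs(m)
  P <- legendre_normalized(l, cos(theta))
  nl <- P[, l * (l + 1) / 2 + am + 1]
  y <- nl * exp(1i * am * phi)
  if (m < 0) y <- (-1)^am * Conj(y)
  y
}

# Real orthonormal basis matrix, n x (L+1)^2. Column layout per degree l:
# m = 0 column N_l0; then for m = 1..l the pair
# sqrt(2) N_lm cos(m phi), sqrt(2) N_lm sin(m phi).
real_sph_basis <- function(L, theta, phi) {
  P <- legendre_normalized(L, cos(theta))
  n <- length(theta)
  B <- matrix(0, n, (L + 1)^2)
  col <- 0L
  pidx <- function(l, m) l * (l + 1) / 2 + m + 1
  for (l in 0:L) {
    col <- col + 1L
    B[, col] <- P[, pidx(l, 0)]
    if (l >= 1) {
      for (m in 1:l) {
        nm <- P[, pidx(l, m)] * sqrt(2)
        B[, col + 1L] <- nm * cos(m * phi)
        B[, col + 2L] <- nm * sin(m * phi)
        col <- col + 2L
      }
    }
  }
  B
}

# Map between the real-basis coefficient layout of real_sph_basis() and the
# complex descriptor layout (l^2 + l + m + 1).
real_coefs_to_complex <- function(A, L) {
  # A: (L+1)^2 x q real matrix -> (L+1)^2 x q complex in (l, m) layout
  out <- matrix(0i, (L + 1)^2, ncol(A))
  col <- 0L
  for (l in 0:L) {
    base <- l^2 + l + 1
    col <- col + 1L
    out[base, ] <- A[col, ]
    if (l >= 1) {
      for (m in 1:l) {
        a <- A[col + 1L, ]; b <- A[col + 2L, ]
        c_pos <- (a - 1i * b) / sqrt(2)
        out[base + m, ] <- c_pos
        out[base - m, ] <- (-1)^m * Conj(c_pos)
        col <- col + 2L
      }
    }
  }
  out
}

complex_coefs_to_real <- function(C, L) {
  out <- matrix(0, (L + 1)^2, ncol(C))
  col <- 0L
  for (l in 0:L) {
    base <- l^2 + l + 1
    col <- col + 1L
    out[col, ] <- Re(C[base, ])
    if (l >= 1) {
      for (m in 1:l) {
        c_pos <- C[base + m, ]
        out[col + 1L, ] <- sqrt(2) * Re(c_pos)
        out[col + 2L, ] <- -sqrt(2) * Im(c_pos)
        col <- col + 2L
      }
    }
  }
  out
}

#' SPHARM descriptor
#'
#' Complex spherical-harmonic coefficients of the three coordinate functions
#' of a parameterized surface.
#'
#' @param coefficients complex `(L+1)^2 x 3` matrix; rows in `(l, m)` order
#'   with index `l^2 + l + m + 1`, columns x, y, z.
#' @param max_order maximum degree L.
#' @return object of class `spharm_descriptor`.
#' @export
spharm_descriptor <- function(coefficients, max_order) {
  coefficients <- as.matrix(coefficients)
  stopifnot(nrow(coefficients) == (max_order + 1)^2, ncol(coefficients) == 3)
  storage.mode(coefficients) <- "complex"
  colnames(coefficients) <- c("x", "y", "z")
  structure(list(coefficients = coefficients, max_order = as.integer(max_order)),
            class = "spharm_descriptor")
}

#' @export
print.spharm_descriptor <- function(x, ...) {
  cat("<spharm_descriptor> L =", x$max_order,
      " (", nrow(x$coefficients), "coefficients per coordinate )\n")
  invisible(x)
}

#' Fit a SPHARM descriptor to a parameterized mesh
#'
#' Least-squares fit of the spherical-harmonic expansion (up to degree `L`)
#' of the x, y, z coordinate functions over the vertex `(theta, phi)` values
#' of a spherical parameterization. By default each vertex is weighted by its
#' share of adjacent spherical face area, approximating the continuous inner
#' product on the sphere; `weighting = "uniform"` gives plain least squares.
#'
#' @param mesh a [surface_mesh].
#' @param map a `spherical_map` for the same mesh (see
#'   [initial_parameterization()]).
#' @param L maximum degree; `(L+1)^2` must not exceed the vertex count.
#' @param weighting `"area"` (default) or `"uniform"`.
#' @param smoothing relative strength of a degree-weighted (Sobolev) ridge
#'   penalty `smoothing * mean(diag(G)) * (l(l+1)/(L(L+1)))^2` on the
#'   coefficients. 0 (default) is the plain least-squares fit; a small value
#'   (the robust pipeline uses 1e-3) damps oscillations of high-degree terms
#'   in sphere regions left uncovered by sliver faces of an imperfect
#'   parameterization, leaving well-covered regions essentially untouched.
#' @return a [spharm_descriptor()].
#' @export
fit_descriptor <- function(mesh, map, L, weighting = c("area", "uniform"),
                           smoothing = 0) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- nrow(mesh$vertices)
  if (length(map$theta) != n) stop("map does not cover all mesh vertices")
  p <- (L + 1)^2
  if (p > n) stop("(L+1)^2 exceeds the vertex count; lower L")
  B <- real_sph_basis(L, map$theta, map$phi)
  w <- if (weighting == "area") {
    areas <- spherical_face_areas(mesh, map)
    va <- vertex_area_share(mesh$faces, areas, n)
    pmax(va, 1e-10)
  } else rep(1, n)
  sw <- sqrt(w)
  Bs <- B * sw
  G <- crossprod(Bs)
  rhs <- crossprod(Bs, mesh$vertices * sw)
  if (smoothing > 0) {
    ldeg <- rep(0:L, times = 2 * (0:L) + 1)
    pen <- (ldeg * (ldeg + 1) / (L * (L + 1)))^2
    G <- G + smoothing * mean(diag(G)) * diag(pen)
  }
  A <- tryCatch(solve(G, rhs), error = function(e) NULL)
  if (is.null(A)) {
    A <- tryCatch(solve(G + diag(1e-10 * mean(diag(G)), p), rhs),
                  error = function(e)
                    stop("rank-deficient basis matrix; lower L"))
  }
  spharm_descriptor(real_coefs_to_complex(A, L), L)
}

# Share the (signed) spherical area of each face equally among its corners.
vertex_area_share <- function(faces, areas, n_vertices) {
  k <- ncol(faces)
  unname(rowsum(rep(areas / k, k), as.vector(faces), reorder = TRUE)[, 1])
}

#' Quasi-uniform triangulated sphere sampling (subdivided icosahedron)
#'
#' @param n_min minimum number of vertices (>= 12); the smallest icosphere
#'   subdivision level with at least this many vertices is returned.
#' @return list with unit `vertices` (`V x 3`) and `triangles` (`F x 3`).
#' @export
icosphere <- function(n_min = 2562L) {
  if (n_min < 12) stop("n_min must be >= 12")
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c( t, 0, -1), c(t, 0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  while (nrow(v) < n_min) {
    nv <- nrow(v)
    a <- as.vector(f); b <- as.vector(f[, c(2, 3, 1)])
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- (lo - 1) * as.numeric(nv) + hi
    ukey <- unique(key)
    mid_id <- match(key, ukey) + nv
    first <- match(ukey, key)
    mids <- (v[lo[first], , drop = FALSE] + v[hi[first], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- matrix(mid_id, ncol = 3)  # midpoints of edges (1,2), (2,3), (3,1)
    f <- rbind(cbind(f[, 1], m12[, 1], m12[, 3]),
               cbind(f[, 2], m12[, 2], m12[, 1]),
               cbind(f[, 3], m12[, 3], m12[, 2]),
               m12)
  }
  list(vertices = v, triangles = f)
}

#' Reconstruct a surface mesh from a SPHARM descriptor
#'
#' Evaluates the truncated expansion on a quasi-uniform sphere sampling
#' (subdivided icosahedron), so reconstructed vertices are in general evenly
#' spaced on the surface.
#'
#' @param desc a [spharm_descriptor()].
#' @param n_vertices minimum number of sample vertices (>= 12).
#' @return a triangulated [surface_mesh].
#' @export
reconstruct_surface <- function(desc, n_vertices = 2562L) {
  stopifnot(inherits(desc, "spharm_descriptor"))
  ico <- icosphere(n_vertices)
  u <- ico$vertices
  theta <- acos(pmin(pmax(u[, 3], -1), 1))
  phi <- atan2(u[, 2], u[, 1])
  B <- real_sph_basis(desc$max_order, theta, phi)
  A <- complex_coefs_to_real(desc$coefficients, desc$max_order)
  im_l0 <- max(abs(Im(desc$coefficients[degree_index(0, 0), ])))
  coords <- B %*% A
  # The real-basis evaluation drops imaginary parts, which vanish for
  # descriptors satisfying the reality constraint; warn if they do not.
  if (im_l0 > 1e-8)
    warning("descriptor violates the reality constraint (imaginary l = 0 terms)")
  surface_mesh_tri(coords, ico$triangles)
}

degree_index <- function(l, m) l^2 + l + m + 1

# surface_mesh allowing triangle faces (reconstructions).
surface_mesh_tri <- function(vertices, triangles) {
  structure(list(vertices = as.matrix(vertices),
                 faces = matrix(as.integer(as.matrix(triangles)),
                                nrow = nrow(triangles)),
                 edges = face_edges(triangles, nrow(vertices))$edges),
            class = "surface_mesh")
}

# Degree-1 part of a descriptor as the real 3x3 matrix M with f(u) = M u for
# unit vectors u (rows: x, y, z coordinate functions).
foe_matrix <- function(desc) {
  k1 <- sqrt(3 / (8 * pi)); k0 <- sqrt(3 / (4 * pi))
  M <- matrix(0, 3, 3)
  for (j in 1:3) {
    cm1 <- desc$coefficients[degree_index(1, -1), j]
    c0  <- desc$coefficients[degree_index(1,  0), j]
    cp1 <- desc$coefficients[degree_index(1,  1), j]
    M[j, 1] <- Re(k1 * (cm1 - cp1))
    M[j, 2] <- Re(-1i * k1 * (cm1 + cp1))
    M[j, 3] <- Re(k0 * c0)
  }
  M
}

# Rotate a descriptor's shape about the spatial Z axis by angle alpha
# (counterclockwise looking down +z), leaving the degree-0 translation
# untouched. Exact on coefficients: mixes the x and y coefficient vectors.
rotate_descriptor_z <- function(desc, alpha) {
  C <- desc$coefficients
  keep <- degree_index(0, 0)
  rows <- setdiff(seq_len(nrow(C)), keep)
  cx <- C[rows, 1]; cy <- C[rows, 2]
  C[rows, 1] <- cos(alpha) * cx - sin(alpha) * cy
  C[rows, 2] <- sin(alpha) * cx + cos(alpha) * cy
  spharm_descriptor(C, desc$max_order)
}

#' First-order-ellipsoid alignment of a SPHARM descriptor
#'
#' Analyzes the degree-1 coefficients (the first-order ellipsoid, FOE) and
#' rotates the shape about the Z axis so the FOE major axis lies in the
#' XZ-plane. The 180-degree ambiguity is resolved by requiring the skewness
#' of the x coordinates of the reconstructed surface (XY projection) to be
#' non-negative. The degree-0 (translation) coefficients are untouched. If
#' the FOE is rotationally degenerate about Z (spherical in XY, or major axis
#' along Z), the descriptor is returned unrotated with attribute
#' `degenerate = TRUE`.
#'
#' @param desc a [spharm_descriptor()] with `max_order >= 1`.
#' @param tol relative tolerance for degeneracy detection.
#' @return the aligned [spharm_descriptor()]; attribute `degenerate` flags
#'   the untouched case, attribute `flipped` records the 180-degree flip.
#' @export
foe_align <- function(desc, tol = 1e-9) {
  stopifnot(inherits(desc, "spharm_descriptor"))
  if (desc$max_order < 1) stop("FOE alignment requires max_order >= 1")
  M <- foe_matrix(desc)
  S <- M %*% t(M)
  eg <- eigen(S, symmetric = TRUE)
  v <- eg$vectors[, 1]
  degen <- (eg$values[1] - eg$values[2]) <= tol * max(eg$values[1], 1e-300) ||
    (v[1]^2 + v[2]^2) <= tol
  if (degen) {
    out <- desc
    attr(out, "degenerate") <- TRUE
    attr(out, "flipped") <- FALSE
    return(out)
  }
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  alpha <- atan2(v[2], v[1])
  out <- rotate_descriptor_z(desc, -alpha)
  sk <- surface_x_skewness(out)
  flipped <- FALSE
  if (sk < 0) {
    out <- rotate_descriptor_z(out, pi)
    flipped <- TRUE
  }
  attr(out, "degenerate") <- FALSE
  attr(out, "flipped") <- flipped
  out
}

# Third standardized moment of the x coordinates of the reconstructed surface
# (XY projection view of the 180-degree disambiguation rule).
surface_x_skewness <- function(desc, n_vertices = 642L) {
  m <- reconstruct_surface(desc, n_vertices)
  x <- m$vertices[, 1]
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 <= 0) return(0)
  mean(x^3) / s2^1.5
}

#' Write a SPHARM descriptor as delimited text
#'
#' One row per `(l, m)` pair with real and imaginary parts of the x, y, z
#' coefficients.
#'
#' @param desc a [spharm_descriptor()].
#' @param path destination path.
#' @export
write_descriptor <- function(desc, path) {
  lm <- descriptor_lm_table(desc$max_order)
  d <- data.frame(l = lm[, 1], m = lm[, 2],
                  re_x = Re(desc$coefficients[, 1]), im_x = Im(desc$coefficients[, 1]),
                  re_y = Re(desc$coefficients[, 2]), im_y = Im(desc$coefficients[, 2]),
                  re_z = Re(desc$coefficients[, 3]), im_z = Im(desc$coefficients[, 3]))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SPHARM descriptor written by [write_descriptor()]
#' @param path file path.
#' @return a [spharm_descriptor()].
#' @export
read_descriptor <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  L <- max(d$l)
  C <- matrix(0i, (L + 1)^2, 3)
  idx <- degree_index(d$l, d$m)
  C[idx, 1] <- complex(real = d$re_x, imaginary = d$im_x)
  C[idx, 2] <- complex(real = d$re_y, imaginary = d$im_y)
  C[idx, 3] <- complex(real = d$re_z, imaginary = d$im_z)
  spharm_descriptor(C, L)
}

descriptor_lm_table <- function(L) {
  l <- rep(0:L, times = 2 * (0:L) + 1)
  m <- unlist(lapply(0:L, function(ll) -ll:ll))
  cbind(l, m)
}
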