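# Robust spherical parameterization (the RPDM pipeline): harmonic initial map
# anchored at graph-diameter poles, area-equalizing Gauss-Newton optimization
# with analytic Jacobians, clipping and box-constrained ADMM updates, and a
# success check with smoothing / alternate-initialization fallbacks.

#' Spherical map of a surface mesh
#'
#' Per-vertex spherical coordinates: colatitude `theta` in `[0, pi]` and
#' longitude `phi` in `[0, 2*pi)`; the two pole vertices carry theta 0 and pi
#' exactly.
#'
#' @param theta,phi numeric vectors, one value per mesh vertex.
#' @param poles integer vertex pair (north, south).
#' @param mesh the source [surface_mesh].
#' @return object of class `spherical_map`.
#' @export
spherical_map <- function(theta, phi, poles, mesh) {
  stopifnot(length(theta) == nrow(mesh$vertices), length(phi) == length(theta))
  structure(list(theta = as.numeric(theta), phi = as.numeric(phi),
                 poles = as.integer(poles), mesh = mesh),
            class = "spherical_map")
}

unit_vectors <- function(theta, phi) {
  st <- sin(theta)
  cbind(st * cos(phi), st * sin(phi), cos(theta))
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Signed solid angle of spherical triangles (rows of unit vectors); positive
# for counterclockwise orientation seen from outside the sphere.
tri_solid_angle <- function(u1, u2, u3) {
  N <- rowSums(u1 * row_cross(u2, u3))
  D <- 1 + rowSums(u1 * u2) + rowSums(u2 * u3) + rowSums(u3 * u1)
  2 * atan2(N, D)
}

# Signed spherical areas of all faces under a map (quads split along the
# consistent (1,3) diagonal).
spherical_face_areas <- function(mesh, map) {
  u <- unit_vectors(map$theta, map$phi)
  f <- mesh$faces
  if (ncol(f) == 3L) {
    tri_solid_angle(u[f[, 1], , drop = FALSE], u[f[, 2], , drop = FALSE],
                    u[f[, 3], , drop = FALSE])
  } else {
    tri_solid_angle(u[f[, 1], , drop = FALSE], u[f[, 2], , drop = FALSE],
                    u[f[, 3], , drop = FALSE]) +
    tri_solid_angle(u[f[, 1], , drop = FALSE], u[f[, 3], , drop = FALSE],
                    u[f[, 4], , drop = FALSE])
  }
}

# Planar face areas of the input mesh (sum of the two triangle areas).
planar_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  t1 <- 0.5 * sqrt(rowSums(row_cross(v[f[, 2], ] - v[f[, 1], ],
                                     v[f[, 3], ] - v[f[, 1], ])^2))
  if (ncol(f) == 3L) return(t1)
  t2 <- 0.5 * sqrt(rowSums(row_cross(v[f[, 3], ] - v[f[, 1], ],
                                     v[f[, 4], ] - v[f[, 1], ])^2))
  t1 + t2
}

# Target spherical areas: 4*pi partitioned proportionally to original areas.
target_face_areas <- function(mesh) {
  a <- planar_face_areas(mesh)
  4 * pi * a / sum(a)
}

#' Harmonic initial spherical parameterization
#'
#' Latitude is the solution of the discrete Laplace equation on the mesh
#' graph (uniform edge weights) with Dirichlet conditions theta = 0 at the
#' north pole and pi at the south pole. Longitude is a second Laplace solve
#' on the mesh cut along one north-south vertex path, with a 2*pi jump
#' across the cut, so phi winds once around the pole axis. The longitude
#' winding is oriented so the total signed spherical area is +4*pi.
#'
#' @param mesh a genus-0 manifold [surface_mesh].
#' @param poles integer vertex pair (north, south), e.g. from
#'   [graph_diameter_poles()].
#' @param equalize redistribute latitude and longitude by cumulative vertex
#'   area after the harmonic solves (default `TRUE`), spreading regions the
#'   harmonic map compresses (long thin protrusions) before optimization.
#' @return a [spherical_map()].
#' @export
initial_parameterization <- function(mesh, poles, equalize = TRUE) {
  nv <- nrow(mesh$vertices)
  north <- poles[1]; south <- poles[2]
  if (north == south) stop("poles must be distinct")
  e <- mesh$edges
  if (any((e[, 1] == north & e[, 2] == south) |
          (e[, 1] == south & e[, 2] == north)))
    stop("poles are adjacent; mesh too small for a spherical map")
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  L <- Matrix::Diagonal(x = deg) - A
  free <- setdiff(seq_len(nv), c(north, south))
  theta <- numeric(nv)
  theta[north] <- 0; theta[south] <- pi
  b <- as.vector(A[free, c(north, south), drop = FALSE] %*% c(0, pi))
  sol <- tryCatch(Matrix::solve(L[free, free], b),
                  error = function(e) stop("singular Laplace system for latitude"))
  theta[free] <- as.vector(sol)

  g <- mesh_graph(mesh)
  path <- as.integer(igraph::shortest_paths(g, from = north, to = south)$vpath[[1]])
  if (length(path) < 3L) stop("poles are adjacent; no interior dateline path")
  cut <- cut_mesh_along_path(mesh, path)
  phi <- solve_longitude(mesh, cut, path)

  map <- spherical_map(theta, phi, poles, mesh)
  if (sum(spherical_face_areas(mesh, map)) < 0) {
    phi <- (2 * pi - phi) %% (2 * pi)
    map <- spherical_map(theta, phi, poles, mesh)
  }
  if (equalize) map <- equalize_map_areas(map)
  map
}

# Monotone redistribution of latitude and longitude by cumulative vertex
# area: after remapping, vertex density is uniform in cos(theta) and in phi,
# which removes the extreme compression harmonic maps show on tubular parts
# and gives the area-equalizing optimizer a well-spread starting point.
equalize_map_areas <- function(map) {
  mesh <- map$mesh
  nv <- nrow(mesh$vertices)
  va <- vertex_area_share(mesh$faces, planar_face_areas(mesh), nv)
  th <- map$theta; ph <- map$phi
  ord <- order(th)
  cum <- (cumsum(va[ord]) - va[ord] / 2) / sum(va)
  th2 <- numeric(nv); th2[ord] <- acos(1 - 2 * cum)
  th2[map$poles] <- c(0, pi)
  ordp <- order(ph)
  cump <- (cumsum(va[ordp]) - va[ordp] / 2) / sum(va)
  ph2 <- numeric(nv); ph2[ordp] <- 2 * pi * cump
  spherical_map(th2, ph2, map$poles, mesh)
}

# Cut the mesh open along a north-south vertex path. Interior path vertices
# are duplicated; faces on one side of the path reference the duplicates.
# Returns list(faces = cut face matrix, dup_of = original index per duplicate
# (indices nv+1 ..), side_faces = logical per face).
cut_mesh_along_path <- function(mesh, path) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  k <- ncol(f)
  nf <- nrow(f)
  # vertex -> incident faces
  v2f <- split(rep(seq_len(nf), k), as.vector(f))
  interior <- path[-c(1L, length(path))]
  dup_of <- integer(0)
  dup_id <- integer(length(interior))  # new index per interior path vertex
  cutf <- f
  side_prev_face <- NA_integer_
  for (ii in seq_along(interior)) {
    vi <- interior[ii]
    vprev <- path[ii]        # path[ii] precedes interior[ii] = path[ii + 1]
    vnext <- path[ii + 2L]
    Fi <- v2f[[as.character(vi)]]
    if (is.null(Fi) || length(Fi) < 2L) stop("degenerate umbrella at path vertex ", vi)
    # neighbors of vi within each incident face
    comp <- umbrella_components(f, Fi, vi, c(vprev, vnext))
    # choose side B: first interior vertex arbitrary (smallest face id side);
    # afterwards the side containing the previous path-edge face
    if (ii == 1L) {
      sideB <- comp == comp[which.min(Fi)]
    } else {
      hit <- match(side_prev_face, Fi)
      if (is.na(hit)) stop("dateline side propagation failed at vertex ", vi)
      sideB <- comp == comp[hit]
    }
    # face adjacent to edge (vi, vnext) lying in side B, for propagation
    nxt_faces <- Fi[sideB & face_has_edge(f, Fi, vi, vnext)]
    if (length(nxt_faces)) side_prev_face <- nxt_faces[1L]
    else if (ii < length(interior)) stop("dateline cut lost the path edge at vertex ", vi)
    newid <- nv + length(dup_of) + 1L
    dup_of <- c(dup_of, vi)
    dup_id[ii] <- newid
    for (fb in Fi[sideB]) cutf[fb, cutf[fb, ] == vi] <- newid
  }
  list(faces = cutf, dup_of = dup_of)
}

face_has_edge <- function(f, Fi, a, b) {
  vapply(Fi, function(ff) {
    row <- f[ff, ]
    nxt <- c(row[-1], row[1])
    any((row == a & nxt == b) | (row == b & nxt == a))
  }, logical(1))
}

# Split the faces incident to vertex vi into the two sides of the path,
# connecting faces that share a non-path edge through vi. Returns an integer
# component label per face of Fi.
umbrella_components <- function(f, Fi, vi, path_neighbors) {
  m <- length(Fi)
  comp <- seq_len(m)
  # neighbors of vi in each face (the two corners adjacent to vi)
  nb <- lapply(Fi, function(ff) {
    row <- f[ff, ]
    p <- which(row == vi)[1]
    k <- length(row)
    row[c((p - 2L) %% k + 1L, p %% k + 1L)]
  })
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  allnb <- unique(unlist(nb))
  for (w in setdiff(allnb, path_neighbors)) {
    sharing <- which(vapply(nb, function(z) w %in% z, logical(1)))
    if (length(sharing) >= 2L) {
      r <- find(sharing[1])
      for (s in sharing[-1]) comp[find(s)] <- r
    }
  }
  vapply(seq_len(m), find, integer(1))
}

# Longitude solve on the cut mesh: one unknown per original non-pole vertex,
# a 2*pi jump carried by the duplicated dateline chain, gauge fixed by
# pinning the first interior path vertex to phi = 0.
solve_longitude <- function(mesh, cut, path) {
  nv <- nrow(mesh$vertices)
  poles <- c(path[1L], path[length(path)])
  cf <- cut$faces
  k <- ncol(cf)
  a <- as.vector(cf); b <- as.vector(cf[, c(2:k, 1L)])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- (lo - 1) * as.numeric(nv + length(cut$dup_of)) + hi
  keep <- !duplicated(key)
  ea <- lo[keep]; eb <- hi[keep]
  orig <- function(v) {
    o <- v
    sel <- v > nv
    o[sel] <- cut$dup_of[v[sel] - nv]
    o
  }
  jump <- function(v) ifelse(v > nv, 2 * pi, 0)
  oa <- orig(ea); ob <- orig(eb)
  ok <- !(oa %in% poles | ob %in% poles)
  oa <- oa[ok]; ob <- ob[ok]
  ja <- jump(ea[ok]); jb <- jump(eb[ok])
  unknown <- setdiff(seq_len(nv), poles)
  pin <- path[2L]
  sys_ids <- setdiff(unknown, pin)
  ix <- integer(nv); ix[sys_ids] <- seq_along(sys_ids)
  n <- length(sys_ids)
  ii <- c(oa, ob); jj <- c(ob, oa)
  # Laplacian entries; rhs from jumps and the pinned vertex (phi = 0)
  diag_i <- c(oa, ob)
  Ld <- Matrix::sparseMatrix(i = ix[diag_i[ix[diag_i] > 0]],
                             j = ix[diag_i[ix[diag_i] > 0]],
                             x = 1, dims = c(n, n))
  offsel <- ix[ii] > 0 & ix[jj] > 0
  Lo <- Matrix::sparseMatrix(i = ix[ii[offsel]], j = ix[jj[offsel]],
                             x = -1, dims = c(n, n))
  L <- Ld + Lo
  rhs <- numeric(n)
  # jump contributions: equation at oa gains (jb - ja); at ob gains (ja - jb)
  contrib <- function(ids, vals) {
    sel <- ix[ids] > 0
    if (any(sel)) {
      agg <- rowsum(vals[sel], ix[ids[sel]])
      rhs[as.integer(rownames(agg))] <<- rhs[as.integer(rownames(agg))] + agg[, 1]
    }
  }
  contrib(oa, jb - ja)
  contrib(ob, ja - jb)
  # pinned vertex has phi + jump as its value; neighbors of pin see jump only
  # (phi[pin] = 0), already handled since pin excluded from ix
  sol <- tryCatch(Matrix::solve(L, rhs),
                  error = function(e) stop("singular Laplace system for longitude"))
  phi <- numeric(nv)
  phi[sys_ids] <- as.vector(sol)
  phi[pin] <- 0
  phi[poles] <- 0
  phi %% (2 * pi)
}

#' Spherical area residuals and their analytic Jacobian
#'
#' Residuals are signed spherical face areas minus target areas (4*pi split
#' proportionally to the original face areas). The Jacobian holds the
#' closed-form partial derivatives of the signed spherical areas with respect
#' to every vertex colatitude and longitude (columns `1..V` are theta,
#' `V+1..2V` are phi).
#'
#' @param map a [spherical_map()].
#' @param targets optional target areas (defaults to area-proportional).
#' @return list with `residuals`, sparse `jacobian` (`F x 2V`), `areas`,
#'   `targets`.
#' @export
compute_area_residuals_and_jacobian <- function(map, targets = NULL) {
  mesh <- map$mesh
  f <- mesh$faces
  if (any(apply(f, 1, anyDuplicated) > 0))
    stop("degenerate face with duplicated vertices")
  if (is.null(targets)) targets <- target_face_areas(mesh)
  nv <- nrow(mesh$vertices)
  nf <- nrow(f)
  theta <- map$theta; phi <- map$phi
  u <- unit_vectors(theta, phi)
  st <- sin(theta); ct <- cos(theta); cp <- cos(phi); sp <- sin(phi)
  dudt <- cbind(ct * cp, ct * sp, -st)
  dudp <- cbind(-st * sp, st * cp, 0)

  tri_corners <- if (ncol(f) == 3L) list(f[, 1:3]) else
    list(f[, c(1, 2, 3)], f[, c(1, 3, 4)])
  areas <- numeric(nf)
  iidx <- integer(0); jidx <- integer(0); xval <- numeric(0)
  for (tc in tri_corners) {
    u1 <- u[tc[, 1], , drop = FALSE]
    u2 <- u[tc[, 2], , drop = FALSE]
    u3 <- u[tc[, 3], , drop = FALSE]
    N <- rowSums(u1 * row_cross(u2, u3))
    D <- 1 + rowSums(u1 * u2) + rowSums(u2 * u3) + rowSums(u3 * u1)
    areas <- areas + 2 * atan2(N, D)
    denom <- N^2 + D^2
    scale <- 2 / denom
    dN <- list(row_cross(u2, u3), row_cross(u3, u1), row_cross(u1, u2))
    dD <- list(u2 + u3, u1 + u3, u1 + u2)
    for (c3 in 1:3) {
      gu <- (dN[[c3]] * D - dD[[c3]] * N) * scale  # dOmega/du for corner c3
      vids <- tc[, c3]
      gt <- rowSums(gu * dudt[vids, , drop = FALSE])
      gp <- rowSums(gu * dudp[vids, , drop = FALSE])
      iidx <- c(iidx, seq_len(nf), seq_len(nf))
      jidx <- c(jidx, vids, nv + vids)
      xval <- c(xval, gt, gp)
    }
  }
  J <- Matrix::sparseMatrix(i = iidx, j = jidx, x = xval, dims = c(nf, 2L * nv))
  list(residuals = areas - targets, jacobian = J, areas = areas,
       targets = targets)
}

#' Box-constrained least squares via ADMM
#'
#' Approximately solves `min ||J d + r||^2` subject to
#' `max(abs(d)) <= step_bound` with the alternating direction method of
#' multipliers; the quadratic subproblem is solved by a cached sparse
#' Cholesky factorization. Returns the feasible iterate.
#'
#' @param J sparse (or dense) matrix.
#' @param r residual vector (`length == nrow(J)`).
#' @param step_bound positive box half-width.
#' @param rho ADMM penalty parameter.
#' @param max_iter inner iteration cap.
#' @param tol primal/dual residual tolerance.
#' @return the update vector `d` with `max(abs(d)) <= step_bound`.
#' @export
admm_constrained_least_squares <- function(J, r, step_bound, rho = 1,
                                           max_iter = 200L, tol = 1e-8) {
  if (step_bound <= 0) stop("step_bound must be positive")
  J <- methods::as(methods::as(J, "CsparseMatrix"), "generalMatrix")
  if (any(!is.finite(J@x)) || any(!is.finite(r))) stop("non-finite entries")
  if (length(J@x) == 0 || all(J@x == 0)) stop("J must be nonzero")
  p <- ncol(J)
  q <- -as.vector(Matrix::crossprod(J, r))
  if (all(q == 0)) return(numeric(p))
  G <- Matrix::crossprod(J)
  factorize <- function(rho)
    Matrix::Cholesky(methods::as(G + rho * Matrix::Diagonal(p),
                                 "symmetricMatrix"), LDL = FALSE)
  Ch <- factorize(rho)
  z <- numeric(p); uu <- numeric(p)
  sp <- sqrt(p)
  refactors <- 0L
  for (it in seq_len(max_iter)) {
    x <- as.vector(Matrix::solve(Ch, q + rho * (z - uu), system = "A"))
    zold <- z
    z <- pmin(pmax(x + uu, -step_bound), step_bound)
    uu <- uu + x - z
    pri <- sqrt(sum((x - z)^2))
    dua <- rho * sqrt(sum((z - zold)^2))
    if (pri <= tol * sp * max(1, sqrt(sum(x^2))) &&
        dua <= tol * sp * max(1, rho * sqrt(sum(uu^2)))) break
    # residual balancing (standard ADMM practice): keep primal and dual
    # residuals within a factor 10 of each other, rescaling the dual variable
    if (refactors < 8L) {
      if (pri > 10 * dua) {
        rho <- rho * 2; uu <- uu / 2
        Ch <- factorize(rho); refactors <- refactors + 1L
      } else if (dua > 10 * pri) {
        rho <- rho / 2; uu <- uu * 2
        Ch <- factorize(rho); refactors <- refactors + 1L
      }
    }
  }
  z
}

default_param_opts <- function(opts = list()) {
  defaults <- list(max_iter = 100L, tol = 1e-3, step_bound = 0.1,
                   clip_quantile = 0.999, rho = 1, admm_max_iter = 200L,
                   admm_tol = 1e-8, min_step = 1 / 64)
  defaults[names(opts)] <- opts
  defaults
}

#' Area-equalizing optimization of a spherical map
#'
#' Gauss-Newton iterations on the spherical area residuals: residual and
#' Jacobian entries are clipped at a high quantile of their magnitudes, the
#' step solves a box-constrained least-squares problem via
#' [admm_constrained_least_squares()], and a backtracking safeguard accepts a
#' step only if the objective decreases and no additional faces become
#' inverted. Pole vertices stay fixed.
#'
#' @param map initial [spherical_map()] (from [initial_parameterization()]).
#' @param opts list overriding defaults: `max_iter` (100), `tol` (1e-3,
#'   relative residual), `step_bound` (0.1 rad), `clip_quantile` (0.999),
#'   `rho` (1), `admm_max_iter` (200), `admm_tol` (1e-8), `min_step` (1/64).
#' @return list with the optimized `map` and `diagnostics` (`converged`,
#'   `iterations`, `max_area_ratio`, `n_inverted`, `objective`).
#' @export
optimize_parameterization <- function(map, opts = list()) {
  opts <- default_param_opts(opts)
  mesh <- map$mesh
  nv <- nrow(mesh$vertices)
  targets <- target_face_areas(mesh)
  free <- setdiff(seq_len(nv), map$poles)
  cols <- c(free, nv + free)
  theta <- map$theta; phi <- map$phi
  tiny <- 1e-6
  converged <- FALSE
  it_done <- 0L
  obj <- NA_real_
  for (it in seq_len(opts$max_iter)) {
    cur <- compute_area_residuals_and_jacobian(
      spherical_map(theta, phi, map$poles, mesh), targets)
    res <- cur$residuals
    obj <- sum(res^2)
    ninv <- sum(cur$areas <= 0)
    relres <- max(abs(res)) / max(targets)
    if (relres < opts$tol) { converged <- TRUE; break }
    cap <- stats::quantile(abs(res), opts$clip_quantile, names = FALSE)
    rc <- pmin(pmax(res, -cap), cap)
    J <- cur$jacobian[, cols, drop = FALSE]
    J <- methods::as(methods::as(J, "CsparseMatrix"), "generalMatrix")
    if (length(J@x)) {
      jcap <- stats::quantile(abs(J@x), opts$clip_quantile, names = FALSE)
      J@x <- pmin(pmax(J@x, -jcap), jcap)
    }
    d <- admm_constrained_least_squares(J, rc, opts$step_bound, rho = opts$rho,
                                        max_iter = opts$admm_max_iter,
                                        tol = opts$admm_tol)
    dt <- d[seq_along(free)]; dp <- d[length(free) + seq_along(free)]
    s <- 1
    accepted <- FALSE
    while (s >= opts$min_step) {
      th2 <- theta; ph2 <- phi
      th2[free] <- pmin(pmax(theta[free] + s * dt, tiny), pi - tiny)
      ph2[free] <- phi[free] + s * dp
      a2 <- spherical_face_areas(mesh, spherical_map(th2, ph2, map$poles, mesh))
      obj2 <- sum((a2 - targets)^2)
      if (obj2 < obj && sum(a2 <= 0) <= ninv) {
        theta <- th2; phi <- ph2
        accepted <- TRUE
        break
      }
      s <- s / 2
    }
    it_done <- it
    if (!accepted) break
    if (!is.finite(obj)) stop("objective diverged during optimization")
  }
  final_map <- spherical_map(theta, phi %% (2 * pi), map$poles, mesh)
  a <- spherical_face_areas(mesh, final_map)
  list(map = final_map,
       diagnostics = list(converged = converged, iterations = it_done,
                          max_area_ratio = max(a / targets),
                          n_inverted = sum(a <= 0),
                          objective = sum((a - targets)^2)))
}

z_extreme_poles <- function(mesh) {
  z <- mesh$vertices[, 3]
  c(which.max(z), which.min(z))
}

#' Robust spherical parameterization of a voxel shape
#'
#' The full pipeline: topology fixation, boundary quad mesh, graph-diameter
#' pole selection, harmonic initial map, area-equalizing constrained
#' optimization, SPHARM fit at the working order, and a success check
#' comparing the reconstructed surface against the original mesh (Hausdorff
#' distance; a parameterization fails if the error exceeds
#' `failure_threshold` pixels). On failure the pipeline retries with (a) one
#' pass of Laplacian surface smoothing and (b) z-extreme pole initialization
#' (the classical pole choice), in that escalation order.
#'
#' @param volume a [voxel_volume] or logical 3D array.
#' @param opts list overriding defaults: `max_order` (31, working degree for
#'   the success check), `failure_threshold` (100 pixels), `max_kernel` (10,
#'   topology fixation), `gn_max_iter` (10, optimization iterations inside
#'   the pipeline), `fit_smoothing` (1e-3, degree-weighted ridge of the
#'   working-order fit, see [fit_descriptor()]), `n_recon_vertices` (2562),
#'   plus any [optimize_parameterization()] options.
#' @return list with `mesh` (the mesh actually parameterized), `map`,
#'   `descriptor` (working-order fit), and `diagnostics` (`failed`,
#'   `reconstruction_error`, `fallbacks_used`, `applied_kernel`, `poles`,
#'   optimization diagnostics).
#' @export
parameterize_robust <- function(volume, opts = list()) {
  defaults <- list(max_order = 31L, failure_threshold = 100,
                   max_kernel = 10L, gn_max_iter = 10L,
                   fit_smoothing = 1e-3, n_recon_vertices = 2562L)
  defaults[names(opts)] <- opts
  o <- defaults
  fixed <- fix_topology(volume, o$max_kernel)
  mesh0 <- voxels_to_quad_mesh(fixed$volume)
  orig_pts <- mesh0$vertices
  gn_opts <- o[intersect(names(o), names(default_param_opts()))]
  gn_opts$max_iter <- o$gn_max_iter

  attempts <- list(
    list(label = "diameter", smooth = FALSE, poles = "diameter", refine = FALSE),
    list(label = "diameter+refine", smooth = FALSE, poles = "diameter", refine = TRUE),
    list(label = "smooth+diameter", smooth = TRUE, poles = "diameter", refine = FALSE),
    list(label = "zpoles", smooth = FALSE, poles = "z", refine = FALSE),
    list(label = "smooth+zpoles", smooth = TRUE, poles = "z", refine = FALSE))
  tried <- character(0)
  best <- NULL
  prev_map <- NULL
  for (att in attempts) {
    tried <- c(tried, att$label)
    result <- tryCatch({
      mesh <- if (att$smooth) smooth_mesh(mesh0, lambda = 0.5) else mesh0
      if (att$refine) {
        # continue optimizing the previous map rather than restarting
        if (is.null(prev_map)) stop("no map to refine")
        opts2 <- gn_opts
        opts2$max_iter <- 2L * o$gn_max_iter
        optres <- optimize_parameterization(prev_map, opts2)
        poles <- prev_map$poles
      } else {
        poles <- if (att$poles == "diameter") graph_diameter_poles(mesh)$poles
                 else z_extreme_poles(mesh)
        init <- initial_parameterization(mesh, poles)
        optres <- optimize_parameterization(init, gn_opts)
      }
      if (!att$smooth) prev_map <- optres$map
      L <- min(o$max_order, floor(sqrt(nrow(mesh$vertices))) - 1L)
      desc <- fit_descriptor(mesh, optres$map, L, smoothing = o$fit_smoothing)
      recon <- reconstruct_surface(desc, o$n_recon_vertices)
      err <- hausdorff_distance(orig_pts, recon$vertices)
      list(mesh = mesh, map = optres$map, descriptor = desc, poles = poles,
           err = err, opt = optres$diagnostics)
    }, error = function(e) e)
    if (inherits(result, "error")) next
    if (is.null(best) || result$err < best$err) best <- result
    if (result$err <= o$failure_threshold) break
  }
  if (is.null(best)) {
    stop(structure(class = c("cellshaper_param_error", "error", "condition"),
                   list(message = paste("all parameterization attempts failed:",
                                        paste(tried, collapse = ", ")),
                        call = sys.call(),
                        diagnostics = list(fallbacks_used = tried,
                                           applied_kernel = fixed$applied_kernel))))
  }
  failed <- best$err > o$failure_threshold
  diagnostics <- c(best$opt,
                   list(failed = failed, reconstruction_error = best$err,
                        fallbacks_used = tried,
                        applied_kernel = fixed$applied_kernel,
                        poles = best$poles))
  if (failed) {
    stop(structure(class = c("cellshaper_param_error", "error", "condition"),
                   list(message = sprintf(
                     "parameterization failed: reconstruction error %.1f > %.1f pixels",
                     best$err, o$failure_threshold),
                     call = sys.call(), diagnostics = diagnostics)))
  }
  list(mesh = best$mesh, map = best$map, descriptor = best$descriptor,
       diagnostics = diagnostics)
}

#' Write a spherical map as per-vertex delimited text
#' @param map a [spherical_map()].
#' @param path destination path.
#' @export
write_spherical_map <- function(map, path) {
  d <- data.frame(vertex = seq_along(map$theta), theta = map$theta, phi = map$phi)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
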