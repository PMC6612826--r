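#' Binary 3D voxel volume
#'
#' Wrapper around a logical 3D array with dims `(x, y, z)`; `z` is the slice
#' axis. Voxel centers sit at 0-based integer coordinates; the surface mesh
#' lives on voxel corners at half-integer coordinates.
#'
#' @param voxels logical (or 0/1) 3D array.
#' @param check verify single nonempty 6-connected foreground component.
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(voxels, check = TRUE) {
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (check) {
    if (!any(voxels)) stop("volume is empty")
    ncomp <- count_components_3d(voxels)
    if (ncomp != 1L)
      stop("volume has ", ncomp, " foreground components; expected exactly 1")
  }
  structure(list(voxels = voxels, shape = dim(voxels)), class = "voxel_volume")
}

as_voxel_array <- function(volume) {
  if (inherits(volume, "voxel_volume")) volume$voxels
  else array(as.logical(volume), dim = dim(volume))
}

#' Quadrilateral surface mesh of a voxel shape
#'
#' @param vertices numeric `V x 3` matrix of vertex coordinates (voxel units).
#' @param faces integer `F x 4` matrix of vertex indices, each row one quad,
#'   oriented counterclockwise viewed from outside.
#' @return object of class `surface_mesh` with derived unique `edges`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), nrow = nrow(faces))
  stopifnot(ncol(vertices) == 3, ncol(faces) == 4)
  structure(list(vertices = vertices, faces = faces,
                 edges = face_edges(faces, nrow(vertices))$edges),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> V =", nrow(x$vertices), " E =", nrow(x$edges),
      " F =", nrow(x$faces), "\n")
  invisible(x)
}

# All face sides as undirected edges; returns unique edges and per-edge
# incidence counts (a closed 2-manifold has every count equal to 2).
face_edges <- function(faces, n_vertices) {
  k <- ncol(faces)
  a <- as.vector(faces)
  b <- as.vector(faces[, c(2:k, 1L)])
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- (lo - 1) * as.numeric(n_vertices) + hi
  tab <- tabulate(match(key, unique(key)))
  ukey <- unique(key)
  edges <- cbind(as.integer((ukey - 1) %/% n_vertices) + 1L,
                 as.integer((ukey - 1) %% n_vertices) + 1L)
  list(edges = edges, counts = tab)
}

#' Convert a voxel volume to its boundary quad mesh
#'
#' Emits one unit-square face for every 6-neighbor (foreground, background)
#' voxel pair (array border counts as background), with faces oriented
#' outward. Vertices are voxel corners shared across faces.
#'
#' @param volume a [voxel_volume] or logical 3D array.
#' @return a [surface_mesh].
#' @export
voxels_to_quad_mesh <- function(volume) {
  vox <- as_voxel_array(volume)
  if (!any(vox)) stop("volume is empty")
  if (!inherits(volume, "voxel_volume")) {
    ncomp <- count_components_3d(vox)
    if (ncomp != 1L)
      stop("volume has ", ncomp, " foreground components; expected exactly 1")
  }
  d <- dim(vox)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nxy <- nx * ny
  # 0-based voxel center coordinates of exposed faces per direction
  exposed <- function(off) which(vox & !shift3(vox, -off))
  # corner offsets (relative to voxel center, each in {-0.5, +0.5}) per
  # direction, ordered counterclockwise viewed from outside
  h <- 0.5
  corner_tabs <- list(
    `+x` = rbind(c(h,-h,-h), c(h, h,-h), c(h, h, h), c(h,-h, h)),
    `-x` = rbind(c(-h,-h,-h), c(-h,-h, h), c(-h, h, h), c(-h, h,-h)),
    `+y` = rbind(c(-h, h,-h), c(-h, h, h), c( h, h, h), c( h, h,-h)),
    `-y` = rbind(c(-h,-h,-h), c( h,-h,-h), c( h,-h, h), c(-h,-h, h)),
    `+z` = rbind(c(-h,-h, h), c( h,-h, h), c( h, h, h), c(-h, h, h)),
    `-z` = rbind(c(-h,-h,-h), c(-h, h,-h), c( h, h,-h), c( h,-h,-h)))
  dirs <- list(`+x` = c(1,0,0), `-x` = c(-1,0,0), `+y` = c(0,1,0),
               `-y` = c(0,-1,0), `+z` = c(0,0,1), `-z` = c(0,0,-1))
  vx <- vy <- vz <- list(); fi <- 0L
  for (nm in names(dirs)) {
    idx <- exposed(dirs[[nm]])
    if (!length(idx)) next
    i0 <- idx - 1L
    cx <- i0 %% nx; cy <- (i0 %/% nx) %% ny; cz <- i0 %/% nxy
    tab <- corner_tabs[[nm]]
    m <- length(idx)
    X <- matrix(0, m, 4); Y <- matrix(0, m, 4); Z <- matrix(0, m, 4)
    for (c4 in 1:4) {
      X[, c4] <- cx + tab[c4, 1]
      Y[, c4] <- cy + tab[c4, 2]
      Z[, c4] <- cz + tab[c4, 3]
    }
    fi <- fi + 1L
    vx[[fi]] <- X; vy[[fi]] <- Y; vz[[fi]] <- Z
  }
  X <- do.call(rbind, vx); Y <- do.call(rbind, vy); Z <- do.call(rbind, vz)
  # dedupe corner vertices via integer keys on doubled coordinates
  kx <- as.integer(round(2 * X)); ky <- as.integer(round(2 * Y))
  kz <- as.integer(round(2 * Z))
  mx <- 2L * nx + 3L; my <- 2L * ny + 3L
  key <- (kx + 1L) + mx * ((ky + 1L) + my * as.numeric(kz + 1L))
  ukey <- unique(as.vector(key))
  vid <- matrix(match(as.vector(key), ukey), nrow = nrow(X))
  first <- match(ukey, as.vector(key))
  vertices <- cbind(as.vector(X)[first], as.vector(Y)[first], as.vector(Z)[first])
  surface_mesh(vertices, vid)
}

#' Euler characteristic of a surface mesh
#'
#' Returns `V - E + F`. Errors if any edge is not shared by exactly two
#' faces (non-manifold surface), identifying the first offending edge.
#'
#' @param mesh a [surface_mesh].
#' @return integer Euler characteristic (2 for genus-0).
#' @export
euler_characteristic <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  fe <- face_edges(mesh$faces, nrow(mesh$vertices))
  bad <- which(fe$counts != 2L)
  if (length(bad))
    stop("non-manifold edge between vertices ", fe$edges[bad[1], 1], " and ",
         fe$edges[bad[1], 2], " (shared by ", fe$counts[bad[1]], " faces)")
  nrow(mesh$vertices) - nrow(fe$edges) + nrow(mesh$faces)
}

# TRUE if the volume's surface is a closed manifold with chi == 2.
is_genus0 <- function(vox) {
  chi <- tryCatch(euler_characteristic(voxels_to_quad_mesh(voxel_volume(vox, check = FALSE))),
                  error = function(e) NA_integer_)
  isTRUE(chi == 2L)
}

#' Fix the topology of a voxel shape
#'
#' Interior cavities are removed by 3D hole filling, then morphological
#' closing with a discrete ball of increasing radius is applied until the
#' boundary surface is a closed manifold with Euler characteristic 2
#' (genus-0). Radius 0 means the hole-filled volume already passed.
#'
#' @param volume a [voxel_volume] or logical 3D array.
#' @param max_kernel largest closing radius to try (default 10).
#' @return list with `volume` (the fixed [voxel_volume]) and `applied_kernel`
#'   (the closing radius used, 0 if untouched beyond hole filling).
#' @export
fix_topology <- function(volume, max_kernel = 10L) {
  vox <- as_voxel_array(volume)
  if (!any(vox)) stop("volume is empty")
  base <- fill_holes_3d(vox)
  last_chi <- NA_integer_
  for (r in 0:max_kernel) {
    cand <- if (r == 0L) base else fill_holes_3d(close3_ball(base, r))
    if (count_components_3d(cand) == 1L) {
      chi <- tryCatch(
        euler_characteristic(voxels_to_quad_mesh(voxel_volume(cand, check = FALSE))),
        error = function(e) NA_integer_)
      if (isTRUE(chi == 2L))
        return(list(volume = voxel_volume(cand, check = FALSE), applied_kernel = r))
      last_chi <- chi
    }
  }
  stop("topology could not be fixed up to kernel radius ", max_kernel,
       " (final Euler characteristic ", last_chi, ")")
}

mesh_graph <- function(mesh) {
  igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
}

#' Graph-diameter pole pair of a mesh
#'
#' Treats the mesh as an unweighted graph and returns two vertices realizing
#' (or, for large meshes, approximating) the graph diameter - the largest
#' shortest-path distance. Exact all-pairs BFS is used for up to
#' `exact_limit` vertices; beyond that a deterministic double-sweep BFS from
#' 8 evenly spaced seeds. Ties are broken by the lexicographically smallest
#' index pair.
#'
#' @param mesh a [surface_mesh].
#' @param exact_limit vertex count up to which the exact search is used.
#' @return list with `poles` (integer vertex pair, north then south) and
#'   `distance` (their graph distance).
#' @export
graph_diameter_poles <- function(mesh, exact_limit = 5000L) {
  g <- mesh_graph(mesh)
  nv <- igraph::vcount(g)
  if (!igraph::is_connected(g)) stop("mesh graph is disconnected")
  if (nv <= exact_limit) {
    dm <- igraph::distances(g)
    best <- max(dm)
    hits <- which(dm == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    return(list(poles = c(hits[1, 1], hits[1, 2]), distance = best))
  }
  seeds <- unique(as.integer(round(seq(1, nv, length.out = 8))))
  best <- -1; bp <- c(1L, 2L)
  for (s in seeds) {
    d1 <- as.vector(igraph::distances(g, v = s))
    u <- which(d1 == max(d1))[1L]
    d2 <- as.vector(igraph::distances(g, v = u))
    v <- which(d2 == max(d2))[1L]
    dd <- d2[v]
    pair <- c(min(u, v), max(u, v))
    if (dd > best || (dd == best && (pair[1] < bp[1] ||
                                     (pair[1] == bp[1] && pair[2] < bp[2])))) {
      best <- dd; bp <- pair
    }
  }
  list(poles = bp, distance = best)
}

# Vertex adjacency list from unique edges.
vertex_adjacency <- function(mesh) {
  nv <- nrow(mesh$vertices)
  adj <- vector("list", nv)
  e <- mesh$edges
  inc <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  adj[as.integer(names(inc))] <- inc
  adj
}

#' One pass of Laplacian vertex smoothing
#'
#' Moves each vertex a fraction `lambda` of the way toward the mean of its
#' edge neighbors. Used as the surface-smoothing fallback in the robust
#' parameterization pipeline.
#'
#' @param mesh a [surface_mesh].
#' @param lambda smoothing weight in (0, 1], default 0.5.
#' @param iterations number of passes.
#' @return the smoothed [surface_mesh] (same connectivity).
#' @export
smooth_mesh <- function(mesh, lambda = 0.5, iterations = 1L) {
  v <- mesh$vertices
  e <- mesh$edges
  nv <- nrow(v)
  deg <- tabulate(c(e[, 1], e[, 2]), nbins = nv)
  for (it in seq_len(iterations)) {
    acc <- matrix(0, nv, 3)
    for (c3 in 1:3) {
      acc[, c3] <- unname(
        rowsum(c(v[e[, 2], c3], v[e[, 1], c3]), c(e[, 1], e[, 2]),
               reorder = TRUE)[, 1])
    }
    v <- v + lambda * (acc / deg - v)
  }
  surface_mesh(v, mesh$faces)
}

#' Triangulate a quad mesh
#'
#' Splits every quad into two triangles along the consistent (1,3) diagonal.
#'
#' @param mesh a [surface_mesh].
#' @return list with `vertices` and integer `triangles` (`2F x 3`).
#' @export
triangulate_mesh <- function(mesh) {
  f <- mesh$faces
  tri <- if (ncol(f) == 3L) f else rbind(f[, c(1, 2, 3)], f[, c(1, 3, 4)])
  list(vertices = mesh$vertices, triangles = tri)
}

#' Write a mesh as Wavefront OBJ (triangulated)
#' @param mesh a [surface_mesh].
#' @param path destination path.
#' @export
write_obj <- function(mesh, path) {
  tr <- triangulate_mesh(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f",
                     tr$vertices[, 1], tr$vertices[, 2], tr$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     tr$triangles[, 1], tr$triangles[, 2], tr$triangles[, 3]), con)
  invisible(path)
}

#' Write a mesh as ASCII PLY (triangulated)
#' @param mesh a [surface_mesh].
#' @param path destination path.
#' @export
write_ply <- function(mesh, path) {
  tr <- triangulate_mesh(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(tr$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(tr$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     tr$vertices[, 1], tr$vertices[, 2], tr$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", tr$triangles[, 1] - 1L,
                     tr$triangles[, 2] - 1L, tr$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Read a binary volume from a multi-page TIFF
#'
#' Pages are z slices; within a page, rows are y and columns are x.
#'
#' @param path TIFF file path.
#' @return a [voxel_volume].
#' @export
read_volume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    t(p > 0)  # -> (x, y)
  })
  vox <- array(FALSE, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- pages[[k]]
  voxel_volume(vox, check = FALSE)
}

#' Write a binary volume as a multi-page TIFF
#' @param volume a [voxel_volume] or logical array.
#' @param path destination path.
#' @export
write_volume <- function(volume, path) {
  vox <- as_voxel_array(volume)
  pages <- lapply(seq_len(dim(vox)[3]), function(k)
    matrix(as.numeric(t(vox[, , k])), nrow = dim(vox)[2]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
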