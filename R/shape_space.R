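# Linear shape spaces over SPHARM descriptors, latent interpolation, and the
# shape-evolution deformation energy.

# Real feature stacking of a descriptor: for each coordinate (x, y, z), for
# l = 0..L and m = 0..l, the pair (Re c_lm, Im c_lm). Coefficients with
# m < 0 are implied by the reality constraint and are not stored.
desc_to_feature <- function(desc) {
  L <- desc$max_order
  idx <- unlist(lapply(0:L, function(l) degree_index(l, 0:l)))
  out <- numeric(0)
  for (j in 1:3) {
    cj <- desc$coefficients[idx, j]
    out <- c(out, as.vector(rbind(Re(cj), Im(cj))))
  }
  out
}

feature_to_desc <- function(v, L) {
  idx <- unlist(lapply(0:L, function(l) degree_index(l, 0:l)))
  per <- 2 * length(idx)
  C <- matrix(0i, (L + 1)^2, 3)
  for (j in 1:3) {
    block <- v[(j - 1) * per + seq_len(per)]
    re <- block[seq(1, per, by = 2)]
    im <- block[seq(2, per, by = 2)]
    C[idx, j] <- complex(real = re, imaginary = im)
  }
  # reality constraint for m < 0
  for (l in seq_len(L)) {
    for (m in 1:l) {
      C[degree_index(l, -m), ] <- (-1)^m * Conj(C[degree_index(l, m), ])
    }
  }
  spharm_descriptor(C, L)
}

#' Fit a PCA shape space over SPHARM descriptors
#'
#' Descriptors are stacked into real feature vectors (interleaved real and
#' imaginary parts of the `m >= 0` coefficients per coordinate; negative
#' orders are implied by the reality constraint) and reduced by PCA. The
#' reported model dimension is `k + 1` (one alignment normalization
#' parameter).
#'
#' @param descriptors list of aligned [spharm_descriptor()] objects with a
#'   common `max_order`.
#' @param k latent dimension.
#' @param n_recon_vertices sphere sampling used when decoding to a mesh.
#' @return object of class `shape_space_model`.
#' @export
fit_descriptor_pca <- function(descriptors, k, n_recon_vertices = 2562L) {
  if (length(descriptors) < 2) stop("need at least 2 descriptors")
  L <- descriptors[[1]]$max_order
  if (!all(vapply(descriptors, function(d) d$max_order, integer(1)) == L))
    stop("descriptors have mixed max_order")
  X <- t(vapply(descriptors, desc_to_feature,
                numeric(length(desc_to_feature(descriptors[[1]])))))
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 0 || k > min(n - 1, ncol(X)))
    stop("k must be between 0 and min(n - 1, feature dim)")
  mu <- colMeans(X)
  sv <- svd(sweep(X, 2, mu), nu = 0, nv = min(n - 1, ncol(X)))
  structure(list(mean = mu, components = fix_component_signs(
                   sv$v[, seq_len(k), drop = FALSE]),
                 k = k, max_order = L,
                 explained_variance = (sv$d^2 / (n - 1))[seq_len(k)],
                 n_recon_vertices = as.integer(n_recon_vertices),
                 n_norm_params = 1L),
            class = "shape_space_model")
}

#' @export
print.shape_space_model <- function(x, ...) {
  cat("<shape_space_model> k =", x$k, " L =", x$max_order,
      " (+", x$n_norm_params, "normalization params )\n")
  invisible(x)
}

#' Embed a descriptor in a shape space
#' @param model a `shape_space_model`.
#' @param descriptor a [spharm_descriptor()] with the model's `max_order`.
#' @return latent vector `z` of length `k`.
#' @export
embed <- function(model, descriptor) {
  stopifnot(inherits(model, "shape_space_model"))
  if (descriptor$max_order != model$max_order)
    stop("descriptor max_order ", descriptor$max_order,
         " does not match model (", model$max_order, ")")
  v <- desc_to_feature(descriptor)
  if (length(v) != length(model$mean)) stop("feature layout mismatch")
  as.vector(crossprod(model$components, v - model$mean))
}

#' Decode a latent point to a SPHARM descriptor
#' @param model a `shape_space_model`.
#' @param z latent vector of length `k`.
#' @return a [spharm_descriptor()].
#' @export
decode_descriptor <- function(model, z) {
  stopifnot(inherits(model, "shape_space_model"))
  if (length(z) != model$k) stop("latent vector length mismatch")
  v <- model$mean + if (model$k > 0) as.vector(model$components %*% z) else 0
  feature_to_desc(v, model$max_order)
}

#' Decode a latent point to a surface mesh
#' @param model a `shape_space_model`.
#' @param z latent vector.
#' @return a triangulated [surface_mesh] from [reconstruct_surface()].
#' @export
decode_shape <- function(model, z) {
  reconstruct_surface(decode_descriptor(model, z), model$n_recon_vertices)
}

# Decoded shape as a point set in the original coordinate space; methods for
# the model classes used by the evolution energy.
decode_points <- function(model, z) UseMethod("decode_points")

#' @export
decode_points.shape_space_model <- function(model, z) {
  decode_shape(model, z)$vertices
}

#' @export
decode_points.outline_pca_model <- function(model, z) {
  pca_decode(model, z)$points
}

#' Linear interpolation path between two latent points
#'
#' Discrete path `x_hat_i = (i * z1 + (N - i) * z2) / N` for `i = 1..N`
#' (so the path starts next to `z2` and ends exactly at `z1`), plus both
#' endpoints for rendering.
#'
#' @param z1,z2 latent vectors of equal length.
#' @param N number of steps (>= 1).
#' @return list with `points` (`N x k` matrix of the `x_hat_i`) and
#'   `rendering` (`(N + 1) x k`: the path ordered from `z1` to `z2`,
#'   appending `z2`).
#' @export
interpolate_path <- function(z1, z2, N) {
  if (length(z1) != length(z2)) stop("latent dimension mismatch")
  N <- as.integer(N)
  if (N < 1) stop("N must be >= 1")
  i <- seq_len(N)
  P <- (outer(i, z1) + outer(N - i, z2)) / N
  list(points = P, rendering = rbind(P[rev(i), , drop = FALSE], z2))
}

#' Shape-evolution energy along the linear latent path
#'
#' Discretized deformation energy of morphing the shape at `z1` into the
#' shape at `z2` along the linear interpolation path:
#' `E = 1/(2N) * sum_i [ D(f(x_hat_i), f(z1)) + D(f(z2), f(x_hat_i)) ]`,
#' with `D` the Hausdorff distance between decoded shapes in the original
#' coordinate space. The normalized energy divides by `D(f(z1), f(z2))`; by
#' the triangle inequality it is always `>= 0.5`, and 0.5 exactly for
#' collinear translation-like families.
#'
#' @param model a `shape_space_model` or `outline_pca_model`.
#' @param z1,z2 latent vectors.
#' @param N number of interpolation steps (default 10).
#' @param eps degenerate-pair guard: error if `D(f(z1), f(z2)) <= eps`.
#' @return object of class `evolution_result` with `path`, `energy`,
#'   `normalized_energy`, `n_steps`, `endpoint_distance`.
#' @export
evolution_energy <- function(model, z1, z2, N = 10L, eps = 1e-6) {
  path <- interpolate_path(z1, z2, N)
  f1 <- decode_points(model, z1)
  f2 <- decode_points(model, z2)
  D <- hausdorff_distance(f1, f2)
  if (D <= eps) stop("source and target decode to (nearly) identical shapes")
  total <- 0
  for (i in seq_len(N)) {
    fi <- decode_points(model, path$points[i, ])
    total <- total + hausdorff_distance(fi, f1) + hausdorff_distance(f2, fi)
  }
  E <- total / (2 * N)
  structure(list(path = path$points, energy = E,
                 normalized_energy = E / D, n_steps = N,
                 endpoint_distance = D),
            class = "evolution_result")
}

#' @export
print.evolution_result <- function(x, ...) {
  cat("<evolution_result> N =", x$n_steps, " energy =", signif(x$energy, 4),
      " normalized =", signif(x$normalized_energy, 4), "\n")
  invisible(x)
}

#' Fit a joint 3D cell + nucleus shape space
#'
#' `"separate"` fits two descriptor PCA models with half the dimensions
#' each; `"joint"` fits one PCA over the concatenated cell + nucleus feature
#' vectors plus the z-scored relative pose (3D nuclear offset and relative
#' Z-angle). Pose features are passed through explicitly for the separate
#' variant.
#'
#' @param cell_descs,nuc_descs equal-length lists of [spharm_descriptor()]
#'   objects.
#' @param rel_pose numeric `n x 4` matrix (dx, dy, dz, dangle) of nuclear
#'   pose relative to the cell.
#' @param total_dims total latent dimensions (even for `"separate"`).
#' @param variant `"separate"` or `"joint"`.
#' @return object of class `joint_shape_space`.
#' @export
fit_joint_3d_model <- function(cell_descs, nuc_descs, rel_pose, total_dims,
                               variant = c("separate", "joint")) {
  variant <- match.arg(variant)
  if (length(cell_descs) != length(nuc_descs)) stop("lists must be paired")
  rel_pose <- as.matrix(rel_pose)
  if (nrow(rel_pose) != length(cell_descs) || ncol(rel_pose) != 4)
    stop("rel_pose must be n x 4 (dx, dy, dz, dangle)")
  if (variant == "separate" && total_dims %% 2 != 0)
    stop("separate variant requires an even total_dims")
  obj <- list(variant = variant, total_dims = as.integer(total_dims),
              L_cell = cell_descs[[1]]$max_order,
              L_nuc = nuc_descs[[1]]$max_order)
  if (variant == "separate") {
    half <- total_dims %/% 2
    obj$cell_model <- fit_descriptor_pca(cell_descs, half)
    obj$nuc_model <- fit_descriptor_pca(nuc_descs, half)
  } else {
    Xc <- t(sapply(cell_descs, desc_to_feature))
    Xn <- t(sapply(nuc_descs, desc_to_feature))
    pm <- colMeans(rel_pose)
    ps <- pmax(apply(rel_pose, 2, stats::sd), 1e-8)
    Z <- cbind(Xc, Xn, sweep(sweep(rel_pose, 2, pm), 2, ps, "/"))
    k <- min(total_dims, nrow(Z) - 1, ncol(Z))
    mu <- colMeans(Z)
    sv <- svd(sweep(Z, 2, mu), nu = 0, nv = k)
    obj$mean <- mu
    obj$components <- fix_component_signs(sv$v)
    obj$k <- k
    obj$len_cell <- ncol(Xc)
    obj$len_nuc <- ncol(Xn)
    obj$pose_center <- pm
    obj$pose_scale <- ps
  }
  obj$n_norm_params <- 1L
  structure(obj, class = "joint_shape_space")
}

#' Encode a 3D cell + nucleus pair
#' @param model a `joint_shape_space`.
#' @param cell_desc,nuc_desc paired descriptors.
#' @param pose length-4 relative pose (dx, dy, dz, dangle).
#' @return latent vector (joint) or list of codes plus pose (separate).
#' @export
joint3d_encode <- function(model, cell_desc, nuc_desc, pose) {
  stopifnot(inherits(model, "joint_shape_space"))
  if (model$variant == "separate") {
    list(cell = embed(model$cell_model, cell_desc),
         nucleus = embed(model$nuc_model, nuc_desc),
         pose = pose)
  } else {
    z <- c(desc_to_feature(cell_desc), desc_to_feature(nuc_desc),
           (pose - model$pose_center) / model$pose_scale)
    as.vector(crossprod(model$components, z - model$mean))
  }
}

#' Decode a 3D cell + nucleus pair
#'
#' Returns both descriptors and, when `as_mesh = TRUE`, both reconstructed
#' meshes with the nucleus posed relative to the cell (offset plus Z
#' rotation).
#'
#' @param model a `joint_shape_space`.
#' @param code output of [joint3d_encode()].
#' @param as_mesh also reconstruct posed meshes.
#' @param n_vertices sphere sampling for reconstruction.
#' @return list with `cell`, `nucleus` (descriptors), `pose`, and optionally
#'   `cell_mesh`, `nucleus_mesh`.
#' @export
joint3d_decode <- function(model, code, as_mesh = FALSE, n_vertices = 642L) {
  stopifnot(inherits(model, "joint_shape_space"))
  if (model$variant == "separate") {
    cd <- decode_descriptor(model$cell_model, code$cell)
    nd <- decode_descriptor(model$nuc_model, code$nucleus)
    pose <- code$pose
  } else {
    z <- model$mean + as.vector(model$components %*% code)
    cd <- feature_to_desc(z[seq_len(model$len_cell)], model$L_cell)
    nd <- feature_to_desc(z[model$len_cell + seq_len(model$len_nuc)], model$L_nuc)
    pose <- z[model$len_cell + model$len_nuc + 1:4] * model$pose_scale +
      model$pose_center
  }
  out <- list(cell = cd, nucleus = nd, pose = pose)
  if (as_mesh) {
    out$cell_mesh <- reconstruct_surface(cd, n_vertices)
    nm <- reconstruct_surface(rotate_descriptor_z(nd, pose[4]), n_vertices)
    nm$vertices <- sweep(nm$vertices, 2, pose[1:3], "+")
    out$nucleus_mesh <- nm
  }
  out
}

#' Serialize a linear shape model to a JSON container
#'
#' Writes the datasets (`mean`, `components`) and metadata attributes (`k`,
#' layout fields, `n_norm_params`, class) of an outline PCA, SCA or
#' descriptor shape-space model.
#'
#' @param model an `outline_pca_model`, `sca_model` or `shape_space_model`.
#' @param path destination `.json` path.
#' @export
write_shape_model <- function(model, path) {
  cls <- class(model)[1]
  payload <- switch(cls,
    outline_pca_model = list(class = cls, mean = model$mean,
      components = model$components, k = model$k, n_points = model$n_points,
      d = model$d, explained_variance = model$explained_variance,
      total_variance = model$total_variance, n_norm_params = model$n_norm_params),
    sca_model = list(class = cls, rotation = model$rotation, r = model$r,
      n_points = model$n_points, eigenvalues = model$eigenvalues,
      n_norm_params = model$n_norm_params),
    shape_space_model = list(class = cls, mean = model$mean,
      components = model$components, k = model$k, max_order = model$max_order,
      explained_variance = model$explained_variance,
      n_recon_vertices = model$n_recon_vertices,
      n_norm_params = model$n_norm_params),
    stop("unsupported model class: ", cls))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model written by [write_shape_model()]
#' @param path `.json` path.
#' @return the restored model object.
#' @export
read_shape_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- p$class
  p$class <- NULL
  fixmat <- function(m) if (is.list(m)) do.call(rbind, m) else as.matrix(m)
  if (cls %in% c("outline_pca_model", "shape_space_model")) {
    p$mean <- as.numeric(p$mean)
    p$components <- fixmat(p$components)
    if (length(p$components) == 0)
      p$components <- matrix(0, length(p$mean), 0)
  }
  if (cls == "sca_model") p$rotation <- fixmat(p$rotation)
  structure(p, class = cls)
}
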