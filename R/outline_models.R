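# Linear 2D generative shape models over outline landmarks: outline PCA,
# shape component analysis (SCA), and joint cell + nucleus variants.

outline_matrix <- function(outlines) {
  n <- outlines[[1]]$n_points
  if (!all(vapply(outlines, function(o) o$n_points, integer(1)) == n))
    stop("outlines have inconsistent n_points")
  t(vapply(outlines, function(o) as.vector(t(o$points)), numeric(2 * n)))
}

# vec layout: the 2 x n coordinate matrix stacked column-wise,
# i.e. (x1, y1, x2, y2, ...); as.vector(t(points)) for n x 2 points.
vec_to_outline <- function(v, n_points) {
  outline_2d(matrix(v, ncol = 2, byrow = TRUE))
}

fix_component_signs <- function(U) {
  if (ncol(U) == 0) return(U)
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

#' Fit an outline PCA model
#'
#' PCA over vectorized, aligned outlines. The model keeps the mean and the
#' top `k` principal directions of the centered data, ordered by explained
#' variance. The reported model dimension for cross-method comparison is
#' `k + n_norm_params`, with one explicit normalization parameter from
#' alignment.
#'
#' @param outlines list of aligned [outline_2d] objects with identical
#'   `n_points`.
#' @param k latent dimension, `0 <= k <= min(n_samples - 1, 2 * n_points)`;
#'   `k = 0` is the degenerate mean-only model.
#' @return object of class `outline_pca_model` with fields `mean`,
#'   `components` (orthonormal columns), `k`, `n_points`, `d`,
#'   `explained_variance`, `n_norm_params`.
#' @export
fit_outline_pca <- function(outlines, k) {
  if (length(outlines) < 2) stop("need at least 2 outlines")
  X <- outline_matrix(outlines)
  n <- length(outlines); nd <- ncol(X)
  k <- as.integer(k)
  if (k < 0 || k > min(n - 1, nd))
    stop("k must be between 0 and min(n_samples - 1, 2 * n_points) = ",
         min(n - 1, nd))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n - 1, nd))
  U <- fix_component_signs(sv$v[, seq_len(k), drop = FALSE])
  ev <- sv$d^2 / (n - 1)
  structure(list(mean = mu, components = U, k = k,
                 n_points = outlines[[1]]$n_points, d = 2L,
                 explained_variance = ev[seq_len(k)],
                 total_variance = sum(ev), n_norm_params = 1L),
            class = "outline_pca_model")
}

#' @export
print.outline_pca_model <- function(x, ...) {
  cat("<outline_pca_model> k =", x$k, " n_points =", x$n_points,
      " (+", x$n_norm_params, "normalization params )\n")
  invisible(x)
}

#' Encode an outline in an outline PCA model
#'
#' `b = U_k' (vec(x) - mu)`.
#'
#' @param model an `outline_pca_model`.
#' @param outline an aligned [outline_2d] matching the model layout.
#' @return numeric latent vector of length `k`.
#' @export
pca_encode <- function(model, outline) {
  stopifnot(inherits(model, "outline_pca_model"))
  if (inherits(outline, "outline_2d")) {
    if (outline$n_points != model$n_points)
      stop("outline layout mismatch: expected n_points = ", model$n_points)
    v <- as.vector(t(outline$points))
  } else {
    v <- as.numeric(outline)
    if (length(v) != length(model$mean)) stop("outline layout mismatch")
  }
  as.vector(crossprod(model$components, v - model$mean))
}

#' Decode a latent vector from an outline PCA model
#'
#' `x_hat = U_k b + mu`, reshaped to landmarks.
#'
#' @param model an `outline_pca_model`.
#' @param b latent vector of length `k`.
#' @return the reconstructed [outline_2d].
#' @export
pca_decode <- function(model, b) {
  stopifnot(inherits(model, "outline_pca_model"))
  if (length(b) != model$k) stop("latent vector has length ", length(b),
                                 "; model expects ", model$k)
  v <- model$mean + if (model$k > 0) as.vector(model$components %*% b) else 0
  vec_to_outline(v, model$n_points)
}

#' Fit a shape component analysis (SCA) model
#'
#' Accumulates `C = sum_j x_j' x_j` over the `d x n` preshape matrices and
#' keeps the first `r` eigenvectors of `C` as the rotation matrix `R`. SCA
#' carries two explicit normalization parameters (alignment and size, the
#' latter because preshapes are size-normalized).
#'
#' @param preshapes list of `preshape` objects (see [to_preshape()]) with a
#'   common landmark count `n`.
#' @param r retained eigenvector count, `1 <= r <= n`.
#' @return object of class `sca_model` with fields `rotation` (`n x r`,
#'   orthonormal columns), `r`, `n_points`, `eigenvalues`, `n_norm_params`.
#' @export
fit_sca <- function(preshapes, r) {
  if (length(preshapes) < 2) stop("need at least 2 preshapes")
  n <- nrow(preshapes[[1]]$points)
  r <- as.integer(r)
  if (r < 1 || r > n) stop("r must be between 1 and n = ", n)
  C <- matrix(0, n, n)
  for (p in preshapes) {
    if (nrow(p$points) != n) stop("preshapes have inconsistent landmark counts")
    C <- C + tcrossprod(p$points)  # x' x with x = t(points) (d x n)
  }
  eg <- eigen(C, symmetric = TRUE)
  R <- fix_component_signs(eg$vectors[, seq_len(r), drop = FALSE])
  structure(list(rotation = R, r = r, n_points = n,
                 eigenvalues = eg$values, n_norm_params = 2L),
            class = "sca_model")
}

#' SCA representation and reconstruction of a preshape
#'
#' The representation is `b_o = x R / ||x R||_F` (unit Frobenius norm) and
#' the reconstruction `x_hat = b_o R'`, both as `d x r` / `d x n` matrices
#' applied to the preshape coordinates. Works for training and unseen
#' preshapes alike (no refitting).
#'
#' @param model an `sca_model`.
#' @param preshape a `preshape` with matching landmark count.
#' @return list with `b` (the `d x r` unit-norm representation) and
#'   `reconstruction` (a `preshape` carrying the input's scale and center).
#' @export
sca_encode_decode <- function(model, preshape) {
  stopifnot(inherits(model, "sca_model"), inherits(preshape, "preshape"))
  if (nrow(preshape$points) != model$n_points)
    stop("preshape has ", nrow(preshape$points), " landmarks; model expects ",
         model$n_points)
  x <- t(preshape$points)               # d x n
  xr <- x %*% model$rotation            # d x r
  nrm <- sqrt(sum(xr^2))
  if (nrm < 1e-12) stop("preshape is orthogonal to the retained SCA space")
  b <- xr / nrm
  xhat <- b %*% t(model$rotation)       # d x n
  rec <- structure(list(points = t(xhat), scale = preshape$scale,
                        center = preshape$center), class = "preshape")
  list(b = b, reconstruction = rec)
}

# Alignment parameters of an outline: centroid, major-axis angle (including
# the skewness flip), and the aligned outline itself.
outline_alignment <- function(outline, iso_tol = 1e-8) {
  p <- outline$points
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  cv <- crossprod(pc) / nrow(pc)
  eg <- eigen(cv, symmetric = TRUE)
  angle <- 0
  if ((eg$values[1] - eg$values[2]) > iso_tol * max(eg$values[1], 1e-300)) {
    v <- eg$vectors[, 1]
    if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
    angle <- atan2(v[2], v[1])
  }
  rot <- rbind(c(cos(angle), sin(angle)), c(-sin(angle), cos(angle)))
  pa <- pc %*% t(rot)
  if (mean(pa[, 1]^3) < 0) {
    pa <- -pa
    angle <- angle + pi
  }
  start <- order(pa[, 1], pa[, 2])[1L]
  if (start != 1L) pa <- pa[c(start:nrow(pa), seq_len(start - 1L)), , drop = FALSE]
  list(center = ctr, angle = angle, aligned = outline_2d(pa))
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# Relative pose of the nucleus with respect to the cell: nuclear centroid
# offset expressed in the cell-aligned frame (2) plus the nuclear major-axis
# angle relative to the cell's (1).
relative_pose_2d <- function(cell_align, nuc_align) {
  off <- nuc_align$center - cell_align$center
  a <- cell_align$angle
  rot <- rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
  off_cf <- as.vector(rot %*% off)
  c(off_cf, wrap_angle(nuc_align$angle - cell_align$angle))
}

#' Fit a joint cell + nucleus outline model
#'
#' Both variants model aligned cell and nuclear outlines and carry the
#' nuclear pose relative to the cell (centroid offset in the cell frame and
#' relative major-axis angle) so pairs can be reconstructed with the proper
#' spatial relationship. `"separate"` splits the latent dimensions half/half
#' between two independent models and passes the pose through explicitly;
#' `"joint"` learns a single PCA over the concatenated cell + nucleus
#' vectors plus the z-scored pose features. `method = "sca"` uses preshapes
#' and the SCA decomposition for the shape blocks (pose always explicit).
#'
#' @param cells,nuclei equal-length lists of paired [outline_2d] objects in
#'   shared image coordinates (unaligned).
#' @param total_dims total latent dimensions (even for `"separate"`).
#' @param variant `"separate"` or `"joint"`.
#' @param method `"pca"` or `"sca"`.
#' @return object of class `joint_outline_model`.
#' @export
fit_joint_outline_model <- function(cells, nuclei, total_dims,
                                    variant = c("separate", "joint"),
                                    method = c("pca", "sca")) {
  variant <- match.arg(variant)
  method <- match.arg(method)
  if (length(cells) != length(nuclei)) stop("cells and nuclei must be paired")
  if (total_dims < 2) stop("total_dims must be >= 2")
  if (variant == "separate" && total_dims %% 2 != 0)
    stop("separate variant requires an even total_dims")
  ca <- lapply(cells, outline_alignment)
  na <- lapply(nuclei, outline_alignment)
  pose <- t(mapply(relative_pose_2d, ca, na))
  cell_out <- lapply(ca, `[[`, "aligned")
  nuc_out <- lapply(na, `[[`, "aligned")
  obj <- list(variant = variant, method = method, total_dims = as.integer(total_dims),
              n_cell = cell_out[[1]]$n_points, n_nuc = nuc_out[[1]]$n_points)
  if (method == "sca") {
    half <- if (variant == "separate") total_dims %/% 2 else total_dims
    if (variant == "separate") {
      obj$cell_model <- fit_sca(lapply(cell_out, to_preshape), half)
      obj$nuc_model <- fit_sca(lapply(nuc_out, to_preshape), half)
    } else {
      # concatenated preshapes: cell and nucleus landmark sets side by side
      cat_pre <- mapply(function(co, no) {
        p <- rbind(to_preshape(co)$points, to_preshape(no)$points)
        structure(list(points = p / sqrt(sum(p^2)), scale = 1,
                       center = c(0, 0)), class = "preshape")
      }, cell_out, nuc_out, SIMPLIFY = FALSE)
      obj$joint_model <- fit_sca(cat_pre, total_dims)
    }
    obj$n_norm_params <- 2L
  } else if (variant == "separate") {
    half <- total_dims %/% 2
    obj$cell_model <- fit_outline_pca(cell_out, half)
    obj$nuc_model <- fit_outline_pca(nuc_out, half)
    obj$n_norm_params <- 1L
  } else {
    pm <- colMeans(pose)
    ps <- pmax(apply(pose, 2, stats::sd), 1e-8)
    Z <- cbind(outline_matrix(cell_out), outline_matrix(nuc_out),
               sweep(sweep(pose, 2, pm), 2, ps, "/"))
    k <- min(total_dims, nrow(Z) - 1, ncol(Z))
    mu <- colMeans(Z)
    sv <- svd(sweep(Z, 2, mu), nu = 0, nv = k)
    obj$mean <- mu
    obj$components <- fix_component_signs(sv$v)
    obj$k <- k
    obj$pose_center <- pm
    obj$pose_scale <- ps
    obj$n_norm_params <- 1L
  }
  structure(obj, class = "joint_outline_model")
}

#' Encode a cell + nucleus pair in a joint outline model
#'
#' @param model a `joint_outline_model`.
#' @param cell,nucleus paired raw [outline_2d] objects.
#' @return for the joint PCA variant a latent vector; otherwise a list with
#'   the per-component codes and the explicit `pose`.
#' @export
joint_encode <- function(model, cell, nucleus) {
  stopifnot(inherits(model, "joint_outline_model"))
  ca <- outline_alignment(cell)
  na <- outline_alignment(nucleus)
  pose <- relative_pose_2d(ca, na)
  if (model$method == "sca") {
    if (model$variant == "separate") {
      list(cell = sca_encode_decode(model$cell_model, to_preshape(ca$aligned))$b,
           nucleus = sca_encode_decode(model$nuc_model, to_preshape(na$aligned))$b,
           pose = pose)
    } else {
      p <- rbind(to_preshape(ca$aligned)$points, to_preshape(na$aligned)$points)
      pre <- structure(list(points = p / sqrt(sum(p^2)), scale = 1,
                            center = c(0, 0)), class = "preshape")
      list(joint = sca_encode_decode(model$joint_model, pre)$b, pose = pose)
    }
  } else if (model$variant == "separate") {
    list(cell = pca_encode(model$cell_model, ca$aligned),
         nucleus = pca_encode(model$nuc_model, na$aligned),
         pose = pose)
  } else {
    z <- c(as.vector(t(ca$aligned$points)), as.vector(t(na$aligned$points)),
           (pose - model$pose_center) / model$pose_scale)
    as.vector(crossprod(model$components, z - model$mean))
  }
}

#' Decode a cell + nucleus pair from a joint outline model
#'
#' Returns both outlines in the cell-aligned frame: the cell at the origin
#' with its major axis along +x, the nucleus placed at the reconstructed
#' relative offset and rotated by the reconstructed relative angle.
#'
#' @param model a `joint_outline_model`.
#' @param code output of [joint_encode()].
#' @return list with `cell`, `nucleus` ([outline_2d] each) and `pose`.
#' @export
joint_decode <- function(model, code) {
  stopifnot(inherits(model, "joint_outline_model"))
  if (model$method == "sca") {
    if (model$variant == "separate") {
      cellp <- t(code$cell %*% t(model$cell_model$rotation))
      nucp <- t(code$nucleus %*% t(model$nuc_model$rotation))
      pose <- code$pose
    } else {
      p <- t(code$joint %*% t(model$joint_model$rotation))
      cellp <- p[seq_len(model$n_cell), , drop = FALSE]
      nucp <- p[model$n_cell + seq_len(model$n_nuc), , drop = FALSE]
      pose <- code$pose
    }
  } else if (model$variant == "separate") {
    cellp <- pca_decode(model$cell_model, code$cell)$points
    nucp <- pca_decode(model$nuc_model, code$nucleus)$points
    pose <- code$pose
  } else {
    z <- model$mean + as.vector(model$components %*% code)
    nc <- 2 * model$n_cell; nn <- 2 * model$n_nuc
    cellp <- matrix(z[seq_len(nc)], ncol = 2, byrow = TRUE)
    nucp <- matrix(z[nc + seq_len(nn)], ncol = 2, byrow = TRUE)
    pose <- z[nc + nn + 1:3] * model$pose_scale + model$pose_center
  }
  a <- pose[3]
  rot <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  nucp <- sweep(nucp %*% t(rot), 2, pose[1:2], "+")
  list(cell = outline_2d(cellp), nucleus = outline_2d(nucp), pose = pose)
}
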