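# Reconstruction-error metrics, joint-error aggregation, and the random-pair
# evolution-energy benchmark.

#' 2D reconstruction error (Hausdorff over outline landmarks)
#'
#' Masks are converted to outline landmarks; outlines are used as-is. The
#' Hausdorff distance between the two landmark sets is returned in pixels.
#'
#' @param original a [mask_image_2d] or [outline_2d].
#' @param reconstructed a [mask_image_2d] or [outline_2d].
#' @param n_points landmarks used when converting masks (default 2000).
#' @return non-negative error in pixels.
#' @export
reconstruction_error_2d <- function(original, reconstructed, n_points = 2000L) {
  to_pts <- function(x) {
    if (inherits(x, "outline_2d")) x$points
    else extract_outline(x, n_points)$points
  }
  hausdorff_distance(to_pts(original), to_pts(reconstructed))
}

#' 3D reconstruction error (Hausdorff over mesh vertices)
#'
#' The original volume is converted to its boundary mesh; the Hausdorff
#' distance between the vertex sets of that mesh and the reconstruction is
#' returned in voxels.
#'
#' @param original a [voxel_volume] (or logical array).
#' @param reconstructed a [surface_mesh].
#' @return non-negative error in voxels.
#' @export
reconstruction_error_3d <- function(original, reconstructed) {
  stopifnot(inherits(reconstructed, "surface_mesh"))
  m <- voxels_to_quad_mesh(original)
  hausdorff_distance(m$vertices, reconstructed$vertices)
}

#' Pixel-level reconstruction error
#'
#' Area of the non-overlapping region between original and reconstructed
#' masks divided by the area of the original.
#'
#' @param original,reconstructed [mask_image_2d] or logical matrices with
#'   identical extents.
#' @return dimensionless fraction (0 for identical masks).
#' @export
pixel_level_error <- function(original, reconstructed) {
  a <- as_mask_pixels(original); b <- as_mask_pixels(reconstructed)
  if (!all(dim(a) == dim(b))) stop("masks must have identical extents")
  na <- sum(a)
  if (na == 0) stop("original mask is empty")
  sum(xor(a, b)) / na
}

#' Joint cell + nucleus error
#'
#' Equal weighting of the two compartments: the average of the mean cell
#' error and the mean nuclear error.
#'
#' @param cell_errors,nuclear_errors nonempty numeric vectors of per-shape
#'   errors (pixels).
#' @return scalar joint error in pixels.
#' @export
joint_error <- function(cell_errors, nuclear_errors) {
  if (!length(cell_errors) || !length(nuclear_errors))
    stop("error lists must be nonempty")
  (mean(cell_errors) + mean(nuclear_errors)) / 2
}

#' Per-dataset error report
#'
#' @param per_shape_errors numeric vector of per-shape errors (pixels).
#' @param method,dataset_id metadata strings.
#' @param latent_dims,n_norm_params model dimension accounting: the reported
#'   total dimension is `latent_dims + n_norm_params`.
#' @return object of class `error_report`.
#' @export
error_report <- function(per_shape_errors, method = "", latent_dims = NA_integer_,
                         n_norm_params = NA_integer_, dataset_id = "") {
  structure(list(per_shape_errors = per_shape_errors,
                 mean_error = mean(per_shape_errors),
                 method = method, latent_dims = latent_dims,
                 n_norm_params = n_norm_params, dataset_id = dataset_id),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("<error_report> ", x$dataset_id, " ", x$method,
      " dims=", x$latent_dims, "+", x$n_norm_params,
      "  mean error = ", signif(x$mean_error, 4), " px (n = ",
      length(x$per_shape_errors), ")\n", sep = "")
  invisible(x)
}

#' Write an error report as TSV plus a JSON summary
#' @param report an [error_report()].
#' @param prefix output path prefix (writes `<prefix>.tsv`, `<prefix>.json`).
#' @export
write_error_report <- function(report, prefix) {
  utils::write.table(
    data.frame(shape = seq_along(report$per_shape_errors),
               error = report$per_shape_errors),
    paste0(prefix, ".tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mean_error = report$mean_error, method = report$method,
         latent_dims = report$latent_dims, n_norm_params = report$n_norm_params,
         dataset_id = report$dataset_id,
         n_shapes = length(report$per_shape_errors)),
    paste0(prefix, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(prefix)
}

#' Random-pair evolution-energy benchmark
#'
#' Samples `n_pairs` distinct index pairs (without replacement, seeded) from
#' an embedded dataset and computes the normalized evolution energy of each
#' linear interpolation path. Degenerate pairs (endpoint Hausdorff distance
#' at most `eps`) are skipped and counted.
#'
#' @param model a `shape_space_model` or `outline_pca_model`.
#' @param embeddings numeric `n x k` matrix of embedded shapes (one row per
#'   shape).
#' @param n_pairs number of pairs to sample (capped at `choose(n, 2)`);
#'   defaults to 2000 for outline (2D) models and 200 for descriptor (3D)
#'   models, a desk-scale version of the published 50000/5000 benchmarks.
#' @param N_steps interpolation steps per pair (default 10).
#' @param seed integer seed.
#' @param eps degenerate-pair threshold in pixels.
#' @return list with `mean`, `energies`, `pairs` (2-column index matrix) and
#'   `n_degenerate`.
#' @export
energy_benchmark <- function(model, embeddings, n_pairs = NULL, N_steps = 10L,
                             seed = 1L, eps = 1e-6) {
  if (is.null(n_pairs))
    n_pairs <- if (inherits(model, "outline_pca_model")) 2000L else 200L
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < 2) stop("need at least 2 embedded shapes")
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  all_pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  n_pairs <- min(n_pairs, nrow(all_pairs))
  pick <- with_local_seed(seed, sample(nrow(all_pairs), n_pairs))
  pairs <- all_pairs[pick, , drop = FALSE]
  energies <- rep(NA_real_, n_pairs)
  degen <- 0L
  for (p in seq_len(n_pairs)) {
    res <- tryCatch(
      evolution_energy(model, embeddings[pairs[p, 1], ],
                       embeddings[pairs[p, 2], ], N = N_steps, eps = eps),
      error = function(e) NULL)
    if (is.null(res)) degen <- degen + 1L
    else energies[p] <- res$normalized_energy
  }
  if (all(is.na(energies))) stop("all sampled pairs are degenerate")
  list(mean = mean(energies, na.rm = TRUE), energies = energies,
       pairs = pairs, n_degenerate = degen)
}
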