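#' Binary 2D mask
#'
#' Light wrapper around a logical matrix holding a single segmented object.
#' Matrices are stored row-major in the sense that `pixels[i, j]` is the pixel
#' with 0-based center coordinate `(x = j - 1, y = i - 1)`; x runs along
#' columns, y along rows (image convention, y down).
#'
#' @param pixels logical or 0/1 matrix.
#' @param check if `TRUE`, verify the mask is nonempty and has exactly one
#'   4/8-connected foreground component (8-connectivity used, matching the
#'   boundary-tracing convention).
#' @return an object of class `mask_image_2d`.
#' @export
mask_image_2d <- function(pixels, check = TRUE) {
  pixels <- matrix(as.logical(pixels), nrow = nrow(pixels))
  if (check) {
    if (!any(pixels)) stop("mask is empty")
    ncomp <- count_components_2d(pixels)
    if (ncomp != 1L)
      stop("mask has ", ncomp, " foreground components; expected exactly 1")
  }
  structure(list(pixels = pixels, pixel_size = 1), class = "mask_image_2d")
}

as_mask_pixels <- function(mask) {
  if (inherits(mask, "mask_image_2d")) mask$pixels
  else matrix(as.logical(mask), nrow = nrow(mask))
}

#' Count 8-connected foreground components of a logical matrix
#' @param pixels logical matrix
#' @return integer component count
#' @keywords internal
count_components_2d <- function(pixels) {
  lab <- label_components_2d(pixels)
  max(lab)
}

# Label 8-connected components by vectorized frontier flood fill.
label_components_2d <- function(pixels) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  lab <- matrix(0L, nr, nc)
  todo <- which(pixels & lab == 0L)
  comp <- 0L
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  while (length(todo)) {
    comp <- comp + 1L
    frontier <- todo[1L]
    lab[frontier] <- comp
    while (length(frontier)) {
      i <- (frontier - 1L) %% nr + 1L
      j <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1]; jj <- j + offs[o, 2]
        ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
        idx <- (jj[ok] - 1L) * nr + ii[ok]
        idx <- idx[pixels[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- comp
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- which(pixels & lab == 0L)
  }
  lab
}

#' Ordered evenly spaced outline of a 2D shape
#'
#' Constructor for outlines: an `n x 2` matrix of `(x, y)` landmark
#' coordinates (0-based pixel centers), ordered along the boundary, closed
#' implicitly (the last point precedes the first).
#'
#' @param points numeric `n x 2` matrix of (x, y) coordinates.
#' @return object of class `outline_2d`.
#' @export
outline_2d <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 3)
  colnames(points) <- c("x", "y")
  structure(list(points = points, n_points = nrow(points)), class = "outline_2d")
}

#' @export
print.outline_2d <- function(x, ...) {
  cat("<outline_2d> ", x$n_points, " landmarks; bbox x [",
      round(min(x$points[, 1]), 2), ", ", round(max(x$points[, 1]), 2),
      "], y [", round(min(x$points[, 2]), 2), ", ",
      round(max(x$points[, 2]), 2), "]\n", sep = "")
  invisible(x)
}

# Moore boundary tracing of the single 8-connected foreground component.
# Returns the closed boundary polygon through pixel centers (0-based (x, y)),
# counterclockwise in image coordinates (y down), starting at the leftmost
# boundary pixel (ties broken by smallest y).
trace_boundary <- function(pixels) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  # pad to avoid border checks
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- pixels
  fg <- which(pad)
  ii <- (fg - 1L) %% (nr + 2L) + 1L
  jj <- (fg - 1L) %/% (nr + 2L) + 1L
  # boundary pixels: any 4-neighbor background
  nrp <- nr + 2L
  is_bg <- function(i, j) !pad[(j - 1L) * nrp + i]
  bnd <- is_bg(ii - 1L, jj) | is_bg(ii + 1L, jj) | is_bg(ii, jj - 1L) | is_bg(ii, jj + 1L)
  bi <- ii[bnd]; bj <- jj[bnd]
  if (!length(bi)) stop("mask has no boundary pixels")
  # leftmost (smallest x = smallest j), tie: smallest y (smallest i)
  ordc <- order(bj, bi)
  si <- bi[ordc[1L]]; sj <- bj[ordc[1L]]
  # Moore neighborhood in clockwise order starting from West, in (di, dj):
  # image coords: x = j, y = i (y down). Clockwise on screen (y down) around
  # the pixel visits W, NW, N, NE, E, SE, S, SW when traversing so that the
  # object stays on the left -> counterclockwise contour in image coords.
  moore <- matrix(c( 0L, -1L,   # W
                    -1L, -1L,   # NW
                    -1L,  0L,   # N
                    -1L,  1L,   # NE
                     0L,  1L,   # E
                     1L,  1L,   # SE
                     1L,  0L,   # S
                     1L, -1L),  # SW
                  ncol = 2L, byrow = TRUE)
  path_i <- integer(0); path_j <- integer(0)
  ci <- si; cj <- sj
  backtrack <- 1L  # entered from the West (nothing to the left of leftmost)
  maxsteps <- 8L * (length(bi) + 8L)
  step <- 0L
  repeat {
    path_i <- c(path_i, ci); path_j <- c(path_j, cj)
    found <- FALSE
    k <- backtrack
    for (t in 0:7) {
      kk <- (k + t - 1L) %% 8L + 1L
      ni <- ci + moore[kk, 1L]; nj <- cj + moore[kk, 2L]
      if (pad[(nj - 1L) * nrp + ni]) {
        # next backtrack: direction of the previous (background) neighbor,
        # i.e. one before kk in the scan order
        backtrack <- (kk - 2L) %% 8L + 1L
        ci <- ni; cj <- nj
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    step <- step + 1L
    if (step > maxsteps) stop("boundary tracing failed to terminate")
    if (ci == si && cj == sj) break
  }
  # convert to 0-based (x, y): x = j - 1 - 1 (padding), y = i - 2
  cbind(x = path_j - 2L, y = path_i - 2L)
}

#' Extract an evenly spaced outline from a binary mask
#'
#' Traces the boundary of the single foreground object through boundary-pixel
#' centers (8-connected foreground) starting at the leftmost boundary pixel
#' (ties broken by smallest y), then places `n_points` landmarks equally
#' spaced in arc length along the closed sub-pixel polygon. Winding is
#' counterclockwise in image coordinates (y down) for every shape.
#'
#' @param mask a [mask_image_2d], or a logical/0-1 matrix.
#' @param n_points number of landmarks (>= 3).
#' @return an [outline_2d] with `n_points` landmarks.
#' @export
extract_outline <- function(mask, n_points = 2000L) {
  pixels <- as_mask_pixels(mask)
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("n_points must be >= 3")
  if (!any(pixels)) stop("mask is empty")
  ncomp <- count_components_2d(pixels)
  if (ncomp != 1L)
    stop("mask has ", ncomp, " foreground components; expected exactly 1")
  if (sum(pixels) < 4L) stop("foreground must contain at least 4 pixels")
  poly <- trace_boundary(pixels)
  if (nrow(poly) < 3L) stop("degenerate boundary (fewer than 3 vertices)")
  # enforce counterclockwise winding in image coords (y down): shoelace area
  # computed in (x, y) with y down is negative for screen-CCW; flip so the
  # signed area convention is consistent for all shapes.
  xs <- poly[, 1]; ys <- poly[, 2]
  a2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
  if (a2 > 0) {
    poly <- poly[c(1L, rev(seq_len(nrow(poly))[-1L])), , drop = FALSE]
  }
  resample_closed_polygon(poly, n_points)
}

# Equal-arc-length resampling of a closed polygon (first vertex kept).
resample_closed_polygon <- function(poly, n_points) {
  poly <- as.matrix(poly)
  # drop duplicate consecutive vertices
  d <- sqrt(rowSums((poly - poly[c(nrow(poly), seq_len(nrow(poly) - 1L)), ])^2))
  keep <- d > 0 | seq_len(nrow(poly)) == 1L
  poly <- poly[keep, , drop = FALSE]
  n <- nrow(poly)
  seg <- poly[c(2:n, 1L), , drop = FALSE] - poly
  seglen <- sqrt(rowSums(seg^2))
  per <- sum(seglen)
  if (per <= 0) stop("degenerate boundary with zero perimeter")
  cum <- c(0, cumsum(seglen))          # length n + 1, cum[n+1] = perimeter
  target <- per * (seq_len(n_points) - 1L) / n_points
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx[idx > n] <- n
  frac <- (target - cum[idx]) / seglen[idx]
  frac[!is.finite(frac)] <- 0
  pts <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  colnames(pts) <- c("x", "y")
  outline_2d(pts)
}

#' Align an outline by centroid and major axis
#'
#' Centers the landmarks at the origin, rotates the second-moment major axis
#' onto +x, resolves the 180-degree ambiguity so the third central moment of
#' the x-coordinates (x-skewness) is non-negative, and re-anchors the landmark
#' ordering at the leftmost point of the rotated outline (ties by smallest y).
#' Nearly isotropic outlines (principal second moments equal to within
#' `iso_tol` relative) are centered but not rotated.
#'
#' @param outline an [outline_2d].
#' @param iso_tol relative eigenvalue gap below which the outline is treated
#'   as isotropic and left unrotated.
#' @return the aligned [outline_2d].
#' @export
align_outline <- function(outline, iso_tol = 1e-8) {
  stopifnot(inherits(outline, "outline_2d"))
  p <- outline$points
  ctr <- colMeans(p)
  p <- sweep(p, 2, ctr)
  if (max(abs(p)) < 1e-12) stop("degenerate outline: all points identical")
  cv <- crossprod(p) / nrow(p)
  eg <- eigen(cv, symmetric = TRUE)
  if ((eg$values[1] - eg$values[2]) > iso_tol * max(eg$values[1], 1e-300)) {
    v <- eg$vectors[, 1]
    if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
    rot <- rbind(c(v[1], v[2]), c(-v[2], v[1]))  # maps v -> (1, 0)
    p <- p %*% t(rot)
  }
  # flip rule: x-skewness (third central moment of x) must be non-negative
  if (mean(p[, 1]^3) < 0) p <- -p
  # re-anchor at leftmost point (tie: smallest y), preserving winding
  start <- order(p[, 1], p[, 2])[1L]
  if (start != 1L) p <- p[c(start:nrow(p), seq_len(start - 1L)), , drop = FALSE]
  outline_2d(p)
}

#' Convert an outline to a preshape
#'
#' Removes location (centroid) and scale (Frobenius norm of the centered
#' coordinate matrix); the removed parameters are retained so the original
#' coordinates can be restored exactly.
#'
#' @param outline an [outline_2d].
#' @return object of class `preshape` with fields `points` (n x 2, centroid 0,
#'   unit Frobenius norm), `scale`, `center`.
#' @export
to_preshape <- function(outline) {
  stopifnot(inherits(outline, "outline_2d"))
  p <- outline$points
  ctr <- colMeans(p)
  p <- sweep(p, 2, ctr)
  s <- sqrt(sum(p^2))
  if (s == 0) stop("zero-norm outline cannot be converted to a preshape")
  structure(list(points = p / s, scale = s, center = ctr), class = "preshape")
}

#' Restore original coordinates from a preshape
#' @param preshape a `preshape` from [to_preshape()].
#' @return an [outline_2d] with the stored scale and center reapplied.
#' @export
from_preshape <- function(preshape) {
  stopifnot(inherits(preshape, "preshape"))
  outline_2d(sweep(preshape$points * preshape$scale, 2, preshape$center, "+"))
}

#' Hausdorff distance between two point sets
#'
#' The worst-match metric: the maximum over both directions of the maximal
#' nearest-neighbor Euclidean distance. Symmetric; zero iff the sets are
#' equal as sets. Works for 2D or 3D point sets; computation is blocked so
#' large sets never materialize a full distance matrix.
#'
#' @param a,b numeric matrices with one point per row and matching column
#'   count (2 or 3).
#' @return non-negative scalar distance in the input units (pixels/voxels).
#' @export
hausdorff_distance <- function(a, b) {
  a <- as_point_matrix(a); b <- as_point_matrix(b)
  if (ncol(a) != ncol(b)) stop("point sets have different spatial dimensions")
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

as_point_matrix <- function(x) {
  if (inherits(x, "outline_2d")) x <- x$points
  if (inherits(x, "preshape")) x <- x$points
  if (inherits(x, "surface_mesh")) x <- x$vertices
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) == 0) stop("point set must be a nonempty numeric matrix")
  x
}

directed_hausdorff <- function(a, b, block = 1024L) {
  nb2 <- rowSums(b^2)
  worst <- 0
  n <- nrow(a)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    ab <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ab^2), nb2, "+") - 2 * tcrossprod(ab, b)
    # recompute the argmin pairs exactly: the expanded form above loses
    # precision by cancellation when points (nearly) coincide
    jmin <- max.col(-d2, ties.method = "first")
    exact <- rowSums((ab - b[jmin, , drop = FALSE])^2)
    worst <- max(worst, max(exact))
  }
  sqrt(max(worst, 0))
}

#' Read a binary mask from a PNG or single-page TIFF file
#'
#' Any nonzero pixel (first channel for multi-channel images) is foreground.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return a [mask_image_2d].
#' @export
read_mask_2d <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask_image_2d(img > 0)
}

#' Write a binary mask to PNG or TIFF
#' @param mask a [mask_image_2d] or logical matrix.
#' @param path destination path (.png/.tif/.tiff).
#' @export
write_mask_2d <- function(mask, path) {
  pixels <- as_mask_pixels(mask)
  img <- matrix(as.numeric(pixels), nrow = nrow(pixels))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported mask format: ", ext))
  invisible(path)
}

#' Write an outline as two-column delimited text
#'
#' Format: a comment header `# n_points = N` followed by one `x<TAB>y` row
#' per landmark.
#'
#' @param outline an [outline_2d].
#' @param path destination path.
#' @export
write_outline <- function(outline, path) {
  stopifnot(inherits(outline, "outline_2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_points = %d", outline$n_points), con)
  utils::write.table(outline$points, con, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an outline written by [write_outline()]
#' @param path file path.
#' @return an [outline_2d].
#' @export
read_outline <- function(path) {
  pts <- utils::read.table(path, comment.char = "#", sep = "\t")
  outline_2d(as.matrix(pts))
}
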