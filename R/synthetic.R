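# Seeded synthetic shape generators: smooth roundish cells/nuclei and
# neuron-like cells ("SNL") with long thin neurites, in 2D and extruded 3D.
# Every generated shape is deterministic given (params, seed) and one RNG
# stream is derived per shape so batches are order-independent.

#' Parameters of the neuron-like cell generator
#'
#' The soma is a radially Fourier-perturbed disk; neurites are curved thick
#' strokes (quadratic Bezier) attached at soma boundary angles separated by
#' at least 60 degrees. All lengths in pixels.
#'
#' @param soma_radius_range soma radius sampling range (default `c(20, 40)`).
#' @param n_neurites integer neurite count, or a range sampled uniformly
#'   (3D default `c(0, 2)`; 2D default fixed 2).
#' @param neurite_length_range stroke length range (default `c(60, 150)`).
#' @param neurite_width_range stroke width range (default `c(3, 7)`).
#' @param boundary_roughness total relative amplitude of the 5 random-phase
#'   Fourier boundary modes, orders 2-8 (default 0.08).
#' @param image_size 2D extent (default `c(256, 256)`).
#' @param seed integer master seed.
#' @return list of class `snl_params`.
#' @export
snl_params <- function(soma_radius_range = c(20, 40), n_neurites = 2L,
                       neurite_length_range = c(60, 150),
                       neurite_width_range = c(3, 7),
                       boundary_roughness = 0.08,
                       image_size = c(256L, 256L), seed = 1L) {
  stopifnot(all(soma_radius_range > 0), all(neurite_length_range > 0),
            all(neurite_width_range > 0), boundary_roughness >= 0,
            all(image_size >= 32))
  structure(list(soma_radius_range = soma_radius_range,
                 n_neurites = n_neurites,
                 neurite_length_range = neurite_length_range,
                 neurite_width_range = neurite_width_range,
                 boundary_roughness = boundary_roughness,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)), class = "snl_params")
}

# Derive a per-shape RNG substream seed below 2^31 from (master, index).
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807 + 12345) %%
               2147483647)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Soma radial profile: rho(alpha) = R * (1 + sum of 5 random-phase Fourier
# modes with orders sampled from 2..8, total amplitude <= roughness).
sample_soma_profile <- function(R, roughness) {
  orders <- sample(2:8, 5)
  amps <- stats::runif(5)
  amps <- amps / sum(amps) * stats::runif(1, 0.5, 1) * roughness
  phases <- stats::runif(5, 0, 2 * pi)
  function(alpha) {
    pert <- rep(0, length(alpha))
    for (q in 1:5) pert <- pert + amps[q] * cos(orders[q] * alpha + phases[q])
    R * pmax(1 + pert, 0.2)
  }
}

# Rasterize pixels inside a radial profile around center (0-based coords).
rasterize_radial <- function(profile, center, size) {
  x <- matrix(rep(0:(size[1] - 1), size[2]), nrow = size[1]) - center[1]
  y <- matrix(rep(0:(size[2] - 1), each = size[1]), nrow = size[1]) - center[2]
  r <- sqrt(x^2 + y^2)
  a <- atan2(y, x)
  r <= profile(a)
}

# Pixels within width/2 of a quadratic Bezier stroke.
rasterize_stroke <- function(p0, p1, p2, width, size) {
  t <- seq(0, 1, length.out = 160)
  bez <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  margin <- 2
  bez[, 1] <- pmin(pmax(bez[, 1], margin), size[1] - 1 - margin)
  bez[, 2] <- pmin(pmax(bez[, 2], margin), size[2] - 1 - margin)
  half <- width / 2
  lo <- floor(apply(bez, 2, min) - half) - 1
  hi <- ceiling(apply(bez, 2, max) + half) + 1
  xs <- max(0, lo[1]):min(size[1] - 1, hi[1])
  ys <- max(0, lo[2]):min(size[2] - 1, hi[2])
  out <- matrix(FALSE, size[1], size[2])
  if (!length(xs) || !length(ys)) return(out)
  gx <- matrix(rep(xs, length(ys)), nrow = length(xs))
  gy <- matrix(rep(ys, each = length(xs)), nrow = length(xs))
  d2 <- matrix(Inf, length(xs), length(ys))
  for (s in seq_len(nrow(bez))) {
    d2 <- pmin(d2, (gx - bez[s, 1])^2 + (gy - bez[s, 2])^2)
  }
  out[cbind(rep(xs, length(ys)) + 1L, rep(ys, each = length(xs)) + 1L)] <-
    as.vector(d2) <= half^2
  out
}

# Internal: generate the SNL-2D soma and neurite masks separately.
snl_2d_parts <- function(params, index = 0L) {
  with_local_seed(derive_seed(params$seed, index), {
    size <- params$image_size
    center <- (size - 1) / 2
    R <- stats::runif(1, params$soma_radius_range[1], params$soma_radius_range[2])
    profile <- sample_soma_profile(R, params$boundary_roughness)
    soma <- rasterize_radial(profile, center, size)
    nn <- params$n_neurites
    if (length(nn) == 2L) nn <- sample(nn[1]:nn[2], 1)
    nn <- as.integer(nn)
    neur <- matrix(FALSE, size[1], size[2])
    if (nn > 0) {
      # attachment angles separated by >= 60 degrees
      for (try in 1:50) {
        ang <- sort(stats::runif(nn, 0, 2 * pi))
        gaps <- if (nn > 1) c(diff(ang), 2 * pi - (ang[nn] - ang[1])) else 2 * pi
        if (all(gaps >= pi / 3)) break
        if (try == 50) stop("neurite placement failed after retries")
      }
      for (j in seq_len(nn)) {
        a <- ang[j]
        dirv <- c(cos(a), sin(a))
        len <- stats::runif(1, params$neurite_length_range[1],
                            params$neurite_length_range[2])
        wid <- stats::runif(1, params$neurite_width_range[1],
                            params$neurite_width_range[2])
        start <- center + 0.85 * profile(a) * dirv
        bend <- stats::runif(1, -pi / 5, pi / 5)
        endd <- c(cos(a + bend), sin(a + bend))
        p2 <- start + len * endd
        lat <- c(-dirv[2], dirv[1]) * stats::runif(1, -0.25, 0.25) * len
        p1 <- start + 0.5 * len * dirv + lat
        neur <- neur | rasterize_stroke(start, p1, p2, wid, size)
      }
    }
    list(soma = soma, neurites = neur, n_neurites = nn, center = center)
  })
}

#' Generate a neuron-like 2D cell mask
#'
#' Soma (Fourier-perturbed disk) plus curved thick neurites, deterministic
#' given `(params, index)`; `index` selects the shape's substream of the
#' master seed so batches are order-independent.
#'
#' @param params an [snl_params()].
#' @param index shape index within the batch (default 0).
#' @return a [mask_image_2d].
#' @export
generate_snl_2d <- function(params = snl_params(), index = 0L) {
  parts <- snl_2d_parts(params, index)
  mask_image_2d(parts$soma | parts$neurites)
}

#' Generate a neuron-like 3D cell volume
#'
#' The central slice comes from the 2D generator; slices above and below are
#' copies of the soma scaled about its centroid following a semicircular
#' taper profile over the occupied slab (12 central slices by default), so
#' the solid is genus-0 by construction. Neurites are retained only within
#' the central third of the occupied slab (thin structures are quasi-2D).
#' Tapered slices that would vanish are clamped to a minimal disk.
#'
#' @param params an [snl_params()]; `image_size` gives the XY extent.
#' @param index shape index within the batch.
#' @param n_slices z extent of the volume (default 24).
#' @param slab_slices number of occupied slices (default 12, centered).
#' @return a [voxel_volume] of extent `image_size x n_slices`.
#' @export
generate_snl_3d <- function(params = snl_params(n_neurites = c(0L, 2L)),
                            index = 0L, n_slices = 24L, slab_slices = 12L) {
  if (n_slices < 3) stop("n_slices must be >= 3")
  parts <- snl_2d_parts(params, index)
  size <- params$image_size
  vox <- array(FALSE, c(size[1], size[2], n_slices))
  kc <- floor(n_slices / 2)          # 0-based central slice
  half <- slab_slices / 2
  # scale about the soma profile center so tapered slices nest (the soma is
  # star-shaped about this point), keeping the solid genus-0
  cen <- parts$center
  for (k in 0:(n_slices - 1)) {
    dz <- k - kc
    if (abs(dz) > half) next
    s <- sqrt(max(1 - (dz / (half + 0.5))^2, 0))
    if (s <= 0) next
    slice <- scale_mask_about(parts$soma, cen, s)
    if (!any(slice)) {
      slice <- matrix(FALSE, size[1], size[2])
      cx <- round(cen[1]) + 1L; cy <- round(cen[2]) + 1L
      slice[cx + c(0L, 1L), cy + c(0L, 1L)] <- TRUE
    }
    if (abs(dz) <= slab_slices / 6) slice <- slice | parts$neurites
    vox[, , k + 1L] <- slice
  }
  voxel_volume(vox)
}

# Nearest-neighbor rescaling of a mask about a fixed 0-based center point.
scale_mask_about <- function(mask, center, s) {
  nr <- nrow(mask); nc <- ncol(mask)
  x <- (0:(nr - 1) - center[1]) / s + center[1]
  y <- (0:(nc - 1) - center[2]) / s + center[2]
  xi <- round(x) + 1L; yi <- round(y) + 1L
  okx <- xi >= 1L & xi <= nr; oky <- yi >= 1L & yi <= nc
  out <- matrix(FALSE, nr, nc)
  out[okx, oky] <- mask[xi[okx], yi[oky]]
  out
}

#' Generate a smooth blob-like 3D volume
#'
#' Voxelized ellipsoid with a smooth low-order spherical-harmonic radial
#' perturbation; star-shaped about its center, hence genus-0 by
#' construction. A smooth stand-in for round adherent cells.
#'
#' @param size base semi-axis in voxels (y and z; x semi-axis is
#'   `size * elongation`).
#' @param elongation x-axis stretch factor (default 1.5).
#' @param roughness relative amplitude of the degree-2 radial perturbation
#'   (default 0.1; keep below ~0.3 for star-shapedness).
#' @param seed integer seed.
#' @param extent integer 3-vector of volume dims (default fits the blob).
#' @param z_aspect z semi-axis as a fraction of `size` (default 0.5,
#'   emulating flat adherent cells).
#' @return a [voxel_volume].
#' @export
generate_blob_3d <- function(size = 16, elongation = 1.5, roughness = 0.1,
                             seed = 1L, extent = NULL, z_aspect = 0.5) {
  with_local_seed(seed, {
    a <- size * elongation; b <- size; cc <- size * z_aspect
    if (is.null(extent))
      extent <- c(ceiling(2.9 * a) + 4, ceiling(2.9 * b) + 4,
                  ceiling(2.9 * cc) + 4)
    extent <- as.integer(extent)
    cen <- (extent - 1) / 2
    coef <- stats::rnorm(5, 0, roughness / 2)
    xg <- (0:(extent[1] - 1) - cen[1]) / a
    yg <- (0:(extent[2] - 1) - cen[2]) / b
    zg <- (0:(extent[3] - 1) - cen[3]) / cc
    X <- array(rep(xg, times = extent[2] * extent[3]), extent)
    Y <- array(rep(rep(yg, each = extent[1]), times = extent[3]), extent)
    Z <- array(rep(zg, each = extent[1] * extent[2]), extent)
    r <- sqrt(X^2 + Y^2 + Z^2)
    r[r == 0] <- 1e-9
    ux <- X / r; uy <- Y / r; uz <- Z / r
    # real degree-2 harmonics (unnormalized shapes suffice for perturbation)
    pert <- coef[1] * (3 * uz^2 - 1) / 2 + coef[2] * (ux * uz) +
      coef[3] * (uy * uz) + coef[4] * (ux^2 - uy^2) + coef[5] * (ux * uy)
    vox <- r <= (1 + pert)
    voxel_volume(vox)
  })
}

#' Generate a paired cell and nucleus 2D mask
#'
#' The cell is a smooth Fourier-perturbed blob; the nucleus a smaller
#' ellipse placed strictly inside it at a configurable offset distribution.
#'
#' @param seed integer seed.
#' @param image_size 2D extent (default `c(160, 160)`).
#' @param cell_radius,nucleus_radius base radii in pixels.
#' @param offset_mean,offset_sd mean and s.d. of the nuclear centroid offset
#'   (x, y) from the cell centroid, in pixels.
#' @param roughness cell boundary perturbation amplitude.
#' @param index shape index within the batch.
#' @return list with `cell` and `nucleus` ([mask_image_2d] each).
#' @export
generate_cell_nucleus_pair_2d <- function(seed = 1L, image_size = c(160L, 160L),
                                          cell_radius = 45, nucleus_radius = 18,
                                          offset_mean = c(6, 0), offset_sd = 3,
                                          roughness = 0.06, index = 0L) {
  with_local_seed(derive_seed(seed, index), {
    size <- as.integer(image_size)
    center <- (size - 1) / 2
    profile <- sample_soma_profile(cell_radius, roughness)
    cell <- rasterize_radial(profile, center, size)
    for (try in 1:60) {
      off <- stats::rnorm(2, offset_mean, offset_sd)
      ang <- stats::runif(1, 0, pi)
      ecc <- stats::runif(1, 1.2, 1.6)
      ncen <- center + off
      x <- matrix(rep(0:(size[1] - 1), size[2]), nrow = size[1]) - ncen[1]
      y <- matrix(rep(0:(size[2] - 1), each = size[1]), nrow = size[1]) - ncen[2]
      xr <- x * cos(ang) + y * sin(ang)
      yr <- -x * sin(ang) + y * cos(ang)
      nuc <- (xr / (nucleus_radius * ecc))^2 + (yr / nucleus_radius)^2 <= 1
      # strict containment with a 2 px margin
      grown <- nuc
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1),
                     c(1, -1), c(-1, 1), c(-1, -1))) {
        sh <- matrix(FALSE, size[1], size[2])
        xs <- seq_len(size[1]); ys <- seq_len(size[2])
        xd <- xs + d[1]; yd <- ys + d[2]
        okx <- xd >= 1 & xd <= size[1]; oky <- yd >= 1 & yd <= size[2]
        sh[xs[okx], ys[oky]] <- nuc[xd[okx], yd[oky]]
        grown <- grown | sh
      }
      grown2 <- grown
      if (all(cell[grown2])) {
        return(list(cell = mask_image_2d(cell), nucleus = mask_image_2d(nuc)))
      }
    }
    stop("nucleus containment failed after retries")
  })
}
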