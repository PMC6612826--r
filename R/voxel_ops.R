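# Vectorized binary 3D array operations: shifts, ball morphology, flood fill.
# Arrays are logical with dims (x, y, z); z is the slice axis.

# Shift a logical array by integer offset (dx, dy, dz), filling with FALSE.
shift3 <- function(x, off) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { dst[[a]] <- seq_len(d[a] - o) + o; src[[a]] <- seq_len(d[a] - o) }
    else        { dst[[a]] <- seq_len(d[a] + o);     src[[a]] <- seq_len(d[a] + o) - o }
    if (length(dst[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

ball_offsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dx = s, dy = s, dz = s)
  g <- g[g$dx^2 + g$dy^2 + g$dz^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

dilate3 <- function(x, offs) {
  out <- array(FALSE, dim(x))
  for (o in seq_len(nrow(offs))) out <- out | shift3(x, offs[o, ])
  out
}

erode3 <- function(x, offs) {
  out <- array(TRUE, dim(x))
  for (o in seq_len(nrow(offs))) out <- out & shift3(x, offs[o, ])
  out
}

# Morphological closing with a discrete ball of radius r; the volume is
# padded so dilation is not clipped at the array border.
close3_ball <- function(x, r) {
  if (r <= 0) return(x)
  offs <- ball_offsets(r)
  d <- dim(x)
  p <- r + 1L
  pad <- array(FALSE, d + 2L * p)
  pad[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- x
  pad <- erode3(dilate3(pad, offs), offs)
  pad[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])]
}

# Frontier flood fill over a logical domain from seed indices.
# connectivity: 6 or 26. Returns logical array of reached voxels.
flood3 <- function(domain, seeds, connectivity = 6L) {
  d <- dim(domain)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  offs <- if (connectivity == 6L) {
    matrix(c(1,0,0, -1,0,0, 0,1,0, 0,-1,0, 0,0,1, 0,0,-1), ncol = 3, byrow = TRUE)
  } else {
    o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    o[rowSums(abs(o)) > 0, , drop = FALSE]
  }
  reached <- array(FALSE, d)
  seeds <- seeds[domain[seeds] & !reached[seeds]]
  reached[seeds] <- TRUE
  frontier <- seeds
  nxy <- nx * ny
  while (length(frontier)) {
    i0 <- (frontier - 1L)
    xi <- i0 %% nx; yi <- (i0 %/% nx) %% ny; zi <- i0 %/% nxy
    nxt <- integer(0)
    for (o in seq_len(nrow(offs))) {
      xx <- xi + offs[o, 1]; yy <- yi + offs[o, 2]; zz <- zi + offs[o, 3]
      ok <- xx >= 0L & xx < nx & yy >= 0L & yy < ny & zz >= 0L & zz < nz
      idx <- xx[ok] + yy[ok] * nx + zz[ok] * nxy + 1L
      idx <- idx[domain[idx] & !reached[idx]]
      if (length(idx)) {
        reached[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  reached
}

# Count foreground connected components (6-connected by default).
count_components_3d <- function(x, connectivity = 6L) {
  remaining <- x
  comp <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    seed <- which(remaining)[1L]
    remaining <- remaining & !flood3(remaining, seed, connectivity)
  }
  comp
}

# Fill interior cavities: background voxels not 26-connected to the array
# border become foreground (26-connected background pairs with 6-connected
# foreground).
fill_holes_3d <- function(x) {
  d <- dim(x)
  bg <- !x
  border <- array(FALSE, d)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  border[, , c(1L, d[3])] <- TRUE
  seeds <- which(bg & border)
  if (!length(seeds)) return(array(TRUE, d))
  outside <- flood3(bg, seeds, connectivity = 26L)
  x | (bg & !outside)
}
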