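# Internal voxel-array helpers. Volumes are plain 3D arrays indexed [x, y, z].

# Translate a 3D array by integer offsets, filling vacated voxels.
shift_volume <- function(a, offset, fill = 0) {
  stopifnot(length(dim(a)) == 3L, length(offset) == 3L)
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- as.integer(offset[ax])
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- (1L + o):d[ax]; src[[ax]] <- 1L:(d[ax] - o)
    } else {
      dst[[ax]] <- 1L:(d[ax] + o); src[[ax]] <- (1L - o):d[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# One step of binary dilation (6- or 26-connectivity) by array shifts.
dilate_step <- function(mask, connectivity = 26L) {
  out <- mask
  offs <- if (connectivity == 6L) {
    list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    o <- o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ]
    lapply(seq_len(nrow(o)), function(i) as.numeric(o[i, ]))
  }
  for (off in offs) out <- out | shift_volume(mask, off, FALSE)
  out
}

erode_step <- function(mask, connectivity = 26L) {
  !dilate_step(!mask, connectivity)
}

binary_close <- function(mask, radius = 1L, connectivity = 6L) {
  m <- mask
  for (i in seq_len(radius)) m <- dilate_step(m, connectivity)
  for (i in seq_len(radius)) m <- erode_step(m, connectivity)
  m
}

# Min-max scale to [0, 1]; a constant volume maps to all zeros.
minmax_scale <- function(a) {
  rng <- range(a)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(a)))
  (a - rng[1]) / (rng[2] - rng[1])
}

# Gradient magnitude by central differences (one-sided at the borders).
gradient_magnitude <- function(a) {
  d <- dim(a)
  g2 <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 2) next
    off <- c(0, 0, 0); off[ax] <- 1
    fwd <- shift_volume(a, -off, NA)   # value at i+1
    bwd <- shift_volume(a, off, NA)    # value at i-1
    grad <- (fwd - bwd) / 2
    grad[is.na(fwd) & !is.na(bwd)] <- (a - bwd)[is.na(fwd) & !is.na(bwd)]
    grad[is.na(bwd) & !is.na(fwd)] <- (fwd - a)[is.na(bwd) & !is.na(fwd)]
    grad[is.na(grad)] <- 0
    g2 <- g2 + grad^2
  }
  sqrt(g2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
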