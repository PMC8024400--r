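# Volume utilities: plain R arrays stand in for NIfTI volumes; dimensions
# are padded to 3-D so vectors and slices work through the same code paths.

# Coerce to a 3-D array (pad trailing dims with 1).
as_volume <- function(x) {
  x <- as.array(x)
  d <- dim(x)
  if (length(d) > 3) stop("volumes must have at most 3 dimensions")
  dim(x) <- c(d, rep(1L, 3 - length(d)))
  x
}

# Neighbour offsets for 6/18/26-connectivity in 3-D.
neighbour_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  ord <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(off)))
  as.matrix(off[keep, ])
}

# Linear indices of in-bounds neighbours of linear index `v` in a volume of
# dim `d`, given precomputed offset matrix.
neighbours_of <- function(v, d, off) {
  k <- (v - 1L) %/% (d[1] * d[2])
  rem <- (v - 1L) %% (d[1] * d[2])
  j <- rem %/% d[1]
  i <- rem %% d[1]
  ni <- i + off[, 1]; nj <- j + off[, 2]; nk <- k + off[, 3]
  ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
  (ni + nj * d[1] + nk * d[1] * d[2])[ok] + 1L
}

# Connected-component labelling of a logical volume. Returns an integer
# volume (0 = background); components numbered by first-encountered voxel
# (ascending linear index), so labelling is deterministic.
label_components <- function(mask, connectivity = 26) {
  mask <- as_volume(mask)
  d <- dim(mask)
  off <- neighbour_offsets(connectivity)
  labels <- array(0L, d)
  nxt <- 0L
  for (v in which(mask)) {
    if (labels[v] != 0L) next
    nxt <- nxt + 1L
    queue <- v
    labels[v] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nb <- neighbours_of(cur, d, off)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      if (length(nb)) {
        labels[nb] <- nxt
        queue <- c(queue, nb)
      }
    }
  }
  labels
}

# Separable 3-D Gaussian smoothing (FWHM in voxel units); zero-padded edges
# with kernel renormalisation inside the volume.
gaussian_smooth <- function(vol, fwhm) {
  vol <- as_volume(vol)
  if (fwhm <= 0) return(vol)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    if (d[axis] == 1) return(a)
    out <- array(0, d)
    wt <- array(0, d)
    for (s in -r:r) {
      w <- k[s + r + 1]
      valid <- seq_len(d[axis]) + s
      ok <- valid >= 1 & valid <= d[axis]
      idx_to <- seq_len(d[axis])[ok]
      idx_from <- valid[ok]
      if (axis == 1) {
        out[idx_to, , ] <- out[idx_to, , ] + w * a[idx_from, , ]
        wt[idx_to, , ] <- wt[idx_to, , ] + w
      } else if (axis == 2) {
        out[, idx_to, ] <- out[, idx_to, ] + w * a[, idx_from, ]
        wt[, idx_to, ] <- wt[, idx_to, ] + w
      } else {
        out[, , idx_to] <- out[, , idx_to] + w * a[, , idx_from]
        wt[, , idx_to] <- wt[, , idx_to] + w
      }
    }
    out / wt
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}
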