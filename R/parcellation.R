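#' Watershed parcellation of a statistical map
#'
#' Floods the (optionally smoothed) statistic restricted to the
#' suprathreshold mask from its local maxima: voxels are visited in
#' decreasing statistic order (plateau ties broken by ascending linear
#' voxel index, so labelling is fully deterministic); a voxel with no
#' labelled neighbour seeds a new ROI, otherwise it joins the labelled
#' neighbour with the highest statistic (ties to the lowest label). ROIs
#' smaller than `min_size` are merged into the neighbouring ROI with the
#' highest shared-boundary statistic, or discarded if isolated.
#'
#' @param map a `stat_map` (or a list with `statistic` and `mask` arrays).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param min_size minimum ROI size in voxels (default 10).
#' @param smooth_fwhm Gaussian pre-smoothing FWHM in voxel units (0 = off).
#' @return A `parcellation`: `labels` (integer volume, 0 = background),
#'   `roi_ids`, `roi_sizes`, `seed_coords` (per-ROI maximum voxel, rows =
#'   x,y,z), and `provenance`.
#' @export
watershed_parcellate <- function(map, connectivity = 26, min_size = 10,
                                 smooth_fwhm = 0) {
  stat <- as_volume(map$statistic)
  mask <- as_volume(map$mask)
  if (!any(mask)) stop("empty mask: nothing to parcellate")
  if (smooth_fwhm > 0) stat <- gaussian_smooth(stat, smooth_fwhm)
  d <- dim(stat)
  off <- neighbour_offsets(connectivity)

  vox <- which(as.vector(mask))
  ord <- vox[order(-stat[vox], vox)]
  labels <- array(0L, d)
  n_lab <- 0L
  for (v in ord) {
    nb <- neighbours_of(v, d, off)
    nb_lab <- labels[nb]
    nb_lab <- nb_lab[nb_lab > 0L]
    if (length(nb_lab) == 0L) {
      n_lab <- n_lab + 1L
      labels[v] <- n_lab
    } else if (length(unique(nb_lab)) == 1L) {
      labels[v] <- nb_lab[1]
    } else {
      nb_in <- nb[labels[nb] > 0L]
      best <- order(-stat[nb_in], labels[nb_in])[1]
      labels[v] <- labels[nb_in[best]]
    }
  }

  ## merge undersized ROIs, smallest first
  repeat {
    sizes <- tabulate(labels[labels > 0L])
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0L) break
    lab <- small[order(sizes[small])][1]
    members <- which(labels == lab)
    cand_lab <- integer(0); cand_stat <- numeric(0)
    for (v in members) {
      nb <- neighbours_of(v, d, off)
      nb <- nb[labels[nb] > 0L & labels[nb] != lab]
      if (length(nb)) {
        cand_lab <- c(cand_lab, labels[nb])
        cand_stat <- c(cand_stat, stat[nb])
      }
    }
    if (length(cand_lab) == 0L) {
      labels[members] <- 0L  # isolated undersized ROI: discard
    } else {
      per <- tapply(cand_stat, cand_lab, max)
      tgt <- as.integer(names(per)[order(-per, as.integer(names(per)))][1])
      labels[members] <- tgt
    }
  }

  ## relabel 1..R by decreasing seed statistic (deterministic)
  old <- sort(unique(labels[labels > 0L]))
  if (length(old) == 0L) stop("all ROIs discarded; lower min_size")
  seed_of <- vapply(old, function(l) {
    m <- which(labels == l)
    m[order(-stat[m], m)][1]
  }, integer(1))
  new_order <- order(-stat[seed_of], seed_of)
  relab <- array(0L, d)
  seeds <- matrix(0L, length(old), 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  for (r in seq_along(new_order)) {
    l <- old[new_order[r]]
    relab[labels == l] <- r
    seeds[r, ] <- as.integer(arrayInd(seed_of[new_order[r]], d)) - 1L
  }
  sizes <- tabulate(relab[relab > 0L])
  out <- list(labels = relab, roi_ids = seq_along(sizes), roi_sizes = sizes,
              seed_coords = seeds,
              provenance = list(connectivity = connectivity,
                                min_size = min_size,
                                smooth_fwhm = smooth_fwhm,
                                source_voxels = sum(mask)))
  class(out) <- "parcellation"
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Watershed parcellation: %d ROIs over %d voxels (sizes %d-%d)\n",
              length(x$roi_ids), sum(x$roi_sizes), min(x$roi_sizes),
              max(x$roi_sizes)))
  invisible(x)
}

#' Extract mean ROI signals from voxel data
#'
#' ROI value = mean across member voxels; ROI order is fixed by `roi_ids`.
#'
#' @param data voxel x (time or event) matrix, rows in grid (linear voxel
#'   index) order, or a vector of per-voxel values.
#' @param parc a `parcellation`.
#' @return ROI x column matrix.
#' @export
extract_roi_signals <- function(data, parc) {
  stopifnot(inherits(parc, "parcellation"))
  data <- if (is.null(dim(data))) matrix(data, ncol = 1) else as.matrix(data)
  if (nrow(data) != length(parc$labels))
    stop("grid mismatch: data rows must equal voxel count of the parcellation")
  lab <- as.vector(parc$labels)
  out <- matrix(NA_real_, length(parc$roi_ids), ncol(data))
  rownames(out) <- paste0("roi", parc$roi_ids)
  for (r in parc$roi_ids) {
    members <- lab == r
    if (!any(members)) stop("ROI ", r, " has no in-grid voxels")
    out[r, ] <- colMeans(data[members, , drop = FALSE])
  }
  out
}
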