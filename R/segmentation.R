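#' Labeled segmentation mask
#'
#' Integer label volume with the same (x, y, z) shape as one channel;
#' label 0 is background, labels 1..n are cell objects.
#'
#' @param labels integer 3-D array.
#' @return An object of class \code{segmentation_mask}.
#' @export
segmentation_mask <- function(labels) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, n_cells = max(0L, max(labels))),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("segmentation_mask: %d x %d x %d voxels, %d cells\n",
              d[1], d[2], d[3], x$n_cells))
  invisible(x)
}

#' Membrane-inverted nuclear contrast image
#'
#' Builds the synthetic contrast image used to separate touching nuclei in
#' crowded tissue: both channels are min-max scaled to [0, 1], the membrane
#' channel is inverted (max minus value) and multiplied voxel-wise with the
#' nuclear channel. Ridges of membrane signal between adjacent cells become
#' valleys of the contrast image, so each nucleus sits on its own peak.
#'
#' @param nuclear nuclear-stain volume (nonnegative).
#' @param membrane pan-membrane volume of the same shape.
#' @return Contrast volume in [0, 1].
#' @export
make_contrast_image <- function(nuclear, membrane) {
  if (!identical(dim(nuclear), dim(membrane)))
    stop("nuclear and membrane volumes differ in shape")
  if (min(nuclear) < 0 || min(membrane) < 0)
    stop("intensities must be nonnegative")
  (1 - minmax_scale(membrane)) * minmax_scale(nuclear)
}

#' Low-pass FFT filter
#'
#' Removes frequency components above a hard spherical cutoff in frequency
#' space (per-axis scaled, as a fraction of each axis' Nyquist frequency).
#' The DC component is always kept, so the image mean is preserved.
#'
#' @param image 3-D volume.
#' @param cutoff_fraction cutoff as a fraction of Nyquist, in (0, 1].
#' @return Filtered real volume.
#' @export
lowpass_fft <- function(image, cutoff_fraction = 0.15) {
  if (cutoff_fraction <= 0) stop("cutoff_fraction must be positive")
  if (cutoff_fraction >= 1) return(image)   # whole spectrum kept
  d <- dim(image)
  freq_axis <- function(n) {
    k <- c(0:floor(n / 2), if (n > 1) -(ceiling(n / 2) - 1):-1 else NULL)
    k / (n / 2)  # units of the Nyquist frequency
  }
  fx <- freq_axis(d[1]); fy <- freq_axis(d[2]); fz <- freq_axis(d[3])
  r2 <- outer(outer(fx^2, fy^2, `+`), fz^2, `+`)
  keep <- r2 <= cutoff_fraction^2
  Fi <- fft(image)
  Fi[!keep] <- 0
  Re(fft(Fi, inverse = TRUE)) / length(image)
}

# Volume-wide Otsu threshold (EBImage's otsu is per-frame; flatten to one
# 2D frame so the histogram covers the whole volume).
otsu_threshold <- function(scaled) {
  flat <- matrix(as.numeric(scaled), nrow = dim(scaled)[1])
  EBImage::otsu(EBImage::Image(flat), range = c(0, 1))
}

otsu_foreground <- function(volume) {
  v <- minmax_scale(volume)
  v > otsu_threshold(v)
}

#' Seeded gradient watershed segmentation
#'
#' Seeds are local maxima of the (already low-pass filtered) contrast image
#' separated by at least \code{min_distance}; the watershed then floods the
#' gradient magnitude of the contrast image in ascending order from those
#' seeds, restricted to a foreground mask. Regions smaller than
#' \code{min_size} are merged into the touching neighbor with the longest
#' shared boundary, or dropped if isolated. Ties during flooding are broken
#' by deterministic insertion order (x, y, z ascending scan), so the result
#' is reproducible.
#'
#' @param contrast contrast volume in [0, 1] (see [make_contrast_image()] and
#'   [lowpass_fft()]).
#' @param min_distance minimum seed separation in voxels (about one expected
#'   cell radius).
#' @param min_size minimum region size in voxels.
#' @param foreground optional logical volume restricting the flood; default
#'   is an Otsu threshold on the contrast image followed by a radius-1
#'   binary closing.
#' @param seed_threshold minimum contrast value for a seed (default: Otsu of
#'   the contrast values inside the foreground).
#' @return A [segmentation_mask()].
#' @export
watershed_segment <- function(contrast, min_distance = 4, min_size = 20,
                              foreground = NULL, seed_threshold = NULL) {
  d <- dim(contrast)
  if (max(contrast) <= 0) return(segmentation_mask(array(0L, d)))
  if (is.null(foreground)) {
    foreground <- binary_close(otsu_foreground(contrast), 1L, 6L)
  }
  if (!any(foreground)) return(segmentation_mask(array(0L, d)))
  if (is.null(seed_threshold)) {
    fgvals <- contrast[foreground]
    seed_threshold <- if (length(unique(fgvals)) > 1)
      otsu_threshold(minmax_scale(contrast)) * 0.5 else 0
  }
  cand <- cx_local_maxima(contrast, d, seed_threshold) & foreground
  idx <- which(cand)
  if (length(idx) == 0) return(segmentation_mask(array(0L, d)))
  # greedy non-maximum suppression: strongest peaks first, then any peak at
  # least min_distance away from all kept peaks
  ord <- idx[order(contrast[idx], decreasing = TRUE)]
  coords <- arrayInd(ord, d)
  keep <- integer(0)
  for (k in seq_along(ord)) {
    if (length(keep) == 0) { keep <- k; next }
    dd <- sqrt(rowSums((coords[keep, , drop = FALSE] -
                          matrix(coords[k, ], length(keep), 3,
                                 byrow = TRUE))^2))
    if (all(dd >= min_distance)) keep <- c(keep, k)
  }
  seed_idx <- ord[keep]
  # deterministic seed labels: ascending linear (x,y,z) order
  seed_idx <- sort(seed_idx)
  seeds <- array(0L, d)
  seeds[seed_idx] <- seq_along(seed_idx)
  # Flood the inverted contrast: each basin descends its nucleus' contrast
  # gradient and opposing basins collide in the membrane valleys, which is
  # where the boundary belongs. (Flooding the gradient-magnitude surface
  # instead lets the first basin that breaches its nucleus-edge wall claim
  # the entire connected zero-gradient cytoplasm network.)
  relief <- max(contrast) - contrast
  labels <- cx_watershed(as.numeric(relief), as.integer(seeds),
                         as.logical(foreground), as.integer(d))
  labels <- merge_small_regions(labels, min_size)
  segmentation_mask(labels)
}

# Merge regions below min_size into the touching neighbor sharing the longest
# boundary; isolated small regions are dropped. Labels are then compacted to
# 1..n in first-appearance order.
merge_small_regions <- function(labels, min_size) {
  d <- dim(labels)
  n <- max(labels)
  if (n == 0) return(labels)
  repeat {
    sizes <- tabulate(labels[labels > 0], nbins = n)
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0) break
    cf <- cx_contact_faces(labels, d, n)
    changed <- FALSE
    for (s in small) {
      touch_i <- cf$j[cf$i == s]; faces_i <- cf$faces[cf$i == s]
      touch_j <- cf$i[cf$j == s]; faces_j <- cf$faces[cf$j == s]
      nbr <- c(touch_i, touch_j); fc <- c(faces_i, faces_j)
      ok <- nbr[sizes[nbr] >= min_size | !(nbr %in% small)]
      fc <- fc[sizes[nbr] >= min_size | !(nbr %in% small)]
      labels[labels == s] <- if (length(ok)) ok[which.max(fc)] else 0L
      changed <- TRUE
    }
    if (!changed) break
  }
  present <- sort(unique(labels[labels > 0]))
  remap <- integer(n)
  remap[present] <- seq_along(present)
  out <- labels
  out[labels > 0] <- remap[labels[labels > 0]]
  out
}

#' Segment a multicycle stack end to end
#'
#' Convenience pipeline: contrast image from the nuclear and reference
#' membrane channels, low-pass FFT filter, foreground mask (Otsu on the sum
#' of the scaled channels, radius-1 closing) and seeded gradient watershed.
#'
#' @param stack an [image_stack()].
#' @param cutoff_fraction low-pass cutoff (fraction of Nyquist).
#' @param min_distance,min_size watershed parameters, see
#'   [watershed_segment()].
#' @return A [segmentation_mask()].
#' @export
segment_stack <- function(stack, cutoff_fraction = 0.15, min_distance = 4,
                          min_size = 20) {
  nuclear <- pmax(stack_channel(stack, "nuclear"), 0)      # clip noise floor
  membrane <- pmax(stack_channel(stack, "membrane"), 0)
  contrast <- make_contrast_image(nuclear, membrane)
  filtered <- lowpass_fft(contrast, cutoff_fraction)
  filtered[filtered < 0] <- 0
  filtered <- minmax_scale(filtered)
  fg <- binary_close(
    otsu_foreground(minmax_scale(nuclear) + minmax_scale(membrane)), 1L, 6L)
  watershed_segment(filtered, min_distance = min_distance,
                    min_size = min_size, foreground = fg)
}

#' Quantify per-cell marker intensities
#'
#' One row per cell object: centroid (unweighted mean of voxel coordinates,
#' 0-based), size in voxels, and for every (cycle, channel) the summed
#' intensity inside the cell divided by its size. Blank-cycle channels are
#' quantified identically and kept (they drive cleanup gating); per-cycle
#' total signal columns (\code{cycle_total_<k>}) support the homogeneity
#' gate.
#'
#' @param mask a [segmentation_mask()].
#' @param stack an [image_stack()] congruent with the mask.
#' @return A cell table data.frame with attribute \code{markers} naming the
#'   marker columns and \code{blanks} naming the blank columns.
#' @export
quantify_cells <- function(mask, stack) {
  d <- dim(stack$voxels)
  if (!identical(dim(mask$labels), d[1:3]))
    stop("mask and stack shapes are not congruent")
  n <- mask$n_cells
  lab <- as.integer(mask$labels)
  inside <- lab > 0L
  labin <- lab[inside]
  size <- tabulate(labin, nbins = n)
  if (any(size == 0)) stop("mask labels are not contiguous 1..n")
  sums_by_label <- function(x) {
    rs <- rowsum(x, labin)
    out <- numeric(n)
    out[as.integer(rownames(rs))] <- rs[, 1]
    out
  }
  coords <- arrayInd(which(inside), d[1:3])
  cx <- sums_by_label(as.numeric(coords[, 1])) / size
  cy <- sums_by_label(as.numeric(coords[, 2])) / size
  cz <- sums_by_label(as.numeric(coords[, 3])) / size
  tab <- data.frame(id = seq_len(n), x = cx - 1, y = cy - 1, z = cz - 1,
                    size = size)
  meta <- stack$channel_meta
  markers <- character(0); blanks <- character(0)
  cycle_total <- matrix(0, n, d[5])
  for (r in seq_len(nrow(meta))) {
    vol <- stack$voxels[, , , meta$channel[r], meta$cycle[r]]
    val <- sums_by_label(as.numeric(vol[inside])) / size
    nm <- meta$marker[r]
    tab[[nm]] <- val
    if (meta$role[r] %in% c("marker", "nuclear")) markers <- c(markers, nm)
    if (isTRUE(meta$blank[r])) blanks <- c(blanks, nm)
    if (meta$role[r] != "membrane")
      cycle_total[, meta$cycle[r]] <- cycle_total[, meta$cycle[r]] + val
  }
  for (k in seq_len(d[5])) tab[[sprintf("cycle_total_%d", k)]] <- cycle_total[, k]
  attr(tab, "markers") <- setdiff(markers, "DRAQ5")
  attr(tab, "nuclear") <- meta$marker[meta$role == "nuclear"][1]
  attr(tab, "blanks") <- blanks
  attr(tab, "n_cycles") <- d[5]
  tab
}

#' Local-background (ring) quantification
#'
#' For each cell, the mean intensity inside the cell minus the mean intensity
#' in an external ring (morphological dilation of the cell by
#' \code{ring_width}, excluding voxels of any other cell). Cells whose ring is
#' empty (fully enclosed by neighbors) fall back to the inside mean and are
#' flagged.
#'
#' @param mask a [segmentation_mask()].
#' @param image single-channel volume congruent with the mask.
#' @param ring_width ring width in voxels (>= 1).
#' @return data.frame with id, inside_mean, ring_mean, value and
#'   ring_empty flag.
#' @export
ring_background_quantify <- function(mask, image, ring_width = 2L) {
  if (ring_width < 1) stop("ring_width must be at least 1")
  if (!identical(dim(mask$labels), dim(image)))
    stop("mask and image shapes differ")
  d <- dim(image)
  n <- mask$n_cells
  out <- data.frame(id = seq_len(n), inside_mean = NA_real_,
                    ring_mean = NA_real_, value = NA_real_,
                    ring_empty = FALSE)
  for (i in seq_len(n)) {
    vox <- which(mask$labels == i)
    co <- arrayInd(vox, d)
    lo <- pmax(apply(co, 2, min) - ring_width, 1)
    hi <- pmin(apply(co, 2, max) + ring_width, d)
    sub_lab <- mask$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    sub_img <- image[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    cell <- sub_lab == i
    ring <- cell
    for (s in seq_len(ring_width)) ring <- dilate_step(ring, 26L)
    ring <- ring & !cell & sub_lab == 0L
    inside <- mean(sub_img[cell])
    out$inside_mean[i] <- inside
    if (any(ring)) {
      out$ring_mean[i] <- mean(sub_img[ring])
      out$value[i] <- inside - out$ring_mean[i]
    } else {
      out$value[i] <- inside
      out$ring_empty[i] <- TRUE
    }
  }
  out
}

#' Benchmark a segmentation against known cell centers
#'
#' Reports the percentage of true centers falling inside any segmented
#' region (nuclei found), the percentage of center-containing regions with
#' exactly one center (singlets), and the percentage of regions containing
#' no center (unlabeled regions).
#'
#' @param mask a [segmentation_mask()].
#' @param true_centers n x 3 matrix of cell centers (1-based voxel
#'   coordinates, as in a phantom's ground truth).
#' @return list with pct_nuclei_found, pct_singlets, pct_unlabeled_regions.
#' @export
benchmark_segmentation <- function(mask, true_centers) {
  d <- dim(mask$labels)
  n_centers <- nrow(true_centers)
  if (n_centers == 0 || mask$n_cells == 0)
    return(list(pct_nuclei_found = 0, pct_singlets = 0,
                pct_unlabeled_regions = if (mask$n_cells) 100 else 0))
  vx <- pmin(pmax(round(true_centers[, 1]), 1), d[1])
  vy <- pmin(pmax(round(true_centers[, 2]), 1), d[2])
  vz <- pmin(pmax(round(true_centers[, 3]), 1), d[3])
  lab_at <- mask$labels[cbind(vx, vy, vz)]
  found <- lab_at > 0
  per_label <- tabulate(lab_at[found], nbins = mask$n_cells)
  with_center <- sum(per_label >= 1)
  list(
    pct_nuclei_found = 100 * mean(found),
    pct_singlets = if (with_center > 0)
      100 * sum(per_label == 1) / with_center else 0,
    pct_unlabeled_regions = 100 * sum(per_label == 0) / mask$n_cells)
}
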