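#' Multicycle, multichannel image stack
#'
#' Voxel container for multicycle acquisitions: a 5-D array indexed
#' \code{[x, y, z, channel, cycle]} plus per-(cycle, channel) metadata naming
#' the marker and flagging blank channels. Exactly one channel is designated
#' nuclear and one the reference membrane channel; the reference channel is
#' present in every cycle so cycles can be aligned against it.
#'
#' @param voxels numeric 5-D array (x, y, z, channel, cycle).
#' @param channel_meta data.frame with columns cycle, channel, marker, role
#'   (one of "nuclear", "membrane", "marker", "blank") and blank (logical).
#' @param voxel_size physical size per axis, e.g. c(x = 0.188, y = 0.188,
#'   z = 0.9) micrometers.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(voxels, channel_meta,
                        voxel_size = c(x = 0.188, y = 0.188, z = 0.9)) {
  if (length(dim(voxels)) != 5L)
    stop("voxels must be a 5-D array (x, y, z, channel, cycle)")
  need <- c("cycle", "channel", "marker", "role", "blank")
  if (!all(need %in% names(channel_meta)))
    stop("channel_meta must have columns ", paste(need, collapse = ", "))
  if (sum(channel_meta$role == "nuclear") != 1L)
    stop("exactly one channel must be designated nuclear")
  if (!any(channel_meta$role == "membrane"))
    stop("a reference membrane channel is required")
  structure(list(voxels = voxels, channel_meta = channel_meta,
                 voxel_size = voxel_size, shifts = NULL),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels, %d channels x %d cycles\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  markers: %s\n",
              paste(x$channel_meta$marker[x$channel_meta$role == "marker"],
                    collapse = ", ")))
  invisible(x)
}

stack_plane <- function(stack, cycle, channel) {
  stack$voxels[, , , channel, cycle, drop = TRUE]
}

# Volume of the channel with the given role (nuclear/membrane); for membrane
# the reference cycle's instance is returned.
stack_channel <- function(stack, role, cycle = NULL) {
  meta <- stack$channel_meta
  hit <- meta[meta$role == role, , drop = FALSE]
  if (nrow(hit) == 0) stop("no channel with role '", role, "'")
  if (is.null(cycle)) cycle <- hit$cycle[1]
  hit <- hit[hit$cycle == cycle, , drop = FALSE]
  if (nrow(hit) == 0) stop("role '", role, "' absent from cycle ", cycle)
  array(stack$voxels[, , , hit$channel[1], cycle], dim(stack$voxels)[1:3])
}

#' Write an image stack as multipage TIFF
#'
#' Pages are ordered cycle-major, then channel, then z-plane. Channel
#' metadata is written alongside as \code{<path>.channels.csv} so that
#' [read_stack()] can restore the stack losslessly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param bits bits per sample (32 or 16). Intensities are stored as
#'   unsigned integers after scaling by the stack maximum (recorded in the
#'   sidecar), so the round trip is exact to one part in 2^bits.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, bits = 32L) {
  d <- dim(stack$voxels)
  lo <- min(stack$voxels)
  span <- max(stack$voxels) - lo
  if (span <= 0) span <- 1
  pages <- vector("list", d[4] * d[5] * d[3])
  k <- 1L
  for (cyc in seq_len(d[5])) for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    # writeTIFF expects row-major [y, x] matrices with values in [0, 1]
    pages[[k]] <- (t(stack$voxels[, , z, ch, cyc]) - lo) / span
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  meta <- stack$channel_meta
  meta$n_x <- d[1]; meta$n_y <- d[2]; meta$n_z <- d[3]
  meta$scale <- span; meta$offset <- lo
  write.csv(meta, paste0(path, ".channels.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a multipage TIFF image stack
#'
#' @param path TIFF path written by [write_stack()], or any multipage TIFF.
#' @param layout optional list with \code{n_z}, \code{n_channel},
#'   \code{n_cycle} and a \code{channel_meta} data.frame; when NULL the
#'   sidecar \code{<path>.channels.csv} is used.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(layout)) {
    side <- paste0(path, ".channels.csv")
    if (!file.exists(side))
      stop("no layout given and sidecar ", side, " not found")
    meta <- read.csv(side, stringsAsFactors = FALSE)
    layout <- list(n_z = meta$n_z[1], n_channel = max(meta$channel),
                   n_cycle = max(meta$cycle),
                   scale = if ("scale" %in% names(meta)) meta$scale[1] else 1,
                   offset = if ("offset" %in% names(meta)) meta$offset[1] else 0,
                   channel_meta = meta[, c("cycle", "channel", "marker",
                                           "role", "blank")])
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  n_pages <- length(pages)
  want <- layout$n_z * layout$n_channel * layout$n_cycle
  if (n_pages != want)
    stop(sprintf("TIFF has %d pages but layout requires %d (%d cycles x %d channels x %d z-planes)",
                 n_pages, want, layout$n_cycle, layout$n_channel, layout$n_z))
  d_yx <- dim(pages[[1]])
  for (p in seq_len(n_pages)) {
    if (!identical(dim(pages[[p]]), d_yx))
      stop("inconsistent page shape at page ", p)
  }
  vox <- array(0, c(d_yx[2], d_yx[1], layout$n_z, layout$n_channel,
                    layout$n_cycle))
  k <- 1L
  scale <- layout$scale %||% 1
  offset <- layout$offset %||% 0
  for (cyc in seq_len(layout$n_cycle)) for (ch in seq_len(layout$n_channel))
    for (z in seq_len(layout$n_z)) {
      vox[, , z, ch, cyc] <- t(pages[[k]]) * scale + offset
      k <- k + 1L
    }
  image_stack(vox, layout$channel_meta)
}

#' Write a labeled segmentation mask as 16-bit TIFF
#' @param mask a \code{segmentation_mask}.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (mask$n_cells > 65535L) stop("more than 65535 labels; 16-bit TIFF overflow")
  d <- dim(mask$labels)
  pages <- lapply(seq_len(d[3]), function(z) t(mask$labels[, , z]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a labeled mask written by [write_mask()]
#' @param path TIFF path.
#' @return A \code{segmentation_mask}.
#' @export
read_mask <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d_yx <- dim(pages[[1]])
  labels <- array(0L, c(d_yx[2], d_yx[1], length(pages)))
  for (z in seq_along(pages))
    labels[, , z] <- as.integer(round(t(pages[[z]]) * 65535))
  segmentation_mask(labels)
}

#' Estimate per-cycle drift against the reference cycle
#'
#' Each cycle's reference membrane channel is aligned to cycle 1 by 3-D phase
#' correlation; the integer-voxel shift maximizing the correlation within
#' \code{max_shift} is returned, with optional subvoxel refinement by
#' parabolic interpolation of the correlation peak.
#'
#' @param stack an [image_stack()].
#' @param max_shift maximum absolute shift searched per axis (voxels).
#' @param subvoxel logical; refine the integer peak by parabolic fit.
#' @return A \code{drift_solution}: matrix of per-cycle shifts (dx, dy, dz);
#'   the reference cycle's shift is exactly (0, 0, 0).
#' @export
estimate_drift <- function(stack, max_shift = 10L, subvoxel = FALSE) {
  d <- dim(stack$voxels)
  ref <- stack_channel(stack, "membrane", cycle = 1L)
  if (var(as.numeric(ref)) == 0)
    stop("reference channel has zero variance; cannot align")
  Fref <- fft(ref)
  shifts <- matrix(0, d[5], 3, dimnames = list(NULL, c("dx", "dy", "dz")))
  for (cyc in seq_len(d[5])[-1]) {
    mov <- stack_channel(stack, "membrane", cycle = cyc)
    if (var(as.numeric(mov)) == 0)
      stop("reference channel of cycle ", cyc, " has zero variance")
    cross <- Fref * Conj(fft(mov))
    mag <- Mod(cross)
    mag[mag == 0] <- 1
    cc <- Re(fft(cross / mag, inverse = TRUE))
    # the correlation peak sits at minus the displacement of this cycle
    shifts[cyc, ] <- -correlation_peak(cc, max_shift, subvoxel)
  }
  structure(list(shifts = shifts, reference_cycle = 1L),
            class = "drift_solution")
}

# Locate the (wrapped) correlation peak within +/- max_shift per axis.
correlation_peak <- function(cc, max_shift, subvoxel) {
  d <- dim(cc)
  offs <- lapply(d, function(n) {
    m <- min(max_shift, n - 1L)
    c(0:m, if (m >= 1) -(1:m) else integer(0))
  })
  idx <- lapply(seq_along(d), function(ax) (offs[[ax]] %% d[ax]) + 1L)
  sub <- cc[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak <- c(offs[[1]][w[1]], offs[[2]][w[2]], offs[[3]][w[3]])
  if (subvoxel) {
    for (ax in 1:3) {
      if (d[ax] < 3) next
      p0 <- peak; pm <- peak; pp <- peak
      pm[ax] <- pm[ax] - 1; pp[ax] <- pp[ax] + 1
      val <- function(p) cc[(p[1] %% d[1]) + 1, (p[2] %% d[2]) + 1,
                            (p[3] %% d[3]) + 1]
      a <- val(pm); b <- val(p0); cst <- val(pp)
      den <- a - 2 * b + cst
      if (den < 0) peak[ax] <- peak[ax] + 0.5 * (a - cst) / den
    }
  }
  peak
}

#' Apply a drift solution to an image stack
#'
#' Translates every channel of each cycle by the negated estimated drift so
#' that all cycles align with the reference; out-of-field voxels are set to
#' \code{fill_value} and the per-cycle valid ranges are recorded on the
#' returned stack.
#'
#' @param stack an [image_stack()].
#' @param drift a \code{drift_solution} from [estimate_drift()].
#' @param fill_value value for voxels shifted in from outside the field.
#' @return The aligned [image_stack()].
#' @export
apply_shifts <- function(stack, drift, fill_value = 0) {
  d <- dim(stack$voxels)
  stopifnot(inherits(drift, "drift_solution"), nrow(drift$shifts) == d[5])
  out <- stack
  for (cyc in seq_len(d[5])) {
    s <- -round(drift$shifts[cyc, ])  # undo the estimated displacement
    if (all(s == 0)) next
    for (ch in seq_len(d[4])) {
      out$voxels[, , , ch, cyc] <-
        shift_volume(array(stack$voxels[, , , ch, cyc], d[1:3]), s, fill_value)
    }
  }
  out$shifts <- drift$shifts
  out
}

#' Export a cell table to CSV or FCS 3.0
#'
#' CSV export is a bit-exact round trip through [read.csv()]. FCS export
#' writes one event per cell with one float parameter per marker plus the
#' x, y, z centroid and cell size, readable by standard cytometry parsers.
#'
#' @param table cell table with numeric marker columns.
#' @param path output file path.
#' @param format "csv" or "fcs".
#' @param markers character vector of marker column names; defaults to the
#'   table's \code{markers} attribute.
#' @return \code{path}, invisibly.
#' @export
export_cells <- function(table, path, format = c("csv", "fcs"),
                         markers = attr(table, "markers")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(table, path, row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(markers)) stop("FCS export needs marker column names")
  spatial <- intersect(c("x", "y", "z", "size"), names(table))
  cols <- c(markers, spatial)
  bad <- cols[!vapply(table[cols], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric parameter columns: ", paste(bad, collapse = ", "))
  write_fcs(as.matrix(table[, cols, drop = FALSE]), path)
  invisible(path)
}
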