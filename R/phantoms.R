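#' Specification of a synthetic tissue phantom
#'
#' A phantom emulates a thin tissue section densely packed with cells: spheres
#' truncated to the imaged slab, concentric nuclei, a membrane shell of fixed
#' thickness, cell-type-specific marker expression, and optional compartments
#' (named regions of the xy plane with their own cell-type frequencies).
#' Phantoms carry complete ground truth, so every downstream stage of the
#' pipeline (segmentation, compensation, interaction and niche statistics) can
#' be validated without external data.
#'
#' @param image_shape integer (x, y, z) volume size in voxels.
#' @param n_cells number of cells to place.
#' @param cell_radius_range (min, max) cell radius in voxels.
#' @param nucleus_radius_fraction nucleus radius as a fraction of cell radius,
#'   in (0, 1). Nuclei of distinct cells never overlap; membranes may touch.
#' @param membrane_thickness membrane shell thickness in voxels.
#' @param cell_types named list; each element is a named numeric vector of
#'   marker intensities (arbitrary units) for that cell type.
#' @param type_freq named numeric vector of cell-type frequencies (summing to
#'   1) used when no compartments are given. Default: uniform.
#' @param compartments optional list of compartments, each a list with
#'   \code{name}, \code{x_range} and \code{y_range} (fractions of the field)
#'   and \code{freqs} (named type frequencies summing to 1).
#' @param noise_gaussian_sd additive Gaussian noise sd (intensity units).
#' @param noise_poisson logical; apply Poisson resampling to nonnegative
#'   intensities (shot noise).
#' @param blur_sigma lateral Gaussian blur sigma in voxels (0 = none),
#'   applied before noise.
#' @param blank_cycles integer cycle indices carrying no marker (blank
#'   imaging cycles used by cleanup gating).
#' @param spill_c global spillover coefficient in [0, 0.5): the fraction of a
#'   cell's membrane signal that bleeds to the neighbor across a fully shared
#'   boundary.
#' @param seed integer RNG seed; fixed seed gives bit-identical phantoms.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(image_shape = c(96L, 96L, 9L),
                         n_cells = 50L,
                         cell_radius_range = c(4, 5),
                         nucleus_radius_fraction = 0.55,
                         membrane_thickness = 1L,
                         cell_types = default_cell_types(),
                         type_freq = NULL,
                         compartments = NULL,
                         noise_gaussian_sd = 0,
                         noise_poisson = FALSE,
                         blur_sigma = 0,
                         blank_cycles = integer(0),
                         spill_c = 0.3,
                         seed = 1L) {
  stopifnot(length(image_shape) == 3L, all(image_shape >= 1),
            length(cell_radius_range) == 2L,
            cell_radius_range[1] <= cell_radius_range[2],
            nucleus_radius_fraction > 0, nucleus_radius_fraction < 1,
            membrane_thickness >= 1,
            is.list(cell_types), length(cell_types) >= 1,
            !is.null(names(cell_types)))
  if (spill_c < 0 || spill_c >= 0.5)
    stop("spill_c must lie in [0, 0.5)")
  markers <- unique(unlist(lapply(cell_types, names)))
  if (is.null(markers)) stop("cell type profiles must be named numeric vectors")
  cell_types <- lapply(cell_types, function(p) {
    full <- setNames(numeric(length(markers)), markers)
    full[names(p)] <- p
    full
  })
  if (is.null(type_freq)) {
    type_freq <- setNames(rep(1 / length(cell_types), length(cell_types)),
                          names(cell_types))
  }
  if (abs(sum(type_freq) - 1) > 1e-9) stop("type_freq must sum to 1")
  if (!is.null(compartments)) {
    for (cp in compartments) {
      if (abs(sum(cp$freqs) - 1) > 1e-9)
        stop("compartment '", cp$name, "': type frequencies must sum to 1")
      if (!all(names(cp$freqs) %in% names(cell_types)))
        stop("compartment '", cp$name, "' names unknown cell types")
    }
  }
  structure(list(
    image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
    cell_radius_range = cell_radius_range,
    nucleus_radius_fraction = nucleus_radius_fraction,
    membrane_thickness = as.integer(membrane_thickness),
    cell_types = cell_types, markers = markers, type_freq = type_freq,
    compartments = compartments, noise_gaussian_sd = noise_gaussian_sd,
    noise_poisson = isTRUE(noise_poisson), blur_sigma = blur_sigma,
    blank_cycles = as.integer(blank_cycles), spill_c = spill_c,
    seed = as.integer(seed)), class = "phantom_spec")
}

#' Default splenic-flavoured cell type panel for phantoms
#'
#' Three coarse immune phenotypes with mutually exclusive lineage markers
#' (B220 vs CD90 vs F4/80) over a shared pan-leukocyte marker (CD45), mirroring
#' the marker logic of lymphoid tissue panels.
#' @return Named list of marker profiles.
#' @export
default_cell_types <- function() {
  list(
    Bcell = c(CD45 = 60, B220 = 100, CD90 = 1, F480 = 1, IgD = 70),
    Tcell = c(CD45 = 60, B220 = 1, CD90 = 100, F480 = 1, IgD = 1),
    Mac   = c(CD45 = 40, B220 = 2, CD90 = 2, F480 = 90, IgD = 2)
  )
}

compartment_at <- function(compartments, x, y, shape) {
  if (is.null(compartments)) return("all")
  fx <- x / shape[1]; fy <- y / shape[2]
  for (cp in compartments) {
    if (fx >= cp$x_range[1] && fx <= cp$x_range[2] &&
        fy >= cp$y_range[1] && fy <= cp$y_range[2]) return(cp$name)
  }
  "all"
}

#' Place cells and derive complete ground truth
#'
#' Samples cell centers by rejection so that no two nuclei overlap, assigns
#' cell types by (per-compartment) frequencies, paints the true label mask by
#' nearest-center claim within each cell radius, and records the true contact
#' graph (shared boundary voxel faces) and expression table.
#'
#' @param spec a [phantom_spec()].
#' @param max_attempts placement attempts before giving up.
#' @return A \code{ground_truth} list: \code{mask} (a
#'   \code{segmentation_mask}), \code{centers} (n x 3), \code{radii},
#'   \code{types}, \code{expression} (cells x markers), \code{contacts}
#'   (data.frame i, j, faces), \code{boundary} (total boundary faces per
#'   cell), \code{compartment_of_cell} and the spec itself.
#' @export
make_cell_map <- function(spec, max_attempts = 400L * max(1L, spec$n_cells)) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$image_shape
  n <- spec$n_cells
  centers <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  types <- character(0)
  compartment <- character(0)
  if (n > 0) {
    rmin <- spec$cell_radius_range[1]; rmax <- spec$cell_radius_range[2]
    attempts <- 0L
    zmid <- (d[3] + 1) / 2
    while (nrow(centers) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop(sprintf(paste0("could not place %d cells without nuclear overlap",
                            " after %d attempts (placed %d, achieved density",
                            " %.3f cells per 100 voxel^2)"),
                     n, max_attempts, nrow(centers),
                     100 * nrow(centers) / (d[1] * d[2])))
      }
      r <- runif(1, rmin, rmax)
      cx <- runif(1, 1 + r, d[1] - r)
      cy <- runif(1, 1 + r, d[2] - r)
      cz <- zmid + runif(1, -0.5, 0.5)
      nr <- r * spec$nucleus_radius_fraction
      ok <- TRUE
      if (nrow(centers) > 0) {
        dd <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 +
                     (centers[, 3] - cz)^2)
        ok <- all(dd >= nr + radii * spec$nucleus_radius_fraction + 1)
      }
      if (ok) {
        centers <- rbind(centers, c(cx, cy, cz))
        radii <- c(radii, r)
        cp <- compartment_at(spec$compartments, cx, cy, d)
        freqs <- spec$type_freq
        if (!is.null(spec$compartments) && cp != "all") {
          for (cpd in spec$compartments) if (cpd$name == cp) freqs <- cpd$freqs
        }
        types <- c(types, sample(names(freqs), 1, prob = freqs))
        compartment <- c(compartment, cp)
      }
    }
  }
  labels <- paint_mask(centers, radii, d)
  cf <- if (n > 0) cx_contact_faces(labels, d, n) else
    list(i = integer(0), j = integer(0), faces = numeric(0),
         boundary = numeric(0))
  expr <- matrix(0, n, length(spec$markers),
                 dimnames = list(NULL, spec$markers))
  for (i in seq_len(n)) expr[i, ] <- spec$cell_types[[types[i]]]
  structure(list(
    mask = segmentation_mask(labels),
    centers = centers, radii = radii, types = types,
    expression = expr,
    contacts = data.frame(i = cf$i, j = cf$j, faces = cf$faces),
    boundary = cf$boundary,
    compartment_of_cell = compartment,
    spec = spec), class = "ground_truth")
}

# Nearest-center painting: each voxel belongs to the closest center whose
# radius covers it, giving a clean partition when cell spheres overlap.
paint_mask <- function(centers, radii, d) {
  labels <- array(0L, d)
  if (nrow(centers) == 0) return(labels)
  bestd <- array(Inf, d)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]; ctr <- centers[i, ]
    xs <- max(1, floor(ctr[1] - r)):min(d[1], ceiling(ctr[1] + r))
    ys <- max(1, floor(ctr[2] - r)):min(d[2], ceiling(ctr[2] + r))
    zs <- max(1, floor(ctr[3] - r)):min(d[3], ceiling(ctr[3] + r))
    dx2 <- (xs - ctr[1])^2; dy2 <- (ys - ctr[2])^2; dz2 <- (zs - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    sub_best <- bestd[xs, ys, zs, drop = FALSE]
    sel <- d2 <= r^2 & d2 < sub_best
    sub_lab <- labels[xs, ys, zs, drop = FALSE]
    sub_lab[sel] <- i
    sub_best[sel] <- d2[sel]
    labels[xs, ys, zs] <- sub_lab
    bestd[xs, ys, zs] <- sub_best
  }
  labels
}

#' Render a phantom ground truth into a multicycle image stack
#'
#' The nuclear channel carries spheres at the nuclei, the membrane reference
#' channel (present in every cycle, as required for drift estimation) carries
#' shells of the stated thickness, and each marker channel carries the
#' membrane shell scaled by the cell's true expression. Blank cycles contain
#' only noise. Blur (if any) is applied before noise; Poisson noise is applied
#' to nonnegative intensities only.
#'
#' @param truth a [make_cell_map()] result.
#' @param spec the same [phantom_spec()]; shapes must agree.
#' @return An [image_stack()].
#' @export
render_image_stack <- function(truth, spec) {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "phantom_spec"))
  if (!identical(dim(truth$mask$labels), spec$image_shape))
    stop("truth mask shape does not match spec image_shape")
  set.seed(spec$seed + 1L)
  d <- spec$image_shape
  labels <- truth$mask$labels
  n <- truth$mask$n_cells

  nuclear <- array(0, d)
  for (i in seq_len(n)) {
    r <- truth$radii[i] * spec$nucleus_radius_fraction
    ctr <- truth$centers[i, ]
    xs <- max(1, floor(ctr[1] - r)):min(d[1], ceiling(ctr[1] + r))
    ys <- max(1, floor(ctr[2] - r)):min(d[2], ceiling(ctr[2] + r))
    zs <- max(1, floor(ctr[3] - r)):min(d[3], ceiling(ctr[3] + r))
    d2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`),
                (zs - ctr[3])^2, `+`)
    sub <- nuclear[xs, ys, zs, drop = FALSE]
    sub[d2 <= r^2] <- 100
    nuclear[xs, ys, zs] <- sub
  }

  memb_mask <- membrane_shell(labels, spec$membrane_thickness)
  membrane <- ifelse(memb_mask, 100, 0)
  dim(membrane) <- d

  markers <- spec$markers
  n_marker_cycles <- ceiling(length(markers) / 2)
  n_cycles <- n_marker_cycles + length(spec$blank_cycles)
  if (length(spec$blank_cycles) &&
      any(spec$blank_cycles < 1 | spec$blank_cycles > n_cycles))
    stop("blank_cycles outside the cycle range 1..", n_cycles)
  marker_cycles <- setdiff(seq_len(n_cycles), spec$blank_cycles)

  vox <- array(0, c(d, 3L, n_cycles))
  meta <- NULL
  owner <- labels[memb_mask]          # cell owning each membrane voxel
  midx <- which(memb_mask)
  mi <- 1L
  for (cyc in seq_len(n_cycles)) {
    vox[, , , 1L, cyc] <- membrane
    meta <- rbind(meta, data.frame(cycle = cyc, channel = 1L,
                                   marker = "CD45m", role = "membrane",
                                   blank = FALSE))
    if (cyc == marker_cycles[1]) {
      vox[, , , 2L, cyc] <- nuclear
      meta <- rbind(meta, data.frame(cycle = cyc, channel = 2L,
                                     marker = "DRAQ5", role = "nuclear",
                                     blank = FALSE))
      chans <- 3L
    } else chans <- c(2L, 3L)
    for (ch in chans) {
      if (cyc %in% spec$blank_cycles || mi > length(markers)) {
        meta <- rbind(meta, data.frame(cycle = cyc, channel = ch,
                                       marker = sprintf("blank_c%d_ch%d", cyc, ch),
                                       role = "blank", blank = TRUE))
      } else {
        mk <- markers[mi]; mi <- mi + 1L
        vol <- array(0, d)
        vol[midx] <- ifelse(owner > 0, truth$expression[pmax(owner, 1L), mk], 0)
        vox[, , , ch, cyc] <- vol
        meta <- rbind(meta, data.frame(cycle = cyc, channel = ch, marker = mk,
                                       role = "marker", blank = FALSE))
      }
    }
  }

  if (spec$blur_sigma > 0) {
    for (cyc in seq_len(n_cycles)) for (ch in 1:3) for (z in seq_len(d[3])) {
      vox[, , z, ch, cyc] <-
        EBImage::gblur(vox[, , z, ch, cyc], sigma = spec$blur_sigma)
    }
  }
  if (spec$noise_poisson) {
    vox[] <- rpois(length(vox), lambda = pmax(vox, 0))
  }
  if (spec$noise_gaussian_sd > 0) {
    vox <- vox + rnorm(length(vox), 0, spec$noise_gaussian_sd)
  }
  image_stack(vox, meta)
}

# Interior membrane shell: voxels of a cell within `thickness` voxels of any
# face where the label changes (to background, another cell, or the edge).
membrane_shell <- function(labels, thickness) {
  d <- dim(labels)
  boundary <- array(FALSE, d)
  for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                   c(0,0,1), c(0,0,-1))) {
    nb <- shift_volume(labels, off, -1L)
    boundary <- boundary | (labels > 0 & nb != labels)
  }
  shell <- boundary
  t <- 1L
  while (t < thickness) {
    shell <- dilate_step(shell, 6L) & labels > 0
    t <- t + 1L
  }
  shell
}

#' Forward model of positional spillover on a true cell table
#'
#' Signals of touching cells blend in proportion to their shared membrane
#' boundary. The observed table is \eqn{S \cdot true} per marker, with the
#' identical column-conservative spill matrix construction used by
#' [compensate()], so the forward and inverse models agree by construction and
#' per-marker totals are conserved.
#'
#' @param true_table data.frame with one row per cell and marker columns.
#' @param contacts data.frame (i, j, faces) of shared boundary faces.
#' @param boundary numeric vector of total boundary faces per cell.
#' @param c spill coefficient in [0, 0.5).
#' @param markers character vector naming the marker columns.
#' @return The table with marker columns replaced by spilled values.
#' @export
apply_spill <- function(true_table, contacts, boundary, c,
                        markers = attr(true_table, "markers")) {
  if (c < 0 || c >= 0.5) stop("spill coefficient c must lie in [0, 0.5)")
  if (is.null(markers)) stop("marker columns must be named")
  S <- spill_matrix(contacts, boundary, c)
  out <- true_table
  X <- as.matrix(true_table[, markers, drop = FALSE])
  spilled <- as.matrix(S$S %*% X)
  for (m in markers) out[[m]] <- spilled[, m]
  attr(out, "markers") <- markers
  out
}

#' Plant pairwise cell-type attractions on a jittered grid
#'
#' Positions cells on a jittered grid, builds their Delaunay neighborhood
#' graph once, then anneals type labels by random label swaps (which preserve
#' type frequencies) until the empirical interaction log-odds of the targeted
#' type pairs are within tolerance of the requested values.
#'
#' @param n_cells number of cells.
#' @param type_freq named type frequencies.
#' @param targets data.frame with columns typeA, typeB, log_odds (finite).
#' @param seed RNG seed.
#' @param tol absolute log-odds tolerance per target.
#' @param max_iter maximum swap proposals.
#' @return list with \code{table} (id, x, y, type), \code{graph}, and
#'   \code{achieved} log-odds matrix. Warns if a target was not reached.
#' @export
plant_interactions <- function(n_cells, type_freq, targets = NULL, seed = 1L,
                               tol = 0.15, max_iter = 100000L) {
  if (!is.null(targets) && !all(is.finite(targets$log_odds)))
    stop("target log-odds must be finite")
  set.seed(seed)
  side <- ceiling(sqrt(n_cells))
  gx <- (seq_len(n_cells) - 1) %% side
  gy <- (seq_len(n_cells) - 1) %/% side
  x <- gx + runif(n_cells, -0.3, 0.3)
  y <- gy + runif(n_cells, -0.3, 0.3)
  graph <- delaunay_graph(cbind(x, y))
  tnames <- names(type_freq)
  types <- sample(rep(tnames, round(type_freq * n_cells))[seq_len(n_cells)])
  types[is.na(types)] <- tnames[1]

  if (!is.null(targets) && nrow(targets) > 0) {
    ei <- graph$edges$i; ej <- graph$edges$j
    # edges touching each node, for O(degree) incremental count updates
    inc_edges <- vector("list", n_cells)
    for (k in seq_along(ei)) {
      inc_edges[[ei[k]]] <- c(inc_edges[[ei[k]]], k)
      inc_edges[[ej[k]]] <- c(inc_edges[[ej[k]]], k)
    }
    counts <- count_edge_types(types[ei], types[ej], tnames)
    obj_of <- function(counts) {
      lo <- log_odds_from_counts(counts)
      s <- 0
      for (r in seq_len(nrow(targets))) {
        v <- lo[targets$typeA[r], targets$typeB[r]]
        s <- s + (if (is.finite(v)) (v - targets$log_odds[r])^2 else 25)
      }
      s
    }
    obj <- obj_of(counts)
    inc_by <- function(counts, a, b, w) {
      i1 <- match(a, tnames); i2 <- match(b, tnames)
      lo <- pmin(i1, i2); hi <- pmax(i1, i2)
      for (k in seq_along(lo)) counts[lo[k], hi[k]] <- counts[lo[k], hi[k]] + w
      counts
    }
    # label-swap simulated annealing: swaps preserve the type frequencies;
    # the temperature schedule lets the chain escape local optima
    temp0 <- 0.02; temp1 <- 1e-4
    it <- 0L
    while (obj > tol^2 && it < max_iter) {
      it <- it + 1L
      u <- sample.int(n_cells, 1L); v <- sample.int(n_cells, 1L)
      if (types[u] == types[v]) next
      touched <- unique(c(inc_edges[[u]], inc_edges[[v]]))
      new_types <- types
      new_types[c(u, v)] <- types[c(v, u)]
      cnew <- inc_by(counts, types[ei[touched]], types[ej[touched]], -1)
      cnew <- inc_by(cnew, new_types[ei[touched]], new_types[ej[touched]], +1)
      onew <- obj_of(cnew)
      temp <- temp0 * (temp1 / temp0)^(it / max_iter)
      if (onew < obj || runif(1) < exp((obj - onew) / temp)) {
        types <- new_types; counts <- cnew; obj <- onew
      }
    }
    achieved <- log_odds_from_counts(counts)
    if (obj > tol^2) {
      warning(sprintf(paste0("planting stopped after %d iterations with",
                             " objective %.4f; achieved log-odds reported"),
                      it, obj))
    }
  } else {
    counts <- count_edge_types(types[graph$edges$i], types[graph$edges$j],
                               tnames)
    achieved <- log_odds_from_counts(counts)
  }
  list(table = data.frame(id = seq_len(n_cells), x = x, y = y,
                          type = types, stringsAsFactors = FALSE),
       graph = graph, achieved = achieved)
}

count_edge_types <- function(ta, tb, tnames) {
  TT <- length(tnames)
  m <- matrix(0, TT, TT, dimnames = list(tnames, tnames))
  i1 <- match(ta, tnames); i2 <- match(tb, tnames)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  tab <- table(factor(lo + TT * (hi - 1), levels = seq_len(TT * TT)))
  m[] <- as.numeric(tab)
  m[lower.tri(m)] <- 0
  m
}

# Upper-triangular count matrix -> symmetric log-odds under the calibrated
# random-mixing convention (fast path mirroring odds_ratio_matrix, used by
# the planting loop).
log_odds_from_counts <- function(upper) {
  m <- upper + t(upper); diag(m) <- diag(upper)
  E <- sum(upper)
  f <- (rowSums(m) + diag(m)) / (2 * E)  # half-edge (degree) fractions
  obs <- m / E
  expd <- 2 * outer(f, f)
  diag(expd) <- f^2
  out <- log(obs / expd)
  out[obs == 0] <- -Inf
  out
}

#' Plant niche archetypes as index cells with multinomial rings
#'
#' Each index cell receives a first-tier ring whose cell types are drawn
#' multinomially from its (planted) archetype composition, providing ground
#' truth for i-niche clustering.
#'
#' @param K number of archetypes.
#' @param archetypes K x T matrix of ring compositions; rows sum to 1,
#'   nonnegative; columns named by cell type.
#' @param n_index_cells number of index cells (>= K).
#' @param ring_size_range (min, max) ring size.
#' @param seed RNG seed.
#' @return list with \code{table} (id, x, y, type, is_index), \code{graph}
#'   (star edges index--ring), and \code{niche} (true archetype per index
#'   cell, NA for ring cells).
#' @export
plant_niches <- function(K, archetypes, n_index_cells, ring_size_range = c(5, 7),
                         seed = 1L) {
  archetypes <- as.matrix(archetypes)
  if (nrow(archetypes) != K) stop("archetypes must have K rows")
  if (any(archetypes < 0)) stop("archetype compositions must be nonnegative")
  if (any(abs(rowSums(archetypes) - 1) > 1e-9))
    stop("archetype compositions must sum to 1")
  if (K > n_index_cells) stop("K exceeds the number of index cells")
  tnames <- colnames(archetypes)
  if (is.null(tnames)) stop("archetype columns must be named by cell type")
  set.seed(seed)
  side <- ceiling(sqrt(n_index_cells))
  spacing <- 10
  niche_of <- sample(rep(seq_len(K), length.out = n_index_cells))
  ids_index <- seq_len(n_index_cells)
  xi <- ((ids_index - 1) %% side) * spacing
  yi <- ((ids_index - 1) %/% side) * spacing
  type_index <- sample(tnames, n_index_cells, replace = TRUE)
  rows <- list(data.frame(id = ids_index, x = xi, y = yi, type = type_index,
                          is_index = TRUE, stringsAsFactors = FALSE))
  edges <- list()
  next_id <- n_index_cells + 1L
  for (i in ids_index) {
    m <- sample(seq(ring_size_range[1], ring_size_range[2]), 1)
    ring_types <- sample(tnames, m, replace = TRUE,
                         prob = archetypes[niche_of[i], ])
    ang <- 2 * pi * seq_len(m) / m
    rid <- next_id:(next_id + m - 1L)
    next_id <- next_id + m
    rows[[length(rows) + 1L]] <-
      data.frame(id = rid, x = xi[i] + 2 * cos(ang), y = yi[i] + 2 * sin(ang),
                 type = ring_types, is_index = FALSE, stringsAsFactors = FALSE)
    edges[[length(edges) + 1L]] <- data.frame(i = i, j = rid)
  }
  table <- do.call(rbind, rows)
  ed <- do.call(rbind, edges)
  ed$length <- sqrt((table$x[ed$i] - table$x[ed$j])^2 +
                      (table$y[ed$i] - table$y[ed$j])^2)
  graph <- neighborhood_graph(table[, c("id", "x", "y")], ed,
                              max_edge_length = Inf)
  niche <- c(niche_of, rep(NA_integer_, nrow(table) - n_index_cells))
  list(table = table, graph = graph, niche = niche)
}
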