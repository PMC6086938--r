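#' Build the cell-to-cell spill matrix from shared boundaries
#'
#' Touching cells exchange membrane signal in proportion to the fraction of
#' boundary they share. With \eqn{b_{ij}} the count of voxel faces shared by
#' cells i and j and \eqn{B_j} the total boundary face count of cell j, the
#' spill matrix is column-conservative:
#' \deqn{S_{ij} = c\, b_{ij} / B_j \; (i \ne j), \qquad
#'       S_{jj} = 1 - c \sum_{i \ne j} b_{ij} / B_j.}
#' Columns sum to 1 exactly (total signal per marker is conserved by the
#' forward model) and the matrix is strictly diagonally dominant, hence
#' invertible, for any c < 0.5. Most cells touch only a handful of others, so
#' the matrix is sparse and banded.
#'
#' @param mask a [segmentation_mask()].
#' @param c global spill coefficient in [0, 0.5).
#' @param connectivity 6 (voxel faces; default).
#' @return A \code{spill_matrix}: sparse \code{S}, the contact table, the
#'   per-cell boundary counts and \code{c}.
#' @export
contact_fractions <- function(mask, c = 0.3, connectivity = 6L) {
  stopifnot(inherits(mask, "segmentation_mask"))
  if (connectivity != 6L) stop("only face (6-)connectivity is implemented")
  cf <- cx_contact_faces(mask$labels, dim(mask$labels), mask$n_cells)
  spill_matrix(data.frame(i = cf$i, j = cf$j, faces = cf$faces),
               cf$boundary, c)
}

#' Construct a spill matrix from a contact table
#'
#' Shared constructor used both by the forward spillover model
#' ([apply_spill()]) and by compensation, so the two are consistent by
#' construction.
#'
#' @param contacts data.frame (i, j, faces) of shared boundary face counts
#'   (each unordered pair listed once).
#' @param boundary total boundary face count per cell.
#' @param c spill coefficient in [0, 0.5).
#' @return A \code{spill_matrix}.
#' @export
spill_matrix <- function(contacts, boundary, c) {
  if (c < 0 || c >= 0.5) stop("spill coefficient c must lie in [0, 0.5)")
  n <- length(boundary)
  if (n == 0) {
    S <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0, 0))
    return(structure(list(S = S, contacts = contacts, boundary = boundary,
                          c = c), class = "spill_matrix"))
  }
  i <- c(contacts$i, contacts$j)
  j <- c(contacts$j, contacts$i)
  x <- c * c(contacts$faces, contacts$faces) / boundary[j]
  off_col_sum <- numeric(n)
  if (length(j)) {
    agg <- rowsum(x, j)
    off_col_sum[as.integer(rownames(agg))] <- agg[, 1]
  }
  S <- Matrix::sparseMatrix(i = c(i, seq_len(n)), j = c(j, seq_len(n)),
                            x = c(x, 1 - off_col_sum), dims = c(n, n))
  structure(list(S = S, contacts = contacts, boundary = boundary, c = c),
            class = "spill_matrix")
}

#' @export
print.spill_matrix <- function(x, ...) {
  cat(sprintf("spill_matrix: %d cells, %d touching pairs, c = %.3f\n",
              nrow(x$S), nrow(x$contacts), x$c))
  invisible(x)
}

#' Export a spill matrix as sparse triplets
#' @param spill a \code{spill_matrix}.
#' @param path CSV output path (columns i, j, value).
#' @export
export_spill_matrix <- function(spill, path) {
  tr <- Matrix::summary(spill$S)
  write.csv(data.frame(i = tr$i, j = tr$j, value = tr$x), path,
            row.names = FALSE)
  invisible(path)
}

#' Compensate positional spillover by inverse multiplication
#'
#' Per marker, the compensated intensity vector is \eqn{S^{-1} \cdot raw}.
#' Negative results (possible under noise) are clamped to zero and flagged in
#' a \code{comp_clamped} column; before clamping, per-marker totals are
#' preserved exactly by the column-conservative construction.
#'
#' @param table cell table with marker columns (one row per cell, in label
#'   order matching the spill matrix).
#' @param spill a \code{spill_matrix} from [contact_fractions()].
#' @param markers marker column names; defaults to the table's
#'   \code{markers} attribute.
#' @param clamp_negatives clamp negative compensated values at zero
#'   (default); set FALSE to inspect the raw, exactly signal-conserving
#'   solution.
#' @return The table with compensated marker columns.
#' @export
compensate <- function(table, spill, markers = attr(table, "markers"),
                       clamp_negatives = TRUE) {
  stopifnot(inherits(spill, "spill_matrix"))
  n <- nrow(spill$S)
  if (nrow(table) != n)
    stop("table has ", nrow(table), " rows but spill matrix is ", n, " x ", n)
  if (is.null(markers)) stop("marker columns must be named")
  if (n == 0) return(table)
  X <- as.matrix(table[, markers, drop = FALSE])
  comp <- tryCatch(
    as.matrix(Matrix::solve(spill$S, X)),
    error = function(e) {
      bad <- which(Matrix::diag(spill$S) <= 0)
      stop("spill matrix is singular",
           if (length(bad)) paste0(" (offending cells: ",
                                   paste(head(bad, 10), collapse = ", "), ")"),
           call. = FALSE)
    })
  clamped <- rowSums(comp < 0) > 0
  if (clamp_negatives) comp[comp < 0] <- 0
  out <- table
  for (m in seq_along(markers)) out[[markers[m]]] <- comp[, m]
  out$comp_clamped <- clamped
  attr(out, "markers") <- markers
  for (a in c("nuclear", "blanks", "n_cycles"))
    attr(out, a) <- attr(table, a)
  out
}

#' Cleanup gate configuration
#'
#' @param density_range (min, max) nuclear signal / cell size.
#' @param homogeneity_max maximum relative variance (var/mean^2) of per-cycle
#'   total signal.
#' @param blank_max maximum tolerated intensity on any blank channel.
#' @param size_range (min, max) cell size in voxels.
#' @return A \code{gate_config}.
#' @export
gate_config <- function(density_range = c(0, Inf), homogeneity_max = Inf,
                        blank_max = Inf, size_range = c(0, Inf)) {
  stopifnot(density_range[1] <= density_range[2],
            size_range[1] <= size_range[2])
  structure(list(density_range = density_range,
                 homogeneity_max = homogeneity_max,
                 blank_max = blank_max, size_range = size_range),
            class = "gate_config")
}

#' Derive default gates from a (ground-truth or trusted) cell table
#'
#' Density and size gates at the [1st, 99th] percentile of the provided
#' cells; blank gate at the 99th percentile of blank-channel values.
#'
#' @param table cell table (e.g. quantified phantom ground truth).
#' @param homogeneity_max maximum relative cycle-to-cycle variance.
#' @param lower,upper percentile bounds for the density and size gates.
#' @return A [gate_config()].
#' @export
default_gates <- function(table, homogeneity_max = Inf, lower = 0.01,
                          upper = 0.99) {
  nuclear <- attr(table, "nuclear")
  blanks <- attr(table, "blanks")
  # quantified channels are already sum/size, so the nuclear value is the
  # stain density (nuclear signal divided by cell size)
  dens <- table[[nuclear]]
  bmax <- if (length(blanks))
    max(vapply(blanks, function(b) quantile(table[[b]], upper), numeric(1)))
  else Inf
  gate_config(
    density_range = quantile(dens, c(lower, upper), names = FALSE),
    homogeneity_max = homogeneity_max,
    blank_max = bmax,
    size_range = quantile(table$size, c(lower, upper), names = FALSE))
}

#' Three-step cleanup gating
#'
#' Sequential quality gates removing debris, doublets and autofluorescent
#' objects: (1) nuclear stain density within range AND cycle-to-cycle profile
#' homogeneity below threshold; (2) every blank-channel value at most
#' \code{blank_max}; (3) cell size within range. The gates are applied in
#' order and the report counts removals per gate.
#'
#' @param table quantified cell table (needs nuclear channel, cycle totals,
#'   blank channels and size; see [quantify_cells()]).
#' @param gates a [gate_config()].
#' @return list(table = gated table, report = data.frame(gate, removed,
#'   remaining)).
#' @export
cleanup_gate <- function(table, gates) {
  stopifnot(inherits(gates, "gate_config"))
  nuclear <- attr(table, "nuclear")
  blanks <- attr(table, "blanks")
  n_cycles <- attr(table, "n_cycles")
  if (is.null(blanks)) stop("table carries no blank channels")
  if (is.null(nuclear) || !nuclear %in% names(table))
    stop("table carries no nuclear channel")
  keep <- rep(TRUE, nrow(table))
  report <- data.frame(gate = character(0), removed = integer(0),
                       remaining = integer(0))
  density <- table[[nuclear]]
  ct <- as.matrix(table[, sprintf("cycle_total_%d", seq_len(n_cycles)),
                        drop = FALSE])
  mu <- rowMeans(ct)
  homog <- apply(ct, 1, var) / ifelse(mu > 0, mu^2, Inf)
  g1 <- density >= gates$density_range[1] & density <= gates$density_range[2] &
    homog <= gates$homogeneity_max
  removed <- sum(keep & !g1)
  keep <- keep & g1
  report <- rbind(report, data.frame(gate = "density_homogeneity",
                                     removed = removed,
                                     remaining = sum(keep)))
  if (length(blanks)) {
    bm <- as.matrix(table[, blanks, drop = FALSE])
    g2 <- apply(bm, 1, max) <= gates$blank_max
  } else g2 <- rep(TRUE, nrow(table))
  removed <- sum(keep & !g2)
  keep <- keep & g2
  report <- rbind(report, data.frame(gate = "blank_background",
                                     removed = removed,
                                     remaining = sum(keep)))
  g3 <- table$size >= gates$size_range[1] & table$size <= gates$size_range[2]
  removed <- sum(keep & !g3)
  keep <- keep & g3
  report <- rbind(report, data.frame(gate = "size",
                                     removed = removed,
                                     remaining = sum(keep)))
  out <- table[keep, , drop = FALSE]
  for (a in c("markers", "nuclear", "blanks", "n_cycles"))
    attr(out, a) <- attr(table, a)
  list(table = out, report = report)
}
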