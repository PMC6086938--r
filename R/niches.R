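#' First-tier neighborhood (i-niche) compositions
#'
#' For every index cell, the fraction of each cell type among its first-tier
#' neighbors on the graph (the ring), excluding the index cell's own
#' identity. Isolated nodes (degree 0) are excluded and reported via the
#' \code{degree} attribute.
#'
#' @param graph a [neighborhood_graph()].
#' @param types type label per node.
#' @return Matrix (cells x types) of ring compositions, rows summing to 1
#'   for every included cell; attributes \code{degree} (per node) and
#'   \code{included} (logical per node).
#' @export
niche_composition <- function(graph, types) {
  n <- nrow(graph$nodes)
  if (length(types) != n) stop("need one type label per node")
  tnames <- sort(unique(as.character(types)))
  ti <- match(as.character(types), tnames)
  comp <- matrix(0, n, length(tnames), dimnames = list(graph$nodes$id, tnames))
  ei <- graph$edges$i; ej <- graph$edges$j
  for (k in seq_along(tnames)) {
    # neighbors of type k seen from each endpoint
    comp[, k] <- tabulate(c(ei[ti[ej] == k], ej[ti[ei] == k]), nbins = n)
  }
  degree <- rowSums(comp)
  included <- degree > 0
  comp[included, ] <- comp[included, , drop = FALSE] / degree[included]
  attr(comp, "degree") <- degree
  attr(comp, "included") <- included
  comp
}

#' Niche model
#'
#' K-means centroids over cell-type composition space plus per-cell niche
#' assignment. Niche ids are ordered by decreasing abundance.
#' @keywords internal
new_niche_model <- function(K, centroids, assignment, seed, included) {
  structure(list(K = K, centroids = centroids, assignment = assignment,
                 seed = seed, included = included), class = "niche_model")
}

#' @export
print.niche_model <- function(x, ...) {
  cat(sprintf("niche_model: K = %d, %d assigned index cells\n",
              x$K, sum(!is.na(x$assignment))))
  invisible(x)
}

#' Cluster i-niche compositions with K-means
#'
#' K-means (squared Euclidean, best of \code{n_init} restarts) on the raw
#' composition fraction vectors. The study-scale default is K = 100; smaller
#' K suits phantom-scale data. Cells with fewer than \code{min_neighbors}
#' ring members are excluded from clustering (tiny rings make fraction
#' vectors degenerate) and get an NA assignment.
#'
#' @param compositions matrix from [niche_composition()].
#' @param K number of niches.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param n_init number of random restarts; best inertia kept.
#' @param min_neighbors minimum ring size for inclusion (default 3).
#' @return A \code{niche_model} with K centroids (rows summing to 1) and a
#'   per-cell assignment (NA for excluded cells); niche ids are ordered by
#'   decreasing abundance.
#' @export
cluster_niches <- function(compositions, K = 100L, seed = 1L, n_init = 10L,
                           min_neighbors = 3L) {
  degree <- attr(compositions, "degree") %||% rep(Inf, nrow(compositions))
  use <- degree >= min_neighbors
  X <- compositions[use, , drop = FALSE]
  if (nrow(X) < K)
    stop("K = ", K, " exceeds the ", nrow(X), " clusterable index cells")
  set.seed(seed)
  km <- kmeans(X, centers = K, nstart = n_init, iter.max = 100L)
  # relabel niches by decreasing abundance (ties: original order)
  ord <- order(tabulate(km$cluster, nbins = K), decreasing = TRUE)
  remap <- integer(K); remap[ord] <- seq_len(K)
  assignment <- rep(NA_integer_, nrow(compositions))
  assignment[use] <- remap[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(K)
  new_niche_model(K, centroids, assignment, seed, use)
}

#' Niche-conditioned marker expression profile
#'
#' Mean marker expression of index cells of one chosen type, per niche.
#' Niches holding no index cell of that type are masked (NA), never imputed.
#'
#' @param table cell table with marker columns (compensated, gated
#'   intensities), one row per cell in node order.
#' @param model a \code{niche_model} from [cluster_niches()].
#' @param types type label per cell.
#' @param index_type the central-cell type to profile.
#' @param markers marker column names (default: the table's \code{markers}
#'   attribute).
#' @return list(profile = niches x markers matrix, n_cells = per-niche count
#'   of contributing index cells, masked = logical per niche).
#' @export
niche_marker_profile <- function(table, model, types, index_type,
                                 markers = attr(table, "markers")) {
  if (!index_type %in% types)
    stop("index_type '", index_type, "' absent from data")
  if (is.null(markers)) stop("marker columns must be named")
  sel <- which(types == index_type & !is.na(model$assignment))
  prof <- matrix(NA_real_, model$K, length(markers),
                 dimnames = list(seq_len(model$K), markers))
  n_cells <- integer(model$K)
  if (length(sel)) {
    a <- model$assignment[sel]
    n_cells <- tabulate(a, nbins = model$K)
    for (m in markers) {
      s <- rowsum(table[[m]][sel], a)
      prof[as.integer(rownames(s)), m] <- s[, 1] / n_cells[as.integer(rownames(s))]
    }
  }
  list(profile = prof, n_cells = n_cells, masked = n_cells == 0)
}

#' Distribution of niches over tissue compartments
#'
#' Per niche, the fraction of its index cells falling in each compartment;
#' niches with a dominant compartment (fraction > \code{threshold}, default
#' 0.9) are flagged compartment-specific. Optionally tabulates per-sample
#' niche abundance for tracking across conditions.
#'
#' @param model a \code{niche_model}.
#' @param compartment_of_cell compartment label per cell.
#' @param sample_of_cell optional sample id per cell.
#' @param threshold specificity threshold on the dominant fraction.
#' @return list(fractions = niches x compartments, specific = data.frame of
#'   flagged niches, abundance = niches x samples count matrix or NULL).
#' @export
niche_compartment_distribution <- function(model, compartment_of_cell,
                                           sample_of_cell = NULL,
                                           threshold = 0.9) {
  ok <- !is.na(model$assignment)
  comp <- factor(compartment_of_cell[ok])
  a <- model$assignment[ok]
  tab <- table(factor(a, levels = seq_len(model$K)), comp)
  fractions <- prop.table(as.matrix(tab) + 0, margin = 1)
  fractions[rowSums(tab) == 0, ] <- NA
  dom <- apply(fractions, 1, function(r) if (all(is.na(r))) NA else max(r))
  domc <- apply(fractions, 1, function(r)
    if (all(is.na(r))) NA_character_ else colnames(fractions)[which.max(r)])
  specific <- data.frame(niche = seq_len(model$K), compartment = domc,
                         fraction = dom)[!is.na(dom) & dom > threshold, ]
  abundance <- NULL
  if (!is.null(sample_of_cell)) {
    abundance <- as.matrix(table(factor(a, levels = seq_len(model$K)),
                                 factor(sample_of_cell[ok])))
  }
  list(fractions = fractions, specific = specific, abundance = abundance)
}

#' Does the niche explain marker expression beyond cell type?
#'
#' Nested linear-model comparison: marker ~ type (reduced) against
#' marker ~ type + niche (full), both as categorical factors. The partial
#' F-statistic \eqn{((RSS_r - RSS_f)/\Delta df) / (RSS_f / df_f)} tests
#' whether the neighborhood adds explanatory power over cell identity alone;
#' the gain in variance explained is reported as delta R-squared.
#'
#' @param table cell table with the marker column.
#' @param types type label per cell.
#' @param model a \code{niche_model} (its assignment supplies the niche
#'   factor).
#' @param marker marker column name.
#' @return list(F, p, df1, df2, delta_r2, n).
#' @export
marker_niche_anova <- function(table, types, model, marker) {
  ok <- !is.na(model$assignment)
  y <- table[[marker]][ok]
  type_f <- droplevels(factor(types[ok]))
  niche_f <- droplevels(factor(model$assignment[ok]))
  if (nlevels(type_f) < 1 || nlevels(niche_f) < 2)
    stop("need at least one type level and two occupied niches")
  n <- length(y)
  if (n <= nlevels(type_f) + nlevels(niche_f))
    stop("fewer cells than model parameters")
  if (nlevels(type_f) == 1L) {
    # a single cell type: the reduced model degenerates to intercept-only
    reduced <- lm(y ~ 1)
    full <- lm(y ~ niche_f)
  } else {
    reduced <- lm(y ~ type_f)
    full <- lm(y ~ type_f + niche_f)
  }
  if (any(is.na(coef(full)))) {
    bad <- names(coef(full))[is.na(coef(full))]
    stop("rank-deficient full model; collinear levels: ",
         paste(bad, collapse = ", "))
  }
  aov2 <- anova(reduced, full)
  r2r <- summary(reduced)$r.squared
  r2f <- summary(full)$r.squared
  list(F = aov2$F[2], p = aov2$`Pr(>F)`[2],
       df1 = aov2$Df[2], df2 = aov2$Res.Df[2],
       delta_r2 = r2f - r2r, n = n)
}

#' Assign cell types from external labels or a baseline K-means
#'
#' Phenotype clustering proper is a pluggable input; this provides
#' validation of external labels and a baseline K-means on standardized
#' marker space, with clusters named by their argmax marker.
#'
#' @param table cell table with numeric marker columns.
#' @param method "external_labels" or "baseline_kmeans".
#' @param labels external label vector (method = "external_labels").
#' @param k number of clusters (method = "baseline_kmeans").
#' @param seed RNG seed for the baseline.
#' @param markers marker column names.
#' @return Character vector of type labels, one per row.
#' @export
assign_cell_types <- function(table, method = c("external_labels",
                                                "baseline_kmeans"),
                              labels = NULL, k = 3L, seed = 1L,
                              markers = attr(table, "markers")) {
  method <- match.arg(method)
  if (method == "external_labels") {
    if (is.null(labels)) stop("external_labels method needs labels")
    if (length(labels) != nrow(table))
      stop("label/id mismatch: ", length(labels), " labels for ",
           nrow(table), " cells")
    return(as.character(labels))
  }
  if (is.null(markers)) stop("marker columns must be named")
  X <- as.matrix(table[, markers, drop = FALSE])
  if (!is.numeric(X)) stop("marker columns must be numeric")
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  set.seed(seed)
  km <- kmeans(Xs, centers = k, nstart = 10L, iter.max = 100L)
  if (k == 1L) return(rep(markers[which.max(colMeans(X))], nrow(table)))
  centers_raw <- rowsum(X, km$cluster) / tabulate(km$cluster, nbins = k)
  nm <- markers[apply(centers_raw, 1, which.max)]
  nm <- make.unique(nm)
  nm[km$cluster]
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between clusterings (1 = identical, ~0 =
#' random), used to score recovery of planted niche archetypes and cell
#' types.
#'
#' @param a,b label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
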