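#' Neighborhood graph container
#'
#' Undirected edge list over cell ids with 2-D centroids; no self edges, no
#' duplicate edges, every edge no longer than \code{max_edge_length}.
#'
#' @param nodes data.frame with columns id, x, y.
#' @param edges data.frame with columns i, j (row indices into nodes) and
#'   length.
#' @param max_edge_length pruning length.
#' @return An object of class \code{neighborhood_graph}.
#' @export
neighborhood_graph <- function(nodes, edges, max_edge_length) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("i", "j") %in% names(edges)))
  if (any(edges$i == edges$j)) stop("self edges are not allowed")
  key <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  structure(list(nodes = nodes, edges = edges,
                 max_edge_length = max_edge_length),
            class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat(sprintf("neighborhood_graph: %d nodes, %d edges (max edge length %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$max_edge_length))
  invisible(x)
}

#' First-tier neighborhood graph by pruned 2-D Delaunay triangulation
#'
#' Triangulates the cell centroids and removes edges longer than
#' \code{max_edge_length} (default: 3 times the median Delaunay edge length),
#' so that spurious long-range links across tissue gaps do not count as
#' contacts.
#'
#' @param centroids n x 2 matrix (x, y) or data.frame with x, y and
#'   optionally id.
#' @param max_edge_length numeric, or NULL for the automatic 3 x median rule.
#' @return A [neighborhood_graph()].
#' @export
delaunay_graph <- function(centroids, max_edge_length = NULL) {
  df <- as.data.frame(centroids)
  if (!all(c("x", "y") %in% names(df))) {
    names(df)[1:2] <- c("x", "y")
  }
  if (nrow(df) < 3) stop("Delaunay triangulation needs at least 3 points")
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  dx <- df$x - df$x[1]; dy <- df$y - df$y[1]
  cross <- dx * dy[2] - dy * dx[2]
  scale2 <- max(dx^2 + dy^2)
  if (all(abs(cross) <= 1e-12 * scale2)) stop("all points are collinear")
  tri <- tryCatch(deldir::deldir(df$x, df$y),
                  error = function(e) stop("Delaunay triangulation failed: ",
                                           conditionMessage(e), call. = FALSE))
  del <- tri$delsgs
  if (is.null(del) || nrow(del) == 0) stop("all points are collinear")
  len <- sqrt((del$x1 - del$x2)^2 + (del$y1 - del$y2)^2)
  if (is.null(max_edge_length)) max_edge_length <- 3 * median(len)
  keep <- len <= max_edge_length
  edges <- data.frame(i = pmin(del$ind1, del$ind2)[keep],
                      j = pmax(del$ind1, del$ind2)[keep],
                      length = len[keep])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  neighborhood_graph(df[, c("id", "x", "y")], edges, max_edge_length)
}

#' Cell-type contact counts on a neighborhood graph
#'
#' \eqn{N_{AB}} is the number of graph edges whose endpoint types are
#' \{A, B\}; homotypic edges are counted once, on the diagonal.
#'
#' @param graph a [neighborhood_graph()].
#' @param types type label per node (same order as \code{graph$nodes}).
#' @return Symmetric count matrix over types (diagonal = homotypic counts,
#'   each such edge counted once).
#' @export
interaction_counts <- function(graph, types) {
  if (length(types) != nrow(graph$nodes))
    stop("need one type label per node")
  if (anyNA(types)) stop("unlabeled node(s): types contain NA")
  tnames <- sort(unique(as.character(types)))
  ta <- as.character(types)[graph$edges$i]
  tb <- as.character(types)[graph$edges$j]
  TT <- length(tnames)
  i1 <- match(ta, tnames); i2 <- match(tb, tnames)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  m <- matrix(0, TT, TT, dimnames = list(tnames, tnames))
  tab <- table(factor(lo + TT * (hi - 1), levels = seq_len(TT * TT)))
  m[] <- as.numeric(tab)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Interaction log-odds ratios from a contact count matrix
#'
#' The observed co-occurrence frequency of types A and B is the mean of the
#' Beta distribution with shape \eqn{\alpha = N_{AB}} and
#' \eqn{\beta = E - N_{AB}} (E = total edges), i.e. \eqn{N_{AB}/E}. The
#' expected frequency is \eqn{f_A f_B}, where \eqn{f_A} is the fraction of
#' edges with at least one endpoint of type A. The log-odds ratio is the
#' natural log of observed over expected; a pair with zero observed edges
#' gets a \code{-Inf} sentinel unless a pseudocount is requested. Positive
#' values flag attraction, negative avoidance.
#'
#' @param counts symmetric count matrix from [interaction_counts()].
#' @param pseudocount added to every \eqn{N_{AB}} (default 0; no pseudocount).
#' @param convention "incident": \eqn{f_A} is the fraction of edges with at
#'   least one endpoint of type A and expected is \eqn{f_A f_B} for every
#'   pair. "mixing" (recommended for significance work): \eqn{f_A} is the
#'   half-edge (degree) fraction and the expected co-occurrence under random
#'   mixing is \eqn{2 f_A f_B} for heterotypic pairs and \eqn{f_A^2} for
#'   homotypic pairs, which makes the log-odds of a randomly labeled graph
#'   center on zero. The "incident" form over-counts shared edges, so its
#'   null sits below zero by a type-frequency-dependent offset.
#' @return list(log_odds, observed, expected, f, total_edges).
#' @export
odds_ratio_matrix <- function(counts, pseudocount = 0,
                              convention = c("incident", "mixing")) {
  convention <- match.arg(convention)
  E <- sum(counts[upper.tri(counts, diag = TRUE)])
  if (E < 1) stop("no edges: cannot form odds ratios")
  N <- counts + pseudocount
  Etot <- E + pseudocount * (length(counts) + nrow(counts)) / 2
  obs <- N / Etot
  if (convention == "incident") {
    f <- rowSums(N) / Etot
    expd <- outer(f, f)
  } else {
    f <- (rowSums(N) + diag(N)) / (2 * Etot)
    expd <- 2 * outer(f, f)
    diag(expd) <- f^2
  }
  lo <- suppressWarnings(log(obs / expd))
  lo[N == 0] <- -Inf
  list(log_odds = lo, observed = obs, expected = expd, f = f,
       total_edges = E)
}

#' One-sided binomial p-values for interaction counts
#'
#' For each type pair, the probability of observing at most \eqn{N_{AB}}
#' interactions among E trials at the expected probability \eqn{f_A f_B}
#' (lower tail), so that small p flags avoidance and, after
#' Benjamini-Hochberg correction, q above 0.95 flags attraction. Exact
#' binomial summation is used up to \eqn{E \le 10^4}; above that, a normal
#' approximation with continuity correction.
#'
#' @param counts count matrix from [interaction_counts()].
#' @param convention see [odds_ratio_matrix()]; default "mixing", whose
#'   expected probabilities are calibrated under random labeling.
#' @return Symmetric matrix of lower-tail p-values.
#' @export
binomial_pvalues <- function(counts, convention = "mixing") {
  orm <- odds_ratio_matrix(counts, pseudocount = 0, convention = convention)
  E <- orm$total_edges
  p <- counts
  for (a in seq_len(nrow(counts))) for (b in seq_len(ncol(counts))) {
    prob <- min(max(orm$expected[a, b], 0), 1)
    n_ab <- counts[a, b]
    if (E <= 1e4) {
      p[a, b] <- pbinom(n_ab, E, prob)
    } else {
      mu <- E * prob
      sd <- sqrt(E * prob * (1 - prob))
      if (sd == 0) {
        p[a, b] <- as.numeric(n_ab >= mu)
      } else {
        # continuity-corrected normal with a first-order Edgeworth
        # (skewness) term; keeps |error| well under 1e-3 at the E = 1e4
        # switchover
        z <- (n_ab + 0.5 - mu) / sd
        skew <- (1 - 2 * prob) / sd
        p[a, b] <- min(1, max(0,
          pnorm(z) + dnorm(z) * skew * (1 - z^2) / 6))
      }
    }
  }
  p
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR correction: \eqn{q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j},
#' clipped at 1. Under the study's dual-threshold rule on lower-tail
#' p-values, q < 0.05 flags significant avoidance and q > 0.95 significant
#' attraction.
#'
#' @param p numeric vector (or matrix) of p-values in [0, 1].
#' @param m number of tests (defaults to \code{length(p)}).
#' @return q-values with the same shape as \code{p}.
#' @export
bh_fdr <- function(p, m = length(p)) {
  q <- p.adjust(as.numeric(p), method = "BH", n = m)
  if (is.matrix(p)) q <- matrix(q, nrow(p), ncol(p), dimnames = dimnames(p))
  q
}

#' Dual-threshold significance flags for interaction q-values
#' @param q q-value matrix from [bh_fdr()] on lower-tail p-values.
#' @param level tail level (default 0.05).
#' @return Character matrix: "avoidance", "attraction" or "ns".
#' @export
significance_flags <- function(q, level = 0.05) {
  out <- matrix("ns", nrow(q), ncol(q), dimnames = dimnames(q))
  out[q < level] <- "avoidance"
  out[q > 1 - level] <- "attraction"
  out
}

#' Full interaction analysis of one sample
#'
#' Counts, log-odds ratios, binomial p-values, BH q-values and dual-threshold
#' flags in one call.
#'
#' @param graph a [neighborhood_graph()].
#' @param types type label per node.
#' @param pseudocount,convention see [odds_ratio_matrix()]; the calibrated
#'   "mixing" convention is the analysis default.
#' @return list with counts, log_odds, observed, expected, f, p, q, flags.
#' @export
interaction_analysis <- function(graph, types, pseudocount = 0,
                                 convention = "mixing") {
  counts <- interaction_counts(graph, types)
  orm <- odds_ratio_matrix(counts, pseudocount, convention)
  p <- binomial_pvalues(counts, convention)
  iu <- upper.tri(p, diag = TRUE)
  q <- p
  q[iu] <- bh_fdr(p[iu])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(counts = counts, log_odds = orm$log_odds, observed = orm$observed,
       expected = orm$expected, f = orm$f, p = p, q = q,
       flags = significance_flags(q))
}

#' Cross-condition comparison of interaction counts
#'
#' Per type pair, a two-sample t-test on per-sample interaction counts
#' normalized to each sample's total edge count, BH-FDR corrected across
#' pairs, with the change in mean (normalized) counts and in mean log-odds
#' reported.
#'
#' @param matrices_A,matrices_B lists of per-sample count matrices (shared
#'   type set), one condition each, at least 2 samples per condition.
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return data.frame per unordered type pair: typeA, typeB, t, p, q,
#'   d_count (mean normalized-count difference B - A), d_count_raw,
#'   d_log_odds, zero_variance flag.
#' @export
compare_conditions <- function(matrices_A, matrices_B, var_equal = TRUE) {
  if (length(matrices_A) < 2 || length(matrices_B) < 2)
    stop("need at least 2 samples per condition")
  tn <- rownames(matrices_A[[1]])
  norm_one <- function(m) m / sum(m[upper.tri(m, diag = TRUE)])
  NA_ <- lapply(matrices_A, norm_one)
  NB_ <- lapply(matrices_B, norm_one)
  LA <- lapply(matrices_A, function(m) odds_ratio_matrix(m, convention = "mixing")$log_odds)
  LB <- lapply(matrices_B, function(m) odds_ratio_matrix(m, convention = "mixing")$log_odds)
  rows <- NULL
  for (a in seq_along(tn)) for (b in a:length(tn)) {
    va <- vapply(NA_, function(m) m[a, b], numeric(1))
    vb <- vapply(NB_, function(m) m[a, b], numeric(1))
    zv <- var(va) == 0 && var(vb) == 0
    if (zv && mean(va) == mean(vb)) {
      tt <- list(statistic = 0, p.value = 1)
    } else if (zv) {
      tt <- list(statistic = sign(mean(vb) - mean(va)) * Inf, p.value = 0)
    } else {
      ht <- t.test(vb, va, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    la <- vapply(LA, function(m) m[a, b], numeric(1))
    lb <- vapply(LB, function(m) m[a, b], numeric(1))
    dlo <- if (all(is.finite(la)) && all(is.finite(lb)))
      mean(lb) - mean(la) else NA_real_
    raw_a <- vapply(matrices_A, function(m) m[a, b], numeric(1))
    raw_b <- vapply(matrices_B, function(m) m[a, b], numeric(1))
    rows <- rbind(rows, data.frame(
      typeA = tn[a], typeB = tn[b], t = tt$statistic, p = tt$p.value,
      d_count = mean(vb) - mean(va),
      d_count_raw = mean(raw_b) - mean(raw_a),
      d_log_odds = dlo, zero_variance = zv, stringsAsFactors = FALSE))
  }
  rows$q <- bh_fdr(rows$p)
  rows[, c("typeA", "typeB", "t", "p", "q", "d_count", "d_count_raw",
           "d_log_odds", "zero_variance")]
}

#' Chi deviation of a matrix from a reference distribution
#'
#' Z-transforms each element by the reference mean and SD and returns the
#' square root of the sum of squared z-scores. Elements with zero (or
#' missing) reference SD are excluded and counted. Applicable identically to
#' interaction count matrices and log-odds matrices, which is how the overall
#' magnitude of interaction change versus mixing change is compared across
#' disease stages.
#'
#' @param matrix observed matrix.
#' @param reference_mean,reference_sd element-wise reference statistics
#'   (e.g. mean and SD across control samples).
#' @return list(chi, n_used, n_excluded).
#' @export
chi_deviation <- function(matrix, reference_mean, reference_sd) {
  stopifnot(identical(dim(matrix), dim(reference_mean)),
            identical(dim(matrix), dim(reference_sd)))
  ok <- is.finite(matrix) & is.finite(reference_mean) &
    is.finite(reference_sd) & reference_sd > 0
  if (!any(ok)) stop("all elements excluded (no positive reference SDs)")
  z <- (matrix[ok] - reference_mean[ok]) / reference_sd[ok]
  list(chi = sqrt(sum(z^2)), n_used = sum(ok), n_excluded = sum(!ok))
}

#' Per-pair interaction changes and their drivers
#'
#' Tabulates, per type pair, the change in interaction counts, in log-odds
#' and in summed incident-edge frequencies between two interaction analyses,
#' and reports the ordinary least-squares R-squared of (count change vs
#' log-odds change) and (count change vs frequency-sum change). When count
#' changes track frequency changes better than odds changes, shifts in
#' cell-type abundance - not in interaction propensity - drive the
#' rewiring.
#'
#' @param results_A,results_B outputs of [interaction_analysis()] on the two
#'   conditions (same type sets).
#' @return list(table, r2_odds, r2_freq, n_excluded) where table has one row
#'   per unordered pair.
#' @export
interaction_change_summary <- function(results_A, results_B) {
  tn <- rownames(results_A$counts)
  if (!identical(tn, rownames(results_B$counts)))
    stop("type sets differ between conditions")
  rows <- NULL
  for (a in seq_along(tn)) for (b in a:length(tn)) {
    rows <- rbind(rows, data.frame(
      typeA = tn[a], typeB = tn[b],
      d_count = results_B$counts[a, b] - results_A$counts[a, b],
      d_log_odds = results_B$log_odds[a, b] - results_A$log_odds[a, b],
      d_freq_sum = (results_B$f[a] + results_B$f[b]) -
        (results_A$f[a] + results_A$f[b]),
      stringsAsFactors = FALSE))
  }
  ok <- is.finite(rows$d_log_odds)
  r2 <- function(y, x) {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    summary(lm(y ~ x))$r.squared
  }
  list(table = rows,
       r2_odds = r2(rows$d_count[ok], rows$d_log_odds[ok]),
       r2_freq = r2(rows$d_count, rows$d_freq_sum),
       n_excluded = sum(!ok))
}
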