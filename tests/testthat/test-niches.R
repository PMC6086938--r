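test_that("niche composition excludes the index cell and normalizes", {
  # star: center 1 with neighbors of types A, A, B
  nodes <- data.frame(id = 1:4, x = c(0, 1, -1, 0), y = c(0, 0, 0, 1))
  edges <- data.frame(i = c(1, 1, 1), j = c(2, 3, 4), length = 1)
  g <- neighborhood_graph(nodes, edges, 2)
  comp <- niche_composition(g, c("B", "A", "A", "B"))
  expect_equal(comp[1, ], c(A = 2 / 3, B = 1 / 3))
  # a lone A surrounded by B's: its own identity never leaks into the ring
  comp2 <- niche_composition(g, c("A", "B", "B", "B"))
  expect_equal(comp2[1, ], c(A = 0, B = 1))
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
})

test_that("grid compositions match a brute-force neighbor tally", {
  g <- expand.grid(x = 0:7, y = 0:7)
  gr <- delaunay_graph(g, max_edge_length = 1.1)
  set.seed(3)
  types <- sample(c("A", "B", "C"), nrow(g), replace = TRUE)
  comp <- niche_composition(gr, types)
  for (node in c(1L, 10L, 37L, 64L)) {
    nb <- c(gr$edges$j[gr$edges$i == node], gr$edges$i[gr$edges$j == node])
    tally <- table(factor(types[nb], levels = c("A", "B", "C")))
    expect_equal(unname(comp[node, ]), as.numeric(tally / sum(tally)))
  }
})

test_that("K-means niches: degenerate K, abundance ordering, inertia", {
  comp <- matrix(rep(c(0.5, 0.3, 0.2), 50), 50, 3, byrow = TRUE)
  colnames(comp) <- c("A", "B", "C")
  attr(comp, "degree") <- rep(5, 50)
  m1 <- cluster_niches(comp, K = 1, seed = 1)
  expect_equal(unname(m1$centroids[1, ]), c(0.5, 0.3, 0.2))
  expect_true(all(m1$assignment == 1L))

  pn <- plant_niches(3, separated_archetypes(3), 200, seed = 2L)
  comp <- niche_composition(pn$graph, pn$table$type)
  idx <- which(pn$table$is_index)
  cidx <- comp[idx, , drop = FALSE]
  attr(cidx, "degree") <- attr(comp, "degree")[idx]
  expect_error(cluster_niches(cidx, K = 10000, seed = 1), "exceeds")

  inertia <- function(K) {
    set.seed(7)
    km <- kmeans(cidx, centers = K, nstart = 10)
    km$tot.withinss
  }
  expect_gte(inertia(2), inertia(4))
  expect_gte(inertia(4), inertia(8))

  m <- cluster_niches(cidx, K = 5, seed = 3)
  ab <- tabulate(m$assignment, 5)
  expect_true(all(diff(ab) <= 0))   # ids ordered by decreasing abundance
  # deterministic under a fixed seed
  m2 <- cluster_niches(cidx, K = 5, seed = 3)
  expect_identical(m$assignment, m2$assignment)
})

test_that("planted archetypes are recovered (ARI > 0.9)", {
  arch <- separated_archetypes(3)
  hits <- 0L
  for (s in 1:5) {
    pn <- plant_niches(3, arch, 250, seed = s)
    comp <- niche_composition(pn$graph, pn$table$type)
    idx <- pn$table$is_index
    cidx <- comp[idx, , drop = FALSE]
    attr(cidx, "degree") <- attr(comp, "degree")[idx]
    m <- cluster_niches(cidx, K = 3, seed = s)
    if (adjusted_rand_index(m$assignment, pn$niche[idx]) > 0.9)
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("niche marker profiles mask empty niches and track planted
           effects", {
  set.seed(19)
  n <- 400
  types <- sample(c("T", "B"), n, replace = TRUE)
  assign <- sample.int(10, n, replace = TRUE)
  model <- structure(list(K = 10L, assignment = assign, centroids = NULL,
                          seed = 1L, included = rep(TRUE, n)),
                     class = "niche_model")
  # marker shifted +2 sd for index T cells in niches 1-3
  base <- rnorm(n, 10, 1)
  eff <- ifelse(types == "T" & assign <= 3, 2, 0)
  tab <- data.frame(CD27 = base + eff)
  attr(tab, "markers") <- "CD27"
  prof <- niche_marker_profile(tab, model, types, "T")
  expect_gt(min(prof$profile[1:3, "CD27"]), max(prof$profile[4:10, "CD27"]))

  # masked exactly where no index cell of the type sits
  small <- structure(list(K = 3L,
                          assignment = c(1L, 1L, 3L),
                          centroids = NULL, seed = 1L,
                          included = rep(TRUE, 3)), class = "niche_model")
  tt <- data.frame(CD27 = c(5, 7, 9))
  attr(tt, "markers") <- "CD27"
  pr <- niche_marker_profile(tt, small, c("T", "T", "B"), "T")
  expect_equal(pr$masked, c(FALSE, TRUE, TRUE))
  expect_equal(pr$profile[1, "CD27"], 6)

  # single index cell in a niche: profile equals that cell's expression
  pr2 <- niche_marker_profile(tt, small, c("T", "B", "B"), "T")
  expect_equal(pr2$profile[1, "CD27"], 5)

  expect_error(niche_marker_profile(tt, small, c("T", "T", "B"), "NK"),
               "absent")
})

test_that("compartment distribution flags specific niches", {
  assign <- c(rep(1L, 20), rep(2L, 20))
  comp_of <- c(rep("PALS", 20), rep("PALS", 2), rep("redpulp", 18))
  model <- structure(list(K = 2L, assignment = assign, centroids = NULL,
                          seed = 1L, included = rep(TRUE, 40)),
                     class = "niche_model")
  res <- niche_compartment_distribution(model, comp_of)
  expect_equal(rowSums(res$fractions), c(1, 1), ignore_attr = TRUE)
  expect_true(1 %in% res$specific$niche)        # 100% PALS
  expect_false(2 %in% res$specific$niche)       # 90% is not > 90%
  expect_equal(res$fractions[2, "redpulp"], 0.9, ignore_attr = TRUE)

  # all one compartment: every niche fully specific
  res2 <- niche_compartment_distribution(model, rep("PALS", 40))
  expect_equal(nrow(res2$specific), 2L)
  expect_true(all(res2$specific$fraction == 1))

  # per-sample abundance sums to assignable cells
  res3 <- niche_compartment_distribution(model, comp_of,
                                         sample_of_cell = rep(c("s1", "s2"),
                                                              20))
  expect_equal(sum(res3$abundance), 40)
})

test_that("nested F-test matches hand RSS arithmetic on a toy table", {
  # single type -> reduced model is the intercept-only baseline
  y <- c(1, 2, 3, 7, 8, 9)
  niche <- c(1L, 1L, 1L, 2L, 2L, 2L)
  model <- structure(list(K = 2L, assignment = niche, centroids = NULL,
                          seed = 1L, included = rep(TRUE, 6)),
                     class = "niche_model")
  tab <- data.frame(m = y)
  res <- marker_niche_anova(tab, rep("T", 6), model, "m")
  rss_r <- sum((y - mean(y))^2)                      # 62
  rss_f <- sum((y - rep(c(2, 8), each = 3))^2)       # 4
  F_hand <- ((rss_r - rss_f) / 1) / (rss_f / 4)
  expect_equal(res$F, F_hand)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)
  expect_equal(res$delta_r2, (rss_r - rss_f) / rss_r)
  expect_equal(res$p, pf(F_hand, 1, 4, lower.tail = FALSE))
})

test_that("F-test is calibrated under the null and powered for planted
           niche effects", {
  sim <- function(s, n, K, effect) {
    set.seed(s)
    types <- sample(c("A", "B", "C"), n, replace = TRUE)
    assign <- sample.int(K, n, replace = TRUE)
    y <- c(A = 1, B = 3, C = 5)[types] + rnorm(n) +
      ifelse(assign <= ceiling(K * 0.1), effect, 0)
    model <- structure(list(K = K, assignment = assign, centroids = NULL,
                            seed = s, included = rep(TRUE, n)),
                       class = "niche_model")
    marker_niche_anova(data.frame(m = y), types, model, "m")$p
  }
  null_p <- vapply(1:300, sim, numeric(1), n = 500, K = 12, effect = 0)
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)
  alt_p <- vapply(1:30, sim, numeric(1), n = 5000, K = 20, effect = 1)
  expect_gte(mean(alt_p < 0.05), 0.9)
})

test_that("cell type assignment: passthrough, baseline k-means, k = 1", {
  truth <- adjacency_truth()
  tab <- truth_table(truth)
  ext <- assign_cell_types(tab, "external_labels", labels = truth$types)
  expect_identical(ext, truth$types)
  expect_error(assign_cell_types(tab, "external_labels",
                                 labels = truth$types[-1]), "mismatch")

  km <- assign_cell_types(tab, "baseline_kmeans", k = 3, seed = 2)
  expect_gt(adjusted_rand_index(km, truth$types), 0.95)

  one <- assign_cell_types(tab, "baseline_kmeans", k = 1, seed = 2)
  expect_equal(length(unique(one)), 1L)
})
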