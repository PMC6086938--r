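test_that("Delaunay graph basics: triangle, grid pruning, degenerate input", {
  tri <- delaunay_graph(cbind(c(0, 1, 0.5), c(0, 0, 1)))
  expect_equal(nrow(tri$edges), 3L)
  deg <- tabulate(c(tri$edges$i, tri$edges$j), 3)
  expect_equal(deg, c(2L, 2L, 2L))

  # unit 10x10 grid pruned at 1.1: only the 180 axis-aligned edges survive
  g <- expand.grid(x = 0:9, y = 0:9)
  gr <- delaunay_graph(g, max_edge_length = 1.1)
  expect_equal(nrow(gr$edges), 180L)
  # brute-force pairwise-distance oracle
  dm <- as.matrix(dist(g))
  expect_equal(sum(dm[upper.tri(dm)] <= 1.1), 180L)
  expect_true(all(gr$edges$length <= 1.1))

  expect_error(delaunay_graph(cbind(c(0, 1), c(0, 0))), "at least 3")
  expect_error(delaunay_graph(cbind(0:4, 0:4)), "collinear")
})

test_that("interaction counts match enumeration and relabeling symmetry", {
  sq <- square_graph()
  counts <- interaction_counts(sq$graph, sq$types)
  expect_equal(counts["A", "B"], 2)
  expect_equal(counts["A", "A"], 1)
  expect_equal(counts["B", "B"], 1)
  expect_equal(sum(counts[upper.tri(counts, diag = TRUE)]), 4)

  renamed <- c(A = "Q", B = "Z")[sq$types]
  counts2 <- interaction_counts(sq$graph, renamed)
  expect_equal(counts2["Q", "Z"], counts["A", "B"])
  expect_equal(counts2["Q", "Q"], counts["A", "A"])

  expect_error(interaction_counts(sq$graph, c("A", NA, "A", "B")),
               "unlabeled")

  # larger planted graph against an independent edge loop
  pl <- plant_interactions(2000, c(A = 0.4, B = 0.3, C = 0.3), seed = 5L)
  cts <- interaction_counts(pl$graph, pl$table$type)
  brute <- matrix(0, 3, 3, dimnames = dimnames(cts))
  for (k in seq_len(nrow(pl$graph$edges))) {
    a <- pl$table$type[pl$graph$edges$i[k]]
    b <- pl$table$type[pl$graph$edges$j[k]]
    brute[a, b] <- brute[a, b] + 1
    if (a != b) brute[b, a] <- brute[b, a] + 1
  }
  expect_equal(cts, brute)
})

test_that("odds ratios reproduce the hand-enumerated square graph", {
  sq <- square_graph()
  counts <- interaction_counts(sq$graph, sq$types)
  orm <- odds_ratio_matrix(counts)   # incident-edge convention
  expect_equal(orm$observed["A", "B"], 0.5)
  expect_equal(unname(orm$f), c(0.75, 0.75))
  expect_equal(orm$expected["A", "B"], 0.5625)
  expect_equal(orm$log_odds["A", "B"], log(0.5 / 0.5625))

  # a single A-B edge: observed = expected = 1, log-odds 0
  g1 <- neighborhood_graph(data.frame(id = 1:3, x = c(0, 1, 5), y = c(0, 0, 5)),
                           data.frame(i = 1, j = 2, length = 1), 2)
  o1 <- odds_ratio_matrix(interaction_counts(g1, c("A", "B", "A"))[1:2, 1:2])
  expect_equal(o1$log_odds["A", "B"], 0)

  # zero-count pair with both types present: -Inf sentinel
  gAB <- square_graph()
  ctsAA <- interaction_counts(gAB$graph, c("A", "A", "A", "B"))
  oAA <- odds_ratio_matrix(ctsAA)
  expect_identical(oAA$log_odds["B", "B"], -Inf)

  expect_error(odds_ratio_matrix(matrix(0, 2, 2)), "no edges")
})

test_that("the mixing convention centers randomly labeled graphs on zero", {
  pl <- plant_interactions(1500, c(A = 0.5, B = 0.5), seed = 9L)
  counts <- interaction_counts(pl$graph, pl$table$type)
  lo_mix <- odds_ratio_matrix(counts, convention = "mixing")$log_odds
  expect_lt(max(abs(lo_mix)), 0.15)
  # the incident convention sits below zero on the same null graph
  lo_inc <- odds_ratio_matrix(counts, convention = "incident")$log_odds
  expect_lt(max(lo_inc), -0.05)
})

test_that("binomial p-values: exact values and the approximation boundary", {
  # expected = 0 with zero observed: p = 1
  counts <- matrix(c(10, 0, 0, 0), 2, 2, dimnames = list(c("A", "B"),
                                                         c("A", "B")))
  p <- binomial_pvalues(counts, convention = "incident")
  expect_equal(p["B", "B"], 1)

  # E = 10, expected 0.5, observed 0 -> p = 2^-10 (hand-checkable tail)
  expect_equal(pbinom(0, 10, 0.5), 2^-10)
  d10 <- matrix(c(5, 0, 0, 5), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  orm <- odds_ratio_matrix(d10, convention = "mixing")
  pd <- binomial_pvalues(d10, convention = "mixing")
  expect_equal(pd["A", "B"],
               pbinom(0, 10, orm$expected["A", "B"]))

  # the approximation path agrees with exact summation at the switchover
  # scale: build a graph with just over 1e4 edges so binomial_pvalues takes
  # the normal branch, then compare with the exact oracle
  set.seed(17)
  E <- 10020L
  for (target in c(0.03, 0.1, 0.3)) {
    n_ab <- rbinom(1, E, target)
    n_ba <- round((E - n_ab) * 0.6)
    counts <- matrix(c(n_ab, E - n_ab - n_ba, E - n_ab - n_ba, n_ba), 2, 2,
                     dimnames = list(c("A", "B"), c("A", "B")))
    approx <- binomial_pvalues(counts, convention = "mixing")
    expected <- odds_ratio_matrix(counts, convention = "mixing")$expected
    for (a in 1:2) for (b in 1:2) {
      exact <- pbinom(counts[a, b], E, expected[a, b])
      expect_lt(abs(exact - approx[a, b]), 1e-3)
    }
  }
})

test_that("BH q-values match the brute-force step-up oracle", {
  # hand computation on the worked 4-value example
  p <- c(0.01, 0.02, 0.04, 0.05)
  expect_equal(bh_fdr(p), c(0.04, 0.04, 0.05, 0.05))

  # step-up oracle: q_(i) = min_{j >= i} m p_(j) / j, on random vectors
  bh_oracle <- function(p, m = length(p)) {
    o <- order(p)
    q <- numeric(length(p))
    sorted <- p[o]
    running <- Inf
    for (i in rev(seq_along(sorted))) {
      running <- min(running, m * sorted[i] / i)
      q[i] <- min(running, 1)
    }
    out <- numeric(length(p))
    out[o] <- q
    out
  }
  set.seed(23)
  for (rep in 1:100) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }

  # permutation equivariance
  p <- runif(12)
  perm <- sample(12)
  expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
  # all-equal p-values are their own q-values
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
})

test_that("cross-condition comparison: identity, textbook t, planted shift", {
  sq <- square_graph()
  base <- interaction_counts(sq$graph, sq$types)
  mats <- list(base, base + 1, base + 2)
  same <- compare_conditions(mats, mats)
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1 | same$zero_variance == FALSE))

  # textbook two-sample t on {1,2,3} vs {4,5,6} via 1x1 count matrices
  mk <- function(v) matrix(v, 1, 1, dimnames = list("A", "A"))
  fake_A <- lapply(c(1, 2, 3) * 10, mk)
  fake_B <- lapply(c(4, 5, 6) * 10, mk)
  # normalized counts are all 1 for a single pair; use raw-count delta instead
  res <- compare_conditions(fake_A, fake_B)
  expect_equal(res$d_count_raw, 30)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(unname(tt$statistic), 3.6742346, tolerance = 1e-6)

  # planted adjacency shift in one pair across 3 + 3 phantom samples:
  # condition B carries 200 extra A-B contacts on top of sample noise
  make_counts <- function(seed, boost = 0) {
    pl <- plant_interactions(600, c(A = 0.25, B = 0.25, C = 0.5),
                             seed = seed)
    cts <- interaction_counts(pl$graph, pl$table$type)
    cts["A", "B"] <- cts["A", "B"] + boost
    cts["B", "A"] <- cts["B", "A"] + boost
    cts
  }
  ctrl <- lapply(1:3, make_counts)
  case <- lapply(4:6, make_counts, boost = 200)
  cmp <- compare_conditions(ctrl, case)
  hit_row <- which(cmp$typeA == "A" & cmp$typeB == "B")
  expect_equal(which.min(cmp$q), hit_row)
  expect_gt(cmp$d_count_raw[hit_row], 150)
})

test_that("chi deviation: zero at reference, analytic one, brute force", {
  m <- matrix(1:9, 3, 3)
  ref_sd <- matrix(2, 3, 3)
  at_ref <- chi_deviation(m, m, ref_sd)
  expect_equal(at_ref$chi, 0)

  one_off <- m
  one_off[2, 2] <- m[2, 2] + 2    # exactly one element, one sd away
  expect_equal(chi_deviation(one_off, m, ref_sd)$chi, 1)

  set.seed(31)
  x <- matrix(rnorm(9), 3, 3)
  mu <- matrix(rnorm(9), 3, 3)
  sd_ <- matrix(runif(9, 0.5, 2), 3, 3)
  brute <- 0
  for (i in 1:3) for (j in 1:3) brute <- brute + ((x[i, j] - mu[i, j]) / sd_[i, j])^2
  expect_equal(chi_deviation(x, mu, sd_)$chi, sqrt(brute))

  # zero-sd elements are excluded and counted; all-excluded errors
  sd0 <- sd_; sd0[1, 1] <- 0
  expect_equal(chi_deviation(x, mu, sd0)$n_excluded, 1L)
  expect_error(chi_deviation(x, mu, matrix(0, 3, 3)), "excluded")

  # monotone under amplification of deviations
  amp <- mu + 2 * (x - mu)
  expect_gt(chi_deviation(amp, mu, sd_)$chi, chi_deviation(x, mu, sd_)$chi)
})

test_that("interaction change summary: identity, hand OLS, frequency-driven
           rewiring", {
  pl <- plant_interactions(800, c(A = 0.4, B = 0.3, C = 0.3), seed = 15L)
  ia <- interaction_analysis(pl$graph, pl$table$type)
  same <- interaction_change_summary(ia, ia)
  expect_true(all(same$table$d_count == 0))
  expect_true(is.na(same$r2_odds))

  # hand OLS on a 3-pair toy
  fake <- function(counts, lo, f) list(counts = counts, log_odds = lo, f = f)
  cts_a <- matrix(c(10, 5, 5, 8), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  lo_a <- matrix(0, 2, 2, dimnames = dimnames(cts_a))
  cts_b <- cts_a + matrix(c(6, 2, 2, 4), 2, 2)
  lo_b <- matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2, dimnames = dimnames(cts_a))
  f_a <- c(A = 0.5, B = 0.5); f_b <- c(A = 0.55, B = 0.45)
  s <- suppressWarnings(interaction_change_summary(fake(cts_a, lo_a, f_a),
                                                   fake(cts_b, lo_b, f_b)))
  y <- s$table$d_count; x <- s$table$d_log_odds
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  expect_equal(s$r2_odds, 1 - ss_res / sum((y - mean(y))^2))

  # when counts scale with type frequencies at fixed mixing, the frequency
  # co-distribution explains the count changes better than the odds one
  set.seed(41)
  plA <- plant_interactions(1200, c(A = 0.25, B = 0.25, C = 0.5), seed = 51L)
  plB <- plant_interactions(1200, c(A = 0.45, B = 0.15, C = 0.4), seed = 52L)
  iaA <- interaction_analysis(plA$graph, plA$table$type)
  iaB <- interaction_analysis(plB$graph, plB$table$type)
  chg <- interaction_change_summary(iaA, iaB)
  expect_gt(chg$r2_freq, chg$r2_odds)
})
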