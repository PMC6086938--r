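# Shared fixtures, built once per test run and cached in this environment.
# All fixture parameters are fixed here: these are the standard phantom
# conditions the whole suite (and the acceptance checks) run under.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Standard dense phantom: 200 touching cells, fixed seed.
dense_spec <- function() {
  phantom_spec(image_shape = c(192L, 192L, 9L), n_cells = 200L,
               blank_cycles = 3L, seed = 7L)
}
dense_truth <- function() memo("dense_truth", make_cell_map(dense_spec()))
dense_stack <- function() memo("dense_stack",
                               render_image_stack(dense_truth(), dense_spec()))
dense_mask <- function() memo("dense_mask", {
  segment_stack(dense_stack(), cutoff_fraction = 0.45, min_distance = 3,
                min_size = 30)
})

# Easy phantom: well-separated cells (centers >= 3 radii apart via low count).
easy_spec <- function() {
  phantom_spec(image_shape = c(128L, 128L, 9L), n_cells = 20L,
               cell_radius_range = c(4, 4.5), blank_cycles = 3L, seed = 21L)
}
easy_truth <- function() memo("easy_truth", make_cell_map(easy_spec()))
easy_stack <- function() memo("easy_stack",
                              render_image_stack(easy_truth(), easy_spec()))

# Adjacency phantom: the standard geometry for spillover work (dense packing,
# mutually exclusive lineage markers on touching neighbors).
adjacency_truth <- function() memo("adjacency_truth", {
  make_cell_map(phantom_spec(image_shape = c(128L, 128L, 9L), n_cells = 120L,
                             seed = 11L))
})

# True expression as a marker table in label order.
truth_table <- function(truth) {
  tab <- as.data.frame(truth$expression)
  tab <- cbind(id = seq_len(nrow(tab)), tab)
  attr(tab, "markers") <- colnames(truth$expression)
  tab
}

# Well-separated niche archetypes: one dominant type per archetype, at the
# purity of real lymphoid compartments (a follicle ring is ~90% B cells).
separated_archetypes <- function(K = 3) {
  tn <- LETTERS[seq_len(max(3, K))]
  arch <- matrix(0.1 / (length(tn) - 1), K, length(tn),
                 dimnames = list(NULL, tn))
  for (k in seq_len(K)) arch[k, k] <- 0.9
  arch
}

# Tiny deterministic graph used across interaction tests: 4 nodes in a
# square, edges A-B, A-B, A-A, B-B.
square_graph <- function() {
  nodes <- data.frame(id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  edges <- data.frame(i = c(1, 3, 1, 2), j = c(2, 4, 3, 4),
                      length = c(1, 1, 1, 1))
  list(graph = neighborhood_graph(nodes, edges, max_edge_length = 2),
       types = c("A", "B", "A", "B"))
}
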