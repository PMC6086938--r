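#' Run the full processing pipeline on a phantom
#'
#' Phantom generation, rendering, TIFF round trip, drift alignment,
#' segmentation, quantification, spillover compensation, cleanup gating,
#' interaction statistics and i-niche clustering, emitting every declared
#' artifact (stack TIFF, mask TIFF, cell tables as CSV and FCS, spill matrix
#' CSV, interaction and niche CSVs) into \code{output_dir}.
#'
#' @param output_dir directory for artifacts (created if missing).
#' @param spec a [phantom_spec()]; the default is a modest dense phantom.
#' @param k_niches K for i-niche clustering.
#' @param spill_c compensation coefficient (matches the phantom's forward
#'   spill by default).
#' @return Invisible list with every intermediate object.
#' @export
run_pipeline <- function(output_dir,
                         spec = phantom_spec(image_shape = c(128L, 128L, 9L),
                                             n_cells = 120L,
                                             noise_gaussian_sd = 2,
                                             blank_cycles = 3L,
                                             seed = 11L),
                         k_niches = 10L, spill_c = spec$spill_c) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(output_dir, ...)

  truth <- make_cell_map(spec)
  stack <- render_image_stack(truth, spec)
  write_stack(stack, p("stack.tif"))
  stack <- read_stack(p("stack.tif"))

  drift <- estimate_drift(stack)
  stack <- apply_shifts(stack, drift)

  nucleus_r <- spec$cell_radius_range[1] * spec$nucleus_radius_fraction
  mask <- segment_stack(stack, cutoff_fraction = min(1, 1 / nucleus_r),
                        min_distance = max(3, floor(nucleus_r)),
                        min_size = 30)
  write_mask(mask, p("mask.tif"))
  bench <- benchmark_segmentation(mask, truth$centers)

  cells <- quantify_cells(mask, stack)
  export_cells(cells, p("cells_raw.csv"), "csv")

  spill <- contact_fractions(mask, c = spill_c)
  export_spill_matrix(spill, p("spill_matrix.csv"))
  cells_comp <- compensate(cells, spill)

  gates <- default_gates(cells_comp)
  gated <- cleanup_gate(cells_comp, gates)
  export_cells(gated$table, p("cells.csv"), "csv")
  export_cells(gated$table, p("cells.fcs"), "fcs")
  write.csv(gated$report, p("gate_report.csv"), row.names = FALSE)

  tab <- gated$table
  types <- assign_cell_types(tab, "baseline_kmeans",
                             k = length(spec$cell_types), seed = spec$seed)
  graph <- delaunay_graph(tab[, c("x", "y")])
  ia <- interaction_analysis(graph, types)
  long <- NULL
  tn <- rownames(ia$counts)
  for (a in seq_along(tn)) for (b in a:length(tn)) {
    long <- rbind(long, data.frame(
      typeA = tn[a], typeB = tn[b], count = ia$counts[a, b],
      log_odds = ia$log_odds[a, b], p = ia$p[a, b], q = ia$q[a, b],
      flag = ia$flags[a, b]))
  }
  write.csv(long, p("interactions.csv"), row.names = FALSE)

  comp <- niche_composition(graph, types)
  model <- cluster_niches(comp, K = k_niches, seed = spec$seed)
  write.csv(data.frame(id = tab$id, niche = model$assignment),
            p("niche_assignment.csv"), row.names = FALSE)
  write.csv(model$centroids, p("niche_centroids.csv"), row.names = TRUE)
  prof <- niche_marker_profile(tab, model, types, index_type = types[1])
  pr <- as.data.frame(prof$profile)
  pr$masked <- prof$masked
  write.csv(pr, p("niche_profile.csv"), row.names = TRUE)

  invisible(list(truth = truth, stack = stack, drift = drift, mask = mask,
                 benchmark = bench, cells = cells, spill = spill,
                 gated = gated, types = types, graph = graph,
                 interactions = ia, niche_model = model, profile = prof))
}
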