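#' Convert filament-tracer VRML exports to a hierarchical tracing
#'
#' The full skeleton-generation pipeline: each input file (one neurite per
#' file, its first fragment closest to the soma) is parsed into fragments;
#' shaft fragments become radius-annotated polylines and are reconnected
#' into a rooted tree, with the connection threshold searched automatically
#' unless given; spine fragments (main geometry only, when an artificial
#' insertion sphere shares the identifier) are attached as spine
#' annotations; near-duplicate points from fragment overlap zones are
#' removed; and a soma is added per `soma_source`, trimming neurite starts
#' that fall inside it.
#'
#' @param paths character vector of VRML files.
#' @param parts neuron part per file (`basal`, `apical` or `axon`),
#'   recycled.
#' @param threshold fixed connection threshold in microns, or `NULL` for
#'   the automatic search.
#' @param cfg a [threshold_config()] for the automatic search.
#' @param soma_source one of `"none"`, `"neurites"` (sphere from
#'   first-order starts), or a [soma_sphere()] / [soma_contours()] /
#'   [soma_mesh()] model.
#' @param dedupe_epsilon repeated-point removal distance in microns.
#' @return a [neuron_tracing()] with attributes `"thresholds"` (chosen
#'   threshold per file) and `"n_unattached_spines"`.
#' @export
vrml_to_tracing <- function(paths, parts = "basal", threshold = NULL,
                            cfg = threshold_config(),
                            soma_source = "neurites",
                            dedupe_epsilon = 1e-3) {
  parts <- rep_len(parts, length(paths))
  combined_nodes <- empty_nodes()
  spine_polys <- list()
  thresholds <- numeric(0)
  id_offset <- 0L
  for (fi in seq_along(paths)) {
    frags <- read_filament_vrml(paths[fi])
    shafts <- Filter(function(f) f$kind == "shaft", frags)
    spines <- Filter(function(f) f$kind == "spine", frags)
    if (!length(shafts))
      stop_neurofil(sprintf("no shaft fragments in '%s'", paths[fi]),
                    "neurofil_empty_input")
    polys <- lapply(shafts, fragment_to_polyline)
    if (is.null(threshold)) {
      res <- auto_connection_threshold(polys, cfg, part = parts[fi])
      tr <- res$tree
      thr <- res$threshold
    } else {
      tr <- build_neurite_tree(polys, threshold, part = parts[fi])
      thr <- threshold
    }
    tr <- dedupe_tree(tr, dedupe_epsilon)
    thresholds <- c(thresholds, thr)
    # select main spine geometries (per repeated identifier) and keep their
    # polylines for attachment against the combined tracing
    if (length(spines)) {
      by_id <- split(spines, vapply(spines, `[[`, character(1),
                                    "source_identifier"))
      for (grp in by_id)
        spine_polys[[length(spine_polys) + 1]] <-
          fragment_to_polyline(select_main_spine_geometry(grp))
    }
    nd <- tr$nodes
    nd$id <- nd$id + id_offset
    nd$parent <- ifelse(nd$parent == 0L, 0L, nd$parent + id_offset)
    combined_nodes <- rbind(combined_nodes, nd)
    id_offset <- max(combined_nodes$id)
  }
  t <- neuron_tracing(combined_nodes)
  attach_thr <- if (is.null(threshold)) max(thresholds) else threshold
  n_before <- length(spine_polys)
  if (n_before) {
    nw <- 0L
    withCallingHandlers(
      t <- attach_spines(t, spine_polys, attach_thr),
      warning = function(w) {
        nw <<- nw + 1L
        invokeRestart("muffleWarning")
      })
  }
  soma <- NULL
  if (inherits(soma_source, "soma_model")) soma <- soma_source
  else if (identical(soma_source, "neurites")) {
    starts <- t$nodes[t$nodes$parent == 0, c("x", "y", "z"), drop = FALSE]
    if (nrow(starts) >= 2)
      soma <- soma_sphere_from_neurites(as.matrix(starts))
  }
  if (!is.null(soma)) t <- trim_neurite_starts(t, soma)
  t <- renumber_tracing(t)
  attr(t, "thresholds") <- thresholds
  attr(t, "n_unattached_spines") <- n_before - nrow(t$spines)
  t
}
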