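# Standard 7-column SWC export: id, type, x, y, z, radius, parent.
# Types: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite; spines are
# written as custom type 5 or omitted.

part_to_swc_type <- function(part) {
  switch(part, soma = 1L, axon = 2L, basal = 3L, apical = 4L, spine = 5L, 3L)
}

#' Write a tracing to SWC
#'
#' Standard 7-column SWC, parents always preceding children. The soma is
#' collapsed to a single type-1 point: its centroid plus an equivalent
#' radius (sphere radius directly, or the radius of the sphere with the
#' model's volume for contour/mesh somata). Neurite roots attach to the
#' soma row when one exists, else have parent -1. Spines are omitted or
#' appended as custom type-5 rows attached to their insertion point,
#' depending on `spine_policy`.
#'
#' @param t a valid [neuron_tracing()].
#' @param path output path.
#' @param spine_policy `"omit"` or `"as_custom_type"`.
#' @return `path`, invisibly.
#' @export
write_swc <- function(t, path, spine_policy = c("omit", "as_custom_type")) {
  spine_policy <- match.arg(spine_policy)
  viol <- validate_tracing(t)
  if (nrow(viol))
    stop_neurofil(paste0("invalid tracing: ", viol$rule[1]),
                  "neurofil_invalid_tracing")
  rows <- character(0)
  offset <- 0L
  soma_id <- -1L
  if (!is.null(t$soma)) {
    sc <- soma_centroid_radius(t$soma)
    rows <- c(rows, sprintf("1 1 %.4f %.4f %.4f %.4f -1",
                            sc$center[1], sc$center[2], sc$center[3],
                            sc$radius))
    offset <- 1L
    soma_id <- 1L
  }
  nd <- t$nodes
  for (i in seq_len(nrow(nd))) {
    parent <- if (nd$parent[i] == 0L) soma_id else nd$parent[i] + offset
    rows <- c(rows, sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                            nd$id[i] + offset, part_to_swc_type(nd$part[i]),
                            nd$x[i], nd$y[i], nd$z[i], nd$radius[i], parent))
  }
  if (spine_policy == "as_custom_type" && nrow(t$spines)) {
    nid <- nrow(nd) + offset
    for (s in seq_len(nrow(t$spines))) {
      nid <- nid + 1L
      rows <- c(rows, sprintf("%d 5 %.4f %.4f %.4f %.4f %d",
                              nid, t$spines$x[s], t$spines$y[s],
                              t$spines$z[s], t$spines$radius[s],
                              t$spines$parent_id[s] + offset))
    }
  }
  writeLines(c("# generated by neurofil",
               "# id type x y z radius parent", rows), path)
  invisible(path)
}

soma_centroid_radius <- function(soma) {
  switch(soma$variant,
         sphere = list(center = soma$center, radius = soma$radius),
         contour_stack = {
           m <- soma_from_contours(soma$contours, remesh = FALSE)
           mm <- mesh_metrics(m)
           list(center = mm$mass_center,
                radius = (3 * mm$volume / (4 * pi))^(1 / 3))
         },
         mesh = {
           mm <- mesh_metrics(soma$mesh)
           list(center = mm$mass_center,
                radius = (3 * mm$volume / (4 * pi))^(1 / 3))
         })
}

#' Read an SWC file
#' @param path an SWC file written by [write_swc()] (or any standard
#'   7-column SWC).
#' @return a [neuron_tracing()]; a type-1 row becomes a sphere soma.
#' @export
read_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!startsWith(trimws(lines), "#")])
  lines <- lines[nzchar(lines)]
  M <- do.call(rbind, lapply(strsplit(lines, "[ \t]+"), as.numeric))
  colnames(M) <- c("id", "type", "x", "y", "z", "radius", "parent")
  soma_rows <- M[, "type"] == 1
  soma <- if (any(soma_rows)) {
    r1 <- M[which(soma_rows)[1], ]
    soma_sphere(r1[c("x", "y", "z")], r1["radius"])
  } else NULL
  spine_rows <- M[, "type"] == 5
  keep <- !soma_rows & !spine_rows
  Mn <- M[keep, , drop = FALSE]
  id_map <- stats::setNames(seq_len(nrow(Mn)), Mn[, "id"])
  parent <- vapply(Mn[, "parent"], function(p) {
    if (p < 0 || !(as.character(p) %in% names(id_map)) ) 0L
    else as.integer(id_map[[as.character(p)]])
  }, integer(1))
  part <- c("soma", "axon", "basal", "apical", "spine")[
    pmin(pmax(Mn[, "type"], 1), 5)]
  nodes <- data.frame(id = seq_len(nrow(Mn)), parent = parent,
                      x = Mn[, "x"], y = Mn[, "y"], z = Mn[, "z"],
                      radius = Mn[, "radius"], part = part,
                      stringsAsFactors = FALSE)
  spines <- if (any(spine_rows)) {
    Ms <- M[spine_rows, , drop = FALSE]
    data.frame(x = Ms[, "x"], y = Ms[, "y"], z = Ms[, "z"],
               radius = Ms[, "radius"],
               parent_id = as.integer(id_map[as.character(Ms[, "parent"])]))
  } else empty_spines()
  neuron_tracing(nodes, soma = soma, spines = spines)
}
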