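#' Core morphology model
#'
#' A `neuron_tracing` is a rooted forest of tracing points. Nodes live in a
#' parent-pointer table (one row per point: id, parent, position, radius,
#' neuron part), so branch decomposition is always derived from the table and
#' the two views cannot fall out of step. Spines are annotations: a single
#' end-point plus a reference to the tracing point it is inserted on; they
#' never alter neurite topology.
#'
#' @param nodes data frame with columns `id` (1..n), `parent` (0 for a
#'   neurite root), `x`, `y`, `z` (microns), `radius` (microns) and `part`
#'   (one of soma, axon, apical, basal, spine).
#' @param soma optional [soma_model()].
#' @param spines data frame of spine attachments with columns `x`, `y`, `z`
#'   (spine end point), `radius` and `parent_id` (insertion tracing point).
#' @return an object of class `neuron_tracing`.
#' @export
neuron_tracing <- function(nodes,
                           soma = NULL,
                           spines = empty_spines()) {
  nodes <- as.data.frame(nodes)
  stopifnot(all(c("id", "parent", "x", "y", "z", "radius", "part") %in%
                  names(nodes)))
  structure(list(nodes = nodes, soma = soma, spines = as.data.frame(spines)),
            class = "neuron_tracing")
}

empty_spines <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
             radius = numeric(0), parent_id = integer(0))
}

empty_nodes <- function() {
  data.frame(id = integer(0), parent = integer(0), x = numeric(0),
             y = numeric(0), z = numeric(0), radius = numeric(0),
             part = character(0), stringsAsFactors = FALSE)
}

TRACING_PARTS <- c("soma", "axon", "apical", "basal", "spine")

#' @export
print.neuron_tracing <- function(x, ...) {
  nb <- tryCatch(length(iter_branches(x)), error = function(e) NA)
  cat(sprintf(
    "<neuron_tracing: %d points, %d neurite(s), %s branch(es), %d spine(s)%s>\n",
    nrow(x$nodes), sum(x$nodes$parent == 0), nb, nrow(x$spines),
    if (!is.null(x$soma)) paste0(", soma: ", x$soma$variant) else ""))
  invisible(x)
}

node_xyz <- function(t) as.matrix(t$nodes[, c("x", "y", "z")])

n_children <- function(t) {
  nd <- t$nodes
  tabulate(match(nd$parent[nd$parent > 0], nd$id), nbins = nrow(nd))
}

#' Validate a tracing against the model invariants
#'
#' Diagnostic operation: checks the structural rules a tracing must obey —
#' acyclicity with parents preceding children, known part labels, finite
#' coordinates, non-negative radii, no consecutive points closer than the
#' dedupe epsilon, and spine attachments referring to existing points.
#'
#' @param t a [neuron_tracing()].
#' @param epsilon minimum distance (microns) allowed between a parent and a
#'   child point; defaults to the package dedupe epsilon of 1e-3.
#' @return data frame of violations (zero rows when valid) with columns
#'   `node`, `rule` and `detail`.
#' @export
validate_tracing <- function(t, epsilon = 1e-3) {
  v <- list()
  add <- function(node, rule, detail)
    v[[length(v) + 1]] <<- data.frame(node = node, rule = rule,
                                      detail = detail)
  nd <- t$nodes
  if (nrow(nd) == 0)
    return(data.frame(node = integer(0), rule = character(0),
                      detail = character(0)))
  if (any(duplicated(nd$id)))
    add(nd$id[duplicated(nd$id)][1], "duplicate id", "node ids must be unique")
  # cycle / ordering check by walking parents
  idx <- match(nd$parent, nd$id)
  for (i in seq_len(nrow(nd))) {
    seen <- integer(0)
    j <- i
    while (!is.na(j) && nd$parent[j] != 0) {
      if (nd$id[j] %in% seen) {
        add(nd$id[i], "cycle", "node is its own ancestor")
        break
      }
      seen <- c(seen, nd$id[j])
      j <- idx[j]
      if (is.na(j)) {
        add(nd$id[i], "missing parent", "parent id not present")
        break
      }
    }
  }
  bad_order <- which(nd$parent > 0 &
                       match(nd$parent, nd$id) >= seq_len(nrow(nd)))
  for (i in bad_order)
    add(nd$id[i], "parent order", "parent must precede child")
  for (i in which(!nd$part %in% TRACING_PARTS))
    add(nd$id[i], "unknown part", nd$part[i])
  for (i in which(!is.finite(nd$x) | !is.finite(nd$y) | !is.finite(nd$z)))
    add(nd$id[i], "non-finite position", "coordinates must be finite")
  for (i in which(nd$radius < 0))
    add(nd$id[i], "negative radius", sprintf("radius %g", nd$radius[i]))
  # repeated points: parent-child pairs closer than epsilon
  has_par <- which(nd$parent > 0 & !is.na(idx))
  if (length(has_par)) {
    P <- as.matrix(nd[has_par, c("x", "y", "z")])
    Q <- as.matrix(nd[idx[has_par], c("x", "y", "z")])
    d <- sqrt(rowSums((P - Q)^2))
    for (k in which(d < epsilon))
      add(nd$id[has_par[k]], "repeated point",
          sprintf("distance to parent %.3g below epsilon %.3g",
                  d[k], epsilon))
  }
  if (nrow(t$spines) && any(!t$spines$parent_id %in% nd$id))
    add(NA_integer_, "dangling spine",
        "spine attachment refers to a missing tracing point")
  if (length(v) == 0)
    return(data.frame(node = integer(0), rule = character(0),
                      detail = character(0)))
  do.call(rbind, v)
}

#' Decompose a tracing into unbranched branches
#'
#' Returns the maximal unbranched paths of the neurite forest, one polyline
#' per path, in depth-first order. Each branch starts at a neurite root or at
#' the child of a bifurcation and runs up to (and including) the next
#' bifurcation point or terminal, so the branches partition the points: every
#' tracing point appears in exactly one branch. For a strictly binary tree
#' with `b` bifurcations this yields `2 b + 1` branches.
#'
#' @param t a valid [neuron_tracing()].
#' @param check validate first (default TRUE).
#' @return list of [polyline()] objects.
#' @export
iter_branches <- function(t, check = TRUE) {
  if (check) {
    viol <- validate_tracing(t)
    if (nrow(viol))
      stop_neurofil(paste0("invalid tracing: ", viol$rule[1], " at node ",
                           viol$node[1]), "neurofil_invalid_tracing")
  }
  nd <- t$nodes
  if (nrow(nd) == 0) return(list())
  kids <- split(nd$id, factor(nd$parent, levels = c(0, nd$id)))
  children_of <- function(id) kids[[as.character(id)]]
  roots <- nd$id[nd$parent == 0]
  branches <- list()
  # depth-first over branch starts
  stack <- as.list(rev(roots))
  while (length(stack)) {
    start <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    run <- start
    repeat {
      ch <- children_of(run[length(run)])
      if (length(ch) == 1) run <- c(run, ch)
      else break
    }
    ch <- children_of(run[length(run)])
    rows <- match(run, nd$id)
    branches[[length(branches) + 1]] <- polyline(
      xyz = as.matrix(nd[rows, c("x", "y", "z")]),
      radius = nd$radius[rows],
      part = nd$part[rows[length(rows)]],
      source_id = length(branches) + 1L,
      node_ids = nd$id[rows],
      min_points = 1L)
    if (length(ch) > 1) for (c_ in rev(ch)) stack[[length(stack) + 1]] <- c_
  }
  branches
}

#' Tracing point polylines
#'
#' Ordered runs of tracing points (position + radius), the unit the hierarchy
#' builder works with. A polyline normally has at least two points;
#' single-point polylines are permitted only when flagged degenerate (they
#' arise from one-slice fragments and may only be absorbed by concatenation).
#'
#' @param xyz n x 3 point matrix (microns).
#' @param radius length-n radii (microns).
#' @param part neuron part label for the points.
#' @param source_id integer identifier, unique within a parse session.
#' @param node_ids optional original node ids (used by [iter_branches()]).
#' @param min_points minimum length to enforce (2 for parsed fragments).
#' @return object of class `polyline`.
#' @export
polyline <- function(xyz, radius, part = "basal", source_id = NA_integer_,
                     node_ids = NULL, min_points = 2L) {
  xyz <- as_point_matrix(xyz)
  stopifnot(nrow(xyz) == length(radius))
  if (nrow(xyz) < min_points)
    stop_neurofil("polyline needs at least 2 points",
                  "neurofil_degenerate_polyline")
  structure(list(xyz = xyz, radius = as.numeric(radius), part = part,
                 source_id = source_id, node_ids = node_ids,
                 degenerate = nrow(xyz) < 2L),
            class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline %s: %d points, part %s%s>\n",
              x$source_id, nrow(x$xyz), x$part,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

npoints <- function(pl) nrow(pl$xyz)

reverse_polyline <- function(pl) {
  pl$xyz <- pl$xyz[rev(seq_len(nrow(pl$xyz))), , drop = FALSE]
  pl$radius <- rev(pl$radius)
  if (!is.null(pl$node_ids)) pl$node_ids <- rev(pl$node_ids)
  pl
}

subset_polyline <- function(pl, idx) {
  pl$xyz <- pl$xyz[idx, , drop = FALSE]
  pl$radius <- pl$radius[idx]
  if (!is.null(pl$node_ids)) pl$node_ids <- pl$node_ids[idx]
  pl$degenerate <- nrow(pl$xyz) < 2L
  pl
}

#' Topology signature of a tracing
#'
#' Summary used to compare a reconstructed tree against ground truth:
#' the sorted branch-degree sequence, terminal count, bifurcation count and
#' branch count. Two trees are topologically isomorphic in the sense used
#' by the round-trip tests when their signatures match.
#'
#' @param t a [neuron_tracing()].
#' @return list with `degree_sequence`, `n_terminals`, `n_bifurcations`,
#'   `n_branches`.
#' @export
topology_signature <- function(t) {
  ch <- n_children(t)
  list(degree_sequence = sort(as.integer(ch)),
       n_terminals = sum(ch == 0),
       n_bifurcations = sum(ch >= 2),
       n_branches = length(iter_branches(t, check = FALSE)))
}
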