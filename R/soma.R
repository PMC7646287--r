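#' Soma models
#'
#' The soma can come from four sources: a stack of 2D contours (traced at
#' successive focal planes), a sphere (center + radius, e.g. approximated
#' from the neurite starting points), an externally supplied closed surface
#' mesh, or nothing at all. `soma_model` wraps the three geometric variants.
#'
#' @param center,radius sphere parameters (microns).
#' @return a `soma_model`.
#' @export
soma_sphere <- function(center, radius) {
  stopifnot(radius > 0)
  structure(list(variant = "sphere", center = as.numeric(center),
                 radius = radius), class = "soma_model")
}

#' @param cs a [contour_stack()].
#' @rdname soma_sphere
#' @export
soma_contours <- function(cs) {
  structure(list(variant = "contour_stack", contours = cs),
            class = "soma_model")
}

#' @param mesh a closed [trimesh()].
#' @rdname soma_sphere
#' @export
soma_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "trimesh"))
  structure(list(variant = "mesh", mesh = mesh), class = "soma_model")
}

#' @export
print.soma_model <- function(x, ...) {
  cat(sprintf("<soma_model: %s>\n", x$variant))
  invisible(x)
}

#' Planar contour stacks
#'
#' A list of closed planar polygons, each at a constant z-level, as used by
#' contour-based soma descriptions in ASC files.
#'
#' @param contours list of n x 3 point matrices; within each matrix the z
#'   column must be constant. Vertices are an implicitly closed ring.
#' @return a `contour_stack`.
#' @export
contour_stack <- function(contours) {
  contours <- lapply(contours, as_point_matrix)
  for (cc in contours) {
    if (nrow(cc) < 3)
      stop_neurofil("each contour needs at least 3 vertices",
                    "neurofil_bad_contour")
    if (diff(range(cc[, 3])) > 1e-9 * max(1, diff(range(cc[, 1:2]))))
      stop_neurofil("contours must be planar with constant z",
                    "neurofil_bad_contour")
  }
  structure(list(contours = contours), class = "contour_stack")
}

# --- 3D convex hull (incremental, quickhull-style) -------------------------

#' Convex hull of a 3D point set
#'
#' Incremental hull with outward-oriented triangular faces. Coplanar or
#' otherwise degenerate input raises a `neurofil_degenerate_hull` error.
#'
#' @param P n x 3 point matrix.
#' @return a watertight convex [trimesh()].
#' @export
convex_hull_3d <- function(P) {
  P <- unique(as_point_matrix(P))
  n <- nrow(P)
  if (n < 4)
    stop_neurofil("need at least 4 points for a 3D hull",
                  "neurofil_degenerate_hull")
  diam <- vnorm(apply(P, 2, max) - apply(P, 2, min))
  tol <- 1e-10 * max(diam, 1)

  # initial simplex: spread points
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) { i1 <- which.min(P[, 2]); i2 <- which.max(P[, 2]) }
  d <- P[i2, ] - P[i1, ]
  ln <- vnorm(d)
  if (ln < tol)
    stop_neurofil("degenerate point set", "neurofil_degenerate_hull")
  u <- d / ln
  w <- sweep(P, 2, P[i1, ])
  perp <- w - outer(as.vector(w %*% u), u)
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) < tol)
    stop_neurofil("collinear points", "neurofil_degenerate_hull")
  nrm <- vcross(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  nrm <- nrm / vnorm(nrm)
  hdist <- as.vector(sweep(P, 2, P[i1, ]) %*% nrm)
  i4 <- which.max(abs(hdist))
  if (abs(hdist[i4]) < tol)
    stop_neurofil("coplanar input: cannot build a 3D hull",
                  "neurofil_degenerate_hull")

  simplex <- c(i1, i2, i3, i4)
  centroid <- colMeans(P[simplex, ])
  mk_face <- function(a, b, c_) {
    nn <- vcross(P[b, ] - P[a, ], P[c_, ] - P[a, ])
    nn <- nn / max(vnorm(nn), 1e-300)
    off <- sum(nn * P[a, ])
    if (sum(nn * centroid) - off > 0) { # flip outward
      tmp <- b; b <- c_; c_ <- tmp
      nn <- -nn; off <- -off
    }
    list(v = c(a, b, c_), n = nn, d = off, outside = integer(0))
  }
  faces <- list(mk_face(i1, i2, i3), mk_face(i1, i2, i4),
                mk_face(i1, i3, i4), mk_face(i2, i3, i4))
  assign_outside <- function(faces, pts) {
    for (p in pts) {
      if (p %in% simplex) next
      best <- 0; bf <- 0
      for (f in seq_along(faces)) {
        if (is.null(faces[[f]])) next
        dd <- sum(faces[[f]]$n * P[p, ]) - faces[[f]]$d
        if (dd > best + tol) { best <- dd; bf <- f }
      }
      if (bf > 0) faces[[bf]]$outside <- c(faces[[bf]]$outside, p)
    }
    faces
  }
  faces <- assign_outside(faces, seq_len(n))

  repeat {
    fi <- 0
    for (f in seq_along(faces))
      if (!is.null(faces[[f]]) && length(faces[[f]]$outside)) { fi <- f; break }
    if (fi == 0) break
    out_pts <- faces[[fi]]$outside
    dd <- vapply(out_pts, function(p) sum(faces[[fi]]$n * P[p, ]) - faces[[fi]]$d,
                 numeric(1))
    p <- out_pts[which.max(dd)]
    visible <- integer(0)
    orphan <- integer(0)
    for (f in seq_along(faces)) {
      if (is.null(faces[[f]])) next
      if (sum(faces[[f]]$n * P[p, ]) - faces[[f]]$d > tol) {
        visible <- c(visible, f)
        orphan <- c(orphan, faces[[f]]$outside)
      }
    }
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(visible, function(f) {
      v <- faces[[f]]$v
      rbind(v[c(1, 2)], v[c(2, 3)], v[c(3, 1)])
    }))
    ek <- paste(edges[, 1], edges[, 2])
    rk <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(ek %in% rk), , drop = FALSE]
    for (f in visible) faces[f] <- list(NULL)
    new_idx <- integer(0)
    for (e in seq_len(nrow(horizon))) {
      nf <- mk_face(horizon[e, 1], horizon[e, 2], p)
      faces[[length(faces) + 1]] <- nf
      new_idx <- c(new_idx, length(faces))
    }
    orphan <- setdiff(unique(orphan), p)
    for (q in orphan) {
      best <- 0; bf <- 0
      for (f in new_idx) {
        dd2 <- sum(faces[[f]]$n * P[q, ]) - faces[[f]]$d
        if (dd2 > best + tol) { best <- dd2; bf <- f }
      }
      if (bf > 0) faces[[bf]]$outside <- c(faces[[bf]]$outside, q)
    }
  }
  keep <- !vapply(faces, is.null, logical(1))
  F <- do.call(rbind, lapply(faces[keep], `[[`, "v"))
  orient_mesh(trimesh(P, F))
}

# --- isotropic remeshing of a convex surface -------------------------------

# Remesh a convex mesh to near-uniform triangles: a subdivided icosphere is
# radially projected from the hull centroid onto the hull (so vertices lie
# exactly on the surface), then relaxed tangentially and re-projected.
remesh_convex <- function(hull, target_edge_length, relax_iters = 12) {
  c0 <- colMeans(hull$vertices)
  nrm <- face_normals(hull)
  off <- rowSums(nrm * hull$vertices[hull$faces[, 1], , drop = FALSE])
  project <- function(p) {
    # ray c0 + t * u against the hull half-space boundary
    u <- p - c0
    un <- vnorm(u)
    if (un < 1e-12) return(p)
    u <- u / un
    denom <- as.vector(nrm %*% u)
    ok <- denom > 1e-12
    tt <- (off[ok] - as.vector(nrm[ok, , drop = FALSE] %*% c0)) / denom[ok]
    c0 + min(tt) * u
  }
  r_med <- stats::median(sqrt(rowSums(sweep(hull$vertices, 2, c0)^2)))
  # probe: project a coarse sphere to measure the hull's mean projected edge,
  # then pick the subdivision level whose halvings land on the target
  probe <- mesh_icosphere(center = c0, radius = r_med, subdiv = 2)
  Vp <- probe$vertices
  for (i in seq_len(nrow(Vp))) Vp[i, ] <- project(Vp[i, ])
  Ep <- unique(mesh_edges(probe))
  mean_edge2 <- mean(sqrt(rowSums((Vp[Ep[, 1], , drop = FALSE] -
                                     Vp[Ep[, 2], , drop = FALSE])^2)))
  subdiv <- max(1, min(6, 2 + round(log2(mean_edge2 / target_edge_length))))
  ico <- mesh_icosphere(center = c0, radius = r_med, subdiv = subdiv)
  V <- ico$vertices
  for (i in seq_len(nrow(V))) V[i, ] <- project(V[i, ])
  E <- unique(mesh_edges(ico))
  nbrs <- split(c(E[, 2], E[, 1]), c(E[, 1], E[, 2]))
  for (it in seq_len(relax_iters)) {
    Vn <- V
    for (i in seq_len(nrow(V)))
      Vn[i, ] <- colMeans(V[nbrs[[as.character(i)]], , drop = FALSE])
    for (i in seq_len(nrow(V))) Vn[i, ] <- project(Vn[i, ])
    V <- Vn
  }
  out <- trimesh(V, ico$faces, clean = FALSE)
  orient_mesh(out)
}

#' Build a soma mesh from a stack of 2D contours
#'
#' Applies a convex-hull algorithm to the full set of contour vertices and
#' then remeshes the hull isotropically so later deformation acts on dense,
#' uniform triangles. The hull step means only convex somata can be
#' represented.
#'
#' @param cs a [contour_stack()] with at least two non-coplanar contours.
#' @param target_edge_length goal edge length of the remeshed surface in
#'   microns; default is hull diameter / 20.
#' @param remesh set FALSE to return the raw hull.
#' @return a watertight convex [trimesh()].
#' @export
soma_from_contours <- function(cs, target_edge_length = NULL, remesh = TRUE) {
  stopifnot(inherits(cs, "contour_stack"))
  if (length(cs$contours) < 2)
    stop_neurofil("need at least two contours for a 3D soma",
                  "neurofil_degenerate_hull")
  P <- do.call(rbind, cs$contours)
  hull <- convex_hull_3d(P)
  if (!remesh) return(hull)
  if (is.null(target_edge_length))
    target_edge_length <- bbox_diagonal(hull) / 20
  remesh_convex(hull, target_edge_length)
}

#' Spherical soma from first-order neurite starts
#'
#' When no soma information is available the soma is approximated by a
#' sphere whose center is the barycenter of the starting points of the
#' first-order neurites and whose radius is the shortest distance from that
#' center to any of those starting points.
#'
#' @param first_order_starts matrix (>= 2 rows) of neurite starting points.
#' @return a sphere [soma_sphere()] model.
#' @export
soma_sphere_from_neurites <- function(first_order_starts) {
  P <- as_point_matrix(first_order_starts)
  if (nrow(P) < 2)
    stop_neurofil("need at least two first-order neurite starts",
                  "neurofil_insufficient_data")
  center <- colMeans(P)
  radius <- sqrt(min(rowSums(sweep(P, 2, center)^2)))
  soma_sphere(center, radius)
}

soma_surface_mesh <- function(soma) {
  switch(soma$variant,
         sphere = mesh_icosphere(soma$center, soma$radius, subdiv = 3),
         mesh = soma$mesh,
         contour_stack = soma_from_contours(soma$contours))
}

soma_contains <- function(soma, P) {
  P <- as_point_matrix(P)
  if (soma$variant == "sphere") {
    sqrt(rowSums(sweep(P, 2, soma$center)^2)) < soma$radius - 1e-12
  } else {
    points_in_mesh(P, soma_surface_mesh(soma))
  }
}

soma_segment_exit <- function(soma, p_in, p_out) {
  if (soma$variant == "sphere") {
    # |p + t d - c|^2 = r^2, smallest t in [0, 1] leaving the sphere
    d <- p_out - p_in
    f <- p_in - soma$center
    a <- sum(d * d); b <- 2 * sum(f * d); cc <- sum(f * f) - soma$radius^2
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(NULL)
    ts <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    tt <- ts[ts >= -1e-9 & ts <= 1 + 1e-9]
    if (!length(tt)) return(NULL)
    t1 <- max(0, min(1, max(tt)))
    list(t = t1, point = p_in + t1 * d)
  } else {
    segment_mesh_intersection(p_in, p_out, soma_surface_mesh(soma))
  }
}

#' Trim neurite starting points inside the soma
#'
#' When a soma geometry is available, the neurite points that fall strictly
#' inside it are removed and the intersection of the first inside-to-outside
#' segment with the soma surface becomes the real initial tracing point,
#' with the radius linearly interpolated along the segment.
#'
#' @param t a [neuron_tracing()].
#' @param soma a [soma_sphere()], [soma_contours()] or [soma_mesh()] model.
#' @return the trimmed tracing (its soma slot set to `soma`).
#' @export
trim_neurite_starts <- function(t, soma) {
  nd <- t$nodes
  roots <- nd$id[nd$parent == 0]
  for (root in roots) {
    # walk the unbranched chain from the root
    chain <- root
    repeat {
      ch <- nd$id[nd$parent == chain[length(chain)]]
      if (length(ch) != 1) break
      chain <- c(chain, ch)
    }
    rows <- match(chain, nd$id)
    P <- as.matrix(nd[rows, c("x", "y", "z")])
    inside <- soma_contains(soma, P)
    if (!inside[1]) next # root already outside
    if (all(inside)) {
      # the chain may end at a bifurcation still inside: treat as swallowed
      stop_neurofil(
        sprintf("neurite rooted at node %d lies entirely inside the soma",
                root),
        "neurofil_neurite_swallowed")
    }
    k <- which(!inside)[1] # first outside point
    hit <- soma_segment_exit(soma, P[k - 1, ], P[k, ])
    if (is.null(hit)) hit <- list(t = 0, point = P[k - 1, ])
    r_new <- nd$radius[rows[k - 1]] +
      hit$t * (nd$radius[rows[k]] - nd$radius[rows[k - 1]])
    new_id <- max(nd$id) + 1L
    nd <- rbind(nd, data.frame(id = new_id, parent = 0L,
                               x = hit$point[1], y = hit$point[2],
                               z = hit$point[3], radius = r_new,
                               part = nd$part[rows[k]],
                               stringsAsFactors = FALSE))
    nd$parent[rows[k]] <- new_id
    nd <- nd[-rows[seq_len(k - 1)], , drop = FALSE]
  }
  t$nodes <- nd
  t$soma <- soma
  renumber_tracing(t)
}

# renumber ids 1..n in parent-before-child order
renumber_tracing <- function(t) {
  nd <- t$nodes
  order_ids <- integer(0)
  kids <- split(nd$id, factor(nd$parent, levels = c(0, nd$id)))
  stack <- as.list(rev(kids[["0"]]))
  while (length(stack)) {
    id <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    order_ids <- c(order_ids, id)
    for (c_ in rev(kids[[as.character(id)]]))
      stack[[length(stack) + 1]] <- c_
  }
  rows <- match(order_ids, nd$id)
  map <- integer(max(nd$id))
  map[order_ids] <- seq_along(order_ids)
  out <- nd[rows, , drop = FALSE]
  out$id <- seq_along(order_ids)
  out$parent <- ifelse(out$parent == 0L, 0L, map[pmax(out$parent, 1L)])
  rownames(out) <- NULL
  if (nrow(t$spines)) t$spines$parent_id <- map[t$spines$parent_id]
  t$nodes <- out
  t
}

#' Convert a soma model to a stack of 2D contours
#'
#' Cross-sections the soma at `n_levels` z-planes evenly spaced over the
#' central 90% of its z-extent (avoiding degenerate pole contours), each
#' contour closed and ordered counterclockwise seen from +z. This is the
#' representation contour-based ASC files use for the cell body.
#'
#' @param soma sphere or closed-mesh [soma_sphere()]/[soma_mesh()] model
#'   (a contour-stack model is returned as-is).
#' @param n_levels number of section planes (>= 3).
#' @param n_vertices vertices per contour for the sphere variant.
#' @return a [contour_stack()].
#' @export
soma_to_contours <- function(soma, n_levels = 7, n_vertices = 64) {
  if (n_levels < 3)
    stop_neurofil("need at least 3 contour levels", "neurofil_bad_argument")
  if (soma$variant == "contour_stack") return(soma$contours)
  if (soma$variant == "sphere") {
    zr <- soma$center[3] + c(-1, 1) * soma$radius
    levels <- seq(zr[1] + 0.05 * diff(zr), zr[2] - 0.05 * diff(zr),
                  length.out = n_levels)
    ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[1:n_vertices]
    contours <- lapply(levels, function(z) {
      r <- sqrt(max(0, soma$radius^2 - (z - soma$center[3])^2))
      cbind(soma$center[1] + r * cos(ang), soma$center[2] + r * sin(ang), z)
    })
    return(contour_stack(contours))
  }
  m <- soma$mesh
  if (!is_watertight(m))
    stop_neurofil("soma mesh must be closed to take cross sections",
                  "neurofil_open_mesh")
  zr <- range(m$vertices[, 3])
  levels <- seq(zr[1] + 0.05 * diff(zr), zr[2] - 0.05 * diff(zr),
                length.out = n_levels)
  contours <- lapply(levels, function(z) mesh_cross_section(m, z))
  contour_stack(contours)
}

# planar section of a convex closed mesh at height z: edge-plane crossings
# ordered by angle about their centroid (CCW from +z)
mesh_cross_section <- function(m, z) {
  V <- m$vertices
  E <- unique(mesh_edges(m))
  za <- V[E[, 1], 3]; zb <- V[E[, 2], 3]
  cross <- which((za - z) * (zb - z) < 0)
  if (length(cross) < 3)
    stop_neurofil(sprintf("no cross-section at z = %g", z),
                  "neurofil_bad_section")
  tt <- (z - za[cross]) / (zb[cross] - za[cross])
  pts <- V[E[cross, 1], , drop = FALSE] +
    tt * (V[E[cross, 2], , drop = FALSE] - V[E[cross, 1], , drop = FALSE])
  ctr <- colMeans(pts)
  ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
  pts <- pts[order(ang), , drop = FALSE]
  pts[, 3] <- z
  pts
}

#' Pull the soma surface toward the neurite starts
#'
#' A simplified surface deformation standing in for the physically based
#' soma-to-neurite join of mesh-growing reconstruction tools: for each
#' first-order neurite start, the nearest soma vertex and its one-ring are
#' displaced toward the start by `pull_fraction` of the remaining gap, then
#' a single Laplacian smoothing pass is applied to all non-displaced
#' vertices. The mesh connectivity is untouched, so closedness is preserved.
#'
#' @param soma_mesh closed [trimesh()].
#' @param first_order_starts matrix of neurite starting points outside the
#'   mesh.
#' @param pull_fraction fraction of the vertex-to-start gap to traverse
#'   (0 = identity, 1 = land on the start).
#' @return the deformed [trimesh()].
#' @export
deform_soma_to_neurites <- function(soma_mesh, first_order_starts,
                                    pull_fraction = 0.8) {
  if (pull_fraction == 0) return(soma_mesh)
  starts <- as_point_matrix(first_order_starts)
  V <- soma_mesh$vertices
  E <- unique(mesh_edges(soma_mesh))
  nbrs <- split(c(E[, 2], E[, 1]), c(E[, 1], E[, 2]))
  moved <- logical(nrow(V))
  for (s in seq_len(nrow(starts))) {
    d2 <- rowSums(sweep(V, 2, starts[s, ])^2)
    vi <- which.min(d2)
    V[vi, ] <- V[vi, ] + pull_fraction * (starts[s, ] - V[vi, ])
    moved[vi] <- TRUE
    for (r in nbrs[[as.character(vi)]]) {
      # one-ring follows at half weight so the pulled patch stays non-degenerate
      V[r, ] <- V[r, ] + 0.5 * pull_fraction * (starts[s, ] - V[r, ])
      moved[r] <- TRUE
    }
  }
  Vs <- V
  for (i in which(!moved))
    Vs[i, ] <- colMeans(V[nbrs[[as.character(i)]], , drop = FALSE])
  soma_mesh$vertices <- Vs
  soma_mesh
}
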