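#' Triangle mesh objects
#'
#' A `trimesh` is the package's surface container: a numeric vertex matrix
#' (one row per vertex, columns x/y/z in microns) and an integer face matrix
#' of 1-based vertex index triples. Degenerate (zero-area) faces and unused
#' vertices are dropped on construction.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions.
#' @param faces integer matrix (m x 3) of 1-based vertex indices.
#' @param clean drop degenerate faces and unreferenced vertices (default TRUE).
#' @return an object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, clean = TRUE) {
  vertices <- as_point_matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop_neurofil("face indices out of range", "neurofil_bad_mesh")
  m <- structure(list(vertices = vertices, faces = unname(faces)),
                 class = "trimesh")
  if (clean) m <- clean_mesh(m)
  m
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh: %d vertices, %d faces%s>\n",
              nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

face_areas <- function(m) {
  V <- m$vertices; F <- m$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(m, normalize = TRUE) {
  V <- m$vertices; F <- m$faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

clean_mesh <- function(m) {
  if (nrow(m$faces) == 0) return(m)
  keep <- face_areas(m) > 1e-14
  F <- m$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(m$vertices))
  remap[used] <- seq_along(used)
  structure(list(vertices = m$vertices[used, , drop = FALSE],
                 faces = matrix(remap[F], ncol = 3)),
            class = "trimesh")
}

mesh_edges <- function(m, directed = FALSE) {
  F <- m$faces
  E <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  if (!directed) E <- cbind(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  E
}

#' Test whether a mesh is watertight
#'
#' Watertight means every undirected edge is shared by exactly two faces and
#' the two incident faces traverse it in opposite directions (consistent
#' orientation), so the surface bounds a well-defined volume.
#'
#' @param m a [trimesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(m) {
  if (nrow(m$faces) == 0) return(FALSE)
  Ed <- mesh_edges(m, directed = TRUE)
  nv <- nrow(m$vertices) + 1
  key <- Ed[, 1] * nv + Ed[, 2]
  rkey <- Ed[, 2] * nv + Ed[, 1]
  und <- pmin(key, rkey)
  if (any(tabulate(match(und, unique(und))) != 2)) return(FALSE)
  # opposite traversal: each directed edge appears exactly once
  !anyDuplicated(key) && all(key %in% rkey)
}

#' Orient a mesh consistently and outward
#'
#' Propagates a consistent winding across edge-connected faces, then flips
#' the whole component if its signed volume is negative, so that face normals
#' point out of the enclosed solid.
#'
#' @param m a closed [trimesh()].
#' @return the reoriented mesh.
#' @export
orient_mesh <- function(m) {
  F <- m$faces
  nf <- nrow(F)
  if (nf == 0) return(m)
  nv <- nrow(m$vertices) + 1
  Ed <- mesh_edges(m, directed = TRUE) # rows f, nf+f, 2nf+f
  dkey <- Ed[, 1] * nv + Ed[, 2]
  rkey <- Ed[, 2] * nv + Ed[, 1]
  # fast path: winding already consistent, only the global sign may be off
  if (!anyDuplicated(dkey) && all(dkey %in% rkey)) {
    if (!is.na(v <- signed_volume(m)) && v < 0)
      m$faces <- m$faces[, c(1, 3, 2)]
    return(m)
  }
  und <- pmin(dkey, rkey)
  ukeys <- unique(und)
  eid <- match(und, ukeys)
  face_of <- rep(seq_len(nf), 3)
  adj <- split(face_of, eid) # faces incident to each undirected edge
  visited <- rep(FALSE, nf)
  flipped <- rep(FALSE, nf)
  queue <- integer(nf)
  for (start in seq_len(nf)) {
    if (visited[start]) next
    qh <- 1L; qt <- 1L
    queue[1] <- start
    visited[start] <- TRUE
    while (qh <= qt) {
      f <- queue[qh]; qh <- qh + 1L
      fe <- c(f, nf + f, 2L * nf + f)
      for (e in fe) {
        for (g in adj[[eid[e]]]) {
          if (g == f || visited[g]) next
          # f's effective direction along this edge
          fdir <- if (flipped[f]) c(Ed[e, 2], Ed[e, 1]) else Ed[e, ]
          ge <- c(g, nf + g, 2L * nf + g)
          gi <- ge[eid[ge] == eid[e]][1]
          same_dir <- Ed[gi, 1] == fdir[1] && Ed[gi, 2] == fdir[2]
          flipped[g] <- same_dir
          visited[g] <- TRUE
          qt <- qt + 1L
          queue[qt] <- g
        }
      }
    }
  }
  F[flipped, ] <- F[flipped, c(1, 3, 2)]
  m$faces <- F
  if (!is.na(v <- signed_volume(m)) && v < 0)
    m$faces <- m$faces[, c(1, 3, 2)]
  m
}

signed_volume <- function(m) {
  V <- m$vertices; F <- m$faces
  if (nrow(F) == 0) return(NA_real_)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

bbox_diagonal <- function(m) {
  r <- apply(m$vertices, 2, range)
  vnorm(r[2, ] - r[1, ])
}

translate_mesh <- function(m, v) {
  m$vertices <- sweep(m$vertices, 2, v, "+")
  m
}

transform_mesh <- function(m, R = diag(3), t = c(0, 0, 0), scale = 1) {
  m$vertices <- sweep(scale * m$vertices %*% t(R), 2, t, "+")
  m
}

# --- primitive meshes (used by soma building and the fixture generator) ----

#' Axis-aligned box mesh
#' @param lo,hi opposite corners (length-3 numeric).
#' @return a watertight [trimesh()].
#' @export
mesh_box <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # corners: 1:(0,0,0) 2:(1,0,0) 3:(0,1,0) 4:(1,1,0) 5:(0,0,1) 6:(1,0,1)
  #          7:(0,1,1) 8:(1,1,1)
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2),   # z = lo (normal -z)
    c(5, 6, 8), c(5, 8, 7),   # z = hi
    c(1, 2, 6), c(1, 6, 5),   # y = lo
    c(3, 7, 8), c(3, 8, 4),   # y = hi
    c(1, 5, 7), c(1, 7, 3),   # x = lo
    c(2, 4, 8), c(2, 8, 6))   # x = hi
  trimesh(v, f)
}

#' UV-sphere mesh
#' @param center sphere center. @param radius sphere radius (microns).
#' @param n_theta,n_phi angular resolution (latitude bands, longitudes).
#' @return a watertight [trimesh()].
#' @export
mesh_sphere <- function(center = c(0, 0, 0), radius = 1,
                        n_theta = 16, n_phi = 32) {
  theta <- seq(0, pi, length.out = n_theta + 1)[2:n_theta]
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[1:n_phi]
  ring <- function(th) cbind(radius * sin(th) * cos(phi),
                             radius * sin(th) * sin(phi),
                             radius * cos(th))
  V <- rbind(c(0, 0, radius), do.call(rbind, lapply(theta, ring)),
             c(0, 0, -radius))
  idx <- function(i, j) 1 + (i - 1) * n_phi + ((j - 1) %% n_phi) + 1
  F <- list()
  for (j in 1:n_phi) F[[length(F) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  for (i in 1:(n_theta - 2)) for (j in 1:n_phi) {
    F[[length(F) + 1]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    F[[length(F) + 1]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  south <- nrow(V)
  for (j in 1:n_phi)
    F[[length(F) + 1]] <- c(south, idx(n_theta - 1, j + 1), idx(n_theta - 1, j))
  m <- trimesh(sweep(V, 2, center, "+"), do.call(rbind, F))
  orient_mesh(m)
}

#' Surface of revolution about the +Y axis
#'
#' Revolves a radial profile `r(y)` around the Y axis. Profile ends with
#' radius 0 become poles; positive end radii are closed with flat discs, so
#' the result is always watertight. Used to build flat-based spine shapes.
#'
#' @param y increasing y-levels of the profile. @param r radii at each level
#'   (non-negative; zero only allowed at the ends).
#' @param n_seg number of segments around the axis.
#' @return a watertight [trimesh()].
#' @export
mesh_revolve <- function(y, r, n_seg = 24) {
  stopifnot(length(y) == length(r), all(diff(y) > 0), all(r >= 0))
  phi <- seq(0, 2 * pi, length.out = n_seg + 1)[1:n_seg]
  V <- NULL
  ring_start <- integer(0)
  for (i in seq_along(y)) {
    if (r[i] > 0) {
      ring_start[i] <- if (is.null(V)) 1 else nrow(V) + 1
      V <- rbind(V, cbind(r[i] * cos(phi), y[i], r[i] * sin(phi)))
    } else {
      ring_start[i] <- if (is.null(V)) 1 else nrow(V) + 1
      V <- rbind(V, c(0, y[i], 0))
    }
  }
  F <- list()
  nxt <- function(j) (j %% n_seg) + 1
  for (i in seq_len(length(y) - 1)) {
    a <- ring_start[i]; b <- ring_start[i + 1]
    if (r[i] > 0 && r[i + 1] > 0) {
      for (j in 1:n_seg) {
        F[[length(F) + 1]] <- c(a + j - 1, a + nxt(j) - 1, b + nxt(j) - 1)
        F[[length(F) + 1]] <- c(a + j - 1, b + nxt(j) - 1, b + j - 1)
      }
    } else if (r[i] == 0) {
      for (j in 1:n_seg)
        F[[length(F) + 1]] <- c(a, b + nxt(j) - 1, b + j - 1)
    } else {
      for (j in 1:n_seg)
        F[[length(F) + 1]] <- c(b, a + j - 1, a + nxt(j) - 1)
    }
  }
  # cap positive-radius ends with fans around an added center vertex
  if (r[1] > 0) {
    V <- rbind(V, c(0, y[1], 0))
    ci <- nrow(V); a <- ring_start[1]
    for (j in 1:n_seg) F[[length(F) + 1]] <- c(ci, a + j - 1, a + nxt(j) - 1)
  }
  if (r[length(r)] > 0) {
    V <- rbind(V, c(0, y[length(y)], 0))
    ci <- nrow(V); a <- ring_start[length(y)]
    for (j in 1:n_seg) F[[length(F) + 1]] <- c(ci, a + nxt(j) - 1, a + j - 1)
  }
  orient_mesh(trimesh(V, do.call(rbind, F)))
}

#' Icosphere mesh (subdivided icosahedron)
#' @param center,radius sphere placement.
#' @param subdiv number of 4-to-1 subdivision rounds.
#' @return a watertight, nearly uniform [trimesh()].
#' @export
mesh_icosphere <- function(center = c(0, 0, 0), radius = 1, subdiv = 2) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(1 + t^2)
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(id <- mid_cache[[k]])) return(id)
      p <- vnormalize((V[a, ] + V[b, ]) / 2)
      V <<- rbind(V, p)
      mid_cache[[k]] <- nrow(V)
      nrow(V)
    }
    Fn <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c_ <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      Fn <- rbind(Fn, c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }
    F <- Fn
  }
  orient_mesh(trimesh(sweep(radius * V, 2, center, "+"), F))
}

# point-in-mesh test by ray parity along +x with jittered origin
points_in_mesh <- function(P, m) {
  P <- as_point_matrix(P)
  V <- m$vertices; F <- m$faces
  out <- logical(nrow(P))
  for (i in seq_len(nrow(P))) {
    p <- P[i, ] + c(0, 1.37e-7, 2.61e-7) * max(1, bbox_diagonal(m))
    crossings <- 0L
    for (f in seq_len(nrow(F))) {
      a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c_ <- V[F[f, 3], ]
      # 2D (y, z) barycentric test for the +x ray
      den <- (b[2] - a[2]) * (c_[3] - a[3]) - (c_[2] - a[2]) * (b[3] - a[3])
      if (abs(den) < 1e-14) next
      l1 <- ((p[2] - a[2]) * (c_[3] - a[3]) - (c_[2] - a[2]) * (p[3] - a[3])) / den
      l2 <- ((b[2] - a[2]) * (p[3] - a[3]) - (p[2] - a[2]) * (b[3] - a[3])) / den
      if (l1 < 0 || l2 < 0 || l1 + l2 > 1) next
      tx <- a[1] + l1 * (b[1] - a[1]) + l2 * (c_[1] - a[1])
      if (tx > p[1]) crossings <- crossings + 1L
    }
    out[i] <- (crossings %% 2L) == 1L
  }
  out
}

# first intersection of segment p->q with the mesh surface, or NULL
segment_mesh_intersection <- function(p, q, m) {
  V <- m$vertices; F <- m$faces
  d <- q - p
  best <- Inf
  hit <- NULL
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c_ <- V[F[f, 3], ]
    e1 <- b - a; e2 <- c_ - a
    h <- vcross(d, e2)
    den <- sum(e1 * h)
    if (abs(den) < 1e-14) next
    s <- p - a
    u <- sum(s * h) / den
    if (u < -1e-9 || u > 1 + 1e-9) next
    qv <- vcross(s, e1)
    v <- sum(d * qv) / den
    if (v < -1e-9 || u + v > 1 + 1e-9) next
    tt <- sum(e2 * qv) / den
    if (tt >= -1e-9 && tt <= 1 + 1e-9 && tt < best) {
      best <- tt
      hit <- list(t = max(0, min(1, tt)), point = p + max(0, min(1, tt)) * d)
    }
  }
  hit
}
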