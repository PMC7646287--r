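#' Canonicalize a spine mesh
#'
#' Spine meshes cut from a dendrite have a flat base where they met the
#' shaft. The base is detected as the largest-area cluster of coplanar
#' faces (normals within 2 degrees of each other and plane offsets within
#' 1e-3 of the bounding-box diagonal, covering at least 5% of the total
#' area). The mesh is then rotated so the base outward normal lies on -Y
#' (the spine body extends toward +Y) and translated so the base centroid
#' sits at the origin. The inverse pose — a unit quaternion plus a
#' translation — is stored so the original world placement can be restored
#' exactly.
#'
#' @param m a [trimesh()] with a detectable flat base.
#' @param source_tag free-text provenance label stored with the record.
#' @param reusable set FALSE for meshes stored verbatim (kept untransformed
#'   and flagged not to be placed on other neurons).
#' @return a `spine_record`: `canonical_mesh`, `world_rotation` (quaternion
#'   w,x,y,z), `world_translation`, `metrics`, `source_tag`, `reusable`.
#' @export
canonicalize_spine <- function(m, source_tag = "", reusable = TRUE) {
  base <- detect_flat_base(m)
  if (is.null(base))
    stop_neurofil("no flat base found on the spine mesh",
                  "neurofil_no_base")
  q <- quat_between(base$normal, c(0, -1, 0))
  canon <- m
  canon$vertices <- quat_rotate(q, sweep(m$vertices, 2, base$centroid))
  rec <- structure(list(
    canonical_mesh = canon,
    world_rotation = quat_conjugate(q),
    world_translation = base$centroid,
    metrics = suppressWarnings(mesh_metrics(canon)),
    source_tag = source_tag,
    reusable = reusable), class = "spine_record")
  rec
}

#' @export
print.spine_record <- function(x, ...) {
  cat(sprintf("<spine_record '%s': %d vertices, height %.3g um%s>\n",
              x$source_tag, nrow(x$canonical_mesh$vertices),
              spine_height(x), if (x$reusable) "" else ", non-reusable"))
  invisible(x)
}

spine_height <- function(rec) max(rec$canonical_mesh$vertices[, 2])

#' Store a spine verbatim, without canonicalization
#'
#' Isosurface-derived spines added in their real position are kept
#' untransformed (identity pose) and flagged non-reusable: lacking a
#' canonical frame they cannot be placed on other neurons.
#'
#' @param m the [trimesh()] in world coordinates.
#' @param source_tag provenance label.
#' @return a non-reusable `spine_record` with identity pose.
#' @export
spine_record_verbatim <- function(m, source_tag = "") {
  structure(list(
    canonical_mesh = m,
    world_rotation = quat_identity(),
    world_translation = c(0, 0, 0),
    metrics = suppressWarnings(mesh_metrics(m)),
    source_tag = source_tag,
    reusable = FALSE), class = "spine_record")
}

#' Restore a spine record to its original world pose
#'
#' Applies the stored quaternion and translation, exactly inverting
#' [canonicalize_spine()].
#'
#' @param rec a `spine_record`.
#' @return the reposed [trimesh()].
#' @export
restore_spine_pose <- function(rec) {
  m <- rec$canonical_mesh
  m$vertices <- sweep(quat_rotate(rec$world_rotation, m$vertices), 2,
                      rec$world_translation, "+")
  m
}

# largest-area cluster of mutually coplanar faces; NULL if no cluster
# reaches 5% of the total area
detect_flat_base <- function(m, angle_tol_deg = 2, area_frac = 0.05) {
  m <- orient_mesh(m)
  nrm <- face_normals(m)
  ar <- face_areas(m)
  ctr <- (m$vertices[m$faces[, 1], , drop = FALSE] +
            m$vertices[m$faces[, 2], , drop = FALSE] +
            m$vertices[m$faces[, 3], , drop = FALSE]) / 3
  off <- rowSums(nrm * ctr)
  offset_tol <- 1e-3 * bbox_diagonal(m)
  cos_tol <- cos(angle_tol_deg * pi / 180)
  unassigned <- rep(TRUE, nrow(nrm))
  best <- NULL
  ord <- order(-ar)
  for (f in ord) {
    if (!unassigned[f]) next
    members <- which(unassigned &
                       (nrm %*% nrm[f, ]) >= cos_tol &
                       abs(off - off[f]) <= offset_tol)
    unassigned[members] <- FALSE
    a <- sum(ar[members])
    if (is.null(best) || a > best$area)
      best <- list(faces = members, area = a)
  }
  if (is.null(best) || best$area < area_frac * sum(ar)) return(NULL)
  members <- best$faces
  w <- ar[members] / sum(ar[members])
  normal <- colSums(nrm[members, , drop = FALSE] * w)
  normal <- vnormalize(normal)
  centroid <- colSums(ctr[members, , drop = FALSE] * w)
  list(normal = normal, centroid = centroid, area = best$area,
       faces = members)
}

#' Spine placement lines
#'
#' In spine-aware ASC tracings each spine is a small line from its insertion
#' point on the dendrite to the spine end, defining both placement and
#' orientation.
#'
#' @param insertion,end distinct 3D points (microns).
#' @return a `spine_line`.
#' @export
spine_line <- function(insertion, end) {
  insertion <- as.numeric(insertion); end <- as.numeric(end)
  if (vnorm(end - insertion) < 1e-12)
    stop_neurofil("spine line has zero length", "neurofil_bad_spine_line")
  structure(list(insertion = insertion, end = end), class = "spine_line")
}

#' Place a stored spine on a placement line
#'
#' Rotates the canonical +Y spine axis onto the line direction (minimal
#' rotation), translates the base centroid to the insertion point and
#' optionally scales the spine uniformly so its canonical height matches
#' the line length (useful when replacing spines from the store; leave off
#' to preserve a measured geometry's size).
#'
#' @param rec a `spine_record`.
#' @param line a [spine_line()].
#' @param scale_to_line logical.
#' @return the placed [trimesh()].
#' @export
place_spine <- function(rec, line, scale_to_line = FALSE) {
  stopifnot(inherits(rec, "spine_record"), inherits(line, "spine_line"))
  d <- line$end - line$insertion
  len <- vnorm(d)
  q <- quat_between(c(0, 1, 0), d / len)
  s <- if (scale_to_line) len / spine_height(rec) else 1
  m <- rec$canonical_mesh
  m$vertices <- sweep(quat_rotate(q, s * m$vertices), 2, line$insertion, "+")
  m
}

#' Attach spines to a tracing
#'
#' For each spine the distance from its insertion point to every tracing
#' point is computed; if the minimum is at or below the connection
#' threshold the spine is attached to that tracing point (ties broken by
#' the earliest point in depth-first order). Attachment only annotates the
#' tracing — neurite topology is never modified. Spines that reach no point
#' are reported with a warning and left out.
#'
#' @param t a [neuron_tracing()].
#' @param spine_insertions list of [spine_line()]s and/or spine
#'   [polyline()]s (first point = insertion, last = end).
#' @param threshold connection threshold in microns.
#' @return the tracing with rows added to its `spines` table.
#' @export
attach_spines <- function(t, spine_insertions, threshold) {
  if (!length(spine_insertions)) return(t)
  P <- node_xyz(t)
  unattached <- 0L
  for (sp in spine_insertions) {
    if (inherits(sp, "spine_line")) {
      ins <- sp$insertion; end <- sp$end; rad <- 0.1
    } else if (inherits(sp, "polyline")) {
      ins <- sp$xyz[1, ]; end <- sp$xyz[nrow(sp$xyz), ]
      rad <- sp$radius[length(sp$radius)]
    } else stop_neurofil("unsupported spine input", "neurofil_bad_argument")
    d2 <- colSums((t(P) - ins)^2)
    k <- which.min(d2) # ties: which.min takes the earliest (DFS order)
    if (sqrt(d2[k]) <= threshold) {
      t$spines <- rbind(t$spines, data.frame(
        x = end[1], y = end[2], z = end[3], radius = rad,
        parent_id = t$nodes$id[k]))
    } else {
      unattached <- unattached + 1L
    }
  }
  if (unattached > 0)
    warning(sprintf("%d spine(s) beyond the connection threshold were left unattached",
                    unattached))
  t
}

#' Spine lines from a length-measurement table
#'
#' Spine length measurements are recorded as ordered point rows measured
#' from the spine tip inward: the first point is the spine's head and the
#' final point its insertion on the shaft. Each row therefore yields a
#' [spine_line()] with `insertion` = last point and `end` = first point.
#' Rows whose endpoints coincide are skipped with a warning.
#'
#' @param rows list of point matrices (>= 2 points each), or a data frame
#'   with columns `spine`, `x`, `y`, `z` grouped by `spine`.
#' @return list of [spine_line()]s.
#' @export
spines_from_length_file <- function(rows) {
  if (is.data.frame(rows))
    rows <- lapply(split(rows[, c("x", "y", "z")], rows$spine), as.matrix)
  out <- list()
  skipped <- 0L
  for (r in rows) {
    r <- as_point_matrix(r)
    if (nrow(r) < 2) { skipped <- skipped + 1L; next }
    head_pt <- r[1, ]; ins <- r[nrow(r), ]
    if (vnorm(head_pt - ins) < 1e-12) { skipped <- skipped + 1L; next }
    out[[length(out) + 1]] <- spine_line(insertion = ins, end = head_pt)
  }
  if (skipped)
    warning(sprintf("%d degenerate spine row(s) skipped", skipped))
  out
}

#' Sample spine positions along the dendrites
#'
#' For inputs without spine information, insertion points are drawn by a
#' Poisson process along the dendritic arclength at the given density.
#' Each spine line leaves the shaft along a random direction perpendicular
#' to the local branch tangent, with length uniform in 0.5-2.5 microns.
#' Reproducible for a fixed seed.
#'
#' @param t a [neuron_tracing()].
#' @param density spines per micron of dendrite (>= 0).
#' @param seed RNG seed.
#' @return list of [spine_line()]s.
#' @export
sample_spine_positions <- function(t, density, seed = 1) {
  stopifnot(density >= 0)
  if (density == 0) return(list())
  branches <- iter_branches(t, check = FALSE)
  branches <- Filter(function(b) b$part %in% c("basal", "apical") &&
                       npoints(b) >= 2, branches)
  if (!length(branches)) return(list())
  seglens <- lapply(branches, function(b)
    sqrt(rowSums((b$xyz[-1, , drop = FALSE] -
                    b$xyz[-npoints(b), , drop = FALSE])^2)))
  total <- sum(unlist(seglens))
  with_seed(seed, {
    n <- stats::rpois(1, density * total)
    if (n == 0) return(list())
    pos <- sort(stats::runif(n, 0, total))
    cum <- cumsum(unlist(seglens))
    seg_branch <- rep(seq_along(branches),
                      vapply(seglens, length, integer(1)))
    seg_local <- unlist(lapply(seglens, seq_along))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      si <- findInterval(pos[i], cum) + 1L
      si <- min(si, length(cum))
      b <- branches[[seg_branch[si]]]
      j <- seg_local[si]
      prev_cum <- if (si == 1) 0 else cum[si - 1]
      frac <- (pos[i] - prev_cum) / (cum[si] - prev_cum)
      p0 <- b$xyz[j, ]; p1 <- b$xyz[j + 1, ]
      ins <- p0 + frac * (p1 - p0)
      tan_ <- vnormalize(p1 - p0)
      pb <- perp_basis(tan_)
      ang <- stats::runif(1, 0, 2 * pi)
      dir <- cos(ang) * pb$u + sin(ang) * pb$v
      len <- stats::runif(1, 0.5, 2.5)
      out[[i]] <- spine_line(ins, ins + len * dir)
    }
    out
  })
}

# --- local on-disk spine store ---------------------------------------------

#' Local on-disk spine store
#'
#' A small directory-backed store holding processed spines in open formats:
#' the canonical mesh as OBJ, and the restoring transform plus metrics in a
#' JSON sidecar, with a plain-text index. Storing extracted morphology this
#' way decouples the data from any proprietary tool.
#'
#' @param store_dir writable directory (created if missing).
#' @param rec a `spine_record`.
#' @param id optional identifier; an unused one is generated by default.
#' @return `spine_store_put`: the id, invisibly. `spine_store_get`: the
#'   reconstructed `spine_record`. `spine_store_list`: character vector of
#'   stored ids.
#' @export
spine_store_put <- function(store_dir, rec, id = NULL) {
  stopifnot(inherits(rec, "spine_record"))
  if (!dir.exists(store_dir))
    dir.create(store_dir, recursive = TRUE)
  existing <- spine_store_list(store_dir)
  if (is.null(id)) {
    i <- length(existing) + 1L
    repeat {
      id <- sprintf("spine_%04d", i)
      if (!id %in% existing) break
      i <- i + 1L
    }
  }
  write_obj(rec$canonical_mesh, file.path(store_dir, paste0(id, ".obj")))
  side <- list(
    id = id,
    world_rotation = rec$world_rotation,
    world_translation = rec$world_translation,
    metrics = list(surface_area = rec$metrics$surface_area,
                   volume = rec$metrics$volume,
                   mass_center = rec$metrics$mass_center),
    source_tag = rec$source_tag,
    reusable = rec$reusable)
  jsonlite::write_json(side, file.path(store_dir, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  idx <- file.path(store_dir, "index.txt")
  writeLines(sort(unique(c(existing, id))), idx)
  invisible(id)
}

#' @rdname spine_store_put
#' @export
spine_store_get <- function(store_dir, id) {
  objp <- file.path(store_dir, paste0(id, ".obj"))
  sidep <- file.path(store_dir, paste0(id, ".json"))
  if (!file.exists(sidep) || !file.exists(objp))
    stop_neurofil(sprintf("spine '%s' missing or corrupt in store", id),
                  "neurofil_store_error")
  side <- tryCatch(jsonlite::read_json(sidep, simplifyVector = TRUE),
                   error = function(e)
                     stop_neurofil(sprintf("corrupt sidecar for '%s': %s",
                                           id, conditionMessage(e)),
                                   "neurofil_store_error"))
  mesh <- read_obj(objp)
  structure(list(
    canonical_mesh = mesh,
    world_rotation = as.numeric(side$world_rotation),
    world_translation = as.numeric(side$world_translation),
    metrics = list(surface_area = side$metrics$surface_area,
                   volume = side$metrics$volume,
                   mass_center = as.numeric(side$metrics$mass_center)),
    source_tag = side$source_tag,
    reusable = isTRUE(side$reusable)), class = "spine_record")
}

#' @rdname spine_store_put
#' @export
spine_store_list <- function(store_dir) {
  if (!dir.exists(store_dir)) return(character(0))
  sort(sub("\\.json$", "",
           basename(list.files(store_dir, pattern = "\\.json$"))))
}

#' Aggregate stored spine metrics to CSV
#' @param store_dir the store directory.
#' @param path output CSV path (default `metrics.csv` inside the store).
#' @return `path`, invisibly.
#' @export
spine_store_metrics_csv <- function(store_dir,
                                    path = file.path(store_dir,
                                                     "metrics.csv")) {
  ids <- spine_store_list(store_dir)
  records <- lapply(ids, function(id) spine_store_get(store_dir, id)$metrics)
  names(records) <- ids
  write_metrics_csv(records, path)
}
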