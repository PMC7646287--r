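# Seeded synthetic-morphology generator: ground-truth neuron trees, their
# fragmentation into the filament-tracer VRML dialect, and spine / broken
# sub-mesh test geometry. Every fixture carries machine-readable ground
# truth so round-trip assertions are self-contained.

#' Generate a ground-truth synthetic neuron
#'
#' Grows a strictly binary neurite tree by a biased random walk:
#' unbranched runs of points `step` microns apart, bifurcating with a
#' 50-80 degree opening angle until exactly `n_bifurcations` bifurcations
#' exist, then terminating every open tip. Radii taper by `taper` per
#' branch order. A minimum inter-branch clearance of `4 * step` (outside
#' the immediate neighborhood of each bifurcation) is enforced by
#' rejection, so proximity-based reconstruction of the fragmented tree is
#' well-posed. Deterministic for a fixed seed.
#'
#' @param seed RNG seed.
#' @param n_bifurcations total number of bifurcations (>= 0).
#' @param step inter-point (and inter-slice) spacing in microns.
#' @param taper radius multiplier per branch order in (0, 1].
#' @param n_neurites number of independent neurites (bifurcations are
#'   spread over them at random).
#' @param base_radius trunk radius in microns.
#' @return a [neuron_tracing()] with `2 * n_bifurcations + n_neurites`
#'   branches.
#' @export
generate_neuron <- function(seed, n_bifurcations = 5, step = 1,
                            taper = 0.85, n_neurites = 1,
                            base_radius = 1) {
  stopifnot(n_bifurcations >= 0, n_neurites >= 1, step > 0)
  with_seed(seed, {
    st <- new.env(parent = emptyenv())
    st$nodes <- list()
    st$pts <- matrix(numeric(0), 0, 3)
    st$next_id <- 0L
    clearance <- 4 * step
    guard <- 6 * step # clearance-exempt zone around a branch start

    add_node <- function(p, radius, parent) {
      st$next_id <- st$next_id + 1L
      st$nodes[[st$next_id]] <- c(st$next_id, parent, p, radius)
      st$pts <- rbind(st$pts, p)
      st$next_id
    }
    snapshot <- function() list(id = st$next_id)
    rollback <- function(snap) {
      st$nodes <- st$nodes[seq_len(snap$id)]
      st$pts <- st$pts[seq_len(snap$id), , drop = FALSE]
      st$next_id <- snap$id
    }
    propose_points <- function(start_pt, dir) {
      npts <- max(3L, round(stats::runif(1, 4, 8) / step))
      pts <- matrix(0, npts, 3)
      p <- start_pt; d <- dir
      for (i in seq_len(npts)) {
        d <- vnormalize(d + stats::rnorm(3, sd = 0.12))
        p <- p + step * d
        pts[i, ] <- p
      }
      ok <- TRUE
      if (nrow(st$pts) > 0) {
        far <- sqrt(rowSums(sweep(st$pts, 2, start_pt)^2)) > guard
        if (any(far)) {
          dmin <- sqrt(min(cross_dist2(pts, st$pts[far, , drop = FALSE])))
          ok <- dmin >= clearance
        }
      }
      if (ok) list(pts = pts, dir = d) else NULL
    }
    commit_branch <- function(pts, start_id, order) {
      npts <- nrow(pts)
      r0 <- base_radius * taper^order
      r1 <- base_radius * taper^(order + 1)
      radii <- r0 + (seq_len(npts) - 1) / max(1, npts - 1) * (r1 - r0)
      last <- start_id
      for (i in seq_len(npts)) last <- add_node(pts[i, ], radii[i], last)
      last
    }
    grow_branch <- function(start_pt, start_id, dir, order, tries = 60) {
      for (attempt in seq_len(tries)) {
        prop <- propose_points(start_pt, dir)
        if (!is.null(prop)) {
          last <- commit_branch(prop$pts, start_id, order)
          return(list(tip_id = last, tip_pt = prop$pts[nrow(prop$pts), ],
                      tip_dir = prop$dir, order = order))
        }
      }
      NULL
    }

    tips <- list()
    for (k in seq_len(n_neurites)) {
      ang <- 2 * pi * (k - 1) / n_neurites + stats::runif(1, 0, 0.3)
      dir <- vnormalize(c(cos(ang), sin(ang), stats::runif(1, -0.3, 0.3)))
      start <- 3 * dir # starts sit on a shell around the (absent) soma
      root_id <- add_node(start, base_radius, 0L)
      tip <- grow_branch(start, root_id, dir, 0)
      if (is.null(tip))
        stop_neurofil("could not grow a trunk with the required clearance",
                      "neurofil_generation_failed")
      tips[[k]] <- tip
    }
    for (b in seq_len(n_bifurcations)) {
      placed <- FALSE
      for (ti in sample.int(length(tips))) {
        tip <- tips[[ti]]
        for (draw in 1:15) { # redraw the bifurcation plane and angles
          snap <- snapshot()
          axis <- perp_basis(tip$tip_dir)
          phi <- stats::runif(1, 0, 2 * pi)
          a <- cos(phi) * axis$u + sin(phi) * axis$v
          half <- stats::runif(1, 30, 40) * pi / 180
          kids <- list()
          for (sgn in c(-1, 1)) {
            q <- quat_from_axis_angle(a, sgn * half)
            child_dir <- as.vector(quat_rotate(q, matrix(tip$tip_dir, 1)))
            kid <- grow_branch(tip$tip_pt, tip$tip_id, child_dir,
                               tip$order + 1, tries = 20)
            if (is.null(kid)) break
            kids[[length(kids) + 1]] <- kid
          }
          if (length(kids) == 2) {
            tips[[ti]] <- NULL
            tips <- c(tips, kids)
            placed <- TRUE
            break
          }
          rollback(snap)
        }
        if (placed) break
      }
      if (!placed)
        stop_neurofil(
          "could not place all bifurcations with the required clearance; try another seed or fewer bifurcations",
          "neurofil_generation_failed")
    }
    rows <- do.call(rbind, st$nodes)
    neuron_tracing(data.frame(
      id = as.integer(rows[, 1]), parent = as.integer(rows[, 2]),
      x = rows[, 3], y = rows[, 4], z = rows[, 5], radius = rows[, 6],
      part = "basal", stringsAsFactors = FALSE))
  })
}

# 17-point elliptical slice perpendicular to `tangent`, centered at p; the
# major semi-axis equals `radius` so the recovered slice radius is exact.
# Eccentricity and start phase are jittered so centroid/max-radius logic is
# exercised beyond circles.
make_slice <- function(p, tangent, radius) {
  pb <- perp_basis(tangent)
  phase <- stats::runif(1, 0, 2 * pi)
  ratio <- stats::runif(1, 1, 1.3)
  ang <- seq(0, 2 * pi, length.out = 18)[1:17] + phase
  ctr <- sweep(outer(radius * cos(ang), pb$u) +
                 outer((radius / ratio) * sin(ang), pb$v), 2, p, "+")
  # recenter exactly so the centroid is p and max distance is radius
  sweep(ctr, 2, colMeans(ctr) - p, "-")
}

polyline_tangents <- function(xyz) {
  n <- nrow(xyz)
  if (n == 1) return(matrix(c(1, 0, 0), 1))
  nxt <- pmin(seq_len(n) + 1L, n)
  prv <- pmax(seq_len(n) - 1L, 1L)
  d <- xyz[nxt, , drop = FALSE] - xyz[prv, , drop = FALSE]
  t(apply(d, 1, vnormalize))
}

#' Fragment a tracing and emit it as filament-tracer VRML
#'
#' Cuts every ground-truth branch into fragments of roughly
#' `mean_fragment_len` microns with a one-slice overlap at each cut
#' (emulating the intersection zones between consecutive exported
#' fragments; the parent bifurcation point is prepended to non-root
#' branches for the same reason). Each fragment is expanded into 17-point
#' elliptical slices perpendicular to the local tangent and written as a
#' `FilamentSegment6`-identified geometry; spine attachments become
#' `FilamentSegment7` geometries, optionally with a small artificial
#' "insertion sphere" secondary geometry under the same identifier.
#' Numeric identifier suffixes restart per branch, so they repeat within
#' the file. Fragments are independently reversed with probability
#' `invert_prob` (never the root fragment, which stays first in the file).
#'
#' @param t a ground-truth [neuron_tracing()] (single neurite per output
#'   file; multi-neurite tracings produce one file per neurite).
#' @param path output path; for multi-neurite tracings a `_nK` suffix is
#'   inserted before the extension.
#' @param seed RNG seed for slicing jitter and inversions.
#' @param mean_fragment_len mean fragment length in microns.
#' @param invert_prob per-fragment inversion probability.
#' @param shuffle shuffle all non-root fragments within each file.
#' @param insertion_sphere_prob probability that a spine also gets the
#'   artificial insertion-sphere geometry.
#' @return invisibly, a list with `files`, `fragment_branch` (ground-truth
#'   branch index per emitted shaft fragment, in file order) and `step`
#'   (the inter-slice spacing of the source tracing).
#' @export
fragment_and_emit_vrml <- function(t, path, seed = 1,
                                   mean_fragment_len = 5,
                                   invert_prob = 0.3, shuffle = FALSE,
                                   insertion_sphere_prob = 0.5) {
  with_seed(seed, {
    branches <- iter_branches(t)
    nd <- t$nodes
    root_of <- function(b) b$node_ids[1]
    # group branches by neurite (root of the tree they belong to)
    neurite_of <- integer(length(branches))
    ancestor_root <- function(id) {
      while (nd$parent[match(id, nd$id)] != 0)
        id <- nd$parent[match(id, nd$id)]
      id
    }
    for (i in seq_along(branches))
      neurite_of[i] <- ancestor_root(root_of(branches[[i]]))
    roots <- unique(neurite_of)
    files <- character(0)
    fragment_branch <- list()
    steps <- numeric(0)
    for (ri in seq_along(roots)) {
      rid <- roots[ri]
      fpath <- if (length(roots) == 1) path
      else sub("(\\.[A-Za-z0-9]+)$", sprintf("_n%d\\1", ri), path)
      sel <- which(neurite_of == rid)
      frag_lines <- list()
      frag_meta <- list()
      for (bi in sel) {
        b <- branches[[bi]]
        xyz <- b$xyz; radii <- b$radius
        par_id <- nd$parent[match(root_of(b), nd$id)]
        if (par_id != 0) { # prepend the bifurcation point (overlap zone)
          pr <- match(par_id, nd$id)
          xyz <- rbind(as.numeric(nd[pr, c("x", "y", "z")]), xyz)
          radii <- c(nd$radius[pr], radii)
        }
        n <- nrow(xyz)
        seg <- sqrt(sum((xyz[min(2, n), ] - xyz[1, ])^2))
        steps <- c(steps, seg)
        pts_per_frag <- max(2L, round(mean_fragment_len / max(seg, 1e-9)))
        starts <- seq(1L, max(1L, n - 1L), by = pts_per_frag - 1L)
        is_root_branch <- (par_id == 0)
        tangents <- polyline_tangents(xyz)
        suffix <- 0L
        for (si in seq_along(starts)) {
          a <- starts[si]
          bnd <- min(n, a + pts_per_frag - 1L)
          if (bnd <= a) next
          idx <- a:bnd
          inverted <- FALSE
          if (!(is_root_branch && si == 1) && stats::runif(1) < invert_prob) {
            idx <- rev(idx)
            inverted <- TRUE
          }
          slices <- lapply(idx, function(i)
            make_slice(xyz[i, ], tangents[i, ], radii[i]))
          suffix <- suffix + 1L
          frag_lines[[length(frag_lines) + 1]] <- list(
            id = sprintf("FilamentSegment6_%04d", suffix),
            slices = slices)
          frag_meta[[length(frag_meta) + 1]] <- list(
            branch = bi, inverted = inverted,
            is_root = is_root_branch && si == 1)
        }
      }
      # spines of this neurite
      sp <- t$spines
      if (nrow(sp)) {
        in_neurite <- vapply(sp$parent_id, function(pid)
          ancestor_root(pid) == rid, logical(1))
        ssuffix <- 0L
        for (s in which(in_neurite)) {
          pr <- match(sp$parent_id[s], nd$id)
          ins <- as.numeric(nd[pr, c("x", "y", "z")])
          end <- c(sp$x[s], sp$y[s], sp$z[s])
          dir <- vnormalize(end - ins)
          L <- vnorm(end - ins)
          npts <- 3L
          spts <- t(sapply(seq(0, 1, length.out = npts),
                           function(f) ins + f * L * dir))
          srad <- sp$radius[s] * c(0.8, 1, 0.9)
          slices <- lapply(seq_len(npts), function(i)
            make_slice(spts[i, ], dir, srad[i]))
          ssuffix <- ssuffix + 1L
          sid <- sprintf("FilamentSegment7_%04d", ssuffix)
          frag_lines[[length(frag_lines) + 1]] <- list(id = sid,
                                                       slices = slices)
          frag_meta[[length(frag_meta) + 1]] <- list(branch = NA_integer_,
                                                     inverted = FALSE,
                                                     is_root = FALSE)
          if (stats::runif(1) < insertion_sphere_prob) {
            # artificial insertion sphere: 2 small slices near the base
            bslices <- lapply(c(0.05, 0.15), function(f)
              make_slice(ins + f * L * dir, dir, 0.6 * sp$radius[s]))
            frag_lines[[length(frag_lines) + 1]] <- list(id = sid,
                                                         slices = bslices)
            frag_meta[[length(frag_meta) + 1]] <- list(branch = NA_integer_,
                                                       inverted = FALSE,
                                                       is_root = FALSE)
          }
        }
      }
      if (shuffle && length(frag_lines) > 2) {
        root_pos <- which(vapply(frag_meta, `[[`, logical(1), "is_root"))[1]
        rest <- setdiff(seq_along(frag_lines), root_pos)
        ord <- c(root_pos, sample(rest))
        frag_lines <- frag_lines[ord]
        frag_meta <- frag_meta[ord]
      }
      frags <- lapply(seq_along(frag_lines), function(i) {
        structure(list(internal_id = i - 1L,
                       kind = if (startsWith(frag_lines[[i]]$id,
                                             "FilamentSegment7"))
                         "spine" else "shaft",
                       source_identifier = frag_lines[[i]]$id,
                       slices = frag_lines[[i]]$slices),
                  class = "fragment")
      })
      write_clean_vrml(frags, fpath)
      files <- c(files, fpath)
      fragment_branch[[length(fragment_branch) + 1]] <-
        vapply(frag_meta, `[[`, integer(1), "branch")
    }
    invisible(list(files = files, fragment_branch = fragment_branch,
                   step = stats::median(steps)))
  })
}

#' Generate a watertight flat-based spine mesh
#'
#' A capped cylinder (neck) merging into a spherical head, built as a
#' single surface of revolution so the result is watertight with a planar
#' base disc, then placed at a random rigid pose. The applied pose is
#' attached as attribute `"pose"` (quaternion + translation) and the
#' analytic volume as attribute `"analytic_volume"`.
#'
#' @param seed RNG seed (controls the pose).
#' @param neck_radius,head_radius,height spine dimensions in microns
#'   (`head_radius > neck_radius`, `height > 2 * head_radius`).
#' @param n_seg azimuthal resolution.
#' @return a watertight [trimesh()].
#' @export
generate_spine_mesh <- function(seed, neck_radius = 0.22,
                                head_radius = 0.4, height = 1.4,
                                n_seg = 28) {
  stopifnot(neck_radius > 0, head_radius > neck_radius,
            height > 2 * head_radius)
  yc <- height - head_radius # head center
  y_join <- yc - sqrt(head_radius^2 - neck_radius^2)
  arc_y <- seq(y_join, height, length.out = 14)
  arc_r <- sqrt(pmax(0, head_radius^2 - (arc_y - yc)^2))
  arc_r[length(arc_r)] <- 0
  prof_y <- c(0, y_join * 0.5, arc_y)
  prof_r <- c(neck_radius, neck_radius, arc_r)
  m <- mesh_revolve(prof_y, prof_r, n_seg = n_seg)
  cap_h <- height - y_join
  vol <- pi * neck_radius^2 * y_join +
    pi * cap_h^2 * (3 * head_radius - cap_h) / 3
  with_seed(seed, {
    ax <- vnormalize(stats::rnorm(3))
    q <- quat_from_axis_angle(ax, stats::runif(1, 0, 2 * pi))
    tr <- stats::runif(3, -10, 10)
    m$vertices <- sweep(quat_rotate(q, m$vertices), 2, tr, "+")
    attr(m, "pose") <- list(rotation = q, translation = tr)
    attr(m, "analytic_volume") <- vol
    m
  })
}

#' Generate a broken spine as disconnected sub-meshes
#'
#' Emulates isosurface exports in which one spine is split over several
#' sub-meshes: a neck cylinder, a head sphere with a hole punched in it,
#' and a detached thin base cap, all near-touching (gaps of 0.04-0.05
#' microns, far below the default closing reach) and sharing one random
#' rigid pose. The exact sum of the component volumes is attached as
#' attribute `"analytic_volume"` for repair-tolerance checks.
#'
#' @param seed RNG seed (controls the pose and the hole location).
#' @return list of [trimesh()] sub-meshes with ground-truth attributes.
#' @export
generate_broken_spine <- function(seed) {
  neck_r <- 0.3
  neck <- mesh_revolve(c(0, 1), c(neck_r, neck_r), n_seg = 28)
  head_r <- 0.5
  head <- mesh_sphere(center = c(0, 1.55, 0), radius = head_r,
                      n_theta = 18, n_phi = 28)
  cap <- mesh_revolve(c(-0.12, -0.04), c(neck_r, neck_r), n_seg = 28)
  vol <- pi * neck_r^2 * 1 + 4 / 3 * pi * head_r^3 + pi * neck_r^2 * 0.08
  with_seed(seed, {
    # punch a hole in the head: drop faces nearest a random direction
    dirv <- vnormalize(stats::rnorm(3))
    ctr <- (head$vertices[head$faces[, 1], ] +
              head$vertices[head$faces[, 2], ] +
              head$vertices[head$faces[, 3], ]) / 3
    ctr <- sweep(ctr, 2, c(0, 1.55, 0))
    sc <- as.vector(ctr %*% dirv) / sqrt(rowSums(ctr^2))
    head$faces <- head$faces[rank(-sc) > 6, , drop = FALSE] # remove 6 faces
    ax <- vnormalize(stats::rnorm(3))
    q <- quat_from_axis_angle(ax, stats::runif(1, 0, 2 * pi))
    tr <- stats::runif(3, -5, 5)
    out <- lapply(list(neck, head, cap), function(m) {
      m$vertices <- sweep(quat_rotate(q, m$vertices), 2, tr, "+")
      m
    })
    attr(out, "analytic_volume") <- vol
    attr(out, "pose") <- list(rotation = q, translation = tr)
    out
  })
}
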