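#' Connection search between a polyline and the unprocessed pool
#'
#' Measures the distance from every point of the polyline being processed to
#' all points of each polyline still in the pool. A pool polyline whose
#' minimum point-to-point distance is at or below the connection threshold
#' yields exactly one connection, at the argmin point pair (ties broken by
#' the lowest `(current_index, other_index)` pair). Connections are returned
#' sorted by ascending `current_index`.
#'
#' Indices are 0-based, matching slice order in the source file.
#'
#' @param current a [polyline()].
#' @param pool list of candidate polylines (must not contain `current`).
#' @param threshold connection threshold in microns.
#' @return data frame with columns `current_index`, `pool_slot`,
#'   `other_index`, `distance`.
#' @export
find_connections <- function(current, pool, threshold) {
  res <- list()
  for (s in seq_along(pool)) {
    other <- pool[[s]]
    if (is.null(other)) next
    d2 <- cross_dist2(current$xyz, other$xyz)
    dmin <- sqrt(min(d2))
    if (dmin <= threshold) {
      hits <- which(d2 <= min(d2) + 1e-18, arr.ind = TRUE)
      hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
      res[[length(res) + 1]] <- data.frame(
        current_index = hits[1, 1] - 1L,
        pool_slot = s,
        other_index = hits[1, 2] - 1L,
        distance = dmin)
    }
  }
  if (!length(res))
    return(data.frame(current_index = integer(0), pool_slot = integer(0),
                      other_index = integer(0), distance = numeric(0)))
  out <- do.call(rbind, res)
  out[order(out$current_index, out$other_index), , drop = FALSE]
}

#' Realign an inverted fragment
#'
#' Exports sometimes store a fragment tip-first. If the connecting point
#' falls on the second half of the fragment's polyline (strictly past the
#' middle index), the fragment is taken to be inverted: the polyline is
#' reversed and the connection index remapped to `length - 1 - index`.
#'
#' @param other the pool [polyline()] the connection refers to.
#' @param other_index 0-based connection index on `other`.
#' @return list with the (possibly reversed) `polyline` and the updated
#'   `other_index`.
#' @export
realign_if_inverted <- function(other, other_index) {
  n <- npoints(other)
  if (other_index > (n - 1) / 2) {
    list(polyline = reverse_polyline(other),
         other_index = n - 1L - as.integer(other_index))
  } else {
    list(polyline = other, other_index = as.integer(other_index))
  }
}

#' Separate connections that share a tracing point
#'
#' When two (or more) posterior connections land on the same intermediate
#' point of the current polyline — or more than two on its final point —
#' the extra connections are reassigned to the nearest unoccupied
#' neighboring index, so that each connection has its own corresponding
#' point (at most two may share the final index, which is a plain
#' bifurcation). The number of connections is preserved.
#'
#' @param current the current [polyline()].
#' @param conns connection data frame from [find_connections()], sorted by
#'   `current_index`.
#' @return the adjusted connection data frame.
#' @export
resolve_duplicate_connection_points <- function(current, conns) {
  if (nrow(conns) < 2) return(conns)
  n <- npoints(current)
  last <- n - 1L
  occupied <- integer(0) # indices already granted to one connection
  n_at_last <- 0L
  ord <- order(conns$distance) # nearer connections keep their point
  assigned <- integer(nrow(conns))
  for (k in ord) {
    want <- conns$current_index[k]
    if (want == last && n_at_last < 2L) {
      n_at_last <- n_at_last + 1L
      assigned[k] <- want
      next
    }
    if (!(want %in% occupied) && want != last) {
      occupied <- c(occupied, want)
      assigned[k] <- want
      next
    }
    # walk outward for the nearest free neighboring index
    found <- NA_integer_
    for (step in seq_len(n)) {
      for (cand in c(want - step, want + step)) {
        if (cand < 0 || cand > last) next
        if (cand == last) {
          if (n_at_last < 2L) { found <- cand; n_at_last <- n_at_last + 1L }
        } else if (!(cand %in% occupied)) {
          found <- cand
          occupied <- c(occupied, cand)
        }
        if (!is.na(found)) break
      }
      if (!is.na(found)) break
    }
    if (is.na(found))
      stop_neurofil(
        sprintf("polyline of %d points cannot separate %d connections",
                n, nrow(conns)),
        "neurofil_unresolvable_connections")
    assigned[k] <- found
  }
  conns$current_index <- assigned
  conns[order(conns$current_index, conns$other_index), , drop = FALSE]
}

#' Build a rooted neurite tree from unconnected polylines
#'
#' The greedy, sequential hierarchy construction used on fragmented
#' filament-tracer exports. The first polyline in input order is taken as
#' the fragment closest to the soma and becomes the neurite root. The
#' current polyline's connections to the pool are searched; inverted
#' fragments are realigned; connections sharing a point are separated; and
#' the connection cases are dispatched:
#'
#' * no connections: the polyline is a terminal fragment, committed as-is;
#' * one connection at the final point: the two polylines are joined into a
#'   single one and processing continues with the joined polyline;
#' * a connection at an intermediate point: the current polyline is split
#'   there, the first part committed, and both the remainder and the
#'   connected polyline are processed as children of the split point;
#' * two connections at the final point: the polyline is committed and both
#'   connected polylines processed as children (a bifurcation);
#' * several connections (intermediate points or more than two): handled
#'   nearest-the-start-first by repeated subdivision; polylines not taken up
#'   at a split stay in the pool and are rediscovered by later searches.
#'
#' After construction, near-duplicate points arising from the overlap zones
#' between consecutive fragments should be removed with [dedupe_tree()].
#'
#' @param polylines nonempty list of [polyline()]s; the first one is the
#'   root fragment. A degenerate single-point polyline may not be the root.
#' @param threshold connection threshold in microns.
#' @param part neuron part label applied to the tree (axon/apical/basal).
#' @return a [neuron_tracing()] holding one neurite.
#' @export
build_neurite_tree <- function(polylines, threshold, part = "basal") {
  if (!length(polylines))
    stop_neurofil("no polylines to process", "neurofil_empty_input")
  if (isTRUE(polylines[[1]]$degenerate))
    stop_neurofil("a degenerate one-point polyline cannot be the root",
                  "neurofil_degenerate_root")
  pool <- polylines[-1]
  # mutable state: the node table grows as polylines are committed
  st <- new.env(parent = emptyenv())
  st$id <- 0L
  st$rows <- vector("list", 256L)
  st$n <- 0L
  add_node <- function(p, radius, parent) {
    st$id <- st$id + 1L
    st$n <- st$n + 1L
    if (st$n > length(st$rows)) st$rows <- c(st$rows, vector("list", st$n))
    st$rows[[st$n]] <- c(st$id, parent, p[1], p[2], p[3], radius)
    st$id
  }
  commit <- function(pl, parent, from = 1L) {
    last <- parent
    for (i in from:npoints(pl))
      last <- add_node(pl$xyz[i, ], pl$radius[i], last)
    last
  }
  take <- function(slot, from_index) {
    pl <- pool[[slot]]
    pool[slot] <<- list(NULL) # keep slot numbering stable
    if (from_index > 0L) # attach from the connection point onward
      pl <- subset_polyline(pl, (from_index + 1L):npoints(pl))
    pl
  }

  tasks <- list(list(pl = polylines[[1]], parent = 0L))
  while (length(tasks)) {
    task <- tasks[[length(tasks)]]
    tasks[[length(tasks)]] <- NULL
    current <- task$pl
    parent <- task$parent
    repeat {
      if (npoints(current) == 1L) { # absorbed degenerate remainder
        commit(current, parent)
        break
      }
      conns <- find_connections(current, pool, threshold)
      if (nrow(conns) == 0) {
        commit(current, parent)
        break
      }
      # realign inverted fragments before dispatch
      for (k in seq_len(nrow(conns))) {
        slot <- conns$pool_slot[k]
        ra <- realign_if_inverted(pool[[slot]], conns$other_index[k])
        pool[[slot]] <- ra$polyline
        conns$other_index[k] <- ra$other_index
      }
      conns <- resolve_duplicate_connection_points(current, conns)
      n <- npoints(current)
      i <- min(conns$current_index)
      if (i == n - 1L) {
        at_end <- conns[conns$current_index == n - 1L, , drop = FALSE]
        if (nrow(at_end) == 1L) {
          # join into a single polyline and keep processing it
          other <- take(at_end$pool_slot[1], at_end$other_index[1])
          current$xyz <- rbind(current$xyz, other$xyz)
          current$radius <- c(current$radius, other$radius)
          current$degenerate <- FALSE
        } else {
          # bifurcation at the final point
          node <- commit(current, parent)
          for (k in seq_len(nrow(at_end))) {
            child <- take(at_end$pool_slot[k], at_end$other_index[k])
            tasks[[length(tasks) + 1]] <- list(pl = child, parent = node)
          }
          break
        }
      } else {
        # split at the connection nearest the start; commit the first part,
        # continue with the remainder and the connected polyline; all other
        # connections stay in the pool for rediscovery
        first_part <- subset_polyline(current, 1:(i + 1L))
        node <- commit(first_part, parent)
        cstar <- conns[conns$current_index == i, , drop = FALSE][1, ]
        child <- take(cstar$pool_slot, cstar$other_index)
        tasks[[length(tasks) + 1]] <- list(pl = child, parent = node)
        current <- subset_polyline(current, (i + 2L):n)
        parent <- node
      }
    }
  }

  leftover <- which(!vapply(pool, is.null, logical(1)))
  if (length(leftover)) {
    ids <- vapply(pool[leftover], function(p) p$source_id, numeric(1))
    stop_neurofil(
      sprintf("%d fragment(s) left unconnected (source ids: %s); the connection threshold may be too small",
              length(leftover), paste(ids, collapse = ", ")),
      "neurofil_unconnected", leftover_ids = ids)
  }
  rows <- do.call(rbind, st$rows[seq_len(st$n)])
  neuron_tracing(data.frame(
    id = as.integer(rows[, 1]), parent = as.integer(rows[, 2]),
    x = rows[, 3], y = rows[, 4], z = rows[, 5], radius = rows[, 6],
    part = part, stringsAsFactors = FALSE))
}

#' Threshold configuration for the automatic connection-threshold search
#'
#' @param initial starting threshold in microns.
#' @param growth_factor multiplicative step (> 1).
#' @param max_threshold give-up bound in microns.
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(initial = 0.2, growth_factor = 2,
                             max_threshold = 16) {
  stopifnot(initial > 0, growth_factor > 1, initial < max_threshold)
  structure(list(initial = initial, growth_factor = growth_factor,
                 max_threshold = max_threshold), class = "threshold_config")
}

#' Automatic connection-threshold search
#'
#' Starts from a small threshold and multiplies it by the growth factor as
#' long as unconnected fragments remain, re-running the hierarchy
#' construction each time. Returns the first threshold in the schedule
#' `initial * growth_factor^k` at which every fragment connects, together
#' with the tree built at that threshold.
#'
#' @param polylines nonempty list of [polyline()]s (root first).
#' @param cfg a [threshold_config()].
#' @param part neuron part label for the tree.
#' @return list with `threshold` (microns) and `tree` (a [neuron_tracing()]).
#' @export
auto_connection_threshold <- function(polylines, cfg = threshold_config(),
                                      part = "basal") {
  t <- cfg$initial
  last_err <- NULL
  while (t <= cfg$max_threshold + 1e-12) {
    res <- tryCatch(build_neurite_tree(polylines, t, part = part),
                    neurofil_unconnected = function(e) e)
    if (inherits(res, "neuron_tracing"))
      return(list(threshold = t, tree = res))
    last_err <- res
    t <- t * cfg$growth_factor
  }
  stop_neurofil(
    sprintf("no threshold up to %g microns connects all fragments (%s)",
            cfg$max_threshold, conditionMessage(last_err)),
    "neurofil_threshold_failed",
    leftover_ids = last_err$leftover_ids)
}

#' Remove repeated points from a tracing
#'
#' The overlap zones between consecutive fragments leave near-duplicate
#' points in the built hierarchy. Traverses the neurites and removes any
#' point closer than `epsilon` to its parent, re-parenting its children to
#' the surviving point. Bifurcation points are never removed; when a
#' bifurcation sits too close to its (unbranched, non-root) parent, the
#' parent is removed instead.
#'
#' @param t a [neuron_tracing()].
#' @param epsilon dedupe distance in microns (default 1e-3).
#' @return the deduplicated tracing.
#' @export
dedupe_tree <- function(t, epsilon = 1e-3) {
  nd <- t$nodes
  repeat {
    idx <- match(nd$parent, nd$id)
    kids_count <- integer(nrow(nd))
    tab <- table(factor(nd$parent[nd$parent > 0], levels = nd$id))
    kids_count <- as.integer(tab)
    P <- as.matrix(nd[, c("x", "y", "z")])
    has_par <- which(nd$parent > 0)
    d <- rep(Inf, nrow(nd))
    d[has_par] <- sqrt(rowSums((P[has_par, , drop = FALSE] -
                                  P[idx[has_par], , drop = FALSE])^2))
    close <- which(d < epsilon)
    if (!length(close)) break
    removed <- FALSE
    for (i in close) {
      pi <- idx[i]
      if (kids_count[i] <= 1L) {
        drop_row <- i # plain chain point (or terminal): drop the child
      } else if (kids_count[pi] == 1L && nd$parent[pi] != 0L) {
        drop_row <- pi # bifurcation too close to an unbranched parent
      } else next
      drop_id <- nd$id[drop_row]
      new_parent <- nd$parent[drop_row]
      nd$parent[nd$parent == drop_id] <- new_parent
      nd <- nd[-drop_row, , drop = FALSE]
      removed <- TRUE
      break # re-derive indices after each removal
    }
    if (!removed) break
  }
  # spines attached to removed points are re-pointed to the nearest survivor
  if (nrow(t$spines)) {
    gone <- !(t$spines$parent_id %in% nd$id)
    if (any(gone)) {
      P <- as.matrix(nd[, c("x", "y", "z")])
      for (s in which(gone)) {
        d2 <- colSums((t(P) - c(t$spines$x[s], t$spines$y[s], t$spines$z[s]))^2)
        t$spines$parent_id[s] <- nd$id[which.min(d2)]
      }
    }
  }
  t$nodes <- nd
  t
}
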