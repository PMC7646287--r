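pl <- function(...) {
  xyz <- rbind(...)
  polyline(xyz, rep(0.3, nrow(xyz)))
}

test_that("connection search finds the argmin pair under the threshold", {
  A <- pl(c(0, 0, 0), c(1, 0, 0))
  B <- pl(c(1.05, 0, 0), c(2, 0, 0))
  cn <- find_connections(A, list(B), 0.1)
  expect_identical(nrow(cn), 1L)
  expect_identical(cn$current_index, 1L)
  expect_identical(cn$other_index, 0L)
  expect_equal(cn$distance, 0.05)

  expect_identical(nrow(find_connections(A, list(B), 0.01)), 0L)

  C <- pl(c(1, 0, 0), c(2, 0, 0)) # endpoint coincides
  cn2 <- find_connections(A, list(C), 0.1)
  expect_equal(cn2$distance, 0)
})

test_that("inverted fragments are detected on the strict second half", {
  p10 <- polyline(cbind(0:9, 0, 0), rep(0.3, 10))
  r <- realign_if_inverted(p10, 8L)
  expect_identical(r$other_index, 1L)
  expect_equal(r$polyline$xyz[, 1], 9:0)

  r2 <- realign_if_inverted(p10, 2L)
  expect_identical(r2$other_index, 2L)
  expect_equal(r2$polyline$xyz[, 1], 0:9)

  p9 <- polyline(cbind(0:8, 0, 0), rep(0.3, 9))
  r3 <- realign_if_inverted(p9, 4L) # exact middle: strict rule, unchanged
  expect_identical(r3$other_index, 4L)
  expect_equal(r3$polyline$xyz[, 1], 0:8)
})

test_that("duplicate connection points are separated to neighbors", {
  p10 <- polyline(cbind(0:9, 0, 0), rep(0.3, 10))
  conns <- data.frame(current_index = c(5L, 5L), pool_slot = 1:2,
                      other_index = c(0L, 0L), distance = c(0.01, 0.02))
  out <- resolve_duplicate_connection_points(p10, conns)
  expect_identical(nrow(out), 2L)
  expect_true(5L %in% out$current_index)
  expect_true(any(out$current_index %in% c(4L, 6L)))
  expect_false(any(duplicated(out$current_index)))

  distinct <- data.frame(current_index = c(2L, 7L), pool_slot = 1:2,
                         other_index = c(0L, 0L), distance = c(0.1, 0.1))
  expect_identical(resolve_duplicate_connection_points(p10, distinct)$current_index,
                   c(2L, 7L))
})

test_that("crowded final points spill to earlier indices or error out", {
  p2 <- polyline(cbind(0:1, 0, 0), rep(0.3, 2))
  conns <- data.frame(current_index = rep(1L, 3), pool_slot = 1:3,
                      other_index = 0L, distance = c(0.01, 0.02, 0.03))
  out <- resolve_duplicate_connection_points(p2, conns)
  expect_identical(sum(out$current_index == 1L), 2L)
  expect_identical(sum(out$current_index == 0L), 1L)

  p1 <- polyline(cbind(0, 0, 0), 0.3, min_points = 1L)
  conns0 <- data.frame(current_index = rep(0L, 3), pool_slot = 1:3,
                       other_index = 0L, distance = c(0.01, 0.02, 0.03))
  expect_error(resolve_duplicate_connection_points(p1, conns0),
               class = "neurofil_unresolvable_connections")
})

test_that("two collinear fragments joined end-to-start give one branch", {
  a <- line_polyline(0, 1, by = 0.25, id = 1)
  b <- line_polyline(1, 2, by = 0.25, id = 2)
  tr <- build_neurite_tree(list(a, b), 0.1)
  tr <- dedupe_tree(tr)
  expect_length(iter_branches(tr), 1L)
  expect_identical(sum(tr$nodes$parent == 0), 1L)
})

test_that("two children at the trunk's final point form a bifurcation", {
  trunk <- line_polyline(0, 2, by = 0.5, id = 1)
  c1 <- polyline(cbind(2 + seq(0, 1, 0.5), seq(0, 1, 0.5), 0), rep(0.3, 3),
                 source_id = 2)
  c2 <- polyline(cbind(2 + seq(0, 1, 0.5), -seq(0, 1, 0.5), 0), rep(0.3, 3),
                 source_id = 3)
  tr <- dedupe_tree(build_neurite_tree(list(trunk, c1, c2), 0.1))
  sig <- topology_signature(tr)
  expect_identical(sig$n_branches, 3L)
  expect_identical(sig$n_bifurcations, 1L)
  expect_identical(sig$n_terminals, 2L)
})

test_that("a child at an intermediate point splits the trunk", {
  trunk <- line_polyline(0, 4, by = 0.5, id = 1)
  child <- polyline(cbind(2, 0.4 + seq(0, 1, 0.5), 0), rep(0.3, 3),
                    source_id = 2)
  tr <- dedupe_tree(build_neurite_tree(list(trunk, child), 0.5))
  sig <- topology_signature(tr)
  expect_identical(sig$n_branches, 3L)
  expect_identical(sig$n_bifurcations, 1L)
})

test_that("two intermediate children are processed nearest-first", {
  trunk <- line_polyline(0, 9, by = 1, id = 1) # 10 points at x = 0..9
  c1 <- polyline(cbind(3, seq(0.4, 1.4, 0.5), 0), rep(0.3, 3), source_id = 2)
  c2 <- polyline(cbind(7, -seq(0.4, 1.4, 0.5), 0), rep(0.3, 3), source_id = 3)
  tr <- dedupe_tree(build_neurite_tree(list(trunk, c1, c2), 0.5))
  sig <- topology_signature(tr)
  # independent oracle for this instance: connecting fragment endpoints by
  # minimum distance yields bifurcations at x = 3 and x = 7, hence 5 branches
  expect_identical(sig$n_branches, 5L)
  expect_identical(sig$n_bifurcations, 2L)
  expect_identical(sig$n_terminals, 3L)
})

test_that("unconnected fragments raise an error carrying their ids", {
  a <- line_polyline(0, 1, by = 0.25, id = 1)
  far <- line_polyline(50, 51, by = 0.25, id = 99)
  err <- tryCatch(build_neurite_tree(list(a, far), 0.5), error = identity)
  expect_s3_class(err, "neurofil_unconnected")
  expect_true(99 %in% err$leftover_ids)
})

test_that("degenerate one-point polylines cannot be the root", {
  p1 <- polyline(cbind(0, 0, 0), 0.3, min_points = 1L)
  expect_error(build_neurite_tree(list(p1, line_polyline(0, 1)), 0.5),
               class = "neurofil_degenerate_root")
})

test_that("the automatic threshold search stops at the first workable value", {
  frs <- gap_fragments(n_frag = 4, gap = 0.4)
  res <- auto_connection_threshold(frs, threshold_config(0.1, 2, 16))
  expect_gte(res$threshold, 0.4)
  expect_lte(res$threshold, 0.8)
  expect_length(iter_branches(dedupe_tree(res$tree)), 1L)

  touching <- gap_fragments(n_frag = 3, gap = 0)
  res2 <- auto_connection_threshold(touching, threshold_config(0.1, 2, 16))
  expect_identical(res2$threshold, 0.1)

  with_far <- c(gap_fragments(n_frag = 2, gap = 0.2),
                list(line_polyline(500, 501, id = 7)))
  err <- tryCatch(auto_connection_threshold(with_far,
                                            threshold_config(0.1, 2, 4)),
                  error = identity)
  expect_s3_class(err, "neurofil_threshold_failed")
  expect_true(7 %in% err$leftover_ids)
})

test_that("dedupe removes repeated points but keeps bifurcations", {
  t <- chain_tracing(4)
  t$nodes$x <- c(0, 1, 1, 2) # two coincident consecutive points
  d <- dedupe_tree(t, 1e-3)
  expect_identical(nrow(d$nodes), 3L)
  expect_identical(nrow(validate_tracing(d)), 0L)

  t2 <- chain_tracing(4)
  expect_identical(dedupe_tree(t2, 1e-3)$nodes, t2$nodes)

  # overlap zone of 3 near-duplicates collapses without changing branches
  y <- y_tracing()
  nd <- y$nodes
  nd <- rbind(nd, data.frame(id = 8:9, parent = c(2L, 8L),
                             x = c(2, 2) + c(1e-5, 2e-5), y = 1e-5, z = 0,
                             radius = 0.5, part = "basal"))
  nd$parent[nd$id == 3] <- 9L
  y2 <- neurofil:::renumber_tracing(neuron_tracing(nd))
  before <- length(iter_branches(y2, check = FALSE))
  d2 <- dedupe_tree(y2, 1e-3)
  expect_identical(length(iter_branches(d2)), before)
  expect_identical(nrow(d2$nodes), 7L)
  expect_identical(nrow(validate_tracing(d2)), 0L)
})

test_that("recovered topology is robust to fragment order permutation", {
  t <- generate_neuron(31, n_bifurcations = 4)
  sig <- topology_signature(t)
  f <- tempfile(fileext = ".wrl")
  for (shuffle_seed in c(1, 2)) {
    fragment_and_emit_vrml(t, f, seed = 31 + shuffle_seed, shuffle = TRUE)
    polys <- lapply(Filter(function(x) x$kind == "shaft",
                           read_filament_vrml(f)), fragment_to_polyline)
    tr <- dedupe_tree(auto_connection_threshold(polys)$tree)
    expect_identical(topology_signature(tr)$degree_sequence,
                     sig$degree_sequence)
  }
})

test_that("success at one threshold persists at moderately larger ones", {
  t <- generate_neuron(33, n_bifurcations = 3)
  f <- tempfile(fileext = ".wrl")
  fragment_and_emit_vrml(t, f, seed = 34)
  polys <- lapply(Filter(function(x) x$kind == "shaft",
                         read_filament_vrml(f)), fragment_to_polyline)
  sigs <- lapply(c(0.2, 0.4, 0.8), function(thr)
    topology_signature(dedupe_tree(build_neurite_tree(polys, thr))))
  expect_identical(sigs[[1]]$degree_sequence, sigs[[2]]$degree_sequence)
  expect_identical(sigs[[1]]$degree_sequence, sigs[[3]]$degree_sequence)
})
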