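# shared in-code fixtures

chain_tracing <- function(n = 3, spacing = 1, radius = 0.5) {
  neuron_tracing(data.frame(
    id = seq_len(n), parent = c(0L, seq_len(n - 1)),
    x = spacing * (seq_len(n) - 1), y = 0, z = 0,
    radius = radius, part = "basal", stringsAsFactors = FALSE))
}

y_tracing <- function() {
  neuron_tracing(data.frame(
    id = 1:7, parent = c(0L, 1L, 2L, 3L, 4L, 3L, 6L),
    x = c(0, 1, 2, 3, 4, 3, 4), y = c(0, 0, 0, 1, 2, -1, -2), z = 0,
    radius = 0.5, part = "basal", stringsAsFactors = FALSE))
}

# straight polyline along +x between x0 and x1 sampled every `by` microns
line_polyline <- function(x0, x1, by = 0.1, id = NA_integer_, radius = 0.3) {
  xs <- seq(x0, x1, by = by)
  polyline(cbind(xs, 0, 0), rep(radius, length(xs)), source_id = id)
}

# collinear fragments with a fixed gap between consecutive fragments
gap_fragments <- function(n_frag = 4, frag_len = 2, gap = 0.5, by = 0.1) {
  lapply(seq_len(n_frag), function(k) {
    x0 <- (k - 1) * (frag_len + gap)
    line_polyline(x0, x0 + frag_len, by = by, id = k)
  })
}

# a 17-point circular slice in a given plane
circle_slice <- function(center, radius, normal = c(0, 0, 1), phase = 0) {
  pb <- neurofil:::perp_basis(normal)
  ang <- seq(0, 2 * pi, length.out = 18)[1:17] + phase
  sweep(outer(radius * cos(ang), pb$u) + outer(radius * sin(ang), pb$v),
        2, center, "+")
}

make_fragment <- function(slices, kind = "shaft", id = 0L,
                          identifier = "FilamentSegment6_0001") {
  structure(list(internal_id = id, kind = kind,
                 source_identifier = identifier, slices = slices),
            class = "fragment")
}

# VRML text for a list of (identifier, coordinate-matrix) geometries
vrml_text <- function(geoms) {
  out <- "#VRML V2.0 utf8"
  for (g in geoms) {
    out <- c(out,
             sprintf("DEF %s Shape {", g$id),
             "  geometry IndexedFaceSet {",
             "    coord Coordinate {",
             "      point [",
             sprintf("        %.6f %.6f %.6f,", g$coords[, 1], g$coords[, 2],
                     g$coords[, 3]),
             "      ]", "    }", "  }", "}")
  }
  paste(out, collapse = "\n")
}

expect_same_topology <- function(a, b) {
  sa <- topology_signature(a)
  sb <- topology_signature(b)
  expect_identical(sa$degree_sequence, sb$degree_sequence)
  expect_identical(sa$n_terminals, sb$n_terminals)
}
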