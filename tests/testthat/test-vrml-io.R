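test_that("fragments are parsed with slice counts and kinds from prefixes", {
  mk <- function(n_slices, x0) do.call(rbind, lapply(seq_len(n_slices),
    function(s) circle_slice(c(x0 + s, 0, 0), 0.5)))
  txt <- vrml_text(list(
    list(id = "FilamentSegment6_0001", coords = mk(3, 0)),
    list(id = "FilamentSegment6_0002", coords = mk(5, 10)),
    list(id = "FilamentSegment7_0001", coords = mk(2, 20))))
  frags <- read_filament_vrml(txt)
  expect_length(frags, 3L)
  expect_identical(vapply(frags, function(f) length(f$slices), integer(1)),
                   c(3L, 5L, 2L))
  expect_identical(vapply(frags, `[[`, character(1), "kind"),
                   c("shaft", "shaft", "spine"))
})

test_that("repeated source identifiers still get distinct internal ids", {
  c1 <- circle_slice(c(0, 0, 0), 1)
  txt <- vrml_text(list(
    list(id = "FilamentSegment7_0004", coords = c1),
    list(id = "FilamentSegment7_0004", coords = circle_slice(c(5, 0, 0), 1))))
  frags <- read_filament_vrml(txt)
  expect_identical(vapply(frags, `[[`, integer(1), "internal_id"), 0:1)
  expect_identical(unique(vapply(frags, `[[`, character(1),
                                 "source_identifier")),
                   "FilamentSegment7_0004")
})

test_that("coordinate counts not divisible by 17 are a hard error", {
  txt <- vrml_text(list(list(id = "FilamentSegment6_0001",
                             coords = matrix(runif(35 * 3), 35, 3))))
  expect_error(read_filament_vrml(txt),
               class = "neurofil_malformed_fragment")
  expect_error(read_filament_vrml(txt), "FilamentSegment6_0001")
})

test_that("unknown identifier prefixes are skipped with a warning", {
  txt <- vrml_text(list(
    list(id = "SomaSurface_01", coords = circle_slice(c(0, 0, 0), 1)),
    list(id = "FilamentSegment6_0001", coords = circle_slice(c(0, 0, 0), 1))))
  expect_warning(frags <- read_filament_vrml(txt), "unknown identifier")
  expect_length(frags, 1L)
  expect_identical(frags[[1]]$internal_id, 0L)
})

test_that("parsing preserves file order and assigns ids 0..n-1", {
  t <- generate_neuron(21, n_bifurcations = 2)
  f <- tempfile(fileext = ".wrl")
  fragment_and_emit_vrml(t, f, seed = 22)
  frags <- read_filament_vrml(f)
  expect_identical(vapply(frags, `[[`, integer(1), "internal_id"),
                   seq_along(frags) - 1L)
})

test_that("clean VRML round-trips coordinates bit-for-bit", {
  t <- generate_neuron(23, n_bifurcations = 2)
  f <- tempfile(fileext = ".wrl")
  fragment_and_emit_vrml(t, f, seed = 24)
  fr1 <- read_filament_vrml(f)
  f2 <- tempfile(fileext = ".wrl")
  write_clean_vrml(fr1, f2)
  fr2 <- read_filament_vrml(f2)
  expect_identical(lapply(fr2, `[[`, "slices"), lapply(fr1, `[[`, "slices"))
  expect_identical(vapply(fr2, `[[`, character(1), "source_identifier"),
                   vapply(fr1, `[[`, character(1), "source_identifier"))
})

test_that("clean VRML contains only geometry nodes", {
  noisy <- paste(
    "#VRML V2.0 utf8",
    "DirectionalLight { direction 0 0 -1 }",
    "DEF FilamentSegment6_0001 Shape {",
    "  appearance Appearance { material Material { diffuseColor 1 0 0 } }",
    "  geometry IndexedFaceSet {",
    "    coord Coordinate { point [",
    paste(sprintf("%.6f %.6f %.6f,", circle_slice(c(0, 0, 0), 1)[, 1],
                  circle_slice(c(0, 0, 0), 1)[, 2], rep(0, 17)),
          collapse = "\n"),
    "    ] }", "  }", "}", sep = "\n")
  frags <- read_filament_vrml(noisy)
  out <- tempfile(fileext = ".wrl")
  write_clean_vrml(frags, out)
  txt <- readLines(out)
  expect_false(any(grepl("Appearance|Material|Light", txt)))
  expect_identical(txt[1], "#VRML V2.0 utf8")
  # loadable by the generic low-level reader too
  geoms <- neurofil:::read_vrml_geometries(out)
  expect_length(geoms, 1L)
  expect_identical(nrow(geoms[[1]]$coordinates), 17L)
})

test_that("write_clean_vrml rejects an empty geometry list", {
  expect_error(write_clean_vrml(list(), tempfile()),
               class = "neurofil_empty_input")
})

test_that("IMX spine tagging applies the inclusive 10..10000 vertex rule", {
  mkv <- function(n) paste(apply(matrix(seq_len(n * 3) / 10, n, 3), 1,
                                 paste, collapse = " "), collapse = "\n")
  p <- tempfile(fileext = ".imx")
  writeLines(sprintf(
    "<Imx>%s</Imx>",
    paste(sprintf("<Geometry name=\"g%d\"><Vertices>%s</Vertices></Geometry>",
                  1:4, c(mkv(9), mkv(10), mkv(10000), mkv(10001))),
          collapse = "")), p)
  g <- read_imx(p)
  expect_identical(vapply(g, `[[`, character(1), "kind"),
                   c("untyped", "spine", "spine", "untyped"))
})

test_that("an IMX file without geometry blocks warns and returns empty", {
  p <- tempfile(fileext = ".imx")
  writeLines("<Imx><Meta>nothing</Meta></Imx>", p)
  expect_warning(g <- read_imx(p), "no geometry")
  expect_length(g, 0L)
})
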