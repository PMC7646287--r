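#' Read a Filament-Tracer VRML export into fragments
#'
#' Parses the VRML 2.0 dialect written by filament-tracing surface exports:
#' a sequence of `DEF <identifier> Shape { geometry IndexedFaceSet { ... } }`
#' nodes whose coordinate lists encode tubular fragments as consecutive
#' 17-point elliptical slices. Identifiers beginning with `FilamentSegment6`
#' are dendritic-shaft fragments and `FilamentSegment7` are spine fragments;
#' the numeric suffixes after the prefix are NOT unique within a file, so
#' every parsed fragment receives a fresh internal id (0-based, in file
#' order — the first fragment of a file is taken to be the one closest to
#' the soma). Geometries with any other identifier prefix are skipped with a
#' warning.
#'
#' @param path path to a `.vrl`/`.wrl` file, or a length-1 character string
#'   containing VRML text (detected by the presence of a newline).
#' @return list of `fragment` objects: `internal_id`, `kind` (shaft/spine),
#'   `source_identifier`, and `slices` (list of 17 x 3 point matrices).
#' @export
read_filament_vrml <- function(path) {
  geoms <- read_vrml_geometries(path)
  frags <- list()
  skipped <- character(0)
  for (g in geoms) {
    kind <- if (startsWith(g$source_identifier, "FilamentSegment6")) "shaft"
    else if (startsWith(g$source_identifier, "FilamentSegment7")) "spine"
    else NA_character_
    if (is.na(kind)) {
      skipped <- c(skipped, g$source_identifier)
      next
    }
    n <- nrow(g$coordinates)
    if (n %% 17L != 0L)
      stop_neurofil(
        sprintf("malformed fragment '%s': %d coordinates is not a multiple of 17",
                g$source_identifier, n),
        "neurofil_malformed_fragment")
    slices <- lapply(seq_len(n %/% 17L), function(s)
      g$coordinates[(17L * (s - 1L) + 1L):(17L * s), , drop = FALSE])
    frags[[length(frags) + 1L]] <- structure(
      list(internal_id = length(frags),
           kind = kind,
           source_identifier = g$source_identifier,
           slices = slices),
      class = "fragment")
  }
  if (length(skipped))
    warning(sprintf("skipped %d geometry node(s) with unknown identifier prefix: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  frags
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment %d '%s': %s, %d slice(s)>\n", x$internal_id,
              x$source_identifier, x$kind, length(x$slices)))
  invisible(x)
}

# low-level scan of DEF'd coordinate geometries; faces (coordIndex) are kept
# when present so mesh-repair inputs survive the same path
read_vrml_geometries <- function(path) {
  txt <- if (length(path) == 1 && grepl("\n", path)) path
  else {
    if (!file.exists(path))
      stop_neurofil(sprintf("cannot read '%s'", path), "neurofil_io_error")
    paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  defs <- gregexpr("DEF[ \t\r\n]+([A-Za-z0-9_.-]+)", txt, perl = TRUE)[[1]]
  if (defs[1] == -1) return(list())
  starts <- as.vector(defs)
  lens <- attr(defs, "match.length")
  ids <- vapply(seq_along(starts), function(i)
    sub("^DEF[ \t\r\n]+", "", substr(txt, starts[i], starts[i] + lens[i] - 1)),
    character(1))
  bounds <- c(starts, nchar(txt) + 1L)
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    seg <- substr(txt, starts[i], bounds[i + 1] - 1L)
    coords <- extract_bracket_numbers(seg, "point")
    if (is.null(coords)) next
    if (length(coords) %% 3 != 0)
      stop_neurofil(sprintf("geometry '%s': coordinate list length %d is not a multiple of 3",
                            ids[i], length(coords)), "neurofil_parse_error")
    faces <- NULL
    fidx <- extract_bracket_numbers(seg, "coordIndex")
    if (!is.null(fidx) && length(fidx)) {
      runs <- split(fidx, cumsum(c(TRUE, fidx[-length(fidx)] == -1)))
      tris <- lapply(runs, function(r) {
        r <- r[r != -1]
        if (length(r) == 3) r + 1 else NULL # only triangles in this dialect
      })
      tris <- tris[!vapply(tris, is.null, logical(1))]
      if (length(tris)) faces <- do.call(rbind, tris)
    }
    out[[i]] <- list(source_identifier = ids[i],
                     internal_id = NA_integer_,
                     coordinates = matrix(coords, ncol = 3, byrow = TRUE),
                     faces = faces)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  for (i in seq_along(out)) out[[i]]$internal_id <- i - 1L
  out
}

# numbers inside `keyword [ ... ]`, or NULL if the keyword is absent
extract_bracket_numbers <- function(txt, keyword) {
  m <- regexpr(paste0(keyword, "[ \t\r\n]*\\["), txt)
  if (m == -1) return(NULL)
  open <- m + attr(m, "match.length") - 1L
  close <- regexpr("\\]", substr(txt, open + 1L, nchar(txt)))
  if (close == -1)
    stop_neurofil(sprintf("unterminated '%s [' block", keyword),
                  "neurofil_parse_error")
  body <- substr(txt, open + 1L, open + close - 1L)
  body <- gsub(",", " ", body)
  nums <- suppressWarnings(as.numeric(strsplit(trimws(body), "[ \t\r\n]+")[[1]]))
  nums[!is.na(nums)]
}

#' Read an IMX-style geometry file with spine tagging
#'
#' Reads the package's documented plain-text IMX dialect (XML blocks
#' `<Geometry name="..."> <Vertices>...</Vertices> [<Triangles>...] `)
#' and applies the vertex-count heuristic used for untagged microscope
#' exports: a geometry with between 10 and 10,000 vertices inclusive is
#' assumed to be a dendritic spine; anything else is left untyped.
#'
#' @param path path to the file.
#' @return list of geometries: `source_identifier`, `kind` (spine/untyped),
#'   `coordinates`, optional `faces`, `internal_id`.
#' @export
read_imx <- function(path) {
  doc <- xml2::read_xml(path)
  blocks <- xml2::xml_find_all(doc, "//Geometry")
  if (length(blocks) == 0) {
    warning("no geometry blocks found in IMX file")
    return(list())
  }
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    nm <- xml2::xml_attr(blocks[[i]], "name")
    if (is.na(nm)) nm <- sprintf("geometry_%03d", i)
    vtxt <- xml2::xml_text(xml2::xml_find_first(blocks[[i]], "./Vertices"))
    nums <- suppressWarnings(as.numeric(strsplit(trimws(vtxt), "[ \t\r\n]+")[[1]]))
    nums <- nums[!is.na(nums)]
    V <- matrix(nums, ncol = 3, byrow = TRUE)
    faces <- NULL
    tn <- xml2::xml_find_first(blocks[[i]], "./Triangles")
    if (!inherits(tn, "xml_missing")) {
      tnum <- suppressWarnings(as.integer(
        strsplit(trimws(xml2::xml_text(tn)), "[ \t\r\n]+")[[1]]))
      tnum <- tnum[!is.na(tnum)]
      if (length(tnum)) faces <- matrix(tnum, ncol = 3, byrow = TRUE) + 1L
    }
    kind <- if (nrow(V) >= 10 && nrow(V) <= 10000) "spine" else "untyped"
    out[[i]] <- list(source_identifier = nm, internal_id = i - 1L,
                     kind = kind, coordinates = V, faces = faces)
  }
  out
}

#' Write a clean VRML 2.0 file
#'
#' Emits only identified indexed-face-set geometry nodes (no lighting,
#' appearance or metadata nodes), preserving identifiers and coordinates with
#' fixed 6-decimal formatting so that re-reading reproduces the coordinate
#' lists bit-for-bit as text. Fragments are written with tube triangulation
#' between consecutive slices so the output loads in a generic VRML viewer.
#'
#' @param geometries nonempty list of `fragment`s (from
#'   [read_filament_vrml()]) or raw geometries (from [read_imx()] /
#'   `read_vrml_geometries`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clean_vrml <- function(geometries, path) {
  if (length(geometries) == 0)
    stop_neurofil("no geometries to write", "neurofil_empty_input")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#VRML V2.0 utf8", con)
  for (g in geometries) {
    if (inherits(g, "fragment")) {
      coords <- do.call(rbind, g$slices)
      faces <- tube_faces(length(g$slices), 17L)
      id <- g$source_identifier
    } else {
      coords <- g$coordinates
      faces <- g$faces
      id <- g$source_identifier
    }
    writeLines(sprintf("DEF %s Shape {", id), con)
    writeLines("  geometry IndexedFaceSet {", con)
    writeLines("    coord Coordinate {", con)
    writeLines("      point [", con)
    writeLines(sprintf("        %.6f %.6f %.6f,",
                       coords[, 1], coords[, 2], coords[, 3]), con)
    writeLines("      ]", con)
    writeLines("    }", con)
    if (!is.null(faces) && nrow(faces)) {
      writeLines("    coordIndex [", con)
      writeLines(sprintf("      %d, %d, %d, -1,",
                         faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L),
                 con)
      writeLines("    ]", con)
    }
    writeLines("  }", con)
    writeLines("}", con)
  }
  invisible(path)
}

# triangles joining consecutive rings of k points (n_slices rings)
tube_faces <- function(n_slices, k = 17L) {
  if (n_slices < 2) return(matrix(integer(0), 0, 3))
  F <- matrix(0L, 0, 3)
  for (s in seq_len(n_slices - 1)) {
    a <- (s - 1L) * k
    b <- s * k
    j2 <- c(2:k, 1L)
    F <- rbind(F,
               cbind(a + 1:k, b + 1:k, b + j2),
               cbind(a + 1:k, b + j2, a + j2))
  }
  F
}
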