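# OBJ / ASCII-PLY mesh readers and writers. Fixed decimal formatting so a
# write/read round trip reproduces coordinates exactly at written precision.

#' Write a mesh
#'
#' @param m a [trimesh()].
#' @param path output path.
#' @param format `"obj"` or `"ply"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         obj = write_obj(m, path),
         ply = write_ply(m, path),
         stop_neurofil(sprintf("unsupported mesh format '%s'", format),
                       "neurofil_bad_argument"))
}

#' @rdname write_mesh
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f",
                     m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     m$faces[, 1], m$faces[, 2], m$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh
#' @param vertex_colors optional n x 3 integer RGB matrix (PLY only).
#' @export
write_ply <- function(m, path, vertex_colors = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(m$vertices); nf <- nrow(m$faces)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (!is.null(vertex_colors))
    hdr <- c(hdr, "property uchar red", "property uchar green",
             "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(vertex_colors)) {
    writeLines(sprintf("%.6f %.6f %.6f", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]), con)
  } else {
    writeLines(sprintf("%.6f %.6f %.6f %d %d %d",
                       m$vertices[, 1], m$vertices[, 2], m$vertices[, 3],
                       vertex_colors[, 1], vertex_colors[, 2],
                       vertex_colors[, 3]), con)
  }
  writeLines(sprintf("3 %d %d %d", m$faces[, 1] - 1L, m$faces[, 2] - 1L,
                     m$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a mesh file
#' @param path an `.obj` or ASCII `.ply` file.
#' @return a [trimesh()]; PLY vertex colors, when present, are attached as
#'   attribute `"vertex_colors"`.
#' @export
read_mesh <- function(path) {
  switch(tolower(tools::file_ext(path)),
         obj = read_obj(path),
         ply = read_ply(path),
         stop_neurofil(sprintf("unsupported mesh file '%s'", path),
                       "neurofil_bad_argument"))
}

#' @rdname read_mesh
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  V <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "[ \t]+"),
                             function(x) as.numeric(x[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "[ \t]+"),
                             function(x) as.integer(sub("/.*", "", x[1:3]))))
  trimesh(V, F, clean = FALSE)
}

#' @rdname read_mesh
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- which(lines == "end_header")[1]
  if (is.na(endh))
    stop_neurofil("not an ASCII PLY file", "neurofil_parse_error")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  has_color <- any(grepl("property uchar red", lines[1:endh]))
  vrows <- lines[(endh + 1):(endh + nv)]
  vm <- do.call(rbind, lapply(strsplit(vrows, "[ \t]+"), as.numeric))
  frows <- lines[(endh + nv + 1):(endh + nv + nf)]
  fm <- do.call(rbind, lapply(strsplit(frows, "[ \t]+"), function(x)
    as.integer(x[2:4]) + 1L))
  m <- trimesh(vm[, 1:3, drop = FALSE], fm, clean = FALSE)
  if (has_color)
    attr(m, "vertex_colors") <- vm[, 4:6, drop = FALSE]
  m
}
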