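#' Tracing point from one elliptical slice
#'
#' The center is the arithmetic centroid of the 17 slice points (exact for
#' the symmetric sampling the exports use, robust otherwise); the stored
#' thickness is the slice radius, defined as the distance from the center to
#' the farthest point of the slice (the major semi-axis for an ellipse).
#'
#' @param slice 17 x 3 point matrix.
#' @return list with `center` (length-3) and `radius` (microns).
#' @export
slice_center_radius <- function(slice) {
  slice <- as_point_matrix(slice)
  if (nrow(slice) != 17)
    stop_neurofil("a slice must have exactly 17 points",
                  "neurofil_bad_slice")
  center <- colMeans(slice)
  d2 <- rowSums(sweep(slice, 2, center)^2)
  list(center = center, radius = sqrt(max(d2)))
}

#' Convert a fragment to a radius-annotated polyline
#'
#' One tracing point per slice, in slice order, positioned at the slice
#' center with the slice radius as thickness. Shaft fragments get the
#' placeholder part `basal` (reassigned when the file's role is known);
#' spine fragments keep part `spine`. A single-slice fragment yields a
#' degenerate one-point polyline flagged for merge-only use.
#'
#' @param f a `fragment` from [read_filament_vrml()].
#' @return a [polyline()].
#' @export
fragment_to_polyline <- function(f) {
  stopifnot(inherits(f, "fragment"))
  cr <- lapply(f$slices, slice_center_radius)
  xyz <- do.call(rbind, lapply(cr, `[[`, "center"))
  polyline(xyz = xyz,
           radius = vapply(cr, `[[`, numeric(1), "radius"),
           part = if (f$kind == "spine") "spine" else "basal",
           source_id = f$internal_id,
           min_points = 1L)
}

#' Select the main geometry among fragments sharing a spine identifier
#'
#' Exports sometimes pair a spine's main geometry with a small artificial
#' "insertion sphere" mesh under the same identifier; only the main geometry
#' should contribute to the tracing (counting the artificial sphere would
#' bias area/volume and skeleton extraction). The main geometry is the
#' candidate with more slices; on a tie, the one with the larger bounding-box
#' diagonal.
#'
#' @param candidates list of 1 or 2 `fragment`s sharing one identifier.
#' @return the selected `fragment`.
#' @export
select_main_spine_geometry <- function(candidates) {
  if (length(candidates) == 1) return(candidates[[1]])
  if (length(candidates) > 2)
    stop_neurofil(
      sprintf("ambiguous spine geometry: %d candidates share identifier(s) %s",
              length(candidates),
              paste(unique(vapply(candidates, `[[`, character(1),
                                  "source_identifier")), collapse = ", ")),
      "neurofil_ambiguous_spine")
  ns <- vapply(candidates, function(f) length(f$slices), integer(1))
  if (ns[1] != ns[2]) return(candidates[[which.max(ns)]])
  diag_of <- function(f) {
    P <- do.call(rbind, f$slices)
    r <- apply(P, 2, range)
    vnorm(r[2, ] - r[1, ])
  }
  candidates[[which.max(vapply(candidates, diag_of, numeric(1)))]]
}
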