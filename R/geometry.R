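#' Fit a directed axis to an ordered coordinate trace
#'
#' The axis is the first principal direction of the centered coordinates,
#' with its sign chosen so that it points from the first toward the last
#' point (N-to-C for a protein trace), making obtuse inter-unit angles
#' representable.
#'
#' @param coords An n x 3 numeric matrix, or a structure tibble with
#'   `x`, `y`, `z` columns, of at least 5 ordered points.
#' @return A list of class `unit_frame`: `centroid` (3-vector), `axis`
#'   (directed unit 3-vector), `collinearity` (fraction of total variance on
#'   the first principal direction, in `[0, 1]`).
#' @export
#' @examples
#' fit_axis(simulate_ideal_helix(20))
fit_axis <- function(coords) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 5) abort("Axis fitting requires at least 5 points.")
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  s <- svd(centered, nu = 0, nv = 3)
  if (s$d[1] < 1e-12) abort("Degenerate coordinates: zero variance.")
  axis <- s$v[, 1]
  span <- coords[nrow(coords), ] - coords[1, ]
  if (sum(axis * span) < 0) axis <- -axis
  structure(
    list(centroid = centroid, axis = axis,
         collinearity = s$d[1]^2 / sum(s$d^2)),
    class = "unit_frame"
  )
}

as_coord_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    if (!all(c("x", "y", "z") %in% names(coords))) {
      abort("Coordinate data frames need `x`, `y`, `z` columns.")
    }
    coords <- cbind(coords$x, coords$y, coords$z)
  }
  if (!is.matrix(coords) || ncol(coords) != 3 || !is.numeric(coords)) {
    abort("`coords` must be an n x 3 numeric matrix or a structure tibble.")
  }
  if (any(!is.finite(coords))) abort("Coordinates must be finite.")
  coords
}

#' @export
print.unit_frame <- function(x, ...) {
  cat(sprintf("<unit_frame> axis (%.3f, %.3f, %.3f), collinearity %.3f\n",
              x$axis[1], x$axis[2], x$axis[3], x$collinearity))
  invisible(x)
}

#' Assembly plane normal
#'
#' The direction of least variance of all representative-atom coordinates —
#' the normal of the "top view" plane in which inter-unit angles are
#' measured. The sign is canonicalized so the first component of magnitude
#' above 1e-9 is positive.
#'
#' @param coords All assembly coordinates (matrix or structure tibble).
#' @return A unit 3-vector.
#' @export
assembly_plane_normal <- function(coords) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 3) abort("Plane fitting requires at least 3 points.")
  centered <- sweep(coords, 2, colMeans(coords))
  s <- svd(centered, nu = 0, nv = 3)
  if (s$d[1] < 1e-12) abort("Degenerate coordinates: zero variance.")
  # isotropic in the two smallest directions: normal ill-defined
  if ((s$d[2] - s$d[3]) / s$d[1] < 1e-9) {
    abort("Coordinate cloud is isotropic in its two minor directions; plane normal undefined.")
  }
  canonicalize_sign(s$v[, 3])
}

canonicalize_sign <- function(v) {
  nz <- which(abs(v) > 1e-9)
  if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
  v
}

#' Projected inter-unit angle
#'
#' Angle between two directed unit axes after projection onto the plane
#' perpendicular to `normal`, in degrees in `[0, 180]`; symmetric in its two
#' arguments. This is the "top view" angle between adjacent dimer units of
#' an oligomeric assembly (about 90 degrees for the tetramer-like
#' dimer-of-dimers, about 120 degrees for the hexamer-like
#' trimer-of-dimers).
#'
#' @param a,b `unit_frame`s (or directed 3-vectors).
#' @param normal Plane normal (unit 3-vector).
#' @return Angle in degrees.
#' @export
#' @examples
#' projected_inter_unit_angle(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
projected_inter_unit_angle <- function(a, b, normal) {
  va <- project_axis(if (inherits(a, "unit_frame")) a$axis else a, normal)
  vb <- project_axis(if (inherits(b, "unit_frame")) b$axis else b, normal)
  cross <- c(va[2] * vb[3] - va[3] * vb[2],
             va[3] * vb[1] - va[1] * vb[3],
             va[1] * vb[2] - va[2] * vb[1])
  atan2(sqrt(sum(cross^2)), sum(va * vb)) * 180 / pi
}

project_axis <- function(v, normal) {
  normal <- normal / sqrt(sum(normal^2))
  p <- v - sum(v * normal) * normal
  len <- sqrt(sum(p^2))
  if (len < 1e-6) abort("Axis is (near-)perpendicular to the assembly plane; projection undefined.")
  p / len
}

#' Parse a unit definition string
#'
#' `"A+A',B+B'"` means two units, the first composed of chains A and A',
#' the second of chains B and B'.
#'
#' @param units A character scalar as above, or a list of character vectors
#'   of chain ids (returned unchanged).
#' @return A named list of chain-id vectors.
#' @export
parse_units <- function(units) {
  if (is.list(units)) {
    out <- units
  } else if (is.character(units) && length(units) == 1) {
    out <- strsplit(strsplit(units, ",", fixed = TRUE)[[1]], "+", fixed = TRUE)
  } else if (is.character(units)) {
    out <- strsplit(units, "+", fixed = TRUE)
  } else {
    abort("`units` must be a string like \"A+A',B+B'\" or a list of chain-id vectors.")
  }
  if (length(out) < 2) abort("At least two units are required.")
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- paste0("unit", seq_along(out))
  }
  lapply(out, trimws)
}

#' Inter-unit angle report for an oligomeric assembly
#'
#' Fits a directed axis to every dimer unit, determines the assembly plane,
#' orders the units by the angular position of their centroids about the
#' plane normal, and measures the projected angle between adjacent directed
#' axes (cyclically for three or more units). The assembly is classified by
#' the median adjacent angle: tetramer-like in `[75, 105)` degrees,
#' hexamer-like in `[105, 135]`, otherwise `other` (windows centered on the
#' 90-degree dimer-of-dimers and 120-degree trimer-of-dimers geometries,
#' with 15-degree margins; configurable).
#'
#' @param structure Structure tibble (`chain`, `resno`, `x`, `y`, `z`), e.g.
#'   from [read_structure()] or [simulate_planar_assembly()].
#' @param units Unit definition: see [parse_units()].
#' @param axis_mode `"unit_pca"` (default; axis over all representative
#'   atoms of the unit's chains) or `"helix"` (axis over an explicit helix
#'   residue range, for when the deposited model's helix boundaries are
#'   known).
#' @param helix_range For `axis_mode = "helix"`: a list per unit of
#'   `list(chain =, start =, end =)` (a single range is recycled).
#' @param windows Classification windows (degrees):
#'   `list(tetramer = c(75, 105), hexamer = c(105, 135))`.
#' @return A list of class `assembly_angles`: `frames` (per-unit
#'   [fit_axis()] results), `normal`, `angles` (tibble `unit_a`, `unit_b`,
#'   `angle_deg`), `median_angle`, `classification`, `windows`.
#' @export
#' @examples
#' assembly_report(simulate_planar_assembly(2, 90), units = list("A", "B"))
assembly_report <- function(structure, units,
                            axis_mode = c("unit_pca", "helix"),
                            helix_range = NULL,
                            windows = list(tetramer = c(75, 105),
                                           hexamer = c(105, 135))) {
  axis_mode <- match.arg(axis_mode)
  stopifnot(is.data.frame(structure),
            all(c("chain", "x", "y", "z") %in% names(structure)))
  units <- parse_units(units)
  missing <- setdiff(unique(unlist(units)), unique(structure$chain))
  if (length(missing) > 0) {
    abort(sprintf("Chain(s) %s not present in the structure.",
                  paste(missing, collapse = ", ")))
  }
  if (axis_mode == "helix") {
    if (is.null(helix_range)) abort("`helix_range` is required when axis_mode = \"helix\".")
    if (!is.null(helix_range$chain)) helix_range <- list(helix_range)
    if (length(helix_range) == 1) helix_range <- rep(helix_range, length(units))
    if (length(helix_range) != length(units)) {
      abort("`helix_range` must supply one range, or one per unit.")
    }
  }

  frames <- lapply(seq_along(units), function(i) {
    unit_coords <- structure[structure$chain %in% units[[i]], ]
    if (axis_mode == "helix") {
      hr <- helix_range[[i]]
      axis_coords <- structure[structure$chain == hr$chain &
                                 structure$resno >= hr$start &
                                 structure$resno <= hr$end, ]
      if (nrow(axis_coords) < 5) {
        abort(sprintf("Helix range %s:%d-%d has fewer than 5 residues.",
                      hr$chain, hr$start, hr$end))
      }
      fr <- fit_axis(axis_coords)
      fr$centroid <- colMeans(as_coord_matrix(unit_coords))
      fr
    } else {
      fit_axis(unit_coords)
    }
  })
  names(frames) <- names(units)

  normal <- assembly_plane_normal(structure)
  # order units by angular position of projected centroids about the normal
  centroids <- do.call(rbind, lapply(frames, `[[`, "centroid"))
  center <- colMeans(centroids)
  e1 <- project_axis(c(centroids[1, ] - center), normal)
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  rel <- sweep(centroids, 2, center)
  ang <- atan2(rel %*% e2, rel %*% e1)
  ord <- order(ang)

  n <- length(units)
  pairs <- if (n >= 3) cbind(ord, ord[c(2:n, 1)]) else cbind(ord[1], ord[2])
  angles <- tibble(
    unit_a = names(units)[pairs[, 1]],
    unit_b = names(units)[pairs[, 2]],
    angle_deg = vapply(seq_len(nrow(pairs)), function(i) {
      projected_inter_unit_angle(frames[[pairs[i, 1]]], frames[[pairs[i, 2]]],
                                 normal)
    }, numeric(1))
  )
  med <- median(angles$angle_deg)
  classification <- if (med >= windows$tetramer[1] && med < windows$tetramer[2]) {
    "tetramer_like"
  } else if (med >= windows$hexamer[1] && med <= windows$hexamer[2]) {
    "hexamer_like"
  } else {
    "other"
  }
  base::structure(
    list(frames = frames, normal = normal, angles = angles,
         median_angle = med, classification = classification,
         windows = windows),
    class = "assembly_angles"
  )
}

#' @export
print.assembly_angles <- function(x, ...) {
  cat(sprintf("<assembly_angles> %d units, median adjacent angle %.2f deg -> %s\n",
              length(x$frames), x$median_angle, x$classification))
  print(x$angles)
  invisible(x)
}

#' @describeIn assembly_report Adjacent projected angles as a tibble.
#' @param x An `assembly_angles` object.
#' @param ... Unused.
#' @export
tidy.assembly_angles <- function(x, ...) x$angles

#' @describeIn assembly_report One-row summary: unit count, median angle,
#'   classification.
#' @export
glance.assembly_angles <- function(x, ...) {
  tibble(
    n_units = length(x$frames),
    n_adjacent_pairs = nrow(x$angles),
    median_angle_deg = x$median_angle,
    min_angle_deg = min(x$angles$angle_deg),
    max_angle_deg = max(x$angles$angle_deg),
    classification = x$classification
  )
}

#' Apply a rigid motion to a structure
#'
#' @param structure Structure tibble.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector.
#' @return The transformed structure tibble.
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as_coord_matrix(structure) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  structure$x <- xyz[, 1]
  structure$y <- xyz[, 2]
  structure$z <- xyz[, 3]
  structure
}
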