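#' Simulate an ideal helix of pseudo-C-alpha points
#'
#' Points lie on an ideal helix with the given per-residue rise and twist,
#' axis along `orientation`, centered on `origin` (the axial coordinate is
#' centered so the point centroid sits on the axis through `origin`).
#' `radius = 0` degenerates to collinear points along the axis, which is the
#' exact-geometry building block used by [simulate_planar_assembly()].
#'
#' @param n_res Number of residues (>= 3).
#' @param rise Rise per residue (Angstrom). Default 1.5 (alpha-helical).
#' @param twist Twist per residue (degrees). Default 100 (alpha-helical).
#' @param radius Helix radius (Angstrom). Default 2.3 (C-alpha trace).
#' @param orientation Axis direction (3-vector, any nonzero length).
#' @param origin Axis anchor point (3-vector).
#' @return An `n_res` x 3 numeric matrix of coordinates.
#' @export
simulate_ideal_helix <- function(n_res = 20L, rise = 1.5, twist = 100,
                                 radius = 2.3,
                                 orientation = c(0, 0, 1),
                                 origin = c(0, 0, 0)) {
  n_res <- check_count(n_res, "n_res", min = 3)
  if (length(orientation) != 3 || sum(orientation^2) == 0) {
    abort("`orientation` must be a nonzero 3-vector.")
  }
  t <- seq_len(n_res) - 1
  theta <- twist * pi / 180 * t
  local <- cbind(radius * cos(theta),
                 radius * sin(theta),
                 rise * (t - (n_res - 1) / 2))
  R <- rotation_to(c(0, 0, 1), orientation / sqrt(sum(orientation^2)))
  sweep(local %*% t(R), 2, origin, "+")
}

# Rotation matrix carrying unit vector a onto unit vector b (Rodrigues).
rotation_to <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-24) {
    if (c_ > 0) return(diag(3))
    # opposite directions: rotate pi about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- p - sum(p * a) * a
    u <- u / sqrt(sum(u^2))
    return(2 * tcrossprod(u) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Random 3D rotation matrix
#'
#' Uniform rotation via QR decomposition of a Gaussian matrix; used to test
#' rigid-motion invariance of the geometry operators.
#'
#' @param seed Integer seed.
#' @return A 3 x 3 rotation matrix (determinant +1).
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R * det(R) # force det +1
}

#' Simulate a planar oligomeric assembly at specified inter-unit angles
#'
#' Builds `n_units` identical rod/helix units whose directed axes all lie in
#' the xy-plane, with consecutive directed axes differing by the requested
#' angles; unit centroids are placed on a circle so their angular order about
#' the plane normal matches unit order. With the default `radius = 0` each
#' unit is a straight rod exactly in-plane, so [assembly_report()] recovers
#' the requested angles to machine precision; `radius > 0` adds helical
#' wobble off the plane.
#'
#' @param n_units Number of dimer-like units (2-6).
#' @param adjacent_angles Angles between consecutive directed unit axes
#'   (degrees, each in (0, 180)); length `n_units - 1`.
#' @param n_res Residues per unit.
#' @param rise,twist,radius Per-unit helix parameters (see
#'   [simulate_ideal_helix()]); `radius` defaults to 0 (exact rods).
#' @param ring_radius Radius of the centroid circle (Angstrom).
#' @param jitter Isotropic Gaussian coordinate noise s.d. (Angstrom).
#' @param seed Integer seed (used only when `jitter > 0`).
#' @return A structure tibble with columns `chain` (one letter per unit),
#'   `resno`, `resname`, `x`, `y`, `z` — the in-memory structure model used
#'   across the geometry functions.
#' @export
#' @examples
#' simulate_planar_assembly(2, 90)
simulate_planar_assembly <- function(n_units, adjacent_angles,
                                     n_res = 20L, rise = 1.5, twist = 100,
                                     radius = 0, ring_radius = 40,
                                     jitter = 0, seed = NULL) {
  n_units <- check_count(n_units, "n_units", min = 2)
  if (n_units > 6) abort("`n_units` must be between 2 and 6.")
  if (length(adjacent_angles) != n_units - 1) {
    abort("`adjacent_angles` must have length `n_units` - 1.")
  }
  if (any(adjacent_angles <= 0 | adjacent_angles >= 180)) {
    abort("All `adjacent_angles` must lie strictly inside (0, 180) degrees.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  heading <- cumsum(c(0, adjacent_angles)) * pi / 180
  psi <- 2 * pi * (seq_len(n_units) - 1) / n_units
  pieces <- lapply(seq_len(n_units), function(i) {
    d <- c(cos(heading[i]), sin(heading[i]), 0)
    centroid <- c(ring_radius * cos(psi[i]), ring_radius * sin(psi[i]), 0)
    xyz <- simulate_ideal_helix(n_res, rise = rise, twist = twist,
                                radius = radius, orientation = d,
                                origin = centroid)
    tibble(chain = LETTERS[i], resno = seq_len(n_res), resname = "ALA",
           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  out <- dplyr::bind_rows(pieces)
  if (jitter > 0) {
    out$x <- out$x + rnorm(nrow(out), sd = jitter)
    out$y <- out$y + rnorm(nrow(out), sd = jitter)
    out$z <- out$z + rnorm(nrow(out), sd = jitter)
  }
  out
}
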