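#' Corneal curvature angle from three displacements
#'
#' Given the three displacements of the corneal triangle -- `d1` the limbus
#' chord (the side opposite the apex) and `d2`, `d3` the apex-to-chord-end
#' sides -- the apex opening angle follows from the law of cosines,
#' \deqn{\theta = \arccos\left(\frac{d_2^2 + d_3^2 - d_1^2}{2 d_2 d_3}\right),}
#' and the angle of curvature is its supplement, `180 - theta` degrees: a
#' flat cornea has a wide apex angle (curvature angle near 0), a sharp cone
#' a small one (curvature angle approaching 180).
#'
#' @param d1,d2,d3 Positive displacements satisfying the triangle
#'   inequality.
#' @return A `curvature_triangle`: list with `d1`, `d2`, `d3`, `theta_deg`
#'   and `angle_of_curvature_deg = 180 - theta_deg`.
#' @export
angle_from_triangle <- function(d1, d2, d3) {
  if (any(c(d1, d2, d3) <= 0))
    kerato_error("displacements must be positive", "kerato3d_geometry_error")
  if (d1 > d2 + d3 || d2 > d1 + d3 || d3 > d1 + d2)
    kerato_error("triangle inequality violated", "kerato3d_geometry_error")
  cosv <- (d2^2 + d3^2 - d1^2) / (2 * d2 * d3)
  theta <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  structure(list(d1 = d1, d2 = d2, d3 = d3,
                 theta_deg = theta,
                 angle_of_curvature_deg = 180 - theta),
            class = "curvature_triangle")
}

#' @export
print.curvature_triangle <- function(x, ...) {
  cat(sprintf("curvature triangle: d1=%.2f d2=%.2f d3=%.2f -> theta=%.2f deg, angle of curvature=%.2f deg\n",
              x$d1, x$d2, x$d3, x$theta_deg, x$angle_of_curvature_deg))
  invisible(x)
}

#' Steepest corneal slope relative to the limbus plane
#'
#' Measures the maximum angle between the corneal surface tangent and the
#' limbus plane -- the quantity the 45/52 degree staging thresholds apply
#' to. Slopes are evaluated as windowed least-squares tangents along the
#' profile (robust against pixel-level jitter in extracted contours); a
#' locally vertical tangent maps to 90 degrees. Profile coordinates are in
#' pixels on both axes (`aspect` rescales the height axis if the two axes
#' are sampled differently, normalising the profile to its enclosing
#' rectangle's true aspect).
#'
#' The input is either a two-column matrix of profile samples
#' `(position along the limbus plane, elevation above it)` -- e.g. a lateral
#' contour re-expressed relative to the chord -- or a reconstructed 3D
#' volume, from which the elevation crest along the apex meridian is
#' extracted first.
#'
#' @param x Two-column numeric matrix, or a 3D array.
#' @param aspect Elevation-axis scale factor applied before slopes are
#'   taken.
#' @param window Half-width (in samples) of the local tangent fit.
#' @param min_samples Minimum profile samples required.
#' @return Steepness in degrees, in `[0, 90]`.
#' @export
measure_steepness <- function(x, aspect = 1, window = 10L, min_samples = 16L) {
  if (is.array(x) && length(dim(x)) == 3) x <- volume_meridian_profile(x)
  x <- as.matrix(x)
  if (nrow(x) < min_samples)
    kerato_error(sprintf("surface too small (%d < %d samples)", nrow(x), min_samples),
                 "kerato3d_config_error")
  ord <- order(x[, 1])
  u <- x[ord, 1]
  z <- x[ord, 2] * aspect
  n <- length(u)
  best <- 0
  for (i in seq_len(n)) {
    lo <- max(1, i - window); hi <- min(n, i + window)
    uu <- u[lo:hi]; zz <- z[lo:hi]
    su <- uu - mean(uu); sz <- zz - mean(zz)
    den <- sum(su^2); num <- sum(su * sz)
    ang <- if (den < 1e-9 * max(sum(sz^2), 1e-12)) {
      if (sum(sz^2) > 1e-12) 90 else 0  # vertical tangent
    } else {
      atan(abs(num / den)) * 180 / pi
    }
    if (ang > best) best <- ang
  }
  best
}

# Elevation crest profile through the apex meridian of a corneal volume:
# for each x column along the meridian row, the highest z whose intensity
# exceeds half the volume maximum.
volume_meridian_profile <- function(vol) {
  thr <- 0.5 * max(vol)
  if (thr <= 0)
    kerato_error("empty volume", "kerato3d_config_error")
  occ <- vol > thr
  elev <- apply(occ, c(1, 2), function(col) {
    w <- which(col)
    if (length(w) == 0) NA_real_ else max(w)
  })
  apex <- which(elev == max(elev, na.rm = TRUE), arr.ind = TRUE)[1, ]
  prof_x <- elev[, apex[2]]
  prof_y <- elev[apex[1], ]
  rbind(cbind(which(!is.na(prof_x)), prof_x[!is.na(prof_x)]),
        cbind(which(!is.na(prof_y)) + 1e4, prof_y[!is.na(prof_y)]))
}

#' Grade keratoconus stage from the steepest corneal slope
#'
#' Staging thresholds: no cone detected gives `normal`; otherwise steepness
#' below 45 degrees is `mild`, 45 to 52 inclusive is `moderate` (the
#' literature also calls this band "advanced"), and above 52 is `severe`.
#' The partition is total and deterministic over `[0, 90)`.
#'
#' @param steepness_deg Steepest corneal slope, degrees in `[0, 90)`.
#' @param cone_detected Logical; whether a corneal cone was detected at all
#'   (in the geometric pipeline: corneal depth exceeding a set fraction of
#'   the iris radius).
#' @return A `stage_result`: list with `steepness_deg` and `stage`.
#' @export
grade_stage <- function(steepness_deg, cone_detected = TRUE) {
  if (!is.finite(steepness_deg) || steepness_deg < 0 || steepness_deg >= 90)
    kerato_error("steepness_deg must lie in [0, 90)", "kerato3d_config_error")
  stage <- if (!cone_detected) "normal"
           else if (steepness_deg < 45) "mild"
           else if (steepness_deg <= 52) "moderate"
           else "severe"
  structure(list(steepness_deg = steepness_deg, stage = stage),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf("stage: %s (steepness %.1f deg)\n", x$stage, x$steepness_deg))
  invisible(x)
}

#' Geometric staging of a lateral profile
#'
#' Convenience wrapper chaining the geometric branch: the corneal arc (the
#' contour part protruding beyond the limbus chord) is expressed relative
#' to the chord, steepness is measured with [measure_steepness()], cone
#' presence is decided by the depth-to-iris-radius ratio, the curvature
#' triangle is built from the three landmarks (`d1 = |p2-p3|`,
#' `d2 = |p1-p2|`, `d3 = |p1-p3|`) and the stage is graded.
#'
#' @param landmarks A [find_depth_landmarks()] result.
#' @param iris An `iris_circle`.
#' @param cone_depth_ratio Depth/iris-radius ratio above which a cone is
#'   declared. The default 0.5 sits between the relative depth of a normal
#'   spherical cap (about 0.27--0.36 for rim tangents of 30--40 degrees)
#'   and that of even the shallowest keratoconic cone flank (about 0.87 at
#'   41 degrees).
#' @return List with `triangle` (`curvature_triangle`), `steepness_deg`,
#'   `cone_detected`, and `stage_result`.
#' @export
stage_from_landmarks <- function(landmarks, iris, cone_depth_ratio = 0.5) {
  chord_col <- (landmarks$p2[2] + landmarks$p3[2]) / 2
  # keep only the strictly protruding part of the contour: a 1 px margin
  # past the chord keeps rim-corner clutter (chord-column contour points at
  # a single row) out of the slope windows
  arc <- landmarks$contour[landmarks$contour[, 2] >= chord_col + 1.0, , drop = FALSE]
  # running mean along the contour path: cancels marching-squares stair
  # jitter without biasing locally linear stretches
  smooth_path <- function(v, k = 9L) {
    if (length(v) < k) return(v)
    as.vector(stats::filter(v, rep(1 / k, k), sides = 2)) -> sm
    sm[is.na(sm)] <- v[is.na(sm)]
    sm
  }
  prof <- cbind(smooth_path(arc[, 1]), smooth_path(arc[, 2] - chord_col))
  steep <- measure_steepness(prof)
  cone <- landmarks$d > cone_depth_ratio * iris$r
  tri <- angle_from_triangle(
    d1 = sqrt(sum((landmarks$p2 - landmarks$p3)^2)),
    d2 = sqrt(sum((landmarks$p1 - landmarks$p2)^2)),
    d3 = sqrt(sum((landmarks$p1 - landmarks$p3)^2)))
  list(triangle = tri, steepness_deg = steep, cone_detected = cone,
       stage_result = grade_stage(steep, cone))
}
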