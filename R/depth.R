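#' Corneal depth from three lateral-view landmarks
#'
#' The lateral corneal profile is summarised by three points: the apex `p1`
#' (the point of maximal protrusion), and the two limbus-chord endpoints
#' `p2` (upper) and `p3` (lower). With `C` the chord midpoint, the corneal
#' depth is the leg of the right triangle whose hypotenuse is `p1`--`p2` and
#' whose base is the half-chord `C`--`p2`:
#' \deqn{d = \sqrt{|p_1 - p_2|^2 - |p_2 - C|^2}.}
#' The construction assumes the apex lies on the perpendicular bisector of
#' the chord (as it does for a symmetric corneal profile); there `d` equals
#' the perpendicular distance from the apex to the chord line. If `p1` lies
#' closer to `p2` than the half-chord length the radicand is negative and a
#' geometry error is raised.
#'
#' @param p1,p2,p3 Numeric `(row, col)` points; `p2 != p3`.
#' @param mode `"chord"` (default) returns the apex-to-chord leg above;
#'   `"hypotenuse"` returns the full apex-to-`p2` distance instead.
#' @return List with `C` (chord midpoint) and `d` (depth, pixels).
#' @export
compute_depth <- function(p1, p2, p3, mode = c("chord", "hypotenuse")) {
  mode <- match.arg(mode)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  if (all(abs(p2 - p3) < 1e-12))
    kerato_error("p2 and p3 coincide: degenerate limbus chord", "kerato3d_degenerate_chord")
  C <- (p2 + p3) / 2
  hyp2 <- sum((p1 - p2)^2)
  half2 <- sum((p2 - C)^2)
  if (mode == "hypotenuse") return(list(C = C, d = sqrt(hyp2)))
  rad <- hyp2 - half2
  tol <- 1e-9 * max(hyp2, half2, 1)
  if (rad < -tol)
    kerato_error("apex lies inside the chord circle (negative radicand)",
                 "kerato3d_geometry_error")
  list(C = C, d = sqrt(max(rad, 0)))
}

# Largest closed iso-contour of the lateral profile at the Otsu threshold,
# extracted subpixel by marching squares. Returns an (n x 2) matrix (row, col).
profile_contour <- function(img) {
  img <- as_grey(img)
  rng <- range(img)
  if (diff(rng) < 1e-6)
    kerato_error("no corneal profile found (flat image)", "kerato3d_segmentation_error")
  thr <- EBImage::otsu(EBImage::Image(img), range = rng)
  cl <- grDevices::contourLines(x = seq_len(nrow(img)), y = seq_len(ncol(img)),
                                z = img, levels = thr)
  if (length(cl) == 0)
    kerato_error("no corneal profile found", "kerato3d_segmentation_error")
  # keep the contour with the largest bounding-box area
  areas <- vapply(cl, function(ct) diff(range(ct$x)) * diff(range(ct$y)), 0)
  ct <- cl[[which.max(areas)]]
  cbind(row = ct$x, col = ct$y)
}

#' Locate the depth landmarks on a lateral view
#'
#' The lateral image is segmented at the Otsu threshold and its largest
#' subpixel iso-contour taken as the eye profile (the view must be
#' canonicalised with the cornea protruding to the right). The apex `p1` is
#' the rightmost contour point (ties broken towards the vertical middle of
#' the profile); the chord endpoints `p2`/`p3` are the rightmost contour
#' points on the top and bottom profile rows, cross-checked against the
#' expected limbus chord length `2 * iris$r` from the frontal view. When the
#' check fails (e.g. eyelid or body clutter widens the silhouette) the
#' endpoints are re-anchored at the rows `iris$r` above/below the profile
#' mid-row and the result is flagged.
#'
#' @param lateral Lateral-view image matrix.
#' @param iris An `iris_circle` from the frontal view (supplies the expected
#'   chord length).
#' @param chord_tolerance Allowed relative mismatch between the measured
#'   chord and `2 * iris$r` before re-anchoring.
#' @param mode Passed to [compute_depth()].
#' @return A `depth_landmarks` object: `p1`, `p2`, `p3`, `C` (each
#'   `(row, col)`), depth `d`, the profile `contour`, and `qc_flags`.
#' @export
find_depth_landmarks <- function(lateral, iris, chord_tolerance = 0.25,
                                 mode = "chord") {
  contour <- profile_contour(lateral)
  qc <- character(0)
  rmin <- min(contour[, 1]); rmax <- max(contour[, 1])
  pick_rightmost <- function(sel) {
    cand <- contour[sel, , drop = FALSE]
    cand[which.max(cand[, 2]), ]
  }
  p2 <- pick_rightmost(contour[, 1] <= rmin + 0.75)
  p3 <- pick_rightmost(contour[, 1] >= rmax - 0.75)
  chord <- sqrt(sum((p2 - p3)^2))
  expected <- 2 * iris$r
  if (abs(chord - expected) > chord_tolerance * expected) {
    mid <- (rmin + rmax) / 2
    p2 <- pick_rightmost(abs(contour[, 1] - (mid - iris$r)) <= 1)
    p3 <- pick_rightmost(abs(contour[, 1] - (mid + iris$r)) <= 1)
    qc <- c(qc, "chord_reanchored")
    if (nrow(contour[abs(contour[, 1] - (mid - iris$r)) <= 1, , drop = FALSE]) == 0 ||
        all(abs(p2 - p3) < 1e-9))
      kerato_error("cannot anchor the limbus chord on the contour",
                   "kerato3d_degenerate_chord")
  }
  apex_band <- contour[contour[, 2] >= max(contour[, 2]) - 0.25, , drop = FALSE]
  mid_row <- (p2[1] + p3[1]) / 2
  p1 <- apex_band[which.min(abs(apex_band[, 1] - mid_row)), ]
  cd <- compute_depth(p1, p2, p3, mode = mode)
  structure(list(p1 = unname(p1), p2 = unname(p2), p3 = unname(p3),
                 C = cd$C, d = cd$d, contour = contour, qc_flags = qc),
            class = "depth_landmarks")
}

#' @export
print.depth_landmarks <- function(x, ...) {
  cat(sprintf("depth landmarks: apex p1=(%.1f, %.1f), chord p2=(%.1f, %.1f) p3=(%.1f, %.1f), d=%.2f px\n",
              x$p1[1], x$p1[2], x$p2[1], x$p2[2], x$p3[1], x$p3[2], x$d))
  invisible(x)
}
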