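#' Detect the iris circle with a circular Hough transform
#'
#' Edge pixels are extracted by Sobel gradient-magnitude thresholding with
#' non-maximum suppression along the quantised gradient direction, then each
#' edge pixel votes for every candidate circle `(m, n, r)` it could lie on:
#' the accumulator entry for centre `(n, m)` (row, col) and integer radius
#' `r` counts the edge pixels whose distance to the centre rounds to `r`.
#' Votes are normalised by the number of lattice positions at that radius,
#' so a complete one-pixel circle scores 1. The reported circle is the
#' arg-max of the normalised accumulator over the full 3D parameter grid,
#' with deterministic tie-breaking (smallest radius, then row, then column).
#' Only circles lying fully inside the image are candidates.
#'
#' @param image Numeric matrix in `[0, 1]` (RGB arrays are converted by
#'   luminance).
#' @param radius_range `c(r_min, r_max)` in pixels; `r_min >= 3` and
#'   `r_max < min(dim)/2`.
#' @param edge_threshold Fraction of the maximum gradient magnitude below
#'   which pixels are not edges.
#' @param min_votes Minimum normalised accumulator score; below it the
#'   detection is rejected (condition class `kerato3d_no_circle`).
#' @param return_accumulator Attach the full accumulator array (for
#'   diagnostics and oracle checks).
#' @return An `iris_circle`: list with `m` (centre col), `n` (centre row),
#'   `r` (radius) and `votes` in `[0, 1]`.
#' @export
detect_iris <- function(image, radius_range, edge_threshold = 0.25,
                        min_votes = 0.25, return_accumulator = FALSE) {
  img <- as_grey(image)
  rmin <- as.integer(radius_range[1]); rmax <- as.integer(radius_range[2])
  if (rmin < 3) kerato_error("r_min must be >= 3", "kerato3d_config_error")
  if (rmax >= min(dim(img)) / 2)
    kerato_error("r_max must be < min(image dims)/2", "kerato3d_config_error")
  if (rmax < rmin) kerato_error("empty radius range", "kerato3d_config_error")
  edges <- sobel_edges(img, edge_threshold)
  if (nrow(edges) == 0)
    kerato_error("no edges found (flat or empty image)", "kerato3d_no_circle")
  acc <- hough_accumulate_cpp(edges[, 1], edges[, 2], nrow(img), ncol(img), rmin, rmax)
  support <- circle_support_counts(rmin, rmax)
  best <- hough_best_cpp(acc, support, nrow(img), ncol(img), rmin, rmax)
  if (best[["r"]] < 0 || best[["votes"]] < min_votes)
    kerato_error(sprintf("no circle with sufficient support (best votes %.3f < %.3f)",
                         max(best[["votes"]], 0), min_votes), "kerato3d_no_circle")
  circ <- structure(list(m = unname(best[["m"]]), n = unname(best[["n"]]),
                         r = unname(best[["r"]]), votes = unname(best[["votes"]])),
                    class = "iris_circle")
  if (return_accumulator) attr(circ, "accumulator") <- acc
  circ
}

#' @export
print.iris_circle <- function(x, ...) {
  cat(sprintf("iris circle: centre (row n=%d, col m=%d), r=%d px, votes=%.3f\n",
              x$n, x$m, x$r, x$votes))
  invisible(x)
}

# Sobel edge map with gradient-direction non-maximum suppression.
# Returns a two-column matrix (row, col) of edge pixel coordinates.
sobel_edges <- function(img, edge_threshold) {
  n <- nrow(img); m <- ncol(img)
  shift <- function(dr, dc) {
    out <- img
    rs <- pmin(pmax(seq_len(n) + dr, 1L), n)
    cs <- pmin(pmax(seq_len(m) + dc, 1L), m)
    out[] <- img[rs, cs]
    out
  }
  gr <- (shift(1, -1) + 2 * shift(1, 0) + shift(1, 1)) -
        (shift(-1, -1) + 2 * shift(-1, 0) + shift(-1, 1))
  gc <- (shift(-1, 1) + 2 * shift(0, 1) + shift(1, 1)) -
        (shift(-1, -1) + 2 * shift(0, -1) + shift(1, -1))
  mag <- sqrt(gr^2 + gc^2)
  mx <- max(mag)
  if (mx <= 1e-9) return(matrix(integer(0), 0, 2))
  thr <- edge_threshold * mx
  # non-maximum suppression along the quantised gradient direction
  ang <- atan2(gr, gc)  # direction of the gradient
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- mag >= thr
  for (s in 0:3) {
    d <- offs[[s + 1]]
    nb1 <- shift_mat(mag, d[1], d[2])
    nb2 <- shift_mat(mag, -d[1], -d[2])
    sel <- sector == s
    keep[sel] <- keep[sel] & mag[sel] >= nb1[sel] & mag[sel] >= nb2[sel]
  }
  keep[c(1, n), ] <- FALSE
  keep[, c(1, m)] <- FALSE
  which(keep, arr.ind = TRUE)
}

shift_mat <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(-Inf, n, m)
  rs <- seq_len(n) + dr; cs <- seq_len(m) + dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= m
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

#' Landmarks derived from a detected iris circle
#'
#' Returns the circle centre, its radius and the two limbus landmarks -- the
#' topmost and bottommost points of the circumference, i.e. the standard
#' circle parametrisation `x = m + r cos(a)`, `y = n + r sin(a)` evaluated at
#' `a = -90` and `a = +90` degrees. These anchor the limbus chord expected in
#' the lateral view.
#'
#' @param circle An `iris_circle`.
#' @return List with `center` (row, col), `radius`, and `limbus_points`, a
#'   2 x 2 matrix with rows `top` and `bottom` in (row, col).
#' @export
iris_landmarks <- function(circle) {
  stopifnot(inherits(circle, "iris_circle"))
  top <- c(circle$n - circle$r, circle$m)
  bottom <- c(circle$n + circle$r, circle$m)
  list(center = c(circle$n, circle$m),
       radius = circle$r,
       limbus_points = rbind(top = top, bottom = bottom))
}
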