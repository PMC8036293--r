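#' Estimate the translational transform aligning the two orthogonal views
#'
#' The frontal and lateral views are orthogonal projections of the same eye
#' sharing one axis (the vertical image row). Each correspondence is lifted
#' into the 3D frame -- the frontal point `(x1, y1)` to `(x1, y1, 0)`, the
#' lateral point `(x2, y2)` to `(0, y2, x2)` (the lateral abscissa carries
#' depth) -- and the transform is the pure translation `T = (tx, ty, tz)`
#' minimising the summed squared 3D distance between the lifted sets, whose
#' closed form is the component-wise mean of the residuals:
#' `tx = mean(x1)` (the x position of the sagittal plane the lateral
#' silhouette lives on), `ty = mean(y1 - y2)` (vertical offset between
#' views), `tz = -mean(x2)` (depth origin). With exactly consistent
#' correspondences the residual after alignment of the shared axis is zero.
#'
#' Points are given as two-column matrices `(x, y)` where `x` is the image
#' column and `y` the image row.
#'
#' @param matches A `match_set` (or `NULL` when `frontal_pts` and
#'   `lateral_pts` are already paired row for row).
#' @param frontal_pts,lateral_pts Two-column `(x, y)` coordinate matrices.
#' @return An `ortho_transform`: list with `tx`, `ty`, `tz` and `n`.
#' @export
estimate_transform <- function(matches, frontal_pts, lateral_pts) {
  frontal_pts <- as.matrix(frontal_pts); lateral_pts <- as.matrix(lateral_pts)
  if (!is.null(matches)) {
    if (nrow(matches) == 0)
      kerato_error("no correspondences to estimate the transform from",
                   "kerato3d_insufficient_matches")
    frontal_pts <- frontal_pts[matches$a_idx, , drop = FALSE]
    lateral_pts <- lateral_pts[matches$b_idx, , drop = FALSE]
  }
  if (nrow(frontal_pts) == 0 || nrow(frontal_pts) != nrow(lateral_pts))
    kerato_error("need >= 1 paired correspondence", "kerato3d_insufficient_matches")
  structure(list(
    tx = mean(frontal_pts[, 1]),
    ty = mean(frontal_pts[, 2] - lateral_pts[, 2]),
    tz = -mean(lateral_pts[, 1]),
    n = nrow(frontal_pts)
  ), class = "ortho_transform")
}

#' @export
print.ortho_transform <- function(x, ...) {
  cat(sprintf("orthogonal-view transform: tx=%.2f ty=%.2f tz=%.2f (from %d correspondences)\n",
              x$tx, x$ty, x$tz, x$n))
  invisible(x)
}

#' Identity transform helper
#' @return An `ortho_transform` with zero offsets.
#' @export
identity_transform <- function() {
  structure(list(tx = 0, ty = 0, tz = 0, n = 0L), class = "ortho_transform")
}

#' Fuse corresponding frontal/lateral 2D points into 3D
#'
#' The frontal view supplies `x` and `y`, the lateral abscissa supplies
#' depth: `x3 = x1`, `y3 = y1`, `z3 = x2 + tz`. The mapping is invertible
#' per point given `T` (see [project_fused()]), and exact for consistent
#' inputs.
#'
#' @param frontal_pts,lateral_pts Equal-length two-column `(x, y)` matrices,
#'   paired row for row.
#' @param transform An `ortho_transform`.
#' @return Data frame of fused points: `x3`, `y3`, `z3` plus the source
#'   coordinates `x1`, `y1`, `x2`, `y2`.
#' @export
fuse_points <- function(frontal_pts, lateral_pts, transform = identity_transform()) {
  frontal_pts <- as.matrix(frontal_pts); lateral_pts <- as.matrix(lateral_pts)
  if (nrow(frontal_pts) != nrow(lateral_pts))
    kerato_error("frontal and lateral point lists differ in length", "kerato3d_config_error")
  data.frame(
    x3 = frontal_pts[, 1],
    y3 = frontal_pts[, 2],
    z3 = lateral_pts[, 1] + transform$tz,
    x1 = frontal_pts[, 1], y1 = frontal_pts[, 2],
    x2 = lateral_pts[, 1], y2 = lateral_pts[, 2]
  )
}

#' Project fused 3D points back onto each view
#'
#' @param fused A [fuse_points()] data frame (only `x3`, `y3`, `z3` used).
#' @param transform The `ortho_transform` used during fusion.
#' @return List with `frontal` and `lateral` two-column `(x, y)` matrices.
#' @export
project_fused <- function(fused, transform = identity_transform()) {
  list(frontal = cbind(x = fused$x3, y = fused$y3),
       lateral = cbind(x = fused$z3 - transform$tz, y = fused$y3 - transform$ty))
}

# Thin-plate spline fit z = f(x, y): classic radial basis r^2 log r with an
# affine part and a small ridge for numerical stability.
tps_fit <- function(x, y, z, lambda = 1e-6) {
  n <- length(x)
  dx <- outer(x, x, `-`); dy <- outer(y, y, `-`)
  r2 <- dx^2 + dy^2
  K <- ifelse(r2 > 0, 0.5 * r2 * log(pmax(r2, 1e-300)), 0)
  P <- cbind(1, x, y)
  A <- rbind(cbind(K + lambda * diag(n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(z, 0, 0, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e)
    kerato_error("thin-plate system is singular (degenerate point layout)",
                 "kerato3d_degenerate_surface"))
  list(w = sol[1:n], a = sol[n + 1:3], x = x, y = y)
}

tps_eval <- function(fit, xq, yq) {
  dx <- outer(xq, fit$x, `-`); dy <- outer(yq, fit$y, `-`)
  r2 <- dx^2 + dy^2
  K <- ifelse(r2 > 0, 0.5 * r2 * log(pmax(r2, 1e-300)), 0)
  as.vector(K %*% fit$w) + fit$a[1] + fit$a[2] * xq + fit$a[3] * yq
}

#' Rasterise fused surface points into a corneal volume
#'
#' Fused points are interpreted as samples of a corneal elevation surface
#' `z(x, y)`. A thin-plate spline interpolates the surface over the convex
#' hull of the `(x, y)` samples, unit intensity is deposited along the
#' interpolated sheet (linearly split between the two nearest voxel layers),
#' and the volume is smoothed with an isotropic 3D Gaussian. The `(x, y)`
#' extent is mapped to the grid with a 10% margin; depth is offset so the
#' minimum interpolated elevation sits near the low-z face.
#'
#' @param points A [fuse_points()] data frame (needs >= 4 non-coplanar
#'   points).
#' @param shape Output dims `c(nx, ny, nz)`.
#' @param smoothing_sigma Gaussian sigma in voxels.
#' @return 3D array with attribute `mapping` (the affine grid mapping).
#' @export
rasterize_volume <- function(points, shape = c(64L, 64L, 64L), smoothing_sigma = 1) {
  if (nrow(points) < 4)
    kerato_error("need at least 4 points", "kerato3d_degenerate_surface")
  P <- cbind(points$x3, points$y3, points$z3)
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (length(sv) < 3 || sv[3] < 1e-8 * max(sv[1], 1))
    kerato_error("all points are coplanar: no surface to rasterise",
                 "kerato3d_degenerate_surface")
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xr <- range(points$x3); yr <- range(points$y3)
  pad_x <- 0.1 * max(diff(xr), 1); pad_y <- 0.1 * max(diff(yr), 1)
  x_lo <- xr[1] - pad_x; x_hi <- xr[2] + pad_x
  y_lo <- yr[1] - pad_y; y_hi <- yr[2] + pad_y
  sx <- (nx - 1) / (x_hi - x_lo); sy <- (ny - 1) / (y_hi - y_lo)
  s <- min(sx, sy)  # isotropic in-plane scale
  fit <- tps_fit(points$x3, points$y3, points$z3)
  gx <- seq_len(nx); gy <- seq_len(ny)
  qx <- x_lo + (rep(gx, times = ny) - 1) / s
  qy <- y_lo + (rep(gy, each = nx) - 1) / s
  hull <- grDevices::chull(points$x3, points$y3)
  inside <- pracma::inpolygon(qx, qy, points$x3[hull], points$y3[hull],
                              boundary = TRUE)
  vol <- array(0, c(nx, ny, nz))
  if (any(inside)) {
    zq <- tps_eval(fit, qx[inside], qy[inside])
    z_lo <- min(points$z3)
    gz <- (zq - z_lo) * s + max(2, round(0.1 * nz))
    keep <- gz >= 1 & gz <= nz
    ii <- rep(gx, times = ny)[inside][keep]
    jj <- rep(gy, each = nx)[inside][keep]
    gz <- gz[keep]
    lo <- floor(gz); frac <- gz - lo
    vol[cbind(ii, jj, lo)] <- pmax(vol[cbind(ii, jj, lo)], 1 - frac)
    up <- lo + 1; okup <- up <= nz
    vol[cbind(ii[okup], jj[okup], up[okup])] <-
      pmax(vol[cbind(ii[okup], jj[okup], up[okup])], frac[okup])
  }
  vol <- gaussian_blur3d(vol, smoothing_sigma)
  if (max(vol) > 0) vol <- vol / max(vol)
  attr(vol, "mapping") <- list(x_lo = x_lo, y_lo = y_lo, scale = s,
                               z_lo = min(points$z3),
                               z_offset = max(2, round(0.1 * nz)))
  vol
}

#' Sum-of-squared-differences score between two volumes
#'
#' The matching score used to compare a constructed corneal volume with a
#' stored reference: `E = sum((I_construct - I_stored)^2)` over all voxels.
#' References on a different grid are first resampled trilinearly onto the
#' constructed volume's grid. Choosing the stored reference with minimal
#' `E` implements the volume-matching test.
#'
#' @param constructed,reference 3D numeric arrays.
#' @return Scalar SSD score.
#' @export
ssd_match <- function(constructed, reference) {
  if (length(dim(constructed)) != 3 || length(dim(reference)) != 3)
    kerato_error("ssd_match expects two 3D arrays", "kerato3d_config_error")
  if (!identical(dim(constructed), dim(reference)))
    reference <- resample_volume(reference, dim(constructed))
  sum((constructed - reference)^2)
}
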