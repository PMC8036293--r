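#' Parametric eye-phantom specification
#'
#' Describes a synthetic eye with analytically known geometry: an iris circle
#' for the frontal view, a corneal profile (spherical cap for normal eyes,
#' cone flank for keratoconic eyes) for the lateral view, and a matching 3D
#' corneal surface. The phantom exists so that every downstream stage --
#' iris detection, depth recovery, fusion, curvature staging, volumetric
#' classification -- can be verified against known ground truth without any
#' external imaging data.
#'
#' The single severity parameter is `steepness_angle_deg`: the maximum angle
#' between the corneal surface tangent and the limbus plane. The corneal apex
#' height `h` (protrusion beyond the limbus chord, in pixels) is derived from
#' it unless supplied explicitly:
#' \itemize{
#'   \item normal (spherical cap): the steepest tangent occurs at the rim,
#'     giving `h = r * tan(S/2)`;
#'   \item keratoconus (cone flank): the flank has constant slope, giving
#'     `h = r * tan(S)`.
#' }
#'
#' @param stage One of `"normal"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param steepness_angle_deg Ground-truth steepest corneal slope, degrees in
#'   (0, 90). Must be consistent with `stage` under the 45/52 degree staging
#'   thresholds (normal phantoms use a spherical cap below 45 degrees).
#' @param image_size Side of the square canvas, pixels (>= 32).
#' @param iris_center `(row, col)` of the iris centre in the frontal view.
#' @param iris_radius Iris radius, pixels (> 0).
#' @param cornea_apex_height Optional explicit apex height, pixels (>= 0);
#'   derived from `steepness_angle_deg` when `NULL`.
#' @param noise_sigma Additive Gaussian intensity noise, in 8-bit counts
#'   (i.e. on the 0--255 scale; images are stored in `[0, 1]`).
#' @param seed Integer seed controlling the noise realisation.
#' @return An object of class `eye_phantom_spec`.
#' @export
eye_phantom_spec <- function(stage = "normal",
                             steepness_angle_deg = 35,
                             image_size = 256L,
                             iris_center = NULL,
                             iris_radius = 34,
                             cornea_apex_height = NULL,
                             noise_sigma = 0,
                             seed = 1L) {
  stage <- match.arg(stage, stage_levels())
  if (image_size < 32) kerato_error("image_size must be >= 32", "kerato3d_config_error")
  if (iris_radius <= 0) kerato_error("iris_radius must be positive", "kerato3d_config_error")
  if (steepness_angle_deg <= 0 || steepness_angle_deg >= 90)
    kerato_error("steepness_angle_deg must lie in (0, 90)", "kerato3d_config_error")
  consistent <- switch(stage,
    normal   = steepness_angle_deg < 45,
    mild     = steepness_angle_deg < 45,
    moderate = steepness_angle_deg >= 45 && steepness_angle_deg <= 52,
    severe   = steepness_angle_deg > 52)
  if (!consistent)
    kerato_error(sprintf("stage '%s' inconsistent with steepness %.1f deg under the 45/52 thresholds",
                         stage, steepness_angle_deg), "kerato3d_config_error")
  if (is.null(iris_center)) iris_center <- c(round(image_size / 2), round(image_size / 2))
  s_rad <- steepness_angle_deg * pi / 180
  if (is.null(cornea_apex_height)) {
    cornea_apex_height <- if (stage == "normal") iris_radius * tan(s_rad / 2)
                          else iris_radius * tan(s_rad)
  }
  if (cornea_apex_height < 0)
    kerato_error("cornea_apex_height must be >= 0", "kerato3d_config_error")
  structure(list(
    stage = stage,
    steepness_angle_deg = steepness_angle_deg,
    image_size = as.integer(image_size),
    iris_center = iris_center,
    iris_radius = iris_radius,
    cornea_apex_height = cornea_apex_height,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "eye_phantom_spec")
}

#' @export
print.eye_phantom_spec <- function(x, ...) {
  cat(sprintf("eye phantom: %s, steepness %.1f deg, iris r=%.1f px at (%d, %d), apex h=%.1f px, noise sd=%.1f/255\n",
              x$stage, x$steepness_angle_deg, x$iris_radius,
              x$iris_center[1], x$iris_center[2], x$cornea_apex_height, x$noise_sigma))
  invisible(x)
}

add_phantom_noise <- function(img, spec, stream = 0L) {
  if (spec$noise_sigma <= 0) return(img)
  noise <- with_seed(spec$seed + stream, rnorm(length(img), sd = spec$noise_sigma / 255))
  pmin(pmax(img + noise, 0), 1)
}

#' Render the frontal view of an eye phantom
#'
#' Draws a dark annular iris (with a darker pupil) on a lighter sclera
#' background, with one-pixel anti-aliased edges so the strongest circular
#' gradient sits exactly at `iris_radius`. Additive Gaussian noise of
#' `noise_sigma` (8-bit counts) is applied when requested; the render is
#' deterministic given the spec's seed, and noise-free renders do not touch
#' the random number generator.
#'
#' @param spec An [eye_phantom_spec()].
#' @return Numeric matrix in `[0, 1]` with the spec attached as attribute
#'   `"spec"`.
#' @export
render_frontal <- function(spec) {
  n <- spec$image_size
  r <- spec$iris_radius
  ctr <- spec$iris_center
  margin <- 3
  if (ctr[1] - r < 1 + margin || ctr[1] + r > n - margin ||
      ctr[2] - r < 1 + margin || ctr[2] + r > n - margin)
    kerato_error("iris circle not fully inside the frame", "kerato3d_geometry_error")
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dist <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  disc_cov <- function(radius) pmin(pmax(radius + 0.5 - dist, 0), 1)
  sclera <- 0.85; iris_int <- 0.30; pupil_int <- 0.22
  img <- sclera +
    (iris_int - sclera) * disc_cov(r) +
    (pupil_int - iris_int) * disc_cov(0.5 * r)
  img <- add_phantom_noise(img, spec, stream = 0L)
  attr(img, "spec") <- spec
  img
}

# Corneal profile height z(y) above the limbus chord, y in [-r, r].
cornea_profile <- function(y, r, h, stage) {
  if (h <= 0) return(rep(0, length(y)))
  z <- if (stage == "normal") {
    Rc <- (r^2 + h^2) / (2 * h)
    h - Rc + sqrt(pmax(Rc^2 - y^2, 0))
  } else {
    h * (1 - abs(y) / r)
  }
  z[abs(y) > r] <- 0
  pmax(z, 0)
}

#' Render the lateral (profile) view of an eye phantom
#'
#' The eye body is a bright rectangle whose right edge is the limbus chord (a
#' vertical segment of length `2 * iris_radius` centred on the iris-centre
#' row, so the vertical axis is shared with the frontal view). The corneal
#' profile protrudes rightwards from the chord: a circular arc for normal
#' phantoms, a straight cone flank for keratoconic ones, with the apex
#' `cornea_apex_height` pixels beyond the chord. Boundaries are anti-aliased
#' per row so subpixel contour extraction recovers the profile accurately.
#'
#' Ground truth is attached as attributes: `apex`, `p2`, `p3` (chord
#' endpoints) as `(row, col)`, `chord_col`, `apex_height`, and
#' `contour_truth`, a finely sampled analytic profile.
#'
#' @inheritParams render_frontal
#' @return Numeric matrix in `[0, 1]` with ground-truth attributes.
#' @export
render_lateral <- function(spec) {
  n <- spec$image_size
  r <- spec$iris_radius
  h <- spec$cornea_apex_height
  c_row <- spec$iris_center[1]
  x0 <- round(0.42 * n)
  body_depth <- round(0.9 * r)
  if (c_row - r < 3 || c_row + r > n - 2 || x0 - body_depth < 3 || x0 + h > n - 2)
    kerato_error("lateral profile does not fit inside the frame", "kerato3d_geometry_error")
  bg <- 0.10; fg <- 0.80
  img <- matrix(bg, n, n)
  rows_in <- (c_row - r):(c_row + r)
  cols <- seq_len(n)
  for (row in rows_in) {
    y <- row - c_row
    edge <- x0 + cornea_profile(y, r, h, spec$stage)
    cov <- pmin(pmax(edge + 0.5 - cols, 0), 1)
    cov[cols < x0 - body_depth] <- 0
    img[row, ] <- bg + (fg - bg) * cov
  }
  img <- add_phantom_noise(img, spec, stream = 1L)
  yy <- seq(-r, r, by = 0.25)
  attr(img, "spec") <- spec
  attr(img, "apex") <- c(c_row, x0 + h)
  attr(img, "p2") <- c(c_row - r, x0)
  attr(img, "p3") <- c(c_row + r, x0)
  attr(img, "chord_col") <- x0
  attr(img, "apex_height") <- h
  attr(img, "contour_truth") <- cbind(row = c_row + yy,
                                      col = x0 + cornea_profile(yy, r, h, spec$stage))
  img
}

#' Render the 3D corneal volume of an eye phantom
#'
#' The cornea is a surface of revolution of the lateral profile about the
#' protrusion axis, deposited as a thin voxel shell over a base disc of
#' radius `0.35 * edge`. Voxel intensity encodes elevation inversely (dark
#' grey = high elevation, light grey = flat), using a fixed elevation scale
#' so that intensities are comparable across cases.
#'
#' @inheritParams render_frontal
#' @param edge Cubic volume edge length, voxels.
#' @return 3D numeric array `edge^3` in `[0, 1]` with attributes `spec`,
#'   `apex_voxel` and `base_z`.
#' @export
render_volume <- function(spec, edge = 64L) {
  r_v <- 0.35 * edge
  scale <- r_v / spec$iris_radius
  h_v <- spec$cornea_apex_height * scale
  z0 <- max(3, round(0.10 * edge))
  if (z0 + h_v > edge - 2)
    kerato_error("corneal apex exceeds the volume extent", "kerato3d_geometry_error")
  ctr <- (edge + 1) / 2
  vol <- array(0, c(edge, edge, edge))
  xs <- matrix(seq_len(edge), edge, edge)
  ys <- matrix(seq_len(edge), edge, edge, byrow = TRUE)
  rho <- sqrt((xs - ctr)^2 + (ys - ctr)^2)
  zeta <- matrix(cornea_profile(as.vector(rho) / scale, spec$iris_radius,
                                spec$cornea_apex_height, spec$stage) * scale,
                 edge, edge)
  on_cornea <- rho <= r_v
  on_ring <- rho > r_v & rho <= min(1.15 * r_v, ctr - 1)
  inten <- 0.9 - 0.75 * zeta / (2.2 * r_v)
  zc <- z0 + zeta
  lo <- floor(zc); frac <- zc - lo
  idx <- which(on_cornea | on_ring)
  for (i in idx) {
    v <- if (on_cornea[i]) inten[i] else 0.9
    x <- ((i - 1) %% edge) + 1
    y <- ((i - 1) %/% edge) + 1
    vol[x, y, lo[i]] <- max(vol[x, y, lo[i]], v * (1 - frac[i]))
    if (lo[i] + 1 <= edge) vol[x, y, lo[i] + 1] <- max(vol[x, y, lo[i] + 1], v * frac[i])
  }
  vol <- if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed + 2L, rnorm(length(vol), sd = spec$noise_sigma / 255))
    pmin(pmax(vol + noise, 0), 1)
  } else vol
  attr(vol, "spec") <- spec
  attr(vol, "apex_voxel") <- c(ctr, ctr, z0 + h_v)
  attr(vol, "base_z") <- z0
  attr(vol, "spacing") <- 1
  vol
}

default_stage_params <- function() {
  list(normal = c(30, 40), mild = c(41, 44), moderate = c(46, 51), severe = c(53, 65))
}

validate_stage_params <- function(stage_params) {
  need <- stage_levels()
  if (!all(need %in% names(stage_params)))
    kerato_error("stage_params must name all four stages", "kerato3d_config_error")
  band <- list(normal = c(0, 45), mild = c(0, 45), moderate = c(45, 52), severe = c(52, 90))
  for (s in need) {
    rg <- stage_params[[s]]
    if (length(rg) != 2 || rg[1] > rg[2])
      kerato_error(sprintf("invalid steepness range for stage '%s'", s), "kerato3d_config_error")
    if (rg[1] < band[[s]][1] || rg[2] > band[[s]][2])
      kerato_error(sprintf("steepness range for stage '%s' straddles a 45/52 staging boundary", s),
                   "kerato3d_config_error")
  }
  ks <- setdiff(need, "normal")
  for (i in seq_along(ks)) for (j in seq_along(ks)) if (i < j) {
    a <- stage_params[[ks[i]]]; b <- stage_params[[ks[j]]]
    if (max(a[1], b[1]) <= min(a[2], b[2]))
      kerato_error("keratoconus stage steepness ranges overlap", "kerato3d_config_error")
  }
  invisible(TRUE)
}

#' Generate a labelled phantom cohort
#'
#' Produces `n_per_stage` cases for each of the four stages with steepness
#' angles drawn uniformly from per-stage ranges. The default ranges (normal
#' 30--40, mild 41--44, moderate 46--51, severe 53--65 degrees) leave 1--2
#' degree guard bands around the 45/52 degree staging boundaries so that no
#' generated label is ambiguous. The cohort is fully determined by `seed`.
#'
#' @param n_per_stage Cases per stage (>= 1).
#' @param seed Integer seed.
#' @param stage_params Named list of `c(lo, hi)` steepness ranges in degrees,
#'   one per stage; validated against the staging thresholds.
#' @param image_size,volume_edge,noise_sigma Passed to the renderers.
#' @param iris_radius_range Range the per-case iris radius is drawn from.
#' @param render_images,render_volumes Toggle the expensive renders when only
#'   part of the phantom is needed.
#' @return A `kerato_cohort`: list with `cases` (each holding `spec`,
#'   `frontal`, `lateral`, `volume`, `stage`) and a `manifest` data frame.
#' @export
generate_cohort <- function(n_per_stage, seed = 1L,
                            stage_params = default_stage_params(),
                            image_size = 256L,
                            iris_radius_range = c(30, 38),
                            volume_edge = 64L,
                            noise_sigma = 0,
                            render_images = TRUE,
                            render_volumes = TRUE) {
  if (n_per_stage < 1) kerato_error("n_per_stage must be >= 1", "kerato3d_config_error")
  validate_stage_params(stage_params)
  stages <- rep(stage_levels(), each = n_per_stage)
  n_total <- length(stages)
  draws <- with_seed(seed, list(
    steep = runif(n_total),
    radius = runif(n_total, iris_radius_range[1], iris_radius_range[2]),
    jit_r = round(runif(n_total, -4, 4)),
    jit_c = round(runif(n_total, -4, 4)),
    case_seed = sample.int(2^30, n_total)
  ))
  cases <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    rg <- stage_params[[stages[i]]]
    steep <- rg[1] + draws$steep[i] * (rg[2] - rg[1])
    ctr <- c(round(image_size / 2) + draws$jit_r[i], round(image_size / 2) + draws$jit_c[i])
    spec <- eye_phantom_spec(stage = stages[i], steepness_angle_deg = steep,
                             image_size = image_size, iris_center = ctr,
                             iris_radius = draws$radius[i],
                             noise_sigma = noise_sigma, seed = draws$case_seed[i])
    cases[[i]] <- list(
      case_id = sprintf("case_%03d_%s", i, stages[i]),
      spec = spec,
      frontal = if (render_images) render_frontal(spec) else NULL,
      lateral = if (render_images) render_lateral(spec) else NULL,
      volume = if (render_volumes) render_volume(spec, edge = volume_edge) else NULL,
      stage = stages[i]
    )
  }
  manifest <- data.frame(
    case_id = vapply(cases, `[[`, "", "case_id"),
    stage = stages,
    steepness_deg = vapply(cases, function(cs) cs$spec$steepness_angle_deg, 0),
    iris_row = vapply(cases, function(cs) cs$spec$iris_center[1], 0),
    iris_col = vapply(cases, function(cs) cs$spec$iris_center[2], 0),
    iris_radius = vapply(cases, function(cs) cs$spec$iris_radius, 0),
    apex_height = vapply(cases, function(cs) cs$spec$cornea_apex_height, 0),
    stringsAsFactors = FALSE
  )
  structure(list(cases = cases, manifest = manifest, seed = seed), class = "kerato_cohort")
}

#' @export
print.kerato_cohort <- function(x, ...) {
  cat(sprintf("kerato_cohort: %d cases (%s)\n", nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$stage)),
                            as.integer(table(x$manifest$stage))), collapse = ", ")))
  invisible(x)
}

#' Write a phantom cohort to disk
#'
#' Frontal/lateral views go out as 8-bit grayscale PNG, volumes as
#' compressed NIfTI, and the ground truth as a CSV manifest.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest with file columns added.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$frontal_file <- file.path(dir, paste0(man$case_id, "_frontal.png"))
  man$lateral_file <- file.path(dir, paste0(man$case_id, "_lateral.png"))
  man$volume_file <- file.path(dir, paste0(man$case_id, ".nii.gz"))
  for (i in seq_along(cohort$cases)) {
    cs <- cohort$cases[[i]]
    if (!is.null(cs$frontal)) write_eye_image(cs$frontal, man$frontal_file[i])
    if (!is.null(cs$lateral)) write_eye_image(cs$lateral, man$lateral_file[i])
    if (!is.null(cs$volume)) RNifti::writeNifti(cs$volume, man$volume_file[i])
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read / write 2D eye images
#'
#' Thin wrappers over EBImage that keep the package's `img[row, col]`
#' matrix convention (EBImage stores images x-major). PNG and TIFF are
#' supported through the file extension.
#'
#' @param path Image file path.
#' @return `read_eye_image()`: numeric matrix (grey) or 3-channel array.
#' @export
read_eye_image <- function(path) {
  if (!file.exists(path)) kerato_error(paste("cannot read image:", path), "kerato3d_io_error")
  im <- EBImage::readImage(path)
  dat <- EBImage::imageData(im)
  if (length(dim(dat)) == 2L) return(t(dat))
  aperm(dat[, , seq_len(min(3, dim(dat)[3])), drop = FALSE], c(2, 1, 3))
}

#' @rdname read_eye_image
#' @param img Numeric matrix in `[0, 1]`.
#' @export
write_eye_image <- function(img, path) {
  EBImage::writeImage(EBImage::Image(t(as.matrix(img))), path, bits.per.sample = 8L)
  invisible(path)
}
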