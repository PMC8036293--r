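#' Extract scale-invariant keypoints (difference-of-Gaussian detector)
#'
#' A staged scale-space filtering detector in the SIFT family, written for
#' this package: a Gaussian pyramid is built over `n_octaves` octaves with
#' `n_scales` sampled scales per octave (base blur `sigma0`, canonical 1.6);
#' keypoints are local extrema of the difference-of-Gaussian stack over
#' space and scale, refined to subpixel position by a 3D quadratic fit,
#' filtered by contrast and by the edge-response (principal-curvature ratio)
#' test; each keypoint receives one or two dominant gradient orientations
#' and a 4 x 4 x 8 = 128-dimensional gradient-histogram descriptor,
#' L2-normalised with the usual 0.2 clamping. The result is deterministic
#' for fixed input.
#'
#' @param image Numeric matrix in `[0, 1]` (RGB arrays converted by
#'   luminance); at least 64 x 64.
#' @param n_octaves Pyramid octaves; the image must remain at least 16
#'   pixels wide at the coarsest octave.
#' @param contrast_threshold Minimum refined |DoG| response.
#' @param n_scales Scales sampled per octave.
#' @param sigma0 Base blur of each octave, pixels.
#' @param edge_ratio Maximum principal-curvature ratio (Lowe's r).
#' @return A `keypoint_set`: list with `points` (data frame: `row`, `col`
#'   subpixel, `scale` in input pixels, `orientation` degrees in [0, 360),
#'   `octave`, `response`) and `descriptors` (n x 128 matrix, unit rows).
#' @export
extract_keypoints <- function(image, n_octaves = 4L, contrast_threshold = 0.03,
                              n_scales = 3L, sigma0 = 1.6, edge_ratio = 10) {
  img <- as_grey(image)
  if (min(dim(img)) < 64)
    kerato_error("image must be at least 64 x 64", "kerato3d_config_error")
  if (min(dim(img)) / 2^(n_octaves - 1) < 8)
    kerato_error("image too small for the requested number of octaves",
                 "kerato3d_config_error")
  k <- 2^(1 / n_scales)
  n_lev <- n_scales + 3L
  pts <- list(); descs <- list()
  base <- gaussian_blur(img, sqrt(max(sigma0^2 - 0.25, 0.01)))
  for (oct in seq_len(n_octaves)) {
    G <- vector("list", n_lev)
    G[[1]] <- base
    for (i in 2:n_lev) {
      sig_inc <- sigma0 * k^(i - 2) * sqrt(k^2 - 1)
      G[[i]] <- gaussian_blur(G[[i - 1]], sig_inc)
    }
    D <- lapply(seq_len(n_lev - 1), function(i) G[[i + 1]] - G[[i]])
    found <- dog_extrema(D, contrast_threshold, edge_ratio, n_scales)
    if (nrow(found) > 0) {
      step <- 2^(oct - 1)
      for (j in seq_len(nrow(found))) {
        f <- found[j, ]
        lev <- as.integer(f[["level"]])
        sig_rel <- sigma0 * k^(lev - 1 + f[["ds"]])
        oris <- keypoint_orientations(G[[lev]], f[["row"]], f[["col"]], sig_rel)
        for (ori in oris) {
          desc <- keypoint_descriptor(G[[lev]], f[["row"]], f[["col"]], sig_rel, ori)
          if (is.null(desc)) next
          pts[[length(pts) + 1L]] <- c(
            row = (f[["row"]] - 1) * step + 1,
            col = (f[["col"]] - 1) * step + 1,
            scale = sig_rel * step,
            orientation = ori,
            octave = oct,
            response = f[["response"]])
          descs[[length(descs) + 1L]] <- desc
        }
      }
    }
    if (oct < n_octaves) {
      nxt <- G[[n_scales + 1L]]  # blur 2*sigma0 relative to octave base
      base <- nxt[seq(1, nrow(nxt), by = 2), seq(1, ncol(nxt), by = 2), drop = FALSE]
    }
  }
  if (length(pts) == 0) {
    points <- data.frame(row = numeric(0), col = numeric(0), scale = numeric(0),
                         orientation = numeric(0), octave = integer(0),
                         response = numeric(0))
    descriptors <- matrix(numeric(0), 0, 128)
  } else {
    points <- as.data.frame(do.call(rbind, pts))
    points$octave <- as.integer(points$octave)
    descriptors <- do.call(rbind, descs)
  }
  structure(list(points = points, descriptors = descriptors), class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("keypoint_set: %d keypoints\n", nrow(x$points)))
  invisible(x)
}

# Local space-and-scale extrema of a DoG stack with quadratic refinement.
# Returns data frame (row, col subpixel in octave coords, level, ds, response).
dog_extrema <- function(D, contrast_threshold, edge_ratio, n_scales) {
  nlev <- length(D)
  n <- nrow(D[[1]]); m <- ncol(D[[1]])
  out <- list()
  nb_extreme <- function(center, lower, same, upper, cmp) {
    ok <- matrix(TRUE, n, m)
    for (dr in -1:1) for (dc in -1:1) {
      s1 <- shift_mat2(same, dr, dc, if (identical(cmp, `>`)) -Inf else Inf)
      if (dr == 0 && dc == 0) {
        ok <- ok & cmp(center, shift_mat2(lower, dr, dc, if (identical(cmp, `>`)) -Inf else Inf)) &
                   cmp(center, shift_mat2(upper, dr, dc, if (identical(cmp, `>`)) -Inf else Inf))
      } else {
        ok <- ok & cmp(center, s1) &
                   cmp(center, shift_mat2(lower, dr, dc, if (identical(cmp, `>`)) -Inf else Inf)) &
                   cmp(center, shift_mat2(upper, dr, dc, if (identical(cmp, `>`)) -Inf else Inf))
      }
    }
    ok
  }
  for (lev in 2:(nlev - 1)) {
    ctr <- D[[lev]]
    strong <- abs(ctr) > 0.5 * contrast_threshold
    strong[c(1:4, (n - 3):n), ] <- FALSE
    strong[, c(1:4, (m - 3):m)] <- FALSE
    if (!any(strong)) next
    is_max <- strong & ctr > 0 & nb_extreme(ctr, D[[lev - 1]], ctr, D[[lev + 1]], `>`)
    is_min <- strong & ctr < 0 & nb_extreme(ctr, D[[lev - 1]], ctr, D[[lev + 1]], `<`)
    cand <- which(is_max | is_min, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    for (j in seq_len(nrow(cand))) {
      r <- unname(cand[j, 1]); c <- unname(cand[j, 2])
      d0 <- D[[lev]]; dm <- D[[lev - 1]]; dp <- D[[lev + 1]]
      g <- c((d0[r + 1, c] - d0[r - 1, c]) / 2,
             (d0[r, c + 1] - d0[r, c - 1]) / 2,
             (dp[r, c] - dm[r, c]) / 2)
      Hrr <- d0[r + 1, c] + d0[r - 1, c] - 2 * d0[r, c]
      Hcc <- d0[r, c + 1] + d0[r, c - 1] - 2 * d0[r, c]
      Hss <- dp[r, c] + dm[r, c] - 2 * d0[r, c]
      Hrc <- (d0[r + 1, c + 1] - d0[r + 1, c - 1] - d0[r - 1, c + 1] + d0[r - 1, c - 1]) / 4
      Hrs <- (dp[r + 1, c] - dp[r - 1, c] - dm[r + 1, c] + dm[r - 1, c]) / 4
      Hcs <- (dp[r, c + 1] - dp[r, c - 1] - dm[r, c + 1] + dm[r, c - 1]) / 4
      H <- matrix(c(Hrr, Hrc, Hrs, Hrc, Hcc, Hcs, Hrs, Hcs, Hss), 3, 3)
      off <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(off) || any(!is.finite(off)) || any(abs(off) > 1.0)) next
      resp <- d0[r, c] + 0.5 * sum(g * off)
      if (abs(resp) < contrast_threshold) next
      trH <- Hrr + Hcc; detH <- Hrr * Hcc - Hrc^2
      if (detH <= 0 || trH^2 / detH >= (edge_ratio + 1)^2 / edge_ratio) next
      out[[length(out) + 1L]] <- c(row = r + off[1], col = c + off[2],
                                   level = lev, ds = off[3], response = resp)
    }
  }
  if (length(out) == 0)
    return(data.frame(row = numeric(0), col = numeric(0), level = numeric(0),
                      ds = numeric(0), response = numeric(0)))
  as.data.frame(do.call(rbind, out))
}

shift_mat2 <- function(x, dr, dc, fill) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(fill, n, m)
  sr <- max(1, 1 + dr):min(n, n + dr)
  sc <- max(1, 1 + dc):min(m, m + dc)
  out[sr - dr, sc - dc] <- x[sr, sc]
  out
}

# Dominant gradient orientation(s) at a keypoint: 36-bin Gaussian-weighted
# histogram, smoothed, peaks >= 0.8 * max (at most two), with parabolic
# interpolation. Angles follow atan2(d_row, d_col) mapped to [0, 360).
keypoint_orientations <- function(G, row, col, sig_rel) {
  n <- nrow(G); m <- ncol(G)
  rad <- max(3L, round(3 * 1.5 * sig_rel))
  r0 <- round(row); c0 <- round(col)
  rs <- max(2, r0 - rad):min(n - 1, r0 + rad)
  cs <- max(2, c0 - rad):min(m - 1, c0 + rad)
  if (length(rs) < 3 || length(cs) < 3) return(numeric(0))
  patch_dr <- (G[rs + 1, cs, drop = FALSE] - G[rs - 1, cs, drop = FALSE]) / 2
  patch_dc <- (G[rs, cs + 1, drop = FALSE] - G[rs, cs - 1, drop = FALSE]) / 2
  mag <- sqrt(patch_dr^2 + patch_dc^2)
  ang <- (atan2(patch_dr, patch_dc) * 180 / pi) %% 360
  dy <- outer(rs - row, rep(1, length(cs)))
  dx <- outer(rep(1, length(rs)), cs - col)
  w <- exp(-(dy^2 + dx^2) / (2 * (1.5 * sig_rel)^2))
  bins <- (floor(ang / 10) %% 36) + 1
  hist <- vapply(1:36, function(b) sum((mag * w)[bins == b]), 0)
  for (pass in 1:2) hist <- (hist + c(tail(hist, 1), head(hist, -1)) +
                             c(tail(hist, -1), head(hist, 1))) / 3
  if (max(hist) <= 0) return(numeric(0))
  peaks <- which(hist >= 0.8 * max(hist) &
                 hist >= c(tail(hist, 1), head(hist, -1)) &
                 hist >= c(tail(hist, -1), head(hist, 1)))
  peaks <- peaks[order(hist[peaks], decreasing = TRUE)]
  peaks <- head(peaks, 2)
  vapply(peaks, function(b) {
    hl <- hist[((b - 2) %% 36) + 1]; hc <- hist[b]; hr <- hist[(b %% 36) + 1]
    denom <- hl - 2 * hc + hr
    off <- if (abs(denom) > 1e-12) 0.5 * (hl - hr) / denom else 0
    ((b - 1 + off) * 10) %% 360
  }, 0)
}

# 4x4 spatial x 8 orientation gradient-histogram descriptor with trilinear
# binning, rotated into the keypoint frame, L2-normalised, clamped at 0.2
# and renormalised.
keypoint_descriptor <- function(G, row, col, sig_rel, orientation) {
  n <- nrow(G); m <- ncol(G)
  cell <- 3 * sig_rel
  rad <- min(round(cell * 2.5 * sqrt(2)) + 1, 60L)
  r0 <- round(row); c0 <- round(col)
  rs <- max(2, r0 - rad):min(n - 1, r0 + rad)
  cs <- max(2, c0 - rad):min(m - 1, c0 + rad)
  if (length(rs) < 4 || length(cs) < 4) return(NULL)
  patch_dr <- (G[rs + 1, cs, drop = FALSE] - G[rs - 1, cs, drop = FALSE]) / 2
  patch_dc <- (G[rs, cs + 1, drop = FALSE] - G[rs, cs - 1, drop = FALSE]) / 2
  mag <- as.vector(sqrt(patch_dr^2 + patch_dc^2))
  ang <- as.vector((atan2(patch_dr, patch_dc) * 180 / pi - orientation) %% 360)
  dy <- as.vector(outer(rs - row, rep(1, length(cs))))
  dx <- as.vector(outer(rep(1, length(rs)), cs - col))
  th <- orientation * pi / 180
  u <- (dx * cos(th) + dy * sin(th)) / cell   # rotated, in cell units
  v <- (-dx * sin(th) + dy * cos(th)) / cell
  inside <- abs(u) < 2.5 & abs(v) < 2.5
  if (!any(inside)) return(NULL)
  u <- u[inside] + 1.5; v <- v[inside] + 1.5   # cell coords in [-1, 4]
  w <- exp(-(u - 1.5)^2 / 8 - (v - 1.5)^2 / 8) * mag[inside]
  o <- ang[inside] / 45                         # orientation bin coord [0, 8)
  desc <- numeric(128)
  u0 <- floor(u); v0 <- floor(v); o0 <- floor(o)
  fu <- u - u0; fv <- v - v0; fo <- o - o0
  for (du in 0:1) for (dv in 0:1) for (do in 0:1) {
    ub <- u0 + du; vb <- v0 + dv; ob <- (o0 + do) %% 8
    wt <- w * (if (du) fu else 1 - fu) * (if (dv) fv else 1 - fv) *
              (if (do) fo else 1 - fo)
    ok <- ub >= 0 & ub <= 3 & vb >= 0 & vb <= 3
    if (!any(ok)) next
    idx <- 1 + ob[ok] + 8 * (ub[ok] + 4 * vb[ok])
    add <- tapply(wt[ok], idx, sum)
    desc[as.integer(names(add))] <- desc[as.integer(names(add))] + add
  }
  nrm <- sqrt(sum(desc^2))
  if (nrm < 1e-9) return(NULL)
  desc <- pmin(desc / nrm, 0.2)
  desc / sqrt(sum(desc^2))
}

#' Match keypoints by the nearest-neighbour distance-ratio test
#'
#' For every keypoint in `a`, the two nearest descriptors in `b` (Euclidean
#' distance) are found; the pair is kept only when the nearest distance is
#' less than `ratio_threshold` times the second-nearest -- the standard
#' guard against ambiguous matches. Each keypoint of `a` therefore appears
#' at most once. With a single candidate in `b` the ratio test is
#' impossible and pairs are kept only below an absolute distance cap.
#'
#' @param a,b `keypoint_set` objects with same-length descriptors.
#' @param ratio_threshold Ratio test threshold in (0, 1]; 0 rejects all.
#' @param abs_cap Absolute distance cap used when `b` has one keypoint.
#' @return A `match_set`: data frame with `a_idx`, `b_idx`, `distance`,
#'   `ratio`, plus attribute `ratio_threshold`.
#' @export
match_keypoints <- function(a, b, ratio_threshold = 0.8, abs_cap = 0.5) {
  empty <- structure(data.frame(a_idx = integer(0), b_idx = integer(0),
                                distance = numeric(0), ratio = numeric(0)),
                     ratio_threshold = ratio_threshold, class = c("match_set", "data.frame"))
  na <- nrow(a$points); nb <- nrow(b$points)
  if (na == 0 || nb == 0) return(empty)
  if (ncol(a$descriptors) != ncol(b$descriptors))
    kerato_error("descriptor lengths differ", "kerato3d_config_error")
  d2 <- pmax(outer(rowSums(a$descriptors^2), rowSums(b$descriptors^2), `+`) -
             2 * tcrossprod(a$descriptors, b$descriptors), 0)
  dist <- sqrt(d2)
  if (nb == 1L) {
    keep <- which(dist[, 1] < abs_cap)
    res <- data.frame(a_idx = keep, b_idx = rep(1L, length(keep)),
                      distance = dist[keep, 1], ratio = rep(NA_real_, length(keep)))
  } else {
    best <- apply(dist, 1, function(row) {
      o <- order(row)[1:2]
      c(o[1], row[o[1]], row[o[2]])
    })
    d1 <- best[2, ]; d2nd <- best[3, ]
    ratio <- ifelse(d2nd > 1e-12, d1 / d2nd, ifelse(d1 <= 1e-12, 0, Inf))
    keep <- which(ratio < ratio_threshold)
    res <- data.frame(a_idx = keep, b_idx = as.integer(best[1, keep]),
                      distance = d1[keep], ratio = ratio[keep])
  }
  structure(res, ratio_threshold = ratio_threshold, class = c("match_set", "data.frame"))
}

#' Overlay keypoints on an image (diagnostic)
#'
#' Draws a black circle of radius equal to each keypoint's scale at its
#' position, leaving all other pixels untouched.
#'
#' @param image Numeric matrix.
#' @param keypoints A `keypoint_set`.
#' @return A copy of the image with the circles drawn.
#' @export
dense_feature_overlay <- function(image, keypoints) {
  img <- as_grey(image)
  if (nrow(keypoints$points) == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  for (i in seq_len(nrow(keypoints$points))) {
    p <- keypoints$points[i, ]
    rad <- max(1, round(p$scale))
    th <- seq(0, 2 * pi, length.out = max(8, ceiling(2 * pi * rad)))
    rr <- round(p$row + rad * sin(th)); cc <- round(p$col + rad * cos(th))
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
    img[cbind(rr[ok], cc[ok])] <- 0
  }
  img
}
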