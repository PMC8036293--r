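# Shared fixtures and independent oracles. Expensive artefacts (the phantom
# cohort, the trained CNN) are built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# 40-case noise-free phantom cohort (10 per stage) with images and volumes.
fixture_cohort40 <- function() memo("cohort40", function() {
  generate_cohort(10, seed = 42)
})

# Full geometric pipeline run over the 40-case cohort.
fixture_cohort40_run <- function() memo("cohort40_run", function() {
  run_cohort(fixture_cohort40())
})

# The desk-scale 64^3 CNN trained on the 40-case cohort volumes.
fixture_cnn <- function() memo("cnn", function() {
  coh <- fixture_cohort40()
  cfg <- cnn_config(seed = 7)
  vols <- lapply(coh$cases, function(cs) preprocess_volume(cs$volume, cfg))
  model <- cnn_build(cfg)
  list(model = cnn_train(model, vols, coh$manifest$stage),
       volumes = vols, labels = coh$manifest$stage, config = cfg)
})

# A small config whose training cost is test-friendly (46 is the smallest
# input edge the four conv/pool blocks admit).
small_cnn_config <- function(...) cnn_config(input_edge = 46L, ...)

# Multi-scale blob field: a jittered grid of high-contrast Gaussian blobs
# spanning several octaves of scale, so invariance tests see features at
# every pyramid level without overlap washing out local contrast.
blob_image <- function(n = 160, cell = 20, seed = 11) {
  set.seed(seed)
  img <- matrix(0, n, n)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  centers <- seq(cell / 2, n - cell / 2, by = cell)
  sign <- 1
  for (r0 in centers) for (c0 in centers) {
    rr <- r0 + runif(1, -4, 4); cc <- c0 + runif(1, -4, 4)
    sg <- runif(1, 1.5, 5.5)
    img <- img + sign * exp(-((rows - rr)^2 + (cols - cc)^2) / (2 * sg^2))
    sign <- -sign
  }
  (img - min(img)) / diff(range(img))
}

# Brute-force circular Hough accumulator: an independent realisation of the
# accumulator definition (count edge pixels whose distance to the centre
# rounds to r; circle fully inside; votes normalised per-radius by lattice
# support), evaluated over the complete (n, m, r) grid.
brute_hough_argmax <- function(img, rmin, rmax, edge_threshold = 0.25) {
  edges <- kerato3d:::sobel_edges(img, edge_threshold)
  n <- nrow(img); m <- ncol(img)
  nr <- rmax - rmin + 1
  acc <- array(0L, c(n, m, nr))
  rows <- matrix(seq_len(n), n, m)
  cols <- matrix(seq_len(m), n, m, byrow = TRUE)
  npix <- n * m
  idx_all <- integer(0)
  for (e in seq_len(nrow(edges))) {
    rad <- round(sqrt((rows - edges[e, 1])^2 + (cols - edges[e, 2])^2))
    sel <- which(rad >= rmin & rad <= rmax)
    idx_all <- c(idx_all, sel + (rad[sel] - rmin) * npix)
  }
  tab <- tabulate(idx_all, nbins = npix * nr)
  acc[] <- tab
  # lattice support per radius, computed independently
  off <- expand.grid(dx = -(rmax + 1):(rmax + 1), dy = -(rmax + 1):(rmax + 1))
  rr <- round(sqrt(off$dx^2 + off$dy^2))
  support <- vapply(rmin:rmax, function(r) sum(rr == r), 0L)
  # mask centres whose circle leaves the image
  votes <- array(0, dim(acc))
  for (ri in seq_len(nr)) {
    r <- rmin + ri - 1
    ok_r <- rows >= r + 1 & rows <= n - r
    ok_c <- cols >= r + 1 & cols <= m - r
    votes[, , ri] <- acc[, , ri] * (ok_r & ok_c) / support[ri]
  }
  best <- which(votes == max(votes))
  cand <- arrayInd(best, dim(votes))
  # deterministic tie-break: smallest radius, then row, then col
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  list(n = cand[1, 1], m = cand[1, 2], r = rmin + cand[1, 3] - 1,
       votes = max(votes))
}

# Random apex-over-midpoint triangle configurations (the geometry the
# right-triangle depth construction assumes).
random_depth_triple <- function() {
  p2 <- runif(2, -50, 50)
  p3 <- runif(2, -50, 50)
  while (sum((p2 - p3)^2) < 1) p3 <- runif(2, -50, 50)
  C <- (p2 + p3) / 2
  u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  v <- c(-u[2], u[1])
  h <- runif(1, 0, 40)
  list(p1 = C + h * v, p2 = p2, p3 = p3, h = h)
}

# Perpendicular distance from point p to the line through a and b.
point_line_distance <- function(p, a, b) {
  ab <- b - a
  abs(ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])) / sqrt(sum(ab^2))
}

# Apex angle measured directly in coordinates (law-of-cosines oracle).
apex_angle_from_coords <- function(A, B, C) {
  u <- B - A; v <- C - A
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}
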