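test_that("transform estimation is exact on consistent data and unbiased under noise", {
  # single correspondence: mapped exactly, zero residual
  tf1 <- estimate_transform(NULL, cbind(10, 20), cbind(30, 25))
  expect_equal(tf1$ty, -5)
  fused <- fuse_points(cbind(10, 20), cbind(30, 25), tf1)
  back <- project_fused(fused, tf1)
  expect_equal(unname(back$frontal[1, ]), c(10, 20))
  expect_equal(unname(back$lateral[1, ]), c(30, 25))
  expect_error(estimate_transform(NULL, cbind(numeric(0), numeric(0)),
                                  cbind(numeric(0), numeric(0))),
               class = "kerato3d_insufficient_matches")
  # Gaussian noise: component error within 3 sigma / sqrt(n)
  set.seed(12)
  n <- 60; sigma <- 0.5; ty <- -4
  y1 <- runif(n, 50, 200)
  y2 <- y1 - ty + rnorm(n, sd = sigma)
  x1 <- runif(n, 50, 200); x2 <- runif(n, 60, 120)
  tf <- estimate_transform(NULL, cbind(x1, y1), cbind(x2, y2))
  expect_lt(abs(tf$ty - ty), 3 * sigma / sqrt(n))
})

test_that("fusion preserves the shared vertical axis and round-trips exactly", {
  fused <- fuse_points(cbind(5, 7), cbind(9, 7))
  expect_equal(fused$y3, 7)
  expect_equal(fused$x3, 5)
  expect_equal(fused$z3, 9)
  set.seed(2)
  fp <- cbind(sample(1:200, 30), sample(1:200, 30))
  tf <- structure(list(tx = 4, ty = -3, tz = 11, n = 30L), class = "ortho_transform")
  # lateral points consistent with the transform's vertical offset
  lp <- cbind(sample(1:200, 30), fp[, 2] - tf$ty)
  back <- project_fused(fuse_points(fp, lp, tf), tf)
  expect_equal(max(abs(back$frontal - fp)), 0)
  expect_equal(max(abs(back$lateral - lp)), 0)
  expect_error(fuse_points(fp, lp[1:10, ]), class = "kerato3d_config_error")
})

test_that("rasterisation deposits a surface sheet and rejects degenerate layouts", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  pts <- fuse_points(cbind(32 + 12 * cos(th), 32 + 12 * sin(th)),
                     cbind(rep(10, 16), 32 + 12 * sin(th)))
  pts <- rbind(pts, fuse_points(cbind(32, 32), cbind(22, 32)))  # raised apex
  vol <- rasterize_volume(pts, c(48, 48, 48), smoothing_sigma = 1)
  expect_equal(dim(vol), c(48, 48, 48))
  expect_gt(sum(vol > 0), 0)
  # support never shrinks when smoothing widens
  vol2 <- rasterize_volume(pts, c(48, 48, 48), smoothing_sigma = 2)
  expect_gte(sum(vol2 > 1e-8), sum(vol > 1e-8))
  expect_true(all(vol2[vol > 1e-8] > 0))
  # coplanar points cannot define a corneal surface
  flat <- fuse_points(cbind(c(10, 30, 10, 30), c(10, 10, 30, 30)),
                      cbind(rep(5, 4), c(10, 10, 30, 30)))
  expect_error(rasterize_volume(flat), class = "kerato3d_degenerate_surface")
  expect_error(rasterize_volume(pts[1:3, ]), class = "kerato3d_degenerate_surface")
})

test_that("SSD volume matching is a pseudo-metric that identifies the right stage", {
  a <- array(runif(12^3), rep(12, 3))
  expect_equal(ssd_match(a, a), 0)
  b <- a; b[3, 4, 5] <- b[3, 4, 5] + 0.25
  expect_equal(ssd_match(a, b), 0.25^2)
  expect_equal(ssd_match(a, b), ssd_match(b, a))
  # a phantom volume is closest to its own stage's stored volume
  specs <- list(
    normal = eye_phantom_spec("normal", 35, seed = 1),
    mild = eye_phantom_spec("mild", 42, seed = 2),
    moderate = eye_phantom_spec("moderate", 49, seed = 3),
    severe = eye_phantom_spec("severe", 60, seed = 4))
  stored <- lapply(specs, render_volume, edge = 32L)
  probe <- render_volume(eye_phantom_spec("severe", 59, seed = 9), edge = 32L)
  scores <- vapply(stored, function(s) ssd_match(probe, s), 0)
  expect_equal(names(which.min(scores)), "severe")
})

test_that("the reconstructed crest sits at the fused apex", {
  spec <- eye_phantom_spec(stage = "severe", steepness_angle_deg = 60)
  cr <- run_case(render_frontal(spec), render_lateral(spec))
  expect_null(cr$error)
  vol <- cr$volume
  mapping <- attr(vol, "mapping")
  occ <- which(vol > 0.5, arr.ind = TRUE)
  crest <- occ[which.max(occ[, 3]), ]
  apex_grid_x <- (cr$iris$m - mapping$x_lo) * mapping$scale + 1
  apex_grid_y <- (cr$iris$n - mapping$y_lo) * mapping$scale + 1
  expect_lt(abs(crest[1] - apex_grid_x), 2.5)
  expect_lt(abs(crest[2] - apex_grid_y), 2.5)
})
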