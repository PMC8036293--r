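test_that("layer shape arithmetic matches hand-computed conv/pool sizes", {
  cfg <- cnn_config(input_edge = 64L)
  expect_equal(cfg$layer_edges, c(62, 31, 29, 14, 12, 6, 4, 2))
  cfg46 <- small_cnn_config()
  expect_equal(cfg46$layer_edges, c(44, 22, 20, 10, 8, 4, 2, 1))
  expect_error(cnn_config(input_edge = 8L), class = "kerato3d_config_error")
  expect_error(cnn_config(input_edge = 38L), class = "kerato3d_config_error")
  expect_error(cnn_config(conv_channels = c(8, 16)), class = "kerato3d_config_error")
})

test_that("initialisation is seed-deterministic and softmax outputs are probabilities", {
  cfg <- small_cnn_config(seed = 21L)
  m1 <- cnn_build(cfg); m2 <- cnn_build(cfg)
  expect_identical(m1$weights, m2$weights)
  expect_gt(m1$n_parameters, 1e6)
  v <- array(runif(46^3), rep(46, 3))
  p1 <- cnn_predict(m1, v)
  expect_equal(sum(p1$probabilities), 1, tolerance = 1e-6)
  expect_true(all(p1$probabilities >= 0))
  expect_identical(p1, cnn_predict(m1, v))
  expect_error(cnn_predict(m1, array(0, rep(20, 3))), class = "kerato3d_config_error")
})

test_that("volume preprocessing normalises shape, keeps the ROI and preserves constants", {
  cfg <- small_cnn_config()
  v <- render_volume(eye_phantom_spec("severe", 60, seed = 2), edge = 56L)
  out <- preprocess_volume(v, cfg)
  expect_equal(dim(out), rep(46L, 3))
  expect_gte(min(out), 0); expect_lte(max(out), 1)
  # the ROI crop retains essentially all of the surface intensity
  occ <- which(v > 0.05 * max(v), arr.ind = TRUE)
  lo <- apply(occ, 2, min); hi <- apply(occ, 2, max)
  expect_gte(sum(v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]) / sum(v), 0.99)
  # constants pass through (unit DC gain), empty volumes are rejected
  const <- array(0.37, rep(10, 3))
  expect_lt(max(abs(preprocess_volume(const, cfg) - 0.37)), 1e-12)
  expect_error(preprocess_volume(array(0, rep(8, 3)), cfg), class = "kerato3d_config_error")
})

test_that("SGD bookkeeping: zero learning rate freezes, same seed reruns identically", {
  cfg <- small_cnn_config(learning_rate = 0, epochs = 2L, early_stop_loss = NA, seed = 5L)
  set.seed(41)
  vols <- lapply(1:8, function(i) array(runif(46^3), rep(46, 3)))
  labels <- rep(c("normal", "mild", "moderate", "severe"), 2)
  m <- cnn_build(cfg)
  tr <- cnn_train(m, vols, labels)
  # parameters unchanged up to the float precision training runs at
  for (i in seq_along(tr$weights))
    expect_equal(unname(as.vector(tr$weights[[i]])),
                 unname(as.vector(m$weights[[i]])), tolerance = 1e-6)
  expect_equal(tr$history$loss[1], tr$history$loss[2])
  cfg2 <- small_cnn_config(learning_rate = 0.01, epochs = 2L, early_stop_loss = NA, seed = 5L)
  t1 <- cnn_train(cnn_build(cfg2), vols, labels)
  t2 <- cnn_train(cnn_build(cfg2), vols, labels)
  expect_identical(t1$history, t2$history)
  expect_error(cnn_train(cnn_build(cfg2), vols[1:6], labels[1:6]),
               class = "kerato3d_config_error")
  expect_error(cnn_train(cnn_build(cfg2), vols, rep("mild", 8)),
               class = "kerato3d_config_error")
})

test_that("full-batch descent on a small memorisation task has non-increasing loss", {
  cfg <- small_cnn_config(learning_rate = 0.005, epochs = 6L, early_stop_loss = NA,
                          seed = 13L)
  set.seed(99)
  base <- lapply(1:4, function(i) array(runif(46^3, max = 0.3), rep(46, 3)))
  vols <- c(base, lapply(base, function(v) pmin(v + 0.02, 1)))
  labels <- rep(c("normal", "mild", "moderate", "severe"), 2)
  tr <- cnn_train(cnn_build(cfg), vols, labels)
  expect_true(all(diff(tr$history$loss) <= 1e-6))
  expect_lt(tr$history$loss[6], tr$history$loss[1])
})

test_that("the trained desk-scale model generalises to held-out phantoms", {
  fx <- fixture_cnn()
  held <- generate_cohort(1, seed = 99, render_images = FALSE)
  preds <- vapply(held$cases, function(cs) {
    cnn_predict(fx$model, preprocess_volume(cs$volume, fx$config))$label
  }, "")
  expect_gte(mean(preds == held$manifest$stage), 0.75)
  expect_equal(preds[held$manifest$stage == "severe"], "severe",
               ignore_attr = TRUE)
})
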