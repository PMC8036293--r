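test_that("a flat image yields no keypoints; small images are rejected", {
  expect_equal(nrow(extract_keypoints(matrix(0.5, 96, 96))$points), 0)
  expect_error(extract_keypoints(matrix(0.5, 40, 40)), class = "kerato3d_config_error")
  expect_error(extract_keypoints(matrix(runif(64 * 64), 64, 64), n_octaves = 6L),
               class = "kerato3d_config_error")
})

test_that("keypoints are deterministic, unit-normalised and contrast-monotone", {
  img <- blob_image()
  kp1 <- extract_keypoints(img)
  kp2 <- extract_keypoints(img)
  expect_identical(kp1, kp2)
  expect_gt(nrow(kp1$points), 20)
  expect_true(all(abs(sqrt(rowSums(kp1$descriptors^2)) - 1) < 1e-6))
  expect_true(all(kp1$points$scale > 0))
  expect_true(all(kp1$points$orientation >= 0 & kp1$points$orientation < 360))
  # raising the contrast threshold never adds keypoints
  counts <- vapply(c(0.01, 0.03, 0.06, 0.12),
                   function(th) nrow(extract_keypoints(img, contrast_threshold = th)$points),
                   0)
  expect_true(all(diff(counts) <= 0))
})

test_that("matching identical keypoint sets is the identity pairing", {
  kp <- extract_keypoints(blob_image())
  m <- match_keypoints(kp, kp)
  expect_equal(nrow(m), nrow(kp$points))
  expect_equal(m$a_idx, m$b_idx)
  expect_true(all(m$distance < 1e-6))
  expect_equal(nrow(match_keypoints(kp, kp, ratio_threshold = 0)), 0)
  empty <- extract_keypoints(matrix(0.5, 96, 96))
  expect_equal(nrow(match_keypoints(kp, empty)), 0)
  expect_equal(nrow(match_keypoints(empty, kp)), 0)
})

test_that("a pure translation is recovered by the match displacement", {
  img <- blob_image()
  n <- nrow(img)
  shifted <- matrix(median(img), n, n)
  shifted[, 6:n] <- img[, 1:(n - 5)]
  kp1 <- extract_keypoints(img)
  kp2 <- extract_keypoints(shifted)
  m <- match_keypoints(kp1, kp2)
  expect_gt(nrow(m), 10)
  dr <- median(kp2$points$row[m$b_idx] - kp1$points$row[m$a_idx])
  dc <- median(kp2$points$col[m$b_idx] - kp1$points$col[m$a_idx])
  expect_lte(abs(dr - 0), 1)
  expect_lte(abs(dc - 5), 1)
})

test_that("keypoint positions are stable under 90-degree rotation", {
  img <- blob_image()
  n <- nrow(img)
  rot <- t(img)[ncol(img):1, ]        # rot[r, c] = img[c, n + 1 - r]
  kp <- extract_keypoints(img)
  kpr <- extract_keypoints(rot)
  mapped_r <- n + 1 - kp$points$col   # image point -> rotated frame
  mapped_c <- kp$points$row
  D <- outer(mapped_r, kpr$points$row, `-`)^2 + outer(mapped_c, kpr$points$col, `-`)^2
  nearest <- sqrt(apply(D, 1, min))
  expect_gte(mean(nearest <= 2), 0.8)
})

test_that("keypoints correspond across a factor-2 scale change", {
  img <- blob_image()
  n <- nrow(img)
  half <- kerato3d:::gaussian_blur(img, 1)[seq(1, n, 2), seq(1, n, 2)]
  kp <- extract_keypoints(img, n_octaves = 3L)
  kph <- extract_keypoints(half, n_octaves = 3L)
  expect_gt(nrow(kph$points), 5)
  # every keypoint of the half-size image maps into the original frame;
  # count those with a counterpart (evaluated in the half-size frame)
  mapped_r <- kp$points$row / 2; mapped_c <- kp$points$col / 2
  D <- outer(kph$points$row, mapped_r, `-`)^2 + outer(kph$points$col, mapped_c, `-`)^2
  nearest <- sqrt(apply(D, 1, min))
  expect_gte(mean(nearest <= 2), 0.6)
})

test_that("feature overlay only paints keypoint circles", {
  img <- blob_image(n = 96)
  empty <- structure(list(points = data.frame(), descriptors = matrix(0, 0, 128)),
                     class = "keypoint_set")
  expect_identical(dense_feature_overlay(img, empty), img)
  one <- structure(list(points = data.frame(row = 10, col = 10, scale = 3,
                                            orientation = 0, octave = 1L,
                                            response = 1),
                        descriptors = matrix(1, 1, 128)),
                   class = "keypoint_set")
  over <- dense_feature_overlay(img, one)
  changed <- which(over != img, arr.ind = TRUE)
  expect_gt(nrow(changed), 4)
  # all painted pixels lie on the circle of radius 3 around (10, 10)
  rad <- sqrt((changed[, 1] - 10)^2 + (changed[, 2] - 10)^2)
  expect_true(all(abs(rad - 3) < 1.2))
  expect_true(all(over[changed] == 0))
  # pixels away from the circle are untouched
  far <- abs(sqrt((row(img) - 10)^2 + (col(img) - 10)^2) - 3) > 2
  expect_identical(over[far], img[far])
})
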