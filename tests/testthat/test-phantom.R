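test_that("frontal render places the iris edge at the requested radius, deterministically", {
  spec <- eye_phantom_spec(stage = "normal", steepness_angle_deg = 35,
                           image_size = 128L, iris_center = c(64, 64),
                           iris_radius = 30, noise_sigma = 0)
  img <- render_frontal(spec)
  expect_equal(dim(img), c(128L, 128L))
  # inside the annulus dark, outside bright, with the transition at r = 30
  expect_lt(img[64, 64 + 28], 0.4)
  expect_gt(img[64, 64 + 32], 0.8)
  # the strongest circular edge is at the iris radius: check via the
  # radial intensity jump
  prof <- img[64, 64:127]
  expect_equal(which.max(abs(diff(prof))), 30, tolerance = 1)
  # noise-free render ignores the seed (pixel payload identical)
  spec2 <- spec; spec2$seed <- 999L
  expect_identical(as.vector(render_frontal(spec2)), as.vector(render_frontal(spec)))
  # seeded noise is reproducible bit for bit
  spec_n <- eye_phantom_spec(stage = "normal", steepness_angle_deg = 35,
                             image_size = 128L, iris_center = c(64, 64),
                             iris_radius = 30, noise_sigma = 5, seed = 3)
  expect_identical(render_frontal(spec_n), render_frontal(spec_n))
  expect_error(render_frontal(eye_phantom_spec(image_size = 128L,
                                               iris_center = c(20, 64),
                                               iris_radius = 30)),
               class = "kerato3d_geometry_error")
})

test_that("lateral render ground truth is self-consistent", {
  spec <- eye_phantom_spec(stage = "severe", steepness_angle_deg = 58,
                           iris_radius = 32, cornea_apex_height = 40)
  lat <- render_lateral(spec)
  apex <- attr(lat, "apex"); p2 <- attr(lat, "p2"); p3 <- attr(lat, "p3")
  Cmid <- (p2 + p3) / 2
  expect_equal(sqrt(sum((apex - Cmid)^2)), 40)
  expect_equal(sqrt(sum((p2 - p3)^2)), 2 * 32)
  # noise-free render ignores the seed (pixel payload identical)
  spec2 <- spec; spec2$seed <- 77L
  expect_identical(as.vector(render_lateral(spec2)), as.vector(render_lateral(spec)))
})

test_that("ground-truth steepness is recovered from the rendered noise-free contour", {
  for (s in c(41, 48, 57, 64)) {
    stage <- if (s < 45) "mild" else if (s <= 52) "moderate" else "severe"
    spec <- eye_phantom_spec(stage = stage, steepness_angle_deg = s, iris_radius = 34)
    lat <- render_lateral(spec)
    iris <- structure(list(m = 128, n = 128, r = 34, votes = 1), class = "iris_circle")
    st <- stage_from_landmarks(find_depth_landmarks(lat, iris), iris)
    expect_lt(abs(st$steepness_deg - s), 1)
  }
})

test_that("cohort generation is labelled, proportioned and seed-deterministic", {
  coh <- generate_cohort(2, seed = 5, render_volumes = FALSE)
  expect_equal(nrow(coh$manifest), 8)
  expect_equal(unname(table(coh$manifest$stage)[c("normal", "mild", "moderate", "severe")]),
               rep(2L, 4), ignore_attr = TRUE)
  # every label agrees with threshold staging of its true steepness
  for (cs in coh$cases) {
    staged <- grade_stage(cs$spec$steepness_angle_deg,
                          cone_detected = cs$stage != "normal")
    expect_equal(staged$stage, cs$stage)
    expect_true(cs$stage != "mild" || cs$spec$steepness_angle_deg < 45)
  }
  coh2 <- generate_cohort(2, seed = 5, render_volumes = FALSE)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(as.vector(coh$cases[[3]]$frontal), as.vector(coh2$cases[[3]]$frontal))
  # ranges that straddle a staging boundary are rejected
  bad <- list(normal = c(30, 40), mild = c(41, 46),
              moderate = c(46, 51), severe = c(53, 65))
  expect_error(generate_cohort(1, seed = 1, stage_params = bad),
               class = "kerato3d_config_error")
})

test_that("volume render encodes elevation as darker grey at the apex", {
  spec <- eye_phantom_spec(stage = "severe", steepness_angle_deg = 60, iris_radius = 34)
  vol <- render_volume(spec, edge = 48L)
  expect_equal(dim(vol), rep(48L, 3))
  apex <- attr(vol, "apex_voxel")
  # intensity at the apex crest is darker than at the flat rim
  apex_i <- max(vol[round(apex[1]), round(apex[2]), ])
  rim_i <- max(vol[round(apex[1]) + 16, round(apex[2]), ])
  expect_lt(apex_i, rim_i)
})

test_that("cohort round-trips through PNG/NIfTI/CSV on disk", {
  dir <- file.path(tempdir(), "kerato3d-cohort")
  on.exit(unlink(dir, recursive = TRUE))
  coh <- generate_cohort(1, seed = 8, image_size = 96L,
                         iris_radius_range = c(12, 14), volume_edge = 32L)
  man <- write_cohort(coh, dir)
  expect_true(all(file.exists(man$frontal_file, man$lateral_file, man$volume_file)))
  back <- read_eye_image(man$frontal_file[1])
  expect_equal(dim(back), dim(coh$cases[[1]]$frontal))
  expect_lt(max(abs(back - coh$cases[[1]]$frontal)), 1 / 255)
  vol <- RNifti::readNifti(man$volume_file[1])
  expect_equal(dim(vol), dim(coh$cases[[1]]$volume))
  expect_lt(max(abs(as.array(vol) - coh$cases[[1]]$volume)), 1e-6)
})
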