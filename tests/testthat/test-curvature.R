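test_that("triangle angles follow the law of cosines with exact supplements", {
  eq <- angle_from_triangle(1, 1, 1)
  expect_equal(eq$theta_deg, 60)
  expect_equal(eq$angle_of_curvature_deg, 120)
  ri <- angle_from_triangle(sqrt(2), 1, 1)
  expect_equal(ri$theta_deg, 90)
  expect_equal(ri$angle_of_curvature_deg, 90)
  known <- angle_from_triangle(2, sqrt(5), sqrt(5))
  expect_equal(known$theta_deg, acos(0.6) * 180 / pi)
  expect_error(angle_from_triangle(10, 1, 1), class = "kerato3d_geometry_error")
  expect_error(angle_from_triangle(1, 0, 1), class = "kerato3d_geometry_error")
})

test_that("staging is a total deterministic partition with inclusive 45/52 bounds", {
  expect_equal(grade_stage(44, TRUE)$stage, "mild")
  expect_equal(grade_stage(45, TRUE)$stage, "moderate")
  expect_equal(grade_stage(50, TRUE)$stage, "moderate")
  expect_equal(grade_stage(52, TRUE)$stage, "moderate")
  expect_equal(grade_stage(52.001, TRUE)$stage, "severe")
  expect_equal(grade_stage(60, TRUE)$stage, "severe")
  expect_equal(grade_stage(60, FALSE)$stage, "normal")
  grid <- seq(0, 89.9, by = 0.1)
  stages <- vapply(grid, function(s) grade_stage(s, TRUE)$stage, "")
  expect_true(all(stages %in% c("mild", "moderate", "severe")))
  # boundaries are the only transition points
  expect_equal(unique(stages[grid < 45]), "mild")
  expect_equal(unique(stages[grid >= 45 & grid <= 52]), "moderate")
  expect_equal(unique(stages[grid > 52]), "severe")
  expect_error(grade_stage(95, TRUE), class = "kerato3d_config_error")
})

test_that("steepness measurement handles cones, hemispheres and flat discs", {
  # cone flank with known slope, via the full lateral pipeline
  spec <- eye_phantom_spec(stage = "severe", steepness_angle_deg = 60, iris_radius = 34)
  iris <- structure(list(m = 128, n = 128, r = 34, votes = 1), class = "iris_circle")
  st <- stage_from_landmarks(find_depth_landmarks(render_lateral(spec), iris), iris)
  expect_lt(abs(st$steepness_deg - 60), 1.5)
  expect_equal(st$stage_result$stage, "severe")
  # hemisphere: tangent at the rim approaches vertical as sampling densifies
  hemi <- function(n) {
    y <- seq(-1, 1, length.out = n)
    cbind(y, sqrt(pmax(1 - y^2, 0)))
  }
  s1 <- measure_steepness(hemi(200), window = 2L)
  s2 <- measure_steepness(hemi(2000), window = 2L)
  expect_gt(s1, 80)
  expect_gt(s2, s1)
  expect_lte(s2, 90)
  # flat disc
  flat <- cbind(seq(0, 40, by = 0.5), 0)
  expect_equal(measure_steepness(flat), 0)
  expect_error(measure_steepness(cbind(1:5, 1:5)), class = "kerato3d_config_error")
})

test_that("steepness can be read back from a reconstructed volume", {
  spec <- eye_phantom_spec(stage = "moderate", steepness_angle_deg = 48)
  cr <- run_case(render_frontal(spec), render_lateral(spec))
  expect_null(cr$error)
  sv <- measure_steepness(cr$volume)
  expect_lt(abs(sv - 48), 4)
})

test_that("the curvature triangle ties to the depth landmarks", {
  spec <- eye_phantom_spec(stage = "severe", steepness_angle_deg = 58, iris_radius = 34)
  iris <- structure(list(m = 128, n = 128, r = 34, votes = 1), class = "iris_circle")
  lm <- find_depth_landmarks(render_lateral(spec), iris)
  st <- stage_from_landmarks(lm, iris)
  # apex angle from the triangle equals the vector angle at p1
  expect_equal(st$triangle$theta_deg,
               apex_angle_from_coords(lm$p1, lm$p2, lm$p3), tolerance = 1e-9)
  expect_equal(st$triangle$angle_of_curvature_deg, 180 - st$triangle$theta_deg)
})
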