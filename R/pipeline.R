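#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with their defaults. A
#' YAML file with the same nested structure can be loaded via `yaml_path`
#' (requires the yaml package); entries present in the file override the
#' defaults.
#'
#' @param ... Named overrides of the default entries (nested lists merged
#'   one level deep).
#' @param yaml_path Optional path to a YAML configuration file.
#' @return A nested `kerato_config` list.
#' @export
kerato_config <- function(..., yaml_path = NULL) {
  cfg <- list(
    iris = list(radius_range = c(20, 48), edge_threshold = 0.25, min_votes = 0.25),
    features = list(n_octaves = 4L, contrast_threshold = 0.03, ratio_threshold = 0.8),
    depth = list(chord_tolerance = 0.25, mode = "chord"),
    curvature = list(cone_depth_ratio = 0.5, boundary_guard_deg = 1),
    reconstruct = list(volume_edge = 64L, smoothing_sigma = 1),
    pipeline = list(min_matches = 4L, cnn_gates_staging = FALSE,
                    save_intermediates = FALSE)
  )
  if (!is.null(yaml_path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      kerato_error("the yaml package is required to read YAML configs",
                   "kerato3d_config_error")
    over <- yaml::read_yaml(yaml_path)
    for (sec in names(over)) cfg[[sec]] <- utils::modifyList(cfg[[sec]], over[[sec]])
  }
  over <- list(...)
  for (sec in names(over)) cfg[[sec]] <- utils::modifyList(cfg[[sec]], over[[sec]])
  structure(cfg, class = "kerato_config")
}

#' Run the full detection pipeline on one case
#'
#' Executes the stage chain on a frontal/lateral image pair: iris detection
#' (circular Hough) on the frontal view; keypoint extraction and cross-view
#' ratio-test matching; depth landmarks on the lateral profile; estimation
#' of the translational view transform (from keypoint matches when at least
#' `min_matches` survive the ratio test, otherwise from the iris/chord
#' geometry, flagged `geometric_alignment`); reconstruction of the corneal
#' surface (the lateral profile revolved around the corneal axis within the
#' frontal iris disc, rasterised to a volume); geometric curvature staging;
#' and, when a trained CNN is supplied, volumetric classification. Any
#' stage error is captured: the result carries the failing stage's name and
#' message instead of aborting a batch.
#'
#' @param frontal,lateral Image matrices (or file paths readable by
#'   [read_eye_image()]).
#' @param config A [kerato_config()].
#' @param model Optional trained [cnn_build()] model for the CNN branch.
#' @param case_id Identifier carried into the result.
#' @return A `case_result`: iris, keypoint/match counts, landmarks,
#'   transform, fused surface volume, curvature triangle, geometric stage,
#'   optional CNN stage, `qc_flags`, and `error`/`failed_stage` when a
#'   stage failed.
#' @export
run_case <- function(frontal, lateral, config = kerato_config(), model = NULL,
                     case_id = "case") {
  res <- structure(list(case_id = case_id, qc_flags = character(0),
                        error = NULL, failed_stage = NULL),
                   class = "case_result")
  if (is.character(frontal)) frontal <- read_eye_image(frontal)
  if (is.character(lateral)) lateral <- read_eye_image(lateral)
  frontal <- as_grey(frontal); lateral <- as_grey(lateral)

  run_stage <- function(stage, expr) {
    if (!is.null(res$error)) return(NULL)
    tryCatch(expr, error = function(e) {
      res$error <<- conditionMessage(e)
      res$failed_stage <<- stage
      NULL
    })
  }

  res$iris <- run_stage("iris", detect_iris(frontal, config$iris$radius_range,
                                            config$iris$edge_threshold,
                                            config$iris$min_votes))
  res$matches <- run_stage("features", {
    kf <- extract_keypoints(frontal, n_octaves = config$features$n_octaves,
                            contrast_threshold = config$features$contrast_threshold)
    kl <- extract_keypoints(lateral, n_octaves = config$features$n_octaves,
                            contrast_threshold = config$features$contrast_threshold)
    m <- match_keypoints(kf, kl, config$features$ratio_threshold)
    attr(m, "frontal_points") <- kf$points
    attr(m, "lateral_points") <- kl$points
    m
  })
  res$landmarks <- run_stage("depth",
    find_depth_landmarks(lateral, res$iris, config$depth$chord_tolerance,
                         config$depth$mode))
  res$transform <- run_stage("reconstruct", {
    m <- res$matches
    use_matches <- !is.null(m) && nrow(m) >= config$pipeline$min_matches
    if (!use_matches) {
      res$qc_flags <- c(res$qc_flags,
                        if (is.null(m) || nrow(m) < config$pipeline$min_matches) "low_matches",
                        "geometric_alignment")
      lm <- iris_landmarks(res$iris)
      fr <- rbind(c(lm$center[2], lm$center[1]),
                  c(lm$limbus_points["top", 2], lm$limbus_points["top", 1]),
                  c(lm$limbus_points["bottom", 2], lm$limbus_points["bottom", 1]))
      la <- rbind(c(res$landmarks$C[2], res$landmarks$C[1]),
                  c(res$landmarks$p2[2], res$landmarks$p2[1]),
                  c(res$landmarks$p3[2], res$landmarks$p3[1]))
      estimate_transform(NULL, fr, la)
    } else {
      fp <- attr(m, "frontal_points"); lp <- attr(m, "lateral_points")
      estimate_transform(m, cbind(fp$col, fp$row), cbind(lp$col, lp$row))
    }
  })
  res$volume <- run_stage("reconstruct", {
    fused <- revolve_profile(res$iris, res$landmarks, res$transform)
    rasterize_volume(fused, rep(config$reconstruct$volume_edge, 3),
                     config$reconstruct$smoothing_sigma)
  })
  res$staging <- run_stage("curvature", {
    st <- stage_from_landmarks(res$landmarks, res$iris,
                               config$curvature$cone_depth_ratio)
    guard <- config$curvature$boundary_guard_deg
    if (min(abs(st$steepness_deg - c(45, 52))) < guard)
      res$qc_flags <- c(res$qc_flags, "boundary_adjacent_angle")
    st
  })
  res$stage_geometric <- if (!is.null(res$staging)) res$staging$stage_result$stage else NA_character_
  if (!is.null(model)) {
    res$stage_cnn <- run_stage("classifier", {
      v <- preprocess_volume(res$volume, model$config)
      cnn_predict(model, v)$label
    })
    if (isTRUE(config$pipeline$cnn_gates_staging) && !is.null(res$stage_cnn) &&
        res$stage_cnn == "normal")
      res$stage_geometric <- "normal"
  } else res$stage_cnn <- NA_character_
  res
}

#' @export
print.case_result <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("case %s: FAILED at stage '%s': %s\n", x$case_id, x$failed_stage, x$error))
  } else {
    cat(sprintf("case %s: stage %s (steepness %.1f deg, depth %.1f px)%s\n",
                x$case_id, x$stage_geometric, x$staging$steepness_deg,
                x$landmarks$d,
                if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]") else ""))
  }
  invisible(x)
}

# Surface samples of the cornea as a solid of revolution: the lateral
# profile (elevation vs distance from the corneal axis) swept around the
# frontal iris disc, expressed as fused 3D points in the frontal frame.
revolve_profile <- function(iris, landmarks, transform, n_radial = 12L, n_azimuth = 16L) {
  chord_col <- (landmarks$p2[2] + landmarks$p3[2]) / 2
  mid_row <- (landmarks$p2[1] + landmarks$p3[1]) / 2
  arc <- landmarks$contour[landmarks$contour[, 2] >= chord_col - 0.5, , drop = FALSE]
  rho_samp <- abs(arc[, 1] - mid_row)
  z_samp <- pmax(arc[, 2] - chord_col, 0)
  rr <- seq(0, iris$r, length.out = n_radial)
  zz <- vapply(rr, function(r0) {
    w <- which(abs(rho_samp - r0) <= 1.5)
    if (length(w) == 0) 0 else max(z_samp[w])
  }, 0)
  th <- seq(0, 2 * pi, length.out = n_azimuth + 1)[-(n_azimuth + 1)]
  pts <- do.call(rbind, lapply(seq_along(rr), function(i) {
    if (i == 1) return(cbind(x = iris$m, y = iris$n, z = zz[1]))
    cbind(x = iris$m + rr[i] * cos(th), y = iris$n + rr[i] * sin(th), z = zz[i])
  }))
  # express as fused points: frontal (x, y); lateral abscissa = chord + z
  fuse_points(cbind(pts[, "x"], pts[, "y"]),
              cbind(chord_col + pts[, "z"], mid_row + (pts[, "y"] - iris$n)),
              transform)
}

#' Run the pipeline over a cohort
#'
#' Accepts either a `kerato_cohort` (in-memory phantoms) or the path of a
#' manifest CSV (columns `case_id`, `stage`, `frontal_file`,
#' `lateral_file`). Failing cases are reported as error rows; the batch
#' continues. When truth labels are available a confusion matrix against
#' the geometric stage is attached.
#'
#' @param cohort A `kerato_cohort` or manifest CSV path.
#' @param config A [kerato_config()].
#' @param model Optional trained CNN.
#' @param verbose Print one line per case.
#' @return List with `results` (data frame), `case_results` (list),
#'   `confusion` (or `NULL`), and `accuracy` (geometric staging accuracy,
#'   percent, over non-failed cases with truth).
#' @export
run_cohort <- function(cohort, config = kerato_config(), model = NULL,
                       verbose = FALSE) {
  if (is.character(cohort)) {
    man <- read.csv(cohort, stringsAsFactors = FALSE)
    cases <- lapply(seq_len(nrow(man)), function(i) {
      list(case_id = man$case_id[i], stage = man$stage[i],
           frontal = man$frontal_file[i], lateral = man$lateral_file[i])
    })
  } else {
    cases <- cohort$cases
  }
  out <- vector("list", length(cases))
  rows <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    cr <- tryCatch(run_case(cs$frontal, cs$lateral, config, model,
                            case_id = cs$case_id),
                   error = function(e) structure(
                     list(case_id = cs$case_id, error = conditionMessage(e),
                          failed_stage = "io", qc_flags = character(0)),
                     class = "case_result"))
    out[[i]] <- cr
    ok <- is.null(cr$error)
    rows[[i]] <- data.frame(
      case_id = cs$case_id,
      true_stage = if (!is.null(cs$stage)) cs$stage else NA_character_,
      pred_stage = if (ok) cr$stage_geometric else NA_character_,
      pred_stage_cnn = if (ok && !is.null(cr$stage_cnn)) cr$stage_cnn else NA_character_,
      steepness_deg = if (ok) cr$staging$steepness_deg else NA_real_,
      theta_deg = if (ok) cr$staging$triangle$theta_deg else NA_real_,
      angle_of_curvature_deg = if (ok) cr$staging$triangle$angle_of_curvature_deg else NA_real_,
      depth_px = if (ok) cr$landmarks$d else NA_real_,
      iris_row = if (ok) cr$iris$n else NA_real_,
      iris_col = if (ok) cr$iris$m else NA_real_,
      iris_radius = if (ok) cr$iris$r else NA_real_,
      qc_flags = paste(cr$qc_flags, collapse = ";"),
      error = if (ok) "" else cr$error,
      failed_stage = if (ok) "" else cr$failed_stage,
      stringsAsFactors = FALSE)
    if (verbose) print(cr)
  }
  results <- do.call(rbind, rows)
  cm <- NULL; acc <- NA_real_
  okrows <- !is.na(results$pred_stage) & !is.na(results$true_stage)
  if (any(okrows)) {
    cm <- confusion(results$true_stage[okrows], results$pred_stage[okrows])
    acc <- 100 * mean(results$pred_stage[okrows] == results$true_stage[okrows])
  }
  list(results = results, case_results = out, confusion = cm, accuracy = acc)
}

#' Write cohort results to disk
#'
#' Emits the per-case results CSV, the confusion-matrix CSV and a metrics
#' JSON. Numeric columns are formatted with fixed precision so identical
#' runs produce byte-identical files.
#'
#' @param run A [run_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- run$results
  num <- vapply(res, is.numeric, TRUE)
  res[num] <- lapply(res[num], function(x) sprintf("%.4f", x))
  paths <- file.path(dir, c("results.csv", "confusion.csv", "metrics.json"))
  write.csv(res, paths[1], row.names = FALSE)
  if (!is.null(run$confusion))
    write.csv(run$confusion$counts, paths[2])
  jsonlite::write_json(list(staging_accuracy_pct = run$accuracy,
                            n_cases = nrow(run$results),
                            n_failed = sum(nzchar(run$results$error))),
                       paths[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
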