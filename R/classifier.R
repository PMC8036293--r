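#' 3D CNN configuration
#'
#' Describes the volumetric classifier: four 3x3x3 convolution blocks with
#' 96, 128, 256 and 512 kernels, each followed by a 2x2x2 max pool, then
#' two fully connected layers of width 1000 and a 4-class softmax; trained
#' with plain stochastic gradient descent, batch size 32, learning rate
#' 0.01, for up to 30 epochs. The cubic input edge is configurable (64 by
#' default -- a desk-scale setting; the layer topology is independent of
#' it) and validated against the conv/pool shape arithmetic: each valid
#' convolution removes 2 voxels per axis and each pool halves (floor), and
#' every intermediate extent must stay positive.
#'
#' @param input_edge Cubic input edge, voxels.
#' @param conv_channels Four convolution channel counts.
#' @param fc_width Fully connected layer width.
#' @param n_classes Number of output classes.
#' @param batch_size,learning_rate,epochs SGD hyperparameters.
#' @param early_stop_loss Training stops before `epochs` once an epoch's
#'   running training accuracy reaches 100% with mean loss at or below this
#'   value (set `NA` to disable and always run all epochs).
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A `cnn_config` with the per-layer output edges in `layer_edges`.
#' @export
cnn_config <- function(input_edge = 64L, conv_channels = c(96L, 128L, 256L, 512L),
                       fc_width = 1000L, n_classes = 4L, batch_size = 32L,
                       learning_rate = 0.01, epochs = 30L,
                       early_stop_loss = 0.25, seed = 1L) {
  if (length(conv_channels) != 4)
    kerato_error("conv_channels must have length 4", "kerato3d_config_error")
  edges <- tryCatch(as.vector(cnn_shapes_cpp(as.integer(input_edge))),
                    error = function(e) kerato_error(conditionMessage(e),
                                                     "kerato3d_config_error"))
  structure(list(input_edge = as.integer(input_edge),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = c(3L, 3L, 3L), pool_kernel = c(2L, 2L, 2L),
                 fc_width = as.integer(fc_width), n_classes = as.integer(n_classes),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 early_stop_loss = early_stop_loss, seed = as.integer(seed),
                 layer_edges = edges),
            class = "cnn_config")
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf("3D CNN config: input %d^3, conv channels (%s), fc %d, %d classes\n",
              x$input_edge, paste(x$conv_channels, collapse = ", "),
              x$fc_width, x$n_classes))
  cat(sprintf("  conv/pool edges: %s\n", paste(x$layer_edges, collapse = " -> ")))
  cat(sprintf("  SGD: batch %d, lr %g, max %d epochs\n",
              x$batch_size, x$learning_rate, x$epochs))
  invisible(x)
}

cnn_flat_features <- function(cfg) {
  tail_edge <- cfg$layer_edges[8]
  tail_edge^3 * cfg$conv_channels[4]
}

#' Build (initialise) the 3D CNN
#'
#' He-normal initialisation, fully determined by `cfg$seed`. The parameter
#' count is a pure function of the configuration and is stored on the
#' model.
#'
#' @param cfg A [cnn_config()].
#' @param class_labels Class labels in output order (ties in prediction
#'   break towards the earlier label).
#' @return A `kerato_cnn`: list with `config`, `weights`, `class_labels`,
#'   `n_parameters`, `history`.
#' @export
cnn_build <- function(cfg, class_labels = stage_levels()) {
  stopifnot(inherits(cfg, "cnn_config"))
  if (length(class_labels) != cfg$n_classes)
    kerato_error("class_labels length must equal n_classes", "kerato3d_config_error")
  weights <- with_seed(cfg$seed, {
    w <- list()
    cin <- 1L
    for (l in 1:4) {
      cout <- cfg$conv_channels[l]
      fan_in <- 27 * cin
      w[[length(w) + 1L]] <- matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
                                    fan_in, cout)
      w[[length(w) + 1L]] <- numeric(cout)
      cin <- cout
    }
    sizes <- c(cnn_flat_features(cfg), cfg$fc_width, cfg$fc_width, cfg$n_classes)
    for (l in 1:3) {
      fan_in <- sizes[l]
      # He for the ReLU layers; a small-variance softmax layer keeps the
      # initial logits near zero and the first SGD steps well-conditioned
      sdev <- if (l < 3) sqrt(2 / fan_in) else 0.01 / sqrt(fan_in)
      w[[length(w) + 1L]] <- matrix(rnorm(sizes[l + 1] * fan_in, sd = sdev),
                                    sizes[l + 1], fan_in)
      w[[length(w) + 1L]] <- numeric(sizes[l + 1])
    }
    w
  })
  n_par <- sum(vapply(weights, length, 0L))
  structure(list(config = cfg, weights = weights, class_labels = class_labels,
                 n_parameters = n_par, history = NULL),
            class = "kerato_cnn")
}

#' @export
print.kerato_cnn <- function(x, ...) {
  cat(sprintf("kerato_cnn: %s classes (%s), %s parameters%s\n",
              x$config$n_classes, paste(x$class_labels, collapse = ", "),
              format(x$n_parameters, big.mark = ","),
              if (is.null(x$history)) " [untrained]"
              else sprintf(", trained %d epochs (final acc %.1f%%)",
                           nrow(x$history), 100 * x$history$accuracy[nrow(x$history)])))
  invisible(x)
}

#' Preprocess a corneal volume for classification
#'
#' Normalises volumes to a common spatial frame: the tight bounding box of
#' supra-threshold voxels (the cornea ROI) is cropped with a 10% pad,
#' resampled trilinearly and *isotropically* -- one scale factor, set by
#' the longest box axis, with the remaining axes centre-padded -- to
#' `input_edge^3`, smoothed with a 3D Gaussian filter (sigma 1 voxel) and
#' linearly rescaled to `[0, 1]`. Isotropic resampling preserves the
#' corneal aspect ratio, so a flat cap and a tall cone remain
#' distinguishable after normalisation. Constant volumes pass through
#' unchanged (the filter has unit DC gain) and empty (all-zero) volumes
#' are rejected.
#'
#' @param v 3D numeric array.
#' @param cfg A [cnn_config()].
#' @param roi_threshold Fraction of the maximum intensity defining the ROI.
#' @param filter_sigma Gaussian sigma in voxels.
#' @return `input_edge^3` array in `[0, 1]`.
#' @export
preprocess_volume <- function(v, cfg, roi_threshold = 0.05, filter_sigma = 1) {
  if (max(v) <= 0) kerato_error("empty ROI: volume has no intensity", "kerato3d_config_error")
  if (max(v) - min(v) < 1e-12) return(resample_volume(v, rep(cfg$input_edge, 3)))
  occ <- which(v > roi_threshold * max(v), arr.ind = TRUE)
  if (nrow(occ) == 0) kerato_error("empty ROI", "kerato3d_config_error")
  d <- dim(v)
  lo <- apply(occ, 2, min); hi <- apply(occ, 2, max)
  pad <- pmax(1, round(0.1 * (hi - lo + 1)))
  lo <- pmax(1, lo - pad); hi <- pmin(d, hi + pad)
  crop <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  scale <- cfg$input_edge / max(dim(crop))
  new_dims <- pmax(1L, pmin(cfg$input_edge, as.integer(round(dim(crop) * scale))))
  iso <- resample_volume(crop, new_dims)
  out <- array(0, rep(cfg$input_edge, 3))
  off <- floor((rep(cfg$input_edge, 3) - new_dims) / 2)
  out[off[1] + seq_len(new_dims[1]), off[2] + seq_len(new_dims[2]),
      off[3] + seq_len(new_dims[3])] <- iso
  out <- gaussian_blur3d(out, filter_sigma)
  mx <- max(out)
  if (mx > 0) out / mx else out
}

#' Train the 3D CNN
#'
#' Minimises cross-entropy with plain mini-batch SGD at the configured
#' batch size and learning rate. All randomness (visit order per epoch)
#' flows through R's RNG seeded from the config, so identical calls yield
#' identical loss trajectories. Training runs at most `cfg$epochs` epochs,
#' stopping earlier once the running training accuracy reaches 100% with
#' mean loss at or below `cfg$early_stop_loss`.
#'
#' @param model A [cnn_build()] model.
#' @param volumes List of preprocessed `input_edge^3` arrays.
#' @param labels Vector/factor of class labels; all classes must be
#'   represented.
#' @return The model with updated weights and a `history` data frame
#'   (`epoch`, `loss`, `accuracy`).
#' @export
cnn_train <- function(model, volumes, labels) {
  stopifnot(inherits(model, "kerato_cnn"))
  cfg <- model$config
  n <- length(volumes)
  if (n < 8) kerato_error("need at least 8 labelled volumes", "kerato3d_config_error")
  y <- match(as.character(labels), model$class_labels) - 1L
  if (any(is.na(y))) kerato_error("labels outside the model's class set", "kerato3d_config_error")
  if (length(unique(y)) < cfg$n_classes)
    kerato_error("every class must be present in the training set", "kerato3d_config_error")
  order_mat <- with_seed(cfg$seed + 1L,
    vapply(seq_len(cfg$epochs), function(e) sample.int(n) - 1L, integer(n)))
  X <- lapply(volumes, function(v) as.numeric(v))
  res <- cnn_train_cpp(model$weights, X, as.integer(y), cfg$input_edge,
                       cfg$conv_channels, cfg$fc_width, cfg$n_classes,
                       cfg$learning_rate, cfg$batch_size, cfg$epochs,
                       order_mat, !is.na(cfg$early_stop_loss),
                       ifelse(is.na(cfg$early_stop_loss), 0, cfg$early_stop_loss))
  ran <- seq_len(res$epochs_run)
  model$weights <- res$weights
  model$history <- data.frame(epoch = ran, loss = res$loss[ran],
                              accuracy = res$accuracy[ran])
  model
}

#' Classify a corneal volume
#'
#' @param model A trained (or untrained) `kerato_cnn`.
#' @param volume Preprocessed `input_edge^3` array.
#' @return List with `probabilities` (named, summing to 1) and `label`
#'   (arg-max; ties break towards the earlier class label).
#' @export
cnn_predict <- function(model, volume) {
  cfg <- model$config
  if (!identical(as.integer(dim(volume)), rep(cfg$input_edge, 3L)))
    kerato_error(sprintf("volume must be %d^3 (got %s)", cfg$input_edge,
                         paste(dim(volume), collapse = "x")), "kerato3d_config_error")
  p <- cnn_forward_cpp(model$weights, as.numeric(volume), cfg$input_edge,
                       cfg$conv_channels, cfg$fc_width, cfg$n_classes)
  names(p) <- model$class_labels
  list(probabilities = p, label = model$class_labels[which.max(p)])
}
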