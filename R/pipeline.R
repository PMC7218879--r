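#' Flatten a pose into a feature vector
#'
#' Joint-major flattening (x, y, z per joint): a J-joint pose becomes a
#' length-`3J` vector, the network's input layout. Invertible via
#' [feature_to_pose()].
#'
#' @param p a `J x 3` pose matrix.
#' @return numeric vector of length `3J`.
#' @export
pose_to_feature <- function(p) {
  p <- pose(p)
  as.vector(t(p))
}

#' Rebuild a pose from a feature vector
#'
#' @param v numeric vector of length `3J` in joint-major order.
#' @return a `J x 3` pose matrix.
#' @export
feature_to_pose <- function(v) {
  if (length(v) %% 3L != 0L) stop("feature length must be a multiple of 3")
  pose(matrix(v, ncol = 3L, byrow = TRUE))
}

# Per-feature z-scoring fitted on training frames. Raw joint coordinates
# can be tens of centimetres, which would saturate the sigmoid units
# under the +-0.1 weight initialisation; standardisation keeps the
# pre-activations in the responsive range. Constant features get scale 1.
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  sc <- apply(X, 2L, stats::sd)
  sc[!is.finite(sc) | sc < 1e-12] <- 1
  list(center = as.numeric(ctr), scale = as.numeric(sc))
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

#' Train an action-recognition model on labelled motions
#'
#' Normalizes every training motion, builds the per-frame labelled
#' feature matrix (all frames by default; keyframes only if
#' `train_on_keyframes`), fits the per-feature z-scaler, and trains the
#' network. Feeding the network all normalized frames follows the
#' training workflow in which keyframe extraction belongs to the testing
#' phase; `train_on_keyframes = TRUE` covers the alternative reading.
#'
#' @param ds a `motion_dataset`.
#' @param config a [net_config()]; `output_dim` is forced to the number
#'   of dataset classes and `input_dim` to `3J`.
#' @param ncfg a [norm_config()].
#' @param normalize normalize motions before feature extraction
#'   (default `TRUE`; `FALSE` exists to quantify what normalization
#'   buys).
#' @param train_on_keyframes train on extracted keyframes only.
#' @param threshold keyframe threshold when `train_on_keyframes`.
#' @return an `action_model`: `params`, `net_config`, `norm_config`,
#'   `scaler`, `normalize`, `report`.
#' @export
train_action_model <- function(ds, config = NULL, ncfg = norm_config(),
                               normalize = TRUE,
                               train_on_keyframes = FALSE, threshold = 30) {
  stopifnot(inherits(ds, "motion_dataset"))
  J <- n_joints(ds$motions[[1L]])
  R <- length(ds$classes)
  if (is.null(config)) config <- net_config(input_dim = 3L * J, output_dim = R)
  config$input_dim <- as.integer(3L * J)
  config$output_dim <- as.integer(R)
  blocks <- lapply(ds$motions, function(m) {
    mm <- if (normalize) normalize_motion(m, ncfg) else m
    F <- mm$frames
    if (train_on_keyframes) {
      kf <- extract_keyframes(mm, threshold = threshold)$keyframes
      F <- F[kf, , drop = FALSE]
    }
    list(F = F, y = rep(match(m$label, ds$classes), nrow(F)))
  })
  X <- do.call(rbind, lapply(blocks, `[[`, "F"))
  y <- unlist(lapply(blocks, `[[`, "y"))
  scaler <- fit_scaler(X)
  fit <- train_network(apply_scaler(X, scaler), y, config,
                       class_names = ds$classes)
  structure(list(params = fit$params, net_config = config,
                 norm_config = ncfg, scaler = scaler,
                 normalize = normalize, report = fit$report),
            class = "action_model")
}

#' @export
print.action_model <- function(x, ...) {
  cfg <- x$net_config
  cat(sprintf(
    "<action_model>  %d-%d-%d-%d network, classes: %s\n  trained %s epochs (stop: %s)\n",
    cfg$input_dim, cfg$hidden1, cfg$hidden2, cfg$output_dim,
    paste(x$params$class_names, collapse = ", "),
    if (is.null(x$report)) "?" else x$report$epochs_run,
    if (is.null(x$report)) "?" else x$report$stop_reason))
  invisible(x)
}

#' Classify a motion by per-frame majority vote
#'
#' Normalizes the (raw) motion, optionally summarises it to keyframes,
#' scores every retained frame with the network, and lets each frame
#' vote for its argmax class. The predicted class is the majority vote;
#' a vote tie is broken by the larger summed probability, then by the
#' lower class index, and flagged in `tie_broken`.
#'
#' @param model an `action_model`.
#' @param m a raw (unnormalized) `motion`.
#' @param use_keyframes score only extracted keyframes (default `TRUE`).
#' @param threshold keyframe threshold.
#' @return an `action_prediction`: `frame_votes` (per scored frame,
#'   1-based class indices), `prob_sums` (named per-class summed
#'   probabilities), `predicted_class`, `tie_broken`, `scored_frames`
#'   (indices into the original motion).
#' @export
classify_motion <- function(model, m, use_keyframes = TRUE, threshold = 30) {
  stopifnot(inherits(model, "action_model"), inherits(m, "motion"))
  mm <- if (isTRUE(model$normalize)) normalize_motion(m, model$norm_config)
        else m
  idx <- seq_len(n_frames(mm))
  if (use_keyframes)
    idx <- extract_keyframes(mm, threshold = threshold)$keyframes
  F <- mm$frames[idx, , drop = FALSE]
  if (ncol(F) != model$net_config$input_dim)
    stop("motion joint count does not match the trained network")
  O <- forward_batch(model$params, apply_scaler(F, model$scaler))$o
  votes <- max.col(O, ties.method = "first")
  prob_sums <- colSums(O)
  names(prob_sums) <- model$params$class_names
  counts <- tabulate(votes, nbins = ncol(O))
  top <- which(counts == max(counts))
  tie_broken <- FALSE
  if (length(top) > 1L) {
    tie_broken <- TRUE
    best <- top[prob_sums[top] == max(prob_sums[top])]
    top <- best[1L]                      # lowest class index last resort
  }
  structure(list(frame_votes = votes, prob_sums = prob_sums,
                 predicted_class = model$params$class_names[top],
                 predicted_index = as.integer(top),
                 tie_broken = tie_broken,
                 scored_frames = idx),
            class = "action_prediction")
}

#' @export
print.action_prediction <- function(x, ...) {
  cat(sprintf("<action_prediction>  '%s' (%d/%d votes%s)\n",
              x$predicted_class,
              sum(x$frame_votes == x$predicted_index),
              length(x$frame_votes),
              if (x$tie_broken) ", tie broken" else ""))
  invisible(x)
}

#' Stratified k-fold split of a dataset
#'
#' Shuffles each class's motions under the seed and deals them
#' round-robin to folds, so fold class counts are balanced within one.
#'
#' @param ds a `motion_dataset`.
#' @param folds number of folds (default 5).
#' @param seed RNG seed for the per-class shuffles.
#' @return list of `folds` elements, each `list(train, test)` of motion
#'   indices into `ds$motions`; the test sets partition the dataset.
#' @export
stratified_kfold <- function(ds, folds = 5L, seed = 1L) {
  stopifnot(inherits(ds, "motion_dataset"))
  labs <- dataset_labels(ds)
  counts <- table(factor(labs, levels = ds$classes))
  if (any(counts < folds))
    stop("every class needs at least ", folds, " motions; smallest has ",
         min(counts))
  assign <- integer(length(labs))
  with_seed(seed, {
    for (cl in ds$classes) {
      idx <- sample(which(labs == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  lapply(seq_len(folds), function(f)
    list(train = which(assign != f), test = which(assign == f)))
}

#' Cross-validate the full recognition pipeline
#'
#' For each fold: train an [train_action_model()] on the training
#' motions, classify every test motion with [classify_motion()], and
#' tally motion-level accuracy and confusion counts (rows = true class).
#' Accuracy is correctly classified motions over test motions; both the
#' fold-mean and the pooled (all test motions together) accuracy are
#' reported.
#'
#' @param ds a `motion_dataset`.
#' @param config a [net_config()] (default: reference architecture).
#' @param ncfg a [norm_config()].
#' @param use_keyframes score test motions on keyframes (default `TRUE`).
#' @param threshold keyframe threshold.
#' @param train_on_keyframes train on keyframes instead of all frames.
#' @param normalize normalize motions (disable to measure the cost of
#'   skipping normalization).
#' @param folds number of folds (default 5).
#' @param seed seed for the fold split and per-fold training.
#' @return a `crossval_report`: `fold_accuracies`, `mean_accuracy`,
#'   `pooled_accuracy`, `confusion_matrix`, `folds`, `seed`.
#' @export
cross_validate <- function(ds, config = NULL, ncfg = norm_config(),
                           use_keyframes = TRUE, threshold = 30,
                           train_on_keyframes = FALSE, normalize = TRUE,
                           folds = 5L, seed = 1L) {
  stopifnot(inherits(ds, "motion_dataset"))
  split <- stratified_kfold(ds, folds = folds, seed = seed)
  R <- length(ds$classes)
  if (is.null(config))
    config <- net_config(input_dim = 3L * n_joints(ds$motions[[1L]]),
                         output_dim = R)
  confusion <- matrix(0L, R, R, dimnames = list(true = ds$classes,
                                                predicted = ds$classes))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr_ds <- motion_dataset(ds$motions[split[[f]]$train], classes = ds$classes)
    cfg <- config
    cfg$seed <- derive_seed(seed, 100L + f)
    model <- train_action_model(tr_ds, config = cfg, ncfg = ncfg,
                                normalize = normalize,
                                train_on_keyframes = train_on_keyframes,
                                threshold = threshold)
    correct <- 0L
    for (i in split[[f]]$test) {
      m <- ds$motions[[i]]
      pred <- classify_motion(model, m, use_keyframes = use_keyframes,
                              threshold = threshold)
      ti <- match(m$label, ds$classes)
      pi <- pred$predicted_index
      confusion[ti, pi] <- confusion[ti, pi] + 1L
      if (pi == ti) correct <- correct + 1L
    }
    fold_acc[f] <- correct / length(split[[f]]$test)
  }
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 pooled_accuracy = sum(diag(confusion)) / sum(confusion),
                 confusion_matrix = confusion,
                 folds = folds, seed = seed),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf(
    "<crossval_report>  %d folds, mean accuracy %.4f (pooled %.4f)\n  folds: %s\n",
    x$folds, x$mean_accuracy, x$pooled_accuracy,
    paste(sprintf("%.4f", x$fold_accuracies), collapse = " ")))
  invisible(x)
}
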