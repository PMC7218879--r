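#' @title Motion CSV dialect and dataset layout
#' @description
#' Motions are persisted in a flat, diff-able CSV dialect: line 1 is the
#' header `j00_x,j00_y,j00_z,...`, line 2 the comment `# fps=<float>`,
#' and every following line one frame of comma-separated decimal floats
#' (UTF-8, LF newlines). Coordinates are written with 17 significant
#' digits so that a write/read round trip reproduces every double
#' exactly. A labelled dataset is a directory tree
#' `<root>/<class_label>/<motion_id>.csv`; class vocabulary order is
#' lexicographic. Coordinates are stored in dataset-native units and
#' never rescaled — the keyframe threshold is interpreted in those same
#' units.
#' @name mocap-io
NULL

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a motion from CSV
#'
#' @param path path to a motion CSV file (see [mocap-io]).
#' @return a `motion`; `motion_id` is the file name without extension,
#'   `fps` comes from the comment line (default 120 if absent).
#' @export
read_motion_csv <- function(path) {
  if (!file.exists(path)) stop("no such motion file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty motion file: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(header) %% 3L != 0L)
    stop("malformed header in ", path, ": ", length(header),
         " columns, not divisible by 3")
  J <- length(header) %/% 3L
  if (!identical(trimws(header), joint_colnames(J)))
    stop("malformed header in ", path,
         ": expected joint-coordinate names j00_x,j00_y,j00_z,...")
  fps <- 120
  body_start <- 2L
  if (length(lines) >= 2L && startsWith(lines[2L], "#")) {
    fm <- regmatches(lines[2L],
                     regexec("^#\\s*fps=([0-9eE.+-]+)\\s*$", lines[2L]))[[1L]]
    if (length(fm) != 2L)
      stop("malformed comment line in ", path, " (expected '# fps=<float>')")
    fps <- as.numeric(fm[2L])
    if (!is.finite(fps) || fps <= 0)
      stop("invalid fps in ", path, ": ", fm[2L])
    body_start <- 3L
  }
  body <- lines[seq.int(body_start, length.out = max(0L, length(lines) - body_start + 1L))]
  body <- body[nzchar(body)]
  if (length(body) == 0L) stop("motion file has no data rows: ", path)
  rows <- strsplit(body, ",", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != 3L * J)) {
    bad <- which(nc != 3L * J)[1L]
    stop("row ", bad, " of ", path, " has ", nc[bad],
         " columns, expected ", 3L * J)
  }
  F <- matrix(NA_real_, length(rows), 3L * J)
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("non-numeric cell at row ", i, ", column ", j, " of ", path)
    }
    F[i, ] <- v
  }
  motion(F, fps = fps,
         motion_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a motion to CSV
#'
#' Emits the dialect described in [mocap-io] exactly; reading the file
#' back reproduces the motion with bit-identical coordinates.
#'
#' @param m a `motion`.
#' @param path destination path.
#' @export
write_motion_csv <- function(m, path) {
  stopifnot(inherits(m, "motion"))
  if (!all(is.finite(m$frames)))
    stop("motion contains non-finite coordinates; nothing written")
  J <- n_joints(m)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(joint_colnames(J), collapse = ","),
               sprintf("# fps=%.17g", m$fps),
               apply(m$frames, 1L, function(r)
                 paste(fmt_num(r), collapse = ","))),
             con, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}

#' Load a labelled dataset directory
#'
#' Expects `<root>/<class_label>/<motion_id>.csv`; classes are the
#' sorted subdirectory names, and every motion is labelled by its parent
#' directory. Deterministic: the same directory always yields the same
#' class and motion ordering (lexicographic).
#'
#' @param root_dir dataset root directory.
#' @return a `motion_dataset`.
#' @export
load_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stop("no such dataset directory: ", root_dir)
  classes <- sort(list.dirs(root_dir, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L)
    stop("dataset directory has no class subdirectories: ", root_dir)
  motions <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(root_dir, cl), pattern = "\\.csv$",
                             full.names = TRUE))
    for (f in files) {
      m <- read_motion_csv(f)
      m$label <- cl
      motions[[length(motions) + 1L]] <- m
    }
  }
  if (length(motions) == 0L)
    stop("dataset directory contains no motion CSV files: ", root_dir)
  motion_dataset(motions, classes = classes)
}

#' Write a dataset to a directory tree
#'
#' Inverse of [load_dataset()]: writes each motion to
#' `<root>/<label>/<motion_id>.csv`.
#'
#' @param ds a `motion_dataset`.
#' @param root_dir destination root (created if missing).
#' @export
write_dataset <- function(ds, root_dir) {
  stopifnot(inherits(ds, "motion_dataset"))
  for (m in ds$motions) {
    d <- file.path(root_dir, m$label)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_motion_csv(m, file.path(d, paste0(m$motion_id, ".csv")))
  }
  invisible(NULL)
}

#' Persist a keyframe extraction result as JSON
#'
#' The file stores 0-based frame indices (keys `keyframes`,
#' `selection_order`, `candidate_sets`) together with `motion_id`, `n`,
#' `threshold`, `k` and `k_policy`; [read_keyframe_index()] restores the
#' 1-based in-memory object losslessly.
#'
#' @param result a `keyframe_result` from [extract_keyframes()].
#' @param path destination path.
#' @export
write_keyframe_index <- function(result, path) {
  stopifnot(inherits(result, "keyframe_result"))
  obj <- list(motion_id = result$motion_id, n = result$n,
              threshold = result$threshold, k = result$k_initial,
              k_policy = result$k_policy,
              keyframes = as.integer(result$keyframes) - 1L,
              selection_order = as.integer(result$selection_order) - 1L,
              candidate_sets = lapply(result$candidate_sets,
                                      function(s) as.integer(s) - 1L))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(NULL)
}

#' Read a keyframe extraction result from JSON
#'
#' @param path path written by [write_keyframe_index()].
#' @return a `keyframe_result` (1-based indices).
#' @export
read_keyframe_index <- function(path) {
  if (!file.exists(path)) stop("no such keyframe index file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(obj$n)
  cs <- obj$candidate_sets
  if (is.matrix(cs)) cs <- split(cs, row(cs))        # uniform-length sets
  cs <- lapply(cs, function(s) as.integer(s) + 1L)
  kf <- as.integer(obj$keyframes) + 1L
  sel <- if (!is.null(obj$selection_order))
    as.integer(obj$selection_order) + 1L else kf
  all_idx <- c(kf, sel, unlist(cs))
  if (any(all_idx < 1L | all_idx > n))
    stop("keyframe index file references frames outside [0, ", n, "): ", path)
  structure(list(keyframes = kf, selection_order = sel,
                 candidate_sets = cs,
                 threshold = as.numeric(obj$threshold),
                 k_initial = as.integer(obj$k),
                 k_policy = if (is.null(obj$k_policy)) "fixed" else obj$k_policy,
                 n = n, motion_id = obj$motion_id),
            class = "keyframe_result")
}

#' Persist a trained action model as JSON
#'
#' Stores layer sizes, the class vocabulary, the training seed, the
#' feature-scaling vectors, the normalization settings and all weight
#' matrices (bias rows included) at full precision.
#'
#' @param model an `action_model` from [train_action_model()].
#' @param path destination path.
#' @export
write_network <- function(model, path) {
  stopifnot(inherits(model, "action_model"))
  cfg <- model$net_config
  obj <- list(
    layer_sizes = c(cfg$input_dim, cfg$hidden1, cfg$hidden2, cfg$output_dim),
    classes = model$params$class_names,
    seed = cfg$seed,
    net_config = unclass(cfg),
    norm_config = unclass(model$norm_config),
    normalize = isTRUE(model$normalize),
    scaler = model$scaler,
    weights = list(w = model$params$w, w_prime = model$params$w_prime,
                   w_dprime = model$params$w_dprime))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(NULL)
}

#' Read a trained action model from JSON
#'
#' @param path path written by [write_network()].
#' @return an `action_model`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nc <- obj$net_config
  cfg <- net_config(input_dim = nc$input_dim, hidden1 = nc$hidden1,
                    hidden2 = nc$hidden2, output_dim = nc$output_dim,
                    learning_rate = nc$learning_rate,
                    max_epochs = nc$max_epochs,
                    min_gradient = nc$min_gradient, patience = nc$patience,
                    validation_fraction = nc$validation_fraction,
                    init_scale = nc$init_scale, batch_mode = nc$batch_mode,
                    seed = nc$seed)
  ncf <- obj$norm_config
  params <- structure(list(w = as.matrix(obj$weights$w),
                           w_prime = as.matrix(obj$weights$w_prime),
                           w_dprime = as.matrix(obj$weights$w_dprime),
                           class_names = obj$classes), class = "net_params")
  structure(list(
    params = params, net_config = cfg,
    norm_config = norm_config(ncf$root_index, ncf$left_hip_index,
                              ncf$right_hip_index, ncf$per_frame),
    scaler = list(center = as.numeric(obj$scaler$center),
                  scale = as.numeric(obj$scaler$scale)),
    normalize = if (is.null(obj$normalize)) TRUE else isTRUE(obj$normalize),
    report = NULL), class = "action_model")
}
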