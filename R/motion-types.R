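#' @title Motion-capture domain objects
#' @description
#' A *pose* is one frame of a skeleton: a `J x 3` numeric matrix of joint
#' positions (columns `x`, `y`, `z`; y points up; dataset-native length
#' units, centimetres by default). A *motion* is an ordered sequence of
#' poses sharing the same joint count, stored internally as an
#' `n x (3*J)` matrix in joint-major order (`j00_x, j00_y, j00_z, ...`),
#' plus a frame rate, an identifier and an optional class label.
#' @name motion-types
NULL

#' Construct a pose
#'
#' @param joints numeric `J x 3` matrix (or anything coercible) of joint
#'   positions, one row per joint, columns x/y/z.
#' @return a `J x 3` numeric matrix with columns named `x`, `y`, `z`.
#' @export
pose <- function(joints) {
  m <- as.matrix(joints)
  storage.mode(m) <- "double"
  if (ncol(m) != 3L)
    stop("a pose needs exactly 3 coordinate columns, got ", ncol(m))
  if (nrow(m) < 2L)
    stop("a pose needs J >= 2 joints (root plus at least one other)")
  if (!all(is.finite(m)))
    stop("pose contains non-finite coordinates")
  colnames(m) <- c("x", "y", "z")
  rownames(m) <- NULL
  m
}

#' Construct a motion
#'
#' @param frames either a list of poses (each `J x 3`) or an `n x (3*J)`
#'   numeric matrix in joint-major order.
#' @param fps frames per second (> 0).
#' @param motion_id identifier string.
#' @param label optional class-name string.
#' @return an object of class `motion` with elements `frames` (flat
#'   `n x 3J` matrix), `fps`, `motion_id`, `label`.
#' @export
motion <- function(frames, fps = 120, motion_id = "motion", label = NULL) {
  if (is.list(frames)) {
    frames <- lapply(frames, pose)
    J <- vapply(frames, nrow, integer(1))
    if (length(unique(J)) != 1L)
      stop("all frames of a motion must share the same joint count")
    frames <- do.call(rbind, lapply(frames, function(p) as.vector(t(p))))
  }
  m <- as.matrix(frames)
  storage.mode(m) <- "double"
  if (nrow(m) < 1L) stop("a motion needs at least one frame")
  if (ncol(m) %% 3L != 0L)
    stop("flat frame matrix must have 3*J columns, got ", ncol(m))
  if (ncol(m) < 6L) stop("a motion needs J >= 2 joints")
  if (!all(is.finite(m))) stop("motion contains non-finite coordinates")
  fps <- as.numeric(fps)
  if (length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("fps must be a single positive number")
  colnames(m) <- joint_colnames(ncol(m) %/% 3L)
  rownames(m) <- NULL
  structure(
    list(frames = m, fps = fps,
         motion_id = as.character(motion_id),
         label = if (is.null(label)) NULL else as.character(label)),
    class = "motion")
}

joint_colnames <- function(J) {
  as.vector(t(outer(sprintf("j%02d", seq_len(J) - 1L), c("x", "y", "z"),
                    paste, sep = "_")))
}

#' Number of frames in a motion
#' @param m a `motion`.
#' @export
n_frames <- function(m) nrow(m$frames)

#' Number of joints in a motion or pose
#' @param x a `motion` or a pose matrix.
#' @export
n_joints <- function(x) {
  if (inherits(x, "motion")) ncol(x$frames) %/% 3L else nrow(x)
}

#' Extract one frame of a motion as a pose
#' @param m a `motion`.
#' @param i frame index (1-based).
#' @return a `J x 3` pose matrix.
#' @export
motion_frame <- function(m, i) {
  stopifnot(inherits(m, "motion"))
  if (i < 1L || i > n_frames(m)) stop("frame index out of range")
  p <- matrix(m$frames[i, ], ncol = 3L, byrow = TRUE)
  colnames(p) <- c("x", "y", "z")
  p
}

#' @export
print.motion <- function(x, ...) {
  cat(sprintf("<motion '%s'>  %d frames, %d joints, %.6g fps%s\n",
              x$motion_id, n_frames(x), n_joints(x), x$fps,
              if (is.null(x$label)) "" else paste0(", label '", x$label, "'")))
  invisible(x)
}

#' Construct a labelled motion dataset
#'
#' @param motions list of labelled `motion` objects.
#' @param classes optional ordered class vocabulary; defaults to the sorted
#'   unique labels. Lexicographic ordering fixes the one-hot target indices.
#' @return an object of class `motion_dataset` with `motions` and `classes`.
#' @export
motion_dataset <- function(motions, classes = NULL) {
  if (length(motions) < 1L) stop("a dataset needs at least one motion")
  labs <- vapply(motions, function(m) {
    if (is.null(m$label)) stop("all motions in a dataset must be labelled")
    m$label
  }, character(1))
  if (is.null(classes)) classes <- sort(unique(labs))
  if (anyDuplicated(classes)) stop("class vocabulary has duplicates")
  if (!all(labs %in% classes))
    stop("motion label(s) not in class vocabulary: ",
         paste(setdiff(labs, classes), collapse = ", "))
  J <- vapply(motions, n_joints, integer(1))
  if (length(unique(J)) != 1L)
    stop("inconsistent joint counts across dataset motions")
  structure(list(motions = motions, classes = as.character(classes)),
            class = "motion_dataset")
}

#' @export
print.motion_dataset <- function(x, ...) {
  cat(sprintf("<motion_dataset>  %d motions, %d classes: %s\n",
              length(x$motions), length(x$classes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

dataset_labels <- function(ds) {
  vapply(ds$motions, function(m) m$label, character(1))
}
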