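#' Average per-joint Euclidean distance between two poses
#'
#' The pose similarity used throughout keyframe extraction:
#' `(1/J) * sum_j ||a_j - b_j||_2`. Symmetric, non-negative, zero exactly
#' when the poses coincide.
#'
#' @param a,b `J x 3` pose matrices with the same J.
#' @return a non-negative scalar.
#' @export
average_pose_distance <- function(a, b) {
  a <- pose(a); b <- pose(b)
  if (nrow(a) != nrow(b))
    stop("poses have different joint counts: ", nrow(a), " vs ", nrow(b))
  mean(sqrt(rowSums((a - b)^2)))
}

# Vectorised distances from one flat frame row to many flat frame rows.
# frames: m x 3J matrix, q: length-3J vector. Returns length-m vector of
# average per-joint Euclidean distances.
flat_frame_distances <- function(frames, q) {
  J <- length(q) %/% 3L
  d <- sweep(frames, 2L, q)^2
  i1 <- seq(1L, 3L * J, by = 3L)
  sq <- d[, i1, drop = FALSE] + d[, i1 + 1L, drop = FALSE] +
    d[, i1 + 2L, drop = FALSE]
  rowMeans(sqrt(sq))
}

#' Nearest neighbours of a frame within a pose collection
#'
#' Ranks frames of the collection by ascending [average_pose_distance()]
#' to the query frame. The query itself is eligible (distance 0, always
#' ranked first when present); distance ties are broken by ascending frame
#' index.
#'
#' @param frames an `n x 3J` flat frame matrix (e.g. `m$frames`) or a
#'   `motion`.
#' @param query_index 1-based index of the query frame within `subset`.
#' @param k number of neighbours requested (>= 0); capped at the
#'   collection size.
#' @param subset optional integer vector of frame indices forming the
#'   collection searched (default: all frames). `query_index` must be a
#'   member.
#' @param exclude_query drop the query itself from the ranking (used by
#'   [extract_keyframes()], where the query is pulled out of the
#'   collection before the search and rejoins the candidate set
#'   unconditionally). Default `FALSE`.
#' @return a list with `neighbor_indices` (frame indices, ascending by
#'   distance) and `distances` (matching, non-decreasing).
#' @export
find_nearest_neighbors <- function(frames, query_index, k, subset = NULL,
                                   exclude_query = FALSE) {
  if (inherits(frames, "motion")) frames <- frames$frames
  n <- nrow(frames)
  if (is.null(subset)) subset <- seq_len(n)
  if (!(query_index %in% subset))
    stop("query_index ", query_index, " not in the searched collection")
  if (k < 0L) stop("k must be >= 0")
  if (exclude_query) subset <- setdiff(subset, query_index)
  k_eff <- min(as.integer(k), length(subset))
  if (k_eff == 0L)
    return(list(neighbor_indices = integer(0), distances = numeric(0)))
  d <- flat_frame_distances(frames[subset, , drop = FALSE],
                            frames[query_index, ])
  ord <- order(d, subset)[seq_len(k_eff)]
  list(neighbor_indices = subset[ord], distances = d[ord])
}

#' Extract keyframes from a motion
#'
#' Iterative motion summarisation: while frames remain, take the
#' lowest-index remaining frame as the query, fetch its `k` nearest
#' neighbours among the remaining frames (the query included, at distance
#' 0), keep as the candidate set `Phi` those neighbours strictly closer
#' than `threshold`, sort `Phi` by frame index, select its lower-median
#' element as the keyframe, and discard all of `Phi`. The candidate sets
#' of successive iterations partition the frame set, so the loop
#' terminates in at most `n` iterations.
#'
#' `k` is fixed once to `floor(n/2)` — so the neighbour list can never
#' exceed the motion — and clamped each iteration to the number of
#' remaining frames. `k_policy = "adaptive"` instead recomputes
#' `floor(remaining/2)` every iteration.
#'
#' Distances are meaningful on normalized poses; the caller is expected
#' (but not forced) to pass a motion through [normalize_motion()] first.
#'
#' @param m a `motion`.
#' @param threshold positive distance threshold `t`, in the same units as
#'   the coordinates (default 30). Larger values merge more frames into
#'   each candidate set, i.e. stronger compression.
#' @param k_policy `"fixed"` (default) or `"adaptive"`, see above.
#' @return an object of class `keyframe_result`: `keyframes` (ascending
#'   1-based indices into the original motion — the temporal summary),
#'   `selection_order` (the same indices in iteration order, aligned with
#'   `candidate_sets`), `candidate_sets` (one ascending index set per
#'   iteration, in iteration order; the sets partition `1..n`),
#'   `threshold`, `k_initial`, `k_policy`, `n`, `motion_id`.
#' @export
extract_keyframes <- function(m, threshold = 30, k_policy = c("fixed", "adaptive")) {
  stopifnot(inherits(m, "motion"))
  k_policy <- match.arg(k_policy)
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be a positive number")
  F <- m$frames
  n <- nrow(F)
  k0 <- n %/% 2L
  remaining <- seq_len(n)
  keyframes <- integer(0)
  candidate_sets <- list()
  while (length(remaining) > 0L) {
    query <- remaining[1L]
    # the query is pulled out of the collection before the neighbour
    # search (so k counts true neighbours), then always rejoins Phi
    others <- remaining[-1L]
    k_eff <- if (k_policy == "fixed") min(k0, length(others))
             else length(remaining) %/% 2L
    phi <- if (k_eff > 0L && length(others) > 0L) {
      nn <- find_nearest_neighbors(F, query, k_eff,
                                   subset = c(query, others),
                                   exclude_query = TRUE)
      nn$neighbor_indices[nn$distances < threshold]
    } else integer(0)
    phi <- sort(unique(c(query, phi)))
    key <- phi[(length(phi) - 1L) %/% 2L + 1L]  # lower median by frame index
    keyframes <- c(keyframes, key)
    candidate_sets <- c(candidate_sets, list(phi))
    remaining <- setdiff(remaining, phi)
  }
  structure(
    list(keyframes = sort(keyframes), selection_order = keyframes,
         candidate_sets = candidate_sets,
         threshold = threshold, k_initial = k0, k_policy = k_policy,
         n = n, motion_id = m$motion_id),
    class = "keyframe_result")
}

#' @export
print.keyframe_result <- function(x, ...) {
  cat(sprintf(
    "<keyframe_result '%s'>  %d of %d frames kept (t = %.6g, compression %.1f%%)\n",
    x$motion_id, length(x$keyframes), x$n, x$threshold,
    100 * (1 - length(x$keyframes) / x$n)))
  invisible(x)
}

#' Keyframe counts across a threshold grid
#'
#' Runs [extract_keyframes()] at each threshold and reports how many
#' keyframes survive, the tool behind compression-versus-threshold
#' tuning curves.
#'
#' @param m a `motion`.
#' @param thresholds positive thresholds, ascending.
#' @return a data frame with columns `threshold` and `keyframe_count`.
#' @export
threshold_sweep <- function(m, thresholds) {
  if (length(thresholds) < 1L || any(!is.finite(thresholds)) ||
      any(thresholds <= 0))
    stop("thresholds must be positive numbers")
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be ascending")
  counts <- vapply(thresholds, function(t)
    length(extract_keyframes(m, threshold = t)$keyframes), integer(1))
  data.frame(threshold = as.numeric(thresholds), keyframe_count = counts)
}
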