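#' Synthetic motion generator configuration
#'
#' The generator emulates the structure real MoCap class data presents
#' to the pipeline: each class is a periodic full-body movement pattern
#' (class-specific frequency and per-joint phases), and every recorded
#' clip carries the nuisance a capture session adds — an arbitrary
#' constant heading, a drifting global position, sensor noise, and a
#' clip length that varies from take to take. The nuisance transforms
#' are deliberately exactly the invariances pose normalization claims to
#' remove, so normalization is falsifiable end to end: disabling it must
#' measurably hurt recognition when headings span the full circle.
#'
#' @param n_classes number of action classes (default 5).
#' @param motions_per_class clips per class (default 30).
#' @param J joints per pose (default 31).
#' @param frame_range inclusive clip-length range, frames (default
#'   c(40, 200), i.e. a third of a second to under two seconds at
#'   120 fps).
#' @param fps frame rate (default 120, typical MoCap capture rate).
#' @param noise_sigma additive Gaussian joint noise sd, coordinate units
#'   (default 0.5 cm — small against limb movements of 5-25 cm, so
#'   default runs are stable across platforms).
#' @param heading_range nuisance heading interval in radians (default
#'   the full circle `c(-pi, pi)`).
#' @param drift_speed global root translation per frame, units
#'   (default 1).
#' @param amplitude_range per-clip movement amplitude range, units
#'   (default c(5, 25)).
#' @param seed master seed; the generator is a pure function of
#'   (config, seed).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_classes = 5L, motions_per_class = 30L, J = 31L,
                         frame_range = c(40L, 200L), fps = 120,
                         noise_sigma = 0.5, heading_range = c(-pi, pi),
                         drift_speed = 1.0, amplitude_range = c(5, 25),
                         seed = 42L) {
  if (n_classes < 1L || motions_per_class < 1L) stop("counts must be positive")
  if (J < 3L) stop("J must be >= 3 (root plus the hip pair)")
  if (frame_range[1L] < 2L) stop("frame_range minimum must be >= 2")
  if (frame_range[2L] < frame_range[1L]) stop("invalid frame_range")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_classes = as.integer(n_classes),
                 motions_per_class = as.integer(motions_per_class),
                 J = as.integer(J), frame_range = as.integer(frame_range),
                 fps = fps, noise_sigma = noise_sigma,
                 heading_range = heading_range, drift_speed = drift_speed,
                 amplitude_range = amplitude_range, seed = seed),
            class = "synth_config")
}

#' Deterministic toy skeleton template
#'
#' A fixed, already-normalized rest pose: root (joint 1) at the origin,
#' the hip pair (joints 2 = left, 3 = right) offset along -z/+z at hip
#' height, and the remaining joints laid out on limb-like rays (spine
#' and head above the root; arms from the shoulders; legs below the
#' hips), with extra joints of large skeletons spaced deterministically
#' along those rays. Dimensions are centimetre-scale for an adult
#' subject. Because the hip-to-hip vector already points along +z with
#' the root at the origin, `normalize_pose(template)` returns the
#' template unchanged.
#'
#' @param J joint count (>= 3, default 31).
#' @return list with `template` (a `J x 3` pose), `root_index`,
#'   `left_hip_index`, `right_hip_index`.
#' @export
make_skeleton_template <- function(J = 31L) {
  if (J < 3L) stop("J must be >= 3")
  # limb rays: from (origin offset) toward (direction), unit = cm
  rays <- list(
    spine = list(from = c(0, 0, 0), dir = c(0, 1, 0), len = 60),
    l_arm = list(from = c(0, 55, -18), dir = c(0, -0.4, -1), len = 55),
    r_arm = list(from = c(0, 55, 18), dir = c(0, -0.4, 1), len = 55),
    l_leg = list(from = c(0, 0, -10), dir = c(0, -1, -0.05), len = 85),
    r_leg = list(from = c(0, 0, 10), dir = c(0, -1, 0.05), len = 85))
  fixed <- rbind(c(0, 0, 0),        # root
                 c(0, 0, -10),      # left hip
                 c(0, 0, 10))       # right hip
  extra <- J - 3L
  pts <- fixed
  if (extra > 0L) {
    ray_of <- rep(seq_along(rays), length.out = extra)
    pos_of <- stats::ave(seq_len(extra), ray_of, FUN = seq_along)
    cnt_of <- stats::ave(seq_len(extra), ray_of, FUN = length)
    more <- t(vapply(seq_len(extra), function(i) {
      r <- rays[[ray_of[i]]]
      u <- r$dir / sqrt(sum(r$dir^2))
      r$from + u * r$len * pos_of[i] / cnt_of[i]
    }, numeric(3)))
    pts <- rbind(pts, more)
  }
  list(template = pose(pts), root_index = 1L,
       left_hip_index = 2L, right_hip_index = 3L)
}

# Class archetype: deterministic per-class motion pattern. Root and both
# hips stay fixed so the archetype is exactly normalization-invariant
# (root at origin, hip vector on +z); every other joint oscillates with
# the class frequency, class-fixed per-coordinate phases and direction
# weights.
class_pattern <- function(class_id, J) {
  with_seed(derive_seed(1234L, class_id), {
    phase <- matrix(stats::runif(J * 3L, 0, 2 * pi), J, 3L)
    weight <- matrix(stats::runif(J * 3L, -1, 1), J, 3L)
    weight[1:3, ] <- 0                  # root + hips immobile
    # class signal lives in the horizontal plane only: heading rotation
    # mixes exactly the informative coordinates, so skipping
    # normalization is measurably costly (the falsifiability property)
    weight[, 2L] <- 0
    list(freq = 0.5 + 0.3 * class_id, phase = phase, weight = weight)
  })
}

# Noise-free normalized archetype frames for a class (n x 3J flat matrix).
archetype_frames <- function(class_id, J, n, fps, amplitude) {
  tmpl <- make_skeleton_template(J)$template
  pat <- class_pattern(class_id, J)
  tt <- (seq_len(n) - 1L) / fps
  F <- matrix(0, n, 3L * J)
  for (a in 1:3) {
    base <- matrix(tmpl[, a], n, J, byrow = TRUE)
    ph <- matrix(pat$phase[, a], n, J, byrow = TRUE)
    w <- matrix(pat$weight[, a], n, J, byrow = TRUE)
    F[, seq(a, 3L * J, by = 3L)] <-
      base + amplitude * w * sin(2 * pi * pat$freq * tt + ph)
  }
  F
}

#' Generate one labelled synthetic motion
#'
#' Builds the class archetype (class-specific sinusoidal joint
#' displacements on the skeleton template, amplitude drawn from
#' `amplitude_range`), then applies the nuisance: a constant random
#' heading rotation about y, a linear global drift of `drift_speed`
#' units per frame in a random horizontal direction, and white Gaussian
#' joint noise of sd `noise_sigma`. Clip length is drawn uniformly from
#' `frame_range`. A pure function of `(class_id, cfg, seed)`.
#'
#' @param class_id 0-based class index in `[0, n_classes)`.
#' @param cfg a [synth_config()].
#' @param seed clip seed.
#' @return a labelled `motion` (label `classNN`).
#' @export
generate_motion <- function(class_id, cfg = synth_config(), seed = 1L) {
  if (class_id < 0L || class_id >= cfg$n_classes)
    stop("class_id must be in [0, ", cfg$n_classes, ")")
  with_seed(seed, {
    # sample.int avoids the sample(x, 1) scalar pitfall when the range
    # is a single length
    n <- cfg$frame_range[1L] +
      sample.int(cfg$frame_range[2L] - cfg$frame_range[1L] + 1L, 1L) - 1L
    amplitude <- stats::runif(1L, cfg$amplitude_range[1L],
                              cfg$amplitude_range[2L])
    F <- archetype_frames(class_id, cfg$J, n, cfg$fps, amplitude)
    # nuisance: constant heading about y
    theta <- stats::runif(1L, cfg$heading_range[1L], cfg$heading_range[2L])
    xc <- seq(1L, 3L * cfg$J, by = 3L); zc <- xc + 2L
    X <- F[, xc, drop = FALSE]; Z <- F[, zc, drop = FALSE]
    F[, xc] <- X * cos(theta) + Z * sin(theta)
    F[, zc] <- -X * sin(theta) + Z * cos(theta)
    # nuisance: linear whole-body drift in a random horizontal direction
    dir <- stats::runif(1L, 0, 2 * pi)
    step <- cfg$drift_speed * c(cos(dir), 0, sin(dir))
    off <- stats::runif(3L, -100, 100) * c(1, 0, 1)   # random start position
    if (cfg$drift_speed == 0) off <- c(0, 0, 0)       # translation off entirely
    for (a in 1:3)
      F[, seq(a, 3L * cfg$J, by = 3L)] <-
        F[, seq(a, 3L * cfg$J, by = 3L)] + off[a] + (seq_len(n) - 1L) * step[a]
    # nuisance: sensor noise
    if (cfg$noise_sigma > 0)
      F <- F + matrix(stats::rnorm(length(F), 0, cfg$noise_sigma), nrow(F))
    motion(F, fps = cfg$fps,
           motion_id = sprintf("class%02d_seed%d", class_id, seed),
           label = sprintf("class%02d", class_id))
  })
}

#' Generate a labelled synthetic dataset
#'
#' `n_classes x motions_per_class` motions with class names
#' `class00, class01, ...`; deterministic under `cfg$seed` (each clip's
#' seed is derived from the master seed and the clip counter).
#'
#' @param cfg a [synth_config()].
#' @return a `motion_dataset`.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  motions <- list()
  counter <- 0L
  for (cl in seq_len(cfg$n_classes) - 1L) {
    for (i in seq_len(cfg$motions_per_class)) {
      counter <- counter + 1L
      m <- generate_motion(cl, cfg, seed = derive_seed(cfg$seed, counter))
      m$motion_id <- sprintf("class%02d_m%03d", cl, i)
      motions[[counter]] <- m
    }
  }
  motion_dataset(motions,
                 classes = sprintf("class%02d", seq_len(cfg$n_classes) - 1L))
}
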