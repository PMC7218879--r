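# Independent oracles and fixture builders. Everything here is written
# naively and separately from the package internals, so agreement is
# evidence, not tautology.

# random pose / motion fixtures -------------------------------------------

random_pose <- function(J = 31, scale = 50) {
  pose(matrix(stats::runif(J * 3, -scale, scale), J, 3))
}

random_motion <- function(n = 20, J = 31, scale = 50, fps = 120) {
  motion(matrix(stats::runif(n * 3 * J, -scale, scale), n, 3 * J),
         fps = fps, motion_id = "random")
}

# explicit y-rotation applied pose-by-pose with a full 3x3 matrix --------

rotate_pose_oracle <- function(p, theta) {
  Ry <- matrix(c(cos(theta), 0, -sin(theta),
                 0, 1, 0,
                 sin(theta), 0, cos(theta)), 3, 3)   # columns: images of e_x,e_y,e_z
  t(Ry %*% t(p))
}

translate_pose <- function(p, v) sweep(p, 2, v, "+")

# rigid nuisance on a whole motion (rotation about y, then translation)
apply_rigid_nuisance <- function(m, theta, v) {
  F <- m$frames
  J <- ncol(F) / 3
  for (i in seq_len(nrow(F))) {
    p <- matrix(F[i, ], ncol = 3, byrow = TRUE)
    p <- translate_pose(rotate_pose_oracle(p, theta), v)
    F[i, ] <- as.vector(t(p))
  }
  m$frames <- F
  m
}

# brute-force average pose distance: explicit double loop ----------------

pose_distance_oracle <- function(a, b) {
  J <- nrow(a)
  total <- 0
  for (j in seq_len(J)) {
    s <- 0
    for (c in 1:3) s <- s + (a[j, c] - b[j, c])^2
    total <- total + sqrt(s)
  }
  unname(total / J)
}

motion_distance_matrix <- function(m) {
  n <- n_frames(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      D[i, j] <- pose_distance_oracle(motion_frame(m, i), motion_frame(m, j))
  D
}

# same matrix via stats::dist per joint (independent of the package's
# vectorisation); fast enough for the 100-motion acceptance suite
motion_distance_matrix_fast <- function(m) {
  J <- n_joints(m)
  n <- n_frames(m)
  D <- matrix(0, n, n)
  for (j in seq_len(J)) {
    cols <- (3 * (j - 1) + 1):(3 * j)
    D <- D + as.matrix(stats::dist(m$frames[, cols, drop = FALSE]))
  }
  unname(D / J)
}

# naive line-by-line transcription of the keyframe extraction loop -------
# (query = lowest-index remaining frame; k fixed to floor(n/2), clamped;
# Phi = query plus neighbours strictly under the threshold; lower median
# of the index-sorted Phi; discard Phi; repeat)

keyframes_oracle <- function(m, threshold, k_policy = "fixed",
                             D = motion_distance_matrix(m)) {
  n <- n_frames(m)
  k0 <- n %/% 2
  remaining <- seq_len(n)
  psi <- integer(0)
  phis <- list()
  while (length(remaining) > 0) {
    query <- min(remaining)
    others <- setdiff(remaining, query)   # query leaves M before the search
    k <- if (k_policy == "fixed") min(k0, length(others))
         else min(length(remaining) %/% 2, length(others))
    d <- D[query, others]
    ord <- order(d, others)               # distance, then frame index
    nn_idx <- others[ord][seq_len(k)]
    nn_d <- d[ord][seq_len(k)]
    phi <- sort(unique(c(query, nn_idx[nn_d < threshold])))
    med <- phi[(length(phi) - 1) %/% 2 + 1]
    psi <- c(psi, med)
    phis[[length(phis) + 1]] <- phi
    remaining <- setdiff(remaining, phi)
  }
  list(keyframes = sort(psi), selection_order = psi, candidate_sets = phis)
}

# central finite-difference gradients for the network --------------------

numeric_gradients <- function(params, feature, target_index, eps = 1e-5) {
  loss_of <- function(p) cross_entropy(forward(p, feature)$o, target_index)
  num_grad_mat <- function(field) {
    G <- params[[field]]
    for (i in seq_len(nrow(G)))
      for (j in seq_len(ncol(G))) {
        pp <- params; pm <- params
        pp[[field]][i, j] <- pp[[field]][i, j] + eps
        pm[[field]][i, j] <- pm[[field]][i, j] - eps
        G[i, j] <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      }
    G
  }
  list(d_w = num_grad_mat("w"),
       d_w_prime = num_grad_mat("w_prime"),
       d_w_dprime = num_grad_mat("w_dprime"))
}

# Frobenius-norm relative error: elementwise relative error is
# meaningless for near-zero gradient entries (central differences carry
# ~1e-11 absolute roundoff at eps = 1e-5, which swamps entries of 1e-6)
max_rel_error <- function(a, b, floor = 1e-12) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(a^2)) + sqrt(sum(b^2)), floor)
}

# pure-R per-sample SGD epoch: the reference the C++ loop must match ----

sgd_epoch_oracle <- function(params, X, y, order, eta) {
  for (i in order) {
    tr <- forward(params, X[i, ])
    g <- backward(params, tr, y[i])
    params <- apply_update(params, g, eta)
  }
  params
}

# linearly separable 3-class features (criterion fixtures) ---------------

separable_features <- function(per_class = 50, d = 4, seed = 7) {
  centers <- matrix(c(3, 0, 0, 0,
                      0, 3, 0, 0,
                      0, 0, 3, 0), 3, d, byrow = TRUE)
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(1:3, function(cl)
      sweep(matrix(stats::rnorm(per_class * d, sd = 0.4), per_class, d),
            2, centers[cl, ], "+")))
    list(X = X, y = rep(1:3, each = per_class))
  })
}
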