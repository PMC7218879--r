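#' Network configuration
#'
#' Hyperparameters of the two-hidden-layer classifier. The defaults are
#' the settings of the reference architecture for 31-joint skeletons:
#' 93 inputs (J x 3 joint coordinates), hidden layers of 85 and 80
#' sigmoid units, a softmax output layer with one unit per class,
#' learning rate 0.01, at most 1000 epochs, a minimum performance
#' gradient of 1e-6, and early stopping after 5 consecutive epochs of
#' worsening validation loss.
#'
#' @param input_dim number of input features (J x 3; default 93).
#' @param hidden1,hidden2 sigmoid hidden-layer sizes P and Q.
#' @param output_dim number of classes R (no default; set from the data).
#' @param learning_rate gradient-descent step size eta (> 0).
#' @param max_epochs epoch cap.
#' @param min_gradient stop when the largest absolute gradient entry
#'   falls below this.
#' @param patience consecutive epochs of worsening validation loss
#'   tolerated before stopping (best-validation weights are returned).
#' @param validation_fraction fraction of training samples held out,
#'   stratified by class, for the validation stop (in (0, 1)).
#' @param init_scale weights are initialised uniformly on
#'   `[-init_scale, init_scale]`.
#' @param batch_mode `"sample"` (default): the update rule is applied
#'   after every training sample, the literal reading of the per-sample
#'   update equations (fast convergence at eta = 0.01); `"batch"`: one
#'   update per epoch from the mean gradient over all training samples
#'   (smooth descent, but far smaller effective steps at the same eta).
#' @param seed integer seed driving initialisation and the validation
#'   split.
#' @return an object of class `net_config`.
#' @export
net_config <- function(input_dim = 93L, hidden1 = 85L, hidden2 = 80L,
                       output_dim, learning_rate = 0.01,
                       max_epochs = 1000L, min_gradient = 1e-6,
                       patience = 5L, validation_fraction = 0.15,
                       init_scale = 0.1, batch_mode = c("sample", "batch"),
                       seed = 1L) {
  batch_mode <- match.arg(batch_mode)
  sizes <- c(input_dim, hidden1, hidden2, output_dim)
  if (any(sizes < 1L)) stop("all layer sizes must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  if (max_epochs < 0L) stop("max_epochs must be >= 0")
  structure(list(
    input_dim = as.integer(input_dim), hidden1 = as.integer(hidden1),
    hidden2 = as.integer(hidden2), output_dim = as.integer(output_dim),
    learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
    min_gradient = min_gradient, patience = as.integer(patience),
    validation_fraction = validation_fraction, init_scale = init_scale,
    batch_mode = batch_mode, seed = seed), class = "net_config")
}

#' Initialise network parameters
#'
#' Draws every weight (bias rows included) uniformly from
#' `[-init_scale, init_scale]` under the config seed. Row 1 of each
#' matrix is the bias row, fed by the fixed unit `x0 = h0 = h'0 = 1`.
#'
#' @param config a [net_config()].
#' @param class_names optional ordered class vocabulary of length
#'   `output_dim`.
#' @return an object of class `net_params` with weight matrices `w`
#'   (`(input_dim+1) x P`), `w_prime` (`(P+1) x Q`), `w_dprime`
#'   (`(Q+1) x R`) and `class_names`.
#' @export
init_parameters <- function(config, class_names = NULL) {
  if (is.null(class_names))
    class_names <- sprintf("class%02d", seq_len(config$output_dim) - 1L)
  if (length(class_names) != config$output_dim)
    stop("class_names length must equal output_dim")
  s <- config$init_scale
  with_seed(config$seed, {
    rmat <- function(nr, nc)
      matrix(stats::runif(nr * nc, -s, s), nr, nc)
    structure(list(
      w = rmat(config$input_dim + 1L, config$hidden1),
      w_prime = rmat(config$hidden1 + 1L, config$hidden2),
      w_dprime = rmat(config$hidden2 + 1L, config$output_dim),
      class_names = as.character(class_names)), class = "net_params")
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable softmax over the rows of a matrix of logits.
# max.col is C-level; ties.method = "first" keeps it deterministic.
softmax_rows <- function(Z) {
  rmax <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - rmax)
  E / rowSums(E)
}

#' Forward pass
#'
#' Computes `h_p = sigmoid(sum_j x_j w_{j,p})` (sum from j = 0, the bias
#' unit), `h'_q = sigmoid(sum_p h_p w'_{p,q})`, and the softmax output
#' `o_r` (computed with max-subtraction for stability; the probabilities
#' sum to 1).
#'
#' @param params a `net_params`.
#' @param feature numeric feature vector of length `input_dim`.
#' @return a forward trace: `x`, `h`, `h_prime` (each including its
#'   leading bias unit 1) and `o` (class probabilities).
#' @export
forward <- function(params, feature) {
  if (length(feature) != nrow(params$w) - 1L)
    stop("feature length ", length(feature), " does not match input_dim ",
         nrow(params$w) - 1L)
  x <- c(1, as.numeric(feature))
  h <- c(1, sigmoid(drop(x %*% params$w)))
  hp <- c(1, sigmoid(drop(h %*% params$w_prime)))
  z <- drop(hp %*% params$w_dprime)
  o <- drop(softmax_rows(matrix(z, 1L)))
  list(x = x, h = h, h_prime = hp, o = o)
}

# Batch forward over an N x input_dim matrix; returns bias-augmented
# activations and the N x R probability matrix.
forward_batch <- function(params, X) {
  X1 <- cbind(1, X)
  H1 <- cbind(1, sigmoid(X1 %*% params$w))
  Hp1 <- cbind(1, sigmoid(H1 %*% params$w_prime))
  O <- softmax_rows(Hp1 %*% params$w_dprime)
  list(x = X1, h = H1, h_prime = Hp1, o = O)
}

#' Cross-entropy loss
#'
#' `E = -sum_r t_r ln(o_r)` with a one-hot target: the negative log
#' probability assigned to the true class, clamped at `o_r >= 1e-300`.
#'
#' @param o probability vector (sums to 1).
#' @param target_index 1-based true-class index.
#' @return a non-negative scalar.
#' @export
cross_entropy <- function(o, target_index) {
  if (target_index < 1L || target_index > length(o))
    stop("target_index out of range")
  -log(max(o[target_index], 1e-300))
}

#' Backward pass (analytic gradients)
#'
#' Backpropagates the cross-entropy error through softmax and the two
#' sigmoid layers: the output error is `delta''_r = o_r - t_r`, giving
#' `dE/dw''_{q,r} = h'_q (o_r - t_r)`; the hidden errors are
#' `delta'_q = h'_q (1 - h'_q) sum_r delta''_r w''_{q,r}` and
#' `delta_p = h_p (1 - h_p) sum_q delta'_q w'_{p,q}`, each multiplied by
#' the layer input to give the weight gradients, bias rows included.
#'
#' @param params a `net_params`.
#' @param trace a forward trace from [forward()] under `params`.
#' @param target_index 1-based true-class index.
#' @return list with gradient matrices `d_w`, `d_w_prime`, `d_w_dprime`
#'   and error terms `delta_r`, `delta_q`, `delta_p`.
#' @export
backward <- function(params, trace, target_index) {
  R <- ncol(params$w_dprime)
  if (target_index < 1L || target_index > R)
    stop("target_index out of range")
  t_vec <- numeric(R); t_vec[target_index] <- 1
  delta_r <- trace$o - t_vec
  d_w_dprime <- outer(trace$h_prime, delta_r)
  hp <- trace$h_prime[-1L]
  delta_q <- hp * (1 - hp) * drop(params$w_dprime[-1L, , drop = FALSE] %*% delta_r)
  d_w_prime <- outer(trace$h, delta_q)
  h <- trace$h[-1L]
  delta_p <- h * (1 - h) * drop(params$w_prime[-1L, , drop = FALSE] %*% delta_q)
  d_w <- outer(trace$x, delta_p)
  list(d_w = d_w, d_w_prime = d_w_prime, d_w_dprime = d_w_dprime,
       delta_r = delta_r, delta_q = delta_q, delta_p = delta_p)
}

#' Apply a gradient-descent update
#'
#' `w <- w - eta * dE/dw` for all three weight matrices.
#'
#' @param params a `net_params`.
#' @param grads gradients from [backward()] (or a batch average).
#' @param learning_rate step size eta.
#' @return the updated `net_params`.
#' @export
apply_update <- function(params, grads, learning_rate) {
  params$w <- params$w - learning_rate * grads$d_w
  params$w_prime <- params$w_prime - learning_rate * grads$d_w_prime
  params$w_dprime <- params$w_dprime - learning_rate * grads$d_w_dprime
  params
}

# Mean cross-entropy of a probability matrix against integer labels.
mean_cross_entropy <- function(O, y) {
  p <- O[cbind(seq_along(y), y)]
  mean(-log(pmax(p, 1e-300)))
}

# Mean gradients over a batch: the average of the per-sample gradients,
# computed with three matrix products.
batch_gradients <- function(params, act, y) {
  N <- length(y)
  Tm <- matrix(0, N, ncol(params$w_dprime))
  Tm[cbind(seq_len(N), y)] <- 1
  Dr <- act$o - Tm                                   # N x R
  d_w_dprime <- crossprod(act$h_prime, Dr) / N
  Hp <- act$h_prime[, -1L, drop = FALSE]
  Dq <- Hp * (1 - Hp) *
    (Dr %*% t(params$w_dprime[-1L, , drop = FALSE])) # N x Q
  d_w_prime <- crossprod(act$h, Dq) / N
  H <- act$h[, -1L, drop = FALSE]
  Dp <- H * (1 - H) *
    (Dq %*% t(params$w_prime[-1L, , drop = FALSE]))  # N x P
  d_w <- crossprod(act$x, Dp) / N
  list(d_w = d_w, d_w_prime = d_w_prime, d_w_dprime = d_w_dprime)
}

grad_max_abs <- function(g)
  max(abs(g$d_w), abs(g$d_w_prime), abs(g$d_w_dprime))

#' Train the classifier
#'
#' Splits off a stratified validation fraction (seeded), then iterates
#' epochs of gradient descent on the training samples. In `"batch"` mode
#' each epoch applies one update from the mean gradient over all
#' training samples; in `"sample"` mode the update is applied after every
#' sample (samples visited in a fixed order). Training stops at
#' `max_epochs`, when the largest absolute gradient entry drops below
#' `min_gradient`, or when validation loss strictly worsens epoch over
#' epoch for `patience` consecutive epochs — in which case the
#' best-validation weights seen so far are returned. If the validation split cannot represent every class, the
#' run falls back to no-validation training with a warning.
#'
#' @param X numeric `N x input_dim` feature matrix.
#' @param y 1-based integer class labels of length N (or a factor).
#' @param config a [net_config()]; `input_dim` and `output_dim` must
#'   match the data.
#' @param class_names optional ordered class vocabulary.
#' @return list with `params` (a `net_params`) and `report` (fields
#'   `epochs_run`, `stop_reason` — one of `"max_epochs"`,
#'   `"min_gradient"`, `"patience"` — `train_loss_trace`,
#'   `validation_loss_trace`).
#' @export
train_network <- function(X, y, config, class_names = NULL) {
  X <- as.matrix(X)
  if (is.factor(y)) {
    if (is.null(class_names)) class_names <- levels(y)
    y <- as.integer(y)
  }
  y <- as.integer(y)
  R <- config$output_dim
  if (ncol(X) != config$input_dim)
    stop("feature dimension ", ncol(X), " does not match config input_dim ",
         config$input_dim)
  if (length(y) != nrow(X)) stop("X and y lengths differ")
  if (any(y < 1L | y > R)) stop("labels outside 1..output_dim")
  counts <- tabulate(y, nbins = R)
  if (any(counts == 0L)) stop("every class needs at least one sample")
  if (R < 2L) stop("training needs at least 2 classes")

  # stratified validation split
  val_idx <- with_seed(derive_seed(config$seed, 1L), {
    unlist(lapply(seq_len(R), function(r) {
      idx <- which(y == r)
      nv <- floor(config$validation_fraction * length(idx))
      if (nv == 0L) integer(0) else sample(idx, nv)
    }))
  })
  use_val <- TRUE
  if (length(val_idx) == 0L ||
      length(unique(y[val_idx])) < R) {
    warning("validation split cannot represent every class; ",
            "training without validation-based stopping")
    use_val <- FALSE
    val_idx <- integer(0)
  }
  tr_idx <- setdiff(seq_along(y), val_idx)
  Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]

  params <- init_parameters(config, class_names)
  eta <- config$learning_rate
  train_trace <- numeric(0)
  val_trace <- numeric(0)
  stop_reason <- "max_epochs"
  best_val <- Inf
  best_params <- params
  bad_epochs <- 0L
  epochs_run <- 0L

  sample_order <- with_seed(derive_seed(config$seed, 2L),
                            sample(seq_along(yt)))

  for (epoch in seq_len(config$max_epochs)) {
    if (config$batch_mode == "batch") {
      act <- forward_batch(params, Xt)
      g <- batch_gradients(params, act, yt)
      params <- apply_update(params, g, eta)
      gmax <- grad_max_abs(g)
      # loss at epoch start, from the same activations the update used
      train_trace[epoch] <- mean_cross_entropy(act$o, yt)
    } else {
      res <- cpp_sgd_epoch(params$w, params$w_prime, params$w_dprime,
                           Xt, yt, sample_order, eta)
      params$w <- res$w
      params$w_prime <- res$w_prime
      params$w_dprime <- res$w_dprime
      gmax <- res$gmax
      train_trace[epoch] <- mean_cross_entropy(forward_batch(params, Xt)$o, yt)
    }
    epochs_run <- epoch
    if (use_val) {
      vloss <- mean_cross_entropy(forward_batch(params, Xv)$o, yv)
      val_trace[epoch] <- vloss
      if (vloss < best_val) {
        best_val <- vloss
        best_params <- params
      }
      # "deteriorates continuously": strict epoch-over-epoch worsening,
      # patience times in a row (a flat plateau does not count)
      if (epoch > 1L && vloss > val_trace[epoch - 1L]) {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= config$patience) {
          stop_reason <- "patience"
          params <- best_params
          break
        }
      } else bad_epochs <- 0L
    }
    if (gmax < config$min_gradient) {
      stop_reason <- "min_gradient"
      break
    }
  }
  list(params = params,
       report = list(epochs_run = epochs_run, stop_reason = stop_reason,
                     train_loss_trace = train_trace,
                     validation_loss_trace = val_trace))
}

#' Class probabilities for one feature vector
#'
#' @param params a `net_params`.
#' @param feature numeric vector of length `input_dim`.
#' @return named probability vector (names = `class_names`).
#' @export
predict_proba <- function(params, feature) {
  o <- forward(params, feature)$o
  names(o) <- params$class_names
  o
}
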