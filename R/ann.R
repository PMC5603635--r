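#' Build the 100-element network input pattern from a breath
#'
#' Under-samples the inspiratory limb of the pressure-volume loop into 50
#' equally spaced (in sample index) coordinate pairs and rescales them to
#' give the network a size-free view of the loop. Index selection takes 50
#' points linearly spaced over the inspiratory window, rounded to the
#' nearest sample, with the first and last inspiratory samples always
#' included. Pressure coordinates are divided by the maximum airway pressure
#' over the inspiratory limb of the presented (possibly perturbed) curve;
#' volume coordinates are divided, by default, by that same pressure maximum
#' (`volume_scale = "paw_max"`), which keeps the compliance-carrying ratio
#' V_T / P_aw,max in the pattern. The alternative `"own_max"` divides volume
#' by its own inspiratory maximum, giving a fully self-normalised (and
#' therefore scale-blind) pattern. Zeros introduced by a disconnection
#' remain zeros after scaling.
#'
#' The pattern layout is 50 pressure values followed by 50 volume values.
#'
#' @param breath A `breath_tracing` with an inspiratory window of at least
#'   50 samples.
#' @param volume_scale `"paw_max"` (default) or `"own_max"`.
#' @return An object of class `input_pattern` with fields `values`
#'   (length-100 numeric), `scale_paw_max` (cmH2O) and `scale_volume`
#'   (L or cmH2O depending on `volume_scale`).
#' @export
build_input_pattern <- function(breath, volume_scale = c("paw_max", "own_max")) {
  stopifnot(inherits(breath, "breath_tracing"))
  volume_scale <- match.arg(volume_scale)
  insp <- breath$insp_start:(breath$insp_end - 1L)
  vr_check(length(insp) >= 50,
           sprintf("inspiratory window has %d samples; 50 are required",
                   length(insp)),
           "resolution_error")
  sel <- insp[round(seq(1, length(insp), length.out = 50))]
  p_max <- max(breath$paw[insp])
  vr_check(is.finite(p_max) && p_max > 0,
           "non-positive pressure scale over the inspiratory limb",
           "degenerate_scale")
  v_scale <- if (volume_scale == "own_max") max(breath$volume[insp]) else p_max
  vr_check(is.finite(v_scale) && v_scale > 0,
           "non-positive volume scale over the inspiratory limb",
           "degenerate_scale")
  values <- c(breath$paw[sel] / p_max, breath$volume[sel] / v_scale)
  vr_check(all(is.finite(values)), "non-finite values in input pattern",
           "degenerate_scale")
  structure(list(values = values, scale_paw_max = p_max,
                 scale_volume = v_scale, indices = sel),
            class = "input_pattern")
}

# ---- network core --------------------------------------------------------

logsig <- function(x) 1 / (1 + exp(-x))

# Parameter layout of the 100-25-1 network: three weighted layers, so
# W1 is 100 x 100, b1 100, W2 25 x 100, b2 25, W3 1 x 25, b3 1 (12651
# parameters), flattened in that order.
ANN_N_IN <- 100L
ANN_N_L1 <- 100L
ANN_N_L2 <- 25L
ANN_N_PAR <- ANN_N_L1 * ANN_N_IN + ANN_N_L1 + ANN_N_L2 * ANN_N_L1 +
  ANN_N_L2 + ANN_N_L2 + 1L

#' Initialise a 100-25-1 multilayer perceptron
#'
#' Fixed three-layer architecture: an input layer of 100 log-sigmoid neurons
#' (one per pattern element), an intermediate layer of 25 log-sigmoid
#' neurons, and 1 linear output neuron yielding compliance in ml/cmH2O.
#' Weights and biases are drawn uniformly from \[-0.5, 0.5\] under the given
#' seed.
#'
#' @param seed Integer seed for the weight draw.
#' @return An object of class `ann_model` (untrained).
#' @export
ann_init <- function(seed = 1) {
  w <- withr::with_seed(as.integer(seed),
                        stats::runif(ANN_N_PAR, -0.5, 0.5))
  m <- structure(
    list(layers = c(ANN_N_L1, ANN_N_L2, 1L),
         activations = c("logsig", "logsig", "linear"),
         trained = FALSE,
         training = list(init_seed = as.integer(seed))),
    class = "ann_model")
  model_with_theta(m, w)
}

# Forward pass on a 100 x n matrix of raw patterns; returns length-n vector.
ann_forward <- function(model, x) {
  a1 <- logsig(model$W1 %*% x + model$b1)
  a2 <- logsig(model$W2 %*% a1 + model$b2)
  as.numeric(model$W3 %*% a2 + model$b3)
}

#' Predict compliance from input patterns
#'
#' @param model A trained `ann_model`.
#' @param patterns A single `input_pattern`, a list of them, or a 100 x n
#'   numeric matrix of raw pattern values.
#' @return Numeric vector of compliance predictions (ml/cmH2O).
#' @export
ann_predict <- function(model, patterns) {
  stopifnot(inherits(model, "ann_model"))
  x <- patterns_to_matrix(patterns)
  ann_forward(model, x)
}

patterns_to_matrix <- function(patterns) {
  if (inherits(patterns, "input_pattern")) patterns <- list(patterns)
  if (is.list(patterns))
    patterns <- vapply(patterns, function(p) p$values, numeric(100))
  stopifnot(is.matrix(patterns), nrow(patterns) == 100)
  patterns
}

#' Estimate compliance from a breath with the trained network
#'
#' Builds the input pattern from the breath's inspiratory limb and runs the
#' forward pass. Bounded activations and the linear output guarantee a
#' finite value for any finite pattern, including all-zero (fully
#' disconnected) pressure blocks.
#'
#' @param model A trained `ann_model`.
#' @param breath A `breath_tracing`.
#' @param volume_scale Passed to [build_input_pattern()].
#' @return Compliance estimate in ml/cmH2O.
#' @export
ann_estimate_crs <- function(model, breath, volume_scale = "paw_max") {
  ann_predict(model, build_input_pattern(breath, volume_scale = volume_scale))
}

#' Training plan for the network
#'
#' Hyperparameters of resilient-backpropagation training with eightfold
#' cross-validated early stopping and multistart model selection. The
#' reference protocol trains 100 independently initialised networks on an
#' 80:20 train/evaluation split and keeps the one with the lowest evaluation
#' MSE; `n_restarts` is configurable down for cheaper runs. Rprop
#' hyperparameters are the standard published defaults.
#'
#' @param n_restarts Number of independently initialised networks.
#' @param split_ratio Fraction of the pool used for training (rest is the
#'   evaluation subset used to select among restarts).
#' @param cv_folds Number of rotating validation folds inside the training
#'   subset (early stopping).
#' @param patience Early-stopping patience, epochs without validation
#'   improvement.
#' @param max_epochs Hard epoch cap per restart.
#' @param eta_plus,eta_minus Step-size increase/decrease factors.
#' @param delta_init,delta_min,delta_max Initial / minimum / maximum
#'   per-weight step sizes.
#' @param seed Master seed for splitting, fold assignment and weight draws.
#' @return An object of class `training_plan`.
#' @export
training_plan <- function(n_restarts = 100,
                          split_ratio = 0.8,
                          cv_folds = 8,
                          patience = 100,
                          max_epochs = 1500,
                          eta_plus = 1.2,
                          eta_minus = 0.5,
                          delta_init = 0.07,
                          delta_min = 1e-6,
                          delta_max = 50,
                          seed = 1) {
  vr_check(n_restarts >= 1, "n_restarts must be >= 1", "invalid_configuration")
  vr_check(split_ratio > 0 && split_ratio < 1,
           "split_ratio must lie in (0, 1)", "invalid_configuration")
  vr_check(cv_folds >= 2, "cv_folds must be >= 2", "invalid_configuration")
  structure(list(n_restarts = as.integer(n_restarts),
                 split_ratio = split_ratio, cv_folds = as.integer(cv_folds),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 eta_plus = eta_plus, eta_minus = eta_minus,
                 delta_init = delta_init, delta_min = delta_min,
                 delta_max = delta_max, seed = as.integer(seed)),
            class = "training_plan")
}

# Backpropagated MSE gradient for the flat parameter vector; x is 100 x n.
# The sigmoid derivative is computed as logsig(z) * logsig(-z): the naive
# a * (1 - a) underflows to an exact 0 once |z| > ~36, which permanently
# kills the gradient sign a saturated unit needs to recover under
# sign-based (Rprop) updates.
ann_mse_grad <- function(theta, x, t) {
  p <- split_theta(theta)
  n <- ncol(x)
  z1 <- p$W1 %*% x + p$b1
  a1 <- logsig(z1)
  z2 <- p$W2 %*% a1 + p$b2
  a2 <- logsig(z2)
  y <- as.numeric(p$W3 %*% a2 + p$b3)
  err <- y - t
  dy <- matrix(2 * err / n, 1, n)
  gW3 <- dy %*% t(a2)
  gb3 <- sum(dy)
  dz2 <- (t(p$W3) %*% dy) * a2 * logsig(-z2)
  gW2 <- dz2 %*% t(a1)
  gb2 <- rowSums(dz2)
  dz1 <- (t(p$W2) %*% dz2) * a1 * logsig(-z1)
  gW1 <- dz1 %*% t(x)
  gb1 <- rowSums(dz1)
  list(mse = mean(err^2),
       grad = c(as.numeric(gW1), gb1, as.numeric(gW2), gb2,
                as.numeric(gW3), gb3))
}

split_theta <- function(theta) {
  stopifnot(length(theta) == ANN_N_PAR)
  i <- 0L
  take <- function(k) { v <- theta[i + seq_len(k)]; i <<- i + k; v }
  list(W1 = matrix(take(ANN_N_L1 * ANN_N_IN), ANN_N_L1, ANN_N_IN),
       b1 = take(ANN_N_L1),
       W2 = matrix(take(ANN_N_L2 * ANN_N_L1), ANN_N_L2, ANN_N_L1),
       b2 = take(ANN_N_L2),
       W3 = matrix(take(ANN_N_L2), 1, ANN_N_L2),
       b3 = take(1L))
}

theta_of <- function(model) {
  c(as.numeric(model$W1), model$b1, as.numeric(model$W2), model$b2,
    as.numeric(model$W3), model$b3)
}

model_with_theta <- function(model, theta) {
  model[c("W1", "b1", "W2", "b2", "W3", "b3")] <- split_theta(theta)
  model
}

#' Train the network with resilient backpropagation
#'
#' Full-batch iRprop- training: each parameter keeps its own step size,
#' multiplied by `eta_plus` while the gradient sign is stable and by
#' `eta_minus` (with the gradient zeroed) when it flips, clamped to
#' `[delta_min, delta_max]`; parameters move by the step in the direction
#' opposite the gradient sign. Training stops at `max_epochs` or when the
#' validation-fold MSE has not improved for `patience` epochs, and the
#' weights from the best validation epoch are returned.
#'
#' @param model An `ann_model` (typically from [ann_init()]).
#' @param patterns Input patterns (list of `input_pattern` or 100 x n matrix).
#' @param targets Reference compliances (ml/cmH2O), one per pattern —
#'   interrupter-technique values of the paired hold breaths.
#' @param plan A [training_plan()].
#' @param fold_assignment Integer vector (values in `1:plan$cv_folds`), one
#'   per pattern; `NULL` assigns folds round-robin after a seed-deterministic
#'   shuffle.
#' @param val_fold Which fold is held out for early stopping.
#' @return The trained `ann_model`, with `$training` metadata (epochs run,
#'   best epoch, per-epoch losses, validation fold).
#' @export
rprop_train <- function(model, patterns, targets, plan = training_plan(),
                        fold_assignment = NULL, val_fold = 1L) {
  stopifnot(inherits(model, "ann_model"), inherits(plan, "training_plan"))
  x <- patterns_to_matrix(patterns)
  t <- as.numeric(targets)
  n <- ncol(x)
  vr_check(n == length(t) && n >= 2, "patterns and targets must pair up (n >= 2)",
           "invalid_configuration")
  if (is.null(fold_assignment)) {
    fold_assignment <- withr::with_seed(plan$seed,
      sample(rep_len(seq_len(plan$cv_folds), n)))
  }
  vr_check(length(fold_assignment) == n &&
             all(fold_assignment %in% seq_len(plan$cv_folds)),
           "fold_assignment must give a fold in 1:cv_folds per pattern",
           "invalid_configuration")
  val <- which(fold_assignment == val_fold)
  tr <- which(fold_assignment != val_fold)
  vr_check(length(tr) >= 1 && length(val) >= 1,
           "training and validation folds must both be non-empty",
           "invalid_configuration")

  theta <- theta_of(model)
  delta <- rep(plan$delta_init, length(theta))
  g_prev <- numeric(length(theta))
  best <- list(mse = Inf, theta = theta, epoch = 0L)
  stall <- 0L
  tr_mse <- val_mse <- numeric(0)
  x_tr <- x[, tr, drop = FALSE]; t_tr <- t[tr]
  x_val <- x[, val, drop = FALSE]; t_val <- t[val]

  for (epoch in seq_len(plan$max_epochs)) {
    bp <- ann_mse_grad(theta, x_tr, t_tr)
    if (!is.finite(bp$mse))
      vr_stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
              "divergence")
    g <- bp$grad
    sg <- sign(g) * sign(g_prev)
    delta <- ifelse(sg > 0, pmin(delta * plan$eta_plus, plan$delta_max),
                    ifelse(sg < 0, pmax(delta * plan$eta_minus, plan$delta_min),
                           delta))
    g[sg < 0] <- 0                        # iRprop-: forget flipped gradients
    theta <- theta - sign(g) * delta
    g_prev <- g

    v_mse <- mean((ann_forward(model_with_theta(model, theta), x_val) - t_val)^2)
    tr_mse <- c(tr_mse, bp$mse); val_mse <- c(val_mse, v_mse)
    if (v_mse < best$mse) {
      best <- list(mse = v_mse, theta = theta, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= plan$patience) break
    }
  }

  out <- model_with_theta(model, best$theta)
  out$trained <- TRUE
  out$training <- c(model$training,
                    list(epochs_run = length(tr_mse), best_epoch = best$epoch,
                         best_val_mse = best$mse, val_fold = as.integer(val_fold),
                         train_mse = tr_mse, val_mse = val_mse,
                         plan_seed = plan$seed))
  out
}

#' Multistart training with selection on the evaluation subset
#'
#' Splits the pool 80:20 (by `plan$split_ratio`) with a seed-deterministic
#' shuffle, trains `plan$n_restarts` independently initialised networks on
#' the training subset (each with a rotating early-stopping validation
#' fold), and returns the network with the lowest mean squared error on the
#' evaluation subset.
#'
#' @param patterns Input patterns (list or 100 x n matrix).
#' @param targets Reference compliances (ml/cmH2O).
#' @param plan A [training_plan()].
#' @return The selected `ann_model`; `$training` additionally records the
#'   restart losses, selected restart index and the evaluation split.
#' @export
train_ensemble_select_best <- function(patterns, targets, plan = training_plan()) {
  stopifnot(inherits(plan, "training_plan"))
  vr_check(plan$n_restarts >= 1, "n_restarts must be >= 1", "invalid_configuration")
  x <- patterns_to_matrix(patterns)
  t <- as.numeric(targets)
  n <- ncol(x)
  vr_check(n >= plan$cv_folds + 2,
           "pool too small for the configured folds", "invalid_configuration")

  rng <- withr::with_seed(plan$seed, {
    perm <- sample.int(n)
    restart_seeds <- sample.int(.Machine$integer.max - 1L, plan$n_restarts)
    list(perm = perm, restart_seeds = restart_seeds)
  })
  n_train <- max(plan$cv_folds, round(plan$split_ratio * n))
  train_idx <- sort(rng$perm[seq_len(n_train)])
  eval_idx <- sort(rng$perm[-seq_len(n_train)])
  vr_check(length(eval_idx) >= 1, "evaluation subset is empty",
           "invalid_configuration")
  folds <- withr::with_seed(plan$seed,
    sample(rep_len(seq_len(plan$cv_folds), length(train_idx))))

  x_tr <- x[, train_idx, drop = FALSE]; t_tr <- t[train_idx]
  x_ev <- x[, eval_idx, drop = FALSE]; t_ev <- t[eval_idx]

  best <- NULL
  restart_mse <- numeric(plan$n_restarts)
  for (r in seq_len(plan$n_restarts)) {
    m0 <- ann_init(seed = rng$restart_seeds[r])
    vf <- ((r - 1L) %% plan$cv_folds) + 1L
    m <- rprop_train(m0, x_tr, t_tr, plan = plan,
                     fold_assignment = folds, val_fold = vf)
    restart_mse[r] <- mean((ann_forward(m, x_ev) - t_ev)^2)
    if (is.null(best) || restart_mse[r] < best$mse)
      best <- list(model = m, mse = restart_mse[r], restart = r)
  }
  model <- best$model
  model$training <- c(model$training,
                      list(restart_mse = restart_mse,
                           selected_restart = best$restart,
                           eval_mse = best$mse,
                           train_idx = train_idx, eval_idx = eval_idx,
                           n_restarts = plan$n_restarts))
  model
}

#' @export
print.ann_model <- function(x, ...) {
  cat("<ann_model> 100-25-1 multilayer perceptron (logsig/logsig/linear)",
      if (x$trained) "[trained]" else "[untrained]", "\n")
  if (x$trained && !is.null(x$training$eval_mse))
    cat(sprintf("  selected restart %d/%d, evaluation MSE %.4g (ml/cmH2O)^2\n",
                x$training$selected_restart, x$training$n_restarts,
                x$training$eval_mse))
  invisible(x)
}

# ---- serialization -------------------------------------------------------

# Doubles are serialised via sprintf("%.17g"), which round-trips IEEE
# doubles exactly, so a loaded model reproduces predictions bit-for-bit.
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)

#' Write / read a network model as flat JSON
#'
#' The file holds layer sizes, activation names, weights (as full-precision
#' decimal strings, so the round trip is bit-exact) and training metadata.
#'
#' @param model An `ann_model`.
#' @param path File path.
#' @return `write_ann_model` returns `path` invisibly; `read_ann_model`
#'   returns the restored `ann_model`.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  meta <- model$training
  meta$train_mse <- NULL; meta$val_mse <- NULL   # bulky per-epoch curves
  obj <- list(
    class = "ann_model",
    layers = model$layers,
    activations = model$activations,
    theta = num_to_chr(theta_of(model)),
    trained = model$trained,
    training = meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  vr_check(file.exists(path), paste("no such model file:", path), "format_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vr_check(identical(obj$class, "ann_model") && length(obj$theta) == ANN_N_PAR,
           "not a serialized ann_model", "format_error")
  m <- structure(
    list(layers = as.integer(obj$layers),
         activations = obj$activations,
         trained = isTRUE(obj$trained),
         training = obj$training),
    class = "ann_model")
  model_with_theta(m, chr_to_num(obj$theta))
}
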