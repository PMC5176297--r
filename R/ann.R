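#' Configuration of the neural-network meta-learner
#'
#' The meta-learner is a fully connected M-input, H-hidden, 1-output
#' network with logistic activations in every hidden node and in the
#' output node, so its output is a score in (0, 1); scores at or above
#' the decision threshold (0.5) are positive calls. It is trained by
#' per-sample (shuffled) gradient descent, and training stops early when
#' accuracy on a held-out test subset has not improved for `patience`
#' consecutive epochs.
#'
#' @param n_inputs Number of input features M (one per ensemble member).
#' @param n_hidden Hidden-layer size H. The explored range is 5--60 with
#'   20 the tuned default; values outside that range trigger a warning,
#'   not an error.
#' @param learning_rate Step size of the per-sample gradient updates.
#' @param max_epochs Hard cap on training epochs.
#' @param patience Early-stopping patience in epochs (default 100).
#' @param init_scale Half-width of the uniform weight initialization.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param loss `"mse"` (squared error against 0/1 targets, the default for
#'   logistic-output networks of this design) or `"logloss"`.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(n_inputs, n_hidden = 20L, learning_rate = 0.1,
                       max_epochs = 1000L, patience = 100L,
                       init_scale = 0.5, seed = 1L,
                       loss = c("mse", "logloss")) {
  loss <- match.arg(loss)
  n_inputs <- as.integer(n_inputs); n_hidden <- as.integer(n_hidden)
  if (n_inputs < 1L || n_hidden < 1L)
    stop("n_inputs and n_hidden must be positive", call. = FALSE)
  if (n_hidden < 5L || n_hidden > 60L)
    warning("hidden-layer size ", n_hidden,
            " is outside the explored range 5-60", call. = FALSE)
  stopifnot(learning_rate > 0, init_scale >= 0, patience >= 1L,
            max_epochs >= 1L)
  structure(list(n_inputs = n_inputs, n_hidden = n_hidden,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 init_scale = init_scale, seed = as.integer(seed),
                 loss = loss),
            class = "ann_config")
}

#' Initialize a network from a configuration
#'
#' Weights are drawn i.i.d. uniform on `[-init_scale, init_scale]` from the
#' seeded generator; biases start at zero.
#'
#' @param config An [ann_config()].
#' @return An object of class `ann_model` with fields `W1` (H x M), `b1`
#'   (H), `W2` (H), `b2` (scalar) and `threshold` (0.5).
#' @export
ann_init <- function(config) {
  stopifnot(inherits(config, "ann_config"))
  m <- config$n_inputs; h <- config$n_hidden; s <- config$init_scale
  with_preserved_rng({
    set.seed(config$seed)
    W1 <- matrix(stats::runif(h * m, -s, s), h, m)
    W2 <- stats::runif(h, -s, s)
  })
  structure(list(W1 = W1, b1 = numeric(h), W2 = W2, b2 = 0,
                 threshold = 0.5),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat("<ann_model> ", ncol(x$W1), " -> ", nrow(x$W1),
      " -> 1, logistic activations, threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Forward pass of the meta-learner
#'
#' @param model An `ann_model`.
#' @param x Length-M numeric vector, or an N x M matrix for a vectorized
#'   pass over rows.
#' @return Score(s) strictly inside (0, 1).
#' @export
ann_forward <- function(model, x) {
  stopifnot(inherits(model, "ann_model"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != ncol(model$W1))
    stop("input has ", ncol(X), " features, model expects ",
         ncol(model$W1), call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite input", call. = FALSE)
  H <- logistic(X %*% t(model$W1) + matrix(model$b1, nrow(X),
                                           length(model$b1), byrow = TRUE))
  out <- logistic(drop(H %*% model$W2 + model$b2))
  if (is.matrix(x)) out else out[[1L]]
}

logistic <- function(z) 1 / (1 + exp(-z))

#' Turn a network score into a class call
#'
#' Scores at or above the threshold are positive calls (+1); below, -1.
#'
#' @param score Numeric score(s) in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @return Integer vector of calls in `{+1, -1}`.
#' @export
ann_classify <- function(score, threshold = 0.5) {
  stopifnot(all(score >= 0 & score <= 1))
  ifelse(score >= threshold, 1L, -1L)
}

#' Train the meta-learner with test-subset early stopping
#'
#' Runs per-sample gradient descent over shuffled training samples, one
#' full pass per epoch. After each epoch the accuracy on the test subset
#' is computed; when it has not exceeded its running maximum for
#' `patience` consecutive epochs, training stops and the model snapshot
#' from the best epoch (earliest on ties) is returned. Class labels +1/-1
#' are mapped to targets 1/0 internally.
#'
#' @param config An [ann_config()].
#' @param train,test `feature_matrix` objects sharing the same columns;
#'   `test` is the early-stopping monitor, not the validation set.
#' @return List with `model` (the best-epoch `ann_model`) and `history`
#'   (class `train_history`: per-epoch `train_loss` and `test_acc`,
#'   `best_epoch`, `best_acc`, `stopped_reason`).
#' @export
ann_train <- function(config, train, test) {
  stopifnot(inherits(config, "ann_config"),
            inherits(train, "feature_matrix"),
            inherits(test, "feature_matrix"))
  if (nrow(train$X) == 0L || nrow(test$X) == 0L)
    stop("empty training or test set", call. = FALSE)
  if (ncol(train$X) != config$n_inputs || ncol(test$X) != config$n_inputs)
    stop("feature count does not match config$n_inputs", call. = FALSE)
  model <- ann_init(config)
  targets <- ifelse(train$labels == 1L, 1, 0)
  fit <- with_preserved_rng({
    set.seed(config$seed + 1L)  # shuffle stream, distinct from init
    cpp_train_ann(train$X, targets, test$X, as.integer(test$labels),
                  model$W1, model$b1, model$W2, model$b2,
                  config$learning_rate, config$max_epochs, config$patience,
                  if (config$loss == "mse") 0L else 1L, model$threshold)
  })
  if (fit$bad_epoch > 0)
    stop("training diverged (non-finite loss) at epoch ", fit$bad_epoch,
         call. = FALSE)
  best <- structure(list(W1 = fit$W1, b1 = fit$b1, W2 = fit$W2,
                         b2 = fit$b2, threshold = model$threshold),
                    class = "ann_model")
  history <- structure(
    list(train_loss = fit$history[, 1L], test_acc = fit$history[, 2L],
         best_epoch = fit$best_epoch, best_acc = fit$best_acc,
         stopped_reason = fit$stopped),
    class = "train_history")
  list(model = best, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat("<train_history> ", length(x$train_loss), " epochs, best epoch ",
      x$best_epoch, " (test ACC ", sprintf("%.3f", x$best_acc),
      "), stopped: ", x$stopped_reason, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore a trained network
#'
#' @param model An `ann_model`.
#' @param path YAML path.
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "ann_model"))
  yaml::write_yaml(list(
    W1 = apply(model$W1, 1L, as.numeric, simplify = FALSE),
    b1 = as.numeric(model$b1), W2 = as.numeric(model$W2),
    b2 = as.numeric(model$b2), threshold = model$threshold),
    path, precision = 17L)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(list(W1 = do.call(rbind, lapply(obj$W1, as.numeric)),
                 b1 = as.numeric(obj$b1), W2 = as.numeric(obj$W2),
                 b2 = as.numeric(obj$b2), threshold = obj$threshold),
            class = "ann_model")
}

# ---- pure-R reference implementations (used by tests as an independent
# route against the compiled trainer, and for the finite-difference
# gradient check) -----------------------------------------------------------

# backprop gradients of the per-sample loss w.r.t. all parameters
ann_gradients <- function(model, x, target, loss = c("mse", "logloss")) {
  loss <- match.arg(loss)
  z1 <- drop(model$W1 %*% x) + model$b1
  hid <- logistic(z1)
  z2 <- sum(model$W2 * hid) + model$b2
  o <- logistic(z2)
  delta2 <- if (loss == "mse") 2 * (o - target) * o * (1 - o) else o - target
  delta1 <- delta2 * model$W2 * hid * (1 - hid)
  list(W1 = outer(delta1, x), b1 = delta1,
       W2 = delta2 * hid, b2 = delta2)
}

ann_loss <- function(model, x, target, loss = c("mse", "logloss")) {
  loss <- match.arg(loss)
  o <- ann_forward(model, x)
  if (loss == "mse") (o - target)^2
  else -target * log(o + 1e-12) - (1 - target) * log(1 - o + 1e-12)
}

# the same Fisher-Yates shuffle the compiled trainer draws from R's RNG
fisher_yates <- function(n) {
  perm <- seq_len(n)
  for (i in n:2) {
    j <- floor(stats::runif(1) * i) + 1
    if (j > i) j <- i
    tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
  }
  perm
}

# one shuffled epoch of per-sample updates; mirrors the compiled loop
ann_epoch_reference <- function(model, X, targets, lr,
                                loss = c("mse", "logloss")) {
  loss <- match.arg(loss)
  perm <- fisher_yates(nrow(X))
  loss_sum <- 0
  for (i in perm) {
    x <- X[i, ]
    loss_sum <- loss_sum + ann_loss(model, x, targets[i], loss)
    g <- ann_gradients(model, x, targets[i], loss)
    model$W1 <- model$W1 - lr * g$W1
    model$b1 <- model$b1 - lr * g$b1
    model$W2 <- model$W2 - lr * g$W2
    model$b2 <- model$b2 - lr * g$b2
  }
  list(model = model, mean_loss = loss_sum / nrow(X))
}
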