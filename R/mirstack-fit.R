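#' Fit a stacked meta-predictor on a score panel
#'
#' The one-stop fitting function: restricts the panel to the chosen
#' ensemble, fits the staged preprocessing transform on the training
#' samples, trains the logistic-network meta-learner with early stopping
#' on a held-out monitor subset, and returns a self-contained model that
#' can score new panels with [predict.mirstack()].
#'
#' If no explicit `monitor` table is supplied, a stratified
#' `monitor_fraction` of the input is split off (seeded) as the
#' early-stopping monitor; the transform is fitted on the remaining
#' training samples only.
#'
#' @param table A [score_table()] of labelled training samples.
#' @param preprocess `"I"`, `"II"` or `"III"` (default: the full pipeline
#'   with sentinels, log and PCA rotation).
#' @param ensemble Predictor names to combine; default all columns.
#' @param log_columns Stage-II/III log columns; `NULL` auto-selects numeric
#'   columns whose dialect admits the `NA` token.
#' @param monitor Optional [score_table()] used as the early-stopping test
#'   subset instead of an internal split.
#' @param monitor_fraction Fraction split off as monitor when `monitor` is
#'   `NULL` (default 1/3, mirroring the 1 train : 1 test : 1 validation
#'   three-fold usage on small panels).
#' @param n_hidden,learning_rate,max_epochs,patience,init_scale,loss
#'   Passed to [ann_config()].
#' @param seed Seed for the monitor split, weight initialization and
#'   epoch shuffling.
#' @return An object of class `mirstack` with components `params`
#'   (fitted `transform_params`), `model` (`ann_model`), `history`
#'   (`train_history`), `ensemble`, `preprocess`, `monitor_metrics`
#'   (a `metric_set` on the monitor subset) and `call`.
#' @examples
#' panel <- generate_panel(synthetic_config(120, 120, seed = 3))
#' fit <- mirstack(panel, max_epochs = 50, patience = 10, seed = 3)
#' fit
#' head(predict(fit, panel, type = "class"))
#' @export
mirstack <- function(table, preprocess = c("III", "II", "I"),
                     ensemble = NULL, log_columns = NULL,
                     monitor = NULL, monitor_fraction = 1 / 3,
                     n_hidden = 20L, learning_rate = 0.1,
                     max_epochs = 1000L, patience = 100L,
                     init_scale = 0.5, loss = c("mse", "logloss"),
                     seed = 1L) {
  preprocess <- match.arg(preprocess)
  loss <- match.arg(loss)
  stopifnot(inherits(table, "score_table"))
  if (is.null(ensemble)) ensemble <- names(table$specs)
  sub <- subset_predictors(table, ensemble)
  if (is.null(monitor)) {
    stopifnot(monitor_fraction > 0, monitor_fraction < 0.5)
    k <- max(3L, as.integer(round(1 / monitor_fraction)))
    plan <- make_folds(sub, k, seed = seed)
    mon_idx <- which(plan$assignment[sub$sample_ids] == 0L)
    monitor_tab <- take_rows(sub, mon_idx)
    train_tab <- take_rows(sub, setdiff(seq_along(sub$sample_ids), mon_idx))
  } else {
    stopifnot(inherits(monitor, "score_table"))
    monitor_tab <- subset_predictors(monitor, ensemble)
    train_tab <- sub
  }
  log_columns <- resolve_log_columns(train_tab, log_columns, preprocess)
  fit <- switch(preprocess,
                I = fit_transform_I(train_tab),
                II = fit_transform_II(train_tab, log_columns),
                III = fit_transform_III(train_tab, log_columns))
  fm_mon <- apply_transform(fit$params, monitor_tab)
  config <- ann_config(n_inputs = length(ensemble), n_hidden = n_hidden,
                       learning_rate = learning_rate,
                       max_epochs = max_epochs, patience = patience,
                       init_scale = init_scale, seed = seed, loss = loss)
  trained <- ann_train(config, fit$features, fm_mon)
  calls <- ann_classify(ann_forward(trained$model, fm_mon$X),
                        trained$model$threshold)
  structure(list(params = fit$params, model = trained$model,
                 history = trained$history, ensemble = ensemble,
                 preprocess = preprocess, config = config,
                 monitor_metrics = metrics(confusion(fm_mon$labels, calls)),
                 n_train = length(train_tab$sample_ids),
                 n_monitor = length(monitor_tab$sample_ids),
                 call = match.call()),
            class = "mirstack")
}

#' @export
print.mirstack <- function(x, ...) {
  cat("Stacked meta-predictor (", length(x$ensemble), " base predictors, stage ",
      x$preprocess, " preprocessing)\n", sep = "")
  cat("  ensemble: ", paste(x$ensemble, collapse = ", "), "\n", sep = "")
  cat("  network: ", x$config$n_inputs, " -> ", x$config$n_hidden,
      " -> 1 (logistic), best epoch ", x$history$best_epoch, "\n", sep = "")
  cat("  monitor subset (n = ", x$n_monitor, "): ", sep = "")
  print(x$monitor_metrics)
  invisible(x)
}

#' @export
summary.mirstack <- function(object, ...) {
  structure(list(fit = object), class = "summary.mirstack")
}

#' @export
print.summary.mirstack <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  training samples: ", f$n_train, "; epochs run: ",
      length(f$history$train_loss), " (stopped: ",
      f$history$stopped_reason, ")\n", sep = "")
  cat("  final train loss: ",
      sprintf("%.4f", utils::tail(f$history$train_loss, 1L)), "\n", sep = "")
  if (!is.null(f$params$eigenvalues))
    cat("  PCA eigenvalues: ",
        paste(sprintf("%.3f", f$params$eigenvalues), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Score new samples with a fitted meta-predictor
#'
#' @param object A fitted [mirstack()] model.
#' @param newdata A [score_table()] containing (at least) the ensemble's
#'   predictor columns.
#' @param type `"response"` for the network score in (0,1), `"class"` for
#'   +1/-1 calls at the fitted threshold.
#' @param ... Unused.
#' @return Named numeric (or integer) vector, one entry per sample.
#' @export
predict.mirstack <- function(object, newdata,
                             type = c("response", "class"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "score_table"))
  fm <- apply_transform(object$params,
                        subset_predictors(newdata, object$ensemble))
  score <- ann_forward(object$model, fm$X)
  names(score) <- fm$sample_ids
  if (type == "response") score
  else ann_classify(score, object$model$threshold)
}

#' @export
coef.mirstack <- function(object, ...) {
  list(W1 = object$model$W1, b1 = object$model$b1,
       W2 = object$model$W2, b2 = object$model$b2)
}

#' Plot the training history of a fitted meta-predictor
#'
#' Two stacked panels: per-epoch training loss and monitor-subset accuracy,
#' with the best (snapshot) epoch marked.
#'
#' @param x A fitted [mirstack()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mirstack <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(seq_along(h$train_loss), h$train_loss, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  graphics::plot(seq_along(h$test_acc), h$test_acc, type = "l",
                 xlab = "epoch", ylab = "monitor ACC", ylim = c(0, 1), ...)
  graphics::abline(v = h$best_epoch, lty = 2)
  invisible(x)
}

#' Evaluate a fitted meta-predictor on a labelled panel
#'
#' @param object A fitted [mirstack()] model.
#' @param table A labelled [score_table()].
#' @return A `metric_set`.
#' @export
evaluate_mirstack <- function(object, table) {
  calls <- predict(object, table, type = "class")
  metrics(confusion(table$labels, calls))
}
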