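#' Stratified fold plan
#'
#' Samples are shuffled within each class with a seeded generator and dealt
#' round-robin to `k` folds, so per-fold positive and negative counts differ
#' from the stratified ideal by at most one. At least three folds are needed
#' because every rotation uses disjoint train / test (early-stopping monitor)
#' / validation subsets.
#'
#' @param table A [score_table()].
#' @param k Number of folds (>= 3).
#' @param seed Integer seed for the within-class shuffles.
#' @return An object of class `fold_plan`: `k`, `seed`, and `assignment`, a
#'   named integer vector mapping sample id to fold index `0..k-1`.
#' @export
make_folds <- function(table, k, seed = 1L) {
  stopifnot(inherits(table, "score_table"))
  k <- as.integer(k)
  if (k < 3L)
    stop("k must be >= 3 (train/test/validation must be disjoint)",
         call. = FALSE)
  for (cls in c(1L, -1L)) {
    n_cls <- sum(table$labels == cls)
    if (n_cls < k)
      stop("class ", cls, " has ", n_cls, " samples, fewer than k = ", k,
           call. = FALSE)
  }
  assignment <- integer(length(table$sample_ids))
  names(assignment) <- table$sample_ids
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (cls in c(1L, -1L)) {
      idx <- which(table$labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- (seq_along(idx) - 1L) %% k
    }
  })
  structure(list(k = k, seed = as.integer(seed), assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> k = ", x$k, ", ", length(x$assignment),
      " samples, seed ", x$seed, "\n", sep = "")
  print(table(fold = x$assignment))
  invisible(x)
}

#' Cross-validated meta-prediction
#'
#' Runs the full pipeline under a k-fold rotation: in rotation `r` the
#' validation subset is fold `r`, the early-stopping test subset is fold
#' `(r + 1) mod k`, and the remaining folds train the model. The
#' preprocessing transform (including the PCA rotation of stage III) is
#' fitted on the training folds only and replayed on the test and
#' validation folds, so no information leaks; the network is freshly
#' initialized each rotation with a seed derived from the master seed.
#' Metrics on the validation fold are computed with the best-epoch model
#' and averaged over the `k` rotations with standard errors
#' (`SD/sqrt(k)`, SD with the n-1 divisor).
#'
#' @param table A [score_table()].
#' @param k Number of folds.
#' @param preprocess `"I"`, `"II"` or `"III"` — which staged transform to
#'   fit per rotation.
#' @param config An [ann_config()] (its `n_inputs` must match the ensemble
#'   size; its `seed` is combined with the rotation index).
#' @param ensemble Character vector of predictor names to combine; default
#'   all predictors in `table`.
#' @param log_columns Numeric columns for the stage-II/III sentinel+log
#'   path. `NULL` auto-selects numeric columns whose dialect admits the
#'   `NA` token (the heavy-tailed probability-ratio style).
#' @param seed Master seed: drives the fold plan and the per-rotation
#'   network seeds.
#' @return An object of class `cv_result`: `per_rotation` data frame
#'   (rotation, SENS, SPEC, ACC, MCC), `mean` and `se` named vectors,
#'   `histories` (list of `train_history`), plus the fold plan and call
#'   parameters.
#' @export
run_cv <- function(table, k, preprocess = c("III", "II", "I"), config,
                   ensemble = NULL, log_columns = NULL, seed = 1L) {
  preprocess <- match.arg(preprocess)
  stopifnot(inherits(table, "score_table"), inherits(config, "ann_config"))
  if (is.null(ensemble)) ensemble <- names(table$specs)
  sub <- subset_predictors(table, ensemble)
  if (config$n_inputs != length(ensemble))
    stop("config$n_inputs (", config$n_inputs,
         ") must equal the ensemble size (", length(ensemble), ")",
         call. = FALSE)
  log_columns <- resolve_log_columns(sub, log_columns, preprocess)
  plan <- make_folds(sub, k, seed = seed)
  fold_of <- plan$assignment[sub$sample_ids]
  rows <- vector("list", k)
  histories <- vector("list", k)
  for (r in seq_len(k) - 1L) {
    val_idx <- which(fold_of == r)
    test_idx <- which(fold_of == (r + 1L) %% k)
    train_idx <- which(!(fold_of %in% c(r, (r + 1L) %% k)))
    tr <- take_rows(sub, train_idx)
    fit <- switch(preprocess,
                  I = fit_transform_I(tr),
                  II = fit_transform_II(tr, log_columns),
                  III = fit_transform_III(tr, log_columns))
    fm_train <- fit$features
    fm_test <- apply_transform(fit$params, take_rows(sub, test_idx))
    fm_val <- apply_transform(fit$params, take_rows(sub, val_idx))
    rot_config <- config
    rot_config$seed <- derive_seed(seed, config$seed, r)
    trained <- tryCatch(
      ann_train(rot_config, fm_train, fm_test),
      error = function(e)
        stop("rotation ", r, ": ", conditionMessage(e), call. = FALSE))
    calls <- ann_classify(ann_forward(trained$model, fm_val$X),
                          trained$model$threshold)
    ms <- metrics(confusion(fm_val$labels, calls))
    rows[[r + 1L]] <- data.frame(rotation = r, SENS = ms$SENS,
                                 SPEC = ms$SPEC, ACC = ms$ACC, MCC = ms$MCC)
    histories[[r + 1L]] <- trained$history
  }
  per_rotation <- do.call(rbind, rows)
  vals <- as.matrix(per_rotation[, c("SENS", "SPEC", "ACC", "MCC")])
  structure(list(per_rotation = per_rotation,
                 mean = colMeans(vals),
                 se = apply(vals, 2L, stats::sd) / sqrt(k),
                 histories = histories, fold_plan = plan,
                 preprocess = preprocess, ensemble = ensemble,
                 k = k, seed = as.integer(seed)),
            class = "cv_result")
}

take_rows <- function(table, idx) {
  score_table(table$sample_ids[idx], table$labels[idx], table$specs,
              table$raw[idx, , drop = FALSE])
}

# per-rotation / per-ensemble seeds, kept well inside 32-bit range
derive_seed <- function(master, base, r) {
  as.integer((as.numeric(master) * 1009 + as.numeric(base) + 7919 *
                as.numeric(r)) %% 2147483629)
}

resolve_log_columns <- function(table, log_columns, preprocess) {
  if (preprocess == "I") return(character())
  if (is.null(log_columns)) {
    auto <- vapply(table$specs, function(sp)
      sp$output_kind == "numeric" && sp$na_policy == "sentinel", logical(1))
    return(names(table$specs)[auto])
  }
  intersect(log_columns, names(table$specs))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$k, "-fold, stage ", x$preprocess, ", ensemble {",
      paste(x$ensemble, collapse = ", "), "}\n", sep = "")
  cat(sprintf(
    "  SENS %.1f +/- %.1f%%  SPEC %.1f +/- %.1f%%  ACC %.1f +/- %.1f%%  MCC %.2f +/- %.2f\n",
    100 * x$mean["SENS"], 100 * x$se["SENS"],
    100 * x$mean["SPEC"], 100 * x$se["SPEC"],
    100 * x$mean["ACC"], 100 * x$se["ACC"],
    x$mean["MCC"], x$se["MCC"]))
  invisible(x)
}

#' Cross-validate every ensemble of the panel's predictors
#'
#' Enumerates all predictor subsets of size >= `min_size` (26 for five
#' predictors) and runs [run_cv()] on each with the same master seed, so
#' every ensemble sees the same fold plan restricted to its columns.
#'
#' @inheritParams run_cv
#' @param min_size Smallest ensemble size (default 2).
#' @return An object of class `ensemble_sweep`: `results` (named list of
#'   `cv_result`), `summary` data frame (ensemble, size, per-metric mean
#'   and SE), and `best`, the ensemble name with the highest mean ACC.
#' @export
sweep_ensembles <- function(table, k, preprocess = c("III", "II", "I"),
                            config, log_columns = NULL, seed = 1L,
                            min_size = 2L) {
  preprocess <- match.arg(preprocess)
  ensembles <- enumerate_ensembles(names(table$specs), min_size)
  results <- vector("list", length(ensembles))
  names(results) <- vapply(ensembles, paste, character(1), collapse = "+")
  for (i in seq_along(ensembles)) {
    cfg <- config
    cfg$n_inputs <- length(ensembles[[i]])
    results[[i]] <- run_cv(table, k, preprocess, cfg,
                           ensemble = ensembles[[i]],
                           log_columns = log_columns, seed = seed)
  }
  summary <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(ensemble = nm, size = length(r$ensemble),
               mean_acc = unname(r$mean["ACC"]), se_acc = unname(r$se["ACC"]),
               mean_sens = unname(r$mean["SENS"]),
               mean_spec = unname(r$mean["SPEC"]),
               mean_mcc = unname(r$mean["MCC"]))
  }))
  structure(list(results = results, summary = summary,
                 best = summary$ensemble[which.max(summary$mean_acc)]),
            class = "ensemble_sweep")
}

#' @export
print.ensemble_sweep <- function(x, ...) {
  cat("<ensemble_sweep> ", nrow(x$summary), " ensembles; best by mean ACC: ",
      x$best, " (", sprintf("%.1f%%",
                            100 * max(x$summary$mean_acc)), ")\n", sep = "")
  by_size <- split(x$summary$mean_acc, x$summary$size)
  for (s in names(by_size))
    cat(sprintf("  size %s: ACC %.1f-%.1f%% over %d ensembles\n", s,
                100 * min(by_size[[s]]), 100 * max(by_size[[s]]),
                length(by_size[[s]])))
  invisible(x)
}

#' Export a cross-validation result
#'
#' Writes per-rotation rows plus a mean/SE summary row as TSV, and the same
#' content as JSON when `json_path` is given.
#'
#' @param result A `cv_result`.
#' @param path TSV output path.
#' @param json_path Optional JSON output path.
#' @export
write_cv_result <- function(result, path, json_path = NULL) {
  stopifnot(inherits(result, "cv_result"))
  pr <- result$per_rotation
  summary_rows <- data.frame(
    rotation = c("mean", "se"),
    SENS = c(result$mean["SENS"], result$se["SENS"]),
    SPEC = c(result$mean["SPEC"], result$se["SPEC"]),
    ACC = c(result$mean["ACC"], result$se["ACC"]),
    MCC = c(result$mean["MCC"], result$se["MCC"]))
  pr$rotation <- as.character(pr$rotation)
  utils::write.table(rbind(pr, summary_rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(k = result$k, preprocess = result$preprocess,
           ensemble = result$ensemble, seed = result$seed,
           per_rotation = result$per_rotation,
           mean = as.list(result$mean), se = as.list(result$se)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
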