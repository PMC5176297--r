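#' @title Staged preprocessing of raw predictor scores
#' @description
#' Before the meta-learner can consume a score table, the heterogeneous
#' predictor outputs must be numericalized and brought onto a common scale.
#' Three staged transforms are provided:
#'
#' * **stage I** — binary tokens become +1/-1; each numeric column is
#'   min-max scaled onto `[-1, 1]` using bounds fitted on the training
#'   data (`NA` cells of numeric columns are first pooled with the raw
#'   value 0).
#' * **stage II** — as stage I, except that designated heavy-tailed
#'   ("log") columns are first mapped through sentinels and a natural
#'   logarithm: `NA -> -30`, exact `0 -> -25`, positive `x -> ln(x)`;
#'   the sentinels sit strictly below the log of any score the dialects
#'   can emit (ln 1e-10 ~ -23.03), so the ordering no-call < zero < score
#'   is preserved.
#' * **stage III** — stage II followed by a principal-component rotation
#'   `Y' = Y %*% E`, where `E` is the eigenvector matrix of the covariance
#'   of the (column-centred) stage-II features.
#'
#' Fitting returns the frozen transform state (`transform_params`) together
#' with the transformed training features; [apply_transform()] replays a
#' fit on new data without refitting, which is what keeps cross-validation
#' folds leak-free.
#' @name preprocess
NULL

#' Fit the stage-I transform (numericalize + normalize)
#'
#' @param table A [score_table()].
#' @return List with components `params` (a `transform_params`) and
#'   `features` (a `feature_matrix`: `sample_ids`, numeric matrix `X`,
#'   `labels`).
#' @rdname preprocess
#' @export
fit_transform_I <- function(table) {
  fit_transform_stage(table, mode = "I", log_columns = character())
}

#' Fit the stage-II transform (sentinels + log on selected columns)
#'
#' @param log_columns Character vector of numeric predictor names to run
#'   through the sentinel/log path (every non-special training value must
#'   be strictly positive).
#' @rdname preprocess
#' @export
fit_transform_II <- function(table, log_columns) {
  fit_transform_stage(table, mode = "II", log_columns = log_columns)
}

#' Fit the stage-III transform (stage II + PCA rotation)
#'
#' Requires more samples than predictors (N > M).
#' @rdname preprocess
#' @export
fit_transform_III <- function(table, log_columns) {
  fit_transform_stage(table, mode = "III", log_columns = log_columns)
}

fit_transform_stage <- function(table, mode, log_columns) {
  stopifnot(inherits(table, "score_table"))
  unknown <- setdiff(log_columns, names(table$specs))
  if (length(unknown))
    stop("log column(s) not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- length(table$sample_ids)
  m <- length(table$specs)
  if (mode == "III" && n <= m)
    stop("PCA rotation needs more samples than predictors (N > M); got N = ",
         n, ", M = ", m, call. = FALSE)
  columns <- list()
  X <- matrix(NA_real_, n, m, dimnames = list(table$sample_ids,
                                              names(table$specs)))
  for (nm in names(table$specs)) {
    sp <- table$specs[[nm]]
    col <- table$raw[[nm]]
    if (sp$output_kind == "binary") {
      columns[[nm]] <- list(kind = "binary",
                            positive_token = sp$positive_token)
      X[, nm] <- ifelse(as.character(col) == sp$positive_token, 1, -1)
    } else {
      log_shift <- nm %in% log_columns
      if (log_shift) {
        if (any(!is.na(col) & col < 0))
          stop("log column '", nm, "' has a negative value", call. = FALSE)
        v <- shifted_log(col, na_sentinel = -30, zero_sentinel = -25)
      } else {
        v <- col
        v[is.na(v)] <- 0  # stage I has no NA sentinel: pool with numeric 0
      }
      if (!any(is.finite(v)))
        stop("numeric column '", nm, "' has no finite values", call. = FALSE)
      lo <- min(v); hi <- max(v)
      constant <- (hi - lo) < .Machine$double.eps * max(1, abs(hi))
      columns[[nm]] <- list(kind = "numeric", log_shift = log_shift,
                            na_sentinel = -30, zero_sentinel = -25,
                            norm_lo = lo, norm_hi = hi, constant = constant)
      X[, nm] <- if (constant) 0 else 2 * (v - lo) / (hi - lo) - 1
    }
  }
  params <- structure(list(mode = mode, columns = columns,
                           eigenmatrix = NULL, column_means = NULL,
                           eigenvalues = NULL),
                      class = "transform_params")
  if (mode == "III") {
    pca <- fit_pca(X)
    params$eigenmatrix <- pca$eigenmatrix
    params$column_means <- pca$column_means
    params$eigenvalues <- pca$eigenvalues
    X <- apply_pca(X, pca$eigenmatrix, pca$column_means)
  }
  list(params = params,
       features = feature_matrix(table$sample_ids, X, table$labels))
}

shifted_log <- function(col, na_sentinel, zero_sentinel) {
  v <- numeric(length(col))
  v[is.na(col)] <- na_sentinel
  zero <- !is.na(col) & col == 0
  v[zero] <- zero_sentinel
  pos <- !is.na(col) & col > 0
  v[pos] <- log(col[pos])
  v
}

#' Bundle transformed features with ids and labels
#'
#' @param sample_ids Character vector.
#' @param X Numeric N x M matrix.
#' @param labels Integer class vector in `{+1, -1}` aligned with rows.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(sample_ids, X, labels) {
  stopifnot(length(sample_ids) == nrow(X), length(labels) == nrow(X))
  structure(list(sample_ids = as.character(sample_ids), X = X,
                 labels = as.integer(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$X), " x ", ncol(x$X), "\n", sep = "")
  invisible(x)
}

#' @export
print.transform_params <- function(x, ...) {
  cat("<transform_params> stage ", x$mode, ", ", length(x$columns),
      " columns", if (!is.null(x$eigenmatrix)) ", PCA rotation fitted",
      "\n", sep = "")
  invisible(x)
}

#' Principal-component rotation of a feature matrix
#'
#' `fit_pca()` eigendecomposes the sample covariance of the column-centred
#' matrix. Eigenvectors are ordered by descending eigenvalue and sign-fixed
#' so that each column's largest-magnitude entry is positive, making the
#' rotation platform-deterministic. `apply_pca()` centres rows with the
#' stored means and multiplies by `E`; being orthonormal, the rotation
#' preserves row norms and total variance.
#'
#' @param X Numeric N x M matrix with N > M.
#' @return `fit_pca()`: list with `eigenmatrix` (M x M, columns are unit
#'   eigenvectors), `column_means`, `eigenvalues`.
#' @export
fit_pca <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n <= m)
    stop("PCA needs more samples than columns (N > M)", call. = FALSE)
  mu <- colMeans(X)
  S <- stats::cov(X)
  if (sum(diag(S)) <= 0)
    stop("degenerate covariance: zero total variance", call. = FALSE)
  eig <- eigen(S, symmetric = TRUE)
  E <- eig$vectors
  for (j in seq_len(m)) {
    i <- which.max(abs(E[, j]))
    if (E[i, j] < 0) E[, j] <- -E[, j]
  }
  dimnames(E) <- list(colnames(X), paste0("PC", seq_len(m)))
  list(eigenmatrix = E, column_means = mu, eigenvalues = eig$values)
}

#' @param E M x M eigenvector matrix from `fit_pca()`.
#' @param means Length-M column-mean vector from `fit_pca()`.
#' @return `apply_pca()`: the rotated N x M matrix.
#' @rdname fit_pca
#' @export
apply_pca <- function(X, E, means) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(E) || nrow(E) != ncol(E) ||
      length(means) != ncol(X))
    stop("shape mismatch between X, E and means", call. = FALSE)
  out <- sweep(X, 2L, means) %*% E
  rownames(out) <- rownames(X)
  out
}

#' Replay a fitted transform on new data
#'
#' Applies the stored sentinels, log, normalization bounds and (stage III)
#' rotation without refitting. Numeric values outside the fitted training
#' range are clipped to `[-1, 1]` after the affine map, keeping the
#' meta-learner's input domain closed.
#'
#' @param params A fitted `transform_params`.
#' @param table A [score_table()] with the same predictor columns.
#' @return A `feature_matrix`.
#' @export
apply_transform <- function(params, table) {
  stopifnot(inherits(params, "transform_params"),
            inherits(table, "score_table"))
  if (!setequal(names(table$specs), names(params$columns)))
    stop("table columns do not match fitted transform", call. = FALSE)
  n <- length(table$sample_ids)
  nms <- names(params$columns)
  X <- matrix(NA_real_, n, length(nms),
              dimnames = list(table$sample_ids, nms))
  for (nm in nms) {
    cp <- params$columns[[nm]]
    col <- table$raw[[nm]]
    if (cp$kind == "binary") {
      X[, nm] <- ifelse(as.character(col) == cp$positive_token, 1, -1)
    } else {
      if (cp$log_shift) {
        if (any(!is.na(col) & col < 0))
          stop("log column '", nm, "' has a negative value", call. = FALSE)
        v <- shifted_log(col, cp$na_sentinel, cp$zero_sentinel)
      } else {
        v <- col
        v[is.na(v)] <- 0
      }
      if (cp$constant) {
        X[, nm] <- 0
      } else {
        z <- 2 * (v - cp$norm_lo) / (cp$norm_hi - cp$norm_lo) - 1
        X[, nm] <- pmin(1, pmax(-1, z))
      }
    }
  }
  if (!is.null(params$eigenmatrix))
    X <- apply_pca(X, params$eigenmatrix, params$column_means)
  feature_matrix(table$sample_ids, X, table$labels)
}

#' Serialize / restore a fitted transform
#'
#' @param params A `transform_params`.
#' @param path Output (or input) YAML path.
#' @return `write_transform_params()`: `path` invisibly;
#'   `read_transform_params()`: the restored `transform_params`.
#' @export
write_transform_params <- function(params, path) {
  stopifnot(inherits(params, "transform_params"))
  obj <- list(mode = params$mode, columns = params$columns,
              eigenmatrix = if (is.null(params$eigenmatrix)) NULL else
                apply(params$eigenmatrix, 1L, as.numeric, simplify = FALSE),
              eigennames = colnames(params$eigenmatrix),
              rownames = rownames(params$eigenmatrix),
              column_means = as.numeric(params$column_means),
              eigenvalues = as.numeric(params$eigenvalues))
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname write_transform_params
#' @export
read_transform_params <- function(path) {
  obj <- yaml::read_yaml(path)
  E <- NULL
  if (!is.null(obj$eigenmatrix)) {
    E <- do.call(rbind, lapply(obj$eigenmatrix, as.numeric))
    dimnames(E) <- list(obj$rownames, obj$eigennames)
  }
  structure(list(mode = obj$mode,
                 columns = obj$columns,
                 eigenmatrix = E,
                 column_means = if (length(obj$column_means))
                   stats::setNames(as.numeric(obj$column_means),
                                   obj$rownames) else NULL,
                 eigenvalues = if (length(obj$eigenvalues))
                   as.numeric(obj$eigenvalues) else NULL),
            class = "transform_params")
}
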