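#' Confusion counts of a set of class calls
#'
#' @param labels Integer vector of true classes in `{+1, -1}`.
#' @param calls Integer vector of predicted classes, aligned with `labels`.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`; the four always sum to `length(labels)`.
#' @export
confusion <- function(labels, calls) {
  if (length(labels) != length(calls))
    stop("labels and calls must have equal length", call. = FALSE)
  if (!all(labels %in% c(1L, -1L)) || !all(calls %in% c(1L, -1L)))
    stop("labels and calls must be +1 or -1", call. = FALSE)
  confusion_counts(TP = sum(labels == 1L & calls == 1L),
                   FP = sum(labels == -1L & calls == 1L),
                   TN = sum(labels == -1L & calls == -1L),
                   FN = sum(labels == 1L & calls == -1L))
}

#' @param TP,FP,TN,FN Non-negative integers; use this constructor to build
#'   counts directly, e.g. from a published benchmark table.
#' @rdname confusion
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP=", x$TP, " FP=", x$FP, " TN=", x$TN,
      " FN=", x$FN, "\n", sep = "")
  invisible(x)
}

#' The four standard accuracy metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any MCC
#' marginal sum is zero the coefficient is defined as 0 (the usual
#' convention for a degenerate caller).
#'
#' @param counts A `confusion_counts`.
#' @return An object of class `metric_set` with fields `SENS`, `SPEC`,
#'   `ACC` (in `[0,1]`) and `MCC` (in `[-1,1]`). The print method shows
#'   percentages at one decimal and MCC at two, the conventional table
#'   precision; full-precision values are always retained.
#' @examples
#' metrics(confusion_counts(TP = 162, FP = 96, TN = 72, FN = 1))
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  n <- tp + fp + tn + fn
  if (n == 0) stop("all counts are zero; metrics undefined", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("need at least one sample of each class for SENS/SPEC",
         call. = FALSE)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(marg))
  structure(list(SENS = tp / (tp + fn), SPEC = tn / (tn + fp),
                 ACC = (tp + tn) / n, MCC = mcc),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("SENS %.1f%%  SPEC %.1f%%  ACC %.1f%%  MCC %.2f\n",
              100 * x$SENS, 100 * x$SPEC, 100 * x$ACC, x$MCC))
  invisible(x)
}

#' Pairwise overlap and coverage of true predictions
#'
#' Restricted to the samples of one class, counts for every predictor its
#' true calls `T_i`, and for every pair the overlap `O_ij` (samples both
#' call correctly) and the non-redundant union `U_ij` (samples at least
#' one calls correctly). The identities `O_ij <= min(T_i, T_j)` and
#' `U_ij = T_i + T_j - O_ij` hold by construction; the union is an upper
#' bound on what any combiner of the pair can get right on that class.
#'
#' @param labels Integer class vector in `{+1, -1}`.
#' @param calls_by_predictor Named list (or matrix with named columns) of
#'   call vectors aligned with `labels`.
#' @param class_side `"positive"` or `"negative"` — which class to restrict
#'   to.
#' @return An object of class `agreement_matrix`: `side`, `n_samples`,
#'   `true_counts` (named vector), `overlap` and `union` (M x M matrices).
#' @export
pairwise_agreement <- function(labels, calls_by_predictor,
                               class_side = c("positive", "negative")) {
  class_side <- match.arg(class_side)
  if (is.matrix(calls_by_predictor))
    calls_by_predictor <- as.data.frame(calls_by_predictor)
  nms <- names(calls_by_predictor)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("calls_by_predictor must be named", call. = FALSE)
  target <- if (class_side == "positive") 1L else -1L
  keep <- labels == target
  correct <- vapply(calls_by_predictor, function(calls) {
    if (length(calls) != length(labels))
      stop("call vector length mismatch", call. = FALSE)
    calls[keep] == target
  }, logical(sum(keep)))
  correct <- matrix(correct, ncol = length(nms), dimnames = list(NULL, nms))
  true_counts <- colSums(correct)
  O <- crossprod(correct)                       # both correct
  U <- outer(true_counts, true_counts, "+") - O # at least one correct
  structure(list(side = class_side, n_samples = sum(keep),
                 true_counts = true_counts, overlap = O, union = U),
            class = "agreement_matrix")
}

#' @export
print.agreement_matrix <- function(x, ...) {
  cat("<agreement_matrix> ", x$side, " class, ", x$n_samples,
      " samples\n", sep = "")
  print(format_agreement(x), quote = FALSE)
  invisible(x)
}

# table layout: diagonal "T/N", off-diagonal "O/U"
format_agreement <- function(x) {
  nms <- names(x$true_counts)
  out <- matrix("---", length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_along(nms)) {
    out[i, i] <- sprintf("(%d/%d)", x$true_counts[i], x$n_samples)
    for (j in seq_along(nms)) if (j > i)
      out[i, j] <- sprintf("%d/%d", x$overlap[i, j], x$union[i, j])
  }
  out
}

#' Accuracy ceiling implied by pairwise coverage
#'
#' Given the union coverage of a predictor pair on the positive and on the
#' negative samples of one dataset, returns the highest sensitivity,
#' specificity and accuracy any combiner of that pair could reach:
#' `U_pos/P`, `U_neg/N` and `(U_pos+U_neg)/(P+N)`.
#'
#' @param union_pos Union count of true calls on positive samples.
#' @param n_pos Number of positive samples P.
#' @param union_neg Union count of true calls on negative samples.
#' @param n_neg Number of negative samples N.
#' @return List with `SENS`, `SPEC`, `ACC` ceilings, class
#'   `coverage_ceiling`.
#' @examples
#' coverage_ceiling(1608, 1679, 664, 674)
#' @export
coverage_ceiling <- function(union_pos, n_pos, union_neg, n_neg) {
  stopifnot(union_pos <= n_pos, union_neg <= n_neg,
            n_pos > 0, n_neg > 0)
  structure(list(SENS = union_pos / n_pos,
                 SPEC = union_neg / n_neg,
                 ACC = (union_pos + union_neg) / (n_pos + n_neg)),
            class = "coverage_ceiling")
}

#' @export
print.coverage_ceiling <- function(x, ...) {
  cat(sprintf("ceiling: SENS %.1f%%  SPEC %.1f%%  ACC %.1f%%\n",
              100 * x$SENS, 100 * x$SPEC, 100 * x$ACC))
  invisible(x)
}

#' Coverage ceiling of a pair taken from agreement matrices
#'
#' @param pos_agreement,neg_agreement `agreement_matrix` objects for the
#'   positive and negative side of the same sample set.
#' @param pair Character vector of the two predictor names.
#' @return A [coverage_ceiling()].
#' @export
pair_coverage_ceiling <- function(pos_agreement, neg_agreement, pair) {
  stopifnot(inherits(pos_agreement, "agreement_matrix"),
            inherits(neg_agreement, "agreement_matrix"),
            length(pair) == 2L)
  if (!setequal(names(pos_agreement$true_counts),
                names(neg_agreement$true_counts)))
    stop("agreement matrices cover different predictor sets", call. = FALSE)
  if (!all(pair %in% names(pos_agreement$true_counts)))
    stop("unknown predictor in pair", call. = FALSE)
  coverage_ceiling(pos_agreement$union[pair[1L], pair[2L]],
                   pos_agreement$n_samples,
                   neg_agreement$union[pair[1L], pair[2L]],
                   neg_agreement$n_samples)
}

#' Published benchmark counts of the five base predictors
#'
#' The package ships the published per-predictor confusion counts and
#' pairwise true-prediction overlap/union counts of the five base
#' predictors on the two reference benchmarks: D163 (163 miRNA precursors
#' + 168 pseudo-hairpins) and D1679 (1679 + 674). They serve as fixed
#' fixtures for the evaluation functions — no sequence data or external
#' predictor runs are needed to recompute the derived metrics.
#' A handful of published off-diagonal cells are internally inconsistent
#' (they violate `U = T_i + T_j - O` against the same table's diagonals);
#' those rows carry `consistent = 0` in the agreement file.
#'
#' @return `benchmark_confusion()`: data frame with columns `dataset`,
#'   `predictor`, `TP`, `FN`, `TN`, `FP`. `benchmark_agreement()`: data
#'   frame with columns `dataset`, `side`, `pred_i`, `pred_j`, `overlap`,
#'   `union_count`, `consistent` (off-diagonal pairs) alongside diagonal
#'   rows (`pred_i == pred_j`) where `overlap` holds the true-call count
#'   and `union_count` the class size.
#' @export
benchmark_confusion <- function() {
  utils::read.delim(system.file("extdata", "benchmark_confusion.tsv",
                                package = "mirstack", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' @rdname benchmark_confusion
#' @export
benchmark_agreement <- function() {
  utils::read.delim(system.file("extdata", "benchmark_agreement.tsv",
                                package = "mirstack", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}
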