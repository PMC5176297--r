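#' Construct a validated score table
#'
#' A score table holds the raw outputs of M base predictors on N labelled
#' RNA samples: one row per sample with a unique id, a class label (+1 for
#' genuine pre-miRNA, -1 for pseudo-hairpin), and one cell per predictor.
#' Binary-predictor cells are stored as their tokens; numeric-predictor
#' cells as doubles, with `NA_real_` representing the literal `NA` token
#' (only legal when the column's spec says `na_policy = "sentinel"`).
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param labels Integer vector of class labels in `{+1, -1}`.
#' @param specs Named list of [predictor_spec()] objects, one per column.
#' @param raw Data frame of raw cells, columns named and ordered as `specs`.
#' @return An object of class `score_table`.
#' @export
score_table <- function(sample_ids, labels, specs, raw) {
  sample_ids <- as.character(sample_ids)
  labels <- as.integer(labels)
  if (length(specs) < 1L) stop("score table needs at least one predictor",
                               call. = FALSE)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  n <- length(sample_ids)
  if (n < 1L) stop("score table needs at least one sample", call. = FALSE)
  if (length(labels) != n || nrow(raw) != n)
    stop("sample_ids, labels and raw rows must have equal length",
         call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(labels %in% c(1L, -1L)))
    stop("labels must be +1 or -1", call. = FALSE)
  if (!identical(names(raw), names(specs)))
    stop("raw columns must match spec names exactly", call. = FALSE)
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    col <- raw[[nm]]
    if (sp$output_kind == "binary") {
      col <- as.character(col)
      bad <- !(col %in% c(sp$positive_token, sp$negative_tokens))
      if (any(bad))
        stop("column '", nm, "', row ", which(bad)[1L],
             ": token '", col[which(bad)[1L]], "' not in dialect",
             call. = FALSE)
      raw[[nm]] <- col
    } else {
      if (!is.numeric(col))
        stop("column '", nm, "' must be numeric", call. = FALSE)
      if (anyNA(col) && sp$na_policy != "sentinel")
        stop("column '", nm, "', row ", which(is.na(col))[1L],
             ": NA not allowed (na_policy = forbid)", call. = FALSE)
      if (any(is.infinite(col)))
        stop("column '", nm, "': non-finite value", call. = FALSE)
      raw[[nm]] <- as.numeric(col)
    }
  }
  structure(list(sample_ids = sample_ids, labels = labels,
                 specs = specs, raw = raw),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table> ", length(x$sample_ids), " samples (",
      sum(x$labels == 1L), " positive / ", sum(x$labels == -1L),
      " negative), ", length(x$specs), " predictors: ",
      paste(names(x$specs), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.score_table <- function(x) c(length(x$sample_ids), length(x$specs))

#' Read a score table from tab-separated text
#'
#' Expects a header row `id <tab> label <tab> <predictor names...>` with the
#' predictor columns exactly matching `specs` (extra or missing columns are
#' schema errors). Labels accept `1`, `+1`, `pos` and `-1`, `neg`. Lines
#' starting with `#` are provenance comments and are skipped. The literal
#' token `NA` is only legal in numeric columns whose spec allows it and in
#' binary columns whose dialect includes it.
#'
#' @param path File path.
#' @param specs Named list of [predictor_spec()]; defaults to the five
#'   shipped dialects restricted to the columns present is NOT done — the
#'   header must match `specs` exactly.
#' @return A [score_table()].
#' @export
read_score_table <- function(path, specs = default_predictor_specs()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 3L || header[1L] != "id" || header[2L] != "label")
    stop("header must be: id, label, <predictors>", call. = FALSE)
  if (is.null(names(specs)))
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  pred_names <- header[-(1:2)]
  extra <- setdiff(pred_names, names(specs))
  if (length(extra))
    stop("unknown predictor column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(names(specs), pred_names)
  if (length(missing))
    stop("missing predictor column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  body <- cells[-1L]
  if (length(body) == 0L) stop("table has a header but no rows", call. = FALSE)
  ncol_expect <- length(header)
  nf <- lengths(body)
  if (any(nf != ncol_expect))
    stop("row ", which(nf != ncol_expect)[1L], " has ",
         nf[nf != ncol_expect][1L], " fields, expected ", ncol_expect,
         call. = FALSE)
  mat <- do.call(rbind, body)
  ids <- mat[, 1L]
  labels <- parse_labels(mat[, 2L])
  raw <- list()
  for (j in seq_along(pred_names)) {
    nm <- pred_names[j]
    sp <- specs[[nm]]
    col <- mat[, j + 2L]
    if (sp$output_kind == "binary") {
      raw[[nm]] <- col
    } else {
      is_na_tok <- col == "NA"
      num <- suppressWarnings(as.numeric(col))
      bad <- !is_na_tok & !is.finite(num)
      if (any(bad))
        stop("column '", nm, "', row ", which(bad)[1L], ": cell '",
             col[which(bad)[1L]], "' is not a number", call. = FALSE)
      num[is_na_tok] <- NA_real_
      raw[[nm]] <- num
    }
  }
  # reorder columns to spec order for a canonical in-memory layout
  raw <- as.data.frame(raw, stringsAsFactors = FALSE,
                       check.names = FALSE)[names(specs)]
  score_table(ids, labels, specs, raw)
}

parse_labels <- function(x) {
  out <- integer(length(x))
  pos <- x %in% c("1", "+1", "pos")
  neg <- x %in% c("-1", "neg")
  if (any(!pos & !neg))
    stop("row ", which(!pos & !neg)[1L], ": unparseable label '",
         x[which(!pos & !neg)[1L]], "'", call. = FALSE)
  out[pos] <- 1L
  out[neg] <- -1L
  out
}

#' Write a score table as tab-separated text
#'
#' Numeric cells are printed with full precision (`%.17g`) so that
#' `read_score_table(write_score_table(t))` is the identity; `NA` tokens
#' are written literally. Optional comment lines record provenance.
#'
#' @param table A [score_table()].
#' @param path Output path.
#' @param comments Character vector written as leading `# `-prefixed lines.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, comments = character()) {
  stopifnot(inherits(table, "score_table"))
  cols <- lapply(names(table$specs), function(nm) {
    col <- table$raw[[nm]]
    if (is.numeric(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  })
  mat <- do.call(cbind, c(list(table$sample_ids,
                               as.character(table$labels)), cols))
  lines <- c(
    if (length(comments)) paste0("# ", comments),
    paste(c("id", "label", names(table$specs)), collapse = "\t"),
    apply(mat, 1L, paste, collapse = "\t"))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Collapse duplicate prediction vectors
#'
#' Samples on which all predictors produced identical raw outputs (and which
#' carry the same class label) are treated as duplicates; one survivor per
#' duplicate group is chosen uniformly at random with a seeded generator, so
#' the filter is reproducible. Groups are visited in canonical (sorted key)
#' order; surviving rows keep their original order.
#'
#' @param table A [score_table()].
#' @param seed Integer seed for the survivor draw.
#' @return A [score_table()] with one row per (label, prediction-vector)
#'   group.
#' @export
deduplicate <- function(table, seed = 1L) {
  stopifnot(inherits(table, "score_table"))
  key_cols <- lapply(table$raw, function(col) {
    if (is.numeric(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else as.character(col)
  })
  keys <- do.call(paste, c(list(table$labels), key_cols, sep = "\x1f"))
  survivors <- integer(0)
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (k in sort(unique(keys))) {
      idx <- which(keys == k)
      survivors <- c(survivors,
                     if (length(idx) == 1L) idx
                     else idx[sample.int(length(idx), 1L)])
    }
  })
  survivors <- sort(survivors)
  score_table(table$sample_ids[survivors], table$labels[survivors],
              table$specs, table$raw[survivors, , drop = FALSE])
}

#' Enumerate predictor ensembles
#'
#' All subsets of the given predictors with at least `min_size` members,
#' each subset sorted, and the whole collection ordered by (size,
#' lexicographic). For five predictors and `min_size = 2` there are
#' C(5,2)+C(5,3)+C(5,4)+C(5,5) = 26 ensembles; in general
#' `2^M - M - 1` for `min_size = 2`.
#'
#' @param predictor_names Character vector of unique names.
#' @param min_size Smallest ensemble size (>= 2).
#' @return List of character vectors, one per ensemble.
#' @examples
#' length(enumerate_ensembles(letters[1:5]))  # 26
#' @export
enumerate_ensembles <- function(predictor_names, min_size = 2L) {
  stopifnot(is.character(predictor_names))
  if (anyDuplicated(predictor_names))
    stop("predictor names must be unique", call. = FALSE)
  m <- length(predictor_names)
  if (min_size < 2L || min_size > m)
    stop("min_size must be between 2 and the number of predictors",
         call. = FALSE)
  sorted <- sort(predictor_names)
  out <- list()
  for (s in seq(min_size, m)) {
    combos <- utils::combn(sorted, s, simplify = FALSE)
    combos <- combos[order(vapply(combos, paste, character(1),
                                  collapse = "\x1f"))]
    out <- c(out, combos)
  }
  out
}

#' Restrict a score table to a subset of predictors
#'
#' @param table A [score_table()].
#' @param predictors Character vector of predictor names to keep.
#' @return A [score_table()] with only those columns.
#' @export
subset_predictors <- function(table, predictors) {
  stopifnot(inherits(table, "score_table"))
  missing <- setdiff(predictors, names(table$specs))
  if (length(missing))
    stop("unknown predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  score_table(table$sample_ids, table$labels, table$specs[predictors],
              table$raw[predictors])
}

#' Binarize raw predictor outputs into class calls
#'
#' Maps each raw cell to a +1/-1 call using the column's dialect: binary
#' columns via their tokens, numeric columns by whether the score reaches
#' the lower bound of the positive-call range (`NA` tokens are negative
#' calls).
#'
#' @param table A [score_table()].
#' @return Integer matrix (N x M) of calls in `{+1, -1}` with predictor
#'   column names and sample-id row names.
#' @export
binarize_calls <- function(table) {
  stopifnot(inherits(table, "score_table"))
  out <- vapply(names(table$specs), function(nm) {
    sp <- table$specs[[nm]]
    col <- table$raw[[nm]]
    if (sp$output_kind == "binary") {
      ifelse(as.character(col) == sp$positive_token, 1L, -1L)
    } else {
      if (is.null(sp$positive_range))
        stop("numeric spec '", nm, "' has no positive_range; cannot binarize",
             call. = FALSE)
      ifelse(!is.na(col) & col >= min(sp$positive_range), 1L, -1L)
    }
  }, integer(length(table$sample_ids)))
  out <- matrix(out, nrow = length(table$sample_ids),
                dimnames = list(table$sample_ids, names(table$specs)))
  out
}

# run code that uses the RNG without disturbing the caller's stream
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}
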