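#' Describe the output dialect of a base predictor
#'
#' Each base pre-miRNA predictor reports its verdict in its own dialect:
#' either a pair of tokens (binary predictors) or a numeric score whose
#' positive and negative calls occupy known ranges, optionally with a
#' literal `NA` token for "no call". A `predictor_spec` captures that
#' dialect so score tables can be validated, binarized, and simulated.
#'
#' @param name Column name of the predictor in score tables.
#' @param output_kind `"binary"` or `"numeric"`.
#' @param positive_token Token emitted for a positive call (binary only).
#' @param negative_tokens Character vector of tokens emitted for a negative
#'   call (binary only); must be disjoint from `positive_token`.
#' @param na_policy For numeric predictors, whether a literal `"NA"` cell is
#'   rejected (`"forbid"`) or accepted as a distinct no-call outcome
#'   (`"sentinel"`).
#' @param positive_range Numeric length-2 range of scores emitted on positive
#'   calls (numeric only); used by [binarize_calls()] and the synthetic
#'   generator.
#' @param negative_range Range (or single value) of numeric scores emitted on
#'   negative calls.
#' @param log_uniform Logical; when simulating, draw scores log-uniformly
#'   over the range (for heavy-tailed score distributions).
#' @param negative_mix For numeric predictors with `na_policy = "sentinel"`,
#'   weights of the three negative-call outcomes `(numeric, zero, NA)`.
#' @return An object of class `predictor_spec`.
#' @examples
#' predictor_spec("MIReNA", "binary", positive_token = "Yes",
#'                negative_tokens = "No")
#' @export
predictor_spec <- function(name, output_kind = c("numeric", "binary"),
                           positive_token = NULL, negative_tokens = NULL,
                           na_policy = c("forbid", "sentinel"),
                           positive_range = NULL, negative_range = NULL,
                           log_uniform = FALSE,
                           negative_mix = c(numeric = 0.5, zero = 0.25, na = 0.25)) {
  output_kind <- match.arg(output_kind)
  na_policy <- match.arg(na_policy)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (output_kind == "binary") {
    if (is.null(positive_token) || is.null(negative_tokens))
      stop("binary predictor spec '", name,
           "' needs positive_token and negative_tokens", call. = FALSE)
    if (positive_token %in% negative_tokens)
      stop("positive and negative tokens of '", name,
           "' must be disjoint", call. = FALSE)
  }
  structure(
    list(name = name, output_kind = output_kind,
         positive_token = positive_token,
         negative_tokens = negative_tokens,
         na_policy = na_policy,
         positive_range = positive_range,
         negative_range = negative_range,
         log_uniform = isTRUE(log_uniform),
         negative_mix = negative_mix),
    class = "predictor_spec")
}

#' @export
print.predictor_spec <- function(x, ...) {
  cat("<predictor_spec> ", x$name, " [", x$output_kind, "]\n", sep = "")
  if (x$output_kind == "binary") {
    cat("  tokens: +", x$positive_token, " / -",
        paste(x$negative_tokens, collapse = ","), "\n", sep = "")
  } else {
    cat("  positive range: [", paste(x$positive_range, collapse = ", "),
        "]  NA policy: ", x$na_policy, "\n", sep = "")
  }
  invisible(x)
}

#' Default dialects of the five base predictors
#'
#' The shipped defaults describe the published output dialects of MiPred
#' (score 50--91 on positive calls, 0 on negative), MIReNA (`Yes`/`No`),
#' miRPara (0.8--1 / 0), ProMiR (probability ratio 0.017--3240 on positive
#' calls; roughly 1e-10--1e-2, exact 0, or `NA` on negative calls) and
#' triplet-SVM (`1`/`NA`). They are also stored as YAML in
#' `system.file("extdata", "predictor_specs.yaml", package = "mirstack")`.
#'
#' @param names Optional subset of predictor names to return.
#' @return Named list of [predictor_spec()] objects.
#' @examples
#' names(default_predictor_specs())
#' @export
default_predictor_specs <- function(names = NULL) {
  specs <- list(
    MiPred = predictor_spec("MiPred", "numeric", na_policy = "forbid",
                            positive_range = c(50, 91), negative_range = 0),
    MIReNA = predictor_spec("MIReNA", "binary", positive_token = "Yes",
                            negative_tokens = "No"),
    miRPara = predictor_spec("miRPara", "numeric", na_policy = "forbid",
                             positive_range = c(0.8, 1), negative_range = 0),
    ProMiR = predictor_spec("ProMiR", "numeric", na_policy = "sentinel",
                            positive_range = c(0.017, 3240),
                            negative_range = c(1e-10, 1e-2),
                            log_uniform = TRUE),
    TripletSVM = predictor_spec("TripletSVM", "binary", positive_token = "1",
                                negative_tokens = "NA")
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(specs))
    if (length(missing))
      stop("unknown predictor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    specs <- specs[names]
  }
  specs
}

#' Load predictor specs from a YAML or JSON config
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file holding a list
#'   of spec entries with the fields of [predictor_spec()].
#' @return Named list of `predictor_spec` objects.
#' @export
read_predictor_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(e) {
    predictor_spec(
      name = e$name,
      output_kind = e$output_kind,
      positive_token = e$positive_token,
      negative_tokens = unlist(e$negative_tokens),
      na_policy = if (is.null(e$na_policy)) "forbid" else e$na_policy,
      positive_range = unlist(e$positive_range),
      negative_range = unlist(e$negative_range),
      log_uniform = isTRUE(e$log_uniform),
      negative_mix = if (is.null(e$negative_mix))
        c(numeric = 0.5, zero = 0.25, na = 0.25) else unlist(e$negative_mix))
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# is a raw cell (character token or number) a positive call under this spec?
spec_is_positive_call <- function(spec, cell_num, cell_chr) {
  if (spec$output_kind == "binary") return(cell_chr == spec$positive_token)
  if (is.na(cell_num)) return(FALSE)
  if (is.null(spec$positive_range))
    stop("numeric spec '", spec$name,
         "' has no positive_range; cannot binarize", call. = FALSE)
  cell_num >= min(spec$positive_range)
}
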