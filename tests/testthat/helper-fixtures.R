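# shared fixture builders; everything is generated in code

# two binary predictors, four hand-written rows
tiny_binary_table <- function() {
  specs <- list(
    A = predictor_spec("A", "binary", positive_token = "Yes",
                       negative_tokens = "No"),
    B = predictor_spec("B", "binary", positive_token = "1",
                       negative_tokens = "NA"))
  score_table(c("s1", "s2", "s3", "s4"), c(1L, 1L, -1L, -1L), specs,
              data.frame(A = c("Yes", "No", "No", "Yes"),
                         B = c("1", "1", "NA", "NA"),
                         stringsAsFactors = FALSE))
}

# one binary + one heavy-tailed numeric column (ProMiR-style dialect)
mixed_table <- function(values = c(0.017, 1.0, 3240, 0, NA, 1e-6),
                        labels = c(1L, 1L, 1L, -1L, -1L, -1L)) {
  specs <- list(
    MIReNA = predictor_spec("MIReNA", "binary", positive_token = "Yes",
                            negative_tokens = "No"),
    ProMiR = predictor_spec("ProMiR", "numeric", na_policy = "sentinel",
                            positive_range = c(0.017, 3240),
                            negative_range = c(1e-10, 1e-2),
                            log_uniform = TRUE))
  score_table(paste0("s", seq_along(values)), labels, specs,
              data.frame(MIReNA = ifelse(labels == 1L, "Yes", "No"),
                         ProMiR = values, stringsAsFactors = FALSE))
}

# labels/calls realizing given confusion counts
counts_to_calls <- function(TP, FN, TN, FP) {
  labels <- rep(c(1L, -1L), c(TP + FN, TN + FP))
  calls <- c(rep(1L, TP), rep(-1L, FN), rep(-1L, TN), rep(1L, FP))
  list(labels = labels, calls = calls)
}

# a linearly separable two-feature panel wrapped as feature matrices
separable_features <- function(n = 20, margin = 0.5, seed = 42) {
  set.seed(seed)
  lab <- rep(c(1L, -1L), length.out = n)
  X <- cbind(lab * (margin + runif(n, 0, 0.5)),
             runif(n, -1, 1))
  feature_matrix(sprintf("s%02d", seq_len(n)), X, lab)
}
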