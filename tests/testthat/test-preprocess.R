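# staged transforms: numericalization, sentinels+log, PCA rotation

test_that("stage I maps tokens to +/-1 and min-max scales numeric columns", {
  specs <- list(
    MIReNA = predictor_spec("MIReNA", "binary", positive_token = "Yes",
                            negative_tokens = "No"),
    TripletSVM = predictor_spec("TripletSVM", "binary",
                                positive_token = "1",
                                negative_tokens = "NA"),
    MiPred = predictor_spec("MiPred", "numeric", na_policy = "forbid",
                            positive_range = c(50, 91)))
  tab <- score_table(
    c("a", "b", "c"), c(1L, -1L, 1L), specs,
    data.frame(MIReNA = c("Yes", "No", "Yes"),
               TripletSVM = c("1", "NA", "1"),
               MiPred = c(0, 45.5, 91), stringsAsFactors = FALSE))
  fit <- fit_transform_I(tab)
  X <- fit$features$X
  expect_equal(unname(X[, "MIReNA"]), c(1, -1, 1))
  expect_equal(unname(X[, "TripletSVM"]), c(1, -1, 1))
  # hand-computed affine map x -> 2(x-min)/(max-min) - 1
  expect_equal(unname(X[, "MiPred"]), c(-1, 0, 1))
  expect_true(all(X >= -1 & X <= 1))
})

test_that("stage I pools numeric NA with raw zero before scaling", {
  tab <- mixed_table(values = c(2, 4, 6, NA, 0, 0))
  X <- fit_transform_I(tab)$features$X
  # NA was treated as 0, the fitted minimum
  expect_equal(unname(X[4:6, "ProMiR"]), c(-1, -1, -1))
  expect_equal(unname(X[, "ProMiR"][2]), 2 * (4 - 0) / 6 - 1)
})

test_that("stage II applies sentinels and natural log, then scales", {
  tab <- mixed_table(values = c(0.017, 1.0, 3240, 0, NA, 1e-6))
  fit <- fit_transform_II(tab, log_columns = "ProMiR")
  cp <- fit$params$columns$ProMiR
  expect_true(cp$log_shift)
  expect_equal(cp$norm_lo, -30)         # NA sentinel is the fitted minimum
  expect_equal(cp$norm_hi, log(3240))
  # hand computation: pre-normalization values
  pre <- c(log(0.017), log(1), log(3240), -25, -30, log(1e-6))
  expect_equal(unname(fit$features$X[, "ProMiR"]),
               2 * (pre - (-30)) / (log(3240) + 30) - 1)
  # the published-dialect ordering: NA < zero-sentinel < ln of any score
  expect_true(-30 < -25 && -25 < log(1e-10))
  expect_error(fit_transform_II(mixed_table(values = c(1, 2, 3, -1, 0, 0)),
                                "ProMiR"),
               "negative value")
})

test_that("stage II is order-preserving on positive scores of a log column", {
  vals <- sort(exp(runif(20, log(1e-9), log(3000))))
  tab <- mixed_table(values = vals, labels = rep(c(1L, -1L), 10))
  X <- fit_transform_II(tab, "ProMiR")$features$X
  expect_false(is.unsorted(X[, "ProMiR"]))
})

test_that("stage II equals stage I on binary-only tables", {
  tab <- tiny_binary_table()
  expect_equal(fit_transform_I(tab)$features$X,
               fit_transform_II(tab, character())$features$X)
})

test_that("fitted numeric columns attain both -1 and +1 on training data", {
  panel <- generate_panel(synthetic_config(60, 60, seed = 21))
  for (fit in list(fit_transform_I(panel),
                   fit_transform_II(panel, "ProMiR"))) {
    X <- fit$features$X
    expect_true(all(X >= -1 & X <= 1))
    for (nm in c("MiPred", "miRPara", "ProMiR")) {
      expect_equal(min(X[, nm]), -1)
      expect_equal(max(X[, nm]), 1)
    }
  }
})

test_that("PCA recovers the closed-form 2x2 eigendecomposition", {
  # five points whose sample covariance is exactly [[2,1],[1,2]]
  X <- rbind(c(sqrt(3), sqrt(3)), -c(sqrt(3), sqrt(3)),
             c(1, -1), c(-1, 1), c(0, 0))
  pca <- fit_pca(X)
  expect_equal(pca$eigenvalues, c(3, 1))
  expect_equal(abs(pca$eigenmatrix),
               matrix(1 / sqrt(2), 2, 2), ignore_attr = TRUE)
  # sign convention: largest-magnitude entry of each column is positive
  expect_true(all(apply(pca$eigenmatrix, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  expect_equal(unname(apply_pca(matrix(c(1, 1), 1), pca$eigenmatrix,
                                c(0, 0))[1, ]),
               c(sqrt(2), 0))
})

test_that("PCA is orthonormal, norm- and variance-preserving", {
  set.seed(8)
  X <- matrix(rnorm(40 * 5), 40, 5) %*% diag(c(3, 2, 1, 0.5, 0.1))
  pca <- fit_pca(X)
  E <- pca$eigenmatrix
  expect_lt(max(abs(crossprod(E) - diag(5))), 1e-8)
  Y <- apply_pca(X, E, pca$column_means)
  centered <- sweep(X, 2, pca$column_means)
  expect_equal(sqrt(rowSums(Y^2)), sqrt(rowSums(centered^2)),
               tolerance = 1e-10)
  expect_equal(sum(apply(Y, 2, var)), sum(apply(X, 2, var)),
               tolerance = 1e-8)
  # identity rotation returns the centered input
  expect_equal(apply_pca(X, diag(5), pca$column_means), centered,
               ignore_attr = TRUE)
})

test_that("PCA rejects degenerate inputs", {
  expect_error(fit_pca(matrix(1:4, 2, 2)), "N > M")
  expect_error(fit_pca(matrix(1, 10, 2)), "degenerate covariance")
  expect_error(apply_pca(matrix(0, 3, 2), diag(3), c(0, 0, 0)),
               "shape mismatch")
})

test_that("stage III equals stage II followed by PCA, step by step", {
  tab <- mixed_table(values = c(0.5, 8, 100, 0, NA, 3e-4),
                     labels = c(1L, 1L, 1L, -1L, -1L, -1L))
  three <- fit_transform_III(tab, "ProMiR")
  two <- fit_transform_II(tab, "ProMiR")
  pca <- fit_pca(two$features$X)
  expect_equal(three$features$X,
               apply_pca(two$features$X, pca$eigenmatrix, pca$column_means))
  expect_equal(three$params$eigenmatrix, pca$eigenmatrix)
  # N = M violates the rank precondition
  small <- take2 <- score_table(tab$sample_ids[1:2], tab$labels[1:2],
                                tab$specs, tab$raw[1:2, ])
  expect_error(fit_transform_III(small, "ProMiR"), "N > M")
})

test_that("apply_transform replays a fit exactly and clips new extremes", {
  panel <- generate_panel(synthetic_config(50, 50, seed = 31))
  for (fit in list(fit_transform_I(panel),
                   fit_transform_II(panel, "ProMiR"),
                   fit_transform_III(panel, "ProMiR"))) {
    replay <- apply_transform(fit$params, panel)
    expect_equal(replay$X, fit$features$X)
  }
  # out-of-range value clips to +1 after the affine map
  fit <- fit_transform_I(mixed_table(values = c(1, 2, 3, 0, 0, 0)))
  extreme <- mixed_table(values = c(99, 2, 3, -5, 0, 0))
  X <- apply_transform(fit$params, extreme)$X
  expect_equal(unname(X[1, "ProMiR"]), 1)
  expect_equal(unname(X[4, "ProMiR"]), -1)
  # binary path has no fitted state
  expect_equal(unname(X[, "MIReNA"]), c(1, 1, 1, -1, -1, -1))
})

test_that("constant numeric columns map to 0 with a flag", {
  tab <- mixed_table(values = rep(5, 6))
  fit <- fit_transform_I(tab)
  expect_true(fit$params$columns$ProMiR$constant)
  expect_equal(unname(fit$features$X[, "ProMiR"]), rep(0, 6))
})

test_that("transform params survive YAML serialization", {
  panel <- generate_panel(synthetic_config(30, 30, seed = 41))
  fit <- fit_transform_III(panel, "ProMiR")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_transform_params(fit$params, path)
  back <- read_transform_params(path)
  expect_equal(back$eigenmatrix, fit$params$eigenmatrix, tolerance = 1e-12)
  expect_equal(apply_transform(back, panel)$X, fit$features$X,
               tolerance = 1e-12)
})
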