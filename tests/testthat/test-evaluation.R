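# confusion counting, the four metrics, agreement/coverage analysis

test_that("confusion counts partition the samples", {
  expect_identical(unclass(confusion(c(1L, 1L, -1L, -1L),
                                     c(1L, 1L, -1L, -1L))),
                   list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  # degenerate all-positive caller
  expect_identical(unclass(confusion(c(1L, -1L), c(1L, 1L))),
                   list(TP = 1L, FP = 1L, TN = 0L, FN = 0L))
  expect_error(confusion(c(1L, -1L), 1L), "equal length")
  expect_error(confusion(c(1L, 0L), c(1L, 1L)), "\\+1 or -1")
  # counting a fixture realized from published per-predictor diagonals
  fx <- counts_to_calls(TP = 162, FN = 1, TN = 72, FP = 96)
  cc <- confusion(fx$labels, fx$calls)
  expect_identical(unclass(cc), list(TP = 162L, FP = 96L, TN = 72L, FN = 1L))
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, length(fx$labels))
})

test_that("metrics reproduce published benchmark rows at printed precision", {
  # MiPred on the small benchmark: 99.4 / 42.9 / 70.7 / 0.51
  m <- metrics(confusion_counts(TP = 162, FP = 96, TN = 72, FN = 1))
  expect_equal(round(100 * m$SENS, 1), 99.4)
  expect_equal(round(100 * m$SPEC, 1), 42.9)
  expect_equal(round(100 * m$ACC, 1), 70.7)
  expect_equal(round(m$MCC, 2), 0.51)
  # ProMiR on the small benchmark: ACC 87.9, MCC 0.78
  m2 <- metrics(confusion_counts(TP = 124, FP = 1, TN = 167, FN = 39))
  expect_equal(round(100 * m2$ACC, 1), 87.9)
  expect_equal(round(m2$MCC, 2), 0.78)
  # perfect predictor
  m3 <- metrics(confusion_counts(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unlist(unclass(m3)), c(SENS = 1, SPEC = 1, ACC = 1, MCC = 1))
})

test_that("metric identities hold on random call sets", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    labels <- sample(c(1L, -1L), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    calls <- ifelse(runif(n) < 0.3, -labels, labels)
    cc <- confusion(labels, calls)
    ms <- metrics(cc)
    expect_equal(ms$ACC, (cc$TP + cc$TN) / n)
    P <- sum(labels == 1L); N <- sum(labels == -1L)
    expect_equal(ms$ACC, (ms$SENS * P + ms$SPEC * N) / (P + N))
    expect_gte(ms$MCC, -1); expect_lte(ms$MCC, 1)
  }
  # MCC = 1 iff no errors with both classes present
  expect_equal(metrics(confusion_counts(5, 0, 7, 0))$MCC, 1)
  # zero marginal: MCC defined as 0
  expect_equal(metrics(confusion_counts(0, 0, 5, 5))$MCC, 0)
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("pairwise agreement counts overlap and union correctly", {
  labels <- c(rep(1L, 6), rep(-1L, 4))
  calls <- list(
    a = c(1L, 1L, 1L, -1L, -1L, -1L, -1L, -1L, 1L, 1L),
    b = c(1L, -1L, 1L, 1L, -1L, -1L, -1L, 1L, -1L, 1L))
  ag <- pairwise_agreement(labels, calls, "positive")
  expect_equal(unname(ag$true_counts), c(3, 3))
  expect_equal(ag$overlap["a", "b"], 2)         # samples 1 and 3
  expect_equal(ag$union["a", "b"], 4)           # samples 1-4
  expect_equal(ag$union["a", "b"],
               ag$true_counts[["a"]] + ag$true_counts[["b"]] -
                 ag$overlap["a", "b"])
  # symmetry and self-agreement
  expect_equal(ag$overlap["b", "a"], ag$overlap["a", "b"])
  expect_equal(ag$overlap["a", "a"], ag$true_counts[["a"]])
  neg <- pairwise_agreement(labels, calls, "negative")
  expect_equal(unname(neg$true_counts), c(2, 2))
  expect_equal(neg$n_samples, 4)
  # identical predictors: O = U = T
  twin <- pairwise_agreement(labels, list(x = calls$a, y = calls$a),
                             "positive")
  expect_equal(twin$overlap["x", "y"], 3)
  expect_equal(twin$union["x", "y"], 3)
})

test_that("agreement identities hold on random panels", {
  set.seed(123)
  for (i in 1:10) {
    n <- 80
    labels <- rep(c(1L, -1L), c(45, 35))
    calls <- replicate(4, ifelse(runif(n) < 0.25, -labels, labels),
                       simplify = FALSE)
    names(calls) <- paste0("p", 1:4)
    for (side in c("positive", "negative")) {
      ag <- pairwise_agreement(labels, calls, side)
      Tc <- ag$true_counts
      expect_true(all(ag$overlap <= outer(Tc, Tc, pmin)))
      expect_equal(ag$union, outer(Tc, Tc, "+") - ag$overlap)
      expect_true(all(ag$union <= ag$n_samples))
      expect_identical(ag$overlap, t(ag$overlap))
    }
  }
})

test_that("coverage ceilings reproduce the published arithmetic", {
  cc <- coverage_ceiling(1608, 1679, 664, 674)
  expect_equal(round(100 * cc$SENS, 1), 95.8)
  expect_equal(round(100 * cc$SPEC, 1), 98.5)
  expect_equal(round(100 * cc$ACC, 1), 96.6)
  perfect <- coverage_ceiling(10, 10, 8, 8)
  expect_equal(unlist(unclass(perfect)), c(SENS = 1, SPEC = 1, ACC = 1))
})

test_that("pair ceilings can be read off agreement matrices", {
  panel <- generate_complementary_panel(120, 120, seed = 2)
  calls <- as.data.frame(binarize_calls(panel))
  pos <- pairwise_agreement(panel$labels, calls, "positive")
  neg <- pairwise_agreement(panel$labels, calls, "negative")
  # every sample is miscalled by at most one predictor, so any pair covers all
  cc <- pair_coverage_ceiling(pos, neg, c("MiPred", "ProMiR"))
  expect_equal(cc$ACC, 1.0)
  expect_error(pair_coverage_ceiling(pos, neg, c("MiPred", "zzz")),
               "unknown predictor")
})

test_that("shipped benchmark counts are internally consistent where flagged", {
  conf <- benchmark_confusion()
  expect_equal(nrow(conf), 10L)
  # class sizes: 163/168 and 1679/674
  expect_true(all(conf$TP + conf$FN ==
                    ifelse(conf$dataset == "D163", 163, 1679)))
  expect_true(all(conf$TN + conf$FP ==
                    ifelse(conf$dataset == "D163", 168, 674)))
  ag <- benchmark_agreement()
  diag <- ag[ag$pred_i == ag$pred_j, ]
  off <- ag[ag$pred_i != ag$pred_j, ]
  expect_equal(nrow(diag), 20L)
  expect_equal(nrow(off), 40L)
  # diagonals agree with the confusion file
  for (r in seq_len(nrow(diag))) {
    row <- diag[r, ]
    truth <- conf[conf$dataset == row$dataset &
                    conf$predictor == row$pred_i, ]
    expect_equal(row$overlap,
                 if (row$side == "positive") truth$TP else truth$TN)
  }
})
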