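test_that("computeMetrics matches direct formula substitution", {
  perfect <- computeMetrics(c(TP = 50, FN = 0, FP = 0, TN = 50))
  expect_equal(unname(perfect), c(100, 100, 100, 0, 1))

  chance <- computeMetrics(c(TP = 25, FN = 25, FP = 25, TN = 25))
  expect_equal(unname(chance[c("ACC", "MCC")]), c(50, 0))

  m <- computeMetrics(c(TP = 90, FN = 10, FP = 20, TN = 80))
  expect_equal(unname(m["ACC"]), 85)
  expect_equal(unname(m["SN"]), 90)
  expect_equal(unname(m["SP"]), 80)
  expect_equal(unname(m["FPR"]), 20)
  expect_equal(unname(m["MCC"]),
               (90 * 80 - 20 * 10) / sqrt(110 * 100 * 100 * 90))
})

test_that("metrics with zero marginals are NA with a warning, and FPR = 100 - SP", {
  expect_warning(
    expect_warning(m <- computeMetrics(c(TP = 0, FN = 0, FP = 3, TN = 7)),
                   "SN undefined"),
    "MCC undefined")
  expect_true(is.na(m["SN"]))
  expect_false(is.na(m["SP"]))
  set.seed(30)
  for (i in 1:20) {
    cc <- c(TP = sample(0:30, 1), FN = sample(0:30, 1),
            FP = sample(1:30, 1), TN = sample(1:30, 1))
    m <- suppressWarnings(computeMetrics(cc))
    expect_equal(unname(m["FPR"]), 100 - unname(m["SP"]))
  }
})

test_that("MCC is bounded and symmetric under class swap", {
  set.seed(31)
  for (i in 1:50) {
    cc <- c(TP = sample(0:10, 1), FN = sample(0:10, 1),
            FP = sample(0:10, 1), TN = sample(0:10, 1))
    m <- suppressWarnings(computeMetrics(cc))
    if (!is.na(m["MCC"])) {
      expect_gte(m[["MCC"]], -1)
      expect_lte(m[["MCC"]], 1)
      swapped <- suppressWarnings(computeMetrics(
        c(TP = cc[["TN"]], FN = cc[["FP"]], FP = cc[["FN"]], TN = cc[["TP"]])))
      expect_equal(m[["MCC"]], swapped[["MCC"]])
    }
  }
})

test_that("kfoldSplit produces near-equal, seeded, optionally stratified folds", {
  ids <- sprintf("s%02d", 1:10)
  f <- kfoldSplit(ids, 5, seed = 1)
  expect_identical(as.integer(table(f)), rep(2L, 5))

  f11 <- kfoldSplit(sprintf("s%02d", 1:11), 5, seed = 1)
  expect_identical(sort(as.integer(table(f11)), decreasing = TRUE),
                   c(3L, 2L, 2L, 2L, 2L))

  expect_identical(kfoldSplit(ids, 5, seed = 42), kfoldSplit(ids, 5, seed = 42))
  expect_false(identical(kfoldSplit(ids, 5, seed = 1), kfoldSplit(ids, 5, seed = 2)))
  expect_error(kfoldSplit(ids, 11), "exceeds")
  expect_error(kfoldSplit(ids, 1), "at least 2")

  ## stratified: every class near-evenly spread, overall sizes within 1
  lab <- rep(c("a", "b", "c"), times = c(10, 6, 5))
  ids3 <- sprintf("t%02d", 1:21)
  f3 <- kfoldSplit(ids3, 3, seed = 3, stratifyBy = lab)
  expect_lte(diff(range(table(f3))), 1L)
  for (cl in c("a", "b", "c"))
    expect_lte(diff(range(table(factor(f3[lab == cl], levels = 1:3)))), 1L)
})

test_that("crossValidate recovers separable data and matches brute-force LOO", {
  set.seed(32)
  x <- rbind(matrix(rnorm(100, -4), ncol = 2), matrix(rnorm(100, 4), ncol = 2))
  rownames(x) <- sprintf("e%02d", 1:100)
  y <- rep(c(-1, 1), each = 50)
  cv <- crossValidate(x, y, gamma = 0.5, cost = 100, k = 5, seed = 7)
  expect_equal(unname(cv$pooled["ACC"]), 100)
  expect_equal(cv$sdACC, 0)
  expect_equal(sum(cv$pooledCounts), 100)

  ## leave-one-out on 6 examples vs an explicit loop
  x6 <- x[c(1:3, 51:53), ]
  y6 <- y[c(1:3, 51:53)]
  loo <- crossValidate(x6, y6, gamma = 0.5, cost = 100, k = 6, seed = 1,
                       stratify = FALSE)
  pred <- vapply(1:6, function(i) {
    m <- trainSVM(x6[-i, ], y6[-i], gamma = 0.5, cost = 100, seed = 1)
    unname(predictLabel(m, x6[i, , drop = FALSE]))
  }, 0)
  looAcc <- 100 * mean(pred == y6)
  expect_equal(unname(loo$pooled["ACC"]), looAcc)

  ## a training fold missing one class is a hard error
  x4 <- x[c(1, 51:53), ]
  expect_error(
    crossValidate(x4, c(1, -1, -1, -1), gamma = 1, cost = 1, k = 2, seed = 1,
                  stratify = FALSE),
    "single class")
})

test_that("rocAuc sweeps thresholds and equals the Mann-Whitney statistic", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))$auc, 1)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, -1, -1))$auc, 0)
  expect_equal(rocAuc(rep(0.5, 6), c(1, 1, 1, -1, -1, -1))$auc, 0.5)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")

  set.seed(33)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    truth <- c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2)))
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    r <- rocAuc(scores, truth)
    expect_equal(r$auc, mannWhitneyAUC(scores, truth))
    ## cross-check against pROC
    expect_equal(r$auc,
                 as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                                direction = "<"))))
    ## complement identity needs tie-free scores
    tf <- rnorm(n)
    expect_equal(rocAuc(tf, truth)$auc + rocAuc(-tf, truth)$auc, 1)
  }
})

test_that("multiclassConfusion tabulates actual vs predicted by id", {
  truth <- c(a = "sHb", b = "flavoHb", c = "trHb", d = "flavoHb")
  correct <- multiclassConfusion(truth, truth)
  expect_true(all(correct[upper.tri(correct) | lower.tri(correct)] == 0))
  expect_equal(sum(diag(correct)), 4L)

  ## one flavoHb called trHb and one trHb called flavoHb: symmetric 1s
  pred <- c(a = "sHb", b = "trHb", c = "flavoHb", d = "flavoHb")
  m <- multiclassConfusion(truth, pred)
  expect_equal(m["flavoHb", "trHb"], 1L)
  expect_equal(m["trHb", "flavoHb"], 1L)
  expect_equal(sum(m), 4L)
  expect_equal(unname(rowSums(m)),
               unname(as.integer(table(factor(truth, levels = rownames(m))))))

  expect_error(multiclassConfusion(character(0), character(0)), "empty")
  expect_error(multiclassConfusion(truth, pred[1:3]), "same ids")
})
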