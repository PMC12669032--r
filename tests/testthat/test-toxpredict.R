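test_that("species selection applies the strict both-datasets threshold", {
  hc <- data.frame(species = c("X", "Y", "Z"),
                   n_hits_A = c(25, 15, 20),
                   n_hits_B = c(30, 40, 21))
  expect_equal(selectSpecies(hc), "X")
  expect_equal(selectSpecies(hc[0, ]), character(0))
})

test_that("stratified splits partition with per-class proportions", {
  y <- c(rep(1, 20), rep(0, 80))
  sp <- stratifiedSplits(y, n_splits = 5, seed = 71)
  for (s in sp) {
    expect_equal(sum(y[s$test] == 1), 4L)
    expect_equal(sum(y[s$test] == 0), 16L)
    expect_equal(sort(c(s$train, s$test)), seq_along(y))
    expect_length(intersect(s$train, s$test), 0L)
  }
  expect_identical(stratifiedSplits(y, n_splits = 5, seed = 71), sp)
  expect_error(stratifiedSplits(c(1, rep(0, 9))), "class")
})

test_that("random forest probabilities behave sanely", {
  set.seed(72)
  x <- matrix(rnorm(200 * 10), 200)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  expect_error(fitPredictRf(x, rep(1L, 200), x), "both classes")
  # a duplicated, confidently positive training point scores > 0.5
  strong <- which(y == 1 & x[, 1] + x[, 2] > 2)[1]
  prob <- fitPredictRf(x, y, x[strong, , drop = FALSE], seed = 73)
  expect_gt(prob, 0.5)
  expect_error(fitPredictRf(x, y, x[, 1:5]), "feature counts")
})

test_that("prevalence thresholding uses >= with boundary behavior", {
  expect_equal(thresholdAtPrevalence(c(0.9, 0.25, 0.20, 0.05), 0.2),
               c(1L, 1L, 1L, 0L))
  expect_equal(thresholdAtPrevalence(c(0.3, 0), 0), c(1L, 1L))
  expect_equal(thresholdAtPrevalence(c(0.99, 1), 1), c(0L, 1L))
})

test_that("balanced accuracy matches confusion-matrix arithmetic", {
  truth <- c(rep(1, 4), rep(0, 96))
  pred <- c(rep(1, 3), 0, rep(1, 6), rep(0, 90))  # TP=3 FN=1 FP=6 TN=90
  expect_equal(balancedAccuracy(truth, pred), 0.84375)
  expect_equal(balancedAccuracy(c(1, 0), c(1, 0)), 1)
  expect_equal(balancedAccuracy(c(1, 1, 0, 0), c(1, 1, 1, 1)), 0.5)
  expect_warning(res <- balancedAccuracy(c(1, 1), c(1, 0)), "absent")
  expect_true(is.na(res))
})

test_that("average precision matches rank-by-rank enumeration", {
  expect_equal(averagePrecision(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(averagePrecision(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # tied scores processed as one block
  expect_equal(averagePrecision(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_warning(res <- averagePrecision(c(0, 0), c(0.2, 0.1)), "positives")
  expect_true(is.na(res))
  # metrics invariant under sample reordering
  set.seed(74)
  truth <- rbinom(50, 1, 0.3)
  truth[1] <- 1
  sc <- runif(50)
  perm <- sample(50)
  expect_equal(averagePrecision(truth, sc),
               averagePrecision(truth[perm], sc[perm]))
})

test_that("the planted-rule library is learned and cross-rule transfer fails", {
  libA <- simCompoundLibrary(400, rule_bits = c(7L, 13L), seed = 75)
  cv <- crossValidateSpecies(libA$dataset, "species1", n_splits = 5, seed = 76)
  expect_gt(mean(cv$balanced_accuracy), 0.85)
  expect_gt(mean(cv$average_precision), 0.8)
  # training on rule A cannot predict rule B (disjoint bits)
  libB <- simCompoundLibrary(400, rule_bits = c(40L, 55L), seed = 77)
  prob <- fitPredictRf(toxFeatures(libA$dataset),
                       toxLabels(libA$dataset)[, 1],
                       toxFeatures(libB$dataset), seed = 78)
  pred <- thresholdAtPrevalence(prob, mean(toxLabels(libA$dataset)[, 1]))
  ba <- balancedAccuracy(toxLabels(libB$dataset)[, 1], pred)
  expect_lt(abs(ba - 0.5), 0.12)
})

test_that("shuffled labels collapse performance to chance", {
  lib <- simCompoundLibrary(400, seed = 79)
  nul <- shuffledLabelNull(lib$dataset, "species1", n_shuffles = 4,
                           n_splits = 4, seed = 80)
  expect_true(all(abs(nul$balanced_accuracy - 0.5) < 0.12))
  nul2 <- shuffledLabelNull(lib$dataset, "species1", n_shuffles = 4,
                            n_splits = 4, seed = 80)
  expect_identical(nul, nul2)
})
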