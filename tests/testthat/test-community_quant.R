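test_that("relative abundances are proportions summing to one", {
  expect_equal(relativeAbundance(c(a = 50, b = 30, c = 20)),
               c(a = 0.5, b = 0.3, c = 0.2))
  expect_equal(relativeAbundance(c(x = 7)), c(x = 1))
  set.seed(81)
  for (i in 1:5) {
    counts <- rpois(10, 100)
    expect_equal(sum(relativeAbundance(counts)), 1, tolerance = 1e-12)
  }
  expect_error(relativeAbundance(c(0, 0)), "all-zero")
})

test_that("absolute abundance proxies scale with OD, not depth", {
  expect_equal(absoluteAbundance(c(a = 50, b = 50), 0.8), c(a = 0.4, b = 0.4))
  counts <- c(a = 30, b = 70)
  expect_equal(absoluteAbundance(2 * counts, 0.5),
               absoluteAbundance(counts, 0.5))
  expect_equal(absoluteAbundance(counts, 1.0),
               2 * absoluteAbundance(counts, 0.5))
  expect_error(absoluteAbundance(counts, 0), "od")
})

test_that("treatment ratios recover per-species fold changes", {
  ctrl <- list(c(a = 100, b = 100), c(a = 110, b = 90))
  trt <- list(c(a = 50, b = 100), c(a = 55, b = 90))
  # identical arms -> unity
  r0 <- treatmentRatio(ctrl, ctrl, c(1, 1), c(1, 1))
  expect_equal(unname(r0), c(1, 1))
  # species a halved in absolute terms (same OD, same depth structure)
  r <- treatmentRatio(trt, ctrl, c(0.75, 0.75), c(1, 1))
  expect_equal(unname(r["a"]), 0.5, tolerance = 0.02)
  # ratios invariant under common sequencing-depth rescaling
  trt2 <- lapply(trt, function(x) x * 10)
  r2 <- treatmentRatio(trt2, ctrl, c(0.75, 0.75), c(1, 1))
  expect_equal(r, r2)
})

test_that("calibration-line quantification matches normal equations", {
  expect_error(linearQuantify(c(0, 10), c(0, 100), 50), ">= 3")
  res <- linearQuantify(c(0, 5, 10), c(0, 50, 100), 50)
  expect_equal(res$concentration, 5)
  expect_false(res$extrapolated)
  # noisy standards: slope equals the closed-form least-squares solution
  set.seed(82)
  conc <- seq(0, 20, by = 2.5)
  sig <- 3 + 7 * conc + rnorm(length(conc), 0, 2)
  fit <- linearQuantify(conc, sig, c(40, 200))
  slope_oracle <- sum((conc - mean(conc)) * (sig - mean(sig))) /
    sum((conc - mean(conc))^2)
  intercept_oracle <- mean(sig) - slope_oracle * mean(conc)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-10)
  expect_equal(fit$intercept, intercept_oracle, tolerance = 1e-10)
  expect_equal(fit$concentration,
               (c(40, 200) - intercept_oracle) / slope_oracle,
               tolerance = 1e-10)
  # signal above the top standard is flagged extrapolated
  expect_true(linearQuantify(c(0, 5, 10), c(0, 50, 100), 120)$extrapolated)
})

test_that("depletion statistics match the stated arithmetic", {
  res <- depletionStats(c(20, 20, 20), c(7.2, 7.2, 7.2))
  expect_equal(res$percent_depletion, 64)
  resn <- depletionStats(c(10, 10.1, 9.9), c(10.05, 9.95, 10))
  expect_equal(resn$percent_depletion, 0, tolerance = 0.01)
  expect_gt(resn$p, 0.5)
  # planted 50% depletion at 6+6 replicates and 5% noise is detected
  set.seed(83)
  pvals <- vapply(1:40, function(i) {
    w <- 20 * rlnorm(6, 0, sqrt(log(1 + 0.05^2)))
    s <- 10 * rlnorm(6, 0, sqrt(log(1 + 0.05^2)))
    depletionStats(w, s)$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.01), 0.95)
})
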