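test_that("baseline correction sets the minimum to zero and is idempotent", {
  expect_equal(baselineCorrect(c(0.1, 0.2, 0.5)), c(0.0, 0.1, 0.4))
  expect_equal(baselineCorrect(c(0, 0.1, 0.4)), c(0, 0.1, 0.4))
  expect_equal(baselineCorrect(c(0.3, 0.3)), c(0, 0))
  curves <- makeCurves(n = 4L, cv = 0.05, seed = 3L)
  once <- baselineCorrect(curves)
  expect_equal(odMatrix(baselineCorrect(once)), odMatrix(once))
  expect_true(all(apply(odMatrix(once), 1L, min) == 0))
})

test_that("trapezoid AUC matches closed forms and a refinement oracle", {
  expect_equal(aucTrapezoid(rep(0, 25), times = 0:24), 0)
  expect_equal(aucTrapezoid(seq(0, 1, length.out = 25), times = 0:24), 12.0)
  # independent oracle: piecewise-linear integration by fine Riemann sums
  set.seed(11)
  od <- runif(25)
  times <- 0:24
  riemann <- sum(vapply(1:24, function(i) {
    g <- seq(times[i], times[i + 1], length.out = 20001L)
    f <- approx(times, od, g)$y
    mean(f) * (times[i + 1] - times[i])
  }, numeric(1)))
  expect_equal(aucTrapezoid(od, times = times), riemann, tolerance = 1e-9)
})

test_that("trapezoid AUC is linear in OD and additive over partitions", {
  set.seed(12)
  times <- sort(runif(20, 0, 24))
  a <- runif(20)
  b <- runif(20)
  expect_equal(aucTrapezoid(2 * a + 3 * b, times = times),
               2 * aucTrapezoid(a, times = times) +
                 3 * aucTrapezoid(b, times = times))
  expect_equal(aucTrapezoid(a, times = times),
               aucTrapezoid(a[1:10], times = times[1:10]) +
                 aucTrapezoid(a[10:20], times = times[10:20]))
})

test_that("logistic fit recovers parameters and its AUC matches quadrature", {
  times <- 0:24
  K <- 1.0; r <- 0.5; n0 <- 0.05
  od <- K / (1 + ((K - n0) / n0) * exp(-r * times))
  fit <- fitLogistic(times, od)
  expect_true(fit$converged)
  expect_equal(fit$K, K, tolerance = 1e-4)
  expect_equal(fit$r, r, tolerance = 1e-4)
  expect_equal(fit$N0, n0, tolerance = 1e-4)
  # quadrature oracle on the recovered parameters
  quad <- integrate(function(t)
    fit$K / (1 + ((fit$K - fit$N0) / fit$N0) * exp(-fit$r * t)),
    0, 24, rel.tol = 1e-10)$value
  expect_equal(fit$auc_fit, quad, tolerance = 1e-6)
  # flat curve is unidentifiable, flagged rather than an error
  expect_false(fitLogistic(times, rep(0.5, 25))$converged)
  expect_error(fitLogistic(0:3, c(0.1, 0.2, 0.4, 0.6)), ">= 5")
})

test_that("logistic fits recover K and r across noisy synthetic curves", {
  set.seed(21)
  times <- 0:24
  rel_err <- t(vapply(1:100, function(i) {
    K <- runif(1, 0.5, 1.2); r <- runif(1, 0.3, 0.9); n0 <- 0.05
    od <- K / (1 + ((K - n0) / n0) * exp(-r * times))
    od <- od * rlnorm(25, 0, sqrt(log(1 + 0.01^2)))
    fit <- fitLogistic(times, od)
    c(abs(fit$K - K) / K, abs(fit$r - r) / r)
  }, numeric(2)))
  expect_lt(median(rel_err[, 1]), 0.05)
  expect_lt(median(rel_err[, 2]), 0.05)
})

test_that("doublings follow the floored log2 ratio with clamping", {
  expect_equal(doublings(c(0.05, 0.3, 0.8)), 4.0)
  expect_equal(doublings(c(0.05, 0.05)), 0)
  expect_equal(doublings(c(0.5, 0.1)), 0)  # decline clamps to zero
  # floor guards near-zero blanks
  expect_equal(doublings(c(0.001, 0.64), floor = 0.01), log2(64))
})

test_that("growthSummary combines AUC and doublings per curve", {
  curves <- makeCurves(n = 3L)
  gs <- growthSummary(curves)
  expect_equal(nrow(gs), 3L)
  expect_equal(gs$raw_auc, aucTrapezoid(baselineCorrect(curves)))
  expect_true(all(gs$G > 0))
})
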