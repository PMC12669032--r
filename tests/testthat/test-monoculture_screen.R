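test_that("vehicle-control normalization divides by the control median", {
  map <- PlateMap("P1", sprintf("A%02d", 1:9),
                  c("x", rep("DMSO", 8L)),
                  c(20, rep(0, 8L)),
                  c("treatment", rep("vehicle_control", 8L)))
  aucs <- setNames(c(5, 10, 10, 10, 12, 12, 12, 8, 8), sprintf("A%02d", 1:9))
  norm <- normalizeDmso(aucs, map)
  expect_equal(unname(norm["A01"]), 0.5)
  expect_equal(median(norm[sprintf("A%02d", 2:9)]), 1)
  # all equal -> all one
  expect_equal(unname(normalizeDmso(setNames(rep(7, 9), sprintf("A%02d", 1:9)),
                                    map)),
               rep(1, 9))
  # zero controls -> plate failure
  expect_error(normalizeDmso(setNames(c(5, rep(0, 8)), sprintf("A%02d", 1:9)),
                             map), "median")
})

test_that("edge correction inverts planted multiplicative row/col effects", {
  wells <- as.vector(outer(LETTERS[1:8], sprintf("%02d", 1:12), paste0))
  # uniform plate maps to 1 (fraction-of-plate scale)
  uni <- setNames(rep(4, 96), wells)
  expect_equal(unname(normalizeEdge(uni)), rep(1, 96))
  # row A uniformly x2: corrected to parity with other rows
  v <- setNames(rep(10, 96), wells)
  v[grepl("^A", wells)] <- 20
  norm <- normalizeEdge(v)
  expect_equal(unname(norm[grepl("^A", wells)]),
               unname(norm[grepl("^B", wells)]), tolerance = 1e-9)
  # planted lognormal row/col effects: residual spread shrinks
  set.seed(31)
  rowf <- exp(runif(8, -0.7, 0.7))
  colf <- exp(runif(12, -0.7, 0.7))
  raw <- setNames(rlnorm(96, log(10), 0.02), wells)
  raw <- raw * rowf[match(substr(wells, 1, 1), LETTERS)] *
    colf[as.integer(substr(wells, 2, 3))]
  spread <- function(x) {
    rm <- tapply(x, substr(names(x), 1, 1), median)
    diff(range(rm)) / median(rm)
  }
  expect_gt(spread(raw), 0.5)
  expect_lt(spread(normalizeEdge(raw)), 0.05)
})

test_that("z-scores and p-values follow the control-median formula", {
  set.seed(32)
  controls <- c(0.9, 0.95, 1.0, 1.05, 1.1)
  res <- zscorePvalue(median(controls), controls)
  expect_equal(res$z, 0)
  expect_equal(res$p, 0.5)
  # z = -2 case with an error-function oracle
  ctrl <- c(1.0, 1.1, 0.9, 1.05, 0.95)
  val <- median(ctrl) - 2 * sd(ctrl)
  res <- zscorePvalue(val, ctrl)
  expect_equal(res$z, -2)
  erf_oracle <- 0.5 * (1 + pracma::erf(-2 / sqrt(2)))
  expect_equal(res$p, erf_oracle, tolerance = 1e-12)
  # growth above the control median can never be an inhibition hit
  expect_gt(zscorePvalue(median(ctrl) + 0.2, ctrl)$p, 0.5)
  expect_error(zscorePvalue(1, rep(1, 5)), "zero")
})

test_that("BH adjustment matches an independent step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04), m = 4), rep(0.04, 4))
  expect_equal(bhAdjust(0.03, m = 1), 0.03)
  set.seed(33)
  for (i in 1:5) {
    p <- runif(50)^2
    m <- 50 + sample(0:100, 1)
    adj <- bhAdjust(p, m = m)
    expect_equal(adj, bhOracle(p, m = m))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("replicate hits require both significance and >20% reduction", {
  expect_true(callReplicateHit(0.01, 0.7))
  expect_false(callReplicateHit(0.01, 0.85))
  expect_false(callReplicateHit(0.2, 0.5))
  # negative normalized AUC clamps to 0 and passes the effect filter
  expect_true(callReplicateHit(0.01, -0.2))
})

test_that("compound hits need two of three significant replicates", {
  rs <- data.frame(
    compound_id = rep(c("a", "b", "c"), each = 3),
    strain_id = "s1",
    replicate = rep(1:3, 3),
    sig = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE),
    norm_auc = rep(0.5, 9))
  hm <- callCompoundHits(rs)
  expect_equal(unname(isHit(hm)[, "s1"]), c(TRUE, FALSE, TRUE))
  expect_equal(unname(nSigReps(hm)[, "s1"]), c(2L, 1L, 3L))
  expect_equal(unname(meanNormAuc(hm)[, "s1"]), rep(0.5, 3))
})

test_that("screen summaries count interactions, active, broad, strong", {
  compounds <- c("A", "B", "C")
  strains <- sprintf("s%02d", 1:22)
  hit <- matrix(FALSE, 3, 22, dimnames = list(compounds, strains))
  hit["A", 1:8] <- TRUE
  hit["B", 1] <- TRUE
  nsig <- matrix(0L, 3, 22, dimnames = dimnames(hit))
  nsig[hit] <- 3L
  mn <- matrix(1, 3, 22, dimnames = dimnames(hit))
  mn[hit] <- 0.5
  mn["B", 1] <- 0.05
  s <- summarizeHits(HitMatrix(hit, nsig, mn), n_species = 22)
  expect_equal(s$n_interactions, 9L)
  expect_equal(s$n_active_compounds, 2L)
  expect_equal(s$n_broad_compounds, 1L)   # A: 8 > 22/3
  expect_equal(s$n_strong_compounds, 1L)  # B at 0.05
  # empty matrix
  s0 <- summarizeHits(HitMatrix(hit & FALSE, nsig * 0L, mn))
  expect_equal(unlist(s0), c(n_interactions = 0L, n_active_compounds = 0L,
                             n_broad_compounds = 0L, n_strong_compounds = 0L))
})

test_that("MIC is the lowest tested dose below threshold, censored otherwise", {
  expect_equal(determineMic(c(2.5, 5, 10, 20), c(0.9, 0.4, 0.05, 0.02))$mic, 10)
  res <- determineMic(c(2.5, 5, 10, 20), c(0.9, 0.6, 0.4, 0.15))
  expect_true(res$censored)
  expect_equal(res$label, ">20")
  # literal rule on a non-monotone series: lowest qualifying dose
  expect_equal(determineMic(c(2.5, 5, 10), c(0.05, 0.6, 0.02))$mic, 2.5)
})

test_that("MIC never increases when inhibition strengthens", {
  set.seed(34)
  concs <- 20 / 2^(7:0)
  for (i in 1:20) {
    vals <- runif(8, 0, 1.2)
    m1 <- determineMic(concs, vals)
    m2 <- determineMic(concs, vals * runif(1, 0.2, 1))  # stronger inhibition
    mic1 <- if (m1$censored) Inf else m1$mic
    mic2 <- if (m2$censored) Inf else m2$mic
    expect_lte(mic2, mic1)
  }
})

test_that("validation concordance counts confirmed hits at or below dose", {
  hit <- matrix(TRUE, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  hm <- HitMatrix(hit, matrix(2L, 2, 2), matrix(0.4, 2, 2))
  val <- data.frame(
    compound_id = c("a", "a", "b", "b"),
    strain_id = c("s1", "s2", "s1", "s2"),
    concentration = c(10, 10, 10, 40),
    norm_auc = c(0.3, 0.9, 0.2, 0.1),
    p_adj = c(0.01, 0.01, 0.001, 0.001))
  res <- validationConcordance(hm, val, main_dose = 20)
  # b:s2 only tested above the main dose -> not confirmed; a:s2 fails effect
  expect_equal(res$n_tested, 4L)
  expect_equal(res$n_confirmed, 2L)
  expect_equal(res$fraction, 0.5)
  # empty overlap
  res0 <- validationConcordance(hm, val[0, ], main_dose = 20)
  expect_equal(res0$n_tested, 0L)
  expect_true(is.na(res0$fraction))
})

test_that("controls score near zero after normalization", {
  sim <- simScreen(n_compounds = 88, n_strains = 1, hit_fraction = 0, seed = 41)
  cd <- as.data.frame(curveData(sim$curves))
  raw <- aucTrapezoid(baselineCorrect(sim$curves))
  map <- sim$maps[[1]]
  w <- wells(map)
  ctrl_wells <- rownames(w)[w$role == "vehicle_control"]
  sel <- cd$replicate == 1
  aucs <- setNames(raw[sel], cd$well[sel])
  z <- zscorePvalue(aucs[ctrl_wells], aucs[ctrl_wells])$z
  expect_lt(abs(median(z)), 0.3)
  norm <- normalizeDmso(aucs, map)
  expect_equal(median(norm[ctrl_wells]), 1)
})

test_that("planted inhibitors are recovered and validation re-screen concurs", {
  sim <- simScreen(n_compounds = 176, n_strains = 2, hit_fraction = 0.1,
                   effect_range = c(0.5, 0.95), noise_cv = 0.05, seed = 42)
  res <- screenCallHits(sim$curves, sim$maps, m = 1076)
  h <- isHit(res$hits)
  truth <- matrix(sim$truth$is_hit, nrow = 176,
                  dimnames = list(unique(sim$truth$compound_id),
                                  unique(sim$truth$strain_id)))
  truth <- truth[rownames(h), colnames(h)]
  sens <- sum(h & truth, na.rm = TRUE) / sum(truth)
  expect_gte(sens, 0.95)
  # independent re-simulation of the same planted effects confirms hits
  effects <- matrix(sim$truth$effect, nrow = 176)
  sim2 <- simScreen(n_compounds = 176, n_strains = 2,
                    planted_effects = effects, noise_cv = 0.05, seed = 43)
  res2 <- screenCallHits(sim2$curves, sim2$maps, m = 1076)
  val <- res2$replicateStats
  val$concentration <- 20
  conc <- validationConcordance(res$hits, val, main_dose = 20)
  expect_gte(conc$fraction, 0.9)
})
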