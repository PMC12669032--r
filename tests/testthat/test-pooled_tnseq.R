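test_that("central mask keeps exactly the middle 80% of a coding region", {
  expect_true(centralMask(50, 1, 100))
  expect_false(centralMask(5, 1, 100))
  expect_false(centralMask(95, 1, 100))
  expect_false(centralMask(150, 1, 100))  # outside the gene
  # exhaustive enumeration over every position of a 100 bp gene
  kept <- which(centralMask(1:100, 1, 100))
  expect_equal(kept, 11:90)
  expect_equal(length(kept), 80L)
})

test_that("TTR normalization equalizes trimmed means and resists outliers", {
  set.seed(51)
  a <- rnbinom(200, mu = 100, size = 5)
  a[a == 0] <- 1
  counts <- cbind(s1 = a, s2 = a)
  res <- ttrNormalize(counts)
  expect_equal(unname(res$factors["s1"]), unname(res$factors["s2"]))
  # doubling depth halves the factor and restores equality
  res2 <- ttrNormalize(cbind(s1 = a, s2 = 2L * a))
  expect_equal(unname(res2$factors["s2"]), unname(res2$factors["s1"]) / 2)
  expect_equal(res2$normalized[, "s1"], res2$normalized[, "s2"],
               ignore_attr = TRUE)
  # one jackpot site barely moves the trimmed factor
  b <- a
  b[1] <- b[1] * 1000L
  f_out <- ttrNormalize(cbind(s1 = a, s2 = b))$factors["s2"]
  f_ref <- ttrNormalize(cbind(s1 = a, s2 = a))$factors["s2"]
  expect_lt(abs(f_out - f_ref) / f_ref, 0.02)
  expect_error(ttrNormalize(cbind(s1 = a, s2 = rep(0L, 200))), "all-zero")
})

test_that("gene aggregation sums retained sites and conserves totals", {
  gt <- data.frame(gene_id = c("g1", "g2"), start = c(1L, 201L),
                   end = c(100L, 300L), strand = c("+", "-"))
  sites <- data.frame(position = c(50L, 60L, 5L, 250L, 150L),
                      gene_id = c("g1", "g1", "g1", "g2", NA))
  counts <- matrix(c(5, 7, 100, 11, 13), ncol = 1,
                   dimnames = list(NULL, "s1"))
  agg <- geneAggregate(counts, sites, gt)
  expect_equal(agg$geneCounts["g1", "s1"], 12)  # masked tail site excluded
  expect_equal(agg$geneCounts["g2", "s1"], 11)
  expect_equal(sum(agg$geneCounts, na.rm = TRUE) + agg$intergenic[["s1"]],
               sum(counts))
  # gene with all sites masked is untestable
  gt2 <- rbind(gt, data.frame(gene_id = "g3", start = 400L, end = 500L,
                              strand = "+"))
  agg2 <- geneAggregate(counts, sites, gt2)
  expect_equal(agg2$untestable, "g3")
})

test_that("resampling p equals exhaustive enumeration on small designs", {
  # identical arms -> null identity
  res <- resamplingTest(c(10, 10), c(10, 10, 10))
  expect_equal(res$log2fc, 0)
  expect_equal(res$p, 1)
  # 2-vs-3: all C(5,2) = 10 assignments enumerated by an independent oracle
  set.seed(52)
  for (i in 1:10) {
    x <- round(rlnorm(5, log(50), 0.6), 1)
    cond <- x[1:2]; ctrl <- x[3:5]
    res <- resamplingTest(cond, ctrl)
    expect_true(res$exhaustive)
    obs <- mean(cond) - mean(ctrl)
    perm <- apply(combn(5, 2), 2, function(ix)
      mean(x[ix]) - mean(x[-ix]))
    expect_equal(res$p, mean(abs(perm) >= abs(obs) - 1e-12))
  }
  # pseudocount arithmetic
  expect_equal(resamplingTest(c(3, 3), c(63, 63))$log2fc, -4)
  expect_error(resamplingTest(numeric(0), c(1, 2)), "non-empty")
})

test_that("sampled and exhaustive permutation p-values agree", {
  set.seed(53)
  x <- rnbinom(12, mu = 80, size = 5)
  ex <- resamplingTest(x[1:6], x[7:12], n_perm = 20000)  # C(12,6)=924, exact
  sa <- resamplingTest(x[1:6], x[7:12], n_perm = 20000, seed = 9,
                       method = "sample")
  expect_true(ex$exhaustive)
  expect_false(sa$exhaustive)
  expect_lt(abs(ex$p - sa$p), 2 / sqrt(20000))
  # fixed seed reproduces sampled p bit-identically
  sa2 <- resamplingTest(x[1:6], x[7:12], n_perm = 20000, seed = 9,
                        method = "sample")
  expect_identical(sa$p, sa2$p)
})

test_that("doublings correction rescales per control doubling", {
  expect_equal(doublingsCorrect(-1, 5, 10)$log2fc_corrected, -2)
  expect_equal(doublingsCorrect(-1.4, 7, 7)$log2fc_corrected, -1.4)
  expect_equal(doublingsCorrect(0, 3, 9)$log2fc_corrected, 0)
  expect_warning(res <- doublingsCorrect(-1, 0, 5), "skipped")
  expect_equal(res$log2fc_corrected, -1)
  expect_false(res$corrected)
})

test_that("gene hit calls require both adjusted p and fold-change", {
  res <- data.frame(p_adj = c(0.01, 0.01, 0.2), log2fc = c(0.3, 0.1, 2.0))
  out <- callGeneHits(res)
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("enriched", "enriched", "enriched"))
})

test_that("term enrichment matches the hypergeometric tail", {
  bg <- sprintf("g%03d", 1:100)
  hits <- bg[1:10]
  tmap <- setNames(rep(list("T1"), 10), c(bg[1:5], bg[96:100]))
  res <- termEnrichment(hits, bg, tmap)
  # oracle: P(X >= 5) for X ~ Hypergeom(10 in term, 90 out, 10 drawn)
  oracle <- phyper(4, 10, 90, 10, lower.tail = FALSE)
  expect_equal(res$p, oracle, tolerance = 1e-12)
  expect_equal(res$n_hits_in_term, 5L)
  # all genes in one term -> p = 1
  tall <- setNames(rep(list("T1"), 100), bg)
  expect_equal(termEnrichment(hits, bg, tall)$p, 1)
  # term with no hits -> p = 1 at the independence extreme
  tnone <- setNames(rep(list("T2"), 5), bg[50:54])
  expect_equal(termEnrichment(bg[1:5], bg, tnone)$p, 1)
})

test_that("null pipeline p-values are near-uniform and planted genes recovered", {
  st <- simTnseq(n_genes = 400, seed = 54)
  ft <- tnseqFit(st$ie, st$geneTable, "treated", "control", n_perm = 5000,
                 seed = 55)
  ks <- suppressWarnings(ks.test(ft$results$p, "punif"))$statistic
  expect_lt(unname(ks), 0.08)
  expect_equal(sum(ft$results$is_hit), 0L)
  # planted 8-fold depleted genes are recovered
  planted <- setNames(rep(-3, 10), sprintf("gene%04d", 1:10))
  st2 <- simTnseq(n_genes = 400, planted = planted, seed = 56)
  ft2 <- tnseqFit(st2$ie, st2$geneTable, "treated", "control", n_perm = 5000,
                  seed = 57)
  hit_planted <- ft2$results$is_hit[ft2$results$gene_id %in% names(planted)]
  expect_gte(mean(hit_planted), 0.9)
  false_hits <- ft2$results$is_hit[!ft2$results$gene_id %in% names(planted)]
  expect_lte(mean(false_hits), 0.01)
  expect_lt(median(ft2$results$log2fc[ft2$results$gene_id %in% names(planted)]),
            -2.5)
})

test_that("fixed seeds make the pipeline bit-reproducible", {
  st <- simTnseq(n_genes = 60, seed = 58)
  f1 <- tnseqFit(st$ie, st$geneTable, "treated", "control", n_perm = 2000,
                 seed = 59)
  f2 <- tnseqFit(st$ie, st$geneTable, "treated", "control", n_perm = 2000,
                 seed = 59)
  expect_identical(f1$results$p, f2$results$p)
})
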