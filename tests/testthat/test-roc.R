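test_that("confusion counts cover perfect, degenerate and random cases", {
  mask <- matrix(0, 20, 20); mask[5:10, 12:16] <- 1
  inside <- which(mask > 0, arr.ind = TRUE)[1:6, ]
  outside <- which(mask == 0, arr.ind = TRUE)[1:6, ]
  sel <- manualSelection(rbind(inside, outside), midline = 10)
  perfect <- fakeResult(c(rep("P", 6), rep("H", 6)), sel)
  cc <- confusionCounts(perfect, sel, mask)
  expect_equal(unname(cc[c("fp", "fn")]), c(0L, 0L))
  expect_equal(sum(cc), 12L)

  allP <- fakeResult(rep("P", 12), sel)
  cc2 <- confusionCounts(allP, sel, mask * 0)
  expect_equal(unname(cc2[c("tp", "fp")]), c(0L, 12L))

  set.seed(31)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    co <- cbind(sample(1:20, n, TRUE), sample(1:20, n, TRUE))
    labs <- sample(c("H", "P"), n, TRUE)
    tm <- matrix(rbinom(400, 1, 0.3), 20)
    selR <- manualSelection(co, midline = 10)
    expect_equal(confusionCounts(fakeResult(labs, selR), selR, tm),
                 naiveConfusion(labs, co, tm))
  }
})

test_that("rates follow the defining formulas with NA for empty denominators", {
  expect_equal(computeRates(c(tp = 5, fp = 0, tn = 5, fn = 0)),
               c(tpr = 1, fpr = 0, acc = 1))
  expect_equal(computeRates(c(tp = 3, fp = 1, tn = 3, fn = 1)),
               c(tpr = 0.75, fpr = 0.25, acc = 0.75))
  r <- computeRates(c(tp = 0, fp = 2, tn = 6, fn = 0))
  expect_true(is.na(r[["tpr"]]))
  expect_equal(r[["acc"]], 0.75)
})

test_that("ROC pooling collapses FPR = 0 subjects and anchors the curve", {
  allZero <- data.frame(tpr = c(0.8, 0.6, 1), fpr = c(0, 0, 0))
  cz <- pooledROC(allZero)
  expect_equal(unname(rocPoints(cz)), rbind(c(0, 0.8), c(1, 1)))

  noZero <- data.frame(tpr = c(0.7, 0.9), fpr = c(0.2, 0.4))
  cn <- pooledROC(noZero)
  expect_equal(unname(rocPoints(cn)[1, ]), c(0, 0))

  tab <- exampleRates()
  expect_equal(nrow(tab), 13)
  curve <- pooledROC(tab, collapseTpr0 = 0.67)
  pts <- rocPoints(curve)
  expect_equal(nrow(pts), 9)
  expect_equal(unname(pts[1, ]), c(0, 0.67))
  expect_equal(unname(pts[nrow(pts), ]), c(1, 1))
  expect_false(is.unsorted(pts[, "fpr"]))
  # without the override, the collapse point is the mean of the six TPRs
  curveM <- pooledROC(tab)
  expect_equal(unname(rocPoints(curveM)[1, "tpr"]),
               mean(tab$tpr[tab$fpr == 0]), tolerance = 1e-12)
})

test_that("trapezoidal AUC handles anchors, duplicates and bad input", {
  expect_equal(aucTrapezoid(rbind(c(0, 0), c(1, 1))), 0.5)
  expect_equal(aucTrapezoid(rbind(c(0, 1), c(1, 1))), 1)
  base <- rbind(c(0, 0), c(0.5, 0.8), c(1, 1))
  expect_equal(aucTrapezoid(rbind(base, c(1, 1))), aucTrapezoid(base))
  expect_error(aucTrapezoid(rbind(c(0.5, 1), c(0, 0))), "sorted")
})

test_that("spline AUC interpolates simple shapes and averages duplicates", {
  diagc <- rbind(c(0, 0), c(0.5, 0.5), c(1, 1))
  expect_lt(abs(aucSmoothed(diagc, p = 1) - 0.5), 0.01)
  flat <- rbind(c(0, 1), c(0.4, 1), c(1, 1))
  expect_lt(abs(aucSmoothed(flat, p = 1) - 1), 0.01)
  dup <- rbind(c(0, 0.4), c(0, 0.8), c(0.5, 0.6), c(1, 1))
  expect_warning(v <- aucSmoothed(dup, p = 0.99), "duplicate")
  expect_true(v > 0 && v < 1)
})

test_that("AUC bands match the stated interpretation thresholds", {
  expect_equal(interpretAUC(0.5), "not informative")
  expect_equal(interpretAUC(0.65), "not accurate")
  expect_equal(interpretAUC(0.7), "not accurate")
  expect_equal(interpretAUC(0.88), "moderately accurate")
  expect_equal(interpretAUC(0.9), "moderately accurate")
  expect_equal(interpretAUC(0.95), "highly accurate")
  expect_equal(interpretAUC(1), "perfect test")
  expect_equal(interpretAUC(0.3), "below chance")
})
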