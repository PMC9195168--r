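test_that("UPGMA reproduces hand-computed merges and degenerate cases", {
  d <- upgmaLinkage(matrix(c(0, 1, 10), ncol = 1))
  expect_equal(d@height, c(1, (10 + 9) / 2))
  expect_equal(d@size[2], 3L)

  same <- upgmaLinkage(matrix(1, 5, 2))
  expect_equal(same@height, rep(0, 4))

  expect_error(upgmaLinkage(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("UPGMA merge heights are monotone and match hclust on distinct data", {
  set.seed(10)
  for (i in 1:5) {
    m <- matrix(rnorm(20 * 3), 20)
    d <- upgmaLinkage(m)
    expect_true(all(diff(d@height) >= -1e-9))
    hc <- hclust(dist(m), method = "average")
    expect_equal(d@height, hc$height, tolerance = 1e-10)
    # cut partitions agree up to label renaming
    for (k in 2:4) {
      a <- cutDendrogram(d, k)
      b <- cutree(hc, k)
      expect_equal(length(unique(paste(a, b))), k)
    }
  }
})

test_that("tie-breaking picks the smallest index pair", {
  # three points pairwise equidistant except one closer pair duplicated:
  # rows 1-2 and 3-4 both at distance 1; the 1-2 merge must come first
  m <- matrix(c(0, 1, 10, 11), ncol = 1)
  d <- upgmaLinkage(m)
  expect_equal(sort(d@merge[1, ]), c(-2L, -1L))
})

test_that("silhouettes match the direct formula and behave at the limits", {
  set.seed(4)
  tight <- rbind(matrix(rnorm(20, 0, 0.05), 10),
                 matrix(rnorm(20, 5, 0.05), 10))
  dend <- upgmaLinkage(tight)
  prof <- silhouetteByK(tight, dend)
  expect_gt(prof$meanSilhouette[prof$k == 2], 0.9)
  expect_equal(selectK(prof), 2L)

  ident <- matrix(1, 6, 2)
  di <- upgmaLinkage(ident)
  expect_equal(silhouetteByK(ident, di, 2, 2)$meanSilhouette, 0)

  m <- matrix(rnorm(30 * 4), 30)
  D <- as.matrix(dist(m))
  for (k in 2:4) {
    assign <- cutDendrogram(upgmaLinkage(m), k)
    expect_equal(RelaxoMRR:::silhouetteWidths(D, assign),
                 naiveSilhouette(m, assign), tolerance = 1e-12)
  }
  expect_error(silhouetteByK(ident, di, 2, 10), "exceeds")
})

test_that("silhouette agrees with the cluster package on a random instance", {
  skip_if_not_installed("cluster")
  set.seed(5)
  m <- matrix(rnorm(25 * 3), 25)
  assign <- cutDendrogram(upgmaLinkage(m), 3)
  ours <- RelaxoMRR:::silhouetteWidths(as.matrix(dist(m)), assign)
  ref <- cluster::silhouette(assign, dist(m))
  expect_equal(ours, unname(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("selectK takes the smallest k on ties and finds true structure", {
  prof <- data.frame(k = 2:5, meanSilhouette = c(0.7, 0.7, 0.5, 0.2))
  expect_equal(selectK(prof), 2L)
  set.seed(6)
  three <- rbind(matrix(rnorm(16, 0, 0.05), 8), matrix(rnorm(16, 4, 0.05), 8),
                 matrix(rnorm(16, 9, 0.05), 8))
  dend <- upgmaLinkage(three)
  expect_equal(selectK(silhouetteByK(three, dend)), 3L)
})

test_that("hemisphere majority labeling implements the rule and its tie-breaks", {
  # cluster 1: 8/10 right; cluster 2: all left -> 1 = H, 2 = P
  co <- rbind(cbind(1:10, c(rep(3, 8), 16, 17)), cbind(1:6, 15))
  sel <- manualSelection(co, midline = 10)
  assign <- rep(1:2, c(10, 6))
  res <- labelByHemisphere(assign, sel)
  expect_equal(unname(res@mapping[c("1", "2")]), c("H", "P"))
  expect_true(all(voxelLabels(res)[assign == 2] == "P"))

  # exact tie on hemisphere fractions -> higher mean fitted T2 is P
  co2 <- rbind(cbind(1:4, c(3, 3, 16, 16)), cbind(1:4, c(4, 4, 15, 15)))
  sel2 <- manualSelection(co2, midline = 10)
  tau <- matrix(90, 20, 20); tau[cbind(1:4, c(4, 4, 15, 15))] <- 160
  t2map <- new("ParameterMap", tauImg = tau, m0Img = tau, sseImg = tau * 0,
               convergedImg = tau * 0 + 1, mask = tau * 0 + 1,
               mode = "t2_series")
  res2 <- labelByHemisphere(rep(1:2, each = 4), sel2, t2map)
  expect_equal(unname(res2@mapping[c("1", "2")]), c("H", "P"))

  # both clusters majority-right: degenerate, warned, larger fraction is H
  co3 <- rbind(cbind(1:10, 3), cbind(1:10, c(rep(4, 6), rep(15, 4))))
  sel3 <- manualSelection(co3, midline = 10)
  expect_warning(res3 <- labelByHemisphere(rep(1:2, each = 10), sel3),
                 "majority")
  expect_equal(unname(res3@mapping["1"]), "H")
})

test_that("noiseless classification separates lesion from mirrored parenchyma", {
  ph <- smallPhantom(seed = 3, shape = "circular", area = 60)
  s1 <- simulateSeries(ph, acquisitionProtocol("t1_series"))
  fs <- fitAndSelect(ph, n = 10)
  res <- classifyVoxels(s1, fs$map, fs$selection)
  expect_equal(res@kUsed, 2L)
  expect_setequal(unique(voxelLabels(res)), c("P", "H"))
  ori <- voxelOrigin(fs$selection)
  expect_true(all(voxelLabels(res)[ori == "selected"] == "P"))
  expect_true(all(voxelLabels(res)[ori == "mirrored"] == "H"))
})

test_that("classification is invariant to input row order up to relabeling", {
  set.seed(12)
  m <- rbind(matrix(rnorm(28, 0, 0.3), 14), matrix(rnorm(28, 6, 0.3), 14))
  base <- cutDendrogram(upgmaLinkage(m), 2)
  perm <- sample(nrow(m))
  permuted <- cutDendrogram(upgmaLinkage(m[perm, ]), 2)
  # same bipartition after undoing the permutation
  expect_equal(length(unique(paste(base[perm], permuted))), 2)
})

test_that("a blended perilesional rim produces misses over repeated runs", {
  fnTotal <- 0
  for (seed in 1:20) {
    ph <- smallPhantom(seed = seed, shape = "circular", area = 40,
                       rimWidthPx = 2, rimMix = 0.5)
    s1 <- simulateSeries(ph, acquisitionProtocol("t1_series", noiseSigma = 5,
                                                 seed = seed))
    fs <- fitAndSelect(ph, noiseSigma = 5, n = 20, seed = seed + 100)
    res <- classifyVoxels(s1, fs$map, fs$selection)
    # histology-style contour: the hemorrhage plus its infiltrated rim
    contour <- pmin(RelaxoMRR:::dilateMask(lesionMask(ph), 2) +
                    lesionMask(ph), 1) * brainMask(ph)
    counts <- confusionCounts(res, fs$selection, contour)
    fnTotal <- fnTotal + counts[["fn"]]
  }
  expect_gt(fnTotal, 0)
})

test_that("clustering hits high sensitivity and specificity on separable phantoms", {
  tprs <- fprs <- numeric(20)
  for (seed in 1:20) {
    ph <- smallPhantom(seed = seed, shape = "circular", area = 60)
    s1 <- simulateSeries(ph, acquisitionProtocol("t1_series", noiseSigma = 5,
                                                 seed = seed))
    fs <- fitAndSelect(ph, noiseSigma = 5, n = 12, seed = seed + 50)
    res <- classifyVoxels(s1, fs$map, fs$selection)
    r <- computeRates(confusionCounts(res, fs$selection, lesionMask(ph)))
    tprs[seed] <- r[["tpr"]]; fprs[seed] <- r[["fpr"]]
  }
  expect_gte(mean(tprs), 0.9)
  expect_lte(mean(fprs), 0.1)
})
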