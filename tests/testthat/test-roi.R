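test_that("midline estimation finds the symmetry axis and is shift-equivariant", {
  # symmetric synthetic slice: two mirrored blobs about column 33
  nr <- 64; nc <- 65
  g <- expand.grid(r = 1:nr, c = 1:nc)
  img <- matrix(exp(-((g$r - 32)^2 + (g$c - 20)^2) / 60) +
                exp(-((g$r - 32)^2 + (g$c - 46)^2) / 60), nr, nc)
  mask <- matrix(as.numeric(img > 0.01), nr, nc)
  expect_equal(estimateMidline(img, mask)$col, 33)

  shifted <- cbind(matrix(0, nr, 3), img[, 1:(nc - 3)])
  maskS <- cbind(matrix(0, nr, 3), mask[, 1:(nc - 3)])
  expect_equal(estimateMidline(shifted, maskS)$col, 36)

  expect_identical(estimateMidline(img, mask, overrideCol = 30),
                   list(col = 30, source = "config"))
})

test_that("noisy midline estimate matches an exhaustive all-column oracle", {
  ph <- smallPhantom(seed = 9, area = 50)
  img <- truthMap(ph, "t2")
  set.seed(21)
  img <- img + matrix(rnorm(length(img), sd = 8), nrow(img)) # 10% of tissue T2
  mask <- brainMask(ph)
  est <- estimateMidline(img, mask)$col
  # independent exhaustive search over every half-column position
  masked <- img; masked[mask == 0] <- NA
  nc <- ncol(img)
  scoreAt <- function(cc) {
    tot <- 0; cnt <- 0
    for (x in 1:nc) {
      mx <- round(2 * cc - x)
      if (mx >= 1 && mx <= nc) {
        dv <- masked[, x] - masked[, mx]
        dv <- dv[!is.na(dv)]
        tot <- tot + sum(dv^2); cnt <- cnt + length(dv)
      }
    }
    # a midline must pair at least half the mask with a mirror partner
    if (cnt < 0.5 * sum(mask)) Inf else tot / cnt
  }
  cand <- seq(2, nc - 1, by = 0.5)
  oracle <- cand[which.min(vapply(cand, scoreAt, numeric(1)))]
  expect_lte(abs(est - oracle), 1)
})

test_that("manual selection passes through and rejects out-of-mask voxels", {
  ph <- smallPhantom(seed = 3)
  fs <- fitAndSelect(ph, n = 5)
  co <- cbind(row = rep(32, 12), col = 41:52)
  sel <- selectSuspectVoxels(fs$map, "manual", midline = fs$midline,
                             brainMask = brainMask(ph), coords = co)
  expect_equal(nSelected(sel), 12L)
  expect_true(all(voxelOrigin(sel) == "selected"))
  expect_equal(voxelCoords(sel)[, "col"], 41:52)
  expect_error(
    selectSuspectVoxels(fs$map, "manual", midline = fs$midline,
                        brainMask = brainMask(ph),
                        coords = rbind(co, c(1, 1))),
    "outside the brain mask")
})

test_that("auto selection stays in the left hemisphere and is T2-enriched", {
  ph <- smallPhantom(seed = 3, area = 60)
  s2 <- simulateSeries(ph, acquisitionProtocol("t2_series"))
  m2 <- fitMap(s2)
  tau <- tauImage(m2); tau[is.na(tau)] <- 0
  mid <- estimateMidline(tau, brainMask(ph))
  sel <- selectSuspectVoxels(m2, "auto", n = 15, midline = mid,
                             brainMask = brainMask(ph), windowMarginPx = 5)
  expect_true(all(hemisphere(sel) == "left"))
  truthT2 <- truthMap(ph, "t2")
  hemi <- brainMask(ph) > 0 & col(truthT2) > mid$col
  expect_gte(mean(truthT2[voxelCoords(sel)]), mean(truthT2[hemi]))
})

test_that("mirroring reflects across the midline and doubles the set", {
  sel <- manualSelection(cbind(30, 80), midline = 64, maskDim = c(100L, 100L))
  m <- mirrorContralateral(sel)
  expect_equal(unname(voxelCoords(m)[2, ]), c(30, 48)) # 2*64 - 80
  sel10 <- manualSelection(cbind(5:14, 12), midline = 10, maskDim = c(20L, 20L))
  m10 <- mirrorContralateral(sel10)
  expect_equal(nrow(voxelCoords(m10)), 20L)
  expect_equal(sum(voxelOrigin(m10) == "mirrored"), 10L)
  expect_setequal(unique(hemisphere(m10)), c("left", "right"))
  # involution: mirroring the mirrored columns returns the originals
  back <- 2 * 10 - voxelCoords(m10)[11:20, "col"]
  expect_equal(unname(back), rep(12, 10))
})

test_that("mirroring refuses midline voxels and out-of-mask mirrors", {
  onMid <- manualSelection(cbind(5, 10), midline = 10)
  expect_error(mirrorContralateral(onMid), "midline")
  mask <- matrix(1, 20, 20); mask[, 1:6] <- 0 # contralateral side missing
  sel <- new("VoxelSelection", coords = cbind(row = 5L, col = 16L),
             hemisphere = "left", origin = "selected", nSelected = 1L,
             midlineCol = 10, brainMask = mask)
  expect_error(mirrorContralateral(sel), "outside the brain mask")
})

test_that("fractional midlines mirror half-away so voxels never land on the midline", {
  sel <- manualSelection(cbind(4, 14), midline = 10.25, maskDim = c(20L, 20L))
  m <- mirrorContralateral(sel)
  expect_false(any(voxelCoords(m)[, "col"] == 10.25))
  expect_lt(voxelCoords(m)[2, "col"], 10.25)
})

test_that("recovery matrix rows follow TR order and distinguish tissues", {
  ph <- smallPhantom(seed = 3, area = 60)
  s1 <- simulateSeries(ph, acquisitionProtocol("t1_series"))
  fs <- fitAndSelect(ph, n = 8)
  rm <- extractRecoveryMatrix(s1, fs$selection)
  expect_equal(ncol(rm), 14)
  expect_equal(nrow(rm), 16)
  expect_false(is.unsorted(attr(rm, "timingMs")))
  # duplicated coordinates give identical rows
  dup <- manualSelection(rbind(c(32, 40), c(32, 40)), midline = 32.5,
                         maskDim = c(64L, 64L))
  rmd <- extractRecoveryMatrix(s1, dup)
  expect_identical(rmd[1, ], rmd[2, ])
  # lesion rows differ from their mirrors (distinct tissue parameters)
  half <- nSelected(fs$selection)
  d <- sqrt(rowSums((rm[1:half, , drop = FALSE] -
                     rm[half + 1:half, , drop = FALSE])^2))
  expect_true(all(d > 0))
})
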