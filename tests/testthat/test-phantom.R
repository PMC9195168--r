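test_that("phantom generation is seed-deterministic and respects the lesion contract", {
  sp <- phantomSpec(grid = c(64, 64), lesionShape = "irregular",
                    lesionAreaPx = 70, seed = 11)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(truthMap(a, "label"), truthMap(b, "label"))
  expect_identical(lesionMask(a), lesionMask(b))

  for (shape in c("linear", "irregular", "circular")) {
    ph <- smallPhantom(seed = 5, shape = shape, area = 80)
    les <- which(lesionMask(ph) > 0, arr.ind = TRUE)
    expect_gt(nrow(les), 0)
    # entire lesion on the subject's left (image right) of the midline
    expect_true(all(les[, 2] > midlineCol(ph)))
    # inside the brain
    expect_true(all(brainMask(ph)[les] > 0))
  }
  expect_error(phantomSpec(lesionShape = "punctiform"), "linear")
})

test_that("circular lesions hit the requested area within 10%", {
  ph <- smallPhantom(seed = 2, shape = "circular", area = 80)
  expect_lt(abs(sum(lesionMask(ph)) - 80), 8)
})

test_that("perilesional rim blends lesion and tissue parameters", {
  ph0 <- smallPhantom(seed = 4, shape = "circular", area = 60)
  ph <- smallPhantom(seed = 4, shape = "circular", area = 60,
                     rimWidthPx = 2, rimMix = 0.5)
  rim <- RelaxoMRR:::dilateMask(lesionMask(ph), 2) *
    (1 - lesionMask(ph)) * brainMask(ph)
  td <- tissueDefaults()
  blood <- td[td$name == "blood", ]
  idx <- which(rim > 0 & truthMap(ph0, "label") == 1) # rim over white matter
  expect_gt(length(idx), 0)
  wm <- td[td$name == "white_matter", ]
  expect_equal(unique(truthMap(ph, "t2")[idx]),
               0.5 * blood$t2_ms + 0.5 * wm$t2_ms)
})

test_that("simulated frames satisfy the signal models exactly when noiseless", {
  tt <- tissueDefaults()
  tt[tt$name == "white_matter", c("t1_ms", "t2_ms", "m0")] <- c(500, 100, 100)
  ph <- generatePhantom(phantomSpec(grid = c(64, 64), lesionShape = "circular",
                                    lesionAreaPx = 40, tissueTable = tt,
                                    seed = 1))
  s1 <- simulateSeries(ph, acquisitionProtocol("t1_series"))
  expect_equal(dim(frames(s1))[3], 14)
  wm <- which(truthMap(ph, "label") == 1, arr.ind = TRUE)[1, , drop = FALSE]
  i500 <- which(timingMs(s1) == 500)
  # M0 = 100, T1 = 500 ms at TR = 500 ms: 100 * (1 - 1/e)
  expect_equal(frames(s1)[wm[1], wm[2], i500], 100 * (1 - exp(-1)),
               tolerance = 1e-12)
  s2 <- simulateSeries(ph, acquisitionProtocol("t2_series"))
  expect_equal(dim(frames(s2))[3], 3)
  expect_equal(frames(s2)[wm[1], wm[2], 2],
               100 * exp(-timingMs(s2)[2] / 100), tolerance = 1e-12)
})

test_that("the strict TR schedule reproduces the printed listing, the default is monotone", {
  expect_length(defaultTRScheduleMs(), 14)
  expect_length(defaultTRScheduleMs(strict = TRUE), 14)
  expect_false(is.unsorted(defaultTRScheduleMs()))
  expect_true(129 %in% defaultTRScheduleMs(strict = TRUE))
  expect_setequal(setdiff(defaultTRScheduleMs(strict = TRUE),
                          defaultTRScheduleMs()), 129)
})

test_that("Rician background magnitude sits at the analytic noise floor", {
  set.seed(99)
  sigma <- 4
  noisy <- addRicianNoise(matrix(0, 100, 100), sigma)
  floorTheory <- sigma * sqrt(pi / 2)
  expect_lt(abs(mean(noisy) - floorTheory) / floorTheory, 0.05)
})

test_that("motion is bounded, recorded, and absent at zero amplitude", {
  ph <- smallPhantom(seed = 6)
  s <- simulateSeries(ph, acquisitionProtocol("t1_series"))
  s0 <- applyMotion(s, 0)
  expect_identical(frames(s0), frames(s))
  sm <- applyMotion(s, 1.5, seed = 8)
  expect_true(all(abs(sm@motionShifts) <= 1.5))
  expect_equal(dim(sm@motionShifts), c(14L, 2L))
})

test_that("macro image: identity settings reproduce the source, shrink scales area", {
  ph <- smallPhantom(seed = 7, shape = "circular", area = 80)
  mi <- makeMacroImage(ph, shrinkLinear = 1, rotationDeg = 0, deformAmpPx = 0)
  expect_equal(macroImg(mi), truthMap(ph, "t2"), tolerance = 1e-12)
  expect_equal(contourTruth(mi), lesionMask(ph))

  s <- 0.7
  mis <- makeMacroImage(ph, shrinkLinear = s, rotationDeg = 0, deformAmpPx = 0)
  ratio <- sum(contourTruth(mis)) / sum(lesionMask(ph))
  expect_lt(abs(ratio - s^2) / s^2, 0.12)  # discretization of a small disk
  # default shrink encodes ~33% volume loss as a 2D section scale
  expect_equal(eval(formals(makeMacroImage)$shrinkLinear), sqrt(1 - 0.33))
  expect_error(makeMacroImage(ph, shrinkLinear = 0.02), "vanish")
})
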