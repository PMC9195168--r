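test_that("registering an image to itself yields the identity", {
  ph <- smallPhantom(seed = 5, grid = c(96L, 96L), area = 80)
  fixed <- truthMap(ph, "t2")
  tf <- registerSimilarity(fixed, fixed, tryReflection = FALSE)
  expect_lt(abs(tf@rotationDeg), 0.2)
  expect_lt(abs(tf@scale - 1), 0.005)
  expect_lt(max(abs(tf@translation)), 0.3)
})

test_that("a mirrored moving image selects the reflected hypothesis", {
  ph <- smallPhantom(seed = 8, grid = c(96L, 96L), shape = "circular",
                     area = 90)
  fixed <- truthMap(ph, "t2")
  moving <- fixed[, ncol(fixed):1]
  tf <- registerSimilarity(moving, fixed, tryReflection = TRUE)
  expect_true(tf@reflect)
  expect_lt(abs(tf@scale - 1), 0.02)
})

test_that("similarity composition with its inverse is the identity", {
  tf <- new("SimilarityTransform", rotationDeg = 17, scale = 0.85,
            translation = c(4, -3), reflect = FALSE,
            centerFixed = c(30, 30), centerMoving = c(30, 30), mse = NA_real_)
  inv <- invertSimilarity(tf)
  p <- list(r = c(10, 25, 40), c = c(12, 33, 48))
  q <- RelaxoMRR:::similarityMap(tf, p$r, p$c)
  back <- RelaxoMRR:::similarityMap(inv, q$r, q$c)
  expect_equal(back$r, p$r, tolerance = 1e-10)
  expect_equal(back$c, p$c, tolerance = 1e-10)
})

test_that("mask warping is exact for identity, translation and scale", {
  mask <- matrix(0, 40, 40); mask[15:25, 18:28] <- 1
  idT <- new("SimilarityTransform", rotationDeg = 0, scale = 1,
             translation = c(0, 0), reflect = FALSE,
             centerFixed = c(20.5, 20.5), centerMoving = c(20.5, 20.5),
             mse = NA_real_)
  expect_equal(transformMask(mask, idT, NULL, c(40L, 40L)), mask)

  trT <- idT; trT@translation <- c(2, 3)
  shifted <- transformMask(mask, trT, NULL, c(40L, 40L))
  expect_equal(shifted[13:23, 15:25], mask[15:25, 18:28])

  scT <- idT; scT@scale <- 0.5    # fixed -> moving shrink = 2x magnified mask
  big <- transformMask(mask, scT, NULL, c(40L, 40L))
  expect_lt(abs(sum(big) / sum(mask) - 4) / 4, 0.05)

  farT <- idT; farT@translation <- c(500, 500)
  expect_error(transformMask(mask, farT, NULL, c(40L, 40L)), "outside")
})

test_that("non-rigid refinement is quiescent on identical images", {
  ph <- smallPhantom(seed = 5, area = 60)
  img <- truthMap(ph, "t2")
  fld <- refineNonrigid(img, img, mask = brainMask(ph))
  expect_lt(max(abs(c(fld$vr, fld$vc))), 0.1)
})

test_that("strong regularization drives the field toward a constant", {
  set.seed(3)
  f <- matrix(rnorm(32 * 32), 32)
  smoothed <- RelaxoMRR:::gaussianBlur(f, 50)
  expect_lt(var(as.vector(smoothed)), var(as.vector(f)) / 1e3)
})
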