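test_that("noiseless voxel fits invert the models", {
  tr <- defaultTRScheduleMs()
  s <- 100 * (1 - exp(-tr / 500))
  f1 <- fitT1Voxel(s, tr)
  expect_true(f1$converged)
  expect_lt(abs(f1$tauMs - 500), 0.5)
  expect_lt(abs(f1$m0 - 100), 0.5)

  te <- defaultTEScheduleMs()
  s2 <- 80 * exp(-te / 100)
  f2 <- fitT2Voxel(s2, te)
  expect_lt(abs(f2$tauMs - 100), 0.1)
  expect_lt(abs(f2$m0 - 80), 0.1)
})

test_that("the two-point closed form initializes T2 correctly", {
  # (136 - 28) / log(60.33 / 20.48) = 99.97, within 0.5 of the true 100
  closedForm <- (136 - 28) / log(60.33 / 20.48)
  expect_lt(abs(closedForm - 100), 0.5)
  f <- fitT2Voxel(c(60.33, 20.48), c(28, 136))
  expect_lt(abs(f$tauMs - 100), 0.5)
})

test_that("degenerate and non-decaying signals are flagged", {
  tr <- defaultTRScheduleMs()
  z <- fitT1Voxel(rep(0, 14), tr)
  expect_false(z$converged)
  nf <- fitT1Voxel(c(rep(1, 13), NaN), tr)
  expect_false(nf$converged)
  up <- fitT2Voxel(c(10, 12, 30), defaultTEScheduleMs())
  expect_match(up$flag, "non-decaying")
})

test_that("simplex fits agree with a brute-force grid oracle under Rician noise", {
  tr <- defaultTRScheduleMs()
  truthS <- 100 * (1 - exp(-tr / 500))
  nrep <- 500
  set.seed(42)
  S <- t(replicate(nrep,
    sqrt((truthS + rnorm(14, sd = 5))^2 + rnorm(14, sd = 5)^2)))
  nmT1 <- apply(S, 1, function(s) fitT1Voxel(s, tr)$tauMs)

  # independent (M0, T1) grid search on the same replicates
  m0g <- seq(80, 120, by = 0.5)
  t1g <- seq(380, 640, by = 1)
  grid <- expand.grid(m0 = m0g, t1 = t1g)
  G <- outer(seq_len(nrow(grid)), seq_along(tr),
             function(i, j) grid$m0[i] * (1 - exp(-tr[j] / grid$t1[i])))
  score <- rowSums(G^2) - 2 * G %*% t(S)    # ||g||^2 - 2 g.s per replicate
  oracleT1 <- grid$t1[apply(score, 2, which.min)]
  band <- quantile(oracleT1, c(0.025, 0.975))
  expect_gte(median(nmT1), band[1])
  expect_lte(median(nmT1), band[2])
  expect_lt(abs(median(nmT1) - median(oracleT1)), 5)
})

test_that("the fit objective never exceeds its value at the initialization", {
  tr <- defaultTRScheduleMs()
  set.seed(7)
  for (i in 1:20) {
    s <- abs(80 * (1 - exp(-tr / runif(1, 200, 900))) + rnorm(14, sd = 8))
    f <- fitT1Voxel(s, tr)
    initSse <- sum((s - max(s) * (1 - exp(-tr / median(tr))))^2)
    expect_lte(f$sse, initSse + 1e-9)
  }
})

test_that("noiseless map fitting recovers the truth maps and is deterministic", {
  ph <- smallPhantom(seed = 3, shape = "circular", area = 60)
  s2 <- simulateSeries(ph, acquisitionProtocol("t2_series"))
  m2a <- fitMap(s2)
  m2b <- fitMap(s2)
  expect_identical(tauImage(m2a), tauImage(m2b))
  inb <- brainMask(ph) > 0
  relErr <- abs(tauImage(m2a) - truthMap(ph, "t2")) / truthMap(ph, "t2")
  expect_lt(max(relErr[inb]), 0.005)
  expect_identical(dim(tauImage(m2a)), dim(frames(s2))[1:2])
})

test_that("co-registration leaves aligned frames alone and recovers known shifts", {
  ph <- smallPhantom(seed = 5, grid = c(96L, 96L), area = 80)
  s <- simulateSeries(ph, acquisitionProtocol("t1_series"))
  cr0 <- coregisterSeries(s, maxShiftPx = 2)
  expect_true(all(abs(cr0$transforms$dr) < 0.1))
  expect_true(all(abs(cr0$transforms$dc) < 0.1))

  sm <- applyMotion(s, 2, seed = 4)
  cr <- coregisterSeries(sm, maxShiftPx = 3)
  # estimates are relative to the (itself shifted) reference frame
  rel <- sweep(sm@motionShifts, 2, sm@motionShifts[1, ])
  est <- cbind(cr$transforms$dr, cr$transforms$dc)
  expect_lt(max(abs(est - rel)), 0.5)
  expect_true(all(cr$transforms$ssdAfter <= cr$transforms$ssdBefore + 1e-12))
})
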