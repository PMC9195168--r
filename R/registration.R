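# Macro-image to MR registration: similarity transform by regular-step
# gradient descent, demons-style non-rigid refinement, and warping of the
# gold-standard lesion contour into image space.

# Map fixed-frame coordinates (r, c) to moving-frame coordinates for a
# SimilarityTransform.
similarityMap <- function(tf, r, c) {
  th <- tf@rotationDeg * pi / 180
  dr <- r - tf@centerFixed[1]
  dc <- c - tf@centerFixed[2]
  if (tf@reflect) dc <- -dc
  qr <- tf@scale * (cos(th) * dr - sin(th) * dc) + tf@centerMoving[1] + tf@translation[1]
  qc <- tf@scale * (sin(th) * dr + cos(th) * dc) + tf@centerMoving[2] + tf@translation[2]
  list(r = qr, c = qc)
}

#' Warp a moving image into the fixed frame under a similarity transform
#'
#' @param moving moving-frame image.
#' @param tf a [SimilarityTransform-class].
#' @param outDim output (fixed-frame) dimensions.
#' @param fill value for unmapped pixels.
#' @return matrix of size `outDim`.
#' @export
applySimilarity <- function(moving, tf, outDim = dim(moving), fill = 0) {
  g <- pixelGrid(outDim)
  q <- similarityMap(tf, g$r, g$c)
  v <- bilinearSample(moving, q$r, q$c)
  v[is.na(v)] <- fill
  matrix(v, outDim[1], outDim[2])
}

#' Invert a similarity transform
#' @param tf a [SimilarityTransform-class] (reflection not supported).
#' @return the inverse [SimilarityTransform-class].
#' @export
invertSimilarity <- function(tf) {
  if (tf@reflect) stop("inversion of reflected transforms is not supported")
  th <- -tf@rotationDeg * pi / 180
  s <- 1 / tf@scale
  t0 <- -tf@translation
  new("SimilarityTransform", rotationDeg = -tf@rotationDeg, scale = s,
      translation = c(s * (cos(th) * t0[1] - sin(th) * t0[2]),
                      s * (sin(th) * t0[1] + cos(th) * t0[2])),
      reflect = FALSE, centerFixed = tf@centerMoving,
      centerMoving = tf@centerFixed, mse = NA_real_)
}

#' Estimate a similarity transform by regular-step gradient descent
#'
#' Registers a moving image (e.g. the macro photograph of the brain
#' section) onto a fixed image (e.g. the T2 map) by minimizing the
#' mean-squared intensity difference over (rotation, log-scale,
#' translation). Both images are intensity-standardized first. The
#' optimizer is a regular-step gradient descent: a step is taken along the
#' normalized finite-difference gradient; on an objective increase the
#' step is reverted and halved, and iteration stops at the minimum step or
#' the iteration cap. A two-level coarse-to-fine pyramid and an optional
#' reflected-start hypothesis (both hypotheses fully optimized, best kept)
#' make the search robust to the macro image's unknown handedness.
#'
#' Initialization is automatic: translation from the intensity centroids,
#' scale from the ratio of intensity spreads.
#'
#' @param moving moving image (matrix or [MacroImage-class]).
#' @param fixed fixed image (matrix or [ParameterMap-class], whose tau
#'   image is used).
#' @param maxIter iteration cap per pyramid level.
#' @param initialStep initial step length in scaled parameter space.
#' @param minStep stopping step length.
#' @param tryReflection also optimize the column-reflected hypothesis.
#' @param scaleInit optional starting scale override.
#' @return a [SimilarityTransform-class] (slot `mse` holds the final
#'   dissimilarity).
#' @export
registerSimilarity <- function(moving, fixed, maxIter = 150,
                               initialStep = 0.25, minStep = 1e-4,
                               tryReflection = TRUE, scaleInit = NULL) {
  if (is(moving, "MacroImage")) moving <- moving@img
  if (is(fixed, "ParameterMap")) {
    f <- fixed@tauImg; f[is.na(f)] <- 0; fixed <- f
  }
  std <- function(img) {
    s <- stats::sd(img)
    if (s == 0) stop("constant image cannot be registered")
    (img - mean(img)) / s
  }
  movS <- std(moving); fixS <- std(fixed)

  # intensity centroid + spread (positive part) for initialization
  stats1 <- function(img) {
    w <- pmax(img - stats::quantile(img, 0.5), 0)
    if (sum(w) == 0) w <- img - min(img)
    g <- pixelGrid(dim(img))
    cr <- sum(g$r * w) / sum(w); cc <- sum(g$c * w) / sum(w)
    spread <- sqrt(sum(((g$r - cr)^2 + (g$c - cc)^2) * w) / sum(w))
    list(ctr = c(cr, cc), spread = spread)
  }
  sm <- stats1(moving); sf <- stats1(fixed)
  s0 <- if (is.null(scaleInit)) sm$spread / sf$spread else scaleInit
  ctrF <- (dim(fixed) + 1) / 2
  ctrM <- (dim(moving) + 1) / 2

  down <- function(img) {
    nr <- floor(nrow(img) / 2); nc2 <- floor(ncol(img) / 2)
    0.25 * (img[2 * seq_len(nr) - 1, 2 * seq_len(nc2) - 1] +
            img[2 * seq_len(nr), 2 * seq_len(nc2) - 1] +
            img[2 * seq_len(nr) - 1, 2 * seq_len(nc2)] +
            img[2 * seq_len(nr), 2 * seq_len(nc2)])
  }

  objective <- function(par, movImg, fixImg, cF, cM, reflect, stride = 1L) {
    tf <- new("SimilarityTransform", rotationDeg = par[1] * 180 / pi,
              scale = exp(par[2]), translation = c(par[3], par[4]),
              reflect = reflect, centerFixed = cF, centerMoving = cM,
              mse = NA_real_)
    rs <- seq(1L, nrow(fixImg), by = stride)
    cs <- seq(1L, ncol(fixImg), by = stride)
    gr <- rep(rs, times = length(cs))
    gc <- rep(cs, each = length(rs))
    q <- similarityMap(tf, gr, gc)
    v <- bilinearSample(movImg, q$r, q$c)
    ok <- !is.na(v)
    if (sum(ok) < 0.25 * length(v)) return(Inf)
    mean((v[ok] - fixImg[cbind(gr[ok], gc[ok])])^2)
  }

  regularStep <- function(par, movImg, fixImg, cF, cM, reflect, step, stride = 1L,
                          iterCap = maxIter) {
    scales <- c(0.03, 0.03, 1.5, 1.5)  # rad, log-scale, px, px
    best <- objective(par, movImg, fixImg, cF, cM, reflect, stride)
    if (!is.finite(best))
      stop("no overlap at initialization; pre-align the images manually")
    it <- 0
    while (step > minStep && it < iterCap) {
      it <- it + 1
      gr <- numeric(4)
      for (k in 1:4) {
        e <- scales[k] * 1e-2
        pp <- par; pp[k] <- pp[k] + e
        pm <- par; pm[k] <- pm[k] - e
        gr[k] <- (objective(pp, movImg, fixImg, cF, cM, reflect, stride) -
                  objective(pm, movImg, fixImg, cF, cM, reflect, stride)) / (2 * e)
      }
      nrm <- sqrt(sum((gr * scales)^2))
      if (!is.finite(nrm) || nrm == 0) break
      cand <- par - step * scales^2 * gr / nrm
      val <- objective(cand, movImg, fixImg, cF, cM, reflect, stride)
      if (is.finite(val) && val < best) {
        par <- cand; best <- val
        step <- step * 1.1
      } else {
        step <- step / 2
      }
    }
    list(par = par, value = best)
  }

  runHypothesis <- function(reflect) {
    movH <- movS
    # centroid-based translation init (in moving frame)
    cmr <- sm$ctr
    if (reflect) cmr[2] <- 2 * ctrM[2] - cmr[2]
    t0 <- cmr - ctrM - s0 * (sf$ctr - ctrF)
    par <- c(0, log(s0), t0[1], t0[2])
    # coarse level: everything halved
    movD <- down(movH); fixD <- down(fixS)
    parD <- c(par[1], par[2], par[3] / 2, par[4] / 2)
    resD <- regularStep(parD, movD, fixD, (dim(fixD) + 1) / 2,
                        (dim(movD) + 1) / 2, reflect, initialStep)
    par <- c(resD$par[1], resD$par[2], resD$par[3] * 2, resD$par[4] * 2)
    res <- regularStep(par, movH, fixS, ctrF, ctrM, reflect, initialStep / 2,
                       stride = 2L)
    # polish at full resolution with a short step schedule
    res <- regularStep(res$par, movH, fixS, ctrF, ctrM, reflect,
                       initialStep / 8, stride = 1L, iterCap = 50L)
    res$reflect <- reflect
    res
  }

  res <- runHypothesis(FALSE)
  if (tryReflection) {
    resR <- tryCatch(runHypothesis(TRUE), error = function(e) NULL)
    if (!is.null(resR) && is.finite(resR$value) && resR$value < res$value)
      res <- resR
  }
  new("SimilarityTransform", rotationDeg = res$par[1] * 180 / pi,
      scale = exp(res$par[2]), translation = c(res$par[3], res$par[4]),
      reflect = res$reflect, centerFixed = ctrF, centerMoving = ctrM,
      mse = res$value)
}

#' Demons-style non-rigid refinement
#'
#' Estimates a smooth per-pixel displacement field aligning an already
#' similarity-aligned moving image to the fixed image, accounting for
#' local tissue shrinkage. Each iteration takes the classic demons update
#' \eqn{\delta v = (F - W) \nabla W / (|\nabla W|^2 + (F - W)^2)} (W the
#' currently warped moving image), caps it at 1 px, and regularizes the
#' accumulated field with a Gaussian of width `sigmaPx`. Iteration stops
#' at the cap or when the dissimilarity grows three consecutive times (the
#' best field so far is returned with a warning). The residual
#' dissimilarity never exceeds the input dissimilarity.
#'
#' @param movingAligned moving image, already similarity-aligned.
#' @param fixed fixed image.
#' @param sigmaPx Gaussian regularization width (px).
#' @param maxIter iteration cap.
#' @param mask optional 0/1 region of interest; the field is zeroed
#'   outside it.
#' @return list with `vr`, `vc` (displacement components, px),
#'   `smoothness` (mean gradient magnitude of the field), `mse` (final
#'   dissimilarity) and `iterations`.
#' @export
refineNonrigid <- function(movingAligned, fixed, sigmaPx = 2, maxIter = 60,
                           mask = NULL) {
  stopifnot(identical(dim(movingAligned), dim(fixed)))
  d <- dim(fixed)
  std <- function(img) (img - mean(img)) / max(stats::sd(img), 1e-12)
  M <- std(movingAligned); Fx <- std(fixed)
  if (is.null(mask)) mask <- matrix(1, d[1], d[2])
  vr <- vc <- matrix(0, d[1], d[2])
  g <- pixelGrid(d)
  warpField <- function(vr, vc) {
    v <- bilinearSample(M, g$r + as.vector(vr), g$c + as.vector(vc))
    v[is.na(v)] <- 0
    matrix(v, d[1], d[2])
  }
  gradR <- function(img) (rbind(img[-1, ], img[d[1], ]) - rbind(img[1, ], img[-d[1], ])) / 2
  gradC <- function(img) (cbind(img[, -1], img[, d[2]]) - cbind(img[, 1], img[, -d[2]])) / 2
  mse <- function(W) mean(((W - Fx) * mask)^2)
  W <- warpField(vr, vc)
  best <- list(vr = vr, vc = vc, mse = mse(W))
  inputMse <- best$mse
  bad <- 0
  it <- 0
  while (it < maxIter) {
    it <- it + 1
    diffI <- (Fx - W) * mask
    gr <- gradR(W); gc2 <- gradC(W)
    denom <- gr^2 + gc2^2 + diffI^2
    ur <- ifelse(denom > 1e-9, diffI * gr / denom, 0)
    uc <- ifelse(denom > 1e-9, diffI * gc2 / denom, 0)
    ur <- pmax(pmin(ur, 1), -1); uc <- pmax(pmin(uc, 1), -1)
    vr <- gaussianBlur(vr + ur, sigmaPx) * mask
    vc <- gaussianBlur(vc + uc, sigmaPx) * mask
    W <- warpField(vr, vc)
    m <- mse(W)
    if (m < best$mse) {
      best <- list(vr = vr, vc = vc, mse = m)
      bad <- 0
    } else {
      bad <- bad + 1
      if (bad >= 3) {
        # three materially worse iterations is divergence; a flat plateau
        # just means the update has converged
        if (m > best$mse * 1.001)
          warning("non-rigid refinement diverged; returning best field so far")
        break
      }
    }
  }
  vr <- best$vr; vc <- best$vc
  sm <- mean(sqrt(gradR(vr)^2 + gradC(vr)^2 + gradR(vc)^2 + gradC(vc)^2))
  stopifnot(best$mse <= inputMse + 1e-12)
  list(vr = vr, vc = vc, smoothness = sm, mse = best$mse, iterations = it)
}

#' Warp a macro-frame mask into image space
#'
#' Nearest-neighbour warping of the binary gold-standard contour through
#' the estimated similarity transform and (optionally) the non-rigid
#' displacement field: the result is the "true lesion contour" in image
#' space used for scoring.
#'
#' @param mask 0/1 matrix in the moving (macro) frame.
#' @param tf a [SimilarityTransform-class].
#' @param field optional displacement field from [refineNonrigid()].
#' @param outDim output dimensions (fixed frame).
#' @return 0/1 matrix in the fixed frame.
#' @export
transformMask <- function(mask, tf, field = NULL, outDim) {
  g <- pixelGrid(outDim)
  r <- g$r; c <- g$c
  if (!is.null(field)) {
    r <- r + as.vector(field$vr)
    c <- c + as.vector(field$vc)
  }
  q <- similarityMap(tf, r, c)
  out <- matrix(nearestSample(mask, q$r, q$c), outDim[1], outDim[2])
  out <- (out > 0.5) + 0
  if (sum(out) == 0) stop("contour mapped entirely outside the image")
  out
}
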