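# Synthetic two-hemisphere brain-slice phantoms and low-field spin-echo
# acquisition simulation. Everything is deterministic given the seeds held
# in PhantomSpec / AcquisitionProtocol.

#' Default tissue relaxation parameters
#'
#' Plausible parenchyma values for a ~0.25 T low-field scanner: white
#' matter, gray matter, CSF and a hemorrhagic blood lesion. The lesion is
#' hyperintense relative to parenchyma on both the T1 and T2 maps, the
#' situation the classifier targets. Values are a configurable modeling
#' default, not measurements.
#'
#' @return data.frame with columns name, t1_ms, t2_ms, m0, class_id.
#' @export
#' @examples
#' tissueDefaults()
tissueDefaults <- function() {
  data.frame(
    name = c("background", "white_matter", "gray_matter", "csf", "blood"),
    t1_ms = c(1, 350, 450, 1200, 650),
    t2_ms = c(1, 80, 95, 400, 160),
    m0 = c(0, 80, 85, 100, 90),
    class_id = 0:4,
    stringsAsFactors = FALSE
  )
}

#' Default variable-TR schedule for the T1 series
#'
#' Fourteen TR values between 50 and 1000 ms. The strict variant replaces
#' the 800 ms entry with 129 ms (a non-monotone schedule retained for
#' compatibility with a published acquisition listing; the monotone 800 ms
#' schedule is the default).
#'
#' @param strict use the verbatim non-monotone listing.
#' @return numeric vector of 14 TR values (ms).
#' @export
defaultTRScheduleMs <- function(strict = FALSE) {
  c(50, 120, 200, 300, 400, 500, 600, 650, 750,
    if (strict) 129 else 800, 850, 900, 950, 1000)
}

#' Default variable-TE schedule for the T2 series
#' @return numeric vector of 3 TE values (ms).
#' @export
defaultTEScheduleMs <- function() c(28, 75, 136)

#' Construct a phantom specification
#'
#' @param grid image size (rows, cols), both >= 64.
#' @param midlineCol midline column; default the image center (may be
#'   fractional). The subject's left hemisphere occupies columns above the
#'   midline (radiological display convention).
#' @param lesionShape `"linear"`, `"irregular"` or `"circular"`.
#' @param lesionAreaPx target lesion area in pixels.
#' @param rimWidthPx perilesional rim thickness (pixels, >= 0).
#' @param rimMix blend fraction in the rim (1 = lesion-like).
#' @param tissueTable tissue parameter table, see [tissueDefaults()].
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(grid = c(96L, 96L), midlineCol = NULL,
                        lesionShape = "irregular", lesionAreaPx = 80,
                        rimWidthPx = 0, rimMix = 0.5,
                        tissueTable = tissueDefaults(), seed = 1L) {
  grid <- as.integer(grid)
  if (is.null(midlineCol)) midlineCol <- (grid[2] + 1) / 2
  new("PhantomSpec", grid = grid, midlineCol = midlineCol,
      lesionShape = lesionShape, lesionAreaPx = lesionAreaPx,
      rimWidthPx = rimWidthPx, rimMix = rimMix,
      tissueTable = tissueTable, seed = as.integer(seed))
}

# Binary dilation of a mask by a disk of the given radius.
dilateMask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  idx <- which(mask > 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  offs <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                      dc = -ceiling(radius):ceiling(radius))
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  for (i in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dr[i]
    cc <- idx[, 2] + offs$dc[i]
    ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    out[cbind(rr[ok], cc[ok])] <- 1
  }
  out
}

# Lesion mask of roughly the target area centered at (r0, c0), restricted
# to `allowed`. Shapes follow the lesion morphologies seen on T2 maps of
# small intracerebral hemorrhages: thin linear tracks (the needle path),
# irregular blobs, and near-circular collections.
makeLesionMask <- function(shape, areaPx, center, allowed) {
  d <- dim(allowed)
  g <- pixelGrid(d)
  r <- g$r - center[1]; c <- g$c - center[2]
  inside <- switch(shape,
    circular = {
      rad <- sqrt(areaPx / pi)
      r^2 + c^2 <= rad^2
    },
    linear = {
      # a thin bar, 2-3 px wide, tilted off-axis like a needle track
      theta <- stats::runif(1, -pi / 3, pi / 3)
      u <- r * cos(theta) + c * sin(theta)
      v <- -r * sin(theta) + c * cos(theta)
      w <- 2.5
      len <- areaPx / (2 * w)
      abs(u) <= len & abs(v) <= w / 2
    },
    irregular = {
      # rank a smooth random field against a quadratic bowl and keep the
      # top-area pixels: a ragged blob of exactly the requested area
      rad <- sqrt(areaPx / pi) * 1.6
      field <- smoothNoiseField(d, sigma = 2.5)
      score <- (1 - (r^2 + c^2) / rad^2) + 0.55 * as.vector(field)
      keep <- score * 0
      cand <- which(allowed > 0)
      cand <- cand[order(score[cand], decreasing = TRUE)]
      keep[cand[seq_len(min(areaPx, length(cand)))]] <- 1
      keep > 0
    },
    stop("unknown lesion shape: ", shape)
  )
  m <- matrix(as.numeric(inside), d[1], d[2]) * allowed
  m
}

#' Generate a digital phantom
#'
#' Builds a two-hemisphere brain slice (elliptical brain, white-matter
#' core, gray-matter ring, small symmetric ventricles near the midline)
#' and paints a hemorrhagic lesion of the requested shape and area into
#' the subject's left hemisphere. An optional perilesional rim blends the
#' lesion and local tissue parameters with weight `rimMix`, emulating
#' blood-infiltrated tissue around the hemorrhage. Deterministic given
#' `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [DigitalPhantom-class].
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(lesionShape = "circular", seed = 7))
#' ph
generatePhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  nr <- spec@grid[1]; nc <- spec@grid[2]
  mid <- spec@midlineCol
  cr <- (nr + 1) / 2
  g <- pixelGrid(c(nr, nc))
  tt <- spec@tissueTable
  prm <- function(name, what) tt[[what]][tt$name == name]

  # elliptical brain; GM ring outside a WM core; ventricles flank midline
  ell <- function(r0, c0, ra, ca) ((g$r - r0) / ra)^2 + ((g$c - c0) / ca)^2 <= 1
  brain <- ell(cr, mid, 0.40 * nr, 0.44 * nc)
  wm <- ell(cr, mid, 0.31 * nr, 0.35 * nc)
  vent <- ell(cr - 0.05 * nr, mid - 0.035 * nc, 0.07 * nr, 0.025 * nc) |
          ell(cr - 0.05 * nr, mid + 0.035 * nc, 0.07 * nr, 0.025 * nc)

  label <- matrix(0L, nr, nc)
  label[matrix(brain, nr, nc)] <- prm("gray_matter", "class_id")
  label[matrix(brain & wm, nr, nc)] <- prm("white_matter", "class_id")
  label[matrix(brain & vent, nr, nc)] <- prm("csf", "class_id")

  # lesion centered in the left-hemisphere white matter so the suspected
  # region and its mirror sit in homogeneous parenchyma
  lesionCenter <- c(cr + 0.04 * nr, mid + 0.17 * nc)
  allowed <- matrix(as.numeric(brain & wm & g$c > mid + 2 & !vent), nr, nc)
  lesion <- makeLesionMask(spec@lesionShape, spec@lesionAreaPx,
                           lesionCenter, allowed)
  if (sum(lesion) < 1)
    stop("lesion does not fit in the left hemisphere with the requested area")
  leftBrainArea <- sum(brain & g$c > mid)
  if (spec@lesionAreaPx >= leftBrainArea / 2)
    stop("lesionAreaPx must be smaller than half the left-hemisphere brain area")
  label[lesion > 0] <- prm("blood", "class_id")

  # parameter images from the label map
  t1 <- t2 <- m0 <- matrix(0, nr, nc)
  for (i in seq_len(nrow(tt))) {
    sel <- label == tt$class_id[i]
    t1[sel] <- tt$t1_ms[i]; t2[sel] <- tt$t2_ms[i]; m0[sel] <- tt$m0[i]
  }
  # avoid zero relaxation times inside the brain (background row is 1 ms)
  t1[brain & t1 <= 0] <- 1; t2[brain & t2 <= 0] <- 1

  if (spec@rimWidthPx > 0 && spec@rimMix > 0) {
    rim <- dilateMask(lesion, spec@rimWidthPx)
    rim <- rim * (1 - lesion) * matrix(as.numeric(brain), nr, nc)
    w <- spec@rimMix
    sel <- rim > 0
    t1[sel] <- w * prm("blood", "t1_ms") + (1 - w) * t1[sel]
    t2[sel] <- w * prm("blood", "t2_ms") + (1 - w) * t2[sel]
    m0[sel] <- w * prm("blood", "m0") + (1 - w) * m0[sel]
  }

  new("DigitalPhantom",
      labelImg = label, t1Truth = t1, t2Truth = t2, m0Truth = m0,
      lesionMask = lesion, brainMask = matrix(as.numeric(brain), nr, nc),
      midlineCol = mid, spec = spec)
}

#' Construct an acquisition protocol
#'
#' @param mode `"t1_series"` (variable TR) or `"t2_series"` (variable TE).
#' @param trListMs TR schedule, t1 mode (default [defaultTRScheduleMs()]).
#' @param teListMs TE schedule, t2 mode (default [defaultTEScheduleMs()]).
#' @param noiseSigma Rician noise scale in signal units.
#' @param seed RNG seed for the noise.
#' @return an [AcquisitionProtocol-class].
#' @export
acquisitionProtocol <- function(mode = c("t1_series", "t2_series"),
                                trListMs = defaultTRScheduleMs(),
                                teListMs = defaultTEScheduleMs(),
                                noiseSigma = 0, seed = 1L) {
  mode <- match.arg(mode)
  new("AcquisitionProtocol", mode = mode,
      timingMs = if (mode == "t1_series") trListMs else teListMs,
      noiseSigma = noiseSigma, seed = as.integer(seed))
}

#' Simulate a relaxation series from a phantom
#'
#' One frame per timing value. Noiseless frames satisfy the spin-echo
#' signal models exactly at every brain voxel:
#' \deqn{S(TR) = M_0 (1 - e^{-TR/T_1})} for the saturation-recovery T1
#' series and \deqn{S(TE) = M_0 e^{-TE/T_2}} for the T2 decay series.
#' Rician noise of scale `noiseSigma` is applied per pixel per frame.
#'
#' @param phantom a [DigitalPhantom-class].
#' @param protocol an [AcquisitionProtocol-class].
#' @return a [RelaxationSeries-class].
#' @export
simulateSeries <- function(phantom, protocol) {
  validObject(protocol)
  t1 <- phantom@t1Truth; t2 <- phantom@t2Truth; m0 <- phantom@m0Truth
  d <- dim(t1)
  tms <- protocol@timingMs
  fr <- array(0, c(d, length(tms)))
  for (i in seq_along(tms)) {
    fr[, , i] <- if (protocol@mode == "t1_series")
      m0 * (1 - exp(-tms[i] / t1))
    else
      m0 * exp(-tms[i] / t2)
  }
  if (protocol@noiseSigma > 0) {
    set.seed(protocol@seed)
    for (i in seq_along(tms))
      fr[, , i] <- addRicianNoise(fr[, , i], protocol@noiseSigma)
  }
  new("RelaxationSeries", frames = fr, timingMs = tms, mode = protocol@mode,
      brainMask = phantom@brainMask, motionShifts = NULL,
      meta = list(noiseSigma = protocol@noiseSigma, seed = protocol@seed))
}

#' Apply random inter-frame motion
#'
#' Rigidly translates each frame by an independent uniform shift with both
#' components bounded by `maxShiftPx`. The applied shifts are stored in the
#' result (`motionShifts` slot) so registration accuracy can be checked
#' against ground truth.
#'
#' @param series a [RelaxationSeries-class].
#' @param maxShiftPx maximum per-axis shift in pixels (>= 0).
#' @param seed RNG seed.
#' @return the shifted series with recorded shifts.
#' @export
applyMotion <- function(series, maxShiftPx, seed = 1L) {
  if (maxShiftPx < 0) stop("maxShiftPx must be >= 0")
  if (maxShiftPx == 0) {
    series@motionShifts <- matrix(0, dim(series@frames)[3], 2)
    return(series)
  }
  set.seed(as.integer(seed))
  nf <- dim(series@frames)[3]
  shifts <- matrix(stats::runif(2 * nf, -maxShiftPx, maxShiftPx), nf, 2)
  for (i in seq_len(nf))
    series@frames[, , i] <- translateImage(series@frames[, , i], shifts[i, ])
  series@motionShifts <- shifts
  series
}

#' Render a deformed gold-standard macro image
#'
#' Emulates the photograph of the formalin-fixed brain section used as the
#' bridge between histology and MR coordinates: the phantom's T2 truth map
#' is isotropically shrunk, rotated and smoothly deformed into its own
#' coordinate frame, and the true lesion mask is carried along identically.
#' The default linear shrink is `sqrt(1 - 0.33)` (about 0.82): a 2D section
#' through tissue that lost ~33% of its volume to formalin fixation, under
#' isotropic shrinkage. The applied transform is stored for use as a
#' registration oracle.
#'
#' @param phantom a [DigitalPhantom-class].
#' @param shrinkLinear linear scale in (0, 1].
#' @param rotationDeg rotation applied in the macro frame (degrees).
#' @param deformAmpPx amplitude of the smooth random deformation (px).
#' @param seed RNG seed for the deformation.
#' @return a [MacroImage-class].
#' @export
makeMacroImage <- function(phantom, shrinkLinear = sqrt(1 - 0.33),
                           rotationDeg = 8, deformAmpPx = 1, seed = 1L) {
  if (shrinkLinear <= 0 || shrinkLinear > 1)
    stop("shrinkLinear must be in (0, 1]")
  src <- phantom@t2Truth
  d <- dim(src)
  ctrSrc <- (d + 1) / 2
  ctrMac <- (d + 1) / 2
  set.seed(as.integer(seed))
  vr <- vc <- matrix(0, d[1], d[2])
  if (deformAmpPx > 0) {
    vr <- smoothNoiseField(d, sigma = 6)
    vc <- smoothNoiseField(d, sigma = 6)
    vr <- vr / max(abs(vr)) * deformAmpPx
    vc <- vc / max(abs(vc)) * deformAmpPx
  }
  # pullback from macro coords m to source coords:
  #   p = R(-theta) * (m - ctrMac - D(m)) / s + ctrSrc
  th <- rotationDeg * pi / 180
  g <- pixelGrid(d)
  mr <- g$r - ctrMac[1] - as.vector(vr)
  mc <- g$c - ctrMac[2] - as.vector(vc)
  pr <- (cos(th) * mr + sin(th) * mc) / shrinkLinear + ctrSrc[1]
  pc <- (-sin(th) * mr + cos(th) * mc) / shrinkLinear + ctrSrc[2]
  img <- bilinearSample(src, pr, pc)
  img[is.na(img)] <- 0
  img <- matrix(img, d[1], d[2])
  contour <- matrix(nearestSample(phantom@lesionMask, pr, pc), d[1], d[2])
  if (sum(contour) < 1)
    stop("shrinkage so severe that the lesion vanished from the macro image")
  new("MacroImage", img = img, contourTruth = contour,
      transform = list(scale = shrinkLinear, rotationDeg = rotationDeg,
                       translation = c(0, 0), centerSource = ctrSrc,
                       centerMacro = ctrMac, vr = vr, vc = vc, seed = seed))
}
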