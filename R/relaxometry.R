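# Voxel-wise two-parameter relaxation fitting and series co-registration.
# Fits are deterministic: fixed initialization, Nelder-Mead simplex, no RNG.

#' Fit options for the relaxation models
#'
#' Soft relaxation-time bounds are enforced by reparameterization (tau is
#' optimized through a logistic transform onto `tauBoundsMs`) so noise-only
#' voxels cannot diverge; fits that land within 1% of a bound are flagged.
#'
#' @param tauBoundsMs search bounds for the relaxation time (ms).
#' @param reltol convergence tolerance on the objective.
#' @param maxit maximum simplex iterations.
#' @return options list.
#' @export
fitOptions <- function(tauBoundsMs = c(1, 5000), reltol = 1e-8, maxit = 500) {
  list(tauBoundsMs = tauBoundsMs, reltol = reltol, maxit = maxit)
}

# tau <-> unconstrained u, logistic reparameterization onto (lo, hi)
tauToU <- function(tau, b) {
  f <- (tau - b[1]) / (b[2] - b[1])
  f <- min(max(f, 1e-6), 1 - 1e-6)
  log(f / (1 - f))
}
uToTau <- function(u, b) b[1] + (b[2] - b[1]) / (1 + exp(-u))

failedFit <- function(n, flag) {
  list(m0 = NA_real_, tauMs = NA_real_, sse = NA_real_, converged = FALSE,
       nPoints = n, boundActive = FALSE, flag = flag)
}

fitRelaxVoxel <- function(signal, timing, model, tauInit, m0Init, opts) {
  n <- length(signal)
  if (any(!is.finite(signal))) return(failedFit(n, "non-finite signal"))
  if (all(signal == 0)) return(failedFit(n, "all-zero signal"))
  b <- opts$tauBoundsMs
  obj <- function(p) {
    pred <- p[1] * model(timing, uToTau(p[2], b))
    sum((signal - pred)^2)
  }
  p0 <- c(m0Init, tauToU(tauInit, b))
  fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = opts$reltol, maxit = opts$maxit))
  tau <- uToTau(fit$par[2], b)
  boundActive <- tau <= b[1] * 1.01 || tau >= b[2] * 0.99
  list(m0 = fit$par[1], tauMs = tau, sse = fit$value,
       converged = fit$convergence == 0 && is.finite(fit$value),
       nPoints = n, boundActive = boundActive, flag = NA_character_)
}

#' Fit the T1 saturation-recovery model at one voxel
#'
#' Minimizes \eqn{\sum_i (s_i - M_0 (1 - e^{-TR_i/T_1}))^2} with a
#' derivative-free Nelder-Mead simplex from a deterministic start
#' (M0 = max signal, T1 = median TR).
#'
#' @param signal measured intensities, one per TR.
#' @param trMs TR values (ms), same length as `signal`.
#' @param opts see [fitOptions()].
#' @return list with `m0`, `tauMs`, `sse`, `converged`, `nPoints`,
#'   `boundActive`, `flag`.
#' @export
#' @examples
#' tr <- defaultTRScheduleMs()
#' s <- 100 * (1 - exp(-tr / 500))
#' fitT1Voxel(s, tr)$tauMs
fitT1Voxel <- function(signal, trMs, opts = fitOptions()) {
  stopifnot(length(signal) == length(trMs), length(signal) >= 2)
  fitRelaxVoxel(signal, trMs, function(t, tau) 1 - exp(-t / tau),
                tauInit = stats::median(trMs), m0Init = max(signal), opts)
}

#' Fit the T2 exponential-decay model at one voxel
#'
#' Minimizes \eqn{\sum_i (s_i - M_0 e^{-TE_i/T_2})^2} by Nelder-Mead. The
#' deterministic initializer is the two-point closed form
#' `T2 = (TE_n - TE_1) / log(s_1 / s_n)` from the first and last echoes;
#' non-decaying or non-positive signals fall back to a median-TE start and
#' are flagged.
#'
#' @param signal measured intensities, one per TE.
#' @param teMs TE values (ms).
#' @param opts see [fitOptions()].
#' @return fit result list, as [fitT1Voxel()].
#' @export
fitT2Voxel <- function(signal, teMs, opts = fitOptions()) {
  stopifnot(length(signal) == length(teMs), length(signal) >= 2)
  if (any(!is.finite(signal))) return(failedFit(length(signal), "non-finite signal"))
  if (all(signal == 0)) return(failedFit(length(signal), "all-zero signal"))
  i1 <- which.min(teMs); i2 <- which.max(teMs)
  flag <- NA_character_
  if (signal[i1] > 0 && signal[i2] > 0 && signal[i1] > signal[i2]) {
    tauInit <- (teMs[i2] - teMs[i1]) / log(signal[i1] / signal[i2])
    m0Init <- signal[i1] * exp(teMs[i1] / tauInit)
  } else {
    tauInit <- stats::median(teMs)
    m0Init <- max(signal, 1e-6)
    flag <- "non-decaying or non-positive signal; bounded fallback start"
  }
  tauInit <- min(max(tauInit, opts$tauBoundsMs[1]), opts$tauBoundsMs[2])
  out <- fitRelaxVoxel(signal, teMs, function(t, tau) exp(-t / tau),
                       tauInit = tauInit, m0Init = m0Init, opts)
  if (!is.na(flag)) out$flag <- flag
  out
}

#' Fit a quantitative parameter map over the brain mask
#'
#' Voxel-wise application of [fitT1Voxel()] or [fitT2Voxel()] (matching the
#' series mode) over the mask. Deterministic; no RNG is involved in the
#' fitting.
#'
#' @param series a co-registered [RelaxationSeries-class].
#' @param opts see [fitOptions()].
#' @param mask optional 0/1 matrix; default the series brain mask.
#' @param verbose log progress every few thousand voxels.
#' @return a [ParameterMap-class].
#' @export
fitMap <- function(series, opts = fitOptions(), mask = NULL, verbose = FALSE) {
  validObject(series)
  d <- dim(series@frames)
  if (is.null(mask)) mask <- series@brainMask
  if (is.null(mask)) mask <- matrix(1, d[1], d[2])
  stopifnot(identical(dim(mask), d[1:2]))
  ord <- order(series@timingMs)
  tms <- series@timingMs[ord]
  fr <- series@frames[, , ord, drop = FALSE]
  fitFun <- if (series@mode == "t1_series") fitT1Voxel else fitT2Voxel

  tau <- m0 <- sse <- matrix(NA_real_, d[1], d[2])
  conv <- matrix(0, d[1], d[2])
  idx <- which(mask > 0, arr.ind = TRUE)
  sig <- matrix(fr, d[1] * d[2], d[3])[which(mask > 0), , drop = FALSE]
  for (i in seq_len(nrow(idx))) {
    f <- fitFun(sig[i, ], tms, opts)
    tau[idx[i, , drop = FALSE]] <- f$tauMs
    m0[idx[i, , drop = FALSE]] <- f$m0
    sse[idx[i, , drop = FALSE]] <- f$sse
    conv[idx[i, , drop = FALSE]] <- as.numeric(isTRUE(f$converged))
    if (verbose && i %% 2000 == 0)
      message(sprintf("fitMap: %d / %d voxels", i, nrow(idx)))
  }
  new("ParameterMap", tauImg = tau, m0Img = m0, sseImg = sse,
      convergedImg = conv, mask = mask + 0, mode = series@mode)
}

#' Co-register the frames of a series to a reference frame
#'
#' Estimates, per frame, a 2D transform (translation plus small rotation
#' and isotropic scale) minimizing the mean-squared difference to the
#' reference frame after within-mask intensity standardization (so frames
#' of different TR/TE contrast can be compared). The search is multi-start
#' coarse-to-fine: an integer-shift grid scan followed by Nelder-Mead
#' refinement; if refinement does not improve the dissimilarity the
#' coarser solution (or identity) is kept, so the post-alignment
#' dissimilarity never exceeds the pre-alignment one.
#'
#' @param series a [RelaxationSeries-class].
#' @param referenceIndex frame used as reference.
#' @param maxShiftPx half-width of the coarse shift scan.
#' @param refine also refine rotation/scale (default translation + rigid).
#' @return list with `series` (aligned) and `transforms`, a data.frame with
#'   per-frame estimated shift (dr, dc), rotation, scale and the SSD before
#'   and after alignment.
#' @export
coregisterSeries <- function(series, referenceIndex = 1L, maxShiftPx = 4L,
                             refine = TRUE) {
  validObject(series)
  d <- dim(series@frames)
  stopifnot(referenceIndex >= 1, referenceIndex <= d[3])
  mask <- series@brainMask
  if (is.null(mask)) mask <- matrix(1, d[1], d[2])
  std <- function(img) {
    # light pre-smoothing suppresses interpolation kinks that bias the
    # sub-pixel optimum
    img <- gaussianBlur(img, 0.75)
    v <- img[mask > 0]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(NULL) # degenerate frame
    (img - mean(v)) / s
  }
  refStd <- std(series@frames[, , referenceIndex])
  if (is.null(refStd)) stop("reference frame is constant")
  # stride-2 subgrid of mask pixels keeps the objective cheap without
  # hurting sub-pixel accuracy on smooth frames
  sub <- which(mask > 0, arr.ind = TRUE)
  sub <- sub[sub[, 1] %% 2 == 0 & sub[, 2] %% 2 == 0, , drop = FALSE]
  if (nrow(sub) < 100) sub <- which(mask > 0, arr.ind = TRUE)
  ctr <- (d[1:2] + 1) / 2
  refSub <- NULL # filled after refStd is known
  ssdTo <- function(imgStd, par) {
    # par = (dr, dc, theta, log s): sample the frame at the transformed
    # reference grid and compare on the mask subgrid
    th <- par[3]; s <- exp(par[4])
    rr <- s * (cos(th) * (sub[, 1] - ctr[1]) - sin(th) * (sub[, 2] - ctr[2])) + ctr[1] + par[1]
    cc <- s * (sin(th) * (sub[, 1] - ctr[1]) + cos(th) * (sub[, 2] - ctr[2])) + ctr[2] + par[2]
    v <- bilinearSample(imgStd, rr, cc)
    ok <- !is.na(v)
    if (sum(ok) < 0.25 * nrow(sub)) return(Inf)
    mean((v[ok] - refSub[ok])^2)
  }
  refSub <- refStd[sub]
  tr <- data.frame(frame = seq_len(d[3]), dr = 0, dc = 0, rotationDeg = 0,
                   scale = 1, ssdBefore = NA_real_, ssdAfter = NA_real_)
  out <- series
  for (i in seq_len(d[3])) {
    img <- series@frames[, , i]
    imgStd <- std(img)
    if (is.null(imgStd)) {
      warning("frame ", i, " is constant; identity transform kept")
      next
    }
    before <- ssdTo(imgStd, c(0, 0, 0, 0))
    tr$ssdBefore[i] <- before
    if (i == referenceIndex) { tr$ssdAfter[i] <- before; next }
    # coarse integer scan
    shifts <- expand.grid(dr = -maxShiftPx:maxShiftPx, dc = -maxShiftPx:maxShiftPx)
    vals <- vapply(seq_len(nrow(shifts)), function(j)
      ssdTo(imgStd, c(shifts$dr[j], shifts$dc[j], 0, 0)), numeric(1))
    jbest <- which.min(vals)
    best <- c(shifts$dr[jbest], shifts$dc[jbest], 0, 0)
    bestVal <- vals[jbest]
    if (refine) {
      opt <- stats::optim(best, function(p) ssdTo(imgStd, p),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-7, maxit = 150))
      if (opt$value < bestVal) { best <- opt$par; bestVal <- opt$value }
    }
    if (bestVal > before) { best <- c(0, 0, 0, 0); bestVal <- before }
    tr$dr[i] <- best[1]; tr$dc[i] <- best[2]
    tr$rotationDeg[i] <- best[3] * 180 / pi; tr$scale[i] <- exp(best[4])
    tr$ssdAfter[i] <- bestVal
    # resample the original frame with the estimated transform
    g <- pixelGrid(d[1:2])
    th <- best[3]; s <- exp(best[4])
    rr <- s * (cos(th) * (g$r - ctr[1]) - sin(th) * (g$c - ctr[2])) + ctr[1] + best[1]
    cc <- s * (sin(th) * (g$r - ctr[1]) + cos(th) * (g$c - ctr[2])) + ctr[2] + best[2]
    v <- bilinearSample(img, rr, cc)
    v[is.na(v)] <- 0
    out@frames[, , i] <- matrix(v, d[1], d[2])
  }
  out@meta$coregistration <- tr
  list(series = out, transforms = tr)
}
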