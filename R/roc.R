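# Scoring of the classification against the registered gold-standard
# contour: confusion counts, per-subject rates, pooled ROC, trapezoidal
# and smoothing-spline AUC, and the qualitative AUC bands.

#' Confusion counts of a classification against the true lesion contour
#'
#' Every one of the 2n classified voxels is scored: pathological inside
#' the contour is a true positive, healthy inside a false negative,
#' pathological outside a false positive, healthy outside a true
#' negative. Voxels from the control hemisphere are included on purpose --
#' a pathological call there is a severe false positive.
#'
#' @param result a [ClassificationResult-class].
#' @param selection the matching [VoxelSelection-class] (defaults to the
#'   one stored in the result).
#' @param trueMask 0/1 "true lesion contour" mask in image space.
#' @return named integer vector (tp, fp, tn, fn) summing to 2n.
#' @export
confusionCounts <- function(result, selection = NULL, trueMask) {
  if (is.null(selection)) selection <- result@selection
  co <- selection@coords
  d <- dim(trueMask)
  if (any(co[, 1] < 1 | co[, 1] > d[1] | co[, 2] < 1 | co[, 2] > d[2]))
    stop("classified voxels outside the image")
  inside <- trueMask[co] > 0
  pathological <- result@labels == "P"
  c(tp = sum(pathological & inside), fp = sum(pathological & !inside),
    tn = sum(!pathological & !inside), fn = sum(!pathological & inside))
}

#' Per-subject rates from confusion counts
#'
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`,
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`. A rate whose denominator is
#' zero is undefined and reported as `NA`, not as 0.
#'
#' @param counts named vector from [confusionCounts()].
#' @return named numeric vector (tpr, fpr, acc).
#' @export
computeRates <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  c(tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    acc = if (tp + tn + fp + fn > 0) (tp + tn) / (tp + tn + fp + fn) else NA_real_)
}

#' Pool per-subject operating points into one ROC curve
#'
#' All subjects with FPR = 0 are collapsed into the single point
#' (0, T0), where T0 is `collapseTpr0` if given and otherwise the mean of
#' their TPRs. The remaining points are sorted by ascending FPR (ties by
#' ascending TPR) and a terminal (1, 1) anchor is appended. When no
#' FPR = 0 point exists a (0, 0) anchor is prepended instead. The raw
#' pooled curve is kept as-is (no monotonicity correction).
#'
#' @param rates data.frame with columns `tpr` and `fpr` (one row per
#'   subject), or a list of vectors from [computeRates()].
#' @param collapseTpr0 optional override for the TPR at FPR = 0.
#' @return a [ROCCurve-class] with the trapezoidal AUC filled in.
#' @export
#' @examples
#' r <- exampleRates()
#' pooledROC(r, collapseTpr0 = 0.67)
pooledROC <- function(rates, collapseTpr0 = NULL) {
  if (is.list(rates) && !is.data.frame(rates))
    rates <- as.data.frame(do.call(rbind, rates))
  if (nrow(rates) < 2) stop("at least two subjects required")
  stopifnot(all(c("tpr", "fpr") %in% names(rates)))
  ok <- stats::complete.cases(rates[, c("tpr", "fpr")])
  rates <- rates[ok, ]
  zero <- rates$fpr == 0
  pts <- NULL
  t0 <- NA_real_
  if (any(zero)) {
    t0 <- if (is.null(collapseTpr0)) mean(rates$tpr[zero]) else collapseTpr0
    pts <- rbind(pts, c(0, t0))
  }
  rest <- rates[!zero, , drop = FALSE]
  if (nrow(rest)) {
    rest <- rest[order(rest$fpr, rest$tpr), , drop = FALSE]
    pts <- rbind(pts, cbind(rest$fpr, rest$tpr))
  }
  if (!any(zero)) pts <- rbind(c(0, 0), pts)
  if (!(pts[nrow(pts), 1] == 1 && pts[nrow(pts), 2] == 1))
    pts <- rbind(pts, c(1, 1))
  colnames(pts) <- c("fpr", "tpr")
  curve <- new("ROCCurve", points = pts, collapseTpr0 = t0,
               aucTrapezoid = NA_real_, aucSmoothed = NA_real_)
  curve@aucTrapezoid <- aucTrapezoid(curve)
  curve
}

rocPointMatrix <- function(curve) {
  if (is(curve, "ROCCurve")) curve@points else as.matrix(curve)
}

#' Trapezoidal AUC of a pooled ROC curve
#'
#' @param curve a [ROCCurve-class] or a two-column (fpr, tpr) matrix with
#'   non-decreasing fpr.
#' @return area under the piecewise-linear curve.
#' @export
aucTrapezoid <- function(curve) {
  p <- rocPointMatrix(curve)
  if (nrow(p) < 2) stop("need at least two points")
  if (any(diff(p[, 1]) < 0)) stop("fpr must be sorted non-decreasing")
  sum(diff(p[, 1]) * (p[-nrow(p), 2] + p[-1, 2]) / 2)
}

# Natural cubic smoothing spline (Green-Silverman): minimizes
#   p * sum (y_i - f(x_i))^2 + (1 - p) * int f''(t)^2 dt
# over all twice-differentiable f; the solution is a natural cubic spline
# with knots at the x_i and fitted values (I + lambda K)^{-1} y,
# lambda = (1 - p) / p, K = Q R^{-1} Q^T.
smoothingSplineFit <- function(x, y, p) {
  n <- length(x)
  stopifnot(n >= 3, !is.unsorted(x))
  h <- diff(x)
  Q <- matrix(0, n, n - 2)
  R <- matrix(0, n - 2, n - 2)
  for (j in 2:(n - 1)) {
    i <- j - 1
    Q[j - 1, i] <- 1 / h[j - 1]
    Q[j, i] <- -1 / h[j - 1] - 1 / h[j]
    Q[j + 1, i] <- 1 / h[j]
    R[i, i] <- (h[j - 1] + h[j]) / 3
    if (i < n - 2) { R[i, i + 1] <- h[j] / 6; R[i + 1, i] <- h[j] / 6 }
  }
  lambda <- (1 - p) / p
  K <- Q %*% solve(R, t(Q))
  yhat <- solve(diag(n) + lambda * K, y)
  list(x = x, yhat = as.vector(yhat))
}

#' Smoothing-spline AUC of a pooled ROC curve
#'
#' Fits a cubic smoothing spline minimizing
#' \deqn{p \sum_i (tpr_i - f(fpr_i))^2 + (1 - p) \int f''(t)^2 \, dt}
#' to the curve's points (duplicate abscissae are averaged first, with a
#' warning) and integrates the fitted curve, clamped to [0, 1], over
#' FPR in [0, 1] on a dense grid. This damps the point-to-point
#' fluctuations a small subject sample produces in the raw pooled curve.
#'
#' @param curve a [ROCCurve-class] or (fpr, tpr) matrix.
#' @param p smoothing parameter in (0, 1]; 1 interpolates.
#' @param gridN grid resolution (>= 1000).
#' @return smoothed AUC.
#' @export
aucSmoothed <- function(curve, p = 0.9995, gridN = 2001) {
  stopifnot(p > 0, p <= 1, gridN >= 1000)
  pts <- rocPointMatrix(curve)
  x <- pts[, 1]; y <- pts[, 2]
  if (anyDuplicated(x)) {
    warning("duplicate fpr abscissae averaged before spline fitting")
    y <- as.vector(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  g <- seq(0, 1, length.out = gridN)
  if (p == 1) {
    f <- stats::spline(x, y, xout = g, method = "natural")$y
  } else {
    fit <- smoothingSplineFit(x, y, p)
    f <- stats::spline(fit$x, fit$yhat, xout = g, method = "natural")$y
  }
  f <- pmin(pmax(f, 0), 1)
  sum(diff(g) * (f[-length(f)] + f[-1]) / 2)
}

#' Qualitative interpretation band of an AUC
#'
#' 0.5 is not informative; (0.5, 0.7] not accurate; (0.7, 0.9] moderately
#' accurate; (0.9, 1) highly accurate; 1 a perfect test. Values below 0.5
#' are reported as below chance.
#'
#' @param auc value in [0, 1].
#' @return character category.
#' @export
#' @examples
#' interpretAUC(0.88)
interpretAUC <- function(auc) {
  stopifnot(auc >= 0, auc <= 1)
  if (auc < 0.5) "below chance"
  else if (auc == 0.5) "not informative"
  else if (auc <= 0.7) "not accurate"
  else if (auc <= 0.9) "moderately accurate"
  else if (auc < 1) "highly accurate"
  else "perfect test"
}

#' Bundled 13-subject example rates table
#'
#' Per-subject classifier operating points (TPR, FPR, accuracy) from a
#' 13-subject rabbit intracerebral-hemorrhage relaxometry study, used by
#' the worked ROC/AUC example and the `repro-table2` command.
#'
#' @return data.frame with columns subject, tpr, fpr, acc.
#' @export
exampleRates <- function() {
  utils::read.csv(system.file("extdata", "example_rates_13subjects.csv",
                              package = "RelaxoMRR"))
}

#' Plot a pooled ROC curve
#'
#' Raw pooled curve, chance diagonal, and optionally the smoothing-spline
#' fit, in the conventional ROC layout.
#'
#' @param curve a [ROCCurve-class].
#' @param splineP smoothing parameter for the overlaid spline (NULL to
#'   omit).
#' @param ... passed to [graphics::plot()].
#' @export
plotROC <- function(curve, splineP = 0.9995, ...) {
  p <- rocPointMatrix(curve)
  graphics::plot(p[, 1], p[, 2], type = "b", pch = 16, xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "False positive rate",
                 ylab = "True positive rate", ...)
  graphics::abline(0, 1, col = "red")
  if (!is.null(splineP) && nrow(p) >= 3) {
    x <- p[, 1]; y <- p[, 2]
    if (anyDuplicated(x)) {
      y <- as.vector(tapply(y, x, mean)); x <- sort(unique(x))
    }
    fit <- smoothingSplineFit(x, y, splineP)
    g <- seq(0, 1, length.out = 400)
    f <- pmin(pmax(stats::spline(fit$x, fit$yhat, xout = g,
                                 method = "natural")$y, 0), 1)
    graphics::lines(g, f, lty = 2)
  }
  invisible(curve)
}
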