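# Suspect-voxel selection on the T2 map and contralateral mirroring.
# The subject's left hemisphere (lesion side) is displayed on the image
# right, i.e. columns above the midline column.

#' Estimate the inter-hemispheric midline column
#'
#' Scans candidate columns over the middle third of the image (half-pixel
#' steps) and returns the one maximizing a left-right reflection symmetry
#' score: the negative sum of squared differences between the image and
#' its column-reflection about the candidate, restricted to the brain
#' mask. Falls back to the mask centroid column (with a warning) when the
#' score is flat.
#'
#' @param image 2D image (e.g. a T2 map or one series frame).
#' @param mask 0/1 brain mask.
#' @param overrideCol optional configured midline (skips estimation).
#' @return list with `col` (fractional column) and `source`
#'   (`"estimated"` or `"config"`).
#' @export
estimateMidline <- function(image, mask, overrideCol = NULL) {
  if (!is.null(overrideCol))
    return(list(col = overrideCol, source = "config"))
  stopifnot(sum(mask) > 0)
  nc <- ncol(image)
  cand <- seq(ceiling(nc / 3), floor(2 * nc / 3), by = 0.5)
  img <- image
  img[mask == 0] <- NA
  score <- vapply(cand, function(cc) {
    cols <- seq_len(nc)
    mcols <- round(2 * cc - cols)
    ok <- mcols >= 1 & mcols <= nc
    diffs <- img[, cols[ok], drop = FALSE] - img[, mcols[ok], drop = FALSE]
    v <- diffs[!is.na(diffs)]
    if (length(v) < 0.1 * sum(mask)) return(-Inf)
    -sum(v^2) / length(v)
  }, numeric(1))
  if (all(!is.finite(score)) || diff(range(score[is.finite(score)])) < 1e-12) {
    warning("flat symmetry score; falling back to mask centroid column")
    return(list(col = mean(which(mask > 0, arr.ind = TRUE)[, 2]),
                source = "estimated"))
  }
  list(col = cand[which.max(score)], source = "estimated")
}

#' Select suspected-lesion voxels on the T2 map
#'
#' Emulates (or ingests) the radiologist's selection of n suspect voxels.
#' In `"auto"` mode the n highest-T2 voxels inside a left-hemisphere
#' search window (brain mask, columns at least `windowMarginPx` above the
#' midline, optionally within `windowRadiusPx` of `seedPoint`) are taken.
#' In `"manual"` mode a (row, col) coordinate list (or CSV file with
#' columns row, col) is passed through.
#'
#' @param t2map a fitted [ParameterMap-class] (t2 mode).
#' @param mode `"auto"` or `"manual"`.
#' @param n number of voxels to select (auto mode).
#' @param midline midline list from [estimateMidline()].
#' @param brainMask 0/1 matrix.
#' @param windowMarginPx minimum distance of the window from the midline.
#' @param seedPoint,windowRadiusPx optional circular window restriction.
#' @param coords manual-mode (row, col) matrix, or a CSV path.
#' @return a [VoxelSelection-class] with all voxels `origin = "selected"`.
#' @export
selectSuspectVoxels <- function(t2map, mode = c("auto", "manual"), n = 12,
                                midline, brainMask,
                                windowMarginPx = 6, seedPoint = NULL,
                                windowRadiusPx = NULL, coords = NULL) {
  mode <- match.arg(mode)
  mid <- midline$col
  if (mode == "manual") {
    if (is.character(coords)) {
      df <- utils::read.csv(coords)
      coords <- as.matrix(df[, c("row", "col")])
    }
    coords <- matrix(as.integer(round(coords)), ncol = 2,
                     dimnames = list(NULL, c("row", "col")))
    bad <- which(brainMask[coords] == 0)
    if (length(bad))
      stop("selected voxels outside the brain mask at indices: ",
           paste(bad, collapse = ", "))
  } else {
    tau <- tauImage(t2map)
    win <- brainMask > 0 & !is.na(tau)
    cols <- col(tau)
    win <- win & cols > mid + windowMarginPx
    # only voxels whose contralateral analog exists in the brain mask are
    # eligible (the mirroring step refuses out-of-mask analogs)
    mcol <- roundAwayFromMidline(2 * mid - cols, mid)
    okm <- mcol >= 1 & mcol <= ncol(tau)
    mIn <- matrix(FALSE, nrow(tau), ncol(tau))
    mIn[okm] <- brainMask[cbind(row(tau)[okm], mcol[okm])] > 0
    win <- win & mIn
    if (!is.null(seedPoint) && !is.null(windowRadiusPx)) {
      rr <- row(tau) - seedPoint[1]; cc <- cols - seedPoint[2]
      win <- win & (rr^2 + cc^2 <= windowRadiusPx^2)
    }
    cand <- which(win)
    if (length(cand) < n)
      stop("search window smaller than n; widen the window or reduce n")
    top <- cand[order(tau[cand], decreasing = TRUE)[seq_len(n)]]
    coords <- cbind(row = as.integer((top - 1) %% nrow(tau) + 1),
                    col = as.integer((top - 1) %/% nrow(tau) + 1))
  }
  hem <- ifelse(coords[, 2] > mid, "left", "right")
  new("VoxelSelection", coords = coords, hemisphere = hem,
      origin = rep("selected", nrow(coords)),
      nSelected = nrow(coords), midlineCol = mid, brainMask = brainMask + 0)
}

# round-half-away-from-midline, so mirrored voxels never land on the midline
roundAwayFromMidline <- function(x, mid) {
  up <- x > mid
  out <- ifelse(up, ceiling(x - 0.5 + 1e-9), floor(x + 0.5 - 1e-9))
  # exact .5 cases move away from the midline
  half <- abs(x - round(x)) == 0.5
  out[half] <- ifelse(up[half], ceiling(x[half]), floor(x[half]))
  out
}

#' Mirror selected voxels into the contralateral hemisphere
#'
#' For each selected voxel (r, c) the analog region in the opposite
#' hemisphere is the exact column reflection (r, 2 * midline - c), rounded
#' half-away-from-the-midline when the midline is fractional. The output
#' holds the n selected voxels followed by their n mirrors (2n total,
#' input order preserved). Mirrored voxels falling outside the brain mask
#' or onto the midline are an error (no silent clamping).
#'
#' @param selection a [VoxelSelection-class] with only selected voxels.
#' @param midline midline list from [estimateMidline()] (defaults to the
#'   midline stored in the selection).
#' @return a [VoxelSelection-class] with 2n voxels.
#' @export
mirrorContralateral <- function(selection, midline = NULL) {
  stopifnot(all(selection@origin == "selected"))
  mid <- if (is.null(midline)) selection@midlineCol else midline$col
  co <- selection@coords
  if (any(co[, 2] == mid))
    stop("voxel exactly on the midline mirrors onto itself; remove it: ",
         paste(which(co[, 2] == mid), collapse = ", "))
  mcol <- roundAwayFromMidline(2 * mid - co[, 2], mid)
  mco <- cbind(row = as.integer(co[, 1]), col = as.integer(mcol))
  inside <- rep(FALSE, nrow(mco))
  okb <- mco[, 2] >= 1 & mco[, 2] <= ncol(selection@brainMask)
  inside[okb] <- selection@brainMask[mco[okb, , drop = FALSE]] > 0
  if (!all(inside))
    stop("mirrored voxels fall outside the brain mask at selected indices: ",
         paste(which(!inside), collapse = ", "))
  storage.mode(co) <- "integer"
  coords <- rbind(co, mco)
  hem <- ifelse(coords[, 2] > mid, "left", "right")
  new("VoxelSelection", coords = coords, hemisphere = hem,
      origin = rep(c("selected", "mirrored"), each = nrow(co)),
      nSelected = nrow(co), midlineCol = mid,
      brainMask = selection@brainMask)
}

#' Extract the raw T1-recovery matrix for a voxel selection
#'
#' Row i holds the raw (unnormalized) T1-series intensities of voxel i
#' across frames, ordered by ascending TR: the "return of the signal to
#' baseline" pattern used as the clustering feature. Optional per-row
#' max-normalization is available but off by default.
#'
#' @param t1series a co-registered T1 [RelaxationSeries-class].
#' @param selection a [VoxelSelection-class].
#' @param normalizeRows divide each row by its maximum.
#' @return numeric matrix (voxels x frames) with attribute `timingMs`.
#' @export
extractRecoveryMatrix <- function(t1series, selection, normalizeRows = FALSE) {
  stopifnot(t1series@mode == "t1_series")
  d <- dim(t1series@frames)
  co <- selection@coords
  if (any(co[, 1] < 1 | co[, 1] > d[1] | co[, 2] < 1 | co[, 2] > d[2]))
    stop("selection outside frame bounds")
  ord <- order(t1series@timingMs)
  m <- matrix(0, nrow(co), d[3])
  for (j in seq_along(ord))
    m[, j] <- t1series@frames[, , ord[j]][co]
  if (any(!is.finite(m)))
    stop("non-finite intensity at voxel index: ",
         paste(unique(which(!is.finite(m), arr.ind = TRUE)[, 1]), collapse = ", "))
  if (normalizeRows) m <- m / pmax(apply(m, 1, max), .Machine$double.eps)
  attr(m, "timingMs") <- t1series@timingMs[ord]
  m
}
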