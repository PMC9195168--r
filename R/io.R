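# Serialization: NIfTI (images, series, maps, masks) with JSON sidecars,
# CSV voxel lists and rates tables, JSON ROC reports, PNG overlays.
# Write-then-read returns an equal object (float32 precision for images,
# exact for masks, labels and coordinates).

#' Write / read a relaxation series (NIfTI + JSON sidecar)
#'
#' Frames are stacked along the third NIfTI axis; the sidecar records the
#' mode, timing list, noise level and seeds.
#'
#' @param series a [RelaxationSeries-class].
#' @param path output path without extension (writes `.nii.gz` + `.json`).
#' @return `writeSeries` the path, invisibly; `readSeries` the series.
#' @export
writeSeries <- function(series, path) {
  RNifti::writeNifti(series@frames, paste0(path, ".nii.gz"))
  side <- list(mode = series@mode, timing_ms = series@timingMs,
               meta = series@meta)
  if (!is.null(series@motionShifts))
    side$motion_shifts <- series@motionShifts
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  if (!is.null(series@brainMask))
    RNifti::writeNifti(array(as.integer(series@brainMask > 0),
                             dim = c(dim(series@brainMask), 1)),
                       paste0(path, "_mask.nii.gz"), datatype = "uint8")
  invisible(path)
}

#' @rdname writeSeries
#' @export
readSeries <- function(path) {
  nii <- RNifti::readNifti(paste0(path, ".nii.gz"))
  fr <- array(as.numeric(nii), dim = dim(nii))
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  mask <- NULL
  mfile <- paste0(path, "_mask.nii.gz")
  if (file.exists(mfile))
    mask <- dropFrame(RNifti::readNifti(mfile)) + 0
  shifts <- NULL
  if (!is.null(side$motion_shifts))
    shifts <- matrix(unlist(side$motion_shifts), ncol = 2)
  new("RelaxationSeries", frames = fr, timingMs = as.numeric(side$timing_ms),
      mode = side$mode, brainMask = mask, motionShifts = shifts,
      meta = if (is.null(side$meta)) list() else as.list(side$meta))
}

#' Write / read a quantitative parameter map (NIfTI float32 + JSON + CSV QC)
#'
#' The tau, M0 and SSE images go into one 3-frame float32 NIfTI; the
#' sidecar records the mode; the per-voxel QC table (row, col, tau, sse,
#' converged) is written as CSV next to it.
#'
#' @param map a [ParameterMap-class].
#' @param path output path without extension.
#' @export
writeParameterMap <- function(map, path) {
  stk <- array(0, c(dim(map@tauImg), 3))
  na0 <- function(m) { m[is.na(m)] <- 0; m }
  stk[, , 1] <- na0(map@tauImg); stk[, , 2] <- na0(map@m0Img)
  stk[, , 3] <- na0(map@sseImg)
  RNifti::writeNifti(stk, paste0(path, ".nii.gz"), datatype = "float")
  RNifti::writeNifti(array(as.integer(map@mask > 0), c(dim(map@mask), 1)),
                     paste0(path, "_mask.nii.gz"), datatype = "uint8")
  writeLines(jsonlite::toJSON(list(mode = map@mode), auto_unbox = TRUE),
             paste0(path, ".json"))
  idx <- which(map@mask > 0, arr.ind = TRUE)
  qc <- data.frame(row = idx[, 1], col = idx[, 2],
                   tau_ms = map@tauImg[idx], sse = map@sseImg[idx],
                   converged = map@convergedImg[idx] > 0)
  utils::write.csv(qc, paste0(path, "_qc.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeParameterMap
#' @export
readParameterMap <- function(path) {
  stk0 <- RNifti::readNifti(paste0(path, ".nii.gz"))
  stk <- array(as.numeric(stk0), dim = dim(stk0))
  mask <- dropFrame(RNifti::readNifti(paste0(path, "_mask.nii.gz"))) + 0
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  qc <- utils::read.csv(paste0(path, "_qc.csv"))
  tau <- stk[, , 1]; m0 <- stk[, , 2]; sse <- stk[, , 3]
  tau[mask == 0] <- NA; m0[mask == 0] <- NA; sse[mask == 0] <- NA
  conv <- matrix(0, nrow(mask), ncol(mask))
  conv[cbind(qc$row, qc$col)] <- as.numeric(qc$converged)
  new("ParameterMap", tauImg = tau, m0Img = m0, sseImg = sse,
      convergedImg = conv, mask = mask, mode = side$mode)
}

#' Write / read a voxel selection as CSV
#'
#' Columns row, col, hemisphere, origin (1-based coordinates); the
#' midline column is kept in a comment-free extra column so the
#' round-trip is exact.
#'
#' @param selection a [VoxelSelection-class].
#' @param path CSV path.
#' @param brainMask mask to attach on read (the CSV stores voxels only).
#' @export
writeSelection <- function(selection, path) {
  df <- data.frame(row = selection@coords[, 1], col = selection@coords[, 2],
                   hemisphere = selection@hemisphere,
                   origin = selection@origin,
                   midline_col = selection@midlineCol)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSelection
#' @export
readSelection <- function(path, brainMask) {
  df <- utils::read.csv(path)
  new("VoxelSelection",
      coords = cbind(row = as.integer(df$row), col = as.integer(df$col)),
      hemisphere = df$hemisphere, origin = df$origin,
      nSelected = sum(df$origin == "selected"),
      midlineCol = df$midline_col[1], brainMask = brainMask + 0)
}

#' Write / read a pooled ROC curve as JSON
#' @param curve a [ROCCurve-class].
#' @param path JSON path.
#' @export
writeROC <- function(curve, path) {
  obj <- list(points = unname(apply(curve@points, 1, as.list)),
              collapse_tpr0 = curve@collapseTpr0,
              auc_trapezoid = curve@aucTrapezoid,
              auc_smoothed = curve@aucSmoothed,
              category = interpretAUC(min(max(curve@aucTrapezoid, 0), 1)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"),
             path)
  invisible(path)
}

#' @rdname writeROC
#' @export
readROC <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  pts <- as.matrix(as.data.frame(obj$points)[, c("fpr", "tpr")])
  dimnames(pts) <- list(NULL, c("fpr", "tpr"))
  new("ROCCurve", points = pts,
      collapseTpr0 = ifelse(is.null(obj$collapse_tpr0), NA_real_,
                            as.numeric(obj$collapse_tpr0)),
      aucTrapezoid = as.numeric(obj$auc_trapezoid),
      aucSmoothed = ifelse(is.null(obj$auc_smoothed) ||
                             is.na(obj$auc_smoothed), NA_real_,
                           as.numeric(obj$auc_smoothed)))
}

#' Write a macro image as PNG + JSON transform record
#'
#' The grayscale image is scaled to [0, 1] for PNG; the contour mask and
#' the applied transform (including the deformation field) go into the
#' JSON record so the object round-trips.
#'
#' @param macro a [MacroImage-class].
#' @param path output path without extension.
#' @export
writeMacroImage <- function(macro, path) {
  img <- macro@img
  rng <- range(img)
  scl <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  png::writePNG(scl, paste0(path, ".png"))
  obj <- list(intensity_range = rng,
              contour_rle = which(macro@contourTruth > 0),
              dim = dim(macro@img),
              transform = macro@transform)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeMacroImage
#' @export
readMacroImage <- function(path) {
  scl <- png::readPNG(paste0(path, ".png"))
  obj <- jsonlite::fromJSON(paste0(path, ".json"))
  rng <- as.numeric(obj$intensity_range)
  img <- scl * diff(rng) + rng[1]
  d <- as.integer(obj$dim)
  contour <- matrix(0, d[1], d[2])
  contour[as.integer(obj$contour_rle)] <- 1
  tf <- obj$transform
  tf$vr <- matrix(unlist(tf$vr), d[1], d[2])
  tf$vc <- matrix(unlist(tf$vc), d[1], d[2])
  new("MacroImage", img = img, contourTruth = contour, transform = tf)
}

#' Classification overlay figure
#'
#' Grayscale fitted T2 map with pathological voxels in red and healthy
#' voxels in yellow, the display convention used throughout.
#'
#' @param result a [ClassificationResult-class].
#' @param t2map the [ParameterMap-class] behind it.
#' @param path PNG path.
#' @export
writeOverlayPNG <- function(result, t2map, path) {
  tau <- t2map@tauImg
  tau[is.na(tau)] <- 0
  rng <- range(tau)
  gray <- if (diff(rng) > 0) (tau - rng[1]) / diff(rng) else tau * 0
  rgb <- array(rep(gray, 3), c(dim(gray), 3))
  co <- result@selection@coords
  for (i in seq_len(nrow(co))) {
    colr <- if (result@labels[i] == "P") c(1, 0, 0) else c(1, 1, 0)
    rgb[co[i, 1], co[i, 2], ] <- colr
  }
  png::writePNG(rgb, path)
  invisible(path)
}

# NIfTI readers may drop or keep singleton third dimensions; normalize to 2D
dropFrame <- function(nii) {
  arr <- as.array(nii)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  matrix(as.numeric(arr), nrow(arr), ncol(arr))
}
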