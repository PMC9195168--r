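#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Phantom specification
#'
#' Describes a two-hemisphere digital brain-slice phantom with a hemorrhagic
#' lesion confined to the subject's left hemisphere (displayed on the image
#' right, radiological convention: columns above the midline column).
#'
#' @slot grid integer(2), (rows, cols), at least 64 x 64.
#' @slot midlineCol midline column index (fractional allowed).
#' @slot lesionShape one of `"linear"`, `"irregular"`, `"circular"`.
#' @slot lesionAreaPx target lesion area in pixels.
#' @slot rimWidthPx perilesional rim thickness in pixels (>= 0).
#' @slot rimMix fraction in [0, 1] blending lesion and local tissue
#'   parameters inside the rim (0 = pure background, 1 = pure lesion).
#' @slot tissueTable data.frame with columns name, t1_ms, t2_ms, m0,
#'   class_id (see [tissueDefaults()]).
#' @slot seed RNG seed making the phantom reproducible.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  grid = "integer", midlineCol = "numeric", lesionShape = "character",
  lesionAreaPx = "numeric", rimWidthPx = "numeric", rimMix = "numeric",
  tissueTable = "data.frame", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@grid) != 2 || any(object@grid < 64))
    msg <- c(msg, "grid must be (rows, cols) with both >= 64")
  if (!object@lesionShape %in% c("linear", "irregular", "circular"))
    msg <- c(msg, "lesionShape must be linear, irregular or circular")
  if (object@rimMix < 0 || object@rimMix > 1)
    msg <- c(msg, "rimMix must be in [0, 1]")
  if (object@rimWidthPx < 0) msg <- c(msg, "rimWidthPx must be >= 0")
  tt <- object@tissueTable
  need <- c("name", "t1_ms", "t2_ms", "m0", "class_id")
  if (!all(need %in% names(tt))) {
    msg <- c(msg, "tissueTable must have columns name, t1_ms, t2_ms, m0, class_id")
  } else {
    if (any(tt$t1_ms <= 0) || any(tt$t2_ms <= 0))
      msg <- c(msg, "tissue relaxation times must be positive")
    if (anyDuplicated(tt$class_id)) msg <- c(msg, "class_id must be unique")
  }
  if (object@midlineCol < 1 || object@midlineCol > object@grid[2])
    msg <- c(msg, "midlineCol outside image bounds")
  if (length(msg)) msg else TRUE
})

#' Digital phantom with ground truth
#'
#' Ground-truth tissue label map, per-pixel T1/T2/M0 parameter images, the
#' true lesion mask (the analogue of a histopathological "true lesion
#' contour"), the brain mask and the anatomical midline column.
#'
#' @slot labelImg integer tissue-class map (0 = background).
#' @slot t1Truth,t2Truth,m0Truth per-pixel parameter images.
#' @slot lesionMask,brainMask logical-valued 0/1 matrices.
#' @slot midlineCol midline column.
#' @slot spec the generating [PhantomSpec-class].
#' @exportClass DigitalPhantom
setClass("DigitalPhantom", representation(
  labelImg = "matrix", t1Truth = "matrix", t2Truth = "matrix",
  m0Truth = "matrix", lesionMask = "matrix", brainMask = "matrix",
  midlineCol = "numeric", spec = "PhantomSpec"
))

setValidity("DigitalPhantom", function(object) {
  msg <- character()
  d <- dim(object@labelImg)
  for (s in c("t1Truth", "t2Truth", "m0Truth", "lesionMask", "brainMask"))
    if (!identical(dim(slot(object, s)), d)) msg <- c(msg, paste(s, "dimension mismatch"))
  if (any(object@lesionMask > 0 & object@brainMask == 0))
    msg <- c(msg, "lesion mask must lie inside the brain mask")
  inb <- object@brainMask > 0
  if (any(object@t1Truth[inb] <= 0) || any(object@t2Truth[inb] <= 0))
    msg <- c(msg, "truth maps must be positive inside the brain mask")
  les <- which(object@lesionMask > 0, arr.ind = TRUE)
  if (nrow(les) && any(les[, 2] <= object@midlineCol))
    msg <- c(msg, "lesion must lie entirely in the left hemisphere (columns above the midline)")
  if (length(msg)) msg else TRUE
})

#' Acquisition protocol
#'
#' Timing schedule and noise level of a variable-TR spin-echo T1 series or
#' a variable-TE fast-spin-echo T2 series. The default T1 schedule has 14
#' TR values and the default T2 schedule 3 TE values.
#'
#' @slot mode `"t1_series"` or `"t2_series"`.
#' @slot timingMs per-frame TR (t1 mode) or TE (t2 mode) values in ms.
#' @slot noiseSigma Rician noise scale in signal units (>= 0).
#' @slot seed RNG seed for the noise.
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol", representation(
  mode = "character", timingMs = "numeric", noiseSigma = "numeric",
  seed = "integer"
))

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  if (!object@mode %in% c("t1_series", "t2_series"))
    msg <- c(msg, "mode must be t1_series or t2_series")
  if (length(object@timingMs) < 1 || any(object@timingMs <= 0))
    msg <- c(msg, "timing values must be positive and non-empty")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Relaxation image series
#'
#' A stack of 2D frames with one TR (T1 series) or TE (T2 series) value per
#' frame: the raw material for both quantitative map fitting and the
#' clustering features.
#'
#' @slot frames numeric array (rows x cols x frames).
#' @slot timingMs per-frame TR or TE (ms), same length as the third dim.
#' @slot mode `"t1_series"` or `"t2_series"`.
#' @slot brainMask optional 0/1 matrix.
#' @slot motionShifts optional (frames x 2) matrix of applied (dr, dc)
#'   shifts, retained as a test oracle by [applyMotion()].
#' @slot meta free-form provenance list (protocol, seeds, coregistration).
#' @exportClass RelaxationSeries
setClass("RelaxationSeries", representation(
  frames = "array", timingMs = "numeric", mode = "character",
  brainMask = "matrixOrNULL", motionShifts = "matrixOrNULL", meta = "list"
))

setValidity("RelaxationSeries", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3) msg <- c(msg, "frames must be a 3D array")
  else if (d[3] != length(object@timingMs))
    msg <- c(msg, "one timing value per frame required")
  if (length(object@timingMs) < 2) msg <- c(msg, "at least 2 frames required")
  if (any(object@timingMs <= 0)) msg <- c(msg, "timing values must be positive")
  if (!object@mode %in% c("t1_series", "t2_series"))
    msg <- c(msg, "mode must be t1_series or t2_series")
  if (length(msg)) msg else TRUE
})

#' Quantitative parameter map
#'
#' Voxel-wise result of fitting the two-parameter relaxation model: the
#' relaxation-time image (T1 or T2 in ms), the amplitude image M0, the
#' residual sum-of-squares image and the fitted-pixel mask.
#'
#' @slot tauImg relaxation time (ms) per pixel, NA outside the mask.
#' @slot m0Img fitted amplitude per pixel.
#' @slot sseImg residual sum of squares per pixel.
#' @slot convergedImg 0/1 convergence flags.
#' @slot mask 0/1 fitted-pixel mask.
#' @slot mode `"t1_series"` or `"t2_series"`.
#' @exportClass ParameterMap
setClass("ParameterMap", representation(
  tauImg = "matrix", m0Img = "matrix", sseImg = "matrix",
  convergedImg = "matrix", mask = "matrix", mode = "character"
))

setValidity("ParameterMap", function(object) {
  msg <- character()
  d <- dim(object@tauImg)
  for (s in c("m0Img", "sseImg", "convergedImg", "mask"))
    if (!identical(dim(slot(object, s)), d)) msg <- c(msg, paste(s, "dimension mismatch"))
  on <- object@mask > 0 & object@convergedImg > 0
  if (any(!is.na(object@tauImg[on]) & object@tauImg[on] <= 0))
    msg <- c(msg, "tau must be positive on converged mask pixels")
  if (length(msg)) msg else TRUE
})

#' Voxel selection (selected + contralateral mirrored)
#'
#' The n radiologist-selected (or automatically emulated) suspect voxels
#' together with their n contralateral mirror images: the 2n-voxel input of
#' the classification step.
#'
#' @slot coords (m x 2) matrix of (row, col), 1-based.
#' @slot hemisphere per-voxel `"left"` or `"right"` (subject side).
#' @slot origin per-voxel `"selected"` or `"mirrored"`.
#' @slot nSelected number of selected voxels (m is n or 2n).
#' @slot midlineCol midline used for hemisphere assignment and mirroring.
#' @slot brainMask 0/1 matrix the voxels must lie in.
#' @exportClass VoxelSelection
setClass("VoxelSelection", representation(
  coords = "matrix", hemisphere = "character", origin = "character",
  nSelected = "integer", midlineCol = "numeric", brainMask = "matrix"
))

setValidity("VoxelSelection", function(object) {
  msg <- character()
  m <- nrow(object@coords)
  if (length(object@hemisphere) != m || length(object@origin) != m)
    msg <- c(msg, "hemisphere/origin length must match coords")
  ns <- sum(object@origin == "selected")
  nm <- sum(object@origin == "mirrored")
  if (ns != object@nSelected) msg <- c(msg, "nSelected inconsistent with origin")
  if (nm > 0 && nm != ns) msg <- c(msg, "mirrored count must equal selected count")
  if (m > 0) {
    inside <- object@brainMask[object@coords] > 0
    if (!all(inside)) msg <- c(msg, "all voxels must lie inside the brain mask")
    hem <- ifelse(object@coords[, 2] > object@midlineCol, "left", "right")
    if (!all(hem == object@hemisphere)) msg <- c(msg, "hemisphere labels inconsistent with midline")
  }
  if (length(msg)) msg else TRUE
})

#' UPGMA dendrogram
#'
#' Agglomeration history of unweighted-average-linkage hierarchical
#' clustering, in `hclust` merge convention (negative entries are leaves).
#' UPGMA merge heights are non-decreasing.
#'
#' @slot merge (n-1 x 2) merge matrix, `hclust` convention.
#' @slot height merge heights, non-decreasing.
#' @slot size number of members of each merged cluster.
#' @slot leafCount number of observations.
#' @exportClass Dendrogram
setClass("Dendrogram", representation(
  merge = "matrix", height = "numeric", size = "integer", leafCount = "integer"
))

setValidity("Dendrogram", function(object) {
  msg <- character()
  if (nrow(object@merge) != object@leafCount - 1L)
    msg <- c(msg, "merge must have leafCount - 1 rows")
  if (length(object@height) > 1 && any(diff(object@height) < -1e-9))
    msg <- c(msg, "UPGMA merge heights must be non-decreasing")
  if (length(object@size) && object@size[length(object@size)] != object@leafCount)
    msg <- c(msg, "root must contain all leaves")
  if (length(msg)) msg else TRUE
})

#' Binary tissue classification of the 2n voxels
#'
#' @slot labels per-voxel `"H"` (healthy) or `"P"` (pathological).
#' @slot clusterAssignment per-voxel cluster id at the chosen cut.
#' @slot kUsed number of classes actually used (2).
#' @slot profile data.frame (k, meanSilhouette) for k in the scanned range.
#' @slot bestK silhouette-maximizing k (ties -> smallest).
#' @slot mapping named character, cluster id -> "H"/"P".
#' @slot dendrogram the [Dendrogram-class] behind the cut.
#' @slot selection the [VoxelSelection-class] the labels refer to.
#' @exportClass ClassificationResult
setClass("ClassificationResult", representation(
  labels = "character", clusterAssignment = "integer", kUsed = "integer",
  profile = "data.frame", bestK = "integer", mapping = "character",
  dendrogram = "Dendrogram", selection = "VoxelSelection"
))

setValidity("ClassificationResult", function(object) {
  msg <- character()
  if (!all(object@labels %in% c("H", "P"))) msg <- c(msg, "labels must be H or P")
  if (length(object@labels) != length(object@clusterAssignment))
    msg <- c(msg, "labels/clusterAssignment length mismatch")
  lab <- object@mapping[as.character(object@clusterAssignment)]
  if (length(lab) && !all(lab == object@labels))
    msg <- c(msg, "mapping inconsistent with assignment")
  if (length(msg)) msg else TRUE
})

#' Deformed gold-standard macro image
#'
#' Emulates the photograph of the fixed brain section ("macro image"): the
#' phantom's T2 truth rendered in its own coordinate frame after isotropic
#' shrinkage (formalin fixation), rotation and a smooth deformation, with
#' the lesion contour carried along and the generating transform retained
#' as a test oracle.
#'
#' @slot img grayscale macro image.
#' @slot contourTruth 0/1 lesion mask in the macro frame.
#' @slot transform list with the applied similarity parameters (scale,
#'   rotationDeg, translation, centers) and deformation field (vr, vc).
#' @exportClass MacroImage
setClass("MacroImage", representation(
  img = "matrix", contourTruth = "matrix", transform = "list"
))

setValidity("MacroImage", function(object) {
  if (!identical(dim(object@img), dim(object@contourTruth)))
    return("img and contourTruth must share dimensions")
  if (sum(object@contourTruth) < 1) return("contour must contain at least one pixel")
  TRUE
})

#' 2D similarity transform (conformal mapping)
#'
#' Rotation, isotropic scale, translation and optional reflection, mapping
#' fixed-frame coordinates to moving-frame coordinates:
#' `q = s * R(theta) * J * (p - centerFixed) + centerMoving + t`, where `J`
#' negates the column axis when `reflect` is set.
#'
#' @slot rotationDeg rotation angle (degrees).
#' @slot scale isotropic scale (> 0).
#' @slot translation (tr, tc) in pixels.
#' @slot reflect logical, column-axis reflection.
#' @slot centerFixed,centerMoving rotation centers in the two frames.
#' @slot mse mean-squared intensity difference at the optimum.
#' @exportClass SimilarityTransform
setClass("SimilarityTransform", representation(
  rotationDeg = "numeric", scale = "numeric", translation = "numeric",
  reflect = "logical", centerFixed = "numeric", centerMoving = "numeric",
  mse = "numeric"
))

setValidity("SimilarityTransform", function(object) {
  if (object@scale <= 0) return("scale must be positive")
  if (length(object@translation) != 2) return("translation must be length 2")
  TRUE
})

#' Pooled ROC curve over subjects
#'
#' Operating points pooled across subjects, with all FPR = 0 subjects
#' collapsed to a single point (0, T0) and a terminal (1, 1) anchor. The
#' raw curve is not monotonicity-corrected.
#'
#' @slot points (m x 2) matrix with columns fpr, tpr; fpr non-decreasing.
#' @slot collapseTpr0 the TPR used at FPR = 0.
#' @slot aucTrapezoid trapezoidal AUC.
#' @slot aucSmoothed smoothing-spline AUC (NA until computed).
#' @exportClass ROCCurve
setClass("ROCCurve", representation(
  points = "matrix", collapseTpr0 = "numeric", aucTrapezoid = "numeric",
  aucSmoothed = "numeric"
))

setValidity("ROCCurve", function(object) {
  p <- object@points
  if (ncol(p) != 2) return("points must have columns (fpr, tpr)")
  if (any(diff(p[, 1]) < 0)) return("fpr must be non-decreasing")
  if (nrow(p) && any(p[nrow(p), ] != c(1, 1))) return("last point must be (1, 1)")
  TRUE
})
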