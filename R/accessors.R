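# Accessors and show methods. Slots are never accessed with @ from user
# code; these are the supported surface.

#' @describeIn RelaxationSeries-class frame stack (rows x cols x frames)
#' @param object a RelaxoMRR object.
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
setMethod("frames", "RelaxationSeries", function(object) object@frames)

#' @describeIn RelaxationSeries-class per-frame TR or TE values (ms)
#' @export
setGeneric("timingMs", function(object) standardGeneric("timingMs"))
setMethod("timingMs", "RelaxationSeries", function(object) object@timingMs)
setMethod("timingMs", "AcquisitionProtocol", function(object) object@timingMs)

#' @describeIn RelaxationSeries-class `"t1_series"` or `"t2_series"`
#' @export
setGeneric("seriesMode", function(object) standardGeneric("seriesMode"))
setMethod("seriesMode", "RelaxationSeries", function(object) object@mode)
setMethod("seriesMode", "AcquisitionProtocol", function(object) object@mode)
setMethod("seriesMode", "ParameterMap", function(object) object@mode)

#' @describeIn DigitalPhantom-class brain mask (0/1 matrix)
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))
setMethod("brainMask", "DigitalPhantom", function(object) object@brainMask)
setMethod("brainMask", "RelaxationSeries", function(object) object@brainMask)
setMethod("brainMask", "VoxelSelection", function(object) object@brainMask)

#' @describeIn DigitalPhantom-class true lesion mask
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))
setMethod("lesionMask", "DigitalPhantom", function(object) object@lesionMask)

#' @describeIn DigitalPhantom-class ground-truth parameter image
#' @param which one of `"t1"`, `"t2"`, `"m0"`, `"label"`.
#' @export
setGeneric("truthMap", function(object, which = "t2") standardGeneric("truthMap"))
setMethod("truthMap", "DigitalPhantom", function(object, which = "t2") {
  switch(match.arg(which, c("t1", "t2", "m0", "label")),
    t1 = object@t1Truth, t2 = object@t2Truth,
    m0 = object@m0Truth, label = object@labelImg)
})

#' @describeIn DigitalPhantom-class midline column
#' @export
setGeneric("midlineCol", function(object) standardGeneric("midlineCol"))
setMethod("midlineCol", "DigitalPhantom", function(object) object@midlineCol)
setMethod("midlineCol", "VoxelSelection", function(object) object@midlineCol)

#' @describeIn ParameterMap-class relaxation-time image (ms)
#' @export
setGeneric("tauImage", function(object) standardGeneric("tauImage"))
setMethod("tauImage", "ParameterMap", function(object) object@tauImg)

#' @describeIn ParameterMap-class fitted amplitude image
#' @export
setGeneric("m0Image", function(object) standardGeneric("m0Image"))
setMethod("m0Image", "ParameterMap", function(object) object@m0Img)

#' @describeIn ParameterMap-class residual sum-of-squares image
#' @export
setGeneric("sseImage", function(object) standardGeneric("sseImage"))
setMethod("sseImage", "ParameterMap", function(object) object@sseImg)

#' @describeIn ParameterMap-class fitted-pixel mask
#' @export
setGeneric("fitMask", function(object) standardGeneric("fitMask"))
setMethod("fitMask", "ParameterMap", function(object) object@mask)

#' @describeIn VoxelSelection-class (row, col) coordinates, 1-based
#' @export
setGeneric("voxelCoords", function(object) standardGeneric("voxelCoords"))
setMethod("voxelCoords", "VoxelSelection", function(object) object@coords)

#' @describeIn VoxelSelection-class per-voxel subject hemisphere
#' @export
setGeneric("hemisphere", function(object) standardGeneric("hemisphere"))
setMethod("hemisphere", "VoxelSelection", function(object) object@hemisphere)

#' @describeIn VoxelSelection-class per-voxel origin (selected/mirrored)
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))
setMethod("voxelOrigin", "VoxelSelection", function(object) object@origin)

#' @describeIn VoxelSelection-class number of selected voxels n
#' @export
setGeneric("nSelected", function(object) standardGeneric("nSelected"))
setMethod("nSelected", "VoxelSelection", function(object) object@nSelected)

#' @describeIn ClassificationResult-class per-voxel H/P labels
#' @export
setGeneric("voxelLabels", function(object) standardGeneric("voxelLabels"))
setMethod("voxelLabels", "ClassificationResult", function(object) object@labels)

#' @describeIn ClassificationResult-class per-voxel cluster ids
#' @export
setGeneric("clusterAssignment", function(object) standardGeneric("clusterAssignment"))
setMethod("clusterAssignment", "ClassificationResult", function(object) object@clusterAssignment)

#' @describeIn ClassificationResult-class silhouette profile (k, meanSilhouette)
#' @export
setGeneric("silhouetteProfile", function(object) standardGeneric("silhouetteProfile"))
setMethod("silhouetteProfile", "ClassificationResult", function(object) object@profile)

#' @describeIn ClassificationResult-class silhouette-optimal k
#' @export
setGeneric("bestK", function(object) standardGeneric("bestK"))
setMethod("bestK", "ClassificationResult", function(object) object@bestK)

#' @describeIn MacroImage-class macro-frame grayscale image
#' @export
setGeneric("macroImg", function(object) standardGeneric("macroImg"))
setMethod("macroImg", "MacroImage", function(object) object@img)

#' @describeIn MacroImage-class lesion contour mask in the macro frame
#' @export
setGeneric("contourTruth", function(object) standardGeneric("contourTruth"))
setMethod("contourTruth", "MacroImage", function(object) object@contourTruth)

#' @describeIn MacroImage-class transform applied at generation (oracle)
#' @export
setGeneric("appliedTransform", function(object) standardGeneric("appliedTransform"))
setMethod("appliedTransform", "MacroImage", function(object) object@transform)

#' @describeIn ROCCurve-class (fpr, tpr) points
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
setMethod("rocPoints", "ROCCurve", function(object) object@points)

setMethod("show", "DigitalPhantom", function(object) {
  cat(sprintf(
    "DigitalPhantom %dx%d | lesion '%s' area %d px | brain %d px | midline col %.1f\n",
    nrow(object@labelImg), ncol(object@labelImg), object@spec@lesionShape,
    sum(object@lesionMask), sum(object@brainMask), object@midlineCol))
})

setMethod("show", "RelaxationSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("RelaxationSeries (%s) %dx%d, %d frames | timing %s ms\n",
    object@mode, d[1], d[2], d[3],
    paste(signif(object@timingMs, 4), collapse = ", ")))
})

setMethod("show", "ParameterMap", function(object) {
  on <- object@mask > 0
  cat(sprintf("ParameterMap (%s) %dx%d | fitted %d px | tau median %.1f ms\n",
    object@mode, nrow(object@tauImg), ncol(object@tauImg), sum(on),
    stats::median(object@tauImg[on], na.rm = TRUE)))
})

setMethod("show", "VoxelSelection", function(object) {
  cat(sprintf("VoxelSelection: n = %d selected, %d mirrored (midline col %.1f)\n",
    object@nSelected, sum(object@origin == "mirrored"), object@midlineCol))
})

setMethod("show", "Dendrogram", function(object) {
  cat(sprintf("Dendrogram (UPGMA): %d leaves, %d merges, heights [%.3g, %.3g]\n",
    object@leafCount, nrow(object@merge),
    min(object@height), max(object@height)))
})

setMethod("show", "ClassificationResult", function(object) {
  cat(sprintf("ClassificationResult: %d voxels, k = %d (bestK = %d) | P = %d, H = %d\n",
    length(object@labels), object@kUsed, object@bestK,
    sum(object@labels == "P"), sum(object@labels == "H")))
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: rot %.2f deg, scale %.3f, t (%.2f, %.2f)%s | MSE %.4g\n",
    object@rotationDeg, object@scale, object@translation[1], object@translation[2],
    if (object@reflect) ", reflected" else "", object@mse))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve: %d points, AUC(trapezoid) = %.3f%s\n",
    nrow(object@points), object@aucTrapezoid,
    if (!is.na(object@aucSmoothed))
      sprintf(", AUC(smoothed) = %.3f", object@aucSmoothed) else ""))
})

setMethod("show", "MacroImage", function(object) {
  cat(sprintf("MacroImage %dx%d | contour %d px | scale %.3f, rot %.1f deg\n",
    nrow(object@img), ncol(object@img), sum(object@contourTruth),
    object@transform$scale, object@transform$rotationDeg))
})
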