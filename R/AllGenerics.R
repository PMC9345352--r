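#' @name accessors
#' @title Accessors for segscore classes
#' @description Slot accessors for the S4 carriers. \code{intensities} and
#'   \code{labelMap} return the arrays of a \linkS4class{LabeledVolume};
#'   \code{spacing} its voxel spacing; \code{roiTable}, \code{backgroundCode}
#'   and \code{mergeMode} describe an \linkS4class{AtlasScheme};
#'   \code{cubeValues}, \code{sourceClass}, \code{sourceBbox} and \code{lMax}
#'   describe an \linkS4class{MBCube}.
#' @param x an object of the documented class.
#' @return The slot value; \code{labelMap} returns \code{NULL} for an
#'   unlabeled volume.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))
#' @rdname accessors
#' @export
setGeneric("backgroundCode", function(x) standardGeneric("backgroundCode"))
#' @rdname accessors
#' @export
setGeneric("mergeMode", function(x) standardGeneric("mergeMode"))
#' @rdname accessors
#' @export
setGeneric("atlasCodes", function(x) standardGeneric("atlasCodes"))
#' @rdname accessors
#' @export
setGeneric("classCount", function(x) standardGeneric("classCount"))
#' @rdname accessors
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))
#' @rdname accessors
#' @export
setGeneric("sourceClass", function(x) standardGeneric("sourceClass"))
#' @rdname accessors
#' @export
setGeneric("sourceBbox", function(x) standardGeneric("sourceBbox"))
#' @rdname accessors
#' @export
setGeneric("lMax", function(x) standardGeneric("lMax"))

#' @rdname accessors
setMethod("intensities", "LabeledVolume", function(x) x@intensity)
#' @rdname accessors
setMethod("labelMap", "LabeledVolume",
          function(x) if (length(x@labels)) x@labels else NULL)
#' @rdname accessors
setMethod("spacing", "LabeledVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("subjectId", "LabeledVolume", function(x) x@subjectId)
#' @rdname accessors
setMethod("roiTable", "AtlasScheme", function(x) x@roiTable)
#' @rdname accessors
setMethod("backgroundCode", "AtlasScheme", function(x) x@backgroundCode)
#' @rdname accessors
setMethod("mergeMode", "AtlasScheme", function(x) x@mergeMode)
#' @rdname accessors
setMethod("atlasCodes", "AtlasScheme",
          function(x) sort(x@roiTable$code))
#' @rdname accessors
setMethod("classCount", "AtlasScheme", function(x) {
  if (x@mergeMode == "symmetric_5")
    length(unique(x@roiTable$family)) else nrow(x@roiTable)
})
#' @rdname accessors
setMethod("cubeValues", "MBCube", function(x) x@values)
#' @rdname accessors
setMethod("sourceClass", "MBCube", function(x) x@sourceClass)
#' @rdname accessors
setMethod("sourceBbox", "MBCube", function(x) x@sourceBbox)
#' @rdname accessors
setMethod("lMax", "MBCube", function(x) x@lMax)

setMethod("show", "AtlasScheme", function(object) {
  fams <- unique(object@roiTable$family)
  cat(sprintf("AtlasScheme: %d ROIs in %d families, mode '%s'\n",
              nrow(object@roiTable), length(fams), object@mergeMode))
  cat("  families:", paste(fams, collapse = ", "), "\n")
  cat("  codes:", paste(sort(object@roiTable$code), collapse = " "), "\n")
})

setMethod("show", "LabeledVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("LabeledVolume '%s': %d x %d x %d voxels, spacing %s mm, %s\n",
              object@subjectId, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = "x"),
              if (length(object@labels)) sprintf("%d labeled voxels",
                sum(object@labels != 0L)) else "unlabeled"))
})

setMethod("show", "MBCube", function(object) {
  cat(sprintf(
    "MBCube: class %d, bbox %s, L_max %d, resampled to %d^3\n",
    object@sourceClass,
    paste(apply(object@sourceBbox, 1, function(r)
      sprintf("[%d,%d)", r[1], r[2])), collapse = " x "),
    object@lMax, object@targetEdge))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d^3 grid, %d families, mirror axis %d, noise sd %.3g\n",
    object@gridEdge, length(object@families), object@mirrorAxis,
    object@noiseSd))
  cat(sprintf("  score = %.3g + linear(volumes) + N(0, %.3g^2)\n",
              object@scoreModel$intercept, object@scoreModel$sigma))
})

setMethod("show", "SegNetConfig", function(object) {
  cat(sprintf(
    "SegNetConfig: %d -> %d classes, %d levels, stem %d, schedule (%s), expansion %d, dilation %d, %s gate\n",
    object@inChannels, object@nClasses, object@levels, object@stemChannels,
    paste(object@channelSchedule, collapse = ", "), object@expansion,
    object@dilationRate, object@seGate))
})

setMethod("show", "RegressorConfig", function(object) {
  cat(sprintf(
    "RegressorConfig: %d^3 x %d input, conv (%s), fc (%s), dropout %.2f\n",
    object@inputEdge, object@inChannels,
    paste(object@convChannels, collapse = ", "),
    paste(object@fcDims, collapse = ", "), object@dropout))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d resample(s), ASD variant '%s'\n",
              object@nResamples, object@asdVariant))
  s <- object@summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %.4f +/- %.4f  (%.4f, %.4f)\n", s$metric[i],
                s$mean[i], s$sd[i], s$lo[i], s$hi[i]))
  }
  if (length(object@perClassDice)) {
    cat("  per-class Dice:",
        paste(sprintf("%s=%.3f", names(object@perClassDice),
                      object@perClassDice), collapse = " "), "\n")
  }
  if (length(object@perClassAsd)) {
    cat("  per-class ASD (mm):",
        paste(sprintf("%s=%.3f", names(object@perClassAsd),
                      object@perClassAsd), collapse = " "), "\n")
  }
})
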