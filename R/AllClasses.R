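#' @useDynLib segscore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif sd var quantile qnorm wilcox.test
#' @importFrom utils read.csv write.csv head tail
NULL

#' AtlasScheme: the 14-ROI label table and its bilateral merge
#'
#' Holds the atlas label table for the 14 regions of interest used by the
#' pipeline (three inferior-frontal-gyrus pairs, hippocampus, amygdala,
#' caudate nucleus and thalamus, each with a left and a right instance) plus
#' the merge mode that decides how atlas codes map to segmentation classes:
#' \code{"symmetric_5"} gives one class per bilateral anatomical family
#' (5 foreground classes), \code{"per_roi_14"} one class per atlas code.
#'
#' @slot roiTable data.frame with columns \code{code} (integer atlas code),
#'   \code{side} ("L" or "R") and \code{family} (anatomical family name).
#' @slot backgroundCode integer label code treated as background (default 0).
#' @slot mergeMode either \code{"symmetric_5"} or \code{"per_roi_14"}.
#' @export
setClass("AtlasScheme",
  representation(roiTable = "data.frame",
                 backgroundCode = "integer",
                 mergeMode = "character"))

setValidity("AtlasScheme", function(object) {
  tb <- object@roiTable
  msgs <- character()
  if (!all(c("code", "side", "family") %in% names(tb)))
    msgs <- c(msgs, "roiTable needs columns code, side, family")
  else {
    if (nrow(tb) != 14L)
      msgs <- c(msgs, "exactly 14 ROI entries are required")
    if (anyDuplicated(tb$code))
      msgs <- c(msgs, "atlas codes must be unique")
    if (!all(tb$side %in% c("L", "R")))
      msgs <- c(msgs, "side must be 'L' or 'R'")
    cnt <- table(tb$family, tb$side)
    if (nrow(cnt) && !all(cnt[, "L"] == cnt[, "R"]))
      msgs <- c(msgs, "every family needs equal numbers of L and R entries")
    if (object@backgroundCode %in% tb$code)
      msgs <- c(msgs, "backgroundCode must not be an ROI code")
  }
  if (!object@mergeMode %in% c("symmetric_5", "per_roi_14"))
    msgs <- c(msgs, "mergeMode must be 'symmetric_5' or 'per_roi_14'")
  if (length(msgs)) msgs else TRUE
})

#' LabeledVolume: a 3D intensity volume with an optional label map
#'
#' The universal carrier between pipeline stages: a real-valued 3D intensity
#' array, an optional voxel-aligned integer label map of identical shape, the
#' voxel spacing in mm, and a subject identifier.
#'
#' @slot intensity numeric 3D array.
#' @slot labels integer 3D array of the same shape, or a 0-length array when
#'   the volume is unlabeled.
#' @slot spacing numeric length-3 voxel spacing in mm (strictly positive).
#' @slot subjectId character scalar.
#' @export
setClass("LabeledVolume",
  representation(intensity = "array", labels = "array",
                 spacing = "numeric", subjectId = "character"))

setValidity("LabeledVolume", function(object) {
  msgs <- character()
  if (length(dim(object@intensity)) != 3L)
    msgs <- c(msgs, "intensity must be a 3D array")
  if (length(object@labels) &&
      !identical(dim(object@labels), dim(object@intensity)))
    msgs <- c(msgs, "labels must match the intensity shape")
  if (length(object@labels) && !is.integer(object@labels))
    msgs <- c(msgs, "labels must be integer")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive values")
  if (length(msgs)) msgs else TRUE
})

#' MBCube: a minimum-bounding-cube extraction of one ROI
#'
#' One region's content cropped at its minimum bounding box and resampled to
#' a fixed cube, together with provenance: the source class code, the
#' original half-open bounding box, and the longest box edge used as the
#' intermediate resampling size.
#'
#' @slot values numeric 3D cube of edge \code{targetEdge}.
#' @slot sourceClass integer class code the cube was extracted for.
#' @slot sourceBbox 3x2 integer matrix of half-open voxel ranges
#'   (rows x/y/z, columns start/end with start inclusive, end exclusive,
#'   0-based).
#' @slot lMax integer, longest edge of the source bounding box.
#' @slot targetEdge integer cube edge.
#' @export
setClass("MBCube",
  representation(values = "array", sourceClass = "integer",
                 sourceBbox = "matrix", lMax = "integer",
                 targetEdge = "integer"))

setValidity("MBCube", function(object) {
  msgs <- character()
  d <- dim(object@values)
  if (length(d) != 3L || length(unique(d)) != 1L)
    msgs <- c(msgs, "values must be a cube")
  if (length(d) == 3L && d[1] != object@targetEdge)
    msgs <- c(msgs, "cube edge must equal targetEdge")
  bb <- object@sourceBbox
  if (!all(dim(bb) == c(3L, 2L)))
    msgs <- c(msgs, "sourceBbox must be 3x2")
  else {
    edges <- bb[, 2] - bb[, 1]
    if (any(edges <= 0))
      msgs <- c(msgs, "sourceBbox must have positive extents")
    else if (object@lMax != max(edges))
      msgs <- c(msgs, "lMax must equal the longest bounding-box edge")
  }
  if (length(msgs)) msgs else TRUE
})

#' PhantomSpec: parameters of the symmetric synthetic-brain generator
#'
#' Describes a skull-stripped-T1-like phantom: a smooth brain envelope plus
#' 14 bilaterally mirrored ellipsoidal ROIs in 5 anatomical families, with
#' per-subject shape jitter, additive intensity noise, and a scalar score
#' generated from the ROI volumes.
#'
#' @slot gridEdge integer grid edge (voxels).
#' @slot families list of family templates; each has \code{name},
#'   \code{codesL}, \code{codesR}, \code{centers} (matrix of left-side
#'   centers as grid fractions), \code{radii} (matrix of radii fractions)
#'   and \code{intensity}.
#' @slot envelope list with \code{center}, \code{radii}, \code{intensity}.
#' @slot mirrorAxis integer axis index of the symmetry plane (1 = x).
#' @slot jitter list with \code{scaleFamily}, \code{scaleSide} (relative
#'   half-ranges of uniform scale jitter) and \code{shift} (voxels).
#' @slot noiseSd numeric additive Gaussian intensity noise sd.
#' @slot scoreModel list with per-family \code{weights}, \code{intercept},
#'   \code{quadratic} coefficient and noise sd \code{sigma}.
#' @slot seed integer base seed.
#' @export
setClass("PhantomSpec",
  representation(gridEdge = "integer", families = "list", envelope = "list",
                 mirrorAxis = "integer", jitter = "list", noiseSd = "numeric",
                 scoreModel = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (object@gridEdge < 16L)
    msgs <- c(msgs, "gridEdge must be at least 16")
  if (!object@mirrorAxis %in% 1:3)
    msgs <- c(msgs, "mirrorAxis must be 1, 2 or 3")
  codes <- unlist(lapply(object@families, function(f) c(f$codesL, f$codesR)))
  if (length(codes) != 14L || anyDuplicated(codes))
    msgs <- c(msgs, "families must emit 14 distinct atlas codes")
  if (object@noiseSd < 0)
    msgs <- c(msgs, "noiseSd must be non-negative")
  sm <- object@scoreModel
  if (length(sm$weights) != length(object@families))
    msgs <- c(msgs, "scoreModel weights must be one per family")
  if (sm$sigma < 0)
    msgs <- c(msgs, "score noise sd must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SegNetConfig: hyperparameters of the segmentation network
#'
#' Architectural configuration of the improved 3D U-Net: a 1x1x1 stem,
#' residual recombination blocks with squeeze-and-excitation attention at
#' every level, max-pool downsampling, transposed-convolution upsampling,
#' projected additive skip connections, an extra projected bottleneck skip,
#' and a softmax head.
#'
#' @slot inChannels integer input channels.
#' @slot nClasses integer output classes (background included).
#' @slot levels integer number of resolution levels including the bottleneck.
#' @slot stemChannels integer channels of the 1x1x1 stem convolution.
#' @slot channelSchedule integer vector, one entry per level.
#' @slot expansion integer inner-width multiplier of the recombination block.
#' @slot dilationRate integer dilation of the attention block's 3x3x3 kernel.
#' @slot seGate \code{"linear"} or \code{"sigmoid"} gate of the attention
#'   weight map.
#' @slot upsample \code{"transposed"} or \code{"nearest"}.
#' @slot seed integer weight-initialization seed.
#' @export
setClass("SegNetConfig",
  representation(inChannels = "integer", nClasses = "integer",
                 levels = "integer", stemChannels = "integer",
                 channelSchedule = "integer", expansion = "integer",
                 dilationRate = "integer", seGate = "character",
                 upsample = "character", seed = "integer"))

setValidity("SegNetConfig", function(object) {
  msgs <- character()
  if (object@levels < 2L) msgs <- c(msgs, "levels must be >= 2")
  if (length(object@channelSchedule) != object@levels)
    msgs <- c(msgs, "channelSchedule needs one entry per level")
  if (any(c(object@channelSchedule, object@stemChannels,
            object@inChannels, object@nClasses) <= 0L))
    msgs <- c(msgs, "all channel counts must be positive")
  if (object@expansion < 1L) msgs <- c(msgs, "expansion must be >= 1")
  if (object@dilationRate < 1L) msgs <- c(msgs, "dilationRate must be >= 1")
  if (!object@seGate %in% c("linear", "sigmoid"))
    msgs <- c(msgs, "seGate must be 'linear' or 'sigmoid'")
  if (!object@upsample %in% c("transposed", "nearest"))
    msgs <- c(msgs, "upsample must be 'transposed' or 'nearest'")
  if (length(msgs)) msgs else TRUE
})

#' RegressorConfig: hyperparameters of the volumetric score regressor
#'
#' Configuration of the cube-to-score CNN: three same-padded 3x3x3
#' convolution + batch-norm + ReLU stages, a flatten, and three fully
#' connected layers with dropout, ending in a single scalar output.
#'
#' @slot inputEdge integer cube edge of the input.
#' @slot inChannels integer input channels (one per anatomical family).
#' @slot convChannels integer length-3 channel schedule of the conv stages.
#' @slot fcDims integer length-3: flattened size and the two hidden widths.
#' @slot dropout numeric dropout rate between fully connected layers.
#' @slot seed integer weight-initialization seed.
#' @export
setClass("RegressorConfig",
  representation(inputEdge = "integer", inChannels = "integer",
                 convChannels = "integer", fcDims = "integer",
                 dropout = "numeric", seed = "integer"))

setValidity("RegressorConfig", function(object) {
  msgs <- character()
  if (length(object@convChannels) != 3L)
    msgs <- c(msgs, "convChannels must have length 3")
  if (length(object@fcDims) != 3L)
    msgs <- c(msgs, "fcDims must have length 3")
  expect <- object@inputEdge^3 * object@convChannels[3]
  if (length(object@fcDims) == 3L && object@fcDims[1] != expect)
    msgs <- c(msgs, sprintf(
      "fcDims[1] (%d) must equal inputEdge^3 * convChannels[3] (%d)",
      object@fcDims[1], expect))
  if (object@dropout < 0 || object@dropout >= 1)
    msgs <- c(msgs, "dropout must be in [0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: resampled evaluation summary
#'
#' Summary of one or more train/test cycles: per-class Dice and average
#' surface distance, scalar MSE, and mean / sd / normal-approximation 95\%
#' confidence intervals over resamples.
#'
#' @slot records list of per-resample named numeric metric vectors.
#' @slot summary data.frame with columns metric, mean, sd, lo, hi.
#' @slot perClassDice named numeric (possibly empty).
#' @slot perClassAsd named numeric (possibly empty), in mm.
#' @slot nResamples integer.
#' @slot asdVariant \code{"directed"} or \code{"symmetric"}.
#' @export
setClass("EvalReport",
  representation(records = "list", summary = "data.frame",
                 perClassDice = "numeric", perClassAsd = "numeric",
                 nResamples = "integer", asdVariant = "character"))

setValidity("EvalReport", function(object) {
  msgs <- character()
  s <- object@summary
  if (nrow(s) && !all(c("metric", "mean", "sd", "lo", "hi") %in% names(s)))
    msgs <- c(msgs, "summary needs columns metric, mean, sd, lo, hi")
  if (nrow(s) && any(!is.na(s$lo) & !is.na(s$hi) & s$lo > s$hi))
    msgs <- c(msgs, "confidence bounds must satisfy lo <= hi")
  if (length(object@perClassDice) &&
      any(object@perClassDice < 0 | object@perClassDice > 1, na.rm = TRUE))
    msgs <- c(msgs, "Dice values must lie in [0, 1]")
  if (length(object@perClassAsd) && any(object@perClassAsd < 0, na.rm = TRUE))
    msgs <- c(msgs, "ASD values must be non-negative")
  if (length(msgs)) msgs else TRUE
})
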