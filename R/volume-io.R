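#' Construct a LabeledVolume
#'
#' @param intensity numeric 3D array.
#' @param labels optional integer 3D array of the same shape.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param subjectId subject identifier.
#' @return A \linkS4class{LabeledVolume}.
#' @export
labeledVolume <- function(intensity, labels = NULL, spacing = c(1, 1, 1),
                          subjectId = "subject") {
  if (is.null(labels)) labels <- array(integer(0), c(0L, 0L, 0L))
  else storage.mode(labels) <- "integer"
  new("LabeledVolume", intensity = intensity, labels = labels,
      spacing = as.numeric(spacing), subjectId = as.character(subjectId))
}

#' Read a volume (and optional label map) from NIfTI
#'
#' Reads a 3D NIfTI image; when \code{labelPath} is given the label map is
#' read alongside and stored voxel-aligned. Label values are rounded to
#' integer codes.
#'
#' @param path path of the intensity image (.nii or .nii.gz).
#' @param labelPath optional path of the label image.
#' @param subjectId subject identifier; defaults to the file stem.
#' @return A \linkS4class{LabeledVolume} with spacing taken from the image
#'   header.
#' @export
readVolume <- function(path, labelPath = NULL, subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  labels <- NULL
  if (!is.null(labelPath)) {
    lab <- RNifti::readNifti(labelPath)
    if (!identical(dim(lab), d))
      stop("label map shape differs from intensity shape")
    labels <- array(as.integer(round(as.array(lab))), d)
  }
  labeledVolume(array(as.numeric(as.array(img)), d), labels,
                spacing = RNifti::pixdim(img)[1:3], subjectId = subjectId)
}

#' Write a volume (and optional label map) to NIfTI
#'
#' Intensities are written as float32-compatible doubles, labels as int16,
#' so that integer label codes round-trip bit-exactly.
#'
#' @param vol a \linkS4class{LabeledVolume}.
#' @param path output path for the intensity image.
#' @param labelPath optional output path for the label map.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path, labelPath = NULL) {
  img <- RNifti::asNifti(intensities(vol))
  RNifti::pixdim(img) <- spacing(vol)
  RNifti::writeNifti(img, path)
  if (!is.null(labelPath)) {
    if (is.null(labelMap(vol))) stop("volume has no label map to write")
    lab <- RNifti::asNifti(labelMap(vol))
    RNifti::pixdim(lab) <- spacing(vol)
    RNifti::writeNifti(lab, labelPath, datatype = "int16")
  }
  invisible(path)
}

#' Centered crop of a labeled volume
#'
#' Extracts the centered \code{outEdge}^3 subvolume of both intensity and
#' labels, discarding the outermost background margin. An even margin is
#' split equally between the two sides; an odd margin puts the extra voxel
#' on the high-index side.
#'
#' @param vol a \linkS4class{LabeledVolume}.
#' @param outEdge integer output edge, at most every input dimension.
#' @return The cropped \linkS4class{LabeledVolume}.
#' @examples
#' v <- labeledVolume(array(rnorm(20^3), c(20, 20, 20)))
#' dim(intensities(centerCrop(v, 16)))   # 16 16 16
#' @export
centerCrop <- function(vol, outEdge) {
  d <- dim(intensities(vol))
  outEdge <- as.integer(outEdge)
  if (any(outEdge > d))
    stop("outEdge (", outEdge, ") exceeds an input dimension (",
         paste(d, collapse = "x"), ")")
  lo <- (d - outEdge) %/% 2L          # extra voxel of an odd margin goes high
  idx <- lapply(1:3, function(a) lo[a] + seq_len(outEdge))
  lab <- labelMap(vol)
  labeledVolume(intensities(vol)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
                if (!is.null(lab)) lab[idx[[1]], idx[[2]], idx[[3]],
                                       drop = FALSE],
                spacing = spacing(vol), subjectId = subjectId(vol))
}

#' Sample random training patches from a volume
#'
#' Draws \code{n} cubic patches of edge \code{patchEdge} with origins
#' uniform over all valid positions; intensity and labels are cut
#' coherently and no resampling takes place. By default sampling is
#' unconditioned on the labels; \code{requireForeground} redraws (with a
#' bounded number of attempts) until each patch holds at least one nonzero
#' label voxel.
#'
#' @param vol a \linkS4class{LabeledVolume}.
#' @param patchEdge integer patch edge, at most every volume dimension.
#' @param n number of patches.
#' @param seed integer RNG seed making the draw reproducible.
#' @param requireForeground logical, default \code{FALSE}.
#' @return A list of \code{n} \linkS4class{LabeledVolume} patches; the patch
#'   origin (0-based) is attached as attribute \code{"origin"}.
#' @export
samplePatches <- function(vol, patchEdge, n, seed = 1L,
                          requireForeground = FALSE) {
  d <- dim(intensities(vol))
  patchEdge <- as.integer(patchEdge)
  if (any(patchEdge > d))
    stop("patchEdge (", patchEdge, ") exceeds a volume dimension")
  lab <- labelMap(vol)
  if (requireForeground && is.null(lab))
    stop("requireForeground needs a labeled volume")
  set.seed(seed)
  maxo <- d - patchEdge
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      o <- vapply(maxo, function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
      idx <- lapply(1:3, function(a) o[a] + seq_len(patchEdge))
      pl <- if (!is.null(lab)) lab[idx[[1]], idx[[2]], idx[[3]],
                                   drop = FALSE]
      if (!requireForeground || any(pl != 0L)) break
    }
    p <- labeledVolume(
      intensities(vol)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], pl,
      spacing = spacing(vol),
      subjectId = sprintf("%s_p%03d", subjectId(vol), i))
    attr(p, "origin") <- o
    out[[i]] <- p
  }
  out
}

#' Z-score intensity normalization
#'
#' Standardizes a volume's intensities to zero mean and unit variance over
#' the brain-mask voxels (intensity > 0), falling back to the whole volume
#' when no voxel is positive. Voxels outside the mask are left at their
#' standardized values so the transform stays affine over the whole array.
#'
#' @param vol a \linkS4class{LabeledVolume}.
#' @return The normalized \linkS4class{LabeledVolume}.
#' @export
normalizeIntensity <- function(vol) {
  x <- intensities(vol)
  m <- x > 0
  if (!any(m)) m <- rep(TRUE, length(x))
  mu <- mean(x[m])
  s <- sd(x[m])
  if (!is.finite(s) || s == 0) s <- 1
  labeledVolume((x - mu) / s, labelMap(vol), spacing(vol), subjectId(vol))
}
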