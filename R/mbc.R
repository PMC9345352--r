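# 3D resampling: separable align-corners trilinear / nearest-neighbor, with
# a normalized Gaussian prefilter on axes that are being shrunk (real-valued
# content only).

.gaussBlurAxis <- function(x, axis, sigma) {
  if (sigma <= 0) return(x)
  n <- dim(x)[axis]
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  base <- outer(seq_len(n), off, "+")
  base <- pmin(pmax(base, 1L), n)          # replicate-edge padding
  k <- exp(-(off^2) / (2 * sigma^2))
  k <- k / sum(k)
  A <- matrix(0, n, n)                     # banded smoothing operator
  for (j in seq_along(off)) {
    idx <- cbind(seq_len(n), base[, j])
    A[idx] <- A[idx] + k[j]
  }
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  y <- array(A %*% matrix(xp, n, prod(dp[-1])), dp)
  aperm(y, order(perm))
}

.resizeAxisLinear <- function(x, axis, nOut) {
  nIn <- dim(x)[axis]
  if (nOut == nIn) return(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  M <- matrix(xp, nIn, prod(dp[-1]))
  if (nIn == 1L) {
    Y <- M[rep(1L, nOut), , drop = FALSE]
  } else {
    src <- if (nOut == 1L) rep((nIn + 1) / 2, 1L)
           else 1 + (seq_len(nOut) - 1) * (nIn - 1) / (nOut - 1)
    lo <- pmax(pmin(floor(src), nIn - 1L), 1L)
    w <- src - lo
    Y <- M[lo, , drop = FALSE] * (1 - w) + M[lo + 1L, , drop = FALSE] * w
  }
  aperm(array(Y, c(nOut, dp[-1])), order(perm))
}

.resizeAxisNearest <- function(x, axis, nOut) {
  nIn <- dim(x)[axis]
  if (nOut == nIn) return(x)
  src <- if (nIn == 1L) rep(1, nOut)
         else if (nOut == 1L) (nIn + 1) / 2
         else 1 + (seq_len(nOut) - 1) * (nIn - 1) / (nOut - 1)
  idx <- pmin(pmax(round(src), 1L), nIn)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  M <- matrix(xp, nIn, prod(dp[-1]))
  aperm(array(M[idx, , drop = FALSE], c(nOut, dp[-1])), order(perm))
}

#' Resample a 3D array to a new shape
#'
#' Separable align-corners resampling: \code{"linear"} (trilinear, with a
#' normalized Gaussian prefilter of sd \code{(inEdge/outEdge - 1)/2} on
#' axes being shrunk, so downscaling is anti-aliased) or \code{"nearest"}.
#' Constants are preserved exactly and linear output stays within the input
#' value range; resampling to the input shape is the identity.
#'
#' @param x numeric 3D array.
#' @param outDims integer length-3 output shape (scalars are recycled).
#' @param method \code{"linear"} or \code{"nearest"}.
#' @param antialias apply the Gaussian prefilter when shrinking (linear
#'   method only).
#' @return Numeric 3D array of shape \code{outDims}.
#' @export
resizeVolume <- function(x, outDims, method = c("linear", "nearest"),
                         antialias = TRUE) {
  method <- match.arg(method)
  if (length(dim(x)) != 3L) stop("x must be a 3D array")
  outDims <- as.integer(rep(outDims, length.out = 3L))
  if (any(outDims < 1L)) stop("output dims must be positive")
  if (method == "linear" && antialias) {
    for (a in 1:3) {
      f <- dim(x)[a] / outDims[a]
      if (f > 1) x <- .gaussBlurAxis(x, a, (f - 1) / 2)
    }
  }
  for (a in 1:3) {
    x <- if (method == "linear") .resizeAxisLinear(x, a, outDims[a])
         else .resizeAxisNearest(x, a, outDims[a])
  }
  x
}

#' Minimum bounding box of one class
#'
#' The tightest axis-aligned half-open voxel box containing every voxel of
#' \code{classCode}.
#'
#' @param labels integer 3D array.
#' @param classCode class value to enclose.
#' @return 3x2 integer matrix: rows are axes, columns \code{start}
#'   (inclusive) and \code{end} (exclusive), 0-based.
#' @examples
#' v <- array(0L, c(8, 8, 8)); v[4, 5, 6] <- 1L
#' minimumBoundingBox(v, 1L)   # rows (3,4) (4,5) (5,6)
#' @export
minimumBoundingBox <- function(labels, classCode) {
  idx <- which(labels == classCode, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("class ", classCode, " is absent from the label volume")
  bb <- cbind(apply(idx, 2, min) - 1L, apply(idx, 2, max))
  storage.mode(bb) <- "integer"
  dimnames(bb) <- list(c("x", "y", "z"), c("start", "end"))
  bb
}

.mbcContent <- function(vol, classCode, content) {
  lab <- labelMap(vol)
  if (is.null(lab)) stop("volume has no label map")
  bb <- minimumBoundingBox(lab, classCode)
  idx <- lapply(1:3, function(a) (bb[a, 1] + 1L):bb[a, 2])
  crop <- intensities(vol)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  mask <- lab[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] == classCode
  vals <- switch(content,
                 intensity = crop,
                 masked_intensity = crop * mask,
                 binary = array(as.numeric(mask), dim(mask)))
  list(vals = vals, bb = bb)
}

#' Extract the minimum bounding cube of one ROI
#'
#' Crops the region's minimum bounding box and normalizes it to a fixed
#' cube by the two-interpolation scheme: the box content is first resampled
#' to \code{lMax^3} (lMax = longest box edge), then resampled again to
#' \code{targetEdge^3}. Interpolation is trilinear for real-valued content
#' and nearest-neighbor for binary content.
#'
#' @param vol a labeled \linkS4class{LabeledVolume}.
#' @param classCode class to extract (in the volume's label map).
#' @param targetEdge output cube edge (>= 2); 64 is the regression model's
#'   input size.
#' @param content \code{"masked_intensity"} (intensity with non-ROI voxels
#'   zeroed; the default), \code{"intensity"} (raw crop) or \code{"binary"}
#'   (the ROI mask).
#' @return An \linkS4class{MBCube} with provenance (source class, bounding
#'   box, lMax).
#' @export
extractMBC <- function(vol, classCode, targetEdge = 64L,
                       content = c("masked_intensity", "intensity",
                                   "binary")) {
  content <- match.arg(content)
  targetEdge <- as.integer(targetEdge)
  if (targetEdge < 2L) stop("targetEdge must be >= 2")
  cc <- .mbcContent(vol, classCode, content)
  lmax <- max(cc$bb[, 2] - cc$bb[, 1])
  method <- if (content == "binary") "nearest" else "linear"
  cube <- resizeVolume(cc$vals, rep(lmax, 3L), method = method)
  cube <- resizeVolume(cube, rep(targetEdge, 3L), method = method)
  new("MBCube", values = cube, sourceClass = as.integer(classCode),
      sourceBbox = cc$bb, lMax = as.integer(lmax),
      targetEdge = targetEdge)
}

#' Single-interpolation resize of one ROI (traditional baseline)
#'
#' As \code{\link{extractMBC}} but with a single interpolation from the
#' bounding-box crop straight to \code{targetEdge^3}; the longest box edge
#' is recorded for provenance only. On a cubic bounding box the two
#' operations coincide exactly.
#'
#' @inheritParams extractMBC
#' @return An \linkS4class{MBCube}.
#' @export
resizeDirect <- function(vol, classCode, targetEdge = 64L,
                         content = c("masked_intensity", "intensity",
                                     "binary")) {
  content <- match.arg(content)
  targetEdge <- as.integer(targetEdge)
  if (targetEdge < 2L) stop("targetEdge must be >= 2")
  cc <- .mbcContent(vol, classCode, content)
  lmax <- max(cc$bb[, 2] - cc$bb[, 1])
  method <- if (content == "binary") "nearest" else "linear"
  cube <- resizeVolume(cc$vals, rep(targetEdge, 3L), method = method)
  new("MBCube", values = cube, sourceClass = as.integer(classCode),
      sourceBbox = cc$bb, lMax = as.integer(lmax),
      targetEdge = targetEdge)
}

#' Extract one cube per anatomical family
#'
#' Maps the volume's atlas-coded label map to the 5-class symmetric scheme
#' (the union of both hemispheres and, for the frontal gyrus, of all three
#' sub-region pairs defines one box per family) and extracts one cube per
#' family class, in class order.
#'
#' @param vol a labeled \linkS4class{LabeledVolume} whose labels carry
#'   atlas codes, or class indices when \code{preMapped = TRUE}.
#' @param scheme an \linkS4class{AtlasScheme}.
#' @param targetEdge,content as in \code{\link{extractMBC}}.
#' @param method \code{"mbc"} (two interpolations) or \code{"direct"}.
#' @param preMapped set TRUE when the label map already holds merged class
#'   indices 1..5 rather than atlas codes.
#' @return Named list of \linkS4class{MBCube}s, one per family.
#' @export
familyMBCs <- function(vol, scheme = defaultAtlas(), targetEdge = 64L,
                       content = "masked_intensity",
                       method = c("mbc", "direct"), preMapped = FALSE) {
  method <- match.arg(method)
  lab <- labelMap(vol)
  if (is.null(lab)) stop("volume has no label map")
  merged <- if (preMapped) lab else mergeSymmetric(lab, scheme)
  mvol <- labeledVolume(intensities(vol), merged, spacing(vol),
                        subjectId(vol))
  lut <- .classLookup(scheme, "symmetric_5")
  fam <- roiTable(scheme)$family
  classOf <- lut[as.character(roiTable(scheme)$code)]
  famNames <- vapply(sort(unique(classOf)), function(k)
    fam[match(k, classOf)], character(1))
  out <- lapply(sort(unique(classOf)), function(k) {
    if (method == "mbc") extractMBC(mvol, k, targetEdge, content)
    else resizeDirect(mvol, k, targetEdge, content)
  })
  names(out) <- famNames
  out
}

#' Serialize / restore a minimum bounding cube
#'
#' Writes the cube values as NIfTI together with a JSON provenance sidecar
#' (source class, bounding box, lMax, target edge) at \code{<path>.json};
#' \code{readMBC} restores the full object.
#'
#' @param cube an \linkS4class{MBCube}.
#' @param path output NIfTI path (.nii or .nii.gz).
#' @return \code{path}, invisibly; \code{readMBC} returns the
#'   \linkS4class{MBCube}.
#' @export
writeMBC <- function(cube, path) {
  RNifti::writeNifti(RNifti::asNifti(cubeValues(cube)), path)
  side <- list(source_class = sourceClass(cube),
               source_bbox = unname(apply(sourceBbox(cube), 1, identity,
                                          simplify = FALSE)),
               l_max = lMax(cube),
               target_edge = cube@targetEdge)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeMBC
#' @export
readMBC <- function(path) {
  vals <- as.array(RNifti::readNifti(path))
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  bb <- side$source_bbox
  bb <- if (is.matrix(bb)) matrix(as.integer(bb), 3L, 2L)
        else matrix(as.integer(unlist(bb)), 3L, 2L, byrow = TRUE)
  dimnames(bb) <- list(c("x", "y", "z"), c("start", "end"))
  new("MBCube", values = array(as.numeric(vals), dim(vals)),
      sourceClass = as.integer(side$source_class), sourceBbox = bb,
      lMax = as.integer(side$l_max),
      targetEdge = as.integer(side$target_edge))
}

#' Stack family cubes into a regressor input
#'
#' @param cubes list of \linkS4class{MBCube}s of a common edge.
#' @return Numeric 4D array (edge, edge, edge, nFamilies).
#' @export
stackCubes <- function(cubes) {
  e <- dim(cubeValues(cubes[[1]]))[1]
  arr <- array(0, c(e, e, e, length(cubes)))
  for (i in seq_along(cubes)) arr[, , , i] <- cubeValues(cubes[[i]])
  arr
}
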