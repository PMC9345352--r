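#' Built-in 14-ROI atlas scheme
#'
#' Returns the default atlas table: the 14 regions of interest in the SRI24
#' labeling used throughout the package, i.e. the three inferior frontal
#' gyrus pairs (codes 11/12 opercular, 13/14 triangular, 15/16 orbital),
#' hippocampus (37/38), amygdala (41/42), caudate nucleus (71/72) and
#' thalamus (77/78); odd-positioned codes are left-hemisphere, their
#' partners right-hemisphere.
#'
#' @param mergeMode \code{"symmetric_5"} (one class per bilateral family,
#'   the default) or \code{"per_roi_14"} (one class per atlas code).
#' @param backgroundCode integer background label, default 0.
#' @return An \linkS4class{AtlasScheme}.
#' @examples
#' scheme <- defaultAtlas()
#' classCount(scheme)            # 5
#' classCount(defaultAtlas("per_roi_14"))  # 14
#' @export
defaultAtlas <- function(mergeMode = c("symmetric_5", "per_roi_14"),
                         backgroundCode = 0L) {
  mergeMode <- match.arg(mergeMode)
  tb <- data.frame(
    code = c(11L, 12L, 13L, 14L, 15L, 16L,
             37L, 38L, 41L, 42L, 71L, 72L, 77L, 78L),
    side = rep(c("L", "R"), 7),
    family = rep(c("frontal_gyrus", "frontal_gyrus", "frontal_gyrus",
                   "hippocampus", "amygdala", "caudate_nucleus", "thalamus"),
                 each = 2),
    stringsAsFactors = FALSE)
  new("AtlasScheme", roiTable = tb,
      backgroundCode = as.integer(backgroundCode), mergeMode = mergeMode)
}

#' Read an atlas scheme from a delimited table
#'
#' Loads an atlas table from CSV or TSV with columns \code{code},
#' \code{side}, \code{family} (extra columns ignored).
#'
#' @param path file path; tab-delimited when the extension is ".tsv".
#' @param mergeMode,backgroundCode as in \code{\link{defaultAtlas}}.
#' @return An \linkS4class{AtlasScheme}.
#' @export
readAtlas <- function(path, mergeMode = c("symmetric_5", "per_roi_14"),
                      backgroundCode = 0L) {
  mergeMode <- match.arg(mergeMode)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tb <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("code", "side", "family") %in% names(tb)))
    stop("atlas table needs columns code, side, family")
  tb <- tb[, c("code", "side", "family")]
  tb$code <- as.integer(tb$code)
  new("AtlasScheme", roiTable = tb,
      backgroundCode = as.integer(backgroundCode), mergeMode = mergeMode)
}

#' Write an atlas scheme to CSV
#'
#' @param scheme an \linkS4class{AtlasScheme}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeAtlas <- function(scheme, path) {
  write.csv(roiTable(scheme), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# code -> class lookup for a scheme and mode; returns an integer vector
# indexed by atlas code (plus background at code backgroundCode -> 0).
# Class indices are deterministic: families ordered by their smallest atlas
# code in symmetric mode; ascending atlas code in per-ROI mode.
.classLookup <- function(scheme, mode) {
  tb <- roiTable(scheme)
  if (mode == "symmetric_5") {
    fam_min <- tapply(tb$code, tb$family, min)
    fam_rank <- rank(fam_min)
    cls <- as.integer(fam_rank[tb$family])
  } else {
    cls <- as.integer(rank(tb$code))
  }
  stats::setNames(cls, tb$code)
}

.applyLookup <- function(labelVolume, scheme, mode) {
  if (!is.array(labelVolume) || length(dim(labelVolume)) != 3L)
    stop("label volume must be a 3D array")
  lut <- .classLookup(scheme, mode)
  codes <- sort(unique(as.vector(labelVolume)))
  codes <- codes[codes != backgroundCode(scheme)]
  unknown <- setdiff(codes, as.integer(names(lut)))
  if (length(unknown))
    stop("unknown label code(s) present: ", paste(unknown, collapse = ", "))
  out <- array(0L, dim(labelVolume))
  for (code in codes)
    out[labelVolume == code] <- lut[[as.character(code)]]
  out
}

#' Merge bilateral ROIs into one class per anatomical family
#'
#' Maps a label volume carrying atlas codes onto the 5-class symmetric
#' scheme in which the left and the right instances of an anatomical family
#' (and all three frontal-gyrus pairs) share a single class. Background maps
#' to class 0; families receive classes 1..5 ordered by their smallest atlas
#' code (frontal gyrus = 1, hippocampus = 2, amygdala = 3, caudate
#' nucleus = 4, thalamus = 5 for the default atlas).
#'
#' @param labelVolume integer 3D array of atlas codes (0 = background).
#' @param scheme an \linkS4class{AtlasScheme}.
#' @return Integer 3D array over 0..5. Unknown codes raise an error naming
#'   the offending code.
#' @examples
#' scheme <- defaultAtlas()
#' v <- array(0L, c(4, 4, 4)); v[1, 1, 1] <- 37L; v[2, 1, 1] <- 38L
#' m <- mergeSymmetric(v, scheme)
#' m[1, 1, 1] == m[2, 1, 1]   # both hippocampi share one class
#' @export
mergeSymmetric <- function(labelVolume, scheme = defaultAtlas()) {
  .applyLookup(labelVolume, scheme, "symmetric_5")
}

#' Map each ROI to its own class
#'
#' Maps a label volume carrying atlas codes onto the 14-class scheme with
#' one class per atlas code, ordered by ascending code; background maps to
#' class 0.
#'
#' @inheritParams mergeSymmetric
#' @return Integer 3D array over 0..14.
#' @export
perRoiClasses <- function(labelVolume, scheme = defaultAtlas()) {
  .applyLookup(labelVolume, scheme, "per_roi_14")
}

#' Map atlas codes to segmentation classes for a scheme's merge mode
#'
#' @param scheme an \linkS4class{AtlasScheme}; its \code{mergeMode} selects
#'   the mapping.
#' @param labelVolume integer 3D array of atlas codes.
#' @return Integer 3D array of class indices (0 = background).
#' @export
mapToClasses <- function(labelVolume, scheme) {
  .applyLookup(labelVolume, scheme, mergeMode(scheme))
}

#' Swap left and right atlas codes
#'
#' Replaces every left-hemisphere code with its right partner and vice
#' versa (partners are the two codes of a family/side pairing: 11<->12,
#' 13<->14, 15<->16, 37<->38, 41<->42, 71<->72, 77<->78 for the default
#' atlas). Used to express mirror equivariance: mirroring a volume across
#' the symmetry plane together with a code swap leaves the family-merged
#' class map mirror-consistent.
#'
#' @inheritParams mergeSymmetric
#' @return Integer 3D array with hemisphere codes exchanged.
#' @export
swapHemisphereCodes <- function(labelVolume, scheme = defaultAtlas()) {
  tb <- roiTable(scheme)
  tb <- tb[order(tb$family, tb$code), ]
  # pair consecutive L/R rows within family in code order
  partner <- integer(0)
  for (fam in unique(tb$family)) {
    sub <- tb[tb$family == fam, ]
    L <- sort(sub$code[sub$side == "L"])
    R <- sort(sub$code[sub$side == "R"])
    partner[as.character(L)] <- R
    partner[as.character(R)] <- L
  }
  out <- labelVolume
  for (code in names(partner))
    out[labelVolume == as.integer(code)] <- partner[[code]]
  out
}
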