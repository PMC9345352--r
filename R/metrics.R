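#' Dice coefficient between two binary masks
#'
#' The region-overlap similarity \code{2|A n B| / (|A| + |B|)}.
#'
#' @param a,b logical (or 0/1) 3D arrays of identical shape.
#' @return Dice coefficient in [0, 1]. Both masks empty is undefined and
#'   raises an error.
#' @examples
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, 1, 1] <- TRUE
#' diceCoefficient(a, a)   # 1
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  a <- a != 0
  b <- b != 0
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0L)
    stop("Dice is undefined for two empty masks")
  2 * sum(a & b) / (sa + sb)
}

# surface voxels: mask voxels with at least one six-connected background
# neighbor; the array border counts as background
.surfaceVoxels <- function(m) {
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- m
  inner <- function(dx, dy, dz)
    pad[1L + dx + seq_len(d[1]), 1L + dy + seq_len(d[2]),
        1L + dz + seq_len(d[3])]
  interiorAll <- inner(1L, 0L, 0L) & inner(-1L, 0L, 0L) &
    inner(0L, 1L, 0L) & inner(0L, -1L, 0L) &
    inner(0L, 0L, 1L) & inner(0L, 0L, -1L)
  m & !interiorAll
}

#' Average surface distance between two masks
#'
#' Extracts the surface voxels of each mask (voxels with at least one
#' six-connected background neighbor, the array border counting as
#' background) and returns the directed mean over surface(A) of the
#' minimum Euclidean distance (in mm, via the voxel spacing) to surface(B).
#' The symmetric variant averages the two directed distances.
#'
#' @param a,b logical (or 0/1) 3D arrays of identical shape; both must be
#'   nonempty.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param symmetric average both directions (default FALSE: directed
#'   A -> B).
#' @return Distance in mm (0 for identical masks).
#' @export
averageSurfaceDistance <- function(a, b, spacing = c(1, 1, 1),
                                   symmetric = FALSE) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  if (any(spacing <= 0)) stop("spacing must be positive")
  a <- a != 0
  b <- b != 0
  if (!sum(a) || !sum(b)) stop("ASD needs two nonempty masks")
  sa <- which(.surfaceVoxels(a), arr.ind = TRUE) - 1L
  sb <- which(.surfaceVoxels(b), arr.ind = TRUE) - 1L
  dab <- cpp_mean_min_dist(sa, sb, as.numeric(spacing))
  if (!symmetric) return(dab)
  (dab + cpp_mean_min_dist(sb, sa, as.numeric(spacing))) / 2
}

#' Mean squared error
#'
#' \code{mean((y - yStar)^2)} between true and predicted scores.
#'
#' @param y true scores.
#' @param yStar predicted scores of the same length.
#' @return The mean squared error.
#' @export
meanSquaredError <- function(y, yStar) {
  if (length(y) != length(yStar)) stop("score vectors differ in length")
  if (!length(y)) stop("empty score vectors")
  mean((y - yStar)^2)
}

#' Per-class segmentation evaluation
#'
#' Dice and directed average surface distance for every foreground class of
#' a predicted class map against the reference.
#'
#' @param pred,ref integer 3D class maps (0 = background).
#' @param nClasses number of classes including background.
#' @param spacing voxel spacing in mm.
#' @return list with named vectors \code{dice} and \code{asd} (NA for
#'   classes empty in both maps or with an empty side).
#' @export
evaluateSegmentation <- function(pred, ref, nClasses,
                                 spacing = c(1, 1, 1)) {
  ks <- seq_len(nClasses - 1L)
  dice <- asd <- stats::setNames(rep(NA_real_, length(ks)), ks)
  for (k in ks) {
    p <- pred == k
    r <- ref == k
    if (sum(p) + sum(r) > 0) dice[as.character(k)] <- diceCoefficient(p, r)
    if (sum(p) > 0 && sum(r) > 0)
      asd[as.character(k)] <- averageSurfaceDistance(p, r, spacing)
  }
  list(dice = dice, asd = asd)
}

.ci95 <- function(x) {
  m <- mean(x)
  s <- if (length(x) > 1) sd(x) else 0
  h <- 1.96 * s / sqrt(length(x))
  c(mean = m, sd = s, lo = m - h, hi = m + h)
}

#' Resampled train/test evaluation with confidence intervals
#'
#' Repeats a full train/test cycle over independent seeded resamples and
#' summarizes every returned metric by its mean, standard deviation and
#' normal-approximation 95\% confidence interval \code{mean +/- 1.96 sd /
#' sqrt(n)}. When a second runner is given, metrics common to both are
#' additionally compared with a two-sided Mann-Whitney (Wilcoxon rank-sum)
#' test across resamples.
#'
#' @param runner function(resample index, seed) returning a named numeric
#'   vector of metrics for one train/test cycle.
#' @param nResamples number of resamples (>= 2).
#' @param seed base seed; resample i receives seed \code{seed + i}.
#' @param runner2 optional second runner to compare against.
#' @param asdVariant label recorded in the report.
#' @return An \linkS4class{EvalReport}; for a comparison the rank-sum
#'   p-values are stored in \code{attr(report, "comparison")}.
#' @export
resampledEval <- function(runner, nResamples = 5L, seed = 1L,
                          runner2 = NULL, asdVariant = "directed") {
  if (nResamples < 2L) stop("nResamples must be >= 2")
  run1 <- lapply(seq_len(nResamples), function(i) {
    r <- tryCatch(runner(i, seed + i), error = function(e)
      stop("runner failed at resample ", i, ": ", conditionMessage(e)))
    r
  })
  mets <- names(run1[[1]])
  M <- do.call(rbind, run1)
  summ <- do.call(rbind, lapply(mets, function(m) {
    s <- .ci95(M[, m])
    data.frame(metric = m, mean = s["mean"], sd = s["sd"], lo = s["lo"],
               hi = s["hi"], row.names = NULL)
  }))
  rep <- new("EvalReport", records = run1, summary = summ,
             perClassDice = numeric(0), perClassAsd = numeric(0),
             nResamples = as.integer(nResamples), asdVariant = asdVariant)
  if (!is.null(runner2)) {
    run2 <- lapply(seq_len(nResamples), function(i) runner2(i, seed + i))
    M2 <- do.call(rbind, run2)
    common <- intersect(mets, colnames(M2))
    pv <- vapply(common, function(m)
      suppressWarnings(wilcox.test(M[, m], M2[, m])$p.value), numeric(1))
    attr(rep, "comparison") <- list(records2 = run2,
                                    p_values = stats::setNames(pv, common))
  }
  rep
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON alongside a human-readable table in the
#' "a +/- b" / "(lo, hi)" format.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param path output JSON path; a sibling .txt table is written as well.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  obj <- list(n_resamples = report@nResamples,
              asd_variant = report@asdVariant,
              summary = report@summary,
              records = lapply(report@records, as.list),
              per_class_dice = as.list(report@perClassDice),
              per_class_asd_mm = as.list(report@perClassAsd))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- utils::capture.output(show(report))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}
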