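# Default structure templates: centers/radii as fractions of the grid edge,
# left-hemisphere side (mirror axis coordinate < 0.5); the right instance is
# the exact mirror. Intensity means are spaced 3 noise-sd apart so families
# are separable yet boundaries remain ambiguous at the voxel level.
.defaultFamilies <- function() {
  list(
    list(name = "frontal_gyrus", codesL = c(11L, 13L, 15L),
         codesR = c(12L, 14L, 16L),
         centers = rbind(c(0.30, 0.68, 0.58),
                         c(0.27, 0.55, 0.70),
                         c(0.30, 0.42, 0.62)),
         radii = rbind(c(0.070, 0.070, 0.070),
                       c(0.070, 0.070, 0.070),
                       c(0.070, 0.070, 0.070)),
         intensity = 0.55),
    list(name = "hippocampus", codesL = 37L, codesR = 38L,
         centers = rbind(c(0.30, 0.35, 0.40)),
         radii = rbind(c(0.070, 0.100, 0.070)),
         intensity = 0.70),
    list(name = "amygdala", codesL = 41L, codesR = 42L,
         centers = rbind(c(0.30, 0.57, 0.33)),
         radii = rbind(c(0.065, 0.065, 0.065)),
         intensity = 0.85),
    list(name = "caudate_nucleus", codesL = 71L, codesR = 72L,
         centers = rbind(c(0.34, 0.72, 0.40)),
         radii = rbind(c(0.060, 0.060, 0.090)),
         intensity = 1.00),
    list(name = "thalamus", codesL = 77L, codesR = 78L,
         centers = rbind(c(0.37, 0.50, 0.48)),
         radii = rbind(c(0.075, 0.075, 0.075)),
         intensity = 1.15))
}

#' Specify a symmetric synthetic-brain phantom
#'
#' Builds a \linkS4class{PhantomSpec} describing skull-stripped-T1-like
#' volumes: a smooth ellipsoidal brain envelope plus 14 mirrored
#' ellipsoidal ROIs (5 anatomical families; the frontal gyrus carries three
#' sub-structure pairs). Per subject, every family draws a shared scale
#' factor, each side a small additional scale and translation, intensities
#' receive additive Gaussian noise, and the scalar score is a linear (plus
#' optional quadratic) function of the normalized family volumes with
#' Gaussian noise.
#'
#' @param gridEdge grid edge in voxels (96 by default; 240 mimics the
#'   full-resolution acquisition grid).
#' @param families structure templates; see \code{.defaultFamilies} source.
#' @param mirrorAxis symmetry-plane axis (default 1).
#' @param jitter list: \code{scaleFamily} and \code{scaleSide} are half
#'   ranges of uniform relative scale jitter, \code{shift} the half range
#'   (voxels) of uniform per-side translation.
#' @param noiseSd additive intensity noise sd.
#' @param scoreModel list: per-family \code{weights} (applied to family
#'   volumes normalized to per-mille of the grid), \code{intercept},
#'   \code{quadratic} (coefficient on the sum of squared normalized
#'   volumes) and score noise sd \code{sigma}.
#' @param envelopeIntensity background brain-envelope intensity.
#' @param seed base seed combined with each subject's seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridEdge = 96L, families = .defaultFamilies(),
                        mirrorAxis = 1L,
                        jitter = list(scaleFamily = 0.15, scaleSide = 0.03,
                                      shift = 1.5),
                        noiseSd = 0.05,
                        scoreModel = list(
                          weights = c(frontal_gyrus = 1.5,
                                      hippocampus = 2.0, amygdala = 2.5,
                                      caudate_nucleus = 2.0,
                                      thalamus = 1.6),
                          intercept = 0, quadratic = 0, sigma = 2.0),
                        envelopeIntensity = 0.35, seed = 1L) {
  new("PhantomSpec", gridEdge = as.integer(gridEdge), families = families,
      envelope = list(center = c(0.5, 0.5, 0.5),
                      radii = c(0.44, 0.46, 0.44),
                      intensity = envelopeIntensity),
      mirrorAxis = as.integer(mirrorAxis), jitter = jitter,
      noiseSd = as.numeric(noiseSd), scoreModel = scoreModel,
      seed = as.integer(seed))
}

# ellipsoid voxel mask on a g^3 grid; center/radii in voxel units (1-based)
.ellipsoidMask <- function(g, center, radii) {
  ax <- seq_len(g)
  q <- lapply(1:3, function(a) ((ax - center[a]) / radii[a])^2)
  outer(outer(q[[1]], q[[2]], "+"), q[[3]], "+") <= 1
}

.insideEnvelope <- function(center, radii, env, g) {
  ec <- env$center * g
  er <- env$radii * g
  for (a in 1:3) {
    for (s in c(-1, 1)) {
      p <- center
      p[a] <- p[a] + s * radii[a]
      if (sum(((p - ec) / er)^2) > 1) return(FALSE)
    }
  }
  TRUE
}

#' Generate one phantom subject
#'
#' Renders the labeled volume, draws the score, and reports the true ROI
#' volumes. Fully reproducible: the RNG is seeded with a combination of the
#' spec seed and \code{subjectSeed}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param subjectSeed integer per-subject seed.
#' @return list with \code{vol} (a \linkS4class{LabeledVolume} whose labels
#'   carry atlas codes), \code{score}, \code{roiVolumes} (voxel counts per
#'   atlas code), and \code{familyVolumes} (per-mille of grid voxels, per
#'   family).
#' @export
generateSubject <- function(spec, subjectSeed = 1L) {
  validObject(spec)
  g <- spec@gridEdge
  mj <- spec@jitter
  for (attempt in 1:10) {
    set.seed((spec@seed * 1009L + subjectSeed * 7L + attempt - 1L) %%
               .Machine$integer.max)
    base <- array(0, c(g, g, g))
    labs <- array(0L, c(g, g, g))
    env <- spec@envelope
    envMask <- .ellipsoidMask(g, env$center * g, env$radii * g)
    base[envMask] <- env$intensity
    ok <- TRUE
    for (f in spec@families) {
      sFam <- runif(1, 1 - mj$scaleFamily, 1 + mj$scaleFamily)
      nSub <- length(f$codesL)
      for (i in seq_len(nSub)) {
        for (side in c("L", "R")) {
          sSide <- runif(1, 1 - mj$scaleSide, 1 + mj$scaleSide)
          shift <- runif(3, -mj$shift, mj$shift)
          ctr <- f$centers[i, ] * g
          if (side == "R") ctr[spec@mirrorAxis] <-
              (g + 1) - ctr[spec@mirrorAxis]
          ctr <- ctr + shift
          rad <- f$radii[i, ] * g * sFam * sSide
          if (any(ctr - rad < 1) || any(ctr + rad > g) ||
              !.insideEnvelope(ctr, rad, env, g)) {
            ok <- FALSE
            break
          }
          m <- .ellipsoidMask(g, ctr, rad)
          code <- if (side == "L") f$codesL[i] else f$codesR[i]
          labs[m] <- code
          base[m] <- f$intensity
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) break
  }
  if (!ok) stop("could not place all structures inside the grid/envelope ",
                "after 10 attempts; reduce the jitter ranges")
  intens <- base
  if (spec@noiseSd > 0) {
    inside <- base > 0
    intens[inside] <- intens[inside] +
      rnorm(sum(inside), 0, spec@noiseSd)
  }
  roiVolumes <- table(labs[labs != 0L])
  roiVolumes <- stats::setNames(as.numeric(roiVolumes),
                                names(roiVolumes))
  famVol <- vapply(spec@families, function(f)
    sum(roiVolumes[as.character(c(f$codesL, f$codesR))],
        na.rm = TRUE) / g^3 * 1000,
    numeric(1))
  names(famVol) <- vapply(spec@families, `[[`, character(1), "name")
  sm <- spec@scoreModel
  w <- sm$weights[names(famVol)]
  score <- sm$intercept + sum(w * famVol) +
    (sm$quadratic %||% 0) * sum(famVol^2) +
    rnorm(1, 0, sm$sigma)
  vol <- labeledVolume(intens, labs, spacing = c(1, 1, 1),
                       subjectId = sprintf("phantom%04d", subjectSeed))
  list(vol = vol, score = score, roiVolumes = roiVolumes,
       familyVolumes = famVol)
}

#' Generate a phantom cohort on disk
#'
#' Writes NIfTI image/label pairs and a CSV manifest (subject_id,
#' image_path, label_path, score) with stable ordering.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param n cohort size.
#' @param dir output directory (created if needed).
#' @param seed cohort seed; subject i uses subject seed \code{seed * 1000 +
#'   i}.
#' @return The manifest data.frame, invisibly; also written to
#'   \code{dir/manifest.csv}.
#' @export
generateCohort <- function(spec, n, dir, seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- generateSubject(spec, subjectSeed = seed * 1000L + i)
    id <- sprintf("sub%04d", i)
    imgPath <- file.path(dir, paste0(id, "_img.nii.gz"))
    labPath <- file.path(dir, paste0(id, "_lab.nii.gz"))
    v <- sub$vol
    v@subjectId <- id
    writeVolume(v, imgPath, labPath)
    rows[[i]] <- data.frame(subject_id = id, image_path = imgPath,
                            label_path = labPath, score = sub$score)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read / write a phantom specification as YAML
#'
#' \code{writePhantomSpec} serializes every generator parameter (including
#' the structure templates) to YAML; \code{readPhantomSpec} restores it.
#' Fields omitted from a hand-written YAML file fall back to the
#' \code{\link{phantomSpec}} defaults, so a minimal file may set only e.g.
#' \code{gridEdge}, \code{noiseSd} and \code{scoreModel$sigma}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param path YAML file path.
#' @return \code{readPhantomSpec} returns a \linkS4class{PhantomSpec};
#'   \code{writePhantomSpec} returns \code{path}, invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  fams <- lapply(spec@families, function(f)
    list(name = f$name, codesL = as.integer(f$codesL),
         codesR = as.integer(f$codesR),
         centers = apply(f$centers, 1, as.numeric, simplify = FALSE),
         radii = apply(f$radii, 1, as.numeric, simplify = FALSE),
         intensity = f$intensity))
  obj <- list(gridEdge = spec@gridEdge, mirrorAxis = spec@mirrorAxis,
              jitter = spec@jitter, noiseSd = spec@noiseSd,
              envelopeIntensity = spec@envelope$intensity,
              scoreModel = list(
                weights = as.list(spec@scoreModel$weights),
                intercept = spec@scoreModel$intercept,
                quadratic = spec@scoreModel$quadratic %||% 0,
                sigma = spec@scoreModel$sigma),
              seed = spec@seed, families = fams)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("gridEdge", "mirrorAxis", "noiseSd", "envelopeIntensity",
               "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$jitter)) args$jitter <- y$jitter
  if (!is.null(y$scoreModel)) {
    sm <- y$scoreModel
    sm$weights <- unlist(sm$weights)
    args$scoreModel <- sm
  }
  if (!is.null(y$families)) {
    args$families <- lapply(y$families, function(f)
      list(name = f$name, codesL = as.integer(unlist(f$codesL)),
           codesR = as.integer(unlist(f$codesR)),
           centers = do.call(rbind, lapply(f$centers, as.numeric)),
           radii = do.call(rbind, lapply(f$radii, as.numeric)),
           intensity = as.numeric(f$intensity)))
  }
  do.call(phantomSpec, args)
}

#' Generate a phantom cohort in memory
#'
#' Convenience for desk-scale experiments: returns the subjects as a list
#' without touching the filesystem.
#'
#' @inheritParams generateCohort
#' @return list with \code{vols} (list of \linkS4class{LabeledVolume}),
#'   \code{scores}, \code{familyVolumes} (matrix n x families).
#' @export
generateCohortInMemory <- function(spec, n, seed = 1L) {
  subs <- lapply(seq_len(n), function(i)
    generateSubject(spec, subjectSeed = seed * 1000L + i))
  list(vols = lapply(subs, `[[`, "vol"),
       scores = vapply(subs, `[[`, numeric(1), "score"),
       familyVolumes = do.call(rbind, lapply(subs, `[[`, "familyVolumes")))
}
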