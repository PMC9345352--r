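test_that("subjects are reproducible and carry exactly the atlas codes", {
  spec <- testPhantom()
  s1 <- generateSubject(spec, subjectSeed = 4L)
  s2 <- generateSubject(spec, subjectSeed = 4L)
  expect_identical(intensities(s1$vol), intensities(s2$vol))
  expect_identical(labelMap(s1$vol), labelMap(s2$vol))
  expect_identical(s1$score, s2$score)
  codes <- sort(unique(as.vector(labelMap(s1$vol))))
  expect_identical(setdiff(codes, 0L), atlasCodes(defaultAtlas()))
  s3 <- generateSubject(spec, subjectSeed = 5L)
  expect_false(identical(s1$score, s3$score))
})

test_that("zero jitter yields an exactly mirror-symmetric label map", {
  spec <- testPhantom(jitter = list(scaleFamily = 0, scaleSide = 0,
                                    shift = 0))
  sub <- generateSubject(spec, subjectSeed = 1L)
  lab <- labelMap(sub$vol)
  expect_identical(swapHemisphereCodes(mirrorX(lab)), lab)
  # merged-class Dice against the mirrored map is exactly 1 per family
  m <- mergeSymmetric(lab)
  for (k in 1:5)
    expect_equal(diceCoefficient(m == k, mirrorX(m) == k), 1)
})

test_that("mirror Dice decreases in expectation as jitter grows", {
  mirrorDice <- function(shift, n = 4) {
    spec <- testPhantom(jitter = list(scaleFamily = 0, scaleSide = 0.0,
                                      shift = shift))
    mean(vapply(seq_len(n), function(i) {
      m <- mergeSymmetric(labelMap(generateSubject(spec, i)$vol))
      mean(vapply(1:5, function(k)
        diceCoefficient(m == k, mirrorX(m) == k), numeric(1)))
    }, numeric(1)))
  }
  d0 <- mirrorDice(0)
  d1 <- mirrorDice(1.5)
  d2 <- mirrorDice(3)
  expect_equal(d0, 1)
  expect_gt(d0, d1)
  expect_gt(d1, d2)
})

test_that("a noiseless linear score is the weighted family-volume sum", {
  spec <- testPhantom(scoreModel = list(
    weights = c(frontal_gyrus = 1.5, hippocampus = 2, amygdala = 2.5,
                caudate_nucleus = 2, thalamus = 1.6),
    intercept = 10, quadratic = 0, sigma = 0))
  sub <- generateSubject(spec, subjectSeed = 6L)
  w <- spec@scoreModel$weights[names(sub$familyVolumes)]
  expect_equal(sub$score, 10 + sum(w * sub$familyVolumes),
               tolerance = 1e-10)
  # family volumes recompute from the emitted per-ROI voxel counts
  tb <- roiTable(defaultAtlas())
  for (fam in unique(tb$family)) {
    codes <- as.character(tb$code[tb$family == fam])
    expect_equal(unname(sub$familyVolumes[fam]),
                 sum(sub$roiVolumes[codes]) / spec@gridEdge^3 * 1000,
                 tolerance = 1e-10)
  }
})

test_that("cohorts on disk have stable manifests and round-trip", {
  spec <- testPhantom(gridEdge = 32L)
  d1 <- file.path(tempdir(), "coh1")
  d2 <- file.path(tempdir(), "coh2")
  m1 <- generateCohort(spec, 3, d1, seed = 2L)
  m2 <- generateCohort(spec, 3, d2, seed = 2L)
  expect_identical(nrow(m1), 3L)
  expect_identical(m1$score, m2$score)
  expect_identical(m1$subject_id, sprintf("sub%04d", 1:3))
  expect_true(all(file.exists(m1$image_path)))
  back <- readVolume(m1$image_path[2], m1$label_path[2])
  gen <- generateSubject(spec, subjectSeed = 2L * 1000L + 2L)
  expect_identical(labelMap(back), labelMap(gen$vol))
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("phantom specifications round-trip through YAML", {
  spec <- testPhantom(gridEdge = 40L, noiseSd = 0.07)
  f <- tempfile(fileext = ".yaml")
  writePhantomSpec(spec, f)
  back <- readPhantomSpec(f)
  expect_identical(back@gridEdge, spec@gridEdge)
  expect_identical(back@noiseSd, spec@noiseSd)
  expect_equal(back@scoreModel$weights, spec@scoreModel$weights)
  expect_equal(back@jitter, spec@jitter)
  expect_length(back@families, 5L)
  expect_equal(back@families[[2]]$centers, spec@families[[2]]$centers)
  # and an identical subject is generated from the restored spec
  s1 <- generateSubject(spec, 3L)
  s2 <- generateSubject(back, 3L)
  expect_identical(labelMap(s1$vol), labelMap(s2$vol))
  expect_identical(s1$score, s2$score)
  # a minimal hand-written file falls back to defaults
  f2 <- tempfile(fileext = ".yaml")
  writeLines(c("gridEdge: 32", "noiseSd: 0.01"), f2)
  mini <- readPhantomSpec(f2)
  expect_identical(mini@gridEdge, 32L)
  expect_identical(mini@noiseSd, 0.01)
  expect_length(mini@families, 5L)
  unlink(c(f, f2))
})

test_that("cohort score variance matches the generative closed form", {
  spec <- testPhantom(gridEdge = 40L)
  coh <- generateCohortInMemory(spec, 120, seed = 30L)
  # closed form: score = sum_f w_f V0_f s_f^3 (sL^3 + sR^3)/2 + noise, with
  # s_f ~ U(1-a, 1+a) per family, sL/sR ~ U(1-b, 1+b) per side, all
  # independent; V0_f is the analytic ellipsoid volume (per-mille of grid)
  a <- spec@jitter$scaleFamily
  b <- spec@jitter$scaleSide
  mU3 <- function(h) if (h == 0) 1 else ((1 + h)^4 - (1 - h)^4) / (8 * h)
  mU6 <- function(h) if (h == 0) 1 else ((1 + h)^7 - (1 - h)^7) / (14 * h)
  V0 <- vapply(spec@families, function(f)
    2 * sum(4 / 3 * pi * apply(f$radii, 1, prod)) * 1000, numeric(1))
  names(V0) <- vapply(spec@families, `[[`, character(1), "name")
  # E[(sL^3+sR^3)/2] = mU3(b); Var[(sL^3+sR^3)/2] = (mU6(b)-mU3(b)^2)/2
  mSide <- mU3(b)
  vSide <- (mU6(b) - mU3(b)^2) / 2
  mFam <- mU3(a)
  vFam <- mU6(a) - mU3(a)^2
  varV <- V0^2 * ((vFam + mFam^2) * (vSide + mSide^2) - (mFam * mSide)^2)
  w <- spec@scoreModel$weights[names(V0)]
  implied <- sum(w^2 * varV) + spec@scoreModel$sigma^2
  obs <- var(coh$scores)
  se <- implied * sqrt(2 / (length(coh$scores) - 1))
  expect_lt(abs(obs - implied), 3 * se)
})
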