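test_that("minimum bounding box is the tightest half-open box", {
  v <- array(0L, c(8, 8, 8))
  v[4, 5, 6] <- 1L
  bb <- minimumBoundingBox(v, 1L)
  expect_identical(unname(bb), cbind(c(3L, 4L, 5L), c(4L, 5L, 6L)))
  v2 <- array(0L, c(10, 10, 10))
  v2[3:6, 2:7, 5:6] <- 2L                       # filled 4 x 6 x 2 block
  bb2 <- minimumBoundingBox(v2, 2L)
  expect_identical(unname(bb2[, 2] - bb2[, 1]), c(4L, 6L, 2L))
  expect_error(minimumBoundingBox(v, 9L), "absent")
})

test_that("two-interpolation cube records lMax and hits the target edge", {
  lab <- array(0L, c(40, 40, 40))
  lab[6:15, 6:25, 6:35] <- 1L                   # 10 x 20 x 30 block
  vol <- labeledVolume(array(runif(40^3), c(40, 40, 40)), lab)
  cube <- extractMBC(vol, 1L, targetEdge = 16L)
  expect_identical(lMax(cube), 30L)             # longest edge of the box
  expect_identical(dim(cubeValues(cube)), c(16L, 16L, 16L))
  expect_identical(sourceClass(cube), 1L)
  expect_identical(unname(sourceBbox(cube)[, 2] - sourceBbox(cube)[, 1]),
                   c(10L, 20L, 30L))
})

test_that("cubic boxes make the two paths coincide; anisotropic ones differ", {
  set.seed(5)
  lab <- array(0L, c(24, 24, 24))
  lab[5:12, 7:14, 9:16] <- 1L                   # cubic 8^3 box
  vol <- labeledVolume(array(rnorm(24^3), c(24, 24, 24)), lab)
  c1 <- extractMBC(vol, 1L, 12L)
  c2 <- resizeDirect(vol, 1L, 12L)
  expect_equal(cubeValues(c1), cubeValues(c2), tolerance = 1e-12)
  # seeded ellipsoid with unequal axes: the interpolation orders differ
  lab2 <- array(0L, c(24, 24, 24))
  ax <- 1:24
  q <- outer(outer(((ax - 12) / 9)^2, ((ax - 12) / 5)^2, "+"),
             ((ax - 12) / 3)^2, "+")
  lab2[q <= 1] <- 1L
  vol2 <- labeledVolume(array(rnorm(24^3), c(24, 24, 24)), lab2)
  d1 <- extractMBC(vol2, 1L, 12L)
  d2 <- resizeDirect(vol2, 1L, 12L)
  expect_gt(max(abs(cubeValues(d1) - cubeValues(d2))), 1e-8)
  expect_identical(lMax(d1), lMax(d2))
})

test_that("constant ROIs map to constant cubes under either path", {
  lab <- array(0L, c(20, 20, 20))
  lab[3:8, 4:13, 5:9] <- 1L
  x <- array(0, c(20, 20, 20))
  x[lab == 1L] <- 2.5
  vol <- labeledVolume(x, lab)
  for (f in list(extractMBC, resizeDirect)) {
    cube <- f(vol, 1L, 10L, content = "masked_intensity")
    inner <- cubeValues(cube)[3:8, 3:8, 3:8]    # well inside the ROI
    expect_equal(unique(as.vector(round(inner, 10))), 2.5)
    bin <- f(vol, 1L, 10L, content = "binary")
    expect_true(all(cubeValues(bin) %in% c(0, 1)))
  }
  # raw-intensity content on a constant volume is exactly constant
  vol3 <- labeledVolume(array(1.2, c(20, 20, 20)), lab)
  cc <- extractMBC(vol3, 1L, 10L, content = "intensity")
  expect_equal(max(abs(cubeValues(cc) - 1.2)), 0, tolerance = 1e-12)
})

test_that("interpolation preserves value bounds", {
  set.seed(9)
  x <- array(runif(15 * 11 * 7, 2, 5), c(15, 11, 7))
  y <- resizeVolume(x, c(9, 13, 4))
  expect_gte(min(y), 2)
  expect_lte(max(y), 5)
  expect_identical(resizeVolume(x, dim(x)), x)   # same-shape identity
})

test_that("extraction is equivariant to integer translation of the ROI", {
  set.seed(13)
  core <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  place <- function(at) {
    x <- array(0, c(20, 20, 20))
    lab <- array(0L, c(20, 20, 20))
    x[at[1] + 1:5, at[2] + 1:6, at[3] + 1:4] <- core
    lab[at[1] + 1:5, at[2] + 1:6, at[3] + 1:4] <- 1L
    labeledVolume(x, lab)
  }
  a <- extractMBC(place(c(2, 3, 4)), 1L, 8L, content = "intensity")
  b <- extractMBC(place(c(9, 1, 11)), 1L, 8L, content = "intensity")
  expect_equal(cubeValues(a), cubeValues(b), tolerance = 1e-12)
})

test_that("cubes round-trip through NIfTI plus the JSON sidecar", {
  lab <- array(0L, c(20, 20, 20))
  lab[3:8, 4:13, 5:9] <- 1L
  vol <- labeledVolume(array(rnorm(20^3), c(20, 20, 20)), lab)
  cube <- extractMBC(vol, 1L, 10L)
  f <- tempfile(fileext = ".nii.gz")
  writeMBC(cube, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- readMBC(f)
  expect_equal(cubeValues(back), cubeValues(cube), tolerance = 1e-6)
  expect_identical(sourceClass(back), sourceClass(cube))
  expect_identical(unname(sourceBbox(back)), unname(sourceBbox(cube)))
  expect_identical(lMax(back), lMax(cube))
  unlink(c(f, paste0(f, ".json")))
})

test_that("family cubes cover all five families with pair-spanning boxes", {
  spec <- testPhantom()
  sub <- generateSubject(spec, subjectSeed = 2L)
  cubes <- familyMBCs(sub$vol, targetEdge = 12L)
  expect_named(cubes, c("frontal_gyrus", "hippocampus", "amygdala",
                        "caudate_nucleus", "thalamus"))
  g <- spec@gridEdge
  for (cb in cubes) {
    expect_identical(dim(cubeValues(cb)), c(12L, 12L, 12L))
    # the union box spans both hemispheres across the mirror plane
    expect_lt(sourceBbox(cb)[1, 1], g / 2)
    expect_gt(sourceBbox(cb)[1, 2], g / 2)
  }
  arr <- stackCubes(cubes)
  expect_identical(dim(arr), c(12L, 12L, 12L, 5L))
})
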