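# Finite-difference checks of every layer primitive; these underwrite the
# training loops, so they are deliberately strict.

fdGrad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a
ns <- asNamespace("segscore")

test_that("dense 3x3x3 convolution matches the loop oracle and its gradients", {
  set.seed(42)
  x <- array(rnorm(4 * 5 * 3 * 2), c(4, 5, 3, 2))
  Wm <- matrix(rnorm(3 * 54), 3, 54)
  b <- rnorm(3)
  y <- ns$.conv3Fw(x, Wm, b)
  expect_equal(y, naiveConv3(x, Wm, b), tolerance = 1e-12)
  loss <- function(y) sum(sin(y))
  bw <- ns$.conv3Bw(cos(y), x, Wm)
  expect_equal(bw$dx, fdGrad(function(z) loss(ns$.conv3Fw(z, Wm, b)), x),
               tolerance = 1e-6)
  expect_equal(bw$dW,
               fdGrad(function(w) loss(ns$.conv3Fw(x, matrix(w, 3), b)), Wm),
               tolerance = 1e-6)
  expect_equal(as.numeric(bw$db),
               as.numeric(fdGrad(function(bb) loss(ns$.conv3Fw(x, Wm, bb)),
                                 b)),
               tolerance = 1e-6)
  # cached-patch backward agrees with the recomputing one (double path)
  withr::local_options(segscore.fp32 = FALSE)
  fc <- ns$.conv3FwC(x, Wm, b)
  expect_equal(fc$y, y, tolerance = 1e-12)
  bwc <- ns$.conv3BwC(cos(y), fc, Wm)
  expect_equal(bwc$dx, bw$dx, tolerance = 1e-12)
  expect_equal(bwc$dW, bw$dW, tolerance = 1e-12)
})

test_that("the mixed-precision convolution path tracks the double path", {
  set.seed(46)
  x <- array(rnorm(6^3 * 3), c(6, 6, 6, 3))
  Wm <- matrix(rnorm(4 * 81), 4, 81)
  b <- rnorm(4)
  f32 <- withr::with_options(list(segscore.fp32 = TRUE),
                             ns$.conv3FwC(x, Wm, b))
  f64 <- withr::with_options(list(segscore.fp32 = FALSE),
                             ns$.conv3FwC(x, Wm, b))
  expect_equal(f32$y, f64$y, tolerance = 1e-5)
  dy <- array(rnorm(6^3 * 4), c(6, 6, 6, 4))
  b32 <- ns$.conv3BwC(dy, f32, Wm)
  b64 <- ns$.conv3BwC(dy, f64, Wm)
  expect_equal(b32$dx, b64$dx, tolerance = 1e-4)
  expect_equal(b32$dW, b64$dW, tolerance = 1e-4)
  expect_equal(b32$db, b64$db, tolerance = 1e-6)
})

test_that("depthwise dilated convolution matches the loop oracle and gradients", {
  set.seed(43)
  x <- array(rnorm(4 * 4 * 5 * 3), c(4, 4, 5, 3))
  Wd <- matrix(rnorm(27 * 3), 27, 3)
  b <- rnorm(3)
  y <- ns$.dwconvFw(x, Wd, b, 2)
  expect_equal(y, naiveDepthwise(x, Wd, b, 2), tolerance = 1e-12)
  loss <- function(y) sum(sin(y))
  bw <- ns$.dwconvBw(cos(y), x, Wd, 2)
  expect_equal(bw$dx, fdGrad(function(z) loss(ns$.dwconvFw(z, Wd, b, 2)), x),
               tolerance = 1e-6)
  expect_equal(bw$dW,
               fdGrad(function(w) loss(ns$.dwconvFw(x, matrix(w, 27), b, 2)),
                      Wd),
               tolerance = 1e-6)
})

test_that("pooling, transposed convolution and batch norm backpropagate", {
  set.seed(44)
  x <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  loss <- function(y) sum(sin(y))
  pf <- ns$.poolFw(x)
  expect_identical(dim(pf$y), c(2L, 2L, 2L, 2L))
  expect_equal(ns$.poolBw(cos(pf$y), pf$cache),
               fdGrad(function(z) loss(ns$.poolFw(z)$y), x),
               tolerance = 1e-6)
  W <- array(rnorm(8 * 2 * 3), c(8, 2, 3))
  b <- rnorm(3)
  uf <- ns$.upFw(x, W, b)
  expect_identical(dim(uf), c(8L, 8L, 8L, 3L))
  ub <- ns$.upBw(cos(uf), x, W)
  expect_equal(ub$dx, fdGrad(function(z) loss(ns$.upFw(z, W, b)), x),
               tolerance = 1e-6)
  expect_equal(ub$dW, fdGrad(function(w) loss(ns$.upFw(x, array(w, dim(W)),
                                                       b)), W),
               tolerance = 1e-6)
  g <- rnorm(2); be <- rnorm(2)
  bf <- ns$.bnFw(x, g, be, ns$.bnState(2), train = TRUE)
  bb <- ns$.bnBw(cos(bf$y), bf$cache, g)
  expect_equal(bb$dx,
               fdGrad(function(z) loss(ns$.bnFw(z, g, be, ns$.bnState(2),
                                                TRUE)$y), x),
               tolerance = 1e-5)
  expect_equal(as.numeric(bb$dgamma),
               as.numeric(fdGrad(function(gg) loss(ns$.bnFw(x, gg, be,
                 ns$.bnState(2), TRUE)$y), g)),
               tolerance = 1e-6)
})

test_that("nearest upsampling inverts pooling shapes and backpropagates", {
  set.seed(45)
  x <- array(rnorm(3^3 * 2), c(3, 3, 3, 2))
  y <- ns$.upNearestFw(x)
  expect_identical(dim(y), c(6L, 6L, 6L, 2L))
  expect_equal(y[2, 2, 2, ], x[1, 1, 1, ])
  dy <- array(rnorm(length(y)), dim(y))
  expect_equal(ns$.upNearestBw(dy, dim(x)),
               fdGrad(function(z) sum(ns$.upNearestFw(z) * dy), x),
               tolerance = 1e-6)
})

test_that("Adam drives a quadratic to its minimum", {
  P <- ns$.paramStore()
  P[["w"]] <- c(5, -3)
  st <- ns$.adamInit(P)
  for (i in 1:2000) {
    G <- ns$.zeroGrads(P)
    G[["w"]] <- 2 * (P[["w"]] - c(1, 2))
    ns$.adamStep(P, G, st, lr = 0.05)
  }
  expect_equal(as.numeric(P[["w"]]), c(1, 2), tolerance = 1e-3)
})
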