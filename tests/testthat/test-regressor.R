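ns <- asNamespace("segscore")

smallRegCfg <- function(edge = 8L, seed = 1L)
  regressorConfig(inputEdge = edge, inChannels = 2L,
                  convChannels = c(3L, 4L, 1L),
                  fcDims = c(edge^3, 16L, 8L), dropout = 0.2, seed = seed)

test_that("configuration arithmetic ties the flatten to the input edge", {
  cfg <- regressorConfig()
  expect_identical(flattenedFeatureLength(cfg), 262144L)
  expect_identical(cfg@fcDims[1], 262144L)
  expect_identical(cfg@convChannels, c(10L, 20L, 1L))
  expect_identical(cfg@dropout, 0.5)
  expect_error(regressorConfig(inputEdge = 32L,
                               fcDims = c(100L, 16L, 8L)),
               "must equal")
  expect_identical(flattenedFeatureLength(smallRegCfg(8L)), 512L)
})

test_that("forward returns one finite scalar and is deterministic in eval", {
  model <- buildRegressor(smallRegCfg())
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  y1 <- regressorForward(model, x)
  y2 <- regressorForward(model, x)
  expect_length(y1, 1L)
  expect_true(is.finite(y1))
  expect_identical(y1, y2)
})

test_that("zero weights with a bias reproduce the bias for any input", {
  model <- buildRegressor(smallRegCfg())
  for (nm in ls(model$P)) model$P[[nm]] <- model$P[[nm]] * 0
  model$P[["fc3/b"]] <- 1.25
  expect_equal(regressorForward(model, array(rnorm(8^3 * 2),
                                             c(8, 8, 8, 2))), 1.25)
  expect_equal(regressorForward(model, array(0, c(8, 8, 8, 2))), 1.25)
})

test_that("the regressor passes an end-to-end gradient check", {
  withr::local_options(segscore.fp32 = FALSE)
  set.seed(8)
  model <- buildRegressor(regressorConfig(inputEdge = 4L, inChannels = 2L,
                                          convChannels = c(2L, 3L, 1L),
                                          fcDims = c(64L, 8L, 4L),
                                          dropout = 0, seed = 2L))
  x <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
  yTrue <- 0.7
  lossAt <- function() (ns$.regFw(model, x, train = TRUE)$y - yTrue)^2
  G <- ns$.zeroGrads(model$P)
  fw <- ns$.regFw(model, x, train = TRUE)
  ns$.regBw(model, fw$cache, 2 * (fw$y - yTrue), G)
  eps <- 1e-6
  for (nm in c("conv1/W", "conv3/W", "bn2/g", "fc1/W", "fc2/b", "fc3/W")) {
    p <- model$P[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      orig <- p[i]
      model$P[[nm]][i] <- orig + eps; lp <- lossAt()
      model$P[[nm]][i] <- orig - eps; lm <- lossAt()
      model$P[[nm]][i] <- orig
      expect_equal(G[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4,
                   label = sprintf("analytic grad of %s[%d]", nm, i))
    }
  }
})

test_that("a constant-score dataset is learned to near-zero MSE", {
  set.seed(10)
  xs <- lapply(1:8, function(i) array(rnorm(8^3 * 2), c(8, 8, 8, 2)))
  ys <- rep(3, 8)
  model <- buildRegressor(smallRegCfg(seed = 3L))
  model <- trainRegressor(model, xs, ys, epochs = 60L, batchSize = 4L,
                          lr = 3e-3, valFrac = 0, seed = 5L)
  finalMse <- meanSquaredError(ys, predictScores(model, xs))
  expect_lt(finalMse, 0.05)   # far below any nonzero score variance
})

test_that("training beats the mean predictor on a volume-driven signal", {
  set.seed(11)
  # cubes whose filled-fraction carries the score
  mk <- function(r) {
    a <- array(0, c(8, 8, 8, 2))
    ax <- 1:8
    q <- outer(outer((ax - 4.5)^2, (ax - 4.5)^2, "+"), (ax - 4.5)^2, "+")
    a[, , , 1] <- (q <= r^2) * 1
    a[, , , 2] <- (q <= (0.8 * r)^2) * 1
    a
  }
  rs <- runif(24, 1.8, 3.6)
  xs <- lapply(rs, mk)
  ys <- 2 * rs + rnorm(24, 0, 0.05)
  model <- buildRegressor(smallRegCfg(seed = 6L))
  model <- trainRegressor(model, xs, ys, epochs = 80L, batchSize = 6L,
                          lr = 3e-3, valFrac = 0.2, seed = 7L)
  test <- 17:24
  preds <- predictScores(model, xs[test])
  mseModel <- meanSquaredError(ys[test], preds)
  mseMean <- meanSquaredError(ys[test], rep(mean(ys[1:16]), length(test)))
  expect_lt(mseModel, mseMean)
  # the evaluation matches an independent direct formula
  expect_equal(mseModel, sum((ys[test] - preds)^2) / length(test),
               tolerance = 1e-12)
})

test_that("training history reports per-epoch train/validation MSE", {
  set.seed(12)
  xs <- lapply(1:10, function(i) array(rnorm(4^3 * 2), c(4, 4, 4, 2)))
  ys <- rnorm(10)
  model <- buildRegressor(regressorConfig(inputEdge = 4L, inChannels = 2L,
                                          convChannels = c(2L, 3L, 1L),
                                          fcDims = c(64L, 8L, 4L),
                                          dropout = 0.2, seed = 2L))
  model <- trainRegressor(model, xs, ys, epochs = 5L, batchSize = 4L,
                          valFrac = 0.2, seed = 3L)
  expect_true(all(c("epoch", "train_mse", "val_mse") %in%
                    names(model$history)))
  expect_gte(nrow(model$history), 1L)
  expect_true(all(is.finite(model$history$train_mse)))
})
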