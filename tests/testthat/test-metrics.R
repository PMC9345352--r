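test_that("Dice matches direct set counts", {
  a <- array(FALSE, c(4, 4, 4))
  b <- a
  a[1:4, 1, 1] <- TRUE               # |A| = 4
  b[3:4, 1, 1] <- TRUE
  b[1:2, 2, 1] <- TRUE               # |B| = 4, overlap 2
  expect_equal(diceCoefficient(a, b), 0.5)
  expect_equal(diceCoefficient(a, a), 1)
  disj <- array(FALSE, c(4, 4, 4))
  disj[1, 4, 4] <- TRUE
  expect_equal(diceCoefficient(a, disj), 0)
  expect_error(diceCoefficient(a * 0, b * 0), "empty")
})

test_that("Dice is symmetric and axis-permutation invariant", {
  set.seed(3)
  for (r in 1:5) {
    a <- array(runif(6^3) < 0.3, c(6, 6, 6))
    b <- array(runif(6^3) < 0.3, c(6, 6, 6))
    if (sum(a) + sum(b) == 0) next
    expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))
    pm <- sample(1:3)
    expect_equal(diceCoefficient(aperm(a, pm), aperm(b, pm)),
                 diceCoefficient(a, b))
  }
})

test_that("directed ASD matches hand cases and scales with spacing", {
  a <- array(FALSE, c(8, 8, 8))
  b <- a
  a[2, 2, 2] <- TRUE
  b[5, 2, 2] <- TRUE                 # 3 voxels apart along x
  expect_equal(averageSurfaceDistance(a, b), 3)
  expect_equal(averageSurfaceDistance(a, a), 0)
  expect_equal(averageSurfaceDistance(a, b, spacing = c(2, 1, 1)), 6)
  expect_error(averageSurfaceDistance(a, a * 0), "nonempty")
})

test_that("ASD agrees with the brute-force pairwise oracle", {
  set.seed(21)
  for (r in 1:8) {
    a <- array(runif(8^3) < 0.25, c(8, 8, 8))
    b <- array(runif(8^3) < 0.25, c(8, 8, 8))
    if (!sum(a) || !sum(b)) next
    sp <- c(1, 1.3, 0.8)
    expect_equal(averageSurfaceDistance(a, b, sp), bruteASD(a, b, sp),
                 tolerance = 1e-12)
    sym <- averageSurfaceDistance(a, b, sp, symmetric = TRUE)
    expect_equal(sym, (bruteASD(a, b, sp) + bruteASD(b, a, sp)) / 2,
                 tolerance = 1e-12)
  }
})

test_that("MSE matches the definition and closed forms", {
  expect_equal(meanSquaredError(c(0, 2), c(1, 1)), 1)
  expect_equal(meanSquaredError(1:5, 1:5), 0)
  y <- rnorm(10)
  expect_equal(meanSquaredError(y, y + 3), 9)
  pm <- sample(10)
  expect_equal(meanSquaredError(y[pm], (y + 1)[pm]),
               meanSquaredError(y, y + 1))
  expect_error(meanSquaredError(1:3, 1:4), "length")
})

test_that("resampled evaluation reports mean, sd and a closed-form CI", {
  runner <- function(i, seed) {
    set.seed(seed)
    c(dice = 0.8 + 0.01 * rnorm(1), mse = 50 + rnorm(1))
  }
  rep5 <- resampledEval(runner, nResamples = 5L, seed = 10L)
  expect_identical(rep5@nResamples, 5L)
  expect_length(rep5@records, 5L)
  vals <- vapply(rep5@records, `[[`, numeric(1), "dice")
  s <- rep5@summary[rep5@summary$metric == "dice", ]
  expect_equal(s$mean, mean(vals))
  expect_equal(s$sd, sd(vals))
  expect_equal(s$lo, mean(vals) - 1.96 * sd(vals) / sqrt(5))
  expect_equal(s$hi, mean(vals) + 1.96 * sd(vals) / sqrt(5))
  # constant runner: sd 0, CI collapses to the point
  cst <- resampledEval(function(i, seed) c(m = 2), nResamples = 3L)
  expect_equal(cst@summary$sd, 0)
  expect_equal(cst@summary$lo, 2)
  expect_equal(cst@summary$hi, 2)
})

test_that("two runners are compared with a rank-sum test", {
  r1 <- function(i, seed) c(dice = 0.9 + 0.001 * i)
  r2 <- function(i, seed) c(dice = 0.5 + 0.001 * i)
  rep2 <- resampledEval(r1, nResamples = 4L, runner2 = r2)
  cmp <- attr(rep2, "comparison")
  expect_true(!is.null(cmp))
  expect_equal(unname(cmp$p_values["dice"]),
               wilcox.test(0.9 + 0.001 * (1:4),
                           0.5 + 0.001 * (1:4))$p.value)
})

test_that("evaluation reports serialize to JSON with the table mirror", {
  rep1 <- resampledEval(function(i, seed) c(mse = 1 + i), nResamples = 3L)
  f <- tempfile(fileext = ".json")
  writeEvalReport(rep1, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$n_resamples, 3)
  expect_true(file.exists(sub("\\.json$", ".txt", f)))
})
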