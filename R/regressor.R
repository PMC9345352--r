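#' Configure the volumetric score regressor
#'
#' Builds a \linkS4class{RegressorConfig}. The default mirrors the
#' full-size architecture: a 64^3 input with 5 channels (one cube per
#' anatomical family), three same-padded 3x3x3 convolution + batch-norm +
#' ReLU stages with 10, 20 and 1 channels, a flatten to 262,144 features,
#' and fully connected layers 262,144 -> 4096 -> 64 -> 1 with dropout 0.5
#' between them. \code{fcDims} defaults to the flattened size followed by
#' the stated hidden widths scaled to the input edge.
#'
#' @param inputEdge cube edge of the input (default 64).
#' @param inChannels input channels (default 5).
#' @param convChannels three conv-stage channel counts (default 10, 20, 1).
#' @param fcDims three fully connected sizes; the first must equal
#'   \code{inputEdge^3 * convChannels[3]}.
#' @param dropout dropout rate between fully connected layers.
#' @param seed weight-initialization seed.
#' @return A \linkS4class{RegressorConfig}.
#' @export
regressorConfig <- function(inputEdge = 64L, inChannels = 5L,
                            convChannels = c(10L, 20L, 1L),
                            fcDims = c(inputEdge^3 * convChannels[3],
                                       4096L, 64L),
                            dropout = 0.5, seed = 1L) {
  new("RegressorConfig", inputEdge = as.integer(inputEdge),
      inChannels = as.integer(inChannels),
      convChannels = as.integer(convChannels), fcDims = as.integer(fcDims),
      dropout = as.numeric(dropout), seed = as.integer(seed))
}

#' Flattened feature length of a regressor configuration
#'
#' The length of the vector entering the first fully connected layer:
#' \code{inputEdge^3 * convChannels[3]} (262,144 for the default 64^3
#' input with a single final conv channel).
#'
#' @param cfg a \linkS4class{RegressorConfig}.
#' @return Integer feature length.
#' @examples
#' flattenedFeatureLength(regressorConfig())   # 262144
#' @export
flattenedFeatureLength <- function(cfg) {
  as.integer(cfg@inputEdge^3 * cfg@convChannels[3])
}

#' Build the score regressor
#'
#' Allocates all parameters of the cube-to-score CNN described by a
#' \linkS4class{RegressorConfig}. Note the full-size default configuration
#' holds a ~10^9-element fully connected weight matrix; use a reduced
#' \code{inputEdge} for desk-scale work.
#'
#' @param cfg a \linkS4class{RegressorConfig}.
#' @return A list of class \code{"regressor"}.
#' @export
buildRegressor <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  cc <- cfg@convChannels
  fc <- cfg@fcDims
  P <- .paramStore()
  S <- new.env(parent = emptyenv())
  cin <- cfg@inChannels
  for (i in 1:3) {
    P[[sprintf("conv%d/W", i)]] <- .heInit(cc[i], cin, 27L)
    P[[sprintf("conv%d/b", i)]] <- numeric(cc[i])
    P[[sprintf("bn%d/g", i)]] <- rep(1, cc[i])
    P[[sprintf("bn%d/be", i)]] <- numeric(cc[i])
    S[[sprintf("bn%d", i)]] <- .bnState(cc[i])
    cin <- cc[i]
  }
  P[["fc1/W"]] <- matrix(rnorm(fc[1] * fc[2], sd = sqrt(2 / fc[1])),
                         fc[1], fc[2])
  P[["fc1/b"]] <- numeric(fc[2])
  P[["fc2/W"]] <- matrix(rnorm(fc[2] * fc[3], sd = sqrt(2 / fc[2])),
                         fc[2], fc[3])
  P[["fc2/b"]] <- numeric(fc[3])
  P[["fc3/W"]] <- matrix(rnorm(fc[3], sd = sqrt(1 / fc[3])), fc[3], 1L)
  P[["fc3/b"]] <- numeric(1L)
  structure(list(cfg = cfg, P = P, S = S), class = "regressor")
}

#' @export
print.regressor <- function(x, ...) {
  nPar <- sum(vapply(ls(x$P), function(nm) length(x$P[[nm]]), numeric(1)))
  cat(sprintf("regressor: %s parameters\n", format(nPar, big.mark = ",")))
  print(x$cfg)
  invisible(x)
}

.regFw <- function(model, x, train = FALSE) {
  P <- model$P
  cfg <- model$cfg
  ca <- list(x = x)
  cur <- x
  for (i in 1:3) {
    ca[[sprintf("in%d", i)]] <- cur
    cv <- .conv3FwC(cur, P[[sprintf("conv%d/W", i)]],
                    P[[sprintf("conv%d/b", i)]], dil = 1L)
    bn <- .bnFw(cv$y, P[[sprintf("bn%d/g", i)]],
                P[[sprintf("bn%d/be", i)]],
                model$S[[sprintf("bn%d", i)]], train)
    ca[[sprintf("cv%d", i)]] <- cv
    ca[[sprintf("bn%d", i)]] <- bn
    cur <- .reluFw(bn$y)
    ca[[sprintf("re%d", i)]] <- cur
  }
  flat <- as.numeric(cur)
  ca$flat <- flat
  h1 <- .fcFw(flat, P[["fc1/W"]], P[["fc1/b"]])
  r1 <- .reluFw(h1)
  dp1 <- .dropoutFw(r1, cfg@dropout, train)
  h2 <- .fcFw(dp1$y, P[["fc2/W"]], P[["fc2/b"]])
  r2 <- .reluFw(h2)
  dp2 <- .dropoutFw(r2, cfg@dropout, train)
  out <- .fcFw(dp2$y, P[["fc3/W"]], P[["fc3/b"]])
  ca$h1 <- h1; ca$dp1 <- dp1; ca$h2 <- h2; ca$dp2 <- dp2
  list(y = out, cache = ca)
}

.regBw <- function(model, cache, dy, G) {
  P <- model$P
  g3 <- .fcBw(dy, cache$dp2$y, P[["fc3/W"]])
  .addGrad(G, "fc3/W", g3$dW); .addGrad(G, "fc3/b", g3$db)
  d <- .dropoutBw(g3$dx, cache$dp2$mask)
  d <- .reluBw(d, cache$h2)
  g2 <- .fcBw(d, cache$dp1$y, P[["fc2/W"]])
  .addGrad(G, "fc2/W", g2$dW); .addGrad(G, "fc2/b", g2$db)
  d <- .dropoutBw(g2$dx, cache$dp1$mask)
  d <- .reluBw(d, cache$h1)
  g1 <- .fcBw(d, cache$flat, P[["fc1/W"]])
  .addGrad(G, "fc1/W", g1$dW); .addGrad(G, "fc1/b", g1$db)
  d <- array(g1$dx, dim(cache$re3))
  for (i in 3:1) {
    d <- .reluBw(d, cache[[sprintf("bn%d", i)]]$y)
    gb <- .bnBw(d, cache[[sprintf("bn%d", i)]]$cache,
                P[[sprintf("bn%d/g", i)]])
    .addGrad(G, sprintf("bn%d/g", i), gb$dgamma)
    .addGrad(G, sprintf("bn%d/be", i), gb$dbeta)
    gc <- .conv3BwC(gb$dx, cache[[sprintf("cv%d", i)]],
                    P[[sprintf("conv%d/W", i)]], dil = 1L)
    .addGrad(G, sprintf("conv%d/W", i), gc$dW)
    .addGrad(G, sprintf("conv%d/b", i), gc$db)
    d <- gc$dx
  }
  invisible(NULL)
}

#' Forward pass of the score regressor
#'
#' @param model a model from \code{\link{buildRegressor}}.
#' @param x numeric 4D array (edge, edge, edge, inChannels), e.g. from
#'   \code{\link{stackCubes}}.
#' @param train logical; enables dropout and batch statistics.
#' @return A single numeric score.
#' @export
regressorForward <- function(model, x, train = FALSE) {
  if (length(dim(x)) != 4L) stop("x must be a (E,E,E,C) array")
  .regFw(model, x, train = train)$y
}

#' Train the score regressor
#'
#' Minimizes mean squared error with Adam on minibatches; reports per-epoch
#' training and validation MSE and keeps the weights of the best validation
#' epoch (early stopping). Evaluation uses eval-mode semantics (dropout off,
#' running batch-norm statistics).
#'
#' @param model a model from \code{\link{buildRegressor}}.
#' @param xs list of input arrays (edge^3 x channels), one per subject.
#' @param ys numeric scores, one per subject.
#' @param epochs maximum epochs.
#' @param batchSize minibatch size.
#' @param lr Adam learning rate.
#' @param valFrac fraction of subjects held out for validation inside the
#'   training loop (0 disables early stopping).
#' @param patience epochs without validation improvement before stopping.
#' @param weightDecay decoupled (AdamW-style) weight decay applied to the
#'   convolution and fully connected weight matrices (not to biases or
#'   batch-norm parameters); 0 disables it.
#' @param augmentFlips randomly mirror each training input along each
#'   spatial axis (probability 1/2 per axis per presentation). Useful when
#'   the score is invariant to reflections of the cubes, as it is for
#'   bilaterally symmetric anatomy; effectively multiplies the training
#'   set eightfold.
#' @param seed RNG seed for shuffling, dropout and the validation split.
#' @param verbose print per-epoch losses.
#' @return The trained model, with \code{model$history} a data.frame of
#'   per-epoch train/validation MSE.
#' @export
trainRegressor <- function(model, xs, ys, epochs = 60L, batchSize = 8L,
                           lr = 1e-3, valFrac = 0.2, patience = 10L,
                           weightDecay = 0, augmentFlips = FALSE,
                           seed = 1L, verbose = FALSE) {
  n <- length(xs)
  if (n == 0L) stop("empty dataset")
  if (length(ys) != n) stop("xs and ys lengths differ")
  set.seed(seed)
  idx <- sample.int(n)
  nVal <- floor(valFrac * n)
  vi <- if (nVal > 0) idx[seq_len(nVal)] else integer(0)
  ti <- setdiff(idx, vi)
  # train on centered scores: the output bias would otherwise have to
  # crawl to the score mean at Adam-step speed
  model$yCenter <- mean(ys[ti])
  ys <- ys - model$yCenter
  st <- .adamInit(model$P)
  hist <- data.frame(epoch = integer(0), train_mse = numeric(0),
                     val_mse = numeric(0))
  best <- Inf
  bestP <- NULL
  bad <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(ti)
    sse <- 0
    for (start in seq(1, length(ord), by = batchSize)) {
      batch <- ord[start:min(start + batchSize - 1L, length(ord))]
      G <- .zeroGrads(model$P)
      for (j in batch) {
        xj <- xs[[j]]
        if (augmentFlips) {
          for (a in 1:3) if (runif(1) < 0.5) {
            idx <- rev(seq_len(dim(xj)[a]))
            xj <- switch(a, xj[idx, , , , drop = FALSE],
                         xj[, idx, , , drop = FALSE],
                         xj[, , idx, , drop = FALSE])
          }
        }
        fw <- .regFw(model, xj, train = TRUE)
        if (!is.finite(fw$y))
          stop("non-finite prediction during training (epoch ", ep, ")")
        err <- fw$y - ys[j]
        sse <- sse + err^2
        .regBw(model, fw$cache, 2 * err / length(batch), G)
      }
      .adamStep(model$P, G, st, lr = lr)
      if (weightDecay > 0) {
        for (nm in grep("/W$", ls(model$P), value = TRUE))
          model$P[[nm]] <- model$P[[nm]] * (1 - lr * weightDecay)
      }
    }
    trainMse <- sse / length(ord)
    valMse <- if (length(vi))
      mean((vapply(vi, function(j) .regFw(model, xs[[j]])$y, numeric(1)) -
              ys[vi])^2) else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_mse = trainMse,
                                   val_mse = valMse))
    if (verbose)
      message(sprintf("epoch %d  train MSE %.4f  val MSE %.4f", ep,
                      trainMse, valMse))
    if (length(vi)) {
      if (valMse < best - 1e-8) {
        best <- valMse
        bad <- 0L
        bestP <- mget(ls(model$P), envir = model$P)
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  }
  if (!is.null(bestP)) for (nm in names(bestP)) model$P[[nm]] <- bestP[[nm]]
  model$history <- hist
  model
}

#' Predict scores for a list of inputs
#'
#' @param model a trained regressor.
#' @param xs list of input arrays.
#' @param flipAverage average the prediction over all 8 axis reflections
#'   of each input (test-time counterpart of \code{augmentFlips}; a
#'   variance-reduction step for reflection-invariant targets).
#' @return Numeric vector of predicted scores.
#' @export
predictScores <- function(model, xs, flipAverage = FALSE) {
  one <- function(x) {
    if (!flipAverage)
      return(.regFw(model, x, train = FALSE)$y)
    tot <- 0
    for (fx in 0:1) for (fy in 0:1) for (fz in 0:1) {
      xi <- x
      if (fx) xi <- xi[rev(seq_len(dim(xi)[1])), , , , drop = FALSE]
      if (fy) xi <- xi[, rev(seq_len(dim(xi)[2])), , , drop = FALSE]
      if (fz) xi <- xi[, , rev(seq_len(dim(xi)[3])), , drop = FALSE]
      tot <- tot + .regFw(model, xi, train = FALSE)$y
    }
    tot / 8
  }
  vapply(xs, one, numeric(1)) + (model$yCenter %||% 0)
}
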