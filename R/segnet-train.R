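#' Forward pass of the segmentation network
#'
#' Runs one volume (or patch) through the network and returns the voxelwise
#' class probabilities. The input spatial dimensions must be divisible by
#' \code{2^(levels-1)}.
#'
#' @param net a model from \code{\link{buildSegNet}}.
#' @param x numeric 3D array (single channel) or 4D array (D, H, W, C).
#' @param train logical; training-mode batch-norm statistics when TRUE.
#' @return Numeric 4D array (D, H, W, nClasses) of probabilities summing to
#'   one at every voxel.
#' @export
segNetForward <- function(net, x, train = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  .segnetFw(net, x, train = train)$probs
}

#' Multi-class soft Dice loss
#'
#' Computes \code{1 - mean} over foreground classes of the soft Dice
#' coefficient \code{(2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)}
#' between predicted class probabilities and a one-hot target. The value
#' lies in [0, 1] and is 0 (to within eps) when the predictions are one-hot
#' equal to the target. Classes absent from both prediction and target
#' contribute a Dice of 1 (no loss), so patches missing some classes train
#' cleanly.
#'
#' @param predProbs numeric 4D array (D, H, W, nClasses) of voxelwise
#'   probabilities.
#' @param targetLabels integer 3D array of class indices 0..nClasses-1.
#' @param nClasses number of classes including background.
#' @param eps smoothing constant.
#' @param includeBackground also average the background class's soft Dice
#'   into the loss (default FALSE: foreground classes only, the reported
#'   metric; the training loop turns this on because the background term
#'   conditions early optimization much better).
#' @return The scalar loss.
#' @export
diceLoss <- function(predProbs, targetLabels, nClasses,
                     eps = 1e-5, includeBackground = FALSE) {
  .diceLossGrad(predProbs, targetLabels, nClasses, eps,
                includeBackground = includeBackground,
                wantGrad = FALSE)$loss
}

.diceLossGrad <- function(probs, target, nClasses, eps = 1e-5,
                          includeBackground = FALSE, wantGrad = TRUE) {
  d <- dim(probs)
  if (d[4] != nClasses) stop("probability channels != nClasses")
  if (!identical(dim(target), d[1:3]))
    stop("target shape does not match predictions")
  V <- prod(d[1:3])
  P <- matrix(probs, V, nClasses)
  tv <- as.integer(target)
  dP <- if (wantGrad) matrix(0, V, nClasses)
  total <- 0
  ks <- if (includeBackground) 0:(nClasses - 1L) else seq_len(nClasses - 1L)
  for (k in ks) {
    tk <- as.numeric(tv == k)
    pk <- P[, k + 1L]
    num <- 2 * sum(pk * tk) + eps
    den <- sum(pk) + sum(tk) + eps
    total <- total + num / den
    if (wantGrad)
      dP[, k + 1L] <- -(2 * tk * den - num) / (den * den) / length(ks)
  }
  list(loss = 1 - total / length(ks),
       dprobs = if (wantGrad) array(dP, d))
}

#' Train the segmentation network on labeled volumes
#'
#' Patch-based training: each iteration draws \code{batchSize} random cubic
#' patches (uniform origins, unconditioned on labels by default) from
#' randomly chosen subjects, runs forward/backward with the multi-class
#' soft Dice loss, and applies one Adam step on the averaged gradients.
#'
#' @param net a model from \code{\link{buildSegNet}}.
#' @param vols list of \linkS4class{LabeledVolume}s whose label maps hold
#'   class indices 0..nClasses-1 (see \code{\link{mapToClasses}}).
#' @param iterations number of optimization steps.
#' @param batchSize patches per step.
#' @param patchEdge cubic patch edge; must be divisible by
#'   \code{2^(levels-1)}.
#' @param lr Adam learning rate; either a scalar or a vector that is
#'   recycled to one value per iteration (a piecewise-constant decay
#'   schedule).
#' @param seed RNG seed for patch sampling.
#' @param requireForeground redraw patches until they contain a foreground
#'   voxel (default FALSE: sampling follows the plain uniform scheme).
#' @param restartOnCollapse multi-class soft-Dice training occasionally
#'   lets one small class collapse (never predicted) at an unlucky
#'   initialization. When TRUE, the trained net is checked by predicting a
#'   training volume; if any foreground class is absent the net is rebuilt
#'   with a shifted initialization seed and retrained once.
#' @param verbose print the running loss every 10 iterations.
#' @return The trained net, with the per-iteration Dice-loss history in
#'   \code{net$history}.
#' @export
trainSegNet <- function(net, vols, iterations = 100L, batchSize = 2L,
                        patchEdge = 32L, lr = 1e-3, seed = 1L,
                        requireForeground = FALSE,
                        restartOnCollapse = FALSE, verbose = FALSE) {
  K <- net$cfg@nClasses
  for (v in vols) if (is.null(labelMap(v)))
    stop("all training volumes need label maps")
  set.seed(seed)
  st <- .adamInit(net$P)
  history <- numeric(iterations)
  lrVec <- rep_len(lr, iterations)
  nv <- length(vols)
  for (it in seq_len(iterations)) {
    G <- .zeroGrads(net$P)
    lossAcc <- 0
    for (b in seq_len(batchSize)) {
      vi <- sample.int(nv, 1L)
      vol <- vols[[vi]]
      d <- dim(intensities(vol))
      for (try in 1:50) {
        o <- vapply(d - patchEdge, function(m) sample.int(m + 1L, 1L) - 1L,
                    integer(1))
        idx <- lapply(1:3, function(a) o[a] + seq_len(patchEdge))
        lab <- labelMap(vol)[idx[[1]], idx[[2]], idx[[3]]]
        if (!requireForeground || any(lab != 0L)) break
      }
      x <- intensities(vol)[idx[[1]], idx[[2]], idx[[3]]]
      dim(x) <- c(dim(x), 1L)
      fw <- .segnetFw(net, x, train = TRUE)
      # optimize with the background term included (better conditioned);
      # the history reports the foreground-only Dice loss, i.e. the metric
      lg <- .diceLossGrad(fw$probs, lab, K, includeBackground = TRUE)
      lossAcc <- lossAcc + .diceLossGrad(fw$probs, lab, K,
                                         wantGrad = FALSE)$loss
      .segnetBw(net, fw$cache, lg$dprobs, G)
    }
    for (nm in ls(G)) G[[nm]] <- G[[nm]] / batchSize
    .adamStep(net$P, G, st, lr = lrVec[it])
    history[it] <- lossAcc / batchSize
    if (verbose && it %% 10L == 0L)
      message(sprintf("iter %d  dice loss %.4f", it,
                      mean(tail(history[seq_len(it)], 10L))))
  }
  net$history <- c(net$history, history)
  if (restartOnCollapse) {
    predTrain <- predictSegmentation(net, vols[[1]],
                                     patchEdge = patchEdge, overlap = 0)
    missing <- setdiff(seq_len(K - 1L), unique(as.vector(predTrain)))
    if (length(missing)) {
      message("class(es) ", paste(missing, collapse = ", "),
              " collapsed during training; retraining from a fresh ",
              "initialization")
      cfg2 <- net$cfg
      cfg2@seed <- cfg2@seed + 1000L
      net2 <- buildSegNet(cfg2)
      net <- trainSegNet(net2, vols, iterations = iterations,
                         batchSize = batchSize, patchEdge = patchEdge,
                         lr = lr, seed = seed + 1000L,
                         requireForeground = requireForeground,
                         restartOnCollapse = FALSE, verbose = verbose)
    }
  }
  net
}

#' Whole-volume inference by sliding-window tiling
#'
#' Predicts a class map for a full volume by tiling it with windows of the
#' training patch size, averaging class probabilities where windows
#' overlap, and taking the voxelwise argmax.
#'
#' @param net a trained model.
#' @param vol a \linkS4class{LabeledVolume} (labels ignored).
#' @param patchEdge window edge.
#' @param overlap fraction of window overlap between neighboring tiles
#'   (default 0.5); the last window along each axis is shifted flush with
#'   the volume edge.
#' @return Integer 3D array of predicted class indices 0..nClasses-1.
#' @export
predictSegmentation <- function(net, vol, patchEdge = 32L, overlap = 0.5) {
  x <- intensities(vol)
  d <- dim(x)
  stride <- max(1L, as.integer(round(patchEdge * (1 - overlap))))
  starts <- lapply(d, function(n) {
    s <- unique(c(seq.int(0L, n - patchEdge, by = stride), n - patchEdge))
    s[s >= 0L]
  })
  K <- net$cfg@nClasses
  acc <- array(0, c(d, K))
  cnt <- array(0, d)
  for (ox in starts[[1]]) for (oy in starts[[2]]) for (oz in starts[[3]]) {
    ix <- ox + seq_len(patchEdge)
    iy <- oy + seq_len(patchEdge)
    iz <- oz + seq_len(patchEdge)
    p <- x[ix, iy, iz]
    dim(p) <- c(dim(p), 1L)
    pr <- .segnetFw(net, p, train = FALSE)$probs
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, ] + pr
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  # voxelwise argmax of the overlap-averaged probabilities
  flat <- matrix(acc, prod(d), K) / as.vector(cnt)
  array(max.col(flat, ties.method = "first") - 1L, d)
}

#' Static shape trace of the segmentation network
#'
#' Computes, without allocating any tensors, the spatial edge and channel
#' count of every named stage of the network for a cubic input, so
#' architectural pins (stem width, level-1 recombination width, the
#' bottleneck-skip projection width at quarter resolution) can be checked
#' directly against a configuration.
#'
#' @param cfg a \linkS4class{SegNetConfig}.
#' @param inputEdge cubic input edge.
#' @return data.frame with columns \code{stage}, \code{edge},
#'   \code{channels}.
#' @examples
#' tr <- segNetShapeTrace(segNetConfig(), 112)
#' subset(tr, stage == "stem")          # 16 channels at 112
#' subset(tr, stage == "bottleneck_skip_projection")  # 96 channels at 28
#' @export
segNetShapeTrace <- function(cfg, inputEdge = 112L) {
  L <- cfg@levels
  ch <- cfg@channelSchedule
  rows <- list()
  add <- function(stage, edge, channels)
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage, edge = edge,
                                             channels = channels)
  e <- as.integer(inputEdge)
  add("input", e, cfg@inChannels)
  add("stem", e, cfg@stemChannels)
  encIn <- c(cfg@stemChannels, ch[seq_len(L - 2L)])
  for (i in seq_len(L - 1L)) {
    add(sprintf("encoder%d_recombination", i), e, ch[i])
    e <- e %/% 2L
    add(sprintf("pool%d", i), e, ch[i])
  }
  add("bottleneck", e, ch[L])
  add("bottleneck_skip_projection", e * 2L, ch[L - 1L])
  for (i in rev(seq_len(L - 1L))) {
    e <- e * 2L
    add(sprintf("upsample%d", i), e, ch[i])
    add(sprintf("decoder%d_recombination", i), e, ch[i])
  }
  add("head", e, cfg@nClasses)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
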