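#' Configure the improved 3D U-Net
#'
#' Builds a \linkS4class{SegNetConfig}. The default architecture has four
#' resolution levels including the bottleneck: a 1x1x1 stem to 16 channels,
#' a recombination block to 32 channels at full resolution, channel schedule
#' (32, 64, 96, 128) over the levels, 2x max-pool downsampling, transposed
#' convolution upsampling, additive skip connections after 1x1x1 projection
#' at every resolution, and an extra bottleneck skip at quarter resolution
#' that projects the 64-channel tensor entering the deepest encoder level to
#' 96 channels. The head is a 1x1x1 convolution to \code{nClasses} followed
#' by a voxelwise softmax.
#'
#' @param inChannels input channels (1 for a single MRI contrast).
#' @param nClasses output classes including background (6 for the
#'   symmetric 5-family scheme, 15 for the per-ROI scheme).
#' @param levels resolution levels including the bottleneck.
#' @param stemChannels channels of the stem convolution.
#' @param channelSchedule one output-channel count per level.
#' @param expansion inner-width multiplier of the recombination block (the
#'   residual path widens C to \code{expansion * C}).
#' @param dilationRate dilation of the attention block's 3x3x3 kernel.
#' @param seGate gate applied to the attention weight map: \code{"linear"}
#'   (none; the literal form) or \code{"sigmoid"}.
#' @param upsample \code{"transposed"} (2x2x2 transposed convolution) or
#'   \code{"nearest"} (nearest-neighbor upsampling plus 1x1x1 projection).
#' @param seed weight-initialization seed.
#' @return A \linkS4class{SegNetConfig}.
#' @export
segNetConfig <- function(inChannels = 1L, nClasses = 6L, levels = 4L,
                         stemChannels = 16L,
                         channelSchedule = c(32L, 64L, 96L, 128L),
                         expansion = 4L, dilationRate = 2L,
                         seGate = c("linear", "sigmoid"),
                         upsample = c("transposed", "nearest"), seed = 1L) {
  new("SegNetConfig", inChannels = as.integer(inChannels),
      nClasses = as.integer(nClasses), levels = as.integer(levels),
      stemChannels = as.integer(stemChannels),
      channelSchedule = as.integer(channelSchedule),
      expansion = as.integer(expansion),
      dilationRate = as.integer(dilationRate),
      seGate = match.arg(seGate), upsample = match.arg(upsample),
      seed = as.integer(seed))
}

# ---- squeeze-and-excitation attention with dilated convolution ----

#' Parameters of a squeeze-and-excitation attention block
#'
#' Allocates the parameter set of \code{\link{segsEBlock}} for \code{C}
#' channels: one 3x3x3 dilated kernel per input channel (depthwise), and C
#' pointwise 1x1x1 kernels mixing the dilated output back to C channels.
#' With \code{init = "passthrough"} the dilated kernels and pointwise
#' weights are zero and the pointwise bias is one, so the weight map is all
#' ones and the block is the identity under the linear gate.
#'
#' @param C number of channels.
#' @param init \code{"passthrough"} or \code{"random"} (He-scaled draws
#'   from the current RNG stream).
#' @return A list with \code{Wd} (27 x C depthwise kernels), \code{bd},
#'   \code{Wp} (C x C pointwise mixing), \code{bp}.
#' @export
segsEParams <- function(C, init = c("passthrough", "random")) {
  init <- match.arg(init)
  if (init == "passthrough") {
    list(Wd = matrix(0, 27, C), bd = numeric(C),
         Wp = matrix(0, C, C), bp = rep(1, C))
  } else {
    list(Wd = matrix(rnorm(27 * C, sd = sqrt(2 / 27)), 27, C),
         bd = numeric(C),
         Wp = matrix(rnorm(C * C, sd = sqrt(2 / C)), C, C),
         bp = numeric(C))
  }
}

#' Squeeze-and-excitation attention block with dilated convolution
#'
#' Computes the attention unit: a depthwise 3x3x3 dilated convolution (one
#' kernel per channel, "same" padding) produces U; a 1x1x1 channel-wise
#' convolution of U produces the weight map W with C channels; W is
#' optionally squashed through a sigmoid; the output is the Hadamard
#' product W * X. Spatial shape and channel count are preserved.
#'
#' @param x numeric 4D array (D, H, W, C).
#' @param params parameter list from \code{\link{segsEParams}}.
#' @param dilation dilation rate of the depthwise kernel (default 2).
#' @param gate \code{"linear"} or \code{"sigmoid"}.
#' @return Numeric 4D array of the same shape as \code{x}.
#' @examples
#' x <- array(rnorm(4^3 * 2), c(4, 4, 4, 2))
#' identical(segsEBlock(x, segsEParams(2)), x)   # passthrough gate
#' @export
segsEBlock <- function(x, params, dilation = 2L,
                       gate = c("linear", "sigmoid")) {
  gate <- match.arg(gate)
  if (length(dim(x)) != 4L) stop("x must be a (D,H,W,C) array")
  if (ncol(params$Wd) != dim(x)[4])
    stop("channel mismatch: x has ", dim(x)[4], " channels, params have ",
         ncol(params$Wd))
  .segsEFwList(x, params, dilation, gate)$y
}

.segsEFwList <- function(x, p, dilation, gate) {
  u <- .dwconvFw(x, p$Wd, p$bd, dilation)
  wpre <- .conv1Fw(u, p$Wp, p$bp)
  w <- if (gate == "sigmoid") .sigmoid(wpre) else wpre
  list(y = w * x, u = u, w = w)
}

.segsEBwList <- function(dy, cache, x, p, dilation, gate) {
  dw <- dy * x
  dx1 <- dy * cache$w
  if (gate == "sigmoid") dw <- dw * cache$w * (1 - cache$w)
  cb <- .conv1Bw(dw, cache$u, p$Wp)
  db <- .dwconvBw(cb$dx, x, p$Wd, dilation)
  list(dx = dx1 + db$dx, dWd = db$dW, dbd = db$db, dWp = cb$dW,
       dbp = cb$db)
}

# ---- recombination block ----

#' Parameters of a recombination block
#'
#' Allocates the residual unit's parameters for input width \code{C} and
#' output width \code{Cout}: a 1x1x1 expansion to \code{expansion * C}
#' channels, a 3x3x3 convolution with batch normalization at that width, a
#' ReLU, an attention block, a 1x1x1 reduction to \code{Cout}, and a 1x1x1
#' shortcut projection from the input to \code{Cout}. Weights are He-scaled
#' draws from the current RNG stream; the attention gate starts as a
#' passthrough.
#'
#' @param C input channels.
#' @param Cout output channels.
#' @param expansion inner-width multiplier (default 4).
#' @return A named parameter list; the batch-norm running state is attached
#'   as attribute \code{"bnState"}.
#' @details Initialization is variance-preserving: the shortcut projection
#'   uses Xavier scaling, the residual path's final 1x1x1 reduction starts
#'   at zero (so every block begins as its shortcut projection and the
#'   network's trunk keeps unit gain at any depth), and the attention gate
#'   starts as a passthrough. Without this the stacked residual sums
#'   amplify activations exponentially with depth and the softmax head
#'   saturates at initialization.
#' @export
recombinationParams <- function(C, Cout, expansion = 4L) {
  e <- expansion * C
  p <- list(
    W2 = matrix(rnorm(C * e, sd = sqrt(2 / C)), C, e), b2 = numeric(e),
    W3 = .heInit(e, e, 27L), b3 = numeric(e),
    g3 = rep(1, e), be3 = numeric(e),
    seWd = matrix(0, 27, e), sebd = numeric(e),
    seWp = matrix(0, e, e), sebp = rep(1, e),
    W6 = matrix(0, e, Cout),
    b6 = numeric(Cout),
    W7 = matrix(rnorm(C * Cout, sd = sqrt(1 / C)), C, Cout),
    b7 = numeric(Cout))
  attr(p, "bnState") <- .bnState(e)
  p
}

#' Recombination block (residual unit with attention)
#'
#' Applies the residual mapping: 1x1x1 expansion, 3x3x3 convolution with
#' batch normalization, ReLU, squeeze-and-excitation attention, 1x1x1
#' reduction; the result is added element-wise to a 1x1x1 shortcut
#' projection of the input. Spatial shape is preserved; the output has
#' \code{Cout} channels. If every residual-path weight is zero the block
#' reduces exactly to the shortcut projection.
#'
#' @param x numeric 4D array (D, H, W, C).
#' @param params parameter list from \code{\link{recombinationParams}}.
#' @param dilation dilation rate of the attention kernel.
#' @param gate attention gate, \code{"linear"} or \code{"sigmoid"}.
#' @param train logical; training-mode batch statistics when \code{TRUE}.
#' @return Numeric 4D array (D, H, W, Cout).
#' @export
recombinationBlock <- function(x, params, dilation = 2L,
                               gate = c("linear", "sigmoid"),
                               train = TRUE) {
  gate <- match.arg(gate)
  if (length(dim(x)) != 4L) stop("x must be a (D,H,W,C) array")
  st <- attr(params, "bnState") %||% .bnState(length(params$b3))
  .recombFwList(x, params, st, dilation, gate, train)$y
}

.recombFwList <- function(x, p, bnState, dilation, gate, train) {
  b2 <- .conv1Fw(x, p$W2, p$b2)
  c3 <- .conv3FwC(b2, p$W3, p$b3, dil = 1L)
  bn <- .bnFw(c3$y, p$g3, p$be3, bnState, train)
  b4 <- .reluFw(bn$y)
  se <- .segsEFwList(b4, list(Wd = p$seWd, bd = p$sebd, Wp = p$seWp,
                              bp = p$sebp), dilation, gate)
  b6 <- .conv1Fw(se$y, p$W6, p$b6)
  b7 <- .conv1Fw(x, p$W7, p$b7)
  list(y = b6 + b7, x = x, b2 = b2, c3 = c3, bn = bn, b4 = b4, se = se)
}

.recombBwList <- function(dy, cache, p, dilation, gate) {
  g6 <- .conv1Bw(dy, cache$se$y, p$W6)
  g7 <- .conv1Bw(dy, cache$x, p$W7)
  gse <- .segsEBwList(g6$dx, cache$se, cache$b4,
                      list(Wd = p$seWd, bd = p$sebd, Wp = p$seWp,
                           bp = p$sebp), dilation, gate)
  drelu <- .reluBw(gse$dx, cache$bn$y)
  gbn <- .bnBw(drelu, cache$bn$cache, p$g3)
  g3 <- .conv3BwC(gbn$dx, cache$c3, p$W3, dil = 1L)
  g2 <- .conv1Bw(g3$dx, cache$x, p$W2)
  list(dx = g2$dx + g7$dx,
       grads = list(W2 = g2$dW, b2 = g2$db, W3 = g3$dW, b3 = g3$db,
                    g3 = gbn$dgamma, be3 = gbn$dbeta,
                    seWd = gse$dWd, sebd = gse$dbd,
                    seWp = gse$dWp, sebp = gse$dbp,
                    W6 = g6$dW, b6 = g6$db, W7 = g7$dW, b7 = g7$db))
}

# store a recombination block's parameters under a prefix in the flat store
.recombInto <- function(P, S, pre, C, Cout, expansion) {
  p <- recombinationParams(C, Cout, expansion)
  for (nm in names(p)) P[[paste0(pre, nm)]] <- p[[nm]]
  S[[pre]] <- attr(p, "bnState")
  invisible(NULL)
}

.recombView <- function(P, pre) {
  list(W2 = P[[paste0(pre, "W2")]], b2 = P[[paste0(pre, "b2")]],
       W3 = P[[paste0(pre, "W3")]], b3 = P[[paste0(pre, "b3")]],
       g3 = P[[paste0(pre, "g3")]], be3 = P[[paste0(pre, "be3")]],
       seWd = P[[paste0(pre, "seWd")]], sebd = P[[paste0(pre, "sebd")]],
       seWp = P[[paste0(pre, "seWp")]], sebp = P[[paste0(pre, "sebp")]],
       W6 = P[[paste0(pre, "W6")]], b6 = P[[paste0(pre, "b6")]],
       W7 = P[[paste0(pre, "W7")]], b7 = P[[paste0(pre, "b7")]])
}

.recombGradsInto <- function(G, pre, grads) {
  for (nm in names(grads)) .addGrad(G, paste0(pre, nm), grads[[nm]])
}

# ---- network construction ----

#' Build the segmentation network
#'
#' Allocates all parameters of the encoder-decoder described by a
#' \linkS4class{SegNetConfig} and returns the model object used by
#' \code{\link{segNetForward}}, \code{\link{trainSegNet}} and
#' \code{\link{predictSegmentation}}.
#'
#' @param cfg a \linkS4class{SegNetConfig}.
#' @return A list of class \code{"segnet"} holding the parameter store, the
#'   batch-norm running state, and the configuration.
#' @export
buildSegNet <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  L <- cfg@levels
  ch <- cfg@channelSchedule
  s <- cfg@stemChannels
  ex <- cfg@expansion
  P <- .paramStore()
  S <- new.env(parent = emptyenv())
  P[["stem/W"]] <- matrix(rnorm(cfg@inChannels * s,
                                sd = sqrt(1 / cfg@inChannels)),
                          cfg@inChannels, s)
  P[["stem/b"]] <- numeric(s)
  encIn <- integer(L - 1L)
  for (i in seq_len(L - 1L)) {
    encIn[i] <- if (i == 1L) s else ch[i - 1L]
    .recombInto(P, S, sprintf("enc%d/", i), encIn[i], ch[i], ex)
  }
  .recombInto(P, S, "bott/", ch[L - 1L], ch[L], ex)
  for (i in seq_len(L - 1L)) {
    cin <- ch[i + 1L]
    if (cfg@upsample == "transposed") {
      P[[sprintf("up%d/W", i)]] <- array(rnorm(8 * cin * ch[i],
                                               sd = sqrt(1 / cin)),
                                         c(8L, cin, ch[i]))
    } else {
      P[[sprintf("up%d/W", i)]] <- matrix(rnorm(cin * ch[i],
                                                sd = sqrt(1 / cin)),
                                          cin, ch[i])
    }
    P[[sprintf("up%d/b", i)]] <- numeric(ch[i])
    P[[sprintf("skip%d/W", i)]] <- matrix(rnorm(ch[i] * ch[i],
                                                sd = sqrt(1 / ch[i])),
                                          ch[i], ch[i])
    P[[sprintf("skip%d/b", i)]] <- numeric(ch[i])
    .recombInto(P, S, sprintf("dec%d/", i), ch[i], ch[i], ex)
  }
  bin <- encIn[L - 1L]   # channels entering the deepest encoder level
  P[["bskip/W"]] <- matrix(rnorm(bin * ch[L - 1L], sd = sqrt(1 / bin)),
                           bin, ch[L - 1L])
  P[["bskip/b"]] <- numeric(ch[L - 1L])
  # small head init keeps the softmax near-uniform at initialization
  P[["head/W"]] <- matrix(rnorm(ch[1] * cfg@nClasses, sd = 0.01),
                          ch[1], cfg@nClasses)
  P[["head/b"]] <- numeric(cfg@nClasses)
  structure(list(cfg = cfg, P = P, S = S, encIn = encIn),
            class = "segnet")
}

#' @export
print.segnet <- function(x, ...) {
  nPar <- sum(vapply(ls(x$P), function(nm) length(x$P[[nm]]), numeric(1)))
  cat(sprintf("segnet: %d levels, %s parameters\n", x$cfg@levels,
              format(nPar, big.mark = ",")))
  print(x$cfg)
  invisible(x)
}

.segnetFw <- function(net, x, train = FALSE) {
  cfg <- net$cfg
  L <- cfg@levels
  d <- dim(x)
  if (any(d[1:3] %% 2L^(L - 1L) != 0L))
    stop("input spatial dims (", paste(d[1:3], collapse = "x"),
         ") must be divisible by ", 2L^(L - 1L))
  P <- net$P
  dil <- cfg@dilationRate
  gate <- cfg@seGate
  ca <- list()
  ca$x <- x
  cur <- .conv1Fw(x, P[["stem/W"]], P[["stem/b"]])
  ca$stemOut <- cur
  ca$enc <- vector("list", L - 1L)
  ca$pool <- vector("list", L - 1L)
  ca$encIn <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {
    ca$encIn[[i]] <- cur
    ca$enc[[i]] <- .recombFwList(cur, .recombView(P, sprintf("enc%d/", i)),
                                 net$S[[sprintf("enc%d/", i)]], dil, gate,
                                 train)
    pl <- .poolFw(ca$enc[[i]]$y)
    ca$pool[[i]] <- pl$cache
    cur <- pl$y
  }
  ca$bott <- .recombFwList(cur, .recombView(P, "bott/"), net$S[["bott/"]],
                           dil, gate, train)
  cur <- ca$bott$y
  ca$dec <- vector("list", L - 1L)
  ca$up <- vector("list", L - 1L)
  ca$add <- vector("list", L - 1L)
  for (i in rev(seq_len(L - 1L))) {
    if (cfg@upsample == "transposed") {
      up <- .upFw(cur, P[[sprintf("up%d/W", i)]], P[[sprintf("up%d/b", i)]])
      ca$up[[i]] <- list(x = cur)
    } else {
      un <- .upNearestFw(cur)
      up <- .conv1Fw(un, P[[sprintf("up%d/W", i)]],
                     P[[sprintf("up%d/b", i)]])
      ca$up[[i]] <- list(x = cur, un = un)
    }
    sk <- .conv1Fw(ca$enc[[i]]$y, P[[sprintf("skip%d/W", i)]],
                   P[[sprintf("skip%d/b", i)]])
    add <- up + sk
    if (i == L - 1L)
      add <- add + .conv1Fw(ca$encIn[[i]], P[["bskip/W"]], P[["bskip/b"]])
    ca$add[[i]] <- add
    ca$dec[[i]] <- .recombFwList(add, .recombView(P, sprintf("dec%d/", i)),
                                 net$S[[sprintf("dec%d/", i)]], dil, gate,
                                 train)
    cur <- ca$dec[[i]]$y
  }
  logits <- .conv1Fw(cur, P[["head/W"]], P[["head/b"]])
  probs <- .softmaxFw(logits)
  ca$lastDec <- cur
  ca$probs <- probs
  list(probs = probs, cache = ca)
}

.segnetBw <- function(net, cache, dprobs, G) {
  cfg <- net$cfg
  L <- cfg@levels
  P <- net$P
  dil <- cfg@dilationRate
  gate <- cfg@seGate
  dlogits <- .softmaxBw(dprobs, cache$probs)
  gh <- .conv1Bw(dlogits, cache$lastDec, P[["head/W"]])
  .addGrad(G, "head/W", gh$dW)
  .addGrad(G, "head/b", gh$db)
  cur <- gh$dx
  dEncOut <- vector("list", L - 1L)   # gradients flowing into encoder tops
  dEncIn <- vector("list", L - 1L)
  for (i in seq_len(L - 1L)) {
    gd <- .recombBwList(cur, cache$dec[[i]],
                        .recombView(P, sprintf("dec%d/", i)), dil, gate)
    .recombGradsInto(G, sprintf("dec%d/", i), gd$grads)
    dadd <- gd$dx
    if (i == L - 1L) {
      gb <- .conv1Bw(dadd, cache$encIn[[i]], P[["bskip/W"]])
      .addGrad(G, "bskip/W", gb$dW)
      .addGrad(G, "bskip/b", gb$db)
      dEncIn[[i]] <- gb$dx
    }
    gs <- .conv1Bw(dadd, cache$enc[[i]]$y, P[[sprintf("skip%d/W", i)]])
    .addGrad(G, sprintf("skip%d/W", i), gs$dW)
    .addGrad(G, sprintf("skip%d/b", i), gs$db)
    dEncOut[[i]] <- gs$dx
    if (cfg@upsample == "transposed") {
      gu <- .upBw(dadd, cache$up[[i]]$x, P[[sprintf("up%d/W", i)]])
      .addGrad(G, sprintf("up%d/W", i), gu$dW)
      .addGrad(G, sprintf("up%d/b", i), gu$db)
      cur <- gu$dx
    } else {
      gc1 <- .conv1Bw(dadd, cache$up[[i]]$un, P[[sprintf("up%d/W", i)]])
      .addGrad(G, sprintf("up%d/W", i), gc1$dW)
      .addGrad(G, sprintf("up%d/b", i), gc1$db)
      cur <- .upNearestBw(gc1$dx, dim(cache$up[[i]]$x))
    }
    # `cur` is now the gradient wrt the next deeper decoder output
    # (or wrt the bottleneck output when i == L-1)
  }
  # bottleneck
  gbott <- .recombBwList(cur, cache$bott, .recombView(P, "bott/"), dil,
                         gate)
  .recombGradsInto(G, "bott/", gbott$grads)
  dcur <- gbott$dx
  for (i in rev(seq_len(L - 1L))) {
    dpool <- .poolBw(dcur, cache$pool[[i]])
    dtop <- dpool + dEncOut[[i]]
    ge <- .recombBwList(dtop, cache$enc[[i]],
                        .recombView(P, sprintf("enc%d/", i)), dil, gate)
    .recombGradsInto(G, sprintf("enc%d/", i), ge$grads)
    dcur <- ge$dx
    if (!is.null(dEncIn[[i]])) dcur <- dcur + dEncIn[[i]]
  }
  gstem <- .conv1Bw(dcur, cache$x, P[["stem/W"]])
  .addGrad(G, "stem/W", gstem$dW)
  .addGrad(G, "stem/b", gstem$db)
  invisible(NULL)
}
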