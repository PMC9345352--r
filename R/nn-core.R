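# Internal neural-network primitives. Feature maps are numeric arrays with
# dims (D, H, W, C); every layer exposes a forward returning (y, cache) and
# a backward mapping the upstream gradient to input/parameter gradients.
# Dense/depthwise 3x3x3 convolutions run through the compiled im2col + GEMM
# kernels; 1x1x1 convolutions, pooling, transposed convolution, batch norm
# and the losses are vectorized R.

.heInit <- function(nOut, nIn, kVol = 1L) {
  matrix(rnorm(nOut * nIn * kVol, sd = sqrt(2 / (nIn * kVol))),
         nOut, nIn * kVol)
}

# ---- 1x1x1 convolution (channel mixing) ----
.conv1Fw <- function(x, W, b) {
  d <- dim(x)
  V <- prod(d[1:3])
  Y <- matrix(x, V, d[4]) %*% W
  Y <- Y + rep(b, each = V)
  array(Y, c(d[1:3], ncol(W)))
}

.conv1Bw <- function(dy, x, W) {
  d <- dim(x)
  V <- prod(d[1:3])
  dY <- matrix(dy, V, ncol(W))
  X2 <- matrix(x, V, d[4])
  list(dx = array(dY %*% t(W), d),
       dW = crossprod(X2, dY),
       db = colSums(dY))
}

# ---- dense 3x3x3 convolution, "same" padding ----
.conv3Fw <- function(x, W, b, dil = 1L) {
  cpp_conv3_fw(x, dim(x), W, b, 3L, as.integer(dil))
}

.conv3Bw <- function(dy, x, W, dil = 1L) {
  cpp_conv3_bw(x, dim(x), W, dy, 3L, as.integer(dil))
}

# variants that carry the im2col patch matrix from forward to backward;
# by default the GEMMs run in single precision (mixed-precision compute,
# double-precision parameters/accumulation) - set
# options(segscore.fp32 = FALSE) for fully double-precision compute
.conv3FwC <- function(x, W, b, dil = 1L) {
  fp32 <- getOption("segscore.fp32", TRUE)
  r <- if (fp32) cpp_conv3_fwc32(x, dim(x), W, b, 3L, as.integer(dil))
       else cpp_conv3_fwc(x, dim(x), W, b, 3L, as.integer(dil))
  r$dims <- dim(x)
  r$fp32 <- fp32
  r
}

.conv3BwC <- function(dy, fwCache, W, dil = 1L) {
  if (fwCache$fp32)
    cpp_conv3_bwc32(fwCache$cols, fwCache$dims, W, dy, 3L, as.integer(dil))
  else
    cpp_conv3_bwc(fwCache$cols, fwCache$dims, W, dy, 3L, as.integer(dil))
}

# ---- depthwise dilated 3x3x3 convolution ----
.dwconvFw <- function(x, Wd, b, dil = 2L) {
  cpp_dwconv3_fw(x, dim(x), Wd, b, 3L, as.integer(dil))
}

.dwconvBw <- function(dy, x, Wd, dil = 2L) {
  cpp_dwconv3_bw(x, dim(x), Wd, dy, 3L, as.integer(dil))
}

# ---- batch normalization (per-sample statistics, running stats for eval) --
.bnFw <- function(x, gamma, beta, run, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  V <- prod(d[1:3])
  X2 <- matrix(x, V, d[4])
  if (train) {
    mu <- colMeans(X2)
    Xc <- X2 - rep(mu, each = V)
    vr <- colMeans(Xc * Xc)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * vr
  } else {
    mu <- run$mean
    Xc <- X2 - rep(mu, each = V)
    vr <- run$var
  }
  invstd <- 1 / sqrt(vr + eps)
  xhat <- Xc * rep(invstd, each = V)
  y <- xhat * rep(gamma, each = V) + rep(beta, each = V)
  list(y = array(y, d), cache = list(xhat = xhat, invstd = invstd, d = d,
                                     train = train))
}

.bnBw <- function(dy, cache, gamma) {
  d <- cache$d
  V <- prod(d[1:3])
  dY <- matrix(dy, V, d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = V)
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dx <- (dxhat - rep(s1 / V, each = V) -
             xhat * rep(s2 / V, each = V)) * rep(cache$invstd, each = V)
  } else {
    dx <- dxhat * rep(cache$invstd, each = V)
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

.bnState <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- numeric(C)
  e$var <- rep(1, C)
  e
}

# ---- activations ----
.reluFw <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

.reluBw <- function(dy, x) {
  dy * (x > 0)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 2x max pooling ----
.poolFw <- function(x) {
  d <- dim(x)
  if (any(d[1:3] %% 2L != 0L))
    stop("spatial dims must be even for 2x pooling (got ",
         paste(d[1:3], collapse = "x"), ")")
  h <- d[1:3] %/% 2L
  subs <- vector("list", 8L)
  t <- 0L
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1) {
    t <- t + 1L
    subs[[t]] <- x[seq.int(1L + od, by = 2L, length.out = h[1]),
                   seq.int(1L + oh, by = 2L, length.out = h[2]),
                   seq.int(1L + ow, by = 2L, length.out = h[3]), ,
                   drop = FALSE]
  }
  y <- Reduce(pmax, subs)
  list(y = y, cache = list(subs = subs, y = y, d = d))
}

.poolBw <- function(dy, cache) {
  d <- cache$d
  h <- d[1:3] %/% 2L
  dx <- array(0, d)
  assigned <- array(FALSE, dim(cache$y))
  t <- 0L
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1) {
    t <- t + 1L
    sel <- !assigned & (cache$subs[[t]] == cache$y)
    if (any(sel)) {
      g <- array(0, dim(cache$y))
      g[sel] <- dy[sel]
      dx[seq.int(1L + od, by = 2L, length.out = h[1]),
         seq.int(1L + oh, by = 2L, length.out = h[2]),
         seq.int(1L + ow, by = 2L, length.out = h[3]), ] <- g
      assigned <- assigned | sel
    }
  }
  dx
}

# ---- 2x transposed convolution (kernel 2, stride 2) ----
# W is an array (8, Cin, Cout): one Cin x Cout mixing matrix per kernel
# offset; each output voxel receives exactly one input voxel.
.upFw <- function(x, W, b) {
  d <- dim(x)
  V <- prod(d[1:3])
  Cin <- d[4]
  Cout <- dim(W)[3]
  X2 <- matrix(x, V, Cin)
  y <- array(rep(b, each = 8L * V), c(2L * d[1:3], Cout))
  t <- 0L
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1) {
    t <- t + 1L
    Yt <- X2 %*% matrix(W[t, , ], Cin, Cout)
    y[seq.int(1L + od, by = 2L, length.out = d[1]),
      seq.int(1L + oh, by = 2L, length.out = d[2]),
      seq.int(1L + ow, by = 2L, length.out = d[3]), ] <- array(
        Yt + rep(b, each = V), c(d[1:3], Cout))
  }
  y
}

.upBw <- function(dy, x, W) {
  d <- dim(x)
  V <- prod(d[1:3])
  Cin <- d[4]
  Cout <- dim(W)[3]
  X2 <- matrix(x, V, Cin)
  dX2 <- matrix(0, V, Cin)
  dW <- array(0, dim(W))
  db <- numeric(Cout)
  t <- 0L
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1) {
    t <- t + 1L
    g <- dy[seq.int(1L + od, by = 2L, length.out = d[1]),
            seq.int(1L + oh, by = 2L, length.out = d[2]),
            seq.int(1L + ow, by = 2L, length.out = d[3]), , drop = FALSE]
    G2 <- matrix(g, V, Cout)
    Wt <- matrix(W[t, , ], Cin, Cout)
    dX2 <- dX2 + G2 %*% t(Wt)
    dW[t, , ] <- crossprod(X2, G2)
    db <- db + colSums(G2)
  }
  list(dx = array(dX2, d), dW = dW, db = db)
}

# ---- nearest-neighbor 2x upsampling (alternative to transposed conv) ----
.upNearestFw <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1:3], d[4]))
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1)
    y[seq.int(1L + od, by = 2L, length.out = d[1]),
      seq.int(1L + oh, by = 2L, length.out = d[2]),
      seq.int(1L + ow, by = 2L, length.out = d[3]), ] <- x
  y
}

.upNearestBw <- function(dy, d) {
  dx <- array(0, d)
  for (ow in 0:1) for (oh in 0:1) for (od in 0:1)
    dx <- dx + dy[seq.int(1L + od, by = 2L, length.out = d[1]),
                  seq.int(1L + oh, by = 2L, length.out = d[2]),
                  seq.int(1L + ow, by = 2L, length.out = d[3]), ,
                  drop = FALSE]
  dx
}

# ---- voxelwise softmax over channels ----
.softmaxFw <- function(x) {
  d <- dim(x)
  V <- prod(d[1:3])
  X2 <- matrix(x, V, d[4])
  m <- X2[, 1]
  for (k in seq_len(d[4])[-1]) m <- pmax(m, X2[, k])
  E <- exp(X2 - m)
  P <- E / rowSums(E)
  array(P, d)
}

# gradient wrt pre-softmax logits given gradient wrt probabilities
.softmaxBw <- function(dprobs, probs) {
  d <- dim(probs)
  V <- prod(d[1:3])
  P <- matrix(probs, V, d[4])
  dP <- matrix(dprobs, V, d[4])
  dz <- P * (dP - rowSums(dP * P))
  array(dz, d)
}

# ---- fully connected ----
.fcFw <- function(x, W, b) {
  as.numeric(x %*% W) + as.numeric(b)
}

.fcBw <- function(dy, x, W) {
  list(dx = as.numeric(W %*% dy), dW = outer(as.numeric(x), dy),
       db = dy)
}

# ---- dropout (inverted scaling) ----
.dropoutFw <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (runif(length(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

.dropoutBw <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- parameter store and Adam ----
.paramStore <- function() new.env(parent = emptyenv())

.zeroGrads <- function(P) {
  G <- new.env(parent = emptyenv())
  for (nm in ls(P)) G[[nm]] <- P[[nm]] * 0   # preserves shape and class
  G
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.addGrad <- function(G, nm, g) {
  G[[nm]] <- G[[nm]] + g
  invisible(NULL)
}

.adamInit <- function(P) {
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- new.env(parent = emptyenv())
  st$v <- new.env(parent = emptyenv())
  for (nm in ls(P)) {
    st$m[[nm]] <- P[[nm]] * 0
    st$v[[nm]] <- P[[nm]] * 0
  }
  st
}

.adamStep <- function(P, G, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in ls(P)) {
    g <- G[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    P[[nm]] <- P[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  invisible(NULL)
}
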