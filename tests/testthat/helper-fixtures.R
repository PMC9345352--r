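# Shared fixtures, all generated in code.

# a tiny label volume carrying a chosen subset of atlas codes
codedVolume <- function(codes, edge = max(6L, length(codes))) {
  v <- array(0L, rep(edge, 3))
  for (i in seq_along(codes)) v[i, 1, 1] <- codes[i]
  v
}

# mirror a 3D (or 4D) array across axis 1
mirrorX <- function(a) {
  idx <- rev(seq_len(dim(a)[1]))
  if (length(dim(a)) == 3L) a[idx, , , drop = FALSE] else a[idx, , , ,
                                                            drop = FALSE]
}

# naive dense 3D convolution oracle ("same" zero padding)
naiveConv3 <- function(x, Wm, b, k = 3, dil = 1) {
  d <- dim(x)
  Cout <- nrow(Wm)
  p <- dil * (k - 1) / 2
  y <- array(0, c(d[1:3], Cout))
  for (co in 1:Cout) for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    acc <- b[co]
    for (c in 1:d[4]) for (kd in 0:(k - 1)) for (kh in 0:(k - 1))
      for (kw in 0:(k - 1)) {
        si <- i + kd * dil - p
        sj <- j + kh * dil - p
        sl <- l + kw * dil - p
        if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2] &&
            sl >= 1 && sl <= d[3]) {
          r <- (c - 1) * k^3 + kd + k * kh + k * k * kw + 1
          acc <- acc + Wm[co, r] * x[si, sj, sl, c]
        }
      }
    y[i, j, l, co] <- acc
  }
  y
}

# naive depthwise dilated convolution oracle
naiveDepthwise <- function(x, Wd, b, dil = 2, k = 3) {
  d <- dim(x)
  p <- dil * (k - 1) / 2
  y <- array(0, d)
  for (c in 1:d[4]) for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    acc <- b[c]
    for (kd in 0:(k - 1)) for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) {
      si <- i + kd * dil - p
      sj <- j + kh * dil - p
      sl <- l + kw * dil - p
      if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2] &&
          sl >= 1 && sl <= d[3])
        acc <- acc + Wd[kd + k * kh + k * k * kw + 1, c] * x[si, sj, sl, c]
    }
    y[i, j, l, c] <- acc
  }
  y
}

# brute-force directed mean minimum surface distance (shares the
# six-connectivity surface definition with the implementation, but computes
# the distances with an O(|A||B|) double loop in R)
bruteASD <- function(a, b, spacing = c(1, 1, 1)) {
  surf <- function(m) {
    d <- dim(m)
    out <- matrix(0, 0, 3)
    for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
      if (!m[i, j, l]) next
      nb <- c(i == 1 || !m[i - 1, j, l], i == d[1] || !m[i + 1, j, l],
              j == 1 || !m[i, j - 1, l], j == d[2] || !m[i, j + 1, l],
              l == 1 || !m[i, j, l - 1], l == d[3] || !m[i, j, l + 1])
      if (any(nb)) out <- rbind(out, c(i, j, l))
    }
    out
  }
  A <- surf(a)
  B <- surf(b)
  total <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      dd <- sum(((A[i, ] - B[j, ]) * spacing)^2)
      if (dd < best) best <- dd
    }
    total <- total + sqrt(best)
  }
  total / nrow(A)
}

# small phantom spec used across tests
testPhantom <- function(gridEdge = 48L, seed = 7L, ...) {
  phantomSpec(gridEdge = gridEdge, seed = seed, ...)
}
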