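# Naive reference implementations, kept deliberately loop-based and
# independent of the package's vectorised code paths.

naiveMask <- function(bankShape, topology = "printed") {
  j <- prod(bankShape)
  m <- matrix(0, j, j)
  for (a in seq_len(j)) for (b in seq_len(j)) {
    if (topology == "printed") {
      m[a, b] <- as.numeric((a - 1) %/% bankShape[2] <= (b - 1) %/% bankShape[2])
    } else {
      m[a, b] <- as.numeric(a <= b)
    }
  }
  m
}

# buffer slice (p, t) = sum_s M[s,t] * A[p,s] * W[s, ]
naiveInhibitionBuffer <- function(A, W, M) {
  n <- nrow(A); j <- nrow(W); i <- ncol(W)
  buf <- matrix(0, n, j * i)
  for (p in seq_len(n)) for (t in seq_len(j)) for (s in seq_len(j)) {
    cols <- ((t - 1) * i + 1):(t * i)
    buf[p, cols] <- buf[p, cols] + M[s, t] * A[p, s] * W[s, ]
  }
  buf
}

# delta[t, ] = alpha * sum_p A[p,t] * (I[p, ] - buffer slice (p, t))
naiveWeightDelta <- function(I, A, W, M, alpha) {
  n <- nrow(I); j <- nrow(W); i <- ncol(W)
  buf <- naiveInhibitionBuffer(A, W, M)
  dw <- matrix(0, j, i)
  for (t in seq_len(j)) for (p in seq_len(n)) {
    slice <- buf[p, ((t - 1) * i + 1):(t * i)]
    dw[t, ] <- dw[t, ] + A[p, t] * (I[p, ] - slice)
  }
  alpha * dw
}

# Sanger's generalised Hebbian (deflation) update, batch form:
# delta w_t = alpha * sum_p a_pt * (x_p - sum_{s <= t} a_ps w_s)
sangerDelta <- function(I, A, W, alpha) {
  j <- nrow(W)
  dw <- 0 * W
  for (t in seq_len(j)) {
    resid <- I - A[, seq_len(t), drop = FALSE] %*% W[seq_len(t), , drop = FALSE]
    dw[t, ] <- alpha * colSums(A[, t] * resid)
  }
  dw
}

# direct loop-based patch gather for small cases: contiguous windows only
naivePatches <- function(img, win) {
  nr <- nrow(img) - win[1] + 1
  nc <- ncol(img) - win[2] + 1
  out <- matrix(0, nr * nc, prod(win))
  p <- 0
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    p <- p + 1
    out[p, ] <- as.vector(t(img[r:(r + win[1] - 1), cc:(cc + win[2] - 1)]))
  }
  out
}

relErr <- function(got, want) {
  denom <- pmax(abs(want), 1e-12)
  max(abs(got - want) / denom)
}
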