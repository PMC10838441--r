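# Vectorized 1-D network primitives (forward + backward) used by the
# spectral regression CNN. Feature maps are 3-D arrays (batch, channels,
# length); convolutions are evaluated as patch-matrix products so each
# call is a handful of small dense multiplications. Weight matrices for a
# convolution with C input channels and kernel width K have C*K rows
# ordered channel-fastest, matching the patch extraction below.

# zero-pad the length dimension of a (B, C, L) array
pad_length <- function(X, pl, pr) {
  if (pl == 0L && pr == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1L], d[2L], d[3L] + pl + pr))
  Xp[, , pl + seq_len(d[3L])] <- X
  Xp
}

conv1d_forward <- function(X, W, b, kernel, stride, pl, pr) {
  d <- dim(X)
  B <- d[1L]; C <- d[2L]; L <- d[3L]
  Xp <- pad_length(X, pl, pr)
  Lp <- L + pl + pr
  L_out <- (Lp - kernel) %/% stride + 1L
  pos <- outer(seq_len(kernel), (seq_len(L_out) - 1L) * stride, "+")  # K x L_out
  P <- Xp[, , as.vector(pos), drop = FALSE]
  dim(P) <- c(B, C, kernel, L_out)
  Pm <- aperm(P, c(1L, 4L, 2L, 3L))
  dim(Pm) <- c(B * L_out, C * kernel)
  Y <- Pm %*% W
  Y <- Y + rep(b, each = nrow(Y))
  dim(Y) <- c(B, L_out, ncol(W))
  list(out = aperm(Y, c(1L, 3L, 2L)),
       cache = list(Pm = Pm, B = B, C = C, L = L, Lp = Lp, L_out = L_out,
                    kernel = kernel, stride = stride, pl = pl))
}

conv1d_backward <- function(dY, W, cache) {
  B <- cache$B; C <- cache$C; K <- cache$kernel; L_out <- cache$L_out
  dYm <- aperm(dY, c(1L, 3L, 2L))
  dim(dYm) <- c(B * L_out, dim(dY)[2L])
  dW <- crossprod(cache$Pm, dYm)
  db <- colSums(dYm)
  dPm <- dYm %*% t(W)
  dim(dPm) <- c(B, L_out, C, K)
  dP <- aperm(dPm, c(1L, 3L, 4L, 2L))   # (B, C, K, L_out)
  dXp <- array(0, c(B, C, cache$Lp))
  base <- (seq_len(L_out) - 1L) * cache$stride
  for (k in seq_len(K)) {
    pos <- base + k
    dXp[, , pos] <- dXp[, , pos] + dP[, , k, ]
  }
  dX <- dXp[, , cache$pl + seq_len(cache$L), drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# non-overlapping average pooling, kernel = stride
avgpool_forward <- function(X, size) {
  d <- dim(X)
  L_out <- d[3L] %/% size
  Y <- array(0, c(d[1L], d[2L], L_out))
  for (k in seq_len(size))
    Y <- Y + X[, , seq(k, by = size, length.out = L_out), drop = FALSE]
  Y / size
}

avgpool_backward <- function(dY, size, L) {
  d <- dim(dY)
  dX <- array(0, c(d[1L], d[2L], L))
  for (k in seq_len(size))
    dX[, , seq(k, by = size, length.out = d[3L])] <- dY / size
  dX
}

# length-preserving average pooling, kernel 3, stride 1, zero padding
avgpool_same3_forward <- function(X) {
  L <- dim(X)[3L]
  Xp <- pad_length(X, 1L, 1L)
  (Xp[, , 1:L, drop = FALSE] + Xp[, , 2:(L + 1L), drop = FALSE] +
      Xp[, , 3:(L + 2L), drop = FALSE]) / 3
}

avgpool_same3_backward <- function(dY) {
  L <- dim(dY)[3L]
  d <- dim(dY)
  dXp <- array(0, c(d[1L], d[2L], L + 2L))
  for (k in 0:2)
    dXp[, , (1:L) + k] <- dXp[, , (1:L) + k] + dY / 3
  dXp[, , 2:(L + 1L), drop = FALSE]
}

fc_forward <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

fc_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))
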