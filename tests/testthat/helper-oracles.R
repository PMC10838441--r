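# Independent oracles and small fixtures shared across the test files.

# Exhaustive Otsu search: split the histogram at every candidate cut and
# recompute both class weights and means from scratch (O(levels^2)).
brute_otsu <- function(v, levels = 256) {
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  bins <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), levels)
  h <- tabulate(bins, levels)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  best <- -Inf
  thr <- NA_real_
  for (t in 1:(levels - 1)) {
    w0 <- sum(h[1:t])
    w1 <- sum(h[(t + 1):levels])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:t] * mids[1:t]) / w0
    m1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) / w1
    bc <- w0 * w1 * (m0 - m1)^2
    if (bc > best) {
      best <- bc
      thr <- breaks[t + 1]
    }
  }
  thr
}

# Successive projections by explicit QR-based Gram-Schmidt at every step.
gs_spa_chain <- function(Xc, start, size) {
  sel <- as.integer(start)
  while (length(sel) < size) {
    Q <- qr.Q(qr(Xc[, sel, drop = FALSE]))
    rn <- sapply(seq_len(ncol(Xc)), function(j) {
      if (j %in% sel) return(-Inf)
      r <- Xc[, j] - Q %*% crossprod(Q, Xc[, j])
      sum(r^2)
    })
    sel <- c(sel, which.max(rn))
  }
  unname(sel)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# a small noiseless spectra matrix plus labels, for fast model tests
tiny_clean_set <- function(n = 6, spad = seq(16, 48, length.out = n)) {
  model <- leaf_spectrum_model(noise_sd = 0)
  wl <- vnir_grid()
  X <- t(sapply(spad, generate_spectrum, wavelengths = wl, model = model))
  list(x = minmax_scale(X), y = spad, wavelengths = wl)
}
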