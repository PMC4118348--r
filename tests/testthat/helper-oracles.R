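# Independent brute-force oracles used by the equivalence tests. These are
# deliberately literal, unoptimized transcriptions kept free of any code
# shared with the implementation under test.

# Literal per-pixel transcription of the mixture update for a calibrated
# model: distance d = |x - mu| to each component in rank order; first
# component with d < c*sigma is matched. Matched background component ->
# mask 0; mean/variance move at rho = alpha * eta clamped to
# [alpha*1e-4, 1]; matched weight (1-alpha)w + alpha, others (1-alpha)w.
# No match -> mask 1, lowest w/sigma component replaced by (x, sigma0, w0).
# Weights renormalized; components re-sorted by w/sigma descending.
oracle_gmm_update <- function(mu, sigma, w, x, p, circular = FALSE,
                              range = 256) {
  G <- nrow(mu); P <- ncol(mu)
  mask <- integer(P)
  for (px in seq_len(P)) {
    m <- NA
    for (i in seq_len(G)) {
      diff <- x[px] - mu[i, px]
      if (circular) {
        if (diff > range / 2) diff <- diff - range
        if (diff < -range / 2) diff <- diff + range
      }
      if (abs(diff) < p$c_match * sigma[i, px]) { m <- i; break }
    }
    cw <- cumsum(w[, px])
    B <- if (any(cw > p$T_bg)) which(cw > p$T_bg)[1] else G
    if (!is.na(m)) {
      mask[px] <- if (m <= B) 0L else 1L
      diff <- x[px] - mu[m, px]
      if (circular) {
        if (diff > range / 2) diff <- diff - range
        if (diff < -range / 2) diff <- diff + range
      }
      s <- sigma[m, px]
      eta <- exp(-0.5 * diff^2 / s^2) / (sqrt(2 * pi) * s)
      rho <- min(max(p$alpha * eta, p$alpha * 1e-4), 1)
      mu_new <- mu[m, px] + rho * diff
      if (circular) {
        if (mu_new < 0) mu_new <- mu_new + range
        if (mu_new >= range) mu_new <- mu_new - range
      }
      dnew <- x[px] - mu_new
      if (circular) {
        if (dnew > range / 2) dnew <- dnew - range
        if (dnew < -range / 2) dnew <- dnew + range
      }
      var_new <- (1 - rho) * s^2 + rho * dnew^2
      mu[m, px] <- mu_new
      sigma[m, px] <- max(sqrt(var_new), p$sigma_min)
      for (i in seq_len(G))
        w[i, px] <- (1 - p$alpha) * w[i, px] + p$alpha * (i == m)
    } else {
      mask[px] <- 1L
      r <- which.min(w[, px] / sigma[, px])
      mu[r, px] <- x[px]
      sigma[r, px] <- p$sigma0
      w[r, px] <- p$w0
    }
    w[, px] <- w[, px] / sum(w[, px])
    ord <- order(w[, px] / sigma[, px], decreasing = TRUE)
    # stable order: ties keep their previous rank (matches insertion sort)
    mu[, px] <- mu[ord, px]; sigma[, px] <- sigma[ord, px]
    w[, px] <- w[ord, px]
  }
  list(mu = mu, sigma = sigma, w = w, mask = mask)
}

# Flood-fill (BFS) 8-connected labeling; labels in order of first appearance
# in column-major scan.
oracle_label8 <- function(mask) {
  M <- nrow(mask); N <- ncol(mask)
  lab <- matrix(0L, M, N)
  nxt <- 0L
  for (j in seq_len(N)) for (i in seq_len(M)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- q[1] + di; jj <- q[2] + dj
        if (ii >= 1 && ii <= M && jj >= 1 && jj <= N &&
            mask[ii, jj] == 1 && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Naive double-loop HOG: per-cell magnitude-weighted histograms from the
# same gradient definition, blocks L2-normalized and concatenated in the
# implementation's block order (x-major blocks, per-block bins x cells
# column-major).
oracle_hog <- function(patch, cell = 8L, block = 2L, bins = 9L,
                       stride = 1L, eps = 1e-5) {
  M <- nrow(patch); N <- ncol(patch)
  ix <- matrix(0, M, N); iy <- matrix(0, M, N)
  for (i in seq_len(M)) for (j in seq_len(N)) {
    jr <- min(j + 1L, N); jl <- max(j - 1L, 1L)
    ir <- min(i + 1L, M); il <- max(i - 1L, 1L)
    ix[i, j] <- patch[i, jr] - patch[i, jl]
    iy[i, j] <- patch[ir, j] - patch[il, j]
  }
  mag <- sqrt(ix^2 + iy^2)
  th <- atan(iy / ix); th[ix == 0] <- pi / 2
  th <- th + pi * (th < 0); th[th >= pi] <- 0
  ny <- M %/% cell; nx <- N %/% cell
  hist <- array(0, c(bins, ny, nx))
  for (cy in seq_len(ny)) for (cx in seq_len(nx))
    for (i in ((cy - 1) * cell + 1):(cy * cell))
      for (j in ((cx - 1) * cell + 1):(cx * cell)) {
        pos <- th[i, j] / (pi / bins) - 0.5
        b0 <- floor(pos); frac <- pos - b0
        lo <- ((b0 %% bins) + bins) %% bins + 1
        hi <- (b0 + 1) %% bins
        hi <- ((hi %% bins) + bins) %% bins + 1
        hist[lo, cy, cx] <- hist[lo, cy, cx] + mag[i, j] * (1 - frac)
        hist[hi, cy, cx] <- hist[hi, cy, cx] + mag[i, j] * frac
      }
  out <- c()
  for (bx in seq(1, nx - block + 1, by = stride))
    for (by in seq(1, ny - block + 1, by = stride)) {
      v <- as.vector(hist[, by:(by + block - 1), bx:(bx + block - 1)])
      out <- c(out, v / sqrt(sum(v^2) + eps^2))
    }
  out
}

# Direct rectangle summation of a Haar feature value on a raw patch
# (0-based half-open rectangles).
oracle_haar_value <- function(patch, feat) {
  rsum <- function(x, y, w, h) {
    if (w <= 0 || h <= 0) return(0)
    sum(patch[(y + 1):(y + h), (x + 1):(x + w)])
  }
  x <- feat$rect[1]; y <- feat$rect[2]; w <- feat$rect[3]; h <- feat$rect[4]
  switch(feat$type,
    h2 = rsum(x, y, w %/% 2, h) - rsum(x + w %/% 2, y, w - w %/% 2, h),
    v2 = rsum(x, y, w, h %/% 2) - rsum(x, y + h %/% 2, w, h - h %/% 2),
    h3 = rsum(x, y, w, h) - 2 * rsum(x + w %/% 3, y, w %/% 3, h),
    v3 = rsum(x, y, w, h) - 2 * rsum(x, y + h %/% 3, w, h %/% 3),
    quad = rsum(x, y, w %/% 2, h %/% 2) +
      rsum(x + w %/% 2, y + h %/% 2, w - w %/% 2, h - h %/% 2) -
      rsum(x + w %/% 2, y, w - w %/% 2, h %/% 2) -
      rsum(x, y + h %/% 2, w %/% 2, h - h %/% 2))
}

# Two label images describe the same partition of foreground pixels when
# the label of each pixel determines the other's label bijectively.
same_partition <- function(a, b) {
  if (!identical(dim(a), dim(b))) return(FALSE)
  if (!identical(a > 0, b > 0)) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}
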