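# Independent oracles used across test files.  These are deliberately
# naive (queue-based flood fill, per-voxel loops, direct formulas) so they
# share no code path with the package implementations they check.

# BFS flood-fill connected components over an explicit offset list.
# mask: 3D logical array; offsets: list of c(dz, dy, dx).
bfsLabel <- function(mask, offsets) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  for (lin in which(mask)) {
    if (lab[lin] > 0L) next
    cur <- cur + 1L
    queue <- lin
    lab[lin] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      i0 <- arrayInd(v, d)
      for (off in offsets) {
        i <- i0 + off
        if (any(i < 1L) || any(i > d)) next
        w <- (i[3L] - 1L) * d[1L] * d[2L] + (i[2L] - 1L) * d[1L] + i[1L]
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

offsets3d8z <- function() {
  out <- list()
  for (dy in -1:1) for (dx in -1:1)
    if (dy || dx) out[[length(out) + 1L]] <- c(0L, dy, dx)
  c(out, list(c(-1L, 0L, 0L), c(1L, 0L, 0L)))
}

offsets2d8 <- function() {
  out <- list()
  for (dy in -1:1) for (dx in -1:1)
    if (dy || dx) out[[length(out) + 1L]] <- c(0L, dy, dx)
  out
}

# Two labelings agree iff they induce the same partition of foreground.
samePartition <- function(a, b) {
  fa <- a[a > 0]; fb <- b[b > 0]
  if (length(fa) != length(fb)) return(FALSE)
  key <- paste(fa, fb)
  length(unique(key)) == length(unique(fa)) &&
    length(unique(key)) == length(unique(fb))
}

# Per-pixel 8-neighbourhood minimum erosion (outside = FALSE), one slice.
erodeOracle2d <- function(m) {
  d <- dim(m)
  out <- m
  for (iy in seq_len(d[1L])) for (ix in seq_len(d[2L])) {
    v <- TRUE
    for (dy in -1:1) for (dx in -1:1) {
      y <- iy + dy; x <- ix + dx
      v <- v && if (y < 1 || y > d[1L] || x < 1 || x > d[2L]) FALSE else m[y, x]
    }
    out[iy, ix] <- v
  }
  out
}

# 4-direction Cauchy-Crofton perimeter of a 2D mask with square pixels.
croftonPerimeter <- function(mask, px) {
  transitions <- function(m) sum(abs(diff(m)))
  Ih <- sum(apply(mask, 1L, transitions))        # along x, line spacing px
  Iv <- sum(apply(mask, 2L, transitions))        # along y
  diagTrans <- function(m) {
    n <- 0L
    for (k in seq(-(nrow(m) - 1L), ncol(m) - 1L)) {
      v <- m[row(m) - col(m) == -k]
      if (length(v) > 1L) n <- n + sum(abs(diff(v)))
    }
    n
  }
  I45 <- diagTrans(mask)
  I135 <- diagTrans(mask[nrow(mask):1, , drop = FALSE])
  # intercept measures: N * line spacing; diagonals are px/sqrt(2) apart
  pi / 2 * mean(c(Ih * px, Iv * px, I45 * px / sqrt(2), I135 * px / sqrt(2)))
}

# Direct-loop weighted mean position (x, y, z) in micrometres.
comOracle <- function(a, vs, mask = NULL) {
  d <- dim(a)
  sw <- 0; sx <- 0; sy <- 0; sz <- 0
  for (iz in seq_len(d[1])) for (iy in seq_len(d[2])) for (ix in seq_len(d[3])) {
    if (!is.null(mask) && !mask[iz, iy, ix]) next
    w <- a[iz, iy, ix]
    sw <- sw + w
    sx <- sx + w * (ix - 1) * vs[3]
    sy <- sy + w * (iy - 1) * vs[2]
    sz <- sz + w * (iz - 1) * vs[1]
  }
  c(sx, sy, sz) / sw
}

# Textbook two-pass Pearson correlation.
pearsonOracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small random binary stack helper.
randomBinary <- function(d, p, vs = c(0.3, 0.1, 0.1)) {
  binaryStack(array(runif(prod(d)) < p, d), vs)
}
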