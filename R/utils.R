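## Internal helpers: array shifting, connected-component labeling, polygon
## geometry, contour tracing, directional sampling, seeded evaluation.

## Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Physical coordinates of voxel centres along each axis (0-based * spacing).
.axisCoords <- function(n, spacing) (seq_len(n) - 1) * spacing

## Shift a 3D array by (dz, dy, dx), filling vacated cells with `fill`.
.shift3d <- function(a, dz, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  if (dz > d[1] || -dz > d[1] || dy > d[2] || -dy > d[2] ||
      dx > d[3] || -dx > d[3]) return(out)
  out[zs, ys, xs] <- a[zs - dz, ys - dy, xs - dx]
  out
}

## Neighbour offsets: 8-connectivity in-plane (dz = 0) plus face adjacency
## along z; `inPlane` = 4 restricts to edge adjacency in-plane.
.neighborOffsets <- function(inPlane = 8L, linkZ = TRUE) {
  off <- list()
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    if (inPlane == 4L && abs(dy) + abs(dx) != 1L) next
    off[[length(off) + 1L]] <- c(0L, dy, dx)
  }
  if (linkZ) off <- c(off, list(c(-1L, 0L, 0L), c(1L, 0L, 0L)))
  off
}

## Connected-component labeling by iterated minimum-label propagation over
## the given offsets; equivalent to union-find on the adjacency graph.
## Returns an integer array, 0 = background, components numbered 1..k in
## first-voxel order (callers re-sort as needed).
.labelComponents <- function(mask, offsets) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)
  repeat {
    nxt <- lab
    for (off in offsets) {
      sh <- .shift3d(lab, off[1], off[2], off[3], fill = 0)
      upd <- mask & sh > 0 & sh < nxt
      if (any(upd)) nxt[upd] <- sh[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  ids <- sort(unique(lab[lab > 0]))
  relab <- array(0L, d)
  if (length(ids)) relab[lab > 0] <- match(lab[lab > 0], ids)
  relab
}

## --- polygon geometry (vertices as N x 2 matrix of (x, y), micrometres) ---

.polyClose <- function(xy) {
  if (!isTRUE(all.equal(xy[1L, ], xy[nrow(xy), ], check.attributes = FALSE)))
    xy <- rbind(xy, xy[1L, , drop = FALSE])
  xy
}

.polyArea <- function(xy) {
  xy <- .polyClose(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- nrow(xy)
  abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
}

.polyPerimeter <- function(xy) {
  xy <- .polyClose(xy)
  sum(sqrt(rowSums(diff(xy)^2)))
}

.polyCentroid <- function(xy) {
  xy <- .polyClose(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- nrow(xy)
  cr <- x[-n] * y[-1L] - x[-1L] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(xy[-n, , drop = FALSE]))
  c(sum((x[-n] + x[-1L]) * cr), sum((y[-n] + y[-1L]) * cr)) / (6 * a)
}

## Even-odd rule point-in-polygon, vectorised over points.
.pointsInPolygon <- function(px, py, xy) {
  xy <- .polyClose(xy)
  n <- nrow(xy) - 1L
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    x1 <- xy[i, 1L]; y1 <- xy[i, 2L]
    x2 <- xy[i + 1L, 1L]; y2 <- xy[i + 1L, 2L]
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

## Scale a polygon by `f` about its centroid.
.polyScale <- function(xy, f) {
  ctr <- .polyCentroid(xy)
  sweep(sweep(xy, 2L, ctr) * f, 2L, ctr, "+")
}

## Trace the outer 0.5-level contour of a 2D logical mask [y, x].
## Returns an N x 2 polygon in physical (x, y) micrometres, or NULL for an
## empty mask.  The mask is padded so border components close properly.
.maskContour <- function(mask, pixelSize) {
  if (!any(mask)) return(NULL)
  dy <- pixelSize[1L]; dx <- pixelSize[2L]
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask)
  ycoord <- (seq_len(nrow(pad)) - 2) * dy
  xcoord <- (seq_len(ncol(pad)) - 2) * dx
  ## contourLines treats rows of z as its x axis; our rows are y
  cl <- grDevices::contourLines(x = ycoord, y = xcoord, z = pad, levels = 0.5)
  if (!length(cl)) return(NULL)
  lens <- vapply(cl, function(cc) .polyPerimeter(cbind(cc$y, cc$x)), 0)
  cc <- cl[[which.max(lens)]]
  cbind(x = cc$y, y = cc$x)
}

## Circular moving-average smoothing of a closed polygon; removes the
## staircase bias of marching-squares contours (~5% on a disc) while
## leaving large-scale shape intact.  Skipped for short contours where the
## window would distort the shape.
.smoothPolygon <- function(xy, window = 5L) {
  xy <- xy[!duplicated(xy), , drop = FALSE]
  n <- nrow(xy)
  if (n < 40L || window <= 1L) return(xy)
  h <- (window - 1L) %/% 2L
  idx <- function(i) ((i - 1L) %% n) + 1L
  out <- xy
  for (i in seq_len(n)) {
    w <- idx((i - h):(i + h))
    out[i, ] <- colMeans(xy[w, , drop = FALSE])
  }
  out
}

## Sample from a von Mises-Fisher distribution on the unit sphere (3D),
## mean direction `mu`, concentration `kappa` (Jakob/Wood construction).
.rvmf <- function(n, mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (kappa < 1e-8) {
    v <- matrix(stats::rnorm(3 * n), ncol = 3L)
    return(v / sqrt(rowSums(v^2)))
  }
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  ang <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(ang), s * sin(ang), w)
  ## rotate local +z to mu
  z <- c(0, 0, 1)
  if (sum(abs(mu - z)) < 1e-12) return(local)
  if (sum(abs(mu + z)) < 1e-12) return(cbind(local[, 1L], -local[, 2L], -local[, 3L]))
  a <- pracma_cross(z, mu)
  a <- a / sqrt(sum(a^2))
  th <- acos(sum(z * mu))
  rotmat <- .axisAngle(a, th)
  local %*% t(rotmat)
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])

.axisAngle <- function(axis, theta) {
  c <- cos(theta); s <- sin(theta); C <- 1 - c
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(x * x * C + c, x * y * C - z * s, x * z * C + y * s,
           y * x * C + z * s, y * y * C + c, y * z * C - x * s,
           z * x * C - y * s, z * y * C + x * s, z * z * C + c),
         3L, 3L, byrow = TRUE)
}

## Separable Gaussian blur of a [z, y, x] stack: EBImage lateral blur per
## slice plus a truncated 1D kernel along z.
.blurStack <- function(a, sigmaLatPx, sigmaAxPx) {
  d <- dim(a)
  if (sigmaLatPx > 0) {
    for (iz in seq_len(d[1L])) {
      a[iz, , ] <- EBImage::imageData(
        EBImage::gblur(EBImage::Image(a[iz, , ]), sigma = sigmaLatPx))
    }
  }
  if (sigmaAxPx > 0) {
    r <- max(1L, ceiling(3 * sigmaAxPx))
    k <- stats::dnorm(-r:r, sd = sigmaAxPx)
    k <- k / sum(k)
    out <- array(0, d)
    for (j in seq_along(k)) {
      sh <- (-r:r)[j]
      out <- out + k[j] * .shift3d(a, sh, 0L, 0L, fill = 0)
    }
    a <- out
  }
  a
}

.checkVoxelMatch <- function(a, b, what = "objects") {
  if (!identical(dim(if (is.array(a)) a else a@data),
                 dim(if (is.array(b)) b else b@data)))
    stop(what, " must share one shape")
  va <- if (is.array(a)) NULL else a@voxelSize
  vb <- if (is.array(b)) NULL else b@voxelSize
  if (!is.null(va) && !is.null(vb) && any(abs(va - vb) > 1e-9))
    stop(what, " must share one voxel size")
  invisible(TRUE)
}
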