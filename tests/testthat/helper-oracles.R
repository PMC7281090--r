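# Independent brute-force oracles. These deliberately re-derive results by
# the most direct method available (per-pixel loops, BFS flood fill) and
# share no code with the package implementation.

# even-odd point-in-polygon test for a single point, counting edge
# crossings of a leftward horizontal ray
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[j] + (py - vy[j]) / (vy[i] - vy[j]) * (vx[i] - vx[j])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(vertices, H, W) {
  m <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W))
    m[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5,
                                       vertices[, 1], vertices[, 2])
  m
}

# random convex polygon inside [0, W] x [0, H]: convex hull of random points
random_convex_polygon <- function(H, W, npts = 8) {
  x <- runif(npts, 0.05 * W, 0.95 * W)
  y <- runif(npts, 0.05 * H, 0.95 * H)
  h <- grDevices::chull(x, y)
  cbind(x[h], y[h])
}

# BFS flood-fill labeling; returns an integer label matrix (labels in
# raster first-encounter order, which callers may ignore when comparing
# partitions)
oracle_flood_fill <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  nxt <- 0L
  stack_r <- integer(H * W); stack_c <- integer(H * W)
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    nxt <- nxt + 1L
    top <- 1L; stack_r[1] <- r0; stack_c[1] <- c0
    lab[r0, c0] <- nxt
    while (top > 0L) {
      pr <- stack_r[top]; pc <- stack_c[top]; top <- top - 1L
      for (t in seq_along(dr)) {
        rr <- pr + dr[t]; cc <- pc + dc[t]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          top <- top + 1L; stack_r[top] <- rr; stack_c[top] <- cc
        }
      }
    }
  }
  lab
}

# partition signature: canonical list of sorted pixel-index sets, for
# label-invariant comparison of two labelings
partition_signature <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  sets <- lapply(ids, function(i) sort(which(lab == i)))
  sets[order(vapply(sets, `[`, numeric(1), 1))]
}

# brute-force binary morphology with square kernels; out-of-image pixels
# follow border replication (ignored by the structuring element), matching
# the package's morphology backend
oracle_erode <- function(m, k) {
  H <- nrow(m); W <- ncol(m); h <- (k - 1) / 2
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rr <- max(1, r - h):min(H, r + h)
    cc <- max(1, c - h):min(W, c + h)
    out[r, c] <- all(m[rr, cc])
  }
  out
}

oracle_dilate <- function(m, k) {
  H <- nrow(m); W <- ncol(m); h <- (k - 1) / 2
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rr <- max(1, r - h):min(H, r + h)
    cc <- max(1, c - h):min(W, c + h)
    out[r, c] <- any(m[rr, cc])
  }
  out
}

oracle_open_close <- function(m, openK, closeK) {
  x <- m
  if (openK > 1) x <- oracle_dilate(oracle_erode(x, openK), openK)
  if (closeK > 1) x <- oracle_erode(oracle_dilate(x, closeK), closeK)
  x
}

# per-pixel weak-label rule: luminance at or below min(percentile cut,
# cap) and red/green ratio below the veto, then opening and closing.
# The percentile cut is computed by explicit sorting and linear
# interpolation (type-7 definition written out by hand).
oracle_weak_label <- function(patch, luminancePercentile = 5,
                              maxLuminance = 110, minChannelRatio = 1.35,
                              openK = 3, closeK = 3) {
  lum <- (patch[, , 1] + patch[, , 2] + patch[, , 3]) / 3
  s <- sort(as.vector(lum))
  n <- length(s)
  hpos <- (n - 1) * luminancePercentile / 100 + 1
  lo <- floor(hpos); hi <- ceiling(hpos)
  q <- s[lo] + (hpos - lo) * (s[hi] - s[lo])
  cut <- min(q, maxLuminance)
  H <- dim(patch)[1]; W <- dim(patch)[2]
  raw <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (lum[r, c] > cut) next
    R <- patch[r, c, 1]; G <- patch[r, c, 2]
    ratio <- if (G == 0) { if (R == 0) 1 else Inf } else R / G
    raw[r, c] <- ratio < minChannelRatio
  }
  oracle_open_close(raw, openK, closeK)
}

# a small synthetic patch with known dark blobs on pink tissue, for
# weak-label oracle comparisons
random_test_patch <- function(H = 64, W = 64, nblobs = 3) {
  p <- array(0, c(H, W, 3))
  bg <- c(235, 200, 210)
  for (k in 1:3) p[, , k] <- bg[k]
  for (b in seq_len(nblobs)) {
    r0 <- sample.int(H - 8, 1); c0 <- sample.int(W - 8, 1)
    sz <- sample(2:7, 2, replace = TRUE)
    shade <- runif(1, 25, 75)
    for (k in 1:3)
      p[r0:(r0 + sz[1]), c0:(c0 + sz[2]), k] <- shade + k
  }
  p <- p + array(rnorm(H * W * 3, 0, 6), c(H, W, 3))
  p <- round(pmin(pmax(p, 0), 255))
  array(as.integer(p), c(H, W, 3))
}
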