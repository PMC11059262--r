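# Brute-force reference implementations used as independent oracles.
# These are deliberately written in plain R, independent of the package's
# kernels, and favour obviousness over speed.

# sliding-window median with edge replication
bf_median <- function(img, win = 3L) {
  H <- nrow(img); W <- ncol(img); h <- win %/% 2
  out <- img
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rr <- pmin(pmax(seq(r - h, r + h), 1L), H)
    cc <- pmin(pmax(seq(c - h, c + h), 1L), W)
    out[r, c] <- median(img[rr, cc])
  }
  out
}

# breadth-first flood fill from in-interval seeds over in-interval pixels
bf_flood <- function(img, seeds, lo, hi, connectivity = 8L) {
  H <- nrow(img); W <- ncol(img)
  ok <- img >= lo & img <= hi
  mask <- matrix(0L, H, W)
  queue <- list()
  for (s in seeds)
    if (ok[s[1], s[2]] && mask[s[1], s[2]] == 0L) {
      mask[s[1], s[2]] <- 1L
      queue[[length(queue) + 1L]] <- s
    }
  nb <- if (connectivity == 8L)
    rbind(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  while (length(queue) > 0L) {
    p <- queue[[1L]]; queue <- queue[-1L]
    for (i in seq_len(nrow(nb))) {
      r <- p[1] + nb[i, 1]; c <- p[2] + nb[i, 2]
      if (r >= 1 && r <= H && c >= 1 && c <= W && ok[r, c] && mask[r, c] == 0L) {
        mask[r, c] <- 1L
        queue[[length(queue) + 1L]] <- c(r, c)
      }
    }
  }
  mask
}

# boundary points (mask cells with an off-mask face neighbour; the array
# border counts as off-mask), as an n x d coordinate matrix
bf_boundary <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) { mask <- array(mask, c(1L, d)); d <- dim(mask) }
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  pts <- which(mask == 1, arr.ind = TRUE)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ] + 1L
    any(pad[p[1] + c(-1, 1), p[2], p[3]] == 0,
        pad[p[1], p[2] + c(-1, 1), p[3]] == 0,
        pad[p[1], p[2], p[3] + c(-1, 1)] == 0)
  }, logical(1))
  pts[keep, , drop = FALSE]
}

# all-pairs HD95: max of the two directed 95th percentiles
bf_hd95 <- function(pred, truth, spacing = NULL) {
  if (is.matrix(pred) && is.null(spacing)) spacing <- c(1, 1)
  if (is.matrix(pred)) spacing <- c(1, spacing)
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  X <- sweep(bf_boundary(pred) - 1, 2, spacing, "*")
  Y <- sweep(bf_boundary(truth) - 1, 2, spacing, "*")
  D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  D <- sqrt(pmax(D2, 0)) # clamp tiny negative rounding residues
  max(quantile(apply(D, 1, min), 0.95, type = 7),
      quantile(apply(D, 2, min), 0.95, type = 7))
}

# per-voxel loop confusion counts
bf_confusion <- function(pred, truth) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (truth[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# SLIC with UNRESTRICTED (global) center search, mirroring the package's
# iteration and stopping rule; valid comparison when 2S >= max(H, W)
bf_slic_global <- function(image, params) {
  H <- nrow(image); W <- ncol(image)
  S <- sqrt(H * W / params$k)
  cen <- init_centers(image, params$k)
  labels <- matrix(0L, H, W)
  for (it in seq_len(params$max_iter)) {
    for (r in seq_len(H)) for (c in seq_len(W)) {
      dc <- abs(image[r, c] - cen[, 1])
      ds <- sqrt((r - 1 - cen[, 2])^2 + (c - 1 - cen[, 3])^2)
      D <- sqrt((dc / params$m)^2 + (ds / S)^2)
      labels[r, c] <- max(which(D == min(D))) # ties -> later center

    }
    maxdisp <- 0
    for (k in seq_len(nrow(cen))) {
      px <- which(labels == k, arr.ind = TRUE)
      if (nrow(px) == 0L) next
      nl <- mean(image[px]); nr <- mean(px[, 1] - 1); nc <- mean(px[, 2] - 1)
      maxdisp <- max(maxdisp, sqrt((nr - cen[k, 2])^2 + (nc - cen[k, 3])^2))
      cen[k, ] <- c(nl, nr, nc)
    }
    if (maxdisp < params$tol) break
  }
  labels
}

# binary dilation / erosion with a disk, plain loops; closing oracle
bf_disk_offsets <- function(radius) {
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off[off$dr^2 + off$dc^2 <= radius^2, ]
}

bf_close2d <- function(mask, radius) {
  # true closing: embed in a zero background (pad = radius), close, crop
  H0 <- nrow(mask); W0 <- ncol(mask)
  P <- matrix(0L, H0 + 2L * radius, W0 + 2L * radius)
  P[radius + seq_len(H0), radius + seq_len(W0)] <- mask
  mask <- P
  H <- nrow(mask); W <- ncol(mask)
  off <- bf_disk_offsets(radius)
  dil <- matrix(0L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    for (i in seq_len(nrow(off))) {
      rr <- r + off$dr[i]; cc <- c + off$dc[i]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc] == 1) {
        dil[r, c] <- 1L; break
      }
    }
  }
  ero <- matrix(1L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    for (i in seq_len(nrow(off))) {
      rr <- r + off$dr[i]; cc <- c + off$dc[i]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && dil[rr, cc] == 0) {
        ero[r, c] <- 0L; break
      }
    }
  }
  ero[radius + seq_len(H0), radius + seq_len(W0)]
}

# two labels sets describe the same partition of the pixels
same_partition <- function(a, b) {
  ta <- as.integer(factor(paste(as.vector(a))))
  tb <- as.integer(factor(paste(as.vector(b))))
  all(tapply(tb, ta, function(x) length(unique(x))) == 1) &&
    all(tapply(ta, tb, function(x) length(unique(x))) == 1)
}

# a noise-free piecewise-constant phantom configuration
noisefree_config <- function() {
  phantom_config(
    noise_sigma = 0,
    organs = list(
      liver = list(center = c(33, 64, 48), semiaxes = c(20, 34, 30),
                   mean = 100, sd = 0),
      spleen = list(center = c(34, 70, 100), semiaxes = c(10, 16, 14),
                    mean = 110, sd = 0)),
    background = list(mean = 40, sd = 0))
}

# calibrate a per-organ key interval from `n` annotated phantoms
calibrate_interval <- function(organ, n = 3, seed0 = 900,
                               config = phantom_config()) {
  samples <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(config, seed = seed0 + i)
    list(volume = preprocess_volume(ph$volume), mask = ph$masks[[organ]])
  })
  key_interval(organ_histogram(samples))
}
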