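#' Region-growing configuration
#'
#' Controls the hierarchical slice-by-slice engine. `alpha` amplifies the
#' local-seed standard deviation into the gray-value acceptance interval
#' `[mu - alpha*sigma, mu + alpha*sigma]`. The three termination rules stop a
#' propagation direction when (1) every carried seed falls outside the key
#' gray range, (2) the slice segments to fewer than `min_voxels` voxels, or
#' (3) the slice's global center jumps more than `max_center_jump` pixels
#' from any of the last `lookback` centers in that direction.
#'
#' @param alpha interval amplification factor (default 3).
#' @param min_voxels termination threshold on the per-slice voxel count
#'   (default 10; a count of exactly 10 continues).
#' @param max_center_jump center-jump threshold in pixels (default 50;
#'   exactly 50 continues).
#' @param lookback how many recent slices condition 3 compares against
#'   (default 10).
#' @param connectivity 4 or 8 (default 8).
#' @param closing_2d,closing_3d disk / ball closing radii (defaults 3 and 2;
#'   0 disables).
#' @param local_seed_mode 0 (global seed only), 2 (adds upper/lower-part
#'   centers, the default) or 4 (adds the four quadrant centers).
#' @param conditions subset of `c(1, 2, 3)`: which termination rules are
#'   active (all by default; ablation switch).
#' @param use_proxy grow on the SLIC proxy intensity (TRUE, default) or on
#'   the raw preprocessed slice (ablation switch).
#' @param gradient_veto if TRUE, pixels whose proxy gradient exceeds
#'   `gradient_threshold` are barred from growth (off by default).
#' @param gradient_threshold veto threshold, same units as the image.
#' @param accumulate_seeds if TRUE (default) the seed lists accumulate over
#'   all segmented slices; if FALSE only the current slice's records are used.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(alpha = 3, min_voxels = 10L, max_center_jump = 50,
                          lookback = 10L, connectivity = 8L,
                          closing_2d = 3L, closing_3d = 2L,
                          local_seed_mode = 2L, conditions = c(1L, 2L, 3L),
                          use_proxy = TRUE, gradient_veto = FALSE,
                          gradient_threshold = Inf,
                          accumulate_seeds = TRUE) {
  if (alpha <= 0) stop("alpha must be positive")
  if (min_voxels < 0) stop("min_voxels must be >= 0")
  if (lookback < 1) stop("lookback must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (!local_seed_mode %in% c(0L, 2L, 4L)) stop("local_seed_mode in {0,2,4}")
  structure(list(alpha = alpha, min_voxels = as.integer(min_voxels),
                 max_center_jump = max_center_jump,
                 lookback = as.integer(lookback),
                 connectivity = as.integer(connectivity),
                 closing_2d = as.integer(closing_2d),
                 closing_3d = as.integer(closing_3d),
                 local_seed_mode = as.integer(local_seed_mode),
                 conditions = as.integer(conditions),
                 use_proxy = isTRUE(use_proxy),
                 gradient_veto = isTRUE(gradient_veto),
                 gradient_threshold = gradient_threshold,
                 accumulate_seeds = isTRUE(accumulate_seeds)),
            class = "growth_config")
}

#' Seed-record lists
#'
#' Bookkeeping for the adaptive interval: `global` holds one record per
#' segmented slice (the organ's global center), `local` holds the global,
#' upper and lower part centers (or quadrant centers) of each slice. The
#' global intensities set the interval's medial axis (mean); the local
#' intensities set its half-width (alpha times their standard deviation).
#'
#' @return An object of class `seed_lists` with data frames `global` and
#'   `local` (columns slice, row, col, value).
#' @export
seed_lists <- function() {
  empty <- data.frame(slice = integer(0), row = integer(0), col = integer(0),
                      value = numeric(0))
  structure(list(global = empty, local = empty), class = "seed_lists")
}

#' Append a slice's seed records
#' @param lists a `seed_lists`.
#' @param slice slice index.
#' @param seeds list of `seed_point`s; the first is the global center.
#' @export
record_seeds <- function(lists, slice, seeds) {
  stopifnot(inherits(lists, "seed_lists"), length(seeds) >= 1L)
  rows <- do.call(rbind, lapply(seeds, function(s)
    data.frame(slice = slice, row = s$row, col = s$col, value = s$value)))
  lists$global <- rbind(lists$global, rows[1, , drop = FALSE])
  lists$local <- rbind(lists$local, rows)
  lists
}

#' Adaptive gray-value interval from the seed lists
#'
#' `mu` is the mean of the global-seed intensities (the medial axis of the
#' interval); `sigma` is the population standard deviation of the local-seed
#' intensities; the interval is `[mu - alpha*sigma, mu + alpha*sigma]`.
#'
#' With only a few recorded slices the local-seed standard deviation is a
#' tiny-sample estimate and can collapse to nearly zero (three centers of one
#' smooth proxy slice are almost equal), strangling growth on the next slice.
#' `sigma_floor` guards against this: the engine passes the bootstrap sigma
#' (key-interval half-width / alpha), so the adaptive interval can widen and
#' drift with the seed records but never undercuts the calibrated organ
#' spread. The bare formula is the `sigma_floor = 0` default.
#'
#' @param lists a `seed_lists` with nonempty global and local records.
#' @param alpha amplification factor.
#' @param sigma_floor lower bound on sigma (same units as the intensities).
#' @return An object of class `growth_interval` with `lo`, `hi`, `mu`,
#'   `sigma`.
#' @export
growth_interval <- function(lists, alpha = 3, sigma_floor = 0) {
  stopifnot(inherits(lists, "seed_lists"))
  if (nrow(lists$global) == 0L || nrow(lists$local) == 0L)
    stop("seed lists are empty")
  mu <- mean(lists$global$value)
  v <- lists$local$value
  sigma <- max(sqrt(mean((v - mean(v))^2)), sigma_floor)
  structure(list(lo = mu - alpha * sigma, hi = mu + alpha * sigma,
                 mu = mu, sigma = sigma),
            class = c("growth_interval", "key_interval"))
}

#' Seeded region growing on one slice
#'
#' Breadth-first growth from every seed whose own intensity lies inside the
#' interval, over the connected component (4- or 8-connectivity) of pixels
#' with `lo <= v <= hi` containing that seed. Seeds with out-of-interval
#' intensity contribute nothing; out-of-bounds seeds are an error.
#'
#' @param intensity numeric matrix to grow on (proxy or raw slice).
#' @param seeds list of `seed_point`s.
#' @param interval object with `lo`, `hi` (a `growth_interval` or
#'   `key_interval`).
#' @param connectivity 4 or 8.
#' @param gradient optional matrix; pixels with `gradient > gradient_threshold`
#'   are barred from growth.
#' @param gradient_threshold veto threshold.
#' @return 0/1 integer matrix.
#' @export
grow_region <- function(intensity, seeds, interval, connectivity = 8L,
                        gradient = NULL, gradient_threshold = Inf) {
  if (length(seeds) == 0L) return(matrix(0L, nrow(intensity), ncol(intensity)))
  img <- intensity
  if (!is.null(gradient) && is.finite(gradient_threshold))
    img[gradient > gradient_threshold] <- Inf
  sm <- do.call(rbind, lapply(seeds, function(s) c(s$row - 1L, s$col - 1L)))
  cpp_grow(img, sm, interval$lo, interval$hi, as.integer(connectivity))
}

# centroid of a 0/1 matrix, rounded and snapped onto the mask
.mask_center <- function(mask, intensity) {
  idx <- which(mask == 1, arr.ind = TRUE)
  sr <- floor(mean(idx[, 1]) + 0.5); sc <- floor(mean(idx[, 2]) + 0.5)
  if (mask[sr, sc] != 1) {
    d2 <- (idx[, 1] - sr)^2 + (idx[, 2] - sc)^2
    pick <- order(d2, idx[, 1], idx[, 2])[1]
    sr <- idx[pick, 1]; sc <- idx[pick, 2]
  }
  seed_point(sr, sc, intensity[sr, sc])
}

.part_center <- function(rows, cols, intensity, fallback) {
  if (length(rows) == 0L) return(fallback)
  sr <- floor(mean(rows) + 0.5); sc <- floor(mean(cols) + 0.5)
  d2 <- (rows - sr)^2 + (cols - sc)^2
  pick <- order(d2, rows, cols)[1]
  seed_point(rows[pick], cols[pick], intensity[rows[pick], cols[pick]])
}

#' Extract the local seeds of a segmented slice
#'
#' The global seed is the mask centroid (snapped to the nearest mask pixel
#' when the centroid falls off-mask). Mode 2 adds the centroids of the upper
#' part (rows above the global center) and the lower part (rows below it);
#' mode 4 adds the four quadrant centroids about the global center. A part
#' with no pixels falls back to the global seed. Part centroids are likewise
#' snapped onto the mask.
#'
#' @param mask nonempty 0/1 matrix.
#' @param intensity matrix the seed values are read from.
#' @param mode 0, 2 or 4.
#' @return list of `seed_point`s; the first is always the global seed.
#' @export
extract_local_seeds <- function(mask, intensity, mode = 2L) {
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  g <- .mask_center(mask, intensity)
  if (mode == 0L) return(list(g))
  r <- idx[, 1]; c <- idx[, 2]
  if (mode == 2L) {
    up <- r < g$row; lo <- r > g$row
    list(g,
         .part_center(r[up], c[up], intensity, g),
         .part_center(r[lo], c[lo], intensity, g))
  } else {
    tl <- r < g$row & c < g$col; tr <- r < g$row & c > g$col
    bl <- r > g$row & c < g$col; br <- r > g$row & c > g$col
    list(g,
         .part_center(r[tl], c[tl], intensity, g),
         .part_center(r[tr], c[tr], intensity, g),
         .part_center(r[bl], c[bl], intensity, g),
         .part_center(r[br], c[br], intensity, g))
  }
}

#' Evaluate the termination conditions for a slice
#'
#' Conditions are evaluated in the order 1 (all seeds outside the key gray
#' range) -> 2 (fewer than `min_voxels` segmented voxels) -> 3 (global center
#' more than `max_center_jump` pixels from one of the up-to-`lookback` most
#' recent centers); the first satisfied condition is reported. Inactive
#' conditions (dropped from `config$conditions`) are skipped.
#'
#' @param mask the slice's segmentation (0/1 matrix).
#' @param seeds list of `seed_point`s used for the slice.
#' @param key_interval the key gray range from histogram analysis.
#' @param center_history matrix with columns (row, col): recent global
#'   centers in the current propagation direction, most recent last.
#' @param config a [growth_config()].
#' @return one of `"none"`, `"seeds_out_of_range"`, `"too_few_voxels"`,
#'   `"center_jump"`.
#' @export
check_termination <- function(mask, seeds, key_interval, center_history,
                              config) {
  if (1L %in% config$conditions && length(seeds) > 0L) {
    vals <- vapply(seeds, function(s) s$value, numeric(1))
    if (all(vals < key_interval$lo | vals > key_interval$hi))
      return("seeds_out_of_range")
  }
  if (2L %in% config$conditions && sum(mask) < config$min_voxels)
    return("too_few_voxels")
  if (3L %in% config$conditions && sum(mask) > 0L &&
      !is.null(center_history) && nrow(center_history) > 0L) {
    ctr <- .mask_center(mask, mask) # intensity irrelevant for the center
    recent <- utils::tail(center_history, config$lookback)
    d <- sqrt((recent[, 1] - ctr$row)^2 + (recent[, 2] - ctr$col)^2)
    if (max(d) > config$max_center_jump) return("center_jump")
  }
  "none"
}

#' Morphological closing of a 2D mask (disk structuring element)
#'
#' Dilation then erosion; fills holes and gaps up to the disk size. Computed
#' on a zero-padded canvas (pad = radius) and cropped back, i.e. the true
#' closing of the mask embedded in an infinite background: extensive
#' (output is a superset of the input) and the identity on solid convex
#' shapes, including near the image border. Radius 0 is the identity.
#'
#' @param mask 0/1 matrix.
#' @param radius disk radius in pixels.
#' @return 0/1 integer matrix.
#' @export
close_mask_2d <- function(mask, radius = 3L) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0L) return(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  r <- as.integer(radius)
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2L * r, W + 2L * r)
  pad[r + seq_len(H), r + seq_len(W)] <- as.integer(mask)
  out <- cpp_morph2d(cpp_morph2d(pad, r, TRUE), r, FALSE)
  out[r + seq_len(H), r + seq_len(W)]
}

#' Morphological closing of a 3D mask (ball structuring element)
#'
#' @param mask 0/1 3D array.
#' @param radius ball radius in voxels.
#' @return 0/1 integer 3D array.
#' @rdname close_mask_2d
#' @export
close_mask_3d <- function(mask, radius = 2L) {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0L) return(array(as.integer(mask), dim(mask)))
  r <- as.integer(radius)
  d <- dim(mask)
  dp <- d + 2L * r
  pad <- array(0L, dp)
  pad[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <-
    as.integer(mask)
  out <- cpp_morph3d(cpp_morph3d(pad, dp, r, TRUE), dp, r, FALSE)
  array(out, dp)[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])]
}

# growing surface of one slice under the configured representation
.growing_image <- function(slice, slic, config) {
  if (config$use_proxy) {
    px <- build_proxy(slice, slic)
    list(intensity = px$intensity,
         gradient = if (config$gradient_veto) px$gradient else NULL)
  } else {
    list(intensity = slice, gradient = NULL)
  }
}

#' Hierarchical slice-by-slice organ segmentation
#'
#' The full engine: select the key slice, localize the growing seed on it,
#' grow the key slice on its proxy image with a bootstrap interval (seed
#' intensity plus/minus the key-interval half-width), close in 2D, record
#' global and local seeds, then propagate to adjacent slices — upward to the
#' first slice, then downward — carrying each slice's local seeds to the same
#' (row, col) on the neighbor, recomputing the interval from the accumulated
#' seed lists, growing, closing and testing the termination rules. A final 3D
#' closing restores inter-slice coherence.
#'
#' A slice on which a termination condition fires is discarded and the
#' direction stops; running off the volume records the `volume_edge` reason.
#' When a slice segments to nothing and no condition is active to stop the
#' direction, the previous seeds are carried onward unchanged.
#'
#' @param vol a preprocessed `ct_volume`.
#' @param key_interval the organ's `key_interval`.
#' @param seed_backend function(slice_matrix) returning a `seed_point` on the
#'   key slice; see [backend_histogram()] and [backend_oracle()].
#' @param slic a [slic_params()] for the proxy images.
#' @param config a [growth_config()].
#' @param key_slice optional: force the key slice index.
#' @return An object of class `organ_segmentation`: the 0/1 `mask` (3D
#'   array), a per-slice `report` data frame (slice, direction, center,
#'   interval, voxels) and the `termination` reasons per direction.
#' @export
segment_organ <- function(vol, key_interval, seed_backend, slic,
                          config = growth_config(), key_slice = NULL) {
  stopifnot(inherits(vol, "ct_volume"), inherits(config, "growth_config"))
  d <- dim(vol$voxels)
  if (is.null(key_slice))
    key_slice <- select_key_slices(vol, key_interval, 1L)[1]
  out <- array(0L, d)
  report <- data.frame()
  lists <- seed_lists()

  slice <- get_slice(vol, key_slice)
  gi <- .growing_image(slice, slic, config)
  seed0 <- seed_backend(slice)
  # bootstrap interval: seed intensity on the growing image, half-width from
  # the key interval so the first interval is commensurate with later ones
  mu0 <- gi$intensity[seed0$row, seed0$col]
  half <- (key_interval$hi - key_interval$lo) / 2
  boot <- structure(list(lo = mu0 - half, hi = mu0 + half),
                    class = "key_interval")
  seed0 <- seed_point(seed0$row, seed0$col, mu0)
  m <- grow_region(gi$intensity, list(seed0), boot, config$connectivity,
                   gi$gradient, config$gradient_threshold)
  m <- close_mask_2d(m, config$closing_2d)
  if (sum(m) == 0L) stop("key slice failed: empty segmentation")
  seeds <- extract_local_seeds(m, gi$intensity, config$local_seed_mode)
  lists <- record_seeds(lists, key_slice, seeds)
  out[key_slice, , ] <- m
  report <- rbind(report, data.frame(
    slice = key_slice, direction = "key", center_row = seeds[[1]]$row,
    center_col = seeds[[1]]$col, lo = boot$lo, hi = boot$hi,
    voxels = sum(m), reason = "none"))

  termination <- c(up = "none", down = "none")
  for (dir in c("up", "down")) {
    step <- if (dir == "up") -1L else 1L
    s <- key_slice + step
    prev_seeds <- seeds
    centers <- matrix(c(seeds[[1]]$row, seeds[[1]]$col), 1)
    reason <- "volume_edge"
    while (s >= 1L && s <= d[1]) {
      sl <- get_slice(vol, s)
      gis <- .growing_image(sl, slic, config)
      cur_seeds <- lapply(prev_seeds, function(p)
        seed_point(p$row, p$col, gis$intensity[p$row, p$col]))
      iv <- if (config$accumulate_seeds)
              growth_interval(lists, config$alpha, sigma_floor = half / config$alpha)
            else
              growth_interval(.last_slice_lists(lists), config$alpha,
                              sigma_floor = half / config$alpha)
      mk <- grow_region(gis$intensity, cur_seeds, iv, config$connectivity,
                        gis$gradient, config$gradient_threshold)
      mk <- close_mask_2d(mk, config$closing_2d)
      why <- check_termination(mk, cur_seeds, key_interval, centers, config)
      if (why != "none") {
        reason <- why
        report <- rbind(report, data.frame(
          slice = s, direction = dir, center_row = NA, center_col = NA,
          lo = iv$lo, hi = iv$hi, voxels = sum(mk), reason = why))
        break
      }
      if (sum(mk) > 0L) {
        sl_seeds <- extract_local_seeds(mk, gis$intensity,
                                        config$local_seed_mode)
        lists <- record_seeds(lists, s, sl_seeds)
        out[s, , ] <- mk
        centers <- rbind(centers, c(sl_seeds[[1]]$row, sl_seeds[[1]]$col))
        prev_seeds <- sl_seeds
        report <- rbind(report, data.frame(
          slice = s, direction = dir, center_row = sl_seeds[[1]]$row,
          center_col = sl_seeds[[1]]$col, lo = iv$lo, hi = iv$hi,
          voxels = sum(mk), reason = "none"))
      } else {
        # nothing grew and no active condition stopped us: carry seeds on
        report <- rbind(report, data.frame(
          slice = s, direction = dir, center_row = NA, center_col = NA,
          lo = iv$lo, hi = iv$hi, voxels = 0L, reason = "none"))
      }
      s <- s + step
    }
    termination[dir] <- reason
  }
  mask <- close_mask_3d(out, config$closing_3d)
  structure(list(mask = mask, report = report, termination = termination,
                 key_slice = key_slice),
            class = "organ_segmentation")
}

.last_slice_lists <- function(lists) {
  last <- max(lists$local$slice)
  structure(list(global = lists$global[lists$global$slice == last, ],
                 local = lists$local[lists$local$slice == last, ]),
            class = "seed_lists")
}

#' @export
print.organ_segmentation <- function(x, ...) {
  cat(sprintf(
    "organ_segmentation: key slice %d, %d voxels, stop: up=%s down=%s\n",
    x$key_slice, sum(x$mask), x$termination["up"], x$termination["down"]))
  invisible(x)
}

#' Seed-localization backends
#'
#' `backend_histogram` localizes via the key-voxel centroid of the slice and
#' refines to the in-patch seed; `backend_oracle` returns a fixed known seed
#' (ground truth, for testing and calibration); `backend_model` uses a
#' trained [locator_model] and refines with [seed_from_patch()]. Each returns
#' a `function(slice)` suitable for [segment_organ()].
#'
#' @param interval the organ's `key_interval`.
#' @param grid a `patch_grid` matching the slice shape.
#' @param row,col the oracle seed coordinate.
#' @param model a trained `locator_model`.
#' @rdname seed_backends
#' @export
backend_histogram <- function(interval, grid) {
  function(slice) {
    idx <- locate_histogram(slice, interval, grid)
    seed_from_patch(slice, idx, interval, grid)
  }
}

#' @rdname seed_backends
#' @export
backend_oracle <- function(row, col) {
  function(slice) seed_point(row, col, slice[row, col])
}

#' @rdname seed_backends
#' @export
backend_model <- function(model, interval, grid) {
  function(slice) {
    idx <- as.integer(locate_model(slice, model))
    seed_from_patch(slice, idx, interval, grid)
  }
}
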