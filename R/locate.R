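#' Patch grid over a slice
#'
#' Divides an H x W slice into non-overlapping P x P patches, indexed
#' row-major starting at 1.
#'
#' @param h,w slice dimensions; both must be divisible by `p`.
#' @param p patch side in pixels (32 for 512 x 512 abdominal CT).
#' @return An object of class `patch_grid` with fields `h`, `w`, `p`,
#'   `rows`, `cols`, `n`.
#' @export
make_patch_grid <- function(h, w, p) {
  if (h %% p != 0 || w %% p != 0)
    stop("h and w must be divisible by p")
  structure(list(h = as.integer(h), w = as.integer(w), p = as.integer(p),
                 rows = as.integer(h / p), cols = as.integer(w / p),
                 n = as.integer((h / p) * (w / p))),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("patch_grid: %d x %d image, %d x %d patches of side %d (N = %d)\n",
              x$h, x$w, x$rows, x$cols, x$p, x$n))
  invisible(x)
}

#' Patch index of a pixel coordinate
#' @param grid a `patch_grid`.
#' @param row,col 1-based pixel coordinates.
#' @return 1-based row-major patch index.
#' @export
patch_of <- function(grid, row, col) {
  stopifnot(inherits(grid, "patch_grid"))
  if (row < 1 || row > grid$h || col < 1 || col > grid$w)
    stop("pixel coordinate outside the grid")
  pr <- (row - 1L) %/% grid$p
  pc <- (col - 1L) %/% grid$p
  as.integer(pr * grid$cols + pc + 1L)
}

#' Patch-grid cell coordinates of a patch index
#' @param grid a `patch_grid`.
#' @param index 1-based patch index.
#' @return integer c(row, col) of the patch cell, 1-based.
#' @export
patch_cell <- function(grid, index) {
  stopifnot(inherits(grid, "patch_grid"))
  if (any(index < 1L | index > grid$n)) stop("patch index out of range")
  cbind(row = (index - 1L) %/% grid$cols + 1L,
        col = (index - 1L) %% grid$cols + 1L)
}

#' Pixel bounds of a patch
#' @param grid a `patch_grid`.
#' @param index 1-based patch index.
#' @return list with 1-based inclusive `rows` and `cols` ranges.
#' @export
patch_bounds <- function(grid, index) {
  cell <- patch_cell(grid, index)
  list(rows = ((cell[1, "row"] - 1L) * grid$p + 1L):(cell[1, "row"] * grid$p),
       cols = ((cell[1, "col"] - 1L) * grid$p + 1L):(cell[1, "col"] * grid$p))
}

# centroid of a set of 1-based (row, col) coordinates, floor rule on the
# 0-based mean (matching the package's pixel arithmetic convention)
.floor_centroid <- function(rows, cols) {
  c(row = floor(mean(rows - 1)) + 1L, col = floor(mean(cols - 1)) + 1L)
}

#' Ground-truth patch label from an organ mask
#'
#' The supervision signal of the patch locator: the index of the patch
#' containing the floor-rounded centroid of the mask. For concave shapes the
#' centroid pixel itself may lie off-mask; the patch containing it is still
#' the label.
#'
#' @param mask 0/1 matrix.
#' @param grid a `patch_grid` matching the mask's shape.
#' @return 1-based patch index.
#' @export
centroid_patch_label <- function(mask, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  ctr <- .floor_centroid(idx[, 1], idx[, 2])
  patch_of(grid, ctr["row"], ctr["col"])
}

#' Histogram-based patch localization
#'
#' Training-free locator backend: the patch containing the centroid of all
#' key voxels (pixels inside the key interval) on the slice.
#'
#' @param slice numeric matrix.
#' @param interval a `key_interval`.
#' @param grid a `patch_grid`.
#' @return 1-based patch index.
#' @export
locate_histogram <- function(slice, interval, grid) {
  stopifnot(inherits(interval, "key_interval"))
  idx <- which(slice >= interval$lo & slice <= interval$hi, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no key voxels on slice")
  ctr <- .floor_centroid(idx[, 1], idx[, 2])
  patch_of(grid, ctr["row"], ctr["col"])
}

#' Growing seed from a localized patch
#'
#' Averages the coordinates of the key voxels inside the identified central
#' patch, rounds, and — if the rounded coordinate is not itself a key voxel —
#' snaps to the nearest in-patch key voxel (ties toward the smaller row, then
#' the smaller column). If the patch contains no key voxel at all, falls back
#' to the slice-wide key-voxel centroid with a warning.
#'
#' @param slice numeric matrix.
#' @param patch_index 1-based patch index.
#' @param interval a `key_interval`.
#' @param grid a `patch_grid`.
#' @return An object of class `seed_point`: `row`, `col` (1-based), `value`.
#' @export
seed_from_patch <- function(slice, patch_index, interval, grid) {
  stopifnot(inherits(interval, "key_interval"))
  b <- patch_bounds(grid, patch_index)
  patch <- slice[b$rows, b$cols, drop = FALSE]
  idx <- which(patch >= interval$lo & patch <= interval$hi, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    warning("patch contains no key voxels; falling back to slice centroid")
    all_idx <- which(slice >= interval$lo & slice <= interval$hi,
                     arr.ind = TRUE)
    if (nrow(all_idx) == 0L) stop("no key voxels on slice")
    idx <- all_idx
    offr <- 0L; offc <- 0L
  } else {
    offr <- b$rows[1] - 1L; offc <- b$cols[1] - 1L
  }
  rows <- idx[, 1] + offr; cols <- idx[, 2] + offc
  sr <- floor(mean(rows) + 0.5); sc <- floor(mean(cols) + 0.5)
  key_here <- slice[sr, sc] >= interval$lo & slice[sr, sc] <= interval$hi
  if (!key_here) {
    d2 <- (rows - sr)^2 + (cols - sc)^2
    pick <- order(d2, rows, cols)[1]
    sr <- rows[pick]; sc <- cols[pick]
  }
  seed_point(sr, sc, slice[sr, sc])
}

#' Seed point constructor
#' @param row,col 1-based pixel coordinates.
#' @param value intensity at the pixel.
#' @export
seed_point <- function(row, col, value = NA_real_) {
  structure(list(row = as.integer(row), col = as.integer(col),
                 value = as.numeric(value)),
            class = "seed_point")
}

#' @export
print.seed_point <- function(x, ...) {
  cat(sprintf("seed_point: (%d, %d), value %.4g\n", x$row, x$col, x$value))
  invisible(x)
}

#' Patch-localization metrics: ACC and EED
#'
#' ACC is the fraction of predictions exactly matching the true patch index.
#' EED is the mean Euclidean distance in patch-grid units over the incorrect
#' cases only (an edge-adjacent miss contributes 1, a vertex-adjacent miss
#' sqrt(2)); with no incorrect case EED is 0.
#'
#' @param pred,truth integer vectors of 1-based patch indices, equal length.
#' @param grid the `patch_grid` the indices refer to.
#' @return list with `acc` and `eed`.
#' @export
localization_metrics <- function(pred, truth, grid) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  if (length(pred) == 0L) stop("empty prediction list")
  wrong <- pred != truth
  acc <- mean(!wrong)
  if (!any(wrong)) return(list(acc = acc, eed = 0))
  pc <- patch_cell(grid, pred[wrong])
  tc <- patch_cell(grid, truth[wrong])
  eed <- mean(sqrt((pc[, "row"] - tc[, "row"])^2 +
                   (pc[, "col"] - tc[, "col"])^2))
  list(acc = acc, eed = eed)
}
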