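#' CT volume container
#'
#' A minimal 3D intensity container: a numeric lattice indexed
#' (slice, row, col) plus per-axis voxel spacing in millimetres. Intensities
#' are Hounsfield units before preprocessing and z-scores afterwards.
#'
#' Rows increase downward, so the "upper part" of an organ on a slice has the
#' smaller row indices. All indices in this package are 1-based.
#'
#' @param voxels numeric 3D array, dimension (slices, rows, cols).
#' @param spacing numeric length-3, mm per voxel along (slice, row, col).
#' @param normalized logical; TRUE once the volume has been z-normalized.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), normalized = FALSE) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("non-3D payload: `voxels` must be a 3D array")
  if (!all(is.finite(voxels)))
    stop("all voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values")
  structure(list(voxels = voxels, spacing = spacing,
                 normalized = isTRUE(normalized)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d x %d x %d (slice x row x col), spacing %s mm, %s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              if (x$normalized) "z-normalized" else "raw HU"))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Extract one axial slice as a matrix
#' @param vol a `ct_volume`.
#' @param s slice index (1-based).
#' @return numeric matrix (rows x cols).
#' @export
get_slice <- function(vol, s) {
  stopifnot(inherits(vol, "ct_volume"))
  d <- dim(vol$voxels)
  if (s < 1L || s > d[1]) stop("slice index out of range")
  matrix(vol$voxels[s, , ], nrow = d[2], ncol = d[3])
}

.is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Read a 3D volume
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`, via RNifti) or an `.rds` file
#' holding a list with `voxels` and `spacing`. NIfTI arrays stored (i, j, k)
#' are reordered so the third (slice) axis comes first, giving the package
#' convention (slice, row, col).
#'
#' @param path file to read.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  if (.is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("non-3D payload in ", path)
    pd <- RNifti::pixdim(img)
    ct_volume(aperm(arr, c(3, 1, 2)), spacing = c(pd[3], pd[1], pd[2]))
  } else if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    if (is.array(obj) && length(dim(obj)) == 3L)
      return(ct_volume(obj))
    if (!is.list(obj) || is.null(obj$voxels)) stop("unreadable format: ", path)
    if (length(dim(obj$voxels)) != 3L) stop("non-3D payload in ", path)
    ct_volume(obj$voxels, spacing = if (is.null(obj$spacing)) c(1, 1, 1)
                                    else obj$spacing,
              normalized = isTRUE(obj$normalized))
  } else stop("unreadable format (expect .nii, .nii.gz or .rds): ", path)
}

#' Write a 3D volume
#'
#' Inverse of [read_volume()]: NIfTI output stores the array as (row, col,
#' slice) with matching pixdim so a round trip is voxel-identical.
#'
#' @param vol a `ct_volume`.
#' @param path destination (`.nii`, `.nii.gz` or `.rds`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (.is_nifti_path(path)) {
    arr <- aperm(vol$voxels, c(2, 3, 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vol$spacing[2], vol$spacing[3], vol$spacing[1])
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(list(voxels = vol$voxels, spacing = vol$spacing,
                 normalized = vol$normalized), path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

#' Write a binary mask next to its reference volume
#'
#' @param mask 0/1 integer 3D array with the same shape as `reference`.
#' @param path destination (`.nii`, `.nii.gz` or `.rds`).
#' @param reference the `ct_volume` the mask annotates; provides spacing.
#' @export
write_mask <- function(mask, path, reference) {
  stopifnot(inherits(reference, "ct_volume"))
  if (!identical(dim(mask), dim(reference$voxels)))
    stop("mask shape does not match reference shape")
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0/1")
  vol <- ct_volume(array(as.numeric(mask), dim(mask)),
                   spacing = reference$spacing)
  write_volume(vol, path)
}

#' Read a binary mask
#' @param path a file written by [write_mask()] (or any volume of 0/1 values).
#' @return integer 0/1 3D array with a `spacing` attribute.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  m <- vol$voxels
  if (!all(m %in% c(0, 1))) stop("not a binary mask: ", path)
  out <- array(as.integer(m), dim(m))
  attr(out, "spacing") <- vol$spacing
  out
}

#' Clip intensities to a HU window
#'
#' @param x numeric array/matrix/vector.
#' @param lo,hi window bounds; values outside are set to the bound.
#' @return clipped object of the same shape.
#' @export
clip_intensities <- function(x, lo = -240, hi = 360) {
  if (lo >= hi) stop("clip_lo must be < clip_hi")
  pmin(pmax(x, lo), hi)
}

#' Preprocess a CT volume
#'
#' The standard pipeline: clip intensities to `[clip_lo, clip_hi]` HU, smooth
#' each axial slice with a 2D median filter (edge replication, no shrinkage),
#' then z-normalize the whole volume to zero mean and unit variance. The three
#' steps can be reordered via `order`; statistics are per-volume.
#'
#' A volume that is constant after clipping has zero variance; it is returned
#' as all zeros with a warning rather than an error.
#'
#' @param vol a `ct_volume` in HU.
#' @param clip_lo,clip_hi clip window in HU (default -240, 360).
#' @param median_window odd window side for the per-slice median (default 3;
#'   1 disables smoothing).
#' @param order character vector permutation of
#'   `c("clip", "median", "normalize")`.
#' @return A z-normalized `ct_volume` (`normalized = TRUE`).
#' @export
preprocess_volume <- function(vol, clip_lo = -240, clip_hi = 360,
                              median_window = 3,
                              order = c("clip", "median", "normalize")) {
  stopifnot(inherits(vol, "ct_volume"))
  if (clip_lo >= clip_hi) stop("clip_lo must be < clip_hi")
  if (median_window < 1 || median_window %% 2 == 0)
    stop("median_window must be odd and >= 1")
  if (!setequal(order, c("clip", "median", "normalize")))
    stop("`order` must be a permutation of clip/median/normalize")
  v <- vol$voxels
  for (step in order) {
    v <- switch(step,
      clip = clip_intensities(v, clip_lo, clip_hi),
      median = {
        if (median_window > 1) {
          d <- dim(v)
          for (s in seq_len(d[1]))
            v[s, , ] <- cpp_median_filter(matrix(v[s, , ], d[2], d[3]),
                                          as.integer(median_window))
        }
        v
      },
      normalize = {
        mu <- mean(v); sg <- sd(as.vector(v))
        if (!is.finite(sg) || sg == 0) {
          warning("constant volume after clipping: returning all zeros")
          array(0, dim(v))
        } else (v - mu) / sg
      })
  }
  ct_volume(v, spacing = vol$spacing, normalized = TRUE)
}
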