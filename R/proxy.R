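#' SLIC parameters
#'
#' @param k requested number of superpixels.
#' @param m compactness: the maximum color distance weighting the intensity
#'   term against the spatial term. Must be commensurate with the intensity
#'   scale: well above the within-region noise contrast (so superpixels
#'   average noise out instead of stratifying by it) and at or below the
#'   organ/background contrast (so boundaries still steer the clustering).
#'   The default 2 sits between those scales for z-normalized CT, where
#'   noise contrast is a few tenths and organ/background contrast about 3.
#'   (For 0-100 luminance scales the classic choice is ~10.)
#' @param max_iter maximum assign/update iterations (default 10).
#' @param tol convergence tolerance on the maximum center displacement in
#'   pixels (default 1e-4).
#' @return An object of class `slic_params`.
#' @export
slic_params <- function(k, m = 2, max_iter = 10L, tol = 1e-4) {
  if (k < 1L) stop("k must be >= 1")
  if (m <= 0) stop("m must be positive")
  structure(list(k = as.integer(k), m = m, max_iter = as.integer(max_iter),
                 tol = tol), class = "slic_params")
}

#' Initialize SLIC cluster centers
#'
#' Places centers on a regular grid of spacing `S = sqrt(N/k)` (N = pixel
#' count), then moves each to the lowest-gradient pixel of its 3x3
#' neighborhood so no center starts on an edge or noisy pixel. Gradient is
#' the 8-neighbor maximum absolute difference. Ties keep the original
#' position if it attains the minimum, otherwise take the first minimum in
#' row-major order.
#'
#' @param image numeric matrix.
#' @param k requested superpixel count (`k <=` pixel count).
#' @return numeric matrix with one row per center and columns `l` (intensity),
#'   `row`, `col` (0-based pixel coordinates).
#' @export
init_centers <- function(image, k) {
  H <- nrow(image); W <- ncol(image); N <- H * W
  if (k > N) stop("k exceeds pixel count")
  S <- sqrt(N / k)
  rows0 <- seq(S / 2, H - 1e-9, by = S)
  cols0 <- seq(S / 2, W - 1e-9, by = S)
  if (length(rows0) == 0L) rows0 <- (H - 1) / 2
  if (length(cols0) == 0L) cols0 <- (W - 1) / 2
  rows0 <- pmin(floor(rows0), H - 1L)
  cols0 <- pmin(floor(cols0), W - 1L)
  grad <- cpp_gradient8(image, FALSE)
  centers <- matrix(0, length(rows0) * length(cols0), 3,
                    dimnames = list(NULL, c("l", "row", "col")))
  i <- 0L
  for (r in rows0) for (c in cols0) {
    i <- i + 1L
    rr <- max(0L, r - 1L):min(H - 1L, r + 1L)
    cc <- max(0L, c - 1L):min(W - 1L, c + 1L)
    g <- grad[rr + 1L, cc + 1L, drop = FALSE]
    if (grad[r + 1L, c + 1L] <= min(g)) {
      br <- r; bc <- c
    } else {
      # first minimum in row-major (across cols, then next row) order
      best <- which(t(g) == min(g), arr.ind = TRUE)[1, ]
      br <- rr[best[2]]; bc <- cc[best[1]]
    }
    centers[i, ] <- c(image[br + 1L, bc + 1L], br, bc)
  }
  centers
}

#' SLIC superpixel segmentation of a grayscale slice
#'
#' Local k-means clustering in (intensity, row, col): each pixel is assigned
#' to the nearest center by the aggregate distance
#' `D = sqrt((d_c/m)^2 + (d_s/S)^2)` searching only centers whose 2S x 2S
#' window covers the pixel; centers are then recomputed as the mean of their
#' pixels, iterating until `max_iter` or the largest center displacement
#' drops below `tol`. Pixels left uncovered by every window attach to the
#' spatially nearest center so the labeling is total.
#'
#' @param image numeric matrix (a preprocessed slice).
#' @param params a [slic_params()].
#' @return An object of class `superpixel_labeling`: integer `labels` matrix
#'   (dense 1-based ids), `centers` (l/row/col per label), `S`, the source
#'   `image` and `params`.
#' @export
slic_segment <- function(image, params) {
  stopifnot(inherits(params, "slic_params"))
  if (length(image) == 0L) stop("image is empty")
  S <- sqrt(length(image) / params$k)
  cen0 <- init_centers(image, params$k)
  res <- cpp_slic(image, cen0, params$m, S, params$max_iter, params$tol)
  labels <- res$labels
  keep <- sort(unique(as.vector(labels)))
  relab <- integer(max(keep)); relab[keep] <- seq_along(keep)
  labels <- matrix(relab[labels], nrow(image), ncol(image))
  centers <- res$centers[keep, , drop = FALSE]
  colnames(centers) <- c("l", "row", "col")
  structure(list(labels = labels, centers = centers, S = S, image = image,
                 params = params),
            class = "superpixel_labeling")
}

#' @export
print.superpixel_labeling <- function(x, ...) {
  cat(sprintf("superpixel_labeling: %d x %d pixels, %d superpixels (S = %.2f)\n",
              nrow(x$labels), ncol(x$labels), nrow(x$centers), x$S))
  invisible(x)
}

.centers_from_labels <- function(image, labels) {
  f <- as.vector(labels)
  l <- as.vector(rowsum(as.vector(image), f) / tabulate(f))
  rr <- as.vector(rowsum(as.vector(row(labels)) - 1, f) / tabulate(f))
  cc <- as.vector(rowsum(as.vector(col(labels)) - 1, f) / tabulate(f))
  cbind(l = l, row = rr, col = cc)
}

#' Enforce 4-connectivity of a superpixel labeling
#'
#' Splits labels with disconnected pixel sets, absorbs fragments smaller than
#' `min_size` into their largest 4-adjacent neighbor, and relabels densely.
#' Centers are recomputed from the final labeling.
#'
#' @param labeling a `superpixel_labeling`.
#' @param min_size smallest fragment kept as its own superpixel; default
#'   `floor(S^2/4)` (a quarter of the nominal superpixel area).
#' @return A `superpixel_labeling` in which every label is 4-connected.
#' @export
enforce_connectivity <- function(labeling, min_size = NULL) {
  stopifnot(inherits(labeling, "superpixel_labeling"))
  if (is.null(min_size)) min_size <- max(1L, floor(labeling$S^2 / 4))
  labels <- cpp_enforce_connectivity(labeling$labels, as.integer(min_size))
  structure(list(labels = labels,
                 centers = .centers_from_labels(labeling$image, labels),
                 S = labeling$S, image = labeling$image,
                 params = labeling$params),
            class = "superpixel_labeling")
}

#' Superpixel mean-colored image
#'
#' Replaces every pixel by the mean intensity of its superpixel — the core of
#' the proxy representation: intra-region noise averages out while region
#' boundaries stay sharp.
#'
#' @param image numeric matrix.
#' @param labeling a `superpixel_labeling` with matching shape.
#' @return numeric matrix of per-superpixel means.
#' @export
superpixel_image <- function(image, labeling) {
  stopifnot(inherits(labeling, "superpixel_labeling"))
  if (!identical(dim(image), dim(labeling$labels)))
    stop("image and labeling shapes differ")
  f <- as.vector(labeling$labels)
  means <- as.vector(rowsum(as.vector(image), f) / tabulate(f))
  matrix(means[f], nrow(image), ncol(image))
}

#' Per-pixel gradient channel
#'
#' Gradient of each pixel against its 8 neighbors, with edge replication at
#' the borders: either the maximum absolute difference (default) or the mean
#' of the 8 absolute differences.
#'
#' @param image numeric matrix.
#' @param method `"max"` or `"mean"`.
#' @return numeric matrix, same shape.
#' @export
gradient_channel <- function(image, method = c("max", "mean")) {
  method <- match.arg(method)
  cpp_gradient8(image, method == "mean")
}

#' Normalized positional channels
#'
#' `pos_x[r, c] = (c-1)/(w-1)` and `pos_y[r, c] = (r-1)/(h-1)` (0 on a
#' singleton axis), encoding absolute position in [0, 1].
#'
#' @param h,w image dimensions.
#' @return list with matrices `pos_x`, `pos_y`.
#' @export
position_channels <- function(h, w) {
  if (h < 1 || w < 1) stop("h and w must be >= 1")
  px <- if (w == 1L) matrix(0, h, w)
        else matrix(rep((seq_len(w) - 1) / (w - 1), each = h), h, w)
  py <- if (h == 1L) matrix(0, h, w)
        else matrix(rep((seq_len(h) - 1) / (h - 1), times = w), h, w)
  list(pos_x = px, pos_y = py)
}

#' Build the proxy image of a slice
#'
#' Runs SLIC, enforces connectivity, mean-colors the superpixels, and attaches
#' the gradient channel (computed on the superpixel image) plus the two
#' positional channels.
#'
#' @param slice numeric matrix (preprocessed).
#' @param params a [slic_params()].
#' @param min_size passed to [enforce_connectivity()].
#' @param gradient_method passed to [gradient_channel()].
#' @return An object of class `proxy_image` with fields `intensity`,
#'   `gradient`, `pos_x`, `pos_y` and the final `labeling`.
#' @export
build_proxy <- function(slice, params, min_size = NULL,
                        gradient_method = "max") {
  lab <- enforce_connectivity(slic_segment(slice, params), min_size)
  intensity <- superpixel_image(slice, lab)
  pos <- position_channels(nrow(slice), ncol(slice))
  structure(list(intensity = intensity,
                 gradient = gradient_channel(intensity, gradient_method),
                 pos_x = pos$pos_x, pos_y = pos$pos_y, labeling = lab),
            class = "proxy_image")
}

#' @export
print.proxy_image <- function(x, ...) {
  cat(sprintf("proxy_image: %d x %d, %d superpixels\n",
              nrow(x$intensity), ncol(x$intensity), nrow(x$labeling$centers)))
  invisible(x)
}
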