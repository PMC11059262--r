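#' Gray-value histogram of an organ
#'
#' Pools the masked voxel intensities of one or more annotated, identically
#' preprocessed volumes into a probability histogram. In the intended
#' workflow a handful of volumes (the calibration set) are annotated once and
#' the histogram then drives key-interval and key-slice selection for all
#' further volumes of the same organ.
#'
#' @param samples list of `list(volume = ct_volume, mask = 0/1 array)` pairs.
#' @param bin_width histogram bin width in image units (default 0.05, suited
#'   to z-scored intensities).
#' @return An object of class `gray_histogram`: `bin_edges` (length B+1,
#'   strictly increasing) and `probabilities` (length B, summing to 1).
#' @export
organ_histogram <- function(samples, bin_width = 0.05) {
  if (length(samples) < 1L) stop("empty sample set")
  vals <- unlist(lapply(samples, function(s) {
    stopifnot(inherits(s$volume, "ct_volume"))
    if (!identical(dim(s$mask), dim(s$volume$voxels)))
      stop("mask shape does not match volume shape")
    s$volume$voxels[s$mask == 1]
  }))
  if (length(vals) == 0L) stop("all masks empty")
  if (bin_width <= 0) stop("bin_width must be positive")
  e0 <- floor(min(vals) / bin_width) * bin_width
  nb <- max(1L, ceiling((max(vals) - e0) / bin_width + 1e-12))
  edges <- e0 + bin_width * (0:nb)
  idx <- pmin(floor((vals - e0) / bin_width) + 1L, nb) # top edge closes last bin
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges, probabilities = counts / length(vals)),
            class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  cat(sprintf("gray_histogram: %d bins on [%.4g, %.4g]\n",
              length(x$probabilities), min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' Key gray-value interval from a histogram
#'
#' Selects bins in descending probability (ties broken toward the lower bin
#' edge) until the cumulative probability reaches `mass`, then returns the
#' convex hull of the selected bins as one inclusive interval. With the
#' default `mass = 0.5` this is the gray range carrying the top half of the
#' organ's probability mass, which downstream stages treat as "key voxels".
#'
#' @param hist a `gray_histogram`.
#' @param mass target cumulative probability in (0, 1].
#' @return An object of class `key_interval` with fields `lo`, `hi`.
#' @export
key_interval <- function(hist, mass = 0.5) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (!is.numeric(mass) || mass <= 0 || mass > 1) stop("invalid mass")
  p <- hist$probabilities
  lo_edges <- hist$bin_edges[-length(hist$bin_edges)]
  ord <- order(-p, lo_edges)
  cum <- cumsum(p[ord])
  n_sel <- which(cum >= mass - 1e-12)[1]
  sel <- ord[seq_len(n_sel)]
  structure(list(lo = min(hist$bin_edges[sel]),
                 hi = max(hist$bin_edges[sel + 1L]),
                 mass = sum(p[sel]), bins = sort(sel)),
            class = "key_interval")
}

#' Construct a key interval directly from bounds
#' @param lo,hi inclusive intensity bounds, `lo <= hi`.
#' @export
as_key_interval <- function(lo, hi) {
  if (lo > hi) stop("lo must be <= hi")
  structure(list(lo = lo, hi = hi), class = "key_interval")
}

#' @export
print.key_interval <- function(x, ...) {
  cat(sprintf("key_interval: [%.6g, %.6g]\n", x$lo, x$hi))
  invisible(x)
}

#' Count pixels of a slice inside a key interval
#' @param slice numeric matrix.
#' @param interval a `key_interval`.
#' @return integer count of pixels p with `lo <= p <= hi`.
#' @export
count_key_voxels <- function(slice, interval) {
  stopifnot(inherits(interval, "key_interval"))
  sum(slice >= interval$lo & slice <= interval$hi)
}

#' Select key slices of a volume
#'
#' The key slice is the axial slice containing the most pixels inside the key
#' interval; it is where segmentation starts. Returns the `k` top slices in
#' descending count, ties broken toward the lower slice index. If no slice
#' contains any key voxel the first slice is returned with a warning so that
#' pipelines fail soft.
#'
#' @param vol a preprocessed `ct_volume`.
#' @param interval a `key_interval`.
#' @param k number of slices to return (default 1).
#' @return integer vector of 1-based slice indices, with the per-slice counts
#'   as attribute `counts`.
#' @export
select_key_slices <- function(vol, interval, k = 1L) {
  stopifnot(inherits(vol, "ct_volume"))
  n <- dim(vol$voxels)[1]
  if (k < 1L || k > n) stop("k out of range")
  counts <- vapply(seq_len(n),
                   function(s) count_key_voxels(get_slice(vol, s), interval),
                   numeric(1))
  if (all(counts == 0))
    warning("no slice contains key voxels; returning the first slice(s)")
  idx <- order(-counts, seq_len(n))[seq_len(k)]
  structure(as.integer(idx), counts = counts)
}

#' Write / read a gray histogram as two-column delimited text
#'
#' Format: one row per bin edge; the probability column holds the probability
#' of the bin starting at that edge and NA on the final (closing) edge, so
#' calibrated histograms can ship as plain-text fixtures.
#'
#' @param hist a `gray_histogram`.
#' @param path text file path.
#' @rdname histogram_io
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "gray_histogram"))
  df <- data.frame(bin_edge = hist$bin_edges,
                   probability = c(hist$probabilities, NA))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname histogram_io
#' @export
read_histogram <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  structure(list(bin_edges = df$bin_edge,
                 probabilities = df$probability[-nrow(df)]),
            class = "gray_histogram")
}
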