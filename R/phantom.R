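#' Synthetic CT phantom configuration
#'
#' Describes a CT-like test volume: Gaussian background tissue, two (or more)
#' ellipsoidal organs with overlapping Gaussian intensity distributions,
#' an optional bright tubular vessel through the first (large) organ, an
#' optional adhering blob of near-organ intensity touching the large organ,
#' and additive lattice-wide noise. All intensities are Hounsfield units.
#'
#' Defaults model a contrast-CT abdomen at reduced resolution: a liver-like
#' 20x34x30 ellipsoid at 100 +/- 15 HU, a spleen-like 10x16x14 ellipsoid at
#' 110 +/- 15 HU, background 40 +/- 20 HU, 10 HU noise, vessel 200 HU.
#'
#' @param shape volume dimensions (slices, rows, cols); default 64x128x128.
#' @param organs named list; each entry has `center` (1-based voxel
#'   coordinates), `semiaxes` (voxels), `mean` and `sd` (HU).
#' @param background list with `mean`, `sd` (HU).
#' @param noise_sigma additive Gaussian noise (HU).
#' @param vessel list: `enabled`, `radius` (voxels), `intensity` (HU).
#' @param adhesion list: `enabled`, `offset` (voxels, relative to the first
#'   organ's center), `semiaxes`, `delta` (HU, |delta| <= 5).
#' @param patch patch side used for ground-truth patch labels (default 32).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 128L, 128L),
                           organs = list(
                             liver = list(center = c(33, 64, 48),
                                          semiaxes = c(20, 34, 30),
                                          mean = 100, sd = 15),
                             spleen = list(center = c(34, 70, 100),
                                           semiaxes = c(10, 16, 14),
                                           mean = 110, sd = 15)),
                           background = list(mean = 40, sd = 20),
                           noise_sigma = 10,
                           vessel = list(enabled = FALSE, radius = 3,
                                         intensity = 200),
                           adhesion = list(enabled = FALSE,
                                           offset = c(0, 41, 0),
                                           semiaxes = c(5, 8, 8),
                                           delta = 5),
                           patch = 32L) {
  shape <- as.integer(shape)
  for (nm in names(organs)) {
    o <- organs[[nm]]
    if (any(o$center - o$semiaxes < 1) || any(o$center + o$semiaxes > shape))
      stop("organ '", nm, "' out of bounds")
    if (o$mean <= -240 || o$mean >= 360)
      stop("organ '", nm, "' mean outside the clip range (-240, 360)")
  }
  if (background$mean <= -240 || background$mean >= 360)
    stop("background mean outside the clip range")
  if (isTRUE(adhesion$enabled) && abs(adhesion$delta) > 5)
    stop("adhesion delta must satisfy |delta| <= 5 HU")
  structure(list(shape = shape, organs = organs, background = background,
                 noise_sigma = noise_sigma, vessel = vessel,
                 adhesion = adhesion, patch = as.integer(patch)),
            class = "phantom_config")
}

.ellipsoid_mask <- function(shape, center, semiaxes) {
  ds <- ((seq_len(shape[1]) - center[1]) / semiaxes[1])^2
  dr <- ((seq_len(shape[2]) - center[2]) / semiaxes[2])^2
  dc <- ((seq_len(shape[3]) - center[3]) / semiaxes[3])^2
  array(as.integer(outer(outer(ds, dr, "+"), dc, "+") <= 1), shape)
}

#' Generate a synthetic CT phantom
#'
#' Fully determined by `seed`: identical config + seed give bit-identical
#' samples. Organ masks are geometric ground truth (computed before noise)
#' and exclude vessel voxels; the adhesion blob is a confuser and belongs to
#' no mask.
#'
#' @param config a [phantom_config()].
#' @param seed RNG seed.
#' @return An object of class `phantom_sample`: `volume` (a raw-HU
#'   `ct_volume`), `masks` (named list of 0/1 arrays) and `truth` (per organ:
#'   key-slice index, centroid on it, central patch index).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(seed)
  shp <- config$shape
  n <- prod(shp)
  vox <- array(rnorm(n, config$background$mean, config$background$sd), shp)
  masks <- list()
  for (nm in names(config$organs)) {
    o <- config$organs[[nm]]
    m <- .ellipsoid_mask(shp, o$center, o$semiaxes)
    for (other in masks)
      if (any(m & other)) stop("organ ellipsoids overlap")
    vox[m == 1] <- rnorm(sum(m), o$mean, o$sd)
    masks[[nm]] <- m
  }
  if (isTRUE(config$vessel$enabled)) {
    o1 <- config$organs[[1]]
    rr <- matrix(seq_len(shp[2]), shp[2], shp[3])
    cc <- matrix(seq_len(shp[3]), shp[2], shp[3], byrow = TRUE)
    disk <- (rr - o1$center[2])^2 + (cc - o1$center[3])^2 <=
      config$vessel$radius^2
    slices <- max(1, floor(o1$center[1] - o1$semiaxes[1])):
      min(shp[1], ceiling(o1$center[1] + o1$semiaxes[1]))
    for (s in slices) {
      sl <- matrix(vox[s, , ], shp[2], shp[3])
      sl[disk] <- config$vessel$intensity
      vox[s, , ] <- sl
      mk <- masks[[1]][s, , ]
      mk[disk] <- 0L
      masks[[1]][s, , ] <- mk
    }
  }
  if (isTRUE(config$adhesion$enabled)) {
    o1 <- config$organs[[1]]
    blob <- .ellipsoid_mask(shp, o1$center + config$adhesion$offset,
                            config$adhesion$semiaxes)
    sel <- blob == 1 & masks[[1]] == 0
    vox[sel] <- rnorm(sum(sel), o1$mean + config$adhesion$delta, o1$sd)
  }
  if (config$noise_sigma > 0)
    vox <- vox + array(rnorm(n, 0, config$noise_sigma), shp)
  grid <- make_patch_grid(shp[2], shp[3], config$patch)
  truth <- lapply(masks, function(m) {
    areas <- apply(m, 1, sum)
    ks <- which.max(areas) # ties -> lower index
    msl <- matrix(m[ks, , ], shp[2], shp[3])
    ctr <- .mask_center(msl, msl)
    list(key_slice = as.integer(ks),
         centroid = c(row = ctr$row, col = ctr$col),
         patch = centroid_patch_label(msl, grid))
  })
  structure(list(volume = ct_volume(vox), masks = masks, truth = truth,
                 config = config, seed = seed),
            class = "phantom_sample")
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample: %s voxels, organs: %s (seed %d)\n",
              paste(dim(x$volume$voxels), collapse = "x"),
              paste(names(x$masks), collapse = ", "), x$seed))
  invisible(x)
}

#' Generate a training set for the patch locator
#'
#' Draws `n` phantoms whose organ centers are jointly jittered (a common
#' integer in-plane shift per phantom, preserving organ disjointness),
#' preprocesses each volume, and returns the target organ's key slice with
#' its centroid-patch label. With the default geometry the large organ's
#' centroid sits near a patch boundary, so the jitter spreads labels over
#' several patches.
#'
#' @param n number of samples (>= 1).
#' @param config a [phantom_config()].
#' @param seed RNG seed; the whole dataset is reproducible from it.
#' @param organ name or index of the target organ (default 1, the large one).
#' @param jitter maximum absolute in-plane shift in voxels (default 8).
#' @return list of `list(slice, label)`; slices are preprocessed matrices.
#' @export
generate_locator_dataset <- function(n, config = phantom_config(), seed = 1L,
                                     organ = 1L, jitter = 8L) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  subseeds <- sample.int(2^20, n)
  dr <- sample(seq(-jitter, jitter), n, replace = TRUE)
  dc <- sample(seq(-jitter, jitter), n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    cfg <- config
    for (nm in names(cfg$organs))
      cfg$organs[[nm]]$center <- cfg$organs[[nm]]$center + c(0, dr[i], dc[i])
    ph <- generate_phantom(cfg, subseeds[i])
    pre <- preprocess_volume(ph$volume)
    ks <- ph$truth[[organ]]$key_slice
    list(slice = get_slice(pre, ks), label = ph$truth[[organ]]$patch)
  })
}
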