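#' Read a run configuration
#'
#' Run configurations are YAML: an input volume, an output directory, a seed,
#' optional preprocessing overrides, and one profile per organ naming its key
#' interval (explicit `lo`/`hi` or a calibrated `histogram` file), SLIC
#' settings, growth-engine overrides and the seed backend. Every ablation
#' switch (proxy on/off, gradient veto, superpixel count, termination subset,
#' closing radii, local-seed mode) is a config key.
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$organs) || length(cfg$organs) == 0L)
    stop("config names no organ profiles")
  cfg
}

.organ_interval <- function(prof) {
  if (!is.null(prof$interval))
    as_key_interval(prof$interval$lo, prof$interval$hi)
  else if (!is.null(prof$histogram))
    key_interval(read_histogram(prof$histogram),
                 mass = if (is.null(prof$mass)) 0.5 else prof$mass)
  else stop("organ profile names neither an interval nor a histogram")
}

.organ_growth <- function(prof) {
  if (is.null(prof$growth)) growth_config()
  else do.call(growth_config, prof$growth)
}

.organ_backend <- function(prof, interval, grid) {
  be <- prof$backend
  if (is.null(be) || identical(be, "histogram"))
    return(backend_histogram(interval, grid))
  if (is.list(be) && !is.null(be$oracle))
    return(backend_oracle(be$oracle[1], be$oracle[2]))
  if (is.list(be) && !is.null(be$model))
    return(backend_model(load_locator(be$model), interval, grid))
  stop("unknown seed backend")
}

#' Run the full segmentation pipeline from a configuration
#'
#' The five stages in order: preprocessing, key-slice selection, proxy-image
#' generation, seed localization, hierarchical region growing. Writes one
#' mask and one per-slice report per organ into `output_dir`.
#'
#' @param config a list as returned by [read_run_config()], or a YAML path.
#' @return invisibly, a named list per organ with `mask` and `report` paths
#'   and the termination reasons.
#' @export
run_segment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$input) || !file.exists(config$input))
    stop("missing input volume: ", config$input)
  outdir <- if (is.null(config$output_dir)) "." else config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  message("[1/5] reading and preprocessing ", config$input)
  vol <- read_volume(config$input)
  pp <- config$preprocess
  pre <- preprocess_volume(vol,
    clip_lo = if (is.null(pp$clip_lo)) -240 else pp$clip_lo,
    clip_hi = if (is.null(pp$clip_hi)) 360 else pp$clip_hi,
    median_window = if (is.null(pp$median_window)) 3 else pp$median_window)
  d <- dim(pre$voxels)
  patch <- if (is.null(config$patch)) 32L else as.integer(config$patch)
  grid <- make_patch_grid(d[2], d[3], patch)
  out <- list()
  for (nm in names(config$organs)) {
    prof <- config$organs[[nm]]
    interval <- .organ_interval(prof)
    slic <- do.call(slic_params, if (is.null(prof$slic)) list(k = 100)
                                 else prof$slic)
    gc_ <- .organ_growth(prof)
    backend <- .organ_backend(prof, interval, grid)
    message(sprintf("[2/5] %s: key interval [%.4g, %.4g]", nm,
                    interval$lo, interval$hi))
    message(sprintf(
      "[3-5/5] %s: SLIC k=%d m=%.3g | alpha=%.3g conditions=%s | growing",
      nm, slic$k, slic$m, gc_$alpha, paste(gc_$conditions, collapse = "")))
    seg <- segment_organ(pre, interval, backend, slic, gc_)
    mask_path <- file.path(outdir, paste0(nm, "_mask.nii.gz"))
    rep_path <- file.path(outdir, paste0(nm, "_report.tsv"))
    write_mask(seg$mask, mask_path, pre)
    write.table(seg$report, rep_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    message(sprintf("%s: %d voxels, stop up=%s down=%s -> %s", nm,
                    sum(seg$mask), seg$termination["up"],
                    seg$termination["down"], mask_path))
    out[[nm]] <- list(mask = mask_path, report = rep_path,
                      termination = seg$termination)
  }
  invisible(out)
}

#' Evaluate predicted masks against ground truth
#'
#' @param pred_paths,truth_paths matched vectors of mask files.
#' @param spacing optional spacing override for HD95 (defaults to the truth
#'   file's header spacing).
#' @return data frame: one row per pair with case, dsc, jsc, recall,
#'   specificity, precision, hd95 (NA where undefined).
#' @export
run_evaluate <- function(pred_paths, truth_paths, spacing = NULL) {
  if (length(pred_paths) != length(truth_paths))
    stop("unmatched prediction/truth pairs")
  if (length(pred_paths) == 0L) stop("no pairs to evaluate")
  rows <- lapply(seq_along(pred_paths), function(i) {
    pred <- read_mask(pred_paths[i])
    truth <- read_mask(truth_paths[i])
    if (!identical(dim(pred), dim(truth)))
      stop("shape mismatch for pair ", i)
    sp <- if (is.null(spacing)) attr(truth, "spacing") else spacing
    cbind(data.frame(case = basename(pred_paths[i])),
          evaluate_masks(pred, truth, sp))
  })
  do.call(rbind, rows)
}
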