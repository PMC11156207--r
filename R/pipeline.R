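#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end pipeline (image -> segmentation
#' -> fovea -> metrics -> report). Serializes to YAML and back with
#' round-trip equality.
#'
#' @param input_dir directory containing the images.
#' @param manifest path to a manifest CSV with columns
#'   `filename,scale_x,scale_y,device,scan_type` and optionally
#'   `eye,fovea_col`.
#' @param output_dir where masks, maps and the metrics table are written.
#' @param method `"unet"` (requires `checkpoint`), `"mmcq"` or `"niblack"`
#'   (both require `region_mask_dir` with region masks named like the
#'   images).
#' @param checkpoint path to a [save_unet()] checkpoint.
#' @param region_mask_dir directory of region-mask PNGs for the
#'   non-learned vessel methods.
#' @param ensemble use the 25-variant majority vote for `"mmcq"`.
#' @param vote_threshold ensemble vote threshold.
#' @param region_threshold,vessel_threshold,peripapillary_vessel_threshold
#'   binarization thresholds.
#' @param roi_half_width_um ETDRS ROI half-width in microns.
#' @param niblack_window,niblack_k Niblack parameters.
#' @param seed run seed.
#' @param verbosity 0 (quiet), 1 (per-stage log lines to stderr).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = ".", manifest = "manifest.csv",
                            output_dir = "out", method = "unet",
                            checkpoint = NULL, region_mask_dir = NULL,
                            ensemble = FALSE, vote_threshold = 15L,
                            region_threshold = 0.5, vessel_threshold = 0.5,
                            peripapillary_vessel_threshold = 0.25,
                            roi_half_width_um = 3000,
                            niblack_window = 51L, niblack_k = -0.05,
                            seed = 1L, verbosity = 1L) {
  method <- match.arg(method, c("unet", "mmcq", "niblack"))
  structure(list(input_dir = input_dir, manifest = manifest,
                 output_dir = output_dir, method = method,
                 checkpoint = checkpoint, region_mask_dir = region_mask_dir,
                 ensemble = isTRUE(ensemble),
                 vote_threshold = as.integer(vote_threshold),
                 region_threshold = as.numeric(region_threshold),
                 vessel_threshold = as.numeric(vessel_threshold),
                 peripapillary_vessel_threshold =
                   as.numeric(peripapillary_vessel_threshold),
                 roi_half_width_um = as.numeric(roi_half_width_um),
                 niblack_window = as.integer(niblack_window),
                 niblack_k = as.numeric(niblack_k),
                 seed = as.integer(seed), verbosity = as.integer(verbosity)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` to save.
#' @param path YAML file path.
#' @export
save_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
}

log_msg <- function(cfg, ...) {
  if (cfg$verbosity > 0) message(sprintf(...))
}

#' Run the end-to-end pipeline
#'
#' For every image in the manifest: load and normalize, segment (U-Net
#' checkpoint, MMCQ, or Niblack), locate the fovea, derive the ETDRS-grid
#' choroid metrics, and write masks plus one metrics row. Per-file failures
#' are recorded and the pipeline continues.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `metrics` (data frame, one row per
#'   successfully processed image), `errors` (named character vector), and
#'   `output_dir`. The metrics table, per-image masks/maps, and a YAML
#'   snapshot of the configuration are written to `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stopifnot(inherits(cfg, "pipeline_config"))
  if (cfg$method == "unet" &&
      (is.null(cfg$checkpoint) || !file.exists(cfg$checkpoint)))
    stop("method 'unet' requires an existing checkpoint", call. = FALSE)
  if (cfg$method != "unet" && is.null(cfg$region_mask_dir))
    stop("methods 'mmcq'/'niblack' require region_mask_dir", call. = FALSE)
  man <- read.csv(file.path(cfg$manifest), stringsAsFactors = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  model <- if (cfg$method == "unet") load_unet(cfg$checkpoint) else NULL

  rows <- list()
  errors <- character(0)
  for (i in seq_len(nrow(man))) {
    fn <- man$filename[i]
    t_start <- proc.time()[["elapsed"]]
    res <- tryCatch({
      scan <- load_bscan(file.path(cfg$input_dir, fn),
                         scale_x = man$scale_x[i], scale_y = man$scale_y[i],
                         device = if ("device" %in% names(man)) man$device[i] else "unknown",
                         scan_type = if ("scan_type" %in% names(man)) man$scan_type[i] else "hline")
      seg <- if (cfg$method == "unet") {
        predict_scan(model, scan)
      } else {
        base_fn <- tools::file_path_sans_ext(fn)
        rm_path <- file.path(cfg$region_mask_dir, paste0(base_fn, "_region.png"))
        if (!file.exists(rm_path)) rm_path <- file.path(cfg$region_mask_dir, fn)
        region <- as_mask(png::readPNG(rm_path))
        vessel <- if (cfg$method == "mmcq") {
          if (cfg$ensemble)
            ensemble_majority_vote(scan$image, region,
                                   ens = ensemble_config(vote_threshold = cfg$vote_threshold))
          else segment_vessels_mmcq(scan$image, region)
        } else {
          segment_vessels_niblack(scan$image, region,
                                  niblack_config(cfg$niblack_window, cfg$niblack_k))
        }
        fov <- if ("fovea_col" %in% names(man) && !is.na(man$fovea_col[i])) {
          fr <- if ("fovea_row" %in% names(man) && !is.na(man$fovea_row[i]))
            man$fovea_row[i] else nrow(scan$image) %/% 2L
          build_fovea_target(dim(scan$image), man$fovea_col[i], fr)
        } else matrix(0, nrow(scan$image), ncol(scan$image))
        structure(list(region_prob = region * 1, vessel_prob = vessel * 1,
                       fovea_prob = fov), class = "segmentation_output")
      }
      base <- tools::file_path_sans_ext(fn)
      write_mask_png(seg$region_prob >= cfg$region_threshold,
                     file.path(cfg$output_dir, paste0(base, "_region.png")))
      write_mask_png(seg$vessel_prob >= cfg$vessel_threshold,
                     file.path(cfg$output_dir, paste0(base, "_vessel.png")))
      write_mask_png(clip01(seg$fovea_prob),
                     file.path(cfg$output_dir, paste0(base, "_fovea.png")))
      met <- analyze_scan(scan, seg,
                          region_threshold = cfg$region_threshold,
                          vessel_threshold = cfg$vessel_threshold,
                          peripapillary_vessel_threshold =
                            cfg$peripapillary_vessel_threshold)
      if (is.null(met$thickness_um)) {   # peripapillary: masks only
        data.frame(filename = fn, fovea_col = NA, thickness_t = NA,
                   thickness_c = NA, thickness_n = NA,
                   thickness_mean_um = NA, area_mm2 = NA, cvi = NA,
                   soft_cvi = NA, flags = "peripapillary")
      } else {
        data.frame(filename = fn, fovea_col = met$fovea_col,
                   thickness_t = met$thickness_um[1],
                   thickness_c = met$thickness_um[2],
                   thickness_n = met$thickness_um[3],
                   thickness_mean_um = met$thickness_mean_um,
                   area_mm2 = met$area_mm2, cvi = met$cvi,
                   soft_cvi = met$soft_cvi,
                   flags = paste(met$flags, collapse = ";"))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[fn] <- conditionMessage(res)
      log_msg(cfg, "[pipeline] %s FAILED: %s", fn, conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
      log_msg(cfg, "[pipeline] %s done in %.2fs", fn,
              proc.time()[["elapsed"]] - t_start)
    }
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filename = character(0))
  write.csv(metrics, file.path(cfg$output_dir, "metrics.csv"),
            row.names = FALSE)
  save_pipeline_config(cfg, file.path(cfg$output_dir, "config_snapshot.yaml"))
  if (length(errors)) {
    err_df <- data.frame(filename = names(errors), error = unname(errors))
    write.csv(err_df, file.path(cfg$output_dir, "errors.csv"),
              row.names = FALSE)
  }
  invisible(list(metrics = metrics, errors = errors,
                 output_dir = cfg$output_dir))
}
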