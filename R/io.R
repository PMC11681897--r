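#' Write a speckle stack to disk (raw binary + JSON sidecar)
#'
#' Frames are stored as a flat little-endian array in C frame order
#' (frame, row, column), either `float32` or, when `quantize = TRUE`,
#' `uint16` scaled to the configured bit depth. All acquisition metadata
#' (shape, dtype, exposure, frame rate, wavelength, pixel pitch, seed,
#' timestamps) goes to a JSON sidecar so the stack round-trips exactly.
#'
#' @param stack a `speckle_stack`.
#' @param path output path for the binary payload (e.g. `stack.raw`).
#' @param metadata_path JSON sidecar path (default `paste0(path, ".json")`).
#' @param quantize store as uint16 (lossy) instead of float32.
#' @return invisibly, the two paths written.
#' @export
write_stack <- function(stack, path, metadata_path = paste0(path, ".json"),
                        quantize = FALSE) {
  if (!inherits(stack, "speckle_stack")) stop_invalid("stack must be a speckle_stack")
  d <- dim(stack$frames)
  # C order: frame-major, then row, then column
  flat <- as.vector(aperm(stack$frames, c(3, 2, 1)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (quantize) {
    maxv <- max(flat)
    scale <- if (maxv > 0) (2^stack$config$bit_depth - 1) / maxv else 1
    q <- as.integer(round(flat * scale))
    writeBin(q, con, size = 4L, endian = "little")   # int32 carrier for uint16 range
    dtype <- "uint16_as_int32"
  } else {
    writeBin(flat, con, size = 8L, endian = "little")
    scale <- 1
    dtype <- "float64"
  }
  meta <- list(
    n_frames = d[1], height = d[2], width = d[3], dtype = dtype,
    order = "frame_row_col", scale = scale,
    exposure_time_s = stack$config$exposure_time,
    frame_rate_hz = stack$config$frame_rate,
    wavelength_m = stack$config$wavelength,
    pixel_pitch_mm = stack$config$pixel_pitch,
    bit_depth = stack$config$bit_depth,
    seed = stack$seed,
    timestamps_s = stack$timestamps,
    phantom_label = stack$phantom_label)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, metadata_path))
}

#' Read a speckle stack written by [write_stack()]
#'
#' Validates the payload length against the sidecar shape and errors with
#' the missing key names if the sidecar is incomplete.
#'
#' @param path binary payload path.
#' @param metadata_path JSON sidecar path.
#' @return a `speckle_stack`.
#' @export
read_stack <- function(path, metadata_path = paste0(path, ".json")) {
  if (!file.exists(metadata_path))
    stop("missing metadata file: ", metadata_path)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  need <- c("n_frames", "height", "width", "dtype", "exposure_time_s",
            "frame_rate_hz", "wavelength_m")
  missing_keys <- setdiff(need, names(meta))
  if (length(missing_keys))
    stop("metadata is missing required keys: ", paste(missing_keys, collapse = ", "))
  n <- meta$n_frames * meta$height * meta$width
  con <- file(path, "rb")
  on.exit(close(con))
  flat <- if (meta$dtype == "float64") {
    readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
  } else {
    readBin(con, "integer", n = n + 1L, size = 4L, endian = "little") / meta$scale
  }
  if (length(flat) != n)
    stop(sprintf("corrupt input: expected %d values, file holds %d", n, length(flat)))
  frames <- aperm(array(flat, dim = c(meta$width, meta$height, meta$n_frames)),
                  c(3, 2, 1))
  cfg <- acquisition_config(
    exposure_time = meta$exposure_time_s, frame_rate = meta$frame_rate_hz,
    wavelength = meta$wavelength_m,
    sensor_shape = c(meta$height, meta$width),
    pixel_pitch = if (is.null(meta$pixel_pitch_mm)) 0.15625 else meta$pixel_pitch_mm,
    bit_depth = if (is.null(meta$bit_depth)) 16L else meta$bit_depth)
  structure(
    list(frames = frames, config = cfg,
         timestamps = if (is.null(meta$timestamps_s))
           (seq_len(meta$n_frames) - 1) / meta$frame_rate_hz else meta$timestamps_s,
         phantom_label = meta$phantom_label,
         seed = if (is.null(meta$seed)) NA_integer_ else meta$seed),
    class = "speckle_stack")
}

#' Write a phantom manifest (JSON + raw tau map)
#' @param phantom a `flow_phantom`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the manifest path.
#' @export
write_phantom <- function(phantom, dir, name = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tau_file <- file.path(dir, paste0(name, "_tau.raw"))
  con <- file(tau_file, "wb")
  tau <- as.vector(t(phantom$tau_map))            # row-major
  tau[!is.finite(tau)] <- -1                      # Inf sentinel on disk
  writeBin(tau, con, size = 8L, endian = "little")
  close(con)
  manifest <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    list(label = phantom$label, beta = phantom$beta,
         tau_map_file = basename(tau_file),
         shape = phantom$shape, static_sentinel = -1),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write / read a cohort table as CSV
#'
#' Header starts with the canonical schema
#' `subject_id,group,SBP,DBP,MAP,HR,RR,SpO2,BT,SI,lactate,ROI1,ROI2,ROI_diff`
#' (extra columns follow). Comma-separated, UTF-8, '.' decimal, header row
#' mandatory.
#'
#' @param cohort a `cohort_table`.
#' @param path CSV path.
#' @return `write_cohort_csv`: invisibly, the path; `read_cohort_csv`: a
#'   `cohort_table`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "SBP", "DBP", "MAP", "HR", "RR", "SpO2",
            "BT", "SI", "ROI1", "ROI2", "ROI_diff")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols))
    stop("cohort CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write / read an ROI time series CSV
#'
#' Schema: `time_s,roi1,roi2,roi_diff,roi_ratio` (per-sample difference and
#' normalized difference included for convenience).
#' @param series an `roi_series`.
#' @param path CSV path.
#' @export
write_roi_csv <- function(series, path) {
  df <- data.frame(time_s = series$time_s, roi1 = series$roi1,
                   roi2 = series$roi2,
                   roi_diff = series$roi1 - series$roi2,
                   roi_ratio = (series$roi1 - series$roi2) / series$roi2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path)
  roi_series(df$time_s, df$roi1, df$roi2)
}

#' Write / read an RR-interval series CSV (`index,rr_ms`)
#' @param rr an `rr_series` or numeric vector (ms).
#' @param path CSV path.
#' @export
write_rr_csv <- function(rr, path) {
  utils::write.csv(data.frame(index = seq_along(rr), rr_ms = as.numeric(rr)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(df$rr_ms, t0 = 0, class = "rr_series")
}

#' Serialize / restore a run configuration (JSON)
#'
#' The run configuration bundles the acquisition settings, contrast window,
#' contrast model, ROI specs, metric window, classifier and seed; it
#' round-trips losslessly through JSON.
#'
#' @param acquisition an [acquisition_config()].
#' @param contrast_window odd window side, px.
#' @param model a [contrast_model_spec()].
#' @param roi_specs list of [roi_spec()].
#' @param metric_window_s shock-metric window, seconds.
#' @param classifier a [classifier_config()].
#' @param seed integer seed.
#' @param output_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(acquisition = acquisition_config(),
                       contrast_window = 7L,
                       model = contrast_model_spec(),
                       roi_specs = list(),
                       metric_window_s = 60,
                       classifier = classifier_config("roi_ratio"),
                       seed = 1L,
                       output_dir = ".") {
  contrast_window <- check_count(contrast_window, "contrast_window", min = 3L)
  if (contrast_window %% 2L == 0L) stop_invalid("contrast_window must be odd")
  structure(list(acquisition = acquisition, contrast_window = contrast_window,
                 model = model, roi_specs = roi_specs,
                 metric_window_s = metric_window_s, classifier = classifier,
                 seed = check_count(seed, "seed", min = 0L),
                 output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(
    acquisition = do.call(acquisition_config, j$acquisition[
      c("exposure_time", "frame_rate", "wavelength", "sensor_shape",
        "pixel_pitch", "bit_depth")]),
    contrast_window = j$contrast_window,
    model = contrast_model_spec(j$model$model, j$model$beta, j$model$literal_form),
    roi_specs = lapply(seq_len(NROW(j$roi_specs)), function(i) {
      r <- if (is.data.frame(j$roi_specs)) as.list(j$roi_specs[i, ]) else j$roi_specs[[i]]
      roi_spec(r$label, unlist(r$center), r$radius, r$units, r$anatomical_hint)
    }),
    metric_window_s = j$metric_window_s,
    classifier = classifier_config(j$classifier$metric, j$classifier$cutoff,
                                   j$classifier$positive_if),
    seed = j$seed, output_dir = j$output_dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Write a run's output file set
#'
#' Emits the ROI series CSV, the evaluation report CSV, per-map perfusion
#' binaries and a JSON run manifest (config hash, seed, file list) with
#' deterministic names. Empty results produce the manifest only.
#'
#' @param results named list; recognized entries: `roi_series`
#'   (`roi_series`), `evaluation` (data.frame report), `perfusion`
#'   (`perfusion_sequence`), `config` (`run_config`).
#' @param output_dir directory (created if needed).
#' @return invisibly, character vector of files written.
#' @export
write_outputs <- function(results, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(results$roi_series)) {
    p <- file.path(output_dir, "roi_series.csv")
    write_roi_csv(results$roi_series, p); files <- c(files, p)
  }
  if (!is.null(results$evaluation)) {
    p <- file.path(output_dir, "evaluation.csv")
    utils::write.csv(results$evaluation, p, row.names = FALSE, quote = FALSE)
    files <- c(files, p)
  }
  if (!is.null(results$perfusion)) {
    for (i in seq_along(results$perfusion$maps)) {
      p <- file.path(output_dir, sprintf("perfusion_%04d.raw", i))
      m <- results$perfusion$maps[[i]]$P
      m[!is.finite(m)] <- -1
      con <- file(p, "wb")
      writeBin(as.vector(t(m)), con, size = 8L, endian = "little")
      close(con)
      files <- c(files, p)
    }
  }
  cfg <- results$config
  cfg_json <- if (!is.null(cfg))
    jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA) else NULL
  manifest <- list(
    files = basename(files),
    seed = if (!is.null(cfg)) cfg$seed else NULL,
    config = if (!is.null(cfg)) jsonlite::fromJSON(cfg_json, simplifyVector = FALSE) else NULL,
    config_hash = if (!is.null(cfg_json))
      sprintf("%08x", sum(utf8ToInt(as.character(cfg_json)) *
                            (seq_len(nchar(cfg_json)) %% 97)) %% .Machine$integer.max)
      else NULL)
  mp <- file.path(output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, mp))
}
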