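#' Write a trap trace as a tab-delimited table
#'
#' Columns: `time_s`, `x_nm`, optionally `y_nm`, optionally `stage_x_um`.
#' Values are written with 10 significant digits so a round trip is lossless
#' at the declared precision; comment lines start with `#`.
#'
#' @param trace a [trap_trace()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "trap_trace"))
  df <- data.frame(time_s = trace$time, x_nm = trace$position_x)
  if (!is.null(trace$position_y)) df$y_nm <- trace$position_y
  if (!is.null(trace$stage_position)) df$stage_x_um <- trace$stage_position
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trap trace, sampling_rate_hz=%.10g, units=%s",
                     trace$sampling_rate, trace$units_flag), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  lines <- do.call(paste, c(lapply(df, function(v) sprintf("%.10g", v)),
                            sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read a trap trace table
#'
#' Tab-delimited with a header naming the columns (`time_s`, `x_nm`,
#' optional `y_nm`, optional `stage_x_um`, any order); lines starting with
#' `#` are comments. A `sampling_rate_hz` annotation in the comments is
#' honoured; otherwise the rate is inferred from the time stamps.
#'
#' @param path file written by [write_trace()] or of the same format
#' @param units_flag "physical" or "detector"
#' @return a [trap_trace()]
#' @export
read_trace <- function(path, units_flag = NULL) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  head_lines <- readLines(path, n = 20)
  comments <- grep("^#", head_lines, value = TRUE)
  fs <- NULL
  m <- regmatches(comments, regexpr("sampling_rate_hz=[0-9.eE+-]+", comments))
  if (length(m) > 0)
    fs <- as.numeric(sub("sampling_rate_hz=", "", m[[1]]))
  if (is.null(units_flag)) {
    units_flag <- if (any(grepl("units=detector", comments))) "detector"
                  else "physical"
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  for (col in c("time_s", "x_nm")) {
    if (!col %in% names(df))
      stop("trace file missing mandatory column '", col, "': ", path)
  }
  trap_trace(time = df$time_s, position_x = df$x_nm,
             position_y = if ("y_nm" %in% names(df)) df$y_nm,
             stage_position = if ("stage_x_um" %in% names(df)) df$stage_x_um,
             sampling_rate = fs, units_flag = units_flag)
}

#' Read an image stack from a TIFF file
#'
#' Single-channel, uniform-shape multi-page TIFF; a single-page file yields
#' one frame. RGB/multi-channel files are rejected.
#'
#' @param path TIFF file
#' @return list of numeric image matrices
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  for (f in frames) {
    if (length(dim(f)) > 2)
      stop("unsupported format: multi-channel (e.g. RGB) TIFF")
  }
  shapes <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(shapes)) != 1) stop("mixed frame shapes in stack")
  frames
}

#' Read an 8-bit ROI mask TIFF
#'
#' @param path TIFF file; nonzero pixels are inside the ROI
#' @return logical matrix
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) > 2) stop("mask must be single-channel")
  m > 0
}

#' Read a pipeline configuration file
#'
#' YAML key/value hierarchy; see [default_config()] for the recognised keys
#' and defaults. Unknown substrate labels and malformed presets are rejected
#' at load time, before any computation.
#'
#' @param path YAML file
#' @return a validated config list (class `pipeline_config`)
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(utils::modifyList(default_config(), cfg))
}

#' Default pipeline configuration
#'
#' @return list of defaults: environment (temperature 298.15 K, viscosity
#'   1e-3 Pa s, bead radius 1.08 um), trap (stiffness 0.05 pN/nm, 20 kHz,
#'   10 s), tether protocol preset and ground truth, TFM parameters, and the
#'   statistics design.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    environment = list(temperature_K = 298.15, viscosity_Pa_s = 1e-3,
                       bead_radius_um = 1.08),
    trap = list(stiffness_pN_nm = 0.05, sampling_rate_Hz = 20000,
                duration_s = 10, n_blocks = 64, band_Hz = c(50, 5000)),
    tether = list(preset = "fibroblast", n_pulls = 10,
                  peak_force_pN = 60, steady_state_force_pN = 30,
                  noise_sd_pN = 2, sampling_rate_Hz = 200),
    tfm = list(substrate = "1kPa", poisson_ratio = 0.5,
               pixel_size_um = 0.1, image_shape = c(256, 256),
               bead_density_per_um2 = 0.3, image_noise_sd = 0.05,
               n_frames = 5, window_px = 32, overlap = 0.75,
               lambda = "auto"),
    stats = list(alpha = 0.05)
  )
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!cfg$tether$preset %in% c("fibroblast", "neuron"))
    stop("unknown tether preset: ", cfg$tether$preset)
  material_preset(cfg$tfm$substrate, cfg$tfm$poisson_ratio)  # errors if unknown
  with(cfg$environment, stopifnot(temperature_K > 0, viscosity_Pa_s > 0,
                                  bead_radius_um > 0))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
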