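#' Reconstruct a time-averaged traction field from a TFM image set
#'
#' The standard TFM chain: PIV displacement of each stressed frame against
#' the reference, drift correction against the cell-free region (mask
#' complement), regularized FTTC inversion per frame, and a componentwise
#' time average. The ROI mask (pixel grid) is downsampled to the PIV grid by
#' nearest-neighbour lookup and returned alongside the field.
#'
#' @param reference reference image matrix (relaxed gel)
#' @param frames list of stressed frames
#' @param mask logical matrix on the pixel grid, TRUE inside the cell/ROI
#' @param material a [material_params()]
#' @param pixel_size um per px
#' @param window,overlap PIV parameters (see [piv_displacement()])
#' @param lambda FTTC regularization: a number, or "auto"/"lcurve" (selected
#'   once with [choose_lambda()] on the first frame, reused for all frames)
#' @param drift_correct subtract median cell-free displacement (default TRUE)
#' @return list: `traction` (time-averaged `vector_field`, Pa),
#'   `displacements` (per-frame fields), `roi` (logical matrix on the PIV
#'   grid), `lambda` (value used), `net_force` (nN, over the ROI),
#'   `summary` (from [traction_summary()])
#' @export
tfm_pipeline <- function(reference, frames, mask, material,
                         pixel_size = 0.1, window = 32, overlap = 0.75,
                         lambda = "auto", drift_correct = TRUE) {
  stopifnot(is.list(frames), length(frames) >= 1)
  disps <- lapply(frames, function(fr)
    piv_displacement(reference, fr, window = window, overlap = overlap,
                     pixel_size = pixel_size))
  grid <- disps[[1]]
  # mask on the PIV grid (nearest pixel at each window centre)
  ri <- pmin(pmax(round(grid$y / pixel_size) + 1L, 1L), nrow(mask))
  ci <- pmin(pmax(round(grid$x / pixel_size) + 1L, 1L), ncol(mask))
  roi <- mask[ri, ci, drop = FALSE]
  if (drift_correct && any(!roi))
    disps <- lapply(disps, correct_drift, cell_mask = roi)
  if (is.character(lambda))
    lambda <- choose_lambda(fill_invalid(disps[[1]]), material,
                            method = if (identical(lambda, "lcurve")) "lcurve"
                                     else "discrepancy")$lambda
  tractions <- lapply(disps, fttc_traction, material = material,
                      lambda = lambda)
  tavg <- time_average(tractions)
  uavg <- time_average(lapply(disps, fill_invalid))
  list(traction = tavg,
       displacements = disps,
       roi = roi,
       lambda = lambda,
       net_force = net_force(tavg, roi),
       summary = traction_summary(tavg, roi, uavg))
}

#' Run the full synthetic pipeline from a configuration
#'
#' Orchestrates simulate -> calibrate -> tether analysis -> TFM -> statistics
#' on synthetic data, writing every intermediate into `out_dir` and a run
#' manifest at the end. Per-stage seeds are derived from the config seed
#' with [derive_seed()], so the run is fully deterministic.
#'
#' @param config a config list from [read_config()]/[default_config()]
#' @param out_dir output directory
#' @return the run manifest (list), invisibly; also written as
#'   `manifest.json`
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  config <- validate_config(utils::modifyList(default_config(), config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("memtension")),
                   seed = config$seed, stages = list(), warnings = character(0),
                   outputs = character(0))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    val <- withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(seconds = as.numeric(Sys.time() - ts,
                                                          units = "secs"))
    val
  }
  env <- config$environment

  # 1. trap calibration on a simulated Brownian recording
  cal <- stage("calibrate", {
    tp <- trap_sim_params(stiffness_kappa = config$trap$stiffness_pN_nm,
                          bead_radius = env$bead_radius_um,
                          viscosity = env$viscosity_Pa_s,
                          temperature = env$temperature_K,
                          sampling_rate = config$trap$sampling_rate_Hz,
                          duration = config$trap$duration_s,
                          seed = derive_seed(config$seed, 1))
    trace <- simulate_trapped_bead(tp)
    write_trace(trace, file.path(out_dir, "calibration_trace.tsv"))
    cal <- calibrate(trace, bead_radius = env$bead_radius_um,
                     viscosity = env$viscosity_Pa_s,
                     temperature = env$temperature_K,
                     band = config$trap$band_Hz,
                     n_blocks = config$trap$n_blocks)
    write_calibration(cal, file.path(out_dir, "calibration.json"))
    cal
  })

  # 2. tether pulls -> PF/SSF metrics table
  metrics <- stage("tether", {
    protocol <- pull_protocol(preset = config$tether$preset)
    pulls <- lapply(seq_len(config$tether$n_pulls), function(i) {
      simulate_tether_pull(tether_sim_params(
        peak_force = config$tether$peak_force_pN,
        steady_state_force = config$tether$steady_state_force_pN,
        noise_sd = config$tether$noise_sd_pN,
        protocol = protocol,
        stiffness_kappa = cal$kappa,
        sampling_rate = config$tether$sampling_rate_Hz,
        seed = derive_seed(config$seed, 100 + i)))$trace
    })
    names(pulls) <- sprintf("pull_%03d", seq_along(pulls))
    metrics <- batch_pulls(pulls, cal, protocol,
                           group = config$tether$preset)
    utils::write.csv(metrics, file.path(out_dir, "tether_metrics.csv"),
                     row.names = FALSE)
    metrics
  })

  # 3. TFM on a synthetic image set
  tfm <- stage("tfm", {
    mat <- material_preset(config$tfm$substrate, config$tfm$poisson_ratio)
    bundle <- simulate_tfm_dataset(tfm_sim_params(
      image_shape = config$tfm$image_shape,
      pixel_size = config$tfm$pixel_size_um,
      bead_density = config$tfm$bead_density_per_um2,
      material = mat,
      image_noise_sd = config$tfm$image_noise_sd,
      seed = derive_seed(config$seed, 200)), n_frames = config$tfm$n_frames)
    write_tfm_dataset(bundle, file.path(out_dir, "tfm"))
    res <- tfm_pipeline(bundle$reference, bundle$frames, bundle$roi, mat,
                        pixel_size = config$tfm$pixel_size_um,
                        window = config$tfm$window_px,
                        overlap = config$tfm$overlap,
                        lambda = config$tfm$lambda)
    utils::write.csv(
      data.frame(cell_id = "synthetic_1", group = config$tfm$substrate,
                 mean_stress_Pa = res$summary[["mean_stress_Pa"]],
                 net_force_nN = res$net_force[["Fmag_nN"]]),
      file.path(out_dir, "tfm_summary.csv"), row.names = FALSE)
    res
  })

  # 4. statistics on the tether metrics (single-group demo design runs only
  # when the metrics table has >= 2 groups)
  stage("stats", {
    ok <- metrics[is.na(metrics$error), , drop = FALSE]
    if (length(unique(ok$group)) >= 2) {
      report <- compare_conditions(ok, list(
        list(metric = "SSF_pN", grouping = "group",
             test = if (length(unique(ok$group)) == 2) "mann_whitney"
                    else "kruskal_wallis+posthoc")))
      write_report(report, file.path(out_dir, "stats_report.json"))
    }
    NULL
  })

  manifest$outputs <- list.files(out_dir, recursive = TRUE)
  manifest$total_seconds <- as.numeric(Sys.time() - t0, units = "secs")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
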