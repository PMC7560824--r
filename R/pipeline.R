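#' Default pipeline configuration
#'
#' Full parameter tree for one simulated examination, at the test scale the
#' package uses by default: a 15 x 15 x 7 voxel grid over 13.2 x 13.2 x 6.6
#' mm centered on the vessels, 4096 time samples per Lissajous period, 20 s
#' of acquisition with injection at 4 s. All values can be overridden via a
#' YAML file or an override list.
#'
#' @return Nested named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    scanner = list(
      base_frequency = 2.5e6,
      frequency_divisors = c(102L, 96L, 99L),
      drive_amplitude_mT = c(12, 12, 12),
      gradient_strength = c(1.25, 1.25, 2.5),
      recon_grid = c(15L, 15L, 7L),
      recon_volume_mm = c(13.2, 13.2, 6.6),
      samples_per_frame = 4096L
    ),
    tracer = list(preset = "mcp3"),
    phantom = list(dose_mmol_kg = 0.1),
    kinetics = list(respiratory_rate_bpm = 60, respiratory_depth = 0.1),
    signal = list(
      duration_s = 20,
      injection_time_s = 4,
      frame_stride = 4L,
      noise_sd = NULL,
      component_snr = 100,
      background_scale = 0.1,
      calibration_concentration = 100,
      max_frequency_index = NULL,
      min_snr = 2,
      max_components = 600L
    ),
    recon = list(
      lambda_rel = 1e-3,
      sweeps = 10L,
      nonneg = TRUE,
      row_order = "snr"
    ),
    analysis = list(
      threshold_fraction = 0.30,
      voi_min_fraction = 0.5,
      t1_offset_frames = 0L
    )
  )
}

#' Load, merge and validate a pipeline configuration
#'
#' Reads a YAML file (or takes an override list), merges it over the
#' defaults, and checks every invariant the domain objects impose,
#' collecting all violations with their key paths before failing.
#'
#' @param file Path to a YAML configuration file, or NULL.
#' @param overrides Named list merged over the file/defaults.
#' @return Normalized configuration list with an attribute
#'   \code{echo} holding derived quantities (frame rate, FOV).
#' @export
validate_config <- function(file = NULL, overrides = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(file)) {
    loaded <- yaml::read_yaml(file)
    cfg <- modify_tree(cfg, loaded)
  }
  if (!is.null(overrides)) cfg <- modify_tree(cfg, overrides)

  errors <- character()
  note <- function(path, msg) errors[[length(errors) + 1L]] <<-
    paste0(path, ": ", msg)

  sc <- try(scanner_config(
    base_frequency = cfg$scanner$base_frequency,
    frequency_divisors = cfg$scanner$frequency_divisors,
    drive_amplitude = cfg$scanner$drive_amplitude_mT / 1e3,
    gradient_strength = cfg$scanner$gradient_strength,
    recon_grid = cfg$scanner$recon_grid,
    recon_volume = cfg$scanner$recon_volume_mm,
    samples_per_frame = cfg$scanner$samples_per_frame
  ), silent = TRUE)
  if (inherits(sc, "try-error")) {
    note("scanner", conditionMessage(attr(sc, "condition")))
  }

  tr <- try(build_tracer(cfg$tracer, cfg$phantom$dose_mmol_kg), silent = TRUE)
  if (inherits(tr, "try-error")) {
    note("tracer", conditionMessage(attr(tr, "condition")))
  } else if (tr$blood_half_life_min <= 0) {
    note("tracer.blood_half_life", "must be positive")
  }
  if (cfg$phantom$dose_mmol_kg < 0) note("phantom.dose_mmol_kg", "must be >= 0")
  if (cfg$kinetics$respiratory_depth < 0 ||
      cfg$kinetics$respiratory_depth >= 1) {
    note("kinetics.respiratory_depth", "must be in [0, 1)")
  }
  if (cfg$kinetics$respiratory_rate_bpm <= 0) {
    note("kinetics.respiratory_rate_bpm", "must be positive")
  }
  if (cfg$signal$duration_s <= cfg$signal$injection_time_s) {
    note("signal.duration_s", "must exceed injection_time_s")
  }
  if (!is.null(cfg$signal$noise_sd) && cfg$signal$noise_sd < 0) {
    note("signal.noise_sd", "must be >= 0")
  }
  if (is.null(cfg$signal$noise_sd) && cfg$signal$component_snr <= 0) {
    note("signal.component_snr", "must be positive")
  }
  if (cfg$recon$sweeps < 1) note("recon.sweeps", "must be >= 1")
  if (cfg$analysis$threshold_fraction <= 0 ||
      cfg$analysis$threshold_fraction > 1) {
    note("analysis.threshold_fraction", "must be in (0, 1]")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  }
  attr(cfg, "echo") <- list(
    frame_rate = frame_rate(sc),
    lissajous_period_s = lissajous_period(sc),
    fov_extent_mm = fov_extent(sc)
  )
  cfg
}

build_tracer <- function(tracer_cfg, dose) {
  if (!is.null(tracer_cfg$preset)) {
    switch(tolower(tracer_cfg$preset),
           mcp3 = tracer_mcp3(dose),
           resovist = tracer_resovist(),
           stop("unknown tracer preset: ", tracer_cfg$preset, call. = FALSE))
  } else {
    tracer_model(
      name = tracer_cfg$name,
      core_populations = data.frame(
        diameter_nm = tracer_cfg$core_diameters_nm,
        number_fraction = tracer_cfg$number_fractions),
      hydrodynamic_diameter_nm = tracer_cfg$hydrodynamic_diameter_nm,
      blood_half_life_min = tracer_cfg$blood_half_life_min,
      stock_concentration = tracer_cfg$stock_concentration %||% NA_real_)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recursively merge override values over a default tree
modify_tree <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      base[[nm]] <- modify_tree(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Run the full simulated examination pipeline
#'
#' Executes the complete chain: phantom generation, system-function
#' calibration, raw-signal simulation with background, noise and
#' respiratory modulation, background subtraction, frame-by-frame Kaczmarz
#' reconstruction, concentration-time curves, t1/t2 selection, digital
#' subtraction, lumen diameter measurement, and respiratory biosignal
#' extraction. Deterministic for a fixed (config, seed) pair.
#'
#' @param config Configuration list from \code{\link{validate_config}}, a
#'   YAML path, or NULL for the defaults.
#' @param seed Integer seed controlling body weight and all noise.
#' @param out_dir Optional directory: when given, the full run container is
#'   written there.
#' @return List of class \code{mpi_run} with stage results (see
#'   \code{\link{run_container}} for the layout).
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir = NULL) {
  if (is.null(config)) config <- validate_config()
  if (is.character(config)) config <- validate_config(config)
  seed <- as.integer(seed)

  sc <- scanner_config(
    base_frequency = config$scanner$base_frequency,
    frequency_divisors = config$scanner$frequency_divisors,
    drive_amplitude = config$scanner$drive_amplitude_mT / 1e3,
    gradient_strength = config$scanner$gradient_strength,
    recon_grid = config$scanner$recon_grid,
    recon_volume = config$scanner$recon_volume_mm,
    samples_per_frame = config$scanner$samples_per_frame
  )
  tracer <- build_tracer(config$tracer, config$phantom$dose_mmol_kg)
  pk <- default_rat_phantom(seed = seed,
                            dose_mmol_kg = config$phantom$dose_mmol_kg,
                            tracer = tracer,
                            injection_time_s = config$signal$injection_time_s)
  pk$kinetics$respiratory_rate_bpm <- config$kinetics$respiratory_rate_bpm
  pk$kinetics$respiratory_depth <- config$kinetics$respiratory_depth
  grid_geom <- recon_grid_geometry(sc)

  stride <- config$signal$frame_stride %||% 1L
  period <- lissajous_period(sc) * stride
  times <- seq(0, config$signal$duration_s, by = period)
  truth <- truth_series(pk$phantom, pk$kinetics, tracer, times, grid_geom)

  sm <- simulate_system_matrix(
    sc, tracer, grid_geom,
    max_frequency_index = config$signal$max_frequency_index,
    calibration_concentration = config$signal$calibration_concentration)

  # receive noise: either an absolute SD, or scaled so the strongest
  # component of the peak-bolus frame has the configured SNR; retention is
  # referenced to the same peak-frame amplitudes
  t_peak <- config$signal$injection_time_s +
    pk$kinetics$ivc_arrival_delay_s + pk$kinetics$dispersion_width_s
  peak_map <- truth_series(pk$phantom, pk$kinetics, tracer, t_peak,
                           grid_geom)
  peak_amp <- abs(peak_map %*% t(sm$entries))[1, ] /
    sm$calibration_concentration
  noise_sd <- config$signal$noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- max(peak_amp) / config$signal$component_snr
  }
  if (noise_sd > 0 && max(peak_amp) > 0) {
    sm <- retain_components(sm, noise_sd,
                            min_snr = config$signal$min_snr,
                            max_components = config$signal$max_components,
                            signal_reference = peak_amp)
  } else if (!is.null(config$signal$max_components)) {
    sm <- retain_components(sm, noise_sd = 1e-300, min_snr = 0,
                            max_components = config$signal$max_components)
  }

  background <- with_seed(seed + 1000L, {
    nc <- nrow(sm$entries)
    amp <- config$signal$background_scale *
      max(abs(sm$entries)) / sm$calibration_concentration
    complex(real = stats::rnorm(nc, 0, amp),
            imaginary = stats::rnorm(nc, 0, amp))
  })
  resp <- respiratory_scale(times, pk$kinetics)
  raw <- simulate_signal(truth, sm, frame_times = times,
                         noise_sd = noise_sd,
                         background = background, respiratory = resp,
                         injection_time_s = config$signal$injection_time_s,
                         seed = seed + 2000L)

  # rate estimation on the post-first-pass plateau, where the respiratory
  # modulation is not masked by the bolus transient
  plateau_start <- config$signal$injection_time_s +
    pk$kinetics$aa_arrival_delay_s + 4 * pk$kinetics$dispersion_width_s
  plateau <- which(times >= plateau_start)
  if (length(plateau) < 2L || diff(range(times[plateau])) < 4) {
    plateau <- seq_along(times)
  }
  biosignal <- extract_biosignal(raw, frames = plateau)
  sub <- subtract_background(raw)
  recon <- reconstruct_series(sub, sm,
                              lambda_rel = config$recon$lambda_rel,
                              sweeps = config$recon$sweeps,
                              nonneg = config$recon$nonneg,
                              row_order = config$recon$row_order)

  voi_ivc <- vessel_voi(pk$phantom, grid_geom, "IVC",
                        min_fraction = config$analysis$voi_min_fraction)
  voi_aa <- vessel_voi(pk$phantom, grid_geom, "AA",
                       min_fraction = config$analysis$voi_min_fraction)
  curve_ivc <- concentration_time_curve(recon, voi_ivc, "IVC")
  curve_aa <- concentration_time_curve(recon, voi_aa, "AA")

  baseline <- which(times < config$signal$injection_time_s)
  analysis <- list(
    curves = data.frame(time_s = times,
                        ivc_ug_per_voxel = curve_ivc$values,
                        aa_ug_per_voxel = curve_aa$values),
    voi = list(ivc = voi_ivc, aa = voi_aa),
    biosignal = data.frame(frequency_hz = biosignal$frequency,
                           power = biosignal$power)
  )
  tp <- try(select_timepoints(curve_ivc, curve_aa, baseline,
                              t1_offset_frames =
                                config$analysis$t1_offset_frames),
            silent = TRUE)
  if (inherits(tp, "try-error")) {
    analysis$bolus_detected <- FALSE
    analysis$bolus_note <- conditionMessage(attr(tp, "condition"))
  } else {
    analysis$bolus_detected <- TRUE
    analysis$timepoints <- list(t1 = tp$t1, t2 = tp$t2,
                                t1_s = times[tp$t1], t2_s = times[tp$t2])
    dsa <- digital_subtraction(recon, tp$t1, tp$t2)
    analysis$dsa <- dsa
    meas <- list(
      AA = try(measure_vessel(dsa, grid_geom, axis = 2L,
                              threshold_fraction =
                                config$analysis$threshold_fraction),
               silent = TRUE),
      IVC = try(measure_vessel(recon_frame(recon, tp$t1), grid_geom,
                               axis = 2L,
                               threshold_fraction =
                                 config$analysis$threshold_fraction),
                silent = TRUE)
    )
    rows <- list()
    for (lab in names(meas)) {
      m <- meas[[lab]]
      if (!inherits(m, "try-error")) {
        rows[[lab]] <- data.frame(vessel = lab, mean_dl_mm = m$mean_mm,
                                  sd_dl_mm = m$sd_mm,
                                  n_slices = nrow(m$slices))
        analysis[[paste0("slices_", tolower(lab))]] <- m$slices
      }
    }
    if (length(rows)) analysis$measurements <- do.call(rbind, rows)
  }
  if (!isTRUE(biosignal$no_modulation)) {
    analysis$respiratory_rate_bpm <- respiratory_rate(biosignal)
  }

  run <- structure(list(
    acquisition = list(config = sc, seed = seed,
                       pipeline_config = config),
    calibration = sm,
    measurement = raw,
    truth = list(concentration = truth, times = times,
                 body_weight_kg = pk$phantom$body_weight_kg),
    reconstruction = recon,
    analysis = analysis
  ), class = c("mpi_run", "list"))

  if (!is.null(out_dir)) write_run_container(unclass_tree(run), out_dir)
  run
}

#' @export
print.mpi_run <- function(x, ...) {
  cat("Simulated MPI examination\n")
  cat(sprintf("  frames: %d, components: %d, grid: %s\n",
              nrow(x$measurement$frames), ncol(x$measurement$frames),
              paste(x$reconstruction$grid_geom$dim, collapse = "x")))
  if (isTRUE(x$analysis$bolus_detected)) {
    tp <- x$analysis$timepoints
    cat(sprintf("  bolus: t1 = %.2f s, t2 = %.2f s\n", tp$t1_s, tp$t2_s))
    if (!is.null(x$analysis$measurements)) {
      m <- x$analysis$measurements
      for (i in seq_len(nrow(m))) {
        cat(sprintf("  %s lumen: %.2f +/- %.2f mm (%d slices)\n",
                    m$vessel[i], m$mean_dl_mm[i], m$sd_dl_mm[i],
                    m$n_slices[i]))
      }
    }
  } else {
    cat("  bolus not detected\n")
  }
  if (!is.null(x$analysis$respiratory_rate_bpm)) {
    cat(sprintf("  respiratory rate: %.1f breaths/min\n",
                x$analysis$respiratory_rate_bpm))
  }
  invisible(x)
}

# strip S3 classes into plain named lists for container serialization,
# remembering them in each node (write_node stores the class attribute)
unclass_tree <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    cl <- class(x)
    x <- lapply(x, unclass_tree)
    class(x) <- cl
  }
  x
}
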