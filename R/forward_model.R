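#' Simulate a system-function calibration measurement
#'
#' Builds the system matrix of a field-free-point scanner by simulating, for
#' every voxel center, the time-domain magnetization response of a point
#' sample over one Lissajous period and Fourier-transforming its time
#' derivative. The field seen by a sample at \code{r} is
#' \code{B_i(t) = G_i (r_i - ffp_i(t))}: far from the instantaneous FFP the
#' sample is saturated and contributes little to the dynamic signal, which
#' is what encodes space.
#'
#' The magnetization per unit iron concentration is the iron-weighted sum of
#' Langevin responses over the tracer's core populations, directed along the
#' local field. One idealized receive channel per axis with unit transfer
#' function is assumed. Matrix entries are scaled to the response of a voxel
#' filled at \code{calibration_concentration}.
#'
#' @param config A \code{scanner_config}.
#' @param tracer A \code{tracer_model}.
#' @param grid_geom Grid geometry (default: the scanner's recon grid).
#' @param max_frequency_index Highest retained frequency index k (components
#'   at k / lissajous_period Hz, k = 1..K, per receive axis).
#' @param calibration_concentration Calibration sample concentration,
#'   mmol Fe/l.
#' @param exclude_fundamentals Drop the components at the three drive
#'   frequencies (default TRUE). On a real scanner these are dominated by
#'   direct feedthrough of the excitation field and are not usable; they
#'   also carry almost no spatial encoding.
#' @return An object of class \code{system_matrix} with complex
#'   \code{entries} (components x voxels), \code{component_frequencies},
#'   \code{component_axis}, \code{component_index}, grid geometry and tracer
#'   reference.
#' @export
simulate_system_matrix <- function(config, tracer,
                                   grid_geom = recon_grid_geometry(config),
                                   max_frequency_index = NULL,
                                   calibration_concentration = 100,
                                   exclude_fundamentals = TRUE) {
  stopifnot(inherits(config, "scanner_config"), inherits(tracer, "tracer_model"))
  n <- config$samples_per_frame
  period <- lissajous_period(config)
  if (is.null(max_frequency_index)) {
    # keep the full band up to Nyquist: the informative mixing components
    # cluster around the drive-frequency harmonics, far above the frame rate
    max_frequency_index <- n %/% 2L - 1L
  }
  K <- as.integer(max_frequency_index)
  stopifnot(K >= 1L, K <= n %/% 2L - 1L)

  tt <- (seq_len(n) - 1L) / n * period
  ffp_mm <- ffp_position(tt, config)
  centers <- grid_geom$centers
  nv <- nrow(centers)

  # field components in T at every (time, voxel); B_i = G_i (r_i - ffp_i)
  Bax <- vector("list", 3L)
  for (i in 1:3) {
    Bi <- matrix(centers[, i], nrow = n, ncol = nv, byrow = TRUE)
    Bi <- (Bi - ffp_mm[, i]) * (config$gradient_strength[i] * 1e-3)
    Bax[[i]] <- Bi
  }
  Bmag <- sqrt(Bax[[1]]^2 + Bax[[2]]^2 + Bax[[3]]^2)
  Bsafe <- pmax(Bmag, .Machine$double.xmin)

  # iron-weighted Langevin response per unit concentration (dimensionless)
  cp <- tracer$core_populations
  Mscale <- 0
  for (p in seq_len(nrow(cp))) {
    xi <- (cp$moment[p] / (.kB * .temperature_K)) * Bmag
    Mscale <- Mscale + cp$iron_weight[p] * langevin(xi)
  }
  rm(Bmag)

  k <- seq_len(K)
  deriv <- 1i * 2 * pi * k / period
  entries <- matrix(0 + 0i, nrow = 3L * K, ncol = nv)
  for (i in 1:3) {
    Mi <- Mscale * Bax[[i]] / Bsafe
    Fi <- stats::mvfft(Mi) / n
    entries[(i - 1L) * K + k, ] <- Fi[k + 1L, , drop = FALSE] * deriv
    Bax[i] <- list(NULL)
  }
  entries <- entries * calibration_concentration

  comp_freq <- rep(k, 3L) / period
  comp_axis <- rep(1:3, each = K)
  comp_index <- rep(k, 3L)
  if (exclude_fundamentals) {
    fund_idx <- config$divisor_lcm / config$frequency_divisors
    drop <- comp_index %in% fund_idx
    if (any(drop)) {
      entries <- entries[!drop, , drop = FALSE]
      comp_freq <- comp_freq[!drop]
      comp_axis <- comp_axis[!drop]
      comp_index <- comp_index[!drop]
    }
  }

  structure(list(
    entries = entries,
    component_frequencies = comp_freq,
    component_axis = comp_axis,
    component_index = comp_index,
    grid_geom = grid_geom,
    tracer_name = tracer$name,
    calibration_concentration = calibration_concentration,
    config = config
  ), class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("MPI system matrix: %d components x %d voxels (tracer %s)\n",
              nrow(x$entries), ncol(x$entries), x$tracer_name))
  cat(sprintf("  grid %s, calibration %.4g mmol Fe/l\n",
              paste(x$grid_geom$dim, collapse = "x"),
              x$calibration_concentration))
  invisible(x)
}

#' Per-component calibration signal-to-noise ratio
#'
#' SNR of each frequency component, defined as the largest response
#' magnitude across voxels of the calibration sample divided by the
#' receive-chain noise standard deviation.
#'
#' @param sm A \code{system_matrix}.
#' @param noise_sd Noise standard deviation per component (real/imag part).
#' @return Numeric vector, one SNR per component (Inf when noise_sd is 0).
#' @export
component_snr <- function(sm, noise_sd) {
  stopifnot(inherits(sm, "system_matrix"), noise_sd >= 0)
  mx <- apply(abs(sm$entries), 1, max)
  if (noise_sd == 0) rep(Inf, length(mx)) else mx / noise_sd
}

#' Drop low-SNR frequency components from a system matrix
#'
#' @param sm A \code{system_matrix}.
#' @param noise_sd Noise standard deviation used for the SNR estimate.
#' @param min_snr Retention threshold (components with SNR >= min_snr kept).
#'   Default 2: mixing components within a factor of a few of the noise
#'   floor still carry useful spatial encoding, and discarding them visibly
#'   blurs the reconstruction at moderate noise.
#' @param max_components Optionally keep at most this many components (by
#'   descending SNR).
#' @param signal_reference Optional per-component signal amplitudes to use
#'   for the SNR estimate instead of the calibration row maxima — e.g. the
#'   clean component amplitudes of the expected peak-bolus frame, so that
#'   retention reflects the SNR of the actual measurement.
#' @return A reduced \code{system_matrix} with a \code{snr} field.
#' @export
retain_components <- function(sm, noise_sd, min_snr = 2,
                              max_components = NULL,
                              signal_reference = NULL) {
  snr <- if (is.null(signal_reference)) {
    component_snr(sm, noise_sd)
  } else {
    stopifnot(length(signal_reference) == nrow(sm$entries), noise_sd >= 0)
    if (noise_sd == 0) rep(Inf, nrow(sm$entries)) else
      abs(signal_reference) / noise_sd
  }
  keep <- which(snr >= min_snr)
  if (!is.null(max_components) && length(keep) > max_components) {
    keep <- keep[order(snr[keep], decreasing = TRUE)[seq_len(max_components)]]
    keep <- sort(keep)
  }
  if (length(keep) == 0L) stop("no components pass the SNR threshold",
                               call. = FALSE)
  sm$entries <- sm$entries[keep, , drop = FALSE]
  sm$component_frequencies <- sm$component_frequencies[keep]
  sm$component_axis <- sm$component_axis[keep]
  sm$component_index <- sm$component_index[keep]
  sm$snr <- snr[keep]
  sm
}

#' Simulate raw per-frame frequency-component signals
#'
#' Applies the linear forward model frame by frame:
#' \code{u_k = resp_k * S c_k / c_cal + background + noise}, with complex
#' Gaussian receive noise of standard deviation \code{noise_sd} on the real
#' and imaginary part of every component.
#'
#' @param maps Matrix frames x voxels of concentrations (mmol Fe/l), or a
#'   single concentration vector for one frame.
#' @param sm A \code{system_matrix}.
#' @param frame_times Frame time stamps, s (default: consecutive Lissajous
#'   periods starting at 0).
#' @param noise_sd Receive noise standard deviation (component units).
#' @param background Complex component vector added to every frame (static
#'   background signal); default zero.
#' @param respiratory Per-frame multiplicative amplitude factors (e.g. from
#'   \code{\link{respiratory_scale}}); default 1.
#' @param injection_time_s Optional metadata: injection time, used by
#'   \code{\link{subtract_background}} to locate pre-injection frames.
#' @param seed Optional seed for the noise generator.
#' @return An object of class \code{raw_signal} with complex \code{frames}
#'   (frames x components), \code{frame_times}, \code{background_reference}.
#' @export
simulate_signal <- function(maps, sm, frame_times = NULL, noise_sd = 0,
                            background = NULL, respiratory = NULL,
                            injection_time_s = NA_real_, seed = NULL) {
  stopifnot(inherits(sm, "system_matrix"))
  if (is.null(dim(maps))) maps <- matrix(maps, nrow = 1L)
  nv <- ncol(sm$entries)
  if (ncol(maps) != nv) {
    stop("concentration map has ", ncol(maps), " voxels; system matrix has ",
         nv, call. = FALSE)
  }
  nf <- nrow(maps)
  nc <- nrow(sm$entries)
  if (is.null(frame_times)) {
    frame_times <- (seq_len(nf) - 1L) * lissajous_period(sm$config)
  }
  stopifnot(length(frame_times) == nf)
  if (is.null(background)) background <- complex(nc)
  stopifnot(length(background) == nc)
  if (is.null(respiratory)) respiratory <- rep(1, nf)
  stopifnot(length(respiratory) == nf)

  clean <- maps %*% t(sm$entries) / sm$calibration_concentration
  frames <- clean * respiratory
  frames <- sweep(frames, 2, background, `+`)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    frames <- frames + matrix(
      complex(real = stats::rnorm(nf * nc, 0, noise_sd),
              imaginary = stats::rnorm(nf * nc, 0, noise_sd)),
      nrow = nf, ncol = nc)
  }
  structure(list(
    frames = frames,
    frame_times = frame_times,
    background_reference = background,
    noise_sd = noise_sd,
    injection_time_s = injection_time_s,
    background_subtracted = FALSE
  ), class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("MPI raw signal: %d frames x %d components (%.1f s)%s\n",
              nrow(x$frames), ncol(x$frames),
              diff(range(x$frame_times)),
              if (isTRUE(x$background_subtracted)) ", background-subtracted"
              else ""))
  invisible(x)
}

#' Subtract the static background signal
#'
#' Uses, in order of preference: an explicitly supplied reference vector;
#' the mean of pre-injection frames (frames before \code{injection_time_s});
#' the stored empty-bore \code{background_reference}.
#'
#' @param raw A \code{raw_signal}.
#' @param reference Optional complex component vector.
#' @return A \code{raw_signal} with the reference subtracted from every
#'   frame and \code{background_subtracted = TRUE}.
#' @export
subtract_background <- function(raw, reference = NULL) {
  stopifnot(inherits(raw, "raw_signal"))
  if (is.null(reference)) {
    pre <- which(raw$frame_times < raw$injection_time_s)
    if (!is.na(raw$injection_time_s) && length(pre) >= 1L) {
      fr <- raw$frames[pre, , drop = FALSE]
      reference <- colMeans(fr)
    } else if (!is.null(raw$background_reference)) {
      reference <- raw$background_reference
    } else {
      stop("no pre-injection frames and no empty-bore reference available",
           call. = FALSE)
    }
  }
  stopifnot(length(reference) == ncol(raw$frames))
  raw$frames <- sweep(raw$frames, 2, reference, `-`)
  raw$subtracted_reference <- reference
  raw$background_subtracted <- TRUE
  raw
}

#' Harmonic spectrum of a tracer under single-axis excitation
#'
#' Simulates the magnetization derivative of a homogeneous sample at the
#' scanner center under a pure sinusoidal drive on one axis (no gradient
#' offset) and returns the magnitudes of the drive-frequency harmonics.
#' For the odd-symmetric Langevin law only odd harmonics are non-zero; how
#' slowly they decay with harmonic index is the tracer's intrinsic MPI
#' quality: large single cores saturate abruptly and sustain high harmonics,
#' small-core mixtures roll off quickly.
#'
#' @param tracer A \code{tracer_model}.
#' @param config A \code{scanner_config} (drive amplitude and frequency).
#' @param axis Excitation axis (1, 2 or 3).
#' @param n_harmonics Highest harmonic index returned.
#' @param n_samples Time samples over one drive period.
#' @return Data frame with \code{harmonic}, \code{amplitude} and
#'   \code{normalized} (relative to the 3rd harmonic).
#' @export
harmonic_spectrum <- function(tracer, config, axis = 1L, n_harmonics = 15L,
                              n_samples = 4096L) {
  stopifnot(inherits(tracer, "tracer_model"), axis %in% 1:3,
            n_harmonics >= 3L, n_samples > 4L * n_harmonics)
  f <- drive_frequencies(config)[axis]
  A <- config$drive_amplitude[axis]
  tt <- (seq_len(n_samples) - 1L) / n_samples / f
  B <- A * sin(2 * pi * f * tt)
  cp <- tracer$core_populations
  M <- 0
  for (p in seq_len(nrow(cp))) {
    M <- M + cp$iron_weight[p] *
      langevin(cp$moment[p] * B / (.kB * .temperature_K))
  }
  co <- stats::fft(M) / n_samples
  h <- seq_len(n_harmonics)
  amp <- abs(co[h + 1L]) * (2 * pi * h * f)   # derivative spectrum
  data.frame(harmonic = h, amplitude = amp, normalized = amp / amp[3L])
}
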