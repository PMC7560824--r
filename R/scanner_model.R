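#' Scanner configuration for a field-free-point MPI system
#'
#' Bundles the drive-field, selection-gradient, timing and reconstruction-grid
#' parameters of a three-axis field-free-point (FFP) scanner. The three drive
#' frequencies are derived from a common base frequency divided by three
#' pairwise distinct integer divisors, so the FFP traces a closed 3D Lissajous
#' trajectory whose repetition period is \code{LCM(divisors) / base_frequency}.
#'
#' Defaults reproduce a preclinical 25/20 FFP scanner: 2.5 MHz base frequency
#' divided by 102/96/99 (x/y/z), 12 mT drive amplitude per axis, selection
#' gradients of 1.25/1.25/2.5 T/m, and a 33x33x33 voxel reconstruction grid
#' over 26.4 x 26.4 x 13.2 mm (an overscan of the 19.2 x 19.2 x 9.6 mm drive
#' field of view).
#'
#' @param base_frequency Drive base frequency in Hz.
#' @param frequency_divisors Integer vector of length 3, pairwise distinct.
#' @param drive_amplitude Drive-field amplitude per axis in tesla.
#' @param gradient_strength Selection-gradient strength per axis in T/m.
#' @param recon_grid Integer voxel counts per axis of the reconstruction grid.
#' @param recon_volume Physical edge lengths of the reconstruction volume in mm.
#' @param samples_per_frame Time samples used when simulating one Lissajous
#'   period. Defaults to \code{LCM(frequency_divisors)}; smaller values
#'   (e.g. 1024) are adequate when only low-index mixing components are kept.
#' @param phase_offsets Drive-field phase offsets in radians (default 0).
#' @return An object of class \code{scanner_config}.
#' @export
scanner_config <- function(base_frequency = 2.5e6,
                           frequency_divisors = c(102L, 96L, 99L),
                           drive_amplitude = c(0.012, 0.012, 0.012),
                           gradient_strength = c(1.25, 1.25, 2.5),
                           recon_grid = c(33L, 33L, 33L),
                           recon_volume = c(26.4, 26.4, 13.2),
                           samples_per_frame = NULL,
                           phase_offsets = c(0, 0, 0)) {
  if (!is.numeric(base_frequency) || length(base_frequency) != 1L ||
      !is.finite(base_frequency) || base_frequency <= 0) {
    stop("base_frequency must be a single positive number", call. = FALSE)
  }
  div <- frequency_divisors
  if (length(div) != 3L || any(!is.finite(div)) || any(div <= 0) ||
      any(div != round(div))) {
    stop("frequency_divisors must be three positive integers", call. = FALSE)
  }
  div <- as.integer(round(div))
  if (anyDuplicated(div)) {
    stop("frequency_divisors must be pairwise distinct", call. = FALSE)
  }
  drive_amplitude <- rep_len(as.numeric(drive_amplitude), 3L)
  gradient_strength <- rep_len(as.numeric(gradient_strength), 3L)
  if (any(drive_amplitude < 0)) {
    stop("drive_amplitude must be non-negative", call. = FALSE)
  }
  recon_grid <- as.integer(rep_len(recon_grid, 3L))
  recon_volume <- as.numeric(rep_len(recon_volume, 3L))
  if (any(recon_grid < 1L) || any(recon_volume <= 0)) {
    stop("recon_grid and recon_volume must be positive", call. = FALSE)
  }
  lcm_div <- pracma::Lcm(pracma::Lcm(div[1L], div[2L]), div[3L])
  if (is.null(samples_per_frame)) samples_per_frame <- lcm_div
  samples_per_frame <- as.integer(samples_per_frame)
  if (samples_per_frame < 8L) {
    stop("samples_per_frame must be at least 8", call. = FALSE)
  }
  structure(list(
    base_frequency = base_frequency,
    frequency_divisors = div,
    drive_amplitude = drive_amplitude,
    gradient_strength = gradient_strength,
    recon_grid = recon_grid,
    recon_volume = recon_volume,
    samples_per_frame = samples_per_frame,
    phase_offsets = rep_len(as.numeric(phase_offsets), 3L),
    divisor_lcm = lcm_div
  ), class = "scanner_config")
}

#' @export
print.scanner_config <- function(x, ...) {
  f <- x$base_frequency / x$frequency_divisors
  cat("MPI scanner configuration\n")
  cat(sprintf("  drive frequencies : %s kHz (base %.4g MHz / %s)\n",
              paste(sprintf("%.2f", f / 1e3), collapse = ", "),
              x$base_frequency / 1e6,
              paste(x$frequency_divisors, collapse = "/")))
  cat(sprintf("  drive amplitude   : %s mT\n",
              paste(x$drive_amplitude * 1e3, collapse = ", ")))
  cat(sprintf("  gradient strength : %s T/m\n",
              paste(x$gradient_strength, collapse = ", ")))
  cat(sprintf("  Lissajous period  : %.4f ms (%d frames/s)\n",
              lissajous_period(x) * 1e3, frame_rate(x)))
  cat(sprintf("  drive FOV         : %s mm\n",
              paste(sprintf("%.1f", fov_extent(x)), collapse = " x ")))
  cat(sprintf("  recon grid        : %s voxels over %s mm\n",
              paste(x$recon_grid, collapse = "x"),
              paste(x$recon_volume, collapse = " x ")))
  invisible(x)
}

#' Drive frequencies per axis
#' @param config A \code{scanner_config}.
#' @return Frequencies in Hz (length 3).
#' @export
drive_frequencies <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  config$base_frequency / config$frequency_divisors
}

#' Lissajous repetition period
#'
#' The FFP trajectory closes after the least common multiple of the three
#' drive periods: \code{LCM(N_x, N_y, N_z) / f_base}. This is the duration of
#' one 3D frame and drives all timing computations.
#'
#' @param config A \code{scanner_config}.
#' @return Period in seconds.
#' @export
lissajous_period <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  config$divisor_lcm / config$base_frequency
}

#' Whole 3D frames acquired per second
#'
#' The reciprocal of the Lissajous period rounded down to an integer, i.e.
#' the number of complete volumes per second.
#'
#' @param config A \code{scanner_config}.
#' @return Integer frames per second.
#' @export
frame_rate <- function(config) {
  as.integer(floor(1 / lissajous_period(config)))
}

#' Field-of-view extent spanned by the FFP
#'
#' Per axis the FFP excursion is \code{A/G} (drive amplitude over gradient),
#' so the scanned box spans \code{2 A / G} per axis.
#'
#' @param config A \code{scanner_config}.
#' @return Extents in mm (length 3).
#' @export
fov_extent <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  if (any(config$gradient_strength <= 0)) {
    stop("gradient_strength must be positive on every axis", call. = FALSE)
  }
  2 * config$drive_amplitude / config$gradient_strength * 1e3
}

#' Field-free-point position along the Lissajous trajectory
#'
#' @param t Time(s) in seconds (vectorized).
#' @param config A \code{scanner_config}.
#' @return A matrix \code{length(t) x 3} of positions in mm, scanner-centered.
#' @export
ffp_position <- function(t, config) {
  stopifnot(inherits(config, "scanner_config"), all(t >= 0))
  f <- drive_frequencies(config)
  amp_mm <- config$drive_amplitude / config$gradient_strength * 1e3
  pos <- vapply(1:3, function(i) {
    amp_mm[i] * sin(2 * pi * f[i] * t + config$phase_offsets[i])
  }, numeric(length(t)))
  matrix(pos, nrow = length(t), ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Langevin function of equilibrium superparamagnetism
#'
#' \code{L(xi) = coth(xi) - 1/xi}, the equilibrium magnetization of an
#' ensemble of non-interacting magnetic moments relative to saturation, with
#' argument \code{xi = m B / (kB T)}. Odd, monotone, bounded in (-1, 1). The
#' removable singularity at 0 is evaluated via the series
#' \code{xi/3 - xi^3/45} for \code{|xi| < 1e-4} to avoid cancellation.
#'
#' @param xi Dimensionless argument (vectorized).
#' @return \code{L(xi)}, same shape as \code{xi}.
#' @export
langevin <- function(xi) {
  if (any(!is.finite(xi))) stop("xi must be finite", call. = FALSE)
  out <- xi
  small <- abs(xi) < 1e-4
  out[small] <- xi[small] / 3 - xi[small]^3 / 45
  xl <- xi[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Voxel centers of the reconstruction grid
#'
#' Scanner-centered coordinates; voxel (i, j, k) (1-based in R) spans a
#' half-open box, and the grid is centered on the origin.
#'
#' @param config A \code{scanner_config}.
#' @return List with \code{centers} (n_voxels x 3 matrix, mm, x fastest),
#'   \code{spacing} (mm per axis) and \code{dim}.
#' @export
recon_grid_geometry <- function(config) {
  stopifnot(inherits(config, "scanner_config"))
  n <- config$recon_grid
  spacing <- config$recon_volume / n
  ax <- lapply(1:3, function(i) {
    (seq_len(n[i]) - (n[i] + 1) / 2) * spacing[i]
  })
  centers <- as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
  list(centers = centers, spacing = spacing, dim = n)
}

# Boltzmann constant (J/K); particle temperature fixed at 300 K throughout.
.kB <- 1.380649e-23
.temperature_K <- 300
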