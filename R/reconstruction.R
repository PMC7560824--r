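#' Tikhonov-regularized Kaczmarz reconstruction of one frame
#'
#' Row-action solver for \code{argmin ||S c - u||^2 + lambda ||c||^2},
#' operating on the real system obtained by stacking real and imaginary
#' parts of the complex frequency components as separate rows. Sweeps visit
#' every row once in a fixed order (deterministic); an optional projection
#' onto \code{c >= 0} follows each sweep. Convergence is declared by sweep
#' count, not by a tolerance, so runs are exactly reproducible.
#'
#' @param sm A \code{system_matrix}, or a real numeric matrix (rows already
#'   stacked).
#' @param frame Complex component vector (length = components of \code{sm}),
#'   or a real vector matching a real matrix input.
#' @param lambda Regularization weight on the scale of the squared row
#'   norms. If \code{NULL}, set to \code{lambda_rel} times the mean squared
#'   row norm.
#' @param lambda_rel Relative regularization (default 1e-3), used when
#'   \code{lambda} is NULL.
#' @param sweeps Number of full sweeps over the rows.
#' @param nonneg Project onto non-negative concentrations after each sweep.
#' @param row_order "snr" (descending component SNR when available, else
#'   descending row norm), "natural", or an explicit integer order over the
#'   stacked real rows.
#' @param c0 Optional warm-start vector.
#' @param track_residual When TRUE, attach per-sweep residual norms of the
#'   lifted system \code{A c + sqrt(lambda) v = u} as attribute
#'   \code{residual} (costs one extra pass per sweep).
#' @return Numeric vector of voxel values (units of the calibration
#'   concentration when \code{sm} is a \code{system_matrix}).
#' @export
kaczmarz_tikhonov <- function(sm, frame, lambda = NULL, lambda_rel = 1e-3,
                              sweeps = 10L, nonneg = TRUE,
                              row_order = c("snr", "natural"), c0 = NULL,
                              track_residual = FALSE) {
  st <- stack_real_system(sm, frame)
  A <- st$A
  u <- st$u
  if (nrow(A) == 0L) stop("empty component set", call. = FALSE)
  if (any(!is.finite(A)) || any(!is.finite(u))) {
    stop("non-finite entries in system or measurement", call. = FALSE)
  }
  rn2 <- rowSums(A^2)
  if (is.null(lambda)) lambda <- lambda_rel * mean(rn2)
  stopifnot(lambda >= 0, sweeps >= 1L)
  if (is.numeric(row_order)) {
    ord <- as.integer(row_order) - 1L
  } else {
    row_order <- match.arg(row_order)
    ord <- switch(row_order,
      natural = seq_len(nrow(A)) - 1L,
      snr = order(st$row_priority, decreasing = TRUE) - 1L
    )
  }
  if (is.null(c0)) c0 <- numeric(ncol(A))
  res <- .kaczmarz_core(A, u, lambda, as.integer(sweeps), isTRUE(nonneg),
                        ord, c0, isTRUE(track_residual))
  out <- res$c
  if (isTRUE(track_residual)) attr(out, "residual") <- res$residual
  out
}

# Stack complex components into real rows; carry a row priority for ordering.
stack_real_system <- function(sm, frame) {
  if (inherits(sm, "system_matrix")) {
    S <- sm$entries
    stopifnot(length(frame) == nrow(S))
    A <- rbind(Re(S), Im(S))
    u <- c(Re(frame), Im(frame))
    pr <- if (!is.null(sm$snr)) rep(sm$snr, 2L) else rowSums(A^2)
    list(A = A, u = u, row_priority = pr)
  } else {
    A <- as.matrix(sm)
    stopifnot(is.numeric(A), length(frame) == nrow(A))
    list(A = A, u = as.numeric(frame), row_priority = rowSums(A^2))
  }
}

#' Closed-form Tikhonov solution (dense reference solver)
#'
#' Solves the normal equations \code{(A'A + lambda I) c = A' u} of the same
#' stacked real system the Kaczmarz solver uses. Intended for small grids
#' and as an exactness reference; no non-negativity constraint.
#'
#' @inheritParams kaczmarz_tikhonov
#' @return Numeric voxel vector.
#' @export
tikhonov_dense <- function(sm, frame, lambda = NULL, lambda_rel = 1e-3) {
  st <- stack_real_system(sm, frame)
  A <- st$A
  if (is.null(lambda)) lambda <- lambda_rel * mean(rowSums(A^2))
  n <- ncol(A)
  solve(crossprod(A) + diag(lambda, n), crossprod(A, st$u))[, 1L]
}

#' Reconstruct a full frame series to iron amount per voxel
#'
#' Runs the Kaczmarz solver frame by frame on a background-subtracted raw
#' signal, rescales the solution from calibration-concentration units to
#' mmol Fe/l, and converts to micrograms of iron per voxel:
#' \code{ug = c [mmol/l] * voxel volume [l] * 55.845 [g/mol] * 1e3}.
#'
#' @param raw A background-subtracted \code{raw_signal}.
#' @param sm The \code{system_matrix} used for the acquisition.
#' @param lambda,lambda_rel,sweeps,nonneg,row_order Solver parameters, see
#'   \code{\link{kaczmarz_tikhonov}}.
#' @param warm_start Reuse each frame's solution to initialize the next
#'   (default FALSE so frames are reconstructed independently; enabling it
#'   speeds up slowly varying series and stays deterministic).
#' @return An object of class \code{recon_series}: \code{volumes} (frames x
#'   voxels, ug iron per voxel), \code{frame_times}, \code{grid_geom},
#'   solver metadata.
#' @export
reconstruct_series <- function(raw, sm, lambda = NULL, lambda_rel = 1e-3,
                               sweeps = 10L, nonneg = TRUE,
                               row_order = "snr", warm_start = FALSE) {
  stopifnot(inherits(raw, "raw_signal"), inherits(sm, "system_matrix"))
  if (ncol(raw$frames) != nrow(sm$entries)) {
    stop("raw signal has ", ncol(raw$frames), " components; system matrix has ",
         nrow(sm$entries), call. = FALSE)
  }
  nf <- nrow(raw$frames)
  nv <- ncol(sm$entries)
  spacing_mm <- sm$grid_geom$spacing
  voxel_volume_l <- prod(spacing_mm) * 1e-6   # mm^3 -> l
  to_ug <- sm$calibration_concentration * voxel_volume_l * 55.845 * 1e3

  volumes <- matrix(0, nrow = nf, ncol = nv)
  c_prev <- numeric(nv)
  for (kf in seq_len(nf)) {
    ck <- kaczmarz_tikhonov(sm, raw$frames[kf, ], lambda = lambda,
                            lambda_rel = lambda_rel, sweeps = sweeps,
                            nonneg = nonneg, row_order = row_order,
                            c0 = if (warm_start) c_prev else NULL)
    volumes[kf, ] <- ck * to_ug
    if (warm_start) c_prev <- ck
  }
  structure(list(
    volumes = volumes,
    frame_times = raw$frame_times,
    grid_geom = sm$grid_geom,
    units = "ug Fe per voxel",
    solver = list(lambda = lambda, lambda_rel = lambda_rel, sweeps = sweeps,
                  nonneg = nonneg, row_order = row_order,
                  warm_start = warm_start)
  ), class = "recon_series")
}

#' @export
print.recon_series <- function(x, ...) {
  cat(sprintf("MPI reconstruction series: %d frames on %s grid (%s)\n",
              nrow(x$volumes), paste(x$grid_geom$dim, collapse = "x"),
              x$units))
  invisible(x)
}

#' Extract one frame of a reconstruction series as a 3D array
#' @param series A \code{recon_series}.
#' @param frame Frame index.
#' @return 3D array over the reconstruction grid.
#' @export
recon_frame <- function(series, frame) {
  stopifnot(inherits(series, "recon_series"),
            frame >= 1L, frame <= nrow(series$volumes))
  array(series$volumes[frame, ], dim = series$grid_geom$dim)
}

#' Crop a reconstructed volume to the drive field of view
#'
#' The reconstruction grid overscans the drive FOV to push border artifacts
#' outside the region of interest. This returns the sub-grid of voxels whose
#' centers lie strictly inside the drive FOV box.
#'
#' @param volume 3D array on the reconstruction grid.
#' @param config The \code{scanner_config} defining grid and FOV.
#' @return List with \code{volume} (cropped 3D array) and \code{index}
#'   (per-axis voxel index ranges kept).
#' @export
overscan_crop <- function(volume, config) {
  stopifnot(inherits(config, "scanner_config"))
  g <- recon_grid_geometry(config)
  stopifnot(identical(dim(volume), as.integer(g$dim)))
  half_fov <- fov_extent(config) / 2
  keep <- lapply(1:3, function(i) {
    ax <- (seq_len(g$dim[i]) - (g$dim[i] + 1) / 2) * g$spacing[i]
    which(abs(ax) < half_fov[i] - 1e-9)
  })
  list(volume = volume[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
       index = keep)
}
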