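#' Volume-of-interest concentration-time curve
#'
#' Mean reconstructed value over a fixed voxel set, per frame. Used to track
#' the bolus through the IVC and the first pass in the AA.
#'
#' @param series A \code{recon_series}.
#' @param voi Integer vector of voxel indices (column-major over the grid).
#' @param label Optional curve label.
#' @return Object of class \code{conc_time_curve}: data frame-like list with
#'   \code{times}, \code{values}, \code{label}.
#' @export
concentration_time_curve <- function(series, voi, label = NA_character_) {
  stopifnot(inherits(series, "recon_series"))
  voi <- as.integer(voi)
  if (length(voi) == 0L) stop("empty VOI", call. = FALSE)
  nv <- ncol(series$volumes)
  if (any(voi < 1L) || any(voi > nv)) {
    stop("VOI indices outside the grid (1..", nv, ")", call. = FALSE)
  }
  structure(list(
    times = series$frame_times,
    values = rowMeans(series$volumes[, voi, drop = FALSE]),
    label = label,
    n_voxels = length(voi)
  ), class = "conc_time_curve")
}

#' Build a VOI from a vessel cross-section of the phantom
#'
#' Voxels whose lumen occupancy fraction exceeds a cutoff, optionally
#' restricted to a slab along the vessel axis — the simulated analogue of
#' drawing a 3D VOI on the vessel cross-section.
#'
#' @param phantom A \code{vessel_phantom}.
#' @param grid_geom Grid geometry.
#' @param label Vessel label ("IVC" or "AA").
#' @param min_fraction Minimum lumen occupancy of a voxel.
#' @param slab Optional numeric length-2 range (mm) along the vessel axis
#'   direction to restrict the VOI.
#' @param axis Grid axis along the vessel (default 2 = y).
#' @return Integer voxel indices.
#' @export
vessel_voi <- function(phantom, grid_geom, label, min_fraction = 0.5,
                       slab = NULL, axis = 2L) {
  frac <- vessel_voxel_fractions(phantom, grid_geom, label)
  idx <- which(frac >= min_fraction)
  if (!is.null(slab)) {
    coord <- grid_geom$centers[idx, axis]
    idx <- idx[coord >= slab[1] & coord <= slab[2]]
  }
  if (length(idx) == 0L) stop("VOI is empty; lower min_fraction", call. = FALSE)
  idx
}

#' Select the bolus (t1) and arterial-phase (t2) frames
#'
#' t1 is the frame of the IVC curve peak (optionally offset by a fixed
#' number of frames), t2 the frame of the AA curve peak. A bolus is only
#' accepted when the peak rises more than \code{min_rise_sd} baseline
#' standard deviations above the pre-injection baseline mean.
#'
#' @param ivc_curve,aa_curve \code{conc_time_curve}s on a shared time base.
#' @param baseline_frames Indices of pre-injection frames used for the
#'   noise floor (default: frames before the curves' global rise, supplied
#'   explicitly in practice).
#' @param t1_offset_frames Frames added to the IVC peak index (default 0,
#'   i.e. t1 is the peak frame itself).
#' @param min_rise_sd Detection threshold in baseline SDs (default 3).
#' @return List with integer \code{t1}, \code{t2} and the peak values.
#' @export
select_timepoints <- function(ivc_curve, aa_curve, baseline_frames,
                              t1_offset_frames = 0L, min_rise_sd = 3) {
  stopifnot(inherits(ivc_curve, "conc_time_curve"),
            inherits(aa_curve, "conc_time_curve"))
  if (!isTRUE(all.equal(ivc_curve$times, aa_curve$times))) {
    stop("curves must share the same time base", call. = FALSE)
  }
  baseline_frames <- as.integer(baseline_frames)
  stopifnot(length(baseline_frames) >= 2L)
  detect <- function(curve) {
    base <- curve$values[baseline_frames]
    mu <- mean(base)
    sd0 <- stats::sd(base)
    post <- setdiff(seq_along(curve$values), baseline_frames)
    pk <- post[which.max(curve$values[post])]
    rise <- curve$values[pk] - mu
    if (!(rise > min_rise_sd * max(sd0, .Machine$double.eps))) {
      stop("bolus not detected in ", curve$label, " curve", call. = FALSE)
    }
    pk
  }
  p1 <- detect(ivc_curve)
  p2 <- detect(aa_curve)
  t1 <- p1 + as.integer(t1_offset_frames)
  if (!(p2 > p1)) {
    stop("AA peak does not follow the IVC peak (non-physiological ordering)",
         call. = FALSE)
  }
  if (t1 >= p2) stop("t1 offset places t1 at or after the AA peak",
                     call. = FALSE)
  list(t1 = t1, t2 = p2,
       ivc_peak_value = ivc_curve$values[p1],
       aa_peak_value = aa_curve$values[p2])
}

#' Digital subtraction angiography volume
#'
#' Subtracts an early post-contrast frame (t1, bolus in the IVC) from a late
#' one (t2, arterial phase): venous signal common to both frames cancels and
#' the arterial phase is isolated. Negative differences are clipped to zero
#' since concentrations are physical.
#'
#' @param series A \code{recon_series}.
#' @param t1,t2 Frame indices (t1 != t2).
#' @return 3D array (grid dims) of the clipped difference.
#' @export
digital_subtraction <- function(series, t1, t2) {
  stopifnot(inherits(series, "recon_series"))
  nf <- nrow(series$volumes)
  t1 <- as.integer(t1); t2 <- as.integer(t2)
  if (any(c(t1, t2) < 1L) || any(c(t1, t2) > nf)) {
    stop("frame index out of range 1..", nf, call. = FALSE)
  }
  if (t1 == t2) stop("t1 and t2 must differ", call. = FALSE)
  d <- series$volumes[t2, ] - series$volumes[t1, ]
  d[d < 0] <- 0
  array(d, dim = series$grid_geom$dim)
}

#' Threshold-based vessel segmentation of one transverse slice
#'
#' Pixels at or above \code{threshold_fraction} of the slice maximum,
#' restricted to the 8-connected component containing the maximum pixel
#' (first in column-major scan order on ties; ties are recorded).
#'
#' @param slice 2D numeric matrix (one transverse plane).
#' @param threshold_fraction Cutoff as a fraction of the slice maximum
#'   (default 0.30).
#' @return Logical mask matrix with attributes \code{threshold} (absolute
#'   cutoff) and \code{tied_maxima} (TRUE when the maximum was not unique).
#' @export
segment_vessel <- function(slice, threshold_fraction = 0.30) {
  stopifnot(is.matrix(slice), threshold_fraction > 0, threshold_fraction <= 1)
  mx <- max(slice)
  if (!(mx > 0)) stop("no vessel in slice (all-zero or negative)",
                      call. = FALSE)
  thr <- threshold_fraction * mx
  above <- slice >= thr
  seeds <- which(slice == mx)
  mask <- connected_component(above, seeds[1L])
  attr(mask, "threshold") <- thr
  attr(mask, "tied_maxima") <- length(seeds) > 1L
  mask
}

# 8-connected component of `above` containing linear index `seed`
connected_component <- function(above, seed) {
  nr <- nrow(above); nc <- ncol(above)
  comp <- matrix(FALSE, nr, nc)
  stack <- seed
  comp[seed] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    i <- (cur - 1L) %% nr + 1L
    j <- (cur - 1L) %/% nr + 1L
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
        if (above[ii, jj] && !comp[ii, jj]) {
          comp[ii, jj] <- TRUE
          stack <- c(stack, (jj - 1L) * nr + ii)
        }
      }
    }
  }
  comp
}

#' Lumen diameter from a segmented cross-section
#'
#' Cross-sectional area = pixel count times in-plane pixel area; the lumen
#' diameter follows from a circular cross-section assumption:
#' \code{D_L = 2 sqrt(area / pi)}.
#'
#' @param mask Logical segmentation mask.
#' @param voxel_size_mm In-plane voxel edge lengths, mm (length 2).
#' @return Diameter in mm, with attribute \code{area_mm2}.
#' @export
lumen_diameter <- function(mask, voxel_size_mm) {
  stopifnot(is.logical(mask), length(voxel_size_mm) == 2L,
            all(voxel_size_mm > 0))
  npix <- sum(mask)
  if (npix == 0L) stop("empty mask", call. = FALSE)
  area <- npix * voxel_size_mm[1] * voxel_size_mm[2]
  d <- 2 * sqrt(area / pi)
  attr(d, "area_mm2") <- area
  d
}

#' Lumen diameter profile along the vessel axis
#'
#' Segments every transverse slice along the longitudinal axis with the
#' intensity threshold, converts each mask to a diameter, and summarizes
#' mean and SD over the segment. Slices whose maximum falls below
#' \code{min_slice_fraction} of the volume maximum are considered outside
#' the vessel-bearing segment and skipped.
#'
#' @param volume 3D array (e.g. a digital-subtraction volume).
#' @param grid_geom Grid geometry (voxel spacing in mm).
#' @param axis Longitudinal grid axis (1, 2 or 3). Default NULL: the axis is
#'   chosen automatically as the one along which the supra-threshold support
#'   extends farthest.
#' @param threshold_fraction Segmentation cutoff (fraction of slice max).
#' @param min_slice_fraction Minimum slice maximum relative to the volume
#'   maximum for a slice to enter the profile.
#' @param slices Optional explicit slice indices to measure.
#' @return Object of class \code{vessel_measurement}: per-slice table
#'   (\code{slice}, \code{area_mm2}, \code{diameter_mm}), \code{mean_mm},
#'   \code{sd_mm}, \code{axis}, \code{threshold_fraction}.
#' @export
measure_vessel <- function(volume, grid_geom, axis = NULL,
                           threshold_fraction = 0.30,
                           min_slice_fraction = 0.10, slices = NULL) {
  stopifnot(length(dim(volume)) == 3L)
  vmax <- max(volume)
  if (!(vmax > 0)) stop("volume contains no vessel-like structure",
                        call. = FALSE)
  if (is.null(axis)) axis <- longitudinal_axis(volume)
  axis <- as.integer(axis)
  stopifnot(axis %in% 1:3)
  inplane <- setdiff(1:3, axis)
  vox <- grid_geom$spacing[inplane]
  n_slices <- dim(volume)[axis]
  if (is.null(slices)) slices <- seq_len(n_slices)

  rows <- list()
  for (s in slices) {
    sl <- slice_along(volume, axis, s)
    if (max(sl) < min_slice_fraction * vmax) next
    mask <- segment_vessel(sl, threshold_fraction)
    d <- lumen_diameter(mask, vox)
    rows[[length(rows) + 1L]] <- data.frame(
      slice = s, area_mm2 = attr(d, "area_mm2"), diameter_mm = as.numeric(d))
  }
  if (length(rows) < 3L) {
    stop("segment too short: fewer than 3 vessel-bearing slices",
         call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  structure(list(
    slices = tab,
    mean_mm = mean(tab$diameter_mm),
    sd_mm = stats::sd(tab$diameter_mm),
    axis = axis,
    threshold_fraction = threshold_fraction
  ), class = "vessel_measurement")
}

#' @export
print.vessel_measurement <- function(x, ...) {
  cat(sprintf(
    "Vessel lumen: D_L = %.2f +/- %.2f mm over %d slices (axis %d, %.0f%% cutoff)\n",
    x$mean_mm, x$sd_mm, nrow(x$slices), x$axis, 100 * x$threshold_fraction))
  invisible(x)
}

# grid axis along which the supra-threshold support extends farthest
longitudinal_axis <- function(volume, fraction = 0.30) {
  idx <- which(volume >= fraction * max(volume), arr.ind = TRUE)
  extents <- apply(idx, 2, function(v) diff(range(v)))
  which.max(extents)
}

# extract slice s perpendicular to `axis` as a matrix
slice_along <- function(volume, axis, s) {
  switch(axis,
         volume[s, , ],
         volume[, s, ],
         volume[, , s])
}
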