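make_series <- function(volumes, times = NULL, spacing = c(1, 1, 1),
                        dims = NULL) {
  if (is.null(dims)) dims <- dim(volumes[[1]])
  vmat <- do.call(rbind, lapply(volumes, as.vector))
  if (is.null(times)) times <- seq_len(nrow(vmat)) - 1
  structure(list(volumes = vmat, frame_times = times,
                 grid_geom = list(dim = dims, spacing = spacing),
                 units = "ug Fe per voxel", solver = list()),
            class = "recon_series")
}

test_that("VOI curves are per-frame means over the voxel set", {
  dims <- c(4L, 4L, 2L)
  v1 <- array(3, dims); v2 <- array(7, dims)
  s <- make_series(list(v1, v2))
  cv <- concentration_time_curve(s, 1:5, "IVC")
  expect_equal(cv$values, c(3, 7))
  # single-voxel VOI returns that voxel's series
  v2[2, 1, 1] <- 99
  s2 <- make_series(list(v1, v2))
  expect_equal(concentration_time_curve(s2, 2L)$values, c(3, 99))
  expect_error(concentration_time_curve(s, integer(0)), "empty VOI")
  expect_error(concentration_time_curve(s, 999L), "outside")
})

test_that("timepoint selection finds the venous and arterial peaks in order", {
  dims <- c(2L, 2L, 1L)
  n <- 40
  base <- 1:10
  tt <- seq_len(n) - 1
  ivc <- c(rep(0, 10), stats::dnorm(11:n, mean = 18, sd = 2))
  aa <- c(rep(0, 10), stats::dnorm(11:n, mean = 26, sd = 3))
  mk_curve <- function(vals, lab) {
    structure(list(times = tt, values = vals, label = lab, n_voxels = 1L),
              class = "conc_time_curve")
  }
  sel <- select_timepoints(mk_curve(ivc, "IVC"), mk_curve(aa, "AA"), base)
  expect_equal(sel$t1, 18L)   # argmax of the IVC curve
  expect_equal(sel$t2, 26L)
  expect_gt(sel$t2, sel$t1)
  # configurable offset after the IVC peak
  sel2 <- select_timepoints(mk_curve(ivc, "IVC"), mk_curve(aa, "AA"), base,
                            t1_offset_frames = 2L)
  expect_equal(sel2$t1, 20L)
  # arterial peak before venous peak is non-physiological
  expect_error(select_timepoints(mk_curve(aa, "IVC"), mk_curve(ivc, "AA"),
                                 base), "ordering")
  # flat noise-only curves: no bolus
  set.seed(5)
  noise <- stats::rnorm(n, 0, 1)
  expect_error(select_timepoints(mk_curve(noise, "IVC"),
                                 mk_curve(noise, "AA"), base),
               "bolus not detected")
})

test_that("digital subtraction clips negatives and isolates the late phase", {
  dims <- c(3L, 3L, 1L)
  early <- array(0, dims); early[1, 1, 1] <- 5
  late <- array(0, dims); late[1, 1, 1] <- 2; late[3, 3, 1] <- 4
  s <- make_series(list(early, late))
  d <- digital_subtraction(s, 1, 2)
  expect_equal(d[1, 1, 1], 0)        # negative difference clipped
  expect_equal(d[3, 3, 1], 4)
  expect_true(all(d >= 0))
  expect_true(all(digital_subtraction(s, 1, 1 + 1L)[, , 1] ==
                    pmax(late - early, 0)[, , 1]))
  expect_error(digital_subtraction(s, 2, 2), "differ")
  expect_error(digital_subtraction(s, 1, 9), "range")
})

test_that("subtraction mass concentrates on the arterial vessel (ground truth)", {
  sc <- fx_scanner_small()
  gg <- recon_grid_geometry(sc)
  pk <- default_rat_phantom(3, injection_time_s = 0)
  kin <- pk$kinetics
  t1 <- kin$ivc_arrival_delay_s + kin$dispersion_width_s
  t2 <- kin$aa_arrival_delay_s + kin$dispersion_width_s
  tr <- truth_series(pk$phantom, kin, tracer_mcp3(), c(t1, t2), gg)
  s <- make_series(list(array(tr[1, ], gg$dim), array(tr[2, ], gg$dim)),
                   spacing = gg$spacing, dims = gg$dim)
  d <- digital_subtraction(s, 1, 2)
  aa <- array(vessel_voxel_fractions(pk$phantom, gg, "AA") > 0, gg$dim)
  expect_gte(sum(d[dilate_mask_3d(aa)]) / sum(d), 0.90)
})

test_that("30% threshold segmentation matches closed-form level sets", {
  # binary slice: mask is exactly the ones
  bin <- matrix(0, 9, 9); bin[4:6, 4:6] <- 1
  m <- segment_vessel(bin)
  expect_equal(unname(which(m)), unname(which(bin == 1)))

  # Gaussian blob: the 30% level set has radius sigma*sqrt(2 ln(1/0.3))
  px <- 0.05
  ax <- seq(-3, 3, by = px)
  sigma <- 0.8
  blob <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma^2))
  mb <- segment_vessel(blob, 0.30)
  r_true <- sigma * sqrt(2 * log(1 / 0.3))
  r_est <- sqrt(sum(mb) * px^2 / pi)
  expect_lt(abs(r_est - r_true), 2 * px)

  # tie: two equal maxima in disjoint blobs -> first in scan order wins
  two <- matrix(0, 7, 7); two[2, 2] <- 1; two[6, 6] <- 1
  mt <- segment_vessel(two)
  expect_true(mt[2, 2] && !mt[6, 6])
  expect_true(attr(mt, "tied_maxima"))

  expect_error(segment_vessel(matrix(0, 3, 3)), "no vessel")
})

test_that("segmentation is threshold-monotone and scale-equivariant", {
  set.seed(8)
  sl <- matrix(0, 15, 15)
  sl[5:10, 5:10] <- stats::runif(36, 0.2, 1)
  sl[7, 7] <- 1.5
  areas <- vapply(c(0.2, 0.3, 0.5, 0.7, 0.9),
                  function(th) sum(segment_vessel(sl, th)), numeric(1))
  expect_true(all(diff(areas) <= 0))
  m1 <- segment_vessel(sl, 0.3)
  m2 <- segment_vessel(sl * 7.3, 0.3)
  expect_equal(which(m1), which(m2))
})

test_that("lumen diameter follows from the circular-area identity", {
  mk <- function(n) {
    m <- matrix(FALSE, 10, 10); m[seq_len(n)] <- TRUE; m
  }
  d9 <- lumen_diameter(mk(9), c(0.8, 0.8))
  expect_equal(as.numeric(d9), 2 * sqrt(9 * 0.64 / pi), tolerance = 1e-12)
  expect_equal(as.numeric(d9), 2.708, tolerance = 1e-3)
  expect_equal(attr(d9, "area_mm2"), 5.76)
  expect_equal(as.numeric(lumen_diameter(mk(1), c(0.8, 0.8))), 0.9027,
               tolerance = 1e-4)
  expect_error(lumen_diameter(mk(0), c(0.8, 0.8)), "empty")

  # rasterized disk of 10 voxel diameter: D_L within 5%
  ax <- seq_len(41) - 21
  disk <- outer(ax^2, ax^2, `+`) <= 5^2
  dd <- lumen_diameter(disk, c(1, 1))
  expect_lt(abs(as.numeric(dd) / 10 - 1), 0.05)
})

test_that("vessel profiles report per-slice diameters consistent with
           their summary", {
  sc <- fx_scanner_08()
  gg <- recon_grid_geometry(sc)
  vol <- array(rasterize_cylinder(gg, c(0, -8, 0), c(0, 8, 0), 2.7), gg$dim)
  m <- measure_vessel(vol, gg, axis = 2L)
  expect_lt(abs(m$mean_mm - 2.7), 0.4)
  expect_equal(m$mean_mm, mean(m$slices$diameter_mm))
  expect_equal(m$sd_mm, stats::sd(m$slices$diameter_mm))
  # automatic axis detection picks the vessel's long axis
  m_auto <- measure_vessel(vol, gg)
  expect_equal(m_auto$axis, 2L)
  # fewer than 3 vessel-bearing slices
  thin <- array(0, gg$dim); thin[13, 12:13, 6] <- 1
  expect_error(measure_vessel(thin, gg, axis = 2L), "segment too short")
  expect_error(measure_vessel(array(0, gg$dim), gg), "no vessel")
})
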