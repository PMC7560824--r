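test_that("tracer presets carry the published sizes and half-lives", {
  m <- tracer_mcp3(0.1)
  expect_equal(m$core_populations$diameter_nm, 32)
  expect_equal(m$blood_half_life_min, 17.4)
  expect_equal(tracer_mcp3(0.05)$blood_half_life_min, 8.8)
  expect_equal(m$hydrodynamic_diameter_nm, 53)

  r <- tracer_resovist()
  expect_equal(r$core_populations$diameter_nm, c(4, 16))
  expect_equal(sum(r$core_populations$number_fraction), 1)
  # the 16 nm cores carry almost all the iron despite being the minority
  expect_gt(r$core_populations$iron_weight[2], 0.9)

  expect_error(tracer_model("x", data.frame(diameter_nm = -1,
                                            number_fraction = 1),
                            60, blood_half_life_min = 5))
  expect_error(tracer_model("x", data.frame(diameter_nm = 10,
                                            number_fraction = 1),
                            60, blood_half_life_min = -5))
})

test_that("bolus concentration is causal, vessel-ordered, and clears
           monoexponentially", {
  kin <- bolus_kinetics(injection_time_s = 10)
  # zero before injection + arrival delay
  expect_equal(bolus_concentration(c(0, 5, 10, 11.2), "IVC", kin),
               rep(0, 4))
  expect_equal(bolus_concentration(12.4, "AA", kin), 0)
  expect_gt(bolus_concentration(12, "IVC", kin), 0)
  expect_error(bolus_concentration(12, "aorta", kin), "unknown vessel")

  # late-time tail halves over one half-life once the gamma washout and
  # recirculation mixing terms have saturated
  hl_s <- kin$clearance_half_life_min * 60
  t_ref <- kin$injection_time_s + kin$ivc_arrival_delay_s + 300
  ratio <- bolus_concentration(t_ref + hl_s, "IVC", kin) /
    bolus_concentration(t_ref, "IVC", kin)
  expect_equal(ratio, 0.5, tolerance = 1e-6)

  # log-concentration slope on the cleared tail = -ln2 / half-life within 1%
  tt <- seq(t_ref, t_ref + 600, by = 5)
  lc <- log(bolus_concentration(tt, "IVC", kin))
  slope <- stats::coef(stats::lm(lc ~ tt))[[2]]
  expect_equal(slope, -log(2) / hl_s, tolerance = 0.01)

  # tracer argument overrides the stored half-life
  ratio2 <- bolus_concentration(t_ref + 8.8 * 60, "IVC", kin,
                                tracer = tracer_mcp3(0.05)) /
    bolus_concentration(t_ref, "IVC", kin, tracer = tracer_mcp3(0.05))
  expect_equal(ratio2, 0.5, tolerance = 1e-5)

  expect_error(bolus_kinetics(ivc_arrival_delay_s = 3, aa_arrival_delay_s = 2))
  expect_error(bolus_kinetics(respiratory_depth = 1.2))
})

test_that("respiratory modulation is a unit-mean sinusoidal factor", {
  kin <- bolus_kinetics(respiratory_rate_bpm = 60, respiratory_depth = 0.15)
  expect_equal(respiratory_scale(c(0.25, 1.25), kin), c(1.15, 1.15))
  # period 1 s at 60/min
  tt <- seq(0, 3, by = 0.01)
  expect_equal(respiratory_scale(tt, kin), respiratory_scale(tt + 1, kin),
               tolerance = 1e-12)
  # mean over whole breaths = 1
  whole <- seq(0, 1, length.out = 1001)[-1001]
  expect_equal(mean(respiratory_scale(whole, kin)), 1, tolerance = 1e-6)
  kin0 <- bolus_kinetics(respiratory_depth = 0)
  expect_equal(respiratory_scale(tt, kin0), rep(1, length(tt)))
})

test_that("cylinder rasterization converges to the analytic cross-section", {
  sc <- fx_scanner_08()
  gg <- recon_grid_geometry(sc)
  for (D in c(2.0, 2.7, 3.0)) {   # all >= 2 voxels in-plane
    frac <- rasterize_cylinder(gg, c(0, -8, 0), c(0, 8, 0), D,
                               supersample = 5L)
    vol_est <- sum(frac) * prod(gg$spacing)
    vol_true <- pi * (D / 2)^2 * 16
    expect_lt(abs(vol_est / vol_true - 1), 0.02)
  }
  # fractions bounded and zero far from the axis
  frac <- rasterize_cylinder(gg, c(0, -8, 0), c(0, 8, 0), 2.7)
  expect_true(all(frac >= 0 & frac <= 1))
  far <- sqrt(gg$centers[, 1]^2 + gg$centers[, 3]^2) > 2.7
  expect_true(all(frac[far] == 0))
})

test_that("concentration maps are non-negative, causal and mass-bounded", {
  sc <- fx_scanner_small()
  gg <- recon_grid_geometry(sc)
  pk <- default_rat_phantom(42, injection_time_s = 5)
  m0 <- concentration_map(pk$phantom, pk$kinetics, tracer_mcp3(), 1, gg)
  expect_true(all(m0 == 0))

  t_peak <- 5 + pk$kinetics$ivc_arrival_delay_s +
    pk$kinetics$dispersion_width_s
  m1 <- concentration_map(pk$phantom, pk$kinetics, tracer_mcp3(), t_peak, gg)
  expect_true(all(m1 >= 0))
  # a voxel fully inside the IVC holds the analytic bolus concentration
  frac <- vessel_voxel_fractions(pk$phantom, gg, "IVC")
  full <- which(frac > 0.999)
  expect_gt(length(full), 0)
  expect_equal(unname(m1[full[1]]),
               bolus_concentration(t_peak, "IVC", pk$kinetics, tracer_mcp3()),
               tolerance = 1e-9)
  # zero outside the dilated vessel envelope
  outside <- which(frac == 0 &
                     vessel_voxel_fractions(pk$phantom, gg, "AA") == 0)
  expect_true(all(m1[outside] == 0))
  # no mass creation: total iron in the map stays below the injected dose
  iron_mmol <- sum(m1) * prod(gg$spacing) * 1e-6
  expect_lt(iron_mmol,
            pk$kinetics$dose_mmol_kg * pk$phantom$body_weight_kg)
})

test_that("default rat phantom is reproducible with the published geometry", {
  a <- default_rat_phantom(7)
  b <- default_rat_phantom(7)
  expect_identical(a, b)
  d <- vapply(a$phantom$vessels, function(v) v$diameter_mm, numeric(1))
  labs <- vapply(a$phantom$vessels, function(v) v$label, character(1))
  expect_equal(d[labs == "IVC"], 2.7, ignore_attr = TRUE)
  expect_equal(d[labs == "AA"], 2.4, ignore_attr = TRUE)
  expect_equal(a$kinetics$ivc_arrival_delay_s, 1.25)
  expect_equal(a$kinetics$aa_arrival_delay_s, 2.5)
  expect_equal(a$kinetics$respiratory_rate_bpm, 60)
  # different seed -> different body weight, same vessel geometry
  c2 <- default_rat_phantom(8)
  expect_false(c2$phantom$body_weight_kg == a$phantom$body_weight_kg)
})
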