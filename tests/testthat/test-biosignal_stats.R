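# build a one-component raw signal whose magnitude is modulated at a known
# rate, through the real simulation chain (1-voxel system, tiny band)
modulated_raw <- function(rate_bpm, depth = 0.1, duration_s = 30,
                          dt = 4 * 53856 / 2.5e6, noise_sd = 0, seed = 1) {
  sc <- scanner_config(recon_grid = c(1L, 1L, 1L), recon_volume = c(1, 1, 1),
                       samples_per_frame = 64L)
  sm <- simulate_system_matrix(sc, tracer_mcp3(), recon_grid_geometry(sc),
                               max_frequency_index = 20L)
  kin <- bolus_kinetics(respiratory_rate_bpm = rate_bpm,
                        respiratory_depth = depth)
  times <- seq(0, duration_s, by = dt)
  conc <- matrix(2, nrow = length(times), ncol = 1L)
  simulate_signal(conc, sm, frame_times = times, noise_sd = noise_sd,
                  respiratory = respiratory_scale(times, kin),
                  injection_time_s = 0, seed = seed)
}

test_that("a known modulation rate appears as the dominant spectral peak", {
  raw <- modulated_raw(60)
  b <- extract_biosignal(raw)
  bin_hz <- 1 / diff(range(raw$frame_times))
  expect_lt(abs(b$dominant_frequency - 1.0), bin_hz + 1e-9)
  expect_equal(respiratory_rate(b), 60, tolerance = 60 * bin_hz)
  expect_equal(respiratory_rate(extract_biosignal(modulated_raw(30))), 30,
               tolerance = 60 * bin_hz)

  # invariant under positive amplitude rescaling
  raw2 <- raw
  raw2$frames <- raw2$frames * 17.3
  expect_equal(respiratory_rate(extract_biosignal(raw2)),
               respiratory_rate(b))
})

test_that("constant series carry no modulation and short records error", {
  raw <- modulated_raw(60, depth = 0)
  b <- extract_biosignal(raw)
  expect_true(b$no_modulation)
  expect_true(is.na(b$dominant_frequency))
  expect_error(respiratory_rate(b), "no modulation")
  expect_error(extract_biosignal(modulated_raw(60, duration_s = 2)),
               "too short")
})

test_that("randomized rates in the physiological band are recovered
           within one spectral bin", {
  hits <- 0L
  n_trials <- 20L
  set.seed(314)
  rates <- stats::runif(n_trials, 40, 90)
  for (i in seq_len(n_trials)) {
    raw <- modulated_raw(rates[i], depth = 0.1, noise_sd = 0, seed = i)
    b <- extract_biosignal(raw)
    bin <- 1 / diff(range(raw$frame_times))
    if (abs(b$dominant_frequency - rates[i] / 60) <= bin + 1e-9) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("clearance gating passes clean baselines and fails residual tracer", {
  sc <- scanner_config(recon_grid = c(1L, 1L, 1L), recon_volume = c(1, 1, 1),
                       samples_per_frame = 64L)
  sm <- simulate_system_matrix(sc, tracer_mcp3(), recon_grid_geometry(sc),
                               max_frequency_index = 20L)
  times <- seq(0, 30, by = 4 * 53856 / 2.5e6)
  nfr <- length(times)
  bg <- complex(real = rep(1, nrow(sm$entries)),
                imaginary = rep(0.5, nrow(sm$entries)))
  noise_sd <- 0.02
  comp <- which.max(abs(sm$entries[, 1]))
  s1 <- abs(sm$entries[comp, 1])
  # residual concentration scaled so its signal sits 20x above the noise
  conc_resid <- 0.4 * sm$calibration_concentration / s1

  # empty-bore reference recording defines the noise floor and the
  # background magnitude statistics
  ref <- simulate_signal(matrix(0, nfr, 1), sm, frame_times = times,
                         background = bg, noise_sd = noise_sd, seed = 1,
                         injection_time_s = NA)
  bref <- extract_biosignal(ref, component = comp)
  band <- bref$frequency >= 40 / 60 & bref$frequency <= 90 / 60
  floor0 <- max(bref$power[band])
  bg_mean <- mean(abs(ref$frames[, comp]))
  bg_sd <- stats::sd(abs(ref$frames[, comp]))

  # tracer-free baseline on a different noise realization: passes
  clean <- simulate_signal(matrix(0, nfr, 1), sm, frame_times = times,
                           background = bg, noise_sd = noise_sd, seed = 2,
                           injection_time_s = NA)
  b0 <- extract_biosignal(clean, component = comp)
  expect_true(clearance_check(b0, floor0, bg_mean, bg_sd)$pass)

  # residual circulating tracer: modulated and elevated -> fails
  kin <- bolus_kinetics(respiratory_rate_bpm = 60, respiratory_depth = 0.1)
  resid <- simulate_signal(matrix(conc_resid, nfr, 1), sm,
                           frame_times = times, background = bg,
                           noise_sd = noise_sd, seed = 3,
                           respiratory = respiratory_scale(times, kin),
                           injection_time_s = NA)
  br <- extract_biosignal(resid, component = comp)
  chk <- clearance_check(br, floor0, bg_mean, bg_sd)
  expect_false(chk$pass)

  # five half-lives later (0.5^5 ~ 3.1% residual): passes again
  faint <- simulate_signal(matrix(conc_resid * 0.5^5, nfr, 1), sm,
                           frame_times = times, background = bg,
                           noise_sd = noise_sd, seed = 4,
                           respiratory = respiratory_scale(times, kin),
                           injection_time_s = NA)
  bf <- extract_biosignal(faint, component = comp)
  expect_true(clearance_check(bf, floor0, bg_mean, bg_sd)$pass)
})

test_that("exact one-tailed Mann-Whitney matches enumeration and wilcox.test", {
  res <- mann_whitney_one_tailed(c(3, 4, 4), c(1, 2, 2))
  expect_equal(res$U, 9)
  expect_equal(res$p, 1 / 20)
  expect_equal(res$method, "exact")

  expect_equal(mann_whitney_one_tailed(3, 3)$p, 1)
  expect_error(mann_whitney_one_tailed(numeric(0), 1), "non-empty")

  set.seed(21)
  for (trial in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:4, na, replace = TRUE)
    b <- sample(1:4, nb, replace = TRUE)
    res <- mann_whitney_one_tailed(a, b)
    expect_equal(res$p, brute_mw(a, b), tolerance = 1e-12)
    if (!anyDuplicated(c(a, b))) {
      wt <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
      expect_equal(res$p, wt$p.value, tolerance = 1e-12)
      expect_equal(res$U, unname(wt$statistic))
    }
  }

  # swapping groups gives the complementary tail (up to the tie at U)
  a <- c(4, 2, 3); b <- c(1, 2, 4)
  p_ab <- mann_whitney_one_tailed(a, b)$p
  # complement: P(U_ba >= U_ba_obs) = P(U_ab <= U_ab_obs)
  r <- rank(c(a, b))
  picks <- utils::combn(6, 3)
  Us <- colSums(matrix(r[picks], nrow = 3)) - 6
  U_obs <- sum(r[1:3]) - 6
  expect_equal(mann_whitney_one_tailed(b, a)$p, mean(Us <= U_obs + 1e-9))
  expect_equal(p_ab + mean(Us < U_obs - 1e-9), 1)
})

test_that("normal approximation engages above the exact-enumeration limit", {
  set.seed(9)
  a <- sample(1:4, 8, replace = TRUE)
  b <- sample(1:4, 8, replace = TRUE)
  res <- mann_whitney_one_tailed(a, b)
  expect_equal(res$method, "normal")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater",
                                            exact = FALSE, correct = TRUE))
  expect_equal(res$p, wt$p.value, tolerance = 1e-6)
})

test_that("VGAS tables validate scores and summarize tracer contrasts", {
  df <- data.frame(
    examination_id = paste0("ex", 1:6),
    tracer = rep(c("MCP3", "Resovist"), each = 3),
    dose_mmolFe_per_kg = rep(0.1, 6),
    ivc_visibility = c(4, 4, 3, 2, 2, 1),
    aa_visibility = c(4, 3, 4, 1, 2, 1),
    background_artifact = c(3, 4, 4, 2, 1, 2)
  )
  tab <- vgas_table(df)
  expect_equal(tab$overall, c(11, 11, 11, 5, 5, 4))
  expect_true(all(tab$overall >= 3 & tab$overall <= 12))

  bad <- df; bad$ivc_visibility[1] <- 5
  expect_error(vgas_table(bad), "1..4")
  expect_error(vgas_table(df[, -4]), "missing columns")

  s <- vgas_summary(tab)
  expect_equal(nrow(s$tests), 4)
  # maximal separation at n = 3 vs 3: the smallest attainable exact p, 0.05
  expect_true(all(s$tests$p == 0.05))
  expect_true(all(s$tests$significant))

  # identical scores: no separation, no significance
  same <- df
  same[4:6, 4:6] <- same[1:3, 4:6]
  s2 <- vgas_summary(vgas_table(same))
  expect_false(any(s2$tests$significant))
  means <- s2$means
  expect_equal(means$overall[1], means$overall[2])

  # maximal separation all-4 vs all-1
  ext <- df
  ext[1:3, 4:6] <- 4; ext[4:6, 4:6] <- 1
  s3 <- vgas_summary(vgas_table(ext))
  expect_equal(s3$tests$p, rep(0.05, 4))
})
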