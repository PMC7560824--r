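#' Extract the respiratory biosignal from raw MPI data
#'
#' Takes the per-frame magnitude of one raw frequency component (before
#' background subtraction), removes the slow trend (bolus passage and
#' clearance) with a centered moving average, applies a Hann window and
#' computes the periodogram. Respiration of the anesthetized animal
#' modulates the signal amplitude, so its rate appears as a distinct
#' spectral peak well below the frame rate.
#'
#' @param raw A \code{raw_signal}.
#' @param component Component (column) index; default NULL picks the
#'   component with the largest mean magnitude (the dominant signal-bearing
#'   component, a stand-in for the highest-SNR component).
#' @param min_duration_s Minimum record length (default 4 s, two cycles at
#'   30 breaths/min).
#' @param min_frequency_hz Lower edge of the peak search band (default
#'   0.4 Hz, i.e. 24 breaths/min): the slow bolus passage and clearance
#'   trend dominate the spectrum below this, so the dominant frequency is
#'   taken as the periodogram argmax above it. The full spectrum from the
#'   first non-DC bin is still returned.
#' @param detrend_window_s Width of the centered moving-average trend
#'   estimate subtracted before spectral analysis (default 2.5 s; 0
#'   disables detrending beyond mean removal).
#' @param frames Optional contiguous frame-index window to analyze (e.g.
#'   the quasi-stationary plateau after the bolus first pass, where the
#'   respiratory modulation is not masked by the transient).
#' @return Object of class \code{biosignal}: \code{times}, \code{amplitude},
#'   \code{frequency} (Hz), \code{power}, \code{dominant_frequency} (NA with
#'   flag \code{no_modulation} when the series carries no modulation).
#' @export
extract_biosignal <- function(raw, component = NULL, min_duration_s = 4,
                              min_frequency_hz = 0.4,
                              detrend_window_s = 2.5,
                              frames = NULL) {
  stopifnot(inherits(raw, "raw_signal"))
  if (!is.null(frames)) {
    frames <- as.integer(frames)
    stopifnot(all(frames >= 1L), all(frames <= nrow(raw$frames)),
              all(diff(frames) == 1L))
    raw$frames <- raw$frames[frames, , drop = FALSE]
    raw$frame_times <- raw$frame_times[frames]
  }
  dur <- diff(range(raw$frame_times))
  if (dur < min_duration_s) {
    stop("record too short: ", round(dur, 2), " s < ", min_duration_s, " s",
         call. = FALSE)
  }
  mag <- abs(raw$frames)
  if (is.null(component)) component <- which.max(colMeans(mag))
  a <- mag[, component]
  n <- length(a)
  dt <- stats::median(diff(raw$frame_times))
  x <- a - moving_average(a, detrend_window_s, dt)
  no_mod <- stats::sd(a) == 0
  w <- hann_window(n)
  p <- Mod(stats::fft(x * w))^2 / sum(w^2)
  nk <- n %/% 2L
  freq <- (seq_len(nk)) / (n * dt)
  power <- p[2L:(nk + 1L)]
  band <- which(freq >= min_frequency_hz)
  dom <- if (no_mod || length(band) == 0L) NA_real_ else
    freq[band[which.max(power[band])]]
  structure(list(
    times = raw$frame_times,
    amplitude = a,
    component = component,
    frequency = freq,
    power = power,
    dominant_frequency = dom,
    no_modulation = no_mod
  ), class = "biosignal")
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# centered moving average with edge-shrinking windows; falls back to the
# series mean when the window is degenerate
moving_average <- function(a, window_s, dt) {
  n <- length(a)
  w <- round(window_s / dt)
  if (w < 3L || w >= n) return(rep(mean(a), n))
  half <- w %/% 2L
  cs <- cumsum(c(0, a))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Respiratory rate from a biosignal
#'
#' @param b A \code{biosignal}.
#' @return Rate in breaths per minute (dominant frequency x 60).
#' @export
respiratory_rate <- function(b) {
  stopifnot(inherits(b, "biosignal"))
  if (isTRUE(b$no_modulation) || is.na(b$dominant_frequency)) {
    stop("no modulation detected; respiratory rate undefined", call. = FALSE)
  }
  b$dominant_frequency * 60
}

#' Tracer clearance check on a baseline recording
#'
#' Gates a repeat injection: passes when (a) the modulation power in the
#' respiratory band does not exceed \code{power_factor} times the supplied
#' noise floor, and (b) the mean component magnitude lies within
#' \code{mean_sd_factor} standard deviations of the empty-bore background
#' level. Residual circulating tracer fails either check: its signal is
#' respiration-modulated and raises the mean magnitude.
#'
#' @param b A \code{biosignal} computed on the baseline window.
#' @param noise_floor Reference periodogram power of a tracer-free record:
#'   the maximum respiratory-band power of an empty-bore (or pre-first-
#'   injection) recording under the same acquisition settings.
#' @param background_mean,background_sd Empty-bore mean component magnitude
#'   and its standard deviation.
#' @param band_bpm Respiratory band searched, breaths/min (default 40-90).
#' @param power_factor,mean_sd_factor Thresholds (defaults 3 and 3).
#' @return List with logical \code{pass} and the two sub-checks.
#' @export
clearance_check <- function(b, noise_floor, background_mean, background_sd,
                            band_bpm = c(40, 90), power_factor = 3,
                            mean_sd_factor = 3) {
  stopifnot(inherits(b, "biosignal"), noise_floor >= 0, background_sd >= 0)
  band_hz <- sort(band_bpm) / 60
  in_band <- b$frequency >= band_hz[1] & b$frequency <= band_hz[2]
  band_power <- if (any(in_band)) max(b$power[in_band]) else 0
  power_ok <- band_power <= power_factor * noise_floor
  mean_ok <- abs(mean(b$amplitude) - background_mean) <=
    mean_sd_factor * background_sd
  list(pass = power_ok && mean_ok,
       modulation_ok = power_ok,
       mean_level_ok = mean_ok,
       band_power = band_power)
}

#' One-tailed Mann-Whitney U test for ordinal scores
#'
#' Tests the alternative "group A stochastically larger than group B".
#' For combined sample sizes up to \code{exact_max_n} the p value is
#' computed by exhaustive enumeration of all group labelings of the
#' combined sample (midranks for ties); above that, a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors of ordinal scores (alternative: a > b).
#' @param exact_max_n Largest combined n for exact enumeration (default 12).
#' @return List with \code{U} (statistic of group a), \code{p}, and
#'   \code{method} ("exact" or "normal").
#' @export
mann_whitney_one_tailed <- function(a, b, exact_max_n = 12L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))                 # midranks
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exact_max_n) {
    picks <- utils::combn(n, na)
    Us <- colSums(matrix(r[picks], nrow = na)) - na * (na + 1) / 2
    p <- mean(Us >= U_obs - 1e-9)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    z <- (U_obs - mu - 0.5) / sigma
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(U = U_obs, p = p, method = method)
}

#' Validate a visual-grading (VGAS) score table
#'
#' Expected columns: \code{examination_id}, \code{tracer},
#' \code{dose_mmolFe_per_kg} and the three 4-point criteria
#' \code{ivc_visibility}, \code{aa_visibility}, \code{background_artifact}
#' (1 = worst, 4 = best). Adds the per-examination \code{overall} score
#' (sum of the three criteria, range 3-12).
#'
#' @param df Data frame of scores.
#' @return Validated data frame of class \code{vgas_table}.
#' @export
vgas_table <- function(df) {
  df <- as.data.frame(df)
  criteria <- c("ivc_visibility", "aa_visibility", "background_artifact")
  need <- c("examination_id", "tracer", "dose_mmolFe_per_kg", criteria)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  for (cr in criteria) {
    v <- df[[cr]]
    if (any(!is.finite(v)) || any(v != round(v)) || any(v < 1) || any(v > 4)) {
      stop("scores in ", cr, " must be integers in 1..4", call. = FALSE)
    }
  }
  df$overall <- df$ivc_visibility + df$aa_visibility + df$background_artifact
  class(df) <- c("vgas_table", "data.frame")
  df
}

#' Summarize VGAS scores and compare tracers
#'
#' Group means per criterion (and the overall sum) by tracer and dose, plus
#' one-tailed Mann-Whitney comparisons of the two tracers per criterion,
#' with the alternative fixed as \code{tracer_a} scoring higher than
#' \code{tracer_b}.
#'
#' @param table A \code{vgas_table}.
#' @param tracer_a,tracer_b Tracer labels compared (alternative: a > b).
#' @param alpha Significance level (default 0.05).
#' @param by_dose Also compute per-dose group means (default TRUE).
#' @return List with \code{means} (per tracer x dose x criterion),
#'   \code{tests} (per criterion: U, p, significant).
#' @export
vgas_summary <- function(table, tracer_a = "MCP3", tracer_b = "Resovist",
                         alpha = 0.05, by_dose = TRUE) {
  stopifnot(inherits(table, "vgas_table"))
  criteria <- c("ivc_visibility", "aa_visibility", "background_artifact",
                "overall")
  grp <- if (by_dose) {
    interaction(table$tracer, table$dose_mmolFe_per_kg, drop = TRUE)
  } else {
    factor(table$tracer)
  }
  means <- aggregate(table[criteria], by = list(group = grp), FUN = mean)

  tests <- lapply(criteria, function(cr) {
    a <- table[[cr]][table$tracer == tracer_a]
    b <- table[[cr]][table$tracer == tracer_b]
    res <- mann_whitney_one_tailed(a, b)
    data.frame(criterion = cr, U = res$U, p = res$p,
               method = res$method, significant = res$p <= alpha)
  })
  list(means = means, tests = do.call(rbind, tests), alpha = alpha,
       alternative = paste(tracer_a, ">", tracer_b))
}
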