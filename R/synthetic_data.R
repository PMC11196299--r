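# Seeded generator of micromotion recordings with known ground truth:
# a respiration carrier with posture-dependent amplitude and apnea/hypopnea
# dips, a BCG wavelet train with cyclic heart-rate variation locked to the
# events, movement bursts, optional PLM-like dip trains, and sensor noise.

#' Configuration of a synthetic micromotion recording
#'
#' Defaults describe a mid-physiological sleeper: 15 breaths/min, heart
#' rate 60 bpm (RR 1000 +/- 50 ms), posture changes about every 30 min with
#' amplitude factors between 0.5 and 2, apnea/hypopnea events of 60% depth
#' lasting 15-60 s, and sensor noise at 5% of the respiration amplitude.
#'
#' @param duration_s Recording length in seconds (default 7200).
#' @param sampling_rate Hz (default 100).
#' @param respiration_hz Breathing frequency (default 0.25 = 15/min).
#' @param respiration_amp Carrier amplitude in sensor units (default 5000).
#' @param breath_amp_sdlog Lognormal SD of the per-breath amplitude factor
#'   (default 0.08, about 8% breath-to-breath coefficient of variation, as
#'   seen in stable NREM breathing; 0 disables).
#' @param event_rate_per_h Mean respiratory event rate (default 12).
#' @param event_depth_percent Relative amplitude reduction during events
#'   (default 60).
#' @param event_duration_s `(min, max)` of the uniform event duration
#'   distribution (default 15-60 s).
#' @param event_taper_s Cosine taper of event transitions (default 3 s), so
#'   the plateau log-envelope depth equals `-ln(1 - depth/100)` exactly.
#' @param posture_shift_every_s Mean interval between posture shifts
#'   (default 1800 s; `Inf` disables shifts).
#' @param shift_factor_range Uniform range of posture amplitude factors.
#' @param bcg List: `mean_rr_ms`, `rr_sd_ms`, `pulse_freq_hz`, `pulse_amp`,
#'   `cvhr_dip_ms` (RR shortening of the post-event tachycardia dip),
#'   `cvhr_width_s` (half-width of the dip bump).
#' @param movement_burst_rate_per_h Gross body-movement bursts per hour.
#' @param movement_burst_amp Burst amplitude in sensor units.
#' @param movement_burst_duration_s `(min, max)` burst length in seconds.
#' @param plm List: `enabled`, `spacing_s` (inter-dip spacing inside a
#'   train), `dip_ms` (RR dip depth), `train_length` (dips per train),
#'   `train_rate_per_h` (trains per hour).
#' @param noise_sd White sensor noise SD in sensor units (default 250 = 5%
#'   of the respiration amplitude).
#' @param seed Mandatory integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 7200,
                              sampling_rate = 100,
                              respiration_hz = 0.25,
                              respiration_amp = 5000,
                              breath_amp_sdlog = 0.08,
                              event_rate_per_h = 12,
                              event_depth_percent = 60,
                              event_duration_s = c(15, 60),
                              event_taper_s = 3,
                              posture_shift_every_s = 1800,
                              shift_factor_range = c(0.5, 2),
                              bcg = list(mean_rr_ms = 1000, rr_sd_ms = 50,
                                         pulse_freq_hz = 8, pulse_amp = 500,
                                         cvhr_dip_ms = 200, cvhr_width_s = 10),
                              movement_burst_rate_per_h = 5,
                              movement_burst_amp = 50000,
                              movement_burst_duration_s = c(2, 5),
                              plm = list(enabled = FALSE, spacing_s = 30,
                                         dip_ms = 100, train_length = 10,
                                         train_rate_per_h = 6),
                              noise_sd = 250,
                              seed = 1) {
  cfg <- as.list(environment())
  bcg_defaults <- list(mean_rr_ms = 1000, rr_sd_ms = 50, pulse_freq_hz = 8,
                       pulse_amp = 500, cvhr_dip_ms = 200, cvhr_width_s = 10)
  plm_defaults <- list(enabled = FALSE, spacing_s = 30, dip_ms = 100,
                       train_length = 10, train_rate_per_h = 6)
  cfg$bcg <- utils::modifyList(bcg_defaults, bcg)
  cfg$plm <- utils::modifyList(plm_defaults, plm)
  if (cfg$duration_s <= 0 || cfg$sampling_rate <= 0) {
    stop("duration_s and sampling_rate must be positive")
  }
  if (cfg$event_rate_per_h < 0 || cfg$noise_sd < 0 ||
      cfg$respiration_amp < 0) {
    stop("rates and amplitudes must be non-negative")
  }
  if (cfg$event_depth_percent < 0 || cfg$event_depth_percent >= 100) {
    stop("event_depth_percent must be in [0, 100)")
  }
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed is mandatory")
  structure(cfg, class = "simulation_config")
}

# Poisson event placement thinned to forbid overlap (10-s minimum gap).
place_events <- function(cfg) {
  hours <- cfg$duration_s / 3600
  n_target <- stats::rpois(1, cfg$event_rate_per_h * hours)
  if (n_target == 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  margin <- min(120, 0.1 * cfg$duration_s)
  lo <- margin
  hi <- cfg$duration_s - margin - cfg$event_duration_s[2]
  if (hi <= lo) stop("recording too short for event placement")
  starts <- sort(stats::runif(n_target, lo, hi))
  durs <- stats::runif(n_target, cfg$event_duration_s[1],
                       cfg$event_duration_s[2])
  keep_start <- numeric(0)
  keep_end <- numeric(0)
  prev_end <- -Inf
  for (i in seq_len(n_target)) {
    if (starts[i] >= prev_end + 10) {
      keep_start <- c(keep_start, starts[i])
      prev_end <- starts[i] + durs[i]
      keep_end <- c(keep_end, prev_end)
    }
  }
  data.frame(start_s = keep_start, end_s = keep_end)
}

# Cosine-tapered dip factor: 1 outside events, 1 - depth at plateau,
# half-cosine ramps of length taper_s at both edges.
event_factor <- function(t, events, depth_frac, taper_s) {
  f <- rep(1, length(t))
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]
    e <- events$end_s[i]
    idx <- which(t >= s & t < e)
    if (!length(idx)) next
    g <- rep(1, length(idx))
    ti <- t[idx]
    ramp_in <- ti < s + taper_s
    g[ramp_in] <- 0.5 - 0.5 * cos(pi * (ti[ramp_in] - s) / taper_s)
    ramp_out <- ti >= e - taper_s
    g[ramp_out] <- 0.5 - 0.5 * cos(pi * (e - ti[ramp_out]) / taper_s)
    f[idx] <- 1 - depth_frac * pmin(1, g)
  }
  f
}

#' Simulate one subject's micromotion recording with ground truth
#'
#' The signal is the sum of (i) an amplitude-modulated respiration carrier
#' whose amplitude follows piecewise-constant posture factors and dips by
#' the configured depth during events (3-s cosine-tapered transitions, so
#' the log-envelope dip equals `-ln(1 - depth/100)` at plateau), (ii) a BCG
#' wavelet train at beat times whose RR intervals carry a tachycardia dip
#' centered on each event's end (the cyclic variation of heart rate) and
#' optional shallow PLM dip trains, (iii) band-limited movement bursts, and
#' (iv) white sensor noise, integer-quantized into the 24-bit range.
#'
#' @param config A [simulation_config()].
#' @return List with `record` (a [micromotion_record()]) and `truth` (list:
#'   `events` data frame, `true_ahi`, `beat_times_s`, `posture_shifts`,
#'   `movement_bursts`, `plm_dips`).
#' @export
simulate_subject <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  rate <- config$sampling_rate
  n <- round(config$duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  hours <- config$duration_s / 3600

  events <- if (config$event_rate_per_h > 0) place_events(config) else
    data.frame(start_s = numeric(0), end_s = numeric(0))

  # posture factors, piecewise constant
  if (is.finite(config$posture_shift_every_s) &&
      config$posture_shift_every_s < config$duration_s) {
    shift_times <- seq(config$posture_shift_every_s, config$duration_s - 1,
                       by = config$posture_shift_every_s)
    shift_times <- shift_times +
      stats::runif(length(shift_times), -0.1, 0.1) *
        config$posture_shift_every_s
    factors <- stats::runif(length(shift_times),
                            config$shift_factor_range[1],
                            config$shift_factor_range[2])
  } else {
    shift_times <- numeric(0)
    factors <- numeric(0)
  }
  posture <- rep(1, n)
  for (i in seq_along(shift_times)) {
    posture[t >= shift_times[i]] <- factors[i]
  }

  dip <- event_factor(t, events, config$event_depth_percent / 100,
                      config$event_taper_s)

  # breath-to-breath tidal amplitude variability: lognormal factor held
  # constant over each breath cycle
  if (config$breath_amp_sdlog > 0) {
    n_breaths <- ceiling(config$duration_s * config$respiration_hz) + 1
    bf <- stats::rlnorm(n_breaths, 0, config$breath_amp_sdlog)
    breath_factor <- bf[floor(t * config$respiration_hz) + 1]
  } else {
    breath_factor <- 1
  }
  respiration <- config$respiration_amp * posture * dip * breath_factor *
    sin(2 * pi * config$respiration_hz * t)

  # RR modulation in ms as a function of time: negative bumps (tachycardia
  # dips) at event ends, plus optional shallow PLM dip trains
  mod_rate <- 10
  mod_t <- seq(0, config$duration_s, by = 1 / mod_rate)
  rr_mod <- rep(0, length(mod_t))
  add_dip <- function(center, depth_ms, half_width_s) {
    idx <- which(abs(mod_t - center) <= half_width_s)
    bump <- 0.5 * (1 + cos(pi * (mod_t[idx] - center) / half_width_s))
    rr_mod[idx] <<- rr_mod[idx] - depth_ms * bump
  }
  for (i in seq_len(nrow(events))) {
    add_dip(events$end_s[i], config$bcg$cvhr_dip_ms, config$bcg$cvhr_width_s)
  }
  plm_dips <- numeric(0)
  if (isTRUE(config$plm$enabled)) {
    n_trains <- stats::rpois(1, config$plm$train_rate_per_h * hours)
    if (n_trains > 0) {
      train_span <- config$plm$spacing_s * config$plm$train_length
      train_starts <- stats::runif(n_trains, 60,
                                   max(61, config$duration_s - train_span - 60))
      for (ts in train_starts) {
        dips <- ts + (seq_len(config$plm$train_length) - 1) *
          config$plm$spacing_s +
          stats::runif(config$plm$train_length, -2, 2)
        dips <- dips[dips < config$duration_s - 30]
        plm_dips <- c(plm_dips, dips)
        # post-movement heart-rate surges last on the order of 10-20 s
        for (d in dips) add_dip(d, config$plm$dip_ms, 12)
      }
      plm_dips <- sort(plm_dips)
    }
  }

  # beat-by-beat RR generation and wavelet pulse train
  bcg_sig <- rep(0, n)
  beat_times <- numeric(0)
  if (config$bcg$pulse_amp > 0) {
    sigma <- 0.1
    tau <- seq(-0.35, 0.35, by = 1 / rate)
    wavelet <- exp(-tau^2 / (2 * sigma^2)) *
      sin(2 * pi * config$bcg$pulse_freq_hz * tau)
    n_beats_max <- ceiling(config$duration_s /
                             (config$bcg$mean_rr_ms / 1000) * 1.5) + 10
    rr_noise <- stats::rnorm(n_beats_max, 0, config$bcg$rr_sd_ms)
    beat_times <- numeric(n_beats_max)
    tb <- 0.5
    k <- 0
    while (tb < config$duration_s - 0.5 && k < n_beats_max) {
      k <- k + 1
      beat_times[k] <- tb
      mod_now <- rr_mod[min(length(rr_mod), floor(tb * mod_rate) + 1)]
      rr <- max(300, config$bcg$mean_rr_ms + rr_noise[k] + mod_now)
      tb <- tb + rr / 1000
    }
    beat_times <- beat_times[seq_len(k)]
    half <- (length(tau) - 1) / 2
    for (bt in beat_times) {
      c0 <- round(bt * rate) + 1
      lo <- max(1, c0 - half)
      hi <- min(n, c0 + half)
      wi <- (lo:hi) - (c0 - half) + 1
      bcg_sig[lo:hi] <- bcg_sig[lo:hi] + config$bcg$pulse_amp * wavelet[wi]
    }
  }

  # gross movement bursts (band-limited around 2.5 Hz), plus brief leg
  # movement blips at PLM dips
  mov_sig <- rep(0, n)
  n_bursts <- stats::rpois(1, config$movement_burst_rate_per_h * hours)
  burst_log <- data.frame(time_s = numeric(0), duration_s = numeric(0))
  if (n_bursts > 0) {
    b_start <- stats::runif(n_bursts, 1, config$duration_s -
                              config$movement_burst_duration_s[2] - 1)
    b_dur <- stats::runif(n_bursts, config$movement_burst_duration_s[1],
                          config$movement_burst_duration_s[2])
    for (i in seq_len(n_bursts)) {
      idx <- which(t >= b_start[i] & t < b_start[i] + b_dur[i])
      if (!length(idx)) next
      ph <- stats::runif(1, 0, 2 * pi)
      hann <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx))
      mov_sig[idx] <- mov_sig[idx] + config$movement_burst_amp * hann *
        sin(2 * pi * 2.5 * t[idx] + ph)
    }
    burst_log <- data.frame(time_s = b_start, duration_s = b_dur)
  }
  for (d in plm_dips) {
    idx <- which(t >= d - 0.2 & t < d + 0.2)
    if (!length(idx)) next
    hann <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / length(idx))
    mov_sig[idx] <- mov_sig[idx] + 2 * config$respiration_amp * hann *
      sin(2 * pi * 2.5 * t[idx])
  }

  signal <- respiration + bcg_sig + mov_sig
  if (config$noise_sd > 0) signal <- signal + stats::rnorm(n, 0, config$noise_sd)
  signal <- round(signal)
  if (any(signal < BIT24_MIN | signal > BIT24_MAX)) {
    stop("saturation: combined amplitudes exceed the 24-bit sensor range")
  }

  list(
    record = micromotion_record(signal, sampling_rate = rate),
    truth = list(
      events = events,
      true_ahi = nrow(events) / hours,
      beat_times_s = beat_times,
      posture_shifts = data.frame(time_s = shift_times, factor = factors),
      movement_bursts = burst_log,
      plm_dips = plm_dips
    )
  )
}

#' Simulate a cohort of subjects with known AHI spectrum
#'
#' Per-subject event rates are drawn from the requested distribution (the
#' lognormal default matches a sleep-clinic population with median AHI
#' around 13/h); per-subject seeds are derived deterministically from the
#' master seed (`seed * 10000 + subject index`), so identical calls yield
#' identical cohorts. The first half of the subjects is labelled
#' `training`, the second half `test`.
#'
#' @param n Number of subjects (>= 2).
#' @param ahi_distribution List describing the event-rate distribution:
#'   `list(type = "lognormal", median, sdlog)`,
#'   `list(type = "uniform", min, max)`, or
#'   `list(type = "fixed", values)` (recycled to `n`).
#' @param base_config A [simulation_config()] supplying everything except
#'   the event rate and seed.
#' @param seed Master seed.
#' @return List of `n` subjects, each a list with `record`, `truth`, and
#'   `meta` (one-row data frame: subject_id, ahi_trt, ahi_tst, plm_index,
#'   group). `ahi_trt` is the planted ground-truth event rate.
#' @export
simulate_cohort <- function(n,
                            ahi_distribution = list(type = "lognormal",
                                                    median = 13, sdlog = 1),
                            base_config = simulation_config(),
                            seed = 1) {
  if (n < 2) stop("cohort needs at least 2 subjects")
  set.seed(seed)
  rates <- switch(
    ahi_distribution$type,
    lognormal = pmin(80, stats::rlnorm(n, log(ahi_distribution$median),
                                       ahi_distribution$sdlog)),
    uniform = stats::runif(n, ahi_distribution$min, ahi_distribution$max),
    fixed = rep_len(ahi_distribution$values, n),
    stop(sprintf("unknown ahi_distribution type '%s'", ahi_distribution$type))
  )
  hours <- base_config$duration_s / 3600
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    cfg$event_rate_per_h <- rates[i]
    cfg$seed <- seed * 10000 + i
    sub <- simulate_subject(cfg)
    plm_index <- length(sub$truth$plm_dips) / hours
    sub$meta <- data.frame(
      subject_id = sprintf("S%03d", i),
      ahi_trt = sub$truth$true_ahi,
      ahi_tst = sub$truth$true_ahi,
      plm_index = plm_index,
      group = if (i <= n / 2) "training" else "test",
      stringsAsFactors = FALSE
    )
    sub
  })
}

#' Write a simulated cohort to disk
#'
#' Writes one sensor CSV and one ground-truth event TSV per subject plus a
#' manifest CSV (`subject_id`, `path`, `ahi_trt`, `ahi_tst`, `plm_index`,
#' `group`) compatible with the `calibrate` and `evaluate` command-line
#' subcommands.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(sub) {
    id <- sub$meta$subject_id
    sig_path <- file.path(dir, paste0(id, ".csv"))
    write_micromotion_csv(sub$record, sig_path)
    write_events_tsv(sub$truth$events, file.path(dir, paste0(id, "_truth.tsv")),
                     subject_id = id)
    cbind(sub$meta[, "subject_id", drop = FALSE],
          path = sig_path,
          sub$meta[, c("ahi_trt", "ahi_tst", "plm_index", "group")])
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
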