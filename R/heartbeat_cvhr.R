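# Heartbeat-interval extraction from the ballistocardiogram and scoring of
# cyclic variation of heart rate (CVHR), yielding Fcv. An externally
# produced interval series (e.g. ECG R-R) can be supplied instead for
# ECG-Fcv.

# Editing rules shared by the BCG detector and the external reader:
# intervals outside [300, 2000] ms, or deviating more than 30% from the
# 7-beat running median, are flagged rejected.
edit_intervals <- function(intervals_ms) {
  n <- length(intervals_ms)
  if (n == 0) return(character(0))
  quality <- rep("valid", n)
  quality[intervals_ms < 300 | intervals_ms > 2000] <- "rejected"
  if (n >= 2) {
    k <- min(7L, if (n %% 2 == 1) n else n - 1L)
    med <- stats::runmed(intervals_ms, k)
    quality[abs(intervals_ms - med) / med > 0.30] <- "rejected"
  }
  quality
}

#' Construct a heartbeat interval series from beat times
#'
#' Successive differences of the beat times give the inter-beat intervals;
#' each interval is flagged `valid` or `rejected` by the editing rules
#' (physiological range 300-2000 ms, and within 30% of the 7-beat running
#' median).
#'
#' @param beat_times_s Strictly increasing beat times in seconds.
#' @param intervals_ms Optional intervals in milliseconds; defaults to the
#'   successive differences of `beat_times_s`. May have one entry per beat
#'   (each interval ending at its beat, as in an external R-R list) or one
#'   fewer.
#' @return An object of class `heartbeat_series`: list with `beat_times_s`,
#'   `intervals_ms`, `interval_times_s` (the closing beat of each interval)
#'   and `quality`.
#' @export
heartbeat_series <- function(beat_times_s,
                             intervals_ms = diff(beat_times_s) * 1000) {
  if (length(beat_times_s) && any(diff(beat_times_s) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  if (any(intervals_ms <= 0)) stop("intervals must be positive")
  n <- length(beat_times_s)
  interval_times <- if (length(intervals_ms) == n) beat_times_s
    else if (length(intervals_ms) == max(0L, n - 1L)) beat_times_s[-1]
    else stop("intervals_ms must have one entry per beat or one fewer")
  structure(
    list(
      beat_times_s = as.numeric(beat_times_s),
      intervals_ms = as.numeric(intervals_ms),
      interval_times_s = as.numeric(interval_times),
      quality = edit_intervals(intervals_ms)
    ),
    class = "heartbeat_series"
  )
}

#' @export
print.heartbeat_series <- function(x, ...) {
  cat(sprintf("<heartbeat_series> %d beats, %d intervals (%d valid)\n",
              length(x$beat_times_s), length(x$intervals_ms),
              sum(x$quality == "valid")))
  invisible(x)
}

#' Detect heartbeats in the ballistocardiogram component
#'
#' Beats are located as peaks of the smoothed BCG energy envelope: the
#' moving RMS of the 4-11 Hz component over `smooth_s`, compared against an
#' adaptive threshold (`threshold_frac` of the running 95th percentile of
#' the envelope over `threshold_window_s`). A refractory period suppresses
#' double-detections within one cardiac cycle, keeping the stronger peak.
#' Beats inside masked (movement) regions are discarded.
#'
#' @param bcg Numeric vector: the 4-11 Hz component.
#' @param rate Sampling rate in Hz.
#' @param mask Optional logical movement mask, same length as `bcg`.
#' @param refractory_s Minimum beat separation in seconds (default 0.4,
#'   i.e. 150 bpm ceiling).
#' @param smooth_s Energy-envelope smoothing window (default 0.12 s, about
#'   one BCG wavelet).
#' @param threshold_window_s Window of the running percentile used as the
#'   adaptive threshold reference (default 30 s).
#' @param threshold_frac Fraction of that percentile a peak must exceed
#'   (default 0.4).
#' @return A [heartbeat_series()].
#' @export
detect_heartbeats <- function(bcg, rate, mask = NULL, refractory_s = 0.4,
                              smooth_s = 0.12, threshold_window_s = 30,
                              threshold_frac = 0.4) {
  n <- length(bcg)
  if (n < 10 * rate) stop("signal shorter than 10 s")
  if (is.null(mask)) mask <- rep(FALSE, n)
  w <- max(1L, round(smooth_s * rate))
  ms <- as.numeric(stats::filter(bcg^2, rep(1 / w, w), sides = 2))
  ms[is.na(ms)] <- 0
  env <- sqrt(ms)

  # adaptive threshold from a coarse running 95th percentile, interpolated
  step <- max(1L, as.integer(rate))  # one support point per second
  centers <- seq(1L, n, by = step)
  ref <- .windowed_percentile(env, rep(TRUE, n), centers,
                              as.integer(round(threshold_window_s * rate / 2)),
                              0.95)
  thr <- stats::approx(centers, ref$value, xout = seq_len(n), rule = 2)$y *
    threshold_frac

  is_peak <- c(FALSE, diff(env) > 0) & c(env[-n] >= env[-1], FALSE) &
    env > thr & !mask
  cand <- which(is_peak)
  if (!length(cand)) return(heartbeat_series(numeric(0), numeric(0)))

  # greedy refractory pass: within refractory_s keep the larger peak
  refr <- refractory_s * rate
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (env[i] > env[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  heartbeat_series((keep - 1) / rate)
}

#' Read an externally produced heartbeat interval series
#'
#' Two-column text (comma, tab or space separated): beat time in seconds
#' and the preceding interval in milliseconds. The same editing rules as
#' for BCG-derived intervals are applied, enabling Fcv computation from an
#' ECG R-R list.
#'
#' @param path Path to the text file (optional header auto-detected).
#' @return A [heartbeat_series()].
#' @export
read_interval_series <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty input file: %s", path))
  parse_row <- function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "[,\t ]+")[[1]]))
  }
  first <- parse_row(lines[1])
  if (anyNA(first)) lines <- lines[-1]  # header
  vals <- t(vapply(lines, parse_row, numeric(2), USE.NAMES = FALSE))
  if (anyNA(vals)) stop("non-numeric payload in interval file")
  if (any(diff(vals[, 1]) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  heartbeat_series(vals[, 1], vals[, 2])
}

#' CVHR detection parameters
#'
#' Constants of the cyclic-variation detector: the valid interval series is
#' resampled to an evenly spaced tachogram; dips are transient decreases of
#' the tachogram below a running upper-quantile baseline whose depth exceeds
#' an adaptive fraction of the local variability; trains are runs of at
#' least `train_min_dips` dips with quasi-regular spacing.
#'
#' @param tachogram_hz Resampling rate of the tachogram (default 2 Hz).
#' @param smooth_s Light tachogram smoothing window in seconds (default 3).
#' @param baseline_window_s Window of the running baseline quantile and the
#'   local variability estimate (default 300 s).
#' @param baseline_quantile Upper quantile used as the local baseline
#'   (default 0.8).
#' @param min_dip_depth_ms Absolute floor on dip depth (default 50 ms).
#' @param depth_frac_iqr Adaptive depth threshold as a fraction of the
#'   local tachogram IQR (default 0.5); the effective threshold is the
#'   larger of this and the absolute floor.
#' @param dip_width_range_s Admissible dip widths, seconds (default 10-120).
#' @param train_min_dips Minimum dips per train (default 3).
#' @param train_spacing_range_s Admissible inter-dip spacing within a train
#'   (default 25-130 s).
#' @param spacing_ratio_range Admissible ratio of neighboring spacings
#'   (default 0.5-2).
#' @return An object of class `cvhr_params`.
#' @export
cvhr_params <- function(tachogram_hz = 2, smooth_s = 3,
                        baseline_window_s = 300, baseline_quantile = 0.8,
                        min_dip_depth_ms = 50, depth_frac_iqr = 0.5,
                        dip_width_range_s = c(10, 120), train_min_dips = 3,
                        train_spacing_range_s = c(25, 130),
                        spacing_ratio_range = c(0.5, 2)) {
  structure(as.list(environment()), class = "cvhr_params")
}

#' Detect cyclic variation of heart rate and compute Fcv
#'
#' Resamples the valid heartbeat intervals to an evenly spaced tachogram,
#' finds transient interval dips (the post-event tachycardia of the cyclic
#' bradycardia-tachycardia pattern accompanying apnea episodes), groups dips
#' with quasi-regular spacing into trains, and reports Fcv: the number of
#' dips belonging to trains per hour of total recording time.
#'
#' @param series A [heartbeat_series()] with at least 10 minutes of valid
#'   intervals.
#' @param trt_hours Total recording time in hours.
#' @param params A [cvhr_params()] object.
#' @return An object of class `cvhr_result`: list with `dip_times_s`,
#'   `trains` (list of dip-index vectors), and `fcv`.
#' @export
detect_cvhr <- function(series, trt_hours, params = cvhr_params()) {
  stopifnot(inherits(series, "heartbeat_series"))
  if (trt_hours <= 0) stop("trt_hours must be positive")
  ok <- series$quality == "valid"
  t_int <- series$interval_times_s[ok]
  x_int <- series$intervals_ms[ok]
  if (length(t_int) < 2 || diff(range(t_int)) < 600) {
    stop("insufficient valid data: need at least 10 min of valid intervals")
  }
  fs <- params$tachogram_hz
  tg_t <- seq(min(t_int), max(t_int), by = 1 / fs)
  tg <- stats::approx(t_int, x_int, xout = tg_t, rule = 2)$y
  w <- max(1L, round(params$smooth_s * fs))
  sm <- as.numeric(stats::filter(tg, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- tg[is.na(sm)]

  n <- length(sm)
  half <- as.integer(round(params$baseline_window_s * fs / 2))
  all_true <- rep(TRUE, n)
  idx <- seq_len(n)
  base <- .windowed_percentile(sm, all_true, idx, half,
                               params$baseline_quantile)$value
  q75 <- .windowed_percentile(sm, all_true, idx, half, 0.75)$value
  q25 <- .windowed_percentile(sm, all_true, idx, half, 0.25)$value
  thr <- pmax(params$min_dip_depth_ms, params$depth_frac_iqr * (q75 - q25))
  dev <- base - sm

  r <- rle(dev >= thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  dip_times <- numeric(0)
  for (k in keep) {
    width <- r$lengths[k] / fs
    if (width >= params$dip_width_range_s[1] &&
        width <= params$dip_width_range_s[2]) {
      seg <- starts[k]:ends[k]
      dip_times <- c(dip_times, tg_t[seg[which.min(sm[seg])]])
    }
  }

  trains <- list()
  if (length(dip_times) >= params$train_min_dips) {
    cur <- 1L
    prev_gap <- NA_real_
    for (i in seq_along(dip_times)[-1]) {
      gap <- dip_times[i] - dip_times[cur[length(cur)]]
      gap_ok <- gap >= params$train_spacing_range_s[1] &&
        gap <= params$train_spacing_range_s[2]
      ratio_ok <- is.na(prev_gap) ||
        (gap / prev_gap >= params$spacing_ratio_range[1] &&
           gap / prev_gap <= params$spacing_ratio_range[2])
      if (gap_ok && ratio_ok) {
        cur <- c(cur, i)
        prev_gap <- gap
      } else {
        if (length(cur) >= params$train_min_dips) {
          trains[[length(trains) + 1L]] <- cur
        }
        cur <- i
        prev_gap <- NA_real_
      }
    }
    if (length(cur) >= params$train_min_dips) {
      trains[[length(trains) + 1L]] <- cur
    }
  }

  structure(
    list(
      dip_times_s = dip_times,
      trains = trains,
      fcv = sum(lengths(trains)) / trt_hours
    ),
    class = "cvhr_result"
  )
}

#' @export
print.cvhr_result <- function(x, ...) {
  cat(sprintf("<cvhr_result> %d dips, %d trains, Fcv = %.2f /h\n",
              length(x$dip_times_s), length(x$trains), x$fcv))
  invisible(x)
}
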