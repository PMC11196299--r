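# The core detector: rectified log respiratory amplitude, fast/slow 95th
# percentile envelopes, depth-threshold dip detection, duration filtering,
# and the respiratory event index (REI).

#' Rectified log amplitude of the respiration component
#'
#' `ln(|x| + epsilon)` per sample. Rectification reflects the magnitude of
#' respiratory motion; the log transform turns multiplicative amplitude
#' changes (posture, gain) into additive offsets, so a percentage amplitude
#' reduction becomes a fixed log-domain separation. `epsilon` of one sensor
#' unit guards the log at zero and is negligible against physiological
#' amplitudes.
#'
#' @param respiration Numeric vector (the respiration component).
#' @param epsilon Additive guard in sensor units (default 1).
#' @return Numeric vector of the same length.
#' @export
log_amplitude <- function(respiration, epsilon = 1) {
  if (!is.numeric(respiration)) stop("respiration must be numeric")
  log(abs(respiration) + epsilon)
}

#' Parameters of the fast and slow percentile envelopes
#'
#' The fast envelope tracks breath-by-breath amplitude over a short window;
#' the slow envelope tracks the local trend of submaximal amplitude over a
#' long window. Both are the 95th percentile of the windowed log amplitude,
#' which discards outliers with an incidence below 5%.
#'
#' @param fast_window_s Fast window length in seconds (default 5, spanning
#'   1-2 breaths at a typical 15 breaths/min; it must stay well below the
#'   minimum event duration, since a centered percentile window shortens
#'   measured dip durations by roughly its own length).
#' @param slow_window_s Slow window length in seconds (default 120, spanning
#'   the pre-event baseline across one or two event cycles).
#' @param percentile Upper percentile as a fraction (default 0.95).
#' @param grid_step_s Spacing of envelope evaluation points in seconds.
#' @return An object of class `envelope_params`.
#' @export
envelope_params <- function(fast_window_s = 5, slow_window_s = 120,
                            percentile = 0.95, grid_step_s = 1) {
  if (!(fast_window_s > 0 && fast_window_s < slow_window_s)) {
    stop("need 0 < fast_window_s < slow_window_s")
  }
  if (!(percentile > 0 && percentile < 1)) stop("percentile must be in (0, 1)")
  if (grid_step_s <= 0) stop("grid_step_s must be positive")
  structure(
    list(fast_window_s = fast_window_s, slow_window_s = slow_window_s,
         percentile = percentile, grid_step_s = grid_step_s),
    class = "envelope_params"
  )
}

#' Compute the fast and slow 95th percentile envelopes
#'
#' At each grid time the envelope value is the nearest-rank percentile of
#' the unmasked log-amplitude samples in a centered window (fast and slow
#' windows respectively). A grid point is valid only if at least 50% of each
#' window is unmasked and inside the recording; invalid points carry `NA`
#' envelope values and never contribute to event detection.
#'
#' @param logamp Numeric vector from [log_amplitude()].
#' @param mask Logical vector flagging movement-contaminated samples
#'   (`NULL` for none).
#' @param rate Sampling rate in Hz.
#' @param params An [envelope_params()] object.
#' @return An object of class `envelope_pair`: list with `times`, `fast`,
#'   `slow`, `valid`, and `grid_step_s`.
#' @export
compute_envelopes <- function(logamp, mask = NULL, rate,
                              params = envelope_params()) {
  n <- length(logamp)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("logamp and mask must have equal length")
  if (n < params$slow_window_s * rate) {
    stop("recording shorter than the slow envelope window")
  }
  times <- seq(0, (n - 1) / rate, by = params$grid_step_s)
  centers <- as.integer(round(times * rate)) + 1L
  half_fast <- as.integer(round(params$fast_window_s * rate / 2))
  half_slow <- as.integer(round(params$slow_window_s * rate / 2))
  fast <- .windowed_percentile(logamp, !mask, centers, half_fast,
                               params$percentile)
  slow <- .windowed_percentile(logamp, !mask, centers, half_slow,
                               params$percentile)
  valid <- fast$frac_valid >= 0.5 & slow$frac_valid >= 0.5
  fast_v <- fast$value
  slow_v <- slow$value
  fast_v[!valid] <- NA_real_
  slow_v[!valid] <- NA_real_
  structure(
    list(times = times, fast = fast_v, slow = slow_v, valid = valid,
         grid_step_s = params$grid_step_s),
    class = "envelope_pair"
  )
}

#' Event detection parameters
#'
#' A respiratory event is a dip of the fast envelope below the slow envelope
#' by at least `depth_percent` relative amplitude reduction, lasting between
#' the duration bounds. A d% amplitude drop corresponds to a log-domain
#' separation of `-ln(1 - d/100)`; at the default 30% this is
#' `ln(1.43) = 0.357`.
#'
#' @param depth_percent Relative amplitude reduction in percent (default 30).
#' @param min_duration_s,max_duration_s Duration criteria in seconds
#'   (defaults 10 and 70).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(depth_percent = 30, min_duration_s = 10,
                             max_duration_s = 70) {
  if (!(depth_percent > 0 && depth_percent < 100)) {
    stop("depth_percent must be in (0, 100)")
  }
  if (!(min_duration_s > 0 && min_duration_s < max_duration_s)) {
    stop("need 0 < min_duration_s < max_duration_s")
  }
  structure(
    list(depth_percent = depth_percent, min_duration_s = min_duration_s,
         max_duration_s = max_duration_s),
    class = "detection_params"
  )
}

#' Log-domain depth threshold for a percent amplitude reduction
#'
#' @param depth_percent Relative amplitude reduction in percent.
#' @return `-ln(1 - depth_percent/100)`, the minimum slow-minus-fast
#'   envelope separation scored as a dip.
#' @export
#' @examples
#' depth_log_threshold(30)  # ln(1/0.7) = ln(1.43) ~ 0.357
depth_log_threshold <- function(depth_percent) {
  if (any(depth_percent <= 0 | depth_percent >= 100)) {
    stop("depth_percent must be in (0, 100)")
  }
  -log(1 - depth_percent / 100)
}

#' Detect respiratory events from an envelope pair
#'
#' Maximal runs of consecutive valid grid points where the slow envelope
#' exceeds the fast by at least the depth threshold become candidate
#' periods; candidates whose duration lies within the duration criteria
#' become events. Invalid (movement-masked) grid points break runs, so
#' movement artifacts are never scored as events. Periods longer than the
#' maximum duration are rejected whole, not split.
#'
#' @param env An [compute_envelopes()] result.
#' @param params A [detection_params()] object.
#' @return Data frame with columns `start_s` (inclusive), `end_s`
#'   (exclusive), `duration_s`, `max_depth_log`, time-ordered and
#'   non-overlapping.
#' @export
detect_events <- function(env, params = detection_params()) {
  stopifnot(inherits(env, "envelope_pair"))
  if (!inherits(params, "detection_params")) {
    params <- do.call(detection_params, params)
  }
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), max_depth_log = numeric(0))
  if (length(env$times) == 0) return(empty)
  if (env$grid_step_s > params$min_duration_s / 5) {
    stop("envelope grid step too coarse for the minimum event duration")
  }
  thr <- depth_log_threshold(params$depth_percent)
  sep <- env$slow - env$fast
  state <- env$valid & !is.na(sep) & sep >= thr
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(empty)
  out <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    dur <- r$lengths[k] * env$grid_step_s
    data.frame(
      start_s = env$times[i0],
      end_s = env$times[i1] + env$grid_step_s,
      duration_s = dur,
      max_depth_log = max(sep[i0:i1])
    )
  })
  out <- do.call(rbind, out)
  out <- out[out$duration_s >= params$min_duration_s &
               out$duration_s <= params$max_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Respiratory event index from detected events
#'
#' REI is the number of respiratory events per hour of total recording time.
#'
#' @param events Data frame of events from [detect_events()].
#' @param trt_hours Total recording time in hours (> 0).
#' @return An object of class `rei_result`: list with `events`, `trt_hours`,
#'   `rei`.
#' @export
compute_rei <- function(events, trt_hours) {
  if (!is.numeric(trt_hours) || length(trt_hours) != 1 || trt_hours <= 0) {
    stop("trt_hours must be a single positive number")
  }
  structure(
    list(events = events, trt_hours = trt_hours,
         rei = nrow(events) / trt_hours),
    class = "rei_result"
  )
}

#' @export
print.rei_result <- function(x, ...) {
  cat(sprintf("<rei_result> %d events in %.2f h: REI = %.2f /h\n",
              nrow(x$events), x$trt_hours, x$rei))
  invisible(x)
}

#' Run the full REI detection pipeline on a recording
#'
#' Composes [extract_components()], [log_amplitude()],
#' [compute_envelopes()], [detect_events()] and [compute_rei()].
#' Deterministic for fixed input and parameters.
#'
#' @param record A [micromotion_record()].
#' @param bands A [filter_bands()] object.
#' @param env_params An [envelope_params()] object.
#' @param det_params A [detection_params()] object.
#' @param keep_envelopes Attach the envelope pair to the result (default
#'   `TRUE`; used for plotting and parameter re-scans).
#' @return An `rei_result`; when `keep_envelopes` is `TRUE` it also carries
#'   `envelopes`.
#' @export
run_detection <- function(record, bands = filter_bands(),
                          env_params = envelope_params(),
                          det_params = detection_params(),
                          keep_envelopes = TRUE) {
  comp <- extract_components(record, bands)
  la <- log_amplitude(comp$respiration)
  env <- compute_envelopes(la, comp$movement_mask, record$sampling_rate,
                           env_params)
  events <- detect_events(env, det_params)
  res <- compute_rei(events, record$trt_seconds / 3600)
  if (keep_envelopes) res$envelopes <- env
  res
}
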