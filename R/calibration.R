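# Grid search for the depth threshold and duration criteria maximizing the
# Pearson correlation between REI and reference AHI_TRT across a training
# cohort. Envelopes are parameter-independent, so they are computed once
# per subject and every grid cell re-runs only the cheap detection stage.

#' Specification of the calibration grid
#'
#' The depth threshold is searched in 1% increments and the duration
#' criteria at 10-s intervals; the default ranges are depth 10-60%, minimum
#' duration \{10, 20, 30\} s and maximum duration \{40, ..., 120\} s.
#'
#' @param depth_percent Integer-like vector of candidate depth thresholds.
#' @param min_duration_s Candidate lower duration bounds (seconds).
#' @param max_duration_s Candidate upper duration bounds (seconds).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(depth_percent = 10:60,
                      min_duration_s = c(10, 20, 30),
                      max_duration_s = seq(40, 120, by = 10)) {
  if (!length(depth_percent) || !length(min_duration_s) ||
      !length(max_duration_s)) {
    stop("empty grid")
  }
  if (any(depth_percent <= 0 | depth_percent >= 100)) {
    stop("depth candidates must be in (0, 100)")
  }
  if (any(min_duration_s <= 0) || any(max_duration_s <= 0)) {
    stop("duration candidates must be positive")
  }
  if (max(min_duration_s) >= min(max_duration_s)) {
    stop("every (min, max) duration pair must satisfy min < max")
  }
  structure(
    list(depth_percent = as.numeric(depth_percent),
         min_duration_s = as.numeric(min_duration_s),
         max_duration_s = as.numeric(max_duration_s)),
    class = "grid_spec"
  )
}

# Envelope + TRT for one cohort entry, whatever form it was supplied in.
cohort_envelope <- function(entry, bands, env_params) {
  if (!is.null(entry$envelope)) {
    env <- entry$envelope
    trt_h <- if (!is.null(entry$trt_hours)) entry$trt_hours else
      (max(env$times) + env$grid_step_s) / 3600
  } else if (!is.null(entry$record)) {
    rec <- entry$record
    comp <- extract_components(rec, bands)
    env <- compute_envelopes(log_amplitude(comp$respiration),
                             comp$movement_mask, rec$sampling_rate,
                             env_params)
    trt_h <- rec$trt_seconds / 3600
  } else {
    stop("each cohort entry needs $record or $envelope")
  }
  list(env = env, trt_hours = trt_h)
}

#' Calibrate detection parameters by exhaustive grid search
#'
#' For every cell of the Cartesian grid, computes each subject's REI and
#' the Pearson correlation r(REI, AHI_TRT); returns the best cell and the
#' full trace. Ties are broken deterministically: smaller depth first, then
#' wider duration band, then scan order.
#'
#' @param cohort List of entries, each a list with `ahi_trt` and either
#'   `record` (a [micromotion_record()]) or `envelope` (a precomputed
#'   [compute_envelopes()] result; add `trt_hours` if the envelope grid
#'   does not span the full recording).
#' @param spec A [grid_spec()].
#' @param bands,env_params Used when entries carry raw records.
#' @return An object of class `grid_search_result`: `best_params`
#'   ([detection_params()]), `best_r`, and `trace` (data frame with one row
#'   per grid cell: depth_percent, min_duration_s, max_duration_s, r).
#' @export
grid_search <- function(cohort, spec = grid_spec(), bands = filter_bands(),
                        env_params = envelope_params()) {
  if (length(cohort) < 3) stop("cohort must have at least 3 subjects")
  ahi <- vapply(cohort, function(e) as.numeric(e$ahi_trt), numeric(1))
  if (anyNA(ahi)) stop("every cohort entry needs ahi_trt")
  if (stats::sd(ahi) == 0) {
    stop("undefined correlation: AHI_TRT is constant across the cohort")
  }

  prep <- lapply(cohort, cohort_envelope, bands = bands,
                 env_params = env_params)

  # per subject and depth: the multiset of qualifying run lengths (seconds);
  # every duration cell then only counts runs inside its bounds
  run_tables <- lapply(prep, function(p) {
    env <- p$env
    sep <- env$slow - env$fast
    lapply(spec$depth_percent, function(d) {
      state <- env$valid & !is.na(sep) & sep >= depth_log_threshold(d)
      r <- rle(state)
      r$lengths[r$values] * env$grid_step_s
    })
  })
  trt_h <- vapply(prep, `[[`, numeric(1), "trt_hours")

  cells <- expand.grid(max_duration_s = spec$max_duration_s,
                       min_duration_s = spec$min_duration_s,
                       depth_percent = spec$depth_percent)
  # scan order: depth outer, then min duration, then max duration
  cells <- cells[, c("depth_percent", "min_duration_s", "max_duration_s")]

  r_vals <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    di <- match(cells$depth_percent[ci], spec$depth_percent)
    lo <- cells$min_duration_s[ci]
    hi <- cells$max_duration_s[ci]
    rei <- vapply(seq_along(run_tables), function(s) {
      runs <- run_tables[[s]][[di]]
      sum(runs >= lo & runs <= hi) / trt_h[s]
    }, numeric(1))
    r_vals[ci] <- if (stats::sd(rei) == 0) NA_real_ else
      stats::cor(rei, ahi)
  }

  trace <- cbind(cells, r = r_vals)
  scored <- ifelse(is.na(r_vals), -Inf, r_vals)
  ord <- order(-scored, cells$depth_percent,
               -(cells$max_duration_s - cells$min_duration_s),
               seq_len(nrow(cells)))
  best <- ord[1]
  structure(
    list(
      best_params = detection_params(
        depth_percent = cells$depth_percent[best],
        min_duration_s = cells$min_duration_s[best],
        max_duration_s = cells$max_duration_s[best]
      ),
      best_r = r_vals[best],
      trace = trace
    ),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  p <- x$best_params
  cat(sprintf(
    "<grid_search_result> best: depth %g%%, duration %g-%g s (r = %.4f; %d cells)\n",
    p$depth_percent, p$min_duration_s, p$max_duration_s, x$best_r,
    nrow(x$trace)
  ))
  invisible(x)
}
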