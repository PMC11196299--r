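# Core data types and I/O: sensor CSV recordings, subject metadata tables,
# event annotation files, and AHI severity banding.

#' Valid sample range of the 24-bit sensor ADC
#'
#' The sheet sensor digitizes micromotion at 100 Hz with a 24-bit dynamic
#' range; as a signed two's-complement integer the representable values are
#' -8,388,608 to +8,388,607.
#' @format Integer scalars.
#' @name bit24-range
#' @keywords internal
BIT24_MIN <- -8388608
BIT24_MAX <- 8388607

#' Severity class labels for sleep apnea
#'
#' Ordinal labels used both for reference AHI banding and for REI-based
#' classification: normal (0), mild (1), moderate (2), severe (3).
#' @export
severity_levels <- c("normal", "mild", "moderate", "severe")

#' Construct a micromotion recording
#'
#' A single-channel micromotion signal from the piezoelectric sheet sensor:
#' an integer-valued amplitude sequence with its sampling rate and total
#' recording time (TRT).
#'
#' @param samples Numeric vector of sensor amplitudes. Every value must lie
#'   within the signed 24-bit range \[-8388608, 8388607\].
#' @param sampling_rate Sampling frequency in Hz (default 100).
#' @param start_time Optional wall-clock start time (`POSIXct` or string);
#'   metadata only.
#' @return An object of class `micromotion_record` with fields `samples`,
#'   `sampling_rate`, `start_time` and `trt_seconds` (= n / rate).
#' @export
#' @examples
#' rec <- micromotion_record(c(100, -200, 300), sampling_rate = 100)
#' rec$trt_seconds  # 0.03
micromotion_record <- function(samples, sampling_rate = 100, start_time = NULL) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop("samples must be a non-empty numeric vector")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite and non-missing")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  bad <- which(samples < BIT24_MIN | samples > BIT24_MAX)
  if (length(bad)) {
    stop(sprintf(
      "sample %d (value %s) outside the 24-bit range [%d, %d]",
      bad[1], format(samples[bad[1]]), BIT24_MIN, BIT24_MAX
    ))
  }
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate = as.numeric(sampling_rate),
      start_time = start_time,
      trt_seconds = length(samples) / sampling_rate
    ),
    class = "micromotion_record"
  )
}

#' @export
print.micromotion_record <- function(x, ...) {
  cat(sprintf(
    "<micromotion_record> %d samples at %g Hz (TRT %.1f s = %.2f h)\n",
    length(x$samples), x$sampling_rate, x$trt_seconds, x$trt_seconds / 3600
  ))
  invisible(x)
}

#' Read a sensor CSV recording
#'
#' Reads the CSV written by the sheet-sensor device: one integer amplitude
#' per row, UTF-8, with an optional single header line and an optional
#' leading timestamp column (both auto-detected). When a timestamp column is
#' present the amplitude is taken from the last column.
#'
#' @param path Path to the CSV file.
#' @param sampling_rate Sampling frequency in Hz (default 100).
#' @return A [micromotion_record()] with `trt_seconds = n / sampling_rate`.
#' @export
read_micromotion_csv <- function(path, sampling_rate = 100) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("empty input file: %s", path))
  fields <- strsplit(lines, ",", fixed = TRUE)
  last_field <- vapply(fields, function(f) trimws(f[[length(f)]]), character(1))
  vals <- suppressWarnings(as.numeric(last_field))
  start_row <- 1L
  if (is.na(vals[1]) && length(vals) > 1) {
    # single header line
    start_row <- 2L
  }
  payload <- vals[start_row:length(vals)]
  rows <- seq.int(start_row, length(vals))
  bad <- which(is.na(payload) | payload %% 1 != 0)
  if (length(bad)) {
    stop(sprintf(
      "row %d of %s: non-integer payload value '%s'",
      rows[bad[1]], path, last_field[rows[bad[1]]]
    ))
  }
  out_of_range <- which(payload < BIT24_MIN | payload > BIT24_MAX)
  if (length(out_of_range)) {
    stop(sprintf(
      "row %d of %s: value %s outside the 24-bit range [%d, %d]",
      rows[out_of_range[1]], path, format(payload[out_of_range[1]]),
      BIT24_MIN, BIT24_MAX
    ))
  }
  micromotion_record(payload, sampling_rate = sampling_rate)
}

#' Write a sensor CSV recording
#'
#' Inverse of [read_micromotion_csv()]: one integer per line, no header.
#'
#' @param record A [micromotion_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_micromotion_csv <- function(record, path) {
  stopifnot(inherits(record, "micromotion_record"))
  writeLines(format(record$samples, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Subject-level reference data as CSV with header columns `subject_id`,
#' `ahi_trt`, `ahi_tst`, `plm_index`, `group` (training or test). AHI_TRT
#' uses total recording time as denominator (the calibration reference);
#' AHI_TST uses total sleep time (the severity reference).
#'
#' @param path Path to the CSV file.
#' @return A data frame with the five columns, rates validated non-negative.
#' @export
read_subject_meta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "ahi_trt", "ahi_tst", "plm_index", "group")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop(sprintf("metadata missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in c("ahi_trt", "ahi_tst", "plm_index")) {
    meta[[col]] <- as.numeric(meta[[col]])
    if (anyNA(meta[[col]]) || any(meta[[col]] < 0)) {
      stop(sprintf("column %s must be numeric and non-negative", col))
    }
  }
  if (!all(meta$group %in% c("training", "test"))) {
    stop("group must be 'training' or 'test'")
  }
  meta[required]
}

#' Classify sleep apnea severity from reference AHI
#'
#' Bands the apnea-hypopnea index (per hour of total sleep time) into the
#' conventional four severity classes: AHI < 5 normal, 5-15 mild, 15-30
#' moderate, >= 30 severe. Boundary values go to the higher class.
#'
#' @param ahi_tst Numeric vector of AHI values (events/h), non-negative.
#' @return An ordered factor with levels [severity_levels].
#' @export
#' @examples
#' severity_class(c(0, 13.4, 15, 30))  # normal, mild, moderate, severe
severity_class <- function(ahi_tst) {
  if (!is.numeric(ahi_tst) || anyNA(ahi_tst)) {
    stop("ahi_tst must be numeric and non-missing")
  }
  if (any(ahi_tst < 0)) stop("ahi_tst must be non-negative")
  cut(ahi_tst, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = severity_levels, ordered_result = TRUE)
}

#' Write detected respiratory events as annotations
#'
#' Tab-separated text with columns `subject_id`, `start_s`, `end_s`,
#' `duration_s`, `max_depth_log`. `start_s` is inclusive, `end_s` exclusive,
#' both in seconds from recording start.
#'
#' @param events Data frame of events as returned by [detect_events()].
#' @param path Output file path.
#' @param subject_id Label written in the first column.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path, subject_id = "subject") {
  duration <- if (!is.null(events$duration_s)) events$duration_s else
    events$end_s - events$start_s
  depth <- if (!is.null(events$max_depth_log)) events$max_depth_log else
    rep(NA_real_, nrow(events))
  out <- data.frame(
    subject_id = rep(subject_id, nrow(events)),
    start_s = events$start_s,
    end_s = events$end_s,
    duration_s = duration,
    max_depth_log = depth
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an event annotation file written by [write_events_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A data frame with the annotation columns.
#' @export
read_events_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
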