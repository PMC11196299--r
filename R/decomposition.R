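# Decomposition of the micromotion signal into respiratory, body-movement,
# and ballistocardiogram components by zero-phase band-pass filtering.

#' Frequency bands of the three micromotion components
#'
#' Respiration, body movement, and ballistocardiogram occupy distinct bands
#' of the micromotion spectrum; the defaults are 0.08-0.5, 2-3, and 4-11 Hz.
#'
#' @param respiration,movement,bcg Length-2 numeric `(low, high)` in Hz.
#' @return An object of class `filter_bands`.
#' @export
filter_bands <- function(respiration = c(0.08, 0.5), movement = c(2, 3),
                         bcg = c(4, 11)) {
  bands <- list(respiration = respiration, movement = movement, bcg = bcg)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.numeric(b) || length(b) != 2 || b[1] <= 0 || b[1] >= b[2]) {
      stop(sprintf("band '%s' must satisfy 0 < low < high", nm))
    }
  }
  structure(bands, class = "filter_bands")
}

# Second-order sections of an even-order Butterworth high- or low-pass.
# Direct-form filtering with the full-order transfer function amplifies
# float rounding by the pole Q (catastrophically so for near-DC cutoffs),
# so each conjugate pole pair is applied as its own unity-gain biquad.
butter_sos <- function(order, fc, rate, type) {
  stopifnot(order %% 2 == 0)
  flt <- signal::butter(order, fc / (rate / 2), type = type)
  p <- polyroot(rev(flt$a))
  pos <- p[Im(p) > 0]
  pos <- pos[order(Re(pos))]
  z0 <- if (type == "high") 1 else -1   # double zero of each biquad
  zr <- if (type == "high") -1 else 1   # unity-gain reference point
  lapply(pos, function(pk) {
    a <- c(1, -2 * Re(pk), Mod(pk)^2)
    b <- c(1, -2 * z0, 1)
    g <- sum(a * zr^(0:2)) / sum(b * zr^(0:2))
    list(b = g * b, a = a)
  })
}

sos_filtfilt <- function(sos, x) {
  for (s in sos) {
    x <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), x)
  }
  x
}

# Zero-phase band-pass: order-4 Butterworth high-pass (low edge) and
# low-pass (high edge) in cascade, each run forward-backward as biquad
# sections, after reflective padding of ~3 settling times of the slowest
# edge so filter transients never reach the data. Bands far below the
# sampling rate (like respiration at 100 Hz) are filtered at a decimated
# rate: the band-pass poles move away from z = 1, which keeps the recursion
# numerically accurate, and the band-limited result is interpolated back.
bandpass_zerophase <- function(x, band, rate, order = 4) {
  if (band[2] >= rate / 2) {
    stop(sprintf("band edge %g Hz at or above Nyquist (%g Hz)",
                 band[2], rate / 2))
  }
  n <- length(x)
  pad <- min(n - 1, ceiling(3 / band[1] * rate))
  xp <- if (pad > 0) c(x[(pad + 1):2], x, x[(n - 1):(n - pad)]) else x

  dec <- band_decimation(band, rate)
  if (dec > 1) {
    aa <- butter_sos(order, 0.4 * rate / dec, rate, "low")
    xa <- sos_filtfilt(aa, xp)
    idx <- seq(1L, length(xp), by = dec)
    xd <- xa[idx]
    rate2 <- rate / dec
    yd <- sos_filtfilt(butter_sos(order, band[2], rate2, "low"),
                       sos_filtfilt(butter_sos(order, band[1], rate2, "high"),
                                    xd))
    y <- stats::approx(idx, yd, xout = seq_along(xp), rule = 2)$y
  } else {
    y <- sos_filtfilt(butter_sos(order, band[2], rate, "low"),
                      sos_filtfilt(butter_sos(order, band[1], rate, "high"),
                                   xp))
  }
  y[(pad + 1):(pad + n)]
}

# decimation factor keeping ~20x oversampling of the band's upper edge
band_decimation <- function(band, rate) {
  max(1L, min(as.integer(rate / (band[2] * 20)), as.integer(rate / 4)))
}

#' Effective frequency response of a band's zero-phase filter
#'
#' Magnitude response of the forward-backward (zero-phase) high-pass +
#' low-pass cascade used by [extract_components()], i.e. the squared
#' magnitude of the single-pass cascade. Useful for verifying passband gain
#' and stopband rejection of the design.
#'
#' @param band Length-2 numeric `(low, high)` in Hz.
#' @param rate Sampling rate in Hz.
#' @param freqs Frequencies (Hz) at which to evaluate.
#' @param order Butterworth order of each cascade stage (default 4).
#' @return Numeric vector of linear magnitude gains at `freqs`.
#' @export
band_gain <- function(band, rate, freqs, order = 4) {
  sos_mag <- function(sos, freqs, rate) {
    w <- 2 * pi * freqs / rate
    out <- rep(1, length(w))
    for (s in sos) {
      num <- vapply(w, function(wi) sum(s$b * exp(-1i * wi * (0:2))),
                    complex(1))
      den <- vapply(w, function(wi) sum(s$a * exp(-1i * wi * (0:2))),
                    complex(1))
      out <- out * Mod(num / den)
    }
    out
  }
  dec <- band_decimation(band, rate)
  if (dec > 1) {
    rate2 <- rate / dec
    single <- sos_mag(butter_sos(order, 0.4 * rate2, rate, "low"),
                      freqs, rate) *
      sos_mag(butter_sos(order, band[1], rate2, "high"), freqs, rate2) *
      sos_mag(butter_sos(order, band[2], rate2, "low"), freqs, rate2)
  } else {
    single <- sos_mag(butter_sos(order, band[1], rate, "high"), freqs, rate) *
      sos_mag(butter_sos(order, band[2], rate, "low"), freqs, rate)
  }
  single^2
}

#' Decompose a micromotion recording into its physiological components
#'
#' Applies a zero-phase band-pass filter per component band and derives a
#' boolean movement mask flagging samples contaminated by gross body
#' movement: samples where the 1-s moving RMS of the movement component
#' exceeds `mask_factor` times its recording-wide median.
#'
#' @param record A [micromotion_record()] of at least 30 s.
#' @param bands A [filter_bands()] object.
#' @param mask_window_s Moving-RMS window for the movement mask, seconds.
#' @param mask_factor Multiple of the median moving RMS above which samples
#'   are masked (default 5).
#' @return An object of class `component_signals`: list with `respiration`,
#'   `movement`, `bcg` (numeric, same length as the input), `movement_mask`
#'   (logical) and `sampling_rate`.
#' @export
extract_components <- function(record, bands = filter_bands(),
                               mask_window_s = 1, mask_factor = 5) {
  stopifnot(inherits(record, "micromotion_record"))
  rate <- record$sampling_rate
  x <- record$samples
  if (length(x) < 30 * rate) {
    stop("recording shorter than 30 s; too short for filter settling")
  }
  for (nm in names(bands)) {
    if (bands[[nm]][2] >= rate / 2) {
      stop(sprintf("band '%s' upper edge %g Hz at or above Nyquist",
                   nm, bands[[nm]][2]))
    }
  }
  respiration <- bandpass_zerophase(x, bands$respiration, rate)
  movement <- bandpass_zerophase(x, bands$movement, rate)
  bcg <- bandpass_zerophase(x, bands$bcg, rate)

  w <- max(1L, round(mask_window_s * rate))
  ms <- as.numeric(stats::filter(movement^2, rep(1 / w, w), sides = 2))
  # edge samples where the centered window runs off the record: carry the
  # nearest interior value so the mask is defined everywhere
  first_ok <- which(!is.na(ms))[1]
  last_ok <- max(which(!is.na(ms)))
  ms[seq_len(first_ok - 1)] <- ms[first_ok]
  if (last_ok < length(ms)) ms[(last_ok + 1):length(ms)] <- ms[last_ok]
  rms <- sqrt(ms)
  movement_mask <- rms > mask_factor * stats::median(rms)

  structure(
    list(
      respiration = respiration,
      movement = movement,
      bcg = bcg,
      movement_mask = movement_mask,
      sampling_rate = rate
    ),
    class = "component_signals"
  )
}

#' @export
print.component_signals <- function(x, ...) {
  cat(sprintf(
    "<component_signals> %d samples at %g Hz; movement mask %.1f%% true\n",
    length(x$respiration), x$sampling_rate, 100 * mean(x$movement_mask)
  ))
  invisible(x)
}
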