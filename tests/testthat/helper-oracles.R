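# Independent brute-force oracles and small builders used across the suite.

# nearest-rank percentile: sorted ascending, value at rank ceil(p * n)
brute_percentile <- function(x, p) {
  s <- sort(x)
  s[max(1L, min(length(s), ceiling(p * length(s))))]
}

# windowed nearest-rank percentile exactly as the envelope contract defines
# it: centered window [c - h, c + h] clipped to the signal, masked samples
# excluded
brute_windowed_percentile <- function(x, mask, center, halfwin, p) {
  lo <- max(1L, center - halfwin)
  hi <- min(length(x), center + halfwin)
  vals <- x[lo:hi][!mask[lo:hi]]
  if (!length(vals)) return(NA_real_)
  brute_percentile(vals, p)
}

# AUC by exhaustive pairwise Mann-Whitney counting with ties scored 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# hand-constructed envelope pair on a 1-s grid
make_envelope <- function(fast, slow, valid = rep(TRUE, length(fast)),
                          grid_step_s = 1) {
  structure(
    list(times = (seq_along(fast) - 1) * grid_step_s,
         fast = fast, slow = slow, valid = valid,
         grid_step_s = grid_step_s),
    class = "envelope_pair"
  )
}

make_sine_record <- function(freq, duration_s, amp = 1000, rate = 100) {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  micromotion_record(round(amp * sin(2 * pi * freq * t)), sampling_rate = rate)
}

# BCG-like pulse train: one 8-Hz Gaussian-windowed wavelet per beat time
make_pulse_train <- function(beat_times_s, duration_s, rate = 100,
                             amp = 500, pulse_hz = 8, sigma = 0.1) {
  n <- round(duration_s * rate)
  tau <- seq(-0.35, 0.35, by = 1 / rate)
  wavelet <- exp(-tau^2 / (2 * sigma^2)) * sin(2 * pi * pulse_hz * tau)
  half <- (length(tau) - 1) / 2
  x <- numeric(n)
  for (bt in beat_times_s) {
    c0 <- round(bt * rate) + 1
    lo <- max(1, c0 - half)
    hi <- min(n, c0 + half)
    x[lo:hi] <- x[lo:hi] + amp * wavelet[(lo:hi) - (c0 - half) + 1]
  }
  x
}
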