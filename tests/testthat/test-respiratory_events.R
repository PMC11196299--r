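test_that("log amplitude rectifies and guards the origin", {
  expect_equal(log_amplitude(rep(exp(1) - 1, 5)), rep(1, 5))
  expect_equal(log_amplitude(c(-5, 5)), rep(log(6), 2))

  # 95th percentile of ln(|sin| + 1) over one sampled period, against the
  # brute-force nearest-rank oracle and the analytic peak ln(2)
  t <- seq(0, 4 - 0.01, by = 0.01)
  la <- log_amplitude(sin(2 * pi * 0.25 * t), epsilon = 1)
  q <- brute_percentile(la, 0.95)
  expect_lt(abs(q - log(1 + 1)), 0.01)
})

test_that("envelopes of a constant equal the constant; oracle equality holds", {
  la <- rep(2.5, 3000)
  env <- compute_envelopes(la, NULL, rate = 10,
                           envelope_params(fast_window_s = 10,
                                           slow_window_s = 120))
  expect_true(all(env$fast[env$valid] == 2.5))
  expect_true(all(env$slow[env$valid] == 2.5))

  set.seed(3)
  la <- rnorm(4000)
  mask <- runif(4000) < 0.1
  p <- envelope_params(fast_window_s = 7, slow_window_s = 60,
                       grid_step_s = 2)
  env <- compute_envelopes(la, mask, rate = 10, p)
  centers <- as.integer(round(env$times * 10)) + 1L
  for (j in seq_along(centers)) {
    if (!env$valid[j]) next
    expect_identical(env$fast[j],
                     brute_windowed_percentile(la, mask, centers[j],
                                               round(7 * 10 / 2), 0.95))
    expect_identical(env$slow[j],
                     brute_windowed_percentile(la, mask, centers[j],
                                               round(60 * 10 / 2), 0.95))
  }
})

test_that("fast envelope reacts within its window, slow within its own", {
  rate <- 10
  la <- c(rep(0, 6000), rep(-1, 6000))  # step at t = 600 s
  env <- compute_envelopes(la, NULL, rate,
                           envelope_params(fast_window_s = 10,
                                           slow_window_s = 120))
  at <- function(tt) which.min(abs(env$times - tt))
  expect_equal(env$fast[at(300)], 0)
  expect_equal(env$slow[at(300)], 0)
  expect_equal(env$fast[at(900)], -1)
  expect_equal(env$slow[at(900)], -1)
  # the fast envelope completes the transition within ~10 s of the step,
  # the slow envelope holds the old level for tens of seconds
  expect_equal(env$fast[at(610)], -1)
  expect_equal(env$slow[at(610)], 0)
  expect_equal(env$slow[at(640)], 0)
})

test_that("dip detection applies depth threshold and duration criteria", {
  n <- 200
  flat <- make_envelope(fast = rep(0, n), slow = rep(0, n))
  expect_equal(nrow(detect_events(flat)), 0)

  # a single 45-s separation of 0.5 (>= ln(1.43)) is one event
  fast <- rep(0, n); fast[61:105] <- -0.5
  env <- make_envelope(fast = fast, slow = rep(0, n))
  ev <- detect_events(env, detection_params(30, 10, 70))
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$duration_s - 45), 1)
  expect_equal(ev$max_depth_log, 0.5)
  expect_gte(ev$max_depth_log, log(1.43) - 1e-6)

  # an 8-s run is too short, an 80-s run too long: both rejected
  fast2 <- rep(0, n); fast2[11:18] <- -0.5; fast2[41:120] <- -0.5
  ev2 <- detect_events(make_envelope(fast = fast2, slow = rep(0, n)))
  expect_equal(nrow(ev2), 0)

  # invalid grid points break candidate runs
  fast3 <- rep(0, n); fast3[61:105] <- -0.5
  valid <- rep(TRUE, n); valid[83] <- FALSE
  ev3 <- detect_events(make_envelope(fast = fast3, slow = rep(0, n),
                                     valid = valid))
  expect_equal(nrow(ev3), 2)
  expect_true(all(ev3$duration_s >= 10 & ev3$duration_s <= 70))

  # coarse grids are refused, empty envelopes are not an error
  expect_error(
    detect_events(make_envelope(rep(0, 50), rep(0, 50), grid_step_s = 5),
                  detection_params(30, 10, 70)),
    "grid step"
  )
  empty <- make_envelope(numeric(0), numeric(0), logical(0))
  expect_equal(nrow(detect_events(empty)), 0)
  expect_error(detection_params(depth_percent = 120), "depth_percent")
  expect_error(detection_params(min_duration_s = 80, max_duration_s = 70),
               "min_duration_s")
})

test_that("REI is events per hour of TRT", {
  ev0 <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    duration_s = numeric(0), max_depth_log = numeric(0))
  expect_equal(compute_rei(ev0, 8)$rei, 0)
  ev56 <- data.frame(start_s = seq_len(56), end_s = seq_len(56) + 0.5,
                     duration_s = rep(0.5, 56), max_depth_log = rep(1, 56))
  expect_equal(compute_rei(ev56, 8)$rei, 7)
  ev14 <- ev56[1:14, ]
  expect_equal(compute_rei(ev14, 7.5)$rei, 14 / 7.5, tolerance = 1e-9)
  expect_error(compute_rei(ev0, 0), "positive")
})

test_that("the full pipeline finds planted apneas and ignores shallow dips", {
  # clean plateaus: no sensor noise, no breath variability, 30-s events
  cfg <- simulation_config(duration_s = 7200, event_rate_per_h = 12,
                           event_depth_percent = 60,
                           event_duration_s = c(30, 30),
                           breath_amp_sdlog = 0, noise_sd = 0,
                           movement_burst_rate_per_h = 0, seed = 21)
  sub <- simulate_subject(cfg)
  res <- run_detection(sub$record)
  n_true <- nrow(sub$truth$events)
  expect_lte(abs(nrow(res$events) - n_true), 2)
  expect_lte(abs(res$rei - sub$truth$true_ahi), 1)

  # events are ordered, non-overlapping, within duration bounds, deep enough
  ev <- res$events
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
  expect_true(all(ev$duration_s >= 10 & ev$duration_s <= 70))
  expect_true(all(ev$max_depth_log >= depth_log_threshold(30)))

  # dips shallower than the 30% threshold must not fire
  cfg10 <- simulation_config(duration_s = 7200, event_rate_per_h = 12,
                             event_depth_percent = 10,
                             event_duration_s = c(30, 30),
                             breath_amp_sdlog = 0, noise_sd = 0,
                             movement_burst_rate_per_h = 0, seed = 21)
  res10 <- run_detection(simulate_subject(cfg10)$record)
  expect_lte(res10$rei, 1)

  # raising the depth threshold never increases the event count here
  counts <- vapply(seq(10, 60, by = 10), function(d) {
    nrow(detect_events(res$envelopes, detection_params(d, 10, 70)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("an all-zero hour of signal yields REI 0", {
  rec <- micromotion_record(rep(0, 360000), sampling_rate = 100)
  expect_equal(run_detection(rec)$rei, 0)
})
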