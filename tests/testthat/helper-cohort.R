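# Shared 20-subject synthetic cohort for the end-to-end acceptance checks:
# clean settings (60% event depth, 15-60 s events, sensor noise at 5% of the
# respiration amplitude), planted AHI uniform over 0-60/h, 2-h recordings.
# Simulation and detection are expensive, so the cohort and its detections
# are computed once per test run and memoized.

.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function() {
  if (!is.null(.cohort_cache$cohort)) return(.cohort_cache$cohort)
  base <- simulation_config(duration_s = 7200, event_depth_percent = 60,
                            event_duration_s = c(15, 60), noise_sd = 250)
  cohort <- simulate_cohort(
    20, ahi_distribution = list(type = "uniform", min = 0, max = 60),
    base_config = base, seed = 11
  )
  detections <- lapply(cohort, function(s) run_detection(s$record))
  .cohort_cache$cohort <- list(subjects = cohort, detections = detections)
  .cohort_cache$cohort
}
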