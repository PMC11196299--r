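test_that("sensor CSV parsing handles payloads, headers and timestamps", {
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("100", "-200", "300"), f)
  rec <- read_micromotion_csv(f, sampling_rate = 100)
  expect_s3_class(rec, "micromotion_record")
  expect_equal(rec$samples, c(100, -200, 300))
  expect_equal(rec$trt_seconds, 0.03)

  writeLines(c("amplitude", "1", "2"), f)
  expect_equal(read_micromotion_csv(f)$samples, c(1, 2))

  writeLines(c("2023-01-01T22:00:00.00,150", "2023-01-01T22:00:00.01,-151"), f)
  expect_equal(read_micromotion_csv(f)$samples, c(150, -151))
})

test_that("a one-hour 100 Hz file yields TRT 3600 s", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(as.character(rep_len(c(-3L, 5L, 12L), 360000L)), f)
  rec <- read_micromotion_csv(f, sampling_rate = 100)
  expect_equal(length(rec$samples), 360000L)
  expect_equal(rec$trt_seconds, 3600)
})

test_that("parse errors name the offending row; range and empty inputs fail", {
  f <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("1", "2", "oops", "4"), f)
  expect_error(read_micromotion_csv(f), "row 3")

  # +2^23 is not representable as a signed 24-bit integer
  writeLines(c("0", "8388608"), f)
  expect_error(read_micromotion_csv(f), "24-bit")
  writeLines(c("8388607", "-8388608"), f)
  expect_equal(read_micromotion_csv(f)$samples, c(8388607, -8388608))

  writeLines(character(0), f)
  expect_error(read_micromotion_csv(f), "empty")
  expect_error(read_micromotion_csv(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("write/read round trip reproduces samples bit-exactly", {
  set.seed(42)
  rec <- micromotion_record(sample(-8388608:8388607, 5000),
                            sampling_rate = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  write_micromotion_csv(rec, f)
  back <- read_micromotion_csv(f, sampling_rate = 100)
  expect_identical(back$samples, rec$samples)
  expect_identical(back$trt_seconds, rec$trt_seconds)
})

test_that("record construction validates range, rate and contents", {
  expect_error(micromotion_record(numeric(0)), "non-empty")
  expect_error(micromotion_record(c(0, 8388608)), "24-bit")
  expect_error(micromotion_record(0, sampling_rate = 0), "positive")
  expect_error(micromotion_record(c(1, NA)), "finite")
  rec <- micromotion_record(rep(1, 250), sampling_rate = 50)
  expect_equal(rec$trt_seconds, 5)
})

test_that("severity banding follows the 5/15/30 boundaries, higher class wins", {
  expect_equal(as.character(severity_class(0)), "normal")
  expect_equal(as.character(severity_class(13.4)), "mild")
  expect_equal(as.character(severity_class(c(5, 15, 30))),
               c("mild", "moderate", "severe"))
  expect_equal(as.character(severity_class(4.999)), "normal")
  expect_error(severity_class(-1), "non-negative")

  # monotone non-decreasing in AHI
  set.seed(1)
  ahi <- sort(runif(200, 0, 60))
  codes <- as.integer(severity_class(ahi))
  expect_true(all(diff(codes) >= 0))
})

test_that("subject metadata reader validates columns and values", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,ahi_trt,ahi_tst,plm_index,group",
               "S01,10.5,13.4,0,training",
               "S02,0,0,22,test"), f)
  meta <- read_subject_meta(f)
  expect_equal(nrow(meta), 2)
  expect_equal(meta$ahi_tst, c(13.4, 0))

  writeLines(c("subject_id,ahi_trt,group", "S01,10,training"), f)
  expect_error(read_subject_meta(f), "missing columns")

  writeLines(c("subject_id,ahi_trt,ahi_tst,plm_index,group",
               "S01,-3,0,0,training"), f)
  expect_error(read_subject_meta(f), "non-negative")
})

test_that("event annotations round trip through TSV", {
  events <- data.frame(start_s = c(100, 400), end_s = c(130, 445),
                       duration_s = c(30, 45), max_depth_log = c(0.5, 0.9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(events, f, subject_id = "S07")
  back <- read_events_tsv(f)
  expect_equal(back$subject_id, c("S07", "S07"))
  expect_equal(back$start_s, events$start_s)
  expect_equal(back$max_depth_log, events$max_depth_log)
})
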