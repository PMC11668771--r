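write_fixture <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

test_that("read_gaze_table parses a small export and derives the interval", {
  f <- write_fixture(c("t\tx\ty\tvalid_left\tvalid_right\tpupil_left\tpupil_right",
                       "0\t10\t20\t1\t1\t3.1\t3.3",
                       "4\t11\t21\t1\t0\t3.2\t",
                       "8\t12\t22\t0\t1\t\t3.0"))
  rec <- read_gaze_table(f, subject_id = "s1", stimulus_id = "tiny")
  expect_s3_class(rec, "gaze_recording")
  expect_equal(nrow(rec$samples), 3)
  expect_equal(rec$sampling_interval, 4)
  expect_equal(rec$samples$t, c(0, 4, 8))
  expect_true(all(rec$samples$valid_left == c(TRUE, TRUE, FALSE)))
})

test_that("all-invalid tables are retained and score zero screen looking", {
  f <- write_fixture(c("t\tx\ty\tvalid_left\tvalid_right\tpupil_left\tpupil_right",
                       "0\t10\t20\t0\t0\t\t",
                       "4\t10\t20\t0\t0\t\t"))
  rec <- read_gaze_table(f)
  expect_equal(nrow(rec$samples), 2)
  expect_true(all(is.na(rec$samples$x)))
  expect_equal(screen_looking_fraction(rec, 100, 100), 0)
})

test_that("missing required columns raise a configuration error naming them", {
  f <- write_fixture(c("x\ty\tvalid_left\tvalid_right\tpupil_left\tpupil_right",
                       "10\t20\t1\t1\t3\t3"))
  expect_error(read_gaze_table(f), "missing required column.*\\bt\\b")
  expect_error(read_gaze_table(write_fixture(
    "t\tx\ty\tvalid_left\tvalid_right\tpupil_left\tpupil_right")),
    "empty gaze table")
})

test_that("unparseable coordinates invalidate the sample instead of dropping it", {
  f <- write_fixture(c("t\tx\ty\tvalid_left\tvalid_right\tpupil_left\tpupil_right",
                       "0\toops\t20\t1\t1\t3.1\t3.1",
                       "4\t11\t21\t1\t1\t3.1\t3.1"))
  rec <- read_gaze_table(f)
  expect_equal(nrow(rec$samples), 2)
  expect_false(rec$samples$valid_left[1] || rec$samples$valid_right[1])
  expect_true(is.na(rec$samples$x[1]))
})

test_that("per-eye dialects average the valid eyes", {
  d <- table_dialect(columns = c(t = "ts", x_left = "xl", y_left = "yl",
                                 x_right = "xr", y_right = "yr",
                                 valid_left = "vl", valid_right = "vr"))
  f <- write_fixture(c("ts\txl\tyl\txr\tyr\tvl\tvr",
                       "0\t10\t20\t20\t40\t1\t1",
                       "4\t10\t20\t90\t90\t1\t0"))
  rec <- read_gaze_table(f, d)
  expect_equal(rec$samples$x, c(15, 10))
  expect_equal(rec$samples$y, c(30, 20))
})

test_that("gaze tables round-trip through write_gaze_table", {
  rec <- simulate_recording(preset_gaze_params("non_asd_like"),
                            tiny_spec(), seed = 11, subject_id = "rt")
  f <- tempfile(fileext = ".tsv")
  write_gaze_table(rec, f)
  back <- read_gaze_table(f, subject_id = "rt", stimulus_id = "tiny")
  expect_equal(back$samples$t, rec$samples$t)
  expect_equal(back$samples$x, rec$samples$x, tolerance = 1e-12)
  expect_equal(back$samples$valid_left, rec$samples$valid_left)
  expect_equal(back$sampling_interval, rec$sampling_interval)
})

test_that("screen_looking_fraction counts valid on-screen samples", {
  # 2 of 8 samples valid and on-screen
  rec <- gaze_recording("s", "tiny", make_samples(
    t = 0:7 * 4,
    x = c(10, 20, -5, 150, 10, 10, 10, 10),
    y = c(10, 20, 10, 10, 200, -1, 10, 10),
    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_equal(screen_looking_fraction(rec, 100, 100), 0.25)
  all_on <- tiny_recording(0:9 * 4, 50, 50)
  expect_equal(screen_looking_fraction(all_on, 100, 100), 1)
})

test_that("screen bounds are half-open", {
  rec <- gaze_recording("s", "tiny", make_samples(
    t = c(0, 4, 8, 12), x = c(0, 99.99, 100, 50), y = c(0, 50, 50, 100)))
  expect_equal(screen_looking_fraction(rec, 100, 100), 0.5)
})

test_that("inclusion filters apply the segment and subject stages", {
  spec <- tiny_spec()
  rec_at <- function(frac, subject, stim) {
    n <- 10L
    k <- round(frac * n)
    tiny_recording(0:(n - 1) * 4, c(rep(50, k), rep(-10, n - k)), 50,
                   subject = subject, stimulus = stim)
  }
  # all good -> everything retained
  good <- lapply(1:3, function(i) rec_at(0.9, "sA", paste0("t", i)))
  good <- lapply(good, function(r) { r$stimulus_id <- "tiny"; r })
  flt <- apply_inclusion_filters(good, spec)
  expect_length(flt$retained, 3)
  expect_equal(nrow(flt$exclusions), 0)

  # 1 of 3 passes the segment filter -> subject fraction 1/3 < 0.5 -> all out
  mixed <- list(rec_at(0.9, "sB", "tiny"), rec_at(0.2, "sB", "tiny"),
                rec_at(0.2, "sB", "tiny"))
  flt <- apply_inclusion_filters(mixed, spec)
  expect_length(flt$retained, 0)
  expect_equal(sum(flt$exclusions$stage == "segment"), 2)
  expect_equal(sum(flt$exclusions$stage == "subject"), 1)

  # 2 of 3 pass -> subject retained with 2 recordings
  ok <- list(rec_at(0.9, "sC", "tiny"), rec_at(0.9, "sC", "tiny"),
             rec_at(0.2, "sC", "tiny"))
  flt <- apply_inclusion_filters(ok, spec)
  expect_length(flt$retained, 2)
  expect_equal(flt$exclusions$stage, "segment")
})

test_that("inclusion filtering is idempotent and conserves counts", {
  spec <- tiny_spec()
  set.seed(5)
  recs <- lapply(1:12, function(i) {
    subj <- paste0("s", (i - 1) %/% 3)
    n <- 10L
    on <- runif(1) < 0.6
    tiny_recording(0:(n - 1) * 4, if (on) 50 else -10, 50, subject = subj)
  })
  flt <- apply_inclusion_filters(recs, spec)
  seg_dropped <- sum(flt$exclusions$stage == "segment")
  subj_dropped_ids <- flt$exclusions$subject_id[flt$exclusions$stage == "subject"]
  subj_of <- vapply(recs, `[[`, character(1), "subject_id")
  dropped_by_subject <- sum(subj_of %in% subj_dropped_ids) -
    sum(flt$exclusions$subject_id %in% subj_dropped_ids &
          flt$exclusions$stage == "segment")
  expect_equal(length(flt$retained) + seg_dropped + dropped_by_subject,
               length(recs))
  again <- apply_inclusion_filters(flt$retained, spec)
  expect_equal(length(again$retained), length(flt$retained))
  expect_equal(nrow(again$exclusions), 0)
  # empty input -> empty output, no error
  empty <- apply_inclusion_filters(list(), spec)
  expect_length(empty$retained, 0)
  expect_equal(nrow(empty$exclusions), 0)
})

test_that("roster validation enforces groups and CSS range", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(subject_id = c("a", "b"), group = c("ASD", "non-ASD"),
                   ados_total = c(7, 3), ados_sa = c(8, NA),
                   ados_rrb = c(6, 2), age_months = c(30, 40),
                   sex = c("M", "F"))
  write.csv(df, f, row.names = FALSE)
  r <- read_roster(f)
  expect_s3_class(r, "subject_roster")
  df$ados_total[1] <- 12
  write.csv(df, f, row.names = FALSE)
  expect_error(read_roster(f), "\\[1, 10\\]")
  df$ados_total[1] <- 7
  df$group[1] <- "autistic"
  write.csv(df, f, row.names = FALSE)
  expect_error(read_roster(f), "group")
})
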