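label_seq <- function(labels, spec = tiny_spec(), interval = 4) {
  t <- (seq_along(labels) - 1) * interval
  rec <- gaze_recording("s", spec$stimulus_id,
                        make_samples(t, 50, 50))
  ls <- assign_labels(rec, spec)
  ls$label <- labels
  ls
}

test_that("total_gaze_count counts labeled samples, optionally windowed", {
  ls <- label_seq(rep("A", 10))
  expect_equal(total_gaze_count(ls, "A"), 10)
  ls2 <- label_seq(c("A", "A", "VACANT", "B"))
  expect_equal(total_gaze_count(ls2, "A"), 2)
  expect_equal(total_gaze_count(ls2, "B", window = c(0, 12)), 0)
  expect_error(total_gaze_count(ls2, "C"), "unknown AOI")
})

test_that("total_fixation_time is dwell time in seconds", {
  ls <- label_seq(rep("A", 250))   # 4 ms interval
  expect_equal(total_fixation_time(ls, "A"), 1.0)
  expect_equal(total_fixation_time(ls, "B"), 0.0)
})

test_that("a full recording in one AOI dwells the whole stimulus", {
  spec <- tiny_spec(duration_ms = 1000)
  n <- 250
  rec <- gaze_recording("s", "tiny", make_samples((0:(n - 1)) * 4, 20, 50))
  ls <- assign_labels(rec, spec)
  expect_lt(abs(total_fixation_time(ls, "A") - 1.0),
            rec$sampling_interval / 1000 + 1e-9)
})

test_that("mean_pupil_size averages available eyes, never imputes", {
  spec <- tiny_spec()
  s <- make_samples(c(0, 4, 8), 20, 50, pupil = NA_real_)
  s$pupil_left <- c(3.0, 3.0, NA); s$pupil_right <- c(3.0, 5.0, NA)
  rec <- gaze_recording("s", "tiny", s)
  ls <- assign_labels(rec, spec)
  expect_equal(mean_pupil_size(rec, ls, "A"), mean(c(3.0, 4.0)))
  expect_true(is.na(mean_pupil_size(rec, ls, "B")))
  s$pupil_left <- NA_real_; s$pupil_right <- NA_real_
  rec2 <- gaze_recording("s", "tiny", s)
  expect_true(is.na(mean_pupil_size(rec2, assign_labels(rec2, spec), "A")))
})

test_that("aoi_switch_count collapses non-AOI samples and counts boundaries", {
  expect_equal(aoi_switch_count(rep("A", 10)), 0)
  expect_equal(aoi_switch_count(c("A", "A", "VACANT", "B", "A")), 2)
  expect_equal(aoi_switch_count(character(0)), 0)
  expect_equal(aoi_switch_count(c("VACANT", "INVALID")), 0)
  # debouncing drops the one-sample B flicker
  expect_equal(aoi_switch_count(c("A", "A", "B", "A", "A"),
                                min_dwell_samples = 2), 0)
  # the trailing single-sample A run is discarded, leaving A(2) -> B(2)
  expect_equal(aoi_switch_count(c("A", "A", "B", "B", "A"),
                                min_dwell_samples = 2), 1)
  expect_equal(aoi_switch_count(c("A", "A", "B", "B", "A", "A"),
                                min_dwell_samples = 2), 2)
})

test_that("aoi_switch_count matches the per-sample loop oracle", {
  set.seed(13)
  for (i in 1:300) {
    labels <- sample(c("A", "B", "VACANT", "OFFSCREEN", "INVALID"),
                     sample(1:30, 1), replace = TRUE)
    expect_equal(aoi_switch_count(labels), asc_loop_oracle(labels))
  }
})

test_that("favored_shift_counts scores per-block pathway adherence", {
  # 4 equal blocks, favored A,B,A,B; per-block (favored, other) counts
  spec <- stimulus_spec("tiny", 100, 100, 1600,
                        list(aoi_region("A", rbind(c(0, 0), c(40, 0),
                                                   c(40, 100), c(0, 100))),
                             aoi_region("B", rbind(c(60, 0), c(100, 0),
                                                   c(100, 100), c(60, 100)))),
                        lapply(1:4, function(i)
                          time_block(i, (i - 1) * 400, i * 400,
                                     c("A", "B", "A", "B")[i])))
  counts <- list(c(10, 2), c(8, 1), c(12, 0), c(5, 5))
  labels <- character(0); t <- numeric(0)
  for (b in 1:4) {
    fav <- c("A", "B", "A", "B")[b]
    oth <- setdiff(c("A", "B"), fav)
    lab <- c(rep(fav, counts[[b]][1]), rep(oth, counts[[b]][2]),
             rep("VACANT", 3))
    labels <- c(labels, lab)
    t <- c(t, (b - 1) * 400 + seq(0, length.out = length(lab), by = 4))
  }
  rec <- gaze_recording("s", "tiny", make_samples(t, 50, 50))
  ls <- assign_labels(rec, spec)
  ls$label <- labels
  fs <- favored_shift_counts(ls, spec)
  expect_equal(fs$fas, 35)
  expect_equal(fs$uas, 8)
  expect_equal(fs$fas_minus_uas, 27)
  # pathway-free stimulus refuses
  expect_error(favored_shift_counts(ls, video2_speaking()),
               "no favored pathway")
})

test_that("perfect and symmetric pathways hit the FAS/UAS extremes", {
  spec <- tiny_spec(duration_ms = 800)
  # always on the favored AOI of the current block (A then B)
  t <- (0:199) * 4
  x <- ifelse(t < 400, 20, 80)
  rec <- gaze_recording("s", "tiny", make_samples(t, x, 50))
  fs <- favored_shift_counts(assign_labels(rec, spec), spec)
  expect_equal(fs$fas, 200)
  expect_equal(fs$uas, 0)
  # even split in every block -> difference 0
  x2 <- rep(c(20, 80), 100)
  rec2 <- gaze_recording("s", "tiny", make_samples(t, x2, 50))
  fs2 <- favored_shift_counts(assign_labels(rec2, spec), spec)
  expect_equal(fs2$fas_minus_uas, 0)
})

test_that("vacancy metrics use the on-screen attended denominator", {
  expect_equal(vacancy_metrics(c(rep("VACANT", 30), rep("A", 70))),
               list(avc = 30L, vacancy_rate = 0.30))
  expect_equal(vacancy_metrics(rep("INVALID", 5)),
               list(avc = 0L, vacancy_rate = 0))
  expect_equal(vacancy_metrics(rep("A", 5)),
               list(avc = 0L, vacancy_rate = 0))
  # invariant to appending INVALID samples
  set.seed(3)
  lab <- sample(c("A", "B", "VACANT"), 50, replace = TRUE)
  expect_equal(vacancy_metrics(lab)$vacancy_rate,
               vacancy_metrics(c(lab, rep("INVALID", 20)))$vacancy_rate)
})

test_that("per_second_series bins counts and conserves the total", {
  spec <- tiny_spec(duration_ms = 3000)
  # uniform 250 Hz gaze always inside A
  n <- 750
  rec <- gaze_recording("s", "tiny", make_samples((0:(n - 1)) * 4, 20, 50))
  ls <- assign_labels(rec, spec)
  series <- per_second_series(ls, "A")
  expect_equal(series, rep(250L, 3))
  expect_equal(sum(series), total_gaze_count(ls, "A"))
  # no samples at all in B
  expect_equal(per_second_series(ls, "B"), rep(0L, 3))
})

test_that("compute_all fills the bundle and respects the pathway contract", {
  v1 <- video1_joint_attention()
  r1 <- simulate_recording(preset_gaze_params("non_asd_like"), v1, seed = 2)
  m1 <- compute_all(r1, v1)
  expect_false(is.null(m1$fas))
  expect_equal(m1$fas + m1$uas,
               sum(m1$tgc))  # video-1 blocks tile the whole stimulus
  v2 <- video2_speaking()
  r2 <- simulate_recording(preset_gaze_params("asd_like"), v2, seed = 3)
  m2 <- compute_all(r2, v2)
  expect_null(m2$fas)
  expect_true(m2$asc >= 0 && m2$avc >= 0)
  # conservation audit
  expect_equal(sum(m2$tgc) + m2$avc + m2$offscreen + m2$invalid,
               m2$n_samples)
})

test_that("metrics are invariant to uniform time translation", {
  spec <- tiny_spec(duration_ms = 1000)
  rec <- simulate_recording(preset_gaze_params("asd_like"), spec, seed = 9)
  m <- compute_all(rec, spec)
  shift <- 200
  shifted_spec <- stimulus_spec("tiny", 100, 100, 1000 + shift,
                                spec$aois,
                                lapply(spec$blocks, function(b)
                                  time_block(b$index, b$start_ms + shift,
                                             b$end_ms + shift, b$favored_aoi)))
  s <- rec$samples; s$t <- s$t + shift
  rec2 <- gaze_recording(rec$subject_id, "tiny", s, rec$sampling_interval)
  m2 <- compute_all(rec2, shifted_spec)
  expect_equal(m2$tgc, m$tgc)
  expect_equal(m2$asc, m$asc)
  expect_equal(m2$fas, m$fas)
  expect_equal(m2$uas, m$uas)
  expect_equal(m2$avc, m$avc)
})

test_that("metrics_table flattens results with per-AOI columns", {
  v1 <- video1_joint_attention(); v2 <- video2_speaking()
  res <- list(compute_all(simulate_recording(preset_gaze_params("asd_like"),
                                             v1, seed = 4), v1),
              compute_all(simulate_recording(preset_gaze_params("asd_like"),
                                             v2, seed = 5), v2))
  mt <- metrics_table(res)
  expect_equal(nrow(mt), 2)
  expect_true(all(c("tgc_face", "tgc_eyes", "fas", "vacancy_rate") %in%
                    names(mt)))
  expect_true(is.na(mt$fas[mt$stimulus_id == "video2_speaking"]))
})

test_that("the dispersion pre-filter keeps stable dwells and drops saccades", {
  spec <- tiny_spec()
  # 30 samples parked in A, 3 fast-moving samples, 30 parked in B
  t <- (0:62) * 4
  x <- c(rep(20, 30), c(45, 50, 55), rep(80, 30))
  rec <- gaze_recording("s", "tiny", make_samples(t, x, 50))
  ls <- assign_labels(rec, spec)
  filtered <- dispersion_prefilter(rec, ls, dispersion_px = 20,
                                   min_duration_ms = 50)
  expect_equal(sum(filtered$label == "A"), 30)
  expect_equal(sum(filtered$label == "B"), 30)
  expect_equal(sum(filtered$label == "INVALID"), 3)
})
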