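test_that("synth_config rejects non-recoverable ground truths", {
  expect_error(synth_config(alpha_true = c(low = 0.7, avg = 0.85, high = 0.9)),
               "must be 1")
  expect_error(synth_config(alpha_true = c(low = 0.6, avg = 0.9, high = 1)),
               "midpoint")
  expect_error(synth_config(alpha_true = c(low = -1, avg = 0, high = 1)))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_participants = 3, days_per_participant = 3, seed = 7)
  b1 <- synthesize_cohort(cfg)
  b2 <- synthesize_cohort(cfg)
  expect_identical(b1$epochs, b2$epochs)
  expect_identical(b1$diary, b2$diary)
  expect_identical(b1$metadata, b2$metadata)
  b3 <- synthesize_cohort(synth_config(n_participants = 3,
                                       days_per_participant = 3, seed = 8))
  expect_false(identical(b1$epochs, b3$epochs))
})

test_that("bundle dimensions follow the configuration", {
  b <- synthesize_cohort(synth_config(n_participants = 5,
                                      days_per_participant = 4, seed = 2))
  expect_equal(length(b$epochs), 5 * 4 * 3) # participants x days x sensors
  expect_equal(nrow(unique(b$diary[c("participant", "date")])), 5 * 4)
  expect_equal(nrow(b$metadata), 5)
  # every day's schedule includes a rest block (u = 0)
  sch <- b$ground_truth$schedule
  rest <- tapply(sch$u, paste(sch$participant, sch$date), min)
  expect_true(all(rest == 0))
})

test_that("bundle round-trips through disk", {
  dir <- withr::local_tempdir()
  b <- synthesize_cohort(synth_config(n_participants = 2,
                                      days_per_participant = 2, seed = 3),
                         out_dir = dir)
  expect_true(file.exists(file.path(dir, "diary.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  b2 <- read_bundle(dir)
  expect_setequal(names(b2$epochs), names(b$epochs))
  k <- names(b$epochs)[1]
  expect_equal(b2$epochs[[k]]$enmo_mean, b$epochs[[k]]$enmo_mean,
               tolerance = 1e-9)
  expect_equal(nrow(b2$diary), nrow(b$diary))
})

test_that("raw segments hit their target mean ENMO within 5%", {
  set.seed(9)
  for (tg in c(0.01, 0.05, 0.2)) {
    seg <- synthesize_raw_segment(tg, 60)
    r <- raw_accel_recording("P", "wrist", "2024-03-04", t = 9 * 3600 + seg$t,
                             ax = seg$ax, ay = seg$ay, az = seg$az)
    expect_equal(mean(compute_enmo(r)$enmo), tg, tolerance = 0.05)
  }
  # zero target: pure gravity
  seg0 <- synthesize_raw_segment(0, 10)
  expect_equal(seg0$ax, rep(0, 1000))
  expect_equal(seg0$az, rep(1, 1000))
  # different seeds: different paths, same mean within tolerance
  set.seed(1); s1 <- synthesize_raw_segment(0.05, 60)
  set.seed(2); s2 <- synthesize_raw_segment(0.05, 60)
  expect_false(identical(s1$ax, s2$ax))
  m <- vapply(list(s1, s2), function(s) {
    r <- raw_accel_recording("P", "wrist", "2024-03-04", 9 * 3600 + s$t,
                             s$ax, s$ay, s$az)
    mean(compute_enmo(r)$enmo)
  }, numeric(1))
  expect_equal(m[1], m[2], tolerance = 0.05)
  expect_error(synthesize_raw_segment(-0.1, 10), "negative")
})

test_that("zero-noise cohort closes the whole pipeline on alpha_true", {
  b <- synthesize_cohort(ideal_cfg(n = 5, days = 4, seed = 42))
  run <- run_agreement(b, pipeline_config())
  truth <- unlist(b$ground_truth$alpha_true)[run$scaling$met_level]
  expect_true(all(abs(run$scaling$alpha - truth) < 1e-6))
  expect_lt(max(run$subject_rmse$rmse), 1e-10)
})

test_that("raw synthesis feeds the signal chain consistently", {
  # small world: 1-hour window so the 100 Hz path stays cheap
  w <- day_window("09:00", "10:00")
  cfg <- synth_config(n_participants = 2, days_per_participant = 3,
                      window = w, record_start = parse_tod("09:00"),
                      record_end = parse_tod("10:00"),
                      sensor_gain = c(ankle = 1, wrist = 1, lower_back = 1),
                      noise_sd = 0, wear_gap_rate = 0, tremor_fraction = 0,
                      tremor_amplitude = 0, seed = 5)
  b <- synthesize_cohort(cfg, raw = TRUE)
  pcfg <- pipeline_config(window = w,
                          rules = qc_rules(min_sensor_hours = 1, window = w))
  run <- run_agreement(b, pcfg)
  truth <- unlist(b$ground_truth$alpha_true)[run$scaling$met_level]
  expect_true(all(abs(run$scaling$alpha - truth) < 1e-3))
  expect_lt(max(run$subject_rmse$rmse), 1e-3)
})

test_that("a wrist response gain above 1 lowers the fitted wrist alpha", {
  cfg <- ideal_cfg(n = 6, days = 3, seed = 11,
                   sensor_gain = c(ankle = 1, wrist = 1.5, lower_back = 1))
  run <- run_agreement(synthesize_cohort(cfg), pipeline_config())
  s <- run$scaling
  for (lv in c("low", "avg", "high")) {
    aw <- s$alpha[s$sensor_position == "wrist" & s$met_level == lv]
    ab <- s$alpha[s$sensor_position == "lower_back" & s$met_level == lv]
    expect_lt(aw, ab)
  }
})
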