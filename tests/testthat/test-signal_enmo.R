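mk_raw <- function(ax, ay, az, fs = 100, start = 9 * 3600) {
  n <- length(az)
  raw_accel_recording("P01", "wrist", "2024-03-04",
                      t = start + (0:(n - 1)) / fs,
                      ax = rep_len(ax, n), ay = rep_len(ay, n), az = az,
                      sampling_rate = fs)
}

test_that("compute_enmo handles constant gravity vectors", {
  n <- 1000 # 10 s at 100 Hz
  expect_equal(compute_enmo(mk_raw(0, 0, rep(1, n)))$enmo, rep(0, n))
  # a constant above 1 g survives the low-pass exactly
  expect_equal(compute_enmo(mk_raw(0, 0, rep(1.5, n)))$enmo, rep(0.5, n),
               tolerance = 1e-9)
  # below 1 g the norm-minus-one is negative and truncates to zero
  expect_equal(compute_enmo(mk_raw(0, 0, rep(0.5, n)))$enmo, rep(0, n))
})

test_that("mean ENMO of a 1 Hz gravity-riding sinusoid matches 0.1/pi", {
  # az = 1 + 0.1 sin(2 pi t): truncation keeps the positive half-wave, whose
  # mean over whole periods is 0.1/pi (analytic integral).
  t <- (0:5999) / 100
  r <- mk_raw(0, 0, 1 + 0.1 * sin(2 * pi * t))
  e <- compute_enmo(r)
  expect_equal(mean(e$enmo), 0.1 / pi, tolerance = 0.01)
})

test_that("bypass mode equals the brute-force norm-minus-one-truncate oracle", {
  set.seed(11)
  for (i in 1:5) {
    n <- 500
    ax <- rnorm(n, 0, 0.3); ay <- rnorm(n, 0, 0.3); az <- rnorm(n, 1, 0.3)
    r <- mk_raw(ax, ay, az)
    e <- compute_enmo(r, filter_config(mode = "bypass"))
    expect_identical(e$enmo, pmax(sqrt(ax^2 + ay^2 + az^2) - 1, 0))
  }
})

test_that("compute_enmo validates inputs", {
  r <- mk_raw(0, 0, rep(1, 100), fs = 30)
  expect_error(compute_enmo(r), "Nyquist")
  expect_error(raw_accel_recording("P", "wrist", "2024-03-04",
                                   t = numeric(0), ax = numeric(0),
                                   ay = numeric(0), az = numeric(0)),
               "empty")
  # non-finite samples are dropped; > 5% triggers a warning
  az <- rep(1.2, 100); az[1:10] <- NA
  expect_warning(e <- compute_enmo(mk_raw(0, 0, az)), "non-finite")
  expect_equal(nrow(e), 90)
})

test_that("aggregate_5s follows the wall-clock grid and gap contract", {
  s <- data.frame(t = 9 * 3600 + (0:499) / 100, enmo = rep(0.2, 500))
  ep <- aggregate_5s(s)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$enmo_mean, 0.2)
  expect_equal(ep$n_samples, 500L)
  expect_equal(ep$epoch_start, 9 * 3600)
  # half zeros, half 0.4 -> mean 0.2
  s2 <- data.frame(t = 9 * 3600 + (0:499) / 100,
                   enmo = rep(c(0, 0.4), each = 250))
  expect_equal(aggregate_5s(s2)$enmo_mean, 0.2)
  # epochs with no samples are absent, not zero-filled
  s3 <- data.frame(t = 9 * 3600 + c((0:99) / 100, 10 + (0:99) / 100),
                   enmo = rep(0.1, 200))
  ep3 <- aggregate_5s(s3)
  expect_equal(ep3$epoch_start, 9 * 3600 + c(0, 10))
  expect_equal(nrow(aggregate_5s(s3[0, ])), 0)
})

test_that("aggregate_slots yields 36 slots with coverage-based validity", {
  w <- day_window()
  full <- data.frame(epoch_start = 9 * 3600 + 5 * (0:179),
                     enmo_mean = rep(0.1, 180), n_samples = 500L)
  sl <- aggregate_slots(full, w)
  expect_equal(nrow(sl), 36)
  expect_equal(sl$enmo_mean[1], 0.1)
  expect_equal(sl$coverage[1], 1)
  expect_true(sl$valid[1])
  expect_false(any(sl$valid[-1]))
  # 90 of 180 epochs: coverage 0.5, invalid at threshold 0.75, mean reported
  half <- full[1:90, ]
  sl2 <- aggregate_slots(half, w, min_coverage = 0.75)
  expect_equal(sl2$coverage[1], 0.5)
  expect_false(sl2$valid[1])
  expect_equal(sl2$enmo_mean[1], 0.1)
  # empty input still yields the full grid
  expect_equal(nrow(aggregate_slots(full[0, ], w)), 36)
  expect_error(day_window("09:00", "17:50"), "multiple")
})

test_that("constant signals propagate exactly through the aggregation chain", {
  for (c0 in c(1.05, 1.5, 2)) {
    r <- mk_raw(0, 0, rep(c0, 100 * 60))
    ep <- aggregate_5s(compute_enmo(r))
    sl <- aggregate_slots(ep)
    expect_equal(sl$enmo_mean[1], c0 - 1, tolerance = 1e-9)
  }
})

test_that("slot mean equals the mean of its 5-second epoch means", {
  set.seed(21)
  ep <- data.frame(epoch_start = 9 * 3600 + 5 * (0:179),
                   enmo_mean = runif(180), n_samples = 500L)
  sl <- aggregate_slots(ep)
  expect_equal(sl$enmo_mean[1], mean(ep$enmo_mean), tolerance = 1e-12)
})

test_that("raw CSV round-trip preserves the recording", {
  dir <- withr::local_tempdir()
  set.seed(3)
  seg <- synthesize_raw_segment(0.03, 10)
  df <- data.frame(
    timestamp = paste0("2024-03-04T", actidiary:::format_tod(floor(9 * 3600 + seg$t)),
                       sprintf(".%03d", round((seg$t %% 1) * 1000))),
    ax = seg$ax, ay = seg$ay, az = seg$az)
  f <- file.path(dir, "P07_2024-03-04_lower_back.csv")
  write.csv(df, f, row.names = FALSE)
  r <- read_raw_accel_csv(f)
  expect_equal(r$participant_id, "P07")
  expect_equal(r$sensor_position, "lower_back")
  expect_equal(r$az, seg$az, tolerance = 1e-12)
  expect_equal(r$t[1], 9 * 3600, tolerance = 1e-3)
})
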