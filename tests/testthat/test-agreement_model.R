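test_that("fit_minmax / apply_minmax follow the Min-Max contract", {
  p <- fit_minmax(c(0, 0.5, 1))
  expect_equal(c(p$min, p$max), c(0, 1))
  expect_equal(apply_minmax(c(0, 0.5, 1), p), c(0, 0.5, 1))
  p2 <- fit_minmax(c(2, 4))
  expect_equal(apply_minmax(c(2, 3, 4), p2), c(0, 0.5, 1))
  expect_warning(p3 <- fit_minmax(c(0.3, 0.3)), "degenerate")
  expect_true(p3$degenerate)
  expect_equal(apply_minmax(c(0.3, 7), p3), c(0, 0))
  expect_error(fit_minmax(c(NA, NaN)), "finite")
})

test_that("group_profile does two-stage averaging with cross-participant SD", {
  panel <- mk_panel(rep(c("A", "B"), each = 2),
                    enmo = c(0.2, 0.2, 0.4, 0.4), met = c(1, 1, 1, 1))
  panel$slot_index <- c(0L, 1L, 0L, 1L)
  gp <- group_profile(panel, "enmo", n_slots = 2L)
  expect_equal(gp$mean, c(0.3, 0.3))
  expect_equal(gp$sd, rep(sd(c(0.2, 0.4)), 2)) # ~0.1414
  expect_equal(gp$n_participants, c(2L, 2L))
  # days average within participant first: A has days 0.1 and 0.3 at slot 0
  p2 <- mk_panel(c("A", "A", "B"), enmo = c(0.1, 0.3, 0.2), met = 1)
  p2$slot_index <- 0L
  p2$date <- c("d1", "d2", "d1")
  gp2 <- group_profile(p2, "enmo", n_slots = 1L)
  expect_equal(gp2$mean, 0.2)
  expect_equal(gp2$sd, sd(c(0.2, 0.2)))
  # single participant: SD NA by default, 0 on request
  p3 <- mk_panel("A", enmo = 0.5, met = 1)
  expect_true(is.na(group_profile(p3, "enmo", n_slots = 1L)$sd))
  expect_equal(group_profile(p3, "enmo", n_slots = 1L,
                             single_sd_zero = TRUE)$sd, 0)
})

test_that("alpha_closed_form is the exact least-squares minimizer", {
  e <- runif(20)
  expect_equal(alpha_closed_form(e, e), 1)
  expect_equal(alpha_closed_form(e, 0.5 * e), 0.5)
  expect_equal(alpha_closed_form(c(1, 2), c(2, 2)), 1.2) # (2+4)/(1+4)
  expect_error(alpha_closed_form(c(0, 0), c(1, 1)), "nonzero")
})

test_that("fit_alpha agrees with the closed form and reports the fit", {
  e <- c(1, 2); m <- c(2, 2)
  sc <- fit_alpha(e, m)
  expect_equal(sc$alpha, 1.2, tolerance = 1e-6)
  expect_equal(sc$init_alpha, mean(m) / mean(e))
  expect_true(sc$converged)
  expect_equal(sc$n_slots_used, 2L)
  # perfect proportionality: alpha 1, zero RMSE
  set.seed(51)
  e3 <- runif(36)
  sc3 <- fit_alpha(e3, e3)
  expect_equal(sc3$alpha, 1, tolerance = 1e-8)
  expect_lt(sc3$fit_rmse, 1e-10)
  expect_error(fit_alpha(c(1, NA), c(1, 2)), "at least two")
})

test_that("Nelder-Mead equals the closed form on random profiles", {
  set.seed(53)
  for (i in 1:20) {
    e <- runif(36, 0, 1)
    m <- runif(36, 0, 1)
    sc <- fit_alpha(e, m)
    expect_equal(sc$alpha, alpha_closed_form(e, m), tolerance = 1e-6)
  }
})

test_that("alpha fitting is scaling-equivariant and order-invariant", {
  set.seed(55)
  e <- runif(36); m <- runif(36)
  base <- fit_alpha(e, m)
  for (cc in c(0.1, 3, 42)) {
    sc <- fit_alpha(cc * e, m)
    expect_equal(sc$alpha, base$alpha / cc, tolerance = 1e-6)
    expect_equal(sc$fit_rmse, base$fit_rmse, tolerance = 1e-9)
  }
  perm <- sample(36)
  expect_equal(fit_alpha(e[perm], m[perm])$fit_rmse, base$fit_rmse,
               tolerance = 1e-12)
})

test_that("subject_rmse matches the direct formula", {
  # alpha * e == m exactly -> zero
  e <- runif(10); pan <- mk_panel("A", e, 0.8 * e)
  expect_equal(subject_rmse(pan, mk_scaling(0.8))$rmse, 0)
  # constant residual d -> rmse |d|
  pan2 <- mk_panel("A", e, e + 0.07)
  expect_equal(subject_rmse(pan2, mk_scaling(1))$rmse, 0.07)
  # random vectors against the brute-force oracle
  set.seed(57)
  for (i in 1:5) {
    ee <- runif(20); mm <- runif(20); a <- runif(1, 0.5, 1.5)
    pan3 <- mk_panel("A", ee, mm)
    expect_equal(subject_rmse(pan3, mk_scaling(a))$rmse,
                 sqrt(mean((a * ee - mm)^2)), tolerance = 1e-12)
  }
  # scaling/panel sensor mismatch is an error
  expect_error(subject_rmse(pan, mk_scaling(1, sensor = "ankle")),
               "different sensor")
  # per-day pooling alternative averages day RMSEs
  pan4 <- mk_panel(c("A", "A"), c(1, 1), c(0.9, 0.7))
  pan4$date <- c("d1", "d2")
  expect_equal(subject_rmse(pan4, mk_scaling(1), per_day = TRUE)$rmse,
               mean(c(0.1, 0.3)))
})

test_that("summarize_rmse reports median/min/max with midpoint medians", {
  a <- data.frame(participant = c("A", "B", "C"), sensor_position = "wrist",
                  met_level = "low", rmse = c(0.1, 0.2, 0.3), n_epochs = 10)
  s <- summarize_rmse(a)
  expect_equal(c(s$median, s$min, s$max), c(0.2, 0.1, 0.3))
  a2 <- a[1, ]
  s2 <- summarize_rmse(a2)
  expect_equal(s2$median, s2$min)
  a4 <- rbind(a, data.frame(participant = "D", sensor_position = "wrist",
                            met_level = "low", rmse = 0.4, n_epochs = 10))
  expect_equal(summarize_rmse(a4)$median, 0.25) # even count: midpoint
})

test_that("tremor grouping respects the <= 1 boundary", {
  lab <- tremor_label(c("A", "B", "C"), c(0, 1, 2))
  expect_equal(lab$group, c("no_minimal", "no_minimal", "stronger"))
  a <- data.frame(participant = rep(c("A", "B", "C"), 2),
                  sensor_position = rep(c("wrist", "lower_back"), each = 3),
                  met_level = "avg", rmse = c(0.1, 0.2, 0.5, 0.1, 0.15, 0.4),
                  n_epochs = 10)
  ts <- tremor_split(lab, a)
  expect_setequal(unique(ts$group), c("no_minimal", "stronger"))
  expect_equal(ts$median[ts$group == "stronger" &
                           ts$sensor_position == "wrist"], 0.5)
  expect_error(tremor_split(lab[1:2, ], a), "unlabeled")
})
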