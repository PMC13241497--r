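comp <- read_compendium()

diary_row <- function(start, end, activity, intensity = "moderate",
                      non_wear = FALSE, participant = "P01",
                      date = "2020-01-02") {
  data.frame(participant = participant, date = date, start = start,
             end = end, activity = activity, intensity = intensity,
             non_wear = non_wear, comment = "", stringsAsFactors = FALSE)
}

test_that("parse_diary validates rows and keeps parallel activities", {
  p <- parse_diary(diary_row("09:00", "09:30", "walking"))
  expect_equal(nrow(p$entries), 1)
  expect_equal(p$entries$end - p$entries$start, 1800)
  expect_false(p$entries$sub_threshold) # 30 min clears the 15-min threshold
  p10 <- parse_diary(diary_row("09:00", "09:10", "walking"))
  expect_true(p10$entries$sub_threshold) # kept but flagged
  # negative duration rejected with reason
  p2 <- parse_diary(diary_row("09:00", "08:00", "walking"))
  expect_equal(nrow(p2$entries), 0)
  expect_match(p2$rejected$reason, "negative duration")
  # unknown intensity token rejected
  p3 <- parse_diary(diary_row("09:00", "10:00", "walking", "extreme"))
  expect_match(p3$rejected$reason, "unknown intensity")
  # two rows over the same span coexist (parallel activities)
  rows <- rbind(diary_row("10:00", "10:30", "housekeeping"),
                diary_row("10:00", "10:30", "watching tv", "mild"))
  expect_equal(nrow(parse_diary(rows)$entries), 2)
})

test_that("assign_met looks up exact pairs, falls back, and flags misses", {
  expect_equal(assign_met("walking", "moderate", comp)$met, 3.5)
  expect_equal(assign_met("watching tv", "mild", comp)$met, 1.3)
  # label-only default row ("any") used when the exact pair is absent
  expect_equal(assign_met("walking", "vigorous", comp)$met, 5.0)
  expect_equal(assign_met("cycling", "mild", comp)$met, 6.8)
  miss <- assign_met("zorbing", "vigorous", comp)
  expect_false(miss$mapped)
  expect_true(is.na(miss$met))
})

test_that("read_compendium validates structure", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  write.csv(data.frame(activity = c("a", "a"), intensity = c("mild", "mild"),
                       code = c("1", "2"), met = c(1, 2)), f,
            row.names = FALSE)
  expect_error(read_compendium(f), "duplicate")
  write.csv(data.frame(activity = "a", intensity = "mild", code = "1",
                       met = -1), f, row.names = FALSE)
  expect_error(read_compendium(f), "> 0")
})

test_that("diary_to_slots maps single and parallel activities", {
  p <- parse_diary(diary_row("09:00", "09:30", "walking"))$entries
  ms <- diary_to_slots(p, comp)
  expect_equal(nrow(ms), 36)
  expect_equal(ms$met_low[1:2], c(3.5, 3.5))
  expect_equal(ms$met_avg[1:2], c(3.5, 3.5))
  expect_equal(ms$met_high[1:2], c(3.5, 3.5))
  expect_false(any(ms$valid[-(1:2)]))
  # housekeeping (3.3) + watching tv (1.3) fully covering a slot
  rows <- rbind(diary_row("10:00", "10:30", "housekeeping"),
                diary_row("10:00", "10:30", "watching tv", "mild"))
  ms2 <- diary_to_slots(parse_diary(rows)$entries, comp)
  j <- which(ms2$slot_start == parse_tod("10:00"))
  expect_equal(ms2$met_low[j], 1.3)
  expect_equal(ms2$met_avg[j], 2.3)
  expect_equal(ms2$met_high[j], 3.3)
  expect_equal(ms2$n_activities[j], 2L)
})

test_that("non-wear and unmapped entries invalidate or drop slots", {
  nw <- diary_row("09:00", "09:30", "non-wear", "", non_wear = TRUE)
  ms <- diary_to_slots(parse_diary(nw)$entries, comp)
  expect_false(any(ms$valid))
  expect_true(all(is.na(ms$met_avg)))
  # non-wear overrides a parallel mapped activity on the same slots
  rows <- rbind(diary_row("09:00", "09:30", "walking"), nw)
  ms2 <- diary_to_slots(parse_diary(rows)$entries, comp)
  expect_false(any(ms2$valid[1:2]))
  # unmapped activities are excluded and counted
  rows3 <- diary_row("11:00", "11:30", "zorbing", "vigorous")
  ms3 <- diary_to_slots(parse_diary(rows3)$entries, comp)
  expect_false(any(ms3$valid))
  expect_equal(attr(ms3, "n_unmapped"), 1L)
})

test_that("overlap rule: half-slot membership vs any overlap", {
  # 10 minutes into a 15-minute slot reaches the half-slot threshold;
  # 5 minutes does not, but counts under the "any" rule
  p10 <- parse_diary(diary_row("09:00", "09:10", "walking"))$entries
  p05 <- parse_diary(diary_row("09:00", "09:05", "walking"))$entries
  expect_true(diary_to_slots(p10, comp)$valid[1])
  expect_false(diary_to_slots(p05, comp)$valid[1])
  expect_true(diary_to_slots(p05, comp, overlap_rule = "any")$valid[1])
})

test_that("slot MET ordering and permutation invariance hold on random diaries", {
  set.seed(31)
  acts <- c("walking", "housekeeping", "watching tv", "reading", "cooking",
            "gardening", "eating", "shopping")
  ints <- c("mild", "moderate", "vigorous")
  for (rep_i in 1:25) {
    n <- sample(2:8, 1)
    s <- sort(sample(seq(9 * 3600, 17 * 3600, by = 300), n))
    rows <- do.call(rbind, lapply(seq_len(n), function(k)
      diary_row(actidiary:::format_tod(s[k]),
                actidiary:::format_tod(s[k] + sample(c(900, 1800, 3600), 1)),
                sample(acts, 1), sample(ints, 1),
                non_wear = runif(1) < 0.1)))
    ents <- parse_diary(rows)$entries
    ms <- diary_to_slots(ents, comp)
    ok <- ms$valid
    expect_true(all(ms$met_low[ok] <= ms$met_avg[ok] + 1e-12))
    expect_true(all(ms$met_avg[ok] <= ms$met_high[ok] + 1e-12))
    expect_lte(sum(ok), 36)
    # order of diary rows must not matter
    perm <- ents[sample(nrow(ents)), , drop = FALSE]
    expect_equal(diary_to_slots(perm, comp), ms, ignore_attr = TRUE)
  }
})
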