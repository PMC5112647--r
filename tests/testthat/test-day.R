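test_that("time-over-run cancellation rules match their definitions", {
  expect_false(should_cancel_for_time("no_start_after_end", 509, 80, 510))
  expect_true(should_cancel_for_time("no_start_after_end", 510, 80, 510))
  expect_true(should_cancel_for_time("cancel_if_lt_half_completable",
                                     480, 100, 510))  # only 30% completable
  expect_false(should_cancel_for_time("cancel_if_lt_half_completable",
                                      480, 50, 510))  # 60% completable
  expect_false(should_cancel_for_time("never_cancel", 700, 80, 510))
})

test_that("paid overtime follows the ceil-increment closed form", {
  expect_equal(paid_overtime_hours(510, 510, 30, 5), 0)
  expect_equal(paid_overtime_hours(511, 510, 30, 5), 2.5)
  expect_equal(paid_overtime_hours(575, 510, 30, 5), 7.5)
  expect_equal(paid_overtime_hours(400, 510, 30, 5), 0)
  # random cross-check against the formula on arbitrary closes
  set.seed(1)
  for (dc in runif(20, 400, 700)) {
    expect_equal(paid_overtime_hours(dc, 510, 30, 5),
                 ceiling(max(0, dc - 510) / 30) * 0.5 * 5)
  }
})

test_that("the degenerate all-means day reproduces the hand-computed schedule", {
  s <- or_streams(1)
  day <- simulate_day(degenerate_policy(), neostigmine_arm(), 0, s)
  # 10 + 5 x 72.9 + 4 x 35.6 = 516.9; close at 531.9 after 15-min cleanup
  expect_equal(day$last_procedure_end, 516.9)
  expect_equal(day$day_close, 531.9)
  expect_false(day$completed_within_day)
  expect_equal(sum(day$procedures$status == "performed"), 5)
  expect_equal(day$overtime_hours_paid, 2.5)  # 21.9 min over -> 1 block

  # sugammadex with everyone verified removes 14 min x 5 procedures
  day2 <- simulate_day(degenerate_policy(), sugammadex_arm(), 1, s)
  expect_equal(day2$last_procedure_end, 516.9 - 70)
  expect_true(day2$completed_within_day)
  expect_equal(day2$overtime_hours_paid, 0)
})

test_that("slots cancelled for other reasons idle their time unless moved up", {
  s <- or_streams(2)
  pol <- degenerate_policy(p_other_cancel = 1)
  day <- simulate_day(pol, neostigmine_arm(), 0, s)
  expect_equal(sum(day$procedures$status == "cancelled_other"), 5)
  expect_equal(sum(day$procedures$status == "performed"), 0)
  # idle time equals the all-performed schedule
  expect_equal(day$last_procedure_end, 516.9)
  # clinical flags never fire on cancelled procedures
  expect_false(any(day$procedures$rnmb | day$procedures$hypoxemia |
                     day$procedures$airway))

  pol_up <- degenerate_policy(p_other_cancel = 1, move_up_on_cancel = TRUE)
  day_up <- simulate_day(pol_up, neostigmine_arm(), 0, s)
  expect_equal(sum(day_up$procedures$status == "cancelled_other"), 5)
  # skipped entirely: the OR is never occupied past the first-patient delay
  expect_equal(day_up$last_procedure_end, 10)
})

test_that("scheduled slots are conserved and performed intervals are ordered", {
  s <- or_streams(33)
  pol <- or_policy(p_emergency = 0.2, p_semi_emergency = 0.3)
  for (d in 1:40) {
    day <- simulate_day(pol, neostigmine_arm(), 0.5, s, day = d)
    p <- day$procedures
    sched <- p[p$kind == "scheduled", ]
    expect_equal(nrow(sched), 5)
    expect_equal(sum(sched$status %in%
                       c("performed", "cancelled_time", "cancelled_other")),
                 5)
    perf <- p[p$status == "performed", ]
    if (nrow(perf) > 1) {
      expect_true(all(diff(perf$start_min) > 0))
      expect_true(all(perf$end_min[-nrow(perf)] <= perf$start_min[-1]))
    }
    expect_true(all(perf$end_min > perf$start_min))
    # base cancel policy: no performed *scheduled* case starts at/after 510
    expect_true(all(perf$start_min[!perf$is_emergency] < 510))
    # overtime is zero exactly when the day closes within the regular day
    expect_equal(day$overtime_hours_paid == 0, day$day_close <= 510)
  }
})

test_that("emergency cases are inserted, performed and never cancelled", {
  s <- or_streams(7)
  pol <- degenerate_policy(p_emergency = 1)
  day <- simulate_day(pol, neostigmine_arm(), 0, s)
  p <- day$procedures
  expect_equal(sum(p$kind == "emergency"), 5)
  expect_true(all(p$status[p$kind == "emergency"] == "performed"))
  # emergencies bump the scheduled case in the same slot
  for (i in 1:5) {
    em <- p[p$kind == "emergency" & p$slot_index == i, ]
    sc <- p[p$kind == "scheduled" & p$slot_index == i, ]
    if (sc$status == "performed") expect_gt(sc$start_min, em$start_min)
  }
  # late emergencies still run even past the regular day end
  expect_gt(max(p$end_min[p$kind == "emergency"]), 510)
})
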