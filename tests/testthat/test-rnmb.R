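test_that("verification assignment follows its Bernoulli law and is degenerate at 0/1", {
  u <- stream_uniforms(or_streams(4), "verification", 1e4)
  expect_false(any(assign_verified(0, u)))
  expect_true(all(assign_verified(1, u)))
  expect_lt(abs(mean(assign_verified(0.25, u)) - 0.25), 0.01)
})

test_that("residual blockade incidence matches arm risks and coupling is monotone", {
  u <- stream_uniforms(or_streams(8), "rnmb", 1e5)
  unverified <- rep(FALSE, length(u))
  neo <- rnmb_event(neostigmine_arm(), unverified, u)
  sug <- rnmb_event(sugammadex_arm(), unverified, u)
  # 60% with neostigmine, 60% x (1 - 93%) = 4.2% with sugammadex
  expect_lt(abs(mean(neo) - 0.60), 3 * sqrt(0.6 * 0.4 / length(u)))
  expect_lt(abs(mean(sug) - 0.042), 3 * sqrt(0.042 * 0.958 / length(u)))
  # shared-uniform coupling: every comparator event is a reference event
  expect_true(all(neo[sug]))
  # verified patients never have residual blockade
  expect_false(any(rnmb_event(neostigmine_arm(), rep(TRUE, length(u)), u)))
})

test_that("complications fire only given residual blockade, at the excess risks", {
  n <- 1e5
  s <- or_streams(9)
  uh <- stream_uniforms(s, "hypoxemia", n)
  ua <- stream_uniforms(s, "airway", n)
  risks <- complication_risks()
  none <- complication_events(rep(FALSE, n), risks, uh, ua)
  expect_false(any(none$hypoxemia) || any(none$airway))
  all_rnmb <- complication_events(rep(TRUE, n), risks, uh, ua)
  expect_lt(abs(mean(all_rnmb$hypoxemia) - 0.245),
            3 * sqrt(0.245 * 0.755 / n))
  expect_lt(abs(mean(all_rnmb$airway) - 0.442),
            3 * sqrt(0.442 * 0.558 / n))
})

test_that("number needed to treat reporting", {
  expect_equal(nnt(90.8, 51), 1.8)
  expect_equal(nnt(90.8, 12), 7.6)
  expect_equal(nnt(90.8, 23), 3.9)
  expect_true(is.na(nnt(100, 0)))
  expect_error(nnt(0, 5), "procedures_treated")
})

test_that("per-patient absolute risk reduction is 55.8% among unverified patients", {
  # analytic: 0.60 x 0.93; printed as 56% after rounding
  arr <- neostigmine_arm()$rnmb_risk_unverified -
    sugammadex_arm()$rnmb_risk_unverified
  expect_equal(arr, 0.558)
  expect_equal(round(100 * arr), 56)
})
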