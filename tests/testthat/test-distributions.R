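test_that("invalid distribution specifications are rejected by name", {
  expect_error(dist_spec("lognormal_mean_sd", c(-1, 5)), "mean must be > 0")
  expect_error(dist_spec("lognormal_mean_sd", c(10, -1)), "sd must be >= 0")
  expect_error(dist_spec("shifted_exponential", c(10, 0)),
               "mean_excess must be > 0")
  expect_error(dist_spec("discrete_cdf", c(0.5, 5, 0.4, 15)),
               "strictly increasing")
  expect_error(dist_spec("discrete_cdf", c(0.5, 5, 0.9, 15)),
               "must equal 1")
  expect_error(dist_spec("triangular", c(15, 7.5, 22.5)),
               "min <= mode <= max")
  expect_error(dist_spec("fixed", c(1, 2)), "single value")
})

test_that("mean/SD lognormal parameterization converts to the underlying normal", {
  # frozen closed-form values: sdlog = sqrt(log(1 + (29.2/72.9)^2)),
  # meanlog = log(72.9) - sdlog^2/2
  lp <- lognormal_moments_to_params(72.9, 29.2)
  expect_equal(lp$sdlog, 0.385744, tolerance = 1e-5)
  expect_equal(lp$meanlog, 4.214689, tolerance = 1e-5)
})

test_that("empirical moments match analytic moments within 3 MC standard errors", {
  specs <- list(
    dist_spec("lognormal_mean_sd", c(72.9, 29.2)),
    dist_spec("shifted_exponential", c(10, 25.6)),
    dist_spec("discrete_cdf", c(0.5, 5, 1, 15)),
    dist_spec("triangular", c(7.5, 15, 22.5)))
  n <- 2e5
  streams <- or_streams(20260901)
  for (spec in specs) {
    x <- draw_variate(spec, n, streams, purpose = spec$kind)
    mo <- dist_moments(spec)
    se_mean <- mo["sd"] / sqrt(n)
    expect_lt(abs(mean(x) - mo[["mean"]]), 3 * se_mean,
              label = paste(spec$kind, "mean error"))
    # SE of the sample SD, normal approximation
    se_sd <- mo["sd"] / sqrt(2 * (n - 1))
    # heavier tails inflate the SD sampling error; allow the lognormal and
    # exponential a kurtosis-corrected band
    kurt_fac <- if (spec$kind %in% c("lognormal_mean_sd",
                                     "shifted_exponential")) 3 else 1
    expect_lt(abs(sd(x) - mo[["sd"]]), 3 * kurt_fac * se_sd,
              label = paste(spec$kind, "sd error"))
  }
})

test_that("draws respect each family's support", {
  streams <- or_streams(11)
  x <- draw_variate(dist_spec("shifted_exponential", c(10, 25.6)), 1e4,
                    streams, "supp1")
  expect_true(all(x >= 10))
  x <- draw_variate(dist_spec("triangular", c(7.5, 15, 22.5)), 1e4,
                    streams, "supp2")
  expect_true(all(x >= 7.5 & x <= 22.5))
  x <- draw_variate(dist_spec("discrete_cdf", c(0.5, 5, 1, 15)), 1e5,
                    streams, "supp3")
  expect_setequal(unique(x), c(5, 15))
  expect_lt(abs(mean(x == 5) - 0.5), 0.01)
  x <- draw_variate(dist_spec("lognormal_mean_sd", c(72.9, 29.2)), 1e4,
                    streams, "supp4")
  expect_true(all(x > 0))
})

test_that("SD scaling preserves the variability ratio", {
  expect_equal(scaled_sd(72.9, 72.9, 29.2), 29.2)
  expect_equal(scaled_sd(145, 72.9, 29.2), 58.079561, tolerance = 1e-6)
  expect_equal(scaled_sd(1, 72.9, 29.2), 0.400549, tolerance = 1e-6)
  expect_error(scaled_sd(0, 72.9, 29.2), "new_mean")
  expect_error(scaled_sd(145, 72.9, -1), "reference_sd")
})
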