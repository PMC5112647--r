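test_that("identical (seed, purpose, replication, day) keys reproduce sequences", {
  a <- stream_uniforms(or_streams(123), "turnover", 50, 3, 7)
  b <- stream_uniforms(or_streams(123), "turnover", 50, 3, 7)
  expect_identical(a, b)
})

test_that("different purpose keys give independent sequences", {
  s <- or_streams(123)
  n <- 2e4
  a <- stream_uniforms(s, "procedure_duration", n, 1, 1)
  b <- stream_uniforms(s, "turnover", n, 1, 1)
  expect_false(identical(a, b))
  expect_lt(abs(cor(a, b)), 4 / sqrt(n))
})

test_that("replication and day indices separate substreams", {
  s <- or_streams(5)
  expect_false(identical(stream_uniforms(s, "rnmb", 10, 1, 1),
                         stream_uniforms(s, "rnmb", 10, 2, 1)))
  expect_false(identical(stream_uniforms(s, "rnmb", 10, 1, 1),
                         stream_uniforms(s, "rnmb", 10, 1, 2)))
  expect_false(identical(stream_uniforms(or_streams(5), "rnmb", 10, 1, 1),
                         stream_uniforms(or_streams(6), "rnmb", 10, 1, 1)))
})

test_that("stream draws do not perturb the global RNG state", {
  set.seed(99)
  before <- .Random.seed
  invisible(stream_uniforms(or_streams(1), "cleanup", 100, 1, 1))
  expect_identical(.Random.seed, before)
})
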