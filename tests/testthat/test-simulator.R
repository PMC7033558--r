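test_that("quit-timer draws match the requested arithmetic moments", {
  p <- simulator_params()
  x <- withr::with_seed(1, draw_quit_time(p, 1e5))
  expect_true(all(x > 0))
  # sample mean within 3 standard errors of 1.6 s
  expect_lt(abs(mean(x) - 1.6), 3 * sd(x) / sqrt(length(x)))
  # sample SD close to 1 s (log-normal sampling error on the SD is ~0.005)
  expect_lt(abs(sd(x) - 1), 0.03)
  # underlying parameters agree with independent moment matching
  expect_equal(unname(quit_lnorm_params(p)),
               unname(lnorm_from_moments(1.6, 1)), tolerance = 1e-12)
})

test_that("degenerate and log-space quit-timer parameterisations behave", {
  p <- simulator_params(quit_sigma = 1e-6)
  x <- withr::with_seed(2, draw_quit_time(p, 1000))
  expect_true(all(abs(x - 1.6) < 1e-3))

  plog <- simulator_params(quit_mean = log(2), quit_sigma = 0.5,
                           quit_log_space = TRUE)
  expect_equal(unname(quit_lnorm_params(plog)), c(log(2), 0.5))
  y <- withr::with_seed(3, draw_quit_time(plog, 1e5))
  expect_lt(abs(mean(log(y)) - log(2)), 3 * 0.5 / sqrt(1e5))
})

test_that("parameter validation rejects inconsistent simulators", {
  expect_error(simulator_params(threshold = -1), "threshold")
  expect_error(simulator_params(start_bias = 0.1, threshold = 0.17), "start_bias")
  expect_error(simulator_params(quit_mean = -2), "quit_mean")
  expect_error(simulator_params(quit_sigma = 0), "quit_sigma")
  expect_error(simulator_params(noise_coef = 0), "noise_coef")
  expect_error(simulator_params(dt = 2, quit_mean = 1.6), "quit-time")
  expect_error(simulate_passage(simulator_params(), drift_sign = 2), "drift_sign")
})

test_that("uncensored passages match the closed-form Wiener oracle", {
  p <- simulator_params(threshold = 0.17, start_bias = 0, quit_mean = 1e6)
  o <- wiener_oracle(0.1, 0.17, 0.085, 0.1)
  expect_equal(unname(absorption_oracle(p, +1)), unname(o), tolerance = 1e-12)

  s <- withr::with_seed(11, simulate_passage(p, +1, n = 2e4, bridge = TRUE))
  ph <- mean(s$event == "accept")
  expect_lt(abs(ph - o[["p"]]), 3 * sqrt(ph * (1 - ph) / 2e4))
  expect_lt(abs(mean(s$decision_time) - o[["t"]]),
            3 * sd(s$decision_time) / sqrt(2e4))
})

test_that("zero drift with no bias gives a fair coin", {
  p <- simulator_params(drift_rate = 0, start_bias = 0, quit_mean = 1e6)
  expect_equal(unname(absorption_oracle(p, +1)),
               c(0.5, 0.085 * 0.085 / 0.01), tolerance = 1e-12)
  s <- withr::with_seed(12, simulate_passage(p, +1, n = 2e4))
  expect_lt(abs(mean(s$event == "accept") - 0.5), 3 * sqrt(0.25 / 2e4))
})

test_that("opposite start biases give complementary absorption probabilities", {
  pp <- simulator_params(drift_rate = 0, start_bias = 0.02, quit_mean = 1e6)
  pm <- simulator_params(drift_rate = 0, start_bias = -0.02, quit_mean = 1e6)
  expect_equal(absorption_oracle(pp, +1)[["p_accept"]] +
                 absorption_oracle(pm, +1)[["p_accept"]], 1, tolerance = 1e-12)
})

test_that("quit events terminate at the drawn quit-time", {
  p <- simulator_params(quit_mean = 0.05, quit_sigma = 1e-6, dt = 1e-3)
  s <- withr::with_seed(13, simulate_passage(p, -1, n = 500))
  quits <- s$decision_time[s$event == "quit"]
  expect_gt(length(quits), 0)
  expect_true(all(abs(quits - 0.05) < 1e-4))
  # at the published congenital parameters a nonzero fraction of trials quit
  pg <- simulator_params(threshold = 0.276)
  sg <- withr::with_seed(14, simulate_passage(pg, +1, n = 2000))
  expect_gt(mean(sg$event == "quit"), 0)
})

test_that("shortening the quit-timer never increases the accept fraction", {
  acc <- vapply(c(0.4, 0.8, 1.6, 3.2, 1e6), function(qm) {
    p <- simulator_params(threshold = 0.17, start_bias = 0, quit_mean = qm)
    s <- withr::with_seed(21, simulate_passage(p, +1, n = 2e4))
    mean(s$event == "accept")
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("identical seeds reproduce the passage sequence exactly", {
  p <- simulator_params(threshold = 0.276)
  a <- withr::with_seed(31, simulate_passage(p, +1, n = 200))
  b <- withr::with_seed(31, simulate_passage(p, +1, n = 200))
  expect_identical(a, b)
})

test_that("simulator parameters survive a YAML round trip", {
  p <- simulator_params(drift_rate = 0.12, threshold = 0.3, start_bias = -0.01)
  f <- tempfile(fileext = ".yml")
  write_simulator_params(p, f)
  expect_equal(read_simulator_params(f), p)
})
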