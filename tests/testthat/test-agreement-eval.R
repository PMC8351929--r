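test_that("Bland-Altman bias and limits behave on canonical inputs", {
  ba <- bland_altman(c(-2, -1, 0, 1, 2))
  expect_equal(ba$bias, 0)
  same <- bland_altman(rep(3.2, 10))
  expect_equal(c(same$bias, same$la_lower, same$la_upper), rep(3.2, 3))
  expect_error(bland_altman(c(1, 2)), "at least 3")
})

test_that("non-parametric limits agree with normal quantiles at large n", {
  set.seed(2024)
  e <- rnorm(10000)
  ba <- bland_altman(e)
  expect_lt(abs(ba$la_lower - qnorm(0.025)), 0.08)
  expect_lt(abs(ba$la_upper - qnorm(0.975)), 0.08)
  expect_gt(ba$normality_p, 0.05)            # normal sample not rejected
  expect_lt(bland_altman(rexp(5000))$normality_p, 0.05)
})

test_that("percentile limits match the first-principles interpolation", {
  set.seed(7)
  for (r in 1:30) {
    e <- rnorm(sample(5:200, 1), sd = sample(1:20, 1))
    ba <- bland_altman(e)
    expect_equal(ba$la_lower, oracle_percentile(e, 0.025), tolerance = 1e-9)
    expect_equal(ba$la_upper, oracle_percentile(e, 0.975), tolerance = 1e-9)
    expect_equal(ba$bias, oracle_percentile(e, 0.5), tolerance = 1e-9)
    # bracketing: with type-7 interpolation at most floor((n-1)p) + 1
    # order statistics can fall outside each limit, and for n >= 200 the
    # limits cover at least 95% of the sample
    n <- length(e)
    k <- floor((n - 1) * 0.025) + 1
    inside <- sum(e >= ba$la_lower & e <= ba$la_upper)
    expect_gte(inside, n - 2 * k)
    if (n >= 200) expect_gte(inside / n, 0.95)
  }
})

test_that("rmse matches hand arithmetic and the loop oracle", {
  expect_equal(rmse(c(0, 0, 0)), 0)
  expect_equal(rmse(c(3, -4)), sqrt(12.5))
  expect_error(rmse(numeric(0)), "empty")
  set.seed(3)
  for (r in 1:100) {
    e <- rnorm(sample(1:50, 1), sd = 10)
    expect_equal(rmse(e), oracle_rmse(e), tolerance = 1e-12)
  }
})

test_that("correlation magnitudes use the published bands exactly", {
  expect_identical(correlation_magnitude(0.0999999), "trivial")
  expect_identical(correlation_magnitude(0.1), "small")      # left-inclusive
  expect_identical(correlation_magnitude(0.2999999), "small")
  expect_identical(correlation_magnitude(0.3), "moderate")
  expect_identical(correlation_magnitude(0.4999999), "moderate")
  expect_identical(correlation_magnitude(0.5), "large")
  expect_identical(correlation_magnitude(-0.35), "moderate") # magnitude only
})

test_that("regression coefficients attach only for non-trivial correlations", {
  x <- 1:50
  exact <- correlate_and_classify(x, 2 * x + 1)
  expect_equal(exact$r, 1)
  expect_identical(exact$magnitude, "large")
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)

  set.seed(10)
  # build data with a tiny correlation: no regression attached
  n <- 2000
  z <- rnorm(n)
  y <- 0.01 * z + rnorm(n)
  res <- correlate_and_classify(z, y)
  expect_identical(res$magnitude, "trivial")
  expect_null(res$slope)
  expect_error(correlate_and_classify(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(correlate_and_classify(1:5, 1:4), "lengths differ")
})

test_that("frame accuracy counts unmasked frames only, like the oracle", {
  p <- matrix(c(.9, .1, .8, .2), 2, 2)
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(frame_accuracy(p, y), 1)
  expect_equal(frame_accuracy(p, 1 - y), 0)
  set.seed(4)
  for (r in 1:50) {
    n <- sample(4:100, 1)
    prob <- matrix(runif(2 * n), 2, n)
    targ <- matrix(rbinom(2 * n, 1, 0.5), 2, n)
    mask <- matrix(rbinom(2 * n, 1, 0.8), 2, n)
    if (sum(mask) == 0) next
    expect_equal(frame_accuracy(prob, targ, mask),
                 oracle_frame_accuracy(prob, targ, mask), tolerance = 1e-12)
  }
  expect_error(frame_accuracy(p, y[, 1, drop = FALSE]), "dimensions differ")
})

test_that("agreement reports satisfy their structural invariants", {
  set.seed(6)
  errs <- data.frame(cycle_id = sprintf("c%d", 1:200),
                     fs_error_ms = rnorm(200, 0, 5),
                     to_error_ms = rnorm(200, 1, 6))
  errs$ct_error_ms <- errs$to_error_ms - errs$fs_error_ms
  rep <- agreement_report(errs, frame_accuracy = 0.99)
  expect_equal(rep$event, c("foot_strike", "toe_off", "contact_time"))
  expect_true(all(rep$la_lower_ms <= rep$bias_ms))
  expect_true(all(rep$bias_ms <= rep$la_upper_ms))
  for (i in 1:3) {
    e <- errs[[c("fs_error_ms", "to_error_ms", "ct_error_ms")[i]]]
    expect_gte(rep$rmse_ms[i] + 1e-12, abs(mean(e)))
  }
  expect_output(print(rep), "frame accuracy: 99.00%")
})
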