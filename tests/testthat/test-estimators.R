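sh <- mdc_sh()

test_that("population decomposition is an exact weighted mean", {
  # Sweden-born group values reproduce the printed population value of 79
  expect_equal(decompose_population(sh, 89, 83, 73), 79.085, tolerance = 1e-3)
  expect_equal(round_half_up(decompose_population(sh, 89, 83, 73)), 79)
  # degenerate mixture: equal groups return the common value
  for (c0 in c(-3, 0, 0.5, 42)) {
    expect_equal(decompose_population(sh, c0, c0, c0), c0)
  }
  # hand arithmetic with simple shares
  sh2 <- group_shares(100, 50, 25)
  expect_equal(decompose_population(sh2, 1, 0, 0), 0.5)
})

test_that("substitution reproduces the printed risk-factor arithmetic", {
  expect_equal(substitution_estimate(sh, 22, 29), 26.647, tolerance = 1e-3)
  expect_equal(substitution_estimate(sh, 7.8, 9.2), 8.729, tolerance = 1e-3)
  expect_equal(substitution_estimate(sh, 5, 5), 5)
})

test_that("substitution equals the decomposition under its own assumption and stays in the hull", {
  set.seed(7)
  for (i in 1:100) {
    y_r <- runif(1, 0, 100)
    y_br <- runif(1, 0, 100)
    # exactness when non-participants match baseline-only participants
    expect_equal(substitution_estimate(sh, y_r, y_br),
                 decompose_population(sh, y_r, y_br, y_br),
                 tolerance = 1e-14)
    est <- substitution_estimate(sh, y_r, y_br)
    expect_gte(est, min(y_r, y_br))
    expect_lte(est, max(y_r, y_br))
  }
})

test_that("the two-point line interpolates its anchor points to machine precision", {
  ln <- fit_extrapolation_line(sh, y_r = 89, y_b = 88)
  expect_equal(ln$beta, -14.1268, tolerance = 1e-4)
  expect_equal(predict(ln, sh$x_r), 89, tolerance = 1e-12)
  expect_equal(predict(ln, sh$x_b), 88, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    y_r <- runif(1, -10, 110)
    y_b <- runif(1, -10, 110)
    ln <- fit_extrapolation_line(sh, y_r, y_b)
    expect_equal(ln$alpha + ln$beta * sh$x_r, y_r, tolerance = 1e-12)
    expect_equal(ln$alpha + ln$beta * sh$x_b, y_b, tolerance = 1e-12)
  }

  flat <- fit_extrapolation_line(sh, 4, 4)
  expect_equal(flat$beta, 0)
  expect_equal(flat$alpha, 4)

  expect_error(fit_extrapolation_line(group_shares(100, 100, 0), 1, 2),
               "x_b = x_r")
})

test_that("extrapolation at x = 1 reproduces the printed cells and is not hull-clamped", {
  hr <- extrapolation_estimate(fit_extrapolation_line(sh, 7.8, 8.0),
                               lower = 0, upper = 100)
  expect_equal(hr$value, 9.676, tolerance = 1e-3)
  expect_false(hr$clipped)
  expect_equal(round_half_up(hr$value), 10)

  # the Sweden-born extrapolation lands BELOW both inputs (88, 89): the
  # estimator must not clamp to the convex hull of its anchors
  sw <- extrapolation_estimate(fit_extrapolation_line(sh, 89, 88),
                               lower = 0, upper = 100)
  expect_equal(sw$value, 79.621, tolerance = 1e-3)
  expect_lt(sw$value, 88)
  expect_equal(round_half_up(sw$value), 80)

  flat <- extrapolation_estimate(fit_extrapolation_line(sh, 6, 6))
  expect_equal(flat$value, 6)

  # out-of-range raw values are clipped and flagged, raw kept
  wild <- extrapolation_estimate(fit_extrapolation_line(sh, 1, 20),
                                 lower = 0, upper = 100)
  expect_true(wild$clipped)
  expect_equal(wild$value, 100)
  expect_gt(wild$raw, 100)
})

test_that("extrapolation recovers the mean of a linear-in-propensity finite population", {
  # brute-force oracle: individuals' values are linear in their propensity
  # rank; the extrapolated estimate must match the direct full-population
  # mean up to discretization error
  N <- 20000
  for (b in c(-20, 5, 40)) {
    a <- 30
    value <- a + b * (seq_len(N) - 0.5) / N  # ascending propensity rank
    x_b <- 0.407
    x_r <- 0.336
    baseline <- seq_len(N) > N * (1 - x_b)
    reexam <- seq_len(N) > N * (1 - x_r)
    shN <- group_shares(N, sum(reexam), sum(baseline) - sum(reexam))
    est <- extrapolation_estimate(
      fit_extrapolation_line(shN, mean(value[reexam]), mean(value[baseline])))
    expect_equal(est$value, mean(value), tolerance = 1e-2)
  }
})

test_that("backing out non-participants inverts the two-group decomposition", {
  expect_equal(back_out_nonparticipants(65068, 79, 26474, 88), 72.826,
               tolerance = 1e-3)
  expect_equal(back_out_nonparticipants(100, 50, 50, 60), 40)
  expect_equal(back_out_nonparticipants(100, 7, 40, 7), 7)

  set.seed(13)
  for (i in 1:50) {
    n <- sample(1000:1e5, 1)
    n_b <- sample(500:(n - 1), 1)
    y_pop <- runif(1, 0, 100)
    y_b <- runif(1, 0, 100)
    y_n <- back_out_nonparticipants(n, y_pop, n_b, y_b)
    # recombining with count weights must return the population value
    expect_equal((n_b * y_b + (n - n_b) * y_n) / n, y_pop,
                 tolerance = 1e-10)
  }

  expect_error(back_out_nonparticipants(100, 50, 100, 50), "exceed")
  expect_warning(back_out_nonparticipants(100, 1, 90, 1.2, lower = 0),
                 "outside")
})

test_that("rate substitution equals the person-time-weighted mean of group rates", {
  # baseline-only mean follow-up backed out from the printed means
  fu_r <- 13.33
  fu_br <- back_out_nonparticipants(26474, 13.25, 21868, 13.33)
  expect_equal(fu_br, 12.870, tolerance = 1e-3)

  cancer <- substitute_rate(sh, prop_r = 296 * fu_r / 1e4,
                            prop_br = 266 * fu_br / 1e4,
                            fu_r = fu_r, fu_br = fu_br)
  expect_equal(cancer, 276.32, tolerance = 1e-2)
  expect_equal(round_half_up(cancer), 276)

  # equal group rates pass through regardless of follow-up times
  r <- substitute_rate(sh, 120 * 10 / 1e4, 120 * 3 / 1e4, 10, 3)
  expect_equal(r, 120)

  # hand arithmetic: proportions (0.2, 0.1), equal follow-ups of 10 years,
  # half the population in each stratum
  sh5 <- group_shares(100, 50, 0)
  expect_equal(substitute_rate(sh5, 0.2, 0.1, 10, 10), 150)

  expect_error(substitute_rate(sh, 0.1, 0.1, 0, 0), "person-time")
})

test_that("half-up rounding follows the report-table convention", {
  expect_equal(round_half_up(26.65), 27)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(8.65, 1), 8.7)
  expect_equal(round_half_up(c(14.992, 9.676)), c(15, 10))
})
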