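# Reproduction of the published MDC comparison tables. Printed cells were
# rounded independently, so recomputed derived cells can differ by the
# propagated input rounding: a convex combination (substitution) moves by at
# most 0.5 units of the last printed digit plus 0.5 for output rounding;
# the extrapolation's leverage (1 - x_b)/(x_b - x_r) amplifies pooled-vs-
# re-examination differences about 8-fold, so its cells get a wider band.

SUB_TOL <- 1.0   # units of the last printed digit
EXT_TOL <- 1.5

test_that("the background-characteristics table is reproduced within rounding", {
  sh <- mdc_sh()
  tab <- mdc_table(1)
  fit <- resist_fit(tab, sh)

  u_sub <- printed_unit(tab$substitution)
  expect_true(all(abs(fit$table$substitution - tab$substitution) <=
                    SUB_TOL * u_sub + 1e-9))
  u_ext <- printed_unit(tab$extrapolation)
  expect_true(all(abs(fit$table$extrapolation - tab$extrapolation) <=
                    EXT_TOL * u_ext + 1e-9))
  expect_false(any(fit$table$clipped))
  # the bulk of the cells agree to the printed digit outright
  expect_gte(mean(round_half_up(fit$table$substitution) == tab$substitution),
             0.6)
})

test_that("the incidence-rate table is reproduced within rounding on the rate scale", {
  sh <- mdc_sh()
  tab <- mdc_table(2)
  fit <- resist_fit(tab, sh)
  rates <- tab$kind == "rate_per_10k_py"

  u_sub <- printed_unit(tab$substitution[rates])
  expect_true(all(abs(fit$table$substitution[rates] -
                        tab$substitution[rates]) <= SUB_TOL * u_sub + 1e-9))
  u_ext <- printed_unit(tab$extrapolation[rates])
  expect_true(all(abs(fit$table$extrapolation[rates] -
                        tab$extrapolation[rates]) <= EXT_TOL * u_ext + 1e-9))

  # substituted all-cause mortality lands between the participant and
  # population values, in the printed direction 237 < 251 < 284
  allc <- which(tab$statistic == "All-cause mortality")
  expect_gt(fit$table$substitution[allc], tab$baseline_all[allc])
  expect_lt(fit$table$substitution[allc], tab$population[allc])
})

test_that("the baseline risk-factor table is reproduced within rounding", {
  sh <- mdc_sh()
  tab <- mdc_table(3)
  fit <- resist_fit(tab, sh)

  expect_true(all(abs(fit$table$substitution - tab$substitution) <=
                    SUB_TOL * printed_unit(tab$substitution) + 1e-9))
  expect_true(all(abs(fit$table$extrapolation - tab$extrapolation) <=
                    EXT_TOL * printed_unit(tab$extrapolation) + 1e-9))
  # the headline cells
  expect_equal(round_half_up(
    fit$table$substitution[tab$statistic == "Smoking: yes, regularly"]), 27)
  expect_equal(round_half_up(
    fit$table$substitution[tab$statistic == "Body mass: obese"]), 15)
})

test_that("recomputed MSE scores agree with the published representativeness ranking", {
  sh <- mdc_sh()
  pub <- mdc_published_mse()

  s1 <- summary(resist_fit(mdc_table(1), sh))$mse
  p1 <- pub[pub$table == 1, ]
  m1 <- s1$mse[match(p1$column, s1$column)]
  # prevalences: published MSEs from unrounded data, recomputed from
  # rounded columns; agreement to +-0.5 squared percentage points
  expect_true(all(abs(m1 - p1$mse) <= 0.5))

  s2 <- summary(resist_fit(mdc_table(2), sh))$mse
  p2 <- pub[pub$table == 2, ]
  m2 <- s2$mse[match(p2$column, s2$column)]
  # rates: squared-error amplification of rounding, 10% relative closeness
  expect_true(all(abs(m2 - p2$mse) / p2$mse <= 0.10))

  # the published ordering of methods is reproduced exactly:
  # baseline-only proxy < substitution < extrapolation < participants (prev)
  expect_identical(p1$column[order(m1)], p1$column[order(p1$mse)])
})

test_that("fit methods expose lines, predictions and summaries coherently", {
  sh <- mdc_sh()
  fit <- resist_fit(mdc_table(3), sh)

  cf <- coef(fit)
  expect_identical(rownames(cf)[1], "Smoking: yes, regularly")
  # line evaluated at x_r returns the re-examination value
  expect_equal(unname(predict(fit, x = sh$x_r)[, 1]),
               fit$input$reexam, tolerance = 1e-12)
  # prediction at x = 1 equals the unclipped extrapolation column
  expect_equal(unname(predict(fit, x = 1)[, 1]),
               fit$table$extrapolation_raw, tolerance = 1e-12)

  expect_output(print(fit), "Continuum-of-resistance")
  s <- summary(fit)
  expect_null(s$mse)  # no population column in the risk-factor table
  expect_output(print(s), "MSE scoring unavailable")

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, statistics = "Smoking: yes, regularly"))
})

test_that("pooled baseline can come from the printed column instead of counts", {
  sh <- mdc_sh()
  tab <- mdc_table(3)
  fit_p <- resist_fit(tab, sh, pooled = "printed")
  expect_equal(fit_p$table$observed_participants, tab$baseline_all)
  # printed pooled for high-risk drinking: the worked 9.68 -> 10
  hr <- tab$statistic == "Alcohol: high risk"
  expect_equal(fit_p$table$extrapolation[hr], 9.676, tolerance = 1e-3)

  # substitution ignores the pooled choice
  expect_equal(fit_p$table$substitution, resist_fit(tab, sh)$table$substitution)
})

test_that("rate rows without follow-up information fall back with a warning", {
  sh <- mdc_sh()
  tab <- mdc_table(2)
  tab2 <- tab[tab$kind == "rate_per_10k_py", ]
  expect_warning(fit <- resist_fit(tab2, sh), "count-share")
  # fallback is the count-share weighting of the rates themselves
  expect_equal(fit$table$substitution,
               substitution_estimate(sh, tab2$reexam, tab2$baseline_only))
})
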