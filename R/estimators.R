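# Core continuum-of-resistance estimators: the population decomposition,
# the substitution estimator, the two-point extrapolation line, backing-out
# of the non-participant group, and the rate-scale substitution algebra.

#' Population decomposition over participation groups
#'
#' The full-population mean of any count-weighted-linear statistic (a
#' prevalence, an outcome proportion, or a mean follow-up time) decomposes
#' exactly over the three participation groups:
#' \deqn{\bar y = \omega_r \bar y_r + \omega_{b \setminus r}
#'   \bar y_{b \setminus r} + (1 - \omega_r - \omega_{b \setminus r}) \bar y_n}
#' where the weights are the groups' population shares. This identity is the
#' scaffold both estimators hang on: substitution replaces the unobserved
#' \eqn{\bar y_n}, extrapolation replaces the whole right-hand side by a line
#' in the participation share.
#'
#' @param shares a [group_shares()] object.
#' @param y_r statistic among re-examination participants.
#' @param y_br statistic among baseline-only participants.
#' @param y_n statistic among baseline non-participants.
#' @return The population value (vectorized over the `y` arguments).
#' @examples
#' sh <- group_shares(65068, 21868, 4606)
#' decompose_population(sh, 89, 83, 73)  # Sweden-born, %
#' @export
decompose_population <- function(shares, y_r, y_br, y_n) {
  assert_group_shares(shares)
  shares$omega_r * y_r + shares$omega_br * y_br +
    (1 - shares$omega_r - shares$omega_br) * y_n
}

#' Substitution estimator of a full-population statistic
#'
#' Assumes the baseline non-participants are distributed as the baseline-only
#' participants (\eqn{\bar y_n = \bar y_{b \setminus r}}), i.e. the most
#' reluctant observed group stands in for the unobserved one. Under that
#' assumption the decomposition collapses to
#' \eqn{\omega_r \bar y_r + (1 - \omega_r) \bar y_{b \setminus r}}.
#' The estimate is a convex combination of its inputs, so it can never leave
#' their range and never needs clipping.
#'
#' @inheritParams decompose_population
#' @return The substituted population value (vectorized).
#' @examples
#' sh <- group_shares(65068, 21868, 4606)
#' substitution_estimate(sh, 22, 29)  # regular smoking, % -> about 26.6
#' @seealso [extrapolation_estimate()], [substitute_rate()]
#' @export
substitution_estimate <- function(shares, y_r, y_br) {
  assert_group_shares(shares)
  shares$omega_r * y_r + (1 - shares$omega_r) * y_br
}

#' Fit the two-point extrapolation line
#'
#' The extrapolation estimator assumes the statistic observed in
#' monotonically growing participant subsets is linear in the population
#' share included: \eqn{\bar y = \alpha + \beta x}. The line is determined
#' exactly by the two observable points \eqn{(x_r, \bar y_r)} (re-examination
#' participants) and \eqn{(x_b, \bar y_b)} (all baseline participants,
#' pooled). Note `y_b` is the pooled baseline statistic, not the
#' baseline-only group's.
#'
#' @inheritParams decompose_population
#' @param y_b statistic among all baseline participants (pooled).
#' @return An object of class `"resist_line"`: list with `alpha`, `beta`,
#'   `x_r`, `x_b`, `y_r`, `y_b` (each possibly vectorized over statistics).
#' @examples
#' sh <- group_shares(65068, 21868, 4606)
#' ln <- fit_extrapolation_line(sh, y_r = 89, y_b = 88)  # Sweden-born
#' coef(ln)                   # slope about -14.1 per unit share
#' predict(ln, x = 1)         # full-population estimate, about 79.6
#' @export
fit_extrapolation_line <- function(shares, y_r, y_b) {
  assert_group_shares(shares)
  if (shares$x_b <= shares$x_r)
    stop("extrapolation undefined: no baseline-only participants (x_b = x_r), slope has zero denominator",
         call. = FALSE)
  beta <- (y_b - y_r) / (shares$x_b - shares$x_r)
  alpha <- y_r - beta * shares$x_r
  structure(list(alpha = alpha, beta = beta,
                 x_r = shares$x_r, x_b = shares$x_b,
                 y_r = y_r, y_b = y_b),
            class = "resist_line")
}

#' @export
coef.resist_line <- function(object, ...) {
  if (length(object$alpha) == 1L)
    c(alpha = object$alpha, beta = object$beta)
  else
    cbind(alpha = object$alpha, beta = object$beta)
}

#' @param x for `predict`, participation share(s) at which to evaluate the
#'   line; `x = 1` is the full population.
#' @rdname fit_extrapolation_line
#' @export
predict.resist_line <- function(object, x = 1, ...) {
  if (length(object$alpha) == 1L)
    object$alpha + object$beta * x
  else
    outer(object$beta, x) + object$alpha
}

#' @export
print.resist_line <- function(x, ...) {
  cat("Two-point extrapolation line: y = alpha + beta * x\n")
  cat(sprintf("  through (x_r = %.4f, y_r) and (x_b = %.4f, y_b)\n",
              x$x_r, x$x_b))
  print(coef(x))
  invisible(x)
}

#' Extrapolation estimator of a full-population statistic
#'
#' Evaluates a fitted [fit_extrapolation_line()] at full participation
#' (`x = 1`). Unlike substitution, the extrapolated value may leave the
#' convex hull of the observed group values -- that is the point of the
#' estimator -- and may even leave the statistic's valid range, in which case
#' it is clipped and flagged.
#'
#' @param line a `"resist_line"` object.
#' @param lower,upper valid range of the statistic, e.g. `c(0, 100)` for a
#'   prevalence in percent. Defaults impose no clipping.
#' @return A list with `value` (clipped), `raw` (unclipped) and `clipped`
#'   (logical), each vectorized like the line.
#' @examples
#' sh <- group_shares(65068, 21868, 4606)
#' extrapolation_estimate(fit_extrapolation_line(sh, 7.8, 8.0),
#'                        lower = 0, upper = 100)$value  # about 9.7
#' @export
extrapolation_estimate <- function(line, lower = -Inf, upper = Inf) {
  if (!inherits(line, "resist_line"))
    stop("'line' must come from fit_extrapolation_line()", call. = FALSE)
  raw <- line$alpha + line$beta  # x = 1
  value <- pmin(pmax(raw, lower), upper)
  list(value = value, raw = raw, clipped = raw < lower | raw > upper)
}

#' Back out the non-participant group's statistic
#'
#' When a statistic is observed both in the full population and among the
#' baseline participants, the value among non-participants follows
#' algebraically from the count weighting:
#' \deqn{\bar y_n = (n \bar y - n_b \bar y_b) / (n - n_b).}
#' This is the exact inverse of the two-group population decomposition. With
#' rounded inputs the result can land outside the statistic's valid range; a
#' warning is raised and clamping is left to the caller.
#'
#' @param n_total population count.
#' @param y_pop statistic in the full population.
#' @param n_b baseline-participant count.
#' @param y_b statistic among baseline participants.
#' @param lower,upper optional valid range used only for the warning.
#' @return The backed-out non-participant value (vectorized over `y`).
#' @examples
#' back_out_nonparticipants(65068, 79, 26474, 88)  # Sweden-born, about 72.8
#' @export
back_out_nonparticipants <- function(n_total, y_pop, n_b, y_b,
                                     lower = -Inf, upper = Inf) {
  if (n_total <= n_b)
    stop("'n_total' must exceed 'n_b': no non-participants to back out",
         call. = FALSE)
  out <- (n_total * y_pop - n_b * y_b) / (n_total - n_b)
  if (any(out < lower | out > upper))
    warning("backed-out value outside the statistic's valid range (likely an input-rounding artifact); not clamped",
            call. = FALSE)
  out
}

#' Substitution estimator on the incidence-rate scale
#'
#' Incidence rates (events per 10,000 person-years) are ratios, so the
#' substitution step is applied to their numerator and denominator
#' separately: the non-participants' outcome proportion and mean follow-up
#' time are both replaced by the baseline-only group's, and the population
#' rate is recomputed as
#' \deqn{10^4 \cdot \frac{\omega_r \bar p_r + (1-\omega_r) \bar p_{b\setminus r}}
#'   {\omega_r \bar f_r + (1-\omega_r) \bar f_{b \setminus r}},}
#' which is algebraically the person-time-weighted mean of the two group
#' rates with weights \eqn{\omega_r \bar f_r} and
#' \eqn{(1-\omega_r)\bar f_{b \setminus r}}.
#'
#' @inheritParams decompose_population
#' @param prop_r,prop_br outcome proportions (0--1) among re-examination and
#'   baseline-only participants.
#' @param fu_r,fu_br mean follow-up times (years) in the same groups.
#' @param per scaling of the returned rate (default events per 10,000
#'   person-years).
#' @return The substituted population rate.
#' @examples
#' sh <- group_shares(65068, 21868, 4606)
#' # equivalent person-time-weighted form, from group rates and follow-ups:
#' substitute_rate(sh, prop_r = 296 * 13.33 / 1e4, prop_br = 266 * 12.87 / 1e4,
#'                 fu_r = 13.33, fu_br = 12.87)
#' @export
substitute_rate <- function(shares, prop_r, prop_br, fu_r, fu_br, per = 1e4) {
  assert_group_shares(shares)
  p_sub <- shares$omega_r * prop_r + (1 - shares$omega_r) * prop_br
  f_sub <- shares$omega_r * fu_r + (1 - shares$omega_r) * fu_br
  if (any(f_sub <= 0))
    stop("zero person-time: substituted mean follow-up is not positive",
         call. = FALSE)
  per * p_sub / f_sub
}

#' Round half away from zero
#'
#' Report tables use conventional half-up rounding to the printed precision
#' (R's `round()` rounds half to even). Raw values are always retained
#' internally; this is only for presentation and for matching published
#' tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return `x` rounded half away from zero.
#' @examples
#' round_half_up(26.65)  # 27
#' round_half_up(0.5)    # 1, where round(0.5) == 0
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
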