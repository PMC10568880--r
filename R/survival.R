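# Kaplan-Meier estimation and the mixture / extrapolation adjustments that
# carry the continuum-of-resistance estimators onto survival curves.

new_km_curve <- function(time, surv, n_risk = rep(NA_real_, length(time)),
                         n_event = rep(NA_real_, length(time)),
                         n = NA_real_, method = "km") {
  stopifnot(length(time) == length(surv), !is.unsorted(time))
  if (any(surv < -1e-12 | surv > 1 + 1e-12) || any(diff(surv) > 1e-12))
    stop("invalid survival curve: values must lie in [0,1] and be non-increasing",
         call. = FALSE)
  structure(list(time = time, surv = pmin(pmax(surv, 0), 1),
                 n_risk = n_risk, n_event = n_event, n = n, method = method),
            class = "km_curve")
}

#' Kaplan-Meier curve from individual cohort records
#'
#' Product-limit estimate of the survival function for one (sub)group of
#' records, via [survival::survfit()]. Right-censored individuals leave the
#' risk set at their follow-up time; ties between events and censorings at
#' the same time are resolved events-first (the standard convention).
#' Records flagged `excluded_pre_followup = 1`, if the column is present,
#' are dropped first.
#'
#' @param records a data frame of individual records with follow-up times
#'   and a 0/1 event column (see [read_individual_records()]).
#' @param outcome name of the event indicator column (default `"event"`).
#' @param time name of the follow-up time column.
#' @return An object of class `"km_curve"`: list with `time`, `surv`,
#'   `n_risk`, `n_event`, `n` and `method`.
#' @examples
#' rec <- data.frame(id = 1:2, group = "reexam",
#'                   followup_time = c(1, 2), event = c(1, 0))
#' km_fit(rec)$surv  # 0.5 after the event at t = 1
#' @seealso [km_eval()], [km_mixture()], [km_extrapolate()]
#' @export
km_fit <- function(records, outcome = "event", time = "followup_time") {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("'records' must be a non-empty data frame", call. = FALSE)
  if ("excluded_pre_followup" %in% names(records))
    records <- records[records$excluded_pre_followup == 0, , drop = FALSE]
  if (nrow(records) == 0)
    stop("all records are excluded before follow-up start", call. = FALSE)
  tt <- records[[time]]
  ee <- records[[outcome]]
  if (is.null(tt) || is.null(ee))
    stop(sprintf("records lack a '%s' or '%s' column", time, outcome),
         call. = FALSE)
  if (any(tt < 0)) stop("negative follow-up times", call. = FALSE)
  if (!all(ee %in% c(0, 1))) stop("events must be coded 0/1", call. = FALSE)
  sf <- survival::survfit(survival::Surv(tt, ee) ~ 1)
  new_km_curve(sf$time, sf$surv, n_risk = sf$n.risk, n_event = sf$n.event,
               n = length(tt), method = "km")
}

#' Evaluate a survival curve as a right-continuous step function
#'
#' Last value carried forward between jump points; `S(t) = 1` for `t`
#' before the first observed time.
#'
#' @param curve a `"km_curve"`.
#' @param t times at which to evaluate.
#' @return Survival probabilities at `t`.
#' @export
km_eval <- function(curve, t) {
  s <- c(1, curve$surv)
  s[findInterval(t, curve$time) + 1L]
}

#' Mixture of group survival curves
#'
#' Pointwise weighted average of survival curves on the union of their jump
#' times. This is how a full-population curve decomposes over participation
#' groups, and how the substitution approach builds its population curve:
#' the re-examination and baseline-only curves mixed with weights
#' \eqn{(\omega_r, 1 - \omega_r)}, i.e. the baseline-only curve stands in
#' for all non-participants.
#'
#' @param curves a list of `"km_curve"` objects.
#' @param weights numeric weights, same length as `curves`, summing to 1
#'   (tolerance 1e-9).
#' @return A `"km_curve"` (with `method = "mixture"`; risk-set bookkeeping
#'   is not defined for a mixture and is left `NA`).
#' @examples
#' sh <- mdc_shares()
#' rec <- simulate_cohort(sim_config(n_population = 2000), seed = 1)$records
#' part <- rec[rec$group != "nonparticipant" & rec$excluded_pre_followup == 0, ]
#' km_sub <- km_mixture(
#'   list(km_fit(part[part$group == "reexam", ]),
#'        km_fit(part[part$group == "baseline_only", ])),
#'   weights = c(sh$omega_r, 1 - sh$omega_r))
#' @export
km_mixture <- function(curves, weights) {
  if (!length(curves) || !all(vapply(curves, inherits, logical(1), "km_curve")))
    stop("'curves' must be a list of km_curve objects", call. = FALSE)
  if (length(weights) != length(curves))
    stop("'weights' must match 'curves' in length", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop(sprintf("weights must sum to 1 (got %.12g)", sum(weights)),
         call. = FALSE)
  grid <- sort(unique(unlist(lapply(curves, `[[`, "time"))))
  surv <- Reduce(`+`, Map(function(cv, w) w * km_eval(cv, grid),
                          curves, weights))
  new_km_curve(grid, surv, n = sum(weights * vapply(curves, `[[`, 1, "n")),
               method = "mixture")
}

#' Extrapolated full-population survival curve
#'
#' Applies the two-point extrapolation pointwise on the survival scale: at
#' every time on the union grid, the line through
#' \eqn{(x_r, S_r(t))} and \eqn{(x_b, S_b(t))} is evaluated at full
#' participation \eqn{x = 1}. Because the transform is affine, extrapolating
#' survival probabilities and extrapolating cumulative incidences are the
#' same operation. The raw pointwise values need not form a valid survival
#' function, so they are clipped into \eqn{[0,1]} and made non-increasing by
#' a running minimum; a message reports when either repair changed anything.
#'
#' @param curve_r `"km_curve"` for the re-examination participants.
#' @param curve_b `"km_curve"` for all baseline participants, pooled.
#' @param shares a [group_shares()] object (supplies `x_r` and `x_b`).
#' @return A `"km_curve"` (`method = "extrapolation"`) with attributes
#'   `"clipped"` and `"repaired"` indicating whether either fix-up changed
#'   any value.
#' @export
km_extrapolate <- function(curve_r, curve_b, shares) {
  assert_group_shares(shares)
  if (shares$x_b <= shares$x_r)
    stop("extrapolation undefined: x_b = x_r", call. = FALSE)
  if (!inherits(curve_r, "km_curve") || !inherits(curve_b, "km_curve"))
    stop("'curve_r' and 'curve_b' must be km_curve objects", call. = FALSE)
  grid <- sort(unique(c(curve_r$time, curve_b$time)))
  s_r <- km_eval(curve_r, grid)
  s_b <- km_eval(curve_b, grid)
  raw <- s_b + (s_b - s_r) / (shares$x_b - shares$x_r) * (1 - shares$x_b)
  clip <- pmin(pmax(raw, 0), 1)
  mono <- cummin(clip)
  clipped <- any(clip != raw)
  repaired <- any(mono != clip)
  if (clipped || repaired)
    message(sprintf(
      "extrapolated survival curve adjusted: clipped to [0,1] = %s, monotonicity repaired = %s",
      clipped, repaired))
  out <- new_km_curve(grid, mono, method = "extrapolation")
  attr(out, "clipped") <- clipped
  attr(out, "repaired") <- repaired
  out
}

#' Participation-group and adjusted Kaplan-Meier curves for a cohort
#'
#' Convenience wrapper producing the whole family of curves that the
#' continuum-of-resistance analysis compares: one per observed participation
#' group, the pooled baseline participants, and the substitution and
#' extrapolation population curves. The population curve itself is included
#' when non-participant records exist (simulation or linked-register
#' settings).
#'
#' @param records individual records (see [read_individual_records()]);
#'   excluded records are dropped.
#' @param shares optional [group_shares()]; by default computed from the
#'   record counts.
#' @param outcome event column name.
#' @return A named list of `"km_curve"` objects: some of `population`,
#'   `baseline_all`, `reexam`, `baseline_only`, `substitution`,
#'   `extrapolation`.
#' @export
cohort_km <- function(records, shares = NULL, outcome = "event") {
  if ("excluded_pre_followup" %in% names(records))
    records <- records[records$excluded_pre_followup == 0, , drop = FALSE]
  records <- validate_records(records)
  if (is.null(shares))
    shares <- group_shares(nrow(records),
                           sum(records$group == "reexam"),
                           sum(records$group == "baseline_only"))
  out <- list()
  if (any(records$group == "nonparticipant"))
    out$population <- km_fit(records, outcome = outcome)
  part <- records[records$group != "nonparticipant", , drop = FALSE]
  out$baseline_all <- km_fit(part, outcome = outcome)
  out$reexam <- km_fit(part[part$group == "reexam", ], outcome = outcome)
  out$baseline_only <- km_fit(part[part$group == "baseline_only", ],
                              outcome = outcome)
  out$substitution <- km_mixture(list(out$reexam, out$baseline_only),
                                 weights = c(shares$omega_r,
                                             1 - shares$omega_r))
  out$extrapolation <- km_extrapolate(out$reexam, out$baseline_all, shares)
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Survival curve (%s): %d time points", x$method, length(x$time)))
  if (!is.na(x$n)) cat(sprintf(", n = %g", x$n))
  cat("\n")
  if (length(x$time)) {
    at <- stats::quantile(seq_along(x$time), c(0, .25, .5, .75, 1), type = 1)
    print(data.frame(time = signif(x$time[at], 4),
                     surv = signif(x$surv[at], 4)), row.names = FALSE)
  }
  invisible(x)
}

#' @param x a `"km_curve"`.
#' @param add draw on top of an existing plot?
#' @param ... passed to [graphics::plot()]/[graphics::lines()].
#' @rdname km_fit
#' @export
plot.km_curve <- function(x, add = FALSE, ...) {
  f <- stats::stepfun(x$time, c(1, x$surv), right = FALSE)
  if (add) graphics::lines(f, do.points = FALSE, ...)
  else graphics::plot(f, do.points = FALSE, xlab = "years",
                      ylab = "survival", main = "", ...)
  invisible(x)
}

#' Tidy a set of survival curves for export or plotting
#'
#' @param curves a named list of `"km_curve"` objects (e.g. [cohort_km()]).
#' @return A long `data.frame` with columns `time`, `curve_label`, `survival`.
#' @export
km_tidy <- function(curves) {
  do.call(rbind, lapply(names(curves), function(nm) {
    cv <- curves[[nm]]
    data.frame(time = cv$time, curve_label = nm, survival = cv$surv,
               stringsAsFactors = FALSE)
  }))
}
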