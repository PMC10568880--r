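# Synthetic selective-participation cohort: a latent participation
# propensity drives nested baseline / re-examination participation,
# propensity-linked binary covariates, and a propensity-dependent hazard,
# so every estimator can be validated against a known population truth.

#' Configuration for the synthetic cohort simulator
#'
#' Each invitee carries a rank-uniform latent participation propensity
#' \eqn{u \sim U(0,1)}. Baseline participation is the top `target_x_b`
#' fraction of propensity, re-examination participation the top
#' `target_x_r` (nested thresholds, so "share participating" is literally
#' the abscissa of the extrapolation model); `reexam_noise` flips
#' re-examination membership among baseline participants with the given
#' probability, breaking the perfect continuum. Binary covariates have
#' prevalence linked to `u`; event times are exponential with hazard
#' `baseline_hazard * exp(hazard_log_slope * (u - 0.5))`, administratively
#' censored at `admin_censor_years`. A fraction
#' `pre_followup_exclusion_prob` of invitees dies/emigrates before
#' follow-up start and is flagged for load-time exclusion.
#'
#' Defaults emulate the MDC setting: 65,068 invitees after exclusions,
#' baseline / re-examination shares 0.407 / 0.336, follow-up capped at
#' 15.33 years, an exclusion probability of 0.122, and a mortality hazard
#' around 0.028/year falling in propensity so that participants are the
#' healthier part of the population.
#'
#' @param n_population number of invitees.
#' @param target_x_b,target_x_r target baseline and re-examination
#'   participation shares, `0 < target_x_r <= target_x_b < 1`.
#' @param covariates named list; each element `c(intercept = , slope = )`
#'   parameterizes one binary covariate's prevalence as a function of `u`.
#' @param link link from propensity to covariate prevalence: `"linear"`
#'   (`intercept + slope * u`, clipped to \[0,1\]), `"logistic"`
#'   (`plogis(intercept + slope * u)`), or `"step"`
#'   (`intercept + slope * 1[u > threshold]`: constant above and below a
#'   participation threshold, see `step_threshold`).
#' @param step_threshold where the `"step"` link jumps: `"reexam"` (default;
#'   everyone below the re-examination propensity threshold -- baseline-only
#'   participants and non-participants alike -- shares one prevalence,
#'   which is exactly the substitution model's assumption) or `"baseline"`
#'   (the jump sits at the baseline-participation threshold instead).
#' @param reexam_noise probability in \[0,1\] that a baseline participant's
#'   re-examination status is re-randomized independently of propensity
#'   (with the marginal re-examination share preserved) instead of
#'   following the nested-threshold rule; this breaks the perfect
#'   continuum without moving the group shares off their targets.
#' @param baseline_hazard events per year at mid propensity.
#' @param hazard_log_slope log-hazard change per unit propensity; negative
#'   values make high-propensity (participating) invitees healthier.
#' @param admin_censor_years administrative censoring horizon in years.
#' @param pre_followup_exclusion_prob probability of death/emigration before
#'   follow-up start (excluded at load time).
#' @param seed optional integer default seed for [simulate_cohort()].
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_population = 65068,
                       target_x_b = 0.407,
                       target_x_r = 0.336,
                       covariates = list(
                         smoker = c(intercept = 0.45, slope = -0.30),
                         obese = c(intercept = 0.24, slope = -0.15)),
                       link = c("linear", "logistic", "step"),
                       step_threshold = c("reexam", "baseline"),
                       reexam_noise = 0.05,
                       baseline_hazard = 0.028,
                       hazard_log_slope = -0.55,
                       admin_censor_years = 15.33,
                       pre_followup_exclusion_prob = 0.122,
                       seed = NULL) {
  link <- match.arg(link)
  step_threshold <- match.arg(step_threshold)
  stopifnot(n_population >= 10, n_population == trunc(n_population))
  if (!(target_x_r > 0 && target_x_r <= target_x_b && target_x_b < 1))
    stop("need 0 < target_x_r <= target_x_b < 1", call. = FALSE)
  stopifnot(reexam_noise >= 0, reexam_noise <= 1,
            baseline_hazard >= 0, admin_censor_years > 0,
            pre_followup_exclusion_prob >= 0,
            pre_followup_exclusion_prob < 1)
  if (!length(covariates) || is.null(names(covariates)) ||
      any(!nzchar(names(covariates))))
    stop("'covariates' must be a non-empty named list", call. = FALSE)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (!all(c("intercept", "slope") %in% names(cv)))
      stop(sprintf("covariate '%s' needs 'intercept' and 'slope'", nm),
           call. = FALSE)
  }
  structure(list(n_population = n_population, target_x_b = target_x_b,
                 target_x_r = target_x_r, covariates = covariates,
                 link = link, step_threshold = step_threshold,
                 reexam_noise = reexam_noise,
                 baseline_hazard = baseline_hazard,
                 hazard_log_slope = hazard_log_slope,
                 admin_censor_years = admin_censor_years,
                 pre_followup_exclusion_prob = pre_followup_exclusion_prob,
                 seed = seed),
            class = "sim_config")
}

link_prevalence <- function(config, u) {
  step_at <- 1 - switch(config$step_threshold,
                        reexam = config$target_x_r,
                        baseline = config$target_x_b)
  lapply(config$covariates, function(cv) {
    p <- switch(config$link,
      linear = cv[["intercept"]] + cv[["slope"]] * u,
      logistic = stats::plogis(cv[["intercept"]] + cv[["slope"]] * u),
      step = cv[["intercept"]] + cv[["slope"]] * as.numeric(u > step_at))
    pmin(pmax(p, 0), 1)
  })
}

#' Simulate a selective-participation cohort
#'
#' Draws one cohort under a [sim_config()] and records, alongside the
#' individual records, the true full-population estimands they were
#' generated from -- computed from all (non-pre-excluded) invitees before
#' any participation-based subsetting. Identical config and seed give
#' bit-identical cohorts.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; overrides `config$seed`. Required through one
#'   of the two.
#' @return An object of class `"synthetic_cohort"`: list with
#'   * `records`: data frame with `id`, `group`, one column per covariate,
#'     `followup_time`, `event`, `excluded_pre_followup`;
#'   * `propensity`: the latent propensities;
#'   * `truth`: list of population estimands (covariate prevalences in %,
#'     all-cause event rate per 10,000 person-years, mean follow-up,
#'     survival at 5/10/15 years, per-group covariate means and counts);
#'   * `config`, `seed`.
#' @examples
#' ch <- simulate_cohort(sim_config(n_population = 5000), seed = 7)
#' ch$truth$prevalence_percent
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required for reproducibility",
                          call. = FALSE)
  set.seed(as.integer(seed))
  n <- config$n_population
  u <- stats::runif(n)

  baseline <- u > 1 - config$target_x_b
  reexam <- baseline & u > 1 - config$target_x_r
  if (config$reexam_noise > 0) {
    redraw <- baseline & stats::runif(n) < config$reexam_noise
    reexam[redraw] <- stats::rbinom(sum(redraw), 1,
                                    config$target_x_r / config$target_x_b) == 1
  }
  group <- ifelse(!baseline, "nonparticipant",
                  ifelse(reexam, "reexam", "baseline_only"))

  prev <- link_prevalence(config, u)
  covs <- lapply(prev, function(p) stats::rbinom(n, 1, p))

  hazard <- config$baseline_hazard *
    exp(config$hazard_log_slope * (u - 0.5))
  t_event <- stats::rexp(n, rate = pmax(hazard, .Machine$double.eps))
  followup <- pmin(t_event, config$admin_censor_years)
  event <- as.integer(t_event <= config$admin_censor_years)

  excluded <- stats::rbinom(n, 1, config$pre_followup_exclusion_prob)

  records <- data.frame(id = seq_len(n), group = group,
                        stringsAsFactors = FALSE)
  for (nm in names(covs)) records[[nm]] <- covs[[nm]]
  records$followup_time <- followup
  records$event <- event
  records$excluded_pre_followup <- excluded

  keep <- excluded == 0
  if (length(unique(group[keep])) < 3 ||
      min(table(group[keep])) == 0)
    stop("infeasible shares: a participation group is empty after noise and exclusions",
         call. = FALSE)

  kept <- records[keep, , drop = FALSE]
  km <- km_fit(kept)
  truth <- list(
    prevalence_percent = vapply(names(covs), function(nm)
      100 * mean(kept[[nm]]), numeric(1)),
    rate_per_10k_py = 1e4 * sum(kept$event) / sum(kept$followup_time),
    mean_followup_years = mean(kept$followup_time),
    survival = stats::setNames(
      km_eval(km, c(5, 10, 15)), c("t5", "t10", "t15")),
    group_means = lapply(stats::setNames(nm = GROUP_LABELS), function(g) {
      sub <- kept[kept$group == g, , drop = FALSE]
      c(n = nrow(sub),
        vapply(names(covs), function(nm) 100 * mean(sub[[nm]]), numeric(1)))
    })
  )

  structure(list(records = records, propensity = u, truth = truth,
                 config = config, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  kept <- x$records[x$records$excluded_pre_followup == 0, ]
  cat(sprintf("Synthetic cohort: %d invitees (%d analyzable), seed %d\n",
              nrow(x$records), nrow(kept), x$seed))
  print(round(prop.table(table(kept$group)), 4))
  cat("population truth (prevalences %, rate /10k py):\n")
  print(signif(c(x$truth$prevalence_percent,
                 rate = x$truth$rate_per_10k_py), 4))
  invisible(x)
}

#' Group-level summary table and shares from individual records
#'
#' Collapses individual records to the group-table format consumed by
#' [resist_fit()]: one prevalence row per binary covariate, an all-cause
#' event rate row, and a mean follow-up row, with the population and
#' non-participant columns filled in when non-participant records are
#' present. Excluded records are dropped first.
#'
#' @param x a `"synthetic_cohort"` or a record data frame.
#' @return A list with `table` (a `group_table`) and `shares`
#'   ([group_shares()] computed from the record counts).
#' @export
summarize_cohort <- function(x) {
  records <- if (inherits(x, "synthetic_cohort")) x$records else x
  if ("excluded_pre_followup" %in% names(records))
    records <- records[records$excluded_pre_followup == 0, , drop = FALSE]
  records <- validate_records(records)
  shares <- group_shares(nrow(records),
                         sum(records$group == "reexam"),
                         sum(records$group == "baseline_only"))
  grp <- function(g) records[records$group == g, , drop = FALSE]
  part <- records[records$group != "nonparticipant", , drop = FALSE]
  blocks <- list(population = records, nonparticipant = grp("nonparticipant"),
                 baseline_all = part, reexam = grp("reexam"),
                 baseline_only = grp("baseline_only"))

  covs <- covariate_columns(records)
  cell <- function(block, f) if (nrow(block) == 0) NA_real_ else f(block)
  rows <- lapply(covs, function(nm) {
    vals <- vapply(blocks, cell, numeric(1), f = function(b) 100 * mean(b[[nm]]))
    c(list(statistic = nm, kind = "prevalence_percent"), as.list(vals))
  })
  rate_row <- c(list(statistic = "all_cause_rate", kind = "rate_per_10k_py"),
                as.list(vapply(blocks, cell, numeric(1), f = function(b)
                  1e4 * sum(b$event) / sum(b$followup_time))))
  fu_row <- c(list(statistic = "mean_followup", kind = "mean_followup_years"),
              as.list(vapply(blocks, cell, numeric(1), f = function(b)
                mean(b$followup_time))))
  tab <- do.call(rbind, lapply(c(rows, list(rate_row, fu_row)),
                               as.data.frame, stringsAsFactors = FALSE))
  list(table = validate_group_table(tab, where = "summarized records"),
       shares = shares)
}

#' Bias and RMSE of the estimators over simulated replicates
#'
#' Repeatedly simulates cohorts, runs every estimator on the participant
#' data alone, and scores each against the cohort's own truth ledger. This
#' is the validation harness for the claim that the substitution and
#' (especially) extrapolation estimators move participant-based statistics
#' toward the full-population values.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of simulated cohorts.
#' @param seed integer seed; replicate `i` uses `seed + i - 1`.
#' @param statistics which truth statistics to score: covariate prevalences
#'   (always) and/or the all-cause rate.
#' @return A data frame with one row per (statistic, method):
#'   `mean_bias` (estimate minus truth, averaged over replicates) and
#'   `rmse`, for methods `observed_participants`, `baseline_only_proxy`,
#'   `substitution`, `extrapolation`.
#' @examples
#' cfg <- sim_config(n_population = 4000, reexam_noise = 0)
#' recovery_experiment(cfg, n_replicates = 3, seed = 1)
#' @export
recovery_experiment <- function(config, n_replicates, seed = 1,
                                statistics = c("prevalence", "rate")) {
  stopifnot(n_replicates >= 1)
  statistics <- match.arg(statistics, several.ok = TRUE)
  errs <- list()
  for (i in seq_len(n_replicates)) {
    ch <- simulate_cohort(config, seed = seed + i - 1)
    kept <- ch$records[ch$records$excluded_pre_followup == 0, , drop = FALSE]
    part <- kept[kept$group != "nonparticipant", , drop = FALSE]
    # estimators see only participant records plus the invitation counts
    s <- summarize_cohort(part)
    shares <- group_shares(nrow(kept), s$shares$n_reexam,
                           s$shares$n_baseline_only)
    fit <- resist_fit(s$table, shares)
    truth <- c(
      if ("prevalence" %in% statistics) ch$truth$prevalence_percent,
      if ("rate" %in% statistics)
        c(all_cause_rate = ch$truth$rate_per_10k_py))
    idx <- match(names(truth), fit$table$statistic)
    errs[[i]] <- data.frame(
      statistic = rep(names(truth), 4),
      method = rep(c("observed_participants", "baseline_only_proxy",
                     "substitution", "extrapolation"), each = length(truth)),
      error = c(fit$table$observed_participants[idx] - truth,
                fit$table$baseline_only_proxy[idx] - truth,
                fit$table$substitution[idx] - truth,
                fit$table$extrapolation[idx] - truth),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, errs)
  agg <- stats::aggregate(error ~ statistic + method, data = all,
                          FUN = function(e) c(mean_bias = mean(e),
                                              rmse = sqrt(mean(e^2))))
  out <- data.frame(agg[c("statistic", "method")],
                    mean_bias = agg$error[, "mean_bias"],
                    rmse = agg$error[, "rmse"],
                    n_replicates = n_replicates,
                    stringsAsFactors = FALSE)
  out[order(out$statistic, out$method), ]
}
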