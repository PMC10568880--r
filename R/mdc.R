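# Published group-level summaries of the Malmö Diet and Cancer (MDC)
# cohort, shipped as plain-text fixtures. The individual-level register
# data behind them is closed; these printed group columns, together with
# the group counts, are everything the estimators need.

#' Participation-group counts and shares of the MDC invited population
#'
#' The post-exclusion counts of the MDC setting (invitees who had neither
#' died nor emigrated before follow-up start): 65,068 invitees, of whom
#' 21,868 participated in the five-year re-examination and 4,606
#' participated at baseline only.
#'
#' @return For `mdc_counts()`, a named integer vector; for `mdc_shares()`,
#'   the corresponding [group_shares()] object.
#' @examples
#' mdc_shares()
#' @export
mdc_counts <- function() {
  tab <- utils::read.csv(
    system.file("extdata", "mdc_group_counts.csv", package = "contresist"),
    stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$n), tab$group)
}

#' @rdname mdc_counts
#' @export
mdc_shares <- function() {
  n <- mdc_counts()
  group_shares(n[["population"]], n[["reexam"]], n[["baseline_only"]])
}

#' Published MDC group-level summary tables
#'
#' Group-table fixtures transcribed from the published MDC comparison
#' tables:
#'
#' * `which = 1`: 25 background-characteristic prevalences (%), including
#'   the normally unobservable population and non-participant columns from
#'   the register linkage;
#' * `which = 2`: 9 mortality and disease incidence rates (events per
#'   10,000 person-years) plus the group mean follow-up times (years);
#' * `which = 3`: 8 baseline risk-factor prevalences (%) -- smoking
#'   categories, high-risk drinking, body-mass categories -- observed among
#'   participants only.
#'
#' Each file also carries the published `substitution` and `extrapolation`
#' columns as reference values; [resist_fit()] ignores them.
#'
#' @param which table number, 1, 2 or 3.
#' @return A `group_table` data frame (see [read_group_table()]).
#' @examples
#' tab <- mdc_table(1)
#' tab[tab$statistic == "Country of birth: Sweden", ]
#' @export
mdc_table <- function(which = 1) {
  file <- switch(as.character(which),
    "1" = "mdc_table1_background.csv",
    "2" = "mdc_table2_rates.csv",
    "3" = "mdc_table3_risk_factors.csv",
    stop("'which' must be 1, 2 or 3", call. = FALSE))
  read_group_table(system.file("extdata", file, package = "contresist"))
}

#' Published MDC mean-squared-error scores
#'
#' The published representativeness scores: MSE of each group or method
#' column against the full-population column, one set for the
#' background-characteristic prevalences and one for the incidence rates.
#' These were computed from unrounded register data and so are not exactly
#' recoverable from the rounded printed columns; the package's recomputed
#' scores agree closely (see the methods vignette).
#'
#' @return A data frame with columns `table`, `column`, `mse`.
#' @export
mdc_published_mse <- function() {
  utils::read.csv(
    system.file("extdata", "mdc_published_mse.csv", package = "contresist"),
    stringsAsFactors = FALSE)
}

#' Reproduce the derivable columns of the MDC comparison tables
#'
#' Recomputes the substitution and extrapolation columns of all three MDC
#' tables from the printed group columns and integer counts, rounded
#' half-up to the printed precision, alongside the published reference
#' columns.
#'
#' @return A named list of data frames, one per table, each with the
#'   recomputed and published derived columns.
#' @examples
#' reproduce_mdc_tables()$table3[, c("statistic", "substitution",
#'                                   "published_substitution")]
#' @export
reproduce_mdc_tables <- function() {
  shares <- mdc_shares()
  lapply(stats::setNames(nm = c("table1", "table2", "table3")), function(nm) {
    which <- as.integer(substring(nm, 6))
    tab <- mdc_table(which)
    fit <- resist_fit(tab, shares)
    digits <- ifelse(tab$substitution %% 1 == 0, 0, 1)
    ext_digits <- ifelse(tab$extrapolation %% 1 == 0, 0, 1)
    data.frame(
      statistic = tab$statistic, kind = tab$kind,
      substitution = round_half_up(fit$table$substitution, digits),
      published_substitution = tab$substitution,
      extrapolation = round_half_up(fit$table$extrapolation, ext_digits),
      published_extrapolation = tab$extrapolation,
      stringsAsFactors = FALSE)
  })
}
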