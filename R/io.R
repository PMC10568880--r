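# Tabular I/O for group-level summary tables and individual cohort records.
# Both formats are plain comma-delimited UTF-8 text with a header row.

GROUP_COLUMNS <- c("population", "nonparticipant", "baseline_all",
                   "reexam", "baseline_only")

STATISTIC_KINDS <- c("prevalence_percent", "outcome_proportion",
                     "mean_followup_years", "rate_per_10k_py")

GROUP_LABELS <- c("nonparticipant", "baseline_only", "reexam")

# Valid range of a statistic on its stored scale.
kind_range <- function(kind) {
  switch(kind,
    prevalence_percent  = c(0, 100),
    outcome_proportion  = c(0, 1),
    mean_followup_years = c(0, Inf),
    rate_per_10k_py     = c(0, Inf),
    stop(sprintf("unknown statistic kind '%s'", kind), call. = FALSE)
  )
}

#' Read a group-level summary table
#'
#' Reads a delimited table with one row per statistic and one column per
#' participation group. Mandatory columns are `statistic`, `kind`, `reexam`
#' and `baseline_only`; the pooled `baseline_all` and the (normally
#' unobservable) `population` and `nonparticipant` columns are optional, as
#' are any further reference columns. `kind` must be one of
#' `"prevalence_percent"` (stored on the 0--100 scale exactly as printed),
#' `"outcome_proportion"` (0--1), `"mean_followup_years"` or
#' `"rate_per_10k_py"`; conversion between percentage and proportion scales
#' is always explicit, never implicit.
#'
#' @param path path to a comma-delimited UTF-8 text file with a header row.
#' @return A validated `data.frame` of class `c("group_table", "data.frame")`.
#' @examples
#' tab <- mdc_table(3)
#' head(tab)
#' @seealso [write_group_table()], [resist_fit()], [mdc_table()]
#' @export
read_group_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  if (file.size(path) == 0)
    stop(sprintf("'%s' is empty", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  validate_group_table(tab, where = path)
}

#' Write a group-level summary table
#'
#' @param table a `group_table` (or compatible data frame).
#' @param path output path; written as comma-delimited UTF-8 with header.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(table, path) {
  table <- validate_group_table(table)
  utils::write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE, na = "")
  invisible(path)
}

validate_group_table <- function(tab, where = "group table") {
  if (!is.data.frame(tab) || nrow(tab) == 0)
    stop(sprintf("'%s' contains no statistic rows", where), call. = FALSE)
  mandatory <- c("statistic", "kind", "reexam", "baseline_only")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing))
    stop(sprintf("'%s' is missing mandatory column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad_kind <- setdiff(unique(tab$kind), STATISTIC_KINDS)
  if (length(bad_kind))
    stop(sprintf("'%s' has unknown statistic kind(s): %s (rows %s)", where,
                 paste(bad_kind, collapse = ", "),
                 paste(which(tab$kind %in% bad_kind), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(tab$statistic))
    stop(sprintf("'%s' has duplicated statistic names: %s", where,
                 paste(unique(tab$statistic[duplicated(tab$statistic)]),
                       collapse = ", ")), call. = FALSE)
  for (col in intersect(GROUP_COLUMNS, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    unparseable <- !is.na(tab[[col]]) & tab[[col]] != "" & is.na(v)
    if (any(unparseable))
      stop(sprintf("'%s': unparseable cell(s) in column '%s', row(s) %s",
                   where, col, paste(which(unparseable), collapse = ", ")),
           call. = FALSE)
    tab[[col]] <- v
    for (i in seq_len(nrow(tab))) {
      if (is.na(v[i])) next
      rng <- kind_range(tab$kind[i])
      if (v[i] < rng[1] || v[i] > rng[2])
        stop(sprintf(
          "'%s': value %g out of range [%g, %g] for kind '%s' (row %d, column '%s')",
          where, v[i], rng[1], rng[2], tab$kind[i], i, col), call. = FALSE)
    }
  }
  class(tab) <- unique(c("group_table", class(tab)))
  tab
}

#' Read individual-level cohort records
#'
#' Reads one row per invitee with columns `id`, `group` (one of
#' `"nonparticipant"`, `"baseline_only"`, `"reexam"`), `followup_time`
#' (years), `event` (0/1) and optionally `excluded_pre_followup` (0/1); any
#' remaining columns are treated as covariates. Individuals flagged as
#' excluded before follow-up start (deaths/emigrations before the follow-up
#' window opens) are dropped here, once, and the number dropped is reported
#' via `message()` -- mirroring a single load-time exclusion step.
#'
#' @param path path to a comma-delimited UTF-8 text file with a header row.
#' @param max_followup optional administrative maximum follow-up in years;
#'   records exceeding it are rejected.
#' @return A `data.frame` of class `c("cohort_records", "data.frame")` with
#'   the exclusion flag column removed, and an attribute `"n_excluded"`.
#' @seealso [write_individual_records()], [simulate_cohort()]
#' @export
read_individual_records <- function(path, max_followup = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  validate_records(rec, where = path, max_followup = max_followup,
                   drop_excluded = TRUE)
}

#' Write individual-level cohort records
#'
#' @param records a `cohort_records` data frame (or the `records` element of
#'   a [simulate_cohort()] result).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_individual_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

validate_records <- function(rec, where = "records", max_followup = NULL,
                             drop_excluded = FALSE) {
  mandatory <- c("id", "group", "followup_time", "event")
  missing <- setdiff(mandatory, names(rec))
  if (length(missing))
    stop(sprintf("'%s' is missing mandatory column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad_group <- !(rec$group %in% GROUP_LABELS)
  if (any(bad_group))
    stop(sprintf("'%s': unknown group label(s) %s in row(s) %s", where,
                 paste(unique(rec$group[bad_group]), collapse = ", "),
                 paste(utils::head(which(bad_group), 5), collapse = ", ")),
         call. = FALSE)
  if (any(!is.finite(rec$followup_time) | rec$followup_time < 0))
    stop(sprintf("'%s': negative or missing followup_time in row(s) %s", where,
                 paste(utils::head(which(!is.finite(rec$followup_time) |
                                           rec$followup_time < 0), 5),
                       collapse = ", ")), call. = FALSE)
  if (!is.null(max_followup) && any(rec$followup_time > max_followup))
    stop(sprintf("'%s': followup_time exceeds the administrative maximum %g",
                 where, max_followup), call. = FALSE)
  if (!all(rec$event %in% c(0, 1)))
    stop(sprintf("'%s': 'event' must be coded 0/1", where), call. = FALSE)
  n_excluded <- 0L
  if ("excluded_pre_followup" %in% names(rec)) {
    if (!all(rec$excluded_pre_followup %in% c(0, 1)))
      stop(sprintf("'%s': 'excluded_pre_followup' must be coded 0/1", where),
           call. = FALSE)
    if (drop_excluded) {
      n_excluded <- sum(rec$excluded_pre_followup == 1)
      if (n_excluded > 0)
        message(sprintf(
          "%s: dropped %d record(s) with events before follow-up start",
          where, n_excluded))
      rec <- rec[rec$excluded_pre_followup == 0, , drop = FALSE]
      rec$excluded_pre_followup <- NULL
      rownames(rec) <- NULL
    }
  }
  if (nrow(rec) == 0)
    stop(sprintf("'%s': no analyzable records remain", where), call. = FALSE)
  attr(rec, "n_excluded") <- n_excluded
  class(rec) <- unique(c("cohort_records", class(rec)))
  rec
}

# Covariate columns of a record data frame.
covariate_columns <- function(records) {
  setdiff(names(records),
          c("id", "group", "followup_time", "event", "excluded_pre_followup",
            "propensity"))
}
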