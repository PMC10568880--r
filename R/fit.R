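#' Fit continuum-of-resistance population estimators to a group table
#'
#' The central fitting function of the package. Takes a group-level summary
#' table (one row per statistic, one column per participation group; see
#' [read_group_table()] for the schema) together with the population
#' [group_shares()], and computes, for every statistic, the two
#' continuum-of-resistance estimates of its full-population value:
#'
#' * **substitution** -- non-participants are assigned the baseline-only
#'   group's value before recombining via population shares; on the rate
#'   scale the substitution is applied to outcome proportions and mean
#'   follow-up times separately (see [substitute_rate()]);
#' * **extrapolation** -- the two-point line through the re-examination and
#'   pooled-baseline points, evaluated at full participation `x = 1`
#'   (see [fit_extrapolation_line()]); rates are extrapolated directly on
#'   the printed rate scale.
#'
#' The pooled baseline value \eqn{\bar y_b} is by default recomputed from the
#' re-examination and baseline-only cells with integer count weights
#' (person-time weights for rates), which avoids compounding the independent
#' rounding of a printed pooled column; set `pooled = "printed"` to use a
#' `baseline_all` column as-is.
#'
#' For rate rows the proportion/follow-up decomposition needs group mean
#' follow-up times; these are taken from a `mean_followup_years` row of the
#' same table. A missing baseline-only follow-up is backed out from the
#' pooled and re-examination values via [back_out_nonparticipants()]. If no
#' follow-up row is present, rate substitution falls back to count-share
#' weighting of the rates (exact when group follow-ups are equal), with a
#' warning.
#'
#' @param table a `group_table` data frame (or path-read result of
#'   [read_group_table()]).
#' @param shares a [group_shares()] object.
#' @param pooled how to obtain the pooled baseline value for extrapolation:
#'   `"counts"` (default, recompute from the two constituent groups) or
#'   `"printed"` (use the `baseline_all` column).
#' @return An object of class `"resist_fit"`: a list with elements
#'   `table` (statistic, kind, `observed_participants`,
#'   `baseline_only_proxy`, `substitution`, `extrapolation`, `clipped`),
#'   `lines` (per-statistic intercepts and slopes), `shares`, and `input`
#'   (the validated input table). Extrapolated values are clipped into the
#'   statistic's valid range and flagged; raw values are kept in
#'   `table$extrapolation_raw`.
#' @examples
#' fit <- resist_fit(mdc_table(3), mdc_shares())
#' fit
#' coef(fit)["Smoking: yes, regularly", ]
#' predict(fit, x = c(0.5, 1))[1:3, ]
#' @seealso [summary.resist_fit()] for MSE-vs-population scoring,
#'   [comparison_table()] for a flat all-columns table.
#' @export
resist_fit <- function(table, shares, pooled = c("counts", "printed")) {
  pooled <- match.arg(pooled)
  assert_group_shares(shares)
  table <- validate_group_table(table)

  fu <- followup_info(table, shares)
  # a follow-up row may carry a backed-out rather than printed baseline-only
  # cell; fill it in so the row is estimable like any other mean
  fu_rows <- which(table$kind == "mean_followup_years")
  if (!is.null(fu) && length(fu_rows) && is.na(table$baseline_only[fu_rows[1]]))
    table$baseline_only[fu_rows[1]] <- fu$fu_br
  if (is.null(fu) && any(table$kind == "rate_per_10k_py"))
    warning("no usable 'mean_followup_years' row: rate substitution falls back to count-share weighting of the rates",
            call. = FALSE)
  n <- nrow(table)
  obs <- bop <- sub <- ext_raw <- ext <- alpha <- beta <- numeric(n)
  clipped <- logical(n)

  for (i in seq_len(n)) {
    kind <- table$kind[i]
    y_r <- table$reexam[i]
    y_br <- table$baseline_only[i]
    if (is.na(y_r) || is.na(y_br))
      stop(sprintf("statistic '%s' (row %d) lacks a reexam or baseline_only value",
                   table$statistic[i], i), call. = FALSE)
    rng <- kind_range(kind)

    if (kind == "rate_per_10k_py") {
      if (!is.null(fu)) {
        sub[i] <- substitute_rate(shares,
                                  prop_r = y_r * fu$fu_r / 1e4,
                                  prop_br = y_br * fu$fu_br / 1e4,
                                  fu_r = fu$fu_r, fu_br = fu$fu_br)
        # person-time-weighted pooled baseline rate
        w_r <- shares$n_reexam * fu$fu_r
        w_br <- shares$n_baseline_only * fu$fu_br
        y_b_counts <- (w_r * y_r + w_br * y_br) / (w_r + w_br)
      } else {
        sub[i] <- substitution_estimate(shares, y_r, y_br)
        y_b_counts <- pooled_baseline(shares, y_r, y_br)
      }
    } else {
      sub[i] <- substitution_estimate(shares, y_r, y_br)
      y_b_counts <- pooled_baseline(shares, y_r, y_br)
    }

    y_b <- if (pooled == "printed") {
      if (!("baseline_all" %in% names(table)) || is.na(table$baseline_all[i]))
        stop(sprintf("pooled = \"printed\" but no baseline_all value for '%s'",
                     table$statistic[i]), call. = FALSE)
      table$baseline_all[i]
    } else y_b_counts

    line <- fit_extrapolation_line(shares, y_r, y_b)
    est <- extrapolation_estimate(line, lower = rng[1], upper = rng[2])
    alpha[i] <- line$alpha
    beta[i] <- line$beta
    ext_raw[i] <- est$raw
    ext[i] <- est$value
    clipped[i] <- est$clipped
    obs[i] <- y_b
    bop[i] <- y_br
  }

  out <- list(
    table = data.frame(statistic = table$statistic, kind = table$kind,
                       observed_participants = obs,
                       baseline_only_proxy = bop,
                       substitution = sub,
                       extrapolation = ext,
                       extrapolation_raw = ext_raw,
                       clipped = clipped,
                       stringsAsFactors = FALSE),
    lines = data.frame(statistic = table$statistic, alpha = alpha, beta = beta,
                       stringsAsFactors = FALSE),
    shares = shares,
    pooled = pooled,
    input = table,
    call = match.call()
  )
  class(out) <- "resist_fit"
  out
}

# Count-weighted pooled baseline value from the two constituent groups.
pooled_baseline <- function(shares, y_r, y_br) {
  (shares$n_reexam * y_r + shares$n_baseline_only * y_br) /
    (shares$n_reexam + shares$n_baseline_only)
}

# Group mean follow-up times for the rate-substitution path, or NULL.
followup_info <- function(table, shares) {
  idx <- which(table$kind == "mean_followup_years")
  if (!length(idx)) return(NULL)
  row <- table[idx[1], ]
  fu_r <- row$reexam
  fu_br <- row$baseline_only
  if (is.na(fu_br)) {
    if (!("baseline_all" %in% names(row)) || is.na(row$baseline_all))
      return(NULL)
    fu_br <- back_out_nonparticipants(
      n_total = shares$n_reexam + shares$n_baseline_only,
      y_pop = row$baseline_all,
      n_b = shares$n_reexam, y_b = fu_r, lower = 0)
  }
  if (is.na(fu_r)) return(NULL)
  list(fu_r = fu_r, fu_br = fu_br)
}

#' @export
print.resist_fit <- function(x, digits = 3, ...) {
  cat("Continuum-of-resistance population estimates\n")
  cat(sprintf("  shares: x_r = %.4f, x_b = %.4f (n = %d)\n",
              x$shares$x_r, x$shares$x_b, x$shares$n_total))
  cat(sprintf("  pooled baseline from: %s\n",
              if (x$pooled == "counts") "group counts" else "printed column"))
  tab <- x$table[, c("statistic", "kind", "observed_participants",
                     "baseline_only_proxy", "substitution", "extrapolation")]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  if (any(x$table$clipped))
    cat(sprintf("  note: %d extrapolated value(s) clipped into range\n",
                sum(x$table$clipped)))
  invisible(x)
}

#' @export
coef.resist_fit <- function(object, ...) {
  m <- as.matrix(object$lines[, c("alpha", "beta")])
  rownames(m) <- object$lines$statistic
  m
}

#' Evaluate the fitted extrapolation lines at participation shares
#'
#' @param object a [resist_fit()] object.
#' @param x participation share(s) in (0, 1]; `x = 1` gives the (unclipped)
#'   full-population extrapolation.
#' @param ... unused.
#' @return A statistics-by-`x` matrix of line values.
#' @export
predict.resist_fit <- function(object, x = 1, ...) {
  m <- outer(object$lines$beta, x) + object$lines$alpha
  dimnames(m) <- list(object$lines$statistic, format(x))
  m
}

#' Summarize a continuum-of-resistance fit
#'
#' When the input table carries a `population` column (observable only in
#' record-linkage settings or in simulation), each candidate column --
#' the pooled baseline participants, the re-examination group, the
#' baseline-only proxy group, and the substitution and extrapolation
#' estimates -- is scored by its mean squared error against the population
#' column. MSEs are computed separately per statistic kind (squared
#' percentage points for prevalences, squared rate units for rates) and are
#' never pooled across scales.
#'
#' @param object a [resist_fit()] object.
#' @param ... unused.
#' @return An object of class `"summary.resist_fit"` with the estimate table
#'   and, when population values exist, a data frame `mse` with one row per
#'   (kind, candidate column).
#' @export
summary.resist_fit <- function(object, ...) {
  input <- object$input
  mse <- NULL
  if ("population" %in% names(input) && any(!is.na(input$population))) {
    candidates <- list(
      baseline_all = if ("baseline_all" %in% names(input)) input$baseline_all,
      reexam = input$reexam,
      baseline_only = input$baseline_only,
      substitution = object$table$substitution,
      extrapolation = object$table$extrapolation
    )
    candidates <- Filter(Negate(is.null), candidates)
    rows <- list()
    for (kind in unique(input$kind)) {
      if (kind == "mean_followup_years") next
      keep <- input$kind == kind & !is.na(input$population)
      if (sum(keep) == 0) next
      ref <- stats::setNames(input$population[keep], input$statistic[keep])
      for (cand in names(candidates)) {
        v <- stats::setNames(candidates[[cand]][keep], input$statistic[keep])
        if (any(is.na(v))) next
        rows[[length(rows) + 1L]] <- data.frame(
          kind = kind, column = cand,
          mse = mse_vs_population(v, ref)$mse,
          n_statistics = sum(keep), stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) mse <- do.call(rbind, rows)
  }
  structure(list(fit = object, mse = mse), class = "summary.resist_fit")
}

#' @export
print.summary.resist_fit <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  if (!is.null(x$mse)) {
    cat("\nMean squared error vs. full population (per statistic kind):\n")
    m <- x$mse
    m$mse <- signif(m$mse, digits + 1)
    print(m, row.names = FALSE)
  } else {
    cat("\n(no population column: MSE scoring unavailable)\n")
  }
  invisible(x)
}

#' Plot the fitted extrapolation lines
#'
#' Draws, for each selected statistic, the line through the re-examination
#' point (`x_r`) and the pooled-baseline point (`x_b`), extended to full
#' participation `x = 1`, with the observed points marked. A dashed vertical
#' line sits at `x = 1`, where the extrapolation estimator reads off its
#' value.
#'
#' @param x a [resist_fit()] object.
#' @param statistics statistic names to draw (default: up to 6).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.resist_fit <- function(x, statistics = NULL, ...) {
  ln <- x$lines
  if (is.null(statistics)) statistics <- utils::head(ln$statistic, 6)
  ln <- ln[ln$statistic %in% statistics, , drop = FALSE]
  if (!nrow(ln)) stop("no matching statistics to plot", call. = FALSE)
  xs <- seq(x$shares$x_r, 1, length.out = 50)
  ys <- t(outer(ln$beta, xs) + ln$alpha)
  graphics::matplot(xs, ys, type = "l", lty = 1,
                    xlab = "participation share x",
                    ylab = "statistic value", ...)
  for (j in seq_len(nrow(ln))) {
    graphics::points(c(x$shares$x_r, x$shares$x_b),
                     ln$alpha[j] + ln$beta[j] * c(x$shares$x_r, x$shares$x_b),
                     pch = 19, col = j)
  }
  graphics::abline(v = 1, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = ln$statistic, lty = 1, bty = "n",
                   col = seq_len(nrow(ln)), cex = 0.8)
  invisible(x)
}
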