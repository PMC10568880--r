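# Representativeness scoring and assembly of comparison tables.

#' Mean squared error of a candidate column against the population
#'
#' The representativeness score used throughout: the unweighted mean of
#' squared differences between a candidate set of statistics (a participation
#' group's observed values, or a model's estimates) and the corresponding
#' full-population values. Units are squared units of whatever scale the
#' statistics are on; scores on different scales (percentage points vs. rate
#' units) must never be pooled.
#'
#' @param candidate named numeric vector of candidate values.
#' @param population named numeric vector of population values over the same
#'   statistic names.
#' @return An object of class `"resist_mse"`: list with `mse`,
#'   `n_statistics` and the per-statistic squared errors `sq_err`.
#' @examples
#' mse_vs_population(c(a = 3, b = 4), c(a = 0, b = 0))$mse  # 12.5
#' @export
mse_vs_population <- function(candidate, population) {
  if (is.null(names(candidate)) || is.null(names(population)))
    stop("'candidate' and 'population' must be named vectors", call. = FALSE)
  miss <- setdiff(names(population), names(candidate))
  extra <- setdiff(names(candidate), names(population))
  if (length(miss) || length(extra))
    stop(sprintf("statistic keys do not match%s%s",
                 if (length(miss)) paste0("; missing from candidate: ",
                                          paste(miss, collapse = ", ")) else "",
                 if (length(extra)) paste0("; missing from population: ",
                                           paste(extra, collapse = ", ")) else ""),
         call. = FALSE)
  sq <- (candidate[names(population)] - population)^2
  structure(list(mse = mean(sq), n_statistics = length(sq), sq_err = sq),
            class = "resist_mse")
}

#' @export
print.resist_mse <- function(x, ...) {
  cat(sprintf("MSE = %.4g over %d statistics\n", x$mse, x$n_statistics))
  invisible(x)
}

#' Assemble a full comparison table
#'
#' Binds the observed group columns of the input table with the substitution
#' and extrapolation estimates from [resist_fit()], one row per statistic.
#' When a `population` column is present, per-kind MSE rows (statistic name
#' `"mse"`) are appended for every scorable column.
#'
#' @inheritParams resist_fit
#' @param ... passed on to [resist_fit()].
#' @return A plain `data.frame` with the observed columns that exist in the
#'   input plus `substitution`, `extrapolation` and `clipped`.
#' @examples
#' head(comparison_table(mdc_table(1), mdc_shares()))
#' @export
comparison_table <- function(table, shares, ...) {
  fit <- resist_fit(table, shares, ...)
  input <- fit$input
  keep <- intersect(c("statistic", "kind", GROUP_COLUMNS), names(input))
  out <- cbind(input[, keep, drop = FALSE],
               substitution = fit$table$substitution,
               extrapolation = fit$table$extrapolation,
               clipped = fit$table$clipped)
  s <- summary(fit)
  if (!is.null(s$mse)) {
    for (kind in unique(s$mse$kind)) {
      block <- s$mse[s$mse$kind == kind, ]
      row <- out[1, , drop = FALSE]
      row[1, ] <- NA
      row$statistic <- "mse"
      row$kind <- kind
      for (j in seq_len(nrow(block))) {
        col <- block$column[j]
        if (col %in% names(row)) row[[col]] <- block$mse[j]
      }
      row$clipped <- NA
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}
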