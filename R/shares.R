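#' Participation-group shares of an invited population
#'
#' Partitions an invited ("background") population into three nested
#' participation groups -- re-examination participants, baseline-only
#' participants, and baseline non-participants -- and derives the population
#' shares used by the continuum-of-resistance estimators: the mixture weights
#' \eqn{\omega_r} and \eqn{\omega_{b \setminus r}} of the population
#' decomposition, and the extrapolation abscissae \eqn{x_r} (share
#' participating in the re-examination) and \eqn{x_b} (share participating at
#' baseline at all).
#'
#' Shares are always computed from integer counts, never from pre-rounded
#' percentages: the extrapolation step multiplies differences between group
#' statistics by roughly \eqn{(1 - x_b)/(x_b - x_r)} (about 8 in the MDC
#' setting, see [mdc_shares()]), so precision of the shares matters.
#'
#' @param n_total number of invitees in the background population.
#' @param n_reexam number who participated in the re-examination.
#' @param n_baseline_only number who participated at baseline but not in the
#'   re-examination.
#'
#' @return An object of class `"group_shares"`: a list with the counts
#'   (`n_total`, `n_reexam`, `n_baseline_only`, `n_nonparticipant`), the
#'   mixture weights `omega_r` and `omega_br`, and the abscissae `x_r`
#'   (`= omega_r`) and `x_b` (`= omega_r + omega_br`).
#'
#' @examples
#' # the post-exclusion MDC counts
#' group_shares(65068, 21868, 4606)
#'
#' @seealso [decompose_population()], [fit_extrapolation_line()], [mdc_shares()]
#' @export
group_shares <- function(n_total, n_reexam, n_baseline_only) {
  counts <- list(n_total = n_total, n_reexam = n_reexam,
                 n_baseline_only = n_baseline_only)
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v < 0 ||
        v != trunc(v)) {
      stop(sprintf("'%s' must be a single non-negative integer count", nm),
           call. = FALSE)
    }
  }
  if (n_total <= 0)
    stop("'n_total' must be positive: the invited population is empty",
         call. = FALSE)
  if (n_reexam + n_baseline_only > n_total)
    stop(sprintf(
      "participant counts exceed the population: 'n_reexam' + 'n_baseline_only' = %d > 'n_total' = %d",
      n_reexam + n_baseline_only, n_total), call. = FALSE)
  if (n_reexam == 0)
    stop("'n_reexam' must be positive: the re-examination group anchors both estimators",
         call. = FALSE)

  omega_r <- n_reexam / n_total
  omega_br <- n_baseline_only / n_total
  structure(list(
    n_total = n_total,
    n_reexam = n_reexam,
    n_baseline_only = n_baseline_only,
    n_nonparticipant = n_total - n_reexam - n_baseline_only,
    omega_r = omega_r,
    omega_br = omega_br,
    x_r = omega_r,
    x_b = omega_r + omega_br
  ), class = "group_shares")
}

#' @export
print.group_shares <- function(x, ...) {
  cat("Participation-group shares\n")
  cat(sprintf("  invited population: %d\n", x$n_total))
  cat(sprintf("  re-examination participants: %d (omega_r = %.4f)\n",
              x$n_reexam, x$omega_r))
  cat(sprintf("  baseline-only participants:  %d (omega_br = %.4f)\n",
              x$n_baseline_only, x$omega_br))
  cat(sprintf("  baseline non-participants:   %d (share = %.4f)\n",
              x$n_nonparticipant, 1 - x$x_b))
  cat(sprintf("  abscissae: x_r = %.4f, x_b = %.4f\n", x$x_r, x$x_b))
  invisible(x)
}

is_group_shares <- function(x) inherits(x, "group_shares")

assert_group_shares <- function(x) {
  if (!is_group_shares(x))
    stop("'shares' must be a 'group_shares' object (see ?group_shares)",
         call. = FALSE)
  invisible(x)
}
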