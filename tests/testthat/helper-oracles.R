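# Shared oracles and fixture builders. Oracles are deliberately independent
# of the package's implementation paths.

# Empirical survival function: with no censoring the product-limit estimate
# must equal this exactly.
empirical_survival <- function(event_times, t) {
  vapply(t, function(tt) mean(event_times > tt), numeric(1))
}

# Printed-precision unit of a published cell (1 for integers, 0.1 for one
# decimal), used to express rounding tolerances in units of the last digit.
printed_unit <- function(x) ifelse(x %% 1 == 0, 1, 0.1)

mdc_sh <- function() group_shares(65068, 21868, 4606)

# A small valid individual-record data frame.
toy_records <- function(n = 12, seed = 42) {
  set.seed(seed)
  data.frame(
    id = seq_len(n),
    group = sample(c("nonparticipant", "baseline_only", "reexam"), n,
                   replace = TRUE, prob = c(0.5, 0.2, 0.3)),
    smoker = rbinom(n, 1, 0.3),
    followup_time = round(runif(n, 0.5, 15), 3),
    event = rbinom(n, 1, 0.4),
    stringsAsFactors = FALSE
  )
}
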