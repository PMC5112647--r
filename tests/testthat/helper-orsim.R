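# a fully degenerate policy: every activity at its base-case mean, no
# cancellations -- the hand-computable schedule used as deterministic oracle
degenerate_policy <- function(..., p_other_cancel = 0) {
  or_policy(
    p_other_cancel = p_other_cancel,
    distributions = list(
      procedure_duration = dist_spec("fixed", 72.9),
      turnover = dist_spec("fixed", 35.6),
      first_patient_delay = dist_spec("fixed", 10),
      cleanup = dist_spec("fixed", 15)),
    ...)
}

base_policy <- or_policy()

deep_policy <- function() {
  or_policy(procedures_per_day = 3,
            distributions = list(
              procedure_duration =
                dist_spec("lognormal_mean_sd",
                          c(145, scaled_sd(145, 72.9, 29.2))),
              turnover = dist_spec("shifted_exponential", c(10, 25.6)),
              first_patient_delay = dist_spec("discrete_cdf",
                                              c(0.5, 5, 1, 15)),
              cleanup = dist_spec("triangular", c(7.5, 15, 22.5))))
}
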