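#' Simulate one month for one reversal arm
#'
#' Runs [simulate_day()] over the policy's working days and tallies the
#' monthly outcome measures. Because all randomness flows through
#' purpose-keyed substreams of `(master seed, replication, day)`, calling
#' this function for two different arms with the same streams and
#' replication index reuses *identical* random inputs — the common random
#' numbers that make paired comparisons sharp.
#'
#' @param policy an [or_policy()].
#' @param arm a [reversal_arm()].
#' @param p_verified probability a patient is verified to full neuromuscular
#'   recovery before extubation.
#' @param streams an [or_streams()] object.
#' @param replication replication (simulated month) index.
#' @param risks a [complication_risks()].
#' @param keep_days if `TRUE`, the per-day `or_day` objects are retained in
#'   `$days`.
#' @return an object of class `or_month`: a list with `$summary`, a named
#'   numeric vector with elements `procedures_performed` (scheduled +
#'   emergency + semi-emergency), `scheduled_performed`, `cancelled_time`,
#'   `cancelled_other`, `overtime_hours`, `days_complete`,
#'   `pct_days_complete`, `rnmb_cases`, `hypoxemia_cases`, `airway_cases`,
#'   and `minutes_saved_per_day` (applied per-procedure time reductions
#'   summed over performed procedures, divided by working days).
#' @export
run_month <- function(policy, arm, p_verified = 0, streams,
                      replication = 1L, risks = complication_risks(),
                      keep_days = FALSE) {
  stopifnot(inherits(policy, "or_policy"), inherits(streams, "or_streams"))
  nd <- policy$working_days
  performed <- 0; sched_perf <- 0; canc_t <- 0; canc_o <- 0
  overtime <- 0; complete <- 0
  rnmb <- 0; hyp <- 0; air <- 0; saved <- 0
  days <- if (keep_days) vector("list", nd) else NULL
  for (d in seq_len(nd)) {
    dy <- simulate_day(policy, arm, p_verified, streams,
                       replication = replication, day = d, risks = risks)
    p <- dy$procedures
    is_perf <- p$status == "performed"
    performed <- performed + sum(is_perf)
    sched_perf <- sched_perf + sum(is_perf & p$kind == "scheduled")
    canc_t <- canc_t + sum(p$status == "cancelled_time")
    canc_o <- canc_o + sum(p$status == "cancelled_other")
    overtime <- overtime + dy$overtime_hours_paid
    complete <- complete + dy$completed_within_day
    rnmb <- rnmb + sum(p$rnmb)
    hyp <- hyp + sum(p$hypoxemia)
    air <- air + sum(p$airway)
    saved <- saved +
      sum(p$drawn_duration[is_perf] - p$effective_duration[is_perf])
    if (keep_days) days[[d]] <- dy
  }
  out <- list(summary = c(
    procedures_performed = performed,
    scheduled_performed = sched_perf,
    cancelled_time = canc_t,
    cancelled_other = canc_o,
    overtime_hours = overtime,
    days_complete = complete,
    pct_days_complete = 100 * complete / nd,
    rnmb_cases = rnmb,
    hypoxemia_cases = hyp,
    airway_cases = air,
    minutes_saved_per_day = saved / nd
  ), days = days, replication = replication, arm = arm$name,
  p_verified = p_verified)
  class(out) <- "or_month"
  out
}

#' @export
print.or_month <- function(x, ...) {
  cat("<or_month>", x$arm, "arm, replication", x$replication,
      sprintf("(%.0f%% verified)\n", 100 * x$p_verified))
  print(round(x$summary, 2))
  invisible(x)
}

#' Per-day event log of a simulated month
#'
#' Binds the per-day procedure records of a month simulated with
#' `keep_days = TRUE` into one data frame suitable for writing as CSV.
#'
#' @param month an `or_month` with retained days.
#' @return data frame with a leading `day` column.
#' @export
event_log <- function(month) {
  stopifnot(inherits(month, "or_month"))
  if (is.null(month$days))
    stop("event_log needs a month run with keep_days = TRUE", call. = FALSE)
  out <- do.call(rbind, lapply(seq_along(month$days), function(d)
    cbind(day = d, month$days[[d]]$procedures)))
  rownames(out) <- NULL
  out
}
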