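#' Time-over-run cancellation rule
#'
#' Decides whether a procedure proposed to start at `proposed_start` (minutes
#' from the day start) is cancelled for lack of OR time:
#' * `no_start_after_end` — cancel iff the start is at or after the
#'   regular-day end (the half-open boundary: starting exactly at the end is
#'   cancelled);
#' * `cancel_if_lt_half_completable` — cancel iff less than 50% of the
#'   procedure fits in the remaining regular day;
#' * `never_cancel` — never cancel for time.
#'
#' @param cancel_policy policy string, or an [or_policy()] from which it and
#'   the day length are taken.
#' @param proposed_start proposed start, minutes from day start (>= 0).
#' @param drawn_duration the duration the procedure would take, minutes (> 0).
#' @param regular_day_length regular OR day length in minutes (default 510).
#' @return logical flag.
#' @examples
#' should_cancel_for_time("no_start_after_end", 509, 80, 510)            # FALSE
#' should_cancel_for_time("cancel_if_lt_half_completable", 480, 100, 510) # TRUE
#' @export
should_cancel_for_time <- function(cancel_policy, proposed_start,
                                   drawn_duration,
                                   regular_day_length = 510) {
  if (inherits(cancel_policy, "or_policy")) {
    regular_day_length <- cancel_policy$regular_day_length
    cancel_policy <- cancel_policy$cancel_policy
  }
  stopifnot(proposed_start >= 0, drawn_duration > 0)
  switch(cancel_policy,
    no_start_after_end = proposed_start >= regular_day_length,
    cancel_if_lt_half_completable =
      (regular_day_length - proposed_start) / drawn_duration < 0.5,
    never_cancel = FALSE,
    stop("unknown cancel_policy: ", cancel_policy, call. = FALSE))
}

#' Paid staff overtime for one day
#'
#' Overtime is paid, to all eligible staff simultaneously, in fixed-minute
#' increments rounded up: `ceil(max(0, day_close - regular_day_length) /
#' increment)` blocks, each worth `increment/60` hours per staff member.
#'
#' @param day_close minute at which the OR closes (last activity + cleanup).
#' @param regular_day_length regular OR day length, minutes.
#' @param increment minutes per paid block (> 0).
#' @param staff number of staff paid overtime.
#' @return total paid overtime in person-hours.
#' @examples
#' paid_overtime_hours(511, 510, 30, 5)  # 2.5 h: 1 block x 0.5 h x 5 staff
#' paid_overtime_hours(575, 510, 30, 5)  # 7.5 h: 65 min -> 3 blocks
#' @export
paid_overtime_hours <- function(day_close, regular_day_length = 510,
                                increment = 30, staff = 5L) {
  stopifnot(day_close >= 0, regular_day_length >= 0, increment > 0,
            staff >= 0)
  overrun <- max(0, day_close - regular_day_length)
  ceiling(overrun / increment) * (increment / 60) * staff
}

# Pre-generate every uniform one simulated day can consume, keyed by purpose
# substream. Both arms of a paired run receive this same object, and each
# uniform has a fixed role (e.g., the turnover *before scheduled slot i*), so
# common random numbers survive even when the arms' cancellation patterns
# diverge. Patient-level uniforms are laid out as
# [scheduled 1..n, emergency 1..n, semi-emergency] (2n + 1 slots).
gen_day_draws <- function(streams, policy, replication, day) {
  n <- policy$procedures_per_day
  np <- 2L * n + 1L
  list(
    first_delay = stream_uniforms(streams, "first_patient_delay", 1L,
                                  replication, day),
    duration = stream_uniforms(streams, "procedure_duration", n,
                               replication, day),
    # turnover layout: [before emergency i] x n, [before slot i] x n, semi
    turnover = stream_uniforms(streams, "turnover", np, replication, day),
    cleanup = stream_uniforms(streams, "cleanup", 1L, replication, day),
    other_cancel = stream_uniforms(streams, "other_cancel", n,
                                   replication, day),
    emergency = stream_uniforms(streams, "emergency", n, replication, day),
    emergency_duration = stream_uniforms(streams, "emergency_duration", n,
                                         replication, day),
    semi_emergency = stream_uniforms(streams, "semi_emergency", 2L,
                                     replication, day),
    verification = stream_uniforms(streams, "verification", np,
                                   replication, day),
    rnmb = stream_uniforms(streams, "rnmb", np, replication, day),
    hypoxemia = stream_uniforms(streams, "hypoxemia", np, replication, day),
    airway = stream_uniforms(streams, "airway", np, replication, day)
  )
}

#' Simulate one operating-room day
#'
#' Plays out one OR day under a scheduling policy for one reversal arm: the
#' first patient arrives after a stochastic delay; each scheduled slot may be
#' preceded by an inserted emergency case, may be cancelled for lack of OR
#' time (evaluated at its proposed start with its arm-effective duration), or
#' cancelled for other reasons (consuming its drawn duration plus turnover as
#' idle time unless the policy moves the next case up); performed procedures
#' run for `max(1, drawn duration + arm delta)` minutes with a turnover
#' between consecutive activities. A semi-emergency case may be appended
#' after the last slot; cleanup closes the day, after which paid overtime is
#' computed. Every performed patient receives verification, residual
#' blockade, and complication draws.
#'
#' `draws` may be supplied directly (both arms of a paired comparison must
#' share one object); otherwise it is generated from `streams` and the
#' `(replication, day)` key.
#'
#' @param policy an [or_policy()].
#' @param arm a [reversal_arm()].
#' @param p_verified probability a patient is verified to full neuromuscular
#'   recovery before extubation.
#' @param streams an [or_streams()] object (ignored if `draws` given).
#' @param replication,day indices keying the substreams.
#' @param risks a [complication_risks()].
#' @param draws optional pre-generated draw set (internal; shared across
#'   arms).
#' @return a list of class `or_day` with elements `procedures` (a data frame
#'   with one row per scheduled/emergency/semi-emergency case: `slot_index`,
#'   `kind`, `is_emergency`, `status`, `start_min`, `end_min`,
#'   `drawn_duration`, `effective_duration`, `verified`, `rnmb`, `hypoxemia`,
#'   `airway`), `last_procedure_end`, `day_close`, `overtime_hours_paid` and
#'   `completed_within_day` (all procedures done, day closed within the
#'   regular day).
#' @export
simulate_day <- function(policy, arm, p_verified, streams = NULL,
                         replication = 1L, day = 1L,
                         risks = complication_risks(), draws = NULL) {
  stopifnot(inherits(policy, "or_policy"), inherits(arm, "reversal_arm"))
  if (p_verified < 0 || p_verified > 1)
    stop("p_verified must be in [0, 1]", call. = FALSE)
  if (is.null(draws)) {
    if (is.null(streams))
      stop("either 'streams' or 'draws' must be supplied", call. = FALSE)
    draws <- gen_day_draws(streams, policy, replication, day)
  }
  n <- policy$procedures_per_day
  L <- policy$regular_day_length
  dists <- policy$distributions

  delay <- dist_quantile(dists$first_patient_delay, draws$first_delay)
  durs <- dist_quantile(dists$procedure_duration, draws$duration)
  turns <- dist_quantile(dists$turnover, draws$turnover)
  cleanup <- dist_quantile(dists$cleanup, draws$cleanup)
  emerg_durs <- dist_quantile(dists$procedure_duration,
                              draws$emergency_duration)
  semi_dur <- dist_quantile(dists$procedure_duration,
                            draws$semi_emergency[2])
  verified <- assign_verified(p_verified, draws$verification)
  delta <- ifelse(verified, arm$delta_verified, arm$delta_unverified)

  nrec <- 2L * n + 1L
  slot_index <- rep(NA_integer_, nrec)
  kind <- character(nrec)
  status <- character(nrec)
  start_min <- rep(NA_real_, nrec)
  end_min <- rep(NA_real_, nrec)
  drawn <- rep(NA_real_, nrec)
  effective <- rep(NA_real_, nrec)
  ver_out <- rep(NA, nrec)
  k <- 0L

  clock <- delay
  first <- TRUE
  # patient index p into the [scheduled, emergency, semi] uniform layout
  perform <- function(p, dur) {
    eff <- max(1, dur + delta[p])
    list(eff = eff, verified = verified[p])
  }

  for (i in seq_len(n)) {
    if (draws$emergency[i] < policy$p_emergency) {
      p <- n + i
      prop <- clock + if (first) 0 else turns[i]
      pe <- perform(p, emerg_durs[i])
      k <- k + 1L
      slot_index[k] <- i; kind[k] <- "emergency"; status[k] <- "performed"
      start_min[k] <- prop; end_min[k] <- prop + pe$eff
      drawn[k] <- emerg_durs[i]; effective[k] <- pe$eff
      ver_out[k] <- pe$verified
      clock <- prop + pe$eff
      first <- FALSE
    }
    prop <- clock + if (first) 0 else turns[n + i]
    eff_i <- max(1, durs[i] + delta[i])
    k <- k + 1L
    slot_index[k] <- i; kind[k] <- "scheduled"
    drawn[k] <- durs[i]
    if (should_cancel_for_time(policy$cancel_policy, prop, eff_i, L)) {
      status[k] <- "cancelled_time"
    } else if (draws$other_cancel[i] < policy$p_other_cancel) {
      status[k] <- "cancelled_other"
      if (!policy$move_up_on_cancel) {
        clock <- prop + durs[i]
        first <- FALSE
      }
    } else {
      status[k] <- "performed"
      start_min[k] <- prop; end_min[k] <- prop + eff_i
      effective[k] <- eff_i
      ver_out[k] <- verified[i]
      clock <- prop + eff_i
      first <- FALSE
    }
  }

  if (draws$semi_emergency[1] < policy$p_semi_emergency) {
    p <- 2L * n + 1L
    prop <- clock + if (first) 0 else turns[p]
    pe <- perform(p, semi_dur)
    k <- k + 1L
    slot_index[k] <- NA_integer_; kind[k] <- "semi_emergency"
    status[k] <- "performed"
    start_min[k] <- prop; end_min[k] <- prop + pe$eff
    drawn[k] <- semi_dur; effective[k] <- pe$eff
    ver_out[k] <- pe$verified
    clock <- prop + pe$eff
  }

  idx <- seq_len(k)
  # clinical cascade, patient-level uniforms aligned to the shared layout
  pat <- ifelse(kind[idx] == "scheduled", slot_index[idx],
                ifelse(kind[idx] == "emergency", n + slot_index[idx],
                       2L * n + 1L))
  performed <- status[idx] == "performed"
  rnmb <- rep(FALSE, k); hyp <- rep(FALSE, k); air <- rep(FALSE, k)
  if (any(performed)) {
    pp <- pat[performed]
    rnmb[performed] <- rnmb_event(arm, verified[pp], draws$rnmb[pp])
    comp <- complication_events(rnmb[performed], risks,
                                draws$hypoxemia[pp], draws$airway[pp])
    hyp[performed] <- comp$hypoxemia
    air[performed] <- comp$airway
  }

  n_cancel_time <- sum(status[idx] == "cancelled_time")
  last_end <- clock
  day_close <- clock + cleanup
  structure(list(
    procedures = data.frame(
      slot_index = slot_index[idx], kind = kind[idx],
      is_emergency = kind[idx] != "scheduled", status = status[idx],
      start_min = start_min[idx], end_min = end_min[idx],
      drawn_duration = drawn[idx], effective_duration = effective[idx],
      verified = ver_out[idx], rnmb = rnmb, hypoxemia = hyp, airway = air,
      stringsAsFactors = FALSE),
    last_procedure_end = last_end,
    day_close = day_close,
    overtime_hours_paid = paid_overtime_hours(
      day_close, L, policy$overtime_increment, policy$overtime_staff),
    completed_within_day = n_cancel_time == 0L && day_close <= L
  ), class = "or_day")
}

#' @export
print.or_day <- function(x, ...) {
  p <- x$procedures
  cat("<or_day>", sum(p$status == "performed"), "performed,",
      sum(p$status == "cancelled_time"), "cancelled (time),",
      sum(p$status == "cancelled_other"), "cancelled (other)\n")
  cat("  day close at minute", round(x$day_close, 1), "-",
      if (x$completed_within_day) "completed within regular day"
      else "ran over / incomplete",
      sprintf("(%.1f h overtime)\n", x$overtime_hours_paid))
  invisible(x)
}
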