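#' Parse an "HH:MM" clock time to minutes since midnight
#'
#' @param x a string like `"07:30"` / `"16:00"`, or a number already in
#'   minutes (returned unchanged).
#' @return minutes since midnight.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.double(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L)
    stop("clock time must be \"HH:MM\" (got \"", x, "\")", call. = FALSE)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23 || mi > 59)
    stop("clock time out of range: \"", x, "\"", call. = FALSE)
  h * 60 + mi
}

#' Operating-room scheduling policy
#'
#' Bundles the hospital/OR rules governing one simulated day: the regular-day
#' boundaries, the number of scheduled procedures, the cancellation policy
#' when OR time runs out, the other-reason cancellation probability,
#' emergency insertion rates, the overtime pay rule, and the stochastic
#' duration specifications for each activity. Defaults are the base-case
#' configuration of a Canadian hospital OR: a 07:30--16:00 day (510 regular
#' minutes), 5 procedures/day over 21 working days, 10.7% other-reason
#' cancellations with no move-up, no emergencies, and overtime paid in 30-min
#' increments to 5 staff (3 RNs, 1 respiratory therapist, 1 nurse aide).
#'
#' @param day_start,day_end `"HH:MM"` strings or minutes since midnight.
#' @param procedures_per_day scheduled procedures per day.
#' @param working_days working days per simulated month.
#' @param cancel_policy `"no_start_after_end"` (a procedure may not begin at
#'   or after the regular-day end), `"cancel_if_lt_half_completable"` (cancel
#'   when less than 50% of the procedure would fit in the remaining regular
#'   day), or `"never_cancel"`.
#' @param move_up_on_cancel if `FALSE` (default), a slot cancelled for other
#'   reasons still occupies its drawn duration plus turnover as idle OR time;
#'   if `TRUE` the next procedure is fully moved up.
#' @param p_other_cancel per-slot probability of cancellation unrelated to OR
#'   time over-run.
#' @param p_emergency per-slot probability that an emergency case is inserted
#'   ahead of the scheduled procedure (bumping it).
#' @param p_semi_emergency per-day probability that a semi-emergency case is
#'   added after the last scheduled slot.
#' @param overtime_increment minutes per paid overtime block (rounded up).
#' @param overtime_staff number of staff paid overtime simultaneously.
#' @param distributions named list of [dist_spec()]s with elements
#'   `procedure_duration`, `turnover`, `first_patient_delay`, `cleanup`.
#' @return an object of class `or_policy`.
#' @examples
#' or_policy()                       # base case
#' or_policy(cancel_policy = "never_cancel")
#' @export
or_policy <- function(day_start = "07:30",
                      day_end = "16:00",
                      procedures_per_day = 5L,
                      working_days = 21L,
                      cancel_policy = c("no_start_after_end",
                                        "cancel_if_lt_half_completable",
                                        "never_cancel"),
                      move_up_on_cancel = FALSE,
                      p_other_cancel = 0.107,
                      p_emergency = 0,
                      p_semi_emergency = 0,
                      overtime_increment = 30,
                      overtime_staff = 5L,
                      distributions = NULL) {
  cancel_policy <- match.arg(cancel_policy)
  day_start <- parse_clock(day_start)
  day_end <- parse_clock(day_end)
  if (day_end <= day_start)
    stop("day_end must be after day_start", call. = FALSE)
  for (nm in c("p_other_cancel", "p_emergency", "p_semi_emergency")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a probability in [0, 1] (got ", v, ")",
           call. = FALSE)
  }
  if (procedures_per_day < 1L) stop("procedures_per_day must be >= 1",
                                    call. = FALSE)
  if (working_days < 1L) stop("working_days must be >= 1", call. = FALSE)
  if (overtime_increment <= 0) stop("overtime_increment must be > 0",
                                    call. = FALSE)
  if (overtime_staff < 0) stop("overtime_staff must be >= 0", call. = FALSE)
  if (is.null(distributions)) distributions <- default_distributions()
  need <- c("procedure_duration", "turnover", "first_patient_delay", "cleanup")
  miss <- setdiff(need, names(distributions))
  if (length(miss))
    stop("distributions missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (nm in need)
    if (!inherits(distributions[[nm]], "dist_spec"))
      stop("distributions$", nm, " must be a dist_spec", call. = FALSE)
  structure(list(
    day_start = day_start, day_end = day_end,
    regular_day_length = day_end - day_start,
    procedures_per_day = as.integer(procedures_per_day),
    working_days = as.integer(working_days),
    cancel_policy = cancel_policy,
    move_up_on_cancel = isTRUE(move_up_on_cancel),
    p_other_cancel = p_other_cancel,
    p_emergency = p_emergency,
    p_semi_emergency = p_semi_emergency,
    overtime_increment = overtime_increment,
    overtime_staff = as.integer(overtime_staff),
    distributions = distributions[need]
  ), class = "or_policy")
}

#' Base-case activity duration distributions
#'
#' Procedure duration LOGN(72.9, 29.2) min (arithmetic mean/SD); turnover
#' 10 + EXPO(25.6) min; first-patient delay DISC{0.5: 5 min, 1: 15 min}
#' (mean 10); cleanup TRIA(7.5, 15, 22.5) min.
#'
#' @return named list of [dist_spec()]s.
#' @export
default_distributions <- function() {
  list(
    procedure_duration = dist_spec("lognormal_mean_sd", c(72.9, 29.2)),
    turnover = dist_spec("shifted_exponential", c(10, 25.6)),
    first_patient_delay = dist_spec("discrete_cdf", c(0.5, 5, 1, 15)),
    cleanup = dist_spec("triangular", c(7.5, 15, 22.5))
  )
}

#' @export
print.or_policy <- function(x, ...) {
  cat("<or_policy>\n")
  cat("  OR day: minute", x$day_start, "to", x$day_end,
      sprintf("(%d regular min)", x$regular_day_length), "\n")
  cat("  ", x$procedures_per_day, "procedures/day over", x$working_days,
      "working days\n")
  cat("  cancel policy:", x$cancel_policy,
      if (x$move_up_on_cancel) "(move up on cancel)" else "(no move up)", "\n")
  cat("  P(other cancel) =", x$p_other_cancel,
      " P(emergency/slot) =", x$p_emergency,
      " P(semi-emergency/day) =", x$p_semi_emergency, "\n")
  cat("  overtime:", x$overtime_increment, "min blocks x",
      x$overtime_staff, "staff\n")
  for (nm in names(x$distributions))
    cat(sprintf("  %-20s %s(%s)\n", nm, x$distributions[[nm]]$kind,
                paste(x$distributions[[nm]]$params, collapse = ", ")))
  invisible(x)
}
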