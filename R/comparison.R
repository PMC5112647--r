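#' Paired two-arm monthly comparison under common random numbers
#'
#' Simulates `n_replications` months for the reference and comparator arms
#' with shared random inputs: within each replication, both arms see the same
#' schedule of procedure durations, delays, turnovers, cancellations,
#' emergency arrivals, verification statuses and clinical-event uniforms.
#' Only the arms' time deltas and residual-blockade thresholds differ, so
#' replication-wise differences isolate the intervention effect.
#'
#' @param policy an [or_policy()].
#' @param arm_reference,arm_comparator [reversal_arm()]s.
#' @param p_verified proportion of patients verified to full neuromuscular
#'   recovery before extubation.
#' @param n_replications number of simulated months per arm.
#' @param master_seed integer seed (or an [or_streams()] object).
#' @param risks a [complication_risks()].
#' @return an object of class `or_comparison`: `$replications` is a data
#'   frame with one row per replication holding each arm's monthly tallies
#'   (suffixes `_ref`/`_cmp`); `$summary` holds the replication means and the
#'   paired differences (cancellations avoided, overtime avoided, cases of
#'   residual blockade/hypoxemia/airway obstruction avoided, minutes saved
#'   per day, absolute per-patient risk reduction, and NNTs).
#' @examples
#' \donttest{
#' cmp <- run_paired(or_policy(), neostigmine_arm(), sugammadex_arm(),
#'                   p_verified = 1, n_replications = 20, master_seed = 1)
#' cmp
#' }
#' @export
run_paired <- function(policy, arm_reference, arm_comparator,
                       p_verified, n_replications = 50L, master_seed = 1L,
                       risks = complication_risks()) {
  stopifnot(n_replications >= 1L)
  streams <- if (inherits(master_seed, "or_streams")) master_seed
             else or_streams(master_seed)
  rows <- vector("list", n_replications)
  for (r in seq_len(n_replications)) {
    mref <- run_month(policy, arm_reference, p_verified, streams, r, risks)
    mcmp <- run_month(policy, arm_comparator, p_verified, streams, r, risks)
    a <- mref$summary; b <- mcmp$summary
    names(a) <- paste0(names(a), "_ref"); names(b) <- paste0(names(b), "_cmp")
    rows[[r]] <- c(replication = r, a, b)
  }
  reps <- as.data.frame(do.call(rbind, rows))
  m <- colMeans(reps)
  cmp_perf <- m[["procedures_performed_cmp"]]
  rnmb_avoided <- m[["rnmb_cases_ref"]] - m[["rnmb_cases_cmp"]]
  hyp_avoided <- m[["hypoxemia_cases_ref"]] - m[["hypoxemia_cases_cmp"]]
  air_avoided <- m[["airway_cases_ref"]] - m[["airway_cases_cmp"]]
  summary <- c(
    minutes_saved_per_day = m[["minutes_saved_per_day_cmp"]],
    procedures_gained = cmp_perf - m[["procedures_performed_ref"]],
    cancellations_avoided = m[["cancelled_time_ref"]] - m[["cancelled_time_cmp"]],
    overtime_avoided = m[["overtime_hours_ref"]] - m[["overtime_hours_cmp"]],
    rnmb_cases_avoided = rnmb_avoided,
    hypoxemia_cases_avoided = hyp_avoided,
    airway_cases_avoided = air_avoided,
    abs_risk_reduction = if (cmp_perf > 0) rnmb_avoided / cmp_perf else 0,
    nnt_rnmb = if (rnmb_avoided > 0) nnt(cmp_perf, rnmb_avoided) else NA_real_,
    nnt_hypoxemia = if (hyp_avoided > 0) nnt(cmp_perf, hyp_avoided)
                    else NA_real_,
    nnt_airway = if (air_avoided > 0) nnt(cmp_perf, air_avoided)
                 else NA_real_,
    m)
  structure(list(replications = reps, summary = summary,
                 p_verified = p_verified,
                 arms = c(reference = arm_reference$name,
                          comparator = arm_comparator$name),
                 n_replications = n_replications,
                 policy = policy),
            class = "or_comparison")
}

#' @export
print.or_comparison <- function(x, ...) {
  s <- x$summary
  cat("<or_comparison>", x$arms["comparator"], "vs", x$arms["reference"],
      sprintf("| %.0f%% verified | %d replications of %d days\n",
              100 * x$p_verified, x$n_replications, x$policy$working_days))
  fmt <- function(lbl, ref, cmp, d = 1)
    cat(sprintf("  %-38s %8.1f %10.1f\n", lbl, ref, cmp))
  cat(sprintf("  %-38s %8s %10s\n", "", x$arms["reference"],
              x$arms["comparator"]))
  fmt("procedures performed", s[["procedures_performed_ref"]],
      s[["procedures_performed_cmp"]])
  fmt("cancelled: lack of OR time", s[["cancelled_time_ref"]],
      s[["cancelled_time_cmp"]])
  fmt("cancelled: other reasons", s[["cancelled_other_ref"]],
      s[["cancelled_other_cmp"]])
  fmt("paid staff overtime (h)", s[["overtime_hours_ref"]],
      s[["overtime_hours_cmp"]])
  fmt("% days completed in regular day", s[["pct_days_complete_ref"]],
      s[["pct_days_complete_cmp"]])
  fmt("residual blockade cases", s[["rnmb_cases_ref"]],
      s[["rnmb_cases_cmp"]])
  cat(sprintf("  minutes saved per day: %.0f | cases avoided: RNMB %.1f, hypoxemia %.1f, airway %.1f\n",
              s[["minutes_saved_per_day"]], s[["rnmb_cases_avoided"]],
              s[["hypoxemia_cases_avoided"]], s[["airway_cases_avoided"]]))
  cat(sprintf("  per-patient absolute RNMB risk reduction: %.0f%% | NNT: %s (RNMB), %s (hypoxemia), %s (airway)\n",
              100 * s[["abs_risk_reduction"]],
              format(s[["nnt_rnmb"]]), format(s[["nnt_hypoxemia"]]),
              format(s[["nnt_airway"]])))
  invisible(x)
}

#' @export
summary.or_comparison <- function(object, ...) object$summary

#' Scenario sweep over the proportion of patients verified
#'
#' Runs the paired comparison once per verification scenario (by default 0%,
#' 5%, 10%, 25%, 50%, 75%, 100% of patients verified to TOF ratio >= 0.9
#' before extubation) and assembles the monthly OR-efficiency and clinical
#' outcome measures into one table with a reference column and one column
#' per scenario. Because substreams are keyed, the reference arm's schedule
#' is identical in every scenario.
#'
#' @param policy an [or_policy()].
#' @param arm_reference,arm_comparator [reversal_arm()]s.
#' @param p_verified vector of verification proportions.
#' @param n_replications replications per scenario.
#' @param master_seed integer seed.
#' @param risks a [complication_risks()].
#' @return an object of class `or_sweep`; `as.data.frame()` yields the
#'   outcome-by-scenario table (values rounded as reported: counts, hours
#'   and percentages to 1 decimal, minutes per day to integers).
#' @export
scenario_sweep <- function(policy = or_policy(),
                           arm_reference = neostigmine_arm(),
                           arm_comparator = sugammadex_arm(),
                           p_verified = c(0, 0.05, 0.10, 0.25, 0.50,
                                          0.75, 1.00),
                           n_replications = 50L, master_seed = 1L,
                           risks = complication_risks()) {
  comparisons <- lapply(p_verified, function(p)
    run_paired(policy, arm_reference, arm_comparator, p,
               n_replications, master_seed, risks))
  structure(list(comparisons = comparisons, p_verified = p_verified,
                 arms = c(reference = arm_reference$name,
                          comparator = arm_comparator$name)),
            class = "or_sweep")
}

#' @export
as.data.frame.or_sweep <- function(x, ...) {
  g <- function(field) vapply(x$comparisons, function(cm)
    cm$summary[[field]], numeric(1))
  ref <- x$comparisons[[1]]$summary
  tab <- rbind(
    `Number of OR minutes saved per day` =
      c(NA, round(g("minutes_saved_per_day"))),
    `% of days all procedures are completed within the regular OR day` =
      c(round(ref[["pct_days_complete_ref"]], 1),
        round(g("pct_days_complete_cmp"), 1)),
    `Number of procedures performed` =
      c(round(ref[["procedures_performed_ref"]], 1),
        round(g("procedures_performed_cmp"), 1)),
    `Procedures cancelled due to lack of OR time` =
      c(round(ref[["cancelled_time_ref"]], 1),
        round(g("cancelled_time_cmp"), 1)),
    `Procedures cancelled for other reasons` =
      c(round(ref[["cancelled_other_ref"]], 1),
        round(g("cancelled_other_cmp"), 1)),
    `Paid hours of staff over-time` =
      c(round(ref[["overtime_hours_ref"]], 1),
        round(g("overtime_hours_cmp"), 1)),
    `Cases of residual blockade avoided` =
      c(NA, round(g("rnmb_cases_avoided"))),
    `Hypoxemia cases avoided` = c(NA, round(g("hypoxemia_cases_avoided"))),
    `Upper airway obstruction cases avoided` =
      c(NA, round(g("airway_cases_avoided"))),
    `Absolute reduction in risk of residual blockade, per patient (%)` =
      c(NA, round(100 * g("abs_risk_reduction"))))
  df <- as.data.frame(tab)
  names(df) <- c(x$arms["reference"],
                 sprintf("%s_%g%%_verified", x$arms["comparator"],
                         100 * x$p_verified))
  df
}

#' @export
print.or_sweep <- function(x, ...) {
  cat("<or_sweep>", x$arms["comparator"], "vs", x$arms["reference"],
      "across verification scenarios\n\n")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
plot.or_sweep <- function(x, ...) {
  p <- 100 * x$p_verified
  saved <- vapply(x$comparisons, function(cm)
    cm$summary[["minutes_saved_per_day"]], numeric(1))
  avoided <- vapply(x$comparisons, function(cm)
    cm$summary[["rnmb_cases_avoided"]], numeric(1))
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(p, saved, type = "b", pch = 16, xlab = "% of patients verified",
       ylab = "OR minutes saved per day", ...)
  graphics::par(new = TRUE)
  plot(p, avoided, type = "b", pch = 1, lty = 2, axes = FALSE,
       xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("residual blockade cases avoided / month", side = 4,
                  line = 2.5)
  graphics::legend("top", legend = c("minutes saved", "RNMB cases avoided"),
                   pch = c(16, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Policy and effect-size sensitivity analyses
#'
#' Re-runs the fully-verified (100% TOF-verified) paired comparison under
#' each sensitivity variant: the two alternative time-cancellation policies,
#' fully moving up the next procedure on cancellation, 15% emergency case
#' insertion, and the pooled-trial 95% CI bounds for the sugammadex OR time
#' saving (2 and 26 min per procedure).
#'
#' @param policy base [or_policy()].
#' @param n_replications replications per variant.
#' @param master_seed integer seed.
#' @param risks a [complication_risks()].
#' @return an object of class `or_sensitivity`; `as.data.frame()` gives one
#'   row per variant and arm with minutes saved per day, % days completed,
#'   time-cancellations and paid overtime.
#' @export
sensitivity_suite <- function(policy = or_policy(), n_replications = 50L,
                              master_seed = 1L,
                              risks = complication_risks()) {
  modify <- function(p, ...) {
    args <- list(...)
    for (nm in names(args)) p[[nm]] <- args[[nm]]
    # keep derived field in step
    p$regular_day_length <- p$day_end - p$day_start
    p
  }
  variants <- list(
    `Primary analysis` = list(policy = policy, arm = sugammadex_arm()),
    `Cancel if < 50% of procedure completable within regular OR day` =
      list(policy = modify(policy,
                           cancel_policy = "cancel_if_lt_half_completable"),
           arm = sugammadex_arm()),
    `Never cancel a procedure due to lack of OR time` =
      list(policy = modify(policy, cancel_policy = "never_cancel"),
           arm = sugammadex_arm()),
    `Fully move up next procedure if a cancellation occurs` =
      list(policy = modify(policy, move_up_on_cancel = TRUE),
           arm = sugammadex_arm()),
    `15% of procedures are emergency cases` =
      list(policy = modify(policy, p_emergency = 0.15),
           arm = sugammadex_arm()),
    `Sugammadex OR time saved at lower 95% CI bound (2 min)` =
      list(policy = policy, arm = sugammadex_arm(delta_verified = -2)),
    `Sugammadex OR time saved at upper 95% CI bound (26 min)` =
      list(policy = policy, arm = sugammadex_arm(delta_verified = -26)))
  comparisons <- lapply(variants, function(v)
    run_paired(v$policy, neostigmine_arm(), v$arm, p_verified = 1,
               n_replications = n_replications, master_seed = master_seed,
               risks = risks))
  structure(list(comparisons = comparisons, variants = names(variants)),
            class = "or_sensitivity")
}

#' @export
as.data.frame.or_sensitivity <- function(x, ...) {
  rows <- lapply(seq_along(x$comparisons), function(i) {
    s <- x$comparisons[[i]]$summary
    data.frame(
      variant = rep(x$variants[i], 2),
      arm = c("neostigmine", "sugammadex"),
      minutes_saved_per_day = c(NA, round(s[["minutes_saved_per_day"]])),
      pct_days_complete = round(c(s[["pct_days_complete_ref"]],
                                  s[["pct_days_complete_cmp"]]), 1),
      cancelled_time = round(c(s[["cancelled_time_ref"]],
                               s[["cancelled_time_cmp"]]), 1),
      overtime_hours = round(c(s[["overtime_hours_ref"]],
                               s[["overtime_hours_cmp"]]), 1),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.or_sensitivity <- function(x, ...) {
  cat("<or_sensitivity> 100%-verified scenario under policy variants\n\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Deep-block exploratory analysis
#'
#' For procedures maintained at a deep level of neuromuscular block to the
#' end of the procedure, neostigmine cannot be used until the block fades, so
#' fewer, longer procedures are scheduled: 3 procedures of mean 145 min per
#' day, with the duration SD rescaled by the base-case variability ratio
#' ([scaled_sd()]). Because no trial quantifies the sugammadex time saving in
#' this setting, a grid of hypothetical per-procedure savings is explored
#' (applied to every performed patient; verification does not change the
#' saving, and the scenario is run at 0% verified).
#'
#' @param savings_grid hypothetical minutes saved per procedure.
#' @param n_replications replications per grid point.
#' @param master_seed integer seed.
#' @param policy base policy; its procedure count and duration distribution
#'   are replaced by the deep-block schedule.
#' @param procedures_per_day,procedure_mean deep-block schedule parameters.
#' @param risks a [complication_risks()].
#' @return an object of class `or_exploratory`; `as.data.frame()` gives the
#'   outcome-by-savings table with a neostigmine reference column.
#' @export
deep_block_exploratory <- function(savings_grid = c(15, 30, 45, 60),
                                   n_replications = 50L, master_seed = 1L,
                                   policy = or_policy(),
                                   procedures_per_day = 3L,
                                   procedure_mean = 145,
                                   risks = complication_risks()) {
  base <- policy$distributions$procedure_duration
  if (base$kind != "lognormal_mean_sd")
    stop("deep-block rescaling expects a lognormal_mean_sd procedure duration",
         call. = FALSE)
  dists <- policy$distributions
  dists$procedure_duration <- dist_spec(
    "lognormal_mean_sd",
    c(procedure_mean,
      scaled_sd(procedure_mean, base$params[1], base$params[2])))
  deep <- policy
  deep$procedures_per_day <- as.integer(procedures_per_day)
  deep$distributions <- dists
  comparisons <- lapply(savings_grid, function(s)
    run_paired(deep, neostigmine_arm(),
               sugammadex_arm(delta_verified = -s, delta_unverified = -s),
               p_verified = 0, n_replications = n_replications,
               master_seed = master_seed, risks = risks))
  structure(list(comparisons = comparisons, savings_grid = savings_grid,
                 policy = deep),
            class = "or_exploratory")
}

#' @export
as.data.frame.or_exploratory <- function(x, ...) {
  g <- function(field) vapply(x$comparisons, function(cm)
    cm$summary[[field]], numeric(1))
  ref <- x$comparisons[[1]]$summary
  tab <- rbind(
    `Number of OR minutes saved per day` =
      c(NA, round(g("minutes_saved_per_day"))),
    `% of days all procedures are completed within the regular OR day` =
      c(round(ref[["pct_days_complete_ref"]], 1),
        round(g("pct_days_complete_cmp"), 1)),
    `Number of procedures performed` =
      c(round(ref[["procedures_performed_ref"]], 1),
        round(g("procedures_performed_cmp"), 1)),
    `Procedures cancelled due to lack of OR time` =
      c(round(ref[["cancelled_time_ref"]], 1),
        round(g("cancelled_time_cmp"), 1)),
    `Procedures cancelled for other reasons` =
      c(round(ref[["cancelled_other_ref"]], 1),
        round(g("cancelled_other_cmp"), 1)),
    `Paid hours of staff over-time` =
      c(round(ref[["overtime_hours_ref"]], 1),
        round(g("overtime_hours_cmp"), 1)),
    `Cases of residual blockade avoided` =
      c(NA, round(g("rnmb_cases_avoided"))),
    `Hypoxemia cases avoided` = c(NA, round(g("hypoxemia_cases_avoided"))),
    `Upper airway obstruction cases avoided` =
      c(NA, round(g("airway_cases_avoided"))),
    `Absolute reduction in risk of residual blockade, per patient (%)` =
      c(NA, round(100 * g("abs_risk_reduction"))))
  df <- as.data.frame(tab)
  names(df) <- c("neostigmine",
                 sprintf("sugammadex_%gmin_saved", x$savings_grid))
  df
}

#' @export
print.or_exploratory <- function(x, ...) {
  cat("<or_exploratory> deep neuromuscular block:",
      x$policy$procedures_per_day, "procedures/day, mean",
      x$policy$distributions$procedure_duration$params[1], "min\n\n")
  print(as.data.frame(x))
  invisible(x)
}
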