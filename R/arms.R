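#' Reversal-arm parameters
#'
#' Describes one neuromuscular block reversal strategy: the per-procedure OR
#' time delta (relative to the neostigmine reference) by whether the patient
#' is verified to full neuromuscular recovery (train-of-four ratio >= 0.9)
#' before extubation, and the risk of residual neuromuscular blockade (RNMB)
#' at extubation for unverified patients. Verified patients carry zero RNMB
#' risk by definition.
#'
#' @param name arm label.
#' @param delta_verified minutes added to each verified patient's procedure
#'   (negative = time saved).
#' @param delta_unverified minutes added to each unverified patient's
#'   procedure.
#' @param rnmb_risk_unverified probability of RNMB at extubation for an
#'   unverified patient.
#' @return an object of class `reversal_arm`.
#' @seealso [neostigmine_arm()], [sugammadex_arm()]
#' @export
reversal_arm <- function(name, delta_verified = 0, delta_unverified = 0,
                         rnmb_risk_unverified = 0) {
  if (!is.numeric(delta_verified) || !is.finite(delta_verified) ||
      !is.numeric(delta_unverified) || !is.finite(delta_unverified))
    stop("arm deltas must be finite numbers", call. = FALSE)
  if (rnmb_risk_unverified < 0 || rnmb_risk_unverified > 1)
    stop("rnmb_risk_unverified must be in [0, 1] (got ",
         rnmb_risk_unverified, ")", call. = FALSE)
  structure(list(name = as.character(name),
                 delta_verified = delta_verified,
                 delta_unverified = delta_unverified,
                 rnmb_risk_unverified = rnmb_risk_unverified),
            class = "reversal_arm")
}

#' @export
print.reversal_arm <- function(x, ...) {
  cat(sprintf(
    "<reversal_arm> %s: delta %+g min (verified) / %+g min (unverified), P(RNMB | unverified) = %g\n",
    x$name, x$delta_verified, x$delta_unverified, x$rnmb_risk_unverified))
  invisible(x)
}

#' The neostigmine reference arm
#'
#' Zero time deltas (it is the reference) and a 60% risk of residual
#' blockade at extubation among unverified patients.
#'
#' @param rnmb_risk_unverified RNMB risk for unverified patients.
#' @return a [reversal_arm()].
#' @export
neostigmine_arm <- function(rnmb_risk_unverified = 0.60) {
  reversal_arm("neostigmine", 0, 0, rnmb_risk_unverified)
}

#' The sugammadex comparator arm
#'
#' Pooled trial data give a 14-min per-procedure OR time saving when full
#' neuromuscular recovery is verified before extubation and no saving when it
#' is not, with a 93% relative reduction in RNMB risk among unverified
#' patients (0.60 x 0.07 = 0.042 residual risk).
#'
#' @param delta_verified minutes added per verified patient (default -14).
#' @param delta_unverified minutes added per unverified patient (default 0;
#'   set negative for the deep-block exploratory analysis).
#' @param neostigmine_risk unverified RNMB risk in the reference arm.
#' @param risk_reduction relative RNMB risk reduction vs neostigmine.
#' @return a [reversal_arm()].
#' @export
sugammadex_arm <- function(delta_verified = -14, delta_unverified = 0,
                           neostigmine_risk = 0.60, risk_reduction = 0.93) {
  if (risk_reduction < 0 || risk_reduction > 1)
    stop("risk_reduction must be in [0, 1]", call. = FALSE)
  reversal_arm("sugammadex", delta_verified, delta_unverified,
               neostigmine_risk * (1 - risk_reduction))
}

#' Excess complication risks of residual blockade
#'
#' Absolute excess risks, among patients with residual blockade at
#' extubation, of hypoxemia (24.5%) and upper airway obstruction (44.2%).
#' Complications include cases both with and without clinical diagnosis.
#'
#' @param hypoxemia_excess,airway_obstruction_excess probabilities.
#' @return an object of class `complication_risks`.
#' @export
complication_risks <- function(hypoxemia_excess = 0.245,
                               airway_obstruction_excess = 0.442) {
  for (nm in c("hypoxemia_excess", "airway_obstruction_excess")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("'", nm, "' must be a probability in [0, 1]", call. = FALSE)
  }
  structure(list(hypoxemia_excess = hypoxemia_excess,
                 airway_obstruction_excess = airway_obstruction_excess),
            class = "complication_risks")
}

#' Verification status from a shared uniform
#'
#' A patient is verified to full neuromuscular recovery with probability
#' `p_verified`. The uniform is drawn once per patient and shared by both
#' comparison arms, so verification status never differs between arms.
#'
#' @param p_verified probability of verification in `[0, 1]`.
#' @param u uniform(s) in `[0, 1)`.
#' @return logical vector.
#' @export
assign_verified <- function(p_verified, u) {
  if (p_verified < 0 || p_verified > 1)
    stop("p_verified must be in [0, 1]", call. = FALSE)
  u < p_verified
}

#' Residual blockade event from a shared uniform
#'
#' Verified patients never have residual blockade. Unverified patients have
#' an event when the shared uniform falls below the arm's unverified RNMB
#' risk; comparing *the same* uniform against both arms' thresholds couples
#' the arms monotonically, so every comparator event is also a reference
#' event and cases avoided are non-negative in every replication.
#'
#' @param arm a [reversal_arm()].
#' @param verified logical vector of verification flags.
#' @param u shared uniforms, same length.
#' @return logical vector of RNMB flags.
#' @export
rnmb_event <- function(arm, verified, u) {
  stopifnot(inherits(arm, "reversal_arm"))
  !verified & u < arm$rnmb_risk_unverified
}

#' Complication events given residual blockade
#'
#' Applies the absolute excess risks of hypoxemia and upper airway
#' obstruction to RNMB-positive patients, using per-patient uniforms shared
#' across arms. Patients without residual blockade have no excess
#' complications (background incidence cancels in the paired design).
#'
#' @param rnmb logical vector of RNMB flags.
#' @param risks a [complication_risks()].
#' @param u_hypoxemia,u_airway shared uniforms, same length as `rnmb`.
#' @return list with logical vectors `hypoxemia` and `airway`.
#' @export
complication_events <- function(rnmb, risks, u_hypoxemia, u_airway) {
  stopifnot(inherits(risks, "complication_risks"))
  list(hypoxemia = rnmb & u_hypoxemia < risks$hypoxemia_excess,
       airway = rnmb & u_airway < risks$airway_obstruction_excess)
}

#' Number needed to treat
#'
#' Patients treated with the comparator per adverse event prevented:
#' `procedures_treated / cases_avoided`, rounded to one decimal for
#' reporting. `NA` (not applicable) when no cases are avoided.
#'
#' @param procedures_treated number of comparator procedures (> 0).
#' @param cases_avoided number of events prevented.
#' @return the NNT rounded to 1 decimal, or `NA` when `cases_avoided` is 0.
#' @examples
#' nnt(90.8, 51)  # residual blockade
#' nnt(90.8, 12)  # hypoxemia
#' @export
nnt <- function(procedures_treated, cases_avoided) {
  if (procedures_treated <= 0)
    stop("procedures_treated must be > 0", call. = FALSE)
  if (cases_avoided == 0) return(NA_real_)
  round(procedures_treated / cases_avoided, 1)
}
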