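#' Load a run configuration
#'
#' Reads a YAML configuration and fills every omitted field with the
#' base-case default, so an empty file yields the full base-case model
#' (5 procedures/day over 21 days, 10.7% other-reason cancellations, 60%
#' unverified residual-blockade risk with a 93% reduction under sugammadex,
#' and the four base-case duration distributions). Unknown keys are rejected
#' by name; invalid values raise errors naming the field and constraint.
#'
#' Recognised top-level keys: `policy` (any [or_policy()] argument; clock
#' times as `"HH:MM"`; `distributions` as named `{kind, params}` maps, with
#' an optional `dialect: arena` tag), `arms` (`reference` / `comparator`
#' with [reversal_arm()] fields or the shortcut `name:
#' neostigmine|sugammadex`), `complication_risks`, `p_verified_scenarios`,
#' `n_replications`, `master_seed`, `output_dir`, `analysis`
#' (`base`, `sensitivity`, `deep_block` or `all`), and `deep_block`
#' (`savings_grid`, `procedures_per_day`, `procedure_mean`). Selecting
#' `analysis: deep_block` forces the deep-block schedule (3 procedures/day of
#' mean 145 min).
#'
#' @param path path to a YAML file, or `NULL` for all defaults.
#' @param text YAML given directly as a string (overrides `path`).
#' @return a list of class `run_config` with elements `policy`, `arms`,
#'   `risks`, `p_verified_scenarios`, `n_replications`, `master_seed`,
#'   `output_dir`, `analysis`, `deep_block`.
#' @examples
#' cfg <- load_config(text = "n_replications: 10\nmaster_seed: 42")
#' cfg$policy$procedures_per_day
#' @export
load_config <- function(path = NULL, text = NULL) {
  raw <- if (!is.null(text)) yaml::yaml.load(text)
         else if (!is.null(path)) {
           if (!file.exists(path))
             stop("config file not found: ", path, call. = FALSE)
           yaml::read_yaml(path)
         } else NULL
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("config must be a YAML mapping", call. = FALSE)
  known <- c("policy", "arms", "complication_risks", "p_verified_scenarios",
             "n_replications", "master_seed", "output_dir", "analysis",
             "deep_block")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  pol_raw <- raw$policy %||% list()
  pol_known <- c("day_start", "day_end", "procedures_per_day",
                 "working_days", "cancel_policy", "move_up_on_cancel",
                 "p_other_cancel", "p_emergency", "p_semi_emergency",
                 "overtime_increment", "overtime_staff", "distributions")
  unknown <- setdiff(names(pol_raw), pol_known)
  if (length(unknown))
    stop("unknown policy key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(pol_raw$distributions))
    pol_raw$distributions <- parse_distributions(pol_raw$distributions)
  policy <- do.call(or_policy, pol_raw)

  arms_raw <- raw$arms %||% list()
  unknown <- setdiff(names(arms_raw), c("reference", "comparator"))
  if (length(unknown))
    stop("unknown arms key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  arms <- list(reference = parse_arm(arms_raw$reference, neostigmine_arm()),
               comparator = parse_arm(arms_raw$comparator, sugammadex_arm()))

  risks <- do.call(complication_risks, raw$complication_risks %||% list())

  scen <- raw$p_verified_scenarios %||% c(0, 0.05, 0.10, 0.25, 0.50, 0.75, 1)
  scen <- as.numeric(scen)
  if (anyNA(scen) || any(scen < 0 | scen > 1))
    stop("p_verified_scenarios must be probabilities in [0, 1]",
         call. = FALSE)

  n_rep <- raw$n_replications %||% 50L
  if (!is.numeric(n_rep) || n_rep < 1)
    stop("n_replications must be a positive integer (got ", n_rep, ")",
         call. = FALSE)

  analysis <- match.arg(raw$analysis %||% "base",
                        c("base", "sensitivity", "deep_block", "all"))

  deep_raw <- raw$deep_block %||% list()
  unknown <- setdiff(names(deep_raw),
                     c("savings_grid", "procedures_per_day",
                       "procedure_mean"))
  if (length(unknown))
    stop("unknown deep_block key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  deep <- list(savings_grid = as.numeric(deep_raw$savings_grid %||%
                                           c(15, 30, 45, 60)),
               procedures_per_day =
                 as.integer(deep_raw$procedures_per_day %||% 3L),
               procedure_mean = as.numeric(deep_raw$procedure_mean %||% 145))

  if (analysis == "deep_block") {
    # the deep-block schedule replaces the base-case one
    policy$procedures_per_day <- deep$procedures_per_day
    base <- policy$distributions$procedure_duration
    policy$distributions$procedure_duration <- dist_spec(
      "lognormal_mean_sd",
      c(deep$procedure_mean,
        scaled_sd(deep$procedure_mean, base$params[1], base$params[2])))
  }

  structure(list(policy = policy, arms = arms, risks = risks,
                 p_verified_scenarios = scen,
                 n_replications = as.integer(n_rep),
                 master_seed = as.integer(raw$master_seed %||% 1L),
                 output_dir = raw$output_dir %||% ".",
                 analysis = analysis, deep_block = deep),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_distributions <- function(x) {
  lapply(x, function(d) {
    if (inherits(d, "dist_spec")) return(d)
    if (!is.list(d) || is.null(d$kind) || is.null(d$params))
      stop("each distribution needs 'kind' and 'params'", call. = FALSE)
    if (!is.null(d$dialect) && !identical(d$dialect, "arena"))
      stop("unknown distribution dialect: ", d$dialect, call. = FALSE)
    dist_spec(d$kind, unlist(d$params))
  })
}

parse_arm <- function(x, default) {
  if (is.null(x)) return(default)
  if (inherits(x, "reversal_arm")) return(x)
  known <- c("name", "delta_verified", "delta_unverified",
             "rnmb_risk_unverified")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown arm key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base <- if (identical(x$name, "sugammadex")) sugammadex_arm()
          else if (identical(x$name, "neostigmine")) neostigmine_arm()
          else default
  reversal_arm(x$name %||% base$name,
               x$delta_verified %||% base$delta_verified,
               x$delta_unverified %||% base$delta_unverified,
               x$rnmb_risk_unverified %||% base$rnmb_risk_unverified)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> analysis:", x$analysis,
      "| replications:", x$n_replications,
      "| seed:", x$master_seed, "\n")
  print(x$policy)
  print(x$arms$reference); print(x$arms$comparator)
  invisible(x)
}
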