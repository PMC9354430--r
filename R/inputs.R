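#' @keywords internal
"_PACKAGE"

## Event vocabulary -----------------------------------------------------------

#' Clinical events tracked by the model
#'
#' `ce_events()` returns the full set of clinical outcomes a model
#' specification must provide for both arms: all-cause mortality, disabling
#' (major) stroke, and the ten costed adverse events. `ce_ae_events()`
#' returns the subset that carries a one-time treatment cost drawn from the
#' adverse-event cost table (this includes disabling stroke, whose cost is
#' attached to the health-state transition).
#'
#' @return Character vector of event names.
#' @export
ce_events <- function() {
  c("all_cause_mortality", "disabling_stroke", "rehospitalisation", "MI",
    "major_vascular", "bleeding", "endocarditis", "AKI", "new_PPI",
    "TIA", "AF", "PAR")
}

#' @rdname ce_events
#' @export
ce_ae_events <- function() setdiff(ce_events(), "all_cause_mortality")

# adverse events applied independently of health state (everything costed
# except the stroke transition itself)
ce_indep_ae_events <- function() setdiff(ce_ae_events(), "disabling_stroke")

ce_arms <- function() c("tavi", "savr")

## Construction ---------------------------------------------------------------

new_model_spec <- function(name, settings, milestone_months, events,
                           hazard_ratios, costs, utilities,
                           ae_disutilities = NULL,
                           description = NULL) {
  spec <- list(
    name = name,
    description = description,
    settings = settings,
    milestone_months = as.numeric(milestone_months),
    events = events,
    hazard_ratios = hazard_ratios,
    costs = costs,
    utilities = utilities,
    ae_disutilities = ae_disutilities
  )
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$name, "\n", sep = "")
  cat("  horizon: ", x$settings$horizon_months, " months; discount ",
      x$settings$annual_discount * 100, "%/y; WTP ",
      format(x$settings$wtp, big.mark = ","), "/QALY\n", sep = "")
  cat("  events: ", length(x$events), "; milestones at months ",
      paste(x$milestone_months, collapse = ", "), "\n", sep = "")
  cat("  AE disutilities: ",
      if (isTRUE(x$settings$apply_ae_disutilities)) "applied" else "off",
      "\n", sep = "")
  invisible(x)
}

## Validation -----------------------------------------------------------------

#' Validate a model specification
#'
#' Checks every structural invariant of a model specification and returns
#' the violations as a character vector (zero-length when the spec is
#' valid). Nothing is silently repaired.
#'
#' Checked invariants include: the full event list present for both arms;
#' milestone months strictly increasing and starting at or after month 1;
#' probabilities within \[0, 1\]; cumulative-incidence tables non-decreasing
#' (prevalence tables are exempt); hazard ratios at least 1; positive cost
#' means with `ci_low <= mean <= ci_high`; utilities within \[0, 1\]; the
#' horizon a multiple of 12 months; and the discount rate within \[0, 0.05\].
#'
#' @param spec A `model_spec` object.
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_model_spec <- function(spec) {
  bad <- character()
  add <- function(msg) bad <<- c(bad, msg)

  s <- spec$settings
  if (is.null(s$horizon_months) || s$horizon_months %% 12 != 0 ||
      s$horizon_months < 12)
    add("settings: horizon_months must be a positive multiple of 12")
  if (!identical(as.numeric(s$cycle_length_months), 1))
    add("settings: cycle_length_months must be 1")
  if (is.null(s$annual_discount) || s$annual_discount < 0 ||
      s$annual_discount > 0.05)
    add("settings: annual_discount must lie in [0, 0.05]")
  if (!is.null(s$mortality_bridge) &&
      !s$mortality_bridge %in% c("linear", "constant"))
    add("settings: mortality_bridge must be 'linear' or 'constant'")

  mm <- spec$milestone_months
  if (length(mm) < 1 || any(mm < 1) || any(diff(mm) <= 0))
    add("milestone_months must be strictly increasing and start at >= 1")

  missing_ev <- setdiff(ce_events(), names(spec$events))
  if (length(missing_ev))
    add(paste0("events: missing table(s): ",
               paste(missing_ev, collapse = ", ")))
  extra_ev <- setdiff(names(spec$events), ce_events())
  if (length(extra_ev))
    add(paste0("events: unknown event(s): ",
               paste(extra_ev, collapse = ", ")))

  for (ev in intersect(names(spec$events), ce_events())) {
    tab <- spec$events[[ev]]
    if (!tab$kind %in% c("cumulative_incidence", "prevalence")) {
      add(paste0("events$", ev, ": unknown kind '", tab$kind, "'"))
      next
    }
    for (arm in ce_arms()) {
      v <- tab[[arm]]
      if (is.null(v) || length(v) != length(mm)) {
        add(paste0("events$", ev, ": arm '", arm,
                   "' must have one value per milestone"))
        next
      }
      if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
        add(paste0("events$", ev, " (", arm,
                   "): probabilities must lie in [0, 1]"))
      if (tab$kind == "cumulative_incidence" && any(diff(v) < 0))
        add(paste0("events$", ev, " (", arm,
                   "): cumulative incidence must be non-decreasing"))
    }
  }

  hr <- spec$hazard_ratios
  if (is.null(hr$by_cycle) || !length(hr$by_cycle) ||
      any(hr$by_cycle < 1) || is.null(hr$after) || hr$after < 1)
    add("hazard_ratios: all HRs (by_cycle and after) must be >= 1")

  co <- spec$costs
  if (is.null(co$index_episode$tavi) || co$index_episode$tavi <= 0 ||
      is.null(co$index_episode$savr) || co$index_episode$savr <= 0)
    add("costs: index episode costs must be positive for both arms")
  if (is.null(co$followup_annual) || co$followup_annual <= 0 ||
      is.null(co$neurologist_visit) || co$neurologist_visit <= 0)
    add("costs: follow-up and neurologist visit costs must be positive")
  missing_ae <- setdiff(ce_ae_events(), names(co$ae))
  if (length(missing_ae))
    add(paste0("costs$ae: missing cost(s) for: ",
               paste(missing_ae, collapse = ", ")))
  for (ev in intersect(names(co$ae), ce_ae_events())) {
    x <- co$ae[[ev]]
    if (is.null(x$mean) || x$mean <= 0)
      add(paste0("costs$ae$", ev, ": mean must be > 0"))
    if (!is.null(x$sd) && x$sd < 0)
      add(paste0("costs$ae$", ev, ": sd must be >= 0"))
    if (!is.null(x$ci_low) && !is.null(x$ci_high) &&
        !(x$ci_low <= x$mean && x$mean <= x$ci_high))
      add(paste0("costs$ae$", ev, ": need ci_low <= mean <= ci_high"))
  }

  ut <- spec$utilities
  for (arm in ce_arms()) {
    nodes <- ut[[arm]]
    if (is.null(nodes) || !length(nodes)) {
      add(paste0("utilities: missing nodes for arm '", arm, "'"))
      next
    }
    months <- vapply(nodes, function(n) as.numeric(n$month), numeric(1))
    means <- vapply(nodes, function(n) as.numeric(n$mean), numeric(1))
    if (!identical(months, c(1, 12, 24)))
      add(paste0("utilities (", arm, "): nodes must sit at months 1, 12, 24"))
    if (any(means < 0) || any(means > 1))
      add(paste0("utilities (", arm, "): values must lie in [0, 1]"))
  }
  if (!identical(as.numeric(ut$pooled_after_month), 24))
    add("utilities: pooled_after_month must be 24")

  if (!is.null(spec$ae_disutilities)) {
    d <- spec$ae_disutilities
    if (is.null(d$stroke_state_decrement) || d$stroke_state_decrement < 0 ||
        d$stroke_state_decrement > 1)
      add("ae_disutilities: stroke_state_decrement must lie in [0, 1]")
    if (any(unlist(d$one_off) < 0))
      add("ae_disutilities: one-off decrements must be >= 0")
  }
  if (isTRUE(spec$settings$apply_ae_disutilities) &&
      is.null(spec$ae_disutilities))
    add("settings: apply_ae_disutilities is on but no ae_disutilities given")

  bad
}

stop_if_invalid <- function(spec) {
  bad <- validate_model_spec(spec)
  if (length(bad))
    stop("invalid model spec '", spec$name, "':\n  ",
         paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(spec)
}

## Load / save ----------------------------------------------------------------

spec_from_list <- function(raw) {
  for (fld in c("name", "settings", "milestone_months", "events",
                "hazard_ratios", "costs", "utilities"))
    if (is.null(raw[[fld]]))
      stop("config is missing required field '", fld, "'", call. = FALSE)
  st <- raw$settings
  defaults <- list(cycle_length_months = 1, wtp = 34091,
                   n_microsim = 10000, n_psa = 5000, seed = 1,
                   apply_ae_disutilities = FALSE,
                   mortality_bridge = "linear",
                   mortality_linear_from = 24,
                   half_cycle_correction = FALSE)
  for (k in names(defaults)) if (is.null(st[[k]])) st[[k]] <- defaults[[k]]
  ev <- lapply(raw$events, function(tab) {
    tab$tavi <- as.numeric(tab$tavi)
    tab$savr <- as.numeric(tab$savr)
    tab
  })
  new_model_spec(
    name = raw$name,
    description = raw$description,
    settings = st,
    milestone_months = raw$milestone_months,
    events = ev,
    hazard_ratios = list(by_cycle = as.numeric(raw$hazard_ratios$by_cycle),
                         after = as.numeric(raw$hazard_ratios$after)),
    costs = raw$costs,
    utilities = raw$utilities,
    ae_disutilities = raw$ae_disutilities
  )
}

#' Load and validate a model specification from a YAML config file
#'
#' Reads the documented YAML schema (see the bundled
#' `partner2a_base.yaml` for a worked template), constructs a
#' `model_spec`, and runs [validate_model_spec()]. Any violation aborts
#' with the full list of problems; nothing is silently fixed.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `model_spec`.
#' @seealso [builtin_parameter_set()], [save_model_spec()]
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("failed to parse '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  spec <- spec_from_list(raw)
  stop_if_invalid(spec)
}

#' Save a model specification back to YAML
#'
#' Writes a `model_spec` in the same schema [load_model_spec()] reads, so
#' that a save-then-load round trip reproduces the spec exactly.
#'
#' @param spec A `model_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model_spec <- function(spec, path) {
  raw <- unclass(spec)
  raw$ae_disutilities <- spec$ae_disutilities  # keep NULL dropped
  raw <- raw[!vapply(raw, is.null, logical(1))]
  yaml::write_yaml(raw, path, precision = 15)
  invisible(path)
}

#' Export a model specification as audit CSV tables
#'
#' Writes four plain CSV files (`<stem>_events.csv`,
#' `<stem>_hazard_ratios.csv`, `<stem>_costs.csv`, `<stem>_utilities.csv`)
#' flattening every input of the spec for audit outside R.
#'
#' @param spec A `model_spec`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the spec name.
#' @return Character vector of the files written, invisibly.
#' @export
export_spec_csv <- function(spec, dir, stem = spec$name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mm <- spec$milestone_months
  ev <- do.call(rbind, lapply(names(spec$events), function(e) {
    tab <- spec$events[[e]]
    do.call(rbind, lapply(ce_arms(), function(a) {
      data.frame(event = e, arm = a, kind = tab$kind, month = mm,
                 probability = tab[[a]])
    }))
  }))
  hr <- data.frame(cycle_since_stroke = seq_along(spec$hazard_ratios$by_cycle),
                   hr = spec$hazard_ratios$by_cycle)
  hr <- rbind(hr, data.frame(cycle_since_stroke = NA,
                             hr = spec$hazard_ratios$after))
  co <- rbind(
    data.frame(item = "index_episode_tavi",
               mean = spec$costs$index_episode$tavi,
               sd = NA, ci_low = NA, ci_high = NA),
    data.frame(item = "index_episode_savr",
               mean = spec$costs$index_episode$savr,
               sd = NA, ci_low = NA, ci_high = NA),
    data.frame(item = "followup_annual", mean = spec$costs$followup_annual,
               sd = NA, ci_low = NA, ci_high = NA),
    data.frame(item = "neurologist_visit",
               mean = spec$costs$neurologist_visit,
               sd = NA, ci_low = NA, ci_high = NA),
    do.call(rbind, lapply(names(spec$costs$ae), function(e) {
      x <- spec$costs$ae[[e]]
      data.frame(item = paste0("ae_", e), mean = x$mean,
                 sd = x$sd %||% NA, ci_low = x$ci_low %||% NA,
                 ci_high = x$ci_high %||% NA)
    })))
  ut <- do.call(rbind, lapply(ce_arms(), function(a) {
    do.call(rbind, lapply(spec$utilities[[a]], function(n) {
      data.frame(arm = a, month = n$month, mean = n$mean,
                 ci_low = n$ci_low %||% NA, ci_high = n$ci_high %||% NA)
    }))
  }))
  files <- file.path(dir, paste0(stem, "_", c("events", "hazard_ratios",
                                              "costs", "utilities"), ".csv"))
  utils::write.csv(ev, files[1], row.names = FALSE)
  utils::write.csv(hr, files[2], row.names = FALSE)
  utils::write.csv(co, files[3], row.names = FALSE)
  utils::write.csv(ut, files[4], row.names = FALSE)
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Built-in parameter sets ----------------------------------------------------

#' Packaged parameter sets for the base case and scenarios
#'
#' Returns one of the analysis-ready parameter bundles shipped with the
#' package:
#'
#' * `partner2a_base` — five-year PARTNER 2A clinical inputs, Singapore
#'   costs, PARTNER 2A EQ-5D utilities; the base case.
#' * `s3i_scenario1` — SAPIEN 3 (PARTNER S3i) one-year outcomes
#'   extrapolated to five years (synthetic reconstruction, see the bundled
#'   file's header).
#' * `surtavi_scenario2` — SURTAVI two-year outcomes with SAVR-rate linear
#'   projection beyond 24 months (synthetic reconstruction).
#' * `base_with_disutilities` — the base case with adverse-event
#'   disutilities switched on (scenario 4).
#' * `horizon20_scenario3` — the base case with the horizon extended from
#'   5 to 20 years (scenario 3); all other inputs unchanged.
#'
#' @param name One of the set names above.
#' @return A validated `model_spec`.
#' @export
builtin_parameter_set <- function(name = c("partner2a_base", "s3i_scenario1",
                                           "surtavi_scenario2",
                                           "base_with_disutilities",
                                           "horizon20_scenario3")) {
  name <- match.arg(name)
  path_of <- function(fn) system.file("extdata", fn, package = "tavicea",
                                      mustWork = TRUE)
  spec <- switch(
    name,
    partner2a_base = load_model_spec(path_of("partner2a_base.yaml")),
    s3i_scenario1 = load_model_spec(path_of("s3i_scenario1_synthetic.yaml")),
    surtavi_scenario2 =
      load_model_spec(path_of("surtavi_scenario2_synthetic.yaml")),
    base_with_disutilities = {
      base <- load_model_spec(path_of("partner2a_base.yaml"))
      dis <- yaml::read_yaml(path_of("ae_disutilities_synthetic.yaml"))
      base$ae_disutilities <- dis
      base$settings$apply_ae_disutilities <- TRUE
      base$name <- "base_with_disutilities"
      base
    },
    horizon20_scenario3 = {
      base <- load_model_spec(path_of("partner2a_base.yaml"))
      base$settings$horizon_months <- 240
      base$name <- "horizon20_scenario3"
      base
    })
  stop_if_invalid(spec)
}
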