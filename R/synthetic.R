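## Synthetic cohorts with known piecewise-constant hazards, for end-to-end
## verification of the milestone -> transition -> engine pipeline.

#' Define a synthetic cohort with known generating parameters
#'
#' Builds the generating description of a synthetic two-arm cohort:
#' piecewise-constant monthly hazards per event and arm, true costs and
#' utilities, and the milestone readout grid. Milestone tables derived
#' from it ([generate_milestone_table()]) follow the exact survival
#' function, or a finite-cohort Kaplan-Meier estimate when sampling noise
#' is requested, emulating digitised trial readouts. There is no
#' censoring process: the emulated inputs are milestone probabilities, not
#' event times.
#'
#' @param hazards Named list `event -> list(tavi = ..., savr = ...)`; each
#'   arm entry is either a single non-negative monthly hazard or a list
#'   `list(breaks = <months>, rates = <hazards>)` of piecewise-constant
#'   rates (rates apply up to the matching break, last rate beyond).
#'   Events omitted get hazard 0.
#' @param milestone_months Readout grid (defaults to the trial layout
#'   1, 12, 24, 60).
#' @param utilities,costs Optional overrides; default to the packaged base
#'   case values.
#' @param hazard_ratios Stroke-mortality HR schedule; defaults to no
#'   excess (all 1), keeping closed forms exact.
#' @param km_cohort_size Finite cohort size for binomial milestone
#'   sampling; `NULL` (default) for exact milestones.
#' @param seed Seed used when sampling noisy milestones.
#' @return A `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(hazards,
                                  milestone_months = c(1, 12, 24, 60),
                                  utilities = NULL, costs = NULL,
                                  hazard_ratios = NULL,
                                  km_cohort_size = NULL, seed = 1) {
  stopifnot(length(milestone_months) >= 1, all(milestone_months >= 1),
            all(diff(milestone_months) > 0))
  norm_arm <- function(h) {
    if (is.numeric(h) && length(h) == 1) list(breaks = Inf, rates = h)
    else list(breaks = c(h$breaks[-length(h$breaks)], Inf), rates = h$rates)
  }
  hz <- lapply(ce_events(), function(ev) {
    h <- hazards[[ev]]
    if (is.null(h)) h <- list(tavi = 0, savr = 0)
    list(tavi = norm_arm(h$tavi), savr = norm_arm(h$savr))
  })
  names(hz) <- ce_events()
  bad <- unlist(lapply(hz, function(h)
    c(h$tavi$rates, h$savr$rates)))
  if (any(bad < 0)) stop("hazards must be >= 0", call. = FALSE)
  structure(list(hazards = hz, milestone_months = milestone_months,
                 utilities = utilities, costs = costs,
                 hazard_ratios = hazard_ratios,
                 km_cohort_size = km_cohort_size, seed = seed),
            class = "synthetic_cohort_spec")
}

# cumulative hazard of a piecewise-constant rate function at time t (months)
piecewise_cumhaz <- function(pw, t) {
  breaks <- c(0, pw$breaks)
  vapply(t, function(tt) {
    H <- 0
    for (i in seq_along(pw$rates)) {
      lo <- breaks[i]; hi <- min(tt, breaks[i + 1])
      if (hi > lo) H <- H + pw$rates[i] * (hi - lo)
      if (breaks[i + 1] >= tt) break
    }
    H
  }, numeric(1))
}

#' Milestone table values for a synthetic cohort
#'
#' Cumulative incidence at the milestone grid for one event and arm:
#' `1 - exp(-cumulative hazard)` exactly, or the empirical cumulative
#' incidence of a simulated finite cohort (inverse-transform sampling of
#' piecewise-exponential event times, no censoring) when the spec has a
#' `km_cohort_size`.
#'
#' @param sspec A [synthetic_cohort_spec()].
#' @param event Event name (see [ce_events()]).
#' @param arm `"tavi"` or `"savr"`.
#' @return Numeric vector of milestone cumulative probabilities.
#' @export
generate_milestone_table <- function(sspec, event, arm = c("tavi", "savr")) {
  arm <- match.arg(arm)
  if (!event %in% ce_events()) stop("unknown event: ", event, call. = FALSE)
  pw <- sspec$hazards[[event]][[arm]]
  mm <- sspec$milestone_months
  exact <- 1 - exp(-piecewise_cumhaz(pw, mm))
  if (is.null(sspec$km_cohort_size)) return(exact)
  # finite-cohort sampling: draw event times by inverting the cumulative
  # hazard, then read the empirical cumulative incidence at the grid
  n <- sspec$km_cohort_size
  set.seed(sspec$seed + match(event, ce_events()) * 1000L +
             match(arm, ce_arms()))
  u <- stats::runif(n)
  target <- -log(u)                      # exponential(1) cumulative hazards
  breaks <- c(0, pw$breaks)
  Hb <- piecewise_cumhaz(pw, pmin(breaks[-1], max(mm)))
  Hb_full <- c(0, Hb)
  times <- rep(Inf, n)
  for (i in seq_along(pw$rates)) {
    sel <- target > Hb_full[i] & target <= Hb_full[i + 1] & pw$rates[i] > 0
    times[sel] <- breaks[i] + (target[sel] - Hb_full[i]) / pw$rates[i]
    if (breaks[i + 1] >= max(mm)) break
  }
  vapply(mm, function(t) mean(times <= t), numeric(1))
}

#' Assemble a full model spec from a synthetic cohort
#'
#' Generates every milestone table from the synthetic cohort's hazards and
#' combines them with its true costs and utilities into a fully validated
#' `model_spec` usable by every downstream module. All generated tables
#' are `cumulative_incidence` except PAR, which keeps its prevalence
#' convention (here: the exact cumulative incidence used as a prevalence
#' readout).
#'
#' @param sspec A [synthetic_cohort_spec()].
#' @param settings Optional overrides merged over the base-case analysis
#'   settings (e.g. `list(horizon_months = 60)`).
#' @param name Spec name.
#' @return A validated `model_spec`.
#' @export
make_synthetic_model_spec <- function(sspec, settings = NULL,
                                      name = "synthetic") {
  base <- builtin_parameter_set("partner2a_base")
  st <- base$settings
  st$mortality_bridge <- "constant"   # keep closed forms exact
  for (k in names(settings %||% list())) st[[k]] <- settings[[k]]
  events <- lapply(ce_events(), function(ev) {
    list(kind = if (ev == "PAR") "prevalence" else "cumulative_incidence",
         tavi = generate_milestone_table(sspec, ev, "tavi"),
         savr = generate_milestone_table(sspec, ev, "savr"))
  })
  names(events) <- ce_events()
  spec <- new_model_spec(
    name = name,
    settings = st,
    milestone_months = sspec$milestone_months,
    events = events,
    hazard_ratios = sspec$hazard_ratios %||%
      list(by_cycle = rep(1, 15), after = 1),
    costs = sspec$costs %||% base$costs,
    utilities = sspec$utilities %||% base$utilities,
    ae_disutilities = base$ae_disutilities
  )
  stop_if_invalid(spec)
}
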