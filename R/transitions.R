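## Milestone probabilities -> per-cycle transition probabilities.

#' Constant monthly event probability over a survival interval
#'
#' Solves `(1 - p)^n_cycles = s_end / s_start` for `p`, the constant
#' per-cycle (monthly) probability that reproduces the drop in event-free
#' survival between two Kaplan-Meier readouts under a constant incidence
#' rate.
#'
#' @param s_start,s_end Event-free survival at the start and end of the
#'   interval, with `0 < s_end <= s_start <= 1`.
#' @param n_cycles Number of monthly cycles in the interval (>= 1).
#' @return Per-cycle probability in \[0, 1\].
#' @examples
#' interval_monthly_prob(1, 0.97, 1)        # 30-day mortality of 3%
#' interval_monthly_prob(0.90, 0.858, 12)   # year 1 -> year 2
#' @export
interval_monthly_prob <- function(s_start, s_end, n_cycles) {
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  if (s_start <= 0 || s_start > 1)
    stop("s_start must lie in (0, 1]", call. = FALSE)
  if (s_end > s_start)
    stop("s_end > s_start: non-monotone cumulative incidence", call. = FALSE)
  if (s_end < 0) stop("s_end must be >= 0", call. = FALSE)
  if (s_end == 0) return(1)
  1 - (s_end / s_start)^(1 / n_cycles)
}

#' Convert a milestone table into per-cycle incidence probabilities
#'
#' Expands milestone probabilities on the Kaplan-Meier readout grid into a
#' vector of per-cycle (monthly) incidence probabilities over the model
#' horizon.
#'
#' For `kind = "cumulative_incidence"` each inter-milestone interval gets
#' either a constant monthly rate (geometric bridging,
#' [interval_monthly_prob()]) or — for intervals starting at or after
#' `linear_from` when `bridge = "linear"` — a linear increase in
#' *cumulative* incidence, converted to conditional per-cycle
#' probabilities. Both modes reproduce every milestone exactly. The
#' published transition formula is the conditional-probability form
#' `1 - S(t)/S(t-1)` (the orientation printed with t and t-1 swapped would
#' yield negative values for decreasing survival).
#'
#' For `kind = "prevalence"` the per-cycle new incidence is the positive
#' part of the prevalence increment spread uniformly over the interval;
#' decreasing prevalence generates zero new incidence (no refunds).
#'
#' Beyond the last milestone the last interval's per-cycle probability is
#' carried forward (cumulative kind) or the floored increment rate is
#' carried forward (prevalence kind).
#'
#' @param values Milestone probabilities (one per milestone month).
#' @param months Milestone months, strictly increasing, first >= 1.
#' @param horizon_months Number of monthly cycles to cover.
#' @param kind `"cumulative_incidence"` or `"prevalence"`.
#' @param bridge `"constant"` (geometric) or `"linear"` (linear cumulative
#'   incidence) for intervals starting at or after `linear_from`.
#' @param linear_from First month from which linear bridging applies
#'   (only used when `bridge = "linear"`).
#' @return Numeric vector of length `horizon_months` of per-cycle
#'   probabilities.
#' @export
km_schedule_to_monthly <- function(values, months, horizon_months,
                                   kind = c("cumulative_incidence",
                                            "prevalence"),
                                   bridge = c("constant", "linear"),
                                   linear_from = 24) {
  kind <- match.arg(kind)
  bridge <- match.arg(bridge)
  if (!length(values)) stop("empty milestone table", call. = FALSE)
  if (length(values) != length(months))
    stop("values and months must have equal length", call. = FALSE)
  if (any(months < 1) || any(diff(months) <= 0))
    stop("milestone months must be strictly increasing, first >= 1",
         call. = FALSE)

  p <- numeric(horizon_months)
  if (kind == "cumulative_incidence") {
    if (any(diff(values) < 0))
      stop("cumulative incidence must be non-decreasing", call. = FALSE)
    cum <- c(0, values)
    mon <- c(0, months)
    for (i in seq_along(values)) {
      t0 <- mon[i]; t1 <- mon[i + 1]
      if (t0 >= horizon_months) break
      cyc <- seq(t0 + 1, min(t1, horizon_months))
      if (cum[i] >= 1) {
        p[cyc] <- 0          # cohort already extinct for this event
      } else if (bridge == "linear" && t0 >= linear_from) {
        # cumulative incidence linear in t within the interval
        ct <- cum[i] + (cum[i + 1] - cum[i]) * (seq(t0, t1) - t0) / (t1 - t0)
        cond <- (ct[-1] - ct[-length(ct)]) / (1 - ct[-length(ct)])
        cond[!is.finite(cond)] <- 0
        p[cyc] <- cond[seq_along(cyc)]
      } else {
        p[cyc] <- interval_monthly_prob(1 - cum[i], 1 - cum[i + 1], t1 - t0)
      }
    }
    if (horizon_months > months[length(months)]) {
      # carry the last interval's constant-rate probability forward
      n <- length(values)
      t0 <- if (n == 1) 0 else months[n - 1]
      c0 <- if (n == 1) 0 else values[n - 1]
      p_last <- if (c0 >= 1) 0 else
        interval_monthly_prob(1 - c0, 1 - values[n], months[n] - t0)
      ext <- seq(months[n] + 1, horizon_months)
      p[ext] <- p_last
    }
  } else {
    prev <- c(0, values)
    mon <- c(0, months)
    rate <- 0
    for (i in seq_along(values)) {
      t0 <- mon[i]; t1 <- mon[i + 1]
      if (t0 >= horizon_months) break
      rate <- max(0, (prev[i + 1] - prev[i]) / (t1 - t0))
      cyc <- seq(t0 + 1, min(t1, horizon_months))
      p[cyc] <- rate
    }
    if (horizon_months > months[length(months)])
      p[seq(months[length(months)] + 1, horizon_months)] <- rate
  }
  p
}

#' Split all-cause mortality by stroke status
#'
#' Given the whole-cohort monthly mortality probability `m_all`, the
#' proportion of the (living) cohort currently in the stroke state
#' `x_stroke`, and the stroke-vs-no-stroke hazard ratio `rr`, returns the
#' mortality pair `(m_no_stroke, m_stroke)` from the mixture identity
#' `m_all = x*rr*m_ns + (1 - x)*m_ns`, i.e.
#' `m_ns = m_all / (x*rr + 1 - x)` and `m_s = rr * m_ns` (capped at 1).
#' The mortality of patients without stroke is the unknown being solved
#' for; the weighted recombination reproduces `m_all` exactly whenever the
#' cap does not bind.
#'
#' @param m_all Monthly all-cause mortality probability in \[0, 1\].
#' @param x_stroke Proportion of the living cohort in the stroke state.
#' @param rr Hazard (relative-risk) ratio, >= 1.
#' @return Named numeric vector `c(m_no_stroke = ..., m_stroke = ...)`.
#' @examples
#' split_mortality_by_stroke(0.01, 0.05, 8.5)
#' @export
split_mortality_by_stroke <- function(m_all, x_stroke, rr) {
  if (m_all < 0 || m_all > 1) stop("m_all must lie in [0, 1]", call. = FALSE)
  if (x_stroke < 0 || x_stroke > 1)
    stop("x_stroke must lie in [0, 1]", call. = FALSE)
  if (rr < 1) stop("rr must be >= 1", call. = FALSE)
  m_ns <- m_all / (x_stroke * rr + (1 - x_stroke))
  c(m_no_stroke = m_ns, m_stroke = min(1, rr * m_ns))
}

# Solve for the no-stroke monthly mortality m_ns such that expected deaths
# equal m_all * alive when stroke strata die at min(1, hr_d * m_ns). The
# uncapped solution is the closed-form mixture split; when a stratum's
# capped probability saturates at 1 the remaining mortality is re-solved
# over the uncapped strata so total deaths still match the milestone table.
solve_mixture_m_ns <- function(m_all, ns, s, hr_dur) {
  alive <- ns + sum(s)
  if (alive <= 0 || m_all <= 0) return(0)
  capped <- rep(FALSE, length(s))
  repeat {
    denom <- ns + sum(s[!capped] * hr_dur[!capped])
    target <- m_all * alive - sum(s[capped])
    m_ns <- if (denom > 0) target / denom else 0
    m_ns <- min(max(m_ns, 0), 1)
    newly <- !capped & (hr_dur * m_ns >= 1) & (s > 0)
    if (!any(newly)) return(m_ns)
    capped <- capped | newly
  }
}

# hazard ratio applicable to a patient d months after stroke onset
hr_for_duration <- function(hazard_ratios, d) {
  hrs <- hazard_ratios$by_cycle
  ifelse(d <= length(hrs), hrs[pmin(d, length(hrs))], hazard_ratios$after)
}

#' Build the per-cycle transition schedule for one arm
#'
#' Converts every milestone table of a validated spec into per-cycle
#' probabilities over the full horizon and derives the no-stroke mortality
#' stream `p_death_ns` by running the deterministic stroke-duration
#' mixture: at each cycle the whole-cohort mortality from the milestone
#' table is divided by the duration-weighted hazard-ratio mixture of the
#' current (deterministic) cohort composition, so that the implied
#' all-cause survival reproduces the milestones exactly while stroke-state
#' patients die at `hr(d) * p_death_ns` during the first 15 months after
#' stroke onset and at the no-stroke rate thereafter.
#'
#' @param spec A validated `model_spec`.
#' @param arm `"tavi"` or `"savr"`.
#' @return A `transition_schedule` list with elements `arm`, `horizon`,
#'   `p_death_all`, `p_death_ns`, `p_stroke`, `p_ae` (cycles x adverse
#'   events matrix), `hr_by_duration` (length 16: months 1..15 and beyond),
#'   and `occupancy` (the deterministic no-stroke/stroke-strata/dead trace
#'   used to derive the split).
#' @export
build_transition_schedule <- function(spec, arm = c("tavi", "savr")) {
  arm <- match.arg(arm)
  stop_if_invalid(spec)
  st <- spec$settings
  H <- st$horizon_months
  mm <- spec$milestone_months
  bridge <- st$mortality_bridge %||% "linear"
  lin_from <- st$mortality_linear_from %||% 24

  sched_of <- function(ev, bridge_mode = "constant", lf = 24) {
    tab <- spec$events[[ev]]
    km_schedule_to_monthly(tab[[arm]], mm, H, kind = tab$kind,
                           bridge = bridge_mode, linear_from = lf)
  }

  p_death_all <- sched_of("all_cause_mortality", bridge, lin_from)
  p_stroke <- sched_of("disabling_stroke")
  ae_events <- ce_indep_ae_events()
  p_ae <- vapply(ae_events, sched_of, numeric(H))
  dimnames(p_ae) <- list(NULL, ae_events)

  n_dur <- length(spec$hazard_ratios$by_cycle)   # tracked stroke durations
  hr_dur <- c(spec$hazard_ratios$by_cycle, spec$hazard_ratios$after)

  # deterministic mixture recursion to derive p_death_ns
  ns <- 1
  s <- numeric(n_dur + 1)   # strata: months since stroke 1..n_dur, then beyond
  p_death_ns <- numeric(H)
  occ <- matrix(0, H + 1, 3,
                dimnames = list(NULL, c("no_stroke", "stroke", "dead")))
  occ[1, ] <- c(1, 0, 0)
  for (t in seq_len(H)) {
    new_s <- ns * p_stroke[t]
    ns1 <- ns - new_s
    s1 <- c(new_s, s[seq_len(n_dur - 1)], s[n_dur] + s[n_dur + 1])
    alive <- ns1 + sum(s1)
    m_ns <- solve_mixture_m_ns(p_death_all[t], ns1, s1, hr_dur)
    m_s <- pmin(1, hr_dur * m_ns)
    ns <- ns1 * (1 - m_ns)
    s <- s1 * (1 - m_s)
    p_death_ns[t] <- m_ns
    occ[t + 1, ] <- c(ns, sum(s), 1 - ns - sum(s))
  }

  structure(list(arm = arm, horizon = H,
                 p_death_all = p_death_all,
                 p_death_ns = p_death_ns,
                 p_stroke = p_stroke,
                 p_ae = p_ae,
                 hr_by_duration = hr_dur,
                 occupancy = occ),
            class = "transition_schedule")
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("<transition_schedule> arm ", x$arm, ", ", x$horizon, " cycles\n",
      sep = "")
  cat("  cumulative mortality at horizon: ",
      round(1 - prod(1 - x$p_death_all), 4), "\n", sep = "")
  invisible(x)
}
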