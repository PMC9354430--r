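## Cohort-expectation and first-order microsimulation evaluation of a
## transition schedule with cost and utility accrual.

#' Monthly discount factor
#'
#' `(1 + annual_rate)^(-cycle/12)`: continuous-in-cycles compounding of an
#' annual discount rate on a monthly cycle grid. Cycle 0 (model entry, the
#' index procedure) is undiscounted.
#'
#' @param cycle Cycle index (months since model entry), >= 0.
#' @param annual_rate Annual discount rate (fraction, >= 0).
#' @return Discount factor(s) in (0, 1].
#' @examples
#' discount_factor(12, 0.03)  # = 1/1.03
#' @export
discount_factor <- function(cycle, annual_rate) {
  if (any(cycle < 0)) stop("cycle must be >= 0", call. = FALSE)
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

#' Utility applicable at a model cycle
#'
#' Linear interpolation of the arm's EQ-5D utility nodes at months 1, 12
#' and 24; beyond the pooling month both arms receive the pooled value
#' (the TAVI month-24 utility). The model starts at cycle 1 with the
#' month-1 utility, so cycle 0 is an error.
#'
#' @param spec A `model_spec`.
#' @param arm `"tavi"` or `"savr"`.
#' @param cycle Cycle index (>= 1); vectorised.
#' @return Utility value(s) in \[0, 1\].
#' @export
utility_at_cycle <- function(spec, arm = c("tavi", "savr"), cycle) {
  arm <- match.arg(arm)
  if (any(cycle < 1))
    stop("cycle must be >= 1 (model starts at cycle 1)", call. = FALSE)
  nodes <- spec$utilities[[arm]]
  months <- vapply(nodes, function(n) as.numeric(n$month), numeric(1))
  means <- vapply(nodes, function(n) as.numeric(n$mean), numeric(1))
  pool_m <- as.numeric(spec$utilities$pooled_after_month)
  pooled <- vapply(spec$utilities$tavi,
                   function(n) as.numeric(n$mean), numeric(1))
  pooled <- pooled[vapply(spec$utilities$tavi,
                          function(n) as.numeric(n$month),
                          numeric(1)) == pool_m]
  out <- stats::approx(months, means, xout = pmin(cycle, pool_m),
                       rule = 2)$y
  out[cycle > pool_m] <- pooled
  out
}

ae_cost_vector <- function(spec, events) {
  vapply(events, function(e) as.numeric(spec$costs$ae[[e]]$mean), numeric(1))
}

ae_disutility_vector <- function(spec, events) {
  if (!isTRUE(spec$settings$apply_ae_disutilities)) return(rep(0, length(events)))
  d <- spec$ae_disutilities$one_off
  vapply(events, function(e) as.numeric(d[[e]] %||% 0), numeric(1))
}

new_ce_result <- function(arm, mode, n, cost_index, cost_ae, cost_followup,
                          qaly, cum_mortality, ae_counts,
                          se_cost = NA_real_, se_qaly = NA_real_) {
  structure(list(arm = arm, mode = mode, n = n,
                 cost_total = cost_index + cost_ae + cost_followup,
                 qaly_total = qaly,
                 cost_index = cost_index, cost_ae = cost_ae,
                 cost_followup = cost_followup,
                 cum_mortality = cum_mortality,
                 ae_counts = ae_counts,
                 se_cost = se_cost, se_qaly = se_qaly),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> ", toupper(x$arm), " (", x$mode, ")\n", sep = "")
  cat(sprintf("  cost  %s (index %s + AE %s + follow-up %s)\n",
              format(round(x$cost_total), big.mark = ","),
              format(round(x$cost_index), big.mark = ","),
              format(round(x$cost_ae), big.mark = ","),
              format(round(x$cost_followup), big.mark = ",")))
  cat(sprintf("  QALYs %.4f\n", x$qaly_total))
  invisible(x)
}

#' Deterministic cohort evaluation of one arm
#'
#' Runs the three-state cohort trace (no stroke, stroke stratified by
#' months since onset, dead) over the horizon and accrues discounted costs
#' and QALYs. Per cycle, in order: adverse events are drawn on the
#' population alive at cycle start (one-time treatment costs, and one-off
#' disutilities when enabled); incident strokes move to the stroke state
#' (one-time stroke cost); deaths are applied with the stroke-status
#' split. Death within a cycle forfeits that cycle's utility and follow-up
#' cost but not adverse-event costs already incurred. The index episode
#' cost is charged undiscounted at entry. Follow-up care accrues as
#' `followup_annual/12` per surviving cycle, plus `neurologist_visit/3`
#' per cycle spent in the stroke state.
#'
#' @param spec A validated `model_spec`.
#' @param arm `"tavi"` or `"savr"`.
#' @param schedule Optionally a precomputed [build_transition_schedule()]
#'   result for this arm (to avoid rebuilding in tight loops).
#' @return List with `trace` (a `cohort_trace` data frame: per-cycle
#'   occupancies, discounted cost/QALY increments and cumulative totals)
#'   and `result` (a `ce_result`).
#' @export
run_cohort <- function(spec, arm = c("tavi", "savr"), schedule = NULL) {
  arm <- match.arg(arm)
  sch <- schedule %||% build_transition_schedule(spec, arm)
  st <- spec$settings
  H <- sch$horizon
  disc <- discount_factor(seq_len(H), st$annual_discount)
  hcc <- isTRUE(st$half_cycle_correction)

  ae_events <- colnames(sch$p_ae)
  ae_cost <- ae_cost_vector(spec, ae_events)
  ae_dis <- ae_disutility_vector(spec, ae_events)
  stroke_cost <- as.numeric(spec$costs$ae$disabling_stroke$mean)
  stroke_dis <- if (isTRUE(st$apply_ae_disutilities))
    as.numeric(spec$ae_disutilities$stroke_state_decrement %||% 0) else 0
  fu_m <- spec$costs$followup_annual / 12
  neuro_m <- spec$costs$neurologist_visit / 3
  u <- utility_at_cycle(spec, arm, seq_len(H))

  n_dur <- length(spec$hazard_ratios$by_cycle)
  hr_dur <- sch$hr_by_duration

  ns <- 1; s <- numeric(n_dur + 1)
  cost_index <- as.numeric(spec$costs$index_episode[[arm]])
  cost_ae <- 0; cost_fu <- 0; qaly <- 0
  ae_counts <- stats::setNames(numeric(length(ae_events) + 1),
                               c(ae_events, "disabling_stroke"))
  occ <- matrix(0, H + 1, 3,
                dimnames = list(NULL, c("no_stroke", "stroke", "dead")))
  occ[1, ] <- c(1, 0, 0)
  cost_cycle <- numeric(H); qaly_cycle <- numeric(H)
  cum_mort <- numeric(H)

  for (t in seq_len(H)) {
    alive0 <- ns + sum(s)
    # adverse events on everyone alive at cycle start
    ae_new <- alive0 * sch$p_ae[t, ]
    ae_counts[ae_events] <- ae_counts[ae_events] + ae_new
    c_t <- sum(ae_new * ae_cost)
    dq_t <- sum(ae_new * ae_dis)
    # stroke transition
    new_s <- ns * sch$p_stroke[t]
    ae_counts["disabling_stroke"] <- ae_counts["disabling_stroke"] + new_s
    c_t <- c_t + new_s * stroke_cost
    ns1 <- ns - new_s
    s1 <- c(new_s, s[seq_len(n_dur - 1)], s[n_dur] + s[n_dur + 1])
    # death split by stroke status and months since stroke
    m_ns <- sch$p_death_ns[t]
    m_s <- pmin(1, hr_dur * m_ns)
    ns <- ns1 * (1 - m_ns)
    s <- s1 * (1 - m_s)
    alive1 <- ns + sum(s); stroke1 <- sum(s)
    # accrual weights: survivors only, optionally half-cycle corrected
    w_all <- if (hcc) (alive0 + alive1) / 2 else alive1
    w_str <- if (hcc) (sum(s1) + stroke1) / 2 else stroke1
    q_t <- (w_all * u[t] - w_str * stroke_dis) / 12 - dq_t
    f_t <- w_all * fu_m + w_str * neuro_m
    cost_ae <- cost_ae + c_t * disc[t]
    cost_fu <- cost_fu + f_t * disc[t]
    qaly <- qaly + q_t * disc[t]
    cost_cycle[t] <- (c_t + f_t) * disc[t]
    qaly_cycle[t] <- q_t * disc[t]
    occ[t + 1, ] <- c(ns, stroke1, 1 - ns - stroke1)
    cum_mort[t] <- 1 - alive1
  }
  trace <- data.frame(cycle = 0:H,
                      no_stroke = occ[, 1], stroke = occ[, 2],
                      dead = occ[, 3],
                      cost = c(cost_index, cost_cycle),  # entry cost at cycle 0
                      qaly = c(0, qaly_cycle))
  trace$cum_cost <- cumsum(trace$cost)
  trace$cum_qaly <- cumsum(trace$qaly)
  class(trace) <- c("cohort_trace", "data.frame")

  res <- new_ce_result(arm, "cohort", NA_integer_, cost_index, cost_ae,
                       cost_fu, qaly, cum_mort, ae_counts)
  list(trace = trace, result = res)
}

#' First-order microsimulation of one arm
#'
#' Simulates `n` individual patients through the same per-cycle transition
#' schedule the cohort mode uses: each alive patient draws adverse events,
#' then stroke incidence, then death (no-stroke rate, or `hr(d)` times it
#' during the first 15 months after stroke onset). Identical seeds give
#' identical results. The cohort trace is the exact expectation of this
#' process, so microsimulation means converge to [run_cohort()] totals at
#' the Monte Carlo rate.
#'
#' @param spec A validated `model_spec`.
#' @param arm `"tavi"` or `"savr"`.
#' @param n Number of simulated patients (>= 1).
#' @param seed Integer seed for the random stream.
#' @param schedule Optional precomputed schedule for this arm.
#' @return A `ce_result` with per-patient means, Monte Carlo standard
#'   errors (`se_cost`, `se_qaly`), cumulative mortality by cycle and mean
#'   adverse-event counts.
#' @export
run_microsim <- function(spec, arm = c("tavi", "savr"), n = NULL,
                         seed = NULL, schedule = NULL) {
  arm <- match.arg(arm)
  sch <- schedule %||% build_transition_schedule(spec, arm)
  st <- spec$settings
  n <- as.integer(n %||% st$n_microsim)
  seed <- as.integer(seed %||% st$seed)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  H <- sch$horizon
  disc <- discount_factor(seq_len(H), st$annual_discount)

  ae_events <- colnames(sch$p_ae)
  ae_cost <- ae_cost_vector(spec, ae_events)
  ae_dis <- ae_disutility_vector(spec, ae_events)
  stroke_cost <- as.numeric(spec$costs$ae$disabling_stroke$mean)
  stroke_dis <- if (isTRUE(st$apply_ae_disutilities))
    as.numeric(spec$ae_disutilities$stroke_state_decrement %||% 0) else 0
  fu_m <- spec$costs$followup_annual / 12
  neuro_m <- spec$costs$neurologist_visit / 3
  u <- utility_at_cycle(spec, arm, seq_len(H))
  n_dur <- length(spec$hazard_ratios$by_cycle)
  hr_dur <- sch$hr_by_duration

  set.seed(seed)
  alive <- rep(TRUE, n)
  dur <- integer(n)              # 0 = no stroke, else months since stroke
  cost <- rep(as.numeric(spec$costs$index_episode[[arm]]), n)
  qaly <- numeric(n)
  ae_counts <- stats::setNames(numeric(length(ae_events) + 1),
                               c(ae_events, "disabling_stroke"))
  cum_mort <- numeric(H)

  for (t in seq_len(H)) {
    ia <- which(alive)
    if (!length(ia)) { cum_mort[t:H] <- 1; break }
    na <- length(ia)
    # adverse events
    for (j in seq_along(ae_events)) {
      p <- sch$p_ae[t, j]
      if (p <= 0) next
      hit <- ia[stats::runif(na) < p]
      if (length(hit)) {
        cost[hit] <- cost[hit] + ae_cost[j] * disc[t]
        if (ae_dis[j] > 0) qaly[hit] <- qaly[hit] - ae_dis[j] * disc[t]
        ae_counts[j] <- ae_counts[j] + length(hit)
      }
    }
    # stroke-state ageing, then incident strokes
    has_s <- ia[dur[ia] > 0L]
    dur[has_s] <- dur[has_s] + 1L
    ns_idx <- ia[dur[ia] == 0L]
    if (length(ns_idx) && sch$p_stroke[t] > 0) {
      newst <- ns_idx[stats::runif(length(ns_idx)) < sch$p_stroke[t]]
      if (length(newst)) {
        dur[newst] <- 1L
        cost[newst] <- cost[newst] + stroke_cost * disc[t]
        ae_counts["disabling_stroke"] <-
          ae_counts["disabling_stroke"] + length(newst)
      }
    }
    # death
    m_ns <- sch$p_death_ns[t]
    p_die <- ifelse(dur[ia] == 0L, m_ns,
                    pmin(1, hr_dur[pmin(dur[ia], n_dur + 1L)] * m_ns))
    dies <- stats::runif(na) < p_die
    alive[ia[dies]] <- FALSE
    surv <- ia[!dies]
    # accrual for survivors of the cycle
    in_stroke <- dur[surv] > 0L
    qaly[surv] <- qaly[surv] +
      (u[t] - ifelse(in_stroke, stroke_dis, 0)) / 12 * disc[t]
    cost[surv] <- cost[surv] + (fu_m + ifelse(in_stroke, neuro_m, 0)) * disc[t]
    cum_mort[t] <- 1 - sum(alive) / n
  }

  idx <- as.numeric(spec$costs$index_episode[[arm]])
  res <- new_ce_result(arm, "microsim", n,
                       cost_index = idx,
                       cost_ae = mean(cost) - idx,  # AE + follow-up combined
                       cost_followup = 0,
                       qaly = mean(qaly), cum_mortality = cum_mort,
                       ae_counts = ae_counts / n,
                       se_cost = stats::sd(cost) / sqrt(n),
                       se_qaly = stats::sd(qaly) / sqrt(n))
  res
}

#' Pairwise cost-effectiveness comparison
#'
#' Computes TAVI-minus-SAVR increments, the ICER or a dominance label, and
#' the incremental net monetary benefit `INB = wtp * dQALY - dCost`.
#'
#' Labels: `"icer"` when the increments share the appropriate signs
#' (`dQALY > 0, dCost > 0` or `dQALY < 0, dCost < 0`); `"dominant"` when
#' TAVI gains QALYs at no extra cost; `"dominated"` when TAVI loses QALYs
#' at no saving; `"undefined"` (with `icer = NA`) when `dQALY = 0`.
#'
#' @param res_tavi,res_savr `ce_result` objects for the two arms.
#' @param wtp Willingness-to-pay threshold (money per QALY).
#' @return A `ce_comparison` list: both results, `d_cost`, `d_qaly`,
#'   `icer`, `label`, `inb`, `wtp`.
#' @export
compare_arms <- function(res_tavi, res_savr, wtp) {
  d_cost <- res_tavi$cost_total - res_savr$cost_total
  d_qaly <- res_tavi$qaly_total - res_savr$qaly_total
  if (d_qaly > 0 && d_cost <= 0) {
    label <- "dominant"; icer <- NA_real_
  } else if (d_qaly < 0 && d_cost >= 0) {
    label <- "dominated"; icer <- NA_real_
  } else if (d_qaly == 0) {
    label <- "undefined"; icer <- NA_real_
  } else {
    label <- "icer"; icer <- d_cost / d_qaly
  }
  structure(list(tavi = res_tavi, savr = res_savr,
                 d_cost = d_cost, d_qaly = d_qaly,
                 icer = icer, label = label,
                 wtp = wtp, inb = wtp * d_qaly - d_cost),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat("<ce_comparison> TAVI vs SAVR\n")
  cat(sprintf("  costs : TAVI %s, SAVR %s, incremental %s (2020 US$)\n",
              format(round(x$tavi$cost_total), big.mark = ","),
              format(round(x$savr$cost_total), big.mark = ","),
              format(round(x$d_cost), big.mark = ",")))
  cat(sprintf("  QALYs : TAVI %.4f, SAVR %.4f, incremental %.4f\n",
              x$tavi$qaly_total, x$savr$qaly_total, x$d_qaly))
  if (x$label == "icer") {
    cat(sprintf("  ICER  : %s per QALY\n",
                format(round(x$icer), big.mark = ",")))
  } else {
    cat("  ICER  : ", x$label, "\n", sep = "")
  }
  cat(sprintf("  INB   : %s at WTP %s per QALY\n",
              format(round(x$inb), big.mark = ","),
              format(round(x$wtp), big.mark = ",")))
  invisible(x)
}
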