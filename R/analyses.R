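## Analysis orchestration: base case, one-way sensitivity analysis,
## probabilistic sensitivity analysis / CEAC, scenarios.

#' Base-case cost-effectiveness comparison
#'
#' Evaluates both arms of a spec and compares them at the configured
#' willingness-to-pay. `mode = "cohort"` (default) uses the deterministic
#' cohort trace, the exact expectation of the microsimulation;
#' `mode = "microsim"` uses first-order Monte Carlo with `n_microsim`
#' patients per arm and the configured seed (common random numbers across
#' arms).
#'
#' @param spec A validated `model_spec`.
#' @param mode `"cohort"` or `"microsim"`.
#' @param n,seed Microsimulation size and seed; default to the spec
#'   settings. Ignored in cohort mode.
#' @return A `ce_comparison`.
#' @export
base_case <- function(spec, mode = c("cohort", "microsim"),
                      n = NULL, seed = NULL) {
  mode <- match.arg(mode)
  res <- lapply(c("tavi", "savr"), function(arm) {
    if (mode == "cohort") run_cohort(spec, arm)$result
    else run_microsim(spec, arm, n = n, seed = seed)
  })
  compare_arms(res[[1]], res[[2]], spec$settings$wtp)
}

## ---- OWSA -------------------------------------------------------------------

# registry of one-way parameters: bounds rule + spec mutator
owsa_parameter_table <- function(spec) {
  params <- list()
  add <- function(name, low, high, mutate) {
    params[[name]] <<- list(name = name, low = low, high = high,
                            mutate = mutate)
  }
  add("discount_rate", 0, 0.05, function(sp, v) {
    sp$settings$annual_discount <- v; sp
  })
  for (arm in ce_arms()) {
    local({
      a <- arm
      m <- spec$costs$index_episode[[a]]
      add(paste0("index_cost_", a), 0.8 * m, 1.2 * m, function(sp, v) {
        sp$costs$index_episode[[a]] <- v; sp
      })
    })
  }
  for (ev in ce_ae_events()) {
    local({
      e <- ev
      x <- spec$costs$ae[[e]]
      lo <- x$ci_low %||% (0.8 * x$mean)
      hi <- x$ci_high %||% (1.2 * x$mean)
      add(paste0("ae_cost_", e), lo, hi, function(sp, v) {
        sp$costs$ae[[e]]$mean <- v; sp
      })
    })
  }
  for (arm in ce_arms()) {
    for (i in seq_along(spec$utilities[[arm]])) {
      local({
        a <- arm; k <- i
        nd <- spec$utilities[[a]][[k]]
        add(paste0("utility_", a, "_m", nd$month),
            nd$ci_low %||% (0.8 * nd$mean),
            nd$ci_high %||% min(1, 1.2 * nd$mean),
            function(sp, v) { sp$utilities[[a]][[k]]$mean <- v; sp })
      })
    }
  }
  for (nm in c("followup_annual", "neurologist_visit")) {
    local({
      f <- nm
      m <- spec$costs[[f]]
      add(paste0("cost_", f), 0.8 * m, 1.2 * m, function(sp, v) {
        sp$costs[[f]] <- v; sp
      })
    })
  }
  params
}

#' One-way (deterministic) sensitivity analysis
#'
#' Re-evaluates the ICER in cohort mode with each parameter set to its
#' lower and upper bound while all others stay at base values. Bounds are
#' the 95% confidence interval where the input tables provide one,
#' otherwise +/-20% of the mean; the discount rate varies from 0 to 5%.
#' Results are ordered by descending tornado bar width.
#'
#' @param spec A validated `model_spec`.
#' @param parameters Optional character vector restricting the parameter
#'   set (default: every registered parameter).
#' @param mode Evaluation mode passed to [base_case()]; `"cohort"`
#'   isolates parameter effects from first-order noise.
#' @return A data frame with one row per parameter: bounds, ICERs at each
#'   bound, base ICER and bar `width`, ordered by descending width.
#' @export
owsa <- function(spec, parameters = NULL, mode = "cohort") {
  registry <- owsa_parameter_table(spec)
  if (!is.null(parameters)) {
    unknown <- setdiff(parameters, names(registry))
    if (length(unknown))
      stop("unknown OWSA parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    registry <- registry[parameters]
  }
  base <- base_case(spec, mode = mode)
  rows <- lapply(registry, function(p) {
    icers <- vapply(c(p$low, p$high), function(v) {
      base_case(p$mutate(spec, v), mode = mode)$icer
    }, numeric(1))
    data.frame(parameter = p$name, low = p$low, high = p$high,
               icer_low = icers[1], icer_high = icers[2],
               icer_base = base$icer,
               width = abs(icers[2] - icers[1]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$width), , drop = FALSE]
}

## ---- PSA --------------------------------------------------------------------

#' Method-of-moments draws from beta or gamma distributions
#'
#' Parameterises a beta (for probabilities/utilities) or gamma (for
#' costs) distribution from its mean and standard deviation and draws from
#' it. `sd = 0` returns the mean (degenerate limit). Infeasible moments
#' (beta with `sd^2 >= mean*(1-mean)`) are an explicit error, never
#' silently clamped.
#'
#' @param kind `"beta"` or `"gamma"`.
#' @param mean,sd Target moments; beta requires `mean` in (0, 1).
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_from_moments <- function(kind = c("beta", "gamma"), mean, sd, n = 1) {
  kind <- match.arg(kind)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) return(rep(mean, n))
  if (kind == "beta") {
    if (mean <= 0 || mean >= 1)
      stop("beta requires mean in (0, 1)", call. = FALSE)
    v <- sd^2
    if (v >= mean * (1 - mean))
      stop("infeasible beta moments: sd^2 >= mean*(1-mean)", call. = FALSE)
    nu <- mean * (1 - mean) / v - 1
    stats::rbeta(n, mean * nu, (1 - mean) * nu)
  } else {
    if (mean <= 0) stop("gamma requires mean > 0", call. = FALSE)
    stats::rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
  }
}

# sd for a probability with no published CI: +/-20% read as a 95% interval
prob_sd <- function(mean) 0.2 * mean / stats::qnorm(0.975)

# one second-order draw of the uncertain parameters; returns the perturbed
# spec plus the sampled values. Month-1 probability draws are retried when
# they break cumulative monotonicity against the next milestone.
psa_draw_spec <- function(spec, sd_scale = 1, max_retry = 100) {
  sampled <- c()
  sp <- spec
  for (ev in ce_events()) {
    tab <- spec$events[[ev]]
    for (arm in ce_arms()) {
      m <- tab[[arm]][1]
      if (m <= 0 || m >= 1) next
      sd <- prob_sd(m) * sd_scale
      if (sd == 0) { draw <- m } else {
        ok <- FALSE
        for (i in seq_len(max_retry)) {
          draw <- sample_from_moments("beta", m, sd, 1)
          if (tab$kind == "prevalence" || length(tab[[arm]]) < 2 ||
              draw <= tab[[arm]][2]) { ok <- TRUE; break }
        }
        if (!ok) stop("could not draw a monotone month-1 probability for ",
                      ev, " (", arm, ")", call. = FALSE)
      }
      sp$events[[ev]][[arm]][1] <- draw
      sampled[paste0("p1_", ev, "_", arm)] <- draw
    }
  }
  for (ev in ce_ae_events()) {
    x <- spec$costs$ae[[ev]]
    sd <- (x$sd %||% 0) * sd_scale
    draw <- if (sd > 0) sample_from_moments("gamma", x$mean, sd, 1) else x$mean
    # the CI describes second-order uncertainty, not a constraint on draws
    sp$costs$ae[[ev]] <- list(mean = draw, sd = x$sd)
    sampled[paste0("cost_", ev)] <- draw
  }
  for (arm in ce_arms()) {
    for (k in seq_along(spec$utilities[[arm]])) {
      nd <- spec$utilities[[arm]][[k]]
      sd <- if (!is.null(nd$ci_low) && !is.null(nd$ci_high))
        (nd$ci_high - nd$ci_low) / (2 * stats::qnorm(0.975)) else 0
      sd <- sd * sd_scale
      draw <- if (sd > 0) sample_from_moments("beta", nd$mean, sd, 1)
              else nd$mean
      sp$utilities[[arm]][[k]]$mean <- draw
      sampled[paste0("utility_", arm, "_m", nd$month)] <- draw
    }
  }
  list(spec = sp, sampled = sampled)
}

#' Probabilistic sensitivity analysis with CEAC
#'
#' Runs `n_outer` second-order Monte Carlo draws. Per draw, month-1 event
#' probabilities and utilities are sampled from method-of-moments beta
#' distributions and adverse-event treatment costs from gamma
#' distributions (means and SDs/CIs from the input tables; probabilities
#' without a published CI use +/-20% read as a 95% interval). Each draw is
#' evaluated in deterministic cohort mode (the exact inner expectation) or
#' by microsimulation.
#'
#' The mean probabilistic ICER is the ratio of mean increments
#' `mean(dCost)/mean(dQALY)` (robust to near-zero denominators); the
#' unstable per-draw-mean alternative is available via
#' `icer_method = "mean_of_ratios"`. The cost-effectiveness acceptability
#' curve reports, at each willingness-to-pay value, the fraction of draws
#' with positive incremental net monetary benefit.
#'
#' @param spec A validated `model_spec`.
#' @param n_outer Number of second-order draws (>= 2); defaults to the
#'   spec's `n_psa`.
#' @param seed Integer seed; defaults to the spec's seed.
#' @param inner `"cohort"` or `"microsim"` inner evaluation.
#' @param wtp_grid Willingness-to-pay grid for the CEAC.
#' @param icer_method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @param sd_scale Multiplier on every sampling SD (0 collapses the PSA to
#'   the deterministic base case; used for verification).
#' @return A `psa_result` list: `samples` (per-draw data frame with
#'   `d_cost`, `d_qaly`, `icer`, `inb`), `params` (matrix of sampled
#'   parameter values), `mean_icer`, `ceac` (data frame `wtp`,
#'   `p_tavi_ce`), `base` comparison, and settings.
#' @export
psa <- function(spec, n_outer = NULL, seed = NULL,
                inner = c("cohort", "microsim"),
                wtp_grid = seq(0, 6e5, by = 5e3),
                icer_method = c("ratio_of_means", "mean_of_ratios"),
                sd_scale = 1) {
  inner <- match.arg(inner)
  icer_method <- match.arg(icer_method)
  n_outer <- as.integer(n_outer %||% spec$settings$n_psa)
  if (n_outer < 2) stop("n_outer must be >= 2", call. = FALSE)
  seed <- as.integer(seed %||% spec$settings$seed)
  set.seed(seed)

  d_cost <- numeric(n_outer); d_qaly <- numeric(n_outer)
  cost_t <- numeric(n_outer); cost_s <- numeric(n_outer)
  qaly_t <- numeric(n_outer); qaly_s <- numeric(n_outer)
  params <- NULL
  for (i in seq_len(n_outer)) {
    dr <- psa_draw_spec(spec, sd_scale = sd_scale)
    if (is.null(params))
      params <- matrix(NA_real_, n_outer, length(dr$sampled),
                       dimnames = list(NULL, names(dr$sampled)))
    params[i, ] <- dr$sampled
    cmp <- if (inner == "cohort") {
      base_case(dr$spec, mode = "cohort")
    } else {
      # inner microsim uses a draw-specific seed derived from the stream
      base_case(dr$spec, mode = "microsim",
                seed = sample.int(.Machine$integer.max, 1))
    }
    d_cost[i] <- cmp$d_cost; d_qaly[i] <- cmp$d_qaly
    cost_t[i] <- cmp$tavi$cost_total; cost_s[i] <- cmp$savr$cost_total
    qaly_t[i] <- cmp$tavi$qaly_total; qaly_s[i] <- cmp$savr$qaly_total
  }
  wtp0 <- spec$settings$wtp
  samples <- data.frame(draw = seq_len(n_outer),
                        cost_tavi = cost_t, cost_savr = cost_s,
                        qaly_tavi = qaly_t, qaly_savr = qaly_s,
                        d_cost = d_cost, d_qaly = d_qaly,
                        icer = ifelse(d_qaly != 0, d_cost / d_qaly, NA_real_),
                        inb = wtp0 * d_qaly - d_cost)
  mean_icer <- if (icer_method == "ratio_of_means") {
    mean(d_cost) / mean(d_qaly)
  } else {
    mean(samples$icer[is.finite(samples$icer)])
  }
  ceac <- data.frame(
    wtp = wtp_grid,
    p_tavi_ce = vapply(wtp_grid,
                       function(w) mean(w * d_qaly - d_cost > 0),
                       numeric(1)))
  structure(list(samples = samples, params = params,
                 mean_icer = mean_icer, ceac = ceac,
                 mean_d_cost = mean(d_cost), mean_d_qaly = mean(d_qaly),
                 base = base_case(spec, mode = "cohort"),
                 n_outer = n_outer, seed = seed, inner = inner,
                 icer_method = icer_method),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result> ", x$n_outer, " draws (", x$inner, " inner)\n", sep = "")
  cat(sprintf("  mean incremental cost %s, mean incremental QALYs %.4f\n",
              format(round(x$mean_d_cost), big.mark = ","), x$mean_d_qaly))
  cat(sprintf("  mean probabilistic ICER %s per QALY\n",
              format(round(x$mean_icer), big.mark = ",")))
  cw <- ceac_crossing(x)
  if (is.finite(cw))
    cat(sprintf("  CEAC crosses 0.5 near WTP %s\n",
                format(round(cw), big.mark = ",")))
  invisible(x)
}

#' Willingness-to-pay at which the CEAC crosses one half
#'
#' Linear interpolation of the first upward crossing of
#' `P(TAVI cost-effective) = 0.5` on the CEAC grid; `Inf` if the curve
#' never reaches 0.5.
#'
#' @param psa_result A [psa()] result.
#' @return WTP value (money per QALY), possibly `Inf`.
#' @export
ceac_crossing <- function(psa_result) {
  cc <- psa_result$ceac
  above <- which(cc$p_tavi_ce >= 0.5)
  if (!length(above)) return(Inf)
  i <- above[1]
  if (i == 1) return(cc$wtp[1])
  w0 <- cc$wtp[i - 1]; w1 <- cc$wtp[i]
  p0 <- cc$p_tavi_ce[i - 1]; p1 <- cc$p_tavi_ce[i]
  if (p1 == p0) return(w1)
  w0 + (0.5 - p0) / (p1 - p0) * (w1 - w0)
}

## ---- Scenarios --------------------------------------------------------------

#' Run a named scenario analysis
#'
#' * `scenario1` — SAPIEN 3 (PARTNER S3i) one-year outcomes extrapolated
#'   to five years.
#' * `scenario2` — SURTAVI two-year outcomes, SAVR-rate projection beyond
#'   24 months.
#' * `scenario3` — base case inputs with a 20-year horizon; per-cycle
#'   probabilities beyond month 60 continue at the last interval's
#'   constant monthly rate, utilities and follow-up costs at their last
#'   values.
#' * `scenario4` — base case with adverse-event disutilities applied
#'   (one-off per incident event; stroke-state utility decrement 0.161
#'   per cycle in the stroke state).
#'
#' @param name `"scenario1"`..`"scenario4"` (aliases `"base"` for the
#'   base case are not accepted here; use [base_case()]).
#' @param base Optional `model_spec` used for scenarios 3 and 4 in place
#'   of the packaged base case.
#' @param mode Evaluation mode, as in [base_case()].
#' @return A `ce_comparison`.
#' @export
run_scenario <- function(name = c("scenario1", "scenario2", "scenario3",
                                  "scenario4"),
                         base = NULL, mode = "cohort") {
  name <- match.arg(name)
  spec <- switch(
    name,
    scenario1 = builtin_parameter_set("s3i_scenario1"),
    scenario2 = builtin_parameter_set("surtavi_scenario2"),
    scenario3 = {
      sp <- base %||% builtin_parameter_set("partner2a_base")
      sp$settings$horizon_months <- 240
      sp$name <- paste0(sp$name, "_horizon20")
      stop_if_invalid(sp)
    },
    scenario4 = {
      if (is.null(base)) builtin_parameter_set("base_with_disutilities")
      else {
        sp <- base
        sp$settings$apply_ae_disutilities <- TRUE
        if (is.null(sp$ae_disutilities))
          sp$ae_disutilities <- builtin_parameter_set(
            "base_with_disutilities")$ae_disutilities
        stop_if_invalid(sp)
      }
    })
  base_case(spec, mode = mode)
}
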