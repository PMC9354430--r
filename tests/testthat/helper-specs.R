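# Shared fixtures, built in code.

base_spec <- function() builtin_parameter_set("partner2a_base")

# a small two-arm synthetic cohort with constant monthly hazards
simple_synth <- function(lam_death_t = 0.008, lam_death_s = 0.010,
                         lam_stroke = 0.001, ...) {
  synthetic_cohort_spec(
    hazards = list(
      all_cause_mortality = list(tavi = lam_death_t, savr = lam_death_s),
      disabling_stroke = list(tavi = lam_stroke, savr = lam_stroke)),
    ...)
}

# bisection oracle: solve (1 - p)^n = s_end/s_start for p
bisect_monthly_prob <- function(s_start, s_end, n, tol = 1e-12) {
  f <- function(p) (1 - p)^n - s_end / s_start
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# cumulative incidence implied by a per-cycle probability vector
implied_cumulative <- function(p) 1 - cumprod(1 - p)
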