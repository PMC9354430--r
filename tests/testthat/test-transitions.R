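test_that("interval_monthly_prob matches direct cases and a bisection oracle", {
  # 30-day mortality applied in a single first cycle
  expect_equal(interval_monthly_prob(1.0, 0.97, 1), 0.03)
  # no events in the interval
  expect_equal(interval_monthly_prob(0.8, 0.8, 7), 0)
  # year-1 -> year-2 TAVI mortality (10% -> 14.2%), vs independent bisection
  p <- interval_monthly_prob(0.90, 0.858, 12)
  expect_equal(p, bisect_monthly_prob(0.90, 0.858, 12), tolerance = 1e-9)
  expect_equal(p, 0.003975, tolerance = 1e-4)
  # error surface
  expect_error(interval_monthly_prob(0.8, 0.9, 12), "non-monotone")
  expect_error(interval_monthly_prob(0, 0, 1), "s_start")
  expect_equal(interval_monthly_prob(0.5, 0, 3), 1)
})

test_that("km_schedule_to_monthly reproduces every milestone exactly", {
  spec <- base_spec()
  mm <- spec$milestone_months
  for (ev in setdiff(ce_events(), "PAR")) {
    for (arm in c("tavi", "savr")) {
      v <- spec$events[[ev]][[arm]]
      for (br in c("constant", "linear")) {
        p <- km_schedule_to_monthly(v, mm, 60, "cumulative_incidence",
                                    bridge = br, linear_from = 24)
        expect_equal(implied_cumulative(p)[mm], v, tolerance = 1e-9,
                     label = paste(ev, arm, br))
      }
    }
  }
})

test_that("single zero milestone expands to an all-zero schedule", {
  expect_equal(km_schedule_to_monthly(0, 1, 60, "cumulative_incidence"),
               rep(0, 60))
})

test_that("synthetic exponential survival is recovered within 1e-6", {
  lam <- 0.01
  mm <- c(1, 12, 24, 60)
  v <- 1 - exp(-lam * mm)            # closed-form cumulative incidence
  p <- km_schedule_to_monthly(v, mm, 60, "cumulative_incidence")
  expect_equal(p, rep(1 - exp(-lam), 60), tolerance = 1e-6)
})

test_that("prevalence tables yield floored positive-increment incidence", {
  spec <- base_spec()
  p <- km_schedule_to_monthly(spec$events$PAR$tavi, spec$milestone_months,
                              60, "prevalence")
  expect_equal(p[1], 0.0375)                       # month-1 prevalence
  expect_equal(p[2:12], rep(0, 11))                # flat to 1 y
  expect_equal(p[13:24], rep((0.0827 - 0.0375) / 12, 12))  # rise to 2 y
  expect_equal(p[25:60], rep(0, 36))               # fall 2 y -> 5 y floored
  expect_true(all(p >= 0))
})

test_that("milestone round trip holds for randomly generated tables", {
  set.seed(42)
  mm <- c(1, 12, 24, 60)
  for (i in 1:25) {
    v <- sort(runif(4, 0, 0.9))
    p <- km_schedule_to_monthly(v, mm, 60, "cumulative_incidence")
    expect_equal(implied_cumulative(p)[mm], v, tolerance = 1e-9)
  }
})

test_that("raising a milestone never lowers per-cycle probabilities in its interval", {
  mm <- c(1, 12, 24, 60)
  v <- c(0.03, 0.10, 0.142, 0.427)
  p0 <- km_schedule_to_monthly(v, mm, 60, "cumulative_incidence")
  v2 <- v; v2[3] <- v[3] + 0.02
  p2 <- km_schedule_to_monthly(v2, mm, 60, "cumulative_incidence")
  expect_true(all(p2[13:24] >= p0[13:24]))
})

test_that("split_mortality_by_stroke follows the mixture identity", {
  out <- split_mortality_by_stroke(0.01, 0.05, 8.5)
  expect_equal(unname(out["m_no_stroke"]), 0.0072727, tolerance = 1e-4)
  expect_equal(unname(out["m_stroke"]), 0.0618182, tolerance = 1e-4)
  # no excess hazard: both equal the cohort mortality
  out1 <- split_mortality_by_stroke(0.037, 0.2, 1)
  expect_equal(unname(out1), c(0.037, 0.037))
  # empty stroke state
  out0 <- split_mortality_by_stroke(0.02, 0, 3)
  expect_equal(unname(out0["m_no_stroke"]), 0.02)
})

test_that("mixture recombination conserves cohort mortality to 1e-12", {
  set.seed(7)
  for (i in 1:50) {
    m <- runif(1, 0, 0.2); x <- runif(1); rr <- 1 + rexp(1, 1 / 3)
    out <- split_mortality_by_stroke(m, x, rr)
    if (out["m_stroke"] < 1) {  # uncapped
      expect_equal(unname(x * out["m_stroke"] + (1 - x) * out["m_no_stroke"]),
                   m, tolerance = 1e-12)
    }
  }
})

test_that("transition schedules reproduce trial mortality and the stroke split", {
  spec <- base_spec()
  for (arm in c("tavi", "savr")) {
    sch <- build_transition_schedule(spec, arm)
    # implied all-cause survival hits every milestone
    expect_equal(implied_cumulative(sch$p_death_all)[spec$milestone_months],
                 spec$events$all_cause_mortality[[arm]], tolerance = 1e-9)
    # the deterministic trace's dead column agrees (mixture conserved)
    expect_equal(sch$occupancy[spec$milestone_months + 1, "dead"],
                 spec$events$all_cause_mortality[[arm]], tolerance = 1e-9)
    expect_true(all(sch$p_death_ns <= sch$p_death_all + 1e-12))
    expect_true(all(sch$p_death_ns >= 0 & sch$p_death_ns <= 1))
    expect_true(all(sch$p_ae >= 0 & sch$p_ae <= 1))
  }
  # SAVR cycle-1 death equals the 30-day 4.1%
  expect_equal(build_transition_schedule(spec, "savr")$p_death_all[1], 0.041)
})

test_that("an all-ones HR schedule removes the stroke mortality excess", {
  spec <- base_spec()
  spec$hazard_ratios$by_cycle <- rep(1, 15)
  sch <- build_transition_schedule(spec, "tavi")
  expect_equal(sch$p_death_ns, sch$p_death_all, tolerance = 1e-12)
})
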