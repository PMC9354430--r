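test_that("discount factors follow annual compounding on the monthly grid", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(12, 0.03), 1 / 1.03)
  expect_equal(discount_factor(37, 0), 1)
  expect_equal(discount_factor(30, 0.03), 1.03^(-2.5))
  expect_error(discount_factor(-1, 0.03), ">= 0")
})

test_that("utility trajectory interpolates linearly and pools after month 24", {
  spec <- base_spec()
  expect_equal(utility_at_cycle(spec, "tavi", 1), 0.81)
  expect_equal(utility_at_cycle(spec, "tavi", 12), 0.79)
  expect_equal(utility_at_cycle(spec, "tavi", 24), 0.78)
  # linear midpoints
  expect_equal(utility_at_cycle(spec, "savr", 6),
               0.73 + (0.80 - 0.73) * 5 / 11)
  expect_equal(utility_at_cycle(spec, "tavi", 18), (0.79 + 0.78) / 2)
  # beyond month 24 both arms carry the TAVI month-24 value
  expect_equal(utility_at_cycle(spec, "savr", 36), 0.78)
  expect_equal(utility_at_cycle(spec, "tavi", 60), 0.78)
  expect_error(utility_at_cycle(spec, "tavi", 0), "cycle 1")
})

test_that("cohort trace occupancies sum to one and death is absorbing", {
  spec <- base_spec()
  for (arm in c("tavi", "savr")) {
    tr <- run_cohort(spec, arm)$trace
    expect_equal(tr$no_stroke + tr$stroke + tr$dead, rep(1, nrow(tr)),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$dead) >= -1e-15))
    expect_true(all(is.finite(tr$cost)) && all(is.finite(tr$qaly)))
  }
})

test_that("cost components decompose exactly and QALYs separate from costs", {
  spec <- base_spec()
  out <- run_cohort(spec, "tavi")
  res <- out$result
  expect_equal(res$cost_total,
               res$cost_index + res$cost_ae + res$cost_followup)
  expect_equal(res$cost_total, sum(out$trace$cost), tolerance = 1e-9)
  expect_equal(res$qaly_total, sum(out$trace$qaly), tolerance = 1e-9)
  expect_gte(res$cost_total, spec$costs$index_episode$tavi)
  expect_lte(res$qaly_total, 5 * 1)
  # zero utilities: QALYs vanish, costs untouched
  sp0 <- spec
  for (arm in c("tavi", "savr"))
    for (k in 1:3) sp0$utilities[[arm]][[k]]$mean <- 0
  res0 <- run_cohort(sp0, "tavi")$result
  expect_equal(res0$qaly_total, 0)
  expect_equal(res0$cost_total, res$cost_total)
})

test_that("immediate extinction leaves index cost plus first-cycle AE costs", {
  spec <- base_spec()
  spec$events$all_cause_mortality$tavi <- c(1, 1, 1, 1)
  res <- run_cohort(spec, "tavi")$result
  # AE draws precede death within the cycle; stroke cost included
  ae1 <- build_transition_schedule(spec, "tavi")$p_ae[1, ]
  exp_ae <- sum(ae1 * vapply(names(ae1),
                             function(e) spec$costs$ae[[e]]$mean,
                             numeric(1))) +
    spec$events$disabling_stroke$tavi[1] *
      spec$costs$ae$disabling_stroke$mean
  expect_equal(res$cost_total,
               spec$costs$index_episode$tavi +
                 exp_ae * discount_factor(1, 0.03),
               tolerance = 1e-9)
  # death forfeits the cycle's utility: no QALYs accrue
  expect_equal(res$qaly_total, 0)
})

test_that("discounting is monotone: higher rates never raise totals", {
  spec <- base_spec()
  rates <- c(0, 0.03, 0.05)
  costs <- qalys <- numeric(3)
  for (i in seq_along(rates)) {
    sp <- spec; sp$settings$annual_discount <- rates[i]
    r <- run_cohort(sp, "savr")$result
    costs[i] <- r$cost_total; qalys[i] <- r$qaly_total
  }
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("microsimulation is seed-deterministic and matches the cohort expectation", {
  spec <- base_spec()
  a <- run_microsim(spec, "tavi", n = 500, seed = 11)
  b <- run_microsim(spec, "tavi", n = 500, seed = 11)
  expect_identical(a$cost_total, b$cost_total)
  expect_identical(a$qaly_total, b$qaly_total)
  c2 <- run_microsim(spec, "tavi", n = 500, seed = 12)
  expect_false(identical(a$cost_total, c2$cost_total))
  # n = 1 degenerate determinism
  d1 <- run_microsim(spec, "savr", n = 1, seed = 3)
  d2 <- run_microsim(spec, "savr", n = 1, seed = 3)
  expect_identical(d1$qaly_total, d2$qaly_total)
  # agreement with the exact expectation within 3 Monte Carlo SEs
  coh <- run_cohort(spec, "tavi")$result
  m <- run_microsim(spec, "tavi", n = 4000, seed = 21)
  expect_lt(abs(m$cost_total - coh$cost_total), 3 * m$se_cost)
  expect_lt(abs(m$qaly_total - coh$qaly_total), 3 * m$se_qaly)
})

test_that("zero stroke incidence keeps every simulated patient stroke-free", {
  spec <- base_spec()
  spec$events$disabling_stroke$tavi <- c(0, 0, 0, 0)
  m <- run_microsim(spec, "tavi", n = 300, seed = 5)
  expect_equal(unname(m$ae_counts["disabling_stroke"]), 0)
  tr <- run_cohort(spec, "tavi")$trace
  expect_equal(tr$stroke, rep(0, nrow(tr)))
})

test_that("compare_arms computes increments, ICER, dominance and INB", {
  mk <- function(cost, qaly, arm) {
    r <- run_cohort(base_spec(), arm)$result
    r$cost_total <- cost; r$qaly_total <- qaly
    r
  }
  # printed per-arm rounded values give the rounded-arithmetic ICER
  cmp <- compare_arms(mk(70959, 2.92, "tavi"), mk(39492, 2.82, "savr"), 34091)
  expect_equal(cmp$d_cost, 31467)
  expect_equal(cmp$d_qaly, 0.10, tolerance = 1e-9)
  expect_equal(cmp$icer, 314670, tolerance = 1e-6)
  expect_equal(cmp$inb, 34091 * 0.10 - 31467, tolerance = 1e-6)
  expect_equal(cmp$inb, -28057.9, tolerance = 1e-3)
  # dominance labelling
  expect_equal(compare_arms(mk(100, 1.1, "tavi"), mk(101, 1.0, "savr"),
                            5e4)$label, "dominant")
  expect_equal(compare_arms(mk(101, 1.0, "tavi"), mk(100, 1.1, "savr"),
                            5e4)$label, "dominated")
  und <- compare_arms(mk(105, 1.0, "tavi"), mk(100, 1.0, "savr"), 5e4)
  expect_equal(und$label, "undefined")
  expect_true(is.na(und$icer))
})

test_that("identical arms give zero increments and an undefined ICER", {
  spec <- base_spec()
  for (ev in ce_events()) spec$events[[ev]]$tavi <- spec$events[[ev]]$savr
  spec$costs$index_episode$tavi <- spec$costs$index_episode$savr
  for (k in 1:3) spec$utilities$tavi[[k]] <- spec$utilities$savr[[k]]
  cmp <- base_case(spec, mode = "cohort")
  expect_equal(cmp$d_cost, 0, tolerance = 1e-9)
  expect_equal(cmp$d_qaly, 0, tolerance = 1e-9)
  expect_equal(cmp$label, "undefined")
})
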