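test_that("bundled base-case spec loads with the printed headline inputs", {
  spec <- base_spec()
  expect_s3_class(spec, "model_spec")
  expect_identical(validate_model_spec(spec), character(0))
  # 30-day all-cause mortality: TAVI 3%, SAVR 4.1%
  expect_equal(spec$events$all_cause_mortality$tavi[1], 0.03)
  expect_equal(spec$events$all_cause_mortality$savr[1], 0.041)
  # index episode charges
  expect_equal(spec$costs$index_episode$tavi, 54301)
  expect_equal(spec$costs$index_episode$savr, 26109)
  # analysis settings
  expect_equal(spec$settings$horizon_months, 60)
  expect_equal(spec$settings$annual_discount, 0.03)
  expect_equal(spec$settings$n_microsim, 10000)
  expect_equal(spec$settings$seed, 1)
})

test_that("every clinical event is present for both arms in every bundled set", {
  for (nm in c("partner2a_base", "s3i_scenario1", "surtavi_scenario2",
               "base_with_disutilities", "horizon20_scenario3")) {
    spec <- builtin_parameter_set(nm)
    expect_identical(validate_model_spec(spec), character(0), label = nm)
    expect_setequal(names(spec$events), ce_events())
    for (ev in ce_events()) {
      expect_length(spec$events[[ev]]$tavi, length(spec$milestone_months))
      expect_length(spec$events[[ev]]$savr, length(spec$milestone_months))
    }
  }
})

test_that("PAR is stored as prevalence (values may fall), others cumulative", {
  spec <- base_spec()
  expect_equal(spec$events$PAR$kind, "prevalence")
  expect_lt(spec$events$PAR$tavi[4], spec$events$PAR$tavi[3])  # 8.27% -> 6.44%
  for (ev in setdiff(ce_events(), "PAR"))
    expect_equal(spec$events[[ev]]$kind, "cumulative_incidence")
})

test_that("validation catches broken invariants instead of fixing them", {
  spec <- base_spec()
  # decreasing cumulative incidence
  sp <- spec
  sp$events$all_cause_mortality$tavi[3] <- 0.05  # 2y < 1y
  expect_match(paste(validate_model_spec(sp), collapse = "; "),
               "non-decreasing")
  # probability out of range
  sp <- spec
  sp$events$MI$savr[4] <- 1.2
  expect_match(paste(validate_model_spec(sp), collapse = "; "), "\\[0, 1\\]")
  # missing event table
  sp <- spec
  sp$events$AF <- NULL
  expect_match(paste(validate_model_spec(sp), collapse = "; "), "missing")
  # hazard ratio below 1
  sp <- spec
  sp$hazard_ratios$by_cycle[2] <- 0.9
  expect_match(paste(validate_model_spec(sp), collapse = "; "), "HR")
  # cost CI inconsistent
  sp <- spec
  sp$costs$ae$TIA$mean <- 1e6
  expect_match(paste(validate_model_spec(sp), collapse = "; "), "ci_low")
  # errors are enumerated, not thrown one at a time
  sp <- spec
  sp$events$MI$savr[4] <- 1.2
  sp$hazard_ratios$after <- 0.5
  expect_gte(length(validate_model_spec(sp)), 2)
})

test_that("load_model_spec rejects a file violating monotonicity", {
  spec <- base_spec()
  spec$events$all_cause_mortality$tavi <- c(0.03, 0.10, 0.08, 0.427)
  f <- withr::local_tempfile(fileext = ".yaml")
  save_model_spec(spec, f)
  expect_error(load_model_spec(f), "non-decreasing")
  expect_error(load_model_spec("no/such/file.yaml"), "not found")
})

test_that("save-then-load round trip reproduces the spec", {
  spec <- base_spec()
  f <- withr::local_tempfile(fileext = ".yaml")
  save_model_spec(spec, f)
  spec2 <- load_model_spec(f)
  expect_equal(spec2$events, spec$events, tolerance = 1e-12)
  expect_equal(spec2$costs, spec$costs, tolerance = 1e-12)
  expect_equal(spec2$utilities, spec$utilities, tolerance = 1e-12)
  expect_equal(spec2$hazard_ratios, spec$hazard_ratios, tolerance = 1e-12)
  expect_equal(spec2$milestone_months, spec$milestone_months)
})

test_that("scenario parameter sets differ from base only where documented", {
  base <- base_spec()
  s3 <- builtin_parameter_set("horizon20_scenario3")
  expect_equal(s3$settings$horizon_months, 240)
  s3$settings$horizon_months <- base$settings$horizon_months
  s3$name <- base$name
  expect_equal(s3$events, base$events)
  expect_equal(s3$costs, base$costs)

  s4 <- builtin_parameter_set("base_with_disutilities")
  expect_true(s4$settings$apply_ae_disutilities)
  expect_equal(s4$ae_disutilities$stroke_state_decrement, 0.161)
  expect_equal(s4$events, base$events)

  expect_error(builtin_parameter_set("no_such_set"))
})

test_that("CSV audit export writes all four flattened tables", {
  d <- withr::local_tempdir()
  files <- export_spec_csv(base_spec(), d)
  expect_true(all(file.exists(files)))
  ev <- read.csv(files[1])
  expect_setequal(unique(ev$event), ce_events())
  expect_equal(nrow(ev), length(ce_events()) * 2 * 4)
})
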