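ut <- default_config()$utilities

test_that("utility composition reproduces the worked health states", {
  expect_equal(utility_at("none", params = ut), 0.807)
  expect_equal(utility_at("major", params = ut), 0.507)
  expect_equal(utility_at("major", on_treatment = TRUE, responder = TRUE,
                          params = ut), 0.657)
  expect_equal(utility_at("minor", params = ut), 0.807)
  # event-year vs prior-history MI decrements, signs as printed
  expect_equal(utility_at("none", comps_event_year = "mi", params = ut),
               0.807 - 0.065)
  expect_equal(utility_at("none", comps_chronic = "mi", params = ut),
               0.807 + 0.008)
  expect_equal(utility_at("none", comps_chronic = "blindness", params = ut),
               0.807 + 0.033)
  # additive stacking and clamping at the EQ-5D floor
  expect_equal(utility_at("major", comps_chronic = c("renal", "stroke", "amputation"),
                          params = ut), 0.807 - 0.3 - 0.263 - 0.165 - 0.172)
  stacked <- utility_at("major",
                        comps_event_year = c("renal", "stroke", "amputation", "chf"),
                        comps_chronic = "ulcer", params = ut)
  expect_gte(stacked, ut$floor)
})

test_that("discounting follows the continuous 3.5% convention", {
  expect_equal(discount(123, 0), 123)
  expect_equal(discount(100, 1), 100 / 1.035)
  expect_equal(discount(100, 20), 100 / 1.035^20)
  expect_equal(discount(100, 1.5, annual = TRUE), 100 / 1.035)  # annual-step switch
  expect_error(discount(100, -1), "negative time")
  expect_equal(discount_integral(0, 2, 0), 2)
  oracle <- stats::integrate(function(s) 1.035^(-s), 1, 7)$value
  expect_equal(discount_integral(1, 7), oracle, tolerance = 1e-8)
})

test_that("ledger aggregation matches direct discounting and rejects bad input", {
  led <- data.frame(
    time = c(0, 1, 2), duration = c(0, 0, 3),
    category = c("gp", "screening", "ongoing_mgmt"),
    amount = c(37, 2, 756)
  )
  out <- accumulate_ledger(led, 0.035)
  expect_equal(out$undiscounted[out$category == "total"], 37 + 2 + 756)
  expect_equal(out$discounted[out$category == "gp"], 37)
  expect_equal(out$discounted[out$category == "screening"], 2 / 1.035)
  expect_equal(out$discounted[out$category == "ongoing_mgmt"],
               756 / 3 * discount_integral(2, 5, 0.035))
  expect_error(accumulate_ledger(transform(led, category = "petrol")),
               "unknown ledger category")
})

test_that("simulated patients conserve costs and respect discounting bounds", {
  cfg <- small_cfg(30L, seed = 9L)
  coh <- generate_cohort(cfg)
  for (i in c(1, 7, 13)) {
    res <- simulate_patient(coh[i, ], "P3", cfg, master_seed = 77, detail = TRUE)
    tot <- res$totals
    cats <- paste0("cost_", LEDGER_CATEGORIES)
    expect_equal(unname(sum(tot[cats])), unname(tot[["cost_total"]]), tolerance = 1e-9)
    expect_lte(tot[["cost_disc_total"]], tot[["cost_total"]] + 1e-9)
    expect_lte(tot[["qalys"]], tot[["life_years"]] * 1 + 1e-9)
    expect_lte(tot[["qalys_disc"]], tot[["life_years_disc"]] + 1e-9)
    # entry-level ledger reconciles exactly with the internal accumulators
    agg <- accumulate_ledger(res$ledger, cfg$economics$discount_rate)
    expect_equal(agg$undiscounted[agg$category == "total"],
                 unname(tot[["cost_total"]]), tolerance = 1e-6)
    expect_equal(agg$discounted[agg$category == "total"],
                 unname(tot[["cost_disc_total"]]), tolerance = 1e-6)
    # unit-cost reconciliation: counts x unit costs = category totals
    expect_equal(unname(tot[["cost_gp"]]),
                 unname(tot[["contacts"]]) * cfg$costs$gp_appointment)
    expect_equal(unname(tot[["cost_screening"]]),
                 unname(tot[["screens"]]) * cfg$costs$opportunistic_screen)
    expect_equal(unname(tot[["cost_interview"]]),
                 unname(tot[["interviews"]]) * cfg$costs$interview)
    expect_equal(unname(tot[["cost_review"]]),
                 unname(tot[["reviews_attended"]]) * cfg$costs$annual_review)
  }
})
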