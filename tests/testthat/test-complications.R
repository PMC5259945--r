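cfg <- default_config()

test_that("exposure multiplier follows the time-weighted linear rule", {
  expect_equal(effective_hazard_multiplier(0, 1, 1.31, 1.36), 1.36)
  expect_equal(effective_hazard_multiplier(0, 0.5, 1.31, 1.36), 1.18)
  expect_equal(effective_hazard_multiplier(1, 0, 1.31, 1.36), 1.31)
  expect_equal(effective_hazard_multiplier(0, 0, 1.31, 1.36), 1)
  expect_equal(effective_hazard_multiplier(0.25, 0.25, 1.31, 1.36),
               1 + 0.25 * 0.31 + 0.25 * 0.36)
  expect_error(effective_hazard_multiplier(0.7, 0.6, 1.31, 1.36))
})

test_that("annual probabilities compose hazard, multiplier and back-conversion", {
  # no exposure: pass-through of the engine's base probabilities
  p0 <- complication_probs(65, 0, 0, cfg)
  h0 <- cfg$complications$engine$base_hazard[colnames(p0)]
  expect_equal(unname(p0[1, ]), unname(-expm1(-h0)))
  # full-year major depression: micro columns scaled on the hazard scale,
  # macro minor HR of 1.00 leaves macro probabilities untouched for minor
  p_major <- complication_probs(65, 0, 1, cfg)
  micro <- cfg$complications$classes$micro
  expect_equal(unname(p_major[1, micro]), unname(-expm1(-h0[micro] * 1.36)))
  p_minor <- complication_probs(65, 1, 0, cfg)
  macro <- cfg$complications$classes$macro
  expect_equal(unname(p_minor[1, macro]), unname(p0[1, macro]))  # HR exactly 1
})

test_that("all four printed hazard ratios are recovered from simulated cohorts", {
  n <- 40000
  years <- 5
  pats <- data.frame(age = rep(65, n))
  classes <- cfg$complications$classes
  sim_events <- function(f_minor, f_major, seed) {
    any_micro <- 0; any_macro <- 0
    set.seed(seed)
    for (y in seq_len(years)) {
      ev <- annual_complication_update(pats, f_minor, f_major, cfg)
      any_micro <- any_micro + sum(rowSums(ev[, classes$micro]) > 0)
      any_macro <- any_macro + sum(rowSums(ev[, classes$macro]) > 0)
    }
    c(micro = any_micro, macro = any_macro)
  }
  haz <- function(k) -log(1 - k / (n * years))
  ref <- sim_events(0, 0, 41)
  dep_major <- sim_events(0, 1, 42)
  dep_minor <- sim_events(1, 0, 43)
  se_ratio <- function(a, b) sqrt(1 / a + 1 / b)
  r_micro_major <- haz(dep_major["micro"]) / haz(ref["micro"])
  expect_lt(abs(r_micro_major - 1.36),
            4 * 1.36 * se_ratio(dep_major["micro"], ref["micro"]))
  r_macro_major <- haz(dep_major["macro"]) / haz(ref["macro"])
  expect_lt(abs(r_macro_major - 1.25),
            4 * 1.25 * se_ratio(dep_major["macro"], ref["macro"]))
  r_micro_minor <- haz(dep_minor["micro"]) / haz(ref["micro"])
  expect_lt(abs(r_micro_minor - 1.31),
            4 * 1.31 * se_ratio(dep_minor["micro"], ref["micro"]))
  r_macro_minor <- haz(dep_minor["macro"]) / haz(ref["macro"])
  expect_lt(abs(r_macro_minor - 1.00),
            4 * se_ratio(dep_minor["macro"], ref["macro"]))
})

test_that("single-occurrence complications cannot recur but recurrent ones can", {
  set.seed(44)
  n <- 2000
  pats <- data.frame(age = rep(65, n), comp_blindness = TRUE, comp_mi = TRUE)
  ev <- annual_complication_update(pats, 0, 0, cfg)
  expect_true(all(!ev[, "blindness"]))
  expect_gt(sum(ev[, "mi"]), 0)
})

test_that("mortality model is age-increasing, complication-loaded and bounded", {
  q65 <- mortality_prob(65, character(0), cfg)
  q85 <- mortality_prob(85, character(0), cfg)
  expect_gt(q85, q65)
  expect_gt(mortality_prob(65, "renal", cfg), q65)
  expect_gt(mortality_prob(65, c("mi", "chf"), cfg), mortality_prob(65, "mi", cfg))

  # remaining life expectancy at 65 under the surrogate: finite and < 40 yrs
  set.seed(45)
  n <- 10000
  alive <- rep(TRUE, n)
  ly <- 0
  for (k in 0:80) {
    q <- mortality_prob(65 + k, character(0), cfg)
    ly <- ly + sum(alive)
    alive <- alive & stats::runif(n) >= q
  }
  le <- ly / n
  expect_gt(le, 5)
  expect_lt(le, 40)
})

test_that("coefficient files load into the pluggable engine", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(type = c("mi", "stroke"),
                              base_hazard = c(0.02, 0.01),
                              age_slope = c(0.05, 0)),
                   path, row.names = FALSE)
  eng <- load_risk_engine(path)
  expect_equal(eng$kind, "table")
  expect_equal(unname(eng$base_hazard["mi"]), 0.02)
  cfg2 <- cfg
  cfg2$complications$types <- c("mi", "stroke")
  cfg2$complications$classes <- list(micro = character(0), macro = c("mi", "stroke"))
  cfg2$complications$engine <- eng
  p <- complication_probs(70, 0, 0, cfg2)
  expect_equal(unname(p[1, "mi"]), -expm1(-0.02 * exp(0.05 * 5)))

  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(type = "mi", base_hazard = -1), bad, row.names = FALSE)
  expect_error(load_risk_engine(bad), "negative base hazard")
})
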