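# One shared medium-size comparison reused across the direction-of-effect
# checks below (the expensive object is computed once per test run).
shared_cfg <- small_cfg(4000L, seed = 2L)
shared_cohort <- generate_cohort(shared_cfg)
shared_cmp <- run_comparison(shared_cohort, c("CP", "P1", "P2", "P3"),
                             shared_cfg, seed = 2)

test_that("policy objects encode the flag pairs and reject unknown ids", {
  expect_true(policy("P3")$cc_enabled && policy("P3")$universal_screen)
  expect_false(policy("CP")$cc_enabled || policy("CP")$universal_screen)
  expect_true(policy("collaborative_care")$cc_enabled)
  expect_false(policy("collaborative_care")$universal_screen)
  expect_true(policy("opportunistic_screening")$universal_screen)
  expect_error(policy("P9"), "unknown policy")
})

test_that("episode accounting is conserved and screening raises identification", {
  tab <- as.data.frame(shared_cmp)
  expect_equal(tab$episodes_identified + tab$episodes_unidentified,
               tab$episodes_total)
  frac <- tab$episodes_identified / tab$episodes_total
  cp <- which(tab$policy == "current_practice")
  p1 <- which(tab$policy == "collaborative_care")
  p2 <- which(tab$policy == "opportunistic_screening")
  p3 <- which(tab$policy == "combined")
  expect_gt(frac[p2], frac[cp])
  expect_gt(frac[p3], frac[cp])
  # the screening policies sharply reduce unidentified episodes;
  # collaborative care leaves the identified fraction essentially unchanged
  # (it only modifies treatment, not screening)
  expect_true(all(tab$episodes_unidentified[c(p2, p3)] <
                    0.5 * tab$episodes_unidentified[cp]))
  expect_lt(abs(frac[p1] - frac[cp]), 3)
  # all three policies reduce total complication counts
  comps <- rowSums(tab[, grep("^comp_", names(tab))])
  expect_true(all(comps[c(p1, p2, p3)] < comps[cp]))
})

test_that("reporting-cohort scaling is exactly linear", {
  sub <- shared_cohort[1:50, ]
  a <- run_comparison(sub, "CP", shared_cfg, seed = 2, scale_to = 2e6)
  b <- run_comparison(sub, "CP", shared_cfg, seed = 2, scale_to = 4e6)
  ext <- setdiff(names(a$current_practice$totals), "death_time")
  expect_equal(2 * a$current_practice$totals[ext], b$current_practice$totals[ext])
})

test_that("policies collapse when their parameter changes are neutralised", {
  # CP == P2 exactly once every contact and review screens under CP too
  cfg <- small_cfg(80L, seed = 3L)
  cfg$screening$p_screen_no_history <- 1
  cfg$screening$p_screen_history <- 1
  cfg$screening$p_review_includes_screen <- 1
  coh <- generate_cohort(cfg)
  cmp <- run_comparison(coh, c("CP", "P2"), cfg, seed = 3)
  expect_identical(cmp$current_practice$totals, cmp$opportunistic_screening$totals)

  # CP == P1 exactly when the collaborative-care modifiers are neutral
  cfg2 <- small_cfg(80L, seed = 4L)
  cfg2$treatment$cc_rr_response <- 1
  cfg2$treatment$cc_rr_dropout_reduction <- 1
  cfg2$treatment$cc_extra_cost <- 0
  coh2 <- generate_cohort(cfg2)
  cmp2 <- run_comparison(coh2, c("CP", "P1"), cfg2, seed = 4)
  expect_identical(cmp2$current_practice$totals, cmp2$collaborative_care$totals)
})

test_that("complication counts decouple across policies when linkage HRs are 1", {
  cfg <- unlinked_cfg(150L)
  coh <- generate_cohort(cfg)
  cmp <- run_comparison(coh, c("CP", "P3"), cfg, seed = 6)
  expect_identical(comp_count_cols(cmp$current_practice$totals),
                   comp_count_cols(cmp$combined$totals))
  expect_equal(cmp$current_practice$totals[["life_years"]],
               cmp$combined$totals[["life_years"]])
})

test_that("incremental analysis computes frontier ICERs and dominance", {
  fake <- function(id, cost, q) {
    structure(list(policy = id,
                   totals = c(cost_disc_total = cost, qalys_disc = q)),
              class = "diadem_policy_result")
  }
  # worked incrementals: 1,050 GBPm / 97k QALYs ~ 10,825 per QALY
  ic <- incremental_icer(list(fake("CP", 29626e6, 12006e3),
                              fake("P1", 30676e6, 12103e3)))
  expect_equal(ic$table$icer[2], 1050e6 / 97e3, tolerance = 1e-12)
  expect_equal(round(ic$table$icer[2]), 10825)

  # strict dominance: costlier with fewer QALYs
  ic2 <- incremental_icer(list(fake("A", 100, 10), fake("B", 120, 8),
                               fake("C", 150, 12)))
  t2 <- ic2$table
  expect_true(t2$dominated[t2$policy == "B"])
  expect_equal(ic2$frontier, c("A", "C"))

  # extended dominance: middle strategy pruned, frontier ICERs increase
  ic3 <- incremental_icer(list(fake("A", 0, 0), fake("B", 100, 1),
                               fake("C", 120, 4)))
  t3 <- ic3$table
  expect_true(t3$extended_dominated[t3$policy == "B"])
  ic_front <- t3$icer[!is.na(t3$icer)]
  expect_true(all(diff(ic_front) >= 0) || length(ic_front) < 2)

  # identical strategies: no ICER emitted, reported as equivalent
  ic4 <- incremental_icer(list(fake("A", 100, 10), fake("B", 100, 10)))
  expect_true(all(is.na(ic4$table$icer) | !is.finite(ic4$table$icer)) ||
                all(is.na(ic4$table$icer[2])))
  # zero QALY gain at positive cost: dominated, not a division error
  ic5 <- incremental_icer(list(fake("A", 100, 10), fake("B", 120, 10)))
  expect_true(ic5$table$dominated[ic5$table$policy == "B"])
})

test_that("frontier ICERs increase for random strategy sets", {
  set.seed(99)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    res <- lapply(seq_len(k), function(i) {
      structure(list(policy = paste0("S", i),
                     totals = c(cost_disc_total = stats::runif(1, 0, 1e6),
                                qalys_disc = stats::runif(1, 0, 1e4))),
                class = "diadem_policy_result")
    })
    ic <- incremental_icer(res)$table
    front <- ic$icer[!is.na(ic$icer)]
    if (length(front) >= 2) expect_true(all(diff(front) > -1e-9))
  }
})

test_that("sensitivity harness isolates parameter changes", {
  cfg <- small_cfg(120L, seed = 5L)
  sweep <- sensitivity_sweep(
    scenarios = list(
      null_change = list(),
      screen_cost_0 = list("costs.opportunistic_screen" = 0),
      screen_cost_4 = list("costs.opportunistic_screen" = 4)
    ),
    config = cfg, n_patients = 120, seed = 5, policies = c("CP", "P2")
  )
  base <- sweep[sweep$scenario == "base", ]
  null <- sweep[sweep$scenario == "null_change", ]
  expect_equal(null$cost, base$cost)
  expect_equal(null$qalys, base$qalys)
  # screening-policy total cost strictly increasing in the screen cost
  p2cost <- function(sn) sweep$cost[sweep$scenario == sn &
                                      sweep$policy == "opportunistic_screening"]
  expect_lt(p2cost("screen_cost_0"), p2cost("base"))
  expect_lt(p2cost("base"), p2cost("screen_cost_4"))
  expect_error(
    sensitivity_sweep(scenarios = list(bad = list("no.such.param" = 1)),
                      config = cfg, n_patients = 10, seed = 1,
                      policies = c("CP", "P2")),
    "unknown parameter"
  )
})

test_that("comparison tables export with the documented layout", {
  dir <- withr::local_tempdir()
  paths <- write_comparison_csv(shared_cmp, dir)
  clin <- utils::read.csv(file.path(dir, "clinical_outcomes.csv"))
  econ <- utils::read.csv(file.path(dir, "economic_outcomes.csv"))
  expect_equal(nrow(clin), 4)
  expect_true(all(c("episodes_total", "comp_mi") %in% names(clin)))
  expect_true(all(c("qalys_disc", "cost_disc_total") %in% names(econ)))
})
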