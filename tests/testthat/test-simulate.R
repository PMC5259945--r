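test_that("with all disease hazards off, only contacts and reviews remain", {
  cfg <- inert_cfg(5L)
  coh <- generate_cohort(cfg)
  res <- simulate_patient(coh[1, ], "CP", cfg, master_seed = 3, detail = TRUE)
  tot <- res$totals
  expect_equal(unname(tot[["episodes_total"]]), 0)
  expect_equal(unname(sum(comp_count_cols(tot))), 0)
  expect_equal(unname(tot[["courses"]]), 0)
  expect_gt(tot[["contacts"]], 0)
  expect_equal(unname(tot[["cost_complication_mgmt"]]), 0)
  # utility stays at baseline so QALYs = 0.807 x life years exactly
  expect_equal(unname(tot[["qalys"]]), unname(0.807 * tot[["life_years"]]),
               tolerance = 1e-9)
})

test_that("simulation is deterministic under a fixed master seed", {
  cfg <- small_cfg(5L)
  coh <- generate_cohort(cfg)
  a <- simulate_patient(coh[2, ], "P3", cfg, master_seed = 10)
  b <- simulate_patient(coh[2, ], "P3", cfg, master_seed = 10)
  expect_identical(a$totals, b$totals)
  c <- simulate_patient(coh[2, ], "P3", cfg, master_seed = 11)
  expect_false(identical(a$totals, c$totals))
})

test_that("policies sharing all active processes give bit-identical timelines", {
  # a patient who can never develop depression never touches the treatment
  # or screening-change pathways: CP vs P1 identical, and P2 vs P3 identical
  cfg <- no_depression_cfg(6L)
  coh <- generate_cohort(cfg)
  for (i in 1:3) {
    cp <- simulate_patient(coh[i, ], "CP", cfg, master_seed = 21, detail = TRUE)
    p1 <- simulate_patient(coh[i, ], "P1", cfg, master_seed = 21, detail = TRUE)
    expect_identical(cp$totals, p1$totals)
    expect_identical(cp$ledger, p1$ledger)
    p2 <- simulate_patient(coh[i, ], "P2", cfg, master_seed = 21)
    p3 <- simulate_patient(coh[i, ], "P3", cfg, master_seed = 21)
    expect_identical(p2$totals, p3$totals)
  }
})

test_that("event timelines are well-formed", {
  cfg <- small_cfg(40L, seed = 5L)
  coh <- generate_cohort(cfg)
  for (i in seq_len(12)) {
    res <- simulate_patient(coh[i, ], sample(c("CP", "P2", "P3"), 1), cfg,
                            master_seed = 31, detail = TRUE)
    ev <- res$events
    expect_true(all(diff(ev$time) >= -1e-9))            # time-ordered log
    expect_true(all(res$ledger$time >= 0))
    is_start <- grepl("^(onset|baseline_episode)", ev$event)
    is_end <- grepl("^episode_end", ev$event)
    # episodes alternate: starts and ends interleave and never overlap
    flow <- ev$event[is_start | is_end]
    state <- 0
    for (e in flow) {
      state <- state + if (grepl("^episode_end", e)) -1 else 1
      expect_true(state %in% c(0, 1))
    }
    # identification and treatment only occur inside an open episode
    open <- cumsum(is_start) - cumsum(is_end)
    expect_true(all(open[grepl("^identified", ev$event)] >= 1))
    # identified + unidentified = total episodes
    tot <- res$totals
    expect_equal(unname(tot[["episodes_identified"]] + tot[["episodes_unidentified"]]),
                 unname(tot[["episodes_total"]]))
    expect_lte(tot[["episodes_identified"]], tot[["courses"]] +
                 unname(tot[["episodes_total"]]))
  }
})

test_that("a worked patient follows the onset-screen-treat-respond pathway", {
  cfg <- small_cfg(1L)
  cfg$cohort$baseline_prevalence_major <- 0
  cfg$cohort$baseline_prevalence_minor <- 0
  cfg$cohort$baseline_history_prob <- 0
  cfg$treatment$p_response <- 1
  cfg$treatment$p_dropout <- 0
  coh <- generate_cohort(cfg)
  res <- simulate_patient(coh[1, ], "P2", cfg, master_seed = 8, detail = TRUE)
  ev <- res$events
  first_onset <- which(grepl("^onset", ev$event))[1]
  expect_false(is.na(first_onset))
  after <- ev$event[first_onset:nrow(ev)]
  ident <- which(grepl("^identified", after))[1]
  treat <- which(grepl("^treatment_start", after))[1]
  endc <- which(grepl("^(treatment_end|episode_end)", after))[1]
  # order: onset -> identification -> treatment start -> course/episode end
  expect_true(!anyNA(c(ident, treat, endc)))
  expect_lt(ident, treat + 1)
  expect_lte(treat, endc)
  expect_true(grepl("responder", after[treat]))
})
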