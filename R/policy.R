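#' Care-pathway policies
#'
#' The four policies compared by the model: current practice (`CP`),
#' collaborative care (`P1`), improved opportunistic screening at every
#' primary-care appointment (`P2`), and the combination of both (`P3`). A
#' policy is just a pair of flags: whether collaborative care modifies
#' treatment, and whether every appointment of a patient without identified
#' depression includes a screen.
#'
#' @param id One of `"current_practice"`/`"CP"`,
#'   `"collaborative_care"`/`"P1"`, `"opportunistic_screening"`/`"P2"`,
#'   `"combined"`/`"P3"`.
#' @return A `diadem_policy` object with fields `id`, `cc_enabled`,
#'   `universal_screen`.
#' @export
policy <- function(id) {
  key <- switch(tolower(as.character(id)),
                "cp" = , "current_practice" = "current_practice",
                "p1" = , "collaborative_care" = "collaborative_care",
                "p2" = , "opportunistic_screening" = "opportunistic_screening",
                "p3" = , "combined" = "combined",
                stop(sprintf("configuration error: unknown policy '%s'", id),
                     call. = FALSE))
  out <- list(
    id = key,
    cc_enabled = key %in% c("collaborative_care", "combined"),
    universal_screen = key %in% c("opportunistic_screening", "combined")
  )
  class(out) <- "diadem_policy"
  out
}

as_policy <- function(x) {
  if (inherits(x, "diadem_policy")) return(x)
  policy(x)
}

#' @export
print.diadem_policy <- function(x, ...) {
  cat(sprintf("<policy %s: collaborative care %s, universal screening %s>\n",
              x$id, if (x$cc_enabled) "on" else "off",
              if (x$universal_screen) "on" else "off"))
  invisible(x)
}

#' Run the multi-policy comparison on a cohort
#'
#' Simulates every patient of the cohort under each policy with common
#' random numbers (per-(patient, process) streams derived from `seed`), and
#' aggregates per-policy totals scaled to the reporting cohort.
#'
#' @param cohort A cohort `data.frame` from [generate_cohort()].
#' @param policies Character vector of policy ids (default all four).
#' @param config A `diadem_config`.
#' @param seed Master simulation seed.
#' @param scale_to Reporting cohort size the totals are multiplied up to
#'   (default `config$reporting$cohort_size`, 2,000,000); the scaling factor
#'   is `scale_to / nrow(cohort)`.
#' @param progress Print a progress line per policy.
#' @return A `diadem_comparison`: list of `diadem_policy_result` objects
#'   (one per policy, in the order given), each with fields `policy`,
#'   `n_simulated`, `scaling`, and `totals` (scaled named vector; see
#'   [simulate_patient()] for the components).
#' @export
run_comparison <- function(cohort, policies = c("CP", "P1", "P2", "P3"),
                           config = default_config(), seed = 1,
                           scale_to = NULL, progress = FALSE) {
  stopifnot(nrow(cohort) >= 1)
  validate_config(config)
  if (is.null(scale_to)) scale_to <- config$reporting$cohort_size
  n <- nrow(cohort)
  scaling <- scale_to / n
  out <- vector("list", length(policies))
  for (pi in seq_along(policies)) {
    pol <- as_policy(policies[[pi]])
    acc <- NULL
    for (i in seq_len(n)) {
      res <- simulate_patient(cohort[i, ], pol, config, master_seed = seed)
      acc <- if (is.null(acc)) res$totals else acc + res$totals
    }
    totals <- acc * scaling
    totals[["death_time"]] <- acc[["death_time"]] / n  # mean survival, not extensive
    pr <- list(policy = pol$id, n_simulated = n, scaling = scaling,
               totals = totals)
    class(pr) <- "diadem_policy_result"
    out[[pi]] <- pr
    if (progress) {
      message(sprintf("policy %s: %d patients, QALYs (disc) %.0f, total cost %.0f",
                      pol$id, n, totals[["qalys_disc"]], totals[["cost_total"]]))
    }
  }
  names(out) <- vapply(out, function(x) x$policy, "")
  class(out) <- "diadem_comparison"
  out
}

#' @export
print.diadem_policy_result <- function(x, ...) {
  cat(sprintf("<policy result: %s (n = %d, scaled x%.1f)>\n",
              x$policy, x$n_simulated, x$scaling))
  t <- x$totals
  cat(sprintf("  life years %.0f | QALYs (disc) %.0f | total cost %.0f (disc %.0f)\n",
              t[["life_years"]], t[["qalys_disc"]], t[["cost_total"]],
              t[["cost_disc_total"]]))
  cat(sprintf("  episodes %.0f (identified %.0f, %.1f%%) | complications %.0f\n",
              t[["episodes_total"]], t[["episodes_identified"]],
              100 * t[["episodes_identified"]] / max(t[["episodes_total"]], 1),
              sum(t[grep("^comp_", names(t))])))
  invisible(x)
}

#' Tabulate a policy comparison
#'
#' @param x A `diadem_comparison`.
#' @param ... Unused.
#' @return `data.frame` with one row per policy and one column per total.
#' @export
as.data.frame.diadem_comparison <- function(x, ...) {
  tab <- do.call(rbind, lapply(x, function(p) p$totals))
  out <- data.frame(policy = vapply(x, function(p) p$policy, ""),
                    tab, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Export comparison tables as CSV
#'
#' Writes two CSVs mirroring the reporting tables: clinical event counts
#' (complications by type, episodes total/identified/unidentified) and
#' economic outcomes (life years, QALYs, cost categories, societal days).
#'
#' @param comparison A `diadem_comparison`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_comparison_csv <- function(comparison, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- as.data.frame(comparison)
  clin_cols <- c("policy", grep("^comp_", names(tab), value = TRUE),
                 "episodes_total", "episodes_identified", "episodes_unidentified")
  econ_cols <- c("policy", "life_years", "life_years_disc", "qalys", "qalys_disc",
                 "qaly_loss_depression_disc", "informal_care_days", "sick_days",
                 grep("^cost_", names(tab), value = TRUE))
  p1 <- file.path(dir, "clinical_outcomes.csv")
  p2 <- file.path(dir, "economic_outcomes.csv")
  utils::write.csv(tab[, clin_cols], p1, row.names = FALSE)
  utils::write.csv(tab[, econ_cols], p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Incremental cost-effectiveness analysis
#'
#' Orders strategies by discounted cost, flags strict dominance (more costly
#' and no more effective than another strategy) and extended dominance
#' (removed until ICERs increase along the frontier), and computes the
#' incremental cost-effectiveness ratios between adjacent strategies on the
#' efficient frontier.
#'
#' @param results A `diadem_comparison`, or a list of objects each carrying
#'   `policy`, and `totals` with `cost_disc_total` and `qalys_disc`.
#' @return A `diadem_icer` object: `data.frame` `table` with per-strategy
#'   cost, QALYs, dominance flags and frontier ICERs, plus `frontier`
#'   (ordered ids).
#' @examples
#' fake <- function(id, cost, q) {
#'   structure(list(policy = id,
#'                  totals = c(cost_disc_total = cost, qalys_disc = q)),
#'             class = "diadem_policy_result")
#' }
#' incremental_icer(list(fake("CP", 2.96e10, 1.2006e10 / 1e3),
#'                       fake("P1", 3.07e10, 1.2103e10 / 1e3)))
#' @export
incremental_icer <- function(results) {
  stopifnot(length(results) >= 2)
  tab <- data.frame(
    policy = vapply(results, function(p) p$policy, ""),
    cost = vapply(results, function(p) unname(p$totals[["cost_disc_total"]]), 0),
    qalys = vapply(results, function(p) unname(p$totals[["qalys_disc"]]), 0),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$cost, tab$qalys), ]
  rownames(tab) <- NULL
  n <- nrow(tab)
  tab$dominated <- FALSE
  tab$extended_dominated <- FALSE
  # strict dominance: some other strategy has cost <= and qalys >=, one strict
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          tab$cost[j] <= tab$cost[i] && tab$qalys[j] >= tab$qalys[i] &&
          (tab$cost[j] < tab$cost[i] || tab$qalys[j] > tab$qalys[i])) {
        tab$dominated[i] <- TRUE
        break
      }
    }
  }
  # extended dominance on the survivors: prune until ICERs increase
  repeat {
    idx <- which(!tab$dominated & !tab$extended_dominated)
    if (length(idx) < 3) break
    ic <- diff(tab$cost[idx]) / diff(tab$qalys[idx])
    bad <- which(diff(ic) < 0)
    if (!length(bad)) break
    tab$extended_dominated[idx[bad[1] + 1]] <- TRUE
  }
  idx <- which(!tab$dominated & !tab$extended_dominated)
  tab$icer <- NA_real_
  if (length(idx) >= 2) {
    dq <- diff(tab$qalys[idx])
    dc <- diff(tab$cost[idx])
    icer <- ifelse(dq > 0, dc / dq, NA_real_)
    tab$icer[idx[-1]] <- icer
  }
  out <- list(table = tab, frontier = tab$policy[idx])
  class(out) <- "diadem_icer"
  out
}

#' @export
print.diadem_icer <- function(x, ...) {
  cat("Incremental cost-effectiveness analysis (discounted)\n")
  tab <- x$table
  tab$cost <- formatC(tab$cost, format = "f", digits = 0, big.mark = ",")
  tab$qalys <- formatC(tab$qalys, format = "f", digits = 0, big.mark = ",")
  tab$icer <- ifelse(is.na(x$table$icer), "-",
                     formatC(x$table$icer, format = "f", digits = 0, big.mark = ","))
  status <- ifelse(x$table$dominated, "dominated",
                   ifelse(x$table$extended_dominated, "ext. dominated", "frontier"))
  print(data.frame(tab[, c("policy", "cost", "qalys", "icer")], status,
                   stringsAsFactors = FALSE), row.names = FALSE)
  invisible(x)
}

#' Univariate sensitivity analyses
#'
#' Re-runs the policy comparison once per scenario, each scenario overriding
#' one or more named parameters of the base configuration (see
#' [apply_overrides()]), under the base seed and cohort so differences
#' isolate the parameter change. The default scenario set varies the relapse
#' time, the bi-directional hazard ratios (including the
#' complication-on-depression ratio to 1.0 and 2.0), the depression
#' disutility, the screen cost (0 and 4) and the collaborative-care add-on
#' cost.
#'
#' @param scenarios Named list of override lists, e.g.
#'   `list(relapse_2yr = list("natural_history.mean_time_relapse" = 2))`,
#'   or a YAML file path with the same structure. `NULL` uses
#'   [default_scenarios()].
#' @param config Base `diadem_config`.
#' @param n_patients Cohort size per scenario run.
#' @param seed Master seed (cohort and simulation).
#' @param policies Policies to compare.
#' @return A `data.frame` with one row per scenario x policy carrying
#'   discounted cost, QALYs, ICER vs the ordered frontier and dominance
#'   status; scenario `"base"` is always included first.
#' @export
sensitivity_sweep <- function(scenarios = NULL, config = default_config(),
                              n_patients = 2000, seed = 1,
                              policies = c("CP", "P1", "P2", "P3")) {
  if (is.null(scenarios)) scenarios <- default_scenarios()
  if (is.character(scenarios) && length(scenarios) == 1) {
    scenarios <- yaml::read_yaml(scenarios)
  }
  stopifnot(is.list(scenarios))
  scenarios <- c(list(base = list()), scenarios)
  rows <- list()
  for (sn in names(scenarios)) {
    cfg <- apply_overrides(config, scenarios[[sn]])
    cfg$cohort$n_patients <- n_patients
    cfg$cohort$seed <- seed
    cohort <- generate_cohort(cfg)
    cmp <- run_comparison(cohort, policies, cfg, seed = seed)
    ic <- incremental_icer(cmp)
    tab <- ic$table
    tab$scenario <- sn
    rows[[sn]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("scenario", setdiff(names(out), "scenario"))]
}

#' @rdname sensitivity_sweep
#' @export
default_scenarios <- function() {
  list(
    relapse_time_2yr = list("natural_history.mean_time_relapse" = 2),
    relapse_time_1yr = list("natural_history.mean_time_relapse" = 1),
    hr_comp_on_dep_1.0 = list("natural_history.hr_complication_on_depression" = 1.0),
    hr_comp_on_dep_2.0 = list("natural_history.hr_complication_on_depression" = 2.0),
    hr_dep_on_comp_null = list(
      "complications.hr_depression.micro.minor" = 1,
      "complications.hr_depression.micro.major" = 1,
      "complications.hr_depression.macro.minor" = 1,
      "complications.hr_depression.macro.major" = 1
    ),
    major_disutility_0.2 = list("utilities.depression.major" = -0.2),
    major_disutility_0.4 = list("utilities.depression.major" = -0.4),
    screen_cost_0 = list("costs.opportunistic_screen" = 0),
    screen_cost_4 = list("costs.opportunistic_screen" = 4),
    cc_cost_half = list("treatment.cc_extra_cost" = 90),
    cc_cost_double = list("treatment.cc_extra_cost" = 360)
  )
}
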