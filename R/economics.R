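#' Ledger cost categories
#'
#' The closed set of cost categories used by the patient ledger, mirroring
#' the cost-breakdown rows of the reporting tables.
#' @export
LEDGER_CATEGORIES <- c("gp", "review", "screening", "interview", "treatment",
                       "complication_mgmt", "ongoing_mgmt")

#' Health-state utility
#'
#' Composes the utility of a patient snapshot: the diabetes baseline (0.807
#' by default) plus additive decrements for every complication present
#' (using the event-year decrement during the year following an event and
#' the prior-history decrement thereafter — these differ only for MI in the
#' default table, where the source reports -0.065 in the event year and
#' +0.008 with prior history; the blindness decrement is likewise +0.033 as
#' printed) and for the current depression state. The major-depression
#' decrement is halved while the patient is on treatment and will ultimately
#' respond to it. The composed value is clamped to the configured floor
#' (-0.594, the EQ-5D minimum) and 1. A multiplicative composition (baseline
#' times per-condition multipliers `1 + decrement`) is available via
#' `utilities.composition = "multiplicative"`.
#'
#' @param depression `"none"`, `"minor"` or `"major"`.
#' @param comps_chronic Character vector of complication types present
#'   beyond their event year.
#' @param comps_event_year Character vector of complication types within a
#'   year of an event.
#' @param on_treatment,responder Logical treatment snapshot; the responder
#'   multiplier applies only when both are `TRUE`.
#' @param params The `utilities` block of a configuration.
#' @return Utility value.
#' @examples
#' u <- default_config()$utilities
#' utility_at("none", params = u)                                   # 0.807
#' utility_at("major", params = u)                                  # 0.507
#' utility_at("major", on_treatment = TRUE, responder = TRUE, params = u)  # 0.657
#' @export
utility_at <- function(depression = "none", comps_chronic = character(0),
                       comps_event_year = character(0),
                       on_treatment = FALSE, responder = FALSE,
                       params = default_config()$utilities) {
  depression <- match.arg(depression, c("none", "minor", "major"))
  dep_dec <- if (depression == "none") 0 else params$depression[[depression]]
  if (depression == "major" && on_treatment && responder) {
    dep_dec <- dep_dec * params$responder_multiplier
  }
  decs <- c(params$event_year[comps_event_year],
            params$chronic[comps_chronic], dep_dec)
  u <- if (identical(params$composition, "multiplicative")) {
    params$baseline * prod(1 + decs)
  } else {
    params$baseline + sum(decs)
  }
  min(1, max(params$floor, u))
}

#' Present value of a future amount
#'
#' Continuous-exponent discounting: `amount / (1 + rate)^time`. With
#' `annual = TRUE` the exponent is `floor(time)` (annual-step discounting).
#'
#' @param amount Amount (vectorised).
#' @param time Time in years, `>= 0`.
#' @param rate Annual discount rate (0.035 by default).
#' @param annual Use annual-step discounting instead of the continuous
#'   exponent.
#' @return Present value.
#' @examples
#' discount(100, 1)    # 96.618...
#' discount(100, 20)   # 50.257...
#' @export
discount <- function(amount, time, rate = 0.035, annual = FALSE) {
  if (any(time < 0)) stop("cannot discount at negative time", call. = FALSE)
  stopifnot(rate >= 0)
  ex <- if (annual) floor(time) else time
  amount / (1 + rate)^ex
}

#' Discount factor integrated over an interval
#'
#' \eqn{\int_{t_0}^{t_1} (1+r)^{-t} dt}; used to discount quantities that
#' accrue continuously (utility time, annual management costs).
#'
#' @param t0,t1 Interval endpoints in years, `0 <= t0 <= t1`.
#' @param rate Annual discount rate.
#' @return The integral (equals `t1 - t0` when `rate = 0`).
#' @export
discount_integral <- function(t0, t1, rate = 0.035) {
  if (any(t0 < 0) || any(t1 < t0)) {
    stop("discount interval must satisfy 0 <= t0 <= t1", call. = FALSE)
  }
  if (rate == 0) return(t1 - t0)
  lv <- log1p(rate)
  ((1 + rate)^(-t0) - (1 + rate)^(-t1)) / lv
}

#' Aggregate a patient ledger
#'
#' Reduces an entry-level ledger (as returned by
#' `simulate_patient(..., detail = TRUE)`) to per-category discounted and
#' undiscounted totals. Lump entries (`duration == 0`) are discounted at
#' their time stamp; accrual entries are spread uniformly over
#' `[time, time + duration]` and discounted by the exact integral. Used by
#' the reconciliation tests to cross-check the simulator's internal
#' accumulators.
#'
#' @param ledger `data.frame` with columns `time`, `duration`, `category`,
#'   `amount`.
#' @param rate Annual discount rate.
#' @return `data.frame` with one row per category plus a `total` row and
#'   columns `undiscounted`, `discounted`.
#' @export
accumulate_ledger <- function(ledger, rate = 0.035) {
  stopifnot(all(c("time", "duration", "category", "amount") %in% names(ledger)))
  if (any(ledger$time < 0)) stop("ledger entry at negative time", call. = FALSE)
  bad <- setdiff(unique(ledger$category), LEDGER_CATEGORIES)
  if (length(bad)) {
    stop(sprintf("unknown ledger category '%s'", bad[1]), call. = FALSE)
  }
  disc <- ifelse(
    ledger$duration <= 0,
    discount(ledger$amount, ledger$time, rate),
    ledger$amount / pmax(ledger$duration, 1e-300) *
      discount_integral(ledger$time, ledger$time + ledger$duration, rate)
  )
  cats <- LEDGER_CATEGORIES
  und <- vapply(cats, function(k) sum(ledger$amount[ledger$category == k]), 0)
  dis <- vapply(cats, function(k) sum(disc[ledger$category == k]), 0)
  out <- data.frame(category = c(cats, "total"),
                    undiscounted = c(und, sum(und)),
                    discounted = c(dis, sum(dis)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
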