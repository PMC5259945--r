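#' Convert an annual event probability to a constant event rate
#'
#' Under a constant-hazard (exponential) model an annual event probability
#' `p` corresponds to the rate \eqn{-\ln(1 - p)} per year; the round trip via
#' [rate_to_annual_prob()] is exact to floating point.
#'
#' @param p Annual probability (vectorised), `0 <= p < 1`.
#' @return Event rate per year.
#' @examples
#' annual_prob_to_rate(0.054)       # 0.05551...
#' rate_to_annual_prob(annual_prob_to_rate(0.42))
#' @export
annual_prob_to_rate <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("annual probability must lie in [0, 1)", call. = FALSE)
  }
  -log1p(-p)
}

#' @rdname annual_prob_to_rate
#' @param rate Event rate per year, `rate >= 0`.
#' @export
rate_to_annual_prob <- function(rate) {
  if (any(!is.finite(rate) & rate != Inf) || any(rate < 0)) {
    stop("rate must be >= 0", call. = FALSE)
  }
  -expm1(-rate)
}

#' Minor-to-major progression rate implied by a fraction-by-horizon input
#'
#' The time to progression is parameterised by the fraction of (untreated,
#' non-recovering) minor episodes that have progressed by a stated horizon;
#' under the exponential model the rate is \eqn{-\ln(1 - f)/h}.
#'
#' @param params The `natural_history` block of a configuration.
#' @return Progression rate per year.
#' @examples
#' progression_rate(default_config()$natural_history)  # -log(0.58)/2
#' @export
progression_rate <- function(params) {
  f <- params$progression_minor_to_major$fraction
  h <- params$progression_minor_to_major$horizon
  annual_prob_to_rate(f) / h
}

# rexp that treats rate 0 as "never" and infinite mean as rate 0
rexp_safe <- function(n, rate) {
  if (rate <= 0 || !is.finite(rate)) return(rep(Inf, n))
  stats::rexp(n, rate)
}

#' Sample depression onset (or relapse) waiting times
#'
#' From the depression-free state, patients with no depression history face
#' two independent competing exponential onset processes (minor and major,
#' rates fitted to the annual incidence probabilities); patients with a
#' history face a single relapse process with the configured mean time to
#' relapse, with the relapse severity re-drawn. While any diabetes-related
#' complication is present every onset hazard is multiplied by the
#' complication-on-depression hazard ratio (the same multiplier whether one
#' or several complications are present).
#'
#' @param params The `natural_history` block of a configuration.
#' @param history Logical: does the patient have a history of depression?
#' @param complication_present Logical: any diabetes-related complication in
#'   the patient's history?
#' @param n Number of independent draws.
#' @param components If `TRUE`, also return the two competing component
#'   waiting times (`t_minor`, `t_major`); for `history = TRUE` the single
#'   relapse time is returned in both the `time` column and `t_relapse`.
#' @return A `data.frame` with columns `time` (years) and `severity`
#'   (`"minor"`/`"major"`), plus component columns when requested. Draws come
#'   from the current RNG state (use [stream_eval()] for stream control).
#' @export
sample_onset_time <- function(params, history = FALSE,
                              complication_present = FALSE, n = 1,
                              components = FALSE) {
  m <- if (complication_present) params$hr_complication_on_depression else 1
  if (history) {
    t <- rexp_safe(n, m / params$mean_time_relapse)
    sev <- ifelse(stats::runif(n) < params$relapse_severity_p_major,
                  "major", "minor")
    out <- data.frame(time = t, severity = sev, stringsAsFactors = FALSE)
    if (components) out$t_relapse <- t
    return(out)
  }
  r_minor <- annual_prob_to_rate(params$annual_incidence_minor) * m
  r_major <- annual_prob_to_rate(params$annual_incidence_major) * m
  t_minor <- rexp_safe(n, r_minor)
  t_major <- rexp_safe(n, r_major)
  out <- data.frame(
    time = pmin(t_minor, t_major),
    severity = ifelse(t_major <= t_minor, "major", "minor"),
    stringsAsFactors = FALSE
  )
  if (components) {
    out$t_minor <- t_minor
    out$t_major <- t_major
  }
  out
}

#' Sample the next natural-history transition of an open episode
#'
#' Minor episodes face competing exponential risks of progression to major
#' depression (rate fitted to the configured fraction-by-horizon) and
#' spontaneous recovery (rate 1 / mean recovery time); major episodes face
#' spontaneous recovery only. The winning event and its waiting time (from
#' episode start or from the current moment, by memorylessness) are returned.
#'
#' @param severity `"minor"` or `"major"`.
#' @param params The `natural_history` block of a configuration.
#' @param n Number of independent draws.
#' @return A `data.frame` with columns `event`
#'   (`"progression"`/`"recovery"`) and `time` (years).
#' @examples
#' cfg <- default_config()
#' set.seed(1)
#' sample_progression_or_recovery("minor", cfg$natural_history, n = 3)
#' @export
sample_progression_or_recovery <- function(severity, params, n = 1) {
  severity <- match.arg(severity, c("minor", "major"))
  if (severity == "major") {
    return(data.frame(event = rep("recovery", n),
                      time = rexp_safe(n, 1 / params$mean_time_recovery_major),
                      stringsAsFactors = FALSE))
  }
  t_prog <- rexp_safe(n, progression_rate(params))
  t_rec <- rexp_safe(n, 1 / params$mean_time_recovery_minor)
  data.frame(
    event = ifelse(t_prog <= t_rec, "progression", "recovery"),
    time = pmin(t_prog, t_rec),
    stringsAsFactors = FALSE
  )
}
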