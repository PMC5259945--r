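#' Collaborative-care adjustment of treatment probabilities
#'
#' Collaborative care is modelled as relative-risk modifiers on the response
#' and drop-out probabilities of a depression treatment course: response is
#' multiplied by the response relative risk (1.79 by default, capped at 1)
#' and drop-out is divided by the drop-out relative risk (1.33 by default,
#' read as quantifying the size of the decrease). Setting
#' `cc_dropout_as_retention = TRUE` switches to the alternative reading in
#' which retention (1 - dropout) is multiplied by 1.33 instead.
#'
#' @param base_p_response,base_p_dropout Base probabilities in `[0, 1]`.
#' @param params The `treatment` block of a configuration.
#' @return Named list with elements `p_response` and `p_dropout`, both valid
#'   probabilities.
#' @examples
#' apply_collaborative_care(0.40, 0.30, default_config()$treatment)
#' @export
apply_collaborative_care <- function(base_p_response, base_p_dropout,
                                     params = default_config()$treatment) {
  stopifnot(base_p_response >= 0, base_p_response <= 1,
            base_p_dropout >= 0, base_p_dropout <= 1)
  p_resp <- pmin(1, base_p_response * params$cc_rr_response)
  p_drop <- if (isTRUE(params$cc_dropout_as_retention)) {
    pmax(0, 1 - pmin(1, (1 - base_p_dropout) * params$cc_rr_dropout_reduction))
  } else {
    base_p_dropout / params$cc_rr_dropout_reduction
  }
  list(p_response = p_resp, p_dropout = pmin(1, pmax(0, p_drop)))
}

# Full-course resource cost by severity/modality. Minor episodes get a
# low-intensity psychotherapy course; major episodes get pharmacotherapy for
# the course duration, plus a high-intensity psychotherapy course for the
# configured fraction of patients (high_intensity is the per-course draw).
course_full_cost <- function(severity, high_intensity, params) {
  if (severity == "minor") {
    params$n_sessions_low * params$session_cost
  } else {
    params$drug_cost_per_day * 365.25 * params$duration +
      if (high_intensity) params$n_sessions_high * params$session_cost else 0
  }
}

#' Simulate depression treatment courses
#'
#' Draws the outcome of `n` single treatment courses for an identified
#' episode of the given severity: drop-out first, then (for completers)
#' response, with collaborative-care adjustment when the policy enables it.
#' Responders keep their natural-history benefits only through the linked
#' patient simulation; this operation exposes the course-level draws so the
#' adjusted response and drop-out probabilities can be recovered empirically.
#'
#' @param severity `"minor"` or `"major"`.
#' @param policy A policy id or [policy()] object (collaborative care is
#'   active under the collaborative-care and combined policies).
#' @param config A full `diadem_config`.
#' @param n Number of courses.
#' @return A `data.frame` with columns `severity`, `collaborative_care`,
#'   `dropped_out`, `responded` (mutually exclusive with `dropped_out`),
#'   `high_intensity`, `planned_duration`, `full_cost` (excluding any
#'   collaborative-care add-on) and `cc_extra_cost`.
#' @export
simulate_course <- function(severity, policy = "current_practice",
                            config = default_config(), n = 1) {
  severity <- match.arg(severity, c("minor", "major"))
  pol <- as_policy(policy)
  tr <- config$treatment
  p <- list(p_response = tr$p_response, p_dropout = tr$p_dropout)
  if (pol$cc_enabled) p <- apply_collaborative_care(p$p_response, p$p_dropout, tr)
  u_drop <- stats::runif(n)
  u_resp <- stats::runif(n)
  u_high <- stats::runif(n)
  dropped <- u_drop < p$p_dropout
  responded <- !dropped & u_resp < p$p_response
  high <- severity == "major" & u_high < tr$p_high_intensity_major
  full_cost <- vapply(high, function(h) course_full_cost(severity, h, tr), 0)
  data.frame(
    severity = severity,
    collaborative_care = pol$cc_enabled,
    dropped_out = dropped,
    responded = responded,
    high_intensity = high,
    planned_duration = tr$duration,
    full_cost = full_cost,
    cc_extra_cost = if (pol$cc_enabled) tr$cc_extra_cost else 0,
    stringsAsFactors = FALSE
  )
}
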