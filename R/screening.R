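#' Primary-care contact process
#'
#' GP appointments (other than appointments that are part of depression
#' treatment) arrive as a Poisson process whose rate tracks the current
#' depression state: 12.5 per year with no depression and 8 per year with
#' minor or major depression by default.
#'
#' @param state Depression state, `"none"`, `"minor"` or `"major"`.
#' @param years Length of the simulated window (years).
#' @param params The `screening` block of a configuration.
#' @return Sorted numeric vector of contact times in `[0, years)`.
#' @examples
#' cfg <- default_config()
#' set.seed(1)
#' length(simulate_contacts("none", 10, cfg$screening)) / 10  # ~12.5/yr
#' @export
simulate_contacts <- function(state, years, params) {
  state <- match.arg(state, c("none", "minor", "major"))
  rate <- params$gp_visits_per_year[[state]]
  if (rate <= 0 || years <= 0) return(numeric(0))
  n <- stats::rpois(1, rate * years)
  sort(stats::runif(n, 0, years))
}

# Screen probability at a GP contact for an unidentified patient.
gp_screen_prob <- function(policy, history, params) {
  if (policy$universal_screen) return(1)
  if (history) params$p_screen_history else params$p_screen_no_history
}

#' Annual-review attendance probability
#'
#' One review is offered per simulated year on the patient's diabetes
#' anniversary; attendance is the depression-free probability multiplied by a
#' state-specific relative risk (0.9 minor, 0.65 major by default).
#'
#' @inheritParams simulate_contacts
#' @return Attendance probability.
#' @examples
#' attend_review_prob("major", default_config()$screening)  # 0.904 * 0.65
#' @export
attend_review_prob <- function(state, params) {
  state <- match.arg(state, c("none", "minor", "major"))
  params$p_attend_review_no_dep * switch(state, none = 1,
                                         minor = params$review_rr_minor,
                                         major = params$review_rr_major)
}

#' Administer an opportunistic or annual-review depression screen
#'
#' Simulates the screening and case-finding cascade at one primary-care
#' contact for a patient without currently identified depression: whether a
#' screen happens at all (probability 5% / 20% by screening history under
#' current practice, 1 under the universal-screening policies for GP
#' contacts; 85.9% or 1 at the annual review), the two-item Whooley screen
#' with imperfect sensitivity/specificity, and the confirmatory structured
#' interview (perfect by default) that turns true positives into identified
#' depression and rules false positives out. Costs of the screen and
#' interview are returned alongside.
#'
#' @param true_state `"none"`, `"minor"` or `"major"`; minor and major count
#'   as depressed for the Whooley sensitivity.
#' @param setting `"gp_appointment"` or `"annual_review"`.
#' @param policy A policy id or [policy()] object.
#' @param history Logical: lifetime history of depression (drives the
#'   current-practice screen probability at GP contacts).
#' @param config A full `diadem_config` (screen/interview costs come from its
#'   `costs` block).
#' @param n Number of independent screen opportunities to simulate.
#' @return A `data.frame` with columns `screened` (logical), `whooley`
#'   (`"positive"`/`"negative"`/`"not_done"`), `interview`
#'   (`"confirmed"`/`"ruled_out"`/`"not_done"`), `identified` (logical) and
#'   `cost` (screen + interview cost incurred).
#' @export
apply_screen <- function(true_state, setting = c("gp_appointment", "annual_review"),
                         policy = "current_practice", history = FALSE,
                         config = default_config(), n = 1) {
  true_state <- match.arg(true_state, c("none", "minor", "major"))
  setting <- match.arg(setting)
  pol <- as_policy(policy)
  params <- config$screening
  p_screen <- if (setting == "gp_appointment") {
    gp_screen_prob(pol, history, params)
  } else {
    if (pol$universal_screen) 1 else params$p_review_includes_screen
  }
  depressed <- true_state != "none"
  screened <- stats::runif(n) < p_screen
  p_pos <- if (depressed) params$whooley_sens else 1 - params$whooley_spec
  pos <- screened & stats::runif(n) < p_pos
  # structured interview: confirms true cases w.p. interview_sens, clears
  # false positives w.p. interview_spec (both 1 by default)
  conf <- pos & (if (depressed) stats::runif(n) < params$interview_sens
                 else stats::runif(n) >= params$interview_spec)
  data.frame(
    screened = screened,
    whooley = ifelse(!screened, "not_done", ifelse(pos, "positive", "negative")),
    interview = ifelse(!pos, "not_done", ifelse(conf, "confirmed", "ruled_out")),
    identified = conf,
    cost = screened * config$costs$opportunistic_screen +
      pos * config$costs$interview,
    stringsAsFactors = FALSE
  )
}
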