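#' Default model configuration
#'
#' Returns the full nested parameter set of the simulation. Every number is
#' config-exposed: the depression natural history, screening and case-finding
#' operating characteristics, treatment pathway, the bi-directional hazard
#' linkage, the surrogate diabetes risk engine, unit costs, utilities,
#' discounting and societal day rates. Values sourced from the model's
#' evidence tables are the defaults; quantities for which no published value
#' exists (treatment course composition, interview unit cost, societal day
#' rates, the surrogate risk engine) are documented placeholders and are the
#' natural handles for the sensitivity-analysis harness.
#'
#' @return A nested list of class `diadem_config`.
#' @seealso [load_config()], [apply_overrides()], [validate_config()]
#' @export
default_config <- function() {
  cfg <- list(
    cohort = list(
      n_patients = 10000L,
      seed = 1L,
      age = list(mean = 65, sd = 10, min = 35, max = 90),
      diabetes_duration = list(mean = 8, sd = 6, min = 0, max = 40),
      p_male = 0.56,
      risk_factors = list(
        hba1c = list(mean = 7.5, sd = 1.2, min = 5, max = 12),
        sbp   = list(mean = 135, sd = 15, min = 90, max = 200),
        bmi   = list(mean = 30, sd = 5, min = 18, max = 50)
      ),
      p_smoker = 0.16,
      baseline_prevalence_major = 0.10,
      baseline_prevalence_minor = 0.10,
      baseline_history_prob = 0.10,
      baseline_identified_prob = 0
    ),
    natural_history = list(
      annual_incidence_minor = 0.054,
      annual_incidence_major = 0.054,
      progression_minor_to_major = list(fraction = 0.42, horizon = 2),
      mean_time_recovery_minor = 0.354,
      mean_time_recovery_major = 0.877,
      mean_time_relapse = 1.359,
      relapse_severity_p_major = 0.5,
      hr_complication_on_depression = 1.5
    ),
    screening = list(
      gp_visits_per_year = c(none = 12.5, minor = 8, major = 8),
      p_screen_no_history = 0.05,
      p_screen_history = 0.20,
      p_attend_review_no_dep = 0.904,
      review_rr_minor = 0.9,
      review_rr_major = 0.65,
      p_review_includes_screen = 0.859,
      whooley_sens = 0.95,
      whooley_spec = 0.66,
      interview_sens = 1.0,
      interview_spec = 1.0
    ),
    treatment = list(
      p_response = 0.5,          # placeholder default, config-exposed
      p_dropout = 0.3,           # placeholder default, config-exposed
      duration = 0.25,           # years, placeholder default
      cc_rr_response = 1.79,
      cc_rr_dropout_reduction = 1.33,
      cc_dropout_as_retention = FALSE,
      dropout_cost_fraction = 0.5,
      n_sessions_low = 6,
      n_sessions_high = 12,
      p_high_intensity_major = 0.25,
      drug_cost_per_day = 0.073,
      session_cost = 88,
      cc_extra_cost = 180        # per-course collaborative-care add-on
    ),
    complications = list(
      types = c("ihd", "mi", "stroke", "chf", "ulcer",
                "amputation", "blindness", "renal"),
      classes = list(
        micro = c("ihd", "blindness", "renal"),
        macro = c("chf", "mi", "stroke", "ulcer", "amputation")
      ),
      recurrent = c("mi", "stroke", "ulcer"),
      hr_depression = list(
        micro = c(minor = 1.31, major = 1.36),
        macro = c(minor = 1.00, major = 1.25)
      ),
      engine = list(
        kind = "surrogate",
        base_hazard = c(ihd = 0.0077, mi = 0.0105, stroke = 0.0076,
                        chf = 0.0061, ulcer = 0.0019, amputation = 0.0024,
                        blindness = 0.0032, renal = 0.0019),
        age_slope = 0
      ),
      mortality = list(
        intercept = -10,
        age_slope = 0.092,
        loadings = c(ihd = 0.2, mi = 0.4, stroke = 0.4, chf = 0.6,
                     ulcer = 0.1, amputation = 0.5, blindness = 0,
                     renal = 1.0)
      ),
      severe_hypo_rate = 0,
      max_age = 110
    ),
    costs = list(
      gp_appointment = 37,
      annual_review = 397,
      opportunistic_screen = 2,
      interview = 80,            # placeholder default, config-exposed
      diabetes_no_complication = 252,
      event_year = c(chf = 3559, ihd = 3139, mi = 6522, stroke = 3793,
                     blindness = 1397, ulcer = 1855, amputation = 13556,
                     renal = 34806),
      subsequent_year = c(chf = 1010, ihd = 790, mi = 744, stroke = 399,
                          blindness = 450, ulcer = 21, amputation = 481,
                          renal = 34806),
      severe_hypo = 390,
      currency_year = 2013
    ),
    utilities = list(
      baseline = 0.807,
      event_year = c(mi = -0.065, ihd = -0.028, stroke = -0.165,
                     chf = -0.101, amputation = -0.172, blindness = 0.033,
                     renal = -0.263, ulcer = -0.016),
      chronic = c(mi = 0.008, ihd = -0.028, stroke = -0.165,
                  chf = -0.101, amputation = -0.172, blindness = 0.033,
                  renal = -0.263, ulcer = -0.016),
      severe_hypo = -0.00186,
      depression = c(minor = 0, major = -0.3),
      responder_multiplier = 0.5,
      floor = -0.594,
      composition = "additive"
    ),
    economics = list(
      discount_rate = 0.035,
      discounting = "continuous",
      societal = list(
        informal_days = c(none = 2, minor = 10, major = 25),
        sick_days = c(none = 5, minor = 20, major = 60),
        complication_informal_add = 10,
        complication_sick_add = 5
      )
    ),
    reporting = list(cohort_size = 2e6)
  )
  class(cfg) <- "diadem_config"
  cfg
}

#' Load a configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over [default_config()],
#' so a file needs to state only the parameters it changes.
#'
#' @param path Path to a YAML or JSON file.
#' @return A validated `diadem_config`.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- merge_config(default_config(), user, path = character(0))
  validate_config(cfg)
}

# Recursive merge of a user list over the defaults; unknown names error so
# typos in config files surface immediately.
merge_config <- function(base, user, path) {
  if (!is.list(user)) {
    return(coerce_leaf(base, user, path))
  }
  if (is.null(names(user)) && !is.list(base)) {
    return(coerce_leaf(base, unlist(user), path))
  }
  for (nm in names(user)) {
    here <- c(path, nm)
    if (is.list(base) && !nm %in% names(base)) {
      stop(sprintf("unknown configuration field '%s'", paste(here, collapse = ".")),
           call. = FALSE)
    }
    if (is.list(base)) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    } else {
      if (!nm %in% names(base)) {
        stop(sprintf("unknown configuration field '%s'", paste(here, collapse = ".")),
             call. = FALSE)
      }
      base[nm] <- as.numeric(user[[nm]])
    }
  }
  class_keep <- class(base)
  base
}

coerce_leaf <- function(base, value, path) {
  if (is.numeric(base) && !is.null(names(base)) && is.list(value) == FALSE &&
      !is.null(names(value))) {
    bad <- setdiff(names(value), names(base))
    if (length(bad)) {
      stop(sprintf("unknown configuration field '%s.%s'",
                   paste(path, collapse = "."), bad[1]), call. = FALSE)
    }
    base[names(value)] <- as.numeric(value)
    return(base)
  }
  if (is.character(base)) return(as.character(value))
  if (is.logical(base)) return(as.logical(value))
  if (length(value) == length(base) || length(base) == 0 || is.null(names(base))) {
    return(if (is.numeric(base)) as.numeric(value) else value)
  }
  stop(sprintf("cannot assign value of length %d to configuration field '%s'",
               length(value), paste(path, collapse = ".")), call. = FALSE)
}

#' Apply named parameter overrides
#'
#' Overrides are given as a named list whose names are dot-separated paths
#' into the configuration, e.g.
#' `list("natural_history.mean_time_relapse" = 2,
#'       "costs.opportunistic_screen" = 0)`. Vector elements are addressed by
#' name: `"screening.gp_visits_per_year.none" = 10`. Unknown paths raise a
#' configuration error naming the field. This is the entry point the
#' sensitivity-analysis harness uses.
#'
#' @param config A `diadem_config`.
#' @param overrides Named list of replacement values (possibly empty).
#' @return The modified, validated configuration.
#' @export
apply_overrides <- function(config, overrides) {
  stopifnot(inherits(config, "diadem_config"))
  if (length(overrides) == 0) return(config)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("overrides must be a fully named list", call. = FALSE)
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    config <- set_path(config, parts, overrides[[key]], key)
  }
  validate_config(config)
}

set_path <- function(node, parts, value, key) {
  nm <- parts[1]
  if (is.list(node)) {
    if (!nm %in% names(node)) {
      stop(sprintf("unknown parameter '%s' (no field '%s')", key, nm), call. = FALSE)
    }
    if (length(parts) == 1) {
      node[[nm]] <- if (is.list(node[[nm]])) value else
        coerce_leaf(node[[nm]], value, key)
    } else {
      node[[nm]] <- set_path(node[[nm]], parts[-1], value, key)
    }
    return(node)
  }
  # named vector leaf
  if (!nm %in% names(node) || length(parts) > 1) {
    stop(sprintf("unknown parameter '%s'", key), call. = FALSE)
  }
  node[nm] <- as.numeric(value)
  node
}

#' Validate a configuration
#'
#' Checks probabilities lie in \[0, 1\], rates, durations and costs are
#' non-negative, hazard ratios are positive and the complication class map is
#' a partition of the complication types. Errors name the offending field.
#'
#' @param config A `diadem_config`.
#' @return The configuration, invisibly usable in a pipeline.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "diadem_config"))
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1)) {
      stop(sprintf("configuration error: '%s' must be a probability in [0, 1]", field),
           call. = FALSE)
    }
  }
  chk_pos <- function(x, field, strict = FALSE) {
    ok <- is.numeric(x) & (if (strict) all(x > 0) else all(x >= 0))
    if (!ok) stop(sprintf("configuration error: '%s' must be %s",
                          field, if (strict) "> 0" else ">= 0"), call. = FALSE)
  }
  co <- config$cohort
  if (co$n_patients < 0) stop("configuration error: 'cohort.n_patients' must be >= 0",
                              call. = FALSE)
  chk_prob(co$baseline_prevalence_major, "cohort.baseline_prevalence_major")
  chk_prob(co$baseline_prevalence_minor, "cohort.baseline_prevalence_minor")
  if (co$baseline_prevalence_major + co$baseline_prevalence_minor > 1) {
    stop("configuration error: baseline depression prevalences sum to > 1", call. = FALSE)
  }
  chk_prob(co$baseline_history_prob, "cohort.baseline_history_prob")
  chk_prob(co$baseline_identified_prob, "cohort.baseline_identified_prob")
  chk_prob(co$p_male, "cohort.p_male")
  chk_prob(co$p_smoker, "cohort.p_smoker")
  for (nm in names(co$risk_factors)) {
    rf <- co$risk_factors[[nm]]
    if (rf$sd < 0 || rf$min > rf$max) {
      stop(sprintf("configuration error: 'cohort.risk_factors.%s' has invalid distribution parameters", nm),
           call. = FALSE)
    }
  }
  if (co$age$sd < 0 || co$age$min > co$age$max || co$age$min < 18) {
    stop("configuration error: 'cohort.age' distribution invalid (adults only, min >= 18)",
         call. = FALSE)
  }

  nh <- config$natural_history
  chk_prob(nh$annual_incidence_minor, "natural_history.annual_incidence_minor")
  chk_prob(nh$annual_incidence_major, "natural_history.annual_incidence_major")
  chk_prob(nh$progression_minor_to_major$fraction,
           "natural_history.progression_minor_to_major.fraction")
  chk_pos(nh$progression_minor_to_major$horizon,
          "natural_history.progression_minor_to_major.horizon", strict = TRUE)
  chk_pos(nh$mean_time_recovery_minor, "natural_history.mean_time_recovery_minor", strict = TRUE)
  chk_pos(nh$mean_time_recovery_major, "natural_history.mean_time_recovery_major", strict = TRUE)
  chk_pos(nh$mean_time_relapse, "natural_history.mean_time_relapse", strict = TRUE)
  chk_prob(nh$relapse_severity_p_major, "natural_history.relapse_severity_p_major")
  chk_pos(nh$hr_complication_on_depression,
          "natural_history.hr_complication_on_depression", strict = TRUE)

  sc <- config$screening
  chk_pos(sc$gp_visits_per_year, "screening.gp_visits_per_year")
  for (f in c("p_screen_no_history", "p_screen_history", "p_attend_review_no_dep",
              "review_rr_minor", "review_rr_major", "p_review_includes_screen",
              "whooley_sens", "whooley_spec", "interview_sens", "interview_spec")) {
    chk_prob(sc[[f]], paste0("screening.", f))
  }

  tr <- config$treatment
  chk_prob(tr$p_response, "treatment.p_response")
  chk_prob(tr$p_dropout, "treatment.p_dropout")
  chk_pos(tr$duration, "treatment.duration", strict = TRUE)
  chk_pos(tr$cc_rr_response, "treatment.cc_rr_response", strict = TRUE)
  chk_pos(tr$cc_rr_dropout_reduction, "treatment.cc_rr_dropout_reduction", strict = TRUE)
  chk_prob(tr$dropout_cost_fraction, "treatment.dropout_cost_fraction")
  chk_prob(tr$p_high_intensity_major, "treatment.p_high_intensity_major")

  cp <- config$complications
  if (!setequal(c(cp$classes$micro, cp$classes$macro), cp$types) ||
      length(intersect(cp$classes$micro, cp$classes$macro)) > 0) {
    stop("configuration error: 'complications.classes' must partition 'complications.types'",
         call. = FALSE)
  }
  chk_pos(unlist(cp$hr_depression), "complications.hr_depression", strict = TRUE)
  chk_pos(cp$engine$base_hazard, "complications.engine.base_hazard")
  chk_pos(cp$severe_hypo_rate, "complications.severe_hypo_rate")

  chk_pos(unlist(config$costs[c("gp_appointment", "annual_review",
                                "opportunistic_screen", "interview",
                                "diabetes_no_complication", "severe_hypo")]),
          "costs")
  chk_pos(config$costs$event_year, "costs.event_year")
  chk_pos(config$costs$subsequent_year, "costs.subsequent_year")
  chk_prob(config$utilities$baseline, "utilities.baseline")
  chk_prob(config$utilities$responder_multiplier, "utilities.responder_multiplier")
  chk_pos(config$economics$discount_rate, "economics.discount_rate")
  chk_pos(config$reporting$cohort_size, "reporting.cohort_size", strict = TRUE)
  config
}

#' @export
print.diadem_config <- function(x, ...) {
  cat("<diadem_config>\n")
  cat(sprintf("  depression incidence (minor/major): %.3f / %.3f per yr\n",
              x$natural_history$annual_incidence_minor,
              x$natural_history$annual_incidence_major))
  cat(sprintf("  progression minor->major: %.0f%% at %g yr; recovery means %.3f / %.3f yr; relapse %.3f yr\n",
              100 * x$natural_history$progression_minor_to_major$fraction,
              x$natural_history$progression_minor_to_major$horizon,
              x$natural_history$mean_time_recovery_minor,
              x$natural_history$mean_time_recovery_major,
              x$natural_history$mean_time_relapse))
  cat(sprintf("  Whooley sens/spec: %.2f / %.2f; screen prob (no hist/hist): %.2f / %.2f\n",
              x$screening$whooley_sens, x$screening$whooley_spec,
              x$screening$p_screen_no_history, x$screening$p_screen_history))
  cat(sprintf("  linkage HRs micro (minor/major): %.2f / %.2f; macro: %.2f / %.2f; complication->depression %.2f\n",
              x$complications$hr_depression$micro[["minor"]],
              x$complications$hr_depression$micro[["major"]],
              x$complications$hr_depression$macro[["minor"]],
              x$complications$hr_depression$macro[["major"]],
              x$natural_history$hr_complication_on_depression))
  cat(sprintf("  discount rate: %.3f/yr; reporting cohort: %s\n",
              x$economics$discount_rate,
              format(x$reporting$cohort_size, big.mark = ",")))
  invisible(x)
}
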