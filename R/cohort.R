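#' Generate a synthetic baseline cohort
#'
#' Draws a seeded synthetic cohort of adults with type-2 diabetes with the
#' structure the simulation assumes: demographics, diabetes risk factors,
#' baseline depression state and depression history. It stands in for the
#' audit-based baseline data real analyses would use; distributions are
#' independent truncated normals (truncation by inverse-CDF, so no rejection
#' loop) plus Bernoulli flags, with all parameters taken from
#' `config$cohort`.
#'
#' Baseline depression state is drawn as a three-way categorical
#' (major / minor / none) from the configured prevalences; anyone currently
#' depressed has `depression_history = TRUE`, and the never-depressed carry a
#' configurable probability of a resolved prior history.
#'
#' @param config A `diadem_config` (or just its `cohort` block inside one).
#' @return A `data.frame` with one row per patient and columns
#'   `id`, `age`, `sex`, `diabetes_duration`, `hba1c`, `sbp`, `bmi`,
#'   `smoker`, `depression_state`, `depression_history`, `identified`,
#'   `alive`. Deterministic given `config$cohort$seed`.
#' @examples
#' cfg <- default_config()
#' cfg$cohort$n_patients <- 5
#' generate_cohort(cfg)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "diadem_config"))
  validate_config(config)
  co <- config$cohort
  n <- as.integer(co$n_patients)
  if (n == 0) return(empty_cohort())
  with_local_seed(co$seed, function() {
    age <- rtruncnorm(n, co$age$mean, co$age$sd, max(18, co$age$min), co$age$max)
    dur <- rtruncnorm(n, co$diabetes_duration$mean, co$diabetes_duration$sd,
                      co$diabetes_duration$min, co$diabetes_duration$max)
    sex <- ifelse(stats::runif(n) < co$p_male, "male", "female")
    rf <- lapply(co$risk_factors, function(p) {
      rtruncnorm(n, p$mean, p$sd, p$min, p$max)
    })
    smoker <- stats::runif(n) < co$p_smoker
    u <- stats::runif(n)
    state <- ifelse(u < co$baseline_prevalence_major, "major",
                    ifelse(u < co$baseline_prevalence_major +
                             co$baseline_prevalence_minor, "minor", "none"))
    history <- state != "none" | stats::runif(n) < co$baseline_history_prob
    identified <- state != "none" & stats::runif(n) < co$baseline_identified_prob
    out <- data.frame(
      id = seq_len(n),
      age = age,
      sex = sex,
      diabetes_duration = dur,
      stringsAsFactors = FALSE
    )
    for (nm in names(rf)) out[[nm]] <- rf[[nm]]
    out$smoker <- smoker
    out$depression_state <- state
    out$depression_history <- history
    out$identified <- identified
    out$alive <- TRUE
    class(out) <- c("diadem_cohort", "data.frame")
    out
  })
}

empty_cohort <- function() {
  out <- data.frame(
    id = integer(0), age = numeric(0), sex = character(0),
    diabetes_duration = numeric(0), hba1c = numeric(0), sbp = numeric(0),
    bmi = numeric(0), smoker = logical(0), depression_state = character(0),
    depression_history = logical(0), identified = logical(0),
    alive = logical(0), stringsAsFactors = FALSE
  )
  class(out) <- c("diadem_cohort", "data.frame")
  out
}

# Truncated-normal draw via inverse CDF; exact (no rejection), vectorised.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Write a cohort to CSV
#'
#' One row per patient, columns as documented in [generate_cohort()].
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' @param path CSV written by [write_cohort_csv()] (or any file with the same
#'   columns).
#' @return A cohort `data.frame`.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "diabetes_duration", "depression_state",
            "depression_history", "alive")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    stop(sprintf("cohort file is missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (!"identified" %in% names(out)) out$identified <- FALSE
  class(out) <- c("diadem_cohort", "data.frame")
  out
}
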