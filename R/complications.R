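#' Depression-exposure hazard multiplier
#'
#' The hazard of a diabetes-related complication is elevated in proportion to
#' the time spent with depression in the preceding year: the multiplier is
#' \deqn{1 + f_{minor}(HR_{minor} - 1) + f_{major}(HR_{major} - 1)}
#' so a full year in major depression reproduces the printed hazard ratio and
#' half a year of exposure halves the elevation. Time spent on treatment by
#' an ultimate responder is excluded from the exposure fractions before they
#' reach this function.
#'
#' @param f_minor,f_major Fractions of the preceding year spent in minor /
#'   major depression that count towards risk (`f_minor + f_major <= 1`).
#' @param hr_minor,hr_major Full-year hazard ratios for the complication
#'   class.
#' @return Multiplier on the hazard scale (vectorised).
#' @examples
#' effective_hazard_multiplier(0, 1, 1.31, 1.36)    # 1.36
#' effective_hazard_multiplier(0, 0.5, 1.31, 1.36)  # 1.18
#' @export
effective_hazard_multiplier <- function(f_minor, f_major, hr_minor, hr_major) {
  stopifnot(all(f_minor >= 0), all(f_major >= 0), all(f_minor + f_major <= 1 + 1e-9))
  1 + f_minor * (hr_minor - 1) + f_major * (hr_major - 1)
}

#' Load a complication risk-engine coefficient file
#'
#' The complication engine is pluggable. The package ships a documented
#' surrogate (constant or log-linear-in-age annual hazards per complication);
#' users holding an externally published coefficient set can supply it as a
#' CSV with columns `type`, `base_hazard` and optionally `age_slope`
#' (per-year log-hazard slope, centred at age 65), or the JSON equivalent.
#'
#' @param path CSV or JSON coefficient file.
#' @return An engine list usable as `config$complications$engine`.
#' @export
load_risk_engine <- function(path) {
  stopifnot(file.exists(path))
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!all(c("type", "base_hazard") %in% names(tab))) {
    stop("risk-engine file must have columns 'type' and 'base_hazard'", call. = FALSE)
  }
  if (any(tab$base_hazard < 0)) {
    stop("model-configuration error: negative base hazard in risk-engine file",
         call. = FALSE)
  }
  h <- stats::setNames(tab$base_hazard, tab$type)
  slope <- if ("age_slope" %in% names(tab)) {
    stats::setNames(tab$age_slope, tab$type)
  } else {
    stats::setNames(rep(0, nrow(tab)), tab$type)
  }
  list(kind = "table", base_hazard = h, age_slope = slope)
}

# Baseline annual hazard for one complication type at a given age.
engine_hazard <- function(type, age, engine) {
  h0 <- engine$base_hazard[[type]]
  slope <- if (length(engine$age_slope) > 1) engine$age_slope[[type]] else engine$age_slope
  h0 * exp(slope * (age - 65))
}

#' Annual complication event probabilities under depression exposure
#'
#' For each complication type the baseline annual probability from the risk
#' engine is converted to the hazard scale, multiplied by the class-specific
#' depression-exposure multiplier, and converted back
#' (\eqn{p = 1 - e^{-h}}).
#'
#' @param age Current age (vectorised).
#' @param f_minor,f_major Exposure fractions of the preceding year (see
#'   [effective_hazard_multiplier()]).
#' @param config A full `diadem_config`.
#' @return Matrix (`length(age)` rows) of annual event probabilities, one
#'   column per complication type.
#' @export
complication_probs <- function(age, f_minor, f_major, config) {
  cp <- config$complications
  types <- cp$types
  out <- matrix(0, nrow = length(age), ncol = length(types),
                dimnames = list(NULL, types))
  mult <- list(
    micro = effective_hazard_multiplier(f_minor, f_major,
                                        cp$hr_depression$micro[["minor"]],
                                        cp$hr_depression$micro[["major"]]),
    macro = effective_hazard_multiplier(f_minor, f_major,
                                        cp$hr_depression$macro[["minor"]],
                                        cp$hr_depression$macro[["major"]])
  )
  for (ty in types) {
    cls <- if (ty %in% cp$classes$micro) "micro" else "macro"
    h <- engine_hazard(ty, age, cp$engine)
    p <- -expm1(-h * mult[[cls]])
    if (any(p < 0 | p >= 1)) {
      stop(sprintf("model-configuration error: annual probability for '%s' outside [0, 1)", ty),
           call. = FALSE)
    }
    out[, ty] <- p
  }
  out
}

#' One annual complication cycle for a cohort
#'
#' Draws, independently per complication type, whether an event occurs in the
#' coming year given each patient's age, complication history (types flagged
#' single-occurrence cannot recur) and depression exposure over the preceding
#' year. Draws come from the current RNG state.
#'
#' @param patients `data.frame` with a numeric `age` column and one logical
#'   history column per complication type named `comp_<type>` (missing
#'   columns are treated as no history).
#' @param f_minor,f_major Exposure fractions (scalar or per patient).
#' @param config A full `diadem_config`.
#' @return Logical matrix of events, one column per complication type.
#' @export
annual_complication_update <- function(patients, f_minor = 0, f_major = 0, config) {
  n <- nrow(patients)
  p <- complication_probs(patients$age, f_minor, f_major, config)
  cp <- config$complications
  ev <- matrix(FALSE, n, length(cp$types), dimnames = list(NULL, cp$types))
  for (ty in cp$types) {
    had <- if (paste0("comp_", ty) %in% names(patients)) {
      patients[[paste0("comp_", ty)]]
    } else rep(FALSE, n)
    blocked <- had & !(ty %in% cp$recurrent)
    ev[, ty] <- !blocked & stats::runif(n) < p[, ty]
  }
  ev
}

#' Annual death probability from the mortality model
#'
#' Surrogate mortality model: a Gompertz-type baseline with log-hazard
#' increasing linearly in age plus additive log-hazard loadings for each
#' complication present in the history,
#' \eqn{q = 1 - \exp(-\exp(a + b \cdot age + \sum_k c_k))}.
#'
#' @param age Current age (vectorised).
#' @param comps Character vector of complication types present, or a logical
#'   matrix with one named column per type (rows matching `age`).
#' @param config A full `diadem_config`.
#' @return Annual death probability.
#' @examples
#' cfg <- default_config()
#' mortality_prob(65, character(0), cfg)
#' mortality_prob(65, "renal", cfg)   # strictly higher
#' @export
mortality_prob <- function(age, comps = character(0), config) {
  mo <- config$complications$mortality
  extra <- if (is.matrix(comps)) {
    as.vector(comps[, names(mo$loadings), drop = FALSE] %*% mo$loadings)
  } else {
    sum(mo$loadings[comps])
  }
  -expm1(-exp(mo$intercept + mo$age_slope * age + extra))
}
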