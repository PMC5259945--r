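#' Simulate one patient timeline under one policy
#'
#' Runs the linked discrete-event simulation for a single patient from
#' baseline to death: depression onset, minor-to-major progression,
#' spontaneous recovery and relapse; GP contacts and annual diabetes reviews
#' with opportunistic / review screening and structured-interview
#' case-finding; treatment courses with response, drop-out and
#' collaborative-care modifiers; annual complication and mortality cycles
#' through the pluggable risk engine with the bi-directional depression
#' linkage; and continuous cost/utility accounting with discounting.
#'
#' Randomness is consumed from per-process streams keyed by
#' `(master_seed, patient id, process)`, so policies share random numbers
#' for every process a policy change does not touch (common random numbers).
#' Waiting times are exponential and are re-drawn from the current state
#' whenever a hazard changes (valid by memorylessness). GP contacts that
#' cannot change the patient's state (no screen, or a screen that cannot
#' identify) are sampled retrospectively per constant-regime segment from
#' the thinned Poisson decomposition, which is distributionally exact and
#' keeps the event loop small.
#'
#' @param profile One cohort row (list or one-row `data.frame`) as produced
#'   by [generate_cohort()].
#' @param policy A policy id or [policy()] object.
#' @param config A `diadem_config`.
#' @param master_seed Master simulation seed; all per-process stream seeds
#'   derive from it and the patient id.
#' @param detail If `TRUE`, also return the entry-level ledger and event log
#'   (intended for audit of single patients, not cohort runs).
#' @return A list with elements `totals` (named numeric vector of life
#'   years, QALYs, discounted/undiscounted costs by category, event counts,
#'   societal days, death time), and when `detail = TRUE` also `ledger`
#'   (`data.frame` of timestamped cost entries) and `events` (`data.frame`
#'   event log).
#' @export
simulate_patient <- function(profile, policy = "current_practice",
                             config = default_config(), master_seed = 1,
                             detail = FALSE) {
  pol <- as_policy(policy)
  nh <- config$natural_history
  sc <- config$screening
  tr <- config$treatment
  cp <- config$complications
  costs <- config$costs
  ut <- config$utilities
  r <- config$economics$discount_rate
  lv <- log1p(r)
  soc <- config$economics$societal

  types <- cp$types
  K <- length(types)
  recur <- types %in% cp$recurrent
  is_micro <- types %in% cp$classes$micro
  hz0 <- unname(cp$engine$base_hazard[types])
  hz_slope <- if (length(cp$engine$age_slope) > 1) {
    unname(cp$engine$age_slope[types])
  } else rep(cp$engine$age_slope, K)
  mort_load <- unname(cp$mortality$loadings[types])
  c_event <- unname(costs$event_year[types])
  c_subseq <- unname(costs$subsequent_year[types])
  u_event <- unname(ut$event_year[types])
  u_chronic <- unname(ut$chronic[types])
  r_prog <- progression_rate(nh)
  r_rec_minor <- 1 / nh$mean_time_recovery_minor
  r_rec_major <- 1 / nh$mean_time_recovery_major
  sens_w <- sc$whooley_sens
  spec_w <- sc$whooley_spec
  sens_i <- sc$interview_sens

  id <- as.numeric(profile$id)
  streams <- patient_streams(master_seed, id)
  age0 <- as.numeric(profile$age)
  t_cap <- max(0, cp$max_age - age0)

  # --- mutable state ---------------------------------------------------
  t <- 0
  dep <- as.character(profile$depression_state)
  history <- isTRUE(profile$depression_history) || dep != "none"
  identified <- FALSE
  episode_open <- dep != "none"
  episode_identified <- FALSE
  on_treat <- FALSE
  responder <- FALSE
  treat_rate <- 0
  t_treat_end <- Inf
  comp_present <- rep(FALSE, K)
  established <- rep(FALSE, K)
  event_until <- rep(-Inf, K)
  comp_counts <- rep(0, K)
  subseq_rate <- 0
  next_dep_time <- Inf
  next_dep_event <- ""
  next_dep_sev <- ""
  t_ident <- Inf
  t_cycle <- 1
  t_death <- Inf
  pend_time <- numeric(0)   # pending complication events / anniversaries
  pend_kind <- integer(0)   # 1 = complication event, 2 = anniversary
  pend_type <- integer(0)
  seg_start <- 0
  e_minor <- 0
  e_major <- 0
  u_cur <- 0
  dep_dec_cur <- 0

  ly_u <- 0; ly_d <- 0; qaly_u <- 0; qaly_d <- 0; dqaly_loss_d <- 0
  informal_days <- 0; sick_days <- 0
  cost_u <- stats::setNames(numeric(length(LEDGER_CATEGORIES)), LEDGER_CATEGORIES)
  cost_d <- cost_u
  n_contacts <- 0; n_screens <- 0; n_interviews <- 0
  n_reviews <- 0; n_courses <- 0
  n_episodes <- 0; n_episodes_identified <- 0
  n_hypo <- 0

  led_t <- list(); led_d <- list(); led_c <- list(); led_a <- list(); led_i <- 0
  ev_t <- list(); ev_w <- list(); ev_i <- 0
  log_ev <- function(when, what) {
    if (detail) {
      ev_i <<- ev_i + 1
      ev_t[[ev_i]] <<- when
      ev_w[[ev_i]] <<- what
    }
  }
  led <- function(when, dur, cat, amount) {
    if (detail && amount != 0) {
      led_i <<- led_i + 1
      led_t[[led_i]] <<- when
      led_d[[led_i]] <<- dur
      led_c[[led_i]] <<- cat
      led_a[[led_i]] <<- amount
    }
  }

  bill_lump <- function(cat, amount, when) {
    cost_u[[cat]] <<- cost_u[[cat]] + amount
    cost_d[[cat]] <<- cost_d[[cat]] + amount * exp(-lv * when)
    led(when, 0, cat, amount)
  }
  bill_lumps <- function(cat, unit, times) {
    n <- length(times)
    if (n == 0) return(invisible())
    cost_u[[cat]] <<- cost_u[[cat]] + unit * n
    cost_d[[cat]] <<- cost_d[[cat]] + unit * sum(exp(-lv * times))
    if (detail) for (tt in times) led(tt, 0, cat, unit)
  }

  recompute_u <- function() {
    dd <- if (dep == "none") 0 else ut$depression[[dep]]
    if (on_treat && responder) dd <- dd * ut$responder_multiplier
    dec <- dd
    if (any(comp_present)) {
      iny <- comp_present & (event_until > t)
      chr <- comp_present & !iny
      dec <- dec + sum(u_event[iny]) + sum(u_chronic[chr])
    }
    u_cur <<- min(1, max(ut$floor, ut$baseline + dec))
    dep_dec_cur <<- dd
  }

  advance <- function(tn) {
    dt <- tn - t
    if (dt <= 0) return(invisible())
    D <- if (r == 0) dt else (exp(-lv * t) - exp(-lv * tn)) / lv
    ly_u <<- ly_u + dt; ly_d <<- ly_d + D
    qaly_u <<- qaly_u + u_cur * dt; qaly_d <<- qaly_d + u_cur * D
    dqaly_loss_d <<- dqaly_loss_d - dep_dec_cur * D
    cost_u[["ongoing_mgmt"]] <<- cost_u[["ongoing_mgmt"]] + costs$diabetes_no_complication * dt
    cost_d[["ongoing_mgmt"]] <<- cost_d[["ongoing_mgmt"]] + costs$diabetes_no_complication * D
    led(t, dt, "ongoing_mgmt", costs$diabetes_no_complication * dt)
    if (subseq_rate > 0) {
      cost_u[["complication_mgmt"]] <<- cost_u[["complication_mgmt"]] + subseq_rate * dt
      cost_d[["complication_mgmt"]] <<- cost_d[["complication_mgmt"]] + subseq_rate * D
      led(t, dt, "complication_mgmt", subseq_rate * dt)
    }
    if (treat_rate > 0) {
      cost_u[["treatment"]] <<- cost_u[["treatment"]] + treat_rate * dt
      cost_d[["treatment"]] <<- cost_d[["treatment"]] + treat_rate * D
      led(t, dt, "treatment", treat_rate * dt)
    }
    if (dep != "none" && !(on_treat && responder)) {
      if (dep == "minor") e_minor <<- e_minor + dt else e_major <<- e_major + dt
    }
    any_comp <- any(comp_present)
    informal_days <<- informal_days +
      (soc$informal_days[[dep]] + if (any_comp) soc$complication_informal_add else 0) * dt
    sick_days <<- sick_days +
      (soc$sick_days[[dep]] + if (any_comp) soc$complication_sick_add else 0) * dt
    t <<- tn
  }

  # retrospective billing of the contacts of the closing constant-regime
  # segment [seg_start, tn); all contacts in it are non-state-changing
  close_contacts <- function(tn) {
    dt <- tn - seg_start
    seg_end <- tn
    if (dt > 1e-12) {
      lam <- sc$gp_visits_per_year[[dep]]
      p_s <- if (identified) 0 else gp_screen_prob(pol, history, sc)
      if (lam > 0) {
        stream_eval(streams$contacts, function() {
          if (dep == "none" || p_s == 0) {
            n <- stats::rpois(1, lam * dt)
            if (n > 0) {
              tt <- seg_start + stats::runif(n) * dt
              n_contacts <<- n_contacts + n
              bill_lumps("gp", costs$gp_appointment, tt)
              if (p_s > 0) {
                scr <- stats::runif(n) < p_s
                if (any(scr)) {
                  n_screens <<- n_screens + sum(scr)
                  bill_lumps("screening", costs$opportunistic_screen, tt[scr])
                  pos <- scr & stats::runif(n) < (1 - spec_w)
                  if (any(pos)) {
                    n_interviews <<- n_interviews + sum(pos)
                    bill_lumps("interview", costs$interview, tt[pos])
                  }
                }
              }
            }
          } else {
            # unidentified depressed segment: identifying contacts occur at
            # rate lam * p_s * sens_w * sens_i and end segments elsewhere;
            # here we sample the complementary (non-identifying) thinning
            q_id <- p_s * sens_w * sens_i
            n <- stats::rpois(1, lam * (1 - q_id) * dt)
            if (n > 0) {
              tt <- seg_start + stats::runif(n) * dt
              n_contacts <<- n_contacts + n
              bill_lumps("gp", costs$gp_appointment, tt)
              u <- stats::runif(n)
              p_neg <- p_s * (1 - sens_w) / (1 - q_id)
              p_unconf <- p_s * sens_w * (1 - sens_i) / (1 - q_id)
              scr_neg <- u < p_neg
              scr_unconf <- u >= p_neg & u < p_neg + p_unconf
              ns <- sum(scr_neg) + sum(scr_unconf)
              if (ns > 0) {
                n_screens <<- n_screens + ns
                bill_lumps("screening", costs$opportunistic_screen,
                           tt[scr_neg | scr_unconf])
              }
              if (any(scr_unconf)) {
                n_interviews <<- n_interviews + sum(scr_unconf)
                bill_lumps("interview", costs$interview, tt[scr_unconf])
              }
            }
          }
          invisible()
        })
      }
    }
    seg_start <<- seg_end
  }

  draw_ident_time <- function(from_t) {
    if (dep == "none" || identified) { t_ident <<- Inf; return(invisible()) }
    lam <- sc$gp_visits_per_year[[dep]]
    p_s <- gp_screen_prob(pol, history, sc)
    rate <- lam * p_s * sens_w * sens_i
    u <- stream_eval(streams$contacts, function() stats::runif(1))
    t_ident <<- if (rate <= 0) Inf else from_t - log(u) / rate
  }

  schedule_onset <- function(from_t) {
    m <- if (any(comp_present)) nh$hr_complication_on_depression else 1
    u <- stream_eval(streams$onset, function() stats::runif(2))
    if (history) {
      rate <- m / nh$mean_time_relapse
      tt <- -log(u[1]) / rate
      sev <- if (u[2] < nh$relapse_severity_p_major) "major" else "minor"
    } else {
      r_mi <- annual_prob_to_rate(nh$annual_incidence_minor) * m
      r_ma <- annual_prob_to_rate(nh$annual_incidence_major) * m
      t_mi <- if (r_mi > 0) -log(u[1]) / r_mi else Inf
      t_ma <- if (r_ma > 0) -log(u[2]) / r_ma else Inf
      tt <- min(t_mi, t_ma)
      sev <- if (t_ma <= t_mi) "major" else "minor"
    }
    next_dep_time <<- from_t + tt
    next_dep_event <<- "onset"
    next_dep_sev <<- sev
  }

  schedule_episode_transition <- function(from_t) {
    u <- stream_eval(streams$episode, function() stats::runif(2))
    if (dep == "minor") {
      t_p <- if (r_prog > 0) -log(u[1]) / r_prog else Inf
      t_r <- if (is.finite(r_rec_minor) && r_rec_minor > 0) -log(u[2]) / r_rec_minor else Inf
      if (t_p <= t_r) {
        next_dep_time <<- from_t + t_p
        next_dep_event <<- "progression"
      } else {
        next_dep_time <<- from_t + t_r
        next_dep_event <<- "recovery"
      }
    } else {
      t_r <- if (is.finite(r_rec_major) && r_rec_major > 0) -log(u[1]) / r_rec_major else Inf
      next_dep_time <<- from_t + t_r
      next_dep_event <<- "recovery"
    }
  }

  start_treatment <- function(ti) {
    if (!identified) stop("internal error: treating an unidentified episode")
    n_courses <<- n_courses + 1
    p_resp <- tr$p_response
    p_drop <- tr$p_dropout
    if (pol$cc_enabled) {
      adj <- apply_collaborative_care(p_resp, p_drop, tr)
      p_resp <- adj$p_response
      p_drop <- adj$p_dropout
    }
    u <- stream_eval(streams$treatment, function() stats::runif(3))
    dropped <- u[1] < p_drop
    responder <<- !dropped && u[2] < p_resp
    high <- dep == "major" && u[3] < tr$p_high_intensity_major
    full_cost <- course_full_cost(dep, high, tr) +
      if (pol$cc_enabled) tr$cc_extra_cost else 0
    dur <- if (dropped) tr$duration * tr$dropout_cost_fraction else tr$duration
    on_treat <<- TRUE
    treat_rate <<- full_cost / tr$duration
    t_treat_end <<- ti + dur
    log_ev(ti, paste0("treatment_start_", dep,
                      if (dropped) "_dropout" else if (responder) "_responder" else "_nonresponder"))
  }

  identify_depression <- function(ti, via_review) {
    if (!via_review) {
      # the identifying GP contact itself
      n_contacts <<- n_contacts + 1
      n_screens <<- n_screens + 1
      n_interviews <<- n_interviews + 1
      bill_lump("gp", costs$gp_appointment, ti)
      bill_lump("screening", costs$opportunistic_screen, ti)
      bill_lump("interview", costs$interview, ti)
    }
    identified <<- TRUE
    episode_identified <<- TRUE
    t_ident <<- Inf
    log_ev(ti, paste0("identified_", if (via_review) "review" else "gp"))
    start_treatment(ti)
    recompute_u()
  }

  end_course <- function() {
    on_treat <<- FALSE
    responder <<- FALSE
    treat_rate <<- 0
    t_treat_end <<- Inf
  }

  close_episode <- function(te, cause) {
    if (episode_identified) n_episodes_identified <<- n_episodes_identified + 1
    episode_open <<- FALSE
    episode_identified <<- FALSE
    dep <<- "none"
    identified <<- FALSE
    t_ident <<- Inf
    log_ev(te, paste0("episode_end_", cause))
  }

  start_episode <- function(ts, sev) {
    dep <<- sev
    episode_open <<- TRUE
    episode_identified <<- FALSE
    n_episodes <<- n_episodes + 1
    history <<- TRUE
    log_ev(ts, paste0("onset_", sev))
    schedule_episode_transition(ts)
    draw_ident_time(ts)
    recompute_u()
  }

  push_pending <- function(when, kind, type_idx) {
    pend_time <<- c(pend_time, when)
    pend_kind <<- c(pend_kind, kind)
    pend_type <<- c(pend_type, type_idx)
  }
  pop_pending <- function(i) {
    pend_time <<- pend_time[-i]
    pend_kind <<- pend_kind[-i]
    pend_type <<- pend_type[-i]
  }

  do_cycle <- function(k) {
    # exposure fractions over the preceding year (k-1, k]
    f_mi <- min(1, e_minor)
    f_ma <- min(1 - f_mi, e_major)
    e_minor <<- 0; e_major <<- 0
    age_now <- age0 + k
    us <- stream_eval(streams$diabetes, function() stats::runif(2 * K + 2))
    m_micro <- effective_hazard_multiplier(f_mi, f_ma,
                                           cp$hr_depression$micro[["minor"]],
                                           cp$hr_depression$micro[["major"]])
    m_macro <- effective_hazard_multiplier(f_mi, f_ma,
                                           cp$hr_depression$macro[["minor"]],
                                           cp$hr_depression$macro[["major"]])
    h <- hz0 * exp(hz_slope * (age_now - 65)) * ifelse(is_micro, m_micro, m_macro)
    p_eff <- -expm1(-h)
    blocked <- comp_present & !recur
    hit <- !blocked & us[seq_len(K)] < p_eff
    if (any(hit)) {
      for (j in which(hit)) push_pending(k + us[K + j], 1L, j)
    }
    q <- -expm1(-exp(cp$mortality$intercept + cp$mortality$age_slope * age_now +
                       sum(mort_load[comp_present])))
    t_death <<- if (us[2 * K + 1] < q) k + us[2 * K + 2] else Inf

    if (cp$severe_hypo_rate > 0) {
      nh_ev <- stream_eval(streams$misc, function() stats::rpois(1, cp$severe_hypo_rate))
      if (nh_ev > 0) {
        n_hypo <<- n_hypo + nh_ev
        tt <- stream_eval(streams$misc, function() k + stats::runif(nh_ev))
        bill_lumps("complication_mgmt", costs$severe_hypo, tt)
        qd <- ut$severe_hypo * exp(-lv * tt)
        qaly_d <<- qaly_d + sum(qd)
        qaly_u <<- qaly_u + nh_ev * ut$severe_hypo
      }
    }

    # annual diabetes review
    ur <- stream_eval(streams$review, function() stats::runif(4))
    if (ur[1] < attend_review_prob(dep, sc)) {
      n_reviews <<- n_reviews + 1
      bill_lump("review", costs$annual_review, k)
      if (!identified) {
        p_inc <- if (pol$universal_screen) 1 else sc$p_review_includes_screen
        if (ur[2] < p_inc) {
          n_screens <<- n_screens + 1
          bill_lump("screening", costs$opportunistic_screen, k)
          if (dep == "none") {
            if (ur[3] < 1 - spec_w) {
              n_interviews <<- n_interviews + 1
              bill_lump("interview", costs$interview, k)
            }
          } else if (ur[3] < sens_w) {
            n_interviews <<- n_interviews + 1
            bill_lump("interview", costs$interview, k)
            if (ur[4] < sens_i) {
              close_contacts(k)
              identify_depression(k, via_review = TRUE)
            }
          }
        }
      }
    }
    t_cycle <<- k + 1
  }

  handle_complication <- function(tc, j) {
    comp_counts[j] <<- comp_counts[j] + 1
    first_ever <- !any(comp_present)
    comp_present[j] <<- TRUE
    event_until[j] <<- tc + 1
    push_pending(tc + 1, 2L, j)
    bill_lump("complication_mgmt", c_event[j], tc)
    log_ev(tc, paste0("complication_", types[j]))
    if (first_ever && dep == "none" && nh$hr_complication_on_depression != 1) {
      schedule_onset(tc)  # onset hazard steps up; memoryless re-draw
    }
    recompute_u()
  }

  handle_anniversary <- function(ta, j) {
    if (!established[j]) {
      established[j] <<- TRUE
      subseq_rate <<- subseq_rate + c_subseq[j]
    }
    recompute_u()  # event-year decrement may have lapsed
  }

  # --- initialisation --------------------------------------------------
  recompute_u()
  if (dep == "none") {
    schedule_onset(0)
  } else {
    n_episodes <- n_episodes + 1
    log_ev(0, paste0("baseline_episode_", dep))
    schedule_episode_transition(0)
    if (isTRUE(profile$identified)) {
      identify_depression(0, via_review = TRUE)  # known at baseline: no new screen billed
    } else {
      draw_ident_time(0)
    }
  }

  # --- event loop ------------------------------------------------------
  repeat {
    t_pend <- if (length(pend_time)) min(pend_time) else Inf
    tn <- min(next_dep_time, t_ident, t_treat_end, t_cycle, t_death, t_pend, t_cap)
    if (tn >= t_death || tn >= t_cap) {
      td <- min(t_death, t_cap)
      advance(td)
      close_contacts(td)
      if (episode_open) close_episode(td, "death")
      log_ev(td, "death")
      break
    }
    if (tn == t_pend) {
      i <- which.min(pend_time)
      kind <- pend_kind[i]; j <- pend_type[i]; when <- pend_time[i]
      pop_pending(i)
      advance(when)
      if (kind == 1L) handle_complication(when, j) else handle_anniversary(when, j)
    } else if (tn == t_cycle) {
      advance(tn)
      do_cycle(tn)
    } else if (tn == next_dep_time) {
      advance(tn)
      ev <- next_dep_event
      next_dep_time <- Inf
      if (ev == "onset") {
        close_contacts(tn)
        start_episode(tn, next_dep_sev)
      } else if (ev == "progression") {
        close_contacts(tn)
        dep <- "major"
        log_ev(tn, "progression")
        schedule_episode_transition(tn)
        if (!identified) draw_ident_time(tn)
        recompute_u()
      } else { # spontaneous recovery
        close_contacts(tn)
        if (on_treat) end_course()
        close_episode(tn, "recovery")
        schedule_onset(tn)
        recompute_u()
      }
    } else if (tn == t_ident) {
      advance(tn)
      close_contacts(tn)
      identify_depression(tn, via_review = FALSE)
    } else { # treatment course end
      advance(tn)
      was_responder <- responder
      end_course()
      log_ev(tn, "treatment_end")
      if (was_responder && episode_open) {
        close_contacts(tn)
        close_episode(tn, "remission")
        schedule_onset(tn)
      }
      recompute_u()
    }
  }

  totals <- c(
    life_years = ly_u, life_years_disc = ly_d,
    qalys = qaly_u, qalys_disc = qaly_d,
    qaly_loss_depression_disc = dqaly_loss_d,
    informal_care_days = informal_days, sick_days = sick_days,
    stats::setNames(cost_u, paste0("cost_", names(cost_u))),
    cost_total = sum(cost_u),
    stats::setNames(cost_d, paste0("cost_disc_", names(cost_d))),
    cost_disc_total = sum(cost_d),
    contacts = n_contacts, screens = n_screens, interviews = n_interviews,
    reviews_attended = n_reviews, courses = n_courses,
    episodes_total = n_episodes, episodes_identified = n_episodes_identified,
    episodes_unidentified = n_episodes - n_episodes_identified,
    severe_hypo_events = n_hypo,
    stats::setNames(comp_counts, paste0("comp_", types)),
    death_time = t
  )
  out <- list(totals = totals)
  if (detail) {
    out$ledger <- data.frame(
      time = unlist(led_t), duration = unlist(led_d),
      category = unlist(led_c), amount = unlist(led_a),
      stringsAsFactors = FALSE
    )
    if (is.null(out$ledger$time)) {
      out$ledger <- data.frame(time = numeric(0), duration = numeric(0),
                               category = character(0), amount = numeric(0))
    }
    out$events <- data.frame(time = unlist(ev_t), event = unlist(ev_w),
                             stringsAsFactors = FALSE)
  }
  out
}
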