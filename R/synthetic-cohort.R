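# Seeded synthetic-cohort simulator.
#
# Generates cohorts with the statistical structure the classifier assumes:
# CD4 declining untreated and recovering on ART, viral load suppressing after
# ART start with occasional blips and failures, and attendance scheduled by
# applying the scheduling rule table to the patient's recorded state, with a
# stochastic delay (disengagement) process layered on top. Because the
# schedule comes from the same rule engine the classifier uses, the true
# in-care / out-of-care label of every month is known by construction, which
# makes the whole pipeline testable end to end without real data.
#
# Trajectories are simple parametric forms (linear CD4 drift, step-wise viral
# load states); they are meant to drive every branch of the rule table, not
# to be clinically realistic.

#' Simulation parameters
#'
#' @param n_patients Number of patients.
#' @param seed Mandatory RNG seed; a run is fully determined by it.
#' @param entry_start,entry_end Calendar window for study entry (diagnosis).
#' @param horizon_months Administrative follow-up horizon per patient
#'   (months); must be at least the shortest rule interval.
#' @param cd4_at_diagnosis_mean,cd4_at_diagnosis_sd CD4 at diagnosis
#'   (cells/uL), truncated below at 30.
#' @param cd4_decline_rate,cd4_decline_sd Untreated CD4 decline
#'   (cells/uL/year), with patient-level noise.
#' @param cd4_recovery_rate On-ART CD4 recovery (cells/uL/year), capped at
#'   1200 cells/uL.
#' @param cd4_noise_sd Measurement noise added to recorded CD4 (cells/uL).
#' @param art_cd4_threshold CD4 (cells/uL) at or below which ART is offered.
#' @param art_defer_prob Probability a due ART start is deferred to the next
#'   visit (keeps untreated low-CD4 rules reachable).
#' @param vl_setpoint_log10_mean,vl_setpoint_log10_sd Untreated viral-load
#'   set point (log10 copies/mL).
#' @param suppression_months Months on ART until the viral load is recorded
#'   below detection.
#' @param blip_prob Per suppressed visit (after at least two suppressed
#'   visits), probability of a transient 51-200 copies/mL blip.
#' @param failure_prob Per suppressed visit, probability of virological
#'   failure (viral load back above 200), answered with a regimen switch at
#'   the following visit.
#' @param hb_only_prob Probability an attended visit records only a
#'   haemoglobin (no CD4/viral load), exercising carry-forward.
#' @param aids_prob Probability of an AIDS diagnosis at study entry.
#' @param p_delay Per scheduled visit, probability the patient attends late.
#' @param delay_dist `"geometric"` (extra months `1 + Geom`) or `"fixed"`.
#' @param delay_mean_extra Mean extra months when delayed (geometric case;
#'   must be >= 1).
#' @param delay_extra Extra months when delayed (fixed case).
#' @return A list of class `eic_sim_params`.
#' @export
sim_params <- function(n_patients = 100,
                       seed,
                       entry_start = as.Date("2000-01-01"),
                       entry_end = as.Date("2010-12-31"),
                       horizon_months = 60,
                       cd4_at_diagnosis_mean = 430,
                       cd4_at_diagnosis_sd = 150,
                       cd4_decline_rate = 60,
                       cd4_decline_sd = 25,
                       cd4_recovery_rate = 80,
                       cd4_noise_sd = 30,
                       art_cd4_threshold = 350,
                       art_defer_prob = 0.3,
                       vl_setpoint_log10_mean = 4.5,
                       vl_setpoint_log10_sd = 0.7,
                       suppression_months = 3,
                       blip_prob = 0.05,
                       failure_prob = 0.02,
                       hb_only_prob = 0.1,
                       aids_prob = 0.05,
                       p_delay = 0.15,
                       delay_dist = c("geometric", "fixed"),
                       delay_mean_extra = 2,
                       delay_extra = 2) {
  if (missing(seed) || !is.finite(seed)) {
    stop("a seed is required for simulation", call. = FALSE)
  }
  delay_dist <- match.arg(delay_dist)
  probs <- c(art_defer_prob, blip_prob, failure_prob, hb_only_prob,
             aids_prob, p_delay)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (horizon_months < 2) {
    stop("horizon_months must be at least 2 (the shortest rule interval)",
         call. = FALSE)
  }
  if (delay_dist == "geometric" && delay_mean_extra < 1) {
    stop("delay_mean_extra must be >= 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "eic_sim_params")
}

#' Simulate a synthetic cohort with known engagement ground truth
#'
#' Each patient is generated by: sampling entry date, demographics and
#' trajectory parameters; then walking visits forward from the diagnosis
#' episode, at each visit recording laboratory values (with measurement
#' noise), deriving the episode's clinical state exactly as the episode
#' builder would, applying the scheduling rule table to get the expected
#' interval `N`, and attending `N + extra` months later, where `extra` is 0
#' or a draw from the delay distribution. Every completed inter-episode
#' interval yields known true labels: the first `N` months in care, any
#' remainder out of care. Follow-up is censored at the last attended visit.
#'
#' @param params An [sim_params()] object.
#' @param dir Optional directory: if given, the four loader-compatible cohort
#'   CSVs plus `ground_truth.csv` and `schedule.csv` are written there.
#' @param config Rule configuration used for scheduling (and expected to be
#'   used for classification). Default [eic_rule_config()].
#' @return A list of class `eic_sim`: `cohort` (named list of `eic_patient`),
#'   `ground_truth` (tibble patient_id / month_index / label), `schedule`
#'   (tibble of per-interval expected and actual gaps) and `params`.
#' @export
simulate_cohort <- function(params, dir = NULL, config = eic_rule_config()) {
  stopifnot(inherits(params, "eic_sim_params"))
  set.seed(params$seed)
  cohort <- list()
  gt <- list()
  sched <- list()

  entry_days <- as.numeric(params$entry_end - params$entry_start)
  for (i in seq_len(params$n_patients)) {
    pid <- sprintf("sim-%04d", i)
    entry <- params$entry_start + floor(runif(1, 0, entry_days + 1))
    gender <- sample(c("male", "female", "other_unknown"), 1,
                     prob = c(0.7, 0.28, 0.02))
    ethnicity <- sample(ETHNICITY_LEVELS, 1, prob = c(0.53, 0.29, 0.09, 0.09))
    acquisition <- sample(ACQUISITION_LEVELS, 1,
                          prob = c(0.5, 0.39, 0.03, 0.08))
    clinic <- sample(sprintf("clinic-%s", LETTERS[1:5]), 1)
    birth <- entry - round(pmax(18, rnorm(1, 36, 8)) * 365.25)
    has_aids <- runif(1) < params$aids_prob

    cd4_true <- max(30, rnorm(1, params$cd4_at_diagnosis_mean,
                              params$cd4_at_diagnosis_sd))
    decline <- max(0, rnorm(1, params$cd4_decline_rate, params$cd4_decline_sd))
    setpoint <- 10^rnorm(1, params$vl_setpoint_log10_mean,
                         params$vl_setpoint_log10_sd)

    on_art <- FALSE
    art_start_month <- NA_integer_
    pending_switch <- FALSE
    n_suppressed <- 0L
    prev_cd4 <- NA_real_          # last recorded CD4 (any earlier month)
    prev_vl <- NA_real_; prev_vl_below <- FALSE
    last_vl <- NA_real_; last_vl_below <- FALSE   # carried-forward state

    labs <- list(); therapy <- list()
    m <- 0L
    ep_months <- integer(0)
    p_gt <- integer(0)            # out-of-care months
    months_on_art_at <- function(mm) mm - art_start_month

    repeat {
      date <- entry + ceiling(m * MONTH_DAYS)
      ep_months <- c(ep_months, m)
      hb_only <- m > 0L && runif(1) < params$hb_only_prob

      started_art <- FALSE; started_switch <- FALSE
      cd4_rec <- NA_real_; vl_rec <- NA_real_; vl_below <- FALSE

      if (hb_only) {
        labs[[length(labs) + 1L]] <- data.frame(
          date = date, kind = "haemoglobin",
          value = round(rnorm(1, 13, 1), 1), below_detection = FALSE)
      } else {
        cd4_rec <- max(10, round(cd4_true + rnorm(1, 0, params$cd4_noise_sd)))
        # viral load state at this visit
        if (!on_art) {
          vl_rec <- round(setpoint * exp(rnorm(1, 0, 0.2)))
        } else {
          since <- months_on_art_at(m)
          if (pending_switch) {
            # failed at the previous visit; switch now, still unsuppressed
            therapy[[length(therapy) + 1L]] <- data.frame(date = date,
                                                          kind = "switch")
            started_switch <- TRUE
            pending_switch <- FALSE
            art_start_month <- m   # restart the suppression clock
            n_suppressed <- 0L
            vl_rec <- round(setpoint * exp(rnorm(1, 0, 0.2)))
          } else if (since < params$suppression_months) {
            # declining towards suppression; low-set-point patients pass
            # through 51-200 copies/mL (non-blip low-level viraemia)
            vl_rec <- max(60, round(setpoint *
                                      10^(-2 * since /
                                            params$suppression_months)))
          } else {
            u <- runif(1)
            if (n_suppressed >= 2L && u < params$blip_prob) {
              vl_rec <- round(runif(1, 60, 180))          # blip
            } else if (u < params$blip_prob + params$failure_prob) {
              vl_rec <- round(setpoint * exp(rnorm(1, 0, 0.2)))  # failure
              pending_switch <- TRUE
              n_suppressed <- 0L
            } else {
              vl_rec <- 50; vl_below <- TRUE              # suppressed
              n_suppressed <- n_suppressed + 1L
            }
          }
        }
        vl_rec <- max(vl_rec, 1)
        labs[[length(labs) + 1L]] <- data.frame(
          date = rep(date, 2), kind = c("cd4", "viral_load"),
          value = c(cd4_rec, vl_rec), below_detection = c(FALSE, vl_below))
        # treatment decision at this visit, based on the recorded CD4
        if (!on_art && cd4_rec <= params$art_cd4_threshold &&
            runif(1) >= params$art_defer_prob) {
          therapy[[length(therapy) + 1L]] <- data.frame(date = date,
                                                        kind = "start")
          on_art <- TRUE
          art_start_month <- m
          started_art <- TRUE
        }
      }

      # episode state exactly as the episode builder derives it
      measured <- !hb_only
      state <- list(
        month_index = m,
        lowest_cd4 = if (measured) cd4_rec else prev_cd4,
        cd4_carried = !measured,
        cd4_drop = if (measured && !is.na(prev_cd4)) prev_cd4 - cd4_rec else
          NA_real_,
        highest_vl = if (measured) vl_rec else last_vl,
        vl_carried = !measured,
        vl_below_detection = if (measured) vl_below else last_vl_below,
        vl_is_blip = measured && !is.na(prev_vl) && {
          cur <- vl_effective(vl_rec, vl_below)
          cur > 50 && cur <= 200 &&
            vl_effective(prev_vl, prev_vl_below) < 50
        },
        on_art = on_art,
        started_art = started_art,
        started_combination = started_switch,
        within_month_of_diagnosis = m == 0L,
        aids_event = has_aids && m == 0L)
      N <- expected_interval(state, config)$months

      if (measured) {
        prev_cd4 <- cd4_rec
        prev_vl <- vl_rec; prev_vl_below <- vl_below
        last_vl <- vl_rec; last_vl_below <- vl_below
      }

      extra <- 0L
      if (runif(1) < params$p_delay) {
        extra <- if (params$delay_dist == "fixed") params$delay_extra else
          1L + rgeom(1, 1 / params$delay_mean_extra)
      }
      nxt <- m + N + extra
      if (nxt > params$horizon_months) break
      sched[[length(sched) + 1L]] <- data.frame(
        patient_id = pid, episode_month = m, expected_months = N,
        actual_gap = N + extra)
      if (extra > 0L) p_gt <- c(p_gt, (m + N + 1L):nxt)

      # advance trajectories over the gap
      dt <- (N + extra) / 12
      cd4_true <- if (on_art) min(1200, cd4_true +
                                    params$cd4_recovery_rate * dt) else
        max(10, cd4_true - decline * dt)
      m <- nxt
    }

    last_month <- ep_months[length(ep_months)]
    if (last_month > 0L) {
      gt[[pid]] <- tibble::tibble(
        patient_id = pid,
        month_index = seq_len(last_month),
        label = ifelse(seq_len(last_month) %in% p_gt, "out_of_care",
                       "in_care"))
    }

    cohort[[pid]] <- patient_record(
      patient_id = pid, gender = gender, birth_date = birth,
      ethnicity = ethnicity, acquisition = acquisition, clinic_id = clinic,
      hiv_diagnosis_date = entry,
      aids_diagnosis_date = if (has_aids) entry else NA,
      admin_end_date = entry + ceiling(params$horizon_months * MONTH_DAYS),
      labs = do.call(rbind, labs),
      therapy = if (length(therapy)) do.call(rbind, therapy) else NULL)
  }

  out <- structure(
    list(cohort = cohort,
         ground_truth = if (length(gt)) dplyr::bind_rows(gt) else
           tibble::tibble(patient_id = character(0),
                          month_index = integer(0), label = character(0)),
         schedule = if (length(sched)) tibble::as_tibble(do.call(rbind, sched))
           else tibble::tibble(patient_id = character(0),
                               episode_month = integer(0),
                               expected_months = numeric(0),
                               actual_gap = numeric(0)),
         params = params),
    class = "eic_sim")

  if (!is.null(dir)) {
    write_cohort(out$cohort, dir)
    utils::write.csv(out$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(out$schedule, file.path(dir, "schedule.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  out
}

#' @export
print.eic_sim <- function(x, ...) {
  cat(sprintf("<eic_sim> %d patient(s), %d ground-truth month(s), seed %s\n",
              length(x$cohort), nrow(x$ground_truth),
              format(x$params$seed)))
  invisible(x)
}

#' Check classifier output against simulation ground truth
#'
#' Classifies a simulated cohort and compares every month's label with the
#' ground truth implied by the simulator's schedule and delays. With full
#' laboratory observation the two must agree exactly (the generator schedules
#' with the same rule engine the classifier applies); disagreements, if any,
#' are reported with their episode context for inspection.
#'
#' @param cohort Named list of `eic_patient` records (e.g. `$cohort` of
#'   [simulate_cohort()] output, or a cohort re-loaded from its files).
#' @param ground_truth Ground-truth label tibble
#'   (patient_id/month_index/label).
#' @param config Rule configuration; must match the one used to schedule.
#' @return A list of class `eic_recovery`: `agreement` (proportion of
#'   ground-truth months with matching labels; `NaN` on an empty cohort),
#'   `n_months`, `disagreements` (tibble with both labels and the anchoring
#'   episode month) and `n_unclassifiable` (patients with fewer than two
#'   attendance dates, which the loader would exclude).
#' @export
classification_recovery <- function(cohort, ground_truth,
                                    config = eic_rule_config()) {
  usable <- Filter(function(p) length(attendance_dates(p)) >= 2L, cohort)
  n_unclassifiable <- length(cohort) - length(usable)
  if (length(usable) == 0L || nrow(ground_truth) == 0L) {
    return(structure(list(agreement = NaN, n_months = 0L,
                          disagreements = tibble::tibble(),
                          n_unclassifiable = n_unclassifiable),
                     class = "eic_recovery"))
  }
  cls <- classify_cohort(usable, config)
  merged <- dplyr::inner_join(
    ground_truth,
    dplyr::rename(cls, classifier_label = "label"),
    by = c("patient_id", "month_index"))
  agree <- merged$label == merged$classifier_label
  structure(
    list(agreement = mean(agree),
         n_months = nrow(merged),
         disagreements = merged[!agree, , drop = FALSE],
         n_unclassifiable = n_unclassifiable),
    class = "eic_recovery")
}

#' @export
print.eic_recovery <- function(x, ...) {
  cat(sprintf("<eic_recovery> %.2f%% agreement over %d month(s); %d disagreement(s)\n",
              100 * x$agreement, x$n_months, nrow(x$disagreements)))
  invisible(x)
}
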