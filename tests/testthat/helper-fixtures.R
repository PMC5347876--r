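# Shared fixture builders. Everything is generated in code; no binary data.

# Minimal patient with labs/therapy given as day offsets from entry.
make_patient <- function(id = "p1",
                         entry = as.Date("2005-03-01"),
                         cd4 = NULL,      # data.frame(day, value)
                         vl = NULL,       # data.frame(day, value, below)
                         hb_days = NULL,
                         art_start_day = NA,
                         art_switch_days = NULL,
                         aids_day = NA,
                         admin_end_day = NA,
                         diagnosis_day = 0,
                         ...) {
  labs <- NULL
  add <- function(labs, day, kind, value, below = FALSE) {
    rbind(labs, data.frame(date = entry + day, kind = kind, value = value,
                           below_detection = below))
  }
  if (!is.null(cd4)) {
    for (i in seq_len(nrow(cd4))) {
      labs <- add(labs, cd4$day[i], "cd4", cd4$value[i])
    }
  }
  if (!is.null(vl)) {
    if (is.null(vl$below)) vl$below <- FALSE
    for (i in seq_len(nrow(vl))) {
      labs <- add(labs, vl$day[i], "viral_load", vl$value[i], vl$below[i])
    }
  }
  for (d in hb_days %||% c()) labs <- add(labs, d, "haemoglobin", 13)
  therapy <- NULL
  if (!is.na(art_start_day)) {
    therapy <- data.frame(date = entry + art_start_day, kind = "start")
  }
  for (d in art_switch_days %||% c()) {
    therapy <- rbind(therapy, data.frame(date = entry + d, kind = "switch"))
  }
  patient_record(
    patient_id = id, hiv_diagnosis_date = entry + diagnosis_day,
    aids_diagnosis_date = if (is.na(aids_day)) NA else entry + aids_day,
    admin_end_date = if (is.na(admin_end_day)) NA else entry + admin_end_day,
    labs = labs, therapy = therapy, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Correlated binary months with a patient-level covariate and an exact
# marginal odds ratio: the patient effect is Beta-distributed with mean equal
# to the marginal probability, so the logistic marginal model holds exactly
# with exchangeable within-patient correlation 1/(1+phi).
simulate_pm_rows <- function(n_patients, n_months, beta0, beta1, phi = 6) {
  x <- rbinom(n_patients, 1, 0.5)
  mu <- plogis(beta0 + beta1 * x)
  p_i <- rbeta(n_patients, phi * mu, phi * (1 - mu))
  tibble::tibble(
    patient_id = rep(sprintf("p%03d", seq_len(n_patients)), each = n_months),
    in_care = rbinom(n_patients * n_months, 1, rep(p_i, each = n_months)),
    on_art = factor(rep(ifelse(x == 1, "yes", "no"), each = n_months),
                    c("no", "yes")))
}

# Random episode state for property tests over the rule engine. Not every
# combination is clinically coherent; the engine must still behave.
random_episode_state <- function() {
  cd4 <- if (runif(1) < 0.85) round(runif(1, 0, 1400)) else NA_real_
  has_drop <- !is.na(cd4) && runif(1) < 0.6
  vl <- if (runif(1) < 0.85) round(10^runif(1, 0, 6.5)) else NA_real_
  below <- !is.na(vl) && vl <= 50 && runif(1) < 0.5
  list(
    lowest_cd4 = cd4,
    cd4_drop = if (has_drop) round(runif(1, -300, 300)) else NA_real_,
    highest_vl = vl,
    vl_below_detection = below,
    vl_is_blip = !is.na(vl) && vl > 50 && vl <= 200 && runif(1) < 0.5,
    on_art = runif(1) < 0.6,
    started_art = runif(1) < 0.1,
    started_combination = runif(1) < 0.1,
    within_month_of_diagnosis = runif(1) < 0.1,
    aids_event = runif(1) < 0.05)
}

# Random episode table (as classify_months consumes it) plus a follow-up end.
random_episode_sequence <- function(max_episodes = 8) {
  n <- sample(2:max_episodes, 1)
  gaps <- sample(1:8, n - 1, replace = TRUE)
  months <- c(0L, cumsum(gaps))
  states <- lapply(seq_len(n), function(i) random_episode_state())
  ep <- as.data.frame(lapply(stats::setNames(nm = names(states[[1]])),
                             function(f) {
    unlist(lapply(states, `[[`, f), use.names = FALSE)
  }))
  ep$month_index <- months
  ep$episode_date <- as.Date("2004-01-01") + ceiling(months * 30.4)
  end <- months[n] + sample(0:6, 1) * (runif(1) < 0.3)
  list(episodes = ep, end = end)
}
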