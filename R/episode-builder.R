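# Grouping of attendance markers into care episodes.
#
# Repeat laboratory tests often cluster around a single "index" visit; to
# avoid counting each cluster member as an independent visit, all markers
# falling in the same 30.4-day month (anchored at study entry) collapse into
# one care episode. Each episode carries the derived clinical state the rule
# engine needs: the lowest CD4 that month and its change from the previous
# measured value, the highest viral load and whether it looks like a blip,
# treatment status and event flags.

# Internal: comparison-time value of a viral load. Values reported as "<X"
# (below the detection bound) are stored as X with a flag; for threshold
# comparisons they behave as "just below X", so "<50" satisfies both
# "<= 50 copies/mL" and "< 50 copies/mL" but never "> 50 copies/mL".
vl_effective <- function(value, below_detection) {
  value - 0.5 * as.numeric(below_detection)
}

#' Build a patient's ordered care-episode sequence
#'
#' Collapses all attendance markers (visits, labs, therapy events) into one
#' episode per 30.4-day month containing at least one marker, with months
#' anchored at the first marker (study entry, month 0). Per-episode clinical
#' state is derived as:
#'
#' * `lowest_cd4` — the minimum CD4 measured that month; if none was measured,
#'   the most recent earlier value is carried forward (`cd4_carried = TRUE`).
#' * `cd4_drop` — previous measured CD4 (any earlier month) minus this month's
#'   lowest; positive values are drops. Defined only between measured values:
#'   carried-forward state never generates a drop.
#' * `highest_vl` — the maximum viral load measured that month (with its
#'   below-detection flag), carried forward analogously.
#' * `vl_is_blip` — this month's VL is 51-200 copies/mL and the most recent
#'   previously measured VL was < 50 copies/mL.
#' * `on_art` — an ART start date on or before the episode date.
#' * `started_art` / `started_combination` — the ART start (or a regimen
#'   switch) falls in this episode's month; a switch recorded on the same date
#'   as the start counts as a start only.
#' * `within_month_of_diagnosis` — episode date within 30.4 days of HIV
#'   diagnosis.
#' * `aids_event` — the AIDS diagnosis date falls in this episode's month.
#'
#' @param patient An `eic_patient` record with at least two distinct
#'   attendance dates.
#' @param config An [eic_rule_config()]; governs the diagnosis window length
#'   and whether the AIDS flag persists past the diagnosis month.
#' @return A data frame of class `eic_episodes`, one row per episode in
#'   increasing `month_index`, with attributes `patient_id` and `entry_date`.
#' @export
build_episodes <- function(patient, config = eic_rule_config()) {
  att <- attendance_dates(patient)
  if (length(att) < 2L) {
    stop("patient ", patient$patient_id,
         " has fewer than two attendance dates", call. = FALSE)
  }
  entry <- att[1L]
  att_month <- month_index(att, entry)
  months <- unique(att_month)
  episode_date <- att[!duplicated(att_month)]

  cd4 <- patient$labs[patient$labs$kind == "cd4" &
                        !is.na(patient$labs$value), , drop = FALSE]
  vl <- patient$labs[patient$labs$kind == "viral_load" &
                       !is.na(patient$labs$value), , drop = FALSE]
  cd4_m <- if (nrow(cd4)) month_index(cd4$date, entry) else integer(0)
  vl_m <- if (nrow(vl)) month_index(vl$date, entry) else integer(0)

  start_date <- patient$therapy$date[patient$therapy$kind == "start"]
  start_date <- if (length(start_date)) start_date[1L] else as.Date(NA)
  switch_dates <- patient$therapy$date[patient$therapy$kind == "switch"]
  if (!is.na(start_date)) {
    switch_dates <- switch_dates[switch_dates != start_date]
  }
  start_month <- if (!is.na(start_date)) month_index(start_date, entry) else
    NA_integer_
  switch_months <- if (length(switch_dates))
    month_index(switch_dates, entry) else integer(0)
  aids_month <- if (!is.na(patient$aids_diagnosis_date) &&
                    patient$aids_diagnosis_date >= entry)
    month_index(patient$aids_diagnosis_date, entry) else NA_integer_

  n <- length(months)
  lowest_cd4 <- rep(NA_real_, n); cd4_carried <- rep(NA, n)
  cd4_drop <- rep(NA_real_, n)
  highest_vl <- rep(NA_real_, n); vl_carried <- rep(NA, n)
  vl_below <- rep(FALSE, n); vl_is_blip <- rep(FALSE, n)

  for (i in seq_len(n)) {
    m <- months[i]

    in_month <- which(cd4_m == m)
    prev_idx <- which(cd4_m < m)
    prev_cd4 <- if (length(prev_idx)) cd4$value[max(prev_idx)] else NA_real_
    if (length(in_month)) {
      lowest_cd4[i] <- min(cd4$value[in_month])
      cd4_carried[i] <- FALSE
      if (!is.na(prev_cd4)) cd4_drop[i] <- prev_cd4 - lowest_cd4[i]
    } else if (!is.na(prev_cd4)) {
      lowest_cd4[i] <- prev_cd4
      cd4_carried[i] <- TRUE
    }

    in_month <- which(vl_m == m)
    prev_idx <- which(vl_m < m)
    if (length(in_month)) {
      j <- in_month[which.max(vl$value[in_month])]
      highest_vl[i] <- vl$value[j]
      vl_below[i] <- vl$below_detection[j]
      vl_carried[i] <- FALSE
      if (length(prev_idx)) {
        k <- max(prev_idx)
        prev_eff <- vl_effective(vl$value[k], vl$below_detection[k])
        cur_eff <- vl_effective(highest_vl[i], vl_below[i])
        vl_is_blip[i] <- cur_eff > 50 && cur_eff <= 200 && prev_eff < 50
      }
    } else if (length(prev_idx)) {
      k <- max(prev_idx)
      highest_vl[i] <- vl$value[k]
      vl_below[i] <- vl$below_detection[k]
      vl_carried[i] <- TRUE
    }
  }

  out <- data.frame(
    month_index = months,
    episode_date = episode_date,
    lowest_cd4 = lowest_cd4,
    cd4_carried = cd4_carried,
    cd4_drop = cd4_drop,
    highest_vl = highest_vl,
    vl_carried = vl_carried,
    vl_below_detection = vl_below,
    vl_is_blip = vl_is_blip,
    on_art = !is.na(start_date) & episode_date >= start_date,
    started_art = !is.na(start_month) & months == start_month,
    started_combination = months %in% switch_months,
    within_month_of_diagnosis = !is.na(patient$hiv_diagnosis_date) &
      as.numeric(episode_date - patient$hiv_diagnosis_date) <=
        config$diagnosis_window_months * MONTH_DAYS,
    aids_event = !is.na(aids_month) &
      (if (config$aids_persistent) months >= aids_month else
         months == aids_month),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, patient_id = patient$patient_id, entry_date = entry,
            class = c("eic_episodes", "data.frame"))
}
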