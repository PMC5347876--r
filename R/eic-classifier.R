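# Core engagement-in-care algorithm: expected-interval rule engine and
# per-month in-care / out-of-care classification.

#' Expected months until the next care episode
#'
#' Evaluates the full rule table against one episode's clinical state and
#' returns the shortest interval over all satisfied rules (when several
#' conditions apply, the next episode is expected within the least number of
#' months among them). Event rules (recent diagnosis, AIDS event, ART start,
#' regimen switch) apply regardless of treatment status; CD4-driven rules
#' apply to untreated episodes and viral-load-driven rules to treated ones.
#' A predicate that needs a lab value is unsatisfied when that value has never
#' been observed; if no rule at all is satisfiable the configurable fallback
#' interval applies with `fired_conditions = "fallback"`.
#'
#' @param episode A single episode: one row of [build_episodes()] output, or
#'   any list with (a subset of) its fields. Missing logical fields default to
#'   `FALSE`, missing lab fields to unobserved.
#' @param config An [eic_rule_config()].
#' @return A list of class `eic_interval` with elements `months` (the minimum
#'   interval) and `fired_conditions` (identifiers of every satisfied rule).
#' @examples
#' ep <- list(on_art = TRUE, highest_vl = 40, lowest_cd4 = 420)
#' expected_interval(ep, eic_rule_config())$months # 6
#' @export
expected_interval <- function(episode, config = eic_rule_config()) {
  episode <- as.list(episode)
  lg <- function(nm) isTRUE(as.logical(episode[[nm]][1]))
  num <- function(nm) {
    v <- episode[[nm]]
    if (is.null(v) || length(v) == 0L || is.na(v[1])) NA_real_ else
      as.numeric(v[1])
  }

  cd4 <- num("lowest_cd4")
  drop <- num("cd4_drop")
  vl <- num("highest_vl")
  vl_eff <- if (is.na(vl)) NA_real_ else
    vl_effective(vl, lg("vl_below_detection"))
  on_art <- lg("on_art")
  blip <- lg("vl_is_blip")

  fired <- character(0)
  hit <- function(id, cond) {
    if (isTRUE(cond)) fired <<- c(fired, id)
  }

  hit("diagnosis", lg("within_month_of_diagnosis"))
  hit("aids", lg("aids_event"))
  hit("art_start", lg("started_art"))
  hit("art_switch", lg("started_combination"))

  if (!on_art && !is.na(cd4)) {
    no_big_drop <- is.na(drop) || drop < config$cd4_drop_high
    hit("cd4_le350_drop",
        cd4 <= config$cd4_low && !is.na(drop) && drop > 0)
    hit("cd4_le350_stable",
        cd4 <= config$cd4_low && (is.na(drop) || drop <= 0))
    hit("cd4_351_499", cd4 > config$cd4_low && cd4 < config$cd4_high)
    hit("cd4_ge500_drop_ge100",
        cd4 >= config$cd4_high && !is.na(drop) &&
          drop >= config$cd4_drop_high)
    hit("cd4_ge500_high_vl",
        cd4 >= config$cd4_high && no_big_drop && !is.na(vl_eff) &&
          vl_eff >= config$vl_high)
    hit("cd4_ge500_low_vl",
        cd4 >= config$cd4_high && no_big_drop && !is.na(vl_eff) &&
          vl_eff < config$vl_high)
  }

  if (on_art && !is.na(vl_eff)) {
    low_level <- vl_eff > config$vl_suppressed && vl_eff <= config$vl_low
    hit("vl_gt200", vl_eff > config$vl_low)
    hit("vl_low_not_blip", low_level && !blip)
    hit("vl_low_blip", low_level && blip)
    hit("vl_supp_cd4_le200",
        vl_eff <= config$vl_suppressed && !is.na(cd4) &&
          cd4 <= config$cd4_on_art)
    hit("vl_supp_cd4_gt200",
        vl_eff <= config$vl_suppressed && !is.na(cd4) &&
          cd4 > config$cd4_on_art)
  }

  if (length(fired) == 0L) {
    return(structure(list(months = config$fallback_months,
                          fired_conditions = "fallback"),
                     class = "eic_interval"))
  }
  months <- min(unlist(config$intervals[fired]))
  structure(list(months = months, fired_conditions = fired),
            class = "eic_interval")
}

#' @export
print.eic_interval <- function(x, ...) {
  cat(sprintf("next care episode expected within %g month(s) [%s]\n",
              x$months, paste(x$fired_conditions, collapse = ", ")))
  invisible(x)
}

#' Classify every follow-up month as in care or out of care
#'
#' Walks a patient's episode sequence and labels each follow-up month (months
#' are counted from 1; the entry month 0 itself is not classified). For an
#' episode at month `m` with expected interval `N`, the months `m+1 ... m+N`
#' (truncated at the next episode or at follow-up end) are in care; any months
#' after `m+N` up to and including the month of the next episode are out of
#' care. The re-attendance month itself is therefore out of care when it falls
#' beyond the expectation window. After the final episode, months up to the
#' follow-up end are labelled against the final expectation window; with the
#' default censoring at the last attendance marker no such trailing months
#' exist.
#'
#' @param episodes [build_episodes()] output (ordered, strictly increasing
#'   `month_index`).
#' @param follow_up_end_month Last follow-up month to classify. Defaults to
#'   the final episode's month (censoring at the last recorded marker); pass a
#'   later month (e.g. derived from an administrative end date) to classify
#'   trailing months.
#' @param config An [eic_rule_config()].
#' @return A tibble with columns `patient_id`, `month_index` (1 ...
#'   `follow_up_end_month`, each exactly once), `label` (`"in_care"` /
#'   `"out_of_care"`) and `anchor_episode_month` (the episode whose
#'   expectation window covers the month). The per-episode intervals are
#'   attached as attribute `"intervals"` and the number of fallback-rule
#'   firings as `"n_fallback"`.
#' @export
classify_months <- function(episodes, follow_up_end_month = NULL,
                            config = eic_rule_config()) {
  ep <- as.data.frame(episodes)
  if (nrow(ep) == 0L) stop("no episodes to classify", call. = FALSE)
  m <- ep$month_index
  if (is.unsorted(m, strictly = TRUE)) {
    stop("episodes must be ordered with strictly increasing month_index",
         call. = FALSE)
  }
  if (m[1] != 0L) {
    stop("entry episode must have month_index 0", call. = FALSE)
  }
  L <- nrow(ep)
  end <- if (is.null(follow_up_end_month)) m[L] else
    as.integer(follow_up_end_month)
  if (end < m[L]) {
    stop("follow_up_end_month precedes the final episode", call. = FALSE)
  }

  cols <- as.list(ep)
  iv <- lapply(seq_len(L), function(i)
    expected_interval(lapply(cols, `[[`, i), config))
  N <- vapply(iv, `[[`, numeric(1), "months")

  label <- character(end)
  anchor <- integer(end)
  for (i in seq_len(L)) {
    nxt <- if (i < L) m[i + 1L] else end
    span <- seq_len(max(0L, nxt - m[i])) + m[i]        # months m+1 ... nxt
    if (length(span)) {
      label[span] <- ifelse(span <= m[i] + N[i], "in_care", "out_of_care")
      anchor[span] <- m[i]
    }
  }

  out <- tibble::new_tibble(list(
    patient_id = rep(attr(episodes, "patient_id") %||% NA_character_, end),
    month_index = seq_len(end),
    label = label,
    anchor_episode_month = anchor
  ), nrow = end)
  attr(out, "intervals") <- tibble::new_tibble(list(
    month_index = m, months = N,
    fired_conditions = vapply(iv, function(x)
      paste(x$fired_conditions, collapse = "+"), character(1))), nrow = L)
  attr(out, "n_fallback") <- sum(vapply(iv, function(x)
    identical(x$fired_conditions, "fallback"), logical(1)))
  out
}

#' Proportion of follow-up months in care
#'
#' The engagement-in-care measure for one patient: the fraction of classified
#' follow-up months labelled in care.
#'
#' @param classifications Output of [classify_months()] (non-empty).
#' @return Proportion in `[0, 1]`.
#' @export
patient_eic <- function(classifications) {
  if (is.null(classifications) || nrow(classifications) == 0L) {
    stop("cannot compute an engagement proportion over zero months",
         call. = FALSE)
  }
  mean(classifications$label == "in_care")
}

#' Classify every patient in a cohort
#'
#' Runs [build_episodes()] and [classify_months()] over a cohort and binds the
#' per-month classifications.
#'
#' @param cohort An `eic_cohort` (or list of `eic_patient` records).
#' @param config An [eic_rule_config()].
#' @param follow_up `"last_marker"` (default) censors each patient at their
#'   last attendance marker; `"admin_end"` extends follow-up to the month of
#'   the patient's administrative end date where one is recorded.
#' @return A tibble of per-month classifications for all patients, with
#'   attributes `n_fallback` (total fallback-rule firings) and `entry_dates`
#'   (named Date vector of per-patient entry dates).
#' @export
classify_cohort <- function(cohort, config = eic_rule_config(),
                            follow_up = c("last_marker", "admin_end")) {
  follow_up <- match.arg(follow_up)
  out <- vector("list", length(cohort))
  n_fallback <- 0L
  entries <- as.Date(character(0))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    ep <- build_episodes(p, config)
    end <- NULL
    if (follow_up == "admin_end" && !is.na(p$admin_end_date) &&
        p$admin_end_date >= attr(ep, "entry_date")) {
      end <- max(month_index(p$admin_end_date, attr(ep, "entry_date")),
                 max(ep$month_index))
    }
    cls <- classify_months(ep, end, config)
    n_fallback <- n_fallback + attr(cls, "n_fallback")
    entries[p$patient_id] <- attr(ep, "entry_date")
    out[[i]] <- cls
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_fallback") <- n_fallback
  attr(res, "entry_dates") <- entries
  res
}

#' Per-patient engagement summary
#'
#' @param classifications Bound per-month classifications (e.g. from
#'   [classify_cohort()]).
#' @return A tibble with one row per patient: total classified months, months
#'   in care, and the engagement proportion `eic`.
#' @export
eic_summary <- function(classifications) {
  dplyr::summarise(
    dplyr::group_by(classifications, .data$patient_id),
    months = dplyr::n(),
    in_care = sum(.data$label == "in_care"),
    eic = .data$in_care / .data$months,
    .groups = "drop")
}
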