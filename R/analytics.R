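# Person-month analytics: the analysis table with time-updated covariates,
# stratified engagement summaries, and the month-level association model.

AGE_LEVELS <- c("<25", "25-45", ">45")
CD4_GROUP_LEVELS <- c("<200", "200-349", ">=350")
PERIOD_LEVELS <- c("2000-2003", "2004-2007", "2008-2012")
TIME_IN_STUDY_LEVELS <- c("<1", "1-5", "5-10", ">10")

PERSON_MONTH_FACTORS <- c("gender", "age_group", "ethnicity", "acquisition",
                          "on_art", "nadir_cd4_group", "current_cd4_group",
                          "calendar_period", "time_in_study_group",
                          "clinic_id")

cd4_group <- function(x) {
  cut(x, breaks = c(-Inf, 200, 350, Inf), labels = CD4_GROUP_LEVELS,
      right = FALSE)
}

#' Build the person-month analysis table
#'
#' One row per classified follow-up month per patient, with covariates
#' evaluated at the month's midpoint date (entry + (month - 0.5) x 30.4
#' days): age group, treatment status, nadir and current CD4 group (from
#' measured values only), calendar period and time since study entry.
#' Covariates that cannot be evaluated (no CD4 ever measured, unknown birth
#' date) are emitted as missing.
#'
#' @param patients An `eic_cohort` (or named list of `eic_patient` records)
#'   covering every patient in `classifications`.
#' @param classifications Per-month classifications from [classify_cohort()]
#'   or bound [classify_months()] outputs.
#' @return A tibble with one row per classified month: `patient_id`,
#'   `month_index`, `in_care` (0/1) plus the factor columns listed in the
#'   vignette.
#' @export
person_month_table <- function(patients, classifications) {
  ids <- unique(classifications$patient_id)
  missing <- setdiff(ids, names(patients))
  if (length(missing)) {
    stop("classifications reference unknown patient(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    pid <- ids[k]
    p <- patients[[pid]]
    cls <- classifications[classifications$patient_id == pid, ]
    entry <- attendance_dates(p)[1L]
    mid <- month_midpoint(cls$month_index - 1L, entry)  # months counted from 1

    age <- as.numeric(mid - p$birth_date) / 365.25
    age_group <- cut(age, breaks = c(-Inf, 25, 45, Inf), labels = AGE_LEVELS,
                     right = TRUE)

    cd4 <- p$labs[p$labs$kind == "cd4" & !is.na(p$labs$value), , drop = FALSE]
    nadir <- current <- rep(NA_real_, nrow(cls))
    if (nrow(cd4)) {
      # running nadir / latest over measurement dates, evaluated at midpoints
      run_min <- cummin(cd4$value)
      pos <- findInterval(as.numeric(mid), as.numeric(cd4$date))
      nadir[pos > 0] <- run_min[pos[pos > 0]]
      current[pos > 0] <- cd4$value[pos[pos > 0]]
    }

    start_date <- p$therapy$date[p$therapy$kind == "start"]
    on_art <- if (length(start_date)) as.integer(mid >= start_date[1L]) else
      0L

    yr <- as.integer(format(mid, "%Y"))
    period <- cut(yr, breaks = c(1999, 2003, 2007, 2012),
                  labels = PERIOD_LEVELS, right = TRUE)
    tis <- as.numeric(mid - entry) / 365.25
    tis_group <- cut(tis, breaks = c(-Inf, 1, 5, 10, Inf),
                     labels = TIME_IN_STUDY_LEVELS, right = FALSE)

    out[[k]] <- tibble::tibble(
      patient_id = pid,
      month_index = cls$month_index,
      in_care = as.integer(cls$label == "in_care"),
      gender = factor(p$gender, GENDER_LEVELS),
      age_group = age_group,
      ethnicity = factor(p$ethnicity, ETHNICITY_LEVELS),
      acquisition = factor(p$acquisition, ACQUISITION_LEVELS),
      on_art = factor(on_art, levels = c(0L, 1L), labels = c("no", "yes")),
      nadir_cd4_group = cd4_group(nadir),
      current_cd4_group = cd4_group(current),
      calendar_period = period,
      time_in_study_group = tis_group,
      clinic_id = p$clinic_id)
  }
  dplyr::bind_rows(out)
}

#' Engagement proportion stratified by one factor
#'
#' @param rows Person-month table from [person_month_table()].
#' @param factor_name One of `gender`, `age_group`, `ethnicity`,
#'   `acquisition`, `on_art`, `nadir_cd4_group`, `current_cd4_group`,
#'   `calendar_period`, `time_in_study_group`, `clinic_id`.
#' @return A tibble with one row per factor level: `factor`, `level`,
#'   `person_months` and `percent_in_care` (0-100; `NA` for empty levels,
#'   which are still reported with a zero count). Months whose covariate is
#'   undefined are reported under an explicit `"(missing)"` level, so the
#'   level counts always partition the person-months.
#' @export
stratified_proportions <- function(rows, factor_name) {
  if (!factor_name %in% PERSON_MONTH_FACTORS) {
    stop("unknown factor '", factor_name, "'; valid factors: ",
         paste(PERSON_MONTH_FACTORS, collapse = ", "), call. = FALSE)
  }
  f <- rows[[factor_name]]
  if (!is.factor(f)) f <- factor(f)
  lev <- levels(f)
  x <- as.character(f)
  if (anyNA(x)) {
    # months with an undefined covariate are reported, not silently dropped,
    # so levels always partition the person-months
    x[is.na(x)] <- "(missing)"
    lev <- c(lev, "(missing)")
  }
  f <- factor(x, lev)
  counts <- as.integer(table(f))
  in_care <- as.numeric(tapply(rows$in_care, f, sum))
  in_care[is.na(in_care)] <- 0
  tibble::tibble(
    factor = factor_name,
    level = lev,
    person_months = counts,
    percent_in_care = ifelse(counts > 0, 100 * in_care / counts, NA_real_))
}

#' Month-level association model for being in care
#'
#' Fits a marginal logistic regression of the in-care indicator on covariate
#' main effects, with within-patient correlation of repeated months handled
#' by generalized estimating equations (exchangeable working correlation,
#' robust variance). Unadjusted fits model one covariate at a time; the
#' adjusted fit includes every requested covariate plus clinic.
#'
#' @param rows Person-month table from [person_month_table()].
#' @param covariates Character vector of covariate names (see
#'   [stratified_proportions()] for the valid set). Default: all except
#'   clinic.
#' @param adjust If `TRUE`, one joint model of all `covariates` plus
#'   `clinic_id`; if `FALSE` (default), a separate univariable model per
#'   covariate.
#' @param conf_level Confidence level for Wald intervals.
#' @return A tibble of class `eic_association`: one row per covariate level
#'   with `factor`, `level`, `person_months`, `or`, `ci_low`, `ci_high`, `p`,
#'   `reference` (logical; reference levels carry `or = 1` exactly) and
#'   `adjusted` (0/1). Model metadata (rows and patients used, rows dropped
#'   for missingness, working-correlation estimates) in attributes.
#' @export
fit_association_model <- function(rows,
                                  covariates = setdiff(PERSON_MONTH_FACTORS,
                                                       "clinic_id"),
                                  adjust = FALSE, conf_level = 0.95) {
  bad <- setdiff(covariates, PERSON_MONTH_FACTORS)
  if (length(bad)) {
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(rows$patient_id)) < 2L) {
    stop("association model needs rows from at least two patients",
         call. = FALSE)
  }

  model_vars <- if (adjust) unique(c(covariates, "clinic_id")) else covariates
  dat <- rows
  for (v in model_vars) {
    if (!is.factor(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    dat[[v]] <- droplevels(dat[[v]])
  }

  fit_one <- function(vars) {
    use <- stats::complete.cases(dat[vars])
    d <- dat[use, , drop = FALSE]
    for (v in vars) {
      if (nlevels(droplevels(d[[v]])) < 2L) {
        stop("covariate '", v, "' has fewer than two observed levels",
             call. = FALSE)
      }
      d[[v]] <- droplevels(d[[v]])
    }
    fml <- stats::as.formula(paste("in_care ~", paste(vars, collapse = " + ")))
    fit <- gee_logit(fml, id = d$patient_id, data = d)
    tidy <- gee_tidy(fit, conf_level)
    res <- list()
    for (v in setdiff(vars, if (adjust) "clinic_id" else character(0))) {
      lv <- levels(d[[v]])
      terms <- paste0(v, lv)
      idx <- match(terms, tidy$term)
      pm <- table(d[[v]])
      res[[v]] <- tibble::tibble(
        factor = v, level = lv,
        person_months = as.integer(pm[lv]),
        or = ifelse(is.na(idx), 1, tidy$or[idx]),
        ci_low = tidy$ci_low[idx],
        ci_high = tidy$ci_high[idx],
        p = tidy$p[idx],
        reference = is.na(idx))
    }
    list(table = dplyr::bind_rows(res), fit = fit,
         n_dropped = sum(!use), n_obs = fit$n_obs,
         n_clusters = fit$n_clusters, alpha = fit$alpha)
  }

  if (adjust) {
    one <- fit_one(model_vars)
    out <- one$table
    out$adjusted <- 1L
    meta <- list(fits = list(adjusted = one$fit),
                 n_dropped = c(adjusted = one$n_dropped),
                 n_obs = one$n_obs, n_clusters = one$n_clusters,
                 alpha = c(adjusted = one$alpha))
  } else {
    pieces <- lapply(covariates, function(v) fit_one(v))
    out <- dplyr::bind_rows(lapply(pieces, `[[`, "table"))
    out$adjusted <- 0L
    meta <- list(fits = stats::setNames(lapply(pieces, `[[`, "fit"),
                                        covariates),
                 n_dropped = stats::setNames(
                   vapply(pieces, `[[`, numeric(1), "n_dropped"), covariates),
                 n_obs = max(vapply(pieces, `[[`, numeric(1), "n_obs")),
                 n_clusters = max(vapply(pieces, `[[`, numeric(1),
                                         "n_clusters")),
                 alpha = stats::setNames(
                   vapply(pieces, `[[`, numeric(1), "alpha"), covariates))
  }
  structure(out, meta = meta,
            class = c("eic_association", class(out)))
}
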