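# Domain types and delimited-text I/O for longitudinal HIV cohort data.
#
# A cohort is a named list of patient records. Each record bundles
# demographics with three dated event streams (visits, labs, therapy) that
# together supply the surrogate attendance markers the classifier consumes:
# CD4 counts, viral loads, haemoglobin measurements and ART start/switch dates
# all imply the patient was seen on that date.

GENDER_LEVELS <- c("male", "female", "other_unknown")
ETHNICITY_LEVELS <- c("white", "black_african", "other", "unknown")
ACQUISITION_LEVELS <- c("msm", "heterosexual", "idu", "other_unknown")
VISIT_SOURCES <- c("clinic_visit", "cd4", "viral_load", "haemoglobin",
                   "art_start", "art_switch")
LAB_KINDS <- c("cd4", "viral_load", "haemoglobin")
THERAPY_KINDS <- c("start", "switch")

#' Construct a patient record
#'
#' Bundles one patient's demographics and dated event streams into the record
#' type the rest of the package consumes. Event streams are stably sorted by
#' date (ties broken by source/kind name) on construction. Events dated before
#' the HIV diagnosis are retained but flagged, since silently dropping them
#' would hide data-quality problems.
#'
#' @param patient_id Opaque patient identifier (string).
#' @param hiv_diagnosis_date Date of HIV diagnosis.
#' @param gender One of `"male"`, `"female"`, `"other_unknown"`.
#' @param birth_date Date of birth (day precision; mid-month imputation for
#'   year-month input happens at load time).
#' @param ethnicity One of `"white"`, `"black_african"`, `"other"`, `"unknown"`.
#' @param acquisition HIV acquisition route: `"msm"`, `"heterosexual"`,
#'   `"idu"`, `"other_unknown"`.
#' @param clinic_id Opaque clinic identifier.
#' @param aids_diagnosis_date Optional Date of AIDS diagnosis (must not precede
#'   HIV diagnosis).
#' @param admin_end_date Optional administrative censoring date; enables
#'   classifying trailing months beyond the last attendance marker.
#' @param visits Data frame with columns `date`, `source` (see
#'   [VISIT_SOURCES][load_cohort]).
#' @param labs Data frame with columns `date`, `kind`, `value`,
#'   `below_detection` (logical; viral loads reported as "<X" are stored as X
#'   with the flag set).
#' @param therapy Data frame with columns `date`, `kind` (`"start"` /
#'   `"switch"`); at most one start, switches after the start.
#' @return An object of class `eic_patient`. Data-quality flags (events before
#'   diagnosis, switch before start, ...) are attached as the `"flags"`
#'   attribute, a character vector.
#' @export
patient_record <- function(patient_id,
                           hiv_diagnosis_date,
                           gender = "other_unknown",
                           birth_date = NA,
                           ethnicity = "unknown",
                           acquisition = "other_unknown",
                           clinic_id = NA_character_,
                           aids_diagnosis_date = NA,
                           admin_end_date = NA,
                           visits = NULL,
                           labs = NULL,
                           therapy = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  gender <- match.arg(gender, GENDER_LEVELS)
  ethnicity <- match.arg(ethnicity, ETHNICITY_LEVELS)
  acquisition <- match.arg(acquisition, ACQUISITION_LEVELS)
  hiv_diagnosis_date <- as.Date(hiv_diagnosis_date)
  aids_diagnosis_date <- as.Date(aids_diagnosis_date)
  admin_end_date <- as.Date(admin_end_date)
  birth_date <- as.Date(birth_date)

  visits <- normalize_stream(visits, c(date = "Date", source = "character"))
  labs <- normalize_stream(labs, c(date = "Date", kind = "character",
                                   value = "numeric",
                                   below_detection = "logical"))
  therapy <- normalize_stream(therapy, c(date = "Date", kind = "character"))
  if (nrow(labs) && is.logical(labs$below_detection)) {
    labs$below_detection[is.na(labs$below_detection)] <- FALSE
  }

  if (nrow(visits) && !all(visits$source %in% VISIT_SOURCES)) {
    stop("unknown visit source for patient ", patient_id, call. = FALSE)
  }
  if (nrow(labs)) {
    if (!all(labs$kind %in% LAB_KINDS)) {
      stop("unknown lab kind for patient ", patient_id, call. = FALSE)
    }
    if (any(!is.na(labs$value) & labs$value < 0)) {
      stop("negative lab value for patient ", patient_id, call. = FALSE)
    }
  }
  if (nrow(therapy) && !all(therapy$kind %in% THERAPY_KINDS)) {
    stop("unknown therapy kind for patient ", patient_id, call. = FALSE)
  }
  if (sum(therapy$kind == "start") > 1L) {
    stop("more than one ART start for patient ", patient_id, call. = FALSE)
  }
  if (!is.na(aids_diagnosis_date) && !is.na(hiv_diagnosis_date) &&
      aids_diagnosis_date < hiv_diagnosis_date) {
    stop("AIDS diagnosis precedes HIV diagnosis for patient ", patient_id,
         call. = FALSE)
  }

  # stable sort: date, then source/kind name, so equal-date events never
  # reorder nondeterministically
  visits <- visits[order(visits$date, visits$source, method = "radix"), ,
                   drop = FALSE]
  labs <- labs[order(labs$date, labs$kind, method = "radix"), , drop = FALSE]
  therapy <- therapy[order(therapy$date, therapy$kind, method = "radix"), ,
                     drop = FALSE]
  rownames(visits) <- rownames(labs) <- rownames(therapy) <- NULL

  flags <- character(0)
  if (!is.na(hiv_diagnosis_date)) {
    for (nm in c("visits", "labs", "therapy")) {
      stream <- get(nm)
      early <- sum(!is.na(stream$date) & stream$date < hiv_diagnosis_date)
      if (early > 0) {
        flags <- c(flags, sprintf("%d %s event(s) precede HIV diagnosis",
                                  early, nm))
      }
    }
  }
  start_date <- therapy$date[therapy$kind == "start"]
  if (length(start_date) == 1L &&
      any(therapy$date[therapy$kind == "switch"] < start_date)) {
    flags <- c(flags, "regimen switch precedes ART start")
  }

  structure(
    list(patient_id = patient_id, gender = gender, birth_date = birth_date,
         ethnicity = ethnicity, acquisition = acquisition,
         clinic_id = clinic_id, hiv_diagnosis_date = hiv_diagnosis_date,
         aids_diagnosis_date = aids_diagnosis_date,
         admin_end_date = admin_end_date,
         visits = visits, labs = labs, therapy = therapy),
    flags = flags,
    class = "eic_patient"
  )
}

# Internal: coerce a possibly-NULL event stream to a data.frame with the given
# column types.
normalize_stream <- function(x, spec) {
  if (is.null(x) || nrow(as.data.frame(x)) == 0L) {
    out <- lapply(names(spec), function(nm) {
      switch(spec[[nm]],
             Date = as.Date(character(0)),
             character = character(0),
             numeric = numeric(0),
             logical = logical(0))
    })
    names(out) <- names(spec)
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing <- setdiff(names(spec), names(x))
  if ("below_detection" %in% missing) {
    x$below_detection <- FALSE
    missing <- setdiff(missing, "below_detection")
  }
  if (length(missing)) {
    stop("event stream missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[names(spec)]
  x$date <- as.Date(x$date)
  if ("value" %in% names(x)) x$value <- as.numeric(x$value)
  if ("below_detection" %in% names(x)) {
    x$below_detection <- as.logical(x$below_detection)
  }
  x
}

#' @export
print.eic_patient <- function(x, ...) {
  cat(sprintf(
    "<eic_patient %s> diagnosed %s; %d visit, %d lab, %d therapy event(s)\n",
    x$patient_id, format(x$hiv_diagnosis_date),
    nrow(x$visits), nrow(x$labs), nrow(x$therapy)))
  invisible(x)
}

#' Dates on which a patient is known to have attended
#'
#' The union of all dated events (visits, labs, therapy), each treated as a
#' surrogate marker of clinic attendance.
#'
#' @param patient An `eic_patient` record.
#' @return Sorted vector of unique Dates.
#' @export
attendance_dates <- function(patient) {
  d <- c(patient$visits$date, patient$labs$date, patient$therapy$date)
  d <- d[!is.na(d)]
  sort(unique(d))
}

#' Load a cohort from delimited files
#'
#' Reads the four cohort CSVs (visits, labs, therapy, demographics), merges
#' event streams per patient, and returns one record per patient present in
#' the demographics file. Patients with fewer than two distinct attendance
#' dates are excluded (a single marker gives the classifier no inter-episode
#' gap to assess) and reported via the `"excluded"` attribute. Malformed rows
#' (unparseable dates, unknown enum codes, negative values) are collected into
#' a row-level error report (`"errors"` attribute) rather than aborting the
#' load; a missing required column is a hard failure.
#'
#' @param visits_path,labs_path,therapy_path,demographics_path CSV paths. See
#'   the package vignette for the column schemas.
#' @return An object of class `eic_cohort`: a named list of `eic_patient`
#'   records, with attributes `excluded` (data frame of patient_id and marker
#'   count), `errors` (data frame file/row/problem) and `flags` (named list of
#'   per-patient data-quality flags).
#' @export
load_cohort <- function(visits_path, labs_path, therapy_path,
                        demographics_path) {
  errors <- list()
  note <- function(file, row, problem) {
    errors[[length(errors) + 1L]] <<- data.frame(
      file = file, row = row, problem = problem, stringsAsFactors = FALSE)
  }

  visits <- read_cohort_csv(visits_path, c("patient_id", "date", "source"))
  labs <- read_cohort_csv(labs_path,
                          c("patient_id", "date", "kind", "value",
                            "below_detection"))
  therapy <- read_cohort_csv(therapy_path, c("patient_id", "date", "kind"))
  demo <- read_cohort_csv(
    demographics_path,
    c("patient_id", "gender", "birth_date", "ethnicity", "acquisition",
      "clinic_id", "hiv_diagnosis_date", "aids_diagnosis_date",
      "admin_end_date"))

  check_rows <- function(df, file, date_cols, enum_cols = list()) {
    keep <- rep(TRUE, nrow(df))
    for (col in date_cols) {
      parsed <- parse_iso_date(df[[col]])
      bad <- which(!is.na(df[[col]]) & nzchar(df[[col]]) & is.na(parsed))
      for (i in bad) note(file, i, sprintf("malformed date in '%s': %s",
                                           col, df[[col]][i]))
      keep[bad] <- FALSE
      df[[col]] <- parsed
    }
    for (col in names(enum_cols)) {
      bad <- which(!is.na(df[[col]]) & nzchar(df[[col]]) &
                     !(df[[col]] %in% enum_cols[[col]]))
      for (i in bad) note(file, i, sprintf("unknown %s: '%s'", col,
                                           df[[col]][i]))
      keep[bad] <- FALSE
    }
    df[keep, , drop = FALSE]
  }

  visits <- check_rows(visits, basename(visits_path), "date",
                       list(source = VISIT_SOURCES))
  labs <- check_rows(labs, basename(labs_path), "date",
                     list(kind = LAB_KINDS))
  therapy <- check_rows(therapy, basename(therapy_path), "date",
                        list(kind = THERAPY_KINDS))
  labs$value <- suppressWarnings(as.numeric(labs$value))
  labs$below_detection <- labs$below_detection %in% c("1", "TRUE", "true")
  bad_val <- which(!is.na(labs$value) & labs$value < 0)
  for (i in bad_val) note(basename(labs_path), i, "negative lab value")
  if (length(bad_val)) labs <- labs[-bad_val, , drop = FALSE]

  demo$birth_date_parsed <- parse_birth_date(demo$birth_date)
  demo <- check_rows(demo, basename(demographics_path),
                     c("hiv_diagnosis_date", "aids_diagnosis_date",
                       "admin_end_date"),
                     list(gender = GENDER_LEVELS,
                          ethnicity = ETHNICITY_LEVELS,
                          acquisition = ACQUISITION_LEVELS))

  patients <- list()
  excluded <- list()
  flags <- list()
  blank_to <- function(x, default) {
    ifelse(is.na(x) | !nzchar(x), default, x)
  }
  demo$gender <- blank_to(demo$gender, "other_unknown")
  demo$ethnicity <- blank_to(demo$ethnicity, "unknown")
  demo$acquisition <- blank_to(demo$acquisition, "other_unknown")

  for (i in seq_len(nrow(demo))) {
    pid <- demo$patient_id[i]
    p <- patient_record(
      patient_id = pid,
      gender = demo$gender[i],
      birth_date = demo$birth_date_parsed[i],
      ethnicity = demo$ethnicity[i],
      acquisition = demo$acquisition[i],
      clinic_id = demo$clinic_id[i],
      hiv_diagnosis_date = demo$hiv_diagnosis_date[i],
      aids_diagnosis_date = demo$aids_diagnosis_date[i],
      admin_end_date = demo$admin_end_date[i],
      visits = visits[visits$patient_id == pid,
                      c("date", "source"), drop = FALSE],
      labs = labs[labs$patient_id == pid,
                  c("date", "kind", "value", "below_detection"), drop = FALSE],
      therapy = therapy[therapy$patient_id == pid,
                        c("date", "kind"), drop = FALSE])
    n_markers <- length(attendance_dates(p))
    if (n_markers < 2L) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        patient_id = pid, n_markers = n_markers, stringsAsFactors = FALSE)
    } else {
      patients[[pid]] <- p
      if (length(attr(p, "flags"))) flags[[pid]] <- attr(p, "flags")
    }
  }

  structure(
    patients,
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(patient_id = character(0), n_markers = integer(0)),
    errors = if (length(errors)) do.call(rbind, errors) else
      data.frame(file = character(0), row = integer(0),
                 problem = character(0)),
    flags = flags,
    class = "eic_cohort"
  )
}

# Internal: read a CSV as character columns, hard-failing on missing columns.
read_cohort_csv <- function(path, required) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @export
print.eic_cohort <- function(x, ...) {
  cat(sprintf("<eic_cohort> %d patient(s); %d excluded (<2 markers); %d row error(s)\n",
              length(x), nrow(attr(x, "excluded")), nrow(attr(x, "errors"))))
  invisible(x)
}

#' Write month classifications (or person-month rows) to CSV
#'
#' Writes with a stable column order so output files are byte-comparable
#' across runs; round-trips losslessly through [read_month_classifications()].
#'
#' @param rows Data frame of month classifications (from [classify_months()]
#'   or [classify_cohort()]) or person-month rows (from
#'   [person_month_table()]).
#' @param path Output CSV path.
#' @export
write_month_classifications <- function(rows, path) {
  rows <- as.data.frame(rows)
  lead <- intersect(c("patient_id", "month_index", "label",
                      "anchor_episode_month", "in_care"), names(rows))
  rows <- rows[c(lead, setdiff(names(rows), lead))]
  ok <- tryCatch({
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write classifications to: ", path, call. = FALSE)
  invisible(path)
}

#' Read month classifications written by [write_month_classifications()]
#'
#' @param path CSV path.
#' @return A tibble with the original column types restored.
#' @export
read_month_classifications <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("month_index", "anchor_episode_month", "in_care"),
                        names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  tibble::as_tibble(df)
}

#' Write a cohort back to the four delimited files
#'
#' Inverse of [load_cohort()] (up to exclusion of sub-threshold patients);
#' used by the simulator to emit loader-compatible files.
#'
#' @param cohort An `eic_cohort` or plain list of `eic_patient` records.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  vis <- list(); lab <- list(); ther <- list(); dem <- list()
  for (p in cohort) {
    if (nrow(p$visits)) {
      vis[[p$patient_id]] <- data.frame(patient_id = p$patient_id,
                                        date = fmt_date(p$visits$date),
                                        source = p$visits$source)
    }
    if (nrow(p$labs)) {
      lab[[p$patient_id]] <- data.frame(
        patient_id = p$patient_id, date = fmt_date(p$labs$date),
        kind = p$labs$kind, value = p$labs$value,
        below_detection = as.integer(p$labs$below_detection))
    }
    if (nrow(p$therapy)) {
      ther[[p$patient_id]] <- data.frame(patient_id = p$patient_id,
                                         date = fmt_date(p$therapy$date),
                                         kind = p$therapy$kind)
    }
    dem[[p$patient_id]] <- data.frame(
      patient_id = p$patient_id, gender = p$gender,
      birth_date = fmt_date(p$birth_date), ethnicity = p$ethnicity,
      acquisition = p$acquisition, clinic_id = p$clinic_id,
      hiv_diagnosis_date = fmt_date(p$hiv_diagnosis_date),
      aids_diagnosis_date = fmt_date(p$aids_diagnosis_date),
      admin_end_date = fmt_date(p$admin_end_date))
  }
  bind <- function(lst, cols) {
    if (length(lst)) do.call(rbind, unname(lst)) else
      stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))),
                      cols)
  }
  paths <- c(visits = file.path(dir, "visits.csv"),
             labs = file.path(dir, "labs.csv"),
             therapy = file.path(dir, "therapy.csv"),
             demographics = file.path(dir, "demographics.csv"))
  utils::write.csv(bind(vis, c("patient_id", "date", "source")),
                   paths[["visits"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(bind(lab, c("patient_id", "date", "kind", "value",
                               "below_detection")),
                   paths[["labs"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(bind(ther, c("patient_id", "date", "kind")),
                   paths[["therapy"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(bind(dem, c("patient_id", "gender", "birth_date",
                               "ethnicity", "acquisition", "clinic_id",
                               "hiv_diagnosis_date", "aids_diagnosis_date",
                               "admin_end_date")),
                   paths[["demographics"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
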