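test_that("the shipped worked-example fixture loads as one patient with five attendance dates", {
  dir <- system.file("extdata", "worked_example", package = "eicare")
  cohort <- load_cohort(file.path(dir, "visits.csv"),
                        file.path(dir, "labs.csv"),
                        file.path(dir, "therapy.csv"),
                        file.path(dir, "demographics.csv"))
  expect_length(cohort, 1L)
  expect_equal(nrow(attr(cohort, "excluded")), 0L)
  expect_length(attendance_dates(cohort[[1]]), 5L)
})

write_tiny_cohort <- function(dir, visits = NULL, labs = NULL,
                              therapy = NULL, demo = NULL) {
  dir.create(dir, showWarnings = FALSE)
  hdr <- list(
    visits = "patient_id,date,source",
    labs = "patient_id,date,kind,value,below_detection",
    therapy = "patient_id,date,kind",
    demographics = paste0("patient_id,gender,birth_date,ethnicity,",
                          "acquisition,clinic_id,hiv_diagnosis_date,",
                          "aids_diagnosis_date,admin_end_date"))
  rows <- list(visits = visits, labs = labs, therapy = therapy,
               demographics = demo)
  paths <- c()
  for (nm in names(hdr)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    writeLines(c(hdr[[nm]], rows[[nm]]), p)
    paths[nm] <- p
  }
  paths
}

test_that("patients with fewer than two distinct attendance dates are excluded and counted", {
  paths <- write_tiny_cohort(
    withr::local_tempdir(),
    visits = c("a,2004-01-01,clinic_visit",
               "b,2004-01-01,clinic_visit", "b,2004-03-01,cd4"),
    demo = c("a,male,1970-01-15,white,msm,c1,2004-01-01,,",
             "b,male,1970-01-15,white,msm,c1,2004-01-01,,"))
  cohort <- load_cohort(paths["visits"], paths["labs"], paths["therapy"],
                        paths["demographics"])
  expect_length(cohort, 1L)
  expect_equal(attr(cohort, "excluded")$patient_id, "a")
  expect_equal(attr(cohort, "excluded")$n_markers, 1L)
})

test_that("empty files with valid headers give an empty cohort without error", {
  paths <- write_tiny_cohort(withr::local_tempdir())
  cohort <- load_cohort(paths["visits"], paths["labs"], paths["therapy"],
                        paths["demographics"])
  expect_length(cohort, 0L)
  expect_equal(nrow(attr(cohort, "errors")), 0L)
})

test_that("malformed dates and unknown enum codes are reported per row, missing columns fail hard", {
  paths <- write_tiny_cohort(
    withr::local_tempdir(),
    visits = c("a,2004-13-45,clinic_visit", "a,2004-02-01,teleport",
               "a,2004-01-01,cd4", "a,2004-03-01,cd4"),
    demo = "a,male,1970-01-15,white,msm,c1,2004-01-01,,")
  cohort <- load_cohort(paths["visits"], paths["labs"], paths["therapy"],
                        paths["demographics"])
  err <- attr(cohort, "errors")
  expect_equal(nrow(err), 2L)
  expect_setequal(err$row, c(1L, 2L))
  expect_match(err$problem[err$row == 1L], "malformed date")
  expect_match(err$problem[err$row == 2L], "unknown source")
  expect_length(cohort, 1L)  # valid rows survive

  bad <- file.path(withr::local_tempdir(), "visits.csv")
  writeLines("patient_id,when", bad)
  expect_error(
    load_cohort(bad, paths["labs"], paths["therapy"], paths["demographics"]),
    "date")
})

test_that("a cohort round-trips through write_cohort and load_cohort", {
  p <- worked_example_patient()
  dir <- withr::local_tempdir()
  paths <- write_cohort(list(p), dir)
  cohort <- load_cohort(paths["visits"], paths["labs"], paths["therapy"],
                        paths["demographics"])
  q <- cohort[[p$patient_id]]
  expect_equal(q$gender, p$gender)
  expect_equal(q$hiv_diagnosis_date, p$hiv_diagnosis_date)
  expect_equal(q$admin_end_date, p$admin_end_date)
  expect_equal(q$labs$value, p$labs$value)
  expect_equal(q$labs$below_detection, p$labs$below_detection)
  expect_equal(q$therapy, p$therapy)
})

test_that("month classifications round-trip losslessly and empty input yields a header-only file", {
  cls <- classify_months(build_episodes(worked_example_patient()), 18)
  f <- withr::local_tempfile(fileext = ".csv")
  write_month_classifications(cls, f)
  back <- read_month_classifications(f)
  expect_equal(as.data.frame(back), as.data.frame(cls[names(back)]),
               ignore_attr = TRUE)
  expect_equal(nrow(back), 18L)

  write_month_classifications(cls[0, ], f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_month_classifications(f)), 0L)
  expect_error(write_month_classifications(cls, file.path(tempdir(),
                                                          "no/such/dir/x.csv")),
               "cannot write")
})

test_that("equal-date events keep a deterministic order and record invariants hold", {
  p <- patient_record(
    "x", hiv_diagnosis_date = as.Date("2004-01-01"),
    labs = data.frame(date = as.Date(c("2004-02-01", "2004-02-01",
                                       "2004-03-01")),
                      kind = c("viral_load", "cd4", "cd4"),
                      value = c(500, 400, 380),
                      below_detection = FALSE))
  expect_equal(p$labs$kind, c("cd4", "viral_load", "cd4"))

  expect_error(
    patient_record("x", hiv_diagnosis_date = as.Date("2004-01-01"),
                   aids_diagnosis_date = as.Date("2003-01-01")),
    "AIDS diagnosis precedes")
  expect_error(
    patient_record("x", hiv_diagnosis_date = as.Date("2004-01-01"),
                   therapy = data.frame(date = as.Date(c("2004-02-01",
                                                         "2004-05-01")),
                                        kind = "start")),
    "more than one ART start")

  flagged <- patient_record(
    "x", hiv_diagnosis_date = as.Date("2004-06-01"),
    labs = data.frame(date = as.Date("2004-01-01"), kind = "cd4",
                      value = 500, below_detection = FALSE))
  expect_match(attr(flagged, "flags"), "precede HIV diagnosis")
})
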