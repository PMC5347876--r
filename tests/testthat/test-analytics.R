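# helper: classify a hand-built cohort and return the person-month table
pm_for <- function(patients) {
  cohort <- stats::setNames(patients,
                            vapply(patients, `[[`, character(1),
                                   "patient_id"))
  cls <- classify_cohort(cohort)
  person_month_table(cohort, cls)
}

test_that("time-updated covariates are evaluated at the month midpoint", {
  entry <- as.Date("2004-01-05")
  # aged 44.9 years at the month-1 midpoint: crosses 45 during follow-up
  birth <- entry + 15 - round(44.9 * 365.25)
  p <- make_patient(id = "age1", entry = entry,
                    cd4 = data.frame(day = c(0, 122), value = c(420, 370)),
                    art_start_day = 100,
                    birth_date = birth)
  pm <- pm_for(list(p))

  expect_equal(as.character(pm$age_group[pm$month_index == 1]), "25-45")
  expect_equal(as.character(pm$age_group[pm$month_index == 4]), ">45")

  # CD4 420 then 370: nadir and current stay in the >= 350 band throughout
  expect_equal(as.character(pm$nadir_cd4_group[pm$month_index == 1]),
               ">=350")
  expect_equal(as.character(pm$current_cd4_group[pm$month_index == 4]),
               ">=350")

  # calendar period and time-in-study from the midpoint date
  expect_true(all(pm$calendar_period == "2004-2007"))
  expect_true(all(pm$time_in_study_group == "<1"))

  # ART started at day 100: month 3's midpoint (day 76) precedes it, month
  # 4's midpoint (day 106) follows it
  expect_equal(as.character(pm$on_art[pm$month_index == 3]), "no")
  expect_equal(as.character(pm$on_art[pm$month_index == 4]), "yes")
})

test_that("undefined covariates are emitted as missing, not dropped", {
  p <- make_patient(id = "nolabs", hb_days = c(0, 70))
  pm <- pm_for(list(p))
  expect_true(all(is.na(pm$nadir_cd4_group)))
  expect_true(all(is.na(pm$current_cd4_group)))
  expect_equal(nrow(pm), 2L)
})

# two ART patients with perfect attendance, two untreated patients attending
# two months late every time
contrast_cohort <- function() {
  # start ART at entry (2-month window met at month 2), then suppressed
  # 6-month routine visits, always on time
  on_art <- lapply(c("a1", "a2"), function(id) {
    days <- ceiling(c(0, 2, 8, 14) * 30.4)
    make_patient(id = id, diagnosis_day = -400,
                 cd4 = data.frame(day = days, value = 420),
                 vl = data.frame(day = days, value = 50, below = TRUE),
                 art_start_day = 0)
  })
  untreated <- lapply(c("u1", "u2"), function(id) {
    days <- ceiling(c(0, 6, 12, 18) * 30.4)    # expected every 4 months
    make_patient(id = id, diagnosis_day = -400,
                 cd4 = data.frame(day = days, value = 420))
  })
  c(on_art, untreated)
}

test_that("stratified proportions partition person-months and rank groups correctly", {
  pm <- pm_for(contrast_cohort())
  tab <- stratified_proportions(pm, "on_art")
  expect_equal(sum(tab$person_months), nrow(pm))
  yes <- unname(tab$percent_in_care[tab$level == "yes"])
  no <- unname(tab$percent_in_care[tab$level == "no"])
  expect_equal(yes, 100)
  expect_equal(no, 100 * 12 / 18)  # 2 of every 6 months out, per patient
  expect_gt(yes, no)

  # invariant to patient order
  pm2 <- pm[rev(seq_len(nrow(pm))), ]
  expect_equal(stratified_proportions(pm2, "on_art"), tab)

  # factor partition holds for every factor
  for (f in c("gender", "age_group", "calendar_period")) {
    expect_equal(sum(stratified_proportions(pm, f)$person_months), nrow(pm))
  }
  expect_error(stratified_proportions(pm, "shoe_size"), "valid factors")
})

test_that("a single fully engaged patient reports 100% in every level", {
  p <- make_patient(id = "solo",
                    cd4 = data.frame(day = c(0, 50), value = c(420, 400)))
  pm <- pm_for(list(p))
  tab <- stratified_proportions(pm, "gender")
  expect_true(all(tab$percent_in_care[tab$person_months > 0] == 100))
  expect_true(all(tab$person_months[tab$level != "other_unknown"] == 0))
})

test_that("the estimating-equation fit matches glm plus a cluster sandwich under independence", {
  set.seed(51)
  d <- simulate_pm_rows(60, 10, -0.3, log(2))
  fit <- gee_logit(in_care ~ on_art, id = d$patient_id, data = d,
                   corstr = "independence")
  ref <- glm(in_care ~ on_art, binomial, d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  skip_if_not_installed("sandwich")
  vc <- sandwich::vcovCL(ref, cluster = d$patient_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(fit$vcov), unname(vc), tolerance = 1e-8)
})

test_that("the unadjusted odds ratio agrees with the closed-form 2x2 table", {
  set.seed(52)
  d <- simulate_pm_rows(80, 12, 0.2, log(1.8))
  tab <- table(d$on_art, d$in_care)
  or_2x2 <- (tab["yes", "1"] * tab["no", "0"]) /
    (tab["yes", "0"] * tab["no", "1"])

  fit_ind <- gee_logit(in_care ~ on_art, id = d$patient_id, data = d,
                       corstr = "independence")
  expect_equal(exp(unname(coef(fit_ind)[2])), unname(or_2x2),
               tolerance = 1e-8)

  # the exchangeable fit reweights clusters but stays close
  res <- fit_association_model(d, "on_art")
  expect_equal(res$or[res$level == "yes"], unname(or_2x2), tolerance = 0.05)
  expect_equal(res$or[res$reference], 1)
  expect_true(all(res$ci_low[!res$reference] < res$or[!res$reference]))
  expect_true(all(res$ci_high[!res$reference] > res$or[!res$reference]))
})

test_that("degenerate model inputs fail with diagnostics rather than silent output", {
  set.seed(53)
  d <- simulate_pm_rows(40, 8, 0, log(2))
  d1 <- d[d$patient_id == "p001", ]
  expect_error(fit_association_model(d1, "on_art"), "two patients")
  d$on_art[] <- "yes"
  expect_error(fit_association_model(d, "on_art"), "two observed levels")

  sep <- tibble::tibble(
    patient_id = rep(sprintf("p%02d", 1:20), each = 6),
    on_art = factor(rep(c("no", "yes"), each = 60), c("no", "yes")),
    in_care = rep(c(0L, 1L), each = 60))
  expect_error(gee_logit(in_care ~ on_art, id = sep$patient_id, data = sep),
               "separation")
})

test_that("rows with missing covariates are dropped from models with a logged count", {
  set.seed(54)
  d <- simulate_pm_rows(30, 6, 0, log(2))
  d$on_art[1:7] <- NA
  res <- fit_association_model(d, "on_art")
  expect_equal(unname(attr(res, "meta")$n_dropped["on_art"]), 7)
  expect_equal(sum(res$person_months), nrow(d) - 7)
})
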