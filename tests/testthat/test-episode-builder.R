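test_that("month_index implements 30.4-day months anchored at entry", {
  e <- as.Date("2004-01-05")
  expect_identical(month_index(e, e), 0L)
  expect_identical(month_index(e + 30, e), 0L)
  expect_identical(month_index(e + 31, e), 1L)
  expect_identical(month_index(e + 122, e), 4L)
  expect_error(month_index(e - 1, e), "precedes entry")
})

test_that("the worked-example patient yields episodes at months 0, 4, 9, 12 and 13 with the expected state", {
  ep <- build_episodes(worked_example_patient())
  expect_equal(ep$month_index, c(0L, 4L, 9L, 12L, 13L))

  expect_equal(ep$lowest_cd4, c(420, 370, 370, 370, 420))
  expect_equal(ep$cd4_carried, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(ep$cd4_drop, c(NA, 50, NA, NA, -50))
  expect_equal(ep$highest_vl, c(10000, 10000, 10000, 10000, 50))
  expect_equal(ep$vl_carried, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(ep$vl_below_detection[5], TRUE)
  expect_equal(ep$on_art, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(ep$started_art, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ep$within_month_of_diagnosis,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("several same-month measurements collapse into one episode using the lowest CD4", {
  p <- make_patient(cd4 = data.frame(day = c(0, 10, 40), value = c(500, 370,
                                                                   450)))
  ep <- build_episodes(p)
  expect_equal(nrow(ep), 2L)
  expect_equal(ep$lowest_cd4[1], 370)    # min of the month-0 cluster
  expect_equal(ep$cd4_drop[2], 370 - 450) # against previous measured value
})

test_that("blips require the preceding measured viral load to be suppressed", {
  on_art <- function(vls, below = FALSE) {
    make_patient(vl = data.frame(day = c(0, 70), value = vls, below = below),
                 cd4 = data.frame(day = c(0, 70), value = c(420, 420)),
                 art_start_day = 0)
  }
  expect_true(build_episodes(on_art(c(45, 120)))$vl_is_blip[2])
  expect_false(build_episodes(on_art(c(400, 120)))$vl_is_blip[2])
  # a "<50" below-detection report counts as suppressed
  expect_true(build_episodes(on_art(c(50, 120),
                                    below = c(TRUE, FALSE)))$vl_is_blip[2])
  # carried-forward viral loads never create blips
  p <- make_patient(vl = data.frame(day = c(0, 70), value = c(45, 120)),
                    hb_days = 130, art_start_day = 0)
  ep <- build_episodes(p)
  expect_true(ep$vl_carried[3])
  expect_false(ep$vl_is_blip[3])
})

test_that("episode count never exceeds distinct attendance dates and clusters collapse", {
  set.seed(20)
  for (i in 1:50) {
    days <- sort(sample(0:400, sample(2:12, 1)))
    p <- make_patient(cd4 = data.frame(day = days,
                                       value = round(runif(length(days), 100,
                                                           900))))
    ep <- build_episodes(p)
    expect_lte(nrow(ep), length(unique(days)))
    expect_false(is.unsorted(ep$month_index, strictly = TRUE))
    expect_identical(ep$month_index[1], 0L)
  }
  # any cluster inside one 30.4-day month is exactly one episode
  p <- make_patient(cd4 = data.frame(day = c(0, 3, 11, 29), value = 500),
                    hb_days = 61)
  expect_equal(build_episodes(p)$month_index, c(0L, 2L))
})

test_that("swapping consecutive CD4 values negates the drop", {
  drop_of <- function(v1, v2) {
    p <- make_patient(cd4 = data.frame(day = c(0, 61), value = c(v1, v2)))
    build_episodes(p)$cd4_drop[2]
  }
  for (pair in list(c(500, 380), c(250, 700), c(400, 400))) {
    expect_equal(drop_of(pair[1], pair[2]), -drop_of(pair[2], pair[1]))
  }
})

test_that("carry-forward fills lab-free episodes without generating drops", {
  p <- make_patient(cd4 = data.frame(day = 0, value = 600),
                    vl = data.frame(day = 0, value = 30000),
                    hb_days = c(70, 160))
  ep <- build_episodes(p)
  expect_equal(ep$lowest_cd4, c(600, 600, 600))
  expect_equal(ep$cd4_carried, c(FALSE, TRUE, TRUE))
  expect_true(all(is.na(ep$cd4_drop)))
  expect_equal(ep$highest_vl, c(30000, 30000, 30000))
  # no labs at all: state stays undefined, flagged by NA
  q <- make_patient(hb_days = c(0, 70))
  epq <- build_episodes(q)
  expect_true(all(is.na(epq$lowest_cd4)))
  expect_true(all(is.na(epq$highest_vl)))
})

test_that("a switch on the ART start date is treated as a start only", {
  p <- make_patient(cd4 = data.frame(day = c(0, 95), value = c(300, 320)),
                    art_start_day = 95, art_switch_days = 95)
  ep <- build_episodes(p)
  expect_true(ep$started_art[2])
  expect_false(ep$started_combination[2])
  # a genuinely later switch does fire
  q <- make_patient(cd4 = data.frame(day = c(0, 95), value = c(300, 320)),
                    art_start_day = 0, art_switch_days = 95)
  expect_true(build_episodes(q)$started_combination[2])
})

test_that("the AIDS flag is scoped to the diagnosis month unless configured persistent", {
  p <- make_patient(cd4 = data.frame(day = c(0, 70, 140), value = 400),
                    aids_day = 70)
  expect_equal(build_episodes(p)$aids_event, c(FALSE, TRUE, FALSE))
  cfg <- eic_rule_config(aids_persistent = TRUE)
  expect_equal(build_episodes(p, cfg)$aids_event, c(FALSE, TRUE, TRUE))
})
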