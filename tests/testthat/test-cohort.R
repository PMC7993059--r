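test_that("reading a cohort merges same-day rows and validates input", {
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "visits.csv")
  pp <- file.path(dir, "patients.csv")
  writeLines(c(
    "patient_id,date,biomarker,value",
    "p1,2012-01-02,sodium,138",
    "p1,2012-01-02,potassium,4.5",
    "p1,2012-01-16,sodium,140",
    "p2,2012-03-01,sodium,136",
    "p2,2012-03-15,sodium,137"
  ), vp)
  writeLines(c(
    "patient_id,sex,diabetic,birth_date,event_type,event_date",
    "p1,M,TRUE,1950-05-01,death,2012-06-01",
    "p2,F,FALSE,1948-02-11,censored,2012-07-01"
  ), pp)
  co <- read_cohort(vp, pp)
  counts <- dplyr::count(dplyr::distinct(co$visits, patient_id, date),
                         patient_id)
  expect_equal(counts$n, c(2L, 2L))
  # same patient+date, two biomarkers -> one visit record
  day1 <- dplyr::filter(co$visits, patient_id == "p1",
                        date == as.Date("2012-01-02"))
  expect_setequal(day1$biomarker, c("sodium", "potassium"))

  # unparseable date reported with row context
  writeLines(c("patient_id,date,biomarker,value",
               "p1,notadate,sodium,138"), vp)
  expect_error(read_cohort(vp, pp), "unparseable date")
  # non-numeric value
  writeLines(c("patient_id,date,biomarker,value",
               "p1,2012-01-02,sodium,abc"), vp)
  expect_error(read_cohort(vp, pp), "non-numeric value")
  # visit patient missing from patient table
  writeLines(c("patient_id,date,biomarker,value",
               "p9,2012-01-02,sodium,138"), vp)
  expect_error(read_cohort(vp, pp), "p9")
})

test_that("conflicting duplicate measurements are rejected, exact ones merged", {
  d0 <- as.Date("2015-01-01")
  pat <- tibble::tibble(patient_id = "x", sex = "M", diabetic = FALSE,
                        birth_date = as.Date("1950-01-01"),
                        event_type = "censored", event_date = d0 + 30)
  vis <- tibble::tibble(patient_id = "x", date = d0,
                        biomarker = c("sodium", "sodium"),
                        value = c(138, 139))
  expect_error(new_cohort(vis, pat), "conflicting duplicate")
  vis$value <- c(138, 138)
  expect_equal(nrow(new_cohort(vis, pat)$visits), 1L)
})

test_that("entry filters implement the exclusion cascade", {
  co <- tiny_cohort()
  cfg <- cohort_filter_config(initial_exclusion_days = 30, min_visits = 3)
  out <- apply_entry_filters(co, cfg, required_markers = "sodium")
  # patient a: visits at days 0,14,28 fall inside 30 days -> 3 retained
  a_dates <- dplyr::distinct(out$visits, patient_id, date) |>
    dplyr::filter(patient_id == "a")
  expect_equal(nrow(a_dates), 3L)
  # patient b: left with 2 visits -> excluded under min_visits = 3
  expect_false("b" %in% out$patients$patient_id)
  rep <- exclusion_report(out)
  expect_equal(rep$rule, c("initial_exclusion_window", "min_visits",
                           "incomplete_biomarker_panel"))
  expect_equal(rep$n_patients, c(0L, 1L, 0L))
  # counts sum: in = out + per-rule exclusions
  expect_equal(n_patients(co), n_patients(out) + sum(rep$n_patients))
})

test_that("entry filters: planted violations are counted exactly (oracle)", {
  set.seed(401)
  d0 <- as.Date("2014-06-01")
  n <- 50
  specs <- tibble::tibble(
    patient_id = sprintf("s%02d", 1:n),
    # visits start this many days after first dialysis
    n_late = sample(2:8, n, replace = TRUE),
    missing_marker = seq_len(n) %% 10 == 0   # every 10th lacks potassium
  )
  visits <- purrr::pmap(specs, function(patient_id, n_late, missing_marker) {
    days <- c(0, 30, 60, 90, seq(200, by = 30, length.out = n_late))
    v <- tibble::tibble(patient_id = patient_id, date = d0 + days,
                        biomarker = "sodium", value = rnorm(length(days), 138))
    if (!missing_marker) {
      v <- dplyr::bind_rows(v, dplyr::mutate(v, biomarker = "potassium",
                                             value = 4.5))
    }
    v
  }) |> dplyr::bind_rows()
  patients <- tibble::tibble(
    patient_id = specs$patient_id, sex = "M", diabetic = FALSE,
    birth_date = as.Date("1950-01-01"), event_type = "censored",
    event_date = d0 + 5000
  )
  co <- new_cohort(visits, patients)
  cfg <- cohort_filter_config(initial_exclusion_days = 183, min_visits = 3)
  out <- apply_entry_filters(co, cfg,
                             required_markers = c("sodium", "potassium"))
  # oracle: after dropping days < 183, remaining visits = n_late; all
  # n_late >= 2 patients... those with n_late < 3 go at rule 2; of the
  # rest, every 10th lacks potassium
  gone_rule2 <- specs$patient_id[specs$n_late < 3]
  gone_rule3 <- setdiff(specs$patient_id[specs$missing_marker], gone_rule2)
  rep <- exclusion_report(out)
  expect_equal(rep$n_patients[rep$rule == "min_visits"],
               length(gone_rule2))
  expect_equal(rep$n_patients[rep$rule == "incomplete_biomarker_panel"],
               length(gone_rule3))
  expect_setequal(out$patients$patient_id,
                  setdiff(specs$patient_id, c(gone_rule2, gone_rule3)))
})

test_that("filtering is idempotent and never edits values", {
  co <- tiny_cohort()
  cfg <- cohort_filter_config(initial_exclusion_days = 30, min_visits = 2)
  once <- apply_entry_filters(co, cfg, required_markers = "sodium")
  twice <- apply_entry_filters(once, cfg, required_markers = "sodium")
  expect_equal(twice$visits, once$visits)
  expect_equal(twice$patients, once$patients)
  # values of surviving visits are untouched
  joined <- dplyr::inner_join(once$visits, co$visits,
                              by = c("patient_id", "date", "biomarker"))
  expect_equal(joined$value.x, joined$value.y)
})

test_that("loss-to-follow-up subsets drop only late-gap deceased patients", {
  d0 <- as.Date("2016-01-01")
  visits <- tibble::tibble(
    patient_id = rep(c("dead45", "cens400"), each = 2),
    date = c(d0, d0 + 55, d0, d0 + 100),
    biomarker = "sodium", value = 138
  )
  patients <- tibble::tibble(
    patient_id = c("dead45", "cens400"),
    sex = "M", diabetic = FALSE, birth_date = as.Date("1950-01-01"),
    event_type = c("death", "censored"),
    event_date = c(d0 + 100, d0 + 500)   # gaps: 45 (death), 400 (censor)
  )
  co <- new_cohort(visits, patients)
  expect_false("dead45" %in%
                 apply_followup_subset(co, 30)$patients$patient_id)
  expect_true("dead45" %in%
                apply_followup_subset(co, 60)$patients$patient_id)
  # censored patients retained under every cutoff
  for (cut in c(30, 60, 90, 183, 365)) {
    expect_true("cens400" %in%
                  apply_followup_subset(co, cut)$patients$patient_id)
  }
  expect_error(apply_followup_subset(co, 45), "30, 60, 90, 183, 365")
})

test_that("transplant subset enforces the two-year quiet period", {
  d0 <- as.Date("2016-01-01")
  visits <- tibble::tibble(
    patient_id = rep(c("tx_visit", "tx_death", "tx_ok"), each = 2),
    date = rep(c(d0, d0 + 30), 3),
    biomarker = "sodium", value = 138
  )
  # tx_visit resumes dialysis 100 days after transplant
  visits <- dplyr::add_row(visits, patient_id = "tx_visit",
                           date = d0 + 60 + 100, biomarker = "sodium",
                           value = 139)
  patients <- tibble::tibble(
    patient_id = c("tx_visit", "tx_death", "tx_ok"),
    sex = "F", diabetic = TRUE, birth_date = as.Date("1955-01-01"),
    event_type = "transplant",
    event_date = d0 + 60,
    death_date = as.Date(c(NA, NA, NA))
  )
  patients$death_date[2] <- d0 + 60 + 400   # dies 400 d post-transplant
  co <- new_cohort(visits, patients)
  out <- apply_transplant_subset(co, quiet_days = 730)
  expect_equal(out$patients$patient_id, "tx_ok")
  # post-transplant visits are not carried into the analysis set
  expect_true(all(out$visits$date <= d0 + 60))
  # missing transplant date is an error
  patients$event_date[3] <- as.Date(NA)
  co2 <- new_cohort(visits, patients)
  expect_error(apply_transplant_subset(co2), "missing transplant date")
})

test_that("age subset uses age at last data collection", {
  d0 <- as.Date("2016-01-01")
  visits <- tibble::tibble(
    patient_id = rep(c("young", "old"), each = 2),
    date = rep(c(d0, d0 + 14), 2),
    biomarker = "sodium", value = 138
  )
  patients <- tibble::tibble(
    patient_id = c("young", "old"), sex = "M", diabetic = FALSE,
    # ages at last visit: ~60 and ~70
    birth_date = c(d0 - round(60 * 365.25), d0 - round(70 * 365.25)),
    event_type = "censored", event_date = d0 + 100
  )
  co <- new_cohort(visits, patients)
  expect_equal(apply_age_subset(co, 65)$patients$patient_id, "old")
})
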