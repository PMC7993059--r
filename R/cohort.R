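#' Longitudinal biomarker cohorts
#'
#' A cohort bundles two tibbles: `visits`, the long-format record of blood
#' sampling visits (`patient_id`, `date`, `biomarker`, `value`), and
#' `patients`, one row of metadata and outcome per patient (`patient_id`,
#' `sex`, `diabetic`, `birth_date`, `event_type`, `event_date`, and the
#' optional columns `death_date` and `first_dialysis_date`). `event_type` is
#' one of `"death"`, `"censored"`, `"transplant"`; `event_date` is the death
#' date, last-contact date, or transplant date respectively.
#'
#' Visits are stored sorted by patient and date, with at most one row per
#' (patient, date, biomarker). For deceased and censored patients the event
#' date must be on or after the last visit; transplant patients may carry
#' dialysis visits *after* the transplant date — that is exactly what
#' [apply_transplant_subset()] screens for.
#'
#' @param visits A data frame of visit rows (`patient_id`, `date`,
#'   `biomarker`, `value`).
#' @param patients A data frame with one row per patient.
#' @return An object of class `mmd_cohort`: a list with elements `visits`
#'   and `patients`, both tibbles.
#' @export
#' @examples
#' cohort <- new_cohort(
#'   visits = data.frame(
#'     patient_id = "p1",
#'     date = as.Date("2010-01-01") + c(0, 0, 14, 14),
#'     biomarker = c("sodium", "potassium", "sodium", "potassium"),
#'     value = c(138, 4.7, 140, 4.9)
#'   ),
#'   patients = data.frame(
#'     patient_id = "p1", sex = "M", diabetic = TRUE,
#'     birth_date = as.Date("1950-06-01"),
#'     event_type = "death", event_date = as.Date("2010-03-01")
#'   )
#' )
#' cohort
new_cohort <- function(visits, patients) {
  visits <- tibble::as_tibble(visits)
  patients <- tibble::as_tibble(patients)

  need_v <- c("patient_id", "date", "biomarker", "value")
  need_p <- c("patient_id", "sex", "diabetic", "birth_date",
              "event_type", "event_date")
  miss_v <- setdiff(need_v, names(visits))
  miss_p <- setdiff(need_p, names(patients))
  if (length(miss_v) > 0) {
    stop("visits table is missing columns: ", paste(miss_v, collapse = ", "),
         call. = FALSE)
  }
  if (length(miss_p) > 0) {
    stop("patients table is missing columns: ", paste(miss_p, collapse = ", "),
         call. = FALSE)
  }

  visits <- dplyr::mutate(
    visits,
    patient_id = as.character(.data$patient_id),
    date = as.Date(.data$date),
    biomarker = as.character(.data$biomarker),
    value = as.double(.data$value)
  )
  patients <- dplyr::mutate(
    patients,
    patient_id = as.character(.data$patient_id),
    sex = as.character(.data$sex),
    diabetic = as.logical(.data$diabetic),
    birth_date = as.Date(.data$birth_date),
    event_type = as.character(.data$event_type),
    event_date = as.Date(.data$event_date)
  )
  if (!"death_date" %in% names(patients)) {
    patients$death_date <- as.Date(NA)
  } else {
    patients$death_date <- as.Date(patients$death_date)
  }
  if (!"first_dialysis_date" %in% names(patients)) {
    patients$first_dialysis_date <- as.Date(NA)
  } else {
    patients$first_dialysis_date <- as.Date(patients$first_dialysis_date)
  }

  bad_type <- setdiff(unique(patients$event_type),
                      c("death", "censored", "transplant"))
  if (length(bad_type) > 0) {
    stop("unknown event_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(patients$patient_id)) {
    stop("patients table has duplicated patient ids", call. = FALSE)
  }

  orphans <- setdiff(unique(visits$patient_id), patients$patient_id)
  if (length(orphans) > 0) {
    stop("patients present in visits but absent from the patient table: ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) " ..." else "", call. = FALSE)
  }

  dup <- dplyr::count(visits, .data$patient_id, .data$date, .data$biomarker)
  dup <- dplyr::filter(dup, .data$n > 1)
  if (nrow(dup) > 0) {
    # allow exact duplicates (same value), reject conflicts
    conf <- visits |>
      dplyr::semi_join(dup, by = c("patient_id", "date", "biomarker")) |>
      dplyr::distinct(.data$patient_id, .data$date, .data$biomarker,
                      .data$value) |>
      dplyr::count(.data$patient_id, .data$date, .data$biomarker) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conf) > 0) {
      ex <- conf[1, ]
      stop("conflicting duplicate measurement for patient ", ex$patient_id,
           ", date ", ex$date, ", biomarker ", ex$biomarker, call. = FALSE)
    }
    visits <- dplyr::distinct(visits, .data$patient_id, .data$date,
                              .data$biomarker, .keep_all = TRUE)
  }

  visits <- dplyr::arrange(visits, .data$patient_id, .data$date,
                           .data$biomarker)

  last_visit <- visits |>
    dplyr::summarise(last = max(.data$date), .by = "patient_id")
  chk <- patients |>
    dplyr::inner_join(last_visit, by = "patient_id") |>
    dplyr::filter(.data$event_type != "transplant",
                  .data$event_date < .data$last)
  if (nrow(chk) > 0) {
    stop("event_date precedes last visit for patient(s): ",
         paste(utils::head(chk$patient_id, 10), collapse = ", "),
         call. = FALSE)
  }

  structure(list(visits = visits, patients = patients),
            class = "mmd_cohort")
}

#' @export
print.mmd_cohort <- function(x, ...) {
  n_p <- nrow(x$patients)
  n_v <- dplyr::n_distinct(x$visits$patient_id, x$visits$date)
  n_m <- dplyr::n_distinct(x$visits$biomarker)
  cat("<mmd_cohort> ", n_p, " patients, ", n_v, " visits, ",
      n_m, " biomarkers\n", sep = "")
  tab <- table(x$patients$event_type)
  cat("  outcomes:",
      paste(names(tab), unname(tab), sep = "=", collapse = ", "), "\n")
  rep <- attr(x, "exclusion_report")
  if (!is.null(rep)) {
    cat("  exclusion report attached (", nrow(rep), " rules); see ",
        "exclusion_report()\n", sep = "")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `mmd_cohort`.
#' @return Integer count of patients.
#' @export
n_patients <- function(cohort) nrow(cohort$patients)

#' Read a cohort from delimited text files
#'
#' Reads the visits and patients tables from CSV (UTF-8, ISO-8601 dates) and
#' assembles a validated [new_cohort()]. Rows with the same
#' (patient, date) are merged into one visit record; a conflicting duplicate
#' (same patient, date and biomarker but different values) is an error.
#'
#' @param visits_path Path to the visits CSV with columns
#'   `patient_id,date,biomarker,value`.
#' @param patients_path Path to the patients CSV with columns
#'   `patient_id,sex,diabetic,birth_date,event_type,event_date` and the
#'   optional `death_date`, `first_dialysis_date`.
#' @return An `mmd_cohort`.
#' @export
read_cohort <- function(visits_path, patients_path) {
  for (p in c(visits_path, patients_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  visits <- readr::read_csv(
    visits_path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_character(),
      biomarker = readr::col_character(),
      value = readr::col_character()
    ),
    progress = FALSE
  )
  # parse manually so bad rows can be reported with line context
  d <- as.Date(visits$date, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(visits$date))
  if (length(bad) > 0) {
    stop("unparseable date in ", visits_path, " at data row ", bad[1],
         ": '", visits$date[bad[1]], "'", call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(visits$value))
  bad <- which(is.na(v) & !is.na(visits$value))
  if (length(bad) > 0) {
    stop("non-numeric value in ", visits_path, " at data row ", bad[1],
         ": '", visits$value[bad[1]], "'", call. = FALSE)
  }
  visits$date <- d
  visits$value <- v

  patients <- readr::read_csv(
    patients_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  for (col in intersect(c("birth_date", "event_date", "death_date",
                          "first_dialysis_date"), names(patients))) {
    d <- as.Date(patients[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(d) & !is.na(patients[[col]]))
    if (length(bad) > 0) {
      stop("unparseable date in ", patients_path, " column ", col,
           " at data row ", bad[1], call. = FALSE)
    }
    patients[[col]] <- d
  }
  if ("diabetic" %in% names(patients)) {
    patients$diabetic <- as.logical(patients$diabetic)
  }
  new_cohort(visits, patients)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: emits the visits and patients tibbles as CSV
#' with ISO-8601 dates. A cohort round-trips losslessly through
#' `write_cohort()` / `read_cohort()`.
#'
#' @param cohort An `mmd_cohort`.
#' @param visits_path,patients_path Output file paths.
#' @return `cohort`, invisibly.
#' @export
write_cohort <- function(cohort, visits_path, patients_path) {
  readr::write_csv(cohort$visits, visits_path, progress = FALSE)
  readr::write_csv(cohort$patients, patients_path, progress = FALSE)
  invisible(cohort)
}

#' Cohort filter settings
#'
#' Collects the entry-filter and subset parameters used by
#' [apply_entry_filters()] and friends. Time quantities are calendar days:
#' "6 months" is fixed at 183 days, "2 years" at 730 days.
#'
#' @param initial_exclusion_days Days after first dialysis to discard
#'   (dialysis initiation is itself a critical transition; default 183).
#' @param min_visits Minimum remaining visits to keep a patient (default 3).
#' @param lost_followup_cutoff_days Optional cutoff in
#'   `c(30, 60, 90, 183, 365)` for the loss-to-follow-up subsets, or `NULL`.
#' @param transplant_quiet_days Quiet period after transplant with no
#'   dialysis visit and no death (default 730).
#' @param age_floor_years Optional age floor (65 for the elderly subset).
#' @param trend_horizon_years Years before the event considered in trend
#'   tables (default 5).
#' @return A list of class `cohort_filter_config`.
#' @export
cohort_filter_config <- function(initial_exclusion_days = 183,
                                 min_visits = 3,
                                 lost_followup_cutoff_days = NULL,
                                 transplant_quiet_days = 730,
                                 age_floor_years = NULL,
                                 trend_horizon_years = 5) {
  stopifnot(initial_exclusion_days > 0, min_visits > 0,
            transplant_quiet_days > 0, trend_horizon_years > 0)
  if (!is.null(lost_followup_cutoff_days) &&
      !lost_followup_cutoff_days %in% c(30, 60, 90, 183, 365)) {
    stop("lost_followup_cutoff_days must be one of 30, 60, 90, 183, 365",
         call. = FALSE)
  }
  if (!is.null(age_floor_years)) stopifnot(age_floor_years > 0)
  structure(
    list(initial_exclusion_days = initial_exclusion_days,
         min_visits = min_visits,
         lost_followup_cutoff_days = lost_followup_cutoff_days,
         transplant_quiet_days = transplant_quiet_days,
         age_floor_years = age_floor_years,
         trend_horizon_years = trend_horizon_years),
    class = "cohort_filter_config"
  )
}

keep_patients <- function(cohort, ids) {
  cohort$visits <- dplyr::filter(cohort$visits, .data$patient_id %in% ids)
  cohort$patients <- dplyr::filter(cohort$patients, .data$patient_id %in% ids)
  cohort
}

#' Apply the cohort entry filters
#'
#' Runs the sequential exclusion cascade: (1) drop each patient's visits
#' falling in the first `initial_exclusion_days` after their first dialysis
#' date (taken as the first observed visit when `first_dialysis_date` is
#' absent), (2) drop patients left with fewer than `min_visits` visits,
#' (3) drop patients for whom some required biomarker was never observed.
#' Each excluded patient is counted once, at the first rule that removed
#' them; the per-rule counts therefore sum to patients in minus patients out.
#'
#' @param cohort An `mmd_cohort`.
#' @param config A [cohort_filter_config()].
#' @param required_markers Character vector of biomarkers each retained
#'   patient must have at least one measurement of. Defaults to
#'   [builtin_markers()] intersected with the biomarkers present in the
#'   cohort, so panels other than the built-in one are not penalised.
#' @return The filtered `mmd_cohort`, with the exclusion report attached as
#'   an attribute; retrieve it with [exclusion_report()]. Filtering only
#'   changes membership, never a biomarker value, and is idempotent.
#' @export
apply_entry_filters <- function(cohort, config = cohort_filter_config(),
                                required_markers = NULL) {
  stopifnot(inherits(cohort, "mmd_cohort"))
  if (is.null(required_markers)) {
    required_markers <- intersect(builtin_markers(),
                                  unique(cohort$visits$biomarker))
  }
  n_pat_in <- nrow(cohort$patients)
  report <- tibble::tibble(rule = character(), n_patients = integer(),
                           n_visits = integer())

  # rule 1: initial exclusion window after first dialysis
  first_dial <- cohort$visits |>
    dplyr::summarise(first_visit = min(.data$date), .by = "patient_id") |>
    dplyr::left_join(
      dplyr::select(cohort$patients, "patient_id", "first_dialysis_date"),
      by = "patient_id"
    ) |>
    dplyr::mutate(fd = dplyr::coalesce(.data$first_dialysis_date,
                                       .data$first_visit))
  # record the anchor actually used, so re-filtering is idempotent
  cohort$patients <- cohort$patients |>
    dplyr::select(-"first_dialysis_date") |>
    dplyr::left_join(dplyr::select(first_dial, "patient_id",
                                   first_dialysis_date = "fd"),
                     by = "patient_id")
  v <- cohort$visits |>
    dplyr::left_join(dplyr::select(first_dial, "patient_id", "fd"),
                     by = "patient_id")
  drop_rows <- as.integer(v$date - v$fd) < config$initial_exclusion_days
  n_visit_cut <- dplyr::n_distinct(v$patient_id[drop_rows],
                                   v$date[drop_rows])
  cohort$visits <- dplyr::select(v[!drop_rows, ], -"fd")
  gone1 <- setdiff(cohort$patients$patient_id,
                   unique(cohort$visits$patient_id))
  cohort <- keep_patients(cohort, unique(cohort$visits$patient_id))
  report <- dplyr::add_row(report, rule = "initial_exclusion_window",
                           n_patients = length(gone1),
                           n_visits = as.integer(n_visit_cut))

  # rule 2: minimum visit count
  counts <- cohort$visits |>
    dplyr::distinct(.data$patient_id, .data$date) |>
    dplyr::count(.data$patient_id)
  keep2 <- counts$patient_id[counts$n >= config$min_visits]
  gone2 <- setdiff(cohort$patients$patient_id, keep2)
  n_visit2 <- sum(counts$n[counts$patient_id %in% gone2])
  cohort <- keep_patients(cohort, keep2)
  report <- dplyr::add_row(report, rule = "min_visits",
                           n_patients = length(gone2),
                           n_visits = as.integer(n_visit2))

  # rule 3: required biomarkers never observed
  if (length(required_markers) > 0) {
    seen <- cohort$visits |>
      dplyr::filter(.data$biomarker %in% required_markers) |>
      dplyr::distinct(.data$patient_id, .data$biomarker) |>
      dplyr::count(.data$patient_id)
    keep3 <- seen$patient_id[seen$n == length(required_markers)]
  } else {
    keep3 <- cohort$patients$patient_id
  }
  gone3 <- setdiff(cohort$patients$patient_id, keep3)
  n_visit3 <- cohort$visits |>
    dplyr::filter(.data$patient_id %in% gone3) |>
    dplyr::distinct(.data$patient_id, .data$date) |>
    nrow()
  cohort <- keep_patients(cohort, keep3)
  report <- dplyr::add_row(report, rule = "incomplete_biomarker_panel",
                           n_patients = length(gone3),
                           n_visits = as.integer(n_visit3))

  report$n_patients_remaining <- n_pat_in - cumsum(report$n_patients)
  if (nrow(cohort$patients) == 0) {
    warning("entry filters removed every patient; the cohort is empty",
            call. = FALSE)
  }
  attr(cohort, "exclusion_report") <- report
  cohort
}

#' Retrieve the exclusion report attached by [apply_entry_filters()]
#' @param cohort A filtered `mmd_cohort`.
#' @return A tibble with columns `rule`, `n_patients`, `n_visits`,
#'   `n_patients_remaining`, or `NULL` if no filter has been applied.
#' @export
exclusion_report <- function(cohort) attr(cohort, "exclusion_report")

#' Loss-to-follow-up subset
#'
#' Drops deceased patients whose last visit is more than `cutoff_days`
#' before their death date; censored and transplant patients are untouched
#' (the rule concerns days preceding the date of death only).
#'
#' @param cohort An `mmd_cohort`.
#' @param cutoff_days One of 30, 60, 90, 183, 365.
#' @return The subset `mmd_cohort`.
#' @export
apply_followup_subset <- function(cohort, cutoff_days) {
  stopifnot(inherits(cohort, "mmd_cohort"))
  if (!cutoff_days %in% c(30, 60, 90, 183, 365)) {
    stop("cutoff_days must be one of 30, 60, 90, 183, 365", call. = FALSE)
  }
  last_visit <- cohort$visits |>
    dplyr::summarise(last = max(.data$date), .by = "patient_id")
  gap <- cohort$patients |>
    dplyr::left_join(last_visit, by = "patient_id") |>
    dplyr::mutate(drop = .data$event_type == "death" &
                    as.integer(.data$event_date - .data$last) > cutoff_days)
  keep_patients(cohort, gap$patient_id[!gap$drop])
}

#' Kidney-transplant subset
#'
#' Returns the transplant patients who had no dialysis visit and did not die
#' within `quiet_days` (default 730, i.e. 2 years) after the transplant
#' date. `event_date` is the transplant date for these patients; a death
#' after transplant, if known, is carried in the optional `death_date`
#' column.
#'
#' @param cohort An `mmd_cohort`.
#' @param quiet_days Length of the post-transplant quiet period in days.
#' @return The subset `mmd_cohort` containing only qualifying transplant
#'   patients.
#' @export
apply_transplant_subset <- function(cohort, quiet_days = 730) {
  stopifnot(inherits(cohort, "mmd_cohort"))
  tx <- dplyr::filter(cohort$patients, .data$event_type == "transplant")
  if (any(is.na(tx$event_date))) {
    stop("transplant patient(s) missing transplant date: ",
         paste(tx$patient_id[is.na(tx$event_date)], collapse = ", "),
         call. = FALSE)
  }
  post_visit <- cohort$visits |>
    dplyr::inner_join(dplyr::select(tx, "patient_id", tx_date = "event_date"),
                      by = "patient_id") |>
    dplyr::filter(.data$date > .data$tx_date,
                  as.integer(.data$date - .data$tx_date) <= quiet_days) |>
    dplyr::distinct(.data$patient_id)
  died_soon <- tx$patient_id[
    !is.na(tx$death_date) &
      as.integer(tx$death_date - tx$event_date) <= quiet_days
  ]
  keep <- setdiff(tx$patient_id, union(post_visit$patient_id, died_soon))
  out <- keep_patients(cohort, keep)
  # post-transplant visits are not analysis visits
  out$visits <- out$visits |>
    dplyr::left_join(dplyr::select(tx, "patient_id", tx_date = "event_date"),
                     by = "patient_id") |>
    dplyr::filter(.data$date <= .data$tx_date) |>
    dplyr::select(-"tx_date")
  out
}

#' Elderly subset (age at last data collection)
#'
#' Keeps patients aged at least `age_floor_years` at their last visit,
#' computed from `birth_date` with 365.25-day years.
#'
#' @param cohort An `mmd_cohort`.
#' @param age_floor_years Age floor in years (default 65).
#' @return The subset `mmd_cohort`.
#' @export
apply_age_subset <- function(cohort, age_floor_years = 65) {
  stopifnot(inherits(cohort, "mmd_cohort"), age_floor_years > 0)
  last_visit <- cohort$visits |>
    dplyr::summarise(last = max(.data$date), .by = "patient_id")
  age <- cohort$patients |>
    dplyr::inner_join(last_visit, by = "patient_id") |>
    dplyr::mutate(age = as.numeric(.data$last - .data$birth_date) / 365.25)
  keep_patients(cohort, age$patient_id[age$age >= age_floor_years])
}
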