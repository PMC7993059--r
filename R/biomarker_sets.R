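#' Built-in biomarker names
#'
#' The 16 routinely measured blood biomarkers of the hemodialysis panel, in
#' the fixed order used for covariance indexing: the 11 biomarkers drawn
#' every two weeks first (hematocrit through white blood cell count), then
#' the monthly four, then albumin (measured every four months).
#'
#' @return Character vector of 16 biomarker names.
#' @export
builtin_markers <- function() {
  c("hematocrit", "hemoglobin", "mch", "mchc", "mcv", "platelets",
    "potassium", "rbc", "rdw", "sodium", "wbc",
    "calcium", "creatinine", "glucose", "phosphate",
    "albumin")
}

# variance-stabilizing transforms; everything else is identity
.log_markers <- c("wbc", "rdw", "glucose")
.sqrt_markers <- c("platelets")

default_transforms <- function(markers) {
  tr <- rep("identity", length(markers))
  tr[markers %in% .log_markers] <- "log"
  tr[markers %in% .sqrt_markers] <- "sqrt"
  stats::setNames(tr, markers)
}

#' Define a biomarker set
#'
#' A biomarker set names an ordered marker panel, the inclusive window (in
#' days) a between-visit gap must fall in for the pair to count as a regular
#' interval, and the per-marker variance-stabilizing transform.
#'
#' @param name Set name.
#' @param markers Ordered character vector of unique biomarker names.
#' @param window_days Length-2 integer vector, inclusive gap window in days.
#' @param transforms Named character vector mapping each marker to one of
#'   `"identity"`, `"log"`, `"sqrt"`. Defaults to the panel convention
#'   (log for WBC, RDW and glucose; square root for platelets).
#' @return A list of class `biomarker_set`.
#' @export
biomarker_set <- function(name, markers, window_days,
                          transforms = default_transforms(markers)) {
  stopifnot(length(markers) > 0, !anyDuplicated(markers),
            length(window_days) == 2, window_days[1] <= window_days[2])
  transforms <- transforms[markers]
  if (any(is.na(transforms)) ||
      !all(transforms %in% c("identity", "log", "sqrt"))) {
    stop("every marker needs exactly one transform in ",
         "{identity, log, sqrt}", call. = FALSE)
  }
  structure(
    list(name = name, markers = markers,
         window_days = as.integer(window_days),
         transforms = transforms),
    class = "biomarker_set"
  )
}

#' @export
print.biomarker_set <- function(x, ...) {
  cat("<biomarker_set> ", x$name, ": ", length(x$markers),
      " markers, gap window [", x$window_days[1], ", ",
      x$window_days[2], "] days\n", sep = "")
  cat("  ", paste(x$markers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' The built-in biomarker sets
#'
#' Returns the six standard sets. Three follow the blood sampling schedule:
#' `two_weeks` (the 11 biomarkers measured every two weeks, gap window
#' 12–16 days), `one_month` (15 biomarkers, window 25–35 days) and
#' `four_months` (all 16 including albumin, window 100–140 days). Three
#' group markers by physiological system: `o2_transport` (7 red-cell
#' markers, window 12–16), `kidney_health` (potassium, sodium, creatinine,
#' albumin; window 100–140 because albumin, its least frequently measured
#' member, sets the interval) and `mbd` (mineral bone disease: calcium and
#' phosphate, window 25–35).
#'
#' MCH, MCHC and MCV are arithmetic combinations of hemoglobin, RBC count
#' and hematocrit; `drop_redundant = TRUE` removes them from any set that
#' contains them (windows unchanged), which is the recommended sensitivity
#' analysis when the pooled covariance is ill-conditioned.
#'
#' @param drop_redundant Remove the redundant MCH/MCHC/MCV trio.
#' @return Named list of [biomarker_set()] objects.
#' @export
builtin_biomarker_sets <- function(drop_redundant = FALSE) {
  m <- builtin_markers()
  sets <- list(
    two_weeks   = biomarker_set("two_weeks", m[1:11], c(12L, 16L)),
    one_month   = biomarker_set("one_month", m[1:15], c(25L, 35L)),
    four_months = biomarker_set("four_months", m, c(100L, 140L)),
    o2_transport = biomarker_set(
      "o2_transport",
      c("hematocrit", "hemoglobin", "mch", "mchc", "mcv", "rbc", "rdw"),
      c(12L, 16L)),
    kidney_health = biomarker_set(
      "kidney_health",
      c("potassium", "sodium", "creatinine", "albumin"),
      c(100L, 140L)),
    mbd = biomarker_set("mbd", c("calcium", "phosphate"), c(25L, 35L))
  )
  if (drop_redundant) {
    redundant <- c("mch", "mchc", "mcv")
    sets <- purrr::map(sets, function(s) {
      kept <- setdiff(s$markers, redundant)
      biomarker_set(s$name, kept, s$window_days, s$transforms[kept])
    })
  }
  sets
}

#' Read biomarker-set definitions from a YAML config
#'
#' Each entry needs `name`, `markers` and `window_days`; `transforms` is an
#' optional marker-to-transform mapping and defaults to the panel
#' convention.
#'
#' @param path Path to a YAML file holding a list of set definitions.
#' @return Named list of [biomarker_set()] objects.
#' @export
read_biomarker_sets <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading set configs requires the 'yaml' package", call. = FALSE)
  }
  defs <- yaml::read_yaml(path)
  sets <- purrr::map(defs, function(d) {
    markers <- as.character(d$markers)
    tr <- default_transforms(markers)
    if (!is.null(d$transforms)) tr[names(d$transforms)] <- unlist(d$transforms)
    biomarker_set(d$name, markers, as.integer(d$window_days), tr)
  })
  stats::setNames(sets, purrr::map_chr(sets, "name"))
}

#' Apply variance-stabilizing transforms
#'
#' Replaces each value by its transform under the set's convention: natural
#' log for the log markers, square root for the square-root markers,
#' untouched otherwise. Markers outside the set pass through unchanged.
#'
#' @param visits Long visit tibble (`patient_id`, `date`, `biomarker`,
#'   `value`).
#' @param set A [biomarker_set()].
#' @return The visits tibble with transformed values.
#' @export
transform_values <- function(visits, set) {
  stopifnot(inherits(set, "biomarker_set"))
  tr <- set$transforms[visits$biomarker]
  tr[is.na(tr)] <- "identity"
  bad_log <- which(tr == "log" & visits$value <= 0)
  if (length(bad_log) > 0) {
    i <- bad_log[1]
    stop("non-positive value for log-transformed marker: patient ",
         visits$patient_id[i], ", date ", visits$date[i], ", marker ",
         visits$biomarker[i], " = ", visits$value[i], call. = FALSE)
  }
  bad_sqrt <- which(tr == "sqrt" & visits$value < 0)
  if (length(bad_sqrt) > 0) {
    i <- bad_sqrt[1]
    stop("negative value for sqrt-transformed marker: patient ",
         visits$patient_id[i], ", date ", visits$date[i], ", marker ",
         visits$biomarker[i], call. = FALSE)
  }
  out <- visits
  is_log <- tr == "log"
  is_sqrt <- tr == "sqrt"
  out$value[is_log] <- log(visits$value[is_log])
  out$value[is_sqrt] <- sqrt(visits$value[is_sqrt])
  out
}

#' Fit population standardization parameters
#'
#' Computes, per marker of the set, the mean and standard deviation (n−1
#' denominator) of the transformed values pooled over the whole cohort —
#' the entire-population reference against which every visit is z-scored.
#'
#' @param visits Long visit tibble of *raw* values; transforms are applied
#'   internally.
#' @param set A [biomarker_set()].
#' @return A tibble (`biomarker`, `mean`, `sd`) in set order, class
#'   `standardization_params`.
#' @export
fit_standardization <- function(visits, set) {
  stopifnot(inherits(set, "biomarker_set"))
  tv <- transform_values(
    dplyr::filter(visits, .data$biomarker %in% set$markers), set)
  params <- tv |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(),
                     .by = "biomarker")
  missing <- setdiff(set$markers, params$biomarker)
  if (length(missing) > 0) {
    stop("no observations for marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(params$n < 2)) {
    stop("fewer than 2 observations for marker(s): ",
         paste(params$biomarker[params$n < 2], collapse = ", "),
         call. = FALSE)
  }
  if (any(params$sd <= 0)) {
    stop("constant marker (zero standard deviation): ",
         paste(params$biomarker[params$sd <= 0], collapse = ", "),
         call. = FALSE)
  }
  params <- params[match(set$markers, params$biomarker),
                   c("biomarker", "mean", "sd")]
  structure(params, class = c("standardization_params", class(params)),
            set_name = set$name)
}

# wide matrix of transformed+standardized eligible visits (all set markers
# present); returns tibble(patient_id, date) + matrix column `x`
standardized_visit_matrix <- function(visits, set, params) {
  tv <- transform_values(
    dplyr::filter(visits, .data$biomarker %in% set$markers), set)
  wide <- tidyr::pivot_wider(tv, id_cols = c("patient_id", "date"),
                             names_from = "biomarker",
                             values_from = "value")
  for (mk in setdiff(set$markers, names(wide))) wide[[mk]] <- NA_real_
  x <- as.matrix(wide[, set$markers, drop = FALSE])
  keep <- stats::complete.cases(x)
  wide <- wide[keep, , drop = FALSE]
  x <- x[keep, , drop = FALSE]
  x <- sweep(x, 2, params$mean, "-")
  x <- sweep(x, 2, params$sd, "/")
  out <- wide[, c("patient_id", "date")]
  out <- dplyr::arrange(out, .data$patient_id, .data$date)
  x <- x[order(wide$patient_id, wide$date), , drop = FALSE]
  out$x <- x
  out
}

#' Build consecutive visit pairs inside the regular-interval window
#'
#' A visit is *eligible* for a set when all of the set's markers were
#' measured; visits missing a marker are skipped and the gap is measured
#' between the remaining neighbours. Each pair of consecutive eligible
#' visits whose gap falls inside the set's inclusive window produces one
#' row; the biomarker vectors are transformed then z-scored against
#' `params`, in set marker order.
#'
#' @param visits Long visit tibble of raw values (one patient or many).
#' @param set A [biomarker_set()].
#' @param params [fit_standardization()] output for the same set.
#' @return A tibble with columns `patient_id`, `date_prev`, `date_curr`,
#'   `gap_days` and two matrix columns `x_prev`, `x_curr` (rows aligned
#'   with the tibble, columns in set marker order). May have zero rows.
#' @export
make_visit_pairs <- function(visits, set, params) {
  stopifnot(inherits(set, "biomarker_set"),
            inherits(params, "standardization_params"))
  sv <- standardized_visit_matrix(visits, set, params)
  p <- length(set$markers)
  if (nrow(sv) == 0) {
    out <- tibble::tibble(patient_id = character(),
                          date_prev = as.Date(character()),
                          date_curr = as.Date(character()),
                          gap_days = integer())
    out$x_prev <- matrix(numeric(0), 0, p, dimnames = list(NULL, set$markers))
    out$x_curr <- matrix(numeric(0), 0, p, dimnames = list(NULL, set$markers))
    attr(out, "markers") <- set$markers
    return(out)
  }
  same <- sv$patient_id == dplyr::lag(sv$patient_id)
  gap <- as.integer(sv$date - dplyr::lag(sv$date))
  ok <- !is.na(same) & same &
    gap >= set$window_days[1] & gap <= set$window_days[2]
  idx <- which(ok)
  out <- tibble::tibble(
    patient_id = sv$patient_id[idx],
    date_prev = sv$date[idx - 1L],
    date_curr = sv$date[idx],
    gap_days = gap[idx]
  )
  out$x_prev <- sv$x[idx - 1L, , drop = FALSE]
  out$x_curr <- sv$x[idx, , drop = FALSE]
  attr(out, "markers") <- set$markers
  out
}
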