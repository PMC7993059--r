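#' Half-year pre-event MMD trend table
#'
#' Averages MMD observations in half-year bins counted back from each
#' patient's anchor date — death for the deceased group, last contact for
#' the censored group, transplant date for the transplant group — out to
#' `horizon_years` before the anchor. A half-year is 182.625 days
#' (365.25-day years); bin 1 is the last half-year before the anchor, with
#' bins right-closed at the anchor. The 95% confidence band is the normal
#' approximation `mean ± 1.96 · SE` (half-width 0 where a bin holds a
#' single observation).
#'
#' @param mmd_tbl Output of [compute_mmd_table()] or [compute_mmd()].
#' @param cohort The `mmd_cohort` the observations came from.
#' @param group One of `"deceased"`, `"censored"`, `"transplant"`.
#' @param horizon_years How many years before the anchor to keep
#'   (default 5).
#' @param bin_days Bin width in days (default 182.625).
#' @return A tibble of class `mmd_trend`: `group`, `bin`, `bin_mid_years`
#'   (years before the anchor at the bin midpoint), `mean_mmd`,
#'   `ci_halfwidth`, `n`.
#' @export
trend_table <- function(mmd_tbl, cohort, group = c("deceased", "censored",
                                                   "transplant"),
                        horizon_years = 5, bin_days = 182.625) {
  if (!is.character(group) || length(group) != 1 ||
      !group %in% c("deceased", "censored", "transplant")) {
    stop("group must be one of 'deceased', 'censored', 'transplant'",
         call. = FALSE)
  }
  stopifnot(inherits(cohort, "mmd_cohort"))
  type <- c(deceased = "death", censored = "censored",
            transplant = "transplant")[[group]]
  anchors <- cohort$patients |>
    dplyr::filter(.data$event_type == type) |>
    dplyr::select("patient_id", anchor = "event_date")
  binned <- mmd_tbl |>
    dplyr::inner_join(anchors, by = "patient_id") |>
    dplyr::mutate(days_before = as.numeric(.data$anchor - .data$date)) |>
    dplyr::filter(.data$days_before >= 0,
                  .data$days_before <= horizon_years * 365.25) |>
    dplyr::mutate(bin = pmax(1, ceiling(.data$days_before / bin_days)))
  out <- binned |>
    dplyr::summarise(
      mean_mmd = mean(.data$mmd),
      ci_halfwidth = if (dplyr::n() > 1) {
        1.96 * stats::sd(.data$mmd) / sqrt(dplyr::n())
      } else 0,
      n = dplyr::n(),
      .by = "bin"
    ) |>
    dplyr::arrange(.data$bin) |>
    dplyr::mutate(group = group,
                  bin_mid_years = (.data$bin - 0.5) * bin_days / 365.25,
                  .before = 1) |>
    dplyr::relocate("group", "bin", "bin_mid_years")
  class(out) <- c("mmd_trend", class(out))
  out
}

#' Plot a pre-event MMD trend
#'
#' Mean MMD per half-year bin with its 95% band, time running toward the
#' anchor (death/last contact/transplant) at the right.
#'
#' @param object An `mmd_trend` (rows from several groups may be bound
#'   together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mmd_trend <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = -.data$bin_mid_years, y = .data$mean_mmd,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_mmd -
                                        .data$ci_halfwidth,
                                      ymax = .data$mean_mmd +
                                        .data$ci_halfwidth),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "years before event", y = "mean MMD",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

# late-vs-early contrast, computed within patient then averaged: each
# patient with observations both in the last half-year bin and in an
# earlier in-horizon bin contributes mean(late) - mean(early). Under
# within-patient shuffling the per-patient contrast has expectation zero
# whatever that patient's distance scale, so the statistic is insensitive
# to the scale inflation shuffling induces on a drifting series.
trend_contrast <- function(mmd_tbl, cohort, group = "deceased",
                           horizon_years = 5, bin_days = 182.625) {
  type <- c(deceased = "death", censored = "censored",
            transplant = "transplant")[[group]]
  anchors <- cohort$patients |>
    dplyr::filter(.data$event_type == type) |>
    dplyr::select("patient_id", anchor = "event_date")
  binned <- mmd_tbl |>
    dplyr::inner_join(anchors, by = "patient_id") |>
    dplyr::mutate(days_before = as.numeric(.data$anchor - .data$date)) |>
    dplyr::filter(.data$days_before >= 0,
                  .data$days_before <= horizon_years * 365.25) |>
    dplyr::mutate(bin = pmax(1, ceiling(.data$days_before / bin_days)))
  per_patient <- binned |>
    dplyr::summarise(
      late = mean(.data$mmd[.data$bin == 1]),
      early = mean(.data$mmd[.data$bin >= 2]),
      .by = "patient_id"
    ) |>
    dplyr::filter(!is.nan(.data$late), !is.nan(.data$early))
  if (nrow(per_patient) == 0) return(NA_real_)
  mean(per_patient$late - per_patient$early)
}

# permute each patient's visit profiles across that patient's own visit
# dates; whole visits move together, dates stay fixed
shuffle_visits_within_patient <- function(visits) {
  key <- visits |>
    dplyr::distinct(.data$patient_id, .data$date) |>
    dplyr::arrange(.data$patient_id, .data$date) |>
    dplyr::mutate(new_date = .data$date[sample.int(dplyr::n())],
                  .by = "patient_id")
  visits |>
    dplyr::inner_join(key, by = c("patient_id", "date")) |>
    dplyr::mutate(date = .data$new_date) |>
    dplyr::select(-"new_date") |>
    dplyr::arrange(.data$patient_id, .data$date, .data$biomarker)
}

#' Shuffled-visit permutation negative control
#'
#' A pre-death rise in MMD could in principle be an artefact of the data
#' boundary rather than genuine growing variability. This control
#' re-computes the MMD pipeline after randomly permuting, within each
#' patient, which visit profile sits on which of that patient's visit
#' dates: the dates (hence the gap-window structure of pairing) are kept,
#' only temporal ordering is destroyed. The summary statistic is the
#' late-vs-early contrast: within each patient of the chosen outcome
#' group, the mean MMD in the last half-year bin minus the mean over all
#' earlier in-horizon bins, averaged over the patients observed in both
#' windows. Computing the contrast within patient keeps it centred at
#' zero under shuffling even though shuffling a drifting series inflates
#' distances by a patient-specific factor (temporally distant profiles
#' get paired). Standardization and the covariance model are unaffected
#' by within-patient permutation (the multiset of visit vectors is
#' preserved) and are reused across replicates.
#'
#' @param cohort An `mmd_cohort`.
#' @param set A [biomarker_set()].
#' @param variant Covariance variant (default `"pooled"`).
#' @param n_replicates Number of shuffled replicates (default 39).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param group Outcome group for the contrast (default `"deceased"`).
#' @param horizon_years Trend horizon in years (default 5).
#' @return An object of class `mmd_shuffle_null`: list with `observed`
#'   contrast, `null_contrasts` (length `n_replicates`), add-one
#'   permutation `p_value` for contrast >= observed, `seed`, `group`.
#' @export
shuffle_null <- function(cohort, set, variant = "pooled",
                         n_replicates = 39, seed = 1L,
                         group = "deceased", horizon_years = 5) {
  stopifnot(inherits(cohort, "mmd_cohort"), n_replicates >= 1)
  params <- fit_standardization(cohort$visits, set)
  model <- estimate_covariance(cohort$visits, set, params,
                               variant = variant,
                               patients = cohort$patients)
  observed_tbl <- compute_mmd(make_visit_pairs(cohort$visits, set, params),
                              model)
  observed <- trend_contrast(observed_tbl, cohort, group = group,
                             horizon_years = horizon_years)
  set.seed(seed)
  null_contrasts <- vapply(seq_len(n_replicates), function(i) {
    sh <- shuffle_visits_within_patient(cohort$visits)
    tbl <- compute_mmd(make_visit_pairs(sh, set, params), model)
    trend_contrast(tbl, cohort, group = group,
                   horizon_years = horizon_years)
  }, numeric(1))
  p <- (1 + sum(null_contrasts >= observed, na.rm = TRUE)) /
    (1 + n_replicates)
  structure(
    list(observed = observed, null_contrasts = null_contrasts,
         p_value = p, seed = seed, group = group,
         n_replicates = n_replicates, biomarker_set = set$name),
    class = "mmd_shuffle_null"
  )
}

#' @export
print.mmd_shuffle_null <- function(x, ...) {
  cat("<mmd_shuffle_null> set=", x$biomarker_set, ", group=", x$group,
      ", replicates=", x$n_replicates, "\n", sep = "")
  cat(sprintf("  observed late-vs-early contrast = %.4f\n", x$observed))
  cat(sprintf("  null contrasts: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$null_contrasts), min(x$null_contrasts),
              max(x$null_contrasts)))
  cat(sprintf("  permutation p (contrast >= observed) = %.4f\n", x$p_value))
  invisible(x)
}

#' @rdname shuffle_null
#' @param x An `mmd_shuffle_null`.
#' @param ... Unused.
#' @export
tidy.mmd_shuffle_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$null_contrasts),
                 contrast = x$null_contrasts,
                 observed = x$observed, p_value = x$p_value)
}

#' @rdname shuffle_null
#' @param object An `mmd_shuffle_null`.
#' @export
autoplot.mmd_shuffle_null <- function(object, ...) {
  df <- tibble::tibble(contrast = object$null_contrasts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contrast)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "late-vs-early MMD contrast (shuffled)",
                  y = "replicates",
                  title = sprintf("observed contrast vs shuffle null (p = %.3f)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
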