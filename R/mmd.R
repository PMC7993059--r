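#' Estimate the population covariance model
#'
#' The covariance `S` shared by all patients is the sample covariance (n−1
#' denominator) of the standardized visit vectors — the *levels*, not the
#' visit-to-visit differences — pooled over the cohort, so it is the
#' biomarker correlation matrix up to sampling error. Three sensitivity
#' variants probe the stationarity assumption:
#'
#' * `"identity_offdiag"` — off-diagonal entries set to zero, variances
#'   kept (variance-only model; MMD reduces to a Euclidean norm on exactly
#'   standardized data);
#' * `"near_death"` — estimated only from deceased patients' visits within
#'   92 days (3 months) before death;
#' * `"far_from_death"` — estimated only from deceased patients' visits at
#'   least 730 days (2 years) before death.
#'
#' @param visits Long visit tibble of raw values.
#' @param set A [biomarker_set()].
#' @param params [fit_standardization()] output for the same set.
#' @param variant One of `"pooled"`, `"identity_offdiag"`, `"near_death"`,
#'   `"far_from_death"`.
#' @param patients Patient tibble with `event_type` and `event_date`;
#'   required for the death-window variants.
#' @param near_death_days,far_from_death_days Day equivalents of the
#'   3-month and 2-year windows.
#' @param rcond_tol Reciprocal-condition-number threshold below which the
#'   matrix is treated as singular. MCH/MCHC/MCV are arithmetic functions
#'   of hemoglobin, RBC count and hematocrit, which can push `S` toward
#'   singularity; the error suggests `drop_redundant`.
#' @return A list of class `covariance_model` with elements `variant`,
#'   `markers`, `S`, `S_inv`, `n_obs`.
#' @export
estimate_covariance <- function(visits, set, params,
                                variant = c("pooled", "identity_offdiag",
                                            "near_death", "far_from_death"),
                                patients = NULL,
                                near_death_days = 92,
                                far_from_death_days = 730,
                                rcond_tol = 1e-10) {
  variant <- match.arg(variant)
  sv <- standardized_visit_matrix(visits, set, params)
  if (variant %in% c("near_death", "far_from_death")) {
    if (is.null(patients)) {
      stop("the ", variant, " variant needs the patients table ",
           "(death dates)", call. = FALSE)
    }
    dd <- patients |>
      dplyr::filter(.data$event_type == "death") |>
      dplyr::select("patient_id", death = "event_date")
    sv <- dplyr::inner_join(sv, dd, by = "patient_id")
    days_before <- as.integer(sv$death - sv$date)
    keep <- if (variant == "near_death") {
      days_before > 0 & days_before <= near_death_days
    } else {
      days_before >= far_from_death_days
    }
    sv <- sv[keep, , drop = FALSE]
  }
  x <- sv$x
  p <- length(set$markers)
  if (nrow(x) <= p) {
    stop("not enough complete visits (", nrow(x), ") to estimate a ", p,
         "x", p, " covariance for variant '", variant, "'", call. = FALSE)
  }
  S <- stats::cov(x)
  if (variant == "identity_offdiag") {
    S <- diag(diag(S), nrow = p)
  }
  dimnames(S) <- list(set$markers, set$markers)
  new_covariance_model(S, variant, set$markers, n_obs = nrow(x),
                       rcond_tol = rcond_tol)
}

#' Construct a covariance model from an explicit matrix
#'
#' @param S Symmetric positive-definite matrix in set marker order.
#' @param variant Variant tag carried through to output tables.
#' @param markers Marker names (defaults to `colnames(S)`).
#' @param n_obs Number of observations behind the estimate, if known.
#' @param rcond_tol Singularity threshold on the reciprocal condition
#'   number.
#' @return A `covariance_model`.
#' @export
new_covariance_model <- function(S, variant = "pooled",
                                 markers = colnames(S), n_obs = NA_integer_,
                                 rcond_tol = 1e-10) {
  S <- as.matrix(S)
  if (!isSymmetric(S, tol = 1e-8)) {
    stop("covariance matrix is not symmetric", call. = FALSE)
  }
  S <- (S + t(S)) / 2
  if (rcond(S) < rcond_tol) {
    stop("covariance matrix is singular or near-singular (rcond < ",
         format(rcond_tol), "); if the set contains MCH/MCHC/MCV consider ",
         "builtin_biomarker_sets(drop_redundant = TRUE)", call. = FALSE)
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  }
  S_inv <- chol2inv(chol(S))
  dimnames(S_inv) <- dimnames(S)
  structure(
    list(variant = variant, markers = markers, S = S, S_inv = S_inv,
         n_obs = n_obs),
    class = "covariance_model"
  )
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("<covariance_model> variant=", x$variant, ", p=", length(x$markers),
      ", n_obs=", x$n_obs, "\n", sep = "")
  invisible(x)
}

#' Mahalanobis distance between two biomarker vectors
#'
#' Computes `sqrt((a - b)' S^{-1} (a - b))` under the model's covariance:
#' symmetric in its arguments, zero only when `a == b`, and a metric for
#' fixed positive-definite `S`. With `b` fixed at the population mean this
#' is the classical dysregulation distance; with `b` the previous visit it
#' is one MMD step.
#'
#' @param a,b Numeric vectors in the model's marker order.
#' @param model A `covariance_model`.
#' @param squared Return the squared distance instead of the root.
#' @return Non-negative scalar.
#' @export
mahalanobis_distance <- function(a, b, model, squared = FALSE) {
  p <- length(model$markers)
  if (length(a) != p || length(b) != p) {
    stop("vectors must have length ", p, " (model marker order)",
         call. = FALSE)
  }
  d <- as.numeric(a) - as.numeric(b)
  q <- as.numeric(d %*% model$S_inv %*% d)
  q <- max(q, 0)
  if (squared) q else sqrt(q)
}

#' Compute the MMD series for visit pairs
#'
#' One Moving Multivariate Distance per pair: the Mahalanobis distance
#' between the standardized biomarker vectors of consecutive eligible
#' visits, timestamped at the later visit. A higher MMD means higher
#' intraindividual multivariate variability over that interval.
#'
#' @param pairs Output of [make_visit_pairs()].
#' @param model A `covariance_model` over the same marker order.
#' @param squared Use squared distances instead of the classical root form.
#' @return A tibble `patient_id`, `date` (later visit), `gap_days`, `mmd`.
#' @export
compute_mmd <- function(pairs, model, squared = FALSE) {
  mk <- attr(pairs, "markers")
  if (!is.null(mk) && !identical(mk, model$markers)) {
    stop("pairs and covariance model use different marker orders",
         call. = FALSE)
  }
  out <- tibble::tibble(patient_id = pairs$patient_id,
                        date = pairs$date_curr,
                        gap_days = pairs$gap_days)
  if (nrow(pairs) == 0) {
    out$mmd <- numeric(0)
    return(out)
  }
  d <- pairs$x_curr - pairs$x_prev
  q <- rowSums((d %*% model$S_inv) * d)
  q <- pmax(q, 0)
  out$mmd <- if (squared) q else sqrt(q)
  out
}

#' Log-MMD with the half-minimum zero rule
#'
#' An MMD of exactly zero (identical consecutive profiles) has no
#' logarithm; such values are replaced, per individual, by half that
#' individual's minimum positive MMD before taking logs. Individuals whose
#' MMDs are all zero have no positive minimum and are dropped with a
#' warning — they cannot enter the survival model.
#'
#' @param mmd_tbl Output of [compute_mmd()] (may hold many patients).
#' @return The tibble with columns `log_mmd` and `zero_replaced` added;
#'   `mmd` itself is left untouched.
#' @export
log_mmd_with_zero_rule <- function(mmd_tbl) {
  out <- mmd_tbl |>
    dplyr::mutate(
      min_pos = {
        mp <- suppressWarnings(min(.data$mmd[.data$mmd > 0]))
        if (is.finite(mp)) mp else NA_real_
      },
      .by = "patient_id"
    )
  all_zero <- unique(out$patient_id[is.na(out$min_pos)])
  if (length(all_zero) > 0) {
    warning("dropping ", length(all_zero), " individual(s) whose MMDs are ",
            "all zero (no positive minimum for the half-minimum rule): ",
            paste(utils::head(all_zero, 5), collapse = ", "), call. = FALSE)
    out <- dplyr::filter(out, !is.na(.data$min_pos))
  }
  out |>
    dplyr::mutate(
      zero_replaced = .data$mmd == 0,
      log_mmd = log(ifelse(.data$zero_replaced, .data$min_pos / 2,
                           .data$mmd))
    ) |>
    dplyr::select(-"min_pos")
}

#' End-to-end MMD table for one biomarker set
#'
#' Convenience wrapper chaining transform, population standardization,
#' window pairing, covariance estimation, MMD and the log zero rule for a
#' whole cohort. Standardization and covariance are fit on `fit_cohort`
#' (default: the cohort itself), so analysis subsets can reuse
#' entire-population references.
#'
#' @param cohort An `mmd_cohort`.
#' @param set A [biomarker_set()].
#' @param variant Covariance variant, see [estimate_covariance()].
#' @param fit_cohort Cohort used to fit standardization and covariance.
#' @param params,model Optional pre-fitted [fit_standardization()] /
#'   `covariance_model` to reuse.
#' @param squared Use squared distances.
#' @return A tibble `patient_id`, `date`, `gap_days`, `biomarker_set`,
#'   `covariance_variant`, `mmd`, `log_mmd`, `zero_replaced`, with the
#'   fitted `params` and `model` attached as attributes.
#' @export
compute_mmd_table <- function(cohort, set, variant = "pooled",
                              fit_cohort = cohort, params = NULL,
                              model = NULL, squared = FALSE) {
  stopifnot(inherits(cohort, "mmd_cohort"))
  if (is.null(params)) params <- fit_standardization(fit_cohort$visits, set)
  if (is.null(model)) {
    model <- estimate_covariance(fit_cohort$visits, set, params,
                                 variant = variant,
                                 patients = fit_cohort$patients)
  }
  pairs <- make_visit_pairs(cohort$visits, set, params)
  out <- compute_mmd(pairs, model, squared = squared)
  out <- log_mmd_with_zero_rule(out)
  out <- dplyr::mutate(out, biomarker_set = set$name,
                       covariance_variant = model$variant,
                       .after = "gap_days")
  attr(out, "params") <- params
  attr(out, "model") <- model
  out
}
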