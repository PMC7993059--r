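#' Default marker parameters for the simulator
#'
#' One row per built-in biomarker with its measurement schedule (`q2w`,
#' `q1m`, `q4m`), variance-stabilizing transform, and the location/scale of
#' the latent process *on the transformed scale*, chosen so the values
#' emitted in clinical units have roughly the means and SDs typical of a
#' hemodialysis panel (for log markers: location `log(mean)`, scale the
#' coefficient of variation; for the square-root marker: location
#' `sqrt(mean)`, scale `sd / (2 sqrt(mean))`).
#'
#' @return A tibble `biomarker`, `schedule`, `transform`, `location`,
#'   `scale`.
#' @export
default_marker_params <- function() {
  tibble::tribble(
    ~biomarker,   ~schedule, ~clinical_mean, ~clinical_sd,
    "hematocrit", "q2w",     0.33,           0.05,
    "hemoglobin", "q2w",     107.72,         15.04,
    "mch",        "q2w",     31.44,          2.15,
    "mchc",       "q2w",     329.70,         11.46,
    "mcv",        "q2w",     95.33,          5.92,
    "platelets",  "q2w",     216.45,         84.94,
    "potassium",  "q2w",     4.76,           0.73,
    "rbc",        "q2w",     3.44,           0.51,
    "rdw",        "q2w",     15.75,          1.96,
    "sodium",     "q2w",     138.26,         3.78,
    "wbc",        "q2w",     7.84,           3.66,
    "calcium",    "q1m",     2.23,           0.19,
    "creatinine", "q1m",     635.88,         291.58,
    "glucose",    "q1m",     7.63,           3.87,
    "phosphate",  "q1m",     1.53,           0.49,
    "albumin",    "q4m",     36.27,          5.56
  ) |>
    dplyr::mutate(
      transform = unname(default_transforms(.data$biomarker)),
      location = dplyr::case_when(
        .data$transform == "log" ~ log(.data$clinical_mean),
        .data$transform == "sqrt" ~ sqrt(.data$clinical_mean),
        TRUE ~ .data$clinical_mean
      ),
      scale = dplyr::case_when(
        .data$transform == "log" ~ .data$clinical_sd / .data$clinical_mean,
        .data$transform == "sqrt" ~
          .data$clinical_sd / (2 * sqrt(.data$clinical_mean)),
        TRUE ~ .data$clinical_sd
      )
    ) |>
    dplyr::select("biomarker", "schedule", "transform", "location", "scale")
}

#' Simulation settings for a synthetic hemodialysis-like cohort
#'
#' The simulator emulates the structure of a chronic hemodialysis cohort:
#' roughly bi-weekly blood sampling with day-level jitter and missed
#' visits, 16 correlated biomarkers of which only the 11 `q2w` markers are
#' measured at every visit (the monthly four on every second scheduled
#' visit, albumin on every eighth), multi-year right-skewed follow-up, a
#' majority-death outcome mix, and an optional linear inflation of the
#' step-to-step innovation SD over the last `inflation_days` before death.
#'
#' Each patient's latent transformed-scale biomarker vector evolves as a
#' correlated random walk: initial state `N(0, init_sd^2 R)`, innovations
#' `N(0, (step_sd * m_t * e^gamma)^2 R)` with `R` the target correlation,
#' `gamma ~ N(0, frailty_sd^2)` a patient-level variability frailty, and
#' `m_t` the inflation multiplier ramping linearly from 1 to
#' `inflation_factor` over the last `inflation_days` before death
#' (deceased patients only; `inflation_factor = 1` switches it off).
#'
#' Two death-time mechanisms are available. *Scheduled* (the default,
#' `hazard_beta = 0`): outcomes are drawn from the
#' death/transplant/censoring fractions and the inflation ramp is anchored
#' to the pre-drawn death date. *Hazard-linked* (`hazard_beta != 0`): death
#' arrives with per-interval hazard
#' `base_hazard * exp(hazard_beta * (z - log sqrt(p)))`, where `z` is the
#' true log step distance of the most recent visit pair under the
#' generating innovation covariance, computed over `hazard_markers`.
#'
#' @param n_patients Number of patients (default 763).
#' @param marker_params Marker table as in [default_marker_params()].
#' @param level_cor Target correlation matrix `R` (default exchangeable
#'   with correlation 0.3), shared by initial levels and innovations so
#'   pooled level and step covariances stay proportional.
#' @param init_sd,step_sd Latent initial-state and per-visit innovation SDs
#'   (transformed-scale z units; defaults 1 and 0.2).
#' @param frailty_sd SD of the patient-level log innovation-scale frailty
#'   (default 0.3).
#' @param gap_days,jitter_days Nominal visit cadence and uniform day-level
#'   jitter (defaults 14 and 2).
#' @param miss_prob Probability a scheduled visit is skipped entirely
#'   (default 0.1).
#' @param followup_meanlog,followup_sdlog Log-normal follow-up duration in
#'   years (defaults give median ~2.1 y with a long right tail), truncated
#'   to `followup_range`.
#' @param followup_range Years; default `c(0.15, 12)`.
#' @param death_frac,transplant_frac Outcome fractions (defaults 0.688 and
#'   0.195; the remainder is other censoring). Scheduled mode only.
#' @param inflation_factor Terminal multiplier `f >= 1` of the innovation
#'   SD at death (default 2).
#' @param inflation_days Ramp length before death in days (default 365).
#' @param hazard_beta Hazard link coefficient on the true log step
#'   distance; 0 (default) selects the scheduled mechanism.
#' @param base_hazard Baseline hazard per year in hazard-linked mode
#'   (default 0.35).
#' @param hazard_markers Markers over which the hazard covariate is
#'   computed (default the 11 two-week markers).
#' @param hazard_window Inclusive gap window (days) inside which a visit
#'   pair updates the hazard covariate (default `c(12, 16)`, the two-week
#'   window). The covariate is a step function that only moves at
#'   in-window pairs — the same observable process a downstream
#'   counting-process fit sees — and stays at its last value otherwise.
#' @param male_frac,diabetic_frac,age_mean,age_sd Patient-mix parameters
#'   (defaults 0.628, 0.512, 64.2, 15.8).
#' @param start_date First possible first-visit calendar date.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 763,
                       marker_params = default_marker_params(),
                       level_cor = NULL,
                       init_sd = 1, step_sd = 0.2, frailty_sd = 0.3,
                       gap_days = 14, jitter_days = 2, miss_prob = 0.1,
                       followup_meanlog = log(2.12), followup_sdlog = 1.4,
                       followup_range = c(0.15, 12),
                       death_frac = 0.688, transplant_frac = 0.195,
                       inflation_factor = 2, inflation_days = 365,
                       hazard_beta = 0, base_hazard = 0.35,
                       hazard_markers = NULL, hazard_window = c(12L, 16L),
                       male_frac = 0.628, diabetic_frac = 0.512,
                       age_mean = 64.2, age_sd = 15.8,
                       start_date = as.Date("2005-01-01"),
                       seed = 1L) {
  p <- nrow(marker_params)
  if (is.null(level_cor)) {
    level_cor <- matrix(0.3, p, p)
    diag(level_cor) <- 1
  }
  stopifnot(nrow(level_cor) == p, ncol(level_cor) == p,
            isSymmetric(level_cor),
            death_frac >= 0, transplant_frac >= 0,
            death_frac + transplant_frac <= 1,
            inflation_factor >= 1, step_sd > 0, init_sd > 0,
            gap_days > 0, miss_prob >= 0, miss_prob < 1)
  ev <- eigen(level_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("level_cor must be symmetric positive definite", call. = FALSE)
  }
  if (is.null(hazard_markers)) {
    hazard_markers <- marker_params$biomarker[marker_params$schedule == "q2w"]
  }
  dimnames(level_cor) <- list(marker_params$biomarker,
                              marker_params$biomarker)
  structure(
    list(n_patients = as.integer(n_patients),
         marker_params = marker_params, level_cor = level_cor,
         init_sd = init_sd, step_sd = step_sd, frailty_sd = frailty_sd,
         gap_days = gap_days, jitter_days = jitter_days,
         miss_prob = miss_prob,
         followup_meanlog = followup_meanlog,
         followup_sdlog = followup_sdlog,
         followup_range = followup_range,
         death_frac = death_frac, transplant_frac = transplant_frac,
         inflation_factor = inflation_factor,
         inflation_days = inflation_days,
         hazard_beta = hazard_beta, base_hazard = base_hazard,
         hazard_markers = hazard_markers,
         hazard_window = as.integer(hazard_window),
         male_frac = male_frac, diabetic_frac = diabetic_frac,
         age_mean = age_mean, age_sd = age_sd,
         start_date = as.Date(start_date), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# MVN draws via the Cholesky factor of the correlation matrix
rmvn_chol <- function(n, chol_R) {
  p <- ncol(chol_R)
  matrix(stats::rnorm(n * p), n, p) %*% chol_R
}

# per-patient substream seed, kept inside 32-bit integer range
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 9973) %% 2147483629)
}

#' Simulate a synthetic hemodialysis-like cohort
#'
#' Generates visits, patient metadata and outcomes per [sim_config()],
#' together with a ground-truth table recording each patient's generating
#' mechanism. The output round-trips losslessly through [write_cohort()] /
#' [read_cohort()]. All randomness flows from `config$seed`; patient `i`
#' draws from a derived substream so any subset of patients is
#' reproducible independently of cohort size.
#'
#' @param config A [sim_config()].
#' @return A list of class `mmd_sim`: `cohort` (an `mmd_cohort`) and
#'   `truth`, a tibble with one row per patient (`patient_id`, `outcome`,
#'   `followup_years`, `frailty`, `inflated`, `mechanism`, `hazard_beta`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  mp <- config$marker_params
  p <- nrow(mp)
  chol_R <- chol(config$level_cor)
  hz_idx <- match(config$hazard_markers, mp$biomarker)
  hz_Sinv <- chol2inv(chol(config$level_cor[hz_idx, hz_idx, drop = FALSE]))
  n <- config$n_patients
  if (n < 1) stop("n_patients must be at least 1", call. = FALSE)
  hazard_mode <- config$hazard_beta != 0

  ids <- sprintf("p%04d", seq_len(n))
  visit_list <- vector("list", n)
  truth_list <- vector("list", n)
  patient_rows <- vector("list", n)

  for (i in seq_len(n)) {
    # every draw for patient i comes from patient i's own substream, so
    # the first k patients of a larger cohort replicate a smaller one
    set.seed(patient_seed(config$seed, i))
    sex_i <- if (stats::runif(1) < config$male_frac) "M" else "F"
    diabetic_i <- stats::runif(1) < config$diabetic_frac
    age_i <- min(max(stats::rnorm(1, config$age_mean, config$age_sd), 18),
                 95)
    entry_offset_i <- sample.int(3653, 1) - 1L
    fu_years_i <- min(max(
      stats::rlnorm(1, config$followup_meanlog, config$followup_sdlog),
      config$followup_range[1]), config$followup_range[2])
    u_out <- stats::runif(1)
    out_drawn <- if (u_out < config$death_frac) "death"
                 else if (u_out < config$death_frac +
                            config$transplant_frac) "transplant"
                 else "censored"
    fu_days <- round(fu_years_i * 365.25)
    n_sched <- floor(fu_days / config$gap_days) + 1L
    jit <- if (config$jitter_days > 0) {
      sample(seq(-config$jitter_days, config$jitter_days),
             n_sched, replace = TRUE)
    } else rep(0L, n_sched)
    t_days <- (seq_len(n_sched) - 1L) * config$gap_days + jit
    t_days[1] <- 0L
    t_days <- pmin(t_days, fu_days)

    gamma <- stats::rnorm(1, 0, config$frailty_sd)
    out_i <- out_drawn
    event_day <- fu_days

    # inflation multiplier per step (step j leads into visit j)
    if (!hazard_mode && out_i == "death" && config$inflation_factor > 1) {
      d_before <- pmax(event_day - t_days, 0)
      m <- 1 + (config$inflation_factor - 1) *
        pmax(0, 1 - d_before / config$inflation_days)
    } else {
      m <- rep(1, n_sched)
    }

    z <- matrix(0, n_sched, p)
    z[1, ] <- rmvn_chol(1, chol_R) * config$init_sd
    if (n_sched > 1) {
      steps <- rmvn_chol(n_sched - 1L, chol_R) *
        (config$step_sd * exp(gamma) * m[-1])
      cs <- apply(steps, 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)
      z[-1, ] <- sweep(cs, 2, z[1, ], "+")
    }

    if (hazard_mode) {
      # death arrives interval by interval. The covariate is the true log
      # step distance of the most recent *in-window* pair — the observable
      # step function a counting-process fit reconstructs — scaled by the
      # population step SD so the patient frailty stays in the covariate,
      # as it does in log-MMD computed against pooled references.
      died <- FALSE
      death_time <- NA_real_
      if (n_sched > 1) {
        sd_true <- config$step_sd
        zcenter <- log(sqrt(length(hz_idx)))
        zcov <- zcenter                    # neutral until first pair seen
        for (j in 2:n_sched) {
          gap_j <- t_days[j] - t_days[j - 1L]
          if (gap_j >= config$hazard_window[1] &&
              gap_j <= config$hazard_window[2]) {
            dz <- (z[j, hz_idx] - z[j - 1L, hz_idx]) / sd_true
            zcov <- log(sqrt(max(as.numeric(dz %*% hz_Sinv %*% dz), 1e-12)))
          }
          if (j < n_sched) {
            lam <- config$base_hazard *
              exp(config$hazard_beta * (zcov - zcenter))
            dt_years <- (t_days[j + 1L] - t_days[j]) / 365.25
            if (stats::runif(1) < 1 - exp(-lam * dt_years)) {
              died <- TRUE
              death_time <- t_days[j] +
                stats::runif(1) * (t_days[j + 1L] - t_days[j])
              keep_n <- j
              break
            }
          }
        }
      }
      if (died) {
        out_i <- "death"
        event_day <- ceiling(death_time)
        z <- z[seq_len(keep_n), , drop = FALSE]
        t_days <- t_days[seq_len(keep_n)]
        m <- m[seq_len(keep_n)]
        n_sched <- keep_n
      } else {
        out_i <- "censored"
      }
    }

    # measurement schedule by scheduled-visit index, then missed visits
    sched_idx <- seq_len(n_sched) - 1L
    measured <- matrix(TRUE, n_sched, p)
    measured[, mp$schedule == "q1m"] <- sched_idx %% 2L == 0L
    measured[, mp$schedule == "q4m"] <- sched_idx %% 8L == 0L
    emit <- stats::runif(n_sched) >= config$miss_prob
    emit[1] <- TRUE
    if (out_i == "death" && any(emit)) {
      # keep the final pre-death visit so late observations exist
      emit[max(which(t_days <= event_day))] <- TRUE
    }

    keep <- which(emit)
    if (length(keep) == 0) next
    zk <- z[keep, , drop = FALSE]
    latent <- sweep(sweep(zk, 2, mp$scale, "*"), 2, mp$location, "+")
    # invert the variance-stabilizing transforms into clinical units
    value <- latent
    for (k in which(mp$transform == "log")) value[, k] <- exp(latent[, k])
    for (k in which(mp$transform == "sqrt")) {
      value[, k] <- pmax(latent[, k], 0.01)^2
    }
    mk <- measured[keep, , drop = FALSE]
    nv <- length(keep)
    entry_date <- config$start_date + entry_offset_i
    long <- tibble::tibble(
      patient_id = ids[i],
      date = rep(entry_date + t_days[keep], each = p),
      biomarker = rep(mp$biomarker, times = nv),
      value = as.vector(t(value))
    )
    long <- long[as.vector(t(mk)), ]
    visit_list[[i]] <- long

    patient_rows[[i]] <- tibble::tibble(
      patient_id = ids[i], sex = sex_i, diabetic = diabetic_i,
      birth_date = entry_date - round(age_i * 365.25),
      event_type = out_i,
      event_date = entry_date + event_day,
      death_date = if (out_i == "death") entry_date + event_day
                   else as.Date(NA),
      first_dialysis_date = entry_date
    )
    truth_list[[i]] <- tibble::tibble(
      patient_id = ids[i], outcome = out_i,
      followup_years = fu_years_i, frailty = gamma,
      inflated = !hazard_mode && out_i == "death" &&
        config$inflation_factor > 1,
      mechanism = if (hazard_mode) "hazard_linked" else "scheduled",
      hazard_beta = config$hazard_beta
    )
  }

  visits <- dplyr::bind_rows(visit_list)
  patients <- dplyr::bind_rows(patient_rows)
  truth <- dplyr::bind_rows(truth_list)
  structure(list(cohort = new_cohort(visits, patients), truth = truth,
                 config = config),
            class = "mmd_sim")
}

#' @export
print.mmd_sim <- function(x, ...) {
  cat("<mmd_sim> seed=", x$config$seed, ", mechanism=",
      if (x$config$hazard_beta != 0) "hazard_linked" else "scheduled",
      "\n", sep = "")
  print(x$cohort)
  invisible(x)
}

#' A small hand-auditable reference cohort
#'
#' Six patients, a handful of visits each, over a four-marker panel
#' (sodium, potassium, glucose, platelets; gap window 12–16 days) that
#' exercises every transform. The cohort is fully synthetic and
#' deterministic (fixed internal seed): it contains a duplicated
#' consecutive profile (an exact zero MMD, triggering the half-minimum
#' rule), a visit missing one marker (exercising the skip rule in
#' pairing), out-of-window gaps, and all three outcome types, with visit
#' epochs spread so several half-year trend bins are populated. Used for
#' frozen-value regression tests.
#'
#' @return A list: `cohort` (an `mmd_cohort`) and `set` (the
#'   [biomarker_set()] to analyse it with).
#' @export
reference_fixture <- function() {
  set.seed(20240)
  mk <- c("sodium", "potassium", "glucose", "platelets")
  base <- c(sodium = 138, potassium = 4.7, glucose = 7.4, platelets = 220)
  sdv <- c(sodium = 3, potassium = 0.5, glucose = 1.8, platelets = 40)
  gen_visit <- function(id, day) {
    tibble::tibble(patient_id = id,
                   date = as.Date("2010-01-05") + day,
                   biomarker = mk,
                   value = round(base + stats::rnorm(4) * sdv, 2))
  }
  rows <- list(
    # p1: deceased, visit epochs spanning ~2 years; one duplicated profile
    lapply(c(0, 14, 400, 414, 700, 714), gen_visit, id = "r1"),
    # p2: censored, two paired epochs
    lapply(c(0, 15, 300, 314), gen_visit, id = "r2"),
    # p3: transplant, one paired epoch
    lapply(c(0, 13), gen_visit, id = "r3"),
    # p4: deceased, single in-window pair
    lapply(c(0, 14), gen_visit, id = "r4"),
    # p5: censored, middle visit missing glucose (skip rule: 0 -> 28 gap
    # is out of window, no pair survives except 28->42)
    lapply(c(0, 14, 28, 42), gen_visit, id = "r5"),
    # p6: deceased, minimal series
    lapply(c(0, 16), gen_visit, id = "r6")
  )
  visits <- dplyr::bind_rows(purrr::map(rows, dplyr::bind_rows))
  # plant the exact duplicate: r1's visit at day 14 repeats day 0's profile
  v0 <- visits$value[visits$patient_id == "r1" &
                       visits$date == as.Date("2010-01-05")]
  visits$value[visits$patient_id == "r1" &
                 visits$date == as.Date("2010-01-05") + 14] <- v0
  # drop glucose from r5's day-14 visit
  visits <- visits[!(visits$patient_id == "r5" &
                       visits$date == as.Date("2010-01-05") + 14 &
                       visits$biomarker == "glucose"), ]

  d0 <- as.Date("2010-01-05")
  patients <- tibble::tibble(
    patient_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    sex = c("M", "F", "M", "F", "M", "M"),
    diabetic = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    birth_date = as.Date(c("1941-03-02", "1955-07-19", "1948-11-30",
                           "1960-02-14", "1939-09-08", "1952-05-23")),
    event_type = c("death", "censored", "transplant", "death",
                   "censored", "death"),
    event_date = d0 + c(760, 340, 50, 60, 80, 30),
    death_date = d0 + c(760, NA, NA, 60, NA, 30)
  )
  set <- biomarker_set("reference_panel", mk, c(12L, 16L))
  list(cohort = new_cohort(visits, patients), set = set)
}
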