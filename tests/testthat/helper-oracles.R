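# Brute-force oracles, kept independent of the package's computation paths.

# Mahalanobis distance via a direct linear solve (no cached inverse)
oracle_maha <- function(a, b, S) {
  d <- a - b
  sqrt(as.numeric(t(d) %*% solve(S, d)))
}

# enumerate consecutive in-window gaps among eligible (complete) visits
oracle_pairs <- function(dates, eligible, window) {
  dates <- dates[eligible]
  if (length(dates) < 2) return(integer(0))
  keep <- integer(0)
  for (j in 2:length(dates)) {
    gap <- as.integer(dates[j] - dates[j - 1])
    if (gap >= window[1] && gap <= window[2]) keep <- c(keep, j)
  }
  keep  # indices (within eligible dates) of the later pair member
}

# random SPD matrix with moderate conditioning
random_spd <- function(p) {
  A <- matrix(rnorm(p * p), p, p)
  crossprod(A) / p + diag(p) * 0.5
}

# tiny two-marker cohort used across filter tests
tiny_cohort <- function() {
  d0 <- as.Date("2015-01-01")
  visits <- tibble::tibble(
    patient_id = rep(c("a", "b"), c(6, 4)),
    date = c(d0 + c(0, 14, 28, 42, 56, 70), d0 + c(0, 14, 200, 214)),
    biomarker = "sodium",
    value = c(135, 136, 137, 138, 139, 140, 141, 142, 143, 144)
  )
  visits <- dplyr::bind_rows(
    visits,
    dplyr::mutate(visits, biomarker = "potassium", value = .data$value / 30)
  )
  patients <- tibble::tibble(
    patient_id = c("a", "b"),
    sex = c("M", "F"), diabetic = c(TRUE, FALSE),
    birth_date = as.Date(c("1950-01-01", "1960-01-01")),
    event_type = c("death", "censored"),
    event_date = d0 + c(100, 250)
  )
  new_cohort(visits, patients)
}

# quick simulated cohort helper for mid-size tests
quick_sim <- function(n = 60, seed = 11, ...) {
  simulate_cohort(sim_config(n_patients = n, seed = seed, ...))
}
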