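test_that("mahalanobis_distance matches closed forms and the solve oracle", {
  I2 <- new_covariance_model(diag(2), markers = c("m1", "m2"))
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), I2), 0)
  expect_equal(mahalanobis_distance(c(3, 4), c(0, 0), I2), 5)

  S <- matrix(c(2, 1, 1, 2), 2)
  m <- new_covariance_model(S, markers = c("m1", "m2"))
  # closed form: S^-1 = (1/3)[[2,-1],[-1,2]], d = (1,1) -> sqrt(2/3)
  expect_equal(mahalanobis_distance(c(1, 1), c(0, 0), m), sqrt(2 / 3))
  expect_error(mahalanobis_distance(c(1, 1, 1), c(0, 0), m), "length")

  set.seed(5)
  for (i in 1:50) {
    p <- sample(2:16, 1)
    S <- random_spd(p)
    mod <- new_covariance_model(S, markers = paste0("m", 1:p))
    a <- rnorm(p); b <- rnorm(p)
    expect_equal(mahalanobis_distance(a, b, mod), oracle_maha(a, b, S),
                 tolerance = 1e-12)
    # symmetry
    expect_equal(mahalanobis_distance(a, b, mod),
                 mahalanobis_distance(b, a, mod))
  }
})

test_that("mahalanobis_distance satisfies the triangle inequality", {
  set.seed(6)
  S <- random_spd(5)
  mod <- new_covariance_model(S, markers = paste0("m", 1:5))
  for (i in 1:50) {
    a <- rnorm(5); b <- rnorm(5); c0 <- rnorm(5)
    dab <- mahalanobis_distance(a, b, mod)
    dbc <- mahalanobis_distance(b, c0, mod)
    dac <- mahalanobis_distance(a, c0, mod)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("pooled covariance of standardized levels is the correlation matrix", {
  sim <- quick_sim(40, seed = 21)
  set <- builtin_biomarker_sets()$two_weeks
  par <- fit_standardization(sim$cohort$visits, set)
  mod <- estimate_covariance(sim$cohort$visits, set, par, "pooled")
  expect_equal(unname(diag(mod$S)), rep(1, 11), tolerance = 1e-10)
  expect_true(all(abs(mod$S[upper.tri(mod$S)]) < 1))

  modI <- estimate_covariance(sim$cohort$visits, set, par,
                              "identity_offdiag")
  expect_equal(unname(modI$S), diag(11), tolerance = 1e-10)
})

test_that("covariance recovers a known generating correlation", {
  p <- 6
  R <- matrix(0.5, p, p); diag(R) <- 1
  mp <- default_marker_params()[1:p, ]
  mp$schedule <- "q2w"
  cfg <- sim_config(n_patients = 80, marker_params = mp, level_cor = R,
                    frailty_sd = 0, miss_prob = 0, inflation_factor = 1,
                    seed = 31)
  sim <- simulate_cohort(cfg)
  set <- biomarker_set("six", mp$biomarker, c(12, 16))
  par <- fit_standardization(sim$cohort$visits, set)
  mod <- estimate_covariance(sim$cohort$visits, set, par, "pooled")
  off <- mod$S[upper.tri(mod$S)]
  # brute-force pairwise covariance on the standardized matrix
  sv <- mmdews:::standardized_visit_matrix(sim$cohort$visits, set, par)
  x <- sv$x
  brute <- sum((x[, 1] - mean(x[, 1])) * (x[, 2] - mean(x[, 2]))) /
    (nrow(x) - 1)
  expect_equal(mod$S[1, 2], brute, tolerance = 1e-12)
  # levels of a correlated random walk keep the innovation correlation
  expect_equal(mean(off), 0.5, tolerance = 0.1)
})

test_that("death-window covariance variants use the right visits", {
  sim <- quick_sim(50, seed = 41)
  set <- builtin_biomarker_sets()$two_weeks
  par <- fit_standardization(sim$cohort$visits, set)
  near <- estimate_covariance(sim$cohort$visits, set, par, "near_death",
                              patients = sim$cohort$patients)
  far <- estimate_covariance(sim$cohort$visits, set, par, "far_from_death",
                             patients = sim$cohort$patients)
  # count the qualifying visits by hand
  dd <- dplyr::filter(sim$cohort$patients, event_type == "death")
  sv <- mmdews:::standardized_visit_matrix(sim$cohort$visits, set, par) |>
    dplyr::inner_join(dplyr::select(dd, patient_id, event_date),
                      by = "patient_id") |>
    dplyr::mutate(db = as.integer(event_date - date))
  expect_equal(near$n_obs, sum(sv$db > 0 & sv$db <= 92))
  expect_equal(far$n_obs, sum(sv$db >= 730))
  expect_error(
    estimate_covariance(sim$cohort$visits, set, par, "near_death"),
    "patients table")
})

test_that("near-singular covariance errors with drop_redundant advice", {
  set.seed(8)
  n <- 60
  x <- cbind(a = rnorm(n), b = rnorm(n))
  S <- stats::cov(cbind(x, s = x[, 1] + x[, 2] + rnorm(n, 0, 1e-9)))
  expect_error(new_covariance_model(S), "drop_redundant")
})

test_that("compute_mmd equals per-pair oracle calls", {
  sim <- quick_sim(15, seed = 51)
  set <- builtin_biomarker_sets()$two_weeks
  par <- fit_standardization(sim$cohort$visits, set)
  mod <- estimate_covariance(sim$cohort$visits, set, par, "pooled")
  pairs <- make_visit_pairs(sim$cohort$visits, set, par)
  got <- compute_mmd(pairs, mod)
  exp_mmd <- vapply(seq_len(nrow(pairs)), function(i) {
    oracle_maha(pairs$x_curr[i, ], pairs$x_prev[i, ], mod$S)
  }, numeric(1))
  expect_equal(got$mmd, exp_mmd, tolerance = 1e-10)
  expect_equal(got$date, pairs$date_curr)   # timestamped at later visit
  # identical consecutive profiles give zero, single pair gives length 1
  one <- pairs[1, ]
  one$x_curr <- one$x_prev
  expect_equal(compute_mmd(one, mod)$mmd, 0)
  expect_equal(nrow(compute_mmd(pairs[3, ], mod)), 1L)
})

test_that("identity-variant MMD reduces to the Euclidean norm", {
  sim <- quick_sim(20, seed = 61)
  set <- builtin_biomarker_sets()$two_weeks
  par <- fit_standardization(sim$cohort$visits, set)
  modI <- estimate_covariance(sim$cohort$visits, set, par,
                              "identity_offdiag")
  pairs <- make_visit_pairs(sim$cohort$visits, set, par)
  got <- compute_mmd(pairs, modI)
  d <- pairs$x_curr - pairs$x_prev
  eu <- sqrt(rowSums((sweep(d, 2, sqrt(diag(modI$S)), "/"))^2))
  expect_equal(got$mmd, eu, tolerance = 1e-10)
})

test_that("affine invariance: a linear remap of the data leaves MMD unchanged", {
  sim <- quick_sim(30, seed = 71)
  set <- builtin_biomarker_sets()$two_weeks
  par <- fit_standardization(sim$cohort$visits, set)
  mod <- estimate_covariance(sim$cohort$visits, set, par, "pooled")
  pairs <- make_visit_pairs(sim$cohort$visits, set, par)
  base <- compute_mmd(pairs, mod)

  set.seed(72)
  p <- length(set$markers)
  A <- matrix(rnorm(p * p), p, p) + diag(p) * 2
  sv <- mmdews:::standardized_visit_matrix(sim$cohort$visits, set, par)
  y <- sv$x %*% t(A)
  S2 <- stats::cov(y)
  mod2 <- new_covariance_model(S2, markers = set$markers)
  pairs2 <- pairs
  pairs2$x_prev <- pairs$x_prev %*% t(A)
  pairs2$x_curr <- pairs$x_curr %*% t(A)
  remapped <- compute_mmd(pairs2, mod2)
  expect_equal(remapped$mmd, base$mmd, tolerance = 1e-8)
})

test_that("zero-MMD half-minimum rule and all-zero drop", {
  tbl <- tibble::tibble(patient_id = "p", date = as.Date("2015-01-01") + 1:3,
                        gap_days = 14L, mmd = c(0, 0.4, 1.0))
  out <- log_mmd_with_zero_rule(tbl)
  expect_equal(out$log_mmd, log(c(0.2, 0.4, 1.0)))
  expect_equal(out$zero_replaced, c(TRUE, FALSE, FALSE))
  expect_equal(out$mmd, tbl$mmd)   # raw MMD untouched

  nz <- dplyr::mutate(tbl, mmd = c(0.5, 0.4, 1.0))
  expect_equal(log_mmd_with_zero_rule(nz)$log_mmd, log(nz$mmd))

  allz <- tibble::tibble(patient_id = c("z", "z", "p"),
                         date = as.Date("2015-01-01") + c(1, 2, 1),
                         gap_days = 14L, mmd = c(0, 0, 0.3))
  expect_warning(out2 <- log_mmd_with_zero_rule(allz), "all zero")
  expect_equal(unique(out2$patient_id), "p")
})

test_that("squared MMD of true-covariance MVN differences is chi-square", {
  set.seed(81)
  p <- 5
  S <- random_spd(p)
  mod <- new_covariance_model(S, markers = paste0("m", 1:p))
  L <- chol(S)
  d <- matrix(rnorm(4000 * p), 4000, p) %*% L
  q <- rowSums((d %*% mod$S_inv) * d)
  expect_equal(mean(q), p, tolerance = 0.1)
  expect_gt(ks.test(q, pchisq, df = p)$p.value, 0.01)
})
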